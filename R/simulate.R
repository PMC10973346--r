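# Synthetic data with the statistical structure the analyses assume: Yule
# trees, threshold-Brownian binary traits optionally coupled through a causal
# DAG, clustered coordinates, and spatially autocorrelated binary fields.

#' Simulate a Yule (pure-birth) tree scaled to unit height
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @return An ultrametric `phylo` with tips `t1..tn` and height exactly 1.
#' @export
simulate_tree <- function(n_tips, seed) {
  if (n_tips < 2) abort("n_tips must be at least 2")
  tree <- withr::with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  scale_tree_height(tree)
}

#' Define a generative scenario for the three-trait system
#'
#' Defaults mirror the study conditions: the observed sample prevalences of
#' the three traits (case 0.33, verb-final 0.37, flexible 0.38) and a
#' liability-scale structural effect of 1.5 per causal edge.
#'
#' @param dag A `causal_dag` over the analysis traits (edges may be empty).
#' @param n_tips Number of tips for the tree.
#' @param effect_sizes Single number recycled per edge, or named vector
#'   `"from->to"`.
#' @param prevalences Named vector of trait prevalences in (0, 1).
#' @param spatial Optional list `(phi, kappa, sigma2, distance_scale)` adding
#'   Matern-correlated noise to every liability.
#' @param seed Integer seed.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(dag, n_tips = 500, effect_sizes = 1.5,
                         prevalences = c(case = 0.33, verb_final = 0.37,
                                         flexible = 0.38),
                         spatial = NULL, seed = 1) {
  stopifnot(inherits(dag, "causal_dag"))
  if (any(prevalences <= 0 | prevalences >= 1)) {
    abort("prevalences must lie strictly in (0, 1)")
  }
  if (nrow(dag$edges) > 0) {
    key <- paste0(dag$edges$from, "->", dag$edges$to)
    if (length(effect_sizes) == 1 && is.null(names(effect_sizes))) {
      effect_sizes <- setNames(rep(effect_sizes, length(key)), key)
    }
    if (!all(key %in% names(effect_sizes))) {
      abort("effect_sizes must cover every edge (named 'from->to')")
    }
    if (any(!is.finite(effect_sizes))) abort("effect sizes must be finite")
  }
  structure(list(dag = dag, n_tips = n_tips, effect_sizes = effect_sizes,
                 prevalences = prevalences, spatial = spatial, seed = seed),
            class = "sim_scenario")
}

#' Built-in generative scenarios
#'
#' Named constructors for the diachronic single-edge scenarios (verb-final
#' word order causes case; flexible word order causes case; case causes
#' flexible word order, whose negation is the rigid-order scenario), the
#' mediation chain `model_c` (verb_final -> case -> flexible) and the `null`
#' scenario of three uncoupled traits.
#'
#' @param name One of `"verb_final_to_case"`, `"flexible_to_case"`,
#'   `"case_to_flexible"`, `"model_c"`, `"null"`.
#' @inheritParams sim_scenario
#' @export
builtin_scenario <- function(name = c("model_c", "null", "verb_final_to_case",
                                      "flexible_to_case", "case_to_flexible"),
                             n_tips = 500, effect_sizes = 1.5, seed = 1, ...) {
  name <- match.arg(name)
  edges <- switch(name,
    model_c = c("verb_final -> case", "case -> flexible"),
    null = NULL,
    verb_final_to_case = "verb_final -> case",
    flexible_to_case = "flexible -> case",
    case_to_flexible = "case -> flexible"
  )
  sim_scenario(make_dag(edges, model_id = name, vertices = analysis_traits()),
               n_tips = n_tips, effect_sizes = effect_sizes, seed = seed, ...)
}

#' Simulate binary traits on a tree under a causal-graph threshold model
#'
#' Traits are generated in topological order of the scenario DAG. Each
#' trait's liability is the sum of `beta * z_parent` over its parents (with
#' `z` the parent's centered binary values) plus a Brownian-motion error with
#' the tree's phylogenetic correlation (unit tip variance on a unit-height
#' tree), optionally plus a Matern-correlated spatial error; the liability is
#' thresholded at the empirical quantile matching the scenario prevalence.
#' A parentless, non-spatial trait follows exactly the same code path as
#' [simulate_threshold_binary()] with seed `derive_seed(seed, trait)`.
#'
#' @param tree A `phylo` (unit height recommended; see [simulate_tree()]).
#' @param scenario A `sim_scenario`.
#' @param locations Optional coordinates tibble, required when the scenario
#'   has a spatial component.
#' @return Tibble `taxon_id` plus one 0/1 column per trait, rows in tip order.
#' @export
simulate_dag_liabilities <- function(tree, scenario, locations = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  dag <- scenario$dag
  n <- ape::Ntip(tree)
  spatial_chol <- NULL
  if (!is.null(scenario$spatial)) {
    if (is.null(locations)) abort("spatial scenario requires locations")
    sp <- scenario$spatial
    D <- haversine_matrix(locations) / (sp$distance_scale %||% 200)
    spatial_chol <- t(chol_safe(matern_covariance(D, phi = sp$phi,
                                                  kappa = sp$kappa,
                                                  sigma2 = sp$sigma2)))
  }
  order <- topo_order(dag)
  out <- matrix(NA_real_, n, length(order),
                dimnames = list(NULL, order))
  for (v in order) {
    prev <- scenario$prevalences[[v]]
    k <- round(prev * n)
    sub_seed <- derive_seed(scenario$seed, v)
    liab <- withr::with_seed(sub_seed, simulate_bm_tips(tree, 1))[, 1]
    for (pa in dag_parents(dag, v)) {
      beta <- scenario$effect_sizes[[paste0(pa, "->", v)]]
      z <- out[, pa] - mean(out[, pa])
      liab <- liab + beta * z
    }
    if (!is.null(spatial_chol)) {
      liab <- liab + withr::with_seed(derive_seed(scenario$seed, v, "spatial"),
                                      drop(spatial_chol %*% rnorm(n)))
    }
    out[, v] <- threshold_at_count(liab, k)
  }
  dplyr::bind_cols(tibble::tibble(taxon_id = tree$tip.label),
                   tibble::as_tibble(out))
}

topo_order <- function(dag) {
  remaining <- dag$vertices
  edges <- dag$edges
  out <- character()
  while (length(remaining) > 0) {
    free <- remaining[vapply(remaining, function(v) {
      !any(edges$to == v & edges$from %in% remaining)
    }, logical(1))]
    if (length(free) == 0) abort("cycle in DAG")  # unreachable for valid DAGs
    out <- c(out, sort(free))
    remaining <- setdiff(remaining, free)
  }
  out
}

#' Simulate clustered geographic coordinates
#'
#' Cluster centres are placed uniformly over inhabited latitudes and points
#' scattered around them with a Gaussian spread, emulating the areal
#' clustering of language locations.
#'
#' @param n Number of points.
#' @param n_clusters Number of clusters.
#' @param spread_km Within-cluster standard deviation in km.
#' @param seed Integer seed.
#' @param taxon_ids Optional ids (default `t1..tn` to match
#'   [simulate_tree()]).
#' @return Tibble `taxon_id`, `latitude`, `longitude`.
#' @export
simulate_coordinates <- function(n, n_clusters = 5, spread_km = 500, seed = 1,
                                 taxon_ids = paste0("t", seq_len(n))) {
  withr::with_seed(seed, {
    centre <- sample.int(n_clusters, n, replace = TRUE)
    clat <- runif(n_clusters, -55, 65)
    clon <- runif(n_clusters, -180, 180)
    lat <- clat[centre] + rnorm(n, 0, spread_km / 111)
    lon <- clon[centre] + rnorm(n, 0, spread_km / 111) / pmax(cos(lat * pi / 180), 0.2)
    tibble::tibble(
      taxon_id = taxon_ids,
      latitude = pmin(pmax(lat, -89), 89),
      longitude = ((lon + 180) %% 360) - 180
    )
  })
}

#' Simulate a spatially autocorrelated binary trait
#'
#' Thresholds a Gaussian field with Matern covariance over great-circle
#' distances at the empirical quantile matching `prevalence`. A small
#' independent nugget is added to the field; because thresholding is
#' scale-invariant, the nugget is what makes the `sigma2 -> 0` limit an
#' exchangeable random subset (i.i.d. Bernoulli at the prevalence) instead
#' of a frozen spatial pattern.
#'
#' @param locations Tibble `taxon_id`, `latitude`, `longitude`.
#' @param phi,kappa,sigma2 Matern parameters (see [matern_covariance()]).
#' @param prevalence Target prevalence in (0, 1).
#' @param seed Integer seed.
#' @param distance_scale Km per distance unit fed to the Matern kernel
#'   (default 200).
#' @param nugget Variance of the independent noise added to the field.
#' @return Binary vector named by `taxon_id`.
#' @export
simulate_spatial_binary <- function(locations, phi = 1.25, kappa = 1,
                                    sigma2 = 1, prevalence = 0.5, seed = 1,
                                    distance_scale = 200, nugget = 1e-4) {
  if (prevalence <= 0 || prevalence >= 1) abort("prevalence must be in (0, 1)")
  D <- haversine_matrix(locations) / distance_scale
  S <- matern_covariance(D, phi = phi, kappa = kappa, sigma2 = sigma2)
  L <- t(chol_safe(S))
  n <- nrow(S)
  field <- withr::with_seed(seed, {
    drop(L %*% rnorm(n)) + sqrt(nugget) * rnorm(n)
  })
  setNames(threshold_at_count(field, round(prevalence * n)), locations$taxon_id)
}

#' Emit a long-format raw feature table from analysis traits
#'
#' Inverse of [derive_features()]: writes GB070/GB131/GB132/GB133/GB136
#' records consistent with the three analysis traits. For non-verb-final
#' languages one of verb-initial/verb-medial is set (chosen by seed, with the
#' verb-medial order the more common outcome).
#'
#' @param matrix Complete tibble `taxon_id`, `case`, `verb_final`, `flexible`.
#' @param seed Integer seed for the non-final order choice.
#' @param p_medial Probability that a non-verb-final language is verb-medial.
#' @return Long tibble `taxon_id`, `feature_id`, `value`.
#' @export
emit_grambank_like <- function(matrix, seed, p_medial = 0.7) {
  matrix <- tibble::as_tibble(matrix)
  if (anyNA(matrix[analysis_traits()])) abort("matrix must be complete (no NA)")
  n <- nrow(matrix)
  medial <- withr::with_seed(derive_seed(seed, "wordorder"),
                             rbinom(n, 1, p_medial))
  vf <- matrix$verb_final
  wide <- tibble::tibble(
    taxon_id = matrix$taxon_id,
    GB070 = matrix$case,
    GB131 = ifelse(vf == 1, 0, 1 - medial),
    GB132 = ifelse(vf == 1, 0, medial),
    GB133 = vf,
    GB136 = 1 - matrix$flexible
  )
  tidyr::pivot_longer(wide, -"taxon_id", names_to = "feature_id",
                      values_to = "value")
}

#' Generate a complete synthetic dataset for a scenario
#'
#' Bundles tree, traits (matrix and raw long form) and coordinates so every
#' pipeline stage can run without external inputs.
#'
#' @param scenario A `sim_scenario`.
#' @return List `tree`, `traits`, `long_table`, `locations`.
#' @export
simulate_dataset <- function(scenario) {
  tree <- simulate_tree(scenario$n_tips, derive_seed(scenario$seed, "tree"))
  locations <- simulate_coordinates(scenario$n_tips,
                                    seed = derive_seed(scenario$seed, "coords"),
                                    taxon_ids = tree$tip.label)
  traits <- simulate_dag_liabilities(tree, scenario, locations)
  list(
    tree = tree,
    traits = traits,
    long_table = emit_grambank_like(traits, derive_seed(scenario$seed, "gb")),
    locations = locations
  )
}
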