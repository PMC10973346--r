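# Orchestration: run the full signal -> path analysis -> mixed-model workflow
# from a single configuration and write report tables with a manifest.

#' Cross-tabulate case against a word-order trait
#'
#' Counts and integer percentages for the four cells case & wo, case & !wo,
#' !case & wo, !case & !wo.
#'
#' @param traits Complete tibble with `case` and the word-order trait.
#' @param wo_trait `"verb_final"` or `"flexible"` (any 0/1 column name).
#' @return Tibble `cell`, `case`, `wo`, `count`, `percent`.
#' @export
cross_tab <- function(traits, wo_trait) {
  if (!wo_trait %in% names(traits)) {
    abort(sprintf("unknown trait name '%s'", wo_trait))
  }
  ca <- traits$case
  wo <- traits[[wo_trait]]
  if (anyNA(ca) || anyNA(wo)) abort("cross_tab requires complete traits")
  n <- length(ca)
  cells <- tibble::tibble(
    cell = c(paste0("case & ", wo_trait), paste0("case & !", wo_trait),
             paste0("!case & ", wo_trait), paste0("!case & !", wo_trait)),
    case = c(1, 1, 0, 0), wo = c(1, 0, 1, 0)
  )
  cells$count <- purrr::map2_int(cells$case, cells$wo,
                                 ~ sum(ca == .x & wo == .y))
  cells$percent <- round(100 * cells$count / n)
  cells
}

default_config <- function() {
  list(
    engine = "logistic",
    seed = 1,
    n_perm = 1000, n_sim = 1000,
    stages = c("crosstabs", "signal", "paths", "glmm_kfold", "glmm_refit"),
    glmm = list(chains = 2, warmup = 400, draws = 600, kfold_K = 10,
                responses = "flexible", check = FALSE),
    spatial = list(phi = 1.25, kappa = 1, distance_scale = 200),
    out_dir = NULL,
    verbose = TRUE
  )
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$tree) || is.null(cfg$traits)) {
    abort("config must provide 'tree' and 'traits'")
  }
  cfg
}

resolve_tree <- function(x) {
  if (inherits(x, "phylo")) return(validate_phylo(x))
  if (is.character(x) && file.exists(x)) {
    return(parse_newick(paste(readLines(x, warn = FALSE), collapse = "")))
  }
  abort("tree must be a phylo object or a Newick file path")
}

resolve_traits <- function(x) {
  tab <- if (is.character(x) && file.exists(x)) read_trait_table(x) else tibble::as_tibble(x)
  if (all(c("taxon_id", "feature_id", "value") %in% names(tab))) {
    derive_features(tab)
  } else {
    tab
  }
}

resolve_locations <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && file.exists(x)) read_geo_table(x) else validate_geo(x)
}

#' Run the full analysis pipeline
#'
#' Executes, per the configured stages: feature derivation and tree/data
#' alignment; case-by-word-order cross-tabulations; the D statistic per
#' trait; the 12-model phylogenetic path analysis with conditional averaging
#' of the supported models; K-fold comparison of phylogenetic vs spatial vs
#' combined random effects; and mixed-model refits of the supported path
#' models. When `out_dir` is set, every table is written as CSV/JSON along
#' with a manifest of checksums and seeds.
#'
#' @param config A list or a YAML file path. Required entries: `tree` (path
#'   or `phylo`), `traits` (long-format path/tibble or derived matrix).
#'   Optional: `coordinates`, `engine`, `seed`, `n_perm`, `n_sim`, `stages`,
#'   `glmm` (chains, warmup, draws, kfold_K, responses, check), `spatial`
#'   (phi, kappa, distance_scale), `out_dir`, `verbose`.
#' @return A report bundle (list) with the aligned data, cross-tabs, signal
#'   table, path analysis, averaged model, and any mixed-model results.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  say <- function(fmt, ...) if (isTRUE(cfg$verbose)) {
    inform(sprintf(paste0("[pipeline] ", fmt), ...))
  }
  t0 <- Sys.time()
  stage_times <- list()
  clock <- function(stage, expr) {
    st <- Sys.time()
    out <- force(expr)
    stage_times[[stage]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    say("%s done in %.1fs", stage, stage_times[[stage]])
    out
  }

  tree <- resolve_tree(cfg$tree)
  traits <- resolve_traits(cfg$traits)
  locations <- resolve_locations(cfg$coordinates)
  aligned <- align_tree_and_traits(tree, traits, locations)
  tree <- scale_tree_height(aligned$tree)
  traits <- aligned$traits
  corr <- phylo_correlation_matrix(tree)
  bundle <- list(config = cfg, n = aligned$n, traits = traits, tree = tree)
  say("aligned sample of %d taxa (seed %d)", aligned$n, cfg$seed)

  if ("crosstabs" %in% cfg$stages) {
    bundle$crosstabs <- clock("crosstabs", dplyr::bind_rows(
      cross_tab(traits, "verb_final"), cross_tab(traits, "flexible")))
  }

  if ("signal" %in% cfg$stages) {
    bundle$signal <- clock("signal", purrr::map_dfr(analysis_traits(), function(tr) {
      d <- d_statistic(tree, traits[[tr]], n_perm = cfg$n_perm,
                       n_sim = cfg$n_sim, seed = derive_seed(cfg$seed, "D", tr))
      dplyr::mutate(tidy(d), trait = tr, .before = 1)
    }))
  }

  if ("paths" %in% cfg$stages) {
    bundle$paths <- clock("paths",
                          fit_path_models(traits[analysis_traits()], corr,
                                          engine = cfg$engine))
    bundle$averaged <- average_top_models(bundle$paths)
  }

  need_spatial <- any(c("glmm_kfold") %in% cfg$stages)
  if (need_spatial && !is.null(aligned$locations)) {
    bundle$corr_spatial <- spatial_correlation_matrix(
      aligned$locations, phi = cfg$spatial$phi, kappa = cfg$spatial$kappa,
      distance_scale = cfg$spatial$distance_scale)
  }

  if ("glmm_kfold" %in% cfg$stages && !is.null(bundle$corr_spatial)) {
    g <- cfg$glmm
    bundle$kfold <- clock("glmm_kfold", purrr::map(
      setNames(g$responses, g$responses), function(resp) {
        kfold_compare(
          traits[[resp]], cbind(`(Intercept)` = rep(1, aligned$n)),
          specs = list(phylo = list(corr_phylo = corr),
                       spatial = list(corr_spatial = bundle$corr_spatial),
                       both = list(corr_phylo = corr,
                                   corr_spatial = bundle$corr_spatial)),
          K = g$kfold_K, seed = derive_seed(cfg$seed, "kfold", resp),
          chains = g$chains, warmup = g$warmup, draws = g$draws)
      }))
  }

  if ("glmm_refit" %in% cfg$stages && "paths" %in% cfg$stages) {
    g <- cfg$glmm
    top <- tryCatch(select_top_models(bundle$paths$table),
                    error = function(e) bundle$paths$table$model_id[1])
    top <- intersect(top, names(bundle$paths$models))
    bundle$refits <- clock("glmm_refit", refit_path_models_glmm(
      traits, corr, models = bundle$paths$models[top],
      seed = derive_seed(cfg$seed, "refit"),
      chains = g$chains, warmup = g$warmup, draws = g$draws,
      check = isTRUE(g$check)))
  }

  if (!is.null(cfg$out_dir)) {
    bundle$manifest <- write_bundle(bundle, cfg$out_dir)
  }
  say("pipeline finished in %.1fs",
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  bundle$stage_times <- stage_times
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  put_csv <- function(df, name) {
    fp <- file.path(out_dir, name)
    utils::write.csv(df, fp, row.names = FALSE)
    paths <<- c(paths, fp)
  }
  if (!is.null(bundle$crosstabs)) put_csv(bundle$crosstabs, "crosstabs.csv")
  if (!is.null(bundle$signal)) put_csv(bundle$signal, "signal.csv")
  if (!is.null(bundle$paths)) put_csv(bundle$paths$table, "path_models.csv")
  if (!is.null(bundle$averaged)) {
    fp <- file.path(out_dir, "averaged_model.json")
    jsonlite::write_json(
      bundle$averaged[c("from", "to", "estimate", "lower95", "upper95")],
      fp, digits = NA)
    paths <- c(paths, fp)
  }
  if (!is.null(bundle$kfold)) {
    put_csv(purrr::imap_dfr(bundle$kfold,
                            ~ dplyr::mutate(tidy(.x), response = .y, .before = 1)),
            "kfold.csv")
  }
  if (!is.null(bundle$refits)) put_csv(bundle$refits, "glmm_refits.csv")
  manifest <- tibble::tibble(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths))
  )
  mf <- file.path(out_dir, "manifest.csv")
  utils::write.csv(dplyr::bind_rows(
    manifest,
    tibble::tibble(file = "_seed", md5 = as.character(bundle$config$seed)),
    tibble::tibble(file = "_n", md5 = as.character(bundle$n))
  ), mf, row.names = FALSE)
  manifest
}
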