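# Phylogenetic signal for binary traits: the D metric.
#
# D rescales the observed sum of sister-clade differences (Sigma-d) of a
# binary trait between two reference points obtained by simulation on the
# same tree: tip-label permutation (phylogenetically random, D = 1) and
# threshold-Brownian evolution (strong signal, D = 0).

# Precompute the postorder sister structure of a (binarised) tree once, so
# Sigma-d can be evaluated for many trait columns with one pass.
prep_sister_structure <- function(tree) {
  tree <- resolve_polytomies(validate_phylo(tree))
  tree <- stats::reorder(tree, "postorder")
  edge <- tree$edge
  len <- tree$edge.length
  floor_len <- max(len, 1e-8) * 1e-8
  w <- 1 / pmax(len, floor_len)
  i1 <- seq(1, nrow(edge), by = 2)
  i2 <- i1 + 1
  if (any(edge[i1, 1] != edge[i2, 1])) {
    # postorder edges should pair by parent for a binary tree
    abort("internal error: postorder edges not paired by parent")
  }
  list(tree = tree, parent = edge[i1, 1], child1 = edge[i1, 2],
       child2 = edge[i2, 2], w1 = w[i1], w2 = w[i2],
       ntip = ape::Ntip(tree), nnode = tree$Nnode)
}

# Sigma-d for each column of a tip-by-trait matrix (rows in tip order).
sister_diff_sums_mat <- function(prep, mat) {
  vals <- matrix(0, prep$ntip + prep$nnode, ncol(mat))
  vals[seq_len(prep$ntip), ] <- mat
  sums <- numeric(ncol(mat))
  for (i in seq_along(prep$parent)) {
    v1 <- vals[prep$child1[i], ]
    v2 <- vals[prep$child2[i], ]
    sums <- sums + abs(v1 - v2)
    vals[prep$parent[i], ] <- (prep$w1[i] * v1 + prep$w2[i] * v2) /
      (prep$w1[i] + prep$w2[i])
  }
  sums
}

# Brownian liabilities at the tips: one preorder pass, many replicates at once.
simulate_bm_tips <- function(tree, n_sim) {
  tree <- stats::reorder(tree, "cladewise")
  edge <- tree$edge
  ntip <- ape::Ntip(tree)
  vals <- matrix(0, ntip + tree$Nnode, n_sim)
  scale <- sqrt(tree$edge.length)
  for (i in seq_len(nrow(edge))) {
    vals[edge[i, 2], ] <- vals[edge[i, 1], ] + scale[i] * rnorm(n_sim)
  }
  vals[seq_len(ntip), , drop = FALSE]
}

align_trait_to_tips <- function(tree, trait) {
  if (!is.null(names(trait))) {
    if (!all(tree$tip.label %in% names(trait))) {
      abort("named trait vector does not cover all tip labels")
    }
    trait <- trait[tree$tip.label]
  }
  if (length(trait) != ape::Ntip(tree)) {
    abort("trait length does not match number of tips")
  }
  unname(trait)
}

#' Ancestral node values by branch-length-weighted averaging
#'
#' Each internal node receives the average of its two children's values
#' weighted by the inverse of the connecting branch lengths, in a single
#' post-order pass (polytomies are resolved first). Tip values are the trait
#' itself; internal values lie in \[0, 1\].
#'
#' @param tree A `phylo` object.
#' @param trait Binary (0/1) vector, in tip order or named by tip label.
#' @return A tibble with columns `node` (ape node number on the binarised
#'   tree) and `value`.
#' @export
estimate_node_values <- function(tree, trait) {
  trait <- check_binary(align_trait_to_tips(tree, trait))
  prep <- prep_sister_structure(tree)
  vals <- matrix(0, prep$ntip + prep$nnode, 1)
  vals[seq_len(prep$ntip), 1] <- trait
  for (i in seq_along(prep$parent)) {
    vals[prep$parent[i], 1] <-
      (prep$w1[i] * vals[prep$child1[i], 1] + prep$w2[i] * vals[prep$child2[i], 1]) /
      (prep$w1[i] + prep$w2[i])
  }
  tibble::tibble(node = seq_len(nrow(vals)), value = vals[, 1])
}

#' Observed sum of sister-clade differences
#'
#' The Sigma-d statistic underlying the D metric: the sum over internal nodes
#' of the absolute difference between the two children's node values.
#'
#' @inheritParams estimate_node_values
#' @return A non-negative scalar.
#' @export
sum_sister_differences <- function(tree, trait) {
  trait <- check_binary(align_trait_to_tips(tree, trait))
  prep <- prep_sister_structure(tree)
  sister_diff_sums_mat(prep, matrix(trait, ncol = 1))
}

#' Simulate a binary trait under threshold-Brownian evolution
#'
#' Brownian liabilities (variance proportional to branch length) are simulated
#' along the tree and thresholded at the empirical quantile so that exactly
#' `round(prevalence * n_tips)` tips carry a 1.
#'
#' @param tree A `phylo` object.
#' @param prevalence Target trait prevalence in (0, 1).
#' @param seed Integer seed; required for reproducibility.
#' @return A binary vector named by tip label.
#' @export
simulate_threshold_binary <- function(tree, prevalence, seed) {
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    abort("prevalence must lie strictly between 0 and 1")
  }
  validate_phylo(tree)
  n <- ape::Ntip(tree)
  k <- round(prevalence * n)
  liab <- withr::with_seed(seed, simulate_bm_tips(tree, 1))[, 1]
  setNames(threshold_at_count(liab, k), tree$tip.label)
}

#' The D statistic of phylogenetic signal for a binary trait
#'
#' Computes the observed sum of sister-clade differences and rescales it
#' between the means of two simulated reference distributions on the same
#' tree: random tip shuffles (D = 1 pole) and threshold-Brownian traits with
#' prevalence matched to the data (D = 0 pole). Tail probabilities against
#' both references are reported: `p_random` is the proportion of permuted
#' Sigma-d at or below the observed value (evidence of clumping relative to a
#' random trait), `p_brownian` the proportion of Brownian Sigma-d at or above
#' it (evidence of overdispersion relative to Brownian evolution).
#'
#' @inheritParams estimate_node_values
#' @param n_perm Number of tip-label permutations.
#' @param n_sim Number of threshold-Brownian simulations.
#' @param seed Integer seed for both null streams.
#' @return An object of class `phylo_d` with fields `d_obs`, `mean_random`,
#'   `mean_brownian`, `D`, `p_random`, `p_brownian`, `n_perm`, `n_sim`,
#'   `n_tips`, `prevalence`, `seed`.
#' @export
#' @examples
#' tree <- simulate_tree(80, seed = 1)
#' trait <- simulate_threshold_binary(tree, 0.5, seed = 2)
#' d_statistic(tree, trait, n_perm = 100, n_sim = 100, seed = 3)
d_statistic <- function(tree, trait, n_perm = 1000, n_sim = 1000, seed) {
  trait <- check_binary(align_trait_to_tips(tree, trait))
  k <- sum(trait)
  n <- length(trait)
  if (k == 0 || k == n) abort("D undefined for a constant trait")
  prep <- prep_sister_structure(tree)
  d_obs <- sister_diff_sums_mat(prep, matrix(trait, ncol = 1))

  perm_sums <- withr::with_seed(derive_seed(seed, "perm"), {
    perms <- vapply(seq_len(n_perm), function(i) sample(trait), numeric(n))
    sister_diff_sums_mat(prep, perms)
  })
  sim_sums <- withr::with_seed(derive_seed(seed, "brownian"), {
    liab <- simulate_bm_tips(prep$tree, n_sim)
    sims <- apply(liab, 2, threshold_at_count, k = k)
    sister_diff_sums_mat(prep, sims)
  })

  mean_random <- mean(perm_sums)
  mean_brownian <- mean(sim_sums)
  structure(list(
    d_obs = d_obs,
    mean_random = mean_random,
    mean_brownian = mean_brownian,
    D = (d_obs - mean_brownian) / (mean_random - mean_brownian),
    p_random = mean(perm_sums <= d_obs),
    p_brownian = mean(sim_sums >= d_obs),
    n_perm = n_perm, n_sim = n_sim,
    n_tips = n, prevalence = k / n, seed = seed
  ), class = "phylo_d")
}

#' @export
print.phylo_d <- function(x, ...) {
  cat(sprintf("D statistic of phylogenetic signal (binary trait, %d tips)\n", x$n_tips))
  cat(sprintf("  D = %.3f  (sum of sister differences = %.2f)\n", x$D, x$d_obs))
  cat(sprintf("  random pole mean = %.2f, Brownian pole mean = %.2f\n",
              x$mean_random, x$mean_brownian))
  cat(sprintf("  P(random | data)   : p = %.3f  [departure from D = 1]\n", x$p_random))
  cat(sprintf("  P(Brownian | data) : p = %.3f  [departure from D = 0]\n", x$p_brownian))
  invisible(x)
}

#' @export
tidy.phylo_d <- function(x, ...) {
  tibble::tibble(
    d_obs = x$d_obs, mean_random = x$mean_random,
    mean_brownian = x$mean_brownian, D = x$D,
    p_random = x$p_random, p_brownian = x$p_brownian
  )
}

#' @export
glance.phylo_d <- function(x, ...) {
  tibble::tibble(n_tips = x$n_tips, prevalence = x$prevalence,
                 n_perm = x$n_perm, n_sim = x$n_sim, seed = x$seed)
}

#' @export
autoplot.phylo_d <- function(object, ...) {
  df <- tibble::tibble(
    pole = factor(c("random shuffle", "Brownian threshold"),
                  levels = c("Brownian threshold", "random shuffle")),
    mean_sum = c(object$mean_random, object$mean_brownian)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_sum, y = .data$pole)) +
    ggplot2::geom_col(width = 0.5, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$d_obs, linetype = 2) +
    ggplot2::labs(
      x = "sum of sister-clade differences",
      y = NULL,
      title = sprintf("D = %.2f (dashed line: observed)", object$D)
    )
}
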