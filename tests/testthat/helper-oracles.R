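# Shared fixtures and independent oracles used across the test files.

# --- brute-force d-separation oracle (path-blocking enumeration) -----------

dag_edge_df <- function(dag) as.data.frame(dag$edges)

oracle_descendants <- function(edges, v) {
  out <- character(); frontier <- v
  while (length(frontier)) {
    ch <- unique(edges$to[edges$from %in% frontier])
    ch <- setdiff(ch, out)
    out <- c(out, ch); frontier <- ch
  }
  out
}

# Enumerate all undirected simple paths between x and y, then apply the
# d-separation blocking rules against conditioning set Z.
oracle_dsep <- function(dag, x, y, Z) {
  edges <- dag_edge_df(dag)
  paths <- list()
  walk <- function(v, path) {
    if (v == y) { paths[[length(paths) + 1]] <<- path; return() }
    nbr <- unique(c(edges$to[edges$from == v], edges$from[edges$to == v]))
    for (w in setdiff(nbr, path)) walk(w, c(path, w))
  }
  walk(x, x)
  if (length(paths) == 0) return(TRUE)
  blocked <- vapply(paths, function(p) {
    if (length(p) == 2) return(FALSE)  # direct edge: never blocked
    for (i in 2:(length(p) - 1)) {
      m <- p[i]
      into_m_left <- any(edges$from == p[i - 1] & edges$to == m)
      into_m_right <- any(edges$from == p[i + 1] & edges$to == m)
      is_collider <- into_m_left && into_m_right
      if (is_collider) {
        if (!m %in% Z && !any(oracle_descendants(edges, m) %in% Z)) return(TRUE)
      } else {
        if (m %in% Z) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  all(blocked)
}

# All DAGs on the given vertex set: each unordered pair is absent, forward or
# backward; cyclic combinations are skipped.
enumerate_dags <- function(vertices) {
  pairs <- utils::combn(vertices, 2, simplify = FALSE)
  states <- expand.grid(rep(list(0:2), length(pairs)))
  out <- list()
  for (r in seq_len(nrow(states))) {
    from <- character(); to <- character()
    for (j in seq_along(pairs)) {
      s <- states[r, j]
      if (s == 1) { from <- c(from, pairs[[j]][1]); to <- c(to, pairs[[j]][2]) }
      if (s == 2) { from <- c(from, pairs[[j]][2]); to <- c(to, pairs[[j]][1]) }
    }
    dag <- tryCatch(
      make_dag(if (length(from)) tibble::tibble(from = from, to = to) else NULL,
               model_id = paste0("enum", r), vertices = vertices),
      error = function(e) NULL)
    if (!is.null(dag)) out[[length(out) + 1]] <- dag
  }
  out
}

# --- small shared fixtures -------------------------------------------------

cherry_tree <- function() parse_newick("(A:1,B:1);")

balanced4_tree <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")

star_tree <- function(n = 5) {
  parse_newick(paste0("(", paste0("t", seq_len(n), ":1", collapse = ","), ");"))
}

# Logistic data with a phylogenetic random intercept on the liability.
sim_logistic_phylo <- function(tree, beta0, beta1 = NULL, sigma = 1,
                               seed = 1) {
  corr <- phylo_correlation_matrix(tree)
  n <- ape::Ntip(tree)
  withr::with_seed(seed, {
    u <- sigma * drop(t(chol(corr)) %*% rnorm(n))
    x <- rnorm(n)
    eta <- beta0 + u + if (!is.null(beta1)) beta1 * x else 0
    list(y = rbinom(n, 1, plogis(eta)), x = x, corr = corr)
  })
}
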