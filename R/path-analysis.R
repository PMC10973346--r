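# Phylogenetic path analysis: test each candidate DAG's independence claims
# with a phylogenetic regression engine, summarise each model with Fisher's C
# and the small-sample information criterion CICc, rank and weight the model
# set, and conditionally average the path coefficients of the supported
# models.

#' Fisher's C statistic
#'
#' `C = -2 * sum(log(p))` over a model's independence-claim p-values;
#' chi-squared with 2k degrees of freedom when all claims hold.
#'
#' @param p_values Vector of p-values in (0, 1]. Values are floored at
#'   1e-300 before taking logs so that underflowing claims keep C finite.
#' @return Non-negative scalar.
#' @export
fisher_c <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  -2 * sum(log(pmax(p_values, 1e-300)))
}

#' Model-level p-value for Fisher's C
#'
#' Upper-tail chi-squared probability with 2k degrees of freedom; small
#' values indicate that the model's independence claims are violated.
#'
#' @param C Fisher's C statistic.
#' @param k Number of independence claims.
#' @export
model_p_value <- function(C, k) {
  stopifnot(C >= 0, k >= 1)
  pchisq(C, df = 2 * k, lower.tail = FALSE)
}

#' C-statistic information criterion corrected for small samples
#'
#' `CICc = C + 2 q n / (n - 1 - q)` with q the model parameter count and n
#' the sample size; lower is better, and differences are comparable across
#' non-nested models.
#'
#' @param C Fisher's C statistic.
#' @param q Parameter count (vertices + edges).
#' @param n Sample size.
#' @export
#' @examples
#' cicc(3.6, 5, 1705)  # 13.64
cicc <- function(C, q, n) {
  if (n <= q + 1) abort("sample size must exceed q + 1")
  C + 2 * q * n / (n - 1 - q)
}

as_claim <- function(claim) {
  if (is.data.frame(claim)) {
    stopifnot(nrow(claim) == 1)
    claim <- list(x = claim$x, y = claim$y, conditioning = claim$conditioning[[1]],
                  claim = claim$claim %||% NA_character_)
  }
  claim
}

#' Test one conditional-independence claim
#'
#' Regresses the claim's designated response `y` on `x` plus the conditioning
#' set under the chosen engine, and reports the coefficient and p-value of
#' `x`. A large p-value is consistent with the claimed independence.
#'
#' @param claim A one-row tibble from [basis_set()] or a list with elements
#'   `x`, `y`, `conditioning`.
#' @param traits Tibble of binary trait columns (complete cases).
#' @param corr Phylogenetic correlation matrix aligned to `traits` rows.
#' @param engine `"logistic"` (phylogenetic logistic regression, default) or
#'   `"gls"` (Gaussian PGLS on the 0/1 response).
#' @return Tibble `claim`, `x`, `y`, `conditioning`, `coefficient`,
#'   `p_value`, `converged`.
#' @export
test_claim <- function(claim, traits, corr, engine = c("logistic", "gls")) {
  engine <- match.arg(engine)
  claim <- as_claim(claim)
  vars <- c(claim$y, claim$x, claim$conditioning)
  if (!all(vars %in% names(traits))) {
    abort(sprintf("claim variables missing from traits: %s",
                  paste(setdiff(vars, names(traits)), collapse = ", ")))
  }
  y <- traits[[claim$y]]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(traits[c(claim$x, claim$conditioning)]))
  fit <- if (engine == "logistic") {
    phylo_logistic_fit(y, X, corr)
  } else {
    pgls_fit(y, X, corr)
  }
  cl <- claim
  tibble::tibble(
    claim = cl$claim %||% NA_character_,
    x = cl$x, y = cl$y, conditioning = list(cl$conditioning),
    coefficient = unname(fit$coefficients[cl$x]),
    p_value = pmax(unname(fit$p_values[cl$x]), 1e-300),
    converged = fit$converged
  )
}

# Claim tests and coefficient regressions are cached per dataset: different
# models share both (e.g. the three Markov-equivalent top models test the
# same pair in at most two directions).
claim_cache_key <- function(y, x, conditioning, engine) {
  paste(engine, y, x, paste(sort(conditioning), collapse = "+"), sep = "|")
}

#' Fit a set of causal path models to aligned trait data
#'
#' For every model this tests the d-separation basis set, computes Fisher's C
#' with its chi-squared p-value and the CICc, fits each directed edge as a
#' regression of effect on its parents to obtain standardized path
#' coefficients, and assembles the ranked comparison table.
#'
#' @param traits Tibble of binary trait columns, rows aligned to `corr`.
#' @param corr Phylogenetic correlation matrix.
#' @param models Named list of `causal_dag` objects
#'   (default [candidate_models()]).
#' @param engine Claim-test engine, `"logistic"` or `"gls"`.
#' @return Object of class `phylo_path` with the comparison `table`, per-model
#'   `claim_tests`, per-model standardized `coefficients`, and equivalence
#'   metadata.
#' @export
fit_path_models <- function(traits, corr, models = candidate_models(),
                            engine = c("logistic", "gls")) {
  engine <- match.arg(engine)
  traits <- tibble::as_tibble(traits)
  n <- nrow(traits)
  cache <- new.env(parent = emptyenv())

  cached_claim <- function(cl) {
    key <- claim_cache_key(cl$y, cl$x, cl$conditioning[[1]], engine)
    if (is.null(cache[[key]])) cache[[key]] <- test_claim(cl, traits, corr, engine)
    cache[[key]]
  }
  cached_edge_fit <- function(response, parents) {
    key <- paste("edgefit", engine, response,
                 paste(sort(parents), collapse = "+"), sep = "|")
    if (is.null(cache[[key]])) {
      X <- cbind(`(Intercept)` = 1, as.matrix(traits[parents]))
      fit <- if (engine == "logistic") {
        phylo_logistic_fit(traits[[response]], X, corr)
      } else {
        pgls_fit(traits[[response]], X, corr)
      }
      std <- standardize_paths(fit, traits)
      cache[[key]] <- dplyr::mutate(std, to = response, .before = 1) |>
        dplyr::rename(from = "term")
    }
    cache[[key]]
  }

  results <- purrr::imap(models, function(dag, id) {
    bs <- basis_set(dag)
    tests <- if (nrow(bs) > 0) {
      dplyr::bind_rows(lapply(seq_len(nrow(bs)), function(i) cached_claim(bs[i, ])))
    } else {
      tibble::tibble(claim = character(), p_value = numeric())
    }
    C <- if (nrow(tests) > 0) fisher_c(tests$p_value) else 0
    k <- nrow(tests)
    q <- dag_n_params(dag)
    coefs <- if (nrow(dag$edges) > 0) {
      dplyr::bind_rows(lapply(unique(dag$edges$to), function(v) {
        ce <- cached_edge_fit(v, dag_parents(dag, v))
        ce[ce$from %in% dag_parents(dag, v), ]
      }))
    } else {
      tibble::tibble(to = character(), from = character(), estimate = numeric(),
                     lower95 = numeric(), upper95 = numeric())
    }
    list(model_id = id, claim_tests = tests, coefficients = coefs,
         k = k, q = q, n = n, C = C,
         model_p = if (k > 0) model_p_value(C, k) else 1,
         CICc = cicc(C, q, n))
  })

  rows <- purrr::map_dfr(results, function(r) {
    tibble::tibble(model_id = r$model_id, k = r$k, q = r$q, C = r$C,
                   model_p = r$model_p, CICc = r$CICc)
  })
  structure(list(
    table = compare_models(rows),
    results = results,
    models = models,
    engine = engine,
    n = n,
    equivalence = flag_equivalent_models(models)
  ), class = "phylo_path")
}

#' Rank path models by CICc
#'
#' Adds `delta_CICc` (difference to the best model), the relative likelihood
#' `exp(-delta/2)` and CICc weights normalized over all supplied models. Ties
#' in CICc are broken by fewer parameters, then model id.
#'
#' @param results Tibble with columns `model_id`, `k`, `q`, `C`, `model_p`,
#'   `CICc` (one row per model), or a list of such rows.
#' @return The sorted comparison tibble.
#' @export
compare_models <- function(results) {
  tab <- tibble::as_tibble(results)
  stopifnot(nrow(tab) >= 1)
  tab <- dplyr::arrange(tab, .data$CICc, .data$q, .data$model_id)
  tab$delta_CICc <- tab$CICc - tab$CICc[1]
  tab$relative_likelihood <- exp(-tab$delta_CICc / 2)
  tab$weight <- tab$relative_likelihood / sum(tab$relative_likelihood)
  dplyr::select(tab, "model_id", "CICc", "delta_CICc", "relative_likelihood",
                "weight", "k", "q", "C", "model_p")
}

#' Select the supported models
#'
#' Models within `delta_threshold` CICc of the best whose C-statistic
#' p-value is non-significant (claims not rejected).
#'
#' @param table Comparison tibble from [compare_models()].
#' @param delta_threshold Maximum `delta_CICc` (default 2).
#' @param alpha Rejection level for the model p-value (default 0.05).
#' @return Character vector of model ids.
#' @export
select_top_models <- function(table, delta_threshold = 2.0, alpha = 0.05) {
  sel <- table$model_id[table$delta_CICc <= delta_threshold &
                          table$model_p >= alpha]
  if (length(sel) == 0) {
    abort("no model passes the CICc/p-value filter; inspect the comparison table")
  }
  sel
}

#' Conditionally average path coefficients across models
#'
#' In conditional mode each path is averaged only over the models that
#' contain it, with those models' weights renormalized; paths unique to one
#' model pass through unchanged. In full mode absent paths contribute zero
#' and the supplied weights are used as-is. Confidence bounds are averaged
#' with the same weights as the estimates.
#'
#' @param fits Named list (by model id) of coefficient tibbles with columns
#'   `from`, `to`, `estimate`, `lower95`, `upper95`.
#' @param weights Named numeric vector of model weights (same names).
#' @param mode `"conditional"` (default) or `"full"`.
#' @return Tibble `from`, `to`, `estimate`, `lower95`, `upper95`,
#'   `contributing_models` (list), `contributing_weights` (list).
#' @export
average_paths <- function(fits, weights, mode = c("conditional", "full")) {
  mode <- match.arg(mode)
  stopifnot(length(fits) >= 1, all(names(fits) %in% names(weights)))
  weights <- weights[names(fits)] / sum(weights[names(fits)])
  all_paths <- dplyr::distinct(
    dplyr::bind_rows(purrr::map(fits, ~ .x[c("from", "to")])))
  purrr::pmap_dfr(all_paths, function(from, to) {
    have <- purrr::map_lgl(fits, ~ any(.x$from == from & .x$to == to))
    w <- if (mode == "conditional") {
      weights[have] / sum(weights[have])
    } else {
      weights
    }
    vals <- purrr::map_dfr(names(fits)[if (mode == "conditional") have else TRUE],
      function(id) {
        row <- fits[[id]][fits[[id]]$from == from & fits[[id]]$to == to, ]
        if (nrow(row) == 0) {
          tibble::tibble(model_id = id, estimate = 0, lower95 = 0, upper95 = 0)
        } else {
          tibble::tibble(model_id = id, estimate = row$estimate,
                         lower95 = row$lower95, upper95 = row$upper95)
        }
      })
    wv <- w[vals$model_id]
    if (mode == "full") wv <- weights[vals$model_id]
    tibble::tibble(
      from = from, to = to,
      estimate = sum(wv * vals$estimate),
      lower95 = sum(wv * vals$lower95),
      upper95 = sum(wv * vals$upper95),
      contributing_models = list(names(fits)[have]),
      contributing_weights = list(w)
    )
  })
}

#' Average the supported models of a fitted path analysis
#'
#' Convenience wrapper: selects the supported models via
#' [select_top_models()], restricts and renormalizes their CICc weights and
#' conditionally averages their standardized path coefficients.
#'
#' @param pp A `phylo_path` object from [fit_path_models()].
#' @inheritParams select_top_models
#' @param mode Passed to [average_paths()].
#' @return Tibble of averaged paths (see [average_paths()]).
#' @export
average_top_models <- function(pp, delta_threshold = 2.0, alpha = 0.05,
                               mode = "conditional") {
  sel <- select_top_models(pp$table, delta_threshold, alpha)
  fits <- purrr::map(pp$results[sel], "coefficients")
  w <- setNames(pp$table$weight, pp$table$model_id)[sel]
  average_paths(fits, w, mode)
}

#' @export
print.phylo_path <- function(x, ...) {
  cat(sprintf("phylogenetic path analysis: %d models, n = %d, engine = %s\n",
              length(x$models), x$n, x$engine))
  print(x$table, n = nrow(x$table))
  invisible(x)
}

#' @export
tidy.phylo_path <- function(x, ...) x$table

#' @export
glance.phylo_path <- function(x, ...) {
  tibble::tibble(n = x$n, n_models = length(x$models), engine = x$engine,
                 best_model = x$table$model_id[1])
}

#' @export
autoplot.phylo_path <- function(object, ...) {
  tab <- object$table
  tab$model_id <- factor(tab$model_id, levels = rev(tab$model_id))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$CICc, y = .data$model_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = min(tab$CICc) + 2, linetype = 3) +
    ggplot2::labs(y = "model", x = "CICc",
                  title = "path model comparison (dotted line: best + 2)")
}

#' Plot an averaged path model
#'
#' @param avg Tibble from [average_paths()] / [average_top_models()].
#' @return A ggplot of standardized coefficients with 95% bounds.
#' @export
plot_averaged_paths <- function(avg) {
  avg$path <- paste(avg$from, "→", avg$to)
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$estimate, y = .data$path)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower95,
                                          xmax = .data$upper95)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "standardized path coefficient", y = NULL)
}
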