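# Bayesian logistic mixed models with phylogenetic and/or Matern spatial
# random effects. The posterior is sampled with elliptical slice sampling on
# the whitened Gaussian block (fixed effects and latent fields), slice
# sampling on the log random-effect scales, an ancillarity-sufficiency
# interweaving step and a likelihood-invariant intercept/field translation
# move; model comparison uses K-fold cross-validated expected log predictive
# density.

#' Great-circle distance matrix
#'
#' Haversine distances in kilometres (Earth radius 6371 km).
#'
#' @param locations Tibble `taxon_id`, `latitude`, `longitude`.
#' @return Symmetric matrix (km) with zero diagonal, dimnames = taxon ids.
#' @export
haversine_matrix <- function(locations) {
  locations <- validate_geo(locations)
  pts <- cbind(locations$longitude, locations$latitude)
  D <- geosphere::distm(pts, fun = function(p1, p2) {
    geosphere::distHaversine(p1, p2, r = 6371000)
  }) / 1000
  dimnames(D) <- list(locations$taxon_id, locations$taxon_id)
  D
}

#' Matern covariance from a distance matrix
#'
#' `C(d) = sigma2 * 2^(1-kappa)/Gamma(kappa) * (d/phi)^kappa * K_kappa(d/phi)`
#' for d > 0 and `C(0) = sigma2`, with `K` the modified Bessel function of
#' the second kind. `kappa = 0.5` reduces to the exponential kernel
#' `sigma2 * exp(-d/phi)`. A diagonal jitter of `1e-8 * sigma2` keeps the
#' result numerically positive definite.
#'
#' @param D Symmetric non-negative distance matrix with zero diagonal.
#' @param phi Range parameter (> 0), in the units of `D`.
#' @param kappa Smoothness parameter (> 0).
#' @param sigma2 Marginal variance (> 0).
#' @return Covariance matrix of the same dimension as `D`.
#' @export
matern_covariance <- function(D, phi, kappa = 1, sigma2 = 1) {
  if (phi <= 0 || kappa <= 0 || sigma2 <= 0) {
    abort("phi, kappa and sigma2 must all be strictly positive")
  }
  u <- D / phi
  C <- matrix(sigma2, nrow(D), ncol(D), dimnames = dimnames(D))
  pos <- u > 0
  C[pos] <- sigma2 * (2^(1 - kappa) / gamma(kappa)) * u[pos]^kappa *
    besselK(u[pos], kappa)
  C <- (C + t(C)) / 2
  C + diag(1e-8 * sigma2, nrow(D))
}

#' Spatial correlation matrix for the mixed model
#'
#' Convenience wrapper: great-circle distances scaled to `distance_scale` km
#' per unit, pushed through the Matern kernel with the default range
#' `phi = 1.25` and smoothness `kappa = 1`, then normalized to unit diagonal.
#' With the default scaling the correlation drops below 0.05 near 1000 km.
#'
#' @inheritParams haversine_matrix
#' @param phi,kappa Matern parameters.
#' @param distance_scale Km per Matern distance unit (default 200).
#' @export
spatial_correlation_matrix <- function(locations, phi = 1.25, kappa = 1,
                                       distance_scale = 200) {
  D <- haversine_matrix(locations) / distance_scale
  stats::cov2cor(matern_covariance(D, phi = phi, kappa = kappa, sigma2 = 1))
}

# Numerically stable Bernoulli log-likelihood on the logit scale.
bernoulli_loglik <- function(eta, y) {
  sum(ifelse(eta > 0, (y - 1) * eta - log1p(exp(-eta)),
             y * eta - log1p(exp(eta))))
}

log_half_t <- function(sigma, df, scale) {
  stats::dt(sigma / scale, df = df, log = TRUE) - log(scale)
}

split_rhat <- function(mat) {
  # mat: iterations x chains
  l <- floor(nrow(mat) / 2)
  halves <- cbind(mat[seq_len(l), , drop = FALSE],
                  mat[nrow(mat) - l + seq_len(l), , drop = FALSE])
  mns <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- l * var(mns)
  if (W == 0) return(1)
  sqrt(((l - 1) / l * W + B / l) / W)
}

ess_basic <- function(mat) {
  m <- ncol(mat); l <- nrow(mat)
  rho_sum <- mean(apply(mat, 2, function(x) {
    if (var(x) == 0) return(0)
    ac <- stats::acf(x, lag.max = min(l - 1, 100), plot = FALSE)$acf[-1]
    # Geyer initial positive sequence on pairs
    s <- 0
    for (i in seq(1, length(ac) - 1, by = 2)) {
      pair <- ac[i] + ac[i + 1]
      if (is.na(pair) || pair <= 0) break
      s <- s + pair
    }
    s
  }))
  max(m * l / (1 + 2 * rho_sum), 1)
}

#' Bayesian logistic mixed model with structured random effects
#'
#' Fits `logit P(y = 1) = X beta + u + v` where `u ~ N(0, sigma_p^2 * C_phylo)`
#' and `v ~ N(0, sigma_s^2 * C_spatial)` (each term present only when its
#' correlation matrix is supplied). Correlation matrices are normalized to
#' unit diagonal so the scales are comparable. Priors: `beta ~ N(0, 2.5^2)`,
#' scales half-Student-t(3, 0, 2.5). Sampling: elliptical slice updates of
#' the whitened Gaussian block (coefficients and latent fields), slice
#' sampling of each log scale, an ancillarity-sufficiency interweaving step
#' that rescales scale and field jointly at fixed latent effects, and a
#' likelihood-invariant translation between the intercept and the field
#' mean. Several sweeps of this cycle are run per stored draw.
#'
#' @param y Binary response vector.
#' @param X Design matrix with intercept.
#' @param corr_phylo,corr_spatial Correlation matrices aligned to `y` (either
#'   may be NULL).
#' @param seed Integer seed (required).
#' @param chains,warmup,draws MCMC configuration.
#' @param sweeps Update sweeps per stored draw (internal thinning).
#' @param priors List overriding `beta_sd`, `sd_scale`, `sd_df`.
#' @param sigma_fixed Optional named vector (names among `phylo`, `spatial`)
#'   fixing a scale instead of sampling it (used for reduction checks).
#' @param check Reject the fit (error) when convergence diagnostics exceed
#'   `rhat_threshold` / fall below `min_ess`.
#' @param rhat_threshold,min_ess Convergence thresholds.
#' @param store_latents Keep thinned draws of the latent fields (needed for
#'   cross-validation).
#' @return Object of class `phylo_glmm`: posterior `summary` tibble, draws,
#'   diagnostics, seed and configuration.
#' @export
fit_glmm <- function(y, X, corr_phylo = NULL, corr_spatial = NULL, seed,
                     chains = 4, warmup = 1000, draws = 1000,
                     priors = list(), sigma_fixed = NULL, check = TRUE,
                     rhat_threshold = 1.01, min_ess = 100,
                     store_latents = FALSE, sweeps = 3) {
  check_binary(y, "response")
  n <- length(y)
  if (sum(y) == 0 || sum(y) == n) abort("response is constant")
  X <- check_design(as.matrix(X), n)
  p <- ncol(X)
  pri <- utils::modifyList(list(beta_sd = 2.5, sd_scale = 2.5, sd_df = 3), priors)

  effects <- c(if (!is.null(corr_phylo)) "phylo",
               if (!is.null(corr_spatial)) "spatial")
  L <- list()
  if (!is.null(corr_phylo)) {
    if (!all(dim(corr_phylo) == n)) abort("corr_phylo misaligned with response")
    L$phylo <- t(chol_safe(stats::cov2cor(corr_phylo)))
  }
  if (!is.null(corr_spatial)) {
    if (!all(dim(corr_spatial) == n)) abort("corr_spatial misaligned with response")
    L$spatial <- t(chol_safe(stats::cov2cor(corr_spatial)))
  }

  total <- warmup + draws
  run_chain <- function(chain_seed) {
    withr::with_seed(chain_seed, {
      beta <- rnorm(p, 0, 0.1)
      z <- lapply(effects, function(e) rnorm(n, 0, 0.1))
      names(z) <- effects
      sigma <- setNames(rep(0.5, length(effects)), effects)
      for (e in names(sigma_fixed %||% c())) sigma[e] <- sigma_fixed[[e]]
      sample_sigma <- setdiff(effects, names(sigma_fixed %||% c()))

      xb <- drop(X %*% beta)
      uraw <- lapply(effects, function(e) drop(L[[e]] %*% z[[e]]))
      names(uraw) <- effects
      # intercept column (for likelihood-invariant translation moves)
      int_col <- which(apply(X, 2, function(cl) all(cl == 1)))[1]
      winv1 <- lapply(effects, function(e) forwardsolve(L[[e]], rep(1, n)))
      names(winv1) <- effects
      tstep <- setNames(rep(0.3, length(effects)), effects)
      taccept <- setNames(rep(0, length(effects)), effects)
      eta_of <- function(xb, uraw, sigma) {
        eta <- xb
        for (e in effects) eta <- eta + sigma[e] * uraw[[e]]
        eta
      }
      ll <- bernoulli_loglik(eta_of(xb, uraw, sigma), y)

      out_beta <- matrix(NA_real_, draws, p)
      out_sigma <- matrix(NA_real_, draws, length(effects),
                          dimnames = list(NULL, effects))
      keep_idx <- if (store_latents) {
        unique(round(seq(1, draws, length.out = min(draws, 200))))
      } else {
        integer()
      }
      out_u <- lapply(effects, function(e) {
        matrix(NA_real_, length(keep_idx), n)
      })
      names(out_u) <- effects
      kept <- 0

      for (it in seq_len(total)) {
       for (sweep in seq_len(sweeps)) {
        ## elliptical slice update of (beta, z) jointly
        nu_b <- rnorm(p, 0, pri$beta_sd)
        nu_z <- lapply(effects, function(e) rnorm(n))
        names(nu_z) <- effects
        xnu <- drop(X %*% nu_b)
        unu <- lapply(effects, function(e) drop(L[[e]] %*% nu_z[[e]]))
        names(unu) <- effects
        ly <- ll + log(runif(1))
        theta <- runif(1, 0, 2 * pi)
        lo <- theta - 2 * pi; hi <- theta
        repeat {
          ct <- cos(theta); st <- sin(theta)
          xb_prop <- xb * ct + xnu * st
          uraw_prop <- lapply(effects, function(e) uraw[[e]] * ct + unu[[e]] * st)
          names(uraw_prop) <- effects
          ll_prop <- bernoulli_loglik(eta_of(xb_prop, uraw_prop, sigma), y)
          if (ll_prop > ly) {
            beta <- beta * ct + nu_b * st
            for (e in effects) z[[e]] <- z[[e]] * ct + nu_z[[e]] * st
            xb <- xb_prop; uraw <- uraw_prop; ll <- ll_prop
            break
          }
          if (theta < 0) lo <- theta else hi <- theta
          theta <- runif(1, lo, hi)
        }

        ## slice sample each log scale in the non-centered conditional
        for (e in sample_sigma) {
          base_eta <- xb
          for (e2 in setdiff(effects, e)) base_eta <- base_eta + sigma[e2] * uraw[[e2]]
          logpost <- function(theta) {
            bernoulli_loglik(base_eta + exp(theta) * uraw[[e]], y) +
              log_half_t(exp(theta), pri$sd_df, pri$sd_scale) + theta
          }
          th0 <- log(sigma[e])
          lp0 <- logpost(th0)
          ly_s <- lp0 + log(runif(1))
          w <- 1
          lo <- th0 - w * runif(1); hi <- lo + w
          steps <- 0
          while (logpost(lo) > ly_s && steps < 20) { lo <- lo - w; steps <- steps + 1 }
          steps <- 0
          while (logpost(hi) > ly_s && steps < 20) { hi <- hi + w; steps <- steps + 1 }
          repeat {
            th1 <- runif(1, lo, hi)
            if (logpost(th1) > ly_s) break
            if (th1 < th0) lo <- th1 else hi <- th1
          }
          sigma[e] <- exp(th1)
          ll <- bernoulli_loglik(eta_of(xb, uraw, sigma), y)

          ## interweaved centered update: holding u = sigma * L z fixed (so
          ## the likelihood is unchanged), sigma's conditional is
          ## prior(sigma) * sigma^-n * exp(-u' C^-1 u / (2 sigma^2)); an
          ## independence draw from the matching inverse-gamma accepts on
          ## the prior ratio alone and decouples sigma from the field scale.
          ## translation move: shift the intercept into / out of the latent
          ## field mean; eta is unchanged, acceptance is on the prior ratio.
          if (!is.na(int_col)) {
            delta <- tstep[e] * rnorm(1)
            z_prop <- z[[e]] - (delta / sigma[e]) * winv1[[e]]
            b0_prop <- beta[int_col] + delta
            lacc3 <- -0.5 * (sum(z_prop^2) - sum(z[[e]]^2)) -
              0.5 * (b0_prop^2 - beta[int_col]^2) / pri$beta_sd^2
            if (log(runif(1)) < lacc3) {
              z[[e]] <- z_prop
              beta[int_col] <- b0_prop
              uraw[[e]] <- uraw[[e]] - delta / sigma[e]  # L %*% winv1 is the ones vector
              xb <- drop(X %*% beta)
              taccept[e] <- taccept[e] + 1
            }
            if (it <= warmup && it %% 50 == 0) {
              tstep[e] <- tstep[e] * exp(0.5 * (taccept[e] / 50 - 0.44))
              taccept[e] <- 0
            }
          }

          s_quad <- sigma[e]^2 * sum(z[[e]]^2)
          if (s_quad > 0) {
            q_prop <- (s_quad / 2) / stats::rgamma(1, (n - 1) / 2)
            lacc2 <- log_half_t(sqrt(q_prop), pri$sd_df, pri$sd_scale) -
              log_half_t(sigma[e], pri$sd_df, pri$sd_scale)
            if (log(runif(1)) < lacc2) {
              ratio <- sigma[e] / sqrt(q_prop)
              z[[e]] <- z[[e]] * ratio
              uraw[[e]] <- uraw[[e]] * ratio
              sigma[e] <- sqrt(q_prop)
            }
          }
        }

       }  # end sweeps

        if (it > warmup) {
          j <- it - warmup
          out_beta[j, ] <- beta
          out_sigma[j, ] <- sigma[effects]
          if (store_latents && j %in% keep_idx) {
            kept <- kept + 1
            for (e in effects) out_u[[e]][kept, ] <- sigma[e] * uraw[[e]]
          }
        }
      }
      list(beta = out_beta, sigma = out_sigma, u = out_u, keep_idx = keep_idx)
    })
  }

  chain_out <- lapply(seq_len(chains), function(ch) {
    run_chain(derive_seed(seed, "chain", ch))
  })

  par_names <- c(colnames(X),
                 if (length(effects)) paste0("sd_", effects))
  draw_mats <- lapply(seq_along(par_names), function(j) {
    vapply(chain_out, function(co) {
      if (j <= p) co$beta[, j] else co$sigma[, j - p]
    }, numeric(draws))
  })
  names(draw_mats) <- par_names

  summary <- purrr::map_dfr(par_names, function(nm) {
    m <- draw_mats[[nm]]
    v <- as.vector(m)
    tibble::tibble(
      term = nm, mean = mean(v), sd = sd(v),
      q2.5 = unname(quantile(v, 0.025)), q97.5 = unname(quantile(v, 0.975)),
      rhat = split_rhat(m), ess = ess_basic(m)
    )
  })

  fixed_sigma_terms <- if (length(sigma_fixed %||% c())) {
    paste0("sd_", names(sigma_fixed))
  } else {
    character()
  }
  diag_rows <- summary[!summary$term %in% fixed_sigma_terms, ]
  if (check) {
    bad <- diag_rows$term[diag_rows$rhat > rhat_threshold |
                            diag_rows$ess < min_ess]
    if (length(bad) > 0) {
      abort(sprintf(
        "GLMM did not converge (rhat > %.3g or ess < %d for: %s)",
        rhat_threshold, min_ess, paste(bad, collapse = ", ")))
    }
  }

  structure(list(
    summary = summary, effects = effects, n = n, seed = seed,
    chains = chains, warmup = warmup, draws = draws,
    draw_mats = draw_mats,
    latents = lapply(chain_out, `[[`, "u"),
    sigma_draws = lapply(chain_out, `[[`, "sigma"),
    beta_draws = lapply(chain_out, `[[`, "beta"),
    keep_idx = chain_out[[1]]$keep_idx,
    terms = colnames(X)
  ), class = "phylo_glmm")
}

#' @export
print.phylo_glmm <- function(x, ...) {
  cat(sprintf(
    "Bayesian logistic mixed model (n = %d; effects: %s; %d chains x %d draws)\n",
    x$n, if (length(x$effects)) paste(x$effects, collapse = " + ") else "none",
    x$chains, x$draws))
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}

#' @export
tidy.phylo_glmm <- function(x, ...) x$summary

#' @export
glance.phylo_glmm <- function(x, ...) {
  tibble::tibble(n = x$n, chains = x$chains, draws = x$draws,
                 max_rhat = max(x$summary$rhat), min_ess = min(x$summary$ess))
}

#' @export
autoplot.phylo_glmm <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$mean, y = .data$term)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$q2.5, xmax = .data$q97.5)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "posterior mean and 95% interval", y = NULL)
}

# Conditional draws of held-out latent effects given the training-set latents
# of one posterior draw: u_test | u_train is Gaussian with the usual Schur
# complement of the (unit-diagonal) correlation matrix, scaled by sigma^2.
fold_predictor <- function(corr, test, train) {
  S11 <- corr[train, train]
  S21 <- corr[test, train, drop = FALSE]
  R11 <- chol_safe(S11)
  A <- t(chol_solve(R11, t(S21)))          # S21 %*% S11^{-1}
  Schur <- corr[test, test] - A %*% t(S21)
  Lc <- t(chol_safe((Schur + t(Schur)) / 2))
  list(A = A, Lc = Lc)
}

#' K-fold cross-validated comparison of mixed-model structures
#'
#' Fits each candidate random-effect structure on K-1 folds and scores the
#' held-out fold by its expected log predictive density (elpd), integrating
#' the held-out latent effects over their conditional Gaussian distribution
#' given the training-fold latents, per retained posterior draw. Pairwise
#' elpd differences with standard errors are reported; models within
#' 2 standard errors are flagged as equivalent.
#'
#' @param y,X Response and design matrix.
#' @param specs Named list of model specifications, each a list with optional
#'   `corr_phylo` and `corr_spatial` entries.
#' @param K Number of folds (default 10).
#' @param seed Integer seed (folds and refits).
#' @param chains,warmup,draws MCMC configuration per refit.
#' @return Object of class `kfold_table`: per-model elpd tibble, pairwise
#'   differences and fold assignment.
#' @export
kfold_compare <- function(y, X, specs, K = 10, seed, chains = 2,
                          warmup = 300, draws = 300) {
  n <- length(y)
  if (K > n) abort("K exceeds the sample size")
  if (length(specs) < 1 || is.null(names(specs))) {
    abort("specs must be a named list of model specifications")
  }
  folds <- withr::with_seed(derive_seed(seed, "folds"),
                            sample(rep(seq_len(K), length.out = n)))
  X <- as.matrix(X)

  elpd_points <- purrr::imap(specs, function(spec, id) {
    pointwise <- numeric(n)
    for (fold in seq_len(K)) {
      test <- which(folds == fold)
      train <- which(folds != fold)
      fit <- fit_glmm(
        y[train], X[train, , drop = FALSE],
        corr_phylo = if (!is.null(spec$corr_phylo)) spec$corr_phylo[train, train],
        corr_spatial = if (!is.null(spec$corr_spatial)) spec$corr_spatial[train, train],
        seed = derive_seed(seed, id, fold), chains = chains,
        warmup = warmup, draws = draws, check = FALSE, store_latents = TRUE
      )
      preds <- lapply(fit$effects, function(e) {
        corr <- stats::cov2cor(if (e == "phylo") spec$corr_phylo else spec$corr_spatial)
        fold_predictor(corr, test, train)
      })
      names(preds) <- fit$effects
      # accumulate P(y_test | draw) over chains and retained draws
      pmat <- matrix(0, length(test), 0)
      for (ch in seq_len(fit$chains)) {
        kidx <- fit$keep_idx
        for (d in seq_along(kidx)) {
          eta <- drop(X[test, , drop = FALSE] %*% fit$beta_draws[[ch]][kidx[d], ])
          for (e in fit$effects) {
            u_train <- fit$latents[[ch]][[e]][d, ]
            sig <- fit$sigma_draws[[ch]][kidx[d], e]
            cond_mean <- drop(preds[[e]]$A %*% u_train)
            eta <- eta + cond_mean +
              sig * drop(preds[[e]]$Lc %*% rnorm(length(test)))
          }
          pmat <- cbind(pmat, plogis(eta))
        }
      }
      prob1 <- rowMeans(pmat)
      pointwise[test] <- log(ifelse(y[test] == 1, prob1, 1 - prob1))
    }
    pointwise
  })

  table <- purrr::imap_dfr(elpd_points, function(pw, id) {
    tibble::tibble(model = id, elpd = sum(pw), se = sqrt(n * var(pw)))
  })
  ids <- names(specs)
  pairs <- if (length(ids) > 1) {
    purrr::map_dfr(utils::combn(ids, 2, simplify = FALSE), function(pr) {
      d <- elpd_points[[pr[1]]] - elpd_points[[pr[2]]]
      diff <- sum(d); se <- sqrt(n * var(d))
      tibble::tibble(model_a = pr[1], model_b = pr[2],
                     elpd_diff = diff, se_diff = se,
                     equivalent = abs(diff) < 2 * se)
    })
  } else {
    tibble::tibble(model_a = character(), model_b = character(),
                   elpd_diff = numeric(), se_diff = numeric(),
                   equivalent = logical())
  }
  structure(list(table = dplyr::arrange(table, dplyr::desc(.data$elpd)),
                 pairwise = pairs, K = K, seed = seed, folds = folds),
            class = "kfold_table")
}

#' @export
print.kfold_table <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", x$K))
  print(x$table)
  if (nrow(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' @export
tidy.kfold_table <- function(x, ...) x$table

#' Refit the supported path models as Bayesian logistic mixed models
#'
#' Each directed path of each model is refit as a logistic mixed model of the
#' effect on its cause(s) with a phylogenetic random effect (the spatial term
#' adds little once phylogeny is in, and a single shared structure keeps the
#' models comparable). Posterior means and 95% credible intervals are
#' reported per path, flagging paths whose interval includes zero.
#'
#' @param traits Tibble of binary trait columns aligned to `corr_phylo`.
#' @param corr_phylo Phylogenetic correlation matrix.
#' @param models Named list of `causal_dag`s (default the supported b/c/d).
#' @param seed Integer seed.
#' @param ... Passed to [fit_glmm()] (chains, warmup, draws, check, ...).
#' @return Tibble `model_id`, `from`, `to`, `mean`, `q2.5`, `q97.5`,
#'   `excludes_zero`.
#' @export
refit_path_models_glmm <- function(traits, corr_phylo,
                                   models = candidate_models()[c("b", "c", "d")],
                                   seed, ...) {
  traits <- tibble::as_tibble(traits)
  purrr::imap_dfr(models, function(dag, id) {
    purrr::map_dfr(unique(dag$edges$to), function(v) {
      parents <- dag_parents(dag, v)
      X <- cbind(`(Intercept)` = 1, as.matrix(traits[parents]))
      fit <- fit_glmm(traits[[v]], X, corr_phylo = corr_phylo,
                      seed = derive_seed(seed, id, v), ...)
      s <- fit$summary[fit$summary$term %in% parents, ]
      tibble::tibble(model_id = id, from = s$term, to = v,
                     mean = s$mean, q2.5 = s$q2.5, q97.5 = s$q97.5,
                     excludes_zero = s$q2.5 > 0 | s$q97.5 < 0)
    })
  })
}
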