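# Regression engines used by the d-separation claim tests: generalized least
# squares under a phylogenetic correlation matrix, and logistic regression
# with phylogenetically correlated working residuals and a jointly estimated
# signal-decay parameter.

new_phylo_fit <- function(method, coefficients, se, p_values, n, df_residual,
                          converged = TRUE, phylo_signal_parameter = NA_real_,
                          extra = list()) {
  structure(c(list(
    method = method, coefficients = coefficients, se = se,
    p_values = p_values, n = n, df_residual = df_residual,
    converged = converged, phylo_signal_parameter = phylo_signal_parameter
  ), extra), class = "phylo_fit")
}

#' @export
print.phylo_fit <- function(x, ...) {
  cat(sprintf("phylo_fit (%s), n = %d%s\n", x$method, x$n,
              if (!x$converged) ", NOT CONVERGED" else ""))
  print(tidy(x), ...)
  if (!is.na(x$phylo_signal_parameter)) {
    cat(sprintf("signal decay parameter alpha = %.4g\n", x$phylo_signal_parameter))
  }
  invisible(x)
}

#' @export
tidy.phylo_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    p.value = unname(x$p_values)
  )
}

#' @export
glance.phylo_fit <- function(x, ...) {
  tibble::tibble(method = x$method, n = x$n, converged = x$converged,
                 phylo_signal_parameter = x$phylo_signal_parameter)
}

check_design <- function(X, n) {
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != n) abort("design matrix rows do not match response length")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("design matrix is rank deficient; collinear columns: %s",
                  paste(drop, collapse = ", ")))
  }
  X
}

#' Phylogenetic generalized least squares
#'
#' GLS estimates under a fixed residual correlation matrix, solved through a
#' Cholesky whitening of the correlation; p-values are t-based with
#' n - rank(X) degrees of freedom.
#'
#' @param y Numeric response vector.
#' @param X Design matrix including an intercept column.
#' @param corr Symmetric positive (semi-)definite correlation matrix aligned
#'   with `y` and the rows of `X`.
#' @return A `phylo_fit` object (`method = "gls"`).
#' @export
pgls_fit <- function(y, X, corr) {
  n <- length(y)
  X <- check_design(as.matrix(X), n)
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8))) {
    abort("correlation matrix is not symmetric")
  }
  R <- chol_safe(corr)
  # whiten: corr = R'R, so L^{-1} = backsolve against R'
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, y, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  p <- ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  XtX_inv <- chol2inv(qr.R(qr(Xw)))
  se <- sqrt(sigma2 * diag(XtX_inv))
  beta <- fit$coefficients
  tval <- beta / se
  pv <- 2 * pt(-abs(tval), df = n - p)
  new_phylo_fit("gls", setNames(beta, colnames(X)), setNames(se, colnames(X)),
                setNames(pv, colnames(X)), n, n - p,
                extra = list(sigma2 = sigma2, vcov = sigma2 * XtX_inv))
}

# Gaussian pseudo-profile-likelihood of Pearson residuals under correlation
# R(alpha) = exp(-alpha * D); used to estimate the signal decay parameter.
alpha_profile_obj <- function(log_alpha, Dmat, r) {
  Ra <- exp(-exp(log_alpha) * Dmat)
  Rc <- chol_safe(Ra)
  q <- backsolve(Rc, r, transpose = TRUE)
  sum(log(diag(Rc))) + length(r) / 2 * log(sum(q^2))
}

#' Phylogenetic logistic regression
#'
#' Logistic regression for a binary response whose working residuals are
#' phylogenetically correlated: the residual correlation between tips i and j
#' is `exp(-alpha * d_ij)` with `d_ij` the patristic distance implied by
#' `corr` (for a unit-height tree, `d = 2 (1 - corr)`). The decay parameter
#' `alpha` is estimated jointly with the coefficients by maximizing a Gaussian
#' pseudo-likelihood of the Pearson residuals, within fixed bounds
#' `[1e-4/h, 50/h]` (h = tree height); the upper bound is treated as the
#' independence limit (identity correlation), where the fit coincides with
#' ordinary logistic maximum likelihood. If the unpenalized fit diverges (separation), a ridge
#' penalty equivalent to a Normal(0, 2) prior on the coefficients is applied
#' and the fit is flagged as penalized.
#'
#' @param y Binary (0/1) response.
#' @param X Design matrix including an intercept column.
#' @param corr Phylogenetic correlation matrix (unit diagonal) aligned to `y`.
#' @param alpha Optional fixed decay parameter (skips estimation).
#' @param max_iter,tol Scoring iteration controls.
#' @return A `phylo_fit` object (`method = "phylo_logistic"`) whose
#'   `phylo_signal_parameter` is the estimated decay `alpha`.
#' @export
phylo_logistic_fit <- function(y, X, corr, alpha = NULL, max_iter = 50,
                               tol = 1e-8) {
  check_binary(y, "response")
  n <- length(y)
  if (sum(y) == 0 || sum(y) == n) abort("response is constant; cannot fit")
  X <- check_design(as.matrix(X), n)
  h <- max(diag(corr))
  Dmat <- pmax(outer(diag(corr), diag(corr), "+") - 2 * corr, 0)
  bounds <- c(1e-4, 50) / h

  irls <- function(alpha_val, ridge = 0) {
    # the upper bound is the independence (no-signal) limit: exact identity
    Ra <- if (alpha_val >= bounds[2]) diag(n) else exp(-alpha_val * Dmat)
    Rc <- chol_safe(Ra)
    beta <- rep(0, ncol(X))
    ok <- FALSE
    for (iter in seq_len(max_iter)) {
      eta <- drop(X %*% beta)
      mu <- pmin(pmax(plogis(eta), 1e-10), 1 - 1e-10)
      s <- sqrt(mu * (1 - mu))
      A <- X * s
      r <- (y - mu) / s
      Aw <- backsolve(Rc, A, transpose = TRUE)
      rw <- backsolve(Rc, r, transpose = TRUE)
      H <- crossprod(Aw) + diag(ridge, ncol(X))
      score <- crossprod(Aw, rw) - ridge * beta
      step <- tryCatch(solve(H, score), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      beta <- beta + drop(step)
      if (max(abs(step)) < tol) { ok <- TRUE; break }
      if (max(abs(beta)) > 50) break
    }
    eta <- drop(X %*% beta)
    mu <- pmin(pmax(plogis(eta), 1e-10), 1 - 1e-10)
    s <- sqrt(mu * (1 - mu))
    list(beta = beta, converged = ok, H = {
      A <- X * s
      Aw <- backsolve(Rc, A, transpose = TRUE)
      crossprod(Aw) + diag(ridge, ncol(X))
    }, pearson = (y - mu) / s)
  }

  estimate_alpha <- is.null(alpha)
  alpha_val <- if (estimate_alpha) bounds[2] else alpha
  ridge <- 0
  irls_guarded <- function(alpha_val) {
    f <- irls(alpha_val, ridge)
    if (!f$converged || max(abs(f$beta)) > 12) {
      # separation / ill-conditioned working correlation:
      # Normal(0, 2) shrinkage keeps the estimates finite
      ridge <<- max(ridge, 0.25)
      f <- irls(alpha_val, ridge)
    }
    f
  }
  fit <- irls_guarded(alpha_val)
  if (estimate_alpha) {
    for (pass in 1:2) {
      opt <- optimize(alpha_profile_obj, interval = log(bounds),
                      Dmat = Dmat, r = fit$pearson, tol = 0.05)
      prev <- alpha_val
      alpha_val <- exp(opt$minimum)
      fit <- irls_guarded(alpha_val)
      if (abs(log(alpha_val) - log(prev)) < 0.3) break
    }
  }
  vcov <- tryCatch(solve(fit$H), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  se <- sqrt(diag(vcov))
  z <- fit$beta / se
  pv <- 2 * pnorm(-abs(z))
  nm <- colnames(X)
  new_phylo_fit("phylo_logistic", setNames(fit$beta, nm), setNames(se, nm),
                setNames(pv, nm), n, n - ncol(X),
                converged = fit$converged,
                phylo_signal_parameter = alpha_val,
                extra = list(vcov = vcov, penalized = ridge > 0,
                             alpha_bounds = bounds))
}

#' Standardize path coefficients by predictor scale
#'
#' Rescales each non-intercept coefficient (and its Wald 95% confidence
#' bounds) by the standard deviation of the corresponding predictor, so that
#' paths are comparable across models; binary predictors are scaled by their
#' sample standard deviation like any other column.
#'
#' @param fit A `phylo_fit`.
#' @param data Data frame/tibble holding the predictor columns by name.
#' @return Tibble `term`, `estimate`, `lower95`, `upper95` (standardized).
#' @export
standardize_paths <- function(fit, data) {
  td <- tidy(fit)
  td <- td[td$term != "(Intercept)", ]
  sds <- vapply(td$term, function(v) {
    if (!v %in% names(data)) abort(sprintf("predictor '%s' not found in data", v))
    stats::sd(data[[v]])
  }, numeric(1))
  if (any(sds == 0)) {
    abort(sprintf("zero-variance predictor: %s",
                  paste(td$term[sds == 0], collapse = ", ")))
  }
  tibble::tibble(
    term = td$term,
    estimate = unname(td$estimate * sds),
    lower95 = unname((td$estimate - 1.96 * td$std.error) * sds),
    upper95 = unname((td$estimate + 1.96 * td$std.error) * sds)
  )
}
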