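test_that("haversine distances match closed-form values", {
  loc <- tibble::tibble(taxon_id = c("a", "b", "c"),
                        latitude = c(0, 0, 0), longitude = c(0, 180, 0))
  D <- haversine_matrix(loc)
  expect_equal(D["a", "c"], 0)
  expect_equal(D["a", "b"], pi * 6371, tolerance = 1)  # half circumference
  expect_equal(D, t(D))
  expect_error(haversine_matrix(tibble::tibble(taxon_id = "x", latitude = 100,
                                               longitude = 0)), "out of range")
})

test_that("the Matern kernel matches its special cases", {
  D <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(diag(matern_covariance(D, phi = 1, kappa = 1, sigma2 = 3))[1],
               3, tolerance = 1e-6)
  # kappa = 1/2: exponential covariance
  d <- seq(0.1, 5, by = 0.3)
  Dm <- rbind(c(0, d), cbind(d, matrix(0, length(d), length(d))))
  Dm <- as.matrix(dist(c(0, cumsum(rep(0.5, 8)))))
  M <- matern_covariance(Dm, phi = 2, kappa = 0.5, sigma2 = 1.3)
  expect_equal(M[1, -1], 1.3 * exp(-Dm[1, -1] / 2), tolerance = 1e-7)
  # kappa = 1 at d = phi: K_1(1)
  M1 <- matern_covariance(matrix(c(0, 1.25, 1.25, 0), 2), phi = 1.25, kappa = 1)
  expect_equal(M1[1, 2], besselK(1, 1), tolerance = 1e-7)
  expect_equal(unname(M1[1, 2]), 0.6019, tolerance = 1e-3)
  # non-increasing in distance
  grid <- as.matrix(dist(seq(0, 10, by = 0.25)))
  Mg <- matern_covariance(grid, phi = 1.25, kappa = 1)
  expect_true(all(diff(Mg[1, -1]) <= 1e-12))
  expect_error(matern_covariance(D, phi = -1), "strictly positive")
})

test_that("the default spatial correlation decays below 0.05 near 1000 km", {
  loc <- tibble::tibble(taxon_id = c("a", "b", "c"),
                        latitude = 0, longitude = c(0, 3, 9))  # ~333, ~1000 km
  S <- spatial_correlation_matrix(loc)
  expect_gt(S["a", "b"], 0.3)   # within several hundred km: strong
  expect_lt(S["a", "c"], 0.05)  # near 1000 km: negligible
})

test_that("the posterior matches exact quadrature on a two-tip problem", {
  corr <- matrix(c(1, .5, .5, 1), 2)
  y <- c(1, 0)
  # oracle: whitened-grid quadrature of the sigma marginal
  zg <- seq(-7, 7, length.out = 101); wz <- dnorm(zg); wz <- wz / sum(wz)
  bg <- seq(-10, 10, length.out = 101); wb <- dnorm(bg, 0, 2.5); wb <- wb / sum(wb)
  sg <- exp(seq(log(0.005), log(40), length.out = 200))
  ws <- dt(sg / 2.5, df = 3) * sg; ws <- ws / sum(ws)
  marg <- vapply(sg, function(s) {
    tot <- 0
    for (i in seq_along(bg)) {
      f1 <- plogis(bg[i] + s * zg)
      g <- vapply(seq_along(zg), function(a) {
        sum((1 - plogis(bg[i] + s * (0.5 * zg[a] + sqrt(0.75) * zg))) * wz)
      }, numeric(1))
      tot <- tot + wb[i] * sum(f1 * g * wz)
    }
    tot
  }, numeric(1))
  post <- marg * ws; post <- post / sum(post)
  exact_p_lt1 <- sum(post[sg < 1])
  exact_mean <- sum(sg * post)

  fit <- fit_glmm(y, cbind(`(Intercept)` = rep(1, 2)), corr_phylo = corr,
                  seed = 5, chains = 2, warmup = 800, draws = 2000,
                  check = FALSE)
  sdr <- as.vector(fit$draw_mats$sd_phylo)
  expect_equal(mean(sdr < 1), exact_p_lt1, tolerance = 0.05)
  expect_equal(mean(sdr), exact_mean, tolerance = 0.35)
})

test_that("without random effects the fit reduces to ordinary logistic", {
  set.seed(81)
  n <- 200
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.3 + 0.9 * x))
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_glmm(y, X, seed = 82, chains = 2, warmup = 300, draws = 700,
                  check = FALSE)
  ref <- glm(y ~ x, family = binomial)
  s <- fit$summary
  for (j in 1:2) {
    expect_lt(abs(s$mean[j] - coef(ref)[j]), 3 * s$sd[j])
    expect_lt(abs(s$sd[j] - summary(ref)$coefficients[j, 2]), 0.1)
  }
  # posterior predictive prevalence tracks the observed prevalence
  b <- fit$draw_mats
  eta <- outer(rep(1, n), as.vector(b[["(Intercept)"]])[1:500]) +
    outer(x, as.vector(b[["x"]])[1:500])
  expect_equal(mean(plogis(eta)), mean(y), tolerance = 0.05)
})

test_that("a near-zero fixed variance reproduces ordinary logistic estimates", {
  tree <- simulate_tree(150, seed = 83)
  corr <- phylo_correlation_matrix(tree)
  dat <- sim_logistic_phylo(tree, beta0 = -0.3, beta1 = 1, sigma = 0, seed = 84)
  X <- cbind(`(Intercept)` = 1, x = dat$x)
  fit <- fit_glmm(dat$y, X, corr_phylo = corr, seed = 85, chains = 2,
                  warmup = 300, draws = 600,
                  sigma_fixed = c(phylo = 1e-4), check = FALSE)
  ref <- glm(dat$y ~ dat$x, family = binomial)
  s <- fit$summary
  expect_lt(abs(s$mean[1] - coef(ref)[1]), 3 * s$sd[1])
  expect_lt(abs(s$mean[2] - coef(ref)[2]), 3 * s$sd[2])
})

test_that("convergence checking rejects a hopeless configuration", {
  set.seed(86)
  y <- rbinom(30, 1, 0.5)
  X <- cbind(`(Intercept)` = rep(1, 30))
  expect_error(
    fit_glmm(y, X, corr_phylo = phylo_correlation_matrix(simulate_tree(30, seed = 87)),
             seed = 88, chains = 2, warmup = 5, draws = 10, sweeps = 1,
             check = TRUE, rhat_threshold = 1.0001, min_ess = 1e5),
    "did not converge")
})

test_that("K-fold assignment partitions the data and scores both models", {
  tree <- simulate_tree(80, seed = 91)
  corr <- phylo_correlation_matrix(tree)
  dat <- sim_logistic_phylo(tree, beta0 = 0, sigma = 1.5, seed = 92)
  X <- cbind(`(Intercept)` = rep(1, 80))
  kf <- kfold_compare(dat$y, X, specs = list(phylo = list(corr_phylo = corr),
                                             none = list()),
                      K = 4, seed = 93, chains = 1, warmup = 150, draws = 150)
  expect_equal(sort(unique(kf$folds)), 1:4)
  expect_equal(length(kf$folds), 80)
  expect_equal(nrow(kf$table), 2)
  expect_true(all(is.finite(kf$table$elpd)))
  expect_equal(nrow(kf$pairwise), 1)
  expect_error(kfold_compare(dat$y, X, specs = list(a = list()), K = 100,
                             seed = 1), "exceeds")
})

test_that("mixed-model refits report credible intervals per path", {
  tree <- simulate_tree(150, seed = 94)
  corr <- phylo_correlation_matrix(tree)
  sc <- builtin_scenario("model_c", n_tips = 150, seed = 95)
  traits <- simulate_dag_liabilities(tree, sc)
  out <- refit_path_models_glmm(traits, corr,
                                models = candidate_models()["c"], seed = 96,
                                chains = 2, warmup = 250, draws = 400,
                                check = FALSE)
  expect_equal(nrow(out), 2)  # verb_final -> case, case -> flexible
  expect_true(all(out$q2.5 <= out$mean & out$mean <= out$q97.5))
  vf <- out[out$from == "verb_final", ]
  expect_true(vf$excludes_zero)  # strong simulated effect is detected
})
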