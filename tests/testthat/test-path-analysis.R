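test_that("Fisher's C matches closed forms", {
  expect_equal(fisher_c(1.0), 0)
  expect_equal(fisher_c(0.1653), 3.60, tolerance = 0.005)
  expect_equal(fisher_c(c(0.5, 0.5)), -2 * 2 * log(0.5), tolerance = 1e-12)
  expect_equal(fisher_c(c(0.2, 0.7)), fisher_c(c(0.7, 0.2)))  # order-invariant
  expect_error(fisher_c(c(0.5, 0)), "0, 1")
  expect_error(fisher_c(-0.1), "0, 1")
})

test_that("model p-values are chi-squared upper tails with 2k df", {
  expect_equal(round(model_p_value(3.6, 1), 2), 0.17)
  expect_equal(round(model_p_value(5.58, 1), 2), 0.06)
  expect_equal(model_p_value(0, 3), 1.0)
  expect_equal(model_p_value(4, 2), pchisq(4, 4, lower.tail = FALSE))
})

test_that("CICc follows the small-sample correction", {
  expect_equal(cicc(3.6, 5, 1705), 13.64, tolerance = 0.005)
  expect_equal(cicc(64.22, 3, 1705), 70.23, tolerance = 0.005)
  expect_equal(cicc(7.7, 0, 100), 7.7)
  expect_error(cicc(1, 5, 6), "sample size")
})

test_that("compare_models ranks, weights and breaks ties deterministically", {
  rows <- tibble::tibble(
    model_id = c("m1", "m2", "m3"),
    k = c(1L, 1L, 2L), q = c(5L, 5L, 4L),
    C = c(3.6, 5.58, 10),
    model_p = c(0.17, 0.06, 0.04),
    CICc = c(13.64, 15.62, 18.1)
  )
  tab <- compare_models(rows)
  expect_equal(tab$model_id[1], "m1")
  expect_equal(tab$delta_CICc[1], 0)
  expect_equal(tab$relative_likelihood[1], 1)
  expect_equal(tab$relative_likelihood[2], exp(-1.98 / 2), tolerance = 1e-9)
  expect_equal(round(tab$relative_likelihood[2], 2), 0.37)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-9)

  # exact CICc tie: fewer parameters first, then model_id
  tie <- tibble::tibble(model_id = c("zz", "aa", "bb"), k = 1L,
                        q = c(4L, 5L, 4L), C = 1, model_p = 0.5,
                        CICc = c(10, 10, 10))
  expect_equal(compare_models(tie)$model_id, c("bb", "zz", "aa"))
})

test_that("select_top_models applies both the delta and p filters", {
  tab <- compare_models(tibble::tibble(
    model_id = c("good", "close_but_rejected", "far"),
    k = 1L, q = 5L, C = c(2, 9.2, 30),
    model_p = c(model_p_value(2, 1), model_p_value(9.2, 1), model_p_value(30, 1)),
    CICc = c(12, 13, 40)
  ))
  expect_equal(select_top_models(tab), "good")  # delta 1 but p = 0.01 excluded
  single <- compare_models(tibble::tibble(model_id = "only", k = 1L, q = 4L,
                                          C = 1, model_p = 0.6, CICc = 9))
  expect_equal(select_top_models(single), "only")
  none <- compare_models(tibble::tibble(model_id = "bad", k = 1L, q = 4L,
                                        C = 30, model_p = 1e-6, CICc = 38))
  expect_error(select_top_models(none), "inspect")
})

test_that("average_paths performs conditional weighted averaging", {
  fits <- list(
    m1 = tibble::tibble(from = c("a", "b"), to = c("b", "c"),
                        estimate = c(0.4, 1.0), lower95 = c(0.2, 0.8),
                        upper95 = c(0.6, 1.2)),
    m2 = tibble::tibble(from = "a", to = "b", estimate = 0.6,
                        lower95 = 0.4, upper95 = 0.8)
  )
  avg <- average_paths(fits, c(m1 = 0.5, m2 = 0.5))
  ab <- avg[avg$from == "a", ]
  expect_equal(ab$estimate, 0.5)           # equal-weight mean
  expect_equal(ab$lower95, 0.3)
  bc <- avg[avg$from == "b", ]
  expect_equal(bc$estimate, 1.0)           # unique path passes through
  expect_equal(bc$contributing_models[[1]], "m1")

  avg2 <- average_paths(fits, c(m1 = 0.75, m2 = 0.25))
  fits2 <- list(m1 = fits$m1[1, ], m2 = dplyr::mutate(fits$m2, estimate = 2,
                                                      lower95 = 2, upper95 = 2))
  fits2$m1$estimate <- 1
  avg3 <- average_paths(fits2, c(m1 = 0.75, m2 = 0.25))
  expect_equal(avg3$estimate[avg3$from == "a"], 1.25)  # 0.75*1 + 0.25*2

  expect_error(average_paths(fits, c(m1 = 0.5, m2 = 0.5), mode = "bogus"))
})

test_that("claim tests keep p in (0, 1] and respect the engine contract", {
  tree <- simulate_tree(150, seed = 61)
  corr <- phylo_correlation_matrix(tree)
  sc <- builtin_scenario("null", n_tips = 150, seed = 62)
  traits <- simulate_dag_liabilities(tree, sc)[analysis_traits()]
  bs <- basis_set(candidate_models()$c)
  for (engine in c("logistic", "gls")) {
    ct <- test_claim(bs[1, ], traits, corr, engine = engine)
    expect_true(ct$p_value > 0 && ct$p_value <= 1)
  }
  expect_error(test_claim(list(x = "nope", y = "case", conditioning = character(0)),
                          traits, corr), "missing")
})

test_that("fitted path models are internally consistent end to end", {
  tree <- simulate_tree(120, seed = 71)
  corr <- phylo_correlation_matrix(tree)
  sc <- builtin_scenario("model_c", n_tips = 120, seed = 72)
  traits <- simulate_dag_liabilities(tree, sc)[analysis_traits()]
  pp <- fit_path_models(traits, corr)
  expect_equal(nrow(pp$table), 13)
  expect_equal(sum(pp$table$weight), 1, tolerance = 1e-9)
  for (r in pp$results) {
    if (r$k > 0) expect_equal(r$C, fisher_c(r$claim_tests$p_value), tolerance = 1e-12)
    expect_equal(r$CICc, cicc(r$C, r$q, r$n), tolerance = 1e-12)
    row <- pp$table[pp$table$model_id == r$model_id, ]
    expect_equal(row$C, r$C)
    expect_equal(row$model_p, r$model_p)
  }
  # Markov-equivalent b and d share the same directed claim test, hence C
  Cb <- pp$table$C[pp$table$model_id == "b"]
  Cd <- pp$table$C[pp$table$model_id == "d"]
  expect_equal(Cb, Cd, tolerance = 1e-12)
  # averaging the supported set returns finite standardized paths
  avg <- average_top_models(pp)
  expect_true(all(is.finite(avg$estimate)))
  expect_true(all(avg$lower95 <= avg$estimate & avg$estimate <= avg$upper95))
})

test_that("a strong structural effect is detected with high power", {
  hits <- vapply(1:10, function(i) {
    tree <- simulate_tree(250, seed = 500 + i)
    sc <- builtin_scenario("case_to_flexible", n_tips = 250, effect_sizes = 2,
                           seed = 600 + i)
    traits <- simulate_dag_liabilities(tree, sc)[analysis_traits()]
    corr <- phylo_correlation_matrix(tree)
    ct <- test_claim(list(x = "case", y = "flexible", conditioning = character(0)),
                     traits, corr)
    ct$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
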