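test_that("simulated Yule trees are reproducible and unit height", {
  tr <- simulate_tree(2, seed = 1)
  expect_equal(ape::Ntip(tr), 2)
  expect_identical(write_newick(simulate_tree(50, seed = 3)),
                   write_newick(simulate_tree(50, seed = 3)))
  expect_false(identical(write_newick(simulate_tree(50, seed = 3)),
                         write_newick(simulate_tree(50, seed = 4))))
  depths <- ape::node.depth.edgelength(simulate_tree(50, seed = 3))[1:50]
  expect_equal(max(depths), 1, tolerance = 1e-12)
  expect_error(simulate_tree(1, seed = 1), "at least 2")
})

test_that("scenario construction validates its inputs", {
  dag <- candidate_models()$c
  expect_error(sim_scenario(dag, prevalences = c(case = 1.2, verb_final = .5,
                                                 flexible = .5)), "prevalences")
  expect_error(sim_scenario(dag, effect_sizes = c(`verb_final->case` = Inf,
                                                  `case->flexible` = 1)),
               "finite|cover")
  sc <- sim_scenario(dag, n_tips = 50, effect_sizes = 2, seed = 9)
  expect_equal(unname(sc$effect_sizes["verb_final->case"]), 2)
})

test_that("liability simulation honours prevalence and topology", {
  tree <- simulate_tree(200, seed = 11)
  sc <- builtin_scenario("model_c", n_tips = 200,
                         prevalences = c(case = 0.3, verb_final = 0.5,
                                         flexible = 0.4), seed = 12)
  traits <- simulate_dag_liabilities(tree, sc)
  expect_equal(sum(traits$case), round(0.3 * 200))
  expect_equal(sum(traits$flexible), round(0.4 * 200))
  # positive structural coupling shows up as positive association
  expect_gt(cor(traits$verb_final, traits$case), 0.1)
  expect_gt(cor(traits$case, traits$flexible), 0.1)
})

test_that("the empty DAG reduces to the threshold-Brownian simulator", {
  tree <- simulate_tree(100, seed = 21)
  sc <- builtin_scenario("null", n_tips = 100, seed = 22)
  traits <- simulate_dag_liabilities(tree, sc)
  for (v in analysis_traits()) {
    direct <- simulate_threshold_binary(tree, sc$prevalences[[v]],
                                        seed = phylocausal:::derive_seed(22, v))
    expect_identical(unname(direct), traits[[v]])
  }
})

test_that("raw-feature emission inverts feature derivation", {
  m <- tibble::tibble(taxon_id = "x", case = 1, verb_final = 1, flexible = 0)
  long <- emit_grambank_like(m, seed = 31)
  w <- tidyr::pivot_wider(long, names_from = feature_id, values_from = value)
  expect_equal(w$GB070, 1); expect_equal(w$GB133, 1)
  expect_equal(w$GB131, 0); expect_equal(w$GB132, 0); expect_equal(w$GB136, 1)

  big <- tibble::tibble(
    taxon_id = paste0("t", 1:1000),
    case = withr::with_seed(32, rbinom(1000, 1, 0.4)),
    verb_final = withr::with_seed(33, rbinom(1000, 1, 0.5)),
    flexible = withr::with_seed(34, rbinom(1000, 1, 0.3))
  )
  back <- derive_features(emit_grambank_like(big, seed = 35))
  expect_equal(back[order(back$taxon_id), ] |> as.data.frame(),
               big[order(big$taxon_id), ] |> as.data.frame())
  # non-verb-final rows carry exactly one non-final order
  w2 <- tidyr::pivot_wider(emit_grambank_like(big, seed = 36),
                           names_from = feature_id, values_from = value)
  nonfinal <- w2[w2$GB133 == 0, ]
  expect_true(all(nonfinal$GB131 + nonfinal$GB132 == 1))
  expect_error(emit_grambank_like(dplyr::mutate(m, case = NA), seed = 1),
               "complete")
})

test_that("spatial binary fields cluster in space and are seed-stable", {
  # two tight, far-apart clusters
  loc <- tibble::tibble(
    taxon_id = paste0("s", 1:40),
    latitude = c(rnorm(20, 0, 0.3), rnorm(20, 40, 0.3)),
    longitude = c(rnorm(20, 0, 0.3), rnorm(20, 90, 0.3))
  )
  within_minus_between <- vapply(1:25, function(i) {
    tr <- simulate_spatial_binary(loc, prevalence = 0.5, seed = 40 + i)
    g1 <- tr[1:20]; g2 <- tr[21:40]
    agree_within <- (mean(outer(g1, g1, "==")) + mean(outer(g2, g2, "=="))) / 2
    agree_between <- mean(outer(g1, g2, "=="))
    agree_within - agree_between
  }, numeric(1))
  expect_gt(mean(within_minus_between), 0.1)
  expect_identical(simulate_spatial_binary(loc, prevalence = 0.5, seed = 77),
                   simulate_spatial_binary(loc, prevalence = 0.5, seed = 77))
  # sigma2 -> 0: no spatial structure left
  flat <- vapply(1:25, function(i) {
    tr <- simulate_spatial_binary(loc, sigma2 = 1e-12, prevalence = 0.5,
                                  seed = 90 + i)
    g1 <- tr[1:20]; g2 <- tr[21:40]
    (mean(outer(g1, g1, "==")) + mean(outer(g2, g2, "=="))) / 2 -
      mean(outer(g1, g2, "=="))
  }, numeric(1))
  expect_lt(abs(mean(flat)), 0.1)
})

test_that("simulated coordinates are valid and deterministic", {
  loc <- simulate_coordinates(100, seed = 51)
  expect_equal(nrow(loc), 100)
  expect_true(all(abs(loc$latitude) <= 90))
  expect_true(all(abs(loc$longitude) <= 180))
  expect_identical(loc, simulate_coordinates(100, seed = 51))
})

test_that("simulate_dataset bundles aligned components", {
  sc <- builtin_scenario("model_c", n_tips = 60, seed = 61)
  ds <- simulate_dataset(sc)
  expect_equal(ds$tree$tip.label, ds$traits$taxon_id)
  expect_equal(ds$tree$tip.label, ds$locations$taxon_id)
  expect_setequal(unique(ds$long_table$feature_id),
                  c("GB070", "GB131", "GB132", "GB133", "GB136"))
})
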