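test_that("parse_newick handles minimal trees and round-trips", {
  tr <- parse_newick("(A:1.0,B:1.0);")
  expect_equal(ape::Ntip(tr), 2)
  expect_equal(unname(ape::node.depth.edgelength(tr)[1:2]), c(1, 1))

  tr3 <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(tr3), 3)
  expect_equal(tr3$Nnode, 2)
  C <- ape::vcv(tr3)
  expect_equal(C["A", "B"], 1)  # shared path from root

  # round trip preserves topology and branch lengths
  back <- parse_newick(write_newick(tr3))
  expect_true(ape::all.equal.phylo(back, tr3, use.edge.length = FALSE))
  expect_equal(sort(ape::node.depth.edgelength(back)),
               sort(ape::node.depth.edgelength(tr3)), tolerance = 1e-9)
})

test_that("parse_newick rejects malformed input", {
  expect_error(parse_newick("(A:1,B:1"), "unbalanced")
  expect_error(parse_newick("(A:1,A:1);"), "duplicate tip")
  expect_error(parse_newick("(A:-1,B:1);"), "negative branch length")
})

test_that("derive_features implements the three trait definitions", {
  tab <- tibble::tibble(
    taxon_id = c("l1", "l1", "l1", "l1", "l1",
                 "l2", "l2", "l2", "l2", "l2",
                 "l3", "l3", "l4"),
    feature_id = c("GB070", "GB131", "GB132", "GB133", "GB136",
                   "GB070", "GB131", "GB132", "GB133", "GB136",
                   "GB132", "GB136", "GB133"),
    value = c(1, 0, 0, 1, 1,
              0, 0, 1, 0, 0,
              1, 1, 1)
  )
  out <- derive_features(tab)
  l1 <- out[out$taxon_id == "l1", ]
  expect_equal(l1$case, 1)
  expect_equal(l1$verb_final, 1)   # GB133=1, GB131=GB132=0
  expect_equal(l1$flexible, 0)     # GB136=1 -> fixed order
  l2 <- out[out$taxon_id == "l2", ]
  expect_equal(l2$verb_final, 0)   # GB132=1
  expect_equal(l2$flexible, 1)
  l3 <- out[out$taxon_id == "l3", ]
  expect_true(is.na(l3$case))      # GB070 missing
  expect_equal(l3$verb_final, 0)
  l4 <- out[out$taxon_id == "l4", ]
  expect_true(is.na(l4$verb_final))  # GB133=1 but GB131/132 unknown
})

test_that("derive_features flags conflicts and unknown features", {
  tab <- tibble::tibble(
    taxon_id = c("x", "x", "x", "x"),
    feature_id = c("GB133", "GB131", "GB132", "GB999"),
    value = c(1, 1, 0, 1)
  )
  expect_warning(expect_warning(out <- derive_features(tab), "unknown feature"),
                 "verb-final alongside")
  expect_equal(out$verb_final, 0)
  out_na <- suppressWarnings(derive_features(tab, conflict = "na"))
  expect_true(is.na(out_na$verb_final))
})

test_that("derive_features is order-independent", {
  tab <- tibble::tibble(
    taxon_id = rep(c("a", "b"), each = 5),
    feature_id = rep(c("GB070", "GB131", "GB132", "GB133", "GB136"), 2),
    value = c(1, 0, 0, 1, 0, 0, 1, 0, 0, 1)
  )
  shuffled <- tab[withr::with_seed(1, sample(nrow(tab))), ]
  expect_equal(dplyr::arrange(derive_features(tab), taxon_id),
               dplyr::arrange(derive_features(shuffled), taxon_id))
})

test_that("trait and coordinate readers tolerate BOM, CRLF, ? and blanks", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste0("﻿taxon_id,feature_id,value\r\na,GB070,1\r\n",
                    "a,GB136,?\r\nb,GB070,\r\nb,GB136,0"), f, sep = "")
  tab <- read_trait_table(f)
  expect_equal(nrow(tab), 4)
  expect_true(is.na(tab$value[2]))
  expect_true(is.na(tab$value[3]))

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines("taxon_id,latitude,longitude\r\na,10,20\r\nb,-30,100", g, sep = "")
  geo <- read_geo_table(g)
  expect_equal(geo$latitude, c(10, -30))
  writeLines("taxon_id,latitude,longitude\na,95,20", g)
  expect_error(read_geo_table(g), "out of range")
})

test_that("align_tree_and_traits prunes to the complete sample", {
  tree <- parse_newick("((A:1,B:1):1,((C:1,D:1):0.5,E:1.5):0.5);")
  traits <- tibble::tibble(
    taxon_id = c("A", "B", "C", "D", "Z"),
    case = c(1, 0, 1, NA, 1),
    verb_final = c(1, 0, 0, 1, 1),
    flexible = c(0, 1, 1, 0, 0)
  )
  out <- suppressMessages(align_tree_and_traits(tree, traits))
  expect_equal(out$n, 3)
  expect_setequal(out$tree$tip.label, c("A", "B", "C"))
  expect_equal(out$traits$taxon_id, out$tree$tip.label)

  # all complete: topology untouched
  full <- tibble::tibble(taxon_id = tree$tip.label, case = 1,
                         verb_final = 0, flexible = rep(c(0, 1), c(2, 3)))
  out2 <- suppressMessages(align_tree_and_traits(tree, full))
  expect_equal(ape::Ntip(out2$tree), 5)
  expect_true(ape::all.equal.phylo(out2$tree, tree, use.edge.length = FALSE))

  bad <- dplyr::mutate(full, taxon_id = paste0("x", taxon_id))
  expect_error(suppressMessages(align_tree_and_traits(tree, bad)), "no taxa")
})

test_that("phylo_correlation_matrix gives shared-path correlations", {
  C2 <- phylo_correlation_matrix(cherry_tree())
  expect_equal(unname(C2), diag(2) * 1 + matrix(c(0, 0, 0, 0), 2), tolerance = 1e-12)

  C3 <- phylo_correlation_matrix(parse_newick("((A:1,B:1):1,C:2);"))
  expect_equal(C3["A", "B"], 0.5)
  expect_equal(C3["A", "C"], 0)
  expect_equal(diag(C3), setNames(rep(1, 3), c("A", "B", "C")))

  # star tree: identity
  expect_equal(unname(phylo_correlation_matrix(star_tree(6))), diag(6))

  # symmetry + PSD on a random tree
  Cr <- phylo_correlation_matrix(simulate_tree(40, seed = 4))
  expect_equal(Cr, t(Cr))
  expect_gt(min(eigen(Cr, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})
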