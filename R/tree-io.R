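#' Parse a Newick string into a validated phylogeny
#'
#' Thin, strict wrapper around [ape::read.tree()]: exactly one tree, balanced
#' parentheses, unique tip labels and non-negative branch lengths are enforced,
#' with errors naming the offending token.
#'
#' @param text A single Newick statement (with or without trailing newline).
#' @return An object of class `phylo`.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    abort(sprintf("unbalanced parentheses in Newick input (%d '(' vs %d ')')",
                  n_open, n_close))
  }
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    abort("could not parse Newick input")
  }
  validate_phylo(tree)
}

#' Validate the structural invariants of a phylogeny
#'
#' Checks for a single root, unique tip labels, non-negative branch lengths
#' and full traversability from the root.
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly usable, after validation.
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) abort("not a 'phylo' object")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate tip labels: %s", paste(unique(dup), collapse = ", ")))
  }
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (any(tree$edge.length < 0)) {
    bad <- which(tree$edge.length < 0)[1]
    abort(sprintf("negative branch length on edge %d (%.4g)",
                  bad, tree$edge.length[bad]))
  }
  # every non-root node must have exactly one parent; root none
  n_node <- ape::Ntip(tree) + tree$Nnode
  parents <- tabulate(tree$edge[, 2], nbins = n_node)
  root <- ape::Ntip(tree) + 1
  if (any(parents[-root] != 1) || parents[root] != 0) {
    abort("tree is not singly rooted / fully traversable")
  }
  tree
}

#' Write a phylogeny as a Newick string
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return A Newick string (no trailing newline).
#' @export
write_newick <- function(tree, digits = 10) {
  ape::write.tree(tree, digits = digits)
}

#' Rescale a tree to unit height
#'
#' Divides all branch lengths by the maximum root-to-tip depth so the deepest
#' tip sits at height 1. Used before building correlation matrices so that
#' regression and signal parameters are comparable across trees.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return The rescaled tree.
#' @export
scale_tree_height <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  h <- max(depths[seq_len(ape::Ntip(tree))])
  if (h <= 0) abort("tree has zero height")
  tree$edge.length <- tree$edge.length / h
  tree
}

#' Phylogenetic correlation matrix
#'
#' Entry (i, j) is the shared root-to-tip path length of tips i and j, scaled
#' so every diagonal entry is 1 (equivalently, the Brownian-motion correlation
#' implied by the tree). Symmetric and positive semi-definite.
#'
#' @param tree A `phylo` object aligned to the analysis sample.
#' @return A tip-by-tip correlation matrix with dimnames set to tip labels.
#' @export
#' @examples
#' C <- phylo_correlation_matrix(parse_newick("((A:1,B:1):1,C:2);"))
#' C["A", "B"]  # 0.5
phylo_correlation_matrix <- function(tree) {
  validate_phylo(tree)
  V <- ape::vcv(tree)
  if (any(diag(V) <= 0)) abort("tree has zero height above some tip")
  stats::cov2cor(V)
}

#' Resolve polytomies deterministically
#'
#' Multifurcations are expanded to binary nodes with zero-length internal
#' branches in left-to-right order, as required by sister-pair comparisons.
#'
#' @param tree A `phylo` object.
#' @return A binary tree.
#' @export
resolve_polytomies <- function(tree) {
  if (ape::is.binary.phylo(tree)) return(tree)
  ape::multi2di(tree, random = FALSE)
}

strip_bom <- function(x) sub("^﻿", "", x)

read_csv_plain <- function(path) {
  # base reader: tolerates CRLF natively; strip a UTF-8 BOM from the header
  raw <- readLines(path, warn = FALSE)
  raw[1] <- strip_bom(raw[1])
  utils::read.csv(text = paste(raw, collapse = "\n"), stringsAsFactors = FALSE,
                  na.strings = c("NA", "", "?"))
}

#' Read a long-format binary trait value table
#'
#' Expects a CSV with header `taxon_id,feature_id,value`; `?` and the empty
#' string parse to `NA`; CRLF line endings and a UTF-8 BOM are tolerated.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `taxon_id`, `feature_id`, `value` (0/1/NA).
#' @export
read_trait_table <- function(path) {
  df <- read_csv_plain(path)
  need <- c("taxon_id", "feature_id", "value")
  if (!all(need %in% names(df))) {
    abort(sprintf("trait table must have columns %s", paste(need, collapse = ", ")))
  }
  out <- tibble::as_tibble(df[need])
  out$value <- suppressWarnings(as.numeric(out$value))
  if (any(!is.na(out$value) & !out$value %in% c(0, 1))) {
    abort("trait values must be 0, 1 or NA")
  }
  if (anyDuplicated(out[c("taxon_id", "feature_id")])) {
    abort("duplicate (taxon_id, feature_id) pairs in trait table")
  }
  out
}

#' Read a coordinates table
#'
#' @param path CSV with header `taxon_id,latitude,longitude` (decimal degrees).
#' @return A tibble with one validated record per taxon.
#' @export
read_geo_table <- function(path) {
  df <- tibble::as_tibble(read_csv_plain(path))
  need <- c("taxon_id", "latitude", "longitude")
  if (!all(need %in% names(df))) {
    abort(sprintf("coordinates table must have columns %s",
                  paste(need, collapse = ", ")))
  }
  validate_geo(df[need])
}

validate_geo <- function(locations) {
  locations <- tibble::as_tibble(locations)
  if (anyDuplicated(locations$taxon_id)) abort("duplicate taxon_id in coordinates")
  if (any(is.na(locations$latitude)) || any(is.na(locations$longitude)) ||
      any(abs(locations$latitude) > 90) || any(abs(locations$longitude) > 180)) {
    abort("coordinates out of range: latitude in [-90, 90], longitude in [-180, 180]")
  }
  locations
}

#' Trait names used throughout the analysis
#' @export
analysis_traits <- function() c("case", "verb_final", "flexible")

grambank_features <- function() c("GB070", "GB131", "GB132", "GB133", "GB136")

#' Derive the three analysis traits from raw feature codes
#'
#' Builds the `case`, `verb_final` and `flexible` columns from the five raw
#' word-order/case features: `case` is GB070 directly; `verb_final` is 1 when
#' the unmarked transitive order is verb-final (GB133 = 1) and neither
#' verb-initial (GB131) nor verb-medial (GB132) order is also unmarked, 0 when
#' a non-final order is attested, NA otherwise; `flexible` is the negation of
#' fixed constituent order (1 - GB136). A language coded both verb-final and
#' verb-initial/medial is treated per `conflict`: not exclusively verb-final
#' (`"zero"`, default, with a warning) or missing (`"na"`).
#'
#' @param table Long tibble with columns `taxon_id`, `feature_id`, `value`.
#' @param conflict How to code GB133 = 1 together with GB131/GB132 = 1.
#' @return A tibble `taxon_id`, `case`, `verb_final`, `flexible` (0/1/NA).
#' @export
derive_features <- function(table, conflict = c("zero", "na")) {
  conflict <- match.arg(conflict)
  table <- tibble::as_tibble(table)
  unknown <- setdiff(unique(table$feature_id), grambank_features())
  if (length(unknown) > 0) {
    warn(sprintf("ignoring unknown feature ids: %s", paste(unknown, collapse = ", ")))
    table <- dplyr::filter(table, .data$feature_id %in% grambank_features())
  }
  wide <- tidyr::pivot_wider(table, id_cols = "taxon_id",
                             names_from = "feature_id", values_from = "value")
  for (f in grambank_features()) {
    if (!f %in% names(wide)) wide[[f]] <- NA_real_
  }

  vf <- rep(NA_real_, nrow(wide))
  gb131 <- wide$GB131; gb132 <- wide$GB132; gb133 <- wide$GB133
  nonfinal <- (!is.na(gb131) & gb131 == 1) | (!is.na(gb132) & gb132 == 1)
  vf[nonfinal] <- 0
  pure_final <- !is.na(gb133) & gb133 == 1 &
    !is.na(gb131) & gb131 == 0 & !is.na(gb132) & gb132 == 0
  vf[pure_final] <- 1
  clash <- !is.na(gb133) & gb133 == 1 & nonfinal
  if (any(clash)) {
    warn(sprintf("%d taxa coded verb-final alongside another unmarked order; coded %s",
                 sum(clash), if (conflict == "zero") "0" else "NA"))
    if (conflict == "na") vf[clash] <- NA_real_
  }

  tibble::tibble(
    taxon_id = wide$taxon_id,
    case = wide$GB070,
    verb_final = vf,
    flexible = 1 - wide$GB136
  )
}

#' Align a tree, a trait matrix and optional coordinates
#'
#' Restricts the analysis to taxa that (a) have complete, non-missing values
#' on all requested traits and (b) are present as tips in the tree, pruning
#' the tree accordingly and returning index-aligned outputs (data rows follow
#' the pruned tree's tip order).
#'
#' @param tree A `phylo` object.
#' @param traits Tibble with `taxon_id` plus trait columns.
#' @param locations Optional tibble `taxon_id`, `latitude`, `longitude`.
#' @param trait_names Traits that must be complete (default all three).
#' @return A list with elements `tree`, `traits`, `locations` (NULL if not
#'   supplied) and `n`.
#' @export
align_tree_and_traits <- function(tree, traits, locations = NULL,
                                  trait_names = analysis_traits()) {
  validate_phylo(tree)
  traits <- tibble::as_tibble(traits)
  missing_cols <- setdiff(trait_names, names(traits))
  if (length(missing_cols) > 0) {
    abort(sprintf("traits table lacks columns: %s", paste(missing_cols, collapse = ", ")))
  }
  complete <- traits$taxon_id[stats::complete.cases(traits[trait_names])]
  keep <- intersect(tree$tip.label, complete)
  if (!is.null(locations)) {
    locations <- validate_geo(locations)
    keep <- intersect(keep, locations$taxon_id)
  }
  if (length(keep) == 0) abort("no taxa shared between tree and complete trait data")
  pruned <- if (length(keep) < ape::Ntip(tree)) {
    ape::keep.tip(tree, keep)
  } else {
    tree
  }
  ord <- match(pruned$tip.label, traits$taxon_id)
  out_traits <- traits[ord, c("taxon_id", trait_names)]
  out_loc <- NULL
  if (!is.null(locations)) {
    out_loc <- locations[match(pruned$tip.label, locations$taxon_id), ]
  }
  inform(sprintf("aligned sample: %d taxa with complete %s",
                 length(keep), paste(trait_names, collapse = "/")))
  list(tree = pruned, traits = out_traits, locations = out_loc, n = length(keep))
}
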