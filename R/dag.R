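# Causal DAGs over trait names, their d-separation basis sets, and the
# built-in 12-model comparison set for the case / word-order system.

#' Construct a validated causal DAG
#'
#' @param edges Either a two-column data frame / tibble with columns `from`
#'   and `to`, or a character vector of `"cause -> effect"` strings. May be
#'   empty (use `vertices` to name the variables of an edgeless null model).
#' @param model_id Stable string identifier for the model.
#' @param vertices Optional vertex names; the union with edge endpoints is
#'   used. Defaults to the three analysis traits when no edges name others.
#' @return An object of class `causal_dag` with fields `vertices`, `edges`
#'   (tibble `from`, `to`) and `model_id`.
#' @export
#' @examples
#' make_dag(c("verb_final -> case", "case -> flexible"), "c")
make_dag <- function(edges = NULL, model_id = "model", vertices = NULL) {
  if (is.character(edges)) {
    parts <- strsplit(edges, "->", fixed = TRUE)
    if (any(lengths(parts) != 2)) abort("edge strings must look like 'cause -> effect'")
    edges <- tibble::tibble(from = trimws(vapply(parts, `[`, "", 1)),
                            to = trimws(vapply(parts, `[`, "", 2)))
  } else if (is.null(edges)) {
    edges <- tibble::tibble(from = character(), to = character())
  } else {
    edges <- tibble::as_tibble(edges)[c("from", "to")]
  }
  vertices <- sort(unique(c(vertices %||% character(), edges$from, edges$to)))
  if (length(vertices) == 0) vertices <- analysis_traits()
  if (any(edges$from == edges$to)) abort("self-loops are not allowed")
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate edge: %s", sub("\r", " -> ", key[duplicated(key)][1])))
  }
  dag <- structure(list(vertices = vertices, edges = edges, model_id = model_id),
                   class = "causal_dag")
  cyc <- find_cycle(dag)
  if (!is.null(cyc)) {
    abort(sprintf("edges contain a directed cycle: %s", paste(cyc, collapse = " -> ")))
  }
  dag
}

#' @export
print.causal_dag <- function(x, ...) {
  cat(sprintf("causal_dag '%s': %d vertices, %d edges\n",
              x$model_id, length(x$vertices), nrow(x$edges)))
  if (nrow(x$edges) > 0) {
    cat(paste0("  ", x$edges$from, " -> ", x$edges$to, collapse = "\n"), "\n")
  }
  invisible(x)
}

# Returns one directed cycle as a vertex sequence, or NULL if acyclic.
find_cycle <- function(dag) {
  adj <- split(dag$edges$to, factor(dag$edges$from, levels = dag$vertices))
  state <- setNames(rep(0L, length(dag$vertices)), dag$vertices)  # 0 new 1 open 2 done
  path <- character()
  cycle <- NULL
  visit <- function(v) {
    if (!is.null(cycle)) return()
    state[v] <<- 1L
    path <<- c(path, v)
    for (w in adj[[v]]) {
      if (!is.null(cycle)) return()
      if (state[w] == 1L) {
        cycle <<- c(path[which(path == w)[1]:length(path)], w)
        return()
      }
      if (state[w] == 0L) visit(w)
    }
    state[v] <<- 2L
    path <<- path[-length(path)]
  }
  for (v in dag$vertices) if (state[v] == 0L) visit(v)
  cycle
}

dag_parents <- function(dag, v) dag$edges$from[dag$edges$to == v]

dag_ancestors <- function(dag, v) {
  anc <- character()
  frontier <- v
  while (length(frontier) > 0) {
    pa <- unique(unlist(lapply(frontier, dag_parents, dag = dag)))
    pa <- setdiff(pa, anc)
    anc <- c(anc, pa)
    frontier <- pa
  }
  anc
}

dag_adjacent <- function(dag, u, v) {
  any(dag$edges$from == u & dag$edges$to == v) ||
    any(dag$edges$from == v & dag$edges$to == u)
}

#' Number of free parameters of a path model
#'
#' Convention: one parameter per vertex (intercept/variance) plus one per
#' causal path, q = |V| + |E|.
#'
#' @param dag A `causal_dag`.
#' @return Integer parameter count.
#' @export
dag_n_params <- function(dag) length(dag$vertices) + nrow(dag$edges)

#' d-separation basis set of a causal DAG
#'
#' One conditional-independence claim per non-adjacent vertex pair. The
#' designated response `y` is the member of the pair that is not a causal
#' ancestor of the other (when neither is, the lexicographically last vertex
#' is the response, so that the claim is tested by regressing the effect-side
#' variable on the cause-side one). The conditioning set is the union of both
#' vertices' parents, minus the pair itself.
#'
#' @param dag A `causal_dag`.
#' @return A tibble with columns `x`, `y`, `conditioning` (list column of
#'   character vectors) and `claim` (canonical label).
#' @export
#' @examples
#' basis_set(make_dag(c("A -> B", "B -> C"), "chain"))  # A _||_ C | B
basis_set <- function(dag) {
  V <- dag$vertices
  pairs <- utils::combn(V, 2, simplify = FALSE)
  claims <- purrr::map(pairs, function(p) {
    u <- p[1]; v <- p[2]
    if (dag_adjacent(dag, u, v)) return(NULL)
    if (u %in% dag_ancestors(dag, v)) {
      x <- u; y <- v
    } else if (v %in% dag_ancestors(dag, u)) {
      x <- v; y <- u
    } else {
      y <- max(u, v); x <- min(u, v)
    }
    cond <- sort(setdiff(union(dag_parents(dag, x), dag_parents(dag, y)), c(x, y)))
    tibble::tibble(
      x = x, y = y, conditioning = list(cond),
      claim = paste0(paste(sort(c(x, y)), collapse = " _||_ "), " | ",
                     if (length(cond) == 0) "{}" else paste(cond, collapse = ", "))
    )
  })
  out <- dplyr::bind_rows(claims)
  if (nrow(out) == 0) {
    out <- tibble::tibble(x = character(), y = character(),
                          conditioning = list(), claim = character())
  }
  out
}

#' The built-in 12-model set for case and word order
#'
#' Twelve causal DAGs over `case`, `verb_final` and `flexible`: four
#' single-edge models (`i`: verb_final -> case, the processing/noisy-channel
#' scenario; `j`: case -> flexible, the licensing scenario; `k` and `l` their
#' reversals) and eight two-edge models: the fork out of case (`b`), the
#' collider into case (`a`, both word-order features feeding case), and all
#' six mediation chains among the three variables (`c`, `d`, `e`, `f`, `g`,
#' `h`). Letters for topologies not pinned down by the published worked rows
#' (`b`, `c`, `d`, `i`–`l`) are a fixed, documented assignment; results should
#' be read by topology. Add `include_null = TRUE` to append the edgeless null.
#'
#' @param include_null Append the edgeless null model (default TRUE).
#' @return Named list of `causal_dag` objects.
#' @export
candidate_models <- function(include_null = TRUE) {
  spec <- list(
    a = c("verb_final -> case", "flexible -> case"),
    b = c("case -> flexible", "case -> verb_final"),
    c = c("verb_final -> case", "case -> flexible"),
    d = c("flexible -> case", "case -> verb_final"),
    e = c("case -> verb_final", "verb_final -> flexible"),
    f = c("flexible -> verb_final", "verb_final -> case"),
    g = c("case -> flexible", "flexible -> verb_final"),
    h = c("verb_final -> flexible", "flexible -> case"),
    i = "verb_final -> case",
    j = "case -> flexible",
    k = "case -> verb_final",
    l = "flexible -> case"
  )
  models <- purrr::imap(spec, function(edges, id) {
    make_dag(edges, model_id = id, vertices = analysis_traits())
  })
  if (include_null) {
    models$null <- make_dag(NULL, model_id = "null", vertices = analysis_traits())
  }
  models
}

#' Flag models whose basis sets coincide up to response designation
#'
#' Markov-equivalent models (same skeleton and v-structures) imply the same
#' unordered independence claims; they can still receive different C
#' statistics because the directed claim tests regress different responses.
#'
#' @param models Named list of `causal_dag` objects.
#' @return Tibble `model_id`, `claim_signature`, `equivalence_class`.
#' @export
flag_equivalent_models <- function(models) {
  sig <- vapply(models, function(m) {
    bs <- basis_set(m)
    paste(sort(bs$claim), collapse = " & ")
  }, character(1))
  tibble::tibble(
    model_id = names(models),
    claim_signature = unname(sig),
    equivalence_class = as.integer(factor(sig, levels = unique(sig)))
  )
}

#' Read / write DAG edge-list files
#'
#' Plain-text format: one `cause -> effect` per line; `#` starts a comment;
#' blank lines ignored. An optional `vertices:` line names isolated vertices.
#'
#' @param path File path.
#' @param model_id Identifier for the model read.
#' @return `read_dag_file`: a `causal_dag`.
#' @export
read_dag_file <- function(path, model_id = tools::file_path_sans_ext(basename(path))) {
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  vert_line <- grepl("^vertices:", lines)
  vertices <- NULL
  if (any(vert_line)) {
    vertices <- trimws(strsplit(sub("^vertices:", "", lines[vert_line][1]), ",")[[1]])
  }
  edge_lines <- lines[!vert_line]
  make_dag(if (length(edge_lines)) edge_lines else NULL, model_id, vertices)
}

#' @rdname read_dag_file
#' @param dag A `causal_dag` to serialize.
#' @export
write_dag_file <- function(dag, path) {
  lines <- c(
    sprintf("# model %s", dag$model_id),
    sprintf("vertices: %s", paste(dag$vertices, collapse = ", ")),
    if (nrow(dag$edges)) paste(dag$edges$from, "->", dag$edges$to)
  )
  writeLines(lines, path)
  invisible(path)
}
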