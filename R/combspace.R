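#' Enumerate the combinatorial space of migration graphs
#'
#' `CombMS(n)` collects all sphere-embedded multigraphs with `n` faces
#' (populations), up to homeomorphism of the sphere (including reflections),
#' stratified by depth: layer 0 is the cubic graphs, and layer `k` is reached
#' by `k` contraction moves.  Enumeration proceeds layer by layer: the cubic
#' layer is the Whitehead-move closure of the prism generator `CL_n` (of
#' `C_3` itself for `n = 3`, which is already cubic), and each deeper layer is
#' the set of all admissible single contractions of the previous one,
#' deduplicated by canonical code.  The deepest layer, at depth `2n - 6`,
#' contains the single two-vertex graph `C_n`.
#'
#' @param n Number of faces, `3 <= n <= 8` (the counts explode beyond that).
#' @param max_depth Deepest layer to compute (default all, `2n - 6`).
#' @return Object of class `combms`: list with `n` and `layers`, a list whose
#'   k-th entry (depth `k - 1`) is a named list of [combmap]s keyed by
#'   canonical code.
#' @export
enumerate_combms <- function(n, max_depth = 2 * n - 6) {
  if (n < 3 || n > 8) stop("size error: supported range is 3 <= n <= 8")
  seed <- if (n == 3) make_Cn(3) else make_CLn(n)
  layer0 <- whitehead_closure(seed)
  layers <- list(layer0)
  depth <- 0
  while (depth < max_depth) {
    nxt <- list()
    for (m in layers[[depth + 1]]) {
      for (e in map_edge_labels(m)) {
        child <- tryCatch(contract_edge(m, e), error = function(err) NULL)
        if (is.null(child)) next
        code <- canonical_code(child)
        if (is.null(nxt[[code]])) nxt[[code]] <- child
      }
    }
    if (!length(nxt)) break
    layers[[depth + 2]] <- nxt
    depth <- depth + 1
  }
  structure(list(n = n, layers = layers), class = "combms")
}

#' @export
print.combms <- function(x, ...) {
  cat("CombMS(", x$n, "): ", sum(lengths(x$layers)), " graphs in ",
      length(x$layers), " layers (", paste(lengths(x$layers), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# Breadth-first closure of a cubic map under Whitehead moves, deduplicated by
# (unlabelled) canonical code.
whitehead_closure <- function(seed) {
  out <- list()
  out[[canonical_code(seed)]] <- seed
  queue <- list(seed)
  while (length(queue)) {
    m <- queue[[1]]; queue <- queue[-1]
    for (e in map_edge_labels(m)) {
      child <- tryCatch(whitehead_move(m, e), error = function(err) NULL)
      if (is.null(child)) next
      code <- canonical_code(child)
      if (is.null(out[[code]])) {
        out[[code]] <- child
        queue[[length(queue) + 1]] <- child
      }
    }
  }
  out
}

# All maps reachable from `m` by expansion moves alone (any depth), as a set
# of canonical codes.  Used to probe whether expansions from C_n suffice to
# generate the whole space (they do not, in general).
expansion_closure <- function(m) {
  out <- list()
  out[[canonical_code(m)]] <- TRUE
  queue <- list(m)
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (v in seq_along(cur$vertices)) {
      cyc <- cur$vertices[[v]]
      k <- length(cyc)
      if (k < 4) next
      for (start in seq_len(k)) for (len in 2:(k - 2)) {
        arc <- cyc[((start - 1 + seq_len(len) - 1) %% k) + 1]
        child <- tryCatch(expand_vertex(cur, arc), error = function(err) NULL)
        if (is.null(child)) next
        code <- canonical_code(child)
        if (is.null(out[[code]])) {
          out[[code]] <- TRUE
          queue[[length(queue) + 1]] <- child
        }
      }
    }
  }
  names(out)
}
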