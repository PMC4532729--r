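#' Combinatorial maps (rotation systems) for sphere-embedded multigraphs
#'
#' A graph embedded in the sphere is encoded by its darts (half-edges):
#' `sigma` is the permutation sending each dart to the next dart
#' counterclockwise around its vertex, and `alpha` is the fixed-point-free
#' involution pairing the two darts of each edge.  Vertices are the orbits of
#' `sigma`, faces the orbits of `sigma(alpha(.))`.  The constructor enforces
#' the migration-graph invariants: no self-loops (the two darts of an edge lie
#' at different vertices), at least two vertices, connectedness, and the Euler
#' relation \eqn{V - E + F = 2} that characterises sphere embeddings.
#'
#' @param sigma Integer permutation (next dart CCW around the vertex).
#' @param alpha Integer fixed-point-free involution (dart pairing).
#' @param edge_label Optional integer vector of per-dart edge labels; both
#'   darts of an edge must share the label.  Defaults to edge index.
#' @return Object of class `combmap` with components `sigma`, `alpha`,
#'   `edge_label`, `vertices` (list of dart cycles), `faces` (list of dart
#'   cycles), and optionally `vertex_names` / `face_names`.
#' @export
combmap <- function(sigma, alpha, edge_label = NULL) {
  n <- length(sigma)
  stopifnot(length(alpha) == n, n >= 2, n %% 2 == 0)
  if (!all(sort(sigma) == seq_len(n))) stop("sigma is not a permutation")
  if (!all(alpha[alpha] == seq_len(n))) stop("alpha is not an involution")
  if (any(alpha == seq_len(n))) stop("alpha has fixed points")
  verts <- perm_orbits(sigma)
  vid <- orbit_index(verts, n)
  if (any(vid[alpha] == vid)) stop("self-loop: both darts of an edge at one vertex")
  if (length(verts) < 2) stop("a migration graph needs at least two vertices")
  # connectedness under <sigma, alpha>
  seen <- rep(FALSE, n); stack <- 1L; seen[1] <- TRUE
  while (length(stack)) {
    d <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (e in c(sigma[d], alpha[d])) if (!seen[e]) { seen[e] <- TRUE; stack <- c(stack, e) }
  }
  if (!all(seen)) stop("map is not connected")
  faces <- perm_orbits(sigma[alpha])
  V <- length(verts); E <- n / 2; F <- length(faces)
  if (V - E + F != 2)
    stop("Euler relation violated (V-E+F = ", V - E + F, "): not a sphere map")
  if (is.null(edge_label)) {
    edge_label <- integer(n)
    nxt <- 1L
    for (d in seq_len(n)) if (edge_label[d] == 0L) {
      edge_label[d] <- nxt; edge_label[alpha[d]] <- nxt; nxt <- nxt + 1L
    }
  } else {
    stopifnot(length(edge_label) == n, all(edge_label == edge_label[alpha]))
  }
  structure(list(sigma = sigma, alpha = alpha, edge_label = edge_label,
                 vertices = verts, faces = faces),
            class = "combmap")
}

perm_orbits <- function(p) {
  n <- length(p)
  seen <- rep(FALSE, n)
  out <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    cyc <- s; seen[s] <- TRUE; d <- p[s]
    while (d != s) { cyc <- c(cyc, d); seen[d] <- TRUE; d <- p[d] }
    out[[length(out) + 1]] <- cyc
  }
  out
}

orbit_index <- function(orbits, n) {
  idx <- integer(n)
  for (i in seq_along(orbits)) idx[orbits[[i]]] <- i
  idx
}

#' Vertex, edge and face counts of a map
#' @param m A [combmap].
#' @return Named integer vector `c(V = , E = , F = )`.
#' @export
map_counts <- function(m) {
  c(V = length(m$vertices), E = length(m$sigma) / 2L, F = length(m$faces))
}

#' @rdname map_counts
#' @export
map_degrees <- function(m) lengths(m$vertices)

#' @rdname map_counts
#' @export
is_cubic <- function(m) all(lengths(m$vertices) == 3L)

#' Depth of a map below the cubic layer
#'
#' A map with `n` faces and `E` edges sits `3n - 6 - E` contraction moves below
#' a cubic map; this number is independent of the contraction path.
#' @param m A [combmap].
#' @return Non-negative integer depth.
#' @export
map_depth <- function(m) {
  ct <- map_counts(m)
  as.integer(3 * ct["F"] - 6 - ct["E"])
}

#' Unique edge labels of a map
#' @param m A [combmap].
#' @export
map_edge_labels <- function(m) sort(unique(m$edge_label))

edge_darts <- function(m, label) {
  d <- which(m$edge_label == label)
  if (length(d) != 2) stop("no edge with label ", label)
  d
}

#' Build a map from per-vertex rotations of edge identifiers
#'
#' Convenience constructor: `rot` lists, for each vertex, the identifiers of
#' its incident edges in counterclockwise cyclic order; every identifier must
#' appear exactly twice overall (parallel edges are fine, self-loops are not).
#'
#' @param rot List of integer vectors (one per vertex).
#' @return A [combmap] whose `edge_label` is the given identifiers.
#' @export
combmap_from_rotations <- function(rot) {
  ids <- unlist(rot)
  tab <- table(ids)
  if (any(tab != 2)) stop("every edge id must appear exactly twice")
  nd <- length(ids)
  sigma <- integer(nd); lab <- integer(nd)
  dart <- 0L
  starts <- integer(length(rot))
  for (v in seq_along(rot)) {
    k <- length(rot[[v]])
    starts[v] <- dart + 1L
    sigma[dart + seq_len(k)] <- dart + c(seq_len(k)[-1], 1L)
    lab[dart + seq_len(k)] <- rot[[v]]
    dart <- dart + k
  }
  alpha <- integer(nd)
  for (id in unique(ids)) {
    pr <- which(lab == id)
    alpha[pr[1]] <- pr[2]; alpha[pr[2]] <- pr[1]
  }
  combmap(sigma, alpha, edge_label = lab)
}

#' The deepest migration graph: two vertices joined by n parallel edges
#'
#' `C_n` is the unique graph at the deepest layer of the combinatorial space:
#' two vertices, `n` parallel edges, `n` bigon faces.  It is the pattern of
#' `n` populations strung along a single great circle.
#'
#' @param n Number of edges (= populations/faces), `n >= 2`.
#' @return A [combmap].
#' @export
make_Cn <- function(n) {
  stopifnot(n >= 2)
  sigma <- c(seq_len(n)[-1], 1L,                      # a_i -> a_{i+1}
             n + c(n, seq_len(n - 1)))                # b_i -> b_{i-1}
  alpha <- c(n + seq_len(n), seq_len(n))
  combmap(sigma, alpha, edge_label = c(seq_len(n), seq_len(n)))
}

#' The prism generator of the cubic layer
#'
#' `CL_n` is the prism over an (n-2)-gon: two concentric copies of a regular
#' polygon with corresponding vertices joined by spokes.  It has `n` faces,
#' `2n - 4` vertices and `3n - 6` edges, all vertex degrees 3, and generates
#' the whole cubic layer under Whitehead moves.
#'
#' @param n Number of faces, `n >= 4`.
#' @return A [combmap].  Edge ids: `1..m` outer polygon, `m+1..2m` inner
#'   polygon, `2m+1..3m` spokes (`m = n - 2`).
#' @export
make_CLn <- function(n) {
  stopifnot(n >= 4)
  m <- n - 2L
  outer <- function(i) ((i - 1L) %% m) + 1L
  rot <- vector("list", 2L * m)
  for (i in seq_len(m)) {
    # outer vertex u_i: edges to u_{i+1}, u_{i-1}, spoke; inner v_i mirrored
    rot[[i]] <- c(outer(i), outer(i - 1L) , 2L * m + i)
    rot[[m + i]] <- c(2L * m + i, m + outer(i - 1L), m + outer(i))
  }
  mp <- combmap_from_rotations(rot)
  stopifnot(length(mp$faces) == n)
  mp
}

#' Contract an edge of a map
#'
#' Continuously shrinks edge `e` to a point, fusing its two endpoints while
#' preserving the cyclic order of all other edges.  `E` and `V` each drop by
#' one, faces are unchanged, and the depth rises by exactly one.  Contractions
#' that would collapse the last pair of vertices, or turn a parallel edge into
#' a self-loop, are refused.
#'
#' @param m A [combmap].
#' @param e Edge label to contract.
#' @return The contracted [combmap] (darts renumbered; labels preserved).
#' @export
contract_edge <- function(m, e) {
  d <- edge_darts(m, e)
  d1 <- d[1]; d2 <- d[2]
  vid <- orbit_index(m$vertices, length(m$sigma))
  if (vid[d1] == vid[d2]) stop("cannot contract: edge is a self-loop")
  if (length(m$vertices) <= 2)
    stop("minimality: contraction would leave a single vertex")
  v1 <- m$vertices[[vid[d1]]]; v2 <- m$vertices[[vid[d2]]]
  par <- setdiff(intersect(v1, m$alpha[v2]), d1)
  if (length(par))
    stop("cannot contract: parallel edge ", m$edge_label[par[1]],
         " would become a self-loop")
  run <- function(start, stop_at) {
    out <- integer(0); x <- start
    while (x != stop_at) { out <- c(out, x); x <- m$sigma[x] }
    out
  }
  merged <- c(run(m$sigma[d1], d1), run(m$sigma[d2], d2))
  sigma <- m$sigma
  k <- length(merged)
  sigma[merged] <- merged[c(seq_len(k)[-1], 1L)]
  keep <- setdiff(seq_along(sigma), c(d1, d2))
  new_id <- integer(length(sigma)); new_id[keep] <- seq_along(keep)
  out <- combmap(new_id[sigma[keep]], new_id[m$alpha[keep]],
                 edge_label = m$edge_label[keep])
  out <- propagate_face_names(m, out, keep)
  attr(out, "dart_map") <- keep
  out
}

# Carry per-face population names across a move.  `new_to_old` maps each dart
# of `new` to its dart in `old` (NA for created darts).  Every surviving dart
# keeps its face across contraction/expansion/Whitehead moves, so each new
# face is owned by the unique old face contributing most darts; a tie would
# indicate a genuinely ambiguous correspondence and raises an error.
propagate_face_names <- function(old, new, new_to_old) {
  if (is.null(old$face_names)) return(new)
  pf <- orbit_index(old$faces, length(old$sigma))
  nm <- vapply(new$faces, function(f) {
    olds <- new_to_old[f]
    olds <- olds[!is.na(olds)]
    tab <- table(pf[olds])
    win <- names(tab)[tab == max(tab)]
    if (length(win) != 1) stop("ambiguous face correspondence across move")
    old$face_names[as.integer(win)]
  }, "")
  if (anyDuplicated(nm)) stop("face tracking collapsed two faces")
  new$face_names <- nm
  new
}

#' Expand (split) a vertex along a contiguous arc
#'
#' Inverse of a contraction: splits a vertex of degree >= 4 into two vertices
#' joined by a new edge.  `arc` gives the darts kept on the first daughter
#' vertex; it must be a contiguous run of the vertex's rotation, of length
#' >= 2, with a complement of length >= 2 (so both new degrees are >= 3,
#' satisfying valence(P1) + valence(P2) = valence(P) + 2).
#'
#' @param m A [combmap].
#' @param arc Integer vector of darts, contiguous in rotation order.
#' @param new_label Label for the created edge (default: max label + 1).
#' @return The expanded [combmap] with two new darts appended.
#' @export
expand_vertex <- function(m, arc, new_label = NULL) {
  nd <- length(m$sigma)
  vid <- orbit_index(m$vertices, nd)
  if (length(unique(vid[arc])) != 1) stop("invalid split: darts span vertices")
  v <- m$vertices[[vid[arc[1]]]]
  if (length(v) < 4) stop("can only expand a vertex of degree >= 4")
  if (length(arc) < 2 || length(v) - length(arc) < 2)
    stop("invalid split: both arcs must have length >= 2")
  for (i in seq_len(length(arc) - 1))
    if (m$sigma[arc[i]] != arc[i + 1]) stop("invalid split: arc not contiguous")
  comp <- integer(0); x <- m$sigma[arc[length(arc)]]
  while (x != arc[1]) { comp <- c(comp, x); x <- m$sigma[x] }
  if (is.null(new_label)) new_label <- max(m$edge_label) + 1L
  e1 <- nd + 1L; e2 <- nd + 2L
  sigma <- c(m$sigma, 0L, 0L)
  sigma[arc[length(arc)]] <- e1; sigma[e1] <- arc[1]
  sigma[comp[length(comp)]] <- e2; sigma[e2] <- comp[1]
  alpha <- c(m$alpha, e2, e1)
  out <- combmap(sigma, alpha, edge_label = c(m$edge_label, new_label, new_label))
  propagate_face_names(m, out, c(seq_len(nd), NA, NA))
}

#' Whitehead move on an edge of a cubic map
#'
#' Contracts edge `e` (joining two distinct degree-3 vertices) to a transient
#' degree-4 vertex and immediately re-expands it the other way.  The result is
#' again cubic with identical vertex/edge/face counts; the re-created edge
#' keeps the label of `e`.  Dart identities of all other edges are preserved,
#' which lets callers track faces across the move.
#'
#' @param m A cubic [combmap].
#' @param e Edge label.
#' @return The transformed [combmap].
#' @export
whitehead_move <- function(m, e) {
  if (!is_cubic(m)) stop("Whitehead moves require a cubic map")
  d <- edge_darts(m, e)
  d1 <- d[1]; d2 <- d[2]
  vid <- orbit_index(m$vertices, length(m$sigma))
  if (vid[d1] == vid[d2]) stop("edge is a self-loop")
  p <- m$sigma[d1]; q <- m$sigma[p]
  r <- m$sigma[d2]; s <- m$sigma[r]
  sigma <- m$sigma
  # old corners (d1,p,q), (d2,r,s); new corners (d1,q,r)... i.e. the other
  # 2+2 split of the transient 4-valent vertex (p q r s)
  sigma[q] <- r; sigma[r] <- d1; sigma[d1] <- q
  sigma[s] <- p; sigma[p] <- d2; sigma[d2] <- s
  out <- tryCatch(combmap(sigma, m$alpha, edge_label = m$edge_label),
                  error = function(err)
                    stop("Whitehead move on edge ", e, " invalid: ",
                         conditionMessage(err)))
  if (!is.null(m$vertex_names)) out$vertex_names <- NULL  # vertices reshuffled
  propagate_face_names(m, out, seq_along(m$sigma))
}

#' Dual map
#'
#' Exchanges vertices and faces (mark a point in each face, join marked points
#' across each edge).  Edge labels are carried over and `dual(dual(m))` is the
#' identity on the encoding.
#'
#' @param m A [combmap].
#' @return The dual [combmap]; `vertex_names`/`face_names` are swapped.
#' @export
map_dual <- function(m) {
  dm <- combmap(m$sigma[m$alpha], m$alpha, edge_label = m$edge_label)
  nd <- length(m$sigma)
  if (!is.null(m$vertex_names)) {
    # primal vertex orbits become dual face orbits (same dart sets)
    pv <- orbit_index(m$vertices, nd)
    dm$face_names <- vapply(dm$faces, function(f) m$vertex_names[pv[f[1]]], "")
  }
  if (!is.null(m$face_names)) {
    pf <- orbit_index(m$faces, nd)
    dm$vertex_names <- vapply(dm$vertices, function(v) m$face_names[pf[v[1]]], "")
  }
  dm
}

#' Canonical code of a map, up to relabelling and reflection
#'
#' Computes a breadth-first encoding of `(sigma, alpha)` from every possible
#' starting dart in both orientations (orientation reversal uses the inverse
#' rotation, so mirror images receive the same code) and returns the
#' lexicographic minimum as a string.  Two maps are equivalent as sphere
#' embeddings if and only if their codes are equal.  With `labeled = TRUE` the
#' encoding additionally carries the absolute edge labels, so codes are equal
#' iff some homeomorphism matches the maps label-for-label.
#'
#' @param m A [combmap].
#' @param labeled Include edge labels in the code?
#' @param face_vals Optional numeric vector, one value per face (in
#'   `m$faces` order, e.g. total loads); included in the code so that maps
#'   equal only up to a permutation of face values receive different codes.
#' @return A character scalar.
#' @export
canonical_code <- function(m, labeled = FALSE, face_vals = NULL) {
  nd <- length(m$sigma)
  sig_inv <- integer(nd); sig_inv[m$sigma] <- seq_len(nd)
  fv <- NULL
  if (!is.null(face_vals)) {
    stopifnot(length(face_vals) == length(m$faces))
    fv <- signif(face_vals, 10)[orbit_index(m$faces, nd)]
  }
  best <- NULL
  for (orient in 1:2) {
    sg <- if (orient == 1) m$sigma else sig_inv
    for (root in seq_len(nd)) {
      lab <- integer(nd); lab[root] <- 1L
      ord <- integer(nd); ord[1] <- root
      cnt <- 1L; i <- 1L
      while (i <= cnt) {
        dd <- ord[i]
        for (nb in c(sg[dd], m$alpha[dd])) if (lab[nb] == 0L) {
          cnt <- cnt + 1L; lab[nb] <- cnt; ord[cnt] <- nb
        }
        i <- i + 1L
      }
      code <- c(lab[sg[ord]], lab[m$alpha[ord]])
      if (labeled) code <- c(code, m$edge_label[ord])
      if (!is.null(fv)) code <- c(code, fv[ord])
      if (is.null(best) || vec_less(code, best)) best <- code
    }
  }
  paste(best, collapse = ",")
}

vec_less <- function(a, b) {
  k <- which(a != b)
  length(k) > 0 && a[k[1]] < b[k[1]]
}

#' @export
print.combmap <- function(x, ...) {
  ct <- map_counts(x)
  cat("Combinatorial map: V =", ct["V"], " E =", ct["E"], " F =", ct["F"],
      if (is_cubic(x)) "(cubic)" else "", "\n")
  invisible(x)
}

#' Export the underlying multigraph as GraphML
#'
#' Writes vertices, edges (with labels) and, as a vertex attribute, the
#' rotation (the CCW cyclic order of incident edge labels) so that the
#' embedding survives the round trip through graph tools.
#'
#' @param m A [combmap].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(m, path) {
  nd <- length(m$sigma)
  vid <- orbit_index(m$vertices, nd)
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '<key id="rot" for="node" attr.name="rotation" attr.type="string"/>',
    '<key id="lab" for="edge" attr.name="label" attr.type="int"/>',
    '<graph edgedefault="undirected">')
  for (v in seq_along(m$vertices)) {
    rot <- paste(m$edge_label[m$vertices[[v]]], collapse = " ")
    lines <- c(lines, sprintf('<node id="n%d"><data key="rot">%s</data></node>',
                              v, rot))
  }
  for (e in map_edge_labels(m)) {
    d <- edge_darts(m, e)
    lines <- c(lines,
      sprintf('<edge source="n%d" target="n%d"><data key="lab">%d</data></edge>',
              vid[d[1]], vid[d[2]], e))
  }
  lines <- c(lines, "</graph>", "</graphml>")
  writeLines(lines, path)
  invisible(path)
}
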