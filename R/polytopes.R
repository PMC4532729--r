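#' H-polytope: equality rows, optional >= rows, and box bounds
#'
#' The open migration-pattern space (strict inequalities `0 < x < 1`) is
#' represented by its closure plus an interior-point query, mirroring the
#' relaxation of `<` to `<=` that turns the linear system into a polytope.
#'
#' @param vars Ordered variable (edge-label) identifiers.
#' @param Aeq,beq Equality rows `Aeq x = beq`.
#' @param lo,hi Per-variable closed bounds.
#' @param Age,bge Optional inequality rows `Age x >= bge`.
#' @param face_names Optional names of the populations behind the equality
#'   rows.
#' @return Object of class `hpolytope`.
#' @export
hpolytope <- function(vars, Aeq, beq, lo, hi, Age = NULL, bge = NULL,
                      face_names = NULL) {
  m <- length(vars)
  Aeq <- as.matrix(Aeq)
  stopifnot(ncol(Aeq) == m, nrow(Aeq) == length(beq),
            length(lo) == m, length(hi) == m)
  if (!is.null(Age)) { Age <- as.matrix(Age); stopifnot(ncol(Age) == m, nrow(Age) == length(bge)) }
  structure(list(vars = vars, Aeq = Aeq, beq = beq, lo = lo, hi = hi,
                 Age = Age, bge = bge, face_names = face_names),
            class = "hpolytope")
}

#' @export
print.hpolytope <- function(x, ...) {
  cat("H-polytope:", length(x$vars), "variables,", nrow(x$Aeq), "equalities,",
      if (is.null(x$Age)) 0 else nrow(x$Age), "inequality rows\n")
  invisible(x)
}

face_incidence <- function(map) {
  labs <- map_edge_labels(map)
  A <- matrix(0, length(map$faces), length(labs),
              dimnames = list(NULL, as.character(labs)))
  for (f in seq_along(map$faces)) {
    tl <- table(map$edge_label[map$faces[[f]]])
    if (any(tl > 1))
      stop("face boundary traverses an edge twice (bridge); unsupported")
    A[f, names(tl)] <- 1
  }
  stopifnot(all(colSums(A) == 2))  # each edge borders exactly two faces
  A
}

#' Load system L(G, T) of a migration graph
#'
#' One variable per edge, bounded to `[0, 1]` (the closed relaxation of the
#' open gene-flow domain), and one equality per population: the incident edge
#' variables must sum to the population's total load `T_i`.
#'
#' @param map A [combmap] whose faces correspond to populations (e.g. the
#'   Voronoi map of a pattern).
#' @param T Total loads: named by population when the map carries
#'   `face_names`, otherwise positional over `map$faces` (a scalar is
#'   recycled).
#' @return An [hpolytope].  If some `T_i` exceeds the face degree the system
#'   is trivially infeasible and the returned object carries attribute
#'   `flagged_infeasible = TRUE`.
#' @export
build_load_system <- function(map, T) {
  A <- face_incidence(map)
  nf <- nrow(A)
  fn <- map$face_names
  if (length(T) == 1) T <- rep(T, nf)
  if (!is.null(fn) && !is.null(names(T))) {
    if (!setequal(names(T), fn)) stop("names(T) do not match the map's faces")
    T <- T[fn]
  } else if (length(T) != nf) stop("T must give one load per face")
  if (any(T <= 0)) stop("total loads must be positive")
  P <- hpolytope(vars = as.integer(colnames(A)), Aeq = A, beq = as.numeric(T),
                 lo = rep(0, ncol(A)), hi = rep(1, ncol(A)),
                 face_names = fn)
  if (any(T > rowSums(A))) {
    warning("some T_i exceeds its face degree: system trivially infeasible")
    attr(P, "flagged_infeasible") <- TRUE
  }
  P
}

#' Angle system (circle-pattern conditions) of a migration graph
#'
#' Variables are the inner angles, bounded to `[0, pi]`; the face condition
#' gives one equality `sum(theta) = 2*pi` per population (face of the Voronoi
#' graph), and every non-facial simple cycle of the Voronoi graph up to
#' `max_cycle_len` contributes an inequality `sum(theta) >= 2*pi` (the closure
#' of the strict condition).  Truncating the exponentially many cycles makes
#' this an outer approximation of the full circle-pattern polytope.
#'
#' @param map The Voronoi [combmap] (faces = populations).
#' @param max_cycle_len Cycle cap for the inequality rows.
#' @return An [hpolytope].
#' @export
build_angle_system <- function(map, max_cycle_len = 8) {
  A <- face_incidence(map)
  cyc <- map_simple_cycles(map, max_cycle_len, exclude_facial = TRUE)
  Age <- NULL; bge <- NULL
  if (length(cyc)) {
    Age <- matrix(0, length(cyc), ncol(A),
                  dimnames = list(NULL, colnames(A)))
    for (k in seq_along(cyc))
      Age[k, as.character(cyc[[k]]$labels)] <- 1
    bge <- rep(2 * pi, length(cyc))
  }
  hpolytope(vars = as.integer(colnames(A)), Aeq = A,
            beq = rep(2 * pi, nrow(A)),
            lo = rep(0, ncol(A)), hi = rep(pi, ncol(A)),
            Age = Age, bge = bge, face_names = map$face_names)
}

#' Feasibility of an H-polytope
#'
#' Linear-programming feasibility on the closed system.
#' @param P An [hpolytope].
#' @return List with `feasible` (logical) and `witness` (a feasible point, or
#'   `NULL`).
#' @export
is_feasible <- function(P) {
  r <- solve_lp(rep(0, length(P$vars)), P$Aeq, P$beq, P$Age, P$bge,
                P$lo, P$hi)
  list(feasible = r$status == "optimal", witness = r$x)
}

#' Max-slack (Chebyshev-style) interior point
#'
#' Maximises the minimum slack of all box bounds within the
#' equality-constrained affine subspace: the solution of
#' `max s : Aeq x = beq, lo + s <= x <= hi - s` (any `>=` rows are kept as
#' hard constraints).  Returns `NULL` when the relative interior with respect
#' to the bounds is empty, i.e. every solution pins some variable to its
#' bound -- exactly the situation where no *open* migration pattern exists.
#'
#' @param P An [hpolytope].
#' @param tol Slack below which the interior is declared empty.
#' @return List with `point` and `slack`, or `NULL`.
#' @export
interior_point <- function(P, tol = 1e-9) {
  m <- length(P$vars)
  smax <- max(P$hi - P$lo) / 2
  if (smax <= 0) return(NULL)
  Aeq2 <- cbind(P$Aeq, numeric(nrow(P$Aeq)))
  Age2 <- rbind(if (!is.null(P$Age)) cbind(P$Age, 0),
                cbind(diag(m), -1),       #  x - s >= lo
                cbind(-diag(m), -1))      # -x - s >= -hi
  bge2 <- c(P$bge, P$lo, -P$hi)
  r <- solve_lp(c(rep(0, m), 1), Aeq2, P$beq, Age2, bge2,
                lo = c(P$lo, 0), hi = c(P$hi, smax), maximize = TRUE)
  if (r$status != "optimal") return(NULL)
  s <- r$x[m + 1]
  if (s <= tol) return(NULL)
  list(point = r$x[seq_len(m)], slack = s)
}

#' Enumerate the vertices of a small equality+box polytope
#'
#' Brute force over active-bound subsets: with `d` the dimension of the
#' null space of the equality matrix, every vertex pins at least `d`
#' variables to a bound; all `choose(m, d) * 2^d` such pinnings are solved
#' and the feasible, consistent solutions kept (deduplicated to `tol`).
#'
#' @param P An [hpolytope] without inequality rows; at most 24 variables.
#' @param tol Feasibility/deduplication tolerance.
#' @return Matrix with one vertex per row (columns = `P$vars`).
#' @export
enumerate_vertices <- function(P, tol = 1e-9) {
  if (!is.null(P$Age)) stop("vertex enumeration supports equality+box systems only")
  m <- length(P$vars)
  if (m > 24) stop("size error: more than 24 variables")
  qa <- qr(P$Aeq)
  d <- m - qa$rank
  if (d > 0 && choose(m, d) * 2^d > 2e6) stop("size error: too many active sets")
  sols <- list()
  try_sol <- function(x) {
    if (any(x < P$lo - 1e-7) || any(x > P$hi + 1e-7)) return()
    if (nrow(P$Aeq) && max(abs(P$Aeq %*% x - P$beq)) > 1e-7) return()
    sols[[length(sols) + 1]] <<- pmin(pmax(x, P$lo), P$hi)
  }
  solve_fixed <- function(fixed_idx, fixed_val) {
    free <- setdiff(seq_len(m), fixed_idx)
    x <- numeric(m); x[fixed_idx] <- fixed_val
    if (length(free)) {
      Af <- P$Aeq[, free, drop = FALSE]
      qf <- qr(Af)
      if (qf$rank < length(free)) return()
      rhs <- P$beq - P$Aeq[, fixed_idx, drop = FALSE] %*% fixed_val
      xf <- qr.coef(qf, rhs)
      if (anyNA(xf)) return()
      if (max(abs(Af %*% xf - rhs)) > 1e-8) return()   # inconsistent pinning
      x[free] <- xf
    }
    try_sol(x)
  }
  if (d == 0) solve_fixed(integer(0), numeric(0))
  else {
    subsets <- utils::combn(m, d)
    grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), d)))
    for (ci in seq_len(ncol(subsets))) {
      S <- subsets[, ci]
      for (g in seq_len(nrow(grid)))
        solve_fixed(S, ifelse(grid[g, ], P$hi[S], P$lo[S]))
    }
  }
  if (!length(sols)) return(matrix(numeric(0), 0, m,
                                   dimnames = list(NULL, P$vars)))
  V <- do.call(rbind, sols)
  keys <- apply(round(V / max(tol, 1e-12)) * tol, 1, paste, collapse = ",")
  V <- V[!duplicated(keys), , drop = FALSE]
  colnames(V) <- P$vars
  V
}

#' Contraction facet x_e = 0
#'
#' Fixing the variable of edge `e` to zero yields the facet shared with the
#' polytope of the contracted graph: any solution of the contracted system is
#' a solution of the original with `x_e = 0` and vice versa.
#'
#' @param P An [hpolytope].
#' @param e Variable (edge label) to pin.
#' @return The restricted [hpolytope].
#' @export
contraction_facet <- function(P, e) {
  k <- match(e, P$vars)
  if (is.na(k)) stop("no variable ", e)
  P$lo[k] <- 0; P$hi[k] <- 0
  P
}

#' Build the polytope complex of labelled cubic graphs
#'
#' Starting from a labelled cubic seed map, performs all possible Whitehead
#' moves breadth-first, inheriting edge labels through each move (the pivot
#' edge keeps its label on the re-expanded edge) and tracking which population
#' sits behind each face.  Each distinct labelled map receives its load
#' polytope; every move edge records the pivot label and the canonical code of
#' the shared contracted graph, whose system is the common facet `x_e = 0`.
#'
#' @param seed A cubic [combmap] with an edge labelling (its `edge_label`).
#' @param T Total loads (scalar recycled, or named by `seed$face_names`).
#' @param n_cap Refuse face counts above this (the labelled complex grows
#'   factorially).
#' @param max_nodes Safety cap on the breadth-first closure.
#' @return Object of class `polytope_complex`: `nodes` (list of
#'   `list(map, polytope, code)`) and `moves` (data frame `from`, `to`,
#'   `pivot`, `shared_code`).
#' @export
build_complex <- function(seed, T = 1, n_cap = 6, max_nodes = 5000) {
  if (!is_cubic(seed)) stop("seed map must be cubic")
  nf <- length(seed$faces)
  if (nf > n_cap) stop("face count ", nf, " above n_cap")
  if (is.null(seed$face_names))
    seed$face_names <- paste0("F", seq_len(nf))
  if (length(T) == 1) T <- stats::setNames(rep(T, nf), seed$face_names)
  if (!setequal(names(T), seed$face_names)) stop("names(T) must match faces")
  key_of <- function(m) canonical_code(m, labeled = TRUE,
                                       face_vals = unname(T[m$face_names]))
  nodes <- list(list(map = seed, polytope = build_load_system(seed, T),
                     code = key_of(seed)))
  seen <- stats::setNames(1L, nodes[[1]]$code)
  moves <- data.frame(from = integer(0), to = integer(0), pivot = integer(0),
                      shared_code = character(0), stringsAsFactors = FALSE)
  queue <- 1L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    m <- nodes[[i]]$map
    for (e in map_edge_labels(m)) {
      child <- tryCatch(whitehead_move(m, e), error = function(err) NULL)
      if (is.null(child)) next
      k <- key_of(child)
      j <- seen[k]
      if (is.na(j)) {
        if (length(nodes) >= max_nodes) stop("complex exceeds max_nodes")
        nodes[[length(nodes) + 1]] <- list(
          map = child, polytope = build_load_system(child, T), code = k)
        j <- length(nodes)
        seen[k] <- j
        queue <- c(queue, j)
      }
      a <- min(i, j); b <- max(i, j)
      if (!any(moves$from == a & moves$to == b & moves$pivot == e)) {
        shared <- contract_edge(m, e)
        moves <- rbind(moves, data.frame(
          from = a, to = b, pivot = e,
          shared_code = canonical_code(shared, labeled = TRUE,
                                       face_vals = unname(T[shared$face_names])),
          stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(nodes = nodes, moves = moves, T = T),
            class = "polytope_complex")
}

#' @export
print.polytope_complex <- function(x, ...) {
  cat("Polytope complex:", length(x$nodes), "labelled cubic maps,",
      nrow(x$moves), "Whitehead moves\n")
  invisible(x)
}
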