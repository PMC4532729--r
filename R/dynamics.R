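#' Split a population into two daughters
#'
#' Replaces population `population` by two points placed symmetrically at
#' angular distance `epsilon/2` on either side along the great circle with the
#' given compass bearing (so their spherical midpoint is the ancestor, making
#' [merge_populations] an exact inverse).  For generic small `epsilon` the
#' Delaunay complex changes locally: one extra vertex, three extra edges, two
#' extra triangles — the rhomboid insertion produced by the perpendicular
#' bisector of the daughter segment.
#'
#' @param populations Data frame (`name`, `longitude_deg`, `latitude_deg`).
#' @param population Name of the population to split.
#' @param epsilon Angular separation of the daughters, radians; must be
#'   positive and should be well below the distance to the nearest other
#'   population (a warning is issued otherwise).
#' @param bearing_deg Azimuth of the daughter axis, degrees clockwise from
#'   north.
#' @param weights Optional edge-weight table (`pop_a`, `pop_b`, `weight`)
#'   covering the pre-split Delaunay edges.  When given, a post-split table
#'   is returned: weights of surviving edges are kept, each daughter inherits
#'   the weight of every ancestral edge it retains, and genuinely new edges
#'   (including the daughter-daughter edge) receive
#'   `new_edge_weight` — by default half the smallest weight incident to the
#'   ancestor.  This inheritance rule is an extrapolation, not part of the
#'   theory; it is exposed so callers can substitute their own model.
#' @param new_edge_weight Weight for edges with no ancestral counterpart.
#' @return List with `populations` (new table; daughters named
#'   `<name>_l`, `<name>_r`), `diff` (see [complex_diff]), the
#'   triangulations `before`/`after`, and (when requested) `weights`.
#' @export
split_population <- function(populations, population, epsilon,
                             bearing_deg = 0, weights = NULL,
                             new_edge_weight = NULL) {
  i <- match(population, populations$name)
  if (is.na(i)) stop("unknown population ", population)
  if (epsilon <= 0) stop("epsilon must be positive")
  p <- latlon_to_unit(populations$longitude_deg[i], populations$latitude_deg[i])
  others <- populations[-i, ]
  dmin <- min(vapply(seq_len(nrow(others)), function(k)
    angular_distance(p, latlon_to_unit(others$longitude_deg[k],
                                       others$latitude_deg[k])), numeric(1)))
  if (epsilon >= dmin)
    warning("epsilon (", epsilon, ") not small relative to nearest neighbour (",
            signif(dmin, 3), "): split may exceed the local pattern")
  b <- bearing_deg * pi / 180
  east <- cross3(c(0, 0, 1), p); east <- east / sqrt(sum(east^2))
  north <- cross3(p, east)
  dir <- cos(b) * north + sin(b) * east
  d1 <- cos(epsilon / 2) * p + sin(epsilon / 2) * dir
  d2 <- cos(epsilon / 2) * p - sin(epsilon / 2) * dir
  new <- populations[-i, , drop = FALSE]
  for (k in 1:2) {
    ll <- unit_to_latlon(if (k == 1) d1 else d2)
    new <- rbind(new, data.frame(name = paste0(population, c("_l", "_r")[k]),
                                 longitude_deg = ll[1], latitude_deg = ll[2]))
  }
  rownames(new) <- NULL
  before <- delaunay_triangulate(populations)
  after <- delaunay_triangulate(new)
  out <- list(populations = new, diff = complex_diff(before, after),
              before = before, after = after)
  if (!is.null(weights)) {
    wkey <- stats::setNames(weights$weight,
                            paste(pmin(weights$pop_a, weights$pop_b),
                                  pmax(weights$pop_a, weights$pop_b), sep = "~"))
    inc <- weights$weight[weights$pop_a == population |
                            weights$pop_b == population]
    if (is.null(new_edge_weight)) new_edge_weight <- 0.5 * min(inc)
    strip <- function(x) ifelse(x %in% paste0(population, c("_l", "_r")),
                                population, x)
    ed <- after$edges
    anc <- paste(pmin(strip(ed$pop_a), strip(ed$pop_b)),
                 pmax(strip(ed$pop_a), strip(ed$pop_b)), sep = "~")
    w <- unname(wkey[anc])               # daughter inherits ancestral weight
    w[is.na(w)] <- new_edge_weight       # daughter-daughter and novel edges
    out$weights <- data.frame(pop_a = ed$pop_a, pop_b = ed$pop_b, weight = w,
                              stringsAsFactors = FALSE)
  }
  out
}

#' Merge two Delaunay-adjacent populations
#'
#' The reverse of a split: the pair is replaced by its spherical midpoint.
#' Daughters named `<stem>_l` / `<stem>_r` merge back to `<stem>`; any other
#' pair merges to `<a>+<b>`.
#'
#' @param populations Data frame of populations.
#' @param a,b Names of the populations to merge; they must be joined by a
#'   Delaunay edge.
#' @return List with `populations`, `diff`, `before`, `after`.
#' @export
merge_populations <- function(populations, a, b) {
  before <- delaunay_triangulate(populations)
  ed <- before$edges
  nm <- sort(c(a, b))
  if (!any(ed$pop_a == nm[1] & ed$pop_b == nm[2]))
    stop("populations ", a, " and ", b, " are not Delaunay-adjacent")
  ia <- match(a, populations$name); ib <- match(b, populations$name)
  pa <- latlon_to_unit(populations$longitude_deg[ia], populations$latitude_deg[ia])
  pb <- latlon_to_unit(populations$longitude_deg[ib], populations$latitude_deg[ib])
  mid <- pa + pb; mid <- mid / sqrt(sum(mid^2))
  stem_a <- sub("_[lr]$", "", a); stem_b <- sub("_[lr]$", "", b)
  name <- if (stem_a == stem_b && grepl("_[lr]$", a) && grepl("_[lr]$", b))
    stem_a else paste0(a, "+", b)
  new <- populations[-c(ia, ib), , drop = FALSE]
  ll <- unit_to_latlon(mid)
  new <- rbind(new, data.frame(name = name, longitude_deg = ll[1],
                               latitude_deg = ll[2]))
  rownames(new) <- NULL
  after <- delaunay_triangulate(new)
  list(populations = new, diff = complex_diff(before, after),
       before = before, after = after)
}

#' Structural difference between two Delaunay complexes
#'
#' @param before,after `delaunay_complex` objects.
#' @return List with the vertex/edge/triangle count deltas and the added and
#'   removed edges (as `pop_a~pop_b` keys).
#' @export
complex_diff <- function(before, after) {
  key <- function(cx) paste(cx$edges$pop_a, cx$edges$pop_b, sep = "~")
  kb <- key(before); ka <- key(after)
  list(vertices_delta = nrow(after$points) - nrow(before$points),
       edges_delta = nrow(after$edges) - nrow(before$edges),
       triangles_delta = nrow(after$triangles) - nrow(before$triangles),
       new_edges = setdiff(ka, kb),
       lost_edges = setdiff(kb, ka))
}

as_pattern_map <- function(x) {
  if (inherits(x, "migration_pattern")) x$graph
  else if (inherits(x, "combmap")) x
  else stop("expected a migration_pattern or combmap")
}

#' Classify the transition between two consecutive patterns
#'
#' Compares the embedded migration graphs of two snapshots and names the
#' single move relating them: `none` (equivalent maps), `whitehead` (both
#' cubic, related by one move; the pivot edge is identified by exhaustive
#' search), `contraction`/`expansion` (edge counts differ by one, same
#' population count), `split`/`merge` (population count differs by one), or
#' `unclassified`.
#'
#' @param pattern_a,pattern_b `migration_pattern`s (or bare [combmap]s).
#' @return List with `kind` and, for Whitehead moves, the `pivot` edge label.
#' @export
classify_transition <- function(pattern_a, pattern_b) {
  ma <- as_pattern_map(pattern_a); mb <- as_pattern_map(pattern_b)
  ca <- map_counts(ma); cb <- map_counts(mb)
  if (cb["F"] - ca["F"] == 1) return(list(kind = "split", pivot = NA))
  if (ca["F"] - cb["F"] == 1) return(list(kind = "merge", pivot = NA))
  if (ca["F"] != cb["F"]) return(list(kind = "unclassified", pivot = NA))
  code_b <- canonical_code(mb)
  if (canonical_code(ma) == code_b) return(list(kind = "none", pivot = NA))
  if (ca["E"] == cb["E"] && is_cubic(ma) && is_cubic(mb)) {
    for (e in map_edge_labels(ma)) {
      w <- tryCatch(whitehead_move(ma, e), error = function(err) NULL)
      if (!is.null(w) && canonical_code(w) == code_b)
        return(list(kind = "whitehead", pivot = e))
    }
  }
  if (ca["E"] - cb["E"] == 1) {
    for (e in map_edge_labels(ma)) {
      ct <- tryCatch(contract_edge(ma, e), error = function(err) NULL)
      if (!is.null(ct) && canonical_code(ct) == code_b)
        return(list(kind = "contraction", pivot = e))
    }
  }
  if (cb["E"] - ca["E"] == 1) {
    rev <- classify_transition(mb, ma)
    if (rev$kind == "contraction")
      return(list(kind = "expansion", pivot = rev$pivot))
  }
  list(kind = "unclassified", pivot = NA)
}

#' Detect facet crossings along a within-graph weight path
#'
#' Within a period where the migration graph is fixed, the weight vector
#' traces a curve inside the graph's load polytope; the graph can only change
#' when that curve reaches a face.  Given sampled states (piecewise-linear
#' interpolation between them), reports every time a weight coordinate
#' reaches 0 or 1 — a contraction-eligible event.
#'
#' @param pattern The segment's `migration_pattern` (fixed graph and loads).
#' @param times Strictly increasing numeric vector.
#' @param W Matrix of weight vectors, one row per time, columns named by edge
#'   label.
#' @param tol Consistency tolerance: every row must satisfy the segment's
#'   load equalities to `tol`, else an inconsistent-path error is raised
#'   (the total flow at each population is constant within a segment).
#' @return Data frame `time`, `label`, `boundary` (0 or 1).
#' @export
detect_facet_crossing <- function(pattern, times, W, tol = 1e-6) {
  stopifnot(length(times) == nrow(W), all(diff(times) > 0))
  ed <- pattern$edges
  W <- W[, as.character(ed$label), drop = FALSE]
  for (r in seq_len(nrow(W))) {
    loads_r <- tapply(c(W[r, ], W[r, ]), c(ed$pop_a, ed$pop_b), sum)
    if (max(abs(loads_r[names(pattern$loads)] - pattern$loads)) > tol)
      stop("inconsistent path: state ", r, " violates the segment's loads")
  }
  ev <- data.frame(time = numeric(0), label = integer(0), boundary = numeric(0))
  for (r in seq_len(nrow(W) - 1)) {
    w0 <- W[r, ]; w1 <- W[r + 1, ]
    for (j in seq_along(w0)) for (bdy in c(0, 1)) {
      a <- w0[j] - bdy; b <- w1[j] - bdy
      hit <- if (abs(a) <= tol) 0 else if (a * b < 0) a / (a - b) else NA
      if (!is.na(hit))
        ev <- rbind(ev, data.frame(
          time = times[r] + hit * (times[r + 1] - times[r]),
          label = ed$label[j], boundary = bdy))
    }
  }
  unique(ev)
}
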