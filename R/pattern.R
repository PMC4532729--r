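#' Read a populations table
#'
#' CSV with header `name,longitude_deg,latitude_deg` (UTF-8, decimal point).
#' @param path File path.
#' @return Data frame with those three columns.
#' @export
read_populations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("name", "longitude_deg", "latitude_deg")
  if (!all(need %in% names(df)))
    stop("populations CSV must have columns ", paste(need, collapse = ", "))
  df$name <- as.character(df$name)
  df
}

#' Read an edge-weight table
#'
#' CSV with header `pop_a,pop_b,weight`; an optional `label` column fixes the
#' integer edge labels (it must then be a bijection onto `1..E`).
#' @param path File path.
#' @return Data frame.
#' @export
read_weights <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("pop_a", "pop_b", "weight") %in% names(df)))
    stop("weights CSV must have columns pop_a, pop_b, weight")
  df
}

#' Assemble a migration pattern M = (G, Theta, W, T)
#'
#' Triangulates the populations on the unit sphere, takes the Voronoi dual as
#' the migration graph `G`, computes the inner intersection angles `Theta`
#' from the geometry, attaches the supplied gene-flow weights `W` (one per
#' Delaunay edge, each strictly in (0,1)), and derives the total loads `T` as
#' the per-population sums of incident edge weights.
#'
#' The weight table must cover exactly the Delaunay edge set: extra or missing
#' population pairs are errors (listed in the message), because a weight on a
#' non-adjacent pair has no edge to live on.
#'
#' @param populations Data frame (`name`, `longitude_deg`, `latitude_deg`) or
#'   path to such a CSV.
#' @param weights Data frame (`pop_a`, `pop_b`, `weight`, optional `label`) or
#'   path to such a CSV.
#' @return Object of class `migration_pattern`: list with `complex`
#'   (the [delaunay_triangulate] result), `graph` (Voronoi [combmap]),
#'   `edges` (data frame `pop_a`, `pop_b`, `label`, `theta`, `weight`),
#'   `loads` (named numeric) and `populations`.
#' @export
assemble_pattern <- function(populations, weights) {
  if (is.character(populations)) populations <- read_populations(populations)
  if (is.character(weights)) weights <- read_weights(weights)
  cx <- delaunay_triangulate(populations)
  ed <- cx$edges
  wkey <- paste(pmin(weights$pop_a, weights$pop_b),
                pmax(weights$pop_a, weights$pop_b), sep = "~")
  ekey <- paste(ed$pop_a, ed$pop_b, sep = "~")
  extra <- setdiff(wkey, ekey); missing <- setdiff(ekey, wkey)
  if (length(extra) || length(missing))
    stop("edge mismatch between weight table and triangulation.",
         if (length(extra)) paste0(" Non-Delaunay pairs: ",
                                   paste(extra, collapse = ", ")),
         if (length(missing)) paste0(" Missing pairs: ",
                                     paste(missing, collapse = ", ")))
  if (anyDuplicated(wkey)) stop("duplicated pairs in weight table")
  ord <- match(ekey, wkey)
  ed$weight <- weights$weight[ord]
  if (any(ed$weight <= 0 | ed$weight >= 1))
    stop("weights must lie strictly in (0,1); offending pairs: ",
         paste(ekey[ed$weight <= 0 | ed$weight >= 1], collapse = ", "))
  if ("label" %in% names(weights)) {
    lab <- as.integer(weights$label[ord])
    if (!setequal(lab, seq_len(nrow(ed)))) stop("label column is not a bijection")
    ed$label <- lab
  }
  cx$edges <- ed
  graph <- voronoi_dual(cx)   # labels inherited from the (relabelled) edge table
  loads <- tapply(c(ed$weight, ed$weight), c(ed$pop_a, ed$pop_b), sum)
  loads <- stats::setNames(as.numeric(loads[as.character(populations$name)]),
                           as.character(populations$name))
  structure(list(complex = cx, graph = graph,
                 edges = ed[, c("pop_a", "pop_b", "label", "theta", "weight")],
                 loads = loads, populations = populations),
            class = "migration_pattern")
}

#' @export
print.migration_pattern <- function(x, ...) {
  cat("Migration pattern:", nrow(x$populations), "populations,",
      nrow(x$edges), "edges\n")
  cat("Total loads:\n"); print(round(x$loads, 5))
  invisible(x)
}

pattern_theta <- function(pattern, theta = NULL) {
  th <- pattern$edges$theta
  if (!is.null(theta)) {
    th <- theta[as.character(pattern$edges$label)]
    if (anyNA(th)) stop("theta override must be named by edge label")
  }
  th
}

#' Rivin face condition: per-population angle sums
#'
#' For a genuine Delaunay pattern the inner angles on the edges incident to
#' each population must sum to exactly \eqn{2\pi}.  Returns the absolute
#' deviations; geometry computed by this package satisfies the condition to
#' ~1e-9, while printed (rounded) angle tables typically reach ~1e-5.
#'
#' @param pattern A `migration_pattern`.
#' @param tol Pass tolerance recorded in the `pass` attribute.
#' @param theta Optional replacement angles, named by edge label (e.g. a
#'   published table to be validated).
#' @return Named numeric vector of deviations `|sum(theta) - 2*pi|` with
#'   attribute `pass`.
#' @export
check_rivin_faces <- function(pattern, tol = 1e-6, theta = NULL) {
  th <- pattern_theta(pattern, theta)
  ed <- pattern$edges
  s <- tapply(c(th, th), c(ed$pop_a, ed$pop_b), sum)
  dev <- abs(s - 2 * pi)[as.character(pattern$populations$name)]
  attr(dev, "pass") <- all(dev < tol)
  dev
}

#' Rivin cycle condition: non-facial Voronoi cycles must exceed 2 pi
#'
#' The face condition fixes the angle sums around each population (each face
#' of the Voronoi graph); the companion condition requires every simple
#' closed path of the Voronoi graph that is *not* a face boundary to carry an
#' angle sum strictly greater than \eqn{2\pi}.  This enumerates those cycles
#' up to `max_cycle_len`, excludes face boundaries, and reports any whose sum
#' fails the bound.  Enumeration is exhaustive and exponential in the length
#' cap; the default 8 is exhaustive enough for graphs of the Sumba size.
#'
#' @param pattern A `migration_pattern`.
#' @param max_cycle_len Maximum cycle length (>= 3; capped at the edge count
#'   with a warning).
#' @param tol Slack: a cycle is a violation when `sum(theta) <= 2*pi + tol`.
#' @param theta Optional replacement angles named by edge label.
#' @return Data frame with columns `cycle` (population path) and `sum`;
#'   zero rows when the condition holds.
#' @export
check_rivin_cycles <- function(pattern, max_cycle_len = 8, tol = 1e-9,
                               theta = NULL) {
  th <- pattern_theta(pattern, theta)
  ed <- pattern$edges
  names(th) <- as.character(ed$label)
  cyc <- map_simple_cycles(pattern$graph, max_cycle_len, exclude_facial = TRUE)
  if (!length(cyc)) return(data.frame(cycle = character(0), sum = numeric(0)))
  sums <- vapply(cyc, function(cc) sum(th[as.character(cc$labels)]), numeric(1))
  bad <- sums <= 2 * pi + tol
  data.frame(cycle = vapply(cyc[bad], function(cc)
    paste(cc$labels, collapse = "-"), ""), sum = sums[bad])
}

# Enumerate simple cycles (by vertex, length >= 2 using parallel edges) of the
# multigraph underlying a map, optionally excluding face boundaries.  Each
# cycle is returned once, as list(vertices = names/ids, labels = edge labels).
map_simple_cycles <- function(m, max_len, exclude_facial = TRUE) {
  nd <- length(m$sigma)
  if (max_len > nd / 2) {
    warning("max_cycle_len capped at edge count ", nd / 2)
    max_len <- nd / 2
  }
  vid <- orbit_index(m$vertices, nd)
  labs <- map_edge_labels(m)
  e_from <- integer(0); e_to <- integer(0)
  for (l in labs) {
    d <- edge_darts(m, l)
    e_from <- c(e_from, vid[d[1]]); e_to <- c(e_to, vid[d[2]])
  }
  nv <- length(m$vertices)
  inc <- lapply(seq_len(nv), function(v) which(e_from == v | e_to == v))
  other <- function(e, v) if (e_from[e] == v) e_to[e] else e_from[e]
  res <- list()
  emit <- function(vs, ls) res[[length(res) + 1]] <<- list(v = vs, l = ls)
  # paths start at their smallest vertex; direction fixed by second < last
  for (s in seq_len(nv)) {
    dfs <- function(path, used_e) {
      v <- path[length(path)]
      for (e in inc[[v]]) {
        if (e %in% used_e) next
        w <- other(e, v)
        if (w == s) {
          if (length(path) >= 2 &&
              (length(path) == 2 || path[2] < path[length(path)]))
            emit(path, c(used_e, e))
          next
        }
        if (w < s || w %in% path) next
        if (length(path) < max_len)
          dfs(c(path, w), c(used_e, e))
      }
    }
    dfs(s, integer(0))
  }
  # length-2 cycles need a distinct parallel edge pair; dfs above finds each
  # unordered pair twice, dedupe by sorted edge set
  keys <- vapply(res, function(cc) paste(sort(cc$l), collapse = ","), "")
  res <- res[!duplicated(keys)]
  face_keys <- vapply(m$faces, function(f)
    paste(sort(unique(m$edge_label[f])), collapse = ","), "")
  out <- list()
  for (cc in res) {
    ls <- sort(labs[cc$l])
    if (length(ls) < length(cc$l)) next         # repeated edge, not simple
    if (exclude_facial && paste(ls, collapse = ",") %in% face_keys) next
    vn <- if (!is.null(m$vertex_names)) m$vertex_names[cc$v] else cc$v
    out[[length(out) + 1]] <- list(vertices = vn, labels = labs[cc$l])
  }
  out
}

#' Validate a migration pattern
#'
#' Aggregates the definitional and geometric checks: weights in (0,1), loads
#' equal to per-population weight sums, Rivin face sums, and Rivin cycle
#' sums.
#'
#' @param pattern A `migration_pattern`.
#' @param tol Face-sum tolerance (1e-6 for computed geometry; use 1e-5 when
#'   the angles come from a rounded printed table).
#' @param max_cycle_len Cycle-enumeration cap, see [check_rivin_cycles].
#' @param theta Optional replacement angles named by edge label.
#' @return Object of class `validation_report` with fields
#'   `face_sum_deviations`, `cycle_violations`, `weight_violations`,
#'   `load_mismatches` and `overall` ("pass"/"fail").
#' @export
validate_pattern <- function(pattern, tol = 1e-6, max_cycle_len = 8,
                             theta = NULL) {
  ed <- pattern$edges
  wbad <- ed[ed$weight <= 0 | ed$weight >= 1, c("pop_a", "pop_b", "weight")]
  loads2 <- tapply(c(ed$weight, ed$weight), c(ed$pop_a, ed$pop_b), sum)
  loads2 <- loads2[names(pattern$loads)]
  lmis <- abs(loads2 - pattern$loads)
  lmis <- lmis[lmis > tol]
  fdev <- check_rivin_faces(pattern, tol = tol, theta = theta)
  cyc <- check_rivin_cycles(pattern, max_cycle_len = max_cycle_len,
                            theta = theta)
  ok <- nrow(wbad) == 0 && length(lmis) == 0 && attr(fdev, "pass") &&
    nrow(cyc) == 0
  structure(list(face_sum_deviations = fdev, cycle_violations = cyc,
                 weight_violations = wbad,
                 load_mismatches = lmis,
                 overall = if (ok) "pass" else "fail", tol = tol),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Migration-pattern validation:", x$overall, "\n")
  cat(" max |face angle sum - 2pi|:",
      format(max(x$face_sum_deviations)), "\n")
  cat(" cycle violations:", nrow(x$cycle_violations),
      " weight violations:", nrow(x$weight_violations),
      " load mismatches:", length(x$load_mismatches), "\n")
  invisible(x)
}

#' Complementary angle convention
#'
#' Some treatments parameterise the dual edge by `1 - x` instead of `x`
#' (angles and gene-flow weights living on the same edge).  The package keeps
#' `Theta` and `W` independent; this helper applies that optional convention
#' explicitly when wanted.
#' @param x Numeric vector in (0,1).
#' @return `1 - x`.
#' @export
complement_convention <- function(x) 1 - x
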