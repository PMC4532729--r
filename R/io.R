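unit_to_latlon <- function(p) {
  c(atan2(p[2], p[1]) * 180 / pi, asin(max(-1, min(1, p[3]))) * 180 / pi)
}

#' The Sumba worked example
#'
#' Eight human populations on the eastern Indonesian island of Sumba with
#' mitochondrial-DNA F_ST values as gene-flow weights on the 18 Delaunay
#' edges.  The bundled edge table carries the conventional integer edge
#' labels 1-18 together with the reference inner angles (rounded to 7
#' figures) for validation.  Label 17 is the Kodi-Rindi edge: the recomputed
#' triangulation places it there (its angle matches uniquely), and the
#' per-population angle sums close to 2*pi only under that assignment.
#' The reference total loads stored alongside follow the original published
#' bookkeeping, which attached edge 17 to Wunga instead; the Wunga and Rindi
#' entries therefore differ from the recomputed loads by exactly w17 (see the
#' vignette).
#'
#' @return List with `populations` (8 rows), `edges` (18 rows: `pop_a`,
#'   `pop_b`, `label`, `weight`, `theta`), and `loads_printed` (named numeric,
#'   the reference totals).
#' @export
load_sumba <- function() {
  ext <- function(f) system.file("extdata", f, package = "migpatterns",
                                 mustWork = TRUE)
  pops <- read_populations(ext("sumba_populations.csv"))
  edges <- utils::read.csv(ext("sumba_edges.csv"), stringsAsFactors = FALSE)
  loads <- utils::read.csv(ext("sumba_loads.csv"), stringsAsFactors = FALSE)
  stopifnot(nrow(pops) == 8, nrow(edges) == 18,
            setequal(edges$label, 1:18),
            all(edges$weight > 0 & edges$weight < 1),
            setequal(loads$population, pops$name))
  deg <- table(c(edges$pop_a, edges$pop_b))
  stopifnot(all(deg >= 3))
  list(populations = pops, edges = edges,
       loads_printed = stats::setNames(loads$total_load, loads$population))
}

#' Seeded synthetic population generator on the sphere
#'
#' Draws `n` population locations either isotropically over the whole sphere
#' (`uniform`) or uniformly within a spherical cap (`cap`), the latter
#' emulating the regional regime of clustered island populations where the
#' convex hull of the points is a near-planar sliver.  All randomness is
#' funnelled through the single `seed`; the caller's RNG state is untouched.
#'
#' @param n Number of populations, `n >= 4`.
#' @param mode `"uniform"` or `"cap"`.
#' @param cap_center Longitude/latitude of the cap centre, degrees.
#' @param cap_radius_deg Angular cap radius, degrees (cap mode).
#' @param seed Integer seed.
#' @return Data frame `name`, `longitude_deg`, `latitude_deg` with attribute
#'   `seed`.
#' @export
random_points <- function(n, mode = c("uniform", "cap"),
                          cap_center = c(119.5, -9.6), cap_radius_deg = 1,
                          seed = 1) {
  mode <- match.arg(mode)
  if (n < 4) stop("size error: need n >= 4")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  if (mode == "uniform") {
    M <- matrix(stats::rnorm(3 * n), n, 3)
    M <- M / sqrt(rowSums(M^2))
  } else {
    if (cap_radius_deg <= 0) stop("cap_radius_deg must be positive")
    r <- cap_radius_deg * pi / 180
    z <- 1 - stats::runif(n) * (1 - cos(r))  # area-uniform in the cap
    az <- stats::runif(n, 0, 2 * pi)
    s <- sqrt(pmax(0, 1 - z^2))
    M <- cbind(s * cos(az), s * sin(az), z)
    ctr <- latlon_to_unit(cap_center[1], cap_center[2])
    east <- cross3(c(0, 0, 1), ctr); east <- east / sqrt(sum(east^2))
    north <- cross3(ctr, east)
    M <- M %*% rbind(east, north, ctr)  # rotate pole onto the cap centre
  }
  ll <- t(apply(M, 1, unit_to_latlon))
  out <- data.frame(name = paste0("P", seq_len(n)), longitude_deg = ll[, 1],
                    latitude_deg = ll[, 2], stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  out
}

# ---- JSON serialisation -----------------------------------------------------

delaunay_to_list <- function(cx) {
  ll <- t(apply(cx$points, 1, unit_to_latlon))
  list(points = data.frame(name = rownames(cx$points),
                           longitude_deg = ll[, 1], latitude_deg = ll[, 2],
                           x = cx$points[, 1], y = cx$points[, 2],
                           z = cx$points[, 3], row.names = NULL),
       triangles = lapply(seq_len(nrow(cx$triangles)), function(t)
         list(vertices = rownames(cx$points)[cx$triangles[t, ]],
              center = unname(cx$centers[t, ]), radius = cx$radii[t])),
       edges = cx$edges[, c("pop_a", "pop_b", "label", "theta")],
       n_candidates = cx$n_candidates)
}

#' Write/read package artifacts as JSON
#'
#' Stable plain-text interchange for the triangulation, migration pattern,
#' polytopes, complexes and maps.  Numbers are written at full precision.
#'
#' @param x Object (`delaunay_complex`, `migration_pattern`, `hpolytope`,
#'   `polytope_complex`, `combmap` or `validation_report`).
#' @param path Output file.
#' @return `path` invisibly.
#' @export
write_migration_json <- function(x, path) {
  lst <- if (inherits(x, "delaunay_complex")) delaunay_to_list(x)
  else if (inherits(x, "migration_pattern"))
    list(populations = x$populations, edges = x$edges,
         loads = as.list(x$loads))
  else if (inherits(x, "hpolytope"))
    list(vars = x$vars, equalities = unname(apply(x$Aeq, 1, as.numeric,
                                                  simplify = FALSE)),
         rhs = x$beq, lo = x$lo, hi = x$hi,
         n_inequalities = if (is.null(x$Age)) 0 else nrow(x$Age))
  else if (inherits(x, "polytope_complex"))
    list(n_nodes = length(x$nodes),
         nodes = lapply(x$nodes, function(nd) list(code = nd$code)),
         moves = x$moves, T = as.list(x$T))
  else if (inherits(x, "combmap")) map_to_list(x)
  else if (inherits(x, "validation_report"))
    list(overall = x$overall,
         face_sum_deviations = as.list(x$face_sum_deviations),
         n_cycle_violations = nrow(x$cycle_violations),
         n_weight_violations = nrow(x$weight_violations),
         n_load_mismatches = length(x$load_mismatches))
  else stop("no JSON serialisation for class ", class(x)[1])
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

map_to_list <- function(m) {
  list(sigma = m$sigma, alpha = m$alpha, edge_label = m$edge_label,
       vertex_names = m$vertex_names, face_names = m$face_names)
}

#' @rdname write_migration_json
#' @export
read_map_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- combmap(as.integer(lst$sigma), as.integer(lst$alpha),
               edge_label = as.integer(lst$edge_label))
  m$vertex_names <- lst$vertex_names
  m$face_names <- lst$face_names
  m
}
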