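#' Convert geographic coordinates to a unit-sphere point
#'
#' Interprets longitude/latitude in decimal degrees as spherical coordinates on
#' the unit sphere and returns the Cartesian vector
#' \eqn{(\cos\phi\cos\lambda, \cos\phi\sin\lambda, \sin\phi)}.  The Earth is
#' treated as the unit sphere throughout the package: every quantity derived
#' from the triangulation (circumradii, inner angles) is an angle and therefore
#' scale-invariant.
#'
#' @param lon Longitude in decimal degrees, east positive.  Values in
#'   \eqn{[-180, 360]} are accepted and normalised to \eqn{(-180, 180]}.
#' @param lat Latitude in decimal degrees, north positive, strictly between
#'   -90 and 90 (the poles are rejected as degenerate for Voronoi purposes).
#' @return Numeric vector of length 3 with unit Euclidean norm.
#' @examples
#' latlon_to_unit(0, 0)   # (1, 0, 0)
#' latlon_to_unit(90, 0)  # (0, 1, 0)
#' @export
latlon_to_unit <- function(lon, lat) {
  if (!is.finite(lon) || !is.finite(lat))
    stop("degenerate coordinate: longitude and latitude must be finite")
  if (lat <= -90 || lat >= 90)
    stop("degenerate coordinate: polar or out-of-range latitude ", lat)
  if (lon < -180 || lon > 360)
    stop("longitude out of accepted range [-180, 360]: ", lon)
  if (lon > 180) lon <- lon - 360
  la <- lat * pi / 180
  lo <- lon * pi / 180
  c(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
}

#' Great-circle (angular) distance between two unit vectors
#'
#' @param u,v Unit vectors of length 3 (norm checked to 1e-9).
#' @return Arc length in radians, in \eqn{[0, \pi]}.
#' @export
angular_distance <- function(u, v) {
  if (abs(sum(u^2) - 1) > 1e-9 || abs(sum(v^2) - 1) > 1e-9)
    stop("angular_distance expects unit vectors")
  # atan2 form is well-conditioned near 0 and pi, unlike plain acos
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cr^2)), sum(u * v))
}

# Clamp an almost-in-range cosine; beyond `tol` it is a conditioning error.
clamp_cos <- function(x, tol = 1e-9) {
  if (x > 1 + tol || x < -1 - tol)
    stop("numerical conditioning: cosine argument ", x, " outside [-1,1]")
  min(1, max(-1, x))
}

#' Spherical Delaunay triangulation by the empty-cap test
#'
#' Enumerates all \eqn{\binom{n}{3}} triples of points and accepts a triple as
#' a Delaunay triangle if and only if all remaining points lie strictly on one
#' side of the plane through the three points: the spherical cap cut off on the
#' other side is then free of points (the empty circumscribed cap test).  This
#' brute-force \eqn{O(n^4)} procedure is deliberate: it is robust in the
#' clustered-cap regime typical of regional population samples, where the
#' convex hull of the points is a near-planar sliver.
#'
#' @param points Either a data frame with columns `name`, `longitude_deg`,
#'   `latitude_deg`, or a numeric matrix of unit row vectors (rownames used as
#'   population names).
#' @param tol Sidedness tolerance on the signed plane distance.  A remaining
#'   point within `tol` of a candidate plane is a four-point degeneracy and
#'   raises an error naming the points rather than silently picking a
#'   triangulation.
#' @return An object of class `delaunay_complex`: a list with
#'   \describe{
#'     \item{points}{matrix of unit vectors, rownames = population names}
#'     \item{triangles}{integer matrix, one row per triangle (vertex indices)}
#'     \item{centers}{matrix of circumcenter unit vectors, one row per triangle}
#'     \item{radii}{spherical circumradii in radians}
#'     \item{edges}{data frame: `i`, `j` (point indices, i < j), `pop_a`,
#'       `pop_b` (names, alphabetical), `label` (integer, assigned by sorted
#'       name pair), `tri1`, `tri2` (adjacent triangle rows), `theta`
#'       (inner angle, radians)}
#'     \item{n_candidates}{number of triples examined, \eqn{\binom{n}{3}}}
#'   }
#' @export
delaunay_triangulate <- function(points, tol = 1e-12) {
  pts <- as_point_matrix(points)
  n <- nrow(pts)
  if (n < 4) stop("need at least 4 points, got ", n)
  if (anyDuplicated(rownames(pts))) stop("duplicated population names")
  d2 <- as.matrix(stats::dist(pts))
  diag(d2) <- Inf
  if (min(d2) < 1e-12) stop("two points coincide")

  combs <- utils::combn(n, 3)
  tris <- matrix(integer(0), ncol = 3)
  centers <- matrix(numeric(0), ncol = 3)
  radii <- numeric(0)
  for (c_i in seq_len(ncol(combs))) {
    v <- combs[, c_i]
    a <- pts[v[1], ]; b <- pts[v[2], ]; cc <- pts[v[3], ]
    nrm <- cross3(b - a, cc - a)
    nn <- sqrt(sum(nrm^2))
    if (nn < 1e-14) stop("degenerate (collinear) triple: ",
                         paste(rownames(pts)[v], collapse = ", "))
    nrm <- nrm / nn
    off <- sum(nrm * a)
    rest <- setdiff(seq_len(n), v)
    s <- pts[rest, , drop = FALSE] %*% nrm - off
    if (any(abs(s) <= tol)) {
      bad <- rest[which.min(abs(s))]
      stop("degeneracy: four nearly cocircular points: ",
           paste(rownames(pts)[c(v, bad)], collapse = ", "))
    }
    if (all(s < 0) || all(s > 0)) {
      # circumcenter = unit plane normal signed toward the empty cap's pole,
      # i.e. away from the remaining points
      ctr <- if (all(s < 0)) nrm else -nrm
      tris <- rbind(tris, v)
      centers <- rbind(centers, ctr)
      radii <- c(radii, angular_distance(ctr, a))
    }
  }
  rownames(tris) <- NULL
  n_tri <- nrow(tris)
  if (n_tri != 2 * n - 4)
    stop("triangulation is not simplicial-complete: ", n_tri,
         " triangles for ", n, " points (expected ", 2 * n - 4, ")")

  edges <- extract_edges(tris, rownames(pts))
  if (nrow(edges) != 3 * n - 6)
    stop("edge count ", nrow(edges), " != 3n-6")

  cx <- structure(list(points = pts, triangles = tris, centers = centers,
                       radii = radii, edges = edges,
                       n_candidates = ncol(combs)),
                  class = "delaunay_complex")
  cx$edges$theta <- vapply(seq_len(nrow(edges)), function(k)
    edge_inner_angle(k, cx), numeric(1))
  cx
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("name", "longitude_deg", "latitude_deg") %in% names(points)))
    pts <- t(mapply(latlon_to_unit, points$longitude_deg, points$latitude_deg))
    rownames(pts) <- as.character(points$name)
    return(pts)
  }
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 3)
  nrms <- sqrt(rowSums(pts^2))
  if (any(abs(nrms - 1) > 1e-9)) stop("points must be unit vectors")
  if (is.null(rownames(pts))) rownames(pts) <- paste0("P", seq_len(nrow(pts)))
  pts
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Build the edge table (each edge = unordered point pair adjacent to exactly
# two triangles); integer labels follow the alphabetical (pop_a, pop_b) order.
extract_edges <- function(tris, names) {
  key <- character(0); i1 <- integer(0); j1 <- integer(0); t1 <- list()
  acc <- new.env(parent = emptyenv())
  for (t_i in seq_len(nrow(tris))) {
    v <- tris[t_i, ]
    for (pr in list(v[c(1, 2)], v[c(1, 3)], v[c(2, 3)])) {
      k <- paste(sort(pr), collapse = "-")
      acc[[k]] <- c(acc[[k]], t_i)
    }
  }
  keys <- ls(acc)
  rows <- lapply(keys, function(k) {
    ts <- acc[[k]]
    if (length(ts) != 2)
      stop("edge ", k, " adjacent to ", length(ts), " triangles (not 2)")
    ij <- as.integer(strsplit(k, "-")[[1]])
    nm <- sort(names[ij])
    data.frame(i = ij[1], j = ij[2], pop_a = nm[1], pop_b = nm[2],
               tri1 = ts[1], tri2 = ts[2], stringsAsFactors = FALSE)
  })
  ed <- do.call(rbind, rows)
  ed <- ed[order(ed$pop_a, ed$pop_b), , drop = FALSE]
  ed$label <- seq_len(nrow(ed))
  rownames(ed) <- NULL
  ed[, c("i", "j", "pop_a", "pop_b", "label", "tri1", "tri2")]
}

#' Inner intersection angle of the two circumcircles adjacent to an edge
#'
#' For a Delaunay edge shared by triangles with circumcircles
#' \eqn{(V_1, r_1)} and \eqn{(V_2, r_2)}, the inner angle is obtained from the
#' spherical law of cosines applied to the triangle \eqn{V_1 P V_2} at a shared
#' endpoint \eqn{P}:
#' \deqn{\cos\theta = \frac{\cos D - \cos r_1 \cos r_2}{\sin r_1 \sin r_2}}
#' with \eqn{D} the angular distance between the two circumcenters.  The angle
#' is identical at either shared endpoint.
#'
#' @param edge Row index into `complex$edges`, or a length-2 character vector
#'   of population names.
#' @param complex A `delaunay_complex`.
#' @return Angle in radians, in \eqn{(0, \pi)}.
#' @export
edge_inner_angle <- function(edge, complex) {
  ed <- complex$edges
  if (is.character(edge)) {
    nm <- sort(edge)
    k <- which(ed$pop_a == nm[1] & ed$pop_b == nm[2])
    if (length(k) != 1) stop("no unique edge ", nm[1], "-", nm[2])
  } else k <- edge
  t1 <- ed$tri1[k]; t2 <- ed$tri2[k]
  r1 <- complex$radii[t1]; r2 <- complex$radii[t2]
  if (min(r1, r2) < 1e-12 || max(r1, r2) > pi - 1e-12)
    stop("degenerate circumradius (0 or pi)")
  D <- angular_distance(complex$centers[t1, ], complex$centers[t2, ])
  th <- acos(clamp_cos((cos(D) - cos(r1) * cos(r2)) / (sin(r1) * sin(r2))))
  if (th <= 0 || th >= pi) stop("inner angle out of (0, pi): ", th)
  th
}

#' Circumcircle of a Delaunay triangle
#'
#' @param tri Row index into `complex$triangles`.
#' @param complex A `delaunay_complex`.
#' @return List with `center` (unit vector, the empty cap's pole) and `radius`
#'   (spherical radius in radians).
#' @export
circumcircle <- function(tri, complex) {
  list(center = complex$centers[tri, ], radius = complex$radii[tri])
}

#' @export
print.delaunay_complex <- function(x, ...) {
  cat("Spherical Delaunay complex:", nrow(x$points), "points,",
      nrow(x$triangles), "triangles,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' The Delaunay triangulation as a combinatorial map
#'
#' Orients all triangles consistently (the sphere is orientable; orientation is
#' propagated across shared edges from the first triangle) and encodes the
#' triangulation as a rotation system whose vertices are populations, whose
#' faces are the triangles, and whose edge labels are the `label` column of the
#' complex's edge table.
#'
#' @param complex A `delaunay_complex`.
#' @return A [combmap] with `vertex_names` set to population names.
#' @export
delaunay_map <- function(complex) {
  tris <- complex$triangles
  n_tri <- nrow(tris)
  ed <- complex$edges
  # adjacency between triangles through the edge table
  adj <- vector("list", n_tri)
  for (k in seq_len(nrow(ed)))
    for (t in c(ed$tri1[k], ed$tri2[k]))
      adj[[t]] <- c(adj[[t]], k)
  # propagate a consistent orientation
  orient <- vector("list", n_tri)
  orient[[1]] <- tris[1, ]
  queue <- 1L
  seen <- rep(FALSE, n_tri); seen[1] <- TRUE
  dir_edges <- function(v) list(v[c(1, 2)], v[c(2, 3)], v[c(3, 1)])
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    for (k in adj[[t]]) {
      t2 <- if (ed$tri1[k] == t) ed$tri2[k] else ed$tri1[k]
      if (seen[t2]) next
      # shared pair must appear in opposite directions in the two triangles
      shr <- c(ed$i[k], ed$j[k])
      de <- dir_edges(orient[[t]])
      hit <- Filter(function(e) all(sort(e) == sort(shr)), de)[[1]]
      v2 <- tris[t2, ]
      cand <- v2[c(1, 2, 3)]
      # orient t2 so that it contains the reversed directed edge
      perms <- list(v2[c(1, 2, 3)], v2[c(1, 3, 2)])
      ok <- vapply(perms, function(p) {
        any(vapply(dir_edges(p), function(e) all(e == rev(hit)), logical(1)))
      }, logical(1))
      orient[[t2]] <- perms[[which(ok)[1]]]
      seen[t2] <- TRUE
      queue <- c(queue, t2)
    }
  }
  # darts = directed edges; sigma defined so faces are the oriented triangles
  dart_key <- character(0)
  from <- integer(0); to <- integer(0)
  for (t in seq_len(n_tri)) {
    for (e in dir_edges(orient[[t]])) {
      dart_key <- c(dart_key, paste(e[1], e[2]))
      from <- c(from, e[1]); to <- c(to, e[2])
    }
  }
  if (anyDuplicated(dart_key)) stop("orientation propagation failed")
  id <- stats::setNames(seq_along(dart_key), dart_key)
  nd <- length(dart_key)
  sigma <- integer(nd); alpha <- integer(nd)
  # faces = orbits of sigma(alpha(d)): within oriented triangle (a,b,c),
  # phi maps (a->b) to (b->c), so sigma(b->a) := (b->c)
  for (t in seq_len(n_tri)) {
    de <- dir_edges(orient[[t]])
    for (q in 1:3) {
      e1 <- de[[q]]; e2 <- de[[q %% 3 + 1]]
      sigma[id[paste(e1[2], e1[1])]] <- id[paste(e2[1], e2[2])]
    }
  }
  for (d in seq_len(nd)) alpha[d] <- id[paste(to[d], from[d])]
  # edge labels from the edge table
  lab <- integer(nd)
  for (k in seq_len(nrow(ed))) {
    d1 <- id[paste(ed$i[k], ed$j[k])]
    lab[d1] <- ed$label[k]; lab[alpha[d1]] <- ed$label[k]
  }
  m <- combmap(sigma, alpha, edge_label = lab)
  # name vertices by population: vertex orbit containing a dart leaving p
  vn <- character(length(m$vertices))
  for (vi in seq_along(m$vertices))
    vn[vi] <- rownames(complex$points)[from[m$vertices[[vi]][1]]]
  m$vertex_names <- vn
  m
}

#' Voronoi diagram of a Delaunay complex, as an embedded map
#'
#' The Voronoi diagram is the dual map: one vertex per Delaunay triangle
#' (its circumcenter), one edge per Delaunay edge (carrying the same label),
#' one face per population.  For a simplicial triangulation every Voronoi
#' vertex has degree 3.
#'
#' @param complex A `delaunay_complex`.
#' @return A [combmap] with `face_names` giving the population of each face.
#' @export
voronoi_dual <- function(complex) {
  map_dual(delaunay_map(complex))
}
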