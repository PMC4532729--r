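# Shared builders for map and geometry tests.

# Regular tetrahedron vertices on the unit sphere.
tetra_points <- function() {
  m <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  rownames(m) <- paste0("T", 1:4)
  m
}

# Tetrahedron (K4) as a combinatorial map.
k4_map <- function() {
  combmap_from_rotations(list(c(1, 2, 3), c(1, 4, 6), c(2, 6, 5), c(3, 5, 4)))
}

# Octahedron map, built directly from its planar rotations (for duality
# checks against the cube = CL_6).
octahedron_map <- function() {
  # edges: 1..4 top spokes, 5..8 equator cycle, 9..12 bottom spokes
  rot <- vector("list", 6)
  rot[[1]] <- c(1, 2, 3, 4)                       # top vertex
  for (i in 1:4)                                  # equatorial vertices
    rot[[1 + i]] <- c(i, 4 + ((i - 2) %% 4) + 1, 8 + i, 4 + i)
  rot[[6]] <- c(9, 12, 11, 10)                    # bottom vertex
  combmap_from_rotations(rot)
}

# Apply `steps` random moves (whitehead / contraction / expansion, whichever
# applies) starting from CL_n; returns the full trajectory of maps.
random_move_walk <- function(n = 5, steps = 6, seed = 1) {
  set.seed(seed)
  m <- make_CLn(n)
  out <- list(m)
  for (s in seq_len(steps)) {
    kind <- sample(c("wh", "con", "exp"), 1)
    nxt <- NULL
    if (kind == "wh" && is_cubic(m)) {
      for (e in sample(map_edge_labels(m))) {
        nxt <- tryCatch(whitehead_move(m, e), error = function(err) NULL)
        if (!is.null(nxt)) break
      }
    } else if (kind == "con") {
      for (e in sample(map_edge_labels(m))) {
        nxt <- tryCatch(contract_edge(m, e), error = function(err) NULL)
        if (!is.null(nxt)) break
      }
    } else {
      vs <- which(lengths(m$vertices) >= 4)
      if (length(vs)) {
        v <- m$vertices[[sample(vs, 1)]]
        k <- length(v)
        len <- sample(2:(k - 2), 1)
        start <- sample(k, 1)
        arc <- v[((start - 1 + seq_len(len) - 1) %% k) + 1]
        nxt <- tryCatch(expand_vertex(m, arc), error = function(err) NULL)
      }
    }
    if (!is.null(nxt)) { m <- nxt; out[[length(out) + 1]] <- m }
  }
  out
}

# Drive C_n up to a cubic map by random expansions.
random_cubic_from_Cn <- function(n, seed) {
  set.seed(seed)
  m <- make_Cn(n)
  while (!is_cubic(m)) {
    vs <- which(lengths(m$vertices) >= 4)
    v <- m$vertices[[sample(vs, 1)]]
    k <- length(v)
    len <- sample(2:(k - 2), 1)
    start <- sample(k, 1)
    arc <- v[((start - 1 + seq_len(len) - 1) %% k) + 1]
    nxt <- tryCatch(expand_vertex(m, arc), error = function(err) NULL)
    if (!is.null(nxt)) m <- nxt
  }
  m
}

# Conjugate a map by a random dart relabelling (an equivalent encoding).
relabel_darts <- function(m, seed) {
  set.seed(seed)
  n <- length(m$sigma)
  p <- sample(n)                      # p[old] = new
  inv <- integer(n); inv[p] <- seq_len(n)
  combmap(p[m$sigma[inv]], p[m$alpha[inv]], edge_label = m$edge_label[inv])
}

# Mirror image: reverse the rotation at every vertex.
mirror_map <- function(m) {
  n <- length(m$sigma)
  sig_inv <- integer(n); sig_inv[m$sigma] <- seq_len(n)
  combmap(sig_inv, m$alpha, edge_label = m$edge_label)
}

sumba_pattern <- function() {
  sb <- load_sumba()
  assemble_pattern(sb$populations, sb$edges)
}

# Random pattern on random points with random admissible weights.
random_pattern <- function(n, mode = "uniform", seed = 1) {
  pts <- random_points(n, mode = mode, seed = seed)
  cx <- delaunay_triangulate(pts)
  set.seed(seed + 1000)
  w <- data.frame(pop_a = cx$edges$pop_a, pop_b = cx$edges$pop_b,
                  weight = stats::runif(nrow(cx$edges), 0.01, 0.99))
  assemble_pattern(pts, w)
}
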