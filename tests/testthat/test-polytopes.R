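test_that("C_4 load system with unit loads is the expected segment", {
  P <- build_load_system(make_Cn(4), 1)
  # hand-solved: faces alternate edges, solutions (t, 1-t, t, 1-t)
  expect_equal(length(P$vars), 4)
  expect_equal(4 - qr(P$Aeq)$rank, 1)       # one-dimensional family
  f <- is_feasible(P)
  expect_true(f$feasible)
  expect_lt(max(abs(P$Aeq %*% f$witness - P$beq)), 1e-9)
  ip <- interior_point(P)
  expect_equal(ip$point, rep(0.5, 4), tolerance = 1e-9)
  V <- sort_rows(enumerate_vertices(P))
  expect_equal(unname(V), rbind(c(0, 1, 0, 1), c(1, 0, 1, 0)),
               tolerance = 1e-9)
  expect_false(is_feasible(build_load_system(make_Cn(4), c(1, 1, 1, 2)))$feasible)
})

test_that("load-system structure: 0/1 rows, every edge in exactly two rows", {
  for (m in list(k4_map(), make_CLn(5), make_Cn(6),
                 sumba_pattern()$graph)) {
    P <- build_load_system(m, 1)
    expect_true(all(P$Aeq %in% c(0, 1)))
    expect_equal(unname(colSums(P$Aeq)), rep(2, length(P$vars)))
    # summing all equalities: sum(T) = 2 sum(x) for any feasible point
    w <- is_feasible(P)$witness
    if (!is.null(w)) expect_equal(sum(P$beq), 2 * sum(w), tolerance = 1e-8)
  }
  expect_error(build_load_system(k4_map(), c(1, 1, 1, -1)), "positive")
  expect_warning(build_load_system(k4_map(), c(1, 1, 1, 3.5)), "infeasible")
})

test_that("Sumba weight vector is a witness of its own load system", {
  p <- sumba_pattern()
  P <- build_load_system(p$graph, p$loads)
  w <- stats::setNames(p$edges$weight, p$edges$label)[as.character(P$vars)]
  expect_lt(max(abs(P$Aeq %*% w - P$beq)), 1e-6)
  expect_true(is_feasible(P)$feasible)
  ip <- interior_point(P)
  expect_gt(ip$slack, 0)                      # an open pattern exists
  expect_lt(max(abs(P$Aeq %*% ip$point - P$beq)), 1e-8)
})

test_that("angle systems: published and symmetric points satisfy them", {
  p <- sumba_pattern()
  A <- build_angle_system(p$graph, max_cycle_len = 8)
  th <- stats::setNames(p$edges$theta, p$edges$label)[as.character(A$vars)]
  expect_lt(max(abs(A$Aeq %*% th - A$beq)), 1e-6)
  sb <- load_sumba()
  thp <- stats::setNames(sb$edges$theta, sb$edges$label)[as.character(A$vars)]
  expect_lt(max(abs(A$Aeq %*% thp - A$beq)), 1e-5)  # printed rounding
  expect_gt(nrow(A$Age), 0)
  expect_gt(min(A$Age %*% th - A$bge), 0)     # strict cycle inequalities
  # tetrahedron: theta = 2*pi/3 on all six edges closes every face
  At <- build_angle_system(k4_map(), 6)
  tt <- rep(2 * pi / 3, 6)
  expect_lt(max(abs(At$Aeq %*% tt - At$beq)), 1e-12)
  # total over equalities: sum over faces of 2*pi = pi * n via double counting
  expect_equal(sum(At$beq), 2 * sum(tt))
})

test_that("interior points: squares, cubes, and boundary-only systems", {
  sq <- hpolytope(1:2, matrix(0, 0, 2), numeric(0), c(0, 0), c(1, 1))
  expect_equal(interior_point(sq)$point, c(0.5, 0.5), tolerance = 1e-9)
  cube <- hpolytope(1:3, matrix(0, 0, 3), numeric(0), rep(0, 3), rep(1, 3))
  expect_equal(nrow(enumerate_vertices(cube)), 8)
  # a system whose only solution pins x at a bound has no interior
  pinned <- hpolytope(1:2, rbind(c(1, 0), c(1, 1)), c(0, 1), c(0, 0), c(1, 1))
  expect_null(interior_point(pinned))
  expect_true(is_feasible(pinned)$feasible)
})

test_that("vertex enumeration agrees with exact rational re-solve", {
  cases <- list(
    list(m = make_Cn(4), T = rep(1, 4)),
    list(m = k4_map(), T = rep(1, 4)),
    list(m = k4_map(), T = c(1, 1, 1.5, 0.5)),
    list(m = make_CLn(4), T = rep(1, 4)))
  for (cs in cases) {
    P <- suppressWarnings(build_load_system(cs$m, cs$T))
    V1 <- sort_rows(enumerate_vertices(P))
    V2 <- sort_rows(rational_vertices(P$Aeq, round(cs$T * 2), rep(2, length(cs$T))))
    expect_equal(nrow(V1), nrow(V2))
    if (nrow(V1)) expect_equal(unname(V1), unname(V2), tolerance = 1e-9)
    # every enumerated vertex is feasible
    if (nrow(V1))
      expect_lt(max(abs(P$Aeq %*% t(V1) - P$beq)), 1e-9)
  }
})

test_that("contraction facets equal the contracted graph's system", {
  k4 <- k4_map()
  k4$face_names <- paste0("F", 1:4)
  T <- stats::setNames(rep(1, 4), k4$face_names)
  P <- build_load_system(k4, T)
  for (e in map_edge_labels(k4)) {
    Pf <- contraction_facet(P, e)
    mc <- contract_edge(k4, e)
    Pc <- build_load_system(mc, T)
    # facet vertices, with x_e dropped, are exactly the contracted vertices
    Vf <- enumerate_vertices(Pf)
    Vc <- enumerate_vertices(Pc)
    keep <- match(Pc$vars, P$vars)
    expect_equal(sort_rows(Vf[, keep, drop = FALSE]), sort_rows(Vc),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # fixing every boundary edge of a face to zero contradicts a positive load
  face_edges <- unique(k4$edge_label[k4$faces[[1]]])
  Pz <- P
  for (e in face_edges) Pz <- contraction_facet(Pz, e)
  expect_false(is_feasible(Pz)$feasible)
  # facet-of-facet commutes
  P12 <- contraction_facet(contraction_facet(P, 1), 2)
  P21 <- contraction_facet(contraction_facet(P, 2), 1)
  expect_equal(P12$lo, P21$lo); expect_equal(P12$hi, P21$hi)
})

test_that("the n=4 polytope complex closes with shared facets", {
  cx <- build_complex(k4_map(), T = 1)
  expect_gt(length(cx$nodes), 1)
  expect_true(all(vapply(cx$nodes, function(nd) is_cubic(nd$map), logical(1))))
  # each node's code is unique: one polytope per labelled cubic map
  expect_false(anyDuplicated(vapply(cx$nodes, `[[`, "", "code")) > 0)
  for (r in seq_len(nrow(cx$moves))) {
    mv <- cx$moves[r, ]
    Pa <- contraction_facet(cx$nodes[[mv$from]]$polytope, mv$pivot)
    Pb <- contraction_facet(cx$nodes[[mv$to]]$polytope, mv$pivot)
    Va <- sort_rows(enumerate_vertices(Pa))
    Vb <- sort_rows(enumerate_vertices(Pb))
    # shared facet: identical solution sets in the shared coordinates
    expect_equal(dim(Va), dim(Vb))
    if (nrow(Va)) {
      ca <- colnames(Va); Vb <- Vb[, ca, drop = FALSE]
      expect_equal(unname(Va), unname(sort_rows(Vb)), tolerance = 1e-9)
    }
  }
  expect_error(build_complex(contract_edge(k4_map(), 1), T = 1), "cubic")
})

test_that("relabelling the seed permutes the complex's coordinates", {
  k4 <- k4_map()
  perm <- c(3L, 1L, 2L, 5L, 6L, 4L)   # relabel edges by this permutation
  k4p <- k4; k4p$edge_label <- perm[k4$edge_label]
  c1 <- build_complex(k4, T = 1)
  c2 <- build_complex(k4p, T = 1)
  expect_equal(length(c1$nodes), length(c2$nodes))
  A1 <- c1$nodes[[1]]$polytope$Aeq[, as.character(1:6)]
  A2 <- c2$nodes[[1]]$polytope$Aeq[, as.character(perm)]
  expect_equal(unname(A1), unname(A2))
})
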