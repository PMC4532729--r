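test_that("C_n and CL_n have the stated counts", {
  expect_equal(unname(map_counts(make_Cn(2))), c(2, 2, 2))
  expect_equal(unname(map_counts(make_Cn(4))), c(2, 4, 4))
  expect_equal(unname(map_counts(make_Cn(10))), c(2, 10, 10))
  expect_equal(unname(map_counts(make_CLn(4))), c(4, 6, 4))
  expect_equal(unname(map_counts(make_CLn(10))), c(16, 24, 10))
  expect_true(is_cubic(make_CLn(10)))
  # cube/octahedron duality
  expect_equal(canonical_code(map_dual(make_CLn(6))),
               canonical_code(octahedron_map()))
})

test_that("contraction bookkeeping: counts, depth, refusals", {
  k4 <- k4_map()
  m3 <- contract_edge(k4, 1)
  expect_equal(unname(map_counts(m3)), c(3, 5, 4))
  expect_equal(map_depth(m3), map_depth(k4) + 1L)
  # C_n has only two vertices: contracting any edge is refused
  expect_error(contract_edge(make_Cn(5), 1), "minimality")
  # contracting one of a parallel pair would create a self-loop
  prism <- make_CLn(4)
  # prism outer/inner edges are parallel pairs; spokes contract fine
  expect_error(contract_edge(prism, 1), "self-loop|parallel")
  expect_equal(unname(map_counts(contract_edge(prism, 5))), c(3, 5, 4))
})

test_that("expansion obeys the valence identity and inverts contraction", {
  k4 <- k4_map()
  m3 <- contract_edge(k4, 6)
  v4 <- which(lengths(m3$vertices) == 4)
  expect_length(v4, 1)
  cyc <- m3$vertices[[v4]]
  # all 2+2 splits of the degree-4 vertex: each gives two degree-3 vertices,
  # and at least one restores a map equivalent to K4
  codes <- character(0)
  for (s in 1:4) {
    arc <- cyc[((s - 1 + 0:1) %% 4) + 1]
    ex <- expand_vertex(m3, arc)
    expect_equal(sort(lengths(ex$vertices)), rep(3L, 4))
    codes <- c(codes, canonical_code(ex))
  }
  expect_true(canonical_code(k4) %in% codes)
  expect_error(expand_vertex(m3, cyc[1:3]), "invalid split")
  expect_error(expand_vertex(k4, k4$vertices[[1]][1:2]), "degree >= 4")
})

test_that("Whitehead moves connect K4 and the bigon prism and are involutive", {
  k4 <- k4_map()
  for (e in map_edge_labels(k4)) {
    w <- whitehead_move(k4, e)
    expect_equal(map_counts(w), map_counts(k4))
    expect_true(is_cubic(w))
    expect_false(canonical_code(w) == canonical_code(k4))
    expect_equal(canonical_code(w), canonical_code(make_CLn(4)))
    expect_equal(canonical_code(whitehead_move(w, e)), canonical_code(k4))
  }
  expect_error(whitehead_move(contract_edge(k4, 1), 2), "cubic")
})

test_that("canonical codes are invariant under relabelling and reflection", {
  for (m in list(k4_map(), make_CLn(5), make_Cn(6))) {
    code <- canonical_code(m)
    for (seed in 1:3)
      expect_equal(canonical_code(relabel_darts(m, seed)), code)
    expect_equal(canonical_code(mirror_map(m)), code)
  }
  expect_false(canonical_code(k4_map()) == canonical_code(make_CLn(4)))
})

test_that("duality is an involution across random move walks", {
  maps <- unlist(lapply(1:8, function(s) random_move_walk(4 + s %% 3, 6, s)),
                 recursive = FALSE)
  expect_gte(length(maps), 30)
  for (m in maps) {
    dm <- map_dual(m)
    ct <- map_counts(m); cd <- map_counts(dm)
    expect_equal(unname(cd[c("F", "V")]), unname(ct[c("V", "F")]))
    expect_equal(canonical_code(map_dual(dm)), canonical_code(m))
  }
  # dual of C_n is the n-cycle map: n vertices, n edges, 2 faces
  expect_equal(unname(map_counts(map_dual(make_Cn(7)))), c(7, 7, 2))
})

test_that("CombMS enumeration matches the known small spaces", {
  cs3 <- enumerate_combms(3)
  expect_equal(sum(lengths(cs3$layers)), 1)
  expect_equal(names(cs3$layers[[1]]), canonical_code(make_Cn(3)))
  cs4 <- enumerate_combms(4)
  expect_equal(lengths(cs4$layers), c(2L, 1L, 1L))
  expect_equal(names(cs4$layers[[3]]), canonical_code(make_Cn(4)))
  expect_error(enumerate_combms(2), "size error")
  expect_error(enumerate_combms(9), "size error")
})

test_that("structure of CombMS(5): depths, edge counts, unique deepest map", {
  cs5 <- enumerate_combms(5)
  expect_equal(length(cs5$layers), 2 * 5 - 6 + 1)  # depths 0 .. 2n-6
  for (k in seq_along(cs5$layers)) {
    for (m in cs5$layers[[k]]) {
      expect_equal(length(m$faces), 5)
      expect_equal(length(m$sigma) / 2, 3 * 5 - 6 - (k - 1))
      expect_equal(map_depth(m), k - 1L)
    }
  }
  expect_length(cs5$layers[[length(cs5$layers)]], 1)
  expect_equal(names(cs5$layers[[length(cs5$layers)]]),
               canonical_code(make_Cn(5)))
})

test_that("cubic layer is connected under Whitehead moves (n = 5)", {
  layer0 <- names(enumerate_combms(5, max_depth = 0)$layers[[1]])
  # independently generated cubic maps (random expansions from C_5) must all
  # lie in the Whitehead closure of CL_5
  for (seed in 1:20) {
    m <- random_cubic_from_Cn(5, seed)
    expect_true(canonical_code(m) %in% layer0)
  }
})

test_that("expansion moves alone do not generate the whole space", {
  cs5 <- enumerate_combms(5)
  all5 <- unlist(lapply(cs5$layers, names))
  reach <- migpatterns:::expansion_closure(make_Cn(5))
  expect_true(all(reach %in% all5))           # soundness
  expect_gt(length(setdiff(all5, reach)), 0)  # strict insufficiency
})
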