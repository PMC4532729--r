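test_that("a generic small split adds one vertex, three edges, two triangles", {
  sb <- load_sumba()
  sp <- split_population(sb$populations, "Anakalang", epsilon = 1e-3,
                         bearing_deg = 30)
  expect_equal(sp$diff$vertices_delta, 1)
  expect_equal(sp$diff$edges_delta, 3)
  expect_equal(sp$diff$triangles_delta, 2)
  # Voronoi view: one new face; faces always equal populations
  expect_equal(unname(map_counts(voronoi_dual(sp$after))["F"]), 9)
})

test_that("post-split weights follow the inheritance convention", {
  sb <- load_sumba()
  sp <- split_population(sb$populations, "Anakalang", epsilon = 1e-3,
                         weights = sb$edges[, c("pop_a", "pop_b", "weight")])
  w <- sp$weights
  expect_equal(nrow(w), nrow(sp$after$edges))
  # a surviving edge keeps its weight
  k <- which((w$pop_a == "Kodi" & w$pop_b == "Loli") |
               (w$pop_a == "Loli" & w$pop_b == "Kodi"))
  expect_equal(w$weight[k], 0.01113)
  # new edges (daughter-daughter among them) get half the min incident weight
  inc <- sb$edges$weight[sb$edges$pop_a == "Anakalang" |
                           sb$edges$pop_b == "Anakalang"]
  dd <- which(grepl("Anakalang_", w$pop_a) & grepl("Anakalang_", w$pop_b))
  expect_equal(w$weight[dd], 0.5 * min(inc))
  # inherited: a daughter adjacent to Loli carries the ancestral Loli weight
  dl <- which((grepl("Anakalang_", w$pop_a) & w$pop_b == "Loli") |
                (w$pop_a == "Loli" & grepl("Anakalang_", w$pop_b)))
  expect_true(all(w$weight[dl] ==
                    sb$edges$weight[(sb$edges$pop_a == "Anakalang" &
                                       sb$edges$pop_b == "Loli") |
                                      (sb$edges$pop_a == "Loli" &
                                         sb$edges$pop_b == "Anakalang")]))
})

test_that("non-incident edges survive a tiny split", {
  sb <- load_sumba()
  sp <- split_population(sb$populations, "Anakalang", epsilon = 1e-5)
  expect_true(all(grepl("Anakalang", sp$diff$lost_edges)))
  expect_true(all(grepl("Anakalang", sp$diff$new_edges)))
})

test_that("merge is the exact inverse of split", {
  sb <- load_sumba()
  sp <- split_population(sb$populations, "Wanokaka", epsilon = 1e-4,
                         bearing_deg = 75)
  mg <- merge_populations(sp$populations, "Wanokaka_l", "Wanokaka_r")
  expect_equal(nrow(mg$populations), 8)
  expect_true("Wanokaka" %in% mg$populations$name)
  key <- function(cx) sort(paste(cx$edges$pop_a, cx$edges$pop_b))
  expect_equal(key(mg$after), key(delaunay_triangulate(sb$populations)))
  # midpoint restores the ancestor location
  i <- match("Wanokaka", mg$populations$name)
  j <- match("Wanokaka", sb$populations$name)
  expect_equal(mg$populations$longitude_deg[i], sb$populations$longitude_deg[j],
               tolerance = 1e-9)
  expect_equal(mg$populations$latitude_deg[i], sb$populations$latitude_deg[j],
               tolerance = 1e-9)
  expect_error(merge_populations(sb$populations, "Kodi", "Rindi_nope"),
               "not Delaunay-adjacent|unknown")
})

test_that("a 5-to-4 merge lands inside the enumerated CombMS(4)", {
  pts <- random_points(5, seed = 77)
  cx <- delaunay_triangulate(pts)
  pair <- cx$edges[1, c("pop_a", "pop_b")]
  mg <- merge_populations(pts, pair$pop_a, pair$pop_b)
  expect_equal(nrow(mg$populations), 4)
  code <- canonical_code(voronoi_dual(mg$after))
  all4 <- unlist(lapply(enumerate_combms(4)$layers, names))
  expect_true(code %in% all4)
})

test_that("transitions between patterns are classified with their pivot", {
  p <- sumba_pattern()
  expect_equal(classify_transition(p, p)$kind, "none")
  k4 <- k4_map()
  w <- whitehead_move(k4, 4)
  cl <- classify_transition(k4, w)
  expect_equal(cl$kind, "whitehead")
  w2 <- whitehead_move(k4, cl$pivot)
  expect_equal(canonical_code(w2), canonical_code(w))
  m3 <- contract_edge(k4, 2)
  expect_equal(classify_transition(k4, m3)$kind, "contraction")
  expect_equal(classify_transition(m3, k4)$kind, "expansion")
  sb <- load_sumba()
  sp <- split_population(sb$populations, "Loli", 1e-4)
  expect_equal(classify_transition(p$graph, voronoi_dual(sp$after))$kind,
               "split")
  expect_equal(classify_transition(voronoi_dual(sp$after), p$graph)$kind,
               "merge")
})

test_that("facet crossings are located by linear interpolation", {
  ll <- t(apply(tetra_points(), 1, migpatterns:::unit_to_latlon))
  pops <- data.frame(name = rownames(tetra_points()),
                     longitude_deg = ll[, 1], latitude_deg = ll[, 2])
  cx <- delaunay_triangulate(tetra_points())
  w <- data.frame(pop_a = cx$edges$pop_a, pop_b = cx$edges$pop_b, weight = 0.5)
  pt <- assemble_pattern(pops, w)
  P <- build_load_system(pt$graph, pt$loads)
  # move along a null direction of the incidence so loads stay constant
  ns <- svd(P$Aeq, nv = 6)$v[, 5:6, drop = FALSE]   # rank 4 of 6
  dir <- ns[, 1] / max(abs(ns[, 1]))
  dir <- dir * sign(dir[which.max(abs(dir))])  # largest coordinate = +1
  w0 <- rep(0.5, 6)
  w1 <- w0 - 0.75 * dir                      # some coordinate crosses 0
  W <- rbind(w0, w1)
  colnames(W) <- as.character(P$vars)
  ev <- detect_facet_crossing(pt, c(0, 1), W)
  expect_gt(nrow(ev), 0)
  j <- which.max(abs(dir))
  hit <- ev[ev$label == P$vars[j] & ev$boundary == 0, ]
  expect_equal(hit$time, 0.5 / 0.75, tolerance = 1e-9)
  # constant interior path: no events
  Wc <- rbind(w0, w0); colnames(Wc) <- as.character(P$vars)
  expect_equal(nrow(detect_facet_crossing(pt, c(0, 1), Wc)), 0)
  # drifting loads violate the fixed-segment conservation
  Wd <- rbind(w0, w0 + 0.1); colnames(Wd) <- as.character(P$vars)
  expect_error(detect_facet_crossing(pt, c(0, 1), Wd), "inconsistent path")
})
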