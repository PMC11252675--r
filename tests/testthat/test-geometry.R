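test_that("the disc monolayer packs hexagonal rings to the exact cell count", {
  d22 <- build_disc_monolayer(22, cell_diameter = 21)
  expect_equal(nrow(d22$cells), 22)
  expect_gte(min(stats::dist(positions(d22))), 0.8 * 21)
  d1 <- build_disc_monolayer(1)
  expect_equal(nrow(d1$cells), 1)
  # centre + first full ring: centre cell touches all six ring cells
  d7 <- build_disc_monolayer(7)
  p <- positions(d7)
  dd <- sqrt(rowSums((p[-1, ] - matrix(p[1, ], 6, 3, byrow = TRUE))^2))
  expect_true(all(abs(dd - 0.85 * 21) < 1e-9))
  g <- neighbours(d7, neighbour_rule("contact"))
  expect_equal(graph_degrees(g)[1], 6)
  expect_error(build_disc_monolayer(7, spacing_factor = 0.7), "overlap")
})

test_that("disc building is deterministic", {
  expect_identical(positions(build_disc_monolayer(22)),
                   positions(build_disc_monolayer(22)))
})

test_that("the spheroid retains close-packed sites in distance order", {
  sp <- build_spheroid(103, spheroid_diameter = 100, cell_diameter = 21)
  expect_equal(nrow(sp$cells), 103)
  expect_lt(abs(sp$meta$bounding_diameter - 100), 20)
  expect_gte(min(stats::dist(positions(sp))), 0.8 * 21 - 1e-9)
  expect_equal(nrow(build_spheroid(1)$cells), 1)
  # distance-sorted retention: rebuild the candidate lattice independently
  # and verify no excluded site is closer than the farthest included one
  a <- sp$meta$spacing * sqrt(2)
  base <- as.matrix(expand.grid(i = -6:6, j = -6:6, k = -6:6))
  offs <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  cand <- do.call(rbind, lapply(1:4, function(b)
    a * (base + matrix(offs[b, ], nrow(base), 3, byrow = TRUE))))
  rmax <- sp$meta$bounding_diameter / 2
  inside <- sum(sqrt(rowSums(cand^2)) < rmax - 1e-9)
  expect_lte(inside, 103)
  expect_error(build_spheroid(500, spheroid_diameter = 100), "infeasible")
})

test_that("the slab is a rectangular lattice with exact counts and extents", {
  sl <- build_slab(31, 11, 7, cell_diameter = 21)
  expect_equal(nrow(sl$cells), 2387)
  expect_equal(unname(sl$meta$extent), c(651, 231, 147))
  p <- positions(sl)
  expect_equal(apply(p, 2, max) - apply(p, 2, min),
               c(30, 10, 6) * 21, ignore_attr = TRUE)
  expect_equal(nrow(build_slab(1, 1, 1)$cells), 1)
  expect_equal(nrow(build_slab(2, 2, 1)$cells), 4)
})

test_that("the radius rule counts 8 in-plane neighbours just above the diagonal", {
  sq <- build_slab(5, 5, 1, cell_diameter = 21)
  g <- neighbours(sq, neighbour_rule("radius", R = 21 * sqrt(2) * 1.01))
  # interior cell of the 5 x 5 plane
  centre <- which(abs(positions(sq)[, 1]) < 1e-9 &
                    abs(positions(sq)[, 2]) < 1e-9)
  expect_equal(graph_degrees(g)[centre], 8)
})

test_that("the contact rule counts 4 neighbours in a square-packed touching monolayer", {
  sq <- build_slab(5, 5, 1, cell_diameter = 21)
  g <- neighbours(sq, neighbour_rule("contact"))
  centre <- which(abs(positions(sq)[, 1]) < 1e-9 &
                    abs(positions(sq)[, 2]) < 1e-9)
  expect_equal(graph_degrees(g)[centre], 4)
})

test_that("an isolated cell has no neighbours", {
  t1 <- tissue(matrix(c(0, 0, 0), 1), radius = 10.5)
  expect_equal(nrow(neighbours(t1, neighbour_rule("radius", R = 50))$edges), 0)
})

test_that("neighbour computation agrees with the brute-force pairwise check", {
  set.seed(8)
  # jittered grid cloud keeps the overlap invariant
  base <- as.matrix(expand.grid(x = 0:4, y = 0:4, z = 0:1)) * 25
  pts <- base[sample(nrow(base), 50), ] + matrix(runif(150, -1, 1), 50, 3)
  tis <- tissue(pts, radius = 10.5)
  for (rule in list(neighbour_rule("radius", R = 30),
                    neighbour_rule("contact", contact_slack = 0.25))) {
    g <- neighbours(tis, rule)
    p <- positions(tis)
    brute <- matrix(integer(0), 0, 2)
    for (i in 1:49) for (j in (i + 1):50) {
      d <- sqrt(sum((p[i, ] - p[j, ])^2))
      hit <- if (rule$kind == "radius") d < rule$R
             else d <= (1 + rule$contact_slack) * 21
      if (hit) brute <- rbind(brute, c(i, j))
    }
    expect_equal(unname(g$edges), unname(brute))
    # symmetric, irreflexive by construction
    expect_false(any(g$edges[, 1] == g$edges[, 2]))
  }
})

test_that("growing the neighbourhood radius never decreases any degree", {
  d22 <- build_disc_monolayer(22)
  degs <- sapply(c(18, 22, 31, 40), function(R)
    graph_degrees(neighbours(d22, neighbour_rule("radius", R = R))))
  expect_true(all(apply(degs, 1, function(x) all(diff(x) >= 0))))
})

test_that("slab interior cells have the maximal degree, boundary cells fewer", {
  sl <- build_slab(5, 4, 3, cell_diameter = 21)
  g <- neighbours(sl, neighbour_rule("contact"))
  deg <- graph_degrees(g)
  p <- positions(sl)
  interior <- abs(p[, 1]) <= 21 + 1e-9 & abs(p[, 2]) <= 10.5 + 1e-9 &
    abs(p[, 3]) < 1e-9  # strictly inside on every axis
  expect_true(all(deg[interior] == 6))
  expect_true(all(deg[!interior] < 6))
})

test_that("tissue and edge-list files round-trip", {
  d7 <- build_disc_monolayer(7)
  d7$cells$frozen[3] <- TRUE
  tf <- tempfile()
  write_tissue(d7, tf)
  back <- read_tissue(tf)
  expect_equal(positions(back), positions(d7), tolerance = 1e-12)
  expect_equal(back$cells$frozen, d7$cells$frozen)
  g <- neighbours(d7, neighbour_rule("contact"))
  ef <- tempfile()
  write_edges(g, ef)
  expect_identical(read_edges(ef, n = 7)$edges, g$edges)
  vf <- tempfile(fileext = ".vtk")
  write_vtk(d7, vf)
  expect_match(readLines(vf, n = 5)[5], "POINTS 7")
})
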