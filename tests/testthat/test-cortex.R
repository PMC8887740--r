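# Geometry, energetics and internal forces of a single cortex loop.

test_that("segment geometry satisfies closed-polygon identities", {
  hexa <- regular_polygon_loop(6, radius = 2)
  geo <- segment_geometry(hexa)
  # unstrained by construction: ell_hat defaults to current lengths
  expect_equal(geo$eps, rep(0, 6), tolerance = 1e-12)
  expect_equal(sum(geo$theta), 2 * pi, tolerance = 1e-10)
  expect_equal(sqrt(rowSums(geo$d3^2)), rep(1, 6), tolerance = 1e-12)
  # circle curvature converges to 1/R under refinement
  for (n in c(40, 160)) {
    circ <- regular_polygon_loop(n, radius = 2)
    geo <- segment_geometry(circ)
    expect_equal(mean(geo$c), 0.5, tolerance = 2e-3 / n * 40)
  }
  # lambda = gamma * alpha identity
  lp <- random_loop(8, seed = 2)
  geo <- segment_geometry(lp)
  lambda <- geo$d / lp$ell_hat
  expect_equal(lambda, lp$gamma * geo$alpha, tolerance = 1e-12)
})

test_that("degenerate segments and invalid construction are rejected", {
  xy <- rbind(c(0, 0), c(1, 0), c(1, 0), c(0, 1))
  expect_error(cortex_loop(xy, cell_id = 7L), "cell 7")
  expect_error(cortex_loop(rbind(c(0, 0), c(1, 0), c(1, 1)), cell_id = 1L),
               "4 nodes")
  lp <- regular_polygon_loop(6)
  expect_error(apply_active_contraction(lp, 1:2, gamma = 1.2), "gamma")
  expect_error(apply_active_contraction(lp, 1:2, gamma = 0), "gamma")
  # figure-eight polyline is rejected as self-intersecting
  fig8 <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_error(cortex_loop(fig8, cell_id = 3L), "intersect")
})

test_that("elastic energy: zero ground state, stretch and bending terms", {
  rod <- open_rod(n = 11, length = 5)
  expect_equal(elastic_energy(rod), 0, tolerance = 1e-14)
  # uniform stretch alpha = 1.1 over reference length L: E = 0.005 L
  stretched <- rod
  stretched$xy[, 2] <- stretched$xy[, 2] * 1.1
  expect_equal(elastic_energy(stretched), 0.005 * 5, tolerance = 1e-10)
  # closed circle of radius R: bending energy -> pi kappa^2 / R within 1%
  for (n in c(60, 240)) {
    circ <- regular_polygon_loop(n, radius = 2, kappa = 0.1)
    expect_equal(elastic_energy(circ), pi * 0.01 / 2,
                 tolerance = 0.01 * (60 / n))
  }
  # free active contraction is stress free: gamma = 0.94 everywhere and
  # current length = gamma * ell_hat gives eps = 0 and zero energy
  lp <- regular_polygon_loop(30, radius = 1, kappa = 0)
  lp <- apply_active_contraction(lp, gamma = 0.94)
  lp$xy <- lp$xy * 0.94
  geo <- segment_geometry(lp)
  expect_equal(geo$alpha, rep(1, 30), tolerance = 1e-12)
  # held-fixed contraction: alpha = 1/gamma, eps = 1/gamma - 1
  held <- regular_polygon_loop(30, radius = 1, kappa = 0)
  held <- apply_active_contraction(held, gamma = 0.94)
  geo <- segment_geometry(held)
  expect_equal(geo$eps, rep(1 / 0.94 - 1, 30), tolerance = 1e-12)
})

test_that("energy is invariant under rigid motions", {
  lp <- random_loop(10, seed = 4)
  E0 <- elastic_energy(lp)
  a <- 0.7
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  moved <- lp
  moved$xy <- lp$xy %*% R + matrix(c(3, -2), nrow(lp$xy), 2, byrow = TRUE)
  expect_equal(elastic_energy(moved), E0, tolerance = 1e-10 * max(1, E0))
})

test_that("internal force is the negative energy gradient and sums to zero", {
  for (seed in 1:3) {
    lp <- random_loop(6, seed = seed)
    f <- internal_force(lp)
    g <- fd_gradient(lp)
    expect_lt(max(abs(f + g)) / max(abs(g)), 1e-6)
    expect_equal(colSums(f), c(0, 0), tolerance = 1e-12)
  }
  # straight unstretched rod: zero force everywhere
  rod <- open_rod(n = 9, length = 4)
  expect_equal(max(abs(internal_force(rod))), 0, tolerance = 1e-13)
})

test_that("remesh conserves reference length and area, and is idempotent", {
  lp <- regular_polygon_loop(40, radius = 3)
  lp$gamma[] <- 0.97
  # stretch one segment 3x by moving a node
  lp$xy[5, ] <- lp$xy[5, ] + 0.9 * (lp$xy[6, ] - lp$xy[5, ])
  L_hat <- sum(lp$ell_hat)
  L_ref <- sum(lp$gamma * lp$ell_hat)
  A <- abs(acam:::polygon_area(lp$xy))
  res <- remesh(lp, target_spacing = 0.5)
  lp2 <- res$loop
  expect_lt(abs(sum(lp2$ell_hat) - L_hat) / L_hat, 1e-9)
  expect_lt(abs(sum(lp2$gamma * lp2$ell_hat) - L_ref) / L_ref, 1e-9)
  expect_lt(abs(abs(acam:::polygon_area(lp2$xy)) - A) / A, 1e-5)
  d <- acam:::segment_lengths(lp2$xy, TRUE)
  expect_true(all(d <= 2 * 0.5 + 1e-9))
  # idempotent after the first pass
  res2 <- remesh(lp2, target_spacing = 0.5)
  expect_identical(nrow(res2$loop$xy), nrow(lp2$xy))
  expect_equal(res2$loop$xy, lp2$xy, tolerance = 1e-12)
  # uniform loop untouched
  uni <- regular_polygon_loop(40, radius = 3)
  expect_identical(nrow(remesh(uni, 0.5)$loop$xy), 40L)
  expect_error(remesh(uni, -1), "positive")
})
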