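# Junction maps, vertex openings, T1 length, areas, tensions, stress.

test_that("areas and perimeters: closed forms and invariances", {
  a <- 2.5
  hexa <- regular_polygon_loop(6, radius = a)
  expect_equal(cell_area(hexa), 3 * sqrt(3) / 2 * a^2, tolerance = 1e-12)
  expect_equal(cell_perimeter(hexa), 6 * a, tolerance = 1e-12)
  moved <- hexa
  moved$xy <- hexa$xy + matrix(c(11, -7), 6, 2, byrow = TRUE)
  expect_equal(cell_area(moved), cell_area(hexa), tolerance = 1e-12)
})

test_that("cortical tension is the elastic strain of each segment", {
  lp <- regular_polygon_loop(20, radius = 2)
  expect_equal(cortical_tension(lp), rep(0, 20), tolerance = 1e-12)
  # held-contracted segment with gamma = 0.94 at unchanged geometry
  lp2 <- apply_active_contraction(lp, gamma = 0.94)
  expect_equal(cortical_tension(lp2), rep(1 / 0.94 - 1, 20),
               tolerance = 1e-12)
})

test_that("junction map finds junctions and vertices on a settled tissue", {
  ts <- three_cell_tissue(pinned = TRUE, mode = "stochastic")
  tr <- simulate_tissue(ts, protocol_none(), n_steps = 4, seed = 11,
                        track_labels = FALSE)
  jm <- detect_junctions(tr$tissue)
  expect_s3_class(jm, "acam_junction_map")
  expect_gte(nrow(jm$junctions), 3L)
  # junction lengths never exceed the cortex perimeter
  per <- min(vapply(tr$tissue$loops, cell_perimeter, numeric(1)))
  expect_true(all(jm$junctions$length < per))
  # determinism given a snapshot
  jm2 <- detect_junctions(tr$tissue)
  expect_identical(jm$junctions, jm2$junctions)
})

test_that("vertex opening measures the inscribed circle radius", {
  # three tangent chords at 120 degrees: their incircle radius equals the
  # apex distance r0 exactly
  mk_chord <- function(angle, r0, cell_id) {
    u <- c(cos(angle), sin(angle))
    tv <- c(-sin(angle), cos(angle))
    t <- seq(-4, 4, by = 0.25)
    xy <- cbind(r0 * u[1] + t * tv[1], r0 * u[2] + t * tv[2])
    cortex_loop(xy, cell_id = cell_id, closed = FALSE, check = FALSE)
  }
  angs <- pi / 2 + c(0, 2, -2) * pi / 3
  ts <- acam_tissue(lapply(1:3, function(k) mk_chord(angs[k], 1.2, k)),
                    params = list())
  dv <- vertex_opening(ts, center = c(0, 0), cells = 1:3,
                       search_radius = 2)
  expect_equal(dv, 1.2, tolerance = 0.01)
  # three cell polygons meeting with (almost) zero gap: opening ~ 0
  b <- acam:::hex_basis(3)
  ctrs <- rbind(c(0, 0), b$u, b$v)
  ctrs <- sweep(ctrs, 2, colMeans(ctrs))
  loops0 <- lapply(1:3, function(k) {
    co <- acam:::polygon_offset(acam:::hexagon_corners(ctrs[k, ], 3), 0.02)
    cortex_loop(acam:::discretise_polygon(co, 0.4)$xy, cell_id = k,
                check = FALSE)
  })
  ts0 <- acam_tissue(loops0, params = list())
  expect_lt(vertex_opening(ts0, center = c(0, 0), cells = 1:3,
                           search_radius = 2), 0.1)
})

test_that("signed T1 length crosses zero at the 4-way configuration", {
  jm <- structure(list(junctions = data.frame(
    cell_i = c(1L, 1L), cell_j = c(2L, 3L), length = c(3.2, 5),
    n_bonds = c(5L, 8L), n_runs = 1L, mid_x = 0, mid_y = 0)),
    class = "acam_junction_map")
  expect_equal(signed_t1_length(jm), -3.2)
  # both absent: exactly zero
  jm$junctions <- jm$junctions[0, ]
  expect_equal(signed_t1_length(jm), 0)
  # growing junction present: positive
  jm$junctions <- data.frame(cell_i = 3L, cell_j = 4L, length = 1.7,
                             n_bonds = 3L, n_runs = 1L, mid_x = 0,
                             mid_y = 0)
  expect_equal(signed_t1_length(jm), 1.7)
})

test_that("cell stress is isotropic under symmetric loading", {
  # circular cell bonded to a concentric circular wall: symmetric pull
  circ <- regular_polygon_loop(60, radius = 3)
  wall_t <- 2 * pi * (0:59) / 60
  wall <- list(xy = cbind(4 * cos(wall_t), 4 * sin(wall_t)),
               corner = rep(FALSE, 60), pinned = FALSE)
  ts <- acam_tissue(list(circ), params = list(mode = "meanfield",
                                              bind_range = 1.4),
                    wall = wall)
  st <- cell_stress(ts, 1L)
  ev <- eigen(st$sigma, symmetric = TRUE)$values
  expect_lt(abs(ev[1] - ev[2]), 0.15 * max(abs(ev)))
  # force-free cell: zero stress
  lone <- acam_tissue(list(circ), params = list())
  st0 <- cell_stress(lone, 1L)
  expect_equal(st0$P_cell, 0, tolerance = 1e-12)
})

test_that("kymograph labels are flat in a passive run", {
  ts <- three_cell_tissue(pinned = TRUE, mode = "stochastic")
  tr <- simulate_tissue(ts, protocol_none(), n_steps = 5, seed = 3)
  ky <- material_kymograph(tr, 1L)
  expect_true(all(c("step", "label", "s", "partner") %in% names(ky)))
  # material points barely move along the cortex in a passive tissue
  drift <- tapply(ky$s, ky$label, function(s) diff(range(s)))
  expect_lt(stats::median(drift), 0.5)
})

test_that("slippage measure is antisymmetric under cortex swap", {
  ts <- three_cell_tissue(pinned = TRUE, mode = "stochastic")
  tr <- simulate_tissue(ts, protocol_none(), n_steps = 5, seed = 3)
  s12 <- slippage_shear(tr, c(1L, 2L))
  s21 <- slippage_shear(tr, c(2L, 1L))
  ok <- stats::complete.cases(cbind(s12$slip, s21$slip))
  expect_gt(sum(ok), 2)
  # opposite sign (tangent direction flips with the reference cortex)
  expect_lt(max(abs(s12$slip[ok] + s21$slip[ok])), 0.6)
})
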