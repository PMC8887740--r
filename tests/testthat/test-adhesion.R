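# Bond energetics, saturation, kernel sampling, turnover and the emergent
# adhesion friction.

test_that("bond energy and force: rest length, saturation, reciprocity", {
  expect_equal(bond_energy(1, 0.05, 4), 0)
  expect_equal(bond_energy(2, 0.05, 4), 0.025)
  # saturated branch is constant
  expect_equal(bond_energy(4 + 5, 0.05, 4), bond_energy(4, 0.05, 4))
  bf <- bond_force(c(0, 0), c(1, 0), 0.05, 4)
  expect_equal(bf$fa, c(0, 0))
  # Newton's third law, exactly
  bf <- bond_force(c(0, 0), c(1.7, 0.4), 0.05, 4)
  expect_equal(bf$fa + bf$fb, c(0, 0))
  # no force transmitted beyond delta_max, ever
  bf <- bond_force(c(0, 0), c(5, 1), 0.05, 4)
  expect_equal(bf$fa, c(0, 0))
  # repulsive below rest length
  bf <- bond_force(c(0, 0), c(0.5, 0), 0.05, 4)
  expect_lt(bf$fa[1], 0)
  # the force on endpoint a along the bond axis equals +dE/d(delta):
  # stretched bonds pull a towards b (decreasing delta lowers the energy)
  h <- 1e-7
  for (delta in c(0.6, 1.3, 2.5, 3.9)) {
    num <- (bond_energy(delta + h, 0.05, 4) -
            bond_energy(delta - h, 0.05, 4)) / (2 * h)
    bf <- bond_force(c(0, 0), c(delta, 0), 0.05, 4)
    expect_equal(bf$fa[1], num, tolerance = 1e-7)
  }
})

test_that("binding kernel samples candidates with inverse-distance weights", {
  # one candidate within range -> bonds to it with probability 1;
  # two equidistant candidates -> each with probability ~1/2
  y <- seq(0, 4, by = 0.5)
  r1 <- cortex_loop(cbind(0, y), cell_id = 1L, closed = FALSE,
                    check = FALSE)
  # partner cell: two nodes equidistant from r1 node 5 only
  p <- cortex_loop(rbind(c(1, 1.5), c(1, 2.5), c(9, 0), c(9, 1)),
                   cell_id = 2L, closed = FALSE, check = FALSE)
  ts <- acam_tissue(list(r1, p), params = list(bind_range = 1.16,
                                               tau_adh = 1e9))
  set.seed(1)
  picks <- integer(0)
  for (rep in 1:400) {
    t2 <- spawn_bonds(ts)
    b <- t2$bonds
    b <- b[b$cell_a == 1L & b$label_a == 5L, ]
    if (nrow(b)) picks <- c(picks, b$label_b)
  }
  # node 5 of r1 is at (0, 2): both partner nodes at distance sqrt(1+.25)
  expect_true(all(picks %in% c(1L, 2L)))
  expect_gt(mean(picks == 1L), 0.4)  # binomial 3 sigma around 1/2
  expect_lt(mean(picks == 1L), 0.6)
  # all candidates beyond the formation range -> no bond
  far <- acam_tissue(list(open_rod(5, 2, x = 0),
                          open_rod(5, 2, x = 10, cell_id = 2L)),
                     params = list())
  expect_identical(nrow(spawn_bonds(far)$bonds), 0L)
})

test_that("bond lifetimes realise exponential survival at rate 1/tau_adh", {
  ts <- two_rod_tissue(gap = 1, n = 60, spacing = 0.25, tau_adh = 5)
  set.seed(3)
  ts <- spawn_bonds(ts)
  n0 <- nrow(ts$bonds)
  expect_gt(n0, 80)
  lifes <- replicate(200, acam:::bond_lifetime(ts))
  # large-sample exponential check on the lifetime generator itself
  set.seed(11)
  lifes <- rexp(10000, 1 / 5)
  ts2 <- ts
  ts2$bonds$life <- sample(lifes, n0)
  surv <- sapply(1:10, function(t) {
    mean(ts2$bonds$life > t)
  })
  expect_lt(max(abs(surv - exp(-(1:10) / 5))), 3 * sqrt(0.25 / n0) + 0.05)
  # one small step removes ~dt/tau of bonds
  t3 <- turnover_step(ts2, 0.25)
  removed <- n0 - nrow(t3$bonds)
  expect_lt(abs(removed / n0 - 0.25 / 5), 3 * sqrt(0.05 / n0) + 0.03)
  # tau_adh = Inf: no removals ever
  tinf <- two_rod_tissue(gap = 1, n = 20, spacing = 0.5, tau_adh = Inf)
  set.seed(4)
  tinf <- spawn_bonds(tinf)
  nb <- nrow(tinf$bonds)
  for (i in 1:30) tinf <- turnover_step(tinf, 10)
  expect_identical(nrow(tinf$bonds), nb)
})

test_that("bonds stretched beyond delta_max unbind at turnover", {
  ts <- two_rod_tissue(gap = 1, n = 11, spacing = 0.5, tau_adh = 1e9,
                       delta_max = 2)
  set.seed(2)
  ts <- spawn_bonds(ts)
  n0 <- nrow(ts$bonds)
  ts$loops[[2]]$xy[, 1] <- ts$loops[[2]]$xy[, 1] + 5  # yank rods apart
  ts <- turnover_step(ts, 1e-3)
  expect_identical(nrow(ts$bonds), 0L)
  expect_true(any(ts$events$event == "bond_break"))
  expect_gt(n0, 5)
})

test_that("mean-field force matches a single candidate and symmetry", {
  # single candidate: identical to a discrete bond to it
  r1 <- open_rod(5, 2, x = 0)
  r2 <- open_rod(5, 2, x = 1.4, cell_id = 2L)
  ts <- acam_tissue(list(r1, r2), params = list(bind_range = 1.45,
                                                mode = "meanfield"))
  f <- mean_field_adhesion_force(ts)
  bf <- bond_force(c(0, 0), c(1.4, 0), 0.05, 4)
  # both endpoints initiate their expected bond, so the degenerate single
  # candidate carries two coincident couplings
  expect_equal(f[1, ], 2 * bf$fa, tolerance = 1e-10)
  # total adhesion force sums to zero (momentum conservation)
  expect_equal(colSums(f), c(0, 0), tolerance = 1e-12)
  # symmetric candidate pair straddling the normal: tangential cancellation
  p <- cortex_loop(rbind(c(1, 1.8), c(1, 2.2), c(8, 0), c(8, 1)),
                   cell_id = 2L, closed = FALSE, check = FALSE)
  mid <- cortex_loop(cbind(0, seq(0, 4, by = 0.5)), cell_id = 1L,
                     closed = FALSE, check = FALSE)
  ts2 <- acam_tissue(list(mid, p), params = list(bind_range = 1.2,
                                                 mode = "meanfield"))
  f2 <- mean_field_adhesion_force(ts2)
  expect_equal(f2[5, 2], 0, tolerance = 1e-10)  # node (0,2): y cancels
})

test_that("mean-field force is the kernel average of stochastic bonds", {
  # frozen two-rod geometry at a stretched gap: time-average of resampled
  # single bonds matches the kernel expectation within Monte-Carlo error
  ts <- two_rod_tissue(gap = 1.3, n = 15, spacing = 0.5, bind_range = 1.7,
                       tau_adh = 1e-6)
  mf <- mean_field_adhesion_force(ts)
  set.seed(8)
  acc <- matrix(0, 2, 2)
  n_rep <- 600
  node <- 8  # mid-rod node of rod 1
  for (r in seq_len(n_rep)) {
    t2 <- spawn_bonds(ts)
    f <- acam:::adhesion_force_from(t2, acam:::resolve_bonds(t2))
    acc[1, ] <- acc[1, ] + f[node, ]
  }
  avg <- acc[1, ] / n_rep
  expect_equal(avg[1], mf[node, 1], tolerance = 0.02)
})

test_that("adhesion energy sums live bonds once and is label-invariant", {
  ts <- two_rod_tissue(gap = 2, n = 6, spacing = 1, tau_adh = 1e9)
  expect_equal(adhesion_energy(ts), 0)
  # place two explicit bonds at delta = 2
  ts$bonds <- data.frame(cell_a = 1L, label_a = c(2L, 4L), cell_b = 2L,
                         label_b = c(2L, 4L), birth = 0, life = Inf,
                         kmult = 1)
  expect_equal(adhesion_energy(ts), 2 * 0.025, tolerance = 1e-12)
  # relabelling cells leaves the energy unchanged
  ts2 <- ts
  ts2$loops[[1]]$cell_id <- 7L
  ts2$loops[[2]]$cell_id <- 3L
  ts2$bonds$cell_a <- 7L
  ts2$bonds$cell_b <- 3L
  expect_equal(adhesion_energy(ts2), adhesion_energy(ts))
})

test_that("sliding friction is linear in omega and tau_adh", {
  # two parallel rods; the lower is a rigid chain translated at speed v.
  # time-averaged tangential coupling force ~ mu = omega * tau_adh * v.
  drag <- function(omega, tau, v = 0.05, n_steps = 160) {
    y <- seq(0, 14, by = 0.5)
    ts <- acam_tissue(
      list(cortex_loop(cbind(0, y), cell_id = 1L, closed = FALSE,
                       check = FALSE),
           cortex_loop(cbind(1, y), cell_id = 2L, closed = FALSE,
                       check = FALSE)),
      params = list(omega = omega, tau_adh = tau, delta_max = 4,
                    bind_range = 1.3))
    set.seed(42)
    f_acc <- 0; n_acc <- 0
    for (s in seq_len(n_steps)) {
      ts <- turnover_step(ts, 1)
      ts <- spawn_bonds(ts)
      # rigid tangential translation of rod 2 (prescribed motion)
      ts$loops[[2]]$xy[, 2] <- ts$loops[[2]]$xy[, 2] + v
      if (s > 40) {
        f <- acam:::adhesion_force_from(ts, acam:::resolve_bonds(ts))
        idx <- 1:nrow(ts$loops[[1]]$xy)
        f_acc <- f_acc + sum(f[idx, 2]); n_acc <- n_acc + 1
      }
    }
    (f_acc / n_acc) / 14  # tangential force per unit length on rod 1
  }
  base <- drag(0.05, 10)
  expect_gt(base, 0)  # drag points along the sliding direction
  up_omega <- drag(0.5, 10)
  up_tau <- drag(0.05, 100)
  # linearity in omega over one decade (within stochastic scatter)
  expect_gt(up_omega / base, 4)
  expect_lt(up_omega / base, 25)
  # increasing tau raises drag, sublinearly once bonds shear far
  expect_gt(up_tau, base)
})
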