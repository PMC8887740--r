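# Canned experiment drivers: each reproduces one of the standard in-silico
# protocols (vertex-geometry map, uniform-contractility fracture, the
# 14-cell T1 neighbour exchange and its variants). These are the building
# blocks used by the figure-replication interface and the acceptance script.

#' Equilibrium vertex geometry of a single cell in a hexagonal wall
#'
#' Quasi-statically ramps the adhesion strength from zero to `omega`,
#' relaxing with recurrent rest-length updates at each increment, until the
#' total cortex length change per cycle falls below `len_tol`; then reads
#' the vertex opening radius at the wall corners (mirror measure).
#'
#' @param kappa,omega mechanical parameters.
#' @param mesh,edge discretisation and hexagon edge length.
#' @param delta_max maximum binding length for this (passive) family.
#' @param n_ramp number of quasi-static adhesion increments.
#' @param len_tol final length-change termination criterion.
#' @return list: `delta_vert` (mean over the six corners), `per_corner`,
#'   `tissue`.
#' @export
exp_vertex_geometry <- function(kappa = 0.01, omega = 0.05, mesh = 0.5,
                                edge = 5, delta_max = 2, n_ramp = 8,
                                len_tol = 1e-4) {
  ts <- single_cell_in_hexagon(kappa, omega, mesh = mesh, edge = edge)
  ts$params$delta_max <- delta_max
  for (om in omega * seq_len(n_ramp) / n_ramp) {
    ts$params$omega <- om
    r <- relax_to_steady(ts, len_tol = if (om < omega) 10 * len_tol else
      len_tol, max_cycles = 400L)
    ts <- r$tissue
  }
  per_corner <- vapply(0:5, function(k) {
    corner <- edge * c(cos(k * pi / 3), sin(k * pi / 3))
    vertex_opening(ts, center = corner, cells = 1L, search_radius = 2.5)
  }, numeric(1))
  list(delta_vert = mean(per_corner), per_corner = per_corner, tissue = ts)
}

#' Fracture threshold under a quasi-static uniform contractility ramp
#'
#' Pinned 3-cell tissue; gamma decreases from 1 in small increments, each
#' relaxed to a steady state by recurrent rest-length updates. Fracture is
#' scored when the interior vertex opening exceeds delta_max (no bond can
#' span the hole).
#'
#' @param kappa,omega,mesh,edge,delta_max as in [exp_vertex_geometry()].
#' @param gamma_seq decreasing sequence of gamma values to scan.
#' @param cycles_per_gamma relaxation cycle budget per increment.
#' @return list: `gamma_fracture` (NA if no fracture in the scan),
#'   `history` (gamma, delta_vert), `tissue`.
#' @export
exp_fracture_ramp <- function(kappa = 0.01, omega = 0.05, mesh = 0.5,
                              edge = 5, delta_max = 2,
                              gamma_seq = seq(0.9975, 0.88, by = -0.0025),
                              cycles_per_gamma = 30L, seed = 1L) {
  ts <- three_cell_tissue(kappa, omega, mesh = mesh, edge = edge,
                          pinned = TRUE, mode = "stochastic")
  ts$params$delta_max <- delta_max
  tr <- simulate_tissue(ts, protocol_none(), n_steps = 10L, seed = seed,
                        track_labels = FALSE)
  ts <- tr$tissue
  hist <- list()
  gamma_fracture <- NA_real_
  opening <- function(t) vertex_opening(t, center = c(0, 0), cells = 1:3,
                                        search_radius = 1.5 * delta_max)
  set.seed(seed + 1L)
  for (g in gamma_seq) {
    fractured <- FALSE
    len0 <- total_cortex_length(ts)
    for (cyc in seq_len(cycles_per_gamma)) {
      for (k in seq_along(ts$loops)) ts$loops[[k]]$gamma[] <- g
      ts <- turnover_step(ts, 1)
      ts <- spawn_bonds(ts)
      ts <- viscoelastic_step(ts)
      ts <- equilibrate(ts, maxit = 800L, restarts = 1L)$tissue
      len1 <- total_cortex_length(ts)
      if (cyc %% 5L == 0L && opening(ts) > delta_max) {
        fractured <- TRUE
        break
      }
      if (abs(len1 - len0) < 1e-4) break
      len0 <- len1
    }
    dv <- opening(ts)
    hist[[length(hist) + 1L]] <- data.frame(gamma = g, delta_vert = dv)
    if (fractured || dv > delta_max) {
      gamma_fracture <- g
      break
    }
  }
  list(gamma_fracture = gamma_fracture, history = do.call(rbind, hist),
       tissue = ts)
}

#' Prepare the 14-cell T1 tissue in its pre-stressed adhered steady state
#'
#' Builds the patch, equilibrates, and runs a few passive settling steps so
#' that adhesion bonds populate the junctions and the background pre-stress
#' gamma0 is established before any junctional activity starts.
#'
#' @param tau_adh adhesion turnover timescale (units of tau_cor); values
#'   below 1 select the mean-field fast-adhesion regime.
#' @param delta_max,delta_gamma binding and sensing ranges.
#' @param gamma0 background pre-stress contraction.
#' @param mesh,edge discretisation.
#' @param seed RNG seed for the settling steps.
#' @param settle number of passive settling steps.
#' @return an `acam_tissue` ready for an active protocol.
#' @export
setup_t1_tissue <- function(tau_adh = 10, delta_max = 4, delta_gamma = 4,
                            gamma0 = 1 - 2e-4, mesh = 0.75, edge = 8,
                            seed = 1L, settle = 5L) {
  mode <- if (tau_adh < 1) "meanfield" else "stochastic"
  ts <- fourteen_cell_tissue(
    kappa = 0.01, omega = 0.05, gamma0 = gamma0, mesh = mesh, edge = edge,
    params = list(tau_adh = tau_adh, delta_max = delta_max,
                  delta_gamma = delta_gamma, mode = mode))
  # bonds must populate the pristine packing before the first minimisation:
  # an unadhered cortex relaxes towards a circle and destroys the fixture
  tr <- simulate_tissue(ts, protocol_none(), n_steps = settle, seed = seed)
  tr$tissue
}

t1_record <- function(tissue, step, report) {
  jm <- tissue$.jm
  ids <- vapply(tissue$loops, `[[`, integer(1), "cell_id")
  a1 <- cell_area(tissue$loops[[match(1L, ids)]])
  a2 <- cell_area(tissue$loops[[match(2L, ids)]])
  list(area1 = a1, area2 = a2,
       L12 = -signed_t1_length(jm, c(1L, 2L), c(0L, 0L)),
       L34 = signed_t1_length(jm, c(0L, 0L), c(3L, 4L)),
       signed_t1 = signed_t1_length(jm))
}

#' Run the standard active T1 neighbour-exchange protocol
#'
#' Junctional contractility `gamma` on the `{1,2}` junction of the 14-cell
#' patch (identity sensing over `delta_gamma`), stepping until the exchange
#' has resolved and the new `{3,4}` junction has extended to
#' `extension_stop`, or `n_steps` is exhausted, or a fracture is detected.
#'
#' @param tissue a tissue from [setup_t1_tissue()] (built if `NULL`).
#' @param gamma junctional contraction factor.
#' @param n_steps step budget.
#' @param seed RNG seed.
#' @param extension_stop stop once signed T1 length exceeds this.
#' @param tau_adh,delta_max,delta_gamma,mesh,gamma0 forwarded to
#'   [setup_t1_tissue()] when `tissue` is NULL.
#' @param watch_fracture record and stop on mid-junction rupture of {1,2}.
#' @return list: `trace` (with per-step areas and junction lengths),
#'   `fracture` (first fracture report or NULL), `resolved` (logical:
#'   {3,4} formed), `tissue`.
#' @export
run_t1 <- function(tissue = NULL, gamma = 0.94, n_steps = 300L, seed = 1L,
                   extension_stop = 2.5, tau_adh = 10, delta_max = 4,
                   delta_gamma = 4, mesh = 0.75, gamma0 = 1 - 2e-4,
                   watch_fracture = TRUE) {
  if (is.null(tissue)) {
    tissue <- setup_t1_tissue(tau_adh = tau_adh, delta_max = delta_max,
                              delta_gamma = delta_gamma, gamma0 = gamma0,
                              mesh = mesh, seed = seed)
  }
  frac <- NULL
  stopfun <- function(t, s) {
    jm <- t$.jm
    if (watch_fracture && is.null(frac)) {
      f <- detect_fracture(t, jm, check_vertices = s %% 5L == 0L)
      if (!is.null(f)) frac <<- c(f, step = s)
    }
    signed_t1_length(jm) >= extension_stop ||
      (!is.null(frac) && frac$kind == "vertex")
  }
  tr <- simulate_tissue(tissue, junction_contractility(c(1L, 2L), gamma),
                        n_steps = n_steps, seed = seed + 1L,
                        record = t1_record, stop_when = stopfun)
  list(trace = tr, fracture = frac, resolved = any(tr$obs$L34 > 0),
       tissue = tr$tissue)
}

#' Area-loss readout of a T1 run
#'
#' Minimum of the mean area of cells 1 and 2, normalised to its value at
#' the start of the active protocol.
#'
#' @param t1 result of [run_t1()].
#' @return list: `min_norm_area`, `loss_percent`.
#' @export
t1_area_loss <- function(t1) {
  ob <- t1$trace$obs
  mean_area <- (ob$area1 + ob$area2) / 2
  norm <- mean_area / mean_area[1]
  list(min_norm_area = min(norm), loss_percent = 100 * (1 - min(norm)))
}

#' Stall test: remove contractility at the unresolved 4-way configuration
#'
#' Runs the standard T1 until junction {1,2} has vanished but {3,4} has not
#' yet formed, then switches the activity back to the background gamma0 and
#' counts the steps for which the configuration remains a 4-way (neither
#' junction present).
#'
#' @param n_stall number of passive steps to observe.
#' @param seed RNG seed.
#' @param ... forwarded to [run_t1()] / [setup_t1_tissue()].
#' @return list: `stalled_steps`, `reached_4way`, `trace`.
#' @export
exp_stall <- function(n_stall = 1000L, seed = 1L, len_tol = 3, ...) {
  jlen <- function(jm, i, j) {
    r <- jm$junctions$cell_i == i & jm$junctions$cell_j == j
    if (any(r)) jm$junctions$length[which(r)[1]] else 0
  }
  # the unresolved 4-way: neither junction of substantial length (bond
  # turnover leaves a few-node contact vestige at the vertex, which is not
  # a junction)
  at_4way <- function(t, s) {
    jm <- t$.jm
    jlen(jm, 1L, 2L) < len_tol && jlen(jm, 3L, 4L) < len_tol
  }
  tissue <- setup_t1_tissue(seed = seed, ...)
  tr <- simulate_tissue(tissue, junction_contractility(c(1L, 2L), 0.94),
                        n_steps = 600L, seed = seed + 1L,
                        record = t1_record, stop_when = at_4way)
  reached <- at_4way(tr$tissue, 0L)
  if (!reached) {
    return(list(stalled_steps = 0L, reached_4way = FALSE, trace = tr))
  }
  count <- 0L
  # the long passive observation phase uses a higher per-step solver
  # budget: residual drift from capped equilibrations can otherwise nudge
  # the metastable 4-way into a spurious resolution
  tr$tissue$params$sim_maxit <- 800L
  keep_counting <- function(t, s) {
    jm <- t$.jm
    if (at_4way(t, s)) count <<- count + 1L
    # only a genuinely re-formed junction ends the stall; the bond vestige
    # at the 4-way fluctuates below the junction scale
    jlen(jm, 1L, 2L) > 3 || jlen(jm, 3L, 4L) > 3
  }
  tr2 <- simulate_tissue(tr$tissue, protocol_none(), n_steps = n_stall,
                         seed = seed + 2L, record = t1_record,
                         stop_when = keep_counting)
  list(stalled_steps = count, reached_4way = TRUE, trace = tr2)
}

#' Binding-range robustness scan of the T1 protocol
#'
#' Repeats the standard T1 protocol over a set of delta_max values with the
#' sensing range delta_gamma held fixed, recording whether the exchange
#' completes or the {1,2} junction ruptures.
#'
#' @param delta_max_values scan values.
#' @param delta_gamma fixed sensing range.
#' @param n_steps,seed,... forwarded to [run_t1()].
#' @return data.frame: delta_max, ruptured, resolved, steps.
#' @export
exp_dmax_scan <- function(delta_max_values = c(2, 3, 4, 6), delta_gamma = 4,
                          n_steps = 300L, seed = 1L, ...) {
  rows <- lapply(delta_max_values, function(dm) {
    r <- run_t1(delta_max = dm, delta_gamma = delta_gamma,
                n_steps = n_steps, seed = seed, ...)
    ruptured <- !is.null(r$fracture) && r$fracture$kind == "junction" &&
      all(sort(unlist(r$fracture$location)) == c(1L, 2L))
    data.frame(delta_max = dm, ruptured = ruptured, resolved = r$resolved,
               steps = nrow(r$trace$obs), min_L12 = min(r$trace$obs$L12))
  })
  do.call(rbind, rows)
}

#' Sequential contraction: second exchange or rosette
#'
#' Runs the standard T1 until the new {3,4} junction has just formed, then
#' applies contractility to the {1,3} junction under a (possibly different)
#' adhesion timescale. With fast turnover the second exchange completes;
#' with slow turnover (high adhesion friction) the two vertices of {3,4}
#' are dragged together into a rosette vertex shared by five cells.
#'
#' @param tau_adh_first,tau_adh_second adhesion timescales of the phases.
#' @param n_steps_second step budget of the second phase.
#' @param seed RNG seed.
#' @param gamma0_second background pre-stress in the second phase (set to 1
#'   to test rosette resolution without tissue tension).
#' @param phase1 optional precomputed first-phase trace (the run stopped
#'   as {3,4} just formed), reused across adhesion-timescale comparisons.
#' @param ... forwarded to [setup_t1_tissue()].
#' @return list: `outcome` ("rosette", "second_exchange" or "neither"),
#'   `rosette_cells` (member count of the merged vertex, NA if none),
#'   `trace2`, `tissue`.
#' @export
exp_sequential <- function(tau_adh_first = 10, tau_adh_second = 100,
                           n_steps_second = 250L, seed = 1L,
                           gamma0_second = 1 - 2e-4, phase1 = NULL, ...) {
  just_formed <- function(t, s) {
    any(t$.jm$junctions$cell_i == 3L & t$.jm$junctions$cell_j == 4L)
  }
  tr1 <- if (is.null(phase1)) {
    tissue <- setup_t1_tissue(tau_adh = tau_adh_first, seed = seed, ...)
    # the approach to the metastable merge needs full solver fidelity:
    # residual drift from capped equilibrations distorts the delicate
    # vertex bookkeeping near resolution
    tissue$params$sim_maxit <- 800L
    simulate_tissue(tissue, junction_contractility(c(1L, 2L), 0.94),
                    n_steps = 600L, seed = seed + 1L,
                    record = t1_record, stop_when = just_formed)
  } else phase1
  ts <- tr1$tissue
  ts$params$sim_maxit <- 800L
  if (!just_formed(ts, 0L)) {
    return(list(outcome = "neither", rosette_cells = NA_integer_,
                trace1 = tr1, trace2 = NULL, tissue = ts))
  }
  ts$params$tau_adh <- tau_adh_second
  ts$params$mode <- if (tau_adh_second < 1) "meanfield" else "stochastic"
  ts$params$gamma0 <- gamma0_second
  # the cell flanking {1,3} opposite cell 4: partner of the second
  # neighbour exchange
  jm0 <- detect_junctions(ts)
  jl <- function(jm, i, j) {
    r <- jm$junctions$cell_i == min(i, j) & jm$junctions$cell_j == max(i, j)
    if (any(r)) jm$junctions$length[which(r)[1]] else 0
  }
  with1 <- unique(c(jm0$junctions$cell_j[jm0$junctions$cell_i == 1L],
                    jm0$junctions$cell_i[jm0$junctions$cell_j == 1L]))
  with3 <- unique(c(jm0$junctions$cell_j[jm0$junctions$cell_i == 3L],
                    jm0$junctions$cell_i[jm0$junctions$cell_j == 3L]))
  flank <- setdiff(intersect(with1, with3), c(1L, 3L, 4L))
  flank <- if (length(flank)) flank[1] else NA_integer_
  rosette <- NA_integer_
  second <- FALSE
  watch <- function(t, s) {
    if (s <= 5L) return(FALSE)
    jm <- t$.jm
    v <- jm$vertices
    # rosette: the endpoints of the nascent {3,4} junction have been
    # dragged together while {1,3} shrank, merging into a vertex shared
    # by five or more cells
    if (jl(jm, 3, 4) < 1.5 && jl(jm, 1, 3) < 1.5 &&
        nrow(v) && any(v$n_cells >= 5L)) {
      rosette <<- v$n_cells[which(v$n_cells >= 5L)[1]]
      return(TRUE)
    }
    # second exchange: {1,3} removed and the junction joining its two
    # flanking cells (4 and `flank`) has formed and extends
    if (!is.na(flank) && jl(jm, 1, 3) < 0.8 &&
        jl(jm, 4, flank) >= 1.5 && jl(jm, 3, 4) >= 1.5) {
      second <<- TRUE
      return(TRUE)
    }
    FALSE
  }
  tr2 <- simulate_tissue(ts, junction_contractility(c(1L, 3L), 0.94),
                         n_steps = n_steps_second, seed = seed + 2L,
                         record = t1_record, stop_when = watch)
  outcome <- if (!is.na(rosette)) "rosette" else
    if (second) "second_exchange" else "neither"
  list(outcome = outcome, rosette_cells = rosette, trace1 = tr1,
       trace2 = tr2, tissue = tr2$tissue)
}
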