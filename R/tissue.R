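# Tissue assembly, quasi-static equilibration, viscoelastic time stepping,
# fracture detection and the main simulation loop.

#' Assemble a tissue
#'
#' A tissue is a set of cortex loops, a live adhesion bond table, an optional
#' fixed boundary wall (a closed node chain the outermost cortices adhere
#' to), and the global mechanical parameters. All lengths are in units of
#' the adhesion rest length delta_0 and time in units of the cortical
#' turnover time tau_cor.
#'
#' @param loops list of [cortex_loop()] objects with distinct cell ids.
#' @param params list of parameters; recognised entries (defaults):
#'   `kappa` (0.01) bending-to-stretching ratio, `omega` (0.05) adhesion
#'   stiffness, `delta_max` (4) maximum binding length (no force beyond),
#'   `bind_range` (1.1) range over which new bonds can form (capped by
#'   delta_max), `delta_gamma` (4) identity-sensing range, `tau_adh` (10) mean bond lifetime, `gamma0` (1)
#'   background contraction, `h` (0.5) target node spacing,
#'   `tol` (1e-6) equilibration residual, `maxit` (1500) iteration budget
#'   of a standalone equilibration, `sim_maxit` (400) per-simulation-step
#'   iteration cap (warm starts make most steps cheap; long passive
#'   observation runs may raise it for extra solver fidelity),
#'   `wall_corner_mult` (50) stiffness
#'   multiplier of wall-corner pins, `lifetime` ("exponential" or "fixed"),
#'   `mode` ("stochastic" or "meanfield": instantaneous kernel-weighted
#'   binding, the fast-adhesion limit used for quasi-static passive runs).
#' @param wall optional list with `xy` (m x 2 matrix of fixed node
#'   positions, a closed chain) and logical `corner` flags.
#' @return an object of class `acam_tissue`.
#' @export
acam_tissue <- function(loops, params = list(), wall = NULL) {
  ids <- vapply(loops, `[[`, integer(1), "cell_id")
  if (anyDuplicated(ids)) stop("cell ids must be distinct")
  if (any(ids < 1L)) stop("cell ids must be >= 1 (0 is the boundary wall)")
  p <- modifyList(list(kappa = 0.01, omega = 0.05, delta_max = 4,
                       bind_range = 1.1, delta_gamma = 4, tau_adh = 10,
                       gamma0 = 1,
                       h = 0.5, tol = 1e-6, wall_corner_mult = 50,
                       lifetime = "exponential", mode = "stochastic",
                       maxit = 1500L, sim_maxit = 400L), params)
  stopifnot(p$kappa > 0, p$omega >= 0, p$delta_max > 1, p$tau_adh > 0)
  for (i in seq_along(loops)) loops[[i]]$kappa <- p$kappa
  structure(list(loops = loops, bonds = empty_bond_table(), wall = wall,
                 params = p, clock = 0, mf = NULL,
                 events = empty_event_log(), jhist = list()),
            class = "acam_tissue")
}

#' @export
print.acam_tissue <- function(x, ...) {
  cat(sprintf(
    "<acam_tissue> %d cells, %d nodes, %d bonds, t = %g tau_cor (%s mode)\n",
    length(x$loops), sum(vapply(x$loops, function(l) nrow(l$xy), 1L)),
    nrow(x$bonds), x$clock, x$params$mode))
  invisible(x)
}

empty_event_log <- function() {
  data.frame(time = numeric(0), event = character(0), value = numeric(0))
}

append_event <- function(events, time, event, value = NA_real_) {
  rbind(events, data.frame(time = time, event = event, value = value))
}

# Flattened view: all node positions stacked, with per-node cell id and
# material label, per-segment reference lengths, and an index matrix mapping
# (cell row, label) -> flat node index.
tissue_flat <- function(tissue) {
  loops <- tissue$loops
  ns <- vapply(loops, function(l) nrow(l$xy), integer(1))
  off <- c(0L, cumsum(ns))
  xy <- do.call(rbind, lapply(loops, `[[`, "xy"))
  cell_ids <- vapply(loops, `[[`, integer(1), "cell_id")
  cell_of_node <- rep(cell_ids, ns)
  label_of_node <- unlist(lapply(loops, `[[`, "labels"))
  maxlab <- max(vapply(loops, function(l) max(l$labels), integer(1)))
  index <- matrix(NA_integer_, length(loops), maxlab)
  for (k in seq_along(loops)) {
    index[k, loops[[k]]$labels] <- off[k] + seq_len(ns[k])
  }
  ell <- unlist(lapply(loops, function(l) {
    e <- l$gamma * l$ell_hat
    if (!l$closed) e <- c(e, 1)
    e
  }))
  list(xy = xy, off = off, ns = ns, cell_ids = cell_ids,
       cell_of_node = cell_of_node, label_of_node = label_of_node,
       index = index, ell = ell,
       closed = vapply(loops, function(l) as.integer(l$closed), integer(1)))
}

tissue_wall_xy <- function(tissue) {
  if (is.null(tissue$wall)) empty_wall else tissue$wall$xy
}

# The resolved spring set acting in the current step: live discrete bonds,
# or the kernel-weighted mean-field couplings in fast-adhesion mode.
tissue_springs <- function(tissue) {
  if (identical(tissue$params$mode, "meanfield")) {
    mf <- if (is.null(tissue$mf)) mean_field_bonds(tissue) else tissue$mf
    if (nrow(tissue$bonds)) {  # persistent vertex pins coexist with kernel
      rb <- resolve_bonds(tissue)
      mf <- list(ba = c(mf$ba, rb$ba), bb = c(mf$bb, rb$bb),
                 bwall = c(mf$bwall, rb$bwall), bk = c(mf$bk, rb$bk))
    }
    mf
  } else {
    resolve_bonds(tissue)
  }
}

#' Total energy of the tissue
#'
#' Sum of the cortical elastic energies of all cells plus the adhesion
#' energy of all live bonds (boundary pins included).
#'
#' @param tissue an `acam_tissue`.
#' @return scalar dimensionless energy.
#' @export
total_energy <- function(tissue) {
  fl <- tissue_flat(tissue)
  rb <- tissue_springs(tissue)
  acam_energy_cpp(as.numeric(t(fl$xy)), fl$off, fl$closed, fl$ell,
                  tissue$params$kappa^2, rb$ba - 1L, rb$bb - 1L, rb$bwall,
                  rb$bk, tissue$params$delta_max, tissue_wall_xy(tissue))
}

#' Relax node positions to mechanical equilibrium
#'
#' Minimises the total energy over all cortex node positions with the bond
#' topology, rest lengths and activity field frozen (limited-memory BFGS
#' with analytic gradients). At convergence every node satisfies the local
#' balance of internal cortical forces, adhesion forces and boundary pins to
#' within `tol`.
#'
#' @param tissue an `acam_tissue`.
#' @param tol maximum admissible per-node residual force.
#' @param maxit iteration budget per restart.
#' @param restarts number of restarts if the residual is not yet met.
#' @return list: the updated `tissue` and `report` (converged flag, residual,
#'   iterations, non-increasing energy trace).
#' @export
equilibrate <- function(tissue, tol = tissue$params$tol,
                        maxit = tissue$params$maxit, restarts = 2L) {
  stopifnot(tol > 0)
  fl <- tissue_flat(tissue)
  rb <- tissue_springs(tissue)
  wall <- tissue_wall_xy(tissue)
  k2 <- tissue$params$kappa^2
  dmax <- tissue$params$delta_max
  ba <- rb$ba - 1L; bb <- rb$bb - 1L
  fn <- function(p) acam_energy_cpp(p, fl$off, fl$closed, fl$ell, k2,
                                    ba, bb, rb$bwall, rb$bk, dmax, wall)
  gr <- function(p) acam_grad_cpp(p, fl$off, fl$closed, fl$ell, k2,
                                  ba, bb, rb$bwall, rb$bk, dmax, wall)
  par <- as.numeric(t(fl$xy))
  e_trace <- fn(par)
  iters <- 0L
  converged <- FALSE
  residual <- Inf
  for (r in seq_len(restarts + 1L)) {
    fit <- optim(par, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = maxit, pgtol = 0.5 * tol,
                                factr = 1e2, lmm = 8))
    par <- fit$par
    iters <- iters + fit$counts[1]
    e_trace <- c(e_trace, fit$value)
    g <- gr(par)
    residual <- max(sqrt(matrix(g, ncol = 2, byrow = TRUE)[, 1]^2 +
                         matrix(g, ncol = 2, byrow = TRUE)[, 2]^2))
    if (residual <= tol) { converged <- TRUE; break }
  }
  xy <- matrix(par, ncol = 2, byrow = TRUE)
  for (k in seq_along(tissue$loops)) {
    tissue$loops[[k]]$xy <- xy[(fl$off[k] + 1L):fl$off[k + 1L], , drop = FALSE]
  }
  list(tissue = tissue,
       report = list(converged = converged, residual = residual,
                     iterations = as.integer(iters), energy = e_trace))
}

#' Viscoelastic rest-length relaxation (one cortical turnover time)
#'
#' Resets every segment's undeformed length to its current length, so that
#' the stress-free reference length becomes gamma * (current length): all
#' residual elastic stress built since the previous step relaxes, while an
#' active field gamma < 1 re-arms its contraction against the new reference.
#' Where gamma = 1 the segment is left exactly unstrained.
#'
#' @param tissue an `acam_tissue` (normally just equilibrated).
#' @return the updated tissue (the simulation clock is advanced by
#'   [simulate_tissue()], which owns the step bookkeeping).
#' @export
viscoelastic_step <- function(tissue) {
  for (k in seq_along(tissue$loops)) {
    l <- tissue$loops[[k]]
    tissue$loops[[k]]$ell_hat <- segment_lengths(l$xy, l$closed)
  }
  tissue
}

# Remesh every loop to the tissue's target spacing and re-attach bonds whose
# endpoint labels were dropped. Errors if a re-attached endpoint would lie
# beyond delta_max of its partner.
remesh_tissue <- function(tissue) {
  h <- tissue$params$h
  changed <- FALSE
  for (k in seq_along(tissue$loops)) {
    l <- tissue$loops[[k]]
    d <- segment_lengths(l$xy, l$closed)
    if (all(d >= 0.5 * h & d <= 2 * h)) next
    res <- remesh(l, h)
    tissue$loops[[k]] <- res$loop
    changed <- TRUE
    if (length(res$label_map) && nrow(tissue$bonds)) {
      b <- tissue$bonds
      ia <- b$cell_a == l$cell_id & b$label_a %in% names(res$label_map)
      if (any(ia)) b$label_a[ia] <- res$label_map[as.character(b$label_a[ia])]
      ib <- b$cell_b == l$cell_id & b$label_b %in% names(res$label_map)
      if (any(ib)) b$label_b[ib] <- res$label_map[as.character(b$label_b[ib])]
      tissue$bonds <- b
    }
  }
  if (changed && nrow(tissue$bonds)) {
    # verify re-attached bonds are still within binding range
    rb <- resolve_bonds(tissue)
    fl <- tissue_flat(tissue)
    wall <- tissue_wall_xy(tissue)
    pa <- fl$xy[rb$ba, , drop = FALSE]
    pb <- matrix(0, length(rb$bb), 2)
    wv <- rb$bwall == 1L
    if (any(wv)) pb[wv, ] <- wall[rb$bb[wv], , drop = FALSE]
    if (any(!wv)) pb[!wv, ] <- fl$xy[rb$bb[!wv], , drop = FALSE]
    delta <- sqrt(rowSums((pb - pa)^2))
    bad <- delta > tissue$params$delta_max
    if (any(bad)) {
      # a re-attached bond beyond range carries no force; drop it
      tissue$bonds <- tissue$bonds[!bad, , drop = FALSE]
    }
  }
  tissue
}

#' Relax a tissue to a steady state by recurrent rest-length updates
#'
#' Alternates [viscoelastic_step()] and [equilibrate()] until the total
#' cortex length changes by less than `len_tol` between cycles (the
#' termination criterion for static problems), or `max_cycles` is reached.
#' In mean-field mode the kernel couplings are refreshed every cycle.
#'
#' @param tissue an `acam_tissue`.
#' @param len_tol termination threshold on the total cortex length change.
#' @param max_cycles cycle budget.
#' @param monitor optional function(tissue, cycle) called after each cycle;
#'   returning `TRUE` stops the iteration early.
#' @return list: `tissue`, `cycles`, `converged`.
#' @export
relax_to_steady <- function(tissue, len_tol = 1e-4, max_cycles = 400L,
                            monitor = NULL) {
  len0 <- total_cortex_length(tissue)
  converged <- FALSE
  cyc <- 0L
  for (cyc in seq_len(max_cycles)) {
    if (identical(tissue$params$mode, "meanfield")) {
      tissue$mf <- mean_field_bonds(tissue)
    }
    tissue <- viscoelastic_step(tissue)
    tissue <- equilibrate(tissue)$tissue
    len1 <- total_cortex_length(tissue)
    stop_now <- !is.null(monitor) && isTRUE(monitor(tissue, cyc))
    if (abs(len1 - len0) < len_tol) {
      converged <- TRUE
      break
    }
    len0 <- len1
    if (stop_now) break
  }
  list(tissue = tissue, cycles = cyc, converged = converged)
}

total_cortex_length <- function(tissue) {
  sum(vapply(tissue$loops,
             function(l) sum(segment_lengths(l$xy, l$closed)), numeric(1)))
}

#' Run a simulation
#'
#' The main loop. One simulation step corresponds to one cortical turnover
#' time tau_cor and executes, in order: protocol update of the activity
#' field, adhesion turnover and re-binding (or mean-field refresh),
#' viscoelastic rest-length relaxation, remeshing where needed, energy
#' minimisation, and recording of observables. Deterministic given
#' (tissue, protocol, seed).
#'
#' @param tissue an `acam_tissue`.
#' @param protocol an activity protocol from [protocol_none()] and friends,
#'   or `NULL` for a passive run at the background gamma0.
#' @param n_steps number of steps.
#' @param seed RNG seed (bond lifetimes and binding-kernel draws).
#' @param record optional function(tissue, step, report) returning a named
#'   list of extra per-step observables.
#' @param snapshot_every store full node-position snapshots at this cadence
#'   (0: never).
#' @param stop_when optional function(tissue, step) -> logical; stops early.
#' @param track_labels record per-step material-label positions (needed for
#'   kymographs and slippage measures).
#' @return an `acam_trace`: list with `tissue` (final state), `obs` (tidy
#'   per-step observable table), `snapshots`, `events`, `label_tracks`.
#' @export
simulate_tissue <- function(tissue, protocol = NULL, n_steps = 100L,
                            seed = 1L, record = NULL, snapshot_every = 0L,
                            stop_when = NULL, track_labels = TRUE) {
  set.seed(seed)
  if (is.null(protocol)) protocol <- protocol_none()
  obs <- vector("list", n_steps)
  snapshots <- list()
  tracks <- vector("list", n_steps)
  arcs <- vector("list", n_steps)
  meanfield <- identical(tissue$params$mode, "meanfield")
  last_step <- 0L
  for (s in seq_len(n_steps)) {
    tissue <- protocol$update(tissue, s)
    if (meanfield) {
      tissue$mf <- NULL
      tissue$clock <- tissue$clock + 1
    } else {
      tissue <- turnover_step(tissue, 1)
      tissue <- spawn_bonds(tissue)
    }
    tissue <- viscoelastic_step(tissue)
    tissue <- remesh_tissue(tissue)
    if (meanfield) tissue$mf <- mean_field_bonds(tissue)
    eq <- equilibrate(tissue,
                      maxit = min(tissue$params$maxit,
                                  tissue$params$sim_maxit),
                      restarts = 1L)
    tissue <- eq$tissue
    if (!eq$report$converged) {
      tissue$events <- append_event(tissue$events, tissue$clock,
                                    "equilibration_incomplete",
                                    eq$report$residual)
    }
    jm <- detect_junctions(tissue)
    tissue$.jm <- jm  # per-step junction map, reusable by record callbacks
    tissue <- update_junction_history(tissue, jm)
    if (!is.null(jm$arcs)) arcs[[s]] <- cbind(step = s, jm$arcs)
    row <- list(step = s, time = tissue$clock,
                energy = eq$report$energy[length(eq$report$energy)],
                residual = eq$report$residual,
                n_bonds = if (meanfield) NA_integer_ else nrow(tissue$bonds))
    if (!is.null(record)) row <- c(row, record(tissue, s, eq$report))
    obs[[s]] <- row
    if (track_labels) tracks[[s]] <- label_positions(tissue, s)
    if (snapshot_every > 0L && s %% snapshot_every == 0L) {
      snapshots[[length(snapshots) + 1L]] <-
        list(step = s, loops = lapply(tissue$loops,
                                      function(l) l[c("xy", "labels")]))
    }
    last_step <- s
    if (!is.null(stop_when) && isTRUE(stop_when(tissue, s))) break
  }
  keep <- seq_len(last_step)
  obs <- do.call(rbind, lapply(obs[keep], function(r) {
    as.data.frame(r, optional = TRUE)
  }))
  structure(list(tissue = tissue, obs = obs, snapshots = snapshots,
                 events = tissue$events,
                 label_tracks = if (track_labels)
                   do.call(rbind, tracks[keep]) else NULL,
                 junction_arcs = do.call(rbind, arcs[keep])),
            class = "acam_trace")
}

# Arc-length coordinates of every material label on every cortex (used by
# kymographs): current position s along the loop and junction membership.
label_positions <- function(tissue, step) {
  out <- lapply(tissue$loops, function(l) {
    d <- segment_lengths(l$xy, l$closed)
    s <- cumsum(c(0, d[-length(d)]))
    data.frame(step = step, cell = l$cell_id, label = l$labels, s = s,
               x = l$xy[, 1], y = l$xy[, 2])
  })
  do.call(rbind, out)
}

update_junction_history <- function(tissue, jm = NULL) {
  if (is.null(jm)) jm <- detect_junctions(tissue)
  if (nrow(jm$junctions)) {
    for (r in seq_len(nrow(jm$junctions))) {
      key <- paste(jm$junctions$cell_i[r], jm$junctions$cell_j[r], sep = "-")
      tissue$jhist[[key]] <- list(
        length = jm$junctions$length[r], time = tissue$clock,
        fractured = isTRUE(tissue$jhist[[key]]$fractured))
      if (tissue$jhist[[key]]$fractured) {
        tissue$events <- append_event(tissue$events, tissue$clock,
                                      paste0("repair_", key))
        tissue$jhist[[key]]$fractured <- FALSE
      }
    }
  }
  tissue
}

#' Detect tissue fracture
#'
#' A vertex fracture is reported when the opening radius of an interior
#' vertex exceeds the maximum binding length delta_max (no bond can span the
#' hole, so it cannot heal while it persists). A mid-junction rupture is
#' reported when a cell pair that recently carried a junction of appreciable
#' length has lost all bonds and its cortices have separated beyond
#' delta_max. Re-adhesion of a ruptured pair is recorded as a repair event
#' by the simulation loop.
#'
#' @param tissue an `acam_tissue`.
#' @param jmap optional precomputed [detect_junctions()] map.
#' @param min_rupture_length junction length below which loss of adhesion is
#'   the normal end of shrinkage, not a rupture.
#' @param check_vertices evaluate vertex openings (the costly part; callers
#'   polling every step may do this at a coarser cadence).
#' @return `NULL` if intact, else a list with `kind` ("vertex" or
#'   "junction") and `location` (vertex centre or cell pair).
#' @export
detect_fracture <- function(tissue, jmap = NULL, min_rupture_length = 2,
                            check_vertices = TRUE) {
  if (is.null(jmap)) jmap <- detect_junctions(tissue)
  if (check_vertices && nrow(jmap$vertices)) {
    for (v in seq_len(nrow(jmap$vertices))) {
      dv <- vertex_opening(tissue, jmap, v)
      if (is.finite(dv) && dv > tissue$params$delta_max) {
        return(list(kind = "vertex",
                    location = c(jmap$vertices$x[v], jmap$vertices$y[v]),
                    opening = dv))
      }
    }
  }
  # former junctions now absent: ruptured if the cortices moved out of range
  if (length(tissue$jhist)) {
    live <- character(0)
    if (nrow(jmap$junctions)) {
      live <- paste(jmap$junctions$cell_i, jmap$junctions$cell_j, sep = "-")
    }
    ids <- vapply(tissue$loops, `[[`, integer(1), "cell_id")
    for (key in setdiff(names(tissue$jhist), live)) {
      h <- tissue$jhist[[key]]
      if (h$length < min_rupture_length) next
      cij <- as.integer(strsplit(key, "-")[[1]])
      if (cij[1] == 0L || cij[2] == 0L) next
      li <- tissue$loops[[match(cij[1], ids)]]
      lj <- tissue$loops[[match(cij[2], ids)]]
      dmin <- min(dist_to_polyline_cpp(li$xy, lj$xy, lj$closed))
      if (dmin > tissue$params$delta_max) {
        return(list(kind = "junction", location = cij, gap = dmin))
      }
    }
  }
  NULL
}
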