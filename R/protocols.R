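# Time-dependent activity fields gamma(segment, t). A protocol is a named
# object with an `update(tissue, step)` method called at the start of every
# simulation step; it rewrites the per-segment gamma fields (background
# gamma0 everywhere, protocol-specific contractile regions on top) before
# the viscoelastic rest-length update re-arms the contraction.

new_protocol <- function(name, update) {
  structure(list(name = name, update = update), class = "acam_protocol")
}

#' @export
print.acam_protocol <- function(x, ...) {
  cat(sprintf("<acam_protocol> %s\n", x$name)); invisible(x)
}

set_background_gamma <- function(tissue) {
  g0 <- tissue$params$gamma0
  for (k in seq_along(tissue$loops)) {
    tissue$loops[[k]]$gamma[] <- g0
  }
  tissue
}

# segment indices of `cell`'s cortex lying within `range` of any partner
# cortex (both segment endpoints must be in range)
segments_near_partners <- function(tissue, cell, partners, range) {
  ids <- vapply(tissue$loops, `[[`, integer(1), "cell_id")
  loop <- tissue$loops[[match(cell, ids)]]
  inr <- rep(FALSE, nrow(loop$xy))
  for (p in partners) {
    pl <- tissue$loops[[match(p, ids)]]
    inr <- inr | dist_to_polyline_cpp(loop$xy, pl$xy, pl$closed) <= range
  }
  n <- nrow(loop$xy)
  nxt <- c(2:n, 1L)
  which(inr & inr[nxt])
}

cells_adhered <- function(tissue, pair) {
  if (identical(tissue$params$mode, "meanfield")) {
    ids <- vapply(tissue$loops, `[[`, integer(1), "cell_id")
    li <- tissue$loops[[match(pair[1], ids)]]
    lj <- tissue$loops[[match(pair[2], ids)]]
    min(dist_to_polyline_cpp(li$xy, lj$xy, lj$closed)) <=
      tissue$params$delta_max
  } else {
    b <- tissue$bonds
    any((b$cell_a == pair[1] & b$cell_b == pair[2]) |
        (b$cell_a == pair[2] & b$cell_b == pair[1]))
  }
}

#' Passive protocol: background pre-stress only
#'
#' Sets gamma = gamma0 on every segment at every step.
#' @return an `acam_protocol`.
#' @export
protocol_none <- function() {
  new_protocol("none", function(tissue, step) set_background_gamma(tissue))
}

#' Uniform whole-cortex contractility ramp
#'
#' At each step sets gamma uniformly on all cortices according to the
#' schedule (a function of the step index or a numeric vector). Used with
#' quasi-static stepping to locate the fracture threshold.
#'
#' @param schedule function(step) -> gamma, or numeric vector indexed by
#'   step (last value held thereafter).
#' @return an `acam_protocol`.
#' @export
uniform_contractility_ramp <- function(schedule) {
  sched <- if (is.function(schedule)) schedule else {
    function(step) schedule[min(step, length(schedule))]
  }
  new_protocol("uniform_ramp", function(tissue, step) {
    g <- sched(step)
    stopifnot(g > 0, g <= 1)
    for (k in seq_along(tissue$loops)) tissue$loops[[k]]$gamma[] <- g
    tissue
  })
}

#' Identity-sensing junctional contractility
#'
#' While the two cells of `pair` are adhered, each step recomputes the
#' contractile region on both cortices as all segments within the surface-
#' receptor sensing range `delta_gamma` of the partner cortex, and sets
#' gamma there (background gamma0 elsewhere). The region shrinks with the
#' junction and vanishes when the pair loses adhesion: after a neighbour
#' exchange there are no adhesions between the pair, hence no contractility.
#'
#' @param pair the two cell ids sharing the contractile junction.
#' @param gamma active contraction factor in (0, 1).
#' @param delta_gamma sensing range; default: the tissue's `delta_gamma`
#'   parameter (taken equal to delta_max in the standard protocol).
#' @return an `acam_protocol`.
#' @export
junction_contractility <- function(pair = c(1L, 2L), gamma = 0.94,
                                   delta_gamma = NULL) {
  stopifnot(gamma > 0, gamma < 1)
  first <- TRUE
  new_protocol("junction_contractility", function(tissue, step) {
    rng <- if (is.null(delta_gamma)) tissue$params$delta_gamma else
      delta_gamma
    tissue <- set_background_gamma(tissue)
    adhered <- cells_adhered(tissue, pair)
    if (first) {
      if (!adhered) stop("cells ", pair[1], " and ", pair[2],
                         " are not adhered at protocol start")
      first <<- FALSE
    }
    if (adhered) {
      ids <- vapply(tissue$loops, `[[`, integer(1), "cell_id")
      for (s in 1:2) {
        cell <- pair[s]
        seg <- segments_near_partners(tissue, cell, pair[3L - s], rng)
        tissue$loops[[match(cell, ids)]]$gamma[seg] <- gamma
      }
    }
    tissue
  })
}

#' Asymmetric contractile cables
#'
#' Contractility on the cortex portions sharing adhesions along two cables
#' centred on the shrinking junction, with different magnitudes on the two
#' sides of each flanking bicellular junction: the strong cells' cortices
#' contract at `gamma_strong` wherever they are in sensing range of any
#' cable partner; the weak cells' cortices contract at `gamma_weak` only
#' along their junctions with the strong cells.
#'
#' @param strong_cells,weak_cells cell ids (defaults: 1,2 and 3,4).
#' @param gamma_strong,gamma_weak contraction factors.
#' @param delta_gamma sensing range override.
#' @return an `acam_protocol`.
#' @export
asymmetric_cables <- function(strong_cells = c(1L, 2L),
                              weak_cells = c(3L, 4L),
                              gamma_strong = 0.99, gamma_weak = 0.9975,
                              delta_gamma = NULL) {
  stopifnot(gamma_strong > 0, gamma_strong <= 1,
            gamma_weak > 0, gamma_weak <= 1)
  new_protocol("asymmetric_cables", function(tissue, step) {
    rng <- if (is.null(delta_gamma)) tissue$params$delta_gamma else
      delta_gamma
    tissue <- set_background_gamma(tissue)
    ids <- vapply(tissue$loops, `[[`, integer(1), "cell_id")
    for (cell in strong_cells) {
      partners <- setdiff(c(strong_cells, weak_cells), cell)
      partners <- partners[vapply(partners, function(p)
        cells_adhered(tissue, c(cell, p)), logical(1))]
      if (!length(partners)) next
      seg <- segments_near_partners(tissue, cell, partners, rng)
      tissue$loops[[match(cell, ids)]]$gamma[seg] <- gamma_strong
    }
    for (cell in weak_cells) {
      partners <- strong_cells[vapply(strong_cells, function(p)
        cells_adhered(tissue, c(cell, p)), logical(1))]
      if (!length(partners)) next
      seg <- segments_near_partners(tissue, cell, partners, rng)
      tissue$loops[[match(cell, ids)]]$gamma[seg] <- gamma_weak
    }
    tissue
  })
}

#' Linearly ramped junctional contractility
#'
#' The magnitude of active contractility 1 - gamma on the target junction
#' grows linearly with simulation time, mimicking gradual motor loading.
#'
#' @param pair target junction cell pair.
#' @param rate increase of (1 - gamma) per step.
#' @param gamma_min floor on gamma.
#' @param delta_gamma sensing range override.
#' @return an `acam_protocol`.
#' @export
linear_ramp_t1 <- function(pair = c(1L, 2L), rate = 5e-4, gamma_min = 0.9,
                           delta_gamma = NULL) {
  stopifnot(rate >= 0)
  new_protocol("linear_ramp_t1", function(tissue, step) {
    g <- max(gamma_min, 1 - rate * step)
    if (g >= 1) return(set_background_gamma(tissue))
    junction_contractility(pair, g, delta_gamma)$update(tissue, step)
  })
}

#' Sequential junction contraction (rosette protocol)
#'
#' Runs [junction_contractility()] on `first` until the `trigger` junction
#' appears in the junction map (the 4-way vertex has just resolved), then
#' switches the contractile target to `second`.
#'
#' @param first,second successive target junction pairs.
#' @param trigger junction whose first appearance fires the switch.
#' @param gamma contraction factor.
#' @param delta_gamma sensing range override.
#' @return an `acam_protocol`; its environment records `fired` and the
#'   switch step.
#' @export
sequential_t1 <- function(first = c(1L, 2L), second = c(1L, 3L),
                          trigger = c(3L, 4L), gamma = 0.94,
                          delta_gamma = NULL) {
  fired <- FALSE
  switch_step <- NA_integer_
  p1 <- junction_contractility(first, gamma, delta_gamma)
  p2 <- NULL
  new_protocol("sequential_t1", function(tissue, step) {
    if (!fired) {
      jm <- detect_junctions(tissue)
      hit <- jm$junctions$cell_i == min(trigger) &
        jm$junctions$cell_j == max(trigger)
      if (any(hit)) {
        fired <<- TRUE
        switch_step <<- step
        p2 <<- junction_contractility(second, gamma, delta_gamma)
        tissue$events <- append_event(tissue$events, tissue$clock,
                                      "sequential_switch", step)
      }
    }
    if (fired) p2$update(tissue, step) else p1$update(tissue, step)
  })
}
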