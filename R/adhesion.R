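# Creation, force transmission, saturation and finite-lifetime turnover of
# adhesion bonds between the cortices of different cells (and between a
# cortex and a fixed boundary wall, treated as pseudo-cell 0).
#
# A bond is a Hookean spring with rest length 1 (the adhesion rest length
# delta_0, the unit of length) and dimensionless stiffness omega. Its energy
# saturates at delta_max: no force is transmitted across a longer bond, ever.
# Bonds are endpoint-addressed by (cell id, material label) so they survive
# remeshing; lifetimes are drawn at birth from an exponential distribution
# with mean tau_adh, realising the linear relaxation of the bond density
# towards the binding kernel at rate 1/tau_adh.

#' Adhesion bond energy
#'
#' `0.5 * omega * (delta - 1)^2` for `delta <= delta_max`, constant
#' (`0.5 * omega * (delta_max - 1)^2`) beyond: the saturated branch stores
#' the unbinding energy but transmits no force.
#'
#' @param delta bond length (units of the adhesion rest length), >= 0.
#' @param omega dimensionless bond stiffness.
#' @param delta_max maximum binding length.
#' @return scalar (vectorised over `delta`).
#' @export
bond_energy <- function(delta, omega, delta_max) {
  stopifnot(all(delta >= 0))
  u <- pmin(delta, delta_max) - 1
  0.5 * omega * u^2
}

#' Force pair transmitted by one adhesion bond
#'
#' Equal-and-opposite central forces of magnitude `omega * |delta - 1|` for
#' `delta <= delta_max` and zero beyond; attractive when stretched
#' (delta > 1), repulsive when compressed (delta < 1), which maintains the
#' inter-cortical spacing.
#'
#' @param pa,pb endpoint positions (length-2 vectors).
#' @param omega bond stiffness; @param delta_max maximum binding length.
#' @return list with `fa`, `fb` (forces on the two endpoints) and `delta`.
#' @export
bond_force <- function(pa, pb, omega, delta_max) {
  v <- pb - pa
  delta <- sqrt(sum(v^2))
  if (delta > delta_max || delta == 0) {
    return(list(fa = c(0, 0), fb = c(0, 0), delta = delta))
  }
  f <- omega * (delta - 1) * v / delta  # pulls a towards b when stretched
  list(fa = f, fb = -f, delta = delta)
}

empty_bond_table <- function() {
  data.frame(cell_a = integer(0), label_a = integer(0),
             cell_b = integer(0), label_b = integer(0),
             birth = numeric(0), life = numeric(0),
             kmult = numeric(0))
}

# Resolve the (cell, label)-addressed bond table to current node indices in
# the flattened tissue. Bonds whose endpoint labels have disappeared raise an
# error: remeshing must re-attach them first.
resolve_bonds <- function(tissue, bonds = tissue$bonds) {
  fl <- tissue_flat(tissue)
  n <- nrow(bonds)
  if (n == 0) {
    return(list(ba = integer(0), bb = integer(0), bwall = integer(0),
                bk = numeric(0)))
  }
  a_idx <- fl$index[cbind(match(bonds$cell_a, fl$cell_ids),
                          bonds$label_a)]
  wall_b <- bonds$cell_b == 0L
  b_idx <- integer(n)
  b_idx[wall_b] <- bonds$label_b[wall_b]
  if (any(!wall_b)) {
    b_idx[!wall_b] <- fl$index[cbind(match(bonds$cell_b[!wall_b], fl$cell_ids),
                                     bonds$label_b[!wall_b])]
  }
  if (anyNA(a_idx) || anyNA(b_idx))
    stop("dangling bond endpoint: node removed without re-attachment")
  list(ba = a_idx, bb = b_idx, bwall = as.integer(wall_b),
       bk = tissue$params$omega * bonds$kmult)
}

# Candidate partners within the bond-formation range for every tissue node:
# cross-cell node pairs plus wall nodes. Returns the raw pair table from the
# spatial hash grid (tissue-tissue pairs once, i < j, usable from either
# side). Adhesion complexes form between apposed membranes (range
# `bind_range`, of order the bond rest length) and can then be stretched up
# to delta_max before saturating; the formation range is capped by
# delta_max. Wall corner nodes carrying explicit vertex pins are not
# ordinary binding partners and are excluded from the kernel.
candidate_pairs <- function(tissue, range = NULL) {
  fl <- tissue_flat(tissue)
  wall <- tissue_wall_xy(tissue)
  if (is.null(range)) {
    range <- min(tissue$params$bind_range, tissue$params$delta_max)
  }
  pr <- neighbor_pairs_cpp(fl$xy, fl$cell_of_node, wall, range)
  if (!is.null(tissue$wall) && isTRUE(tissue$wall$pinned)) {
    drop <- pr$wall == 1L & tissue$wall$corner[pr$j]
    pr <- pr[!drop, , drop = FALSE]
  }
  pr
}

# Binding kernel: weights proportional to 1 / delta over the candidate set,
# normalised; zero outside delta_max (enforced upstream by the cutoff).
kernel_weights <- function(d) {
  w <- 1 / pmax(d, 1e-9)
  w / sum(w)
}

#' Spawn adhesion bonds for unpaired cortex nodes
#'
#' Every unpaired cortex node with at least one foreign-cortex (or wall)
#' node within `delta_max` gains exactly one new bond, its partner sampled
#' from the inverse-distance binding kernel over the candidate set. A node
#' is unpaired when it holds no bond of its own initiation; it may still
#' carry bonds received from other cortices, so nodes accumulate multiple
#' couplings. Bond lifetimes are drawn at birth: exponential with mean
#' `tau_adh` (or deterministic `tau_adh` when
#' `tissue$params$lifetime == "fixed"`).
#'
#' @param tissue an `acam_tissue`.
#' @param pairs optional precomputed candidate pair table.
#' @return the tissue with its bond table extended.
#' @export
spawn_bonds <- function(tissue, pairs = NULL) {
  fl <- tissue_flat(tissue)
  if (is.null(pairs)) pairs <- candidate_pairs(tissue)
  bonds <- tissue$bonds
  paired <- rep(FALSE, nrow(fl$xy))
  if (nrow(bonds)) {
    rb <- resolve_bonds(tissue, bonds)
    paired[rb$ba] <- TRUE
  }
  if (!nrow(pairs)) return(tissue)
  # per-node candidate lists (tissue-tissue pairs usable from both sides)
  tt <- pairs$wall == 0L
  from <- c(pairs$i, pairs$j[tt])
  to <- c(pairs$j, pairs$i[tt])
  iswall <- c(pairs$wall, integer(sum(tt)))
  dd <- c(pairs$d, pairs$d[tt])
  ord <- order(from)
  from_o <- from[ord]
  starts <- c(1L, which(diff(from_o) > 0) + 1L, length(from_o) + 1L)
  node_at <- from_o[head(starts, -1L)]
  na <- nb <- la <- lb <- integer(0)
  lf <- numeric(0)
  for (k in seq_along(node_at)) {
    i <- node_at[k]
    if (paired[i]) next
    sel <- ord[starts[k]:(starts[k + 1L] - 1L)]
    w <- kernel_weights(dd[sel])
    pick <- sel[sample.int(length(sel), 1L, prob = w)]
    j <- to[pick]
    na <- c(na, fl$cell_of_node[i]); la <- c(la, fl$label_of_node[i])
    if (iswall[pick]) {
      nb <- c(nb, 0L); lb <- c(lb, j)
    } else {
      nb <- c(nb, fl$cell_of_node[j]); lb <- c(lb, fl$label_of_node[j])
    }
    lf <- c(lf, bond_lifetime(tissue))
    paired[i] <- TRUE
  }
  if (length(na)) {
    tissue$bonds <- rbind(bonds, data.frame(
      cell_a = na, label_a = la, cell_b = nb, label_b = lb,
      birth = tissue$clock, life = lf, kmult = 1))
  }
  tissue
}

bond_lifetime <- function(tissue) {
  tau <- tissue$params$tau_adh
  if (!is.finite(tau)) return(Inf)
  if (identical(tissue$params$lifetime, "fixed")) return(tau)
  rexp(1, rate = 1 / tau)
}

#' Remove adhesion bonds that have outlived their scheduled lifetime
#'
#' A bond is removed once its age (current time minus birth) exceeds the
#' lifetime drawn at its birth; freed endpoints become eligible for
#' [spawn_bonds()] in the same step. With `tau_adh = Inf` no bond is ever
#' removed (infinite sliding friction between apposed cortices).
#'
#' @param tissue an `acam_tissue`.
#' @param dt time increment (units of tau_cor) by which ages advance.
#' @return the tissue with expired bonds dropped and its clock advanced.
#' @export
turnover_step <- function(tissue, dt = 1) {
  stopifnot(dt > 0)
  tissue$clock <- tissue$clock + dt
  b <- tissue$bonds
  if (nrow(b)) {
    keep <- (tissue$clock - b$birth) <= b$life
    died <- sum(!keep)
    if (died) {
      tissue$bonds <- b <- b[keep, , drop = FALSE]
      tissue$events <- append_event(tissue$events, tissue$clock,
                                    "bond_death", died)
    }
  }
  # bonds stretched beyond the maximum binding length have unbound: they
  # transmit no force and their endpoints are free to re-bind locally
  if (nrow(b)) {
    rb <- resolve_bonds(tissue, b)
    fl <- tissue_flat(tissue)
    wall <- tissue_wall_xy(tissue)
    pb <- matrix(0, length(rb$bb), 2)
    wv <- rb$bwall == 1L
    if (any(wv)) pb[wv, ] <- wall[rb$bb[wv], , drop = FALSE]
    if (any(!wv)) pb[!wv, ] <- fl$xy[rb$bb[!wv], , drop = FALSE]
    delta <- sqrt(rowSums((pb - fl$xy[rb$ba, , drop = FALSE])^2))
    broke <- delta > tissue$params$delta_max & b$kmult <= 1
    if (any(broke)) {
      tissue$bonds <- b[!broke, , drop = FALSE]
      tissue$events <- append_event(tissue$events, tissue$clock,
                                    "bond_break", sum(broke))
    }
  }
  tissue
}

# Mean-field (instantaneous-binding) adhesion: every node is coupled to all
# foreign candidates within delta_max with inverse-distance weights
# normalised per node, i.e. the binding-kernel expectation of a single bond.
# Weights are frozen at the step's start geometry, so within an equilibration
# they define a proper energy. Returns a resolved spring table.
mean_field_bonds <- function(tissue, pairs = NULL) {
  if (is.null(pairs)) pairs <- candidate_pairs(tissue)
  tt <- pairs$wall == 0L
  from <- c(pairs$i, pairs$j[tt])
  to <- c(pairs$j, pairs$i[tt])
  iswall <- c(pairs$wall, integer(sum(tt)))
  dd <- c(pairs$d, pairs$d[tt])
  if (!length(from)) {
    return(list(ba = integer(0), bb = integer(0), bwall = integer(0),
                bk = numeric(0)))
  }
  w <- 1 / pmax(dd, 1e-9)
  wsum <- tapply(w, from, sum)
  w <- w / as.numeric(wsum[as.character(from)])
  list(ba = from, bb = to, bwall = as.integer(iswall),
       bk = tissue$params$omega * w)
}

#' Mean-field adhesion force per node (fast-adhesion regime)
#'
#' The inverse-distance-kernel expectation of the bond force over all
#' candidates within `delta_max`, used when adhesion turnover is much faster
#' than cortical relaxation so that no persistent bond state is meaningful.
#'
#' @param tissue an `acam_tissue`.
#' @return n x 2 matrix of adhesion forces on the tissue nodes.
#' @export
mean_field_adhesion_force <- function(tissue) {
  mf <- mean_field_bonds(tissue)
  adhesion_force_from(tissue, mf)
}

adhesion_force_from <- function(tissue, rb) {
  fl <- tissue_flat(tissue)
  n <- nrow(fl$xy)
  f <- matrix(0, n, 2)
  if (!length(rb$ba)) return(f)
  wall <- tissue_wall_xy(tissue)
  pa <- fl$xy[rb$ba, , drop = FALSE]
  pb <- matrix(0, length(rb$bb), 2)
  wv <- rb$bwall == 1L
  if (any(wv)) pb[wv, ] <- wall[rb$bb[wv], , drop = FALSE]
  if (any(!wv)) pb[!wv, ] <- fl$xy[rb$bb[!wv], , drop = FALSE]
  v <- pb - pa
  delta <- sqrt(rowSums(v^2))
  mag <- ifelse(delta <= tissue$params$delta_max & delta > 0,
                rb$bk * (delta - 1) / pmax(delta, 1e-12), 0)
  fv <- v * mag
  for (k in seq_along(rb$ba)) {
    f[rb$ba[k], ] <- f[rb$ba[k], ] + fv[k, ]
    if (!wv[k]) f[rb$bb[k], ] <- f[rb$bb[k], ] - fv[k, ]
  }
  f
}

#' Total adhesion energy of the tissue
#'
#' Sum of [bond_energy()] over live bonds, each counted once (mean-field
#' mode: kernel-weighted sum over all in-range candidate couplings).
#'
#' @param tissue an `acam_tissue`.
#' @return scalar energy.
#' @export
adhesion_energy <- function(tissue) {
  rb <- tissue_springs(tissue)
  if (!length(rb$ba)) return(0)
  fl <- tissue_flat(tissue)
  wall <- tissue_wall_xy(tissue)
  pa <- fl$xy[rb$ba, , drop = FALSE]
  pb <- matrix(0, length(rb$bb), 2)
  wv <- rb$bwall == 1L
  if (any(wv)) pb[wv, ] <- wall[rb$bb[wv], , drop = FALSE]
  if (any(!wv)) pb[!wv, ] <- fl$xy[rb$bb[!wv], , drop = FALSE]
  delta <- sqrt(rowSums((pb - pa)^2))
  u <- pmin(delta, tissue$params$delta_max) - 1
  sum(0.5 * rb$bk * u^2)
}
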