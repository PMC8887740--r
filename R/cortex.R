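# Geometry, energetics and internal forces of a single closed (or open)
# morphoelastic viscoelastic rod: one cell's junctional cortex.
#
# Per-segment state: undeformed length ell_hat and active contraction
# gamma in (0, 1]. The stress-free reference length is ell = gamma * ell_hat;
# the elastic stretch is alpha = d / ell so that the total stretch
# lambda = gamma * alpha decomposes into active and elastic parts.

#' Construct a cortex loop
#'
#' A cortex loop is the discretised apical cortex of one cell: an ordered,
#' counter-clockwise polyline of node positions (closed by default), with
#' per-segment undeformed lengths, per-segment active contraction factors and
#' persistent per-node material labels used for kymograph tracking.
#'
#' @param xy n x 2 matrix of node positions, in units of the adhesion rest
#'   length delta_0. Ordering is made counter-clockwise if it is not already.
#' @param cell_id integer label of the cell.
#' @param kappa dimensionless bending-to-stretching ratio
#'   (sqrt(bending modulus / stretching modulus) / delta_0).
#' @param ell_hat per-segment undeformed lengths; defaults to the current
#'   segment lengths (so the initial configuration is unstrained).
#' @param gamma per-segment active contraction factors in (0, 1]; default 1.
#' @param closed logical; closed rope-loop (the cortex) or open test rod.
#' @param check check simplicity (no self-intersection) of the polyline.
#' @return an object of class `cortex_loop`.
#' @export
cortex_loop <- function(xy, cell_id = 1L, kappa = 0.01, ell_hat = NULL,
                        gamma = NULL, closed = TRUE, check = TRUE) {
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  n <- nrow(xy)
  if (n < 4L) stop("a cortex loop needs at least 4 nodes")
  if (closed && polygon_area(xy) < 0) xy <- xy[n:1, , drop = FALSE]
  nseg <- if (closed) n else n - 1L
  d <- segment_lengths(xy, closed)
  if (any(d <= 0)) {
    stop(sprintf("degenerate segment (zero length) in cell %d at segment %d",
                 cell_id, which(d <= 0)[1]))
  }
  if (is.null(ell_hat)) ell_hat <- d
  if (is.null(gamma)) gamma <- rep(1, nseg)
  if (length(ell_hat) != nseg || length(gamma) != nseg)
    stop("ell_hat and gamma must have one entry per segment")
  if (any(ell_hat <= 0)) stop("all undeformed lengths must be positive")
  if (any(gamma <= 0 | gamma > 1)) stop("gamma must lie in (0, 1]")
  if (check && closed && is_self_intersecting(xy))
    stop(sprintf("cell %d: initial cortex polyline self-intersects", cell_id))
  structure(list(cell_id = as.integer(cell_id), xy = xy,
                 ell_hat = as.numeric(ell_hat), gamma = as.numeric(gamma),
                 labels = seq_len(n), next_label = n + 1L,
                 kappa = kappa, closed = closed),
            class = "cortex_loop")
}

#' @export
print.cortex_loop <- function(x, ...) {
  cat(sprintf("<cortex_loop> cell %d: %d nodes (%s), kappa = %g, L_ref = %.3f\n",
              x$cell_id, nrow(x$xy), if (x$closed) "closed" else "open",
              x$kappa, sum(x$gamma * x$ell_hat)))
  invisible(x)
}

segment_lengths <- function(xy, closed = TRUE) {
  n <- nrow(xy)
  idx <- if (closed) c(2:n, 1L) else 2:n
  from <- if (closed) 1:n else 1:(n - 1L)
  sqrt(rowSums((xy[idx, , drop = FALSE] - xy[from, , drop = FALSE])^2))
}

polygon_area <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  0.5 * sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])
}

# O(n^2) segment-crossing test; used at construction only.
is_self_intersecting <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  a <- xy; b <- xy[j, , drop = FALSE]
  for (s in 1:(n - 2L)) {
    rng <- (s + 2L):n
    # skip the pair (1, n) which shares node 1
    if (s == 1L) rng <- rng[rng != n]
    if (!length(rng)) next
    if (any(segments_cross(a[s, ], b[s, ], a[rng, , drop = FALSE],
                           b[rng, , drop = FALSE]))) return(TRUE)
  }
  FALSE
}

segments_cross <- function(p1, p2, q1, q2) {
  q1 <- matrix(q1, ncol = 2); q2 <- matrix(q2, ncol = 2)
  d1 <- (p2[1] - p1[1]) * (q1[, 2] - p1[2]) - (p2[2] - p1[2]) * (q1[, 1] - p1[1])
  d2 <- (p2[1] - p1[1]) * (q2[, 2] - p1[2]) - (p2[2] - p1[2]) * (q2[, 1] - p1[1])
  d3 <- (q2[, 1] - q1[, 1]) * (p1[2] - q1[, 2]) - (q2[, 2] - q1[, 2]) * (p1[1] - q1[, 1])
  d4 <- (q2[, 1] - q1[, 1]) * (p2[2] - q1[, 2]) - (q2[, 2] - q1[, 2]) * (p2[1] - q1[, 1])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Per-segment and per-node geometry of a cortex loop
#'
#' Recomputes, never stores: current segment lengths d, elastic stretch
#' alpha = d / (gamma * ell_hat), strain eps = alpha - 1, unit tangents d3,
#' leftward (interior, for a CCW loop) unit normals d1, nodal turning angles
#' theta and curvature c = theta per unit reference arc length.
#'
#' @param loop a [cortex_loop()].
#' @return list with per-segment `d`, `alpha`, `eps`, `d3`, `d1`, `ell`
#'   (reference lengths) and per-node `theta`, `c` (NA at the free ends of an
#'   open rod).
#' @export
segment_geometry <- function(loop) {
  xy <- loop$xy
  n <- nrow(xy)
  closed <- loop$closed
  d <- segment_lengths(xy, closed)
  if (any(d <= 0)) {
    stop(sprintf("degenerate segment (zero length) in cell %d at segment %d",
                 loop$cell_id, which(d <= 0)[1]))
  }
  ell <- loop$gamma * loop$ell_hat
  alpha <- d / ell
  idx <- if (closed) c(2:n, 1L) else 2:n
  from <- if (closed) 1:n else 1:(n - 1L)
  t3 <- (xy[idx, , drop = FALSE] - xy[from, , drop = FALSE]) / d
  d1 <- cbind(-t3[, 2], t3[, 1])  # rotate +90 deg: interior side of CCW loop
  theta <- rep(NA_real_, n)
  curv <- rep(NA_real_, n)
  nodes <- if (closed) 1:n else 2:(n - 1L)
  for (j in nodes) {
    sp <- if (closed) ((j - 2L) %% n) + 1L else j - 1L  # incoming segment
    sn <- if (closed) j else j                          # outgoing segment id
    # for open rods segment j starts at node j; incoming is j-1
    if (!closed) sn <- j
    t1 <- t3[sp, ]; t2 <- t3[if (closed) j else j, ]
    theta[j] <- atan2(t1[1] * t2[2] - t1[2] * t2[1], sum(t1 * t2))
    curv[j] <- theta[j] / (0.5 * (ell[sp] + ell[if (closed) j else j]))
  }
  list(d = d, alpha = alpha, eps = alpha - 1, d3 = t3, d1 = d1, ell = ell,
       theta = theta, c = curv)
}

flat_args_loop <- function(loop) {
  n <- nrow(loop$xy)
  ell <- loop$gamma * loop$ell_hat
  if (!loop$closed) ell <- c(ell, 1)  # padding for the absent wrap segment
  list(x = as.numeric(t(loop$xy)), off = c(0L, n),
       closed = as.integer(loop$closed), ell = ell)
}

no_bonds <- list(ba = integer(0), bb = integer(0), bwall = integer(0),
                 bk = numeric(0))
empty_wall <- matrix(numeric(0), ncol = 2)

#' Elastic energy of a cortex loop
#'
#' Integral of 1/2 kappa^2 c^2 + 1/2 eps^2 over the active reference
#' configuration: per segment 1/2 eps^2 * ell, per node
#' 1/2 kappa^2 theta^2 / a with a the mean reference length of the two
#' incident segments. Zero iff the rod is straight and unstretched.
#'
#' @param loop a [cortex_loop()].
#' @return scalar dimensionless energy.
#' @export
elastic_energy <- function(loop) {
  fa <- flat_args_loop(loop)
  acam_energy_cpp(fa$x, fa$off, fa$closed, fa$ell, loop$kappa^2,
                  no_bonds$ba, no_bonds$bb, no_bonds$bwall, no_bonds$bk,
                  Inf, empty_wall)
}

#' Internal cortical force per node
#'
#' The negative gradient of [elastic_energy()] with respect to node
#' positions: the discrete embodiment of the internal force divergence of the
#' rod. Sums to zero over a closed loop (no self-propulsion).
#'
#' @param loop a [cortex_loop()].
#' @return n x 2 matrix of force vectors.
#' @export
internal_force <- function(loop) {
  fa <- flat_args_loop(loop)
  g <- acam_grad_cpp(fa$x, fa$off, fa$closed, fa$ell, loop$kappa^2,
                     no_bonds$ba, no_bonds$bb, no_bonds$bwall, no_bonds$bk,
                     Inf, empty_wall)
  matrix(-g, ncol = 2, byrow = TRUE)
}

#' Apply active contraction to a region of the cortex
#'
#' Sets the active contraction factor gamma on the given segments, shrinking
#' their stress-free reference length to gamma * ell_hat. Free rods contract
#' without stress; held-fixed regions acquire a pre-stress with
#' alpha = 1/gamma.
#'
#' @param loop a [cortex_loop()].
#' @param region integer indices of segments (default: all).
#' @param gamma contraction factor in (0, 1].
#' @return the updated loop.
#' @export
apply_active_contraction <- function(loop, region = NULL, gamma) {
  if (length(gamma) != 1 || gamma <= 0 || gamma > 1)
    stop("gamma must be a single value in (0, 1]")
  if (is.null(region)) region <- seq_along(loop$gamma)
  loop$gamma[region] <- gamma
  loop
}

#' Remesh a cortex loop to a target node spacing
#'
#' Splits segments longer than twice the target spacing and merges segments
#' shorter than half of it, conserving the total undeformed and reference
#' lengths exactly and the enclosed area to high precision (a node is only
#' removed where the polyline is locally near-straight). Material labels are
#' carried on surviving nodes; newly inserted nodes receive fresh labels.
#'
#' @param loop a [cortex_loop()].
#' @param target_spacing target current segment length (> 0).
#' @param area_tol maximum admissible relative enclosed-area change for a
#'   single node removal.
#' @return list with the updated `loop` and `label_map`, a named integer
#'   vector mapping every dropped label to its nearest surviving label.
#' @export
remesh <- function(loop, target_spacing, area_tol = 1e-7) {
  if (target_spacing <= 0) stop("target_spacing must be positive")
  A0 <- if (loop$closed) abs(polygon_area(loop$xy)) else 1
  # node-wise records so splits/merges are local list operations
  n <- nrow(loop$xy)
  pts <- lapply(seq_len(n), function(i) {
    list(xy = loop$xy[i, ], label = loop$labels[i])
  })
  nseg <- length(loop$ell_hat)
  segs <- lapply(seq_len(nseg), function(i) {
    list(ell_hat = loop$ell_hat[i], gamma = loop$gamma[i])
  })
  nxt <- loop$next_label
  dropped <- integer(0); dropped_to <- integer(0)

  # --- split pass ---
  d <- segment_lengths(loop$xy, loop$closed)
  out_pts <- list(); out_segs <- list()
  for (i in seq_len(nseg)) {
    j <- if (i < n) i + 1L else 1L
    out_pts[[length(out_pts) + 1L]] <- pts[[i]]
    if (d[i] > 2 * target_spacing) {
      k <- ceiling(d[i] / target_spacing)
      p0 <- pts[[i]]$xy; p1 <- pts[[j]]$xy
      for (m in seq_len(k - 1L)) {
        u <- m / k
        out_pts[[length(out_pts) + 1L]] <-
          list(xy = (1 - u) * p0 + u * p1, label = nxt)
        nxt <- nxt + 1L
      }
      for (m in seq_len(k)) {
        out_segs[[length(out_segs) + 1L]] <-
          list(ell_hat = segs[[i]]$ell_hat / k, gamma = segs[[i]]$gamma)
      }
    } else {
      out_segs[[length(out_segs) + 1L]] <- segs[[i]]
    }
  }
  if (!loop$closed) out_pts[[length(out_pts) + 1L]] <- pts[[n]]
  pts <- out_pts; segs <- out_segs

  # --- merge pass (closed loops; open rods are test fixtures, not merged) ---
  if (loop$closed) {
    repeat {
      m <- length(pts)
      xy <- do.call(rbind, lapply(pts, `[[`, "xy"))
      d <- segment_lengths(xy, TRUE)
      cand <- which(d < 0.5 * target_spacing)
      if (!length(cand)) break
      removed_any <- FALSE
      for (i in cand) {
        m <- length(pts)
        if (m <= 4L) break
        if (i > m) next
        xy <- do.call(rbind, lapply(pts, `[[`, "xy"))
        d <- segment_lengths(xy, TRUE)
        if (i > length(d) || d[i] >= 0.5 * target_spacing) next
        # removing the *end* node of segment i merges segments i and i+1
        j <- if (i < m) i + 1L else 1L
        jn <- if (j < m) j + 1L else 1L
        sj <- if (j == 1L) m else j  # segment leaving node j has index j
        tri <- abs(0.5 * ((xy[j, 1] - xy[i, 1]) * (xy[jn, 2] - xy[i, 2]) -
                          (xy[jn, 1] - xy[i, 1]) * (xy[j, 2] - xy[i, 2])))
        if (tri > area_tol * A0) next
        new_len <- sqrt(sum((xy[jn, ] - xy[i, ])^2))
        if (new_len > 2 * target_spacing) next
        e1 <- segs[[i]]$ell_hat; e2 <- segs[[j]]$ell_hat
        g <- (segs[[i]]$gamma * e1 + segs[[j]]$gamma * e2) / (e1 + e2)
        segs[[i]] <- list(ell_hat = e1 + e2, gamma = g)
        # nearest surviving neighbour inherits the dropped label's bonds
        to <- if (d[i] <= d[j]) pts[[i]]$label else pts[[jn]]$label
        dropped <- c(dropped, pts[[j]]$label)
        dropped_to <- c(dropped_to, to)
        pts[[j]] <- NULL; segs[[j]] <- NULL
        removed_any <- TRUE
        break  # geometry changed: recompute
      }
      if (!removed_any) break
    }
  }

  xy <- do.call(rbind, lapply(pts, `[[`, "xy"))
  new <- loop
  new$xy <- xy
  new$labels <- vapply(pts, `[[`, integer(1), "label")
  new$ell_hat <- vapply(segs, `[[`, numeric(1), "ell_hat")
  new$gamma <- vapply(segs, `[[`, numeric(1), "gamma")
  new$next_label <- nxt
  # resolve re-attachment chains: the inheritor of a dropped label may
  # itself have been dropped later in the pass
  map <- setNames(dropped_to, dropped)
  if (length(map)) {
    for (k in seq_along(map)) {
      guard <- 0L
      while (as.character(map[k]) %in% names(map) && guard < 100L) {
        map[k] <- map[[as.character(map[k])]]
        guard <- guard + 1L
      }
    }
  }
  list(loop = new, label_map = map)
}
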