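# Deterministic construction of the standard tissue fixtures: a single cell
# adhered inside a hexagonal wall, a 3-cell tissue with one interior vertex,
# and a 14-cell hexagonal patch for T1 neighbour-exchange protocols.
#
# Geometry conventions: cells sit on a regular hexagonal lattice with edge
# length `edge` (units of the adhesion rest length); cortices are the cell
# hexagons offset inward, and walls are patch outlines offset outward, by
# half the bond rest length, so apposed cortices start one adhesion rest
# length apart -- the equilibrium spacing of the near-field binding kernel.
# Flat-top hexagons: corners at 60k degrees.

cortex_offset <- 0.5  # half the equilibrium inter-cortical spacing

hexagon_corners <- function(center, edge) {
  ang <- (0:5) * pi / 3
  cbind(center[1] + edge * cos(ang), center[2] + edge * sin(ang))
}

# inward (d > 0) or outward (d < 0) miter offset of a closed CCW polygon
polygon_offset <- function(xy, d) {
  n <- nrow(xy)
  nxt <- c(2:n, 1L)
  e <- xy[nxt, , drop = FALSE] - xy
  len <- sqrt(rowSums(e^2))
  t <- e / len
  nrm <- cbind(-t[, 2], t[, 1])  # left normal = interior for CCW
  p <- xy + d * nrm              # shifted edge base points
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    # intersect edge j (through p[j] along t[j]) with edge i
    A <- cbind(t[j, ], -t[i, ])
    if (abs(det(A)) < 1e-12) { out[i, ] <- p[i, ]; next }
    s <- solve(A, p[i, ] - p[j, ])
    out[i, ] <- p[j, ] + s[1] * t[j, ]
  }
  out
}

# nodes along a closed polygon at spacing ~ h; returns positions and a flag
# marking the polygon's corners
discretise_polygon <- function(corners, h) {
  n <- nrow(corners)
  nxt <- c(2:n, 1L)
  pts <- list(); corner <- list()
  for (i in seq_len(n)) {
    a <- corners[i, ]; b <- corners[nxt[i], ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, round(len / h))
    u <- (seq_len(k) - 1L) / k
    seg <- cbind(a[1] + u * (b[1] - a[1]), a[2] + u * (b[2] - a[2]))
    pts[[i]] <- seg
    corner[[i]] <- c(TRUE, rep(FALSE, k - 1L))
  }
  list(xy = do.call(rbind, pts), corner = unlist(corner))
}

discretise_circle <- function(center, radius, h) {
  k <- max(8L, round(2 * pi * radius / h))
  ang <- 2 * pi * (seq_len(k) - 1L) / k
  cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang))
}

# cell loop: hexagon at `center`, offset inward, discretised
hex_cell_loop <- function(center, edge, h, cell_id, kappa) {
  co <- hexagon_corners(center, edge)
  co <- polygon_offset(co, cortex_offset)
  dp <- discretise_polygon(co, h)
  cortex_loop(dp$xy, cell_id = cell_id, kappa = kappa, check = FALSE)
}

# outline of a union of lattice hexagons: boundary edges (not shared by two
# cells), chained into one closed CCW polygon
patch_outline <- function(centers, edge) {
  edges <- list()
  for (c_i in seq_len(nrow(centers))) {
    co <- hexagon_corners(centers[c_i, ], edge)
    nxt <- c(2:6, 1L)
    for (k in 1:6) {
      edges[[length(edges) + 1L]] <- cbind(co[k, , drop = FALSE],
                                           co[nxt[k], , drop = FALSE])
    }
  }
  E <- do.call(rbind, edges)  # rows: x1 y1 x2 y2
  midkey <- paste(round((E[, 1] + E[, 3]) / 2, 6),
                  round((E[, 2] + E[, 4]) / 2, 6))
  boundary <- E[midkey %in% names(which(table(midkey) == 1L)), , drop = FALSE]
  # chain boundary edges by endpoints
  key <- function(p) paste(round(p[1], 6), round(p[2], 6))
  starts <- apply(boundary, 1, function(r) key(r[1:2]))
  used <- rep(FALSE, nrow(boundary))
  path <- boundary[1, 1:2]
  cur <- key(boundary[1, 3:4]); used[1] <- TRUE
  pts <- list(boundary[1, 1:2], boundary[1, 3:4])
  repeat {
    i <- which(!used & starts == cur)[1]
    if (is.na(i)) {
      # edge may be stored in the opposite orientation
      ends <- apply(boundary, 1, function(r) key(r[3:4]))
      i <- which(!used & ends == cur)[1]
      if (is.na(i)) break
      boundary[i, ] <- boundary[i, c(3, 4, 1, 2)]
    }
    used[i] <- TRUE
    cur <- key(boundary[i, 3:4])
    if (cur == key(pts[[1]])) break
    pts[[length(pts) + 1L]] <- boundary[i, 3:4]
  }
  poly <- do.call(rbind, pts)
  if (polygon_area(poly) < 0) poly <- poly[nrow(poly):1, , drop = FALSE]
  poly
}

make_wall <- function(outline, h, offset = cortex_offset) {
  wxy <- polygon_offset(outline, -offset)
  dp <- discretise_polygon(wxy, h)
  list(xy = dp$xy, corner = dp$corner, pinned = FALSE)
}

# pin each wall corner to the nearest cortex node with a permanent
# extra-stiff adhesion, so boundary vertices stay at the wall's angular
# points; pinned corner wall nodes leave the ordinary binding kernel
pin_wall_corners <- function(tissue) {
  w <- tissue$wall
  fl <- tissue_flat(tissue)
  rows <- list()
  for (j in which(w$corner)) {
    d2 <- rowSums(sweep(fl$xy, 2, w$xy[j, ])^2)
    i <- which.min(d2)
    rows[[length(rows) + 1L]] <- data.frame(
      cell_a = fl$cell_of_node[i], label_a = fl$label_of_node[i],
      cell_b = 0L, label_b = j, birth = 0, life = Inf,
      kmult = tissue$params$wall_corner_mult)
  }
  tissue$bonds <- rbind(tissue$bonds, do.call(rbind, rows))
  tissue$wall$pinned <- TRUE
  tissue
}

#' Single cell adhered inside a hexagonal wall
#'
#' A circular cortex inscribed in a fixed regular hexagonal boundary, used
#' to read off the equilibrium vertex-opening size set by kappa^2/omega.
#' Built in mean-field (instantaneous binding) mode: the passive relaxation
#' is quasi-static, so the adhesion density equals the binding kernel.
#'
#' @param kappa,omega mechanical parameters (> 0).
#' @param mesh target node spacing h (units of the adhesion rest length).
#' @param edge hexagon edge length.
#' @return an `acam_tissue` with the wall attached.
#' @export
single_cell_in_hexagon <- function(kappa = 0.01, omega = 0.05, mesh = 0.5,
                                   edge = 5) {
  stopifnot(kappa > 0, omega > 0)
  if (mesh > 0.7) {
    warning("mesh spacing too coarse to resolve vertex openings of order ",
            "the adhesion rest length")
  }
  wallpoly <- hexagon_corners(c(0, 0), edge)
  wall <- list(xy = discretise_polygon(wallpoly, mesh)$xy,
               corner = discretise_polygon(wallpoly, mesh)$corner)
  apothem <- edge * sqrt(3) / 2
  cell <- cortex_loop(discretise_circle(c(0, 0), apothem - 1, mesh),
                      cell_id = 1L, kappa = kappa, check = FALSE)
  # plain omega bonds everywhere on this wall (no corner pinning)
  acam_tissue(list(cell),
              params = list(kappa = kappa, omega = omega, h = mesh,
                            mode = "meanfield", wall_corner_mult = 1),
              wall = wall)
}

# lattice basis for flat-top hexagons of edge a: neighbours at distance
# sqrt(3) a in directions 30 + 60k degrees
hex_basis <- function(edge) {
  D <- sqrt(3) * edge
  list(u = D * c(cos(pi / 6), sin(pi / 6)), v = D * c(0, 1))
}

#' Three mutually adhered cells with one interior vertex
#'
#' @param kappa,omega mechanical parameters.
#' @param mesh target node spacing; @param edge cell edge length.
#' @param pinned attach a fixed outer wall (pinned-boundary variant).
#' @param mode adhesion mode ("meanfield" for quasi-static passive runs).
#' @return an `acam_tissue`; the interior vertex sits at the centroid.
#' @export
three_cell_tissue <- function(kappa = 0.01, omega = 0.05, mesh = 0.5,
                              edge = 5, pinned = FALSE, mode = "meanfield") {
  b <- hex_basis(edge)
  centers <- rbind(c(0, 0), b$u, b$v)
  centers <- sweep(centers, 2, colMeans(centers))
  loops <- lapply(1:3, function(i) {
    hex_cell_loop(centers[i, ], edge, mesh, i, kappa)
  })
  wall <- if (pinned) make_wall(patch_outline(centers, edge), mesh) else NULL
  ts <- acam_tissue(loops, params = list(kappa = kappa, omega = omega,
                                         h = mesh, mode = mode),
                    wall = wall)
  if (pinned) ts <- pin_wall_corners(ts)
  ts
}

#' Fourteen-cell patch for T1 neighbour-exchange protocols
#'
#' Cells 1 and 2 share the central junction; cells 3 and 4 flank it (the
#' pair brought into contact by the exchange); cells 5-14 form the
#' surrounding ring so that all four central cells are fully surrounded.
#' The outer boundary is a fixed wall, pinned with extra-stiff adhesions at
#' its angular points. All cortices carry the background pre-stress gamma0.
#'
#' @param kappa,omega mechanical parameters.
#' @param gamma0 background active contraction (pre-stress), e.g.
#'   `1 - 2e-4`.
#' @param mesh target node spacing; @param edge cell edge length.
#' @param params extra parameter overrides (tau_adh, delta_max, mode, ...).
#' @return an `acam_tissue` with labelled cells and pinned boundary.
#' @export
fourteen_cell_tissue <- function(kappa = 0.01, omega = 0.05,
                                 gamma0 = 1 - 2e-4, mesh = 0.5, edge = 5,
                                 params = list()) {
  b <- hex_basis(edge)
  c1 <- c(0, 0); c2 <- b$v; c3 <- b$u; c4 <- b$v - b$u
  core <- rbind(c1, c2, c3, c4)
  # ring: lattice cells adjacent to the core quartet
  cand <- list()
  for (i in -2:2) for (j in -2:2) {
    p <- i * b$u + j * b$v
    cand[[length(cand) + 1L]] <- p
  }
  cand <- do.call(rbind, cand)
  D <- sqrt(3) * edge
  is_core <- apply(cand, 1, function(p) {
    any(sqrt(rowSums(sweep(core, 2, p)^2)) < 1e-6)
  })
  near_core <- apply(cand, 1, function(p) {
    any(abs(sqrt(rowSums(sweep(core, 2, p)^2)) - D) < 1e-6)
  })
  ring <- cand[!is_core & near_core, , drop = FALSE]
  ctr <- colMeans(core)
  ring <- ring[order(atan2(ring[, 2] - ctr[2], ring[, 1] - ctr[1])), ,
               drop = FALSE]
  centers <- rbind(core, ring)
  centers <- sweep(centers, 2, ctr)
  loops <- lapply(seq_len(nrow(centers)), function(i) {
    hex_cell_loop(centers[i, ], edge, mesh, i, kappa)
  })
  wall <- make_wall(patch_outline(centers, edge), mesh)
  p <- modifyList(list(kappa = kappa, omega = omega, h = mesh,
                       gamma0 = gamma0), params)
  ts <- acam_tissue(loops, params = p, wall = wall)
  pin_wall_corners(ts)
}

#' Log-uniform grid of (kappa, omega) parameter samples
#'
#' @param kappa_range,omega_range length-2 ranges (> 0).
#' @param n samples per axis.
#' @return data.frame with columns `kappa`, `omega` (n^2 rows).
#' @export
parameter_grid <- function(kappa_range, omega_range, n) {
  stopifnot(n >= 1, all(kappa_range > 0), all(omega_range > 0))
  logseq <- function(r) {
    if (n == 1L) return(sqrt(r[1] * r[2]))
    exp(seq(log(r[1]), log(r[2]), length.out = n))
  }
  expand.grid(kappa = logseq(kappa_range), omega = logseq(omega_range))
}
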