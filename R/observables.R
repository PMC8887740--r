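# Derived measurements: junction/vertex topology, vertex opening radius,
# signed T1 length, areas, tensions, slippage, kymographs and cell stress.
#
# A bicellular junction is the maximal contiguous run of adhesion couplings
# between the cortices of two cells; a vertex is the geometric point where
# three or more cells' junction intervals meet -- not a material point, so
# cortical material can flow past it.

#' Junction and vertex topology of a tissue
#'
#' Junction `{i, j}`: maximal contiguous run of bonds (kernel couplings in
#' mean-field mode) between cortices i and j; runs separated by at most
#' `gap_tol` unbonded nodes are merged so single bond-turnover events do not
#' fragment a junction. Vertices are single-linkage clusters of junction
#' interval endpoints with three or more distinct member cells.
#'
#' @param tissue an `acam_tissue`.
#' @param gap_tol largest unbonded node gap merged into a junction run.
#' @param link_radius single-linkage distance for vertex clustering.
#' @param max_delta only couplings at or below this length define junction
#'   membership: apposed cortices sit near the adhesion rest length, while
#'   bonds stretched across a vertex opening are transient tethers, not
#'   part of a bicellular junction.
#' @param min_nodes minimum bonded nodes per run for a junction interval.
#' @return list of class `acam_junction_map`: `junctions` (cell_i, cell_j,
#'   length, n_bonds, n_runs, mid_x, mid_y), `detail` (per-junction bonded
#'   node indices and arc intervals per cortex), `vertices` (x, y, n_cells,
#'   members as comma string).
#' @export
detect_junctions <- function(tissue, gap_tol = 2L, link_radius = 2,
                             max_delta = 1.25, min_nodes = 3L) {
  fl <- tissue_flat(tissue)
  rb <- tissue_springs(tissue)
  delta <- sqrt(rowSums((fl$xy[ifelse(rb$bwall == 1L, rb$ba, rb$bb), ,
                               drop = FALSE] -
                         fl$xy[rb$ba, , drop = FALSE])^2))
  # (wall springs get a dummy same-point delta of 0 above; they are dropped
  # by the tissue-tissue filter next)
  tt <- rb$bwall == 0L & delta <= max_delta
  ja <- rb$ba[tt]; jb <- rb$bb[tt]
  ca <- fl$cell_of_node[ja]; cb <- fl$cell_of_node[jb]
  lo <- pmin(ca, cb); hi <- pmax(ca, cb)
  keys <- paste(lo, hi, sep = "-")
  junctions <- list(); detail <- list()
  ep_key <- character(0); ep_ci <- ep_cj <- integer(0)
  ep_x <- ep_y <- numeric(0)
  arcs <- list()
  for (key in unique(keys)) {
    sel <- keys == key
    cij <- c(lo[sel][1], hi[sel][1])
    nodes_i <- unique(c(ja[sel][ca[sel] == cij[1]], jb[sel][cb[sel] == cij[1]]))
    nodes_j <- unique(c(ja[sel][ca[sel] == cij[2]], jb[sel][cb[sel] == cij[2]]))
    ri <- circular_runs(nodes_i, fl, cij[1], gap_tol)
    rj <- circular_runs(nodes_j, fl, cij[2], gap_tol)
    ri <- prune_runs(ri, min_nodes)
    rj <- prune_runs(rj, min_nodes)
    if (!length(ri$runs) || !length(rj$runs)) next
    len_i <- max(ri$lengths); len_j <- max(rj$lengths)
    main_i <- ri$runs[[which.max(ri$lengths)]]
    main_j <- rj$runs[[which.max(rj$lengths)]]
    mid <- colMeans(rbind(fl$xy[main_i, , drop = FALSE],
                          fl$xy[main_j, , drop = FALSE]))
    junctions[[key]] <- c(cij[1], cij[2], 0.5 * (len_i + len_j), sum(sel),
                          max(length(ri$runs), length(rj$runs)),
                          mid[1], mid[2])
    detail[[key]] <- list(nodes_i = nodes_i, nodes_j = nodes_j,
                          runs_i = ri$runs, runs_j = rj$runs)
    for (rr in c(ri$runs, rj$runs)) {
      ii <- c(rr[1], rr[length(rr)])
      ep_key <- c(ep_key, key, key)
      ep_ci <- c(ep_ci, cij[1], cij[1]); ep_cj <- c(ep_cj, cij[2], cij[2])
      ep_x <- c(ep_x, fl$xy[ii, 1]); ep_y <- c(ep_y, fl$xy[ii, 2])
    }
    arcs[[key]] <- junction_arc_rows(fl, cij, ri, rj)
  }
  junctions <- if (length(junctions)) {
    m <- do.call(rbind, junctions)
    data.frame(cell_i = as.integer(m[, 1]), cell_j = as.integer(m[, 2]),
               length = m[, 3], n_bonds = as.integer(m[, 4]),
               n_runs = as.integer(m[, 5]), mid_x = m[, 6], mid_y = m[, 7])
  } else {
    data.frame(cell_i = integer(0), cell_j = integer(0), length = numeric(0),
               n_bonds = integer(0), n_runs = integer(0),
               mid_x = numeric(0), mid_y = numeric(0))
  }
  rownames(junctions) <- NULL
  endpoints <- data.frame(key = ep_key, cell_i = ep_ci, cell_j = ep_cj,
                          x = ep_x, y = ep_y)
  vertices <- cluster_vertices(endpoints, link_radius)
  structure(list(junctions = junctions, detail = detail, vertices = vertices,
                 arcs = if (length(arcs)) do.call(rbind, arcs) else NULL),
            class = "acam_junction_map")
}

prune_runs <- function(r, min_nodes) {
  keep <- vapply(r$runs, length, integer(1)) >= min_nodes
  list(runs = r$runs[keep], lengths = r$lengths[keep])
}

# contiguous circular runs of bonded node indices on one cortex, merging
# runs separated by <= gap_tol unbonded nodes; lengths are current arc spans
circular_runs <- function(nodes, fl, cell, gap_tol) {
  k <- match(cell, fl$cell_ids)
  off <- fl$off[k]; n <- fl$ns[k]
  loc <- sort(nodes - off)
  if (!length(loc)) return(list(runs = list(), lengths = numeric(0)))
  gaps <- diff(loc) - 1L
  wrap_gap <- (loc[1] + n - loc[length(loc)]) - 1L
  brk <- which(gaps > gap_tol)
  if (!length(brk) && wrap_gap <= gap_tol) {
    runs <- list(loc)  # covers (almost) the whole cortex
  } else {
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(loc))
    runs <- mapply(function(s, e) loc[s:e], starts, ends, SIMPLIFY = FALSE)
    if (length(runs) > 1L && wrap_gap <= gap_tol) {
      runs[[1L]] <- c(runs[[length(runs)]], runs[[1L]])
      runs[[length(runs)]] <- NULL
    }
  }
  xy <- fl$xy[(off + 1L):(off + n), , drop = FALSE]
  d <- segment_lengths(xy, TRUE)
  arc_span <- function(from, to) {
    if (from == to) return(0)
    if (to > from) sum(d[from:(to - 1L)])
    else sum(d[from:n]) + (if (to > 1L) sum(d[1:(to - 1L)]) else 0)
  }
  lens <- vapply(runs, function(r) {
    if (length(r) < 2L) return(0)
    arc_span(r[1], r[length(r)])
  }, numeric(1))
  list(runs = lapply(runs, function(r) r + off), lengths = lens)
}

junction_arc_rows <- function(fl, cij, ri, rj) {
  cell <- part <- s0 <- s1 <- NULL
  for (side in 1:2) {
    runs <- if (side == 1) ri$runs else rj$runs
    k <- match(cij[side], fl$cell_ids)
    off <- fl$off[k]; n <- fl$ns[k]
    xy <- fl$xy[(off + 1L):(off + n), , drop = FALSE]
    d <- segment_lengths(xy, TRUE)
    s <- cumsum(c(0, d[-n]))
    for (rr in runs) {
      loc <- rr - off
      cell <- c(cell, cij[side]); part <- c(part, cij[3L - side])
      s0 <- c(s0, s[loc[1]]); s1 <- c(s1, s[loc[length(loc)]])
    }
  }
  data.frame(cell = cell, partner = part, s_start = s0, s_end = s1)
}

cluster_vertices <- function(ep, link_radius) {
  empty <- data.frame(x = numeric(0), y = numeric(0), n_cells = integer(0),
                      members = character(0))
  if (nrow(ep) < 2L) return(empty)
  cl <- stats::cutree(stats::hclust(stats::dist(ep[, c("x", "y")]),
                                    method = "single"), h = link_radius)
  out <- lapply(split(seq_len(nrow(ep)), cl), function(idx) {
    cx <- mean(ep$x[idx]); cy <- mean(ep$y[idx])
    # single-linkage chains can bridge adjacent vertices; membership is
    # re-counted from endpoints within the link radius of the centroid
    near <- idx[sqrt((ep$x[idx] - cx)^2 + (ep$y[idx] - cy)^2) <=
                  link_radius]
    if (!length(near)) near <- idx
    cells <- sort(unique(c(ep$cell_i[near], ep$cell_j[near])))
    data.frame(x = cx, y = cy, n_cells = length(cells),
               members = paste(cells, collapse = ","))
  })
  out <- do.call(rbind, out)
  out <- out[out$n_cells >= 3L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Vertex opening radius
#'
#' Radius of the largest circle inscribed in the cortex-free region at a
#' vertex: the maximal-inscribed-circle radius among the member cortices'
#' polylines (and the boundary wall, if within reach), found by maximising
#' the minimum distance to the bounding polylines over the circle centre.
#'
#' @param tissue an `acam_tissue`.
#' @param jmap an `acam_junction_map` (or `NULL` to use `center`/`cells`).
#' @param vertex row index into `jmap$vertices`.
#' @param center,cells explicit vertex centre guess and member cell ids,
#'   used instead of `jmap` (e.g. a wall corner of the hexagonal boundary).
#' @param search_radius how far from the initial centre the circle centre
#'   may move.
#' @return opening radius delta_vert (units of the adhesion rest length).
#' @export
vertex_opening <- function(tissue, jmap = NULL, vertex = 1L, center = NULL,
                           cells = NULL, search_radius = NULL) {
  if (is.null(search_radius)) search_radius <- tissue$params$delta_max
  if (is.null(center)) {
    stopifnot(!is.null(jmap), nrow(jmap$vertices) >= vertex)
    center <- c(jmap$vertices$x[vertex], jmap$vertices$y[vertex])
    cells <- as.integer(strsplit(jmap$vertices$members[vertex], ",")[[1]])
  }
  ids <- vapply(tissue$loops, `[[`, integer(1), "cell_id")
  polys <- lapply(tissue$loops[match(cells, ids)],
                  function(l) list(xy = l$xy, closed = l$closed))
  if (!is.null(tissue$wall)) {
    wd <- dist_to_polyline_cpp(matrix(center, 1), tissue$wall$xy, TRUE)
    if (wd < 2 * search_radius) {
      # the wall stands in for apposed tissue: reflect the member cortices
      # across the adjacent wall edges so the opening is measured between
      # cortices, as at an interior vertex, not cut off by the wall line
      polys <- c(polys, wall_mirror_polys(tissue, center, polys))
    }
  }
  fobj <- function(p) {
    excess <- max(0, sqrt(sum((p - center)^2)) - search_radius)
    dmin <- Inf
    inside <- FALSE
    for (pl in polys) {
      d <- dist_to_polyline_cpp(matrix(p, 1), pl$xy, pl$closed)
      dmin <- min(dmin, d)
      # the opening is the cortex-free region *outside* every cell
      if (pl$closed && point_in_polygon(p, pl$xy)) inside <- TRUE
    }
    -(dmin - 10 * excess - (if (inside) 100 else 0))
  }
  best <- -fobj(center)
  # restart offsets scale with the current opening so the simplex never
  # jumps across a cortex into a cell interior
  off <- min(0.3, max(0.02, 0.5 * best))
  for (st in list(c(0, 0), c(off, 0), c(-off, 0), c(0, off), c(0, -off))) {
    fit <- optim(center + st, fobj, method = "Nelder-Mead",
                 control = list(maxit = 300, reltol = 1e-10))
    if (-fit$value > best) best <- -fit$value
  }
  best
}

point_in_polygon <- function(p, xy) {
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1L))
  xi <- xy[, 1]; yi <- xy[, 2]
  xj <- xy[j, 1]; yj <- xy[j, 2]
  crossings <- ((yi > p[2]) != (yj > p[2])) &
    (p[1] < (xj - xi) * (p[2] - yi) / (yj - yi) + xi)
  sum(crossings, na.rm = TRUE) %% 2L == 1L
}

# reflect the member polylines across the wall edge lines adjacent to the
# wall corner nearest to `center`
wall_mirror_polys <- function(tissue, center, polys) {
  w <- tissue$wall
  cidx <- which(w$corner)
  if (!length(cidx)) return(list())
  cxy <- w$xy[cidx, , drop = FALSE]
  k <- which.min(rowSums(sweep(cxy, 2, center)^2))
  a <- cxy[k, ]
  nb <- cxy[c(if (k == 1L) nrow(cxy) else k - 1L,
              if (k == nrow(cxy)) 1L else k + 1L), , drop = FALSE]
  out <- list()
  for (m in 1:2) {
    b <- nb[m, ]
    t <- (b - a) / sqrt(sum((b - a)^2))
    for (pl in polys) {
      rel <- sweep(pl$xy, 2, a)
      proj <- outer(as.numeric(rel %*% t), t)
      out[[length(out) + 1L]] <-
        list(xy = sweep(2 * proj - rel, 2, a, "+"), closed = pl$closed)
    }
  }
  out
}

#' Signed T1 junction length
#'
#' `L_{3,4} - L_{1,2}` (by default): negative while the first junction is
#' shrinking, zero at the 4-way configuration, positive while the new
#' junction extends.
#'
#' @param jmap an `acam_junction_map`.
#' @param shrinking,growing cell pairs.
#' @return scalar length.
#' @export
signed_t1_length <- function(jmap, shrinking = c(1L, 2L),
                             growing = c(3L, 4L)) {
  jlen <- function(p) {
    r <- jmap$junctions$cell_i == min(p) & jmap$junctions$cell_j == max(p)
    if (any(r)) jmap$junctions$length[which(r)[1]] else 0
  }
  jlen(growing) - jlen(shrinking)
}

#' Cell area (shoelace) and perimeter
#'
#' @param loop a [cortex_loop()].
#' @return scalar.
#' @export
cell_area <- function(loop) abs(polygon_area(loop$xy))

#' @rdname cell_area
#' @export
cell_perimeter <- function(loop) sum(segment_lengths(loop$xy, loop$closed))

#' Per-segment cortical tension
#'
#' The tangential internal force component, `T = alpha - 1` in
#' nondimensional units: positive where the cortex is elastically stretched
#' beyond its active reference length.
#'
#' @param loop a [cortex_loop()].
#' @return numeric vector, one value per segment.
#' @export
cortical_tension <- function(loop) segment_geometry(loop)$eps

#' Isotropic cell stress and principal axis
#'
#' Virial-type stress from the external (adhesion and wall) forces on a
#' cell's cortex nodes: `sigma = (1/A) sum f (x - centroid)^T`;
#' `P_cell = tr(sigma) / 2`; the principal axis is the leading eigenvector.
#' Qualitative observable (orientation and ordering only).
#'
#' @param tissue an `acam_tissue`; @param cell_id which cell.
#' @return list `P_cell`, `axis` (unit 2-vector), `sigma` (2 x 2 matrix).
#' @export
cell_stress <- function(tissue, cell_id) {
  fl <- tissue_flat(tissue)
  f <- adhesion_force_from(tissue, tissue_springs(tissue))
  k <- match(cell_id, fl$cell_ids)
  idx <- (fl$off[k] + 1L):fl$off[k + 1L]
  xy <- fl$xy[idx, , drop = FALSE]
  ctr <- colMeans(xy)
  A <- abs(polygon_area(xy))
  r <- sweep(xy, 2, ctr)
  fc <- f[idx, , drop = FALSE]
  sigma <- crossprod(fc, r) / A
  sigma <- 0.5 * (sigma + t(sigma))
  ev <- eigen(sigma, symmetric = TRUE)
  list(P_cell = 0.5 * sum(diag(sigma)), axis = ev$vectors[, 1],
       sigma = sigma)
}

#' Material kymograph of one cortex
#'
#' Positions of labelled (Lagrangian) material points along the cortex
#' against the arc extents of its junctions over time. Labels crossing a
#' junction boundary indicate cortical material passing a vertex between
#' junctions.
#'
#' @param trace an `acam_trace` from [simulate_tissue()] run with the
#'   default label tracking.
#' @param cell_id which cortex.
#' @return data.frame (step, label, s, partner): arc coordinate and the
#'   junction (partner cell, NA between junctions) each label sits in.
#' @export
material_kymograph <- function(trace, cell_id) {
  lt <- trace$label_tracks
  lt <- lt[lt$cell == cell_id, , drop = FALSE]
  ja <- trace$junction_arcs
  out <- lt[, c("step", "label", "s")]
  out$partner <- NA_integer_
  if (!is.null(ja)) {
    ja <- ja[ja$cell == cell_id, , drop = FALSE]
    for (r in seq_len(nrow(ja))) {
      s0 <- ja$s_start[r]; s1 <- ja$s_end[r]
      m <- out$step == ja$step[r] &
        (if (s0 <= s1) out$s >= s0 & out$s <= s1 else out$s >= s0 | out$s <= s1)
      out$partner[m] <- ja$partner[r]
    }
  }
  out
}

#' Tangential slippage between apposed cortices of a junction
#'
#' Tracks the two material points (one per cortex) apposed at the junction
#' centre when tracking starts, and reports the signed tangential offset
#' that develops between them: the shear displacement of the apposed
#' cortices. Antisymmetric under swapping the two cortices.
#'
#' @param trace an `acam_trace`.
#' @param pair the two cell ids of the junction.
#' @param from_step step at which the reference apposed pair is chosen.
#' @return data.frame (step, slip).
#' @export
slippage_shear <- function(trace, pair = c(1L, 3L), from_step = 1L) {
  ja <- trace$junction_arcs
  lt <- trace$label_tracks
  stopifnot(!is.null(ja), !is.null(lt))
  sel <- ja$step == from_step & ja$cell == pair[1] & ja$partner == pair[2]
  if (!any(sel)) stop("junction not present at from_step")
  smid <- mean(c(ja$s_start[which(sel)[1]], ja$s_end[which(sel)[1]]))
  lt1 <- lt[lt$cell == pair[1], ]
  lt2 <- lt[lt$cell == pair[2], ]
  at1 <- lt1[lt1$step == from_step, ]
  lab1 <- at1$label[which.min(abs(at1$s - smid))]
  p1 <- at1[at1$label == lab1, c("x", "y")]
  at2 <- lt2[lt2$step == from_step, ]
  lab2 <- at2$label[which.min((at2$x - p1$x)^2 + (at2$y - p1$y)^2)]
  steps <- sort(unique(lt$step))
  steps <- steps[steps >= from_step]
  slip <- vapply(steps, function(st) {
    a1 <- lt1[lt1$step == st, ]
    a2 <- lt2[lt2$step == st, ]
    i1 <- match(lab1, a1$label); i2 <- match(lab2, a2$label)
    if (is.na(i1) || is.na(i2)) return(NA_real_)
    # local tangent of cortex 1 at the tracked label
    o <- order(a1$s)
    pos <- match(i1, o)
    nb <- o[c(max(1, pos - 1), min(length(o), pos + 1))]
    tv <- c(a1$x[nb[2]] - a1$x[nb[1]], a1$y[nb[2]] - a1$y[nb[1]])
    tv <- tv / sqrt(sum(tv^2))
    sum((c(a2$x[i2], a2$y[i2]) - c(a1$x[i1], a1$y[i1])) * tv)
  }, numeric(1))
  data.frame(step = steps, slip = slip)
}

#' Internal angles at the end vertices of a junction
#'
#' For each end vertex of the junction between `pair`, collects the
#' junctions meeting there and returns the angles between successive
#' junction directions around the vertex (estimated from the vertex to
#' each junction's midpoint). At a relaxed three-way vertex the angles
#' approach 2 pi / 3.
#'
#' @param tissue an `acam_tissue`.
#' @param pair the junction whose end-vertex angles are measured.
#' @param reach how far from the vertex a junction endpoint may lie to
#'   count as meeting it.
#' @return numeric vector of angles (radians), possibly empty.
#' @export
t1_vertex_angles <- function(tissue, pair = c(3L, 4L), reach = 2.5) {
  jm <- detect_junctions(tissue)
  jj <- jm$junctions
  r <- which(jj$cell_i == min(pair) & jj$cell_j == max(pair))
  if (!length(r)) return(numeric(0))
  key <- paste(min(pair), max(pair), sep = "-")
  det <- jm$detail[[key]]
  fl <- tissue_flat(tissue)
  main <- det$runs_i[[1]]
  ends <- fl$xy[c(main[1], main[length(main)]), , drop = FALSE]
  out <- numeric(0)
  for (e in 1:2) {
    E <- ends[e, ]
    dirs <- c()
    for (q in seq_len(nrow(jj))) {
      kq <- paste(jj$cell_i[q], jj$cell_j[q], sep = "-")
      dq <- jm$detail[[kq]]
      epts <- do.call(rbind, lapply(c(dq$runs_i, dq$runs_j), function(rr) {
        fl$xy[c(rr[1], rr[length(rr)]), , drop = FALSE]
      }))
      if (min(sqrt(rowSums(sweep(epts, 2, E)^2))) > reach) next
      v <- c(jj$mid_x[q], jj$mid_y[q]) - E
      nv <- sqrt(sum(v^2))
      if (nv < 1e-9) next
      dirs <- c(dirs, atan2(v[2], v[1]))
    }
    if (length(dirs) >= 3) {
      dirs <- sort(dirs)
      gaps <- diff(c(dirs, dirs[1] + 2 * pi))
      out <- c(out, gaps)
    }
  }
  out
}
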