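# Physiological tiling constants (printed cell footprints, um):
# an EC is 65 x 10 (long axis axial), an SMC 50 x 5 (long axis
# circumferential). Five ECs cover the same area as 13 SMCs; together they
# form the 65 x 50 um "fundamental unit". A 4 x 4 grid of units fills one
# quadrilateral computational domain: 80 ECs (4 axial rows x 20
# circumferential columns) and 208 SMCs (52 x 4), 288 cells.
EC_LEN_UM <- 65; EC_WID_UM <- 10
SMC_LEN_UM <- 50; SMC_WID_UM <- 5
UNITS_PER_QUAD <- 4L
EC_ROWS <- 4L; EC_COLS <- 20L
SMC_ROWS <- 52L; SMC_COLS <- 4L
QUAD_AX_MM <- UNITS_PER_QUAD * EC_LEN_UM / 1000 # 0.26
QUAD_CIRC_MM <- UNITS_PER_QUAD * SMC_LEN_UM / 1000 # 0.20

#' Geometry specification for a symmetric Y bifurcation
#'
#' Branch length, diameter and branch angle define the three centrelines;
#' quad resolution per segment is either given explicitly or derived from
#' the physiological quad footprint (0.26 mm axial x 0.20 mm
#' circumferential, the size of a 4 x 4 grid of fundamental cell units).
#'
#' @param branch_length length of the parent and of each branch along its
#'   centreline (mm).
#' @param diameter vessel diameter (mm), identical for all three segments.
#' @param branch_angle angle between each branch centreline and the parent
#'   axis (degrees), strictly between 0 and 90.
#' @param m,n quads per segment axially / circumferentially. `n` must be a
#'   multiple of 4 (the junction splits each circumference into quarters).
#'   Defaults follow the physiological quad footprint.
#' @param a biharmonic anisotropy constant, passed to [patch_boundary()].
#' @return A `vw_geometry_spec` list.
#' @export
geometry_spec <- function(branch_length = 8.84, diameter = 2.55,
                          branch_angle = 30, m = NULL, n = NULL, a = 0.1) {
  if (branch_length <= 0 || diameter <= 0) abort("lengths must be positive")
  if (branch_angle <= 0 || branch_angle >= 90) {
    abort("branch_angle must lie strictly between 0 and 90 degrees")
  }
  if (is.null(m)) m <- max(3L, as.integer(round(branch_length / QUAD_AX_MM)))
  if (is.null(n)) {
    n <- as.integer(round(pi * diameter / QUAD_CIRC_MM / 4) * 4)
  }
  if (n %% 4 != 0 || n < 4) abort("n must be a positive multiple of 4")
  structure(list(branch_length = branch_length,
                 max_length = 2 * branch_length,
                 diameter = diameter, branch_angle = branch_angle,
                 m = as.integer(m), n = as.integer(n), a = a),
            class = "vw_geometry_spec")
}

# sample a planar-arc seam curve between an in-plane point P0 = (x0, y0, 0)
# and the top/bottom pole (0/x_t, 0, +-R): s in [0, 1]
seam_curve <- function(s, x0, y0, R, zsign) {
  th <- s * pi / 2
  cbind(x0 * cos(th), y0 * cos(th), zsign * R * sin(th))
}

half_circle <- function(center, e1, e2, R, v) {
  th <- v * pi
  sweep(R * (outer(cos(th), e1) + outer(sin(th), e2)), 2, center, "+")
}

line_edge <- function(p0, p1, u) {
  cbind(p0[1] + u * (p1[1] - p0[1]),
        p0[2] + u * (p1[2] - p0[2]),
        p0[3] + u * (p1[3] - p0[3]))
}

# Solve one semi-tubular patch given edge closures; returns point array.
solve_patch <- function(m, n2, a, u0, u1, v0, v1, du0, du1, dv0, dv1) {
  b <- patch_boundary(u0 = u0, u1 = u1, v0 = v0, v1 = v1,
                      du0 = du0, du1 = du1, dv0 = dv0, dv1 = dv1,
                      m = m, n = n2, a = a)
  solve_biharmonic(b)
}

#' Build a straight-tube surface mesh
#'
#' A single tubular segment composed of two stitched semi-tubular patches,
#' each generated by the biharmonic solver between two end half-circles with
#' axial Neumann data. The tube axis lies along `x` from 0 to `length`.
#'
#' @param m,n axial / circumferential quad counts; `n` must be even and at
#'   least 4 (each semi-tubular patch uses `n/2` columns).
#' @param length tube length (mm).
#' @param diameter tube diameter (mm).
#' @param a biharmonic anisotropy constant.
#' @param tile if `TRUE` (default) the quads are tiled with cells.
#' @return A `vw_mesh`.
#' @export
tube_mesh <- function(m = 8, n = 8, length = m * QUAD_AX_MM,
                      diameter = n * QUAD_CIRC_MM / pi, a = 0.1,
                      tile = TRUE) {
  m <- as.integer(m); n <- as.integer(n)
  if (n %% 2 != 0 || n < 4) abort("tube n must be even and >= 4")
  R <- diameter / 2
  n2 <- n %/% 2L
  u_seq <- seq(0, 1, length.out = m + 1)
  v_seq <- seq(0, 1, length.out = n2 + 1)

  patches <- list()
  for (half in 1:2) {
    # upper half: theta = v*pi from (0, R, 0) over +z; lower: theta = pi + v*pi
    e1 <- c(0, 1, 0)
    e2 <- if (half == 1) c(0, 0, 1) else c(0, 0, -1)
    if (half == 2) e1 <- c(0, -1, 0)
    u0 <- half_circle(c(0, 0, 0), e1, e2, R, v_seq)
    u1 <- half_circle(c(length, 0, 0), e1, e2, R, v_seq)
    v0 <- line_edge(u0[1, ], u1[1, ], u_seq)
    v1 <- line_edge(u0[n2 + 1, ], u1[n2 + 1, ], u_seq)
    du <- matrix(rep(c(length, 0, 0), each = n2 + 1), ncol = 3)
    zs <- if (half == 1) 1 else -1
    dv0 <- matrix(rep(c(0, 0, zs * pi * R), each = m + 1), ncol = 3)
    dv1 <- matrix(rep(c(0, 0, -zs * pi * R), each = m + 1), ncol = 3)
    patches[[half]] <- solve_patch(m, n2, a, u0, u1, v0, v1, du, du, dv0, dv1)
  }

  segs <- list(list(seg = 1L, patches = patches, axial0 = 0,
                    axial_len = length))
  mesh <- assemble_mesh(segs, m = m, n = n, R = R, kind = "tube",
                        spec = list(length = length, diameter = diameter,
                                    m = m, n = n, a = a))
  mesh$neighbors <- tube_neighbors(mesh)
  if (tile) mesh <- tile_cells(mesh) else mesh
}

#' Build a symmetric Y-bifurcation surface mesh
#'
#' Three tubular segments (parent plus two branches), each composed of two
#' semi-tubular biharmonic patches, meet at the junction along three seam
#' curves joining the top and bottom poles of the junction through the
#' outer-wall points and the carina apex. Seam discretisations are shared
#' exactly, so the stitched mesh is watertight. The parent runs along
#' negative `x` (inlet at `x = -branch_length`, junction at 0); branches
#' leave at `+-branch_angle` in the `x`-`y` plane.
#'
#' @param spec a [geometry_spec()].
#' @param tile tile quads with cells (default `TRUE`).
#' @return A `vw_mesh` with three segments and `Q = 3 * m * n` quads.
#' @export
bifurcation_mesh <- function(spec = geometry_spec(), tile = TRUE) {
  stopifnot(inherits(spec, "vw_geometry_spec"))
  m <- spec$m; n <- spec$n; a <- spec$a
  R <- spec$diameter / 2
  L <- spec$branch_length
  al <- spec$branch_angle * pi / 180
  n2 <- n %/% 2L; q <- n %/% 4L
  u_seq <- seq(0, 1, length.out = m + 1)
  v_seq <- seq(0, 1, length.out = n2 + 1)

  # junction anchor points
  tN <- R * (1 - cos(al)) / sin(al)
  xN <- tN * cos(al) - R * sin(al)
  Npt <- c(xN, R, 0); Spt <- c(xN, -R, 0)
  xA <- R / sin(al)
  Apt <- c(xA, 0, 0)
  dplus <- c(cos(al), sin(al), 0); dminus <- c(cos(al), -sin(al), 0)
  in2 <- c(sin(al), cos(al), 0)      # inner-wall direction of branch 2
  out1 <- c(-sin(al), cos(al), 0)    # outer-wall direction of branch 1
  O1 <- L * dplus; O2 <- L * dminus

  # junction edges: concatenation of two half-seam curves sampled with q
  # intervals each (shared between adjacent segments)
  junction_edge <- function(first, second) rbind(first[-nrow(first), ], second)
  sq <- seq(0, 1, length.out = q + 1)
  seam_p1u <- seam_curve(sq, xN, R, R, 1)    # N -> T
  seam_p2u <- seam_curve(sq, xN, -R, R, 1)   # S -> T
  seam_12u <- seam_curve(sq, xA, 0, R, 1)    # A -> T
  seam_p1l <- seam_curve(sq, xN, R, R, -1)   # N -> B
  seam_p2l <- seam_curve(sq, xN, -R, R, -1)  # S -> B
  seam_12l <- seam_curve(sq, xA, 0, R, -1)   # A -> B
  rev_rows <- function(mat) mat[rev(seq_len(nrow(mat))), , drop = FALSE]

  axial_du <- function(dir, len, rows) matrix(rep(dir * len, each = rows), ncol = 3)
  circ_dv <- function(zsign, rows) {
    matrix(rep(c(0, 0, zsign * pi * R), each = rows), ncol = 3)
  }

  solve6 <- list()
  # --- parent segment, upper then lower patch
  inlet_c <- c(-L, 0, 0)
  for (half in 1:2) {
    zs <- if (half == 1) 1 else -1
    e1 <- if (half == 1) c(0, 1, 0) else c(0, -1, 0)
    e2 <- c(0, 0, zs)
    u0 <- half_circle(inlet_c, e1, e2, R, v_seq)
    u1 <- if (half == 1) {
      junction_edge(seam_p1u, rev_rows(seam_p2u))        # N -> T -> S
    } else {
      junction_edge(seam_p2l, rev_rows(seam_p1l))        # S -> B -> N
    }
    v0 <- line_edge(u0[1, ], u1[1, ], u_seq)
    v1 <- line_edge(u0[n2 + 1, ], u1[n2 + 1, ], u_seq)
    du <- axial_du(c(1, 0, 0), L, n2 + 1)
    solve6[[half]] <- solve_patch(m, n2, a, u0, u1, v0, v1, du, du,
                                  circ_dv(zs, m + 1), circ_dv(-zs, m + 1))
  }
  # --- branch 1 (north, +alpha)
  for (half in 1:2) {
    zs <- if (half == 1) 1 else -1
    u0 <- if (half == 1) {
      junction_edge(seam_p1u, rev_rows(seam_12u))        # N -> T -> A
    } else {
      junction_edge(seam_12l, rev_rows(seam_p1l))        # A -> B -> N
    }
    e1 <- if (half == 1) out1 else -out1
    u1 <- half_circle(O1, e1, c(0, 0, zs), R, v_seq)
    v0 <- line_edge(u0[1, ], u1[1, ], u_seq)
    v1 <- line_edge(u0[n2 + 1, ], u1[n2 + 1, ], u_seq)
    du <- axial_du(dplus, L, n2 + 1)
    solve6[[2 + half]] <- solve_patch(m, n2, a, u0, u1, v0, v1, du, du,
                                      circ_dv(zs, m + 1), circ_dv(-zs, m + 1))
  }
  # --- branch 2 (south, -alpha)
  for (half in 1:2) {
    zs <- if (half == 1) 1 else -1
    u0 <- if (half == 1) {
      junction_edge(seam_12u, rev_rows(seam_p2u))        # A -> T -> S
    } else {
      junction_edge(seam_p2l, rev_rows(seam_12l))        # S -> B -> A
    }
    e1 <- if (half == 1) in2 else -in2
    u1 <- half_circle(O2, e1, c(0, 0, zs), R, v_seq)
    v0 <- line_edge(u0[1, ], u1[1, ], u_seq)
    v1 <- line_edge(u0[n2 + 1, ], u1[n2 + 1, ], u_seq)
    du <- axial_du(dminus, L, n2 + 1)
    solve6[[4 + half]] <- solve_patch(m, n2, a, u0, u1, v0, v1, du, du,
                                      circ_dv(zs, m + 1), circ_dv(-zs, m + 1))
  }

  segs <- list(
    list(seg = 1L, patches = solve6[1:2], axial0 = -L, axial_len = L),
    list(seg = 2L, patches = solve6[3:4], axial0 = 0, axial_len = L),
    list(seg = 3L, patches = solve6[5:6], axial0 = 0, axial_len = L)
  )
  mesh <- assemble_mesh(segs, m = m, n = n, R = R, kind = "bifurcation",
                        spec = spec)
  mesh$neighbors <- bifurcation_neighbors(mesh)
  if (tile) mesh <- tile_cells(mesh) else mesh
}

# Merge per-segment patch node grids into global nodes + quad table.
# Each segment contributes 2 patches of (m+1) x (n2+1) nodes; circumferential
# index v_glob runs 0..n-1 (upper patch columns 0..n2, lower n2..n with wrap).
assemble_mesh <- function(segs, m, n, R, kind, spec) {
  n2 <- n %/% 2L
  key_of <- function(p) {
    q <- round(p, 9)
    q[q == 0] <- 0 # clear negative zero so keys match across seams
    sprintf("%.9f|%.9f|%.9f", q[, 1], q[, 2], q[, 3])
  }
  node_env <- new.env()
  nodes <- list(); n_nodes <- 0L
  get_ids <- function(pts) {
    keys <- key_of(pts)
    ids <- integer(length(keys))
    for (t in seq_along(keys)) {
      id <- node_env[[keys[t]]]
      if (is.null(id)) {
        n_nodes <<- n_nodes + 1L
        id <- n_nodes
        node_env[[keys[t]]] <- id
        nodes[[id]] <<- pts[t, ]
      }
      ids[t] <- id
    }
    ids
  }

  quad_rows <- list()
  for (sg in segs) {
    # node id grid (m+1) x (n+1) around the tube; column n+1 repeats column 1
    grid_ids <- matrix(0L, m + 1, n + 1)
    for (half in 1:2) {
      ph <- sg$patches[[half]]
      pts <- cbind(as.vector(ph[, , 1]), as.vector(ph[, , 2]),
                   as.vector(ph[, , 3]))
      ids <- matrix(get_ids(pts), m + 1, n2 + 1)
      cols <- if (half == 1) 1:(n2 + 1) else (n2 + 1):(n + 1)
      grid_ids[, cols] <- ids
    }
    if (!all(grid_ids[, n + 1] == grid_ids[, 1])) {
      abort("segment seam nodes failed to merge; geometry is not watertight")
    }
    iu <- rep(0:(m - 1), times = n)
    iv <- rep(0:(n - 1), each = m)
    quad_rows[[length(quad_rows) + 1]] <- tibble(
      seg = sg$seg, iu = iu, iv = iv,
      n00 = grid_ids[cbind(iu + 1, iv + 1)],
      n10 = grid_ids[cbind(iu + 2, iv + 1)],
      n11 = grid_ids[cbind(iu + 2, iv + 2)],
      n01 = grid_ids[cbind(iu + 1, iv + 2)],
      axial0 = sg$axial0 + iu * sg$axial_len / m,
      axial1 = sg$axial0 + (iu + 1) * sg$axial_len / m
    )
  }
  quads <- dplyr::bind_rows(quad_rows)
  quads$quad_id <- seq_len(nrow(quads))
  node_mat <- do.call(rbind, nodes)
  colnames(node_mat) <- c("x", "y", "z")

  structure(list(kind = kind, spec = spec, m = m, n = n, R = R,
                 nodes = node_mat, quads = quads, neighbors = NULL,
                 cells = NULL),
            class = "vw_mesh")
}

# quad lookup helper: id by (seg, iu, iv)
quad_index <- function(mesh) {
  q <- mesh$quads
  arr <- array(0L, c(max(q$seg), mesh$m, mesh$n))
  arr[cbind(q$seg, q$iu + 1, q$iv + 1)] <- q$quad_id
  arr
}

tube_neighbors <- function(mesh) {
  qi <- quad_index(mesh)
  m <- mesh$m; n <- mesh$n
  rows <- list()
  add <- function(a, b, side, reversed = FALSE) {
    rows[[length(rows) + 1]] <<- tibble(quad = a, nbr = b, side = side,
                                        reversed = reversed)
  }
  for (iu in 0:(m - 1)) {
    for (iv in 0:(n - 1)) {
      id <- qi[1, iu + 1, iv + 1]
      if (iu < m - 1) add(id, qi[1, iu + 2, iv + 1], "u_plus")
      add(id, qi[1, iu + 1, (iv + 1) %% n + 1], "v_plus")
    }
  }
  symmetrize_neighbors(dplyr::bind_rows(rows))
}

bifurcation_neighbors <- function(mesh) {
  qi <- quad_index(mesh)
  m <- mesh$m; n <- mesh$n; q <- n %/% 4L; n2 <- n %/% 2L
  rows <- list()
  add <- function(a, b, side, reversed = FALSE) {
    rows[[length(rows) + 1]] <<- tibble(quad = a, nbr = b, side = side,
                                        reversed = reversed)
  }
  for (sg in 1:3) {
    for (iu in 0:(m - 1)) {
      for (iv in 0:(n - 1)) {
        id <- qi[sg, iu + 1, iv + 1]
        if (iu < m - 1) add(id, qi[sg, iu + 2, iv + 1], "u_plus")
        add(id, qi[sg, iu + 1, (iv + 1) %% n + 1], "v_plus")
      }
    }
  }
  for (iv in 0:(n - 1)) {
    # parent outlet row attaches to the branch quarters
    pid <- qi[1, m, iv + 1]
    if (iv < q) {
      add(pid, qi[2, 1, iv + 1], "u_plus")                 # N-T quarter
    } else if (iv < n2) {
      add(pid, qi[3, 1, iv + 1], "u_plus")                 # T-S quarter
    } else if (iv < 3 * q) {
      add(pid, qi[3, 1, iv + 1], "u_plus")                 # S-B quarter
    } else {
      add(pid, qi[2, 1, iv + 1], "u_plus")                 # B-N quarter
    }
  }
  # carina seams: branch1 inner quarters meet branch2 inner quarters,
  # with reversed circumferential orientation
  for (iv in q:(n2 - 1)) {                                  # upper: T -> A
    add(qi[2, 1, iv + 1], qi[3, 1, (n2 - 1 - iv) + 1], "u_minus",
        reversed = TRUE)
  }
  for (iv in n2:(3 * q - 1)) {                              # lower: A -> B
    add(qi[2, 1, iv + 1], qi[3, 1, (3 * n2 - 1 - iv) + 1], "u_minus",
        reversed = TRUE)
  }
  symmetrize_neighbors(dplyr::bind_rows(rows))
}

# store each adjacency once per direction; derive the reverse direction
symmetrize_neighbors <- function(nb) {
  opp <- c(u_plus = "u_minus", u_minus = "u_plus",
           v_plus = "v_minus", v_minus = "v_plus")
  # a u_minus <-> u_minus pairing (carina) stays u_minus from both sides
  same_side <- nb$side == "u_minus"
  rev_nb <- tibble(quad = nb$nbr, nbr = nb$quad,
                   side = ifelse(same_side, "u_minus", unname(opp[nb$side])),
                   reversed = nb$reversed)
  out <- dplyr::distinct(dplyr::bind_rows(nb, rev_nb))
  dplyr::arrange(out, .data$quad, .data$side)
}

#' Tile a mesh with endothelial and smooth muscle cells
#'
#' Fills every quadrilateral with the fundamental 4 x 4 unit grid: 80 ECs
#' (4 axial rows x 20 circumferential columns, footprint 65 x 10 um) and 208
#' SMCs (52 x 4, footprint 50 x 5 um). Cell centres are placed by bilinear
#' interpolation of the quad corners; axial positions are measured along the
#' centreline path (negative upstream of a bifurcation's junction).
#'
#' @param mesh a `vw_mesh`.
#' @return The mesh with a `cells` tibble: `cell_id` (within layer), `layer`
#'   (`"EC"`/`"SMC"`), `quad_id`, `row`, `col`, `x`, `y`, `z`, `axial` (mm).
#' @export
tile_cells <- function(mesh) {
  stopifnot(inherits(mesh, "vw_mesh"))
  q <- mesh$quads
  layer_cells <- function(nrow_, ncol_, layer) {
    grid <- expand.grid(row = seq_len(nrow_), col = seq_len(ncol_))
    nq <- nrow(q)
    ncell <- nrow_ * ncol_
    quad_rep <- rep(q$quad_id, each = ncell)
    row <- rep(grid$row, times = nq)
    col <- rep(grid$col, times = nq)
    uf <- (row - 0.5) / nrow_
    vf <- (col - 0.5) / ncol_
    i0 <- rep(seq_len(nq), each = ncell)
    p00 <- mesh$nodes[q$n00[i0], , drop = FALSE]
    p10 <- mesh$nodes[q$n10[i0], , drop = FALSE]
    p11 <- mesh$nodes[q$n11[i0], , drop = FALSE]
    p01 <- mesh$nodes[q$n01[i0], , drop = FALSE]
    pos <- p00 * ((1 - uf) * (1 - vf)) + p10 * (uf * (1 - vf)) +
      p11 * (uf * vf) + p01 * ((1 - uf) * vf)
    tibble(
      layer = layer, quad_id = quad_rep, row = row, col = col,
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      axial = q$axial0[i0] + uf * (q$axial1[i0] - q$axial0[i0])
    )
  }
  ec <- layer_cells(EC_ROWS, EC_COLS, "EC")
  smc <- layer_cells(SMC_ROWS, SMC_COLS, "SMC")
  ec$cell_id <- seq_len(nrow(ec))
  smc$cell_id <- seq_len(nrow(smc))
  mesh$cells <- dplyr::bind_rows(ec, smc)
  mesh
}

#' Mesh cell census
#'
#' @param mesh a tiled `vw_mesh`.
#' @return One-row tibble with quad and cell counts.
#' @export
mesh_census <- function(mesh) {
  stopifnot(inherits(mesh, "vw_mesh"))
  nq <- nrow(mesh$quads)
  if (is.null(mesh$cells)) {
    tibble(quads = nq, n_ec = nq * EC_ROWS * EC_COLS,
           n_smc = nq * SMC_ROWS * SMC_COLS,
           total = nq * (EC_ROWS * EC_COLS + SMC_ROWS * SMC_COLS))
  } else {
    tibble(quads = nq,
           n_ec = sum(mesh$cells$layer == "EC"),
           n_smc = sum(mesh$cells$layer == "SMC"),
           total = nrow(mesh$cells))
  }
}

#' @exportS3Method base::print
print.vw_mesh <- function(x, ...) {
  cen <- mesh_census(x)
  cat("<vw_mesh>", x$kind, "with", cen$quads, "quads;",
      if (is.null(x$cells)) "untiled" else
        paste0(cen$n_ec, " ECs + ", cen$n_smc, " SMCs = ", cen$total, " cells"),
      "\n")
  invisible(x)
}

#' Extract cells as a tibble
#'
#' @param x a tiled `vw_mesh`.
#' @param ... unused.
#' @export
as_tibble.vw_mesh <- function(x, ...) {
  if (is.null(x$cells)) abort("mesh is not tiled; call tile_cells() first")
  x$cells
}

# counts of V - E + F for the quad complex (topology diagnostics)
mesh_euler <- function(mesh) {
  q <- mesh$quads
  edges <- rbind(cbind(q$n00, q$n10), cbind(q$n10, q$n11),
                 cbind(q$n11, q$n01), cbind(q$n01, q$n00))
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  nE <- length(unique(ekey))
  nV <- nrow(mesh$nodes)
  nF <- nrow(q)
  list(V = nV, E = nE, F = nF, chi = nV - nE + nF,
       edge_use = table(table(ekey)))
}
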