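#' Patch boundary data for the biharmonic surface solver
#'
#' A surface patch is generated on the unit parameter square, `u` axial and
#' `v` circumferential, by solving the anisotropic biharmonic equation
#' `(d^2/du^2 + a^2 d^2/dv^2)^2 phi = 0` per Cartesian coordinate. The
#' boundary data prescribe positions (Dirichlet) on all four edges and the
#' first parameter derivative across each edge (Neumann), which controls the
#' speed and direction with which the surface leaves its boundary.
#'
#' @param u0,u1 Dirichlet positions on the `u = 0` / `u = 1` edges,
#'   `(n+1) x 3` matrices (mm).
#' @param v0,v1 Dirichlet positions on the `v = 0` / `v = 1` edges,
#'   `(m+1) x 3` matrices. Corner rows must agree with `u0`/`u1`.
#' @param du0,du1 Neumann data: `d phi / d u` on the two `u` edges,
#'   `(n+1) x 3`.
#' @param dv0,dv1 Neumann data on the two `v` edges, `(m+1) x 3`.
#' @param m,n number of grid intervals in `u` and `v` (at least 3).
#' @param a anisotropy constant of the operator (dimensionless). Small
#'   values weight axial smoothness and keep long tubes from pinching; see
#'   the methods vignette.
#' @return An object of class `vw_patch_boundary`.
#' @export
patch_boundary <- function(u0, u1, v0, v1, du0, du1, dv0, dv1, m, n, a = 0.1) {
  if (m < 2 || n < 2) abort("patch resolution m, n must be >= 2")
  dims_ok <- function(x, len) is.matrix(x) && nrow(x) == len && ncol(x) == 3
  if (!dims_ok(u0, n + 1) || !dims_ok(u1, n + 1) ||
      !dims_ok(du0, n + 1) || !dims_ok(du1, n + 1)) {
    abort("u-edge data must be (n+1) x 3 matrices")
  }
  if (!dims_ok(v0, m + 1) || !dims_ok(v1, m + 1) ||
      !dims_ok(dv0, m + 1) || !dims_ok(dv1, m + 1)) {
    abort("v-edge data must be (m+1) x 3 matrices")
  }
  corner_gap <- max(
    abs(v0[1, ] - u0[1, ]), abs(v1[1, ] - u0[n + 1, ]),
    abs(v0[m + 1, ] - u1[1, ]), abs(v1[m + 1, ] - u1[n + 1, ])
  )
  if (corner_gap > 1e-9) abort("boundary loops do not close at the corners")
  structure(list(u0 = u0, u1 = u1, v0 = v0, v1 = v1, du0 = du0, du1 = du1,
                 dv0 = dv0, dv1 = dv1, m = m, n = n, a = a),
            class = "vw_patch_boundary")
}

#' Solve the biharmonic surface equation on a patch
#'
#' Discretises `(d^2/du^2 + a^2 d^2/dv^2)^2 phi = 0` with the 13-point
#' finite-difference stencil obtained by composing the second-order operator
#' with itself; Dirichlet values are imposed exactly on the boundary nodes
#' and Neumann derivatives through one ghost layer eliminated by central
#' differences. The three coordinates share one sparse factorisation.
#'
#' @param boundary a [patch_boundary()].
#' @return An `(m+1) x (n+1) x 3` array of surface points; dimnames mark the
#'   coordinate slab.
#' @export
solve_biharmonic <- function(boundary) {
  stopifnot(inherits(boundary, "vw_patch_boundary"))
  m <- boundary$m; n <- boundary$n; a <- boundary$a
  h <- 1 / m; k <- 1 / n
  cu <- 1 / h^2; cv <- a^2 / k^2; cc <- -2 * cu - 2 * cv

  # 13-point stencil of the composed operator
  offs <- rbind(
    c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
    c(2, 0), c(-2, 0), c(0, 2), c(0, -2),
    c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)
  )
  coefs <- c(cc^2 + 2 * cu^2 + 2 * cv^2,
             2 * cu * cc, 2 * cu * cc, 2 * cv * cc, 2 * cv * cc,
             cu^2, cu^2, cv^2, cv^2,
             2 * cu * cv, 2 * cu * cv, 2 * cu * cv, 2 * cu * cv)

  # full Dirichlet grid with NA interior
  grid_val <- array(NA_real_, c(m + 1, n + 1, 3))
  grid_val[1, , ] <- boundary$u0
  grid_val[m + 1, , ] <- boundary$u1
  grid_val[, 1, ] <- boundary$v0
  grid_val[, n + 1, ] <- boundary$v1

  idx <- function(i, j) (j - 2) * (m - 1) + (i - 1) # interior (2..m, 2..n) in 1-based grid
  n_unk <- (m - 1) * (n - 1)
  rhs <- matrix(0, n_unk, 3)

  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add_entry <- function(row, i, j, coef) {
    # classify target node (1-based grid indices, possibly ghost)
    if (i >= 2 && i <= m && j >= 2 && j <= n) {
      ii[[length(ii) + 1]] <<- row; jj[[length(jj) + 1]] <<- idx(i, j)
      vv[[length(vv) + 1]] <<- coef
    } else if (i >= 1 && i <= m + 1 && j >= 1 && j <= n + 1) {
      rhs[row, ] <<- rhs[row, ] - coef * grid_val[i, j, ]
    } else if (i == 0) { # ghost beyond u = 0: phi(-1) = phi(1) - 2h * du0
      rhs[row, ] <<- rhs[row, ] + coef * 2 * h * boundary$du0[j, ]
      add_entry(row, 2, j, coef)
    } else if (i == m + 2) { # ghost beyond u = 1
      rhs[row, ] <<- rhs[row, ] - coef * 2 * h * boundary$du1[j, ]
      add_entry(row, m, j, coef)
    } else if (j == 0) {
      rhs[row, ] <<- rhs[row, ] + coef * 2 * k * boundary$dv0[i, ]
      add_entry(row, i, 2, coef)
    } else if (j == n + 2) {
      rhs[row, ] <<- rhs[row, ] - coef * 2 * k * boundary$dv1[i, ]
      add_entry(row, i, n, coef)
    } else {
      abort("internal error: stencil reached an unexpected ghost node")
    }
  }

  for (j in 2:n) {
    for (i in 2:m) {
      row <- idx(i, j)
      for (s in seq_len(nrow(offs))) {
        add_entry(row, i + offs[s, 1], j + offs[s, 2], coefs[s])
      }
    }
  }

  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n_unk, n_unk))
  sol <- tryCatch(
    as.matrix(Matrix::solve(A, rhs)),
    error = function(e) abort(paste0(
      "biharmonic system is singular; boundary data are deficient (",
      conditionMessage(e), ")"))
  )
  for (j in 2:n) {
    for (i in 2:m) {
      grid_val[i, j, ] <- sol[idx(i, j), ]
    }
  }
  dimnames(grid_val) <- list(NULL, NULL, c("x", "y", "z"))
  grid_val
}

# residual of the discrete composed operator on interior-of-interior nodes
# (those whose full stencil avoids ghosts); used by tests and diagnostics
biharmonic_residual <- function(phi, a) {
  m <- dim(phi)[1] - 1; n <- dim(phi)[2] - 1
  if (m < 5 || n < 5) return(0)
  h <- 1 / m; k <- 1 / n
  res <- 0
  for (cmp in 1:3) {
    g <- phi[, , cmp]
    lap <- matrix(0, m + 1, n + 1)
    for (i in 2:m) {
      for (j in 2:n) {
        lap[i, j] <- (g[i - 1, j] - 2 * g[i, j] + g[i + 1, j]) / h^2 +
          a^2 * (g[i, j - 1] - 2 * g[i, j] + g[i, j + 1]) / k^2
      }
    }
    for (i in 3:(m - 1)) {
      for (j in 3:(n - 1)) {
        r <- (lap[i - 1, j] - 2 * lap[i, j] + lap[i + 1, j]) / h^2 +
          a^2 * (lap[i, j - 1] - 2 * lap[i, j] + lap[i, j + 1]) / k^2
        res <- max(res, abs(r))
      }
    }
  }
  res
}
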