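# apply the discrete anisotropic biharmonic operator by two successive
# applications of the second-order operator, with ghost layers eliminated by
# the Neumann central differences; independent of the package's assembly
apply_bih_oracle <- function(phi, b) {
  m <- b$m; n <- b$n; a <- b$a; h <- 1 / m; k <- 1 / n
  ext <- matrix(NA_real_, m + 3, n + 3) # indices 0..m+2 -> 1..m+3
  ext[2:(m + 2), 2:(n + 2)] <- phi
  ext[1, 2:(n + 2)] <- phi[2, ] - 2 * h * b$du0_c
  ext[m + 3, 2:(n + 2)] <- phi[m, ] + 2 * h * b$du1_c
  ext[2:(m + 2), 1] <- phi[, 2] - 2 * k * b$dv0_c
  ext[2:(m + 2), n + 3] <- phi[, n] + 2 * k * b$dv1_c
  A_of <- function(f, i, j) { # f indexed on the extended grid
    (f[i - 1, j] - 2 * f[i, j] + f[i + 1, j]) / h^2 +
      a^2 * (f[i, j - 1] - 2 * f[i, j] + f[i, j + 1]) / k^2
  }
  lap <- matrix(NA_real_, m + 1, n + 1)
  for (i in 1:(m + 1)) {
    for (j in 1:(n + 1)) {
      lap[i, j] <- A_of(ext, i + 1, j + 1)
    }
  }
  res <- matrix(NA_real_, m + 1, n + 1)
  lap_ext <- matrix(NA_real_, m + 3, n + 3)
  lap_ext[2:(m + 2), 2:(n + 2)] <- lap
  for (i in 2:m) {
    for (j in 2:n) {
      res[i, j] <- A_of(lap_ext, i + 1, j + 1)
    }
  }
  res[2:m, 2:n]
}

# boundary helper for one coordinate slab of a patch_boundary
slab <- function(b, cmp) {
  list(m = b$m, n = b$n, a = b$a,
       du0_c = b$du0[, cmp], du1_c = b$du1[, cmp],
       dv0_c = b$dv0[, cmp], dv1_c = b$dv1[, cmp])
}

test_that("a plane is an exact solution of the biharmonic patch problem", {
  m <- 7; n <- 5
  u <- seq(0, 1, length.out = m + 1); v <- seq(0, 1, length.out = n + 1)
  plane <- function(u, v) cbind(u, v, 2 * u + 3 * v - 1)
  b <- patch_boundary(
    u0 = plane(0, v), u1 = plane(1, v),
    v0 = plane(u, 0), v1 = plane(u, 1),
    du0 = cbind(rep(1, n + 1), 0, 2), du1 = cbind(rep(1, n + 1), 0, 2),
    dv0 = cbind(0, rep(1, m + 1), 3), dv1 = cbind(0, rep(1, m + 1), 3),
    m = m, n = n, a = 0.4
  )
  phi <- solve_biharmonic(b)
  for (i in 1:(m + 1)) {
    expect_equal(unname(phi[i, , 3]),
                 unname(2 * u[i] + 3 * v - 1), tolerance = 1e-10)
  }
})

test_that("the dense operator oracle reproduces the sparse solve", {
  m <- 6; n <- 6
  v <- seq(0, 1, length.out = n + 1); u <- seq(0, 1, length.out = m + 1)
  R <- 0.6
  # half-cylinder boundary, z-coordinate slab is the interesting one
  th <- v * pi
  b <- patch_boundary(
    u0 = cbind(0, R * cos(th), R * sin(th)),
    u1 = cbind(1.5, R * cos(th), R * sin(th)),
    v0 = cbind(u * 1.5, R, 0), v1 = cbind(u * 1.5, -R, 0),
    du0 = cbind(rep(1.5, n + 1), 0, 0), du1 = cbind(rep(1.5, n + 1), 0, 0),
    dv0 = cbind(0, rep(0, m + 1), pi * R),
    dv1 = cbind(0, rep(0, m + 1), -pi * R),
    m = m, n = n, a = 0.1
  )
  phi <- solve_biharmonic(b)

  for (cmp in 1:3) {
    sb <- slab(b, cmp)
    # dense system by probing the oracle operator with unit vectors
    n_unk <- (m - 1) * (n - 1)
    base <- phi[, , cmp]
    zero_interior <- base
    zero_interior[2:m, 2:n] <- 0
    r0 <- as.vector(apply_bih_oracle(zero_interior, sb))
    L <- matrix(0, n_unk, n_unk)
    for (kk in seq_len(n_unk)) {
      e <- matrix(0, m + 1, n + 1)
      e[2:m, 2:n][kk] <- 1
      nb <- sb; nb$du0_c <- nb$du1_c <- nb$dv0_c <- nb$dv1_c <- rep(0, max(m, n) + 1)
      L[, kk] <- as.vector(apply_bih_oracle(e, nb))
    }
    dense_sol <- solve(L, -r0)
    expect_equal(as.vector(base[2:m, 2:n]), dense_sol, tolerance = 1e-8)
    # and the discrete residual of the package solution vanishes relative
    # to the operator norm times the solution magnitude
    res <- apply_bih_oracle(base, sb)
    op_norm <- (2 * m^2 + 2 * sb$a^2 * n^2)^2
    expect_lt(max(abs(res)) / (op_norm * max(abs(base), 1)), 1e-8)
  }
})

test_that("tube meshes recover the analytic cylinder within 1% of diameter", {
  D <- 1.2
  tm <- tube_mesh(6, 8, length = 3, diameter = D, tile = FALSE)
  r <- sqrt(tm$nodes[, "y"]^2 + tm$nodes[, "z"]^2)
  expect_lt(max(abs(r - D / 2)), 0.01 * D)
  # axial coordinate spans [0, length]
  expect_equal(range(tm$nodes[, "x"]), c(0, 3))
})

test_that("cell tiling yields the fixed per-quad census", {
  tm <- make_fixture("tube_small")
  expect_identical(nrow(tm$quads), 16L)
  cen <- mesh_census(tm)
  expect_identical(cen$n_ec, 16L * 80L)
  expect_identical(cen$n_smc, 16L * 208L)
  expect_identical(cen$total, 4608L)
  per_quad <- dplyr::count(tm$cells, .data$quad_id)
  expect_true(all(per_quad$n == 288L))
  per_quad_layer <- dplyr::count(tm$cells, .data$quad_id, .data$layer)
  expect_true(all(per_quad_layer$n[per_quad_layer$layer == "EC"] == 80L))
  expect_true(all(per_quad_layer$n[per_quad_layer$layer == "SMC"] == 208L))
})

test_that("five EC footprints cover the same area as 13 SMC footprints", {
  ec_area <- vasowave:::EC_LEN_UM * vasowave:::EC_WID_UM
  smc_area <- vasowave:::SMC_LEN_UM * vasowave:::SMC_WID_UM
  expect_identical(5 * ec_area, 13 * smc_area)
  expect_identical(5 * ec_area / smc_area / 5, 13 / 5)
})

test_that("the bifurcation mesh is watertight with pair-of-pants topology", {
  bm <- make_fixture("bif_mini")
  expect_identical(nrow(bm$quads), 120L)
  eu <- vasowave:::mesh_euler(bm)
  # chi = V - E + F = -1 for a three-holed sphere
  expect_identical(eu$chi, -1L)
  # every edge bounds 1 (mesh boundary) or 2 quads; boundary edges are the
  # three open circles, n quads each
  uses <- as.integer(names(eu$edge_use))
  expect_true(all(uses %in% c(1L, 2L)))
  expect_identical(unname(eu$edge_use[uses == 1L]), 3L * bm$n)
  expect_identical(mesh_census(bm)$total, 120L * 288L)
})

test_that("geometry defaults derive the canonical resolution from footprints", {
  gs <- geometry_spec()
  expect_identical(gs$m, 34L)
  expect_identical(gs$n, 40L)
  expect_identical(3L * gs$m * gs$n, 4080L)
  expect_error(geometry_spec(branch_angle = 95), "branch_angle")
  expect_error(geometry_spec(diameter = -1), "positive")
})
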