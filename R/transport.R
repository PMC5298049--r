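#' Channel specification for the reduced ATP transport solver
#'
#' Steady advection-diffusion of ATP in a 2D channel half-height domain
#' (`y = 0` wall, `y = half_height` symmetry plane) over a prescribed
#' analytic Poiseuille profile, with a reactive Robin condition at the wall:
#' hydrolysis by ecto-nucleotidases at rate `K` and shear-dependent release
#' `S(x) = s_max * tau_w(x) / tau_m`. This stands in for a full 3D CFD
#' species solve; its product is a wall ATP profile convertible to a J_PLC
#' map.
#'
#' @param length channel length (mm).
#' @param half_height channel half-height (mm).
#' @param nx,ny finite-volume cells axially / wall-normal.
#' @param diffusivity ATP diffusion coefficient (mm^2/s).
#' @param inlet inlet ATP concentration (uM); the canonical value is 0.1.
#' @param K wall hydrolysis rate constant (mm/s).
#' @param tau_m wall-shear-stress normalisation of the source term (Pa).
#' @param s_max source magnitude at `tau_w = tau_m` (uM mm/s).
#' @param u_mean mean axial velocity (mm/s); 0 gives pure diffusion.
#' @param nu kinematic viscosity (mm^2/s).
#' @param rho fluid density (kg/m^3).
#' @param centre_bc condition at the channel centreline: `"symmetry"` (zero
#'   flux, the physical half-channel) or `"dirichlet"` (concentration held
#'   at the inlet value; useful for closed-form checks).
#' @return A `vw_channel_spec`; prints the Peclet number.
#' @export
channel_spec <- function(length = 10, half_height = 0.5, nx = 200, ny = 40,
                         diffusivity = 2.36e-4, inlet = 0.1, K = 1.67e-3,
                         tau_m = 1, s_max = 1.67e-4, u_mean = 20,
                         nu = 3.3, rho = 1050,
                         centre_bc = c("symmetry", "dirichlet")) {
  centre_bc <- match.arg(centre_bc)
  vals <- c(length, half_height, nx, ny, diffusivity, inlet, tau_m, nu, rho)
  if (any(vals <= 0) || K < 0 || s_max < 0 || u_mean < 0) {
    abort("channel parameters must be positive (K, s_max, u_mean non-negative)")
  }
  structure(list(length = length, half_height = half_height,
                 nx = as.integer(nx), ny = as.integer(ny),
                 diffusivity = diffusivity, inlet = inlet, K = K,
                 tau_m = tau_m, s_max = s_max, u_mean = u_mean, nu = nu,
                 rho = rho, centre_bc = centre_bc,
                 peclet = u_mean * 2 * half_height / diffusivity),
            class = "vw_channel_spec")
}

#' @exportS3Method base::print
print.vw_channel_spec <- function(x, ...) {
  cat("<vw_channel_spec>", x$length, "x", 2 * x$half_height,
      "mm channel; Pe =", format(x$peclet, digits = 4), "\n")
  invisible(x)
}

# parabolic profile on the half domain: u(0) = 0 at the wall,
# u(half_height) = 1.5 u_mean at the symmetry plane
poiseuille_u <- function(spec, y) {
  H <- spec$half_height
  1.5 * spec$u_mean * (1 - ((y - H) / H)^2)
}

#' Wall shear stress of the prescribed channel flow
#'
#' `tau_w = mu * du/dy` at the wall; constant along a uniform channel and
#' linear in the flow rate.
#'
#' @param spec a [channel_spec()].
#' @return Tibble `x` (cell centres, mm), `tau_w` (Pa).
#' @export
wss_profile <- function(spec) {
  stopifnot(inherits(spec, "vw_channel_spec"))
  x <- (seq_len(spec$nx) - 0.5) * spec$length / spec$nx
  mu <- spec$rho * spec$nu * 1e-6 # Pa s
  dudy <- 3 * spec$u_mean / spec$half_height # 1/s
  tibble(x = x, tau_w = rep(mu * dudy, spec$nx))
}

#' Solve the reduced ATP transport problem
#'
#' Finite-volume discretisation (first-order upwind advection, second-order
#' central diffusion) of `u . grad(phi) = D lap(phi)` with inlet Dirichlet,
#' outlet zero-gradient, symmetry at the channel centre and the reactive
#' Robin wall condition `D dphi/dy|wall = K phi_wall - S(x)`. As in the
#' source methodology the wall condition is applied iteratively: the wall
#' flux computed from the current wall concentration is imposed as a Neumann
#' condition, the transport equation re-solved, and the loop repeated (with
#' under-relaxation) until the relative change falls below `tol`.
#'
#' @param spec a [channel_spec()].
#' @param tol relative-change convergence tolerance of the wall iteration.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   residual trace.
#' @param relax under-relaxation factor on the wall concentration update.
#' @return A `vw_transport` with the concentration field (uM), the wall
#'   profile, the convergence history and a species mass balance.
#' @export
solve_transport <- function(spec = channel_spec(), tol = 1e-8,
                            max_iter = 500, relax = 0.5) {
  stopifnot(inherits(spec, "vw_channel_spec"))
  nx <- spec$nx; ny <- spec$ny
  dx <- spec$length / nx; dy <- spec$half_height / ny
  D <- spec$diffusivity
  y_c <- (seq_len(ny) - 0.5) * dy
  u <- poiseuille_u(spec, y_c) # per row (constant in x)
  tau <- wss_profile(spec)
  S <- spec$s_max * tau$tau_w / spec$tau_m # uM mm / s

  id <- function(i, j) (j - 1L) * nx + i
  n_unk <- nx * ny
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  rhs0 <- numeric(n_unk)
  push <- function(r, c, val) {
    ii[[length(ii) + 1]] <<- r; jj[[length(jj) + 1]] <<- c
    vv[[length(vv) + 1]] <<- val
  }
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      r <- id(i, j)
      diag_c <- 0
      # west face
      if (i == 1) {
        # inlet Dirichlet: advective influx u*phi_in*dy plus diffusive
        # D*(phi_in - phi_P)/(dx/2)*dy
        rhs0[r] <- rhs0[r] + u[j] * spec$inlet * dy +
          D * spec$inlet / (dx / 2) * dy
        diag_c <- D / (dx / 2) * dy
      } else {
        push(r, id(i - 1, j), -(u[j] * dy + D * dy / dx))
        diag_c <- D * dy / dx
      }
      # east face
      if (i == nx) {
        diag_c <- diag_c + u[j] * dy # advective outflow, zero diffusion
      } else {
        push(r, id(i + 1, j), -D * dy / dx)
        diag_c <- diag_c + u[j] * dy + D * dy / dx
      }
      # south face (wall) handled via rhs (Neumann iteration)
      if (j > 1) {
        push(r, id(i, j - 1), -D * dx / dy)
        diag_c <- diag_c + D * dx / dy
      }
      # north face: interior, symmetry (zero flux) or centre Dirichlet
      if (j < ny) {
        push(r, id(i, j + 1), -D * dx / dy)
        diag_c <- diag_c + D * dx / dy
      } else if (spec$centre_bc == "dirichlet") {
        rhs0[r] <- rhs0[r] + D * spec$inlet / (dy / 2) * dx
        diag_c <- diag_c + D / (dy / 2) * dx
      }
      push(r, r, diag_c)
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n_unk, n_unk))

  phi_wall <- rep(spec$inlet, nx)
  history <- numeric(0)
  phi <- NULL
  for (it in seq_len(max_iter)) {
    q_wall <- spec$K * phi_wall - S # flux out of the domain (uM mm/s)
    rhs <- rhs0
    rhs[id(seq_len(nx), 1L)] <- rhs[id(seq_len(nx), 1L)] - q_wall * dx
    sol <- as.numeric(Matrix::solve(A, rhs))
    phi <- matrix(sol, nx, ny)
    # reconstruct wall value from flux continuity between cell centre and wall
    new_wall <- (D * phi[, 1] / (dy / 2) + S) / (spec$K + D / (dy / 2))
    change <- max(abs(new_wall - phi_wall)) / max(abs(new_wall), 1e-30)
    # the explicit Neumann update amplifies when the wall Biot number
    # K * H / D exceeds one; shrink the relaxation whenever the residual
    # stops contracting
    if (length(history) && change > 0.9 * history[length(history)]) {
      relax <- max(0.02, relax / 2)
    }
    phi_wall <- relax * new_wall + (1 - relax) * phi_wall
    history <- c(history, change)
    if (change < tol) break
  }
  if (history[length(history)] >= tol) {
    abort(paste0("wall-condition iteration did not converge; residual trace: ",
                 paste(signif(tail(history, 5), 3), collapse = ", ")))
  }

  x_c <- (seq_len(nx) - 0.5) * dx
  # species mass balance (uM mm^2/s): inlet - outlet - net wall exchange
  influx <- sum(u * spec$inlet * dy) +
    sum(D * (spec$inlet - phi[1, ]) / (dx / 2) * dy)
  outflux <- sum(u * phi[nx, ] * dy)
  wall_net <- sum((spec$K * phi_wall - S) * dx)
  centre_in <- if (spec$centre_bc == "dirichlet") {
    sum(D * (spec$inlet - phi[, ny]) / (dy / 2) * dx)
  } else 0
  structure(list(
    spec = spec, x = x_c, y = y_c, phi = phi,
    wall = tibble(x = x_c, tau_w = tau$tau_w, phi_wall = phi_wall,
                  source = S),
    iterations = length(history), history = history,
    balance = tibble(influx = influx, centre_in = centre_in,
                     outflux = outflux, wall_net = wall_net,
                     residual = influx + centre_in - outflux - wall_net)
  ), class = "vw_transport")
}

#' @exportS3Method base::print
print.vw_transport <- function(x, ...) {
  cat("<vw_transport>", x$spec$nx, "x", x$spec$ny, "cells;",
      x$iterations, "wall iterations; wall ATP range [",
      signif(min(x$wall$phi_wall), 4), ",", signif(max(x$wall$phi_wall), 4),
      "] uM\n")
  invisible(x)
}

#' Agonist map from a transport solution
#'
#' Projects the wall ATP concentration onto the mesh's EC positions
#' (nearest axial node; the channel `x = 0` is aligned with the most
#' upstream EC) and converts ATP to J_PLC with [atp_to_jplc()].
#'
#' @param field a `vw_transport`.
#' @param mesh a tiled `vw_mesh`.
#' @param slope,intercept conversion coefficients, see [atp_to_jplc()].
#' @return A `vw_agonist` with provenance `"transport"`.
#' @export
map_from_transport <- function(field, mesh, slope, intercept = 0) {
  stopifnot(inherits(field, "vw_transport"), inherits(mesh, "vw_mesh"))
  if (is.null(mesh$cells)) abort("mesh is not tiled")
  ecs <- dplyr::filter(mesh$cells, .data$layer == "EC")
  x_rel <- ecs$axial - min(ecs$axial)
  if (max(x_rel) > field$spec$length + 1e-9) {
    abort(sprintf(
      "mesh axial extent %.3f mm exceeds the channel length %.3f mm",
      max(x_rel), field$spec$length))
  }
  nearest <- pmin(pmax(round(x_rel / (field$spec$length / field$spec$nx) + 0.5),
                       1), field$spec$nx)
  atp <- field$wall$phi_wall[nearest]
  new_agonist(tibble(ec = ecs$cell_id, axial = ecs$axial,
                     j_plc = atp_to_jplc(atp, slope, intercept)),
              provenance = "transport")
}

#' Export the transport field
#'
#' @param field a `vw_transport`.
#' @param path base path; writes `<path>_wall.csv` (wall profile) and
#'   `<path>_field.csv` (full concentration grid, long format).
#' @export
transport_export_csv <- function(field, path) {
  readr::write_csv(field$wall, paste0(path, "_wall.csv"), progress = FALSE)
  grid <- expand.grid(x = field$x, y = field$y)
  grid$phi <- as.vector(field$phi)
  readr::write_csv(grid, paste0(path, "_field.csv"), progress = FALSE)
  invisible(path)
}
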