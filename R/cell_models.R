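#' Single-cell state constructors
#'
#' An SMC carries five state variables: cytosolic Ca2+ `ca_i` (uM),
#' sarcoplasmic-reticulum store Ca2+ `ca_sr` (uM), membrane potential `v_m`
#' (mV), the open-state fraction of Ca2+-activated K+ channels `w_k`
#' (dimensionless) and cytosolic IP3 `ip3` (uM). An EC carries four:
#' cytosolic Ca2+ `ca_j`, endoplasmic-reticulum store Ca2+ `ca_er`, membrane
#' potential `v_m` and IP3 `ip3`. States are plain named numeric vectors in
#' this fixed order.
#'
#' @param ca_i,ca_sr,v_m,w_k,ip3 SMC state values.
#' @return Named numeric vector.
#' @export
smc_state <- function(ca_i = 0.2, ca_sr = 1, v_m = -50, w_k = 0.1, ip3 = 0.1) {
  c(ca_i = ca_i, ca_sr = ca_sr, v_m = v_m, w_k = w_k, ip3 = ip3)
}

#' @rdname smc_state
#' @param ca_j,ca_er EC cytosolic and store Ca2+ (uM).
#' @export
ec_state <- function(ca_j = 0.2, ca_er = 1, v_m = -60, ip3 = 0.1) {
  c(ca_j = ca_j, ca_er = ca_er, v_m = v_m, ip3 = ip3)
}

smc_names <- c("ca_i", "ca_sr", "v_m", "w_k", "ip3")
ec_names <- c("ca_j", "ca_er", "v_m", "ip3")

#' Smooth muscle cell right-hand side
#'
#' Time derivatives of the five SMC state variables. The pathway set is:
#' IP3-receptor-mediated store release, SERCA uptake, calcium-induced calcium
#' release (CICR), voltage-dependent membrane extrusion, store leak,
#' voltage-operated Ca2+ channels (VOCC), Na+/Ca2+ exchange, Na+/K+-ATPase,
#' chloride and Ca2+-activated K+ currents, first-order K+ channel activation
#' and linear IP3 degradation. The SMC has no intrinsic IP3 production;
#' IP3 arrives only through gap-junction influx.
#'
#' @param state named numeric vector as from [smc_state()].
#' @param params parameter set from [model_params()].
#' @param influx additive gap-junction flux terms, a numeric vector with
#'   elements `ca` (uM/s), `ip3` (uM/s) and `v` (mV/s); zero when uncoupled.
#' @return Named numeric vector of derivatives (per second), same order as
#'   the state.
#' @export
smc_rhs <- function(state, params, influx = c(ca = 0, ip3 = 0, v = 0)) {
  ca <- state[["ca_i"]]; sr <- state[["ca_sr"]]; v <- state[["v_m"]]
  w <- state[["w_k"]]; ip3 <- state[["ip3"]]

  j_ip3 <- pget(params, "F_i") * ip3^2 / (pget(params, "Kr_i")^2 + ip3^2)
  j_sru <- pget(params, "B_i") * ca^2 / (pget(params, "cb_i")^2 + ca^2)
  j_cicr <- pget(params, "C_i") * sr^2 / (pget(params, "sc_i")^2 + sr^2) *
    ca^4 / (pget(params, "cc_i")^4 + ca^4)
  j_extr <- pget(params, "D_i") * ca *
    (1 + (v - pget(params, "vd_i")) / pget(params, "Rd_i"))
  j_leak <- pget(params, "L_i") * sr
  j_vocc <- pget(params, "G_Ca") * (v - pget(params, "v_Ca1")) /
    (1 + exp(-(v - pget(params, "v_Ca2")) / pget(params, "R_Ca")))
  j_naca <- pget(params, "G_NaCa") * ca / (ca + pget(params, "c_NaCa")) *
    (v - pget(params, "v_NaCa"))
  j_nak <- pget(params, "F_NaK")
  j_cl <- pget(params, "G_Cl") * (v - pget(params, "v_Cl"))
  j_k <- pget(params, "G_K") * w * (v - pget(params, "v_K"))
  k_act <- (ca + pget(params, "c_w"))^2 /
    ((ca + pget(params, "c_w"))^2 +
       pget(params, "beta_i") * exp(-(v - pget(params, "v_Ca3")) / pget(params, "R_K")))

  c(
    ca_i = j_ip3 - j_sru + j_cicr - j_extr + j_leak - j_vocc + j_naca +
      influx[["ca"]],
    ca_sr = j_sru - j_cicr - j_leak,
    v_m = pget(params, "gamma_i") * (-j_nak - j_cl - 2 * j_vocc - j_naca - j_k) +
      influx[["v"]],
    w_k = pget(params, "lambda_i") * (k_act - w),
    ip3 = -pget(params, "k_i") * ip3 + influx[["ip3"]]
  )
}

#' Endothelial cell right-hand side
#'
#' Time derivatives of the four EC state variables. Pathways: agonist-driven
#' IP3 production (the constant flux `j_plc`, entering only the IP3
#' equation), IP3-receptor store release, ER uptake, CICR, linear membrane
#' extrusion, store leak, a Ca2+-gated nonselective cation influx, a constant
#' background influx, BKCa and SKCa potassium currents and a residual leak
#' current setting the membrane potential, and linear IP3 degradation.
#'
#' @inheritParams smc_rhs
#' @param state named numeric vector as from [ec_state()].
#' @return Named numeric vector of derivatives (per second).
#' @export
ec_rhs <- function(state, params, influx = c(ca = 0, ip3 = 0, v = 0)) {
  ca <- state[["ca_j"]]; er <- state[["ca_er"]]; v <- state[["v_m"]]
  ip3 <- state[["ip3"]]

  j_ip3 <- pget(params, "F_j") * ip3^2 / (pget(params, "Kr_j")^2 + ip3^2)
  j_eru <- pget(params, "B_j") * ca^2 / (pget(params, "cb_j")^2 + ca^2)
  j_cicr <- pget(params, "C_j") * er^2 / (pget(params, "sc_j")^2 + er^2) *
    ca^4 / (pget(params, "cc_j")^4 + ca^4)
  j_extr <- pget(params, "D_j") * ca
  j_leak <- pget(params, "L_j") * er
  lca <- log10(ca)
  j_cat <- pget(params, "G_cat") * (pget(params, "E_Ca") - v) * 0.5 *
    (1 + tanh((lca - pget(params, "m3_cat")) / pget(params, "m4_cat")))
  p_bk <- 0.2 * (1 + tanh(
    ((lca - pget(params, "c0_j")) * (v - pget(params, "b_j")) - pget(params, "a1_j")) /
      (pget(params, "m3b_j") *
         (v + pget(params, "a2_j") * (lca - pget(params, "c0_j")) - pget(params, "b_j"))^2 +
         pget(params, "m4b_j"))
  ))
  p_sk <- 0.3 * (1 + tanh((lca - pget(params, "m3s_j")) / pget(params, "m4s_j")))
  i_k <- pget(params, "G_tot") * (v - pget(params, "v_K_j")) * (p_bk + p_sk)
  i_r <- pget(params, "G_R") * (v - pget(params, "v_rest_j"))

  c(
    ca_j = j_ip3 - j_eru + j_cicr - j_extr + j_leak + j_cat +
      pget(params, "J0_j") + influx[["ca"]],
    ca_er = j_eru - j_cicr - j_leak,
    v_m = -(i_k + i_r) / pget(params, "C_m") + influx[["v"]],
    ip3 = pget(params, "j_plc") - pget(params, "k_j") * ip3 + influx[["ip3"]]
  )
}

#' Coupled EC/SMC unit right-hand side
#'
#' Nine derivatives for one EC and one SMC joined by heterocellular gap
#' junctions. For each coupled species the flux entering the SMC is the exact
#' negative of the flux entering the EC (pairwise conservation):
#' `g * (x_ec - x_smc)` into the SMC and `g * (x_smc - x_ec)` into the EC.
#'
#' @param ec,smc named state vectors.
#' @param params parameter set from [model_params()].
#' @param coupling a [coupling_config()]; only its heterocellular flags and
#'   rates are used here.
#' @return Numeric vector of 9 derivatives, EC block (4) then SMC block (5),
#'   named with `ec.` and `smc.` prefixes.
#' @export
unit_rhs <- function(ec, smc, params, coupling = coupling_case(1)) {
  g_v <- if (coupling$hetero$v) coupling$rates$g_v_hetero else 0
  g_ca <- if (coupling$hetero$ca) coupling$rates$g_ca_hetero else 0
  g_ip <- if (coupling$hetero$ip3) coupling$rates$g_ip3_hetero else 0

  into_ec <- c(
    ca = g_ca * (smc[["ca_i"]] - ec[["ca_j"]]),
    ip3 = g_ip * (smc[["ip3"]] - ec[["ip3"]]),
    v = g_v * (smc[["v_m"]] - ec[["v_m"]])
  )
  into_smc <- c(
    ca = -into_ec[["ca"]],
    ip3 = -into_ec[["ip3"]],
    v = -into_ec[["v"]]
  )
  d_ec <- ec_rhs(ec, params, into_ec)
  d_smc <- smc_rhs(smc, params, into_smc)
  c(setNames(d_ec, paste0("ec.", ec_names)),
    setNames(d_smc, paste0("smc.", smc_names)))
}

#' Isolated-cell rest states
#'
#' Finds the resting fixed point of the isolated EC and SMC at `j_plc = 0`:
#' the cell is relaxed by integration for `t_relax` seconds from a generic
#' physiological guess, then the root of the right-hand side is polished with
#' a damped Newton solve. This parameter-derived state is the package's
#' initial-condition convention for all tissue simulations.
#'
#' @param params parameter set from [model_params()] (its `j_plc` is ignored;
#'   rest is always computed at zero agonist).
#' @param t_relax relaxation horizon (s).
#' @return List with named vectors `ec` and `smc` and the residual norms
#'   `ec_residual`, `smc_residual` (per-second units).
#' @export
rest_state <- function(params = model_params(), t_relax = 500) {
  p0 <- model_params(j_plc = 0)
  keep <- setdiff(names(params), "j_plc")
  p0[keep] <- params[keep]

  relax <- function(y0, rhs) {
    f <- function(t, y, parms) list(unname(rhs(setNames(y, names(y0)), p0)))
    out <- deSolve::ode(y = y0, times = c(0, t_relax), func = f, parms = NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    setNames(as.numeric(out[nrow(out), -1]), names(y0))
  }
  polish <- function(y0, rhs) {
    fn <- function(y) unname(rhs(setNames(y, names(y0)), p0))
    sol <- pracma::fsolve(fn, unname(y0), tol = 1e-13)
    x <- sol$x
    x[abs(x) < 1e-12] <- 0 # snap numerically-zero concentrations
    setNames(x, names(y0))
  }

  ec0 <- polish(relax(ec_state(), ec_rhs), ec_rhs)
  smc0 <- polish(relax(smc_state(), smc_rhs), smc_rhs)
  list(
    ec = ec0, smc = smc0,
    ec_residual = max(abs(ec_rhs(ec0, p0))),
    smc_residual = max(abs(smc_rhs(smc0, p0)))
  )
}

#' Check a trajectory for model-consistency violations
#'
#' Concentrations and the K+ open fraction are not clamped during
#' integration; a trajectory that leaves its physical range signals a
#' transcription or tolerance problem. Returns (invisibly) a tibble of
#' violations and warns if any are found.
#'
#' @param archive a simulation archive or a plain tibble with columns
#'   `variable` and `value`.
#' @param tol tolerance below zero / above one treated as violation.
#' @export
check_state_bounds <- function(archive, tol = 1e-8) {
  df <- if (inherits(archive, "vw_archive")) as_tibble(archive) else archive
  bad <- dplyr::bind_rows(
    dplyr::filter(df, .data$variable %in% c("ca", "store", "ip3"),
                  .data$value < -tol),
    dplyr::filter(df, .data$variable == "w", .data$value < -tol | .data$value > 1 + tol)
  )
  if (nrow(bad)) {
    warning(sprintf("state bounds violated at %d sample(s); min value %.3g",
                    nrow(bad), min(bad$value)))
  }
  invisible(as_tibble(bad))
}
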