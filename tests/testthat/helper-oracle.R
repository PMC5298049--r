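# Independent second transcription of the coupled EC/SMC pathway model,
# written directly from the parameter table and kept deliberately separate
# from the package implementation (different structure: Hill helpers and a
# frozen parameter vector). Used as the oracle for the right-hand sides.

hill2 <- function(x, k) x^2 / (k^2 + x^2)
hill4 <- function(x, k) x^4 / (k^4 + x^4)

oracle_p <- c(
  # SMC
  F_i = 0.23, Kr_i = 1, B_i = 2.025, cb_i = 1, C_i = 55, sc_i = 2,
  cc_i = 0.9, D_i = 0.24, vd_i = -100, Rd_i = 250, L_i = 0.025,
  G_Ca = 0.00129, v_Ca1 = 100, v_Ca2 = -24, R_Ca = 8.5,
  G_NaCa = 0.00316, c_NaCa = 0.5, v_NaCa = -30, F_NaK = 0.0432,
  G_Cl = 0.00134, v_Cl = -25, G_K = 0.00446, v_K = -94, lambda_i = 45,
  c_w = 0, beta_i = 0.13, v_Ca3 = -27, R_K = 12, gamma_i = 1970, k_i = 0.1,
  # EC
  F_j = 0.23, Kr_j = 1, B_j = 0.5, cb_j = 1, C_j = 5, sc_j = 2, cc_j = 0.9,
  D_j = 0.24, L_j = 0.025, G_cat = 0.00066, E_Ca = 50, m3_cat = -0.18,
  m4_cat = 0.37, J0_j = 0.029, C_m = 25.8, G_tot = 6927, v_K_j = -80,
  a1_j = 53.3, a2_j = 53.3, b_j = -80.8, c0_j = -0.4, m3b_j = 1.32e-3,
  m4b_j = 0.3, m3s_j = -0.28, m4s_j = 0.389, G_R = 955, v_rest_j = -31.1,
  k_j = 0.1
)

oracle_smc_deriv <- function(s, influx = c(ca = 0, ip3 = 0, v = 0),
                             p = oracle_p) {
  with(as.list(c(s, p)), {
    rel <- F_i * hill2(ip3, Kr_i)                       # IP3R release
    pump <- B_i * hill2(ca_i, cb_i)                     # SERCA
    cicr <- C_i * hill2(ca_sr, sc_i) * hill4(ca_i, cc_i)
    out <- D_i * ca_i * (1 + (v_m - vd_i) / Rd_i)       # extrusion
    leak <- L_i * ca_sr
    vocc <- G_Ca * (v_m - v_Ca1) / (1 + exp((v_Ca2 - v_m) / R_Ca))
    ncx <- G_NaCa * (v_m - v_NaCa) * ca_i / (ca_i + c_NaCa)
    cl <- G_Cl * (v_m - v_Cl)
    kca <- G_K * w_k * (v_m - v_K)
    act <- (ca_i + c_w)^2 /
      ((ca_i + c_w)^2 + beta_i * exp((v_Ca3 - v_m) / R_K))
    c(rel - pump + cicr - out + leak - vocc + ncx + influx[["ca"]],
      pump - cicr - leak,
      -gamma_i * (F_NaK + cl + 2 * vocc + ncx + kca) + influx[["v"]],
      lambda_i * (act - w_k),
      influx[["ip3"]] - k_i * ip3)
  })
}

oracle_ec_deriv <- function(s, j_plc = 0, influx = c(ca = 0, ip3 = 0, v = 0),
                            p = oracle_p) {
  with(as.list(c(s, p)), {
    rel <- F_j * hill2(ip3, Kr_j)
    pump <- B_j * hill2(ca_j, cb_j)
    cicr <- C_j * hill2(ca_er, sc_j) * hill4(ca_j, cc_j)
    out <- D_j * ca_j
    leak <- L_j * ca_er
    lc <- log10(ca_j)
    cat_gate <- 0.5 * (1 + tanh((lc - m3_cat) / m4_cat))
    cation <- G_cat * (E_Ca - v_m) * cat_gate
    bk_num <- (lc - c0_j) * (v_m - b_j) - a1_j
    bk_den <- m3b_j * (v_m + a2_j * (lc - c0_j) - b_j)^2 + m4b_j
    bk <- 0.2 * (1 + tanh(bk_num / bk_den))
    sk <- 0.3 * (1 + tanh((lc - m3s_j) / m4s_j))
    ik <- G_tot * (v_m - v_K_j) * (bk + sk)
    ir <- G_R * (v_m - v_rest_j)
    c(rel - pump + cicr - out + leak + cation + J0_j + influx[["ca"]],
      pump - cicr - leak,
      influx[["v"]] - (ik + ir) / C_m,
      j_plc - k_j * ip3 + influx[["ip3"]])
  })
}

# convenience: a plausible mid-oscillation state pair used across tests
oracle_states <- function() {
  list(
    ec = c(ca_j = 0.48, ca_er = 1.1, v_m = -58.2, ip3 = 1.7),
    smc = c(ca_i = 0.36, ca_sr = 1.45, v_m = -41.7, w_k = 0.21, ip3 = 0.62)
  )
}
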