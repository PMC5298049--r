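test_that("EC and SMC right-hand sides agree with the independent transcription", {
  p <- model_params(j_plc = 0.7)
  st <- oracle_states()
  states <- list(
    st,
    list(ec = ec_state(0.12, 0.31, -38.3, 0.02),
         smc = smc_state(0.24, 1.27, -26.3, 0.32, 0.05)),
    list(ec = ec_state(1.4, 0.6, -70, 3.2),
         smc = smc_state(0.9, 2.3, -55, 0.6, 1.1))
  )
  influx <- c(ca = 0.013, ip3 = -0.004, v = 2.5)
  for (s in states) {
    got_ec <- ec_rhs(s$ec, p, influx)
    exp_ec <- oracle_ec_deriv(s$ec, j_plc = 0.7, influx = influx)
    expect_equal(unname(got_ec), unname(exp_ec), tolerance = 1e-12)
    got_smc <- smc_rhs(s$smc, p, influx)
    exp_smc <- oracle_smc_deriv(s$smc, influx = influx)
    expect_equal(unname(got_smc), unname(exp_smc), tolerance = 1e-12)
  }
})

test_that("IP3 balance is pure degradation plus sources", {
  p0 <- model_params(j_plc = 0)
  s_ec <- ec_state(ip3 = 0)
  expect_identical(unname(ec_rhs(s_ec, p0)[["ip3"]]), 0)
  s_smc <- smc_state(ip3 = 0)
  expect_identical(unname(smc_rhs(s_smc, p0)[["ip3"]]), 0)

  # doubling j_plc adds exactly the increment to the EC IP3 equation only
  s <- oracle_states()$ec
  d1 <- ec_rhs(s, model_params(j_plc = 1.3))
  d2 <- ec_rhs(s, model_params(j_plc = 2.6))
  expect_equal(d2[["ip3"]] - d1[["ip3"]], 1.3, tolerance = 1e-12)
  expect_equal(d1[c("ca_j", "ca_er", "v_m")], d2[c("ca_j", "ca_er", "v_m")],
               tolerance = 1e-14)
})

test_that("missing parameters raise a configuration error naming the symbol", {
  p <- model_params()
  p$G_Ca <- NULL
  expect_error(smc_rhs(smc_state(), p), "G_Ca", class = "vw_config_error")
  p2 <- model_params()
  p2$G_tot <- NA_real_
  expect_error(ec_rhs(ec_state(), p2), "G_tot", class = "vw_config_error")
  expect_error(model_params(nonsense = 2), "unknown model parameter")
})

test_that("isolated rest states are fixed points", {
  rs <- rest_state()
  expect_lt(rs$ec_residual, 1e-9)
  expect_lt(rs$smc_residual, 1e-9)
  expect_true(all(rs$ec[c("ca_j", "ca_er", "ip3")] >= 0))
  expect_true(all(rs$smc[c("ca_i", "ca_sr", "ip3")] >= 0))
  expect_true(rs$smc[["w_k"]] >= 0 && rs$smc[["w_k"]] <= 1)
})

test_that("unit_rhs decouples exactly and conserves heterocellular fluxes", {
  p <- model_params(j_plc = 2)
  st <- oracle_states()
  off <- coupling_config(smc_homo = character(0), ec_homo = character(0),
                         hetero = character(0))
  d <- unit_rhs(st$ec, st$smc, p, off)
  expect_identical(unname(d[1:4]), unname(ec_rhs(st$ec, p)))
  expect_identical(unname(d[5:9]), unname(smc_rhs(st$smc, p)))

  # antisymmetry: coupling-induced changes are equal and opposite per species
  cfg <- coupling_case(2) # v, ip3 and ca heterocellular
  set.seed(7)
  for (k in 1:20) {
    ec <- ec_state(runif(1, 0.05, 1.5), runif(1, 0.2, 2),
                   runif(1, -80, -20), runif(1, 0, 3))
    smc <- smc_state(runif(1, 0.05, 1.5), runif(1, 0.2, 2),
                     runif(1, -80, -20), runif(1, 0, 1), runif(1, 0, 3))
    dc <- unit_rhs(ec, smc, p, cfg)
    d0 <- unit_rhs(ec, smc, p, off)
    delta <- dc - d0
    expect_equal(delta[["ec.ca_j"]], -delta[["smc.ca_i"]], tolerance = 1e-8)
    expect_equal(delta[["ec.ip3"]], -delta[["smc.ip3"]], tolerance = 1e-8)
    expect_equal(delta[["ec.v_m"]], -delta[["smc.v_m"]], tolerance = 1e-8)
    # store and gating equations carry no coupling terms
    expect_equal(delta[["ec.ca_er"]], 0)
    expect_equal(delta[["smc.w_k"]], 0)
  }

  # zero gradient: equal IP3 on both sides produces no IP3 flux
  ec <- st$ec; smc <- st$smc
  ec[["ip3"]] <- smc[["ip3"]] <- 0.8
  only_ip3 <- coupling_config(smc_homo = character(0),
                              ec_homo = character(0), hetero = "ip3",
                              g_ip3_hetero = 123)
  expect_identical(unname(unit_rhs(ec, smc, p, only_ip3)),
                   unname(unit_rhs(ec, smc, p, off)))
})

test_that("the coupled unit shows the three agonist bands", {
  # steady below the window, oscillatory inside, steady above
  ptp <- function(j, t_end = 400) {
    tr <- integrate_unit(j, coupling_case(1), times = seq(0, t_end, 0.5),
                         rtol = 1e-7, atol = 1e-9)
    ca <- tr[tr[, "time"] >= 200, "smc.ca_i"]
    max(ca) - min(ca)
  }
  expect_lt(ptp(0), 1e-3)
  expect_lt(ptp(2), 1e-3)
  expect_gt(ptp(4.5), 0.1)
  expect_lt(ptp(12), 2e-2)
})

test_that("long unit trajectories are insensitive to integrator tolerance", {
  run <- function(rtol) {
    tr <- integrate_unit(2, coupling_case(1), times = seq(0, 1000, 1),
                         rtol = rtol, atol = rtol * 1e-2)
    tr[nrow(tr), "smc.ca_i"]
  }
  expect_lt(abs(run(1e-8) - run(5e-9)), 1e-4)
})
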