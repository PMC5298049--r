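p_std <- model_params()

test_that("zero-duration runs archive exactly the initial snapshot", {
  mesh <- tube_mesh(2, 4)
  cfg <- simulation_config(duration = 0, output_interval = 1)
  ag <- rep(1, mesh_census(mesh)$n_ec)
  arc <- simulate_tissue(mesh, coupling_case(1), ag, cfg, params = p_std)
  expect_identical(length(arc$times), 1L)
  adj <- build_adjacency(mesh)
  expect_equal(arc$states[1, ], tissue_initial_state(adj, p_std))
})

test_that("simulation configs are validated", {
  expect_error(simulation_config(10, comm_interval = 2, output_interval = 1),
               "comm_interval")
  expect_error(simulation_config(1, output_interval = 2), "duration")
  expect_error(simulation_config(10, comm_interval = 0.03,
                                 output_interval = 1), "multiple")
  expect_error(simulation_config(10, rtol = -1), "positive")
})

test_that("with coupling off every cell follows the single-cell solution", {
  mesh <- tube_mesh(2, 4)
  adj <- build_adjacency(mesh)
  off <- coupling_config(smc_homo = character(0), ec_homo = character(0),
                         hetero = character(0))
  jv <- 4
  ag <- rep(jv, adj$n_ec)
  cfg <- simulation_config(duration = 20, comm_interval = 0.01,
                           output_interval = 1, rtol = 1e-8, atol = 1e-10)
  arc <- simulate_tissue(mesh, off, ag, cfg, params = p_std, adj = adj)

  # reference: isolated EC and SMC integrated by an independent method
  rs <- rest_state(p_std)
  pj <- model_params(j_plc = jv)
  f_ec <- function(t, y, parms) {
    list(unname(ec_rhs(stats::setNames(y, names(rs$ec)), pj)))
  }
  f_smc <- function(t, y, parms) {
    list(unname(smc_rhs(stats::setNames(y, names(rs$smc)), p_std)))
  }
  ref_ec <- deSolve::ode(unname(rs$ec), seq(0, 20, 1), f_ec, NULL,
                         rtol = 1e-10, atol = 1e-12)
  ref_smc <- deSolve::ode(unname(rs$smc), seq(0, 20, 1), f_smc, NULL,
                          rtol = 1e-10, atol = 1e-12)

  ec_ca <- vasowave:::archive_variable(arc, "EC", "ca")
  smc_ca <- vasowave:::archive_variable(arc, "SMC", "ca")
  # all ECs identical to the isolated trajectory
  expect_lt(max(abs(sweep(ec_ca, 1, ref_ec[, 2]))), 1e-5)
  expect_lt(max(abs(sweep(smc_ca, 1, ref_smc[, 2]))), 1e-5)
})

test_that("homocellular coupling fluxes sum to zero over the closed surface", {
  mesh <- tube_mesh(2, 4)
  adj <- build_adjacency(mesh)
  set.seed(3)
  st <- tissue_initial_state(adj, p_std) * (1 + 0.1 * runif(4 * adj$n_ec + 5 * adj$n_smc, -1, 1))
  ag <- rep(2, adj$n_ec)
  hom_only <- coupling_config(smc_homo = c("v", "ca", "ip3"),
                              ec_homo = c("v", "ca", "ip3"),
                              hetero = character(0))
  off <- coupling_config(smc_homo = character(0), ec_homo = character(0),
                         hetero = character(0))
  d1 <- tissue_rhs(st, adj, hom_only, ag, p_std)
  d0 <- tissue_rhs(st, adj, off, ag, p_std)
  coupling_part <- d1 - d0
  n_ec <- adj$n_ec
  for (k in c(1, 3, 4)) { # EC ca, v, ip3 equations
    idx <- (seq_len(n_ec) - 1) * 4 + k
    expect_lt(abs(sum(coupling_part[idx])), 1e-7 * n_ec)
  }
  for (k in c(1, 3, 5)) { # SMC ca, v, ip3 equations
    idx <- 4 * n_ec + (seq_len(adj$n_smc) - 1) * 5 + k
    expect_lt(abs(sum(coupling_part[idx])), 1e-7 * adj$n_smc)
  }
})

test_that("solutions converge as the communication interval shrinks", {
  mesh <- tube_mesh(2, 4)
  adj <- build_adjacency(mesh)
  ag <- sigmoid_map(mesh, sigmoid_spec(2, 5, x_center = 0.26, steepness = 5))
  two_dom <- decompose_domains(mesh, quads_per_domain = 4L)
  mono <- decompose_domains(mesh, quads_per_domain = nrow(mesh$quads))
  run <- function(domains, comm) {
    cfg <- simulation_config(duration = 2, comm_interval = comm,
                             output_interval = 1, rtol = 1e-8, atol = 1e-10)
    simulate_tissue(mesh, coupling_case(1), ag, cfg, params = p_std,
                    adj = adj, domains = domains)$states
  }
  ref <- run(mono, 0.01)
  err_coarse <- max(abs(run(two_dom, 0.1) - ref))
  err_fine <- max(abs(run(two_dom, 0.01) - ref))
  expect_lt(err_fine, err_coarse)
  expect_gt(err_coarse, 0) # the splitting genuinely perturbs the solution
})

test_that("serial and parallel backends agree bitwise on a 4-domain tube", {
  mesh <- tube_mesh(2, 4)
  adj <- build_adjacency(mesh)
  doms <- decompose_domains(mesh, quads_per_domain = 2L) # 4 domains
  ag <- sigmoid_map(mesh, sigmoid_spec(2, 5, x_center = 0.26, steepness = 5))
  run <- function(backend) {
    cfg <- simulation_config(duration = 0.2, comm_interval = 0.01,
                             output_interval = 0.1, backend = backend)
    simulate_tissue(mesh, coupling_case(1), ag, cfg, params = p_std,
                    adj = adj, domains = doms)$states
  }
  expect_identical(run("serial"), run("parallel"))
})

test_that("identical configurations give identical archives", {
  mesh <- tube_mesh(2, 4)
  adj <- build_adjacency(mesh)
  ag <- rep(3, adj$n_ec)
  cfg <- simulation_config(duration = 1, comm_interval = 0.01,
                           output_interval = 0.5)
  a1 <- simulate_tissue(mesh, coupling_case(1), ag, cfg, params = p_std,
                        adj = adj)
  a2 <- simulate_tissue(mesh, coupling_case(1), ag, cfg, params = p_std,
                        adj = adj)
  expect_identical(a1$states, a2$states)
})

test_that("rotating the tube rotates the solution identically", {
  mesh <- tube_mesh(2, 4)
  adj <- build_adjacency(mesh)
  # axially varying, circumferentially uniform agonist
  ag <- sigmoid_map(mesh, sigmoid_spec(2, 5, x_center = 0.26, steepness = 5))
  # permutation rotating every cell by one quad column (iv -> iv + 1 mod n)
  perm_layer <- function(layer) {
    cells <- mesh$cells[mesh$cells$layer == layer, ]
    q <- mesh$quads
    iv_next <- (q$iv + 1L) %% mesh$n
    target_quad <- q$quad_id[order(q$seg, q$iu, q$iv)]
    qmap <- integer(nrow(q))
    for (r in seq_len(nrow(q))) {
      qmap[q$quad_id[r]] <- q$quad_id[q$seg == q$seg[r] & q$iu == q$iu[r] &
                                        q$iv == iv_next[r]]
    }
    key <- paste(cells$quad_id, cells$row, cells$col)
    rot_key <- paste(qmap[cells$quad_id], cells$row, cells$col)
    match(rot_key, key) # rotated cell id for each cell
  }
  pe <- perm_layer("EC"); ps <- perm_layer("SMC")
  rot_state <- function(st) {
    out <- numeric(length(st))
    n_ec <- adj$n_ec
    for (k in 1:4) out[(pe - 1) * 4 + k] <- st[(seq_along(pe) - 1) * 4 + k]
    for (k in 1:5) {
      out[4 * n_ec + (ps - 1) * 5 + k] <-
        st[4 * n_ec + (seq_along(ps) - 1) * 5 + k]
    }
    out
  }
  set.seed(5)
  init <- tissue_initial_state(adj, p_std, perturb = 0.02, seed = 5)
  cfg <- simulation_config(duration = 2, comm_interval = 0.01,
                           output_interval = 1, rtol = 1e-8, atol = 1e-10)
  a_plain <- simulate_tissue(mesh, coupling_case(1), ag, cfg, params = p_std,
                             adj = adj, init = init)
  a_rot <- simulate_tissue(mesh, coupling_case(1), ag, cfg, params = p_std,
                           adj = adj, init = rot_state(init))
  final_plain_rotated <- rot_state(a_plain$states[nrow(a_plain$states), ])
  final_rot <- a_rot$states[nrow(a_rot$states), ]
  expect_equal(final_rot, final_plain_rotated, tolerance = 1e-6)
})

test_that("ghost-cell exchange is a symmetric, idempotent gather", {
  mesh <- tube_mesh(2, 4)
  adj <- build_adjacency(mesh)
  doms <- decompose_domains(mesh) # one quad per domain
  tables <- ghost_edge_tables(mesh, adj, doms)
  # pairing: every export of (a -> b) has a counterpart (b -> a)
  key <- paste(tables$domain, tables$neighbour_domain)
  rev_key <- paste(tables$neighbour_domain, tables$domain)
  expect_true(all(rev_key %in% key))
  st <- tissue_initial_state(adj, p_std)
  g1 <- exchange_ghosts(st, tables, adj$n_ec)
  g2 <- exchange_ghosts(st, tables, adj$n_ec)
  expect_identical(g1, g2)
  # ghost values equal the owner's state slice exactly
  smc_rows <- g1[g1$layer == "SMC", ]
  i <- smc_rows$cell[1]
  expect_identical(smc_rows$ca[1], st[4 * adj$n_ec + (i - 1) * 5 + 1])
  # total transferred = 2 x number of cross-domain boundary cells per
  # direction pairing
  expect_identical(nrow(g1), nrow(tables))
})
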