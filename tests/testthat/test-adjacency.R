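tube22 <- tube_mesh(2, 4)
adj22 <- build_adjacency(tube22)

test_that("homocellular adjacency is symmetric with correct degrees", {
  for (layer in c("EC", "SMC")) {
    csr <- if (layer == "EC") adj22$ec else adj22$smc
    n <- if (layer == "EC") adj22$n_ec else adj22$n_smc
    deg <- diff(csr$ptr)
    # circumferential wrap means no lateral boundary: every cell has 3 or 4
    # neighbours (3 only on the axial ends), interior cells exactly 4
    expect_true(all(deg %in% c(3L, 4L)))
    # symmetry
    edges <- cbind(rep(seq_len(n), deg), csr$idx)
    key <- paste(edges[, 1], edges[, 2])
    rev_key <- paste(edges[, 2], edges[, 1])
    expect_true(all(rev_key %in% key))
  }
  # an SMC away from both axial ends has exactly 4 neighbours
  smc_interior <- which(diff(adj22$smc$ptr) == 4L)
  expect_gt(length(smc_interior), 0)
  expect_identical(length(vasowave:::neighbours_of(adj22, "SMC",
                                                   smc_interior[1])), 4L)
})

test_that("circumferential periodicity links the first and last columns", {
  # EC grid on this tube: 8 axial rows x 80 circumferential columns
  # cell id of (quad, row, col): quads are stacked per column blocks
  first_col_cell <- 1L # quad 1, row 1, col 1
  nb <- vasowave:::neighbours_of(adj22, "EC", first_col_cell)
  # its circumferential neighbours must include a cell in the last column of
  # the wrap-around quad (quad with iv = n-1)
  last_col_quad <- tube22$quads$quad_id[tube22$quads$iv == max(tube22$quads$iv)]
  ec_cells_last <- with(tube22$cells[tube22$cells$layer == "EC", ],
                        cell_id[quad_id %in% last_col_quad & col == 20])
  expect_true(any(nb %in% ec_cells_last))
})

test_that("heterocellular pairing is the fundamental-unit bipartite graph", {
  het <- adj22$het
  # every EC participates; weights are normalised per SMC
  w_by_ec <- tapply(het$weight, het$ec, sum)
  expect_identical(length(w_by_ec), as.integer(adj22$n_ec))
  w_by_smc <- tapply(het$weight, het$smc, sum)
  expect_true(all(abs(w_by_smc - 1) < 1e-12))
  expect_true(all(w_by_ec > 0))
  # each EC couples to exactly 13 SMCs, each SMC to exactly 5 ECs
  expect_true(all(table(het$ec) == 13L))
  expect_true(all(table(het$smc) == 5L))
  # one fundamental unit contributes 5 x 13 = 65 pairs
  expect_identical(nrow(het), nrow(tube22$quads) * 16L * 65L)
})

test_that("junction seams connect all three segments at cell level", {
  bm <- make_fixture("bif_mini")
  adj <- build_adjacency(bm)
  q <- bm$quads
  ec_quad_of <- adj$ec_quad
  seg_of_quad <- q$seg[order(q$quad_id)]
  # parent outlet-edge ECs must have neighbours in a branch segment
  parent_end <- q$quad_id[q$seg == 1 & q$iu == max(q$iu[q$seg == 1])]
  ecs <- with(bm$cells[bm$cells$layer == "EC", ],
              cell_id[quad_id %in% parent_end & row == 4])
  cross <- vapply(ecs, function(i) {
    any(seg_of_quad[ec_quad_of[vasowave:::neighbours_of(adj, "EC", i)]] != 1L)
  }, logical(1))
  expect_true(all(cross))
  # carina: branch-1 junction-edge SMCs in the inner quarters reach branch 2
  n <- bm$n; q4 <- n %/% 4L
  car_quads <- q$quad_id[q$seg == 2 & q$iu == 0 & q$iv >= q4 & q$iv < 3 * q4]
  smcs <- with(bm$cells[bm$cells$layer == "SMC", ],
               cell_id[quad_id %in% car_quads & row == 1])
  smc_quad_of <- adj$smc_quad
  cross2 <- vapply(smcs, function(i) {
    any(seg_of_quad[smc_quad_of[vasowave:::neighbours_of(adj, "SMC", i)]] == 3L)
  }, logical(1))
  expect_true(all(cross2))
})

test_that("vectorised tissue assembly matches a naive per-cell loop", {
  set.seed(11)
  mesh <- tube22; adj <- adj22
  p <- model_params()
  cfg <- coupling_case(2)
  ag <- sigmoid_map(mesh, sigmoid_spec(j_min = 1, j_max = 5,
                                       x_center = 0.26, steepness = 4))
  st <- tissue_initial_state(adj, p)
  st <- st * (1 + 0.05 * runif(length(st), -1, 1))
  fast <- tissue_rhs(st, adj, cfg, ag, p)

  n_ec <- adj$n_ec; n_smc <- adj$n_smc; r <- cfg$rates
  ecs <- lapply(seq_len(n_ec), function(i)
    stats::setNames(st[(i - 1) * 4 + 1:4], c("ca_j", "ca_er", "v_m", "ip3")))
  smcs <- lapply(seq_len(n_smc), function(i)
    stats::setNames(st[4 * n_ec + (i - 1) * 5 + 1:5],
                    c("ca_i", "ca_sr", "v_m", "w_k", "ip3")))
  slow <- numeric(length(st))
  het <- adj$het
  for (i in seq_len(n_ec)) {
    self <- ecs[[i]]
    infl <- c(ca = 0, ip3 = 0, v = 0)
    for (j in vasowave:::neighbours_of(adj, "EC", i)) {
      o <- ecs[[j]]
      if (cfg$ec_homo$ca) infl["ca"] <- infl["ca"] + r$g_chem_homo * (o[["ca_j"]] - self[["ca_j"]])
      if (cfg$ec_homo$v) infl["v"] <- infl["v"] + r$g_v_homo * (o[["v_m"]] - self[["v_m"]])
      if (cfg$ec_homo$ip3) infl["ip3"] <- infl["ip3"] + r$g_chem_homo * (o[["ip3"]] - self[["ip3"]])
    }
    hh <- het[het$ec == i, ]
    for (k in seq_len(nrow(hh))) {
      o <- smcs[[hh$smc[k]]]; w <- hh$weight[k]
      if (cfg$hetero$ca) infl["ca"] <- infl["ca"] + r$g_ca_hetero * w * (o[["ca_i"]] - self[["ca_j"]])
      if (cfg$hetero$v) infl["v"] <- infl["v"] + r$g_v_hetero * w * (o[["v_m"]] - self[["v_m"]])
      if (cfg$hetero$ip3) infl["ip3"] <- infl["ip3"] + r$g_ip3_hetero * w * (o[["ip3"]] - self[["ip3"]])
    }
    pp <- p; pp$j_plc <- ag$j_plc[i]
    slow[(i - 1) * 4 + 1:4] <- ec_rhs(self, pp, infl)
  }
  for (i in seq_len(n_smc)) {
    self <- smcs[[i]]
    infl <- c(ca = 0, ip3 = 0, v = 0)
    for (j in vasowave:::neighbours_of(adj, "SMC", i)) {
      o <- smcs[[j]]
      if (cfg$smc_homo$ca) infl["ca"] <- infl["ca"] + r$g_chem_homo * (o[["ca_i"]] - self[["ca_i"]])
      if (cfg$smc_homo$v) infl["v"] <- infl["v"] + r$g_v_homo * (o[["v_m"]] - self[["v_m"]])
      if (cfg$smc_homo$ip3) infl["ip3"] <- infl["ip3"] + r$g_chem_homo * (o[["ip3"]] - self[["ip3"]])
    }
    hh <- het[het$smc == i, ]
    for (k in seq_len(nrow(hh))) {
      o <- ecs[[hh$ec[k]]]; w <- hh$weight[k]
      if (cfg$hetero$ca) infl["ca"] <- infl["ca"] + r$g_ca_hetero * w * (o[["ca_j"]] - self[["ca_i"]])
      if (cfg$hetero$v) infl["v"] <- infl["v"] + r$g_v_hetero * w * (o[["v_m"]] - self[["v_m"]])
      if (cfg$hetero$ip3) infl["ip3"] <- infl["ip3"] + r$g_ip3_hetero * w * (o[["ip3"]] - self[["ip3"]])
    }
    slow[4 * n_ec + (i - 1) * 5 + 1:5] <- smc_rhs(self, p, infl)
  }
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("state length mismatches are rejected", {
  expect_error(
    tissue_rhs(numeric(10), adj22, coupling_case(1),
               rep(1, adj22$n_ec), model_params()),
    "state length")
})

test_that("adjacency exports a well-formed edge list", {
  edges <- adjacency_edges(adj22)
  expect_true(all(edges$layer %in% c("EC", "SMC", "EC-SMC")))
  hom <- dplyr::filter(edges, .data$layer != "EC-SMC")
  expect_true(all(hom$from < hom$to))
  expect_identical(nrow(dplyr::filter(edges, .data$layer == "EC-SMC")),
                   nrow(adj22$het))
})
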