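#' Simulation configuration
#'
#' @param duration physiological seconds to simulate.
#' @param comm_interval communication interval (s): cross-domain neighbour
#'   states are frozen within an interval and exchanged at its end.
#'   Default 0.01 s.
#' @param output_interval snapshot cadence (s), default 1 s; must be a
#'   multiple of `comm_interval` and divide `duration`.
#' @param rtol,atol adaptive integrator tolerances.
#' @param backend `"serial"` (reference) or `"parallel"` (multicore over
#'   domains; identical frozen-ghost semantics, bitwise-equal results).
#' @param seed recorded for provenance; the physics core is deterministic
#'   and draws no random numbers.
#' @return A `vw_sim_config` list.
#' @export
simulation_config <- function(duration, comm_interval = 0.01,
                              output_interval = 1, rtol = 1e-6, atol = 1e-9,
                              backend = c("serial", "parallel"),
                              seed = NULL) {
  backend <- match.arg(backend)
  if (comm_interval <= 0 || rtol <= 0 || atol <= 0) {
    abort("comm_interval and tolerances must be positive")
  }
  if (duration < 0) abort("duration must be >= 0")
  if (duration > 0 && (comm_interval > output_interval + 1e-12 ||
                       output_interval > duration + 1e-12)) {
    abort("need comm_interval <= output_interval <= duration")
  }
  ratio <- output_interval / comm_interval
  if (abs(ratio - round(ratio)) > 1e-8) {
    abort("output_interval must be a multiple of comm_interval")
  }
  structure(list(duration = duration, comm_interval = comm_interval,
                 output_interval = output_interval, rtol = rtol, atol = atol,
                 backend = backend, seed = seed),
            class = "vw_sim_config")
}

# effective (flag x rate) coupling vector in the engine's fixed order
coupling_rates_vector <- function(coupling) {
  r <- coupling$rates
  c(
    ec_v = if (coupling$ec_homo$v) r$g_v_homo else 0,
    ec_ca = if (coupling$ec_homo$ca) r$g_chem_homo else 0,
    ec_ip3 = if (coupling$ec_homo$ip3) r$g_chem_homo else 0,
    smc_v = if (coupling$smc_homo$v) r$g_v_homo else 0,
    smc_ca = if (coupling$smc_homo$ca) r$g_chem_homo else 0,
    smc_ip3 = if (coupling$smc_homo$ip3) r$g_chem_homo else 0,
    het_v = if (coupling$hetero$v) r$g_v_hetero else 0,
    het_ca = if (coupling$hetero$ca) r$g_ca_hetero else 0,
    het_ip3 = if (coupling$hetero$ip3) r$g_ip3_hetero else 0
  )
}

# assemble the list consumed by the compiled core
build_system <- function(adj, coupling, agonist_values, params,
                         dom_ec = NULL, dom_smc = NULL) {
  if (length(agonist_values) != adj$n_ec) {
    abort(sprintf("agonist map length %d does not match the %d ECs",
                  length(agonist_values), adj$n_ec))
  }
  if (any(agonist_values < 0)) abort("agonist values must be >= 0")
  pv <- param_vectors(params)
  het <- adj$het
  o_ec <- order(het$ec)
  het_counts <- tabulate(het$ec, nbins = adj$n_ec)
  o_smc <- order(het$smc)
  hetT_counts <- tabulate(het$smc, nbins = adj$n_smc)
  list(
    n_ec = adj$n_ec, n_smc = adj$n_smc,
    ec_ptr = as.integer(adj$ec$ptr), ec_idx = as.integer(adj$ec$idx - 1L),
    smc_ptr = as.integer(adj$smc$ptr), smc_idx = as.integer(adj$smc$idx - 1L),
    het_ptr = as.integer(c(0L, cumsum(het_counts))),
    het_smc = as.integer(het$smc[o_ec] - 1L),
    het_w = as.numeric(het$weight[o_ec]),
    hetT_ptr = as.integer(c(0L, cumsum(hetT_counts))),
    hetT_ec = as.integer(het$ec[o_smc] - 1L),
    hetT_w = as.numeric(het$weight[o_smc]),
    rates = unname(coupling_rates_vector(coupling)),
    agonist = as.numeric(agonist_values),
    p_smc = unname(pv$smc), p_ec = unname(pv$ec),
    dom_ec = if (is.null(dom_ec)) integer(adj$n_ec) else as.integer(dom_ec),
    dom_smc = if (is.null(dom_smc)) integer(adj$n_smc) else as.integer(dom_smc)
  )
}

#' Full-tissue right-hand side
#'
#' Derivative of the flat tissue state: each cell's intrinsic pathway model
#' plus all enabled gap-junction fluxes. The flat layout is the EC block
#' (4 values per EC: ca, store, v, ip3) followed by the SMC block (5 values:
#' ca, store, v, w, ip3), cell-major.
#'
#' @param state flat state vector of length `4 n_ec + 5 n_smc`.
#' @param adj a `vw_adjacency`.
#' @param coupling a `vw_coupling`.
#' @param agonist an agonist map ([sigmoid_map()] or friends) or a bare
#'   numeric vector of per-EC `j_plc` values (uM/s).
#' @param params model parameters.
#' @return Flat derivative vector.
#' @export
tissue_rhs <- function(state, adj, coupling, agonist, params = model_params()) {
  vals <- agonist_values(agonist)
  sys <- build_system(adj, coupling, vals, params)
  expected <- 4L * adj$n_ec + 5L * adj$n_smc
  if (length(state) != expected) {
    abort(sprintf("state length %d; expected 4*%d + 5*%d = %d",
                  length(state), adj$n_ec, adj$n_smc, expected))
  }
  tissue_deriv_cpp(as.numeric(state), sys)
}

#' Initial tissue state
#'
#' Every cell starts at its isolated rest state (zero agonist); optionally a
#' small seeded perturbation is applied to cytosolic Ca2+ to break the exact
#' symmetry of idealised meshes.
#'
#' @param adj a `vw_adjacency`.
#' @param params model parameters.
#' @param perturb standard deviation (uM) of Gaussian noise added to every
#'   cytosolic Ca2+; 0 (default) for none.
#' @param seed RNG seed used when `perturb > 0`.
#' @return Flat state vector.
#' @export
tissue_initial_state <- function(adj, params = model_params(), perturb = 0,
                                 seed = 1L) {
  rs <- rest_state(params)
  y <- c(rep(unname(rs$ec), adj$n_ec), rep(unname(rs$smc), adj$n_smc))
  if (perturb > 0) {
    set.seed(seed)
    ec_ca <- (seq_len(adj$n_ec) - 1L) * 4L + 1L
    smc_ca <- 4L * adj$n_ec + (seq_len(adj$n_smc) - 1L) * 5L + 1L
    y[ec_ca] <- pmax(1e-6, y[ec_ca] + stats::rnorm(adj$n_ec, 0, perturb))
    y[smc_ca] <- pmax(1e-6, y[smc_ca] + stats::rnorm(adj$n_smc, 0, perturb))
  }
  y
}

#' Run a tissue simulation
#'
#' Advances all cells through `config$duration` seconds. Within each
#' communication interval every domain is integrated independently with the
#' adaptive Runge-Kutta 5(4) scheme while cross-domain neighbour states are
#' held frozen at their start-of-interval values; at interval boundaries the
#' edge states are exchanged. The serial backend is the reference; the
#' parallel backend applies the identical frozen-ghost contract over worker
#' processes and yields bitwise-identical archives.
#'
#' @param mesh a tiled `vw_mesh`.
#' @param coupling a `vw_coupling`.
#' @param agonist agonist map or per-EC numeric vector (uM/s).
#' @param config a [simulation_config()].
#' @param params model parameters.
#' @param adj adjacency; computed from the mesh when omitted.
#' @param domains a [decompose_domains()] table; default one quad per domain.
#' @param init initial flat state; default [tissue_initial_state()].
#' @param cores worker count for the parallel backend.
#' @return A `vw_archive`.
#' @export
simulate_tissue <- function(mesh, coupling, agonist, config,
                            params = model_params(),
                            adj = build_adjacency(mesh),
                            domains = decompose_domains(mesh),
                            init = NULL, cores = 2L) {
  stopifnot(inherits(config, "vw_sim_config"))
  vals <- agonist_values(agonist)
  dom_of <- domains$domain
  sys <- build_system(adj, coupling, vals, params,
                      dom_ec = dom_of[adj$ec_quad] - 1L,
                      dom_smc = dom_of[adj$smc_quad] - 1L)
  if (is.null(init)) init <- tissue_initial_state(adj, params)
  if (config$duration == 0) {
    return(structure(list(
      times = 0, states = matrix(as.numeric(init), nrow = 1),
      n_ec = adj$n_ec, n_smc = adj$n_smc, census = mesh_census(mesh),
      config = config, coupling = coupling, agonist = vals
    ), class = "vw_archive"))
  }
  out_times <- seq(0, config$duration, by = config$output_interval)
  if (abs(out_times[length(out_times)] - config$duration) > 1e-9) {
    abort("duration must be a multiple of output_interval")
  }

  states <- if (config$backend == "serial") {
    integrate_tissue_cpp(as.numeric(init), out_times, config$comm_interval,
                         sys, config$rtol, config$atol)
  } else {
    run_parallel_backend(init, out_times, sys, config, max(dom_of), cores)
  }

  structure(list(
    times = out_times, states = states, n_ec = adj$n_ec, n_smc = adj$n_smc,
    census = mesh_census(mesh), config = config, coupling = coupling,
    agonist = vals
  ), class = "vw_archive")
}

run_parallel_backend <- function(init, out_times, sys, config, n_dom, cores) {
  n_iv <- round(config$duration / config$comm_interval)
  # ODE indices owned by each domain
  ec_dom <- sys$dom_ec + 1L
  smc_dom <- sys$dom_smc + 1L
  own <- lapply(seq_len(n_dom), function(d) {
    e <- which(ec_dom == d); s <- which(smc_dom == d)
    c(as.vector(outer(1:4, (e - 1L) * 4L, "+")),
      4L * sys$n_ec + as.vector(outer(1:5, (s - 1L) * 5L, "+")))
  })
  chunks <- split(seq_len(n_dom), rep(seq_len(cores), length.out = n_dom))
  h_last <- rep(-1, n_dom)
  state <- as.numeric(init)
  snaps <- matrix(NA_real_, length(out_times), length(state))
  snaps[1, ] <- state
  next_out <- 2L
  t <- out_times[1]
  t_end <- out_times[length(out_times)]
  for (iv in seq_len(n_iv)) {
    t1 <- min(t + config$comm_interval, t_end) # clamp exactly as the core
    res <- parallel::mclapply(chunks, function(ds) {
      advance_domains_cpp(state, as.integer(ds - 1L), t, t1, sys,
                          config$rtol, config$atol, h_last[ds])
    }, mc.cores = cores)
    for (k in seq_along(chunks)) {
      ds <- chunks[[k]]
      for (j in seq_along(ds)) {
        idx <- own[[ds[j]]]
        state[idx] <- res[[k]]$state[idx]
        h_last[ds[j]] <- res[[k]]$h_last[j]
      }
    }
    t <- t1
    if (next_out <= length(out_times) &&
        abs(t - out_times[next_out]) < 1e-9 * max(1, abs(t))) {
      snaps[next_out, ] <- state
      next_out <- next_out + 1L
    }
  }
  snaps
}

#' Integrate a single coupled EC/SMC unit
#'
#' Convenience wrapper around the tissue engine for one EC and one SMC with
#' heterocellular coupling only (the configuration used for bifurcation
#' diagrams).
#'
#' @param j_plc agonist flux (uM/s).
#' @param coupling a `vw_coupling`; only heterocellular flags/rates act.
#' @param times output times (s).
#' @param params model parameters.
#' @param init optional length-9 state (EC block then SMC block); default
#'   the isolated rest states.
#' @param rtol,atol integrator tolerances.
#' @return Matrix with a time column and the 9 state columns (prefixed
#'   `ec.`/`smc.`).
#' @export
integrate_unit <- function(j_plc, coupling = coupling_case(1),
                           times = seq(0, 500, 0.25),
                           params = model_params(), init = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  adj <- unit_adjacency()
  p <- params
  p$j_plc <- j_plc
  sys <- build_system(adj, coupling, j_plc, p)
  if (is.null(init)) {
    rs <- rest_state(params)
    init <- c(unname(rs$ec), unname(rs$smc))
  }
  snaps <- integrate_tissue_cpp(as.numeric(init), times,
                                comm_interval = min(diff(times)), sys,
                                rtol, atol)
  colnames(snaps) <- c(paste0("ec.", ec_names), paste0("smc.", smc_names))
  cbind(time = times, snaps)
}

#' @exportS3Method base::print
print.vw_archive <- function(x, ...) {
  cat("<vw_archive>", length(x$times), "snapshots over", max(x$times),
      "s;", x$n_ec, "ECs +", x$n_smc, "SMCs\n")
  invisible(x)
}

#' Archive snapshots as a long tibble
#'
#' @param x a `vw_archive`.
#' @param ... unused.
#' @return Tibble with `time`, `layer`, `cell`, `variable`
#'   (`ca`, `store`, `v`, `w`, `ip3`) and `value`.
#' @export
as_tibble.vw_archive <- function(x, ...) {
  nt <- length(x$times)
  ec_block <- x$states[, seq_len(4 * x$n_ec), drop = FALSE]
  smc_block <- x$states[, 4 * x$n_ec + seq_len(5 * x$n_smc), drop = FALSE]
  ec_vars <- c("ca", "store", "v", "ip3")
  smc_vars <- c("ca", "store", "v", "w", "ip3")
  # layout: block columns are cell-major (cell 1 vars, cell 2 vars, ...)
  mk <- function(block, vars, layer, n) {
    tibble(
      time = rep(x$times, times = n * length(vars)),
      layer = layer,
      cell = rep(rep(seq_len(n), each = length(vars)), each = nt),
      variable = rep(rep(vars, times = n), each = nt),
      value = as.vector(block)
    )
  }
  dplyr::bind_rows(mk(ec_block, ec_vars, "EC", x$n_ec),
                   mk(smc_block, smc_vars, "SMC", x$n_smc))
}

# matrix of one state variable over time: rows = times, cols = cells
archive_variable <- function(archive, layer = c("SMC", "EC"),
                             variable = "ca") {
  layer <- match.arg(layer)
  vars <- if (layer == "EC") c("ca", "store", "v", "ip3") else
    c("ca", "store", "v", "w", "ip3")
  k <- match(variable, vars)
  if (is.na(k)) abort(paste0("unknown variable for ", layer, ": ", variable))
  n <- if (layer == "EC") archive$n_ec else archive$n_smc
  offset <- if (layer == "EC") 0L else 4L * archive$n_ec
  cols <- offset + (seq_len(n) - 1L) * length(vars) + k
  archive$states[, cols, drop = FALSE]
}

#' Save / load an archive
#'
#' Archives are persisted as RDS; [archive_export_csv()] writes a plain
#' long-format CSV of selected variables for interoperability.
#'
#' @param archive a `vw_archive`.
#' @param path file path.
#' @export
archive_save <- function(archive, path) {
  stopifnot(inherits(archive, "vw_archive"))
  saveRDS(archive, path)
  invisible(path)
}

#' @rdname archive_save
#' @export
archive_load <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "vw_archive")) abort("file does not contain an archive")
  x
}

#' @rdname archive_save
#' @param layer,variable what to export.
#' @export
archive_export_csv <- function(archive, path, layer = "SMC",
                               variable = "ca") {
  m <- archive_variable(archive, layer, variable)
  df <- as.data.frame(m)
  names(df) <- paste0("cell_", seq_len(ncol(m)))
  readr::write_csv(cbind(tibble(time = archive$times), df), path,
                   progress = FALSE)
  invisible(path)
}
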