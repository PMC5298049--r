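#' Single-unit bifurcation sweep
#'
#' Maps the J_PLC oscillatory window of one coupled EC/SMC unit: for each
#' agonist value the unit (heterocellular coupling of the chosen case,
#' homocellular coupling absent) is integrated through a settle window, then
#' the extrema of SMC cytosolic Ca2+ are recorded over a measurement window.
#' A value is oscillatory when the peak-to-peak excursion exceeds
#' `osc_tol_frac` of its mean. The lower and upper onsets are located on a
#' coarse grid, refined to a 0.05 uM/s grid around each crossing, and
#' bisected to 0.01 uM/s.
#'
#' @param case_id coupling case 1-4, or a `vw_coupling` object.
#' @param j_range scanned J_PLC interval (uM/s).
#' @param by coarse grid spacing (uM/s).
#' @param params model parameters.
#' @param settle,measure settle and measurement windows (s).
#' @param osc_tol_frac oscillation tolerance as a fraction of the mean.
#' @param osc_tol_abs absolute amplitude floor (uM) below which a
#'   peak-to-peak excursion is treated as residual transient rather than a
#'   limit cycle; slowly decaying relaxation from the rest state can
#'   otherwise masquerade as oscillation at very low agonist, where the
#'   mean itself is tiny.
#' @param rtol,atol integrator tolerances.
#' @return A `vw_bifdiag`: tibble of `j_plc`, `ca_min`, `ca_max`,
#'   `oscillatory` with attributes `lower_threshold`, `upper_threshold`,
#'   `case_id`.
#' @export
bifurcation_sweep <- function(case_id, j_range = c(0, 8), by = 0.25,
                              params = model_params(), settle = 200,
                              measure = 300, osc_tol_frac = 0.01,
                              osc_tol_abs = 0.01, rtol = 1e-7, atol = 1e-9) {
  coupling <- if (inherits(case_id, "vw_coupling")) case_id else
    coupling_case(case_id)
  rs <- rest_state(params)
  init <- c(unname(rs$ec), unname(rs$smc))
  times <- seq(0, settle + measure, by = 0.25)
  keep <- times >= settle
  ca_col <- 1L + 4L + 1L # time + EC block, then smc ca

  classify <- function(j) {
    tr <- integrate_unit(j, coupling, times = times, params = params,
                         init = init, rtol = rtol, atol = atol)
    ca <- tr[keep, ca_col]
    c(ca_min = min(ca), ca_max = max(ca))
  }
  osc <- function(cl) {
    ptp <- cl["ca_max"] - cl["ca_min"]
    ptp > max(osc_tol_frac * (cl["ca_max"] + cl["ca_min"]) / 2, osc_tol_abs)
  }

  grid <- seq(j_range[1], j_range[2], by = by)
  res <- vapply(grid, classify, numeric(2))
  oscil <- apply(res, 2, function(cl) unname(osc(cl)))

  bisect <- function(j_steady, j_osc) {
    while (abs(j_osc - j_steady) > 0.01) {
      mid <- (j_steady + j_osc) / 2
      if (osc(classify(mid))) j_osc <- mid else j_steady <- mid
    }
    (j_steady + j_osc) / 2
  }
  refine <- function(i_before, i_after) {
    # fine grid at 0.05 between the bracketing coarse points, then bisection
    fine <- seq(grid[i_before], grid[i_after], by = 0.05)
    fo <- vapply(fine, function(j) unname(osc(classify(j))), logical(1))
    k <- which(fo != fo[1])[1]
    if (is.na(k)) return(bisect(grid[i_before], grid[i_after]))
    bisect(fine[k - 1], fine[k])
  }

  lower <- upper <- NA_real_
  if (any(oscil)) {
    i1 <- which(oscil)[1]
    if (i1 > 1) lower <- refine(i1 - 1L, i1)
    i2 <- max(which(oscil))
    if (i2 < length(grid)) {
      # above the window the roles are swapped: steady lies after
      fine <- seq(grid[i2], grid[i2 + 1L], by = 0.05)
      fo <- vapply(fine, function(j) unname(osc(classify(j))), logical(1))
      k <- which(!fo)[1]
      upper <- if (is.na(k)) bisect(grid[i2 + 1L], grid[i2]) else
        bisect(fine[k], fine[k - 1])
    }
  }

  structure(
    tibble(j_plc = grid, ca_min = res[1, ], ca_max = res[2, ],
           oscillatory = oscil),
    lower_threshold = lower, upper_threshold = upper,
    case_id = coupling$case_id, osc_tol_frac = osc_tol_frac,
    class = c("vw_bifdiag", class(tibble()))
  )
}

#' @exportS3Method base::print
print.vw_bifdiag <- function(x, ...) {
  cat("<vw_bifdiag> case", attr(x, "case_id") %||% "custom",
      ": oscillatory window [",
      round(attr(x, "lower_threshold"), 2), ",",
      round(attr(x, "upper_threshold"), 2), "] uM/s J_PLC\n")
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.vw_bifdiag <- function(x, ...) {
  tibble(j_plc = x$j_plc, ca_min = x$ca_min, ca_max = x$ca_max,
         oscillatory = x$oscillatory)
}

#' @export
glance.vw_bifdiag <- function(x, ...) {
  tibble(case_id = attr(x, "case_id") %||% NA_integer_,
         lower_threshold = attr(x, "lower_threshold"),
         upper_threshold = attr(x, "upper_threshold"),
         n_grid = nrow(x))
}

#' @export
autoplot.vw_bifdiag <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j_plc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ca_min,
                                      ymax = .data$ca_max),
                         fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ca_min)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ca_max)) +
    ggplot2::labs(x = expression(J[PLC] ~ "(" * mu * "M/s)"),
                  y = expression("SMC" ~ Ca^{"2+"} ~ "extrema (" * mu * "M)")) +
    ggplot2::theme_minimal()
}

#' Extraction line specification
#'
#' A path along the vessel from inlet to outlet at fixed circumferential
#' position, used to sample SMC state for space-time (kymograph) analysis.
#' The default follows the outer wall: circumferential quad column 0 and SMC
#' column 1, across the parent and the first branch of a bifurcation (or the
#' single segment of a tube).
#'
#' @param v_column circumferential quad column (0-based).
#' @param smc_col SMC column within the quad (1-based, 1..4).
#' @param segments segment ids to traverse; default all for a tube,
#'   `c(1, 2)` for a bifurcation.
#' @export
line_spec <- function(v_column = 0L, smc_col = 1L, segments = NULL) {
  structure(list(v_column = as.integer(v_column),
                 smc_col = as.integer(smc_col), segments = segments),
            class = "vw_line_spec")
}

#' Extract a space-time map along a line
#'
#' @param archive a `vw_archive` from [simulate_tissue()].
#' @param mesh the simulated mesh.
#' @param line a [line_spec()].
#' @return A `vw_spacetime`: list with `positions` (mm, ordered along the
#'   path), `times` (s), `ca` (time x position matrix of SMC cytosolic
#'   Ca2+), `cells` (SMC indices).
#' @export
extract_line <- function(archive, mesh, line = line_spec()) {
  stopifnot(inherits(archive, "vw_archive"), inherits(mesh, "vw_mesh"))
  segs <- line$segments %||%
    (if (mesh$kind == "bifurcation") c(1L, 2L) else 1L)
  quads <- dplyr::filter(mesh$quads, .data$seg %in% segs,
                         .data$iv == line$v_column)
  if (nrow(quads) == 0) abort("extraction line intersects no quads")
  smc <- dplyr::filter(mesh$cells, .data$layer == "SMC",
                       .data$quad_id %in% quads$quad_id,
                       .data$col == line$smc_col)
  smc <- dplyr::arrange(smc, .data$axial)
  ca <- archive_variable(archive, "SMC", "ca")[, smc$cell_id, drop = FALSE]
  structure(list(positions = smc$axial, times = archive$times, ca = ca,
                 cells = smc$cell_id),
            class = "vw_spacetime")
}

#' @exportS3Method base::print
print.vw_spacetime <- function(x, ...) {
  cat("<vw_spacetime>", length(x$positions), "positions x",
      length(x$times), "times; axial [", round(min(x$positions), 3), ",",
      round(max(x$positions), 3), "] mm\n")
  invisible(x)
}

#' @export
as_tibble.vw_spacetime <- function(x, ...) {
  tibble(
    time = rep(x$times, times = length(x$positions)),
    position = rep(x$positions, each = length(x$times)),
    ca = as.vector(x$ca)
  )
}

#' @export
autoplot.vw_spacetime <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$time,
                                   fill = .data$ca)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(Ca^{"2+"} ~ "(" * mu * "M)")) +
    ggplot2::labs(x = "axial position (mm)", y = "time (s)") +
    ggplot2::theme_minimal()
}

peak_times <- function(ca, times) {
  rng <- range(ca)
  if (diff(rng) <= 0) return(numeric(0))
  thr <- rng[1] + 0.5 * diff(rng)
  n <- length(ca)
  is_peak <- c(FALSE, ca[2:(n - 1)] > ca[1:(n - 2)] &
                 ca[2:(n - 1)] >= ca[3:n], FALSE) & ca > thr
  times[is_peak]
}

#' Wave metrics from a space-time map
#'
#' Per-position oscillation amplitude (max minus min over the measurement
#' span) and period (mean spacing of successive peaks); the wave-front
#' trajectory, defined at each time as the most upstream position whose
#' local amplitude (sliding window) exceeds `amp_tol`; and the propagation
#' direction inferred from the front displacement. Amplitude exceedance
#' rather than phase is used because wave-packet phenomena make phase
#' tracking ill-posed.
#'
#' @param stmap a `vw_spacetime`.
#' @param amp_tol amplitude threshold (uM) above which a position counts as
#'   oscillating.
#' @param window sliding window width (s) for the front trajectory.
#' @param t_skip initial time span (s) excluded from all metrics; removes
#'   the relaxation transient of simulations started from the isolated-cell
#'   rest state, which is not wave dynamics.
#' @return A `vw_wave_metrics` list: `per_position` tibble (`position`,
#'   `amplitude`, `period`), `front` tibble (`time`, `front_position`),
#'   `direction` (`"upstream"`, `"downstream"` or `"stationary"`),
#'   `oscillatory` flag. When nothing oscillates the metrics are flagged
#'   absent (`oscillatory = FALSE`, empty tables).
#' @export
wave_metrics <- function(stmap, amp_tol = 0.05, window = 30, t_skip = 0) {
  stopifnot(inherits(stmap, "vw_spacetime"))
  if (t_skip > 0) {
    keep <- stmap$times >= stmap$times[1] + t_skip
    stmap$times <- stmap$times[keep]
    stmap$ca <- stmap$ca[keep, , drop = FALSE]
  }
  nt <- length(stmap$times); np <- length(stmap$positions)
  amp_total <- apply(stmap$ca, 2, function(z) max(z) - min(z))
  per <- vapply(seq_len(np), function(k) {
    pk <- peak_times(stmap$ca[, k], stmap$times)
    if (length(pk) >= 3) mean(diff(pk)) else NA_real_
  }, numeric(1))
  oscillatory <- any(amp_total > amp_tol)
  if (!oscillatory) {
    return(structure(list(
      per_position = tibble(position = stmap$positions,
                            amplitude = amp_total, period = per),
      front = tibble(time = numeric(0), front_position = numeric(0)),
      direction = "stationary", oscillatory = FALSE
    ), class = "vw_wave_metrics"))
  }

  half_w <- max(1L, round(window / 2 / max(diff(stmap$times))))
  front <- vapply(seq_len(nt), function(ti) {
    lo <- max(1L, ti - half_w); hi <- min(nt, ti + half_w)
    win <- stmap$ca[lo:hi, , drop = FALSE]
    amp <- apply(win, 2, function(z) max(z) - min(z))
    on <- which(amp > amp_tol)
    if (length(on)) min(stmap$positions[on]) else NA_real_
  }, numeric(1))
  fr <- tibble(time = stmap$times, front_position = front)
  fr_ok <- dplyr::filter(fr, is.finite(.data$front_position))
  direction <- "stationary"
  if (nrow(fr_ok) >= 2) {
    disp <- fr_ok$front_position[nrow(fr_ok)] - fr_ok$front_position[1]
    span <- diff(range(stmap$positions))
    if (disp < -0.02 * span) direction <- "upstream"
    if (disp > 0.02 * span) direction <- "downstream"
  }
  structure(list(
    per_position = tibble(position = stmap$positions, amplitude = amp_total,
                          period = per),
    front = fr, direction = direction, oscillatory = TRUE
  ), class = "vw_wave_metrics")
}

#' @exportS3Method base::print
print.vw_wave_metrics <- function(x, ...) {
  if (!x$oscillatory) {
    cat("<vw_wave_metrics> no oscillations detected; metrics absent\n")
  } else {
    cat("<vw_wave_metrics> direction:", x$direction,
        "; median period", round(stats::median(x$per_position$period,
                                               na.rm = TRUE), 2),
        "s; max amplitude",
        round(max(x$per_position$amplitude), 3), "uM\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
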