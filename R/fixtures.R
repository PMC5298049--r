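#' Deterministic test fixtures
#'
#' Small self-contained assets used throughout the test-suite and examples;
#' generation is deterministic given the arguments (the seed covers the
#' optional initial-state perturbation only).
#'
#' Kinds:
#' \describe{
#'   \item{`tube_small`}{4 x 4-quad straight tube (16 quads, 4608 cells).}
#'   \item{`tube_demo`}{60 x 20-quad tube (1200 quads, ~346k cells); build
#'     only, intended for demonstration runs outside the default suite.}
#'   \item{`bif_mini`}{miniature Y bifurcation, 5 x 8 quads per segment
#'     (Q = 120).}
#'   \item{`analytic_wave`}{closed-form travelling sine wave as a
#'     space-time map, the oracle for [wave_metrics()]:
#'     `ca(x, t) = offset + amp * sin(k x + omega t)`.}
#' }
#'
#' @param kind fixture kind, see details.
#' @param ... overrides: `m`, `n` for tubes; `omega`, `k_wave`, `amp`,
#'   `offset`, `duration` for the analytic wave.
#' @return A `vw_mesh` or `vw_spacetime` as appropriate.
#' @export
make_fixture <- function(kind = c("tube_small", "tube_demo", "bif_mini",
                                  "analytic_wave"), ...) {
  kind <- match.arg(kind)
  args <- list(...)
  switch(kind,
    tube_small = tube_mesh(m = args$m %||% 4L, n = args$n %||% 4L),
    tube_demo = tube_mesh(m = args$m %||% 60L, n = args$n %||% 20L),
    bif_mini = bifurcation_mesh(geometry_spec(
      branch_length = 5 * QUAD_AX_MM, diameter = 8 * QUAD_CIRC_MM / pi,
      m = 5L, n = 8L)),
    analytic_wave = {
      omega <- args$omega %||% (2 * pi / 5)  # 5 s period
      k_wave <- args$k_wave %||% (2 * pi / 1) # 1 mm wavelength
      amp <- args$amp %||% 0.2
      offset <- args$offset %||% 0.3
      duration <- args$duration %||% 60
      positions <- seq(0, 2, by = 0.02)
      times <- seq(0, duration, by = 0.25)
      ca <- outer(times, positions,
                  function(t, x) offset + amp * sin(k_wave * x + omega * t))
      structure(list(positions = positions, times = times, ca = ca,
                     cells = seq_along(positions)),
                class = "vw_spacetime")
    }
  )
}
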