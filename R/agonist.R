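#' Sigmoid agonist map specification
#'
#' The synthetic agonist map assigns every EC a J_PLC value (the IP3
#' production flux driven by luminal ATP) from a sigmoid in the axial
#' coordinate only: low plateau `j_min` upstream, high plateau `j_max`
#' downstream, inflection at `x_center` (default the bifurcation point,
#' axial 0).
#'
#' @param j_min,j_max plateau J_PLC values (uM/s), `j_max > j_min >= 0`.
#'   The defaults span the oscillatory window of the non-pathological
#'   coupling case (lower onset near 3.6 uM/s, see [bifurcation_sweep()]),
#'   so that a mapped vessel contains steady, oscillatory and again steady
#'   axial bands.
#' @param x_center axial position of the inflection (mm).
#' @param steepness sigmoid steepness (1/mm).
#' @return A `vw_sigmoid_spec`.
#' @export
sigmoid_spec <- function(j_min = 2, j_max = 5.5, x_center = 0,
                         steepness = 2) {
  if (!(j_max > j_min) || j_min < 0) abort("need j_max > j_min >= 0")
  if (steepness <= 0) abort("steepness must be positive")
  structure(list(j_min = j_min, j_max = j_max, x_center = x_center,
                 steepness = steepness), class = "vw_sigmoid_spec")
}

#' Generate a sigmoid agonist map
#'
#' @param mesh a tiled `vw_mesh`.
#' @param spec a [sigmoid_spec()].
#' @return A `vw_agonist` tibble: `ec` (EC index), `axial` (mm), `j_plc`
#'   (uM/s); provenance attribute `"sigmoid"`.
#' @export
sigmoid_map <- function(mesh, spec = sigmoid_spec()) {
  stopifnot(inherits(mesh, "vw_mesh"), inherits(spec, "vw_sigmoid_spec"))
  if (is.null(mesh$cells)) abort("mesh is not tiled; call tile_cells() first")
  ecs <- dplyr::filter(mesh$cells, .data$layer == "EC")
  j <- spec$j_min + (spec$j_max - spec$j_min) /
    (1 + exp(-spec$steepness * (ecs$axial - spec$x_center)))
  new_agonist(tibble(ec = ecs$cell_id, axial = ecs$axial, j_plc = j),
              provenance = "sigmoid")
}

new_agonist <- function(df, provenance) {
  structure(dplyr::arrange(df, .data$ec),
            provenance = provenance,
            class = c("vw_agonist", class(tibble())))
}

# accept a vw_agonist or a bare numeric vector
agonist_values <- function(agonist) {
  if (inherits(agonist, "vw_agonist")) return(agonist$j_plc)
  if (is.numeric(agonist)) return(as.numeric(agonist))
  abort("agonist must be a vw_agonist table or a numeric vector")
}

#' Linear ATP to J_PLC conversion
#'
#' The relationship between luminal ATP concentration and the EC IP3
#' production rate is monotone increasing over the physiological ATP range
#' and is modelled as affine, floored at zero.
#'
#' @param atp ATP concentration(s) (uM), non-negative.
#' @param slope (uM/s of J_PLC) per (uM of ATP).
#' @param intercept J_PLC at zero ATP (uM/s), default 0.
#' @return J_PLC value(s) (uM/s).
#' @export
atp_to_jplc <- function(atp, slope, intercept = 0) {
  if (any(atp < 0)) abort("atp must be >= 0")
  pmax(0, slope * atp + intercept)
}

#' Save / load agonist maps
#'
#' Maps are stored as two-column CSV tables (`ec`, `j_plc`), one row per EC
#' in mesh enumeration order; `load_map` verifies length and non-negativity
#' against the mesh.
#'
#' @param map a `vw_agonist`.
#' @param path CSV file path.
#' @export
save_map <- function(map, path) {
  stopifnot(inherits(map, "vw_agonist"))
  # full 17-digit formatting so that load(save(m)) round-trips exactly
  df <- tibble(ec = map$ec, j_plc = sprintf("%.17g", map$j_plc))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname save_map
#' @param mesh the tiled mesh the map must index.
#' @export
load_map <- function(path, mesh) {
  # base read.csv for correctly-rounded double parsing (exact round trips)
  df <- utils::read.csv(path)
  df$ec <- as.integer(df$ec)
  if (!all(c("ec", "j_plc") %in% names(df))) {
    abort("agonist file must have columns ec, j_plc")
  }
  ecs <- dplyr::filter(mesh$cells, .data$layer == "EC")
  if (nrow(df) != nrow(ecs)) {
    abort(sprintf("agonist file has %d rows but the mesh has %d ECs",
                  nrow(df), nrow(ecs)))
  }
  if (any(df$j_plc < 0)) abort("agonist values must be >= 0")
  df <- dplyr::arrange(df, .data$ec)
  ax <- ecs$axial[order(ecs$cell_id)][df$ec]
  new_agonist(tibble(ec = df$ec, axial = ax, j_plc = df$j_plc),
              provenance = "file")
}

#' @exportS3Method base::print
print.vw_agonist <- function(x, ...) {
  cat("<vw_agonist>", nrow(x), "ECs; provenance:",
      attr(x, "provenance"), "; range [",
      round(min(x$j_plc), 3), ",", round(max(x$j_plc), 3), "] uM/s\n")
  NextMethod()
}

#' Plot an agonist map against axial position
#'
#' @param object a `vw_agonist`.
#' @param ... unused.
#' @export
autoplot.vw_agonist <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$axial, y = .data$j_plc)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::labs(x = "axial position (mm)",
                  y = expression(J[PLC] ~ "(" * mu * "M/s)")) +
    ggplot2::theme_minimal()
}
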