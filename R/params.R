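#' Model parameter defaults
#'
#' Returns the full, symbol-keyed parameter set of the coupled EC/SMC pathway
#' model. Defaults are shipped as a flat text table
#' (`system.file("extdata", "model_parameters.tsv", package = "vasowave")`),
#' one line per rate constant, half-saturation constant, conductance or pump
#' rate, and can be overridden by name. Units are micromolar, millivolt and
#' second throughout; the endothelial IP3 production flux `j_plc` (uM/s) is
#' the agonist input and defaults to 0.
#'
#' @param ... named numeric overrides, e.g. `model_params(k_i = 0.12)`.
#' @param j_plc IP3 production flux at the EC (uM/s).
#'
#' @return A named list of parameter values with attribute `"table"` holding
#'   the full parameter tibble (symbol, value, unit, cell, description).
#' @export
#'
#' @examples
#' p <- model_params()
#' p$G_Ca
model_params <- function(..., j_plc = 0) {
  tab <- param_table()
  p <- as.list(setNames(tab$value, tab$symbol))
  p$j_plc <- j_plc
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      abort("parameter overrides must be named")
    }
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown)) {
      abort(paste0("unknown model parameter(s): ", paste(unknown, collapse = ", ")))
    }
    p[names(overrides)] <- overrides
  }
  structure(p, table = tab, class = c("vw_params", "list"))
}

param_table <- function() {
  path <- system.file("extdata", "model_parameters.tsv", package = "vasowave")
  if (path == "") abort("parameter defaults file not found; is the package installed?")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @exportS3Method base::print
print.vw_params <- function(x, ...) {
  cat("<vw_params> coupled EC/SMC model parameters (uM, mV, s)\n")
  cat("  j_plc =", x$j_plc, "uM/s;", length(x) - 1L, "model constants\n")
  invisible(x)
}

# Fetch a parameter, failing loudly with the symbol name if absent.
pget <- function(params, symbol) {
  v <- params[[symbol]]
  if (is.null(v) || !is.finite(v)) {
    abort(paste0("missing or non-finite model parameter: ", symbol),
          class = "vw_config_error")
  }
  v
}

# Assemble the fixed-order numeric parameter vectors handed to compiled code.
smc_param_order <- c(
  "F_i", "Kr_i", "B_i", "cb_i", "C_i", "sc_i", "cc_i", "D_i", "vd_i", "Rd_i",
  "L_i", "G_Ca", "v_Ca1", "v_Ca2", "R_Ca", "G_NaCa", "c_NaCa", "v_NaCa",
  "F_NaK", "G_Cl", "v_Cl", "G_K", "v_K", "lambda_i", "c_w", "beta_i",
  "v_Ca3", "R_K", "gamma_i", "k_i"
)

ec_param_order <- c(
  "F_j", "Kr_j", "B_j", "cb_j", "C_j", "sc_j", "cc_j", "D_j", "L_j",
  "G_cat", "E_Ca", "m3_cat", "m4_cat", "J0_j", "C_m", "G_tot", "v_K_j",
  "a1_j", "a2_j", "b_j", "c0_j", "m3b_j", "m4b_j", "m3s_j", "m4s_j",
  "G_R", "v_rest_j", "k_j"
)

param_vectors <- function(params) {
  list(
    smc = vapply(smc_param_order, function(s) pget(params, s), numeric(1)),
    ec  = vapply(ec_param_order, function(s) pget(params, s), numeric(1))
  )
}
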