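#' Gap-junction coupling configuration
#'
#' A coupling configuration holds per-species on/off flags for homocellular
#' coupling within the SMC layer, homocellular coupling within the EC layer
#' and heterocellular EC-SMC coupling, together with the rate coefficients.
#' Species are membrane potential (`v`), Ca2+ (`ca`) and IP3 (`ip3`).
#'
#' Default rates: homocellular electrical coupling 1000 1/s for both layers;
#' homocellular Ca2+ and IP3 coupling 0.05 1/s; heterocellular electrical
#' coupling 50 1/s; heterocellular Ca2+ coupling 0.05 1/s. The heterocellular
#' IP3 permeability is small relative to the homocellular value (its default
#' is calibrated so that the single-unit oscillation window of the
#' non-pathological case starts near an IP3 production flux of 3.7 uM/s, see
#' [bifurcation_sweep()]); all rates are user-configurable.
#'
#' @param smc_homo,ec_homo,hetero character vectors naming coupled species,
#'   subsets of `c("v", "ca", "ip3")`.
#' @param g_v_homo,g_chem_homo homocellular electrical and chemical
#'   (Ca2+/IP3) coupling rates (1/s), applied to both layers.
#' @param g_v_hetero,g_ca_hetero,g_ip3_hetero heterocellular rates (1/s).
#' @return An object of class `vw_coupling`.
#' @export
coupling_config <- function(smc_homo = c("v", "ca", "ip3"),
                            ec_homo = c("v", "ca"),
                            hetero = c("v", "ip3"),
                            g_v_homo = 1000,
                            g_chem_homo = 0.05,
                            g_v_hetero = 50,
                            g_ca_hetero = 0.05,
                            g_ip3_hetero = 0.0026) {
  species <- c("v", "ca", "ip3")
  chk <- function(x, what) {
    bad <- setdiff(x, species)
    if (length(bad)) abort(paste0("unknown species in ", what, ": ",
                                  paste(bad, collapse = ", ")))
    setNames(species %in% x, species)
  }
  rates <- list(g_v_homo = g_v_homo, g_chem_homo = g_chem_homo,
                g_v_hetero = g_v_hetero, g_ca_hetero = g_ca_hetero,
                g_ip3_hetero = g_ip3_hetero)
  if (any(unlist(rates) < 0)) abort("coupling rates must be >= 0")
  structure(list(
    smc_homo = as.list(chk(smc_homo, "smc_homo")),
    ec_homo = as.list(chk(ec_homo, "ec_homo")),
    hetero = as.list(chk(hetero, "hetero")),
    rates = rates
  ), class = "vw_coupling")
}

#' Table-defined coupling cases
#'
#' The four canonical coupling regimes spanning healthy and pathological
#' gap-junction communication:
#' \describe{
#'   \item{Case 1}{Non-pathological: SMC homocellular v/Ca/IP3, EC
#'     homocellular v/Ca, heterocellular v/IP3.}
#'   \item{Case 2}{Case 1 plus heterocellular Ca2+ coupling.}
#'   \item{Case 3}{Case 2 plus homocellular IP3 coupling in the EC layer
#'     (lesion-prone connexin upregulation).}
#'   \item{Case 4}{Progressive pathology: only IP3 remains in the EC
#'     homocellular and the heterocellular pathways (membrane-potential and
#'     Ca2+ routes removed); SMC homocellular coupling is unchanged.}
#' }
#'
#' @param case_id integer 1-4.
#' @param ... rate overrides forwarded to [coupling_config()].
#' @return A `vw_coupling` object.
#' @export
coupling_case <- function(case_id, ...) {
  if (!length(case_id) == 1 || !case_id %in% 1:4) {
    abort("case_id must be one of 1, 2, 3, 4")
  }
  sets <- list(
    list(smc = c("v", "ca", "ip3"), ec = c("v", "ca"), het = c("v", "ip3")),
    list(smc = c("v", "ca", "ip3"), ec = c("v", "ca"), het = c("v", "ip3", "ca")),
    list(smc = c("v", "ca", "ip3"), ec = c("v", "ca", "ip3"), het = c("v", "ip3", "ca")),
    list(smc = c("v", "ca", "ip3"), ec = "ip3", het = "ip3")
  )[[case_id]]
  cfg <- coupling_config(smc_homo = sets$smc, ec_homo = sets$ec,
                         hetero = sets$het, ...)
  cfg$case_id <- as.integer(case_id)
  cfg
}

#' @exportS3Method base::print
print.vw_coupling <- function(x, ...) {
  on <- function(fl) paste(names(fl)[unlist(fl)], collapse = ",")
  cat("<vw_coupling>", if (!is.null(x$case_id)) paste0("case ", x$case_id) else "custom", "\n")
  cat("  SMC homo: {", on(x$smc_homo), "}  EC homo: {", on(x$ec_homo),
      "}  hetero: {", on(x$hetero), "}\n", sep = "")
  cat("  rates (1/s): v_homo=", x$rates$g_v_homo, " chem_homo=", x$rates$g_chem_homo,
      " v_het=", x$rates$g_v_hetero, " ca_het=", x$rates$g_ca_hetero,
      " ip3_het=", x$rates$g_ip3_hetero, "\n", sep = "")
  invisible(x)
}

#' Linear gap-junction flux
#'
#' Pure diffusive coupling: the flux into a cell is
#' `rate * sum(x_neighbours - x_self)`. The electro-diffusive drift
#' contribution to membrane-potential coupling is omitted (negligible for
#' this model class), so potential couples by the same linear form as the
#' chemical species.
#'
#' @param x_self value at the receiving cell (uM or mV).
#' @param x_neighbours numeric vector of neighbour values.
#' @param rate coupling rate coefficient (1/s), must be non-negative.
#' @return Flux in units of `x` per second.
#' @export
gap_flux <- function(x_self, x_neighbours, rate) {
  if (rate < 0) abort("coupling rate must be >= 0")
  rate * sum(x_neighbours - x_self)
}
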