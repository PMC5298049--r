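#' Decompose a mesh into computational domains
#'
#' The canonical decomposition maps one quadrilateral to one domain (one
#' task per cell neighbourhood, Cartesian per segment with the
#' circumferential wrap periodic). Quads may also be grouped to form larger
#' domains, down to a single monolithic domain.
#'
#' @param mesh a `vw_mesh`.
#' @param quads_per_domain group this many consecutive quads per domain.
#' @return A `vw_domains` tibble mapping `quad_id` to `domain` (1-based).
#' @export
decompose_domains <- function(mesh, quads_per_domain = 1L) {
  stopifnot(inherits(mesh, "vw_mesh"))
  nq <- nrow(mesh$quads)
  domain <- ((seq_len(nq) - 1L) %/% as.integer(quads_per_domain)) + 1L
  structure(tibble(quad_id = mesh$quads$quad_id, domain = domain),
            class = c("vw_domains", class(tibble())))
}

#' Ghost-cell edge tables
#'
#' For every ordered pair of adjacent domains, lists the cells whose state
#' must be exported to (equivalently imported by) the neighbouring domain to
#' evaluate coupling fluxes across the domain boundary.
#'
#' @param mesh a tiled `vw_mesh`.
#' @param adj its [build_adjacency()].
#' @param domains a [decompose_domains()] table.
#' @return Tibble with columns `domain`, `neighbour_domain`, `layer`,
#'   `cell` — cell `cell` is owned by `domain` and read by
#'   `neighbour_domain`.
#' @export
ghost_edge_tables <- function(mesh, adj, domains = decompose_domains(mesh)) {
  dom_of <- domains$domain
  per_layer <- function(csr, quad_map, layer) {
    n <- length(quad_map)
    deg <- diff(csr$ptr)
    from <- rep(seq_len(n), deg)
    to <- csr$idx
    dfrom <- dom_of[quad_map[from]]
    dto <- dom_of[quad_map[to]]
    keep <- dfrom != dto
    out <- tibble(domain = dfrom[keep], neighbour_domain = dto[keep],
                  layer = layer, cell = from[keep])
    dplyr::distinct(out)
  }
  out <- dplyr::bind_rows(
    per_layer(adj$ec, adj$ec_quad, "EC"),
    per_layer(adj$smc, adj$smc_quad, "SMC")
  )
  dplyr::arrange(out, .data$domain, .data$neighbour_domain, .data$layer,
                 .data$cell)
}

#' Exchange ghost states
#'
#' Gathers, for every domain, the current state of the edge cells it imports
#' from its neighbours. Exchanging twice without integrating in between
#' returns identical buffers (the operation is a pure gather).
#'
#' @param state flat tissue state vector (EC block then SMC block).
#' @param tables a [ghost_edge_tables()] result.
#' @param n_ec number of ECs (defines the state layout).
#' @return Tibble keyed by the importing domain: `domain` (importer),
#'   `from_domain` (owner), `layer`, `cell` and one column per state
#'   variable (`ca`, `store`, `v`, `w`, `ip3`; `w` is `NA` for ECs).
#' @export
exchange_ghosts <- function(state, tables, n_ec) {
  ec_part <- dplyr::filter(tables, .data$layer == "EC")
  smc_part <- dplyr::filter(tables, .data$layer == "SMC")
  ec_off <- (ec_part$cell - 1L) * 4L
  smc_off <- 4L * n_ec + (smc_part$cell - 1L) * 5L
  out <- dplyr::bind_rows(
    tibble(domain = ec_part$neighbour_domain, from_domain = ec_part$domain,
           layer = "EC", cell = ec_part$cell,
           ca = state[ec_off + 1L], store = state[ec_off + 2L],
           v = state[ec_off + 3L], w = NA_real_, ip3 = state[ec_off + 4L]),
    tibble(domain = smc_part$neighbour_domain, from_domain = smc_part$domain,
           layer = "SMC", cell = smc_part$cell,
           ca = state[smc_off + 1L], store = state[smc_off + 2L],
           v = state[smc_off + 3L], w = state[smc_off + 4L],
           ip3 = state[smc_off + 5L])
  )
  dplyr::arrange(out, .data$domain, .data$from_domain, .data$layer, .data$cell)
}
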