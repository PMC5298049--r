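# cell indexing within a layer: cells are ordered quad-major, then
# column-major within the quad grid (row varies fastest)
cell_index <- function(quad, row, col, nrow_) {
  (quad - 1L) * (nrow_ * if (nrow_ == EC_ROWS) EC_COLS else SMC_COLS) +
    (col - 1L) * nrow_ + row
}

#' Build the cell adjacency of a tiled mesh
#'
#' Homocellular neighbour structure is the 4-neighbour grid within each
#' layer, continued across quad boundaries (including circumferential
#' periodicity and the junction seams of a bifurcation). Heterocellular
#' pairs connect each EC with the 13 SMCs of its fundamental unit; the
#' printed footprints overlap uniformly (each EC column strip crosses each
#' SMC row strip in an equal 10 x 5 um rectangle), so every pair carries the
#' same weight. Weights are normalised per SMC (1/5 each, an SMC's weights
#' summing to one): this keeps the SMC-side heterocellular influx -- the
#' pathway that drives the Ca2+ oscillations -- identical to the
#' single-unit model whose bifurcation diagram anchors the coupling rates,
#' so tissue oscillations switch on at the single-unit thresholds.
#'
#' @param mesh a tiled `vw_mesh`.
#' @return A `vw_adjacency` with CSR neighbour lists per layer, the
#'   heterocellular pair list and the cell-to-quad maps.
#' @export
build_adjacency <- function(mesh) {
  stopifnot(inherits(mesh, "vw_mesh"))
  if (is.null(mesh$cells)) abort("mesh is not tiled; call tile_cells() first")
  nq <- nrow(mesh$quads)
  quads <- seq_len(nq)

  layer_edges <- function(nrow_, ncol_) {
    ncell <- nrow_ * ncol_
    # within-quad vertical (axial) pairs: (r, c) - (r+1, c)
    g1 <- expand.grid(row = seq_len(nrow_ - 1L), col = seq_len(ncol_))
    # within-quad horizontal pairs: (r, c) - (r, c+1)
    g2 <- expand.grid(row = seq_len(nrow_), col = seq_len(ncol_ - 1L))
    qrep1 <- rep(quads, each = nrow(g1))
    qrep2 <- rep(quads, each = nrow(g2))
    e_in <- rbind(
      cbind(cell_index(qrep1, rep(g1$row, nq), rep(g1$col, nq), nrow_),
            cell_index(qrep1, rep(g1$row + 1L, nq), rep(g1$col, nq), nrow_)),
      cbind(cell_index(qrep2, rep(g2$row, nq), rep(g2$col, nq), nrow_),
            cell_index(qrep2, rep(g2$row, nq), rep(g2$col + 1L, nq), nrow_))
    )

    nb <- mesh$neighbors
    ax <- dplyr::filter(nb, .data$side == "u_plus")
    crc <- dplyr::filter(nb, .data$side == "v_plus")
    car <- dplyr::filter(nb, .data$side == "u_minus", .data$reversed,
                         .data$quad < .data$nbr)
    e_ax <- if (nrow(ax)) {
      cols <- rep(seq_len(ncol_), times = nrow(ax))
      qa <- rep(ax$quad, each = ncol_); qb <- rep(ax$nbr, each = ncol_)
      rv <- rep(ax$reversed, each = ncol_)
      cbind(cell_index(qa, nrow_, cols, nrow_),
            cell_index(qb, 1L, ifelse(rv, ncol_ + 1L - cols, cols), nrow_))
    }
    e_car <- if (nrow(car)) {
      cols <- rep(seq_len(ncol_), times = nrow(car))
      qa <- rep(car$quad, each = ncol_); qb <- rep(car$nbr, each = ncol_)
      cbind(cell_index(qa, 1L, cols, nrow_),
            cell_index(qb, 1L, ncol_ + 1L - cols, nrow_))
    }
    e_crc <- if (nrow(crc)) {
      rws <- rep(seq_len(nrow_), times = nrow(crc))
      qa <- rep(crc$quad, each = nrow_); qb <- rep(crc$nbr, each = nrow_)
      cbind(cell_index(qa, rws, ncol_, nrow_),
            cell_index(qb, rws, 1L, nrow_))
    }
    e <- rbind(e_in, e_ax, e_car, e_crc)
    # dedupe undirected pairs
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e[!duplicated(key) & e[, 1] != e[, 2], , drop = FALSE]
  }

  ec_e <- layer_edges(EC_ROWS, EC_COLS)
  smc_e <- layer_edges(SMC_ROWS, SMC_COLS)
  n_ec <- nq * EC_ROWS * EC_COLS
  n_smc <- nq * SMC_ROWS * SMC_COLS

  # heterocellular pairs: per quad, per 4 x 4 unit, all 5 x 13 combinations
  units <- expand.grid(a = 1:UNITS_PER_QUAD, b = 1:UNITS_PER_QUAD)
  pair <- expand.grid(e = 1:5, s = 1:13)
  per_quad <- merge(units, pair)
  ec_row <- per_quad$a
  ec_col <- (per_quad$b - 1L) * 5L + per_quad$e
  smc_row <- (per_quad$a - 1L) * 13L + per_quad$s
  smc_col <- per_quad$b
  qrep <- rep(quads, each = nrow(per_quad))
  het <- tibble(
    ec = cell_index(qrep, rep(ec_row, nq), rep(ec_col, nq), EC_ROWS),
    smc = cell_index(qrep, rep(smc_row, nq), rep(smc_col, nq), SMC_ROWS),
    weight = 1 / 5
  )

  cells <- mesh$cells
  ec_quad <- cells$quad_id[cells$layer == "EC"]
  smc_quad <- cells$quad_id[cells$layer == "SMC"]

  structure(list(
    n_ec = n_ec, n_smc = n_smc,
    ec = csr_from_edges(ec_e, n_ec),
    smc = csr_from_edges(smc_e, n_smc),
    het = het,
    ec_quad = ec_quad, smc_quad = smc_quad
  ), class = "vw_adjacency")
}

csr_from_edges <- function(edges, n) {
  both_i <- c(edges[, 1], edges[, 2])
  both_j <- c(edges[, 2], edges[, 1])
  o <- order(both_i, both_j)
  counts <- tabulate(both_i, nbins = n)
  list(ptr = c(0L, cumsum(counts)), idx = both_j[o])
}

# neighbour list of one cell (1-based), for tests and inspection
neighbours_of <- function(adj, layer = c("EC", "SMC"), i) {
  layer <- match.arg(layer)
  csr <- if (layer == "EC") adj$ec else adj$smc
  csr$idx[(csr$ptr[i] + 1L):csr$ptr[i + 1L]]
}

#' Adjacency as an edge-list tibble
#'
#' @param adj a `vw_adjacency`.
#' @return Tibble with columns `layer`, `from`, `to`, `weight` (1 for
#'   homocellular grid edges; overlap weight for heterocellular pairs, layer
#'   `"EC-SMC"`). Suitable for CSV export.
#' @export
adjacency_edges <- function(adj) {
  stopifnot(inherits(adj, "vw_adjacency"))
  expand <- function(csr, n, layer) {
    deg <- diff(csr$ptr)
    tibble(layer = layer, from = rep(seq_len(n), deg), to = csr$idx,
           weight = 1)
  }
  e1 <- expand(adj$ec, adj$n_ec, "EC")
  e2 <- expand(adj$smc, adj$n_smc, "SMC")
  dplyr::bind_rows(
    dplyr::filter(e1, .data$from < .data$to),
    dplyr::filter(e2, .data$from < .data$to),
    tibble(layer = "EC-SMC", from = adj$het$ec, to = adj$het$smc,
           weight = adj$het$weight)
  )
}

# adjacency of a single isolated EC/SMC unit (no homocellular neighbours,
# one heterocellular pair of weight 1)
unit_adjacency <- function() {
  structure(list(
    n_ec = 1L, n_smc = 1L,
    ec = list(ptr = c(0L, 0L), idx = integer(0)),
    smc = list(ptr = c(0L, 0L), idx = integer(0)),
    het = tibble(ec = 1L, smc = 1L, weight = 1),
    ec_quad = 1L, smc_quad = 1L
  ), class = "vw_adjacency")
}

#' @exportS3Method base::print
print.vw_adjacency <- function(x, ...) {
  cat("<vw_adjacency>", x$n_ec, "ECs,", x$n_smc, "SMCs;",
      length(x$ec$idx) / 2, "EC edges,", length(x$smc$idx) / 2, "SMC edges,",
      nrow(x$het), "heterocellular pairs\n")
  invisible(x)
}
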