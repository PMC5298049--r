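#' Write a snapshot as a VTK unstructured grid (VTU)
#'
#' Emits an ASCII XML `.vtu` file with one quad cell per biological cell
#' (the cell's footprint rectangle mapped onto the surface) and cell-data
#' arrays for cytosolic Ca2+, IP3, membrane potential and a layer tag
#' (0 = EC, 1 = SMC). Readable by standard VTK tools.
#'
#' @param mesh a tiled `vw_mesh`.
#' @param archive a `vw_archive` for this mesh.
#' @param time snapshot time (s); must be one of `archive$times`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_snapshot_vtu <- function(mesh, archive, time, path) {
  stopifnot(inherits(mesh, "vw_mesh"), inherits(archive, "vw_archive"))
  if (is.null(mesh$cells)) abort("mesh is not tiled")
  ti <- which(abs(archive$times - time) < 1e-9)
  if (length(ti) != 1) abort("time is not an archived snapshot")
  cen <- mesh_census(mesh)
  if (cen$n_ec != archive$n_ec || cen$n_smc != archive$n_smc) {
    abort("archive does not belong to this mesh")
  }

  cells <- mesh$cells
  ec <- cells[cells$layer == "EC", ]
  smc <- cells[cells$layer == "SMC", ]
  cells <- rbind(ec[order(ec$cell_id), ], smc[order(smc$cell_id), ])

  corner_uv <- function(df, nrow_, ncol_) {
    list(u0 = (df$row - 1) / nrow_, u1 = df$row / nrow_,
         v0 = (df$col - 1) / ncol_, v1 = df$col / ncol_)
  }
  uv <- list(corner_uv(ec, EC_ROWS, EC_COLS),
             corner_uv(smc, SMC_ROWS, SMC_COLS))
  u0 <- c(uv[[1]]$u0, uv[[2]]$u0); u1 <- c(uv[[1]]$u1, uv[[2]]$u1)
  v0 <- c(uv[[1]]$v0, uv[[2]]$v0); v1 <- c(uv[[1]]$v1, uv[[2]]$v1)

  q <- mesh$quads[cells$quad_id, ]
  bil <- function(uf, vf) {
    mesh$nodes[q$n00, , drop = FALSE] * ((1 - uf) * (1 - vf)) +
      mesh$nodes[q$n10, , drop = FALSE] * (uf * (1 - vf)) +
      mesh$nodes[q$n11, , drop = FALSE] * (uf * vf) +
      mesh$nodes[q$n01, , drop = FALSE] * ((1 - uf) * vf)
  }
  pts <- rbind(bil(u0, v0), bil(u1, v0), bil(u1, v1), bil(u0, v1))
  ncell <- nrow(cells)
  # connectivity: corners of cell k are rows k, k+n, k+2n, k+3n (0-based)
  conn <- cbind(seq_len(ncell) - 1L, seq_len(ncell) - 1L + ncell,
                seq_len(ncell) - 1L + 2L * ncell,
                seq_len(ncell) - 1L + 3L * ncell)

  st <- archive$states[ti, ]
  n_ec <- archive$n_ec
  ecb <- function(k) st[(seq_len(n_ec) - 1L) * 4L + k]
  smcb <- function(k) st[4L * n_ec + (seq_len(archive$n_smc) - 1L) * 5L + k]
  ca <- c(ecb(1), smcb(1))
  vm <- c(ecb(3), smcb(3))
  ip3 <- c(ecb(4), smcb(5))
  layer_tag <- c(rep(0L, n_ec), rep(1L, archive$n_smc))

  num <- function(x) paste(formatC(x, format = "g", digits = 9),
                           collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">',
            4L * ncell, ncell))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(num(as.vector(t(pts))))
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  w(paste(as.vector(t(conn)), collapse = " "))
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  w(paste(4L * seq_len(ncell), collapse = " "))
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(9L, ncell), collapse = " "))
  w('</DataArray></Cells>')
  w('<CellData Scalars="ca">')
  w('<DataArray type="Float64" Name="ca" format="ascii">')
  w(num(ca))
  w('</DataArray><DataArray type="Float64" Name="ip3" format="ascii">')
  w(num(ip3))
  w('</DataArray><DataArray type="Float64" Name="v" format="ascii">')
  w(num(vm))
  w('</DataArray><DataArray type="UInt8" Name="layer" format="ascii">')
  w(paste(layer_tag, collapse = " "))
  w('</DataArray></CellData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}
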