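# Legacy ASCII VTK export of the mesh and cell fields, for inspection in
# ParaView. Cells are written as hexahedra spanned by the eight spherical
# corner points of each finite-volume cell.

#' Export mesh and cell fields to a legacy VTK file
#'
#' Writes an ASCII `UNSTRUCTURED_GRID` file with one hexahedron per cell
#' and the given per-cell arrays as `CELL_DATA`. The region tag is always
#' written as the integer array `region`.
#'
#' @param mesh an `ln_mesh`.
#' @param fields named list of numeric per-cell vectors (optional).
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_vtk <- function(mesh, fields = list(), file) {
  c_ <- mesh$cell
  n <- mesh$n
  rb <- mesh$r_breaks; tb <- mesh$th_breaks; pb <- mesh$ph_breaks
  corner <- function(ir, it, ip) {
    r <- rb[ir]; th <- tb[it]; ph <- pb[ip]
    cbind(r * sin(th) * cos(ph), r * sin(th) * sin(ph), r * cos(th))
  }
  # VTK_HEXAHEDRON ordering: bottom face CCW then top face CCW
  pts <- rbind(
    corner(c_$i,     c_$j,     c_$k),
    corner(c_$i + 1, c_$j,     c_$k),
    corner(c_$i + 1, c_$j + 1, c_$k),
    corner(c_$i,     c_$j + 1, c_$k),
    corner(c_$i,     c_$j,     c_$k + 1),
    corner(c_$i + 1, c_$j,     c_$k + 1),
    corner(c_$i + 1, c_$j + 1, c_$k + 1),
    corner(c_$i,     c_$j + 1, c_$k + 1))
  con <- file(file, open = "wt")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "lnchemosim idealized lymph node", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", 8L * n)), con)
  write(t(round(pts, 4)), con, ncolumns = 3)
  writeLines(sprintf("CELLS %d %d", n, 9L * n), con)
  idx0 <- seq_len(n) - 1L
  cells <- cbind(8L, idx0, idx0 + n, idx0 + 2L * n, idx0 + 3L * n,
                 idx0 + 4L * n, idx0 + 5L * n, idx0 + 6L * n, idx0 + 7L * n)
  write(t(cells), con, ncolumns = 9)
  writeLines(sprintf("CELL_TYPES %d", n), con)
  write(rep(12L, n), con, ncolumns = 20)
  writeLines(sprintf("CELL_DATA %d", n), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  write(c_$region, con, ncolumns = 20)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
    write(signif(fields[[nm]], 7), con, ncolumns = 9)
  }
  invisible(file)
}
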