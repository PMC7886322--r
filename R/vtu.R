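# Minimal ASCII VTU (VTK unstructured grid XML) writer for meshes and
# solution fields; enough for ParaView-style inspection of the sweep.

#' Write a mesh or solution field to a VTU file
#'
#' Quadratic tetrahedra (VTK cell type 24) with the sub-tendon label as
#' cell data; for solutions, nodal displacement and element Cauchy/von
#' Mises stress are attached.
#'
#' @param x a `tendon_mesh` or `solution_field`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_vtu <- function(x, file) {
  mesh <- if (inherits(x, "solution_field")) x$mesh else x
  stopifnot(inherits(mesh, "tendon_mesh"))
  N <- nrow(mesh$nodes); E <- nrow(mesh$elements)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(v) paste(format(v, digits = 9, trim = TRUE), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="%d" NumberOfCells="%d">', N, E)
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(mesh$nodes, 1, num), con)
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$elements - 1L, 1, num), con)
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(num(seq_len(E) * 10L), con)
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(num(rep(24L, E)), con)
  w('</DataArray></Cells>')
  if (inherits(x, "solution_field")) {
    w('<PointData Vectors="displacement">')
    w('<DataArray type="Float64" Name="displacement" NumberOfComponents="3" format="ascii">')
    writeLines(apply(x$u, 1, num), con)
    w('</DataArray></PointData>')
  }
  w('<CellData Scalars="sub_tendon">')
  w('<DataArray type="Int32" Name="sub_tendon" format="ascii">')
  writeLines(num(match(mesh$label, SUB_TENDONS)), con)
  if (inherits(x, "solution_field")) {
    w('</DataArray><DataArray type="Float64" Name="von_mises" format="ascii">')
    writeLines(num(x$vm), con)
    w('</DataArray><DataArray type="Float64" Name="cauchy_stress" NumberOfComponents="6" format="ascii">')
    writeLines(apply(x$stress, 1, num), con)
  }
  w('</DataArray></CellData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(file)
}
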