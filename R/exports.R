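# Mesh and map exchange: Abaqus .inp subset, legacy VTK, gridded CSV.

#' Write a mesh as an Abaqus input deck subset
#'
#' NODE / ELEMENT (C3D8) / NSET / SURFACE blocks, for cross-checking against
#' external solvers.
#'
#' @param mesh a `hex_mesh`
#' @param path output file
#' @param part part name
#' @return `path` invisibly
#' @export
write_inp <- function(mesh, path, part = "PART-1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "*HEADING",
    paste0("okfea mesh export: ", part),
    "*NODE"
  ), con)
  writeLines(sprintf(
    "%d, %.10g, %.10g, %.10g",
    seq_len(nrow(mesh$nodes)), mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]
  ), con)
  writeLines("*ELEMENT, TYPE=C3D8, ELSET=ALL", con)
  writeLines(sprintf(
    "%d, %d, %d, %d, %d, %d, %d, %d, %d",
    seq_len(nrow(mesh$elems)),
    mesh$elems[, 1], mesh$elems[, 2], mesh$elems[, 3], mesh$elems[, 4],
    mesh$elems[, 5], mesh$elems[, 6], mesh$elems[, 7], mesh$elems[, 8]
  ), con)
  for (nm in names(mesh$nsets)) {
    writeLines(sprintf("*NSET, NSET=%s", toupper(nm)), con)
    ids <- mesh$nsets[[nm]]
    rows <- split(ids, ceiling(seq_along(ids) / 16))
    writeLines(vapply(rows, function(r) paste(r, collapse = ", "), ""), con)
  }
  for (nm in names(mesh$facets)) {
    writeLines(sprintf("*SURFACE, NAME=%s, TYPE=NODE", toupper(nm)), con)
    ids <- sort(unique(as.vector(mesh$facets[[nm]])))
    rows <- split(ids, ceiling(seq_along(ids) / 16))
    writeLines(vapply(rows, function(r) paste(r, collapse = ", "), ""), con)
  }
  invisible(path)
}

#' Write a mesh (optionally with a nodal field) as legacy ASCII VTK
#'
#' @param mesh a `hex_mesh`
#' @param path output file
#' @param point_data optional named list of nodal scalar vectors
#' @return `path` invisibly
#' @export
write_vtk <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  ne <- nrow(mesh$elems)
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "okfea mesh", "ASCII", "DATASET UNSTRUCTURED_GRID",
    sprintf("POINTS %d double", n)
  ), con)
  writeLines(sprintf(
    "%.10g %.10g %.10g", mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]
  ), con)
  writeLines(sprintf("CELLS %d %d", ne, 9 * ne), con)
  writeLines(apply(mesh$elems - 1L, 1L, function(r) paste(c(8L, r), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("12", ne), con)
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(
        sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"
      ), con)
      writeLines(sprintf("%.10g", point_data[[nm]]), con)
    }
  }
  invisible(path)
}

#' Write a common-grid map as CSV with a location header
#'
#' @param map a `grid_map`
#' @param path output file
#' @return `path` invisibly
#' @export
write_grid_csv <- function(map, path) {
  con <- file(path, "w")
  writeLines(c(
    sprintf("# origin_x: %g", min(map$grid$x)),
    sprintf("# origin_y: %g", min(map$grid$y)),
    sprintf("# step: %g", map$grid$step),
    sprintf("# unit: %s", map$unit)
  ), con)
  close(con)
  utils::write.table(map$values, path,
    append = TRUE, sep = ",",
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
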