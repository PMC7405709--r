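#' Export a mesh (and optional point data) to VTK XML
#'
#' Writes an ASCII `.vtu` unstructured-grid file with the hexahedral
#' connectivity and any per-node data arrays (for example a displacement
#' field), readable by ParaView and other VTK tools.
#'
#' @param mesh An `eye_mesh`.
#' @param path Output file path (conventionally `.vtu`).
#' @param point_data Named list of per-node data: numeric vectors
#'   (length = nodes) or matrices (nodes x k).
#' @return The path, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list()) {
  stopifnot(inherits(mesh, "eye_mesh"))
  n <- nrow(mesh$nodes)
  e <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, e))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(mesh$nodes, 1, paste, collapse = " "), con)
  w('</DataArray></Points>')
  w('<Cells>')
  w('<DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$elems - 1L, 1, paste, collapse = " "), con)
  w('</DataArray>')
  w('<DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(as.character(seq_len(e) * 8L), con)
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(rep("12", e), con)  # VTK_HEXAHEDRON
  w('</DataArray>')
  w('</Cells>')
  w('<PointData>')
  for (nm in names(point_data)) {
    v <- point_data[[nm]]
    if (is.matrix(v)) {
      stopifnot(nrow(v) == n)
      w(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
                nm, ncol(v)))
      writeLines(apply(v, 1, paste, collapse = " "), con)
    } else {
      stopifnot(length(v) == n)
      w(sprintf('<DataArray type="Float64" Name="%s" format="ascii">', nm))
      writeLines(as.character(v), con)
    }
    w('</DataArray>')
  }
  w('</PointData>')
  w('</Piece>')
  w('</UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Read back nodes, connectivity and point data from a `.vtu` file
#'
#' Minimal reader for the ASCII files produced by [write_vtu()] (requires
#' the xml2 package).
#'
#' @param path A `.vtu` file path.
#' @return List with `nodes`, `elems` and `point_data`.
#' @export
read_vtu <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("read_vtu requires the xml2 package")
  }
  doc <- xml2::read_xml(path)
  parse_num <- function(node) scan(text = xml2::xml_text(node), quiet = TRUE)
  pts <- parse_num(xml2::xml_find_first(doc, ".//Points/DataArray"))
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  arrays <- xml2::xml_find_all(doc, ".//Cells/DataArray")
  names(arrays) <- xml2::xml_attr(arrays, "Name")
  conn <- parse_num(arrays[[which(xml2::xml_attr(arrays, "Name") == "connectivity")]])
  elems <- matrix(as.integer(conn) + 1L, ncol = 8, byrow = TRUE)
  pd <- xml2::xml_find_all(doc, ".//PointData/DataArray")
  point_data <- list()
  for (a in pd) {
    nm <- xml2::xml_attr(a, "Name")
    k <- xml2::xml_attr(a, "NumberOfComponents")
    v <- parse_num(a)
    point_data[[nm]] <- if (!is.na(k)) {
      matrix(v, ncol = as.integer(k), byrow = TRUE)
    } else {
      v
    }
  }
  list(nodes = nodes, elems = elems, point_data = point_data)
}
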