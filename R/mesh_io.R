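# Mesh interchange: Gmsh MSH v2.2 (read/write) and VTK VTU (write, read).
#
# Dialect: region labels are stored as the physical group of the triangles
# (codes 1..3); tagged edges are 2-node line elements whose physical group is
# 10 + tag code.  VTU files carry the same codes as integer cell-data arrays
# "region" (triangles; 0 on lines) and "tag" (lines; 0 on triangles).

#' Write a mesh in Gmsh MSH v2.2 format
#'
#' @param mesh a `pnp_mesh`.
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_mesh_msh <- function(mesh, path) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri); B <- nrow(mesh$bedges)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(n)), con)
  writeLines(sprintf("%d %.17g %.17g 0", seq_len(n),
                     mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(c("$EndNodes", "$Elements", as.character(m + B)), con)
  if (B > 0)
    writeLines(sprintf("%d 1 2 %d %d %d %d", seq_len(B), 10L + mesh$btag,
                       10L + mesh$btag, mesh$bedges[, 1], mesh$bedges[, 2]),
               con)
  writeLines(sprintf("%d 2 2 %d %d %d %d %d", B + seq_len(m), mesh$region,
                     mesh$region, mesh$tri[, 1], mesh$tri[, 2], mesh$tri[, 3]),
             con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a mesh from Gmsh MSH v2.2 format
#'
#' Triangles must carry a physical-group region label (1 intra, 2 membrane,
#' 3 extra); 2-node line elements with physical group 11..16 become tagged
#' edges.
#'
#' @param path file path.
#' @return a `pnp_mesh`.
#' @export
read_mesh_msh <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1))
      stop(sprintf("MSH: missing $%s section", name), call. = FALSE)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- strsplit(sec("MeshFormat")[1], "\\s+")[[1]]
  if (fmt[1] != "2.2")
    stop("unknown format: only Gmsh MSH v2.2 is supported", call. = FALSE)
  nl <- sec("Nodes")
  n <- as.integer(nl[1])
  nm <- matrix(as.numeric(unlist(strsplit(nl[1 + seq_len(n)], "\\s+"))),
               ncol = 4, byrow = TRUE)
  nodes <- nm[order(nm[, 1]), 2:3, drop = FALSE]
  el <- sec("Elements")
  ne <- as.integer(el[1])
  tri <- matrix(integer(0), 0, 3); region <- integer(0)
  bed <- matrix(integer(0), 0, 2); btag <- integer(0)
  for (ln in el[1 + seq_len(ne)]) {
    v <- as.integer(strsplit(trimws(ln), "\\s+")[[1]])
    type <- v[2]; ntags <- v[3]
    phys <- if (ntags >= 1) v[4] else NA_integer_
    conn <- v[(4 + ntags):length(v)]
    if (type == 2L) {
      if (is.na(phys) || !(phys %in% 1:3))
        stop("MSH: missing region labels on triangle elements", call. = FALSE)
      tri <- rbind(tri, conn); region <- c(region, phys)
    } else if (type == 1L) {
      if (is.na(phys) || !(phys %in% 11:16))
        stop("MSH: missing boundary tag on line element", call. = FALSE)
      bed <- rbind(bed, conn); btag <- c(btag, phys - 10L)
    }
  }
  if (nrow(tri) == 0) stop("MSH: no triangles found", call. = FALSE)
  new_pnp_mesh(nodes, tri, region, bed, btag)
}

#' Write a mesh (and optional nodal fields) as ASCII VTU
#'
#' Triangles and tagged line edges become cells; region labels and edge tags
#' are integer cell-data arrays.  Fields (named list of per-vertex numeric
#' vectors, or `discrete_field` objects whose vertex values are extracted)
#' become point data on the mesh nodes.
#'
#' @param mesh a `pnp_mesh`.
#' @param path output path.
#' @param fields optional named list of nodal fields.
#' @return invisibly `path`.
#' @export
write_mesh_vtu <- function(mesh, path, fields = NULL) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri); B <- nrow(mesh$bedges)
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  ints <- function(x) paste(x, collapse = " ")
  pts <- as.vector(t(cbind(mesh$nodes, 0)))
  conn <- c(as.vector(t(mesh$tri - 1L)), as.vector(t(mesh$bedges - 1L)))
  offs <- c(seq_len(m) * 3L, m * 3L + seq_len(B) * 2L)
  types <- c(rep(5L, m), rep(3L, B))
  pd <- ""
  if (!is.null(fields) && length(fields)) {
    arr <- vapply(names(fields), function(nm) {
      f <- fields[[nm]]
      v <- if (inherits(f, "discrete_field")) field_vertex_values(f) else f
      if (length(v) != n)
        stop("VTU: field length must match the number of mesh nodes",
             call. = FALSE)
      sprintf('<DataArray type="Float64" Name="%s" format="ascii">\n%s\n</DataArray>',
              nm, num(v))
    }, character(1))
    pd <- paste0("<PointData>\n", paste(arr, collapse = "\n"), "\n</PointData>\n")
  }
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">\n',
    "<UnstructuredGrid>\n",
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">\n', n, m + B),
    "<Points>\n",
    '<DataArray type="Float64" NumberOfComponents="3" format="ascii">\n',
    num(pts), "\n</DataArray>\n</Points>\n<Cells>\n",
    '<DataArray type="Int32" Name="connectivity" format="ascii">\n',
    ints(conn), "\n</DataArray>\n",
    '<DataArray type="Int32" Name="offsets" format="ascii">\n',
    ints(offs), "\n</DataArray>\n",
    '<DataArray type="UInt8" Name="types" format="ascii">\n',
    ints(types), "\n</DataArray>\n</Cells>\n",
    "<CellData>\n",
    '<DataArray type="Int32" Name="region" format="ascii">\n',
    ints(c(mesh$region, rep(0L, B))), "\n</DataArray>\n",
    '<DataArray type="Int32" Name="tag" format="ascii">\n',
    ints(c(rep(0L, m), mesh$btag)), "\n</DataArray>\n</CellData>\n",
    pd,
    "</Piece>\n</UnstructuredGrid>\n</VTKFile>\n")
  writeLines(xml, path)
  invisible(path)
}

#' Read a mesh from an ASCII VTU file written by [write_mesh_vtu()]
#'
#' Requires the `xml2` package.
#'
#' @param path file path.
#' @return a `pnp_mesh`; point-data arrays, if present, are attached as the
#'   `fields` attribute (named list of vertex vectors).
#' @export
read_mesh_vtu <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("reading VTU requires the xml2 package", call. = FALSE)
  doc <- xml2::read_xml(path)
  getarr <- function(xpath, what = as.numeric) {
    nd <- xml2::xml_find_first(doc, xpath)
    if (inherits(nd, "xml_missing")) return(NULL)
    what(strsplit(trimws(xml2::xml_text(nd)), "\\s+")[[1]])
  }
  pts <- getarr(".//Points/DataArray")
  if (is.null(pts)) stop("VTU: missing points", call. = FALSE)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)[, 1:2, drop = FALSE]
  conn <- getarr(".//Cells/DataArray[@Name='connectivity']", as.integer)
  offs <- getarr(".//Cells/DataArray[@Name='offsets']", as.integer)
  types <- getarr(".//Cells/DataArray[@Name='types']", as.integer)
  region_all <- getarr(".//CellData/DataArray[@Name='region']", as.integer)
  tag_all <- getarr(".//CellData/DataArray[@Name='tag']", as.integer)
  if (is.null(region_all))
    stop("VTU: missing region labels", call. = FALSE)
  starts <- c(1L, head(offs, -1L) + 1L)
  tri <- matrix(integer(0), 0, 3); region <- integer(0)
  bed <- matrix(integer(0), 0, 2); btag <- integer(0)
  for (k in seq_along(types)) {
    cell <- conn[starts[k]:offs[k]] + 1L
    if (types[k] == 5L) {
      tri <- rbind(tri, cell); region <- c(region, region_all[k])
    } else if (types[k] == 3L) {
      if (is.null(tag_all) || tag_all[k] == 0L)
        stop("VTU: missing boundary tag on line cell", call. = FALSE)
      bed <- rbind(bed, cell); btag <- c(btag, tag_all[k])
    }
  }
  mesh <- new_pnp_mesh(nodes, tri, region, bed, btag)
  pd <- xml2::xml_find_all(doc, ".//PointData/DataArray")
  if (length(pd)) {
    flds <- lapply(pd, function(nd)
      as.numeric(strsplit(trimws(xml2::xml_text(nd)), "\\s+")[[1]]))
    names(flds) <- vapply(pd, function(nd) xml2::xml_attr(nd, "Name"),
                          character(1))
    attr(mesh, "fields") <- flds
  }
  mesh
}

#' Read or write a mesh, dispatching on file extension
#'
#' `.msh` uses Gmsh MSH v2.2; `.vtu` uses ASCII VTU.
#'
#' @param path file path (`.msh` or `.vtu`).
#' @param mesh a `pnp_mesh` (for [write_mesh()]).
#' @return [read_mesh()]: a `pnp_mesh`; [write_mesh()]: invisibly `path`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         msh = read_mesh_msh(path),
         vtu = read_mesh_vtu(path),
         stop(sprintf("unknown format '%s' (supported: msh, vtu)", ext),
              call. = FALSE))
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         msh = write_mesh_msh(mesh, path),
         vtu = write_mesh_vtu(mesh, path),
         stop(sprintf("unknown format '%s' (supported: msh, vtu)", ext),
              call. = FALSE))
}
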