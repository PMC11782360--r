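#' Read a 3D volume from NIfTI or MetaImage
#'
#' Supported formats are NIfTI (`.nii`, `.nii.gz`) and MetaImage
#' (`.mha`, `.mhd`). Only axis-aligned, identity-orientation volumes are
#' supported; files with an oblique direction matrix are rejected with an
#' explicit error rather than silently reinterpreted.
#'
#' @param path file path.
#' @return an [image_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    vt_stop(sprintf("file not found: %s", path), "vt_validation_error")
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz", ".gz")) {
    img <- RNifti::readNifti(path)
    m <- RNifti::xform(img)
    rot <- m[1:3, 1:3]
    if (any(abs(rot[row(rot) != col(rot)]) > 1e-6))
      vt_stop("oblique/rotated NIfTI orientation is not supported; resample to an axis-aligned grid first",
              "vt_validation_error")
    if (any(diag(rot) < 0))
      vt_stop("NIfTI axis flips are not supported; only identity orientation is handled",
              "vt_validation_error")
    d <- dim(img)
    if (length(d) != 3L)
      vt_stop("only 3D volumes are supported", "vt_validation_error")
    image_volume(array(as.numeric(img), dim = d),
                 spacing = diag(rot), origin = m[1:3, 4])
  } else if (ext %in% c(".mha", ".mhd")) {
    read_metaimage(path)
  } else {
    vt_stop(sprintf("unsupported volume format: %s", path), "vt_validation_error")
  }
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' @param vol an [image_volume()].
#' @param path output path; format chosen by extension
#'   (`.nii`, `.nii.gz`, `.mha`, `.mhd`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vt_validate(inherits(vol, "image_volume"), "`vol` must be an image_volume")
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz", ".gz")) {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- vol$spacing
    m <- diag(c(vol$spacing, 1))
    m[1:3, 4] <- vol$origin
    RNifti::sform(img) <- structure(m, code = 2L)
    RNifti::qform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path)
  } else if (ext %in% c(".mha", ".mhd")) {
    write_metaimage(vol, path)
  } else {
    vt_stop(sprintf("unsupported volume format: %s", path), "vt_validation_error")
  }
  invisible(path)
}

# --- MetaImage (ITK .mha/.mhd), uncompressed, identity orientation ---------

meta_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                MET_SHORT = "integer", MET_USHORT = "integer",
                MET_INT = "integer", MET_UINT = "integer",
                MET_FLOAT = "double", MET_DOUBLE = "double")
meta_sizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
                MET_INT = 4L, MET_UINT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      vt_stop("malformed MetaImage header: no ElementDataFile", "vt_validation_error")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) next
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!is.null(hdr$CompressedData) && tolower(hdr$CompressedData) == "true")
    vt_stop("compressed MetaImage data is not supported", "vt_validation_error")
  if (!is.null(hdr$TransformMatrix)) {
    tm <- as.numeric(strsplit(hdr$TransformMatrix, "\\s+")[[1]])
    if (any(abs(tm - as.numeric(diag(3))) > 1e-6))
      vt_stop("oblique MetaImage TransformMatrix is not supported", "vt_validation_error")
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  vt_validate(length(dims) == 3L, "only 3D MetaImage volumes are supported")
  etype <- hdr$ElementType
  vt_validate(etype %in% names(meta_types),
              sprintf("unsupported MetaImage ElementType: %s", etype))
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  msb <- isTRUE(tolower(hdr$ElementByteOrderMSB %||% hdr$BinaryDataByteOrderMSB %||% "false") == "true")
  n <- prod(dims)
  datafile <- hdr$ElementDataFile
  if (identical(datafile, "LOCAL")) {
    raw <- readBin(con, what = meta_types[[etype]], n = n,
                   size = meta_sizes[[etype]],
                   signed = !(etype %in% c("MET_UCHAR", "MET_USHORT")),
                   endian = if (msb) "big" else "little")
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath))
      vt_stop(sprintf("MetaImage data file not found: %s", rawpath), "vt_validation_error")
    con2 <- file(rawpath, "rb")
    on.exit(close(con2), add = TRUE)
    raw <- readBin(con2, what = meta_types[[etype]], n = n,
                   size = meta_sizes[[etype]],
                   signed = !(etype %in% c("MET_UCHAR", "MET_USHORT")),
                   endian = if (msb) "big" else "little")
  }
  vt_validate(length(raw) == n, "MetaImage data shorter than DimSize promises")
  image_volume(array(as.numeric(raw), dim = dims), spacing, origin)
}

write_metaimage <- function(vol, path) {
  local_data <- grepl("\\.mha$", path, ignore.case = TRUE)
  datafile <- if (local_data) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(format(vol$origin, digits = 17), collapse = " ")),
           paste("ElementSpacing =", paste(format(vol$spacing, digits = 17), collapse = " ")),
           paste("DimSize =", paste(dim(vol$data), collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (local_data) {
    writeBin(as.numeric(vol$data), con, size = 8L, endian = "little")
  } else {
    con2 <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(con2), add = TRUE)
    writeBin(as.numeric(vol$data), con2, size = 8L, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- Mesh and centerline writers -------------------------------------------

#' Write a surface mesh to STL, PLY or VTP
#'
#' ASCII formats only, chosen by file extension. VTP files are written as
#' uncompressed ASCII VTK XML PolyData readable by ParaView/VTK.
#'
#' @param mesh a `surface_mesh` as returned by [extract_surface()].
#' @param path output path ending in `.stl`, `.ply` or `.vtp`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  vt_validate(inherits(mesh, "surface_mesh"), "`mesh` must be a surface_mesh")
  ext <- tolower(tools::file_ext(path))
  V <- mesh$vertices; Tr <- mesh$triangles
  if (ext == "stl") {
    con <- file(path, "w"); on.exit(close(con), add = TRUE)
    writeLines("solid vesseltrace", con)
    for (i in seq_len(nrow(Tr))) {
      p <- V[Tr[i, ], , drop = FALSE]
      nrm <- cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])
      nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
      writeLines(c(sprintf("facet normal %g %g %g", nrm[1], nrm[2], nrm[3]),
                   "  outer loop",
                   sprintf("    vertex %g %g %g", p[, 1], p[, 2], p[, 3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid vesseltrace", con)
  } else if (ext == "ply") {
    con <- file(path, "w"); on.exit(close(con), add = TRUE)
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(V)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(Tr)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%g %g %g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("3 %d %d %d", Tr[, 1] - 1L, Tr[, 2] - 1L, Tr[, 3] - 1L), con)
  } else if (ext == "vtp") {
    con <- file(path, "w"); on.exit(close(con), add = TRUE)
    writeLines(c('<?xml version="1.0"?>',
                 '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">',
                 '  <PolyData>',
                 sprintf('    <Piece NumberOfPoints="%d" NumberOfPolys="%d">', nrow(V), nrow(Tr)),
                 '      <Points>',
                 '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">'), con)
    writeLines(paste(t(V), collapse = " "), con)
    writeLines(c('        </DataArray>', '      </Points>', '      <Polys>',
                 '        <DataArray type="Int64" Name="connectivity" format="ascii">'), con)
    writeLines(paste(t(Tr) - 1L, collapse = " "), con)
    writeLines(c('        </DataArray>',
                 '        <DataArray type="Int64" Name="offsets" format="ascii">'), con)
    writeLines(paste(3L * seq_len(nrow(Tr)), collapse = " "), con)
    writeLines(c('        </DataArray>', '      </Polys>', '    </Piece>',
                 '  </PolyData>', '</VTKFile>'), con)
  } else {
    vt_stop(sprintf("unsupported mesh format: .%s", ext), "vt_validation_error")
  }
  invisible(path)
}

#' Write / read a centerline tree
#'
#' Centerlines are exchanged either as VTK XML PolyData polylines with a
#' `radius` point array (`.vtp`) or as a small JSON schema (`.json`):
#' a list of branches, each with `points` (n-by-3, mm) and `radius` (length n).
#'
#' @param tree a `centerline_tree` (see [trace_centerline()]).
#' @param path output path ending in `.vtp` or `.json`.
#' @return `path` (writer) or a `centerline_tree` (reader).
#' @export
write_centerline <- function(tree, path) {
  vt_validate(inherits(tree, "centerline_tree"), "`tree` must be a centerline_tree")
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    br <- lapply(tree$branches, function(b)
      list(points = unname(b$points), radius = unname(b$radius)))
    jsonlite::write_json(list(branches = br), path, digits = NA, auto_unbox = TRUE)
  } else if (ext == "vtp") {
    pts <- do.call(rbind, lapply(tree$branches, function(b) b$points))
    rad <- unlist(lapply(tree$branches, function(b) b$radius))
    lens <- vapply(tree$branches, function(b) nrow(b$points), integer(1))
    offs <- cumsum(lens)
    conn <- seq_len(sum(lens)) - 1L
    con <- file(path, "w"); on.exit(close(con), add = TRUE)
    writeLines(c('<?xml version="1.0"?>',
                 '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">',
                 '  <PolyData>',
                 sprintf('    <Piece NumberOfPoints="%d" NumberOfLines="%d">', nrow(pts), length(lens)),
                 '      <PointData Scalars="radius">',
                 '        <DataArray type="Float64" Name="radius" format="ascii">'), con)
    writeLines(paste(rad, collapse = " "), con)
    writeLines(c('        </DataArray>', '      </PointData>', '      <Points>',
                 '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">'), con)
    writeLines(paste(t(pts), collapse = " "), con)
    writeLines(c('        </DataArray>', '      </Points>', '      <Lines>',
                 '        <DataArray type="Int64" Name="connectivity" format="ascii">'), con)
    writeLines(paste(conn, collapse = " "), con)
    writeLines(c('        </DataArray>',
                 '        <DataArray type="Int64" Name="offsets" format="ascii">'), con)
    writeLines(paste(offs, collapse = " "), con)
    writeLines(c('        </DataArray>', '      </Lines>', '    </Piece>',
                 '  </PolyData>', '</VTKFile>'), con)
  } else {
    vt_stop(sprintf("unsupported centerline format: .%s", ext), "vt_validation_error")
  }
  invisible(path)
}

#' @rdname write_centerline
#' @export
read_centerline <- function(path) {
  vt_validate(tolower(tools::file_ext(path)) == "json",
              "only the JSON centerline schema is read back")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  branches <- lapply(seq_len(if (is.data.frame(obj$branches)) nrow(obj$branches) else length(obj$branches)),
                     function(i) {
    b <- if (is.data.frame(obj$branches)) obj$branches[i, ] else obj$branches[[i]]
    pts <- b$points
    if (is.list(pts) && !is.matrix(pts)) pts <- do.call(rbind, pts)
    if (is.list(pts)) pts <- pts[[1]]
    list(points = matrix(as.numeric(pts), ncol = 3),
         radius = as.numeric(unlist(b$radius)))
  })
  centerline_tree(branches)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
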