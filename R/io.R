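# File interfaces: label volumes as multi-page uint16 TIFF or NRRD, meshes
# as PLY, morphometry/dynamics tables as CSV, phantom specs as JSON/YAML.

#' Write a labeled volume as a multi-page TIFF
#'
#' Pages run along z; labels are stored as 16-bit grayscale. TIFF carries no
#' spacing metadata, so [read_labels_tiff] takes the spacing explicitly.
#'
#' @param vol a [labeled_volume] (or integer/numeric 3D array).
#' @param path output path.
#' @export
write_labels_tiff <- function(vol, path) {
  v <- if (inherits(vol, "labeled_volume")) vol$voxels else vol
  mx <- max(1L, max(v))
  if (mx > 65535L) stop("labels exceed uint16 range")
  pages <- lapply(seq_len(dim(v)[1]),
                  function(z) v[z, , , drop = TRUE] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "deflate")
  invisible(path)
}

#' Read a labeled volume from a multi-page TIFF
#' @param path TIFF written by [write_labels_tiff].
#' @param spacing voxel spacing (dz, dy, dx), micrometres.
#' @param ... metadata forwarded to [labeled_volume].
#' @return a [labeled_volume].
#' @export
read_labels_tiff <- function(path, spacing, ...) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]]))
  v <- array(0L, d)
  for (z in seq_along(pages)) v[z, , ] <- as.integer(pages[[z]])
  labeled_volume(v, spacing, ...)
}

#' Write a volume as NRRD
#'
#' Minimal NRRD0004 writer: uint16 for label volumes, double for grayscale;
#' raw or gzip encoding; `space directions` carries the (x, y, z) spacing in
#' micrometres.
#'
#' @param vol a [labeled_volume] or numeric 3D array.
#' @param path output path.
#' @param spacing spacing when `vol` is a bare array.
#' @param encoding `"gzip"` or `"raw"`.
#' @export
write_nrrd <- function(vol, path, spacing = NULL, encoding = c("gzip", "raw")) {
  encoding <- match.arg(encoding)
  if (inherits(vol, "labeled_volume")) {
    spacing <- vol$spacing
    v <- vol$voxels
  } else {
    v <- vol
    if (is.null(spacing)) stop("spacing required for a bare array")
    spacing <- rep(as.numeric(spacing), length.out = 3)
  }
  is_int <- is.integer(v) || all(v == round(v))
  type <- if (is_int) "unsigned short" else "double"
  d <- dim(v)
  # NRRD is x-fastest; our arrays are z-fastest, so emit x-fastest order
  perm <- aperm(v, c(3, 2, 1))
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           "dimension: 3",
           "space: right-anterior-superior",
           paste0("sizes: ", d[3], " ", d[2], " ", d[1]),
           sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)",
                   spacing[3], spacing[2], spacing[1]),
           "endian: little",
           paste0("encoding: ", encoding),
           "")
  con <- file(path, "wb")
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  payload <- if (is_int) writeBin(as.integer(perm), raw(), size = 2,
                                  endian = "little")
             else writeBin(as.numeric(perm), raw(), size = 8,
                           endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, "gzip")
  writeBin(payload, con)
  close(con)
  invisible(path)
}

#' Read a NRRD volume
#' @param path NRRD file (3D, little-endian, raw or gzip encoding).
#' @param ... metadata forwarded to [labeled_volume] for integer types.
#' @return a [labeled_volume] for integer types, else a numeric array with
#'   attribute `spacing`.
#' @export
read_nrrd <- function(path, ...) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- character(0)
  repeat {
    line <- readLines(con, 1)
    if (length(line) == 0 || line == "") break
    hdr <- c(hdr, line)
  }
  get <- function(key) {
    hit <- grep(paste0("^", key, ":"), hdr, value = TRUE)
    if (length(hit) == 0) return(NULL)
    trimws(sub(paste0("^", key, ":"), "", hit[1]))
  }
  type <- get("type")
  sizes <- as.integer(strsplit(get("sizes"), "\\s+")[[1]])
  enc <- get("encoding")
  sd <- get("space directions")
  spacing <- c(1, 1, 1)
  if (!is.null(sd)) {
    nums <- regmatches(sd, gregexpr("-?[0-9.eE+]+", sd))[[1]]
    m <- matrix(as.numeric(nums), 3, 3, byrow = TRUE)
    spacing <- rev(sqrt(rowSums(m^2)))          # (dz, dy, dx)
  }
  payload <- readBin(con, "raw", n = file.size(path))
  if (identical(enc, "gzip")) payload <- memDecompress(payload, "gzip")
  n <- prod(sizes)
  int_types <- c("unsigned short", "uint16", "uint16_t", "short", "int",
                 "unsigned char", "uchar", "uint8")
  if (type %in% int_types) {
    size <- if (type %in% c("unsigned char", "uchar", "uint8")) 1 else 2
    v <- readBin(payload, "integer", n = n, size = size, signed = FALSE,
                 endian = "little")
  } else {
    size <- if (type %in% c("float")) 4 else 8
    v <- readBin(payload, "numeric", n = n, size = size, endian = "little")
  }
  arr <- aperm(array(v, sizes), c(3, 2, 1))     # back to (z, y, x)
  if (type %in% int_types) return(labeled_volume(arr, spacing, ...))
  attr(arr, "spacing") <- spacing
  arr
}

#' Write a mesh as ASCII PLY
#' @param mesh a [surface_mesh].
#' @param path output path.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nv),
               "property double x", "property double y", "property double z",
               paste("element face", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(formatC(mesh$vertices, digits = 17, format = "g"),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASCII PLY mesh
#' @param path PLY file with vertex x/y/z and triangular faces.
#' @return a [surface_mesh].
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  endh <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vtx <- do.call(rbind, lapply(lines[endh + seq_len(nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  fac <- do.call(rbind, lapply(lines[endh + nv + seq_len(nf)], function(l) {
    x <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    if (x[1] != 3L) stop("only triangular faces are supported")
    x[2:4] + 1L
  }))
  surface_mesh(vtx, fac)
}

#' Export a generated phantom unit to a directory
#'
#' Writes per-state label volumes (uint16 TIFF and NRRD), per-structure
#' meshes (PLY), the ground-truth tables (CSV) and a JSON sidecar echoing
#' the generating spec.
#'
#' @param unit a [generate_unit] result.
#' @param dir output directory (created if missing).
#' @param volumes also voxelize and write the label volumes.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(unit, dir, volumes = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (state in c("exp", "insp")) {
    meshes <- if (state == "exp") unit$meshes_exp else unit$meshes_insp
    for (m in meshes)
      write_ply(m, file.path(dir, sprintf("%s_%s.ply", state, m$id)))
    if (volumes) {
      vol <- phantom_volume(unit, if (state == "exp") "expiration"
                            else "inspiration")
      write_labels_tiff(vol, file.path(dir, paste0("labels_", state,
                                                   ".tiff")))
      write_nrrd(vol, file.path(dir, paste0("labels_", state, ".nrrd")))
    }
  }
  utils::write.csv(unit$truth$structures,
                   file.path(dir, "truth_structures.csv"), row.names = FALSE)
  utils::write.csv(unit$truth$unit, file.path(dir, "truth_unit.csv"),
                   row.names = FALSE)
  utils::write.csv(unit$truth$pairs, file.path(dir, "truth_pairs.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    c(unclass(unit$spec), list(q_true = unit$truth$q_true)),
    file.path(dir, "phantom_spec.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Build a phantom spec from a YAML config
#' @param path YAML file whose keys match [phantom_spec] arguments.
#' @return a [phantom_spec].
#' @export
phantom_spec_from_yaml <- function(path) {
  do.call(phantom_spec, yaml::read_yaml(path))
}
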