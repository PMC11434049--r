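# Labeled voxel volumes and mesh voxelization. Volumes are integer arrays
# with dim = c(nz, ny, nx) (axes ordered z, y, x, 0-based voxel indices on
# the C++ side); voxel centers sit at origin + (index + 0.5) * spacing.

#' Construct a labeled volume
#'
#' The segmentation product the pipeline consumes: 0 = tissue/background,
#' 1 = duct lumen, labels >= 2 = alveolar lumina.
#'
#' @param voxels integer 3D array, dim (nz, ny, nx).
#' @param spacing voxel spacing in micrometres, scalar or (dz, dy, dx).
#' @param state `"expiration"`, `"inspiration"` or `NA`.
#' @param condition list with entries `PEEP` and `IPP` (cm H2O).
#' @param origin physical position (z, y, x) of the corner of voxel
#'   (0, 0, 0), micrometres.
#' @return an object of class `labeled_volume`.
#' @export
labeled_volume <- function(voxels, spacing, state = NA_character_,
                           condition = list(PEEP = NA_real_, IPP = NA_real_),
                           origin = c(0, 0, 0)) {
  stopifnot(length(dim(voxels)) == 3)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing <= 0)) stop("spacing components must be positive")
  storage.mode(voxels) <- "integer"
  if (any(voxels < 0, na.rm = TRUE)) stop("labels must be non-negative")
  if (!is.na(state))
    state <- match.arg(state, c("expiration", "inspiration"))
  structure(list(voxels = voxels, spacing = spacing, state = state,
                 condition = condition, origin = as.numeric(origin)),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$voxels)
  labs <- setdiff(sort(unique(as.vector(x$voxels))), 0L)
  cat(sprintf(
    "<labeled_volume> %d x %d x %d (z,y,x) @ (%.3g, %.3g, %.3g) um, %d structure(s)%s\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], length(labs),
    if (!is.na(x$state)) paste0(", ", x$state) else ""))
  invisible(x)
}

#' Count voxels per label
#' @param vol a [labeled_volume].
#' @return named integer vector of voxel counts (foreground labels only).
#' @export
label_counts <- function(vol) {
  tab <- table(vol$voxels[vol$voxels > 0])
  stats::setNames(as.integer(tab), names(tab))
}

#' Voxelize closed meshes into a labeled volume
#'
#' Each voxel is assigned the label of the structure whose interior contains
#' its center (ray-parity test along x); the complement is background (0).
#' Meshes must be closed and pairwise interior-disjoint.
#'
#' @param meshes list of closed [surface_mesh] objects; labels are taken from
#'   the `label` attribute of each mesh if present, else assigned 1, 2, ...
#'   in list order.
#' @param spacing voxel spacing in micrometres (scalar or (dz, dy, dx)).
#' @param pad tissue margin added around the joint bounding box, micrometres.
#' @param bbox optional 2x3 matrix (rows = min, max; columns x, y, z)
#'   overriding the bounding box, micrometres.
#' @param min_voxels a structure resolved by fewer interior voxels than this
#'   triggers a degenerate-resolution error.
#' @param state,condition metadata forwarded to [labeled_volume].
#' @return a [labeled_volume]; its `origin` places the meshes' coordinates.
#' @export
voxelize <- function(meshes, spacing, pad = 3, bbox = NULL, min_voxels = 10,
                     state = NA_character_,
                     condition = list(PEEP = NA_real_, IPP = NA_real_)) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (length(meshes) == 0 && is.null(bbox)) {
    return(labeled_volume(array(0L, c(1, 1, 1)), spacing, state, condition))
  }
  if (is.null(bbox)) {
    allv <- do.call(rbind, lapply(meshes, function(m) m$vertices))
    bbox <- rbind(apply(allv, 2, min) - pad, apply(allv, 2, max) + pad)
  }
  # grid dims; spacing order (dz, dy, dx), bbox columns (x, y, z)
  ext <- bbox[2, ] - bbox[1, ]
  nx <- max(1L, ceiling(ext[1] / spacing[3]))
  ny <- max(1L, ceiling(ext[2] / spacing[2]))
  nz <- max(1L, ceiling(ext[3] / spacing[1]))
  dims <- c(nz, ny, nx)
  origin <- c(bbox[1, 3], bbox[1, 2], bbox[1, 1])  # (z, y, x)
  vox <- array(0L, dims)
  labs <- vapply(seq_along(meshes), function(i) {
    l <- attr(meshes[[i]], "label")
    if (is.null(l)) i else as.integer(l)
  }, integer(1))
  for (i in seq_along(meshes)) {
    m <- meshes[[i]]
    if (!mesh_is_closed(m)) stop("voxelize requires closed meshes")
    inside <- .cpp_voxelize_mesh(m$vertices, m$faces, as.integer(dims),
                                 spacing, origin)
    ncell <- sum(inside)
    if (ncell < min_voxels)
      stop(sprintf(
        "degenerate resolution: structure %s occupies %d voxel(s) (< %d) at spacing (%g, %g, %g)",
        ifelse(is.na(m$id), as.character(labs[i]), m$id), ncell, min_voxels,
        spacing[1], spacing[2], spacing[3]))
    if (any(vox[inside] != 0L))
      warning("overlapping mesh interiors: later mesh overwrites earlier label")
    vox[inside] <- labs[i]
  }
  labeled_volume(vox, spacing, state, condition, origin)
}

#' Render a labeled volume as a grayscale image
#'
#' Two-material model standing in for reconstructed phase-contrast slices:
#' air (any lumen label) maps to a low intensity, tissue to a high one, with
#' additive Gaussian noise. Deterministic for a given seed.
#'
#' @param vol a [labeled_volume].
#' @param noise_sd standard deviation of the additive noise, grayscale units.
#' @param seed integer RNG seed.
#' @param air,tissue the two mean intensities.
#' @return numeric 3D array with the dimensions of `vol$voxels`.
#' @export
render_grayscale <- function(vol, noise_sd = 0, seed = 1,
                             air = 50, tissue = 200) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  img <- array(ifelse(vol$voxels > 0L, air, tissue), dim(vol$voxels))
  if (noise_sd > 0) {
    img <- img + with_seed(seed, array(rnorm(length(img), 0, noise_sd),
                                       dim(img)))
  }
  img
}
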