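# Single-state morphometry: isosurface extraction from labels, the
# equivalent-sphere diameter, entrance-ring detection, thinnest septal wall
# thickness, inter-alveolar angles, and assembly of the gas-exchange-unit
# (AAD = alveoli + duct) record.

#' Extract a closed surface mesh for one label
#'
#' Marching-tetrahedra isosurface of the label's binary indicator at level
#' 0.5 after a mild Gaussian anti-aliasing of the indicator (sigma in
#' voxels). The smoothing acts on the sampled indicator, not the mesh;
#' without it binary isosurfaces carry a faceting bias of several percent in
#' surface area. The volume is padded so the surface always closes.
#'
#' @param vol a [labeled_volume].
#' @param id label to extract; `0` extracts the union of all foreground
#'   labels (the whole air space).
#' @param sigma Gaussian pre-smoothing SD in voxels; `0` disables it. The
#'   default 0.8 balances the faceting bias of raw binary isosurfaces
#'   against corner rounding of the smoothed field.
#' @param min_voxels degenerate-resolution guard.
#' @return a closed, outward-oriented [surface_mesh] in physical
#'   micrometres (the volume's coordinate frame).
#' @export
extract_mesh <- function(vol, id, sigma = 0.8, min_voxels = 10) {
  stopifnot(inherits(vol, "labeled_volume"))
  mask <- if (id == 0) vol$voxels > 0L else vol$voxels == as.integer(id)
  n <- sum(mask)
  if (n == 0) stop(sprintf("unknown label: %s not present in volume", id))
  if (n < min_voxels)
    stop(sprintf("degenerate resolution: label %s has %d voxel(s) (< %d)",
                 id, n, min_voxels))
  comp <- .cpp_label26(mask, as.integer(dim(mask)))
  ncomp <- max(comp)
  if (ncomp > 1) {
    sizes <- tabulate(comp[comp > 0], ncomp)
    if (max(sizes) < 0.99 * n)
      stop(sprintf("label %s is fragmented into %d components", id, ncomp))
    mask <- comp == which.max(sizes)    # stray voxels only: keep main body
  }
  # crop to the structure's bounding box before padding and smoothing
  idx <- which(mask) - 1L
  d0 <- dim(mask)
  zi <- idx %% d0[1]
  yi <- (idx %/% d0[1]) %% d0[2]
  xi <- idx %/% (d0[1] * d0[2])
  lo <- c(min(zi), min(yi), min(xi)) + 1L
  hi <- c(max(zi), max(yi), max(xi)) + 1L
  mask <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  pad <- max(4L, ceiling(3 * sigma) + 1L)
  dims <- dim(mask) + 2L * pad
  field <- array(0, dims)
  field[pad + seq_len(dim(mask)[1]), pad + seq_len(dim(mask)[2]),
        pad + seq_len(dim(mask)[3])] <- as.numeric(mask)
  if (sigma > 0)
    field <- .cpp_gauss3(field, as.integer(dims), sigma)
  origin <- vol$origin + (lo - 1L - pad) * vol$spacing   # (z, y, x)
  res <- .cpp_march_tets(field, as.integer(dims), 0.5, vol$spacing, origin)
  if (nrow(res$faces) == 0)
    stop(sprintf("manifold failure: no isosurface produced for label %s", id))
  mesh <- surface_mesh(res$vertices, res$faces, id = as.character(id))
  if (!mesh_is_closed(mesh))
    stop(sprintf("manifold failure: open surface extracted for label %s", id))
  mesh_orient_outward(mesh)
}

#' Equivalent spherical diameter from a volume
#'
#' `D_A = (6 V / pi)^(1/3)`, the diameter of the sphere with the same volume.
#'
#' @param V volume in cubic micrometres (> 0).
#' @return diameter in micrometres.
#' @export
equivalent_diameter <- function(V) {
  if (any(V <= 0)) stop("V must be positive")
  (6 * V / pi)^(1 / 3)
}

#' Detect the entrance ring of an alveolus
#'
#' The aperture between an alveolar lumen and its duct: alveolar voxels
#' 26-adjacent to duct voxels define the mouth patch; a plane is fitted to
#' it (principal components), the patch is projected, and the ring is the
#' convex boundary loop offset outward by half a voxel (compensating the
#' half-voxel shrinkage of voxel-center sampling). The ring closes the
#' alveolus for volume purposes; its area is excluded from the membrane
#' surface.
#'
#' @param vol a [labeled_volume].
#' @param alveolus_id alveolar label.
#' @param duct_id duct label (default 1).
#' @return an object of class `entrance_ring`: `loop` (closed polyline,
#'   physical micrometres, first row repeated last), `perimeter`,
#'   `area`, `center`, `normal` (unit, pointing from alveolus into duct),
#'   `planarity` (max residual), `alveolus_id`.
#' @export
detect_entrance_ring <- function(vol, alveolus_id, duct_id = 1,
                                 n_bins = 24) {
  v <- vol$voxels
  dims <- dim(v)
  sp <- mean(vol$spacing)
  # 6-adjacency on both sides of the aperture: the open air-air interface
  # between alveolar and duct lumen (diagonal adjacency would leak around
  # one-voxel-thin tissue at the rim)
  adj6 <- function(src) {
    acc <- array(FALSE, dims)
    for (ax in 1:3) for (by in c(-1, 1)) {
      n <- dims[ax]
      ia <- if (by > 0) 2:n else 1:(n - 1)
      ib <- if (by > 0) 1:(n - 1) else 2:n
      if (ax == 1) acc[ia, , ] <- acc[ia, , ] | src[ib, , ]
      else if (ax == 2) acc[, ia, ] <- acc[, ia, ] | src[, ib, ]
      else acc[, , ia] <- acc[, , ia] | src[, , ib]
    }
    acc
  }
  isduct <- v == as.integer(duct_id)
  isalv <- v == as.integer(alveolus_id)
  patch_a <- adj6(isduct) & isalv          # alveolar side of the interface
  patch_d <- adj6(isalv) & isduct          # duct side
  if (!any(patch_a))
    stop(sprintf("alveolus %s is not attached to duct %s",
                 alveolus_id, duct_id))
  # multiple disjoint apertures: keep the largest interface component
  un <- patch_a | patch_d
  pc <- .cpp_label26(un, as.integer(dims))
  npc <- max(pc)
  if (npc > 1) {
    sizes <- tabulate(pc[pc > 0], npc)
    if (sum(sizes > max(3, 0.05 * max(sizes))) > 1)
      warning(sprintf(
        "alveolus %s has multiple disjoint apertures; keeping largest",
        alveolus_id))
    keepc <- which.max(sizes)
    patch_a <- patch_a & pc == keepc
    patch_d <- patch_d & pc == keepc
  }
  coords <- function(mask) {
    w <- which(mask, arr.ind = TRUE)
    cbind(vol$origin[3] + (w[, 3] - 0.5) * vol$spacing[3],
          vol$origin[2] + (w[, 2] - 0.5) * vol$spacing[2],
          vol$origin[1] + (w[, 1] - 0.5) * vol$spacing[1])
  }
  pa <- coords(patch_a)
  pu <- rbind(pa, coords(patch_d))
  # mouth plane: principal plane of the two-sided interface; the two voxel
  # layers straddle the true aperture plane symmetrically
  ctr <- colMeans(pu)
  cc <- sweep(pu, 2, ctr)
  eg <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  normal <- eg$vectors[, 3]
  duct_idx <- which(isduct, arr.ind = TRUE)
  dctr <- c(
    vol$origin[3] + (mean(duct_idx[, 3]) - 0.5) * vol$spacing[3],
    vol$origin[2] + (mean(duct_idx[, 2]) - 0.5) * vol$spacing[2],
    vol$origin[1] + (mean(duct_idx[, 1]) - 0.5) * vol$spacing[1])
  if (sum(normal * (dctr - ctr)) < 0) normal <- -normal
  e1 <- eg$vectors[, 1]; e2 <- eg$vectors[, 2]

  # The lumen cross-section flares with height above the mouth plane (the
  # wall of a cup-shaped alveolus leans outward), so the first voxel layer
  # overshoots the rim. Per angular bin, the outermost radius is measured
  # in the two layers nearest the plane and extrapolated linearly to h = 0.
  aw <- which(isalv, arr.ind = TRUE)
  pall <- cbind(vol$origin[3] + (aw[, 3] - 0.5) * vol$spacing[3],
                vol$origin[2] + (aw[, 2] - 0.5) * vol$spacing[2],
                vol$origin[1] + (aw[, 1] - 0.5) * vol$spacing[1])
  hh <- as.vector(sweep(pall, 2, ctr) %*% (-normal))   # height into alveolus
  # Just outside the rim the tissue wedge between the alveolar wall and the
  # duct face thins below one voxel and stops being sampled, so the first
  # voxel layer above the plane leaks beyond the rim and carries no usable
  # rim information; the flare is sampled in the layers above it, which lie
  # genuinely inside the lumen, and extrapolated down to h = 0
  sel <- hh > 1.0 * sp & hh <= 3.5 * sp
  ps <- pall[sel, , drop = FALSE]; hs <- hh[sel]
  uv <- sweep(ps, 2, ctr) %*% cbind(e1, e2)
  rho <- sqrt(rowSums(uv^2))
  ang <- atan2(uv[, 2], uv[, 1])
  bin <- pmin(n_bins, 1L + floor((ang + pi) / (2 * pi) * n_bins))
  stratum <- ifelse(hs <= 2.0 * sp, 1L, 2L)
  # wall flare: one pooled slope (median of per-bin two-layer slopes) keeps
  # the per-bin extrapolation from amplifying max-radius sampling noise
  r1 <- h1 <- r2 <- h2 <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    i1 <- which(bin == b & stratum == 1L)
    i2 <- which(bin == b & stratum == 2L)
    if (length(i1) > 0) {
      j1 <- i1[which.max(rho[i1])]
      r1[b] <- rho[j1]; h1[b] <- hs[j1]
    }
    if (length(i2) > 0) {
      j2 <- i2[which.max(rho[i2])]
      r2[b] <- rho[j2]; h2[b] <- hs[j2]
    }
  }
  # wall-model dichotomy, decided by the measured radial flare between the
  # two layers: cup-shaped (spherical-cap) walls satisfy
  # rho^2 + h^2 = a^2 + 2 c h, linear in h, so extrapolating
  # y = rho^2 + h^2 to h = 0 recovers the rim radius exactly; straight
  # (cylindrical/box) walls have no flare and the first reliable layer
  # already sits at the rim radius
  flare <- (r2 - r1) / (h2 - h1)
  flare <- flare[is.finite(flare)]
  straight <- length(flare) >= 3 && stats::median(flare) < 0.15
  if (straight) {
    a_b <- ifelse(!is.na(r1), r1, r2)
  } else {
    y1 <- r1^2 + h1^2; y2 <- r2^2 + h2^2
    sl <- (y2 - y1) / (h2 - h1)
    sl <- sl[is.finite(sl)]
    slope <- if (length(sl) >= 3) max(stats::median(sl), 0) else 0
    a_b <- ifelse(!is.na(y1), sqrt(pmax(y1 - slope * h1, 0)),
                  ifelse(!is.na(y2), sqrt(pmax(y2 - slope * h2, 0)),
                         NA_real_))
  }
  ok <- which(!is.na(a_b))
  if (length(ok) < 3)
    stop(sprintf("aperture of alveolus %s too small to trace a ring",
                 alveolus_id))
  a_b[-ok] <- stats::approx(ok, a_b[ok], xout = seq_len(n_bins)[-ok],
                            rule = 2)$y
  a_b <- a_b + sp / 6       # binned max-radius sampling undershoot
  # circular moving average over bins: bin-level sampling jitter would
  # otherwise lengthen the polygon (a jagged ring reads as a longer rim)
  w <- c(1, 2, 3, 2, 1); w <- w / sum(w)
  a_b <- vapply(seq_len(n_bins), function(b) {
    sum(w * a_b[((b - 3 + seq_along(w) - 1) %% n_bins) + 1])
  }, numeric(1))

  # scale from slab volumes: the lumen volume between two heights is a
  # linear function of the aperture area and the flare, and voxel counts
  # average the boundary-sampling noise that per-bin maxima amplify.
  # Vol(ha, hb) = pi [ a^2 w + c (hb^2 - ha^2) - (hb^3 - ha^3)/3 ]
  voxvol <- prod(vol$spacing)
  hh_a <- hh[hh > 0]
  slab <- cbind(1:4, 2:5) * sp
  M <- matrix(0, 4, 2); rhs <- numeric(4)
  for (i in 1:4) {
    ha <- slab[i, 1]; hb <- slab[i, 2]
    cnt <- sum(hh_a > ha & hh_a <= hb)
    M[i, ] <- c(hb - ha, hb^2 - ha^2)
    rhs[i] <- cnt * voxvol / pi +
      if (straight) 0 else (hb^3 - ha^3) / 3
  }
  fit <- tryCatch(qr.solve(M, rhs), error = function(e) NULL)
  a_fit2 <- if (!is.null(fit) && fit[1] > 0 && fit[2] >= 0) fit[1] else NA

  th <- (seq_len(n_bins) - 0.5) * 2 * pi / n_bins - pi
  poly <- cbind(a_b * cos(th), a_b * sin(th))
  parea <- abs(sum(poly[, 1] * c(poly[-1, 2], poly[1, 2]) -
                   c(poly[-1, 1], poly[1, 1]) * poly[, 2])) / 2
  if (!is.na(a_fit2) && parea > 0)
    poly <- poly * sqrt(pi * a_fit2 / parea)   # pin area, keep shape
  loop3 <- sweep(poly[, 1] %o% e1 + poly[, 2] %o% e2, 2, ctr, "+")
  loop3 <- rbind(loop3, loop3[1, , drop = FALSE])
  seglen <- sqrt(rowSums(diff(loop3)^2))
  area <- abs(sum(poly[, 1] * c(poly[-1, 2], poly[1, 2]) -
                  c(poly[-1, 1], poly[1, 1]) * poly[, 2])) / 2
  pl <- sweep(pu, 2, ctr) %*% normal
  structure(list(loop = loop3, perimeter = sum(seglen), area = area,
                 center = ctr, normal = normal,
                 planarity = max(abs(pl)),
                 alveolus_id = as.character(alveolus_id)),
            class = "entrance_ring")
}

#' @export
print.entrance_ring <- function(x, ...) {
  cat(sprintf(
    "<entrance_ring> alveolus %s: perimeter %.2f um, area %.2f um^2\n",
    x$alveolus_id, x$perimeter, x$area))
  invisible(x)
}

#' Thinnest septal wall thickness of an alveolus
#'
#' The tissue mask is partitioned by the Euclidean feature transform of the
#' air labels; ridge voxels where the partition cell of the alveolus meets
#' the cell of another permitted air region carry twice the distance-to-air
#' as the local septal thickness, and `T_A` is its minimum (corrected by one
#' voxel for the center-to-center measurement). The duct aperture is not a
#' septum, so the duct label is excluded by default.
#'
#' @param vol a [labeled_volume].
#' @param alveolus_id alveolar label.
#' @param exclude labels never counted as septal partners (default: duct
#'   label 1).
#' @param edt optional precomputed feature transform of `vol$voxels`
#'   (internal reuse across structures).
#' @return thickness in micrometres.
#' @export
wall_thickness <- function(vol, alveolus_id, exclude = 1L, edt = NULL) {
  v <- vol$voxels
  dims <- dim(v)
  id <- as.integer(alveolus_id)
  if (!any(v == id)) stop(sprintf("unknown label: %s", alveolus_id))
  if (is.null(edt))
    edt <- .cpp_feature_edt(v, as.integer(dims), vol$spacing)
  nearest <- edt$nearest
  tissue <- v == 0L
  partners <- setdiff(setdiff(sort(unique(as.vector(v))), 0L),
                      c(id, as.integer(exclude)))
  if (length(partners) == 0)
    stop(sprintf("wall thickness undefined: alveolus %s has no septal partner",
                 alveolus_id))
  npart <- array(nearest, dims)
  npart[!tissue] <- -1L                   # restrict the partition to tissue
  # ridge pairs: adjacent tissue voxels whose partition cells belong to the
  # alveolus and to a permitted partner; the septal thickness through the
  # pair is the sum of the two distances-to-air (one voxel is subtracted for
  # the center-to-center measurement). Using the pair sum rather than twice
  # one distance keeps asymmetric ridge points (near triple junctions with
  # the duct cell) from underestimating the septum.
  d <- edt$distance
  base <- npart == id
  tmin <- Inf
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    sz <- dims[1]; sy <- dims[2]; sx <- dims[3]
    iz <- seq_len(sz); iy <- seq_len(sy); ix <- seq_len(sx)
    az <- iz[(iz + dz) >= 1 & (iz + dz) <= sz]
    ay <- iy[(iy + dy) >= 1 & (iy + dy) <= sy]
    ax <- ix[(ix + dx) >= 1 & (ix + dx) <= sx]
    nb_part <- npart[az + dz, ay + dy, ax + dx, drop = FALSE]
    ok <- base[az, ay, ax, drop = FALSE] &
      array(nb_part %in% partners, dim(nb_part))
    if (!any(ok)) next
    step <- sqrt(sum((c(dz, dy, dx) * vol$spacing)^2))
    tot <- d[az, ay, ax, drop = FALSE][ok] +
      d[az + dz, ay + dy, ax + dx, drop = FALSE][ok] + step
    tmin <- min(tmin, min(tot))
  }
  if (!is.finite(tmin))
    stop(sprintf(
      "wall thickness undefined: no tissue ridge between alveolus %s and labels {%s}",
      alveolus_id, paste(partners, collapse = ",")))
  max(tmin - mean(vol$spacing), mean(vol$spacing))
}

#' Angle between two neighboring alveoli
#'
#' Theta is measured at the midpoint of the two mouth-plane centers, between
#' the rays pointing to the two lumen centroids; reported in degrees in
#' \[0, 180\]. Scale- and rigid-motion-invariant.
#'
#' @param a,b morphometry records (single rows with `cx, cy, cz`) or length-3
#'   centroid vectors.
#' @param ring_a,ring_b the matching [detect_entrance_ring] results (or
#'   length-3 mouth centers).
#' @return angle in degrees.
#' @export
angle_between_alveoli <- function(a, b, ring_a, ring_b) {
  cen <- function(x) {
    if (is.data.frame(x)) c(x$cx, x$cy, x$cz) else as.numeric(x)
  }
  mc <- function(x) if (inherits(x, "entrance_ring")) x$center else
    as.numeric(x)
  ca <- cen(a); cb <- cen(b)
  vertex <- (mc(ring_a) + mc(ring_b)) / 2
  u1 <- ca - vertex; u2 <- cb - vertex
  n1 <- sqrt(sum(u1^2)); n2 <- sqrt(sum(u2^2))
  if (n1 == 0 || n2 == 0 || all(ca == cb))
    stop("degenerate angle: coincident centroids or centroid at vertex")
  acos(pmin(1, pmax(-1, sum(u1 * u2) / (n1 * n2)))) * 180 / pi
}

#' Measure every structure in a labeled volume
#'
#' Runs mesh extraction and all single-state measures for each label,
#' producing one morphometry record per structure plus (optionally) the
#' whole gas-exchange-unit record measured on the union air space.
#'
#' For alveoli, `S_um2` is the membrane area (total boundary minus the
#' entrance-ring aperture area); `S_total_um2` keeps the raw closed-mesh
#' area. The duct row reports its total boundary area.
#'
#' @param vol a [labeled_volume].
#' @param duct_id duct label (see [duct_label]).
#' @param rings,walls compute entrance rings / wall thicknesses for alveoli.
#' @param unit append a `unit_AAD` row for the whole gas-exchange unit.
#' @param unit_method `"assembled"` sums the per-structure meshes via
#'   [assemble_unit] (exact when the aperture label boundaries are planar,
#'   as in generator-truth labels); `"union"` measures one isosurface of the
#'   union air mask (robust to the irregular instance boundaries a
#'   watershed split produces, and therefore the right choice downstream of
#'   [split_instances]).
#' @param sigma smoothing passed to [extract_mesh].
#' @return data.frame of morphometry records; attribute `rings` holds the
#'   [detect_entrance_ring] objects keyed by structure id.
#' @export
measure_structures <- function(vol, duct_id = NULL, rings = TRUE,
                               walls = TRUE, unit = TRUE,
                               unit_method = c("assembled", "union"),
                               sigma = 0.8) {
  unit_method <- match.arg(unit_method)
  labs <- setdiff(sort(unique(as.vector(vol$voxels))), 0L)
  if (length(labs) == 0) stop("no structure: volume has no labels")
  if (is.null(duct_id)) duct_id <- duct_label(vol)
  edt <- if (walls && length(labs) > 2)
    .cpp_feature_edt(vol$voxels, as.integer(dim(vol$voxels)), vol$spacing)
  else NULL
  ringlist <- list()
  rows <- lapply(labs, function(id) {
    mesh <- extract_mesh(vol, id, sigma = sigma)
    V <- mesh_volume(mesh, check = FALSE)
    S <- mesh_area(mesh)
    ctr <- mesh_centroid(mesh)
    role <- if (id == duct_id) "duct" else "alveolus"
    rp <- NA_real_; ra <- NA_real_; ta <- NA_real_
    if (role == "alveolus" && rings) {
      ring <- tryCatch(detect_entrance_ring(vol, id, duct_id),
                       error = function(e) NULL)
      if (!is.null(ring)) {
        ringlist[[as.character(id)]] <<- ring
        rp <- ring$perimeter; ra <- ring$area
      }
    }
    if (role == "alveolus" && walls && length(labs) > 2) {
      ta <- tryCatch(wall_thickness(vol, id, exclude = duct_id, edt = edt),
                     error = function(e) NA_real_)
    }
    data.frame(structure_id = as.character(id), role = role,
               state = vol$state,
               PEEP = vol$condition$PEEP, IPP = vol$condition$IPP,
               V_um3 = V,
               S_um2 = if (role == "alveolus" && !is.na(ra)) S - ra else S,
               S_total_um2 = S,
               D_A_um = equivalent_diameter(V), T_A_um = ta,
               ring_perimeter_um = rp, ring_area_um2 = ra,
               cx = ctr[1], cy = ctr[2], cz = ctr[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (unit) {
    if (unit_method == "assembled") {
      # per-structure masks have no sub-voxel tissue crevices at the
      # aperture rims, so the assembled S_AAD avoids the thin-feature loss
      # a union-mask isosurface suffers
      alv <- out[out$role == "alveolus" & !is.na(out$ring_area_um2), ,
                 drop = FALSE]
      urow <- assemble_unit(alv, out[out$role == "duct", , drop = FALSE])
    } else {
      um <- extract_mesh(vol, 0, sigma = sigma)
      V <- mesh_volume(um, check = FALSE)
      ctr <- mesh_centroid(um)
      urow <- data.frame(
        structure_id = "unit", role = "unit_AAD", state = vol$state,
        PEEP = vol$condition$PEEP, IPP = vol$condition$IPP,
        V_um3 = V, S_um2 = mesh_area(um), S_total_um2 = mesh_area(um),
        D_A_um = equivalent_diameter(V), T_A_um = NA_real_,
        ring_perimeter_um = NA_real_, ring_area_um2 = NA_real_,
        cx = ctr[1], cy = ctr[2], cz = ctr[3], stringsAsFactors = FALSE)
    }
    out <- rbind(out, urow)
  }
  attr(out, "rings") <- ringlist
  out
}

#' Assemble the gas-exchange-unit record from its parts
#'
#' `V_AAD` is the sum of the duct and alveolar volumes (the aperture caps
#' cancel between duct and alveolus); `S_AAD` is the external surface of the
#' union: the duct's total boundary minus each aperture disk, plus each
#' alveolar membrane.
#'
#' @param alveoli data.frame of alveolar morphometry records (rows with
#'   `role == "alveolus"`; `ring_area_um2` must be present for the aperture
#'   correction).
#' @param duct single duct morphometry record.
#' @return a one-row `unit_AAD` morphometry record.
#' @export
assemble_unit <- function(alveoli, duct) {
  stopifnot(nrow(duct) == 1, duct$role == "duct")
  if (nrow(alveoli) > 0) {
    stopifnot(all(alveoli$role == "alveolus"))
    if (any(is.na(alveoli$ring_perimeter_um)))
      stop(sprintf("alveolus %s is not attached to the duct (no ring)",
                   alveoli$structure_id[which(
                     is.na(alveoli$ring_perimeter_um))[1]]))
  }
  V <- duct$V_um3 + sum(alveoli$V_um3)
  S <- duct$S_total_um2 - sum(alveoli$ring_area_um2) + sum(alveoli$S_um2)
  data.frame(structure_id = "unit", role = "unit_AAD", state = duct$state,
             PEEP = duct$PEEP, IPP = duct$IPP,
             V_um3 = V, S_um2 = S, S_total_um2 = S,
             D_A_um = equivalent_diameter(V), T_A_um = NA_real_,
             ring_perimeter_um = NA_real_, ring_area_um2 = NA_real_,
             cx = NA_real_, cy = NA_real_, cz = NA_real_,
             stringsAsFactors = FALSE)
}
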