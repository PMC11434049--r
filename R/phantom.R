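# Synthetic gas-exchange-unit phantoms: an alveolar duct with attached
# cup-shaped alveoli, generated in two respiratory states with closed-form
# ground truth for every measured quantity.
#
# Geometry. The duct lumen is a right regular N-gonal prism (apothem R_d,
# length L along z, flat ends). Each alveolus is a spherical-cap lumen of
# sphere radius r whose planar mouth disk (radius a = r sin(alpha),
# sin(alpha) = mouth_fraction) lies flush in one prism face, so the aperture
# is genuinely open into the duct while volume, surface, ring perimeter,
# centroid and inter-alveolar angle all stay closed-form.

#' Parameterize a synthetic gas-exchange unit
#'
#' Defaults describe a murine-scale unit: alveolar equivalent diameters in
#' the 50-100 um range, a duct carrying roughly 40% of the unit volume, and
#' imaging at 0.65 um isotropic voxels.
#'
#' @param duct_radius duct apothem (axis to face midline), micrometres.
#' @param duct_length duct length, micrometres; `NULL` derives it from
#'   `duct_volume_fraction` and the sampled alveolar volumes.
#' @param n_alveoli number of alveoli attached to the duct (>= 1).
#' @param alveolar_radius mean alveolar sphere radius, micrometres.
#' @param alveolar_dispersion fractional SD of alveolar radii (truncated at
#'   1.5 SD).
#' @param mouth_fraction aperture radius / alveolar radius, in (0, 1).
#' @param placement_seed integer seed for radii and mouth placement.
#' @param deformation_mode `"isotropic"`, `"alveolus_dominant"` or
#'   `"duct_dominant"`.
#' @param volume_ratio target whole-unit V_insp / V_exp (> 1).
#' @param voxel_spacing voxel spacing for rendering, micrometres.
#' @param noise_sd grayscale noise SD used by [render_grayscale].
#' @param n_duct_faces number of prism faces (one alveolus mouth per face
#'   position; several alveoli may share a face at different heights).
#' @param duct_volume_fraction duct share of the unit volume used when
#'   `duct_length` is `NULL`.
#' @param minor_scale fraction of the isotropic linear strain assigned to
#'   the non-dominant compartment in the anisotropic modes.
#' @param min_septum minimum tissue gap enforced between alveolar spheres,
#'   micrometres.
#' @param neighbor_gap_frac two alveoli are "neighbors" (theta is tracked)
#'   when their expiratory septal gap is below this fraction of r_i + r_j.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(duct_radius = 40, duct_length = NULL, n_alveoli = 8,
                         alveolar_radius = 30, alveolar_dispersion = 0.15,
                         mouth_fraction = 0.4, placement_seed = 1,
                         deformation_mode = c("isotropic", "alveolus_dominant",
                                              "duct_dominant"),
                         volume_ratio = 1.5, voxel_spacing = 0.65,
                         noise_sd = 0, n_duct_faces = 6,
                         duct_volume_fraction = 0.4, minor_scale = 0.3,
                         min_septum = 2.5, neighbor_gap_frac = 0.35) {
  deformation_mode <- match.arg(deformation_mode)
  stopifnot(duct_radius > 0, alveolar_radius > 0, n_alveoli >= 1,
            mouth_fraction > 0, mouth_fraction < 1, volume_ratio > 1,
            voxel_spacing > 0, noise_sd >= 0, n_duct_faces >= 3,
            duct_volume_fraction > 0, duct_volume_fraction < 1,
            minor_scale >= 0, minor_scale < 1, min_septum > 0,
            alveolar_dispersion >= 0)
  if (!is.null(duct_length)) stopifnot(duct_length > 0)
  structure(list(
    duct_radius = duct_radius, duct_length = duct_length,
    n_alveoli = as.integer(n_alveoli), alveolar_radius = alveolar_radius,
    alveolar_dispersion = alveolar_dispersion,
    mouth_fraction = mouth_fraction,
    placement_seed = as.integer(placement_seed),
    deformation_mode = deformation_mode, volume_ratio = volume_ratio,
    voxel_spacing = voxel_spacing, noise_sd = noise_sd,
    n_duct_faces = as.integer(n_duct_faces),
    duct_volume_fraction = duct_volume_fraction, minor_scale = minor_scale,
    min_septum = min_septum, neighbor_gap_frac = neighbor_gap_frac),
    class = "phantom_spec")
}

# linear scale factors (duct, alveoli) per state for a given mode
deformation_scales <- function(mode, volume_ratio, V_duct, V_alv_total,
                               minor_scale) {
  s <- volume_ratio^(1 / 3)
  V_tot <- V_duct + V_alv_total
  if (mode == "isotropic") return(list(s_d = s, s_a = s))
  if (mode == "alveolus_dominant") {
    s_d <- 1 + minor_scale * (s - 1)
    cube <- (volume_ratio * V_tot - s_d^3 * V_duct) / V_alv_total
    if (cube <= 0) stop("infeasible deformation split (alveolus_dominant)")
    return(list(s_d = s_d, s_a = cube^(1 / 3)))
  }
  s_a <- 1 + minor_scale * (s - 1)
  cube <- (volume_ratio * V_tot - s_a^3 * V_alv_total) / V_duct
  if (cube <= 0) stop("infeasible deformation split (duct_dominant)")
  list(s_d = cube^(1 / 3), s_a = s_a)
}

# duct closed forms: apothem R, length L, N faces
duct_volume_cf <- function(R, L, N) N * R^2 * tan(pi / N) * L
duct_area_cf <- function(R, L, N)
  2 * N * R * tan(pi / N) * L + 2 * N * R^2 * tan(pi / N)

# Euclidean projection onto a cap solid (ball o halfspace intersection) by
# Dykstra's alternating projections; both sets convex, so this is exact in
# the limit and well inside 1e-9 after a few dozen sweeps
project_cap <- function(x, c0, r, m, n) {
  p <- x
  y1 <- y2 <- c(0, 0, 0)
  for (it in 1:60) {
    z <- p + y1
    d <- sum((z - m) * n)
    p <- if (d >= 0) z else z - d * n
    y1 <- z - p
    z <- p + y2
    dc <- sqrt(sum((z - c0)^2))
    p <- if (dc <= r) z else c0 + (z - c0) * (r / dc)
    y2 <- z - p
  }
  p
}

# minimal distance between two spherical-cap lumina (0 if they touch)
cap_pair_distance <- function(cA, rA, mA, nA, cB, rB, mB, nB) {
  q <- cB
  p <- project_cap(q, cA, rA, mA, nA)
  for (it in 1:80) {
    q <- project_cap(p, cB, rB, mB, nB)
    p <- project_cap(q, cA, rA, mA, nA)
  }
  sqrt(sum((p - q)^2))
}

#' Generate a two-state synthetic gas-exchange unit
#'
#' Places `n_alveoli` spherical-cap alveoli with open circular mouths on the
#' faces of a prismatic duct by rejection sampling, derives the inspiration
#' state by the mode-specific deformation, and computes the full ground-truth
#' morphometry analytically from the generating parameters (never from the
#' meshes).
#'
#' @param spec a [phantom_spec].
#' @param max_attempts placement attempts per alveolus before a
#'   placement-failure error is raised.
#' @return an object of class `phantom_unit`: a list with `meshes_exp` and
#'   `meshes_insp` (lists of closed [surface_mesh], `label` attribute 1 for
#'   the duct and 2... for alveoli), `truth` (see Details) and `spec`.
#'
#' @details `truth$structures` holds one row per structure and state with
#'   true V (um^3), S (um^2; membrane area for alveoli, total boundary for
#'   the duct), D_A, ring perimeter/area, thinnest inter-alveolar wall and
#'   centroid; `truth$unit` the per-state V_AAD, S_AAD and k plus `q_true`;
#'   `truth$pairs` theta at both states and `d_theta_true` per neighboring
#'   pair; `truth$scales` the linear scale factors applied to duct and
#'   alveoli.
#' @export
generate_unit <- function(spec, max_attempts = 10000) {
  stopifnot(inherits(spec, "phantom_spec"))
  N <- spec$n_duct_faces
  Rd <- spec$duct_radius
  alpha <- asin(spec$mouth_fraction)
  m_edge <- max(1, spec$voxel_spacing * 2)   # mouth-to-face-edge margin, um
  m_mouth <- 2                               # mouth-to-mouth margin, um

  res <- with_seed(spec$placement_seed, {
    # alveolar radii: truncated-normal dispersion around the mean
    r <- vapply(seq_len(spec$n_alveoli), function(i) {
      z <- rnorm(1)
      while (abs(z) > 1.5) z <- rnorm(1)
      spec$alveolar_radius * (1 + spec$alveolar_dispersion * z)
    }, numeric(1))
    a <- r * sin(alpha)

    V_alv <- cap_volume(r, alpha)
    L <- spec$duct_length
    if (is.null(L)) {
      f <- spec$duct_volume_fraction
      L <- (f / (1 - f)) * sum(V_alv) / (N * Rd^2 * tan(pi / N))
    }
    V_duct <- duct_volume_cf(Rd, L, N)
    sc <- deformation_scales(spec$deformation_mode, spec$volume_ratio,
                             V_duct, sum(V_alv), spec$minor_scale)

    w2 <- Rd * tan(pi / N)                   # face half-width
    # faces are rotated off the lattice axes: real lungs have no
    # lattice-aligned septa, and an axis-aligned mouth plane would make its
    # sub-voxel position (hence the rim radius) unidentifiable from labels
    phis <- seq_len(N) * 2 * pi / N + pi / 18
    nhat <- cbind(cos(phis), sin(phis), 0)
    that <- cbind(-sin(phis), cos(phis), 0)

    place <- matrix(NA_real_, spec$n_alveoli, 3)  # face, u, z
    centers_of <- function(sd, sa) {
      t(vapply(seq_len(spec$n_alveoli), function(i) {
        fc <- place[i, 1]
        sd * (Rd * nhat[fc, ] + place[i, 2] * that[fc, ] +
                c(0, 0, place[i, 3])) + sa * r[i] * cos(alpha) * nhat[fc, ]
      }, numeric(3)))
    }
    ok_state <- function(i, sd, sa) {
      fc <- place[i, 1]
      ai <- sa * a[i]
      if (abs(sd * place[i, 2]) + ai + m_edge > sd * w2) return(FALSE)
      zi <- sd * place[i, 3]
      if (zi < ai + m_edge || zi > sd * L - ai - m_edge) return(FALSE)
      others <- setdiff(which(!is.na(place[, 1])), i)
      if (length(others) == 0) return(TRUE)
      cen <- centers_of(sd, sa)
      for (j in others) {
        if (place[j, 1] == fc) {
          du <- sd * (place[i, 2] - place[j, 2])
          dz <- sd * (place[i, 3] - place[j, 3])
          if (sqrt(du^2 + dz^2) < ai + sa * a[j] + m_mouth) return(FALSE)
        }
        if (sqrt(sum((cen[i, ] - cen[j, ])^2)) <
            sa * (r[i] + r[j]) + spec$min_septum) return(FALSE)
      }
      TRUE
    }
    # feasible mouth-center band on a face, over both states
    u_max <- pmin(w2 - a - m_edge,
                  (sc$s_d * w2 - sc$s_a * a - m_edge) / sc$s_d)
    z_min <- pmax(a + m_edge, (sc$s_a * a + m_edge) / sc$s_d)
    if (any(u_max < 0) || any(z_min > L - z_min))
      stop(sprintf(
        "phantom placement failure: an alveolar mouth does not fit a duct face (placement_seed = %d, n_alveoli = %d)",
        spec$placement_seed, spec$n_alveoli))
    # sequential rejection sampling with whole-placement restarts on dead
    # ends; the total attempt budget is max_attempts, never a silent
    # reduction of n_alveoli
    budget <- max_attempts * spec$n_alveoli
    done <- FALSE
    while (!done && budget > 0) {
      place[] <- NA_real_
      done <- TRUE
      for (i in order(-r)) {          # pack the largest alveoli first
        placed <- FALSE
        while (budget > 0) {
          budget <- budget - 1
          place[i, ] <- c(sample.int(N, 1),
                          runif(1, -u_max[i], u_max[i]),
                          runif(1, z_min[i], L - z_min[i]))
          if (ok_state(i, 1, 1) && ok_state(i, sc$s_d, sc$s_a)) {
            placed <- TRUE
            break
          }
          if (budget %% 500 == 0) break     # dead end: restart placement
        }
        if (!placed) { done <- FALSE; break }
      }
    }
    if (!done)
      stop(sprintf(
        "phantom placement failure: %d alveoli could not be placed in %d attempts (placement_seed = %d)",
        spec$n_alveoli, max_attempts, spec$placement_seed))
    list(r = r, a = a, L = L, sc = sc, place = place, nhat = nhat,
         that = that, w2 = w2, V_duct = V_duct, V_alv = V_alv)
  })

  r <- res$r; a <- res$a; L <- res$L; sc <- res$sc; place <- res$place
  nhat <- res$nhat

  build_state <- function(sd, sa, state) {
    edge <- spec$voxel_spacing
    duct <- prism_mesh(sd * Rd, sd * L, N, edge = max(edge * 4, sd * Rd / 8),
                       azimuth = pi / 18)
    duct$id <- "1"; duct$role <- "duct"
    attr(duct, "label") <- 1L
    meshes <- list(duct)
    for (i in seq_len(spec$n_alveoli)) {
      fc <- place[i, 1]
      mouth <- sd * (Rd * nhat[fc, ] + place[i, 2] * res$that[fc, ] +
                       c(0, 0, place[i, 3]))
      center <- mouth + sa * r[i] * cos(alpha) * nhat[fc, ]
      m <- spherical_cap_mesh(sa * r[i], alpha, center, nhat[fc, ],
                              edge = min(edge, sa * r[i] / 10))
      m$id <- as.character(i + 1L); m$role <- "alveolus"
      attr(m, "label") <- i + 1L
      meshes[[i + 1L]] <- m
    }
    meshes
  }

  truth_state <- function(sd, sa, state) {
    ri <- sa * r
    Vi <- cap_volume(ri, alpha)
    Si <- cap_sphere_area(ri, alpha)
    ai <- cap_mouth_radius(ri, alpha)
    mouth <- t(vapply(seq_len(spec$n_alveoli), function(i) {
      fc <- place[i, 1]
      sd * (Rd * nhat[fc, ] + place[i, 2] * res$that[fc, ] +
              c(0, 0, place[i, 3]))
    }, numeric(3)))
    cen <- mouth + (sa * r * cos(alpha)) * nhat[place[, 1], , drop = FALSE]
    centroid <- cen + cap_centroid_offset(ri, alpha) *
      nhat[place[, 1], , drop = FALSE]
    gap <- function(i) {
      if (spec$n_alveoli < 2) return(NA_real_)
      min(vapply(setdiff(seq_len(spec$n_alveoli), i), function(j)
        cap_pair_distance(cen[i, ], ri[i], mouth[i, ],
                          nhat[place[i, 1], ],
                          cen[j, ], ri[j], mouth[j, ],
                          nhat[place[j, 1], ]), numeric(1)))
    }
    Vd <- duct_volume_cf(sd * Rd, sd * L, N)
    Sd <- duct_area_cf(sd * Rd, sd * L, N)
    structures <- data.frame(
      structure_id = c("1", as.character(seq_len(spec$n_alveoli) + 1L)),
      role = c("duct", rep("alveolus", spec$n_alveoli)),
      state = state,
      V = c(Vd, Vi),
      S = c(Sd, Si),
      D_A = (6 * c(Vd, Vi) / pi)^(1 / 3),
      T_A = c(NA_real_, vapply(seq_len(spec$n_alveoli), gap, numeric(1))),
      ring_perimeter = c(NA_real_, 2 * pi * ai),
      ring_area = c(NA_real_, pi * ai^2),
      cx = c(0, centroid[, 1]), cy = c(0, centroid[, 2]),
      cz = c(sd * L / 2, centroid[, 3]),
      stringsAsFactors = FALSE)
    V_AAD <- Vd + sum(Vi)
    S_AAD <- Sd - sum(pi * ai^2) + sum(Si)
    list(structures = structures, mouth = mouth, centroid = centroid,
         V_AAD = V_AAD, S_AAD = S_AAD, k = S_AAD / V_AAD^(2 / 3))
  }

  tr_exp <- truth_state(1, 1, "expiration")
  tr_insp <- truth_state(sc$s_d, sc$s_a, "inspiration")

  # neighboring pairs and the inter-alveolar angle theta: vertex at the
  # midpoint of the two mouth centers, rays to the lumen centroids
  theta_of <- function(tr, i, j) {
    v <- (tr$mouth[i, ] + tr$mouth[j, ]) / 2
    u1 <- tr$centroid[i, ] - v; u2 <- tr$centroid[j, ] - v
    acos(pmin(1, pmax(-1, sum(u1 * u2) /
                        sqrt(sum(u1^2) * sum(u2^2))))) * 180 / pi
  }
  pairs <- NULL
  if (spec$n_alveoli >= 2) {
    cen_exp <- tr_exp$mouth + (r * cos(alpha)) * nhat[place[, 1], ,
                                                      drop = FALSE]
    comb <- utils::combn(spec$n_alveoli, 2)
    keep <- apply(comb, 2, function(ij) {
      i <- ij[1]; j <- ij[2]
      g <- sqrt(sum((cen_exp[i, ] - cen_exp[j, ])^2)) - r[i] - r[j]
      g <= spec$neighbor_gap_frac * (r[i] + r[j])
    })
    if (any(keep)) {
      comb <- comb[, keep, drop = FALSE]
      pairs <- data.frame(
        id_a = as.character(comb[1, ] + 1L),
        id_b = as.character(comb[2, ] + 1L),
        theta_exp = apply(comb, 2, function(ij)
          theta_of(tr_exp, ij[1], ij[2])),
        theta_insp = apply(comb, 2, function(ij)
          theta_of(tr_insp, ij[1], ij[2])),
        stringsAsFactors = FALSE)
      pairs$d_theta_true <- pairs$theta_insp - pairs$theta_exp
    }
  }
  if (is.null(pairs))
    pairs <- data.frame(id_a = character(), id_b = character(),
                        theta_exp = numeric(), theta_insp = numeric(),
                        d_theta_true = numeric())

  truth <- list(
    structures = rbind(tr_exp$structures, tr_insp$structures),
    unit = data.frame(
      state = c("expiration", "inspiration"),
      V_AAD = c(tr_exp$V_AAD, tr_insp$V_AAD),
      S_AAD = c(tr_exp$S_AAD, tr_insp$S_AAD),
      k = c(tr_exp$k, tr_insp$k), stringsAsFactors = FALSE),
    q_true = tr_insp$k / tr_exp$k,
    pairs = pairs,
    scales = c(s_d = sc$s_d, s_a = sc$s_a),
    duct_length = L)

  structure(list(
    meshes_exp = build_state(1, 1, "expiration"),
    meshes_insp = build_state(sc$s_d, sc$s_a, "inspiration"),
    truth = truth, spec = spec), class = "phantom_unit")
}

#' @export
print.phantom_unit <- function(x, ...) {
  cat(sprintf(
    "<phantom_unit> %d alveoli on a %d-face duct, mode %s, q_true = %.4f\n",
    x$spec$n_alveoli, x$spec$n_duct_faces, x$spec$deformation_mode,
    x$truth$q_true))
  invisible(x)
}

#' Voxelize one state of a phantom unit
#'
#' Convenience wrapper around [voxelize] using the spec's voxel spacing and a
#' joint bounding box common to both states (so paired volumes share a grid).
#'
#' @param unit a [generate_unit] result.
#' @param state `"expiration"` or `"inspiration"`.
#' @param spacing voxel spacing, defaulting to the spec's.
#' @param pad tissue margin around the joint bounding box, micrometres.
#' @return a [labeled_volume].
#' @export
phantom_volume <- function(unit, state = c("expiration", "inspiration"),
                           spacing = NULL, pad = 3) {
  state <- match.arg(state)
  if (is.null(spacing)) spacing <- unit$spec$voxel_spacing
  allv <- do.call(rbind, lapply(c(unit$meshes_exp, unit$meshes_insp),
                                function(m) m$vertices))
  bbox <- rbind(apply(allv, 2, min) - pad, apply(allv, 2, max) + pad)
  meshes <- if (state == "expiration") unit$meshes_exp else unit$meshes_insp
  voxelize(meshes, spacing, bbox = bbox, state = state)
}
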