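# Triangle-mesh container and the mesh-integral morphometry primitives.
# Vertices are physical coordinates in micrometres, columns (x, y, z);
# faces are 1-based vertex index triples, oriented so that face normals
# point out of the enclosed lumen.

#' Construct a surface mesh
#'
#' A closed, outward-oriented triangle mesh is the carrier of the volume and
#' surface-area measurements: `V` by signed tetrahedral decomposition against
#' the origin and `S` by summed triangle areas.
#'
#' @param vertices numeric matrix, one row per vertex, columns (x, y, z) in
#'   micrometres.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param id optional structure identifier carried through the pipeline.
#' @param role one of `"alveolus"`, `"duct"`, `"unit_AAD"` or `NA`.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, id = NA_character_,
                         role = NA_character_) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3,
                  nrow = NROW(faces))
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces,
                 id = id, role = role),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %s (%s): %d vertices, %d faces\n",
              ifelse(is.na(x$id), "?", x$id),
              ifelse(is.na(x$role), "?", x$role),
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Test whether a mesh is closed (watertight)
#'
#' A mesh is closed when every undirected edge is shared by exactly two faces.
#'
#' @param mesh a [surface_mesh].
#' @return `TRUE` or `FALSE`.
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  nv <- nrow(mesh$vertices)
  key <- pmin(e[, 1], e[, 2]) * (nv + 1) + pmax(e[, 1], e[, 2])
  all(rle(sort(key))$lengths == 2L)
}

#' Enclosed volume of a closed mesh
#'
#' The volume is the sum of signed tetrahedra spanned by the origin and each
#' triangle (divergence theorem); it is exact for polyhedra and invariant
#' under translation of the origin.
#'
#' @param mesh a closed, outward-oriented [surface_mesh].
#' @param check verify closedness first (default `TRUE`).
#' @return volume in cubic micrometres (positive for outward orientation).
#' @export
mesh_volume <- function(mesh, check = TRUE) {
  if (check && !mesh_is_closed(mesh))
    stop("mesh is not closed: volume is undefined for open surfaces")
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  # scalar triple product a . (b x c) per face
  det3 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
          a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
          a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(det3) / 6
}

#' Surface area of a mesh
#'
#' @param mesh a [surface_mesh].
#' @return total triangle area in square micrometres.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0) return(0)
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Flip a mesh outward if its signed volume is negative
#' @param mesh a closed [surface_mesh].
#' @return the mesh, outward-oriented.
#' @export
mesh_orient_outward <- function(mesh) {
  if (mesh_volume(mesh, check = FALSE) < 0)
    mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

#' Centroid of the enclosed volume
#' @param mesh a closed, outward-oriented [surface_mesh].
#' @return numeric (x, y, z) in micrometres.
#' @export
mesh_centroid <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  det3 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
          a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
          a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  ctr <- (a + b + cc) / 4            # tetrahedron centroid (origin at 0)
  vol <- sum(det3) / 6
  colSums(ctr * det3 / 6) / vol
}

#' Affine transform of a mesh
#' @param mesh a [surface_mesh].
#' @param scale scalar or length-3 scale, or a 3x3 matrix.
#' @param offset length-3 translation in micrometres.
#' @return the transformed mesh (re-oriented outward if `scale` inverts).
#' @export
mesh_transform <- function(mesh, scale = 1, offset = c(0, 0, 0)) {
  if (is.matrix(scale)) {
    mesh$vertices <- mesh$vertices %*% t(scale)
  } else {
    mesh$vertices <- sweep(mesh$vertices, 2, rep(scale, length.out = 3), "*")
  }
  mesh$vertices <- sweep(mesh$vertices, 2, offset, "+")
  mesh_orient_outward(mesh)
}

# ---------------------------------------------------------------------------
# analytic primitives

#' Icosphere mesh
#'
#' Recursively subdivided icosahedron with all vertices projected onto the
#' sphere; the standard refinement series used as the spherical oracle
#' (inscribed, so V and S converge to 4/3 pi r^3 and 4 pi r^2 from below).
#'
#' @param radius sphere radius, micrometres.
#' @param refine subdivision level (0 = icosahedron, 20 faces; each level
#'   quadruples the face count).
#' @param center sphere center (x, y, z).
#' @return a closed [surface_mesh].
#' @export
icosphere <- function(radius = 1, refine = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(refine)) {
    mid <- new.env()
    nv <- nrow(v)
    vres <- v
    getmid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- mid[[key]]
      if (!is.null(id)) return(id)
      p <- (vres[i, ] + vres[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      vres <<- rbind(vres, p)
      id <- nrow(vres)
      mid[[key]] <- id
      id
    }
    fres <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- getmid(a, b); bc <- getmid(b, cc); ca <- getmid(cc, a)
      fres[(t - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- vres; f <- fres
  }
  v <- sweep(v * radius, 2, center, "+")
  mesh_orient_outward(surface_mesh(v, f))
}

#' Axis-aligned cuboid mesh (12 triangles)
#' @param lx,ly,lz edge lengths in micrometres.
#' @param center cuboid center (x, y, z).
#' @return a closed [surface_mesh].
#' @export
cuboid_mesh <- function(lx, ly = lx, lz = lx, center = c(0, 0, 0)) {
  h <- c(lx, ly, lz) / 2
  v <- as.matrix(expand.grid(x = c(-h[1], h[1]), y = c(-h[2], h[2]),
                             z = c(-h[3], h[3])))
  # vertex order: x fastest; faces as quads split into triangles
  quads <- rbind(c(1, 2, 4, 3), c(5, 7, 8, 6),   # z- , z+
                 c(1, 5, 6, 2), c(3, 4, 8, 7),   # y- , y+
                 c(1, 3, 7, 5), c(2, 6, 8, 4))   # x- , x+
  f <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  mesh_orient_outward(surface_mesh(sweep(v, 2, center, "+"), f))
}

#' Regular prism mesh (duct lumen primitive)
#'
#' Right regular n-gonal prism along the z axis, from z = 0 to z = length,
#' described by its apothem (inradius). Flat ends.
#'
#' @param apothem distance from axis to face midline, micrometres.
#' @param length prism length along z, micrometres.
#' @param nfaces number of lateral faces.
#' @param edge target edge length for the axial tessellation (micrometres);
#'   controls triangle density only, not the geometry.
#' @param azimuth rotation of the face centers about z, radians.
#' @return a closed [surface_mesh].
#' @export
prism_mesh <- function(apothem, length, nfaces = 8, edge = apothem / 4,
                       azimuth = 0) {
  R <- apothem / cos(pi / nfaces)           # circumradius
  # face k is centred on azimuth k * 2pi/nfaces + azimuth
  ang <- (seq_len(nfaces) - 0.5) * 2 * pi / nfaces + azimuth
  nz <- max(2L, ceiling(length / edge) + 1L)
  zs <- seq(0, length, length.out = nz)
  ring <- cbind(R * cos(ang), R * sin(ang))
  v <- do.call(rbind, lapply(zs, function(z) cbind(ring, z)))
  nfv <- nfaces
  idx <- function(iz, ia) (iz - 1L) * nfv + ((ia - 1L) %% nfv) + 1L
  f <- list()
  for (iz in seq_len(nz - 1)) for (ia in seq_len(nfv)) {
    a <- idx(iz, ia); b <- idx(iz, ia + 1)
    c2 <- idx(iz + 1, ia + 1); d <- idx(iz + 1, ia)
    f[[length(f) + 1]] <- rbind(c(a, b, c2), c(a, c2, d))
  }
  # end caps: fans around center vertices
  v <- rbind(v, c(0, 0, 0), c(0, 0, length))
  c0 <- nrow(v) - 1L; c1 <- nrow(v)
  for (ia in seq_len(nfv)) {
    f[[length(f) + 1]] <- rbind(c(c0, idx(1, ia + 1), idx(1, ia)),
                                c(c1, idx(nz, ia), idx(nz, ia + 1)))
  }
  mesh_orient_outward(surface_mesh(v, do.call(rbind, f)))
}

#' Spherical-cap mesh (alveolar lumen primitive)
#'
#' The lumen of a cup-shaped alveolus: the portion of a sphere of radius `r`
#' on the far side of its mouth plane, closed by the flat mouth disk. The
#' mouth half-angle `alpha` satisfies `sin(alpha) = mouth radius / r`; the
#' cap height is `r (1 + cos alpha)` so small `alpha` approaches the full
#' sphere.
#'
#' @param r sphere radius, micrometres.
#' @param alpha mouth half-angle in radians, in (0, pi/2).
#' @param center sphere center (x, y, z).
#' @param axis unit vector from the mouth toward the cap pole.
#' @param edge target triangle edge length, micrometres.
#' @return a closed [surface_mesh]; the flat disk face lies in the plane
#'   through `center - r cos(alpha) * axis` with normal `axis`.
#' @export
spherical_cap_mesh <- function(r, alpha, center = c(0, 0, 0),
                               axis = c(0, 0, 1), edge = r / 12) {
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal frame
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  phimax <- pi - alpha                      # polar angle from pole to mouth
  nphi <- max(4L, ceiling(r * phimax / edge))
  ntheta <- max(12L, ceiling(2 * pi * r / edge))
  # pole vertex + rings; ring i at polar angle phi_i
  v <- matrix(center + r * axis, 1, 3, byrow = TRUE)
  ringstart <- integer(nphi)
  for (i in seq_len(nphi)) {
    phi <- phimax * i / nphi
    ringstart[i] <- nrow(v) + 1L
    th <- (seq_len(ntheta) - 1) * 2 * pi / ntheta
    rho <- r * sin(phi); zax <- r * cos(phi)
    pts <- outer(rho * cos(th), e1) + outer(rho * sin(th), e2)
    pts <- sweep(pts, 2, center + zax * axis, "+")
    v <- rbind(v, pts)
  }
  f <- list()
  # pole fan
  s1 <- ringstart[1]
  for (j in seq_len(ntheta))
    f[[length(f) + 1]] <- c(1L, s1 + (j %% ntheta), s1 + (j - 1L))
  # bands
  for (i in seq_len(nphi - 1)) {
    sa <- ringstart[i]; sb <- ringstart[i + 1]
    for (j in seq_len(ntheta)) {
      a <- sa + (j - 1L); b <- sa + (j %% ntheta)
      d <- sb + (j - 1L); cc <- sb + (j %% ntheta)
      f[[length(f) + 1]] <- c(a, b, cc)
      f[[length(f) + 1]] <- c(a, cc, d)
    }
  }
  # mouth disk fan
  mouthc <- center - r * cos(alpha) * axis
  v <- rbind(v, mouthc)
  cm <- nrow(v)
  sl <- ringstart[nphi]
  for (j in seq_len(ntheta))
    f[[length(f) + 1]] <- c(cm, sl + (j - 1L), sl + (j %% ntheta))
  mesh_orient_outward(surface_mesh(v, do.call(rbind, f)))
}

# closed-form measures of the spherical-cap lumen -----------------------------

cap_height <- function(r, alpha) r * (1 + cos(alpha))

cap_volume <- function(r, alpha) {
  h <- cap_height(r, alpha)
  pi * h^2 * (3 * r - h) / 3
}

cap_sphere_area <- function(r, alpha) 2 * pi * r * cap_height(r, alpha)

cap_mouth_radius <- function(r, alpha) r * sin(alpha)

# axial centroid offset of the cap from the sphere center, toward the pole
cap_centroid_offset <- function(r, alpha) {
  z0 <- -r * cos(alpha)
  num <- pi * (r^4 / 4 - (r^2 * z0^2 / 2 - z0^4 / 4))
  num / cap_volume(r, alpha)
}
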