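# Mesh extraction from labels, entrance rings, wall thickness, angles, and
# unit assembly.

test_that("extracted meshes recover analytic volumes", {
  vol <- sphere_fixture()
  m <- extract_mesh(vol, 1)
  expect_true(mesh_is_closed(m))
  expect_lt(abs(mesh_volume(m) / (4 / 3 * pi * 25^3) - 1), 0.015)

  # axis-aligned 20^3 voxel box at 1 um spacing
  box <- array(0L, c(28, 28, 28))
  box[5:24, 5:24, 5:24] <- 1L
  bv <- labeled_volume(box, 1)
  bm <- extract_mesh(bv, 1)
  expect_lt(abs(mesh_volume(bm) / 8000 - 1), 0.02)

  expect_error(extract_mesh(vol, 7), "unknown label")
  tiny <- labeled_volume(array(c(rep(0L, 13), 1L, rep(0L, 13)), c(3, 3, 3)),
                         1)
  expect_error(extract_mesh(tiny, 1), "degenerate resolution")
})

test_that("mesh volume tracks the voxel count as spacing shrinks", {
  s <- icosphere(20, 4)
  attr(s, "label") <- 1L
  errs <- vapply(c(2, 1), function(sp) {
    v <- voxelize(list(s), sp)
    m <- extract_mesh(v, 1)
    abs(mesh_volume(m) / (sum(v$voxels == 1L) * sp^3) - 1)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.01)
})

test_that("entrance ring of a 15 um mouth is recovered within 2%", {
  errs <- vapply(c(1, 2, 3), function(seed) {
    spec <- phantom_spec(duct_radius = 30, alveolar_radius = 37.5,
                         n_alveoli = 1, alveolar_dispersion = 0,
                         mouth_fraction = 0.4, duct_volume_fraction = 0.35,
                         placement_seed = seed)
    u <- generate_unit(spec)
    vol <- phantom_volume(u, "expiration")
    ring <- detect_entrance_ring(vol, 2)
    ring$perimeter / (2 * pi * 15) - 1
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.02)
  expect_lt(max(abs(errs)), 0.035)
})

test_that("entrance rings match generator truth on a multi-alveolus phantom", {
  fx <- strain_fixture()
  tr <- fx$unit$truth$structures
  tr <- tr[tr$state == "expiration" & tr$role == "alveolus", ]
  rec <- fx$rec_exp[fx$rec_exp$role == "alveolus", ]
  err <- rec$ring_perimeter_um /
    tr$ring_perimeter[match(rec$structure_id, tr$structure_id)] - 1
  expect_lt(max(abs(err)), 0.05)
  expect_lt(abs(mean(err)), 0.02)
})

test_that("a square aperture is traced near its true perimeter", {
  # duct box below, alveolus box above, sharing a 10 x 10 um opening
  d <- c(26L, 26L, 26L)
  v <- array(0L, d)
  v[3:12, 3:24, 3:24] <- 1L                  # duct slab
  v[13:22, 9:18, 9:18] <- 2L                 # alveolar box over an opening
  vol <- labeled_volume(v, 1)
  ring <- detect_entrance_ring(vol, 2)
  # the rim tracer models outward-flaring cup walls; straight-walled
  # synthetic apertures read several percent low but stay in band
  expect_lt(abs(ring$perimeter / 40 - 1), 0.15)
})

test_that("ring detection errors when the alveolus is detached", {
  d <- c(12L, 12L, 12L)
  v <- array(0L, d)
  v[2:4, 2:4, 2:4] <- 1L
  v[8:11, 8:11, 8:11] <- 2L
  expect_error(detect_entrance_ring(labeled_volume(v, 1), 2),
               "not attached")
})

test_that("wall thickness recovers constructed septa", {
  # two air slabs separated by a 5-voxel tissue wall at 0.65 um spacing
  d <- c(20L, 20L, 25L)
  v <- array(0L, d)
  v[, , 3:9] <- 2L
  v[, , 15:21] <- 3L
  vol <- labeled_volume(v, 0.65)
  t_est <- wall_thickness(vol, 2, exclude = integer(0))
  expect_lt(abs(t_est - 5 * 0.65), 0.66)     # within one voxel

  # concentric shell: air core, 4 um tissue shell, exterior air
  d2 <- rep(36L, 3)
  v2 <- array(0L, d2)
  ctr <- 18.5
  for (x in 1:36) for (y in 1:36) for (z in 1:36) {
    rr <- sqrt((x - ctr)^2 + (y - ctr)^2 + (z - ctr)^2) * 0.65
    if (rr <= 6) v2[z, y, x] <- 2L
    else if (rr > 10) v2[z, y, x] <- 3L
  }
  vol2 <- labeled_volume(v2, 0.65)
  t2 <- wall_thickness(vol2, 2, exclude = integer(0))
  expect_lt(abs(t2 - 4), 0.66)

  expect_error(wall_thickness(vol, 2, exclude = 3L), "undefined")
})

test_that("wall thickness matches generator truth within a voxel", {
  spec <- phantom_spec(duct_radius = 22, alveolar_radius = 20,
                       n_alveoli = 5, duct_volume_fraction = 0.5,
                       placement_seed = 2)
  u <- generate_unit(spec)
  vol <- phantom_volume(u, "expiration")
  tr <- u$truth$structures
  tr <- tr[tr$state == "expiration" & tr$role == "alveolus", ]
  edt <- alveodyn:::.cpp_feature_edt(vol$voxels, as.integer(dim(vol$voxels)),
                                     vol$spacing)
  for (id in tr$structure_id) {
    t_est <- wall_thickness(vol, as.integer(id), edt = edt)
    expect_lt(abs(t_est - tr$T_A[tr$structure_id == id]), 0.66)
  }
})

test_that("inter-alveolar angles follow the vertex-ray construction", {
  rec <- function(cx, cy, cz)
    data.frame(cx = cx, cy = cy, cz = cz)
  # two centroids at right angles around a common vertex at the origin
  expect_equal(angle_between_alveoli(rec(10, 0, 0), rec(0, 10, 0),
                                     c(1, 1, 0), c(-1, -1, 0)), 90,
               tolerance = 1e-10)
  # antipodal centroids: collinear rays, 180 degrees
  expect_equal(angle_between_alveoli(rec(10, 0, 0), rec(-10, 0, 0),
                                     c(0, 1, 0), c(0, -1, 0)), 180,
               tolerance = 1e-10)
  # uniform scaling leaves the angle unchanged
  a <- rec(8, 3, -2); b <- rec(-5, 7, 4)
  th1 <- angle_between_alveoli(a, b, c(1, 2, 0), c(2, 1, 0))
  th2 <- angle_between_alveoli(rec(24, 9, -6), rec(-15, 21, 12),
                               3 * c(1, 2, 0), 3 * c(2, 1, 0))
  expect_equal(th1, th2, tolerance = 1e-12)
  expect_error(angle_between_alveoli(rec(1, 1, 1), rec(1, 1, 1),
                                     c(1, 1, 1), c(1, 1, 1)),
               "degenerate")
})

test_that("angles measured on a symmetric phantom match construction", {
  # two equal alveoli on faces 90 degrees apart at the same height
  spec <- phantom_spec(duct_radius = 20, alveolar_radius = 12,
                       n_alveoli = 2, alveolar_dispersion = 0,
                       n_duct_faces = 4, duct_length = 60,
                       neighbor_gap_frac = 3, placement_seed = 1)
  u <- generate_unit(spec)
  pr <- u$truth$pairs
  # truth for orthogonal faces, computed from the generator geometry
  if (nrow(pr) == 1) {
    vol <- phantom_volume(u, "expiration")
    rec <- measure_structures(vol, walls = FALSE)
    ang <- pair_angles(rec, rec, pr[, c("id_a", "id_b")])
    expect_equal(ang$theta_exp, pr$theta_exp, tolerance = 0.03)
    expect_equal(ang$d_theta, 0, tolerance = 1e-8)
  } else {
    succeed("alveoli placed on non-adjacent faces; angle truth untested")
  }
})

test_that("unit assembly is additive and equals the duct when empty", {
  fx <- strain_fixture()
  rec <- fx$rec_exp
  duct <- rec[rec$role == "duct", ]
  alv <- rec[rec$role == "alveolus", ]
  unit <- assemble_unit(alv, duct)
  expect_equal(unit$V_um3, duct$V_um3 + sum(alv$V_um3))
  expect_equal(unit$S_um2,
               duct$S_total_um2 - sum(alv$ring_area_um2) + sum(alv$S_um2))
  empty <- assemble_unit(alv[0, ], duct)
  expect_equal(empty$V_um3, duct$V_um3)
  expect_equal(empty$S_um2, duct$S_total_um2)
  # measured unit record agrees with generator truth within 1%
  mu <- rec[rec$role == "unit_AAD", ]
  expect_lt(abs(mu$V_um3 / fx$unit$truth$unit$V_AAD[1] - 1), 0.01)
  expect_lt(abs(mu$S_um2 / fx$unit$truth$unit$S_AAD[1] - 1), 0.01)
})
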