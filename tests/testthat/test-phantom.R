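# Synthetic gas-exchange-unit generator: determinism, analytic ground
# truth, deformation-mode structure, voxelization, rendering.

test_that("generation is deterministic for a fixed placement seed", {
  s <- phantom_spec(placement_seed = 11)
  u1 <- generate_unit(s)
  u2 <- generate_unit(s)
  expect_identical(u1$meshes_exp[[2]]$vertices, u2$meshes_exp[[2]]$vertices)
  expect_identical(u1$truth, u2$truth)
})

test_that("isotropic deformation gives q_true = 1 and the exact volume ratio", {
  for (seed in c(1, 5, 9)) {
    u <- generate_unit(phantom_spec(deformation_mode = "isotropic",
                                    volume_ratio = 1.5,
                                    placement_seed = seed))
    expect_equal(u$truth$q_true, 1, tolerance = 1e-12)
    expect_equal(u$truth$unit$V_AAD[2] / u$truth$unit$V_AAD[1], 1.5,
                 tolerance = 1e-12)
    if (nrow(u$truth$pairs) > 0)
      expect_equal(max(abs(u$truth$pairs$d_theta_true)), 0,
                   tolerance = 1e-8)
  }
})

test_that("anisotropic modes order the compartment strains and sign q and d_theta", {
  for (seed in c(2, 3)) {
    ua <- generate_unit(phantom_spec(deformation_mode = "alveolus_dominant",
                                     placement_seed = seed))
    ud <- generate_unit(phantom_spec(deformation_mode = "duct_dominant",
                                     placement_seed = seed))
    # per-compartment linear scales order as the mode demands
    expect_gt(ua$truth$scales["s_a"], ua$truth$scales["s_d"])
    expect_lt(ud$truth$scales["s_a"], ud$truth$scales["s_d"])
    # whole-unit target volume ratio still holds
    expect_equal(ua$truth$unit$V_AAD[2] / ua$truth$unit$V_AAD[1], 1.5,
                 tolerance = 1e-9)
    expect_equal(ud$truth$unit$V_AAD[2] / ud$truth$unit$V_AAD[1], 1.5,
                 tolerance = 1e-9)
    expect_gt(ua$truth$q_true, 1)
    expect_lt(ud$truth$q_true, 1)
    if (nrow(ua$truth$pairs) > 0)
      expect_lt(mean(ua$truth$pairs$d_theta_true), 0)
    if (nrow(ud$truth$pairs) > 0)
      expect_gt(mean(ud$truth$pairs$d_theta_true), 0)
  }
})

test_that("a vanishing mouth approaches a full sphere", {
  u <- generate_unit(phantom_spec(n_alveoli = 1, mouth_fraction = 0.05,
                                  alveolar_dispersion = 0,
                                  duct_length = 120, placement_seed = 1))
  tr <- u$truth$structures
  alv <- tr[tr$role == "alveolus" & tr$state == "expiration", ]
  r <- 30
  expect_lt(abs(alv$S / (4 * pi * r^2) - 1), 0.01)
  expect_lt(abs(alv$V / (4 / 3 * pi * r^3) - 1), 0.01)
})

test_that("ground truth agrees with brute-force mesh integration", {
  u <- generate_unit(phantom_spec(placement_seed = 3))
  tr <- u$truth$structures[u$truth$structures$state == "expiration", ]
  for (i in seq_along(u$meshes_exp)) {
    m <- u$meshes_exp[[i]]
    t <- tr[tr$structure_id == m$id, ]
    St <- if (t$role == "duct") t$S else t$S + t$ring_area
    expect_lt(abs(mesh_volume(m) / t$V - 1), 0.005)
    expect_lt(abs(mesh_area(m) / St - 1), 0.005)
  }
})

test_that("cap-pair distance (wall-thickness truth) matches closed-form cases", {
  alpha <- asin(0.4)
  r1 <- 9; r2 <- 7
  mk <- function(r, mouth, axis) {
    axis <- axis / sqrt(sum(axis^2))
    list(c0 = mouth + r * cos(alpha) * axis, r = r, m = mouth, n = axis)
  }
  dist_caps <- function(A, B)
    alveodyn:::cap_pair_distance(A$c0, A$r, A$m, A$n, B$c0, B$r, B$m, B$n)

  # far caps, parallel axes: closest points on the spherical parts, so the
  # distance is the center separation minus both radii
  A <- mk(r1, c(0, 0, 0), c(0, 0, 1))
  B <- mk(r2, c(25, 0, 0), c(0, 0, 1))
  expect_equal(dist_caps(A, B),
               sqrt(sum((B$c0 - A$c0)^2)) - r1 - r2, tolerance = 1e-6)

  # independent oracle: dense boundary sampling with local refinement
  sample_cap <- function(C, nth = 60, nph = 40) {
    ref <- if (abs(C$n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * C$n) * C$n; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(C$n[2] * e1[3] - C$n[3] * e1[2],
            C$n[3] * e1[1] - C$n[1] * e1[3],
            C$n[1] * e1[2] - C$n[2] * e1[1])
    phimax <- pi - alpha
    ph <- seq(0, phimax, length.out = nph)
    th <- seq(0, 2 * pi, length.out = nth + 1)[-1]
    g <- expand.grid(th = th, ph = ph)
    sph <- C$c0[rep(1, nrow(g)), drop = FALSE]
    pts <- outer(C$r * sin(g$ph) * cos(g$th), e1) +
      outer(C$r * sin(g$ph) * sin(g$th), e2) +
      outer(C$r * cos(g$ph), C$n)
    pts <- sweep(pts, 2, C$c0, "+")
    # mouth disk
    rr <- seq(0, C$r * sin(alpha), length.out = 15)
    gd <- expand.grid(th = th, rr = rr)
    disk <- outer(gd$rr * cos(gd$th), e1) + outer(gd$rr * sin(gd$th), e2)
    disk <- sweep(disk, 2, C$m, "+")
    rbind(pts, disk)
  }
  oracle <- function(CA, CB) {
    pa <- sample_cap(CA); pb <- sample_cap(CB)
    best <- Inf
    for (i in seq(1, nrow(pa), by = 400)) {
      idx <- i:min(i + 399, nrow(pa))
      d2 <- outer(rowSums(pa[idx, ]^2), rowSums(pb^2), "+") -
        2 * pa[idx, ] %*% t(pb)
      best <- min(best, min(d2))
    }
    sqrt(max(best, 0))
  }
  a1 <- r1 * sin(alpha); a2 <- r2 * sin(alpha)
  B2 <- mk(r2, c(a1 + a2 + 2.5, 0, 0), c(0, 0, -1))
  for (CB in list(B2, mk(6, c(17, 3, 2), c(0.3, 0.1, -1)))) {
    d_dyk <- dist_caps(A, CB)
    d_orc <- oracle(A, CB)
    # sampled boundary distance can only overestimate the true minimum
    expect_lte(d_dyk, d_orc + 1e-6)
    expect_lt(abs(d_dyk - d_orc), 0.25)
  }

  # symmetry and uniform-scale equivariance
  set.seed(3)
  for (i in 1:5) {
    B3 <- mk(runif(1, 5, 10), c(runif(1, 18, 30), runif(1, -5, 5), 0),
             c(runif(1, -1, 1), runif(1, -1, 1), runif(1, 0.2, 1)))
    d1 <- dist_caps(A, B3)
    expect_equal(dist_caps(B3, A), d1, tolerance = 1e-8)
    A2 <- mk(2 * A$r, 2 * A$m, A$n); B4 <- mk(2 * B3$r, 2 * B3$m, B3$n)
    expect_equal(dist_caps(A2, B4), 2 * d1, tolerance = 1e-6)
  }
})

test_that("infeasible placement raises an error naming the configuration", {
  expect_error(
    generate_unit(phantom_spec(n_alveoli = 12, duct_length = 40,
                               placement_seed = 6),
                  max_attempts = 200),
    "placement failure.*placement_seed")
})

test_that("voxelization recovers analytic volumes and converges with spacing", {
  vol <- sphere_fixture()
  Vt <- 4 / 3 * pi * 25^3
  err_fine <- abs(sum(vol$voxels == 1L) * 0.65^3 / Vt - 1)
  expect_lt(err_fine, 0.01)
  s <- icosphere(25, 4)
  attr(s, "label") <- 1L
  coarse <- voxelize(list(s), 1.3)
  err_coarse <- abs(sum(coarse$voxels == 1L) * 1.3^3 / Vt - 1)
  expect_lt(err_fine, err_coarse)

  empty <- voxelize(list(), 1)
  expect_true(all(empty$voxels == 0L))

  expect_error(voxelize(list(icosphere(2, 2)), spacing = 2),
               "degenerate resolution")
})

test_that("grayscale rendering is a seeded two-material model", {
  u <- generate_unit(acc_spec("isotropic", 1, noise_sd = 0))
  vol <- phantom_volume(u, "expiration")
  img0 <- render_grayscale(vol, 0)
  expect_length(unique(as.vector(img0)), 2L)
  img1 <- render_grayscale(vol, 10, seed = 5)
  img2 <- render_grayscale(vol, 10, seed = 5)
  expect_identical(img1, img2)
  # noise SD in a pure-air region within 5%
  core <- img1[vol$voxels == 1L]
  expect_lt(abs(sd(core) / 10 - 1), 0.05)
  expect_error(render_grayscale(vol, -1), "noise_sd")
})
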