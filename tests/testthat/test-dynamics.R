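# Shape factor, q, strains, and angle differences.

test_that("the shape factor is scale-invariant with its known anchors", {
  for (L in c(1, 10, 137.2)) {
    expect_equal(shape_factor(6 * L^2, L^3), 6)
  }
  r <- 4.2
  expect_equal(shape_factor(4 * pi * r^2, 4 / 3 * pi * r^3), k_sphere())
  S <- 123.4; V <- 77.1
  for (s in c(0.2, 3, 11)) {
    expect_equal(shape_factor(s^2 * S, s^3 * V), shape_factor(S, V),
                 tolerance = 1e-12)
  }
  expect_error(shape_factor(-1, 1), "positive")
  expect_error(shape_factor(1, 0), "positive")
})

test_that("q is 1 under uniform scaling and guards its pairing", {
  mkrec <- function(S, V, role = "unit_AAD", id = "unit")
    data.frame(structure_id = id, role = role, S_um2 = S, V_um3 = V)
  base <- mkrec(2000, 9000)
  for (s in c(1.1, 1.5, 2.4)) {
    expect_equal(q_statistic(base, mkrec(s^2 * 2000, s^3 * 9000)), 1,
                 tolerance = 1e-12)
  }
  expect_error(q_statistic(base, mkrec(1, 1, role = "duct")), "pairing")
  expect_error(q_statistic(base, mkrec(1, 1, id = "other")), "pairing")
})

test_that("q is invariant under rigid motion of either state", {
  s <- icosphere(12, 3)
  cap <- spherical_cap_mesh(9, asin(0.4), center = c(30, 0, 0),
                            axis = c(1, 0, 0), edge = 0.8)
  k_of <- function(m) shape_factor(mesh_area(m), mesh_volume(m))
  th <- 1.1
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  for (m in list(s, cap)) {
    m2 <- mesh_transform(m, scale = R, offset = c(7, -3, 2))
    expect_equal(k_of(m2) / k_of(m), 1, tolerance = 1e-10)
  }
})

test_that("strain algebra passes its exact values and round trip", {
  expect_equal(area_strain(100, 100), 0)
  expect_equal(area_strain(100, 225), 1.25)
  expect_lt(area_strain(100, 80), 0)         # negative strain is allowed
  expect_equal(linear_strain(0), 0)
  expect_equal(linear_strain(1.25), 0.5)
  expect_equal(linear_strain(0.21), 0.1)
  # round trip to machine precision over a sweep of strains
  eps <- seq(-0.4, 1.5, by = 0.01)
  dS <- (1 + eps)^2 - 1
  expect_equal(linear_strain(dS), eps, tolerance = 1e-14)
  expect_error(linear_strain(-1), "dS")
  expect_error(area_strain(0, 1), "positive")
})

test_that("ring strain is the plain perimeter ratio", {
  expect_equal(ring_strain(50, 50), 0)
  expect_equal(ring_strain(50, 55), 0.1)
  expect_error(ring_strain(0, 1), "positive")
})

test_that("delta theta is a guarded signed difference", {
  expect_equal(delta_theta(90, 90), 0)
  expect_equal(delta_theta(120, 95), -25)
  expect_error(delta_theta(-1, 10), "0, 180")
  expect_error(delta_theta(10, 190), "0, 180")
})

test_that("state pairing falls back to centroids and reports unmatched", {
  mk <- function(id, role, x, S = 100, V = 100, rp = NA)
    data.frame(structure_id = id, role = role, PEEP = 3, IPP = 13,
               V_um3 = V, S_um2 = S, S_total_um2 = S, D_A_um = 1,
               T_A_um = NA, ring_perimeter_um = rp, ring_area_um2 = NA,
               cx = x, cy = 0, cz = 0)
  rec_e <- rbind(mk("1", "duct", 0), mk("2", "alveolus", 30, rp = 20),
                 mk("3", "alveolus", 60, rp = 22))
  rec_i <- rbind(mk("1", "duct", 1), mk("9", "alveolus", 31, rp = 21),
                 mk("4", "alveolus", 200, rp = 30))
  expect_warning(dyn <- pair_dynamics(rec_e, rec_i, max_displacement = 10),
                 "unmatched")
  expect_setequal(attr(dyn, "unmatched"), c("3", "4"))
  expect_equal(nrow(dyn), 2)
  al <- dyn[dyn$role == "alveolus", ]
  expect_equal(al$eps_ER, ring_strain(20, 21))
})

test_that("the measured isotropic phantom is strain-consistent", {
  fx <- strain_fixture()
  alv <- fx$dyn[fx$dyn$role == "alveolus", ]
  eps_true <- 1.5^(1 / 3) - 1
  # membrane strain from areas matches the linear ground truth closely
  expect_lt(abs(mean(alv$eps_A) / eps_true - 1), 0.01)
  # dS and eps_A satisfy the conversion identity exactly
  expect_equal(alv$dS, (1 + alv$eps_A)^2 - 1, tolerance = 1e-12)
  # q of the unit is 1 within measurement tolerance
  expect_lt(abs(fx$dyn$q[fx$dyn$role == "unit_AAD"] - 1), 0.005)
})
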