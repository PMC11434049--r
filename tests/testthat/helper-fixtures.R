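# Shared fixtures, built once per test run on first use.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# acceptance-scale phantom: a whole two-state unit inside a 64-128^3 grid
# at 0.65 um voxels
acc_spec <- function(mode, seed, noise_sd = 10) {
  phantom_spec(duct_radius = 11, alveolar_radius = 9, n_alveoli = 5,
               duct_volume_fraction = 0.5, deformation_mode = mode,
               placement_seed = seed, noise_sd = noise_sd)
}

# mid-scale isotropic phantom used for strain and absolute-accuracy checks
strain_fixture <- function() {
  fixture("strain_pair", function() {
    spec <- phantom_spec(duct_radius = 22, alveolar_radius = 20,
                         n_alveoli = 5, duct_volume_fraction = 0.5,
                         deformation_mode = "isotropic", placement_seed = 2)
    unit <- generate_unit(spec)
    ve <- phantom_volume(unit, "expiration")
    vi <- phantom_volume(unit, "inspiration")
    me <- measure_structures(ve, walls = FALSE)
    mi <- measure_structures(vi, walls = FALSE)
    list(unit = unit, vol_exp = ve, vol_insp = vi,
         rec_exp = me, rec_insp = mi,
         dyn = pair_dynamics(me, mi))
  })
}

# voxelized sphere of radius 25 um at 0.65 um spacing
sphere_fixture <- function() {
  fixture("sphere25", function() {
    s <- icosphere(25, 4)
    attr(s, "label") <- 1L
    voxelize(list(s), 0.65)
  })
}

# two spheres bridged by a thin neck, as a label array with spacing 1 um
neck_fixture <- function() {
  d <- c(24L, 24L, 46L)
  arr <- array(FALSE, d)
  cz <- 12.5; cy <- 12.5
  for (cx in c(12.5, 34.5)) {
    for (x in 1:d[3]) for (y in 1:d[2]) for (z in 1:d[1]) {
      if ((z - cz)^2 + (y - cy)^2 + (x - cx)^2 <= 8^2) arr[z, y, x] <- TRUE
    }
  }
  arr[12:13, 12:13, 20:28] <- TRUE            # 2-voxel-wide bridge
  arr
}
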