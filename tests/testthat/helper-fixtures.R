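# Shared heavy fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Reference phantom pair at the package's study conditions
# (0.3 mm spacing, PSF sigma 0.6 mm, fg 1000 / bg 0, noiseless CT).
default_phantom <- function() {
  cached("default_phantom", function() {
    spec <- phantom_spec()
    pair <- make_phantom_pair(spec, spacing = 0.3)
    lm <- withr::with_seed(spec$seed + 3L, {
      vi <- sample.int(nrow(pair$mesh$vertices), 6)
      src <- pair$mesh$vertices[vi, , drop = FALSE]
      tgt <- apply_transform(src, spec$true_pose) +
        matrix(stats::rnorm(18, sd = 0.1), 6, 3)
      landmark_set(src, tgt)
    })
    c(pair, list(spec = spec, landmarks = lm,
                 init = landmark_register(lm)))
  })
}

# Blurred-sphere CT fixture (radius 8 mm, same contrast/PSF).
blurred_sphere <- function() {
  cached("blurred_sphere", function() {
    mesh <- make_sphere_mesh(8, 4)
    vol <- voxelize_mesh(mesh, spacing = 0.4, padding = 3, fg = 1000, bg = 0)
    list(mesh = mesh, ct = simulate_ct(vol, psf_sigma = 0.6, noise_sd = 0))
  })
}

arch_mesh_default <- function() {
  cached("arch_mesh_default", function() make_arch_mesh(phantom_spec()))
}

# Threshold optimisation on the reference phantom, shared by the threshold
# and acceptance suites (registration + search run once per test session).
default_optimize <- function() {
  cached("default_optimize", function() {
    fix <- default_phantom()
    optimize_threshold(fix$ct, fix$optical, bracket = c(200, 800),
                       init = fix$init, icp = icp_params(seed = fix$spec$seed + 2L),
                       seed = fix$spec$seed + 4L)
  })
}
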