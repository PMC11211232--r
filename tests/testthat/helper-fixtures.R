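# Shared fixtures, built in code and cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small static 16^2 acquisition (2 coils, 48 golden-angle spokes, one frozen
# motion state) used by the operator-oracle tests.
tiny_raw <- function() {
  cached("tiny_raw", function() {
    ph <- make_phantom(phantom_config(grid_size = 16, voxel_mm = 2,
                                      resp_amplitude_mm = c(0, 0, 0),
                                      vessel_radius_mm = 5))
    cfg <- sequence_config("FISS", mode = "2d", n_interleaves = 2,
                           fov_mm = 32, resolution_mm = 2, oversampling = 1)
    sched <- build_schedule(cfg, 0)
    coils <- make_coil_maps(2, 16, 2, seed = 3)
    raw <- simulate_scan(ph, sched, coils, noise_sd = 0,
                         n_cardiac_states = 1L)
    list(phantom = ph, raw = raw)
  })
}

# Explicit DFT matrix oracle for a radial acquisition: rows follow the
# schedule (sample fastest), columns the voxel grid.
explicit_dft_matrix <- function(raw) {
  g <- synaps4d:::acq_geometry(raw)
  K <- do.call(rbind, lapply(seq_len(nrow(raw$schedule)), function(r) {
    outer(g$rs$t, as.numeric(g$dirs[r, ]))
  }))
  exp(-2i * pi * (K %*% t(g$coords)))
}

# 60 s pilot-tone simulation at the default phantom rates with noise,
# drift and an inter-sequence gap (per-channel SNR ~ 10).
pt_sim <- function() {
  cached("pt_sim", function() {
    ph <- make_phantom(phantom_config())
    list(phantom = ph,
         pt = simulate_pt(ph, 60, noise_sd = 0.1, drift_per_min = 0.5,
                          gap_time = 25))
  })
}

# Desk-scale end-to-end pipeline run (the study conditions of the default
# pipeline_config), shared across pipeline and acceptance tests.
e2e_session <- function() {
  cached("e2e", function() {
    out <- file.path(tempdir(), "synaps4d-e2e")
    res <- suppressMessages(run_pipeline(pipeline_config(), out_dir = out))
    list(out_dir = out, report = res$report, manifest = res$manifest)
  })
}

# Reduced configuration for pipeline smoke/determinism tests.
smoke_config <- function(seed = 7L) {
  pipeline_config(grid_size = 48, n_phases = 4L, fiss_interleaves = 40L,
                  pc_interleaves = 56L, n_iterations = 4L, seed = seed)
}
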