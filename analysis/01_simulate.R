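#!/usr/bin/env Rscript

# Stage 1: generate every synthetic input the downstream analyses need.
#
# The molecular-dynamics engine is replaced by two generators:
#  * umbrella windows drawn from analytic double-well potentials along the
#    reaction coordinate R, one potential per methyl-transfer step and
#    enzyme, programmed with the per-step barriers of the bundled barrier
#    table (WT 13.4/15.8/22.1, F1209Y 13.8/17.4, Y1124F 13.9/15.9/13.3
#    kcal/mol);
#  * reactant-complex frame ensembles with controlled r(CM..Nzeta) and
#    theta statistics: the reactive preset (mean r 3.0 A, mean theta 30
#    deg) and the non-reactive third-transfer preset (mean r 4.5 A, broad
#    theta).
#
# Raw samples are bulky and fully regenerable from the seed, so they land
# under scratch/synthetic_data/ as plain text (window series + XYZ); the
# downstream stages read them from there and write their summary tables
# under results/.

suppressMessages(library(methylpmf))

seed <- 2026L
out_root <- file.path("scratch", "synthetic_data")
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

barriers <- read_barriers(system.file("extdata", "glp_barriers.csv",
                                      package = "methylpmf"))

cat("== synthetic umbrella windows (20 windows, k in 50-400, 5000/window, 283.15 K)\n")
for (enz in names(barriers)) {
  b <- barriers[[enz]]$barriers
  for (step in seq_along(b)) {
    if (is.na(b[step])) next
    pot <- make_potential("quartic_double_well", barrier = b[step],
                          r_a = -1.4, r_b = 1.2)
    proto <- umbrella_protocol(pot, n_windows = 20, k_limits = c(50, 400))
    w <- gen_umbrella_windows(pot, proto$centers, proto$force_constants,
                              n_per_window = 5000, temperature = 283.15,
                              seed = seed + 10L * step)
    dir <- file.path(out_root, sprintf("%s_step%d", enz, step))
    write_window_series(w, dir)
    cat(sprintf("  %s step %d: programmed barrier %.1f kcal/mol -> %s\n",
                enz, step, b[step], dir))
  }
}

cat("== synthetic reactant-complex ensembles (n = 10000 frames each)\n")
for (preset in c("reactive_wt_like", "nonreactive_wt3_like")) {
  fs <- gen_frames(frame_preset(preset, n_frames = 10000, seed = seed))
  path <- file.path(out_root, paste0(preset, ".xyz"))
  write_frames_xyz(fs, path)
  cat(sprintf("  %s -> %s\n", preset, path))
}
cat("done; run analysis/02_geometry.R next\n")
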