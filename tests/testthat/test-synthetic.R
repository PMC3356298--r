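test_that("model potentials have their programmed stationary structure", {
  h <- make_potential("harmonic", kappa = 4)
  expect_equal(h$U(1), 2.0)

  for (drp in c(0, -2.1, 3.3)) {
    q <- make_potential("quartic_double_well", barrier = 13.4,
                        r_a = -1.4, r_b = 1.2, delta_rp = drp)
    expect_equal(q$U(q$r_a), 0, tolerance = 1e-12)
    expect_equal(q$U(q$r_t) - q$U(q$r_a), 13.4, tolerance = 1e-10)
    expect_equal(q$U(q$r_b) - q$U(q$r_a), drp, tolerance = 1e-10)
    # stationary points are genuine: numeric gradient vanishes
    hstep <- 1e-6
    for (x in c(q$r_a, q$r_t, q$r_b)) {
      expect_lt(abs((q$U(x + hstep) - q$U(x - hstep)) / (2 * hstep)), 1e-4)
    }
  }

  pc <- make_potential("piecewise_cubic", barrier = 8, r_a = -1, r_b = 1,
                       delta_rp = -1)
  expect_equal(pc$U(pc$r_t), 8, tolerance = 1e-12)
  expect_equal(pc$U(pc$r_b), -1, tolerance = 1e-12)

  expect_error(make_potential("quartic_double_well", barrier = 0,
                              r_a = -1, r_b = 1), "ordering")
  expect_error(make_potential("quartic_double_well", barrier = 5,
                              r_a = 1, r_b = -1), "r_a < r_b")
  expect_error(make_potential("quartic_double_well", barrier = 5,
                              r_a = -1, r_b = 1, delta_rp = 6), "barrier")
})

test_that("a strong bias on a flat-bottomed potential samples the Gaussian law", {
  # near the minimum of a very soft harmonic the potential is flat relative
  # to a k = 400 restraint: samples follow N(center, kT / (2k))
  pot <- make_potential("harmonic", kappa = 1e-6, range = c(-1, 1))
  w <- gen_umbrella_windows(pot, centers = 0.3, force_constants = 400,
                            n_per_window = 1e5, temperature = 283.15,
                            seed = 4)[[1]]
  kT <- kB_ref * 283.15
  target_var <- kT / (2 * 400)
  se_mean <- sqrt(target_var / 1e5)
  expect_lt(abs(mean(w$samples) - 0.3), 3 * se_mean)
  expect_lt(abs(var(w$samples) - target_var) / target_var, 0.05)
})

test_that("window generation is bitwise reproducible and seed-sensitive", {
  pot <- make_potential("quartic_double_well", barrier = 5,
                        r_a = -1.4, r_b = 1.2)
  a <- gen_umbrella_windows(pot, c(-1, 0, 1), c(100, 100, 100), 500,
                            seed = 42)
  b <- gen_umbrella_windows(pot, c(-1, 0, 1), c(100, 100, 100), 500,
                            seed = 42)
  expect_identical(lapply(a, `[[`, "samples"), lapply(b, `[[`, "samples"))
  c3 <- gen_umbrella_windows(pot, c(-1, 0, 1), c(100, 100, 100), 500,
                             seed = 43)
  expect_false(identical(a[[1]]$samples, c3[[1]]$samples))
})

test_that("sampled windows pass a goodness-of-fit test against the biased density", {
  pot <- make_potential("quartic_double_well", barrier = 13.4,
                        r_a = -1.4, r_b = 1.2)
  kT <- kB_ref * 283.15
  n <- 1e5
  n_grid <- 4096
  edges <- seq(pot$range[1], pot$range[2], length.out = n_grid + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  passes <- vapply(1:10, function(s) {
    w <- gen_umbrella_windows(pot, centers = -0.4, force_constants = 80,
                              n_per_window = n, seed = s)[[1]]
    # expected histogram from the discretised target density, bins of 64
    # grid cells so observed and expected share the discretisation
    loge <- -(pot$U(mids) + 80 * (mids + 0.4)^2) / kT
    p <- exp(loge - max(loge)); p <- p / sum(p)
    grp <- rep(seq_len(n_grid / 64), each = 64)
    p_bin <- tapply(p, grp, sum)
    obs <- tabulate(grp[findInterval(w$samples, edges,
                                     rightmost.closed = TRUE)],
                    nbins = n_grid / 64)
    keep <- p_bin * n >= 5
    stat <- sum((obs[keep] - n * p_bin[keep])^2 / (n * p_bin[keep]))
    pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE) > 0.01
  }, logical(1))
  expect_gte(sum(passes), 9)
})

test_that("zero-variance ensembles reproduce their means exactly", {
  fs <- gen_frames(frame_ensemble_spec(20, mean_r = 3.0, sd_r = 0,
                                       mean_theta = 30, sd_theta = 0,
                                       sd_r_cs = 0, seed = 1))
  g <- compute_geometry(fs)
  expect_equal(g$r_cn, rep(3.0, 20), tolerance = 1e-12)
  expect_equal(g$theta, rep(30, 20), tolerance = 1e-6)
})

test_that("the generator/analyzer closure holds to 1e-6", {
  for (m in 0:2) {
    fs <- gen_frames(frame_ensemble_spec(300, methylation = m,
                                         sd_theta = 40, seed = 50 + m))
    g <- compute_geometry(fs)
    d <- attr(fs, "drawn")
    expect_lt(max(abs(g$r_cn - d$r_cn)), 1e-6)
    expect_lt(max(abs(g$r_cs - d$r_cs)), 1e-6)
    expect_lt(max(abs(g$theta - d$theta)), 1e-6)
  }
})

test_that("frame ensembles hit their target statistics at large n", {
  fs <- gen_frames(frame_preset("reactive_wt_like", n_frames = 10000,
                                seed = 7))
  g <- compute_geometry(fs)
  expect_lt(abs(mean(g$r_cn) - 3.0), 3 * 0.15 / sqrt(10000))
  # theta truncates at 0, which shifts the mean slightly above 30
  a <- (0 - 30) / 12; b <- (180 - 30) / 12
  tn_mean <- 30 + 12 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_lt(abs(mean(g$theta) - tn_mean), 3 * sd(g$theta) / sqrt(10000))
})

test_that("different seeds give different coordinates, same statistics", {
  f1 <- gen_frames(frame_preset("reactive_wt_like", n_frames = 4000,
                                seed = 1))
  f2 <- gen_frames(frame_preset("reactive_wt_like", n_frames = 4000,
                                seed = 2))
  expect_false(identical(f1$coords, f2$coords))
  g1 <- compute_geometry(f1); g2 <- compute_geometry(f2)
  se <- sqrt(0.15^2 / 4000 * 2)
  expect_lt(abs(mean(g1$r_cn) - mean(g2$r_cn)), 4 * se)
})

test_that("infeasible ensemble specs are refused", {
  expect_error(
    gen_frames(frame_ensemble_spec(10, mean_r = 1.50001, sd_r = 1e-6,
                                   seed = 1)),
    NA)  # just feasible: half the mass survives truncation
  expect_error(
    gen_frames(frame_ensemble_spec(10, mean_r = 1.6, sd_r = 0.01,
                                   mean_theta = 179.9, sd_theta = 0.01,
                                   seed = 1)),
    NA)
  spec <- frame_ensemble_spec(10, mean_r = 3, sd_r = 0.1, seed = 1)
  spec$mean_r <- 0.2   # force an out-of-range mean past the constructor
  expect_error(gen_frames(spec), "infeasible")
})
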