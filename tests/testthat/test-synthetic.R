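test_that("generators are bit-reproducible under a fixed seed and leave the RNG alone", {
  for (gen in list(function(s) gen_ar1_rr(200, seed = s),
                   function(s) gen_mix_rr(200, 0.4, seed = s),
                   function(s) gen_rsa_rr(200, noise_sd = 10, seed = s))) {
    expect_identical(as.numeric(gen(7)), as.numeric(gen(7)))
  }
  set.seed(123); before <- .Random.seed
  invisible(gen_ar1_rr(50, seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("AR(1) marginal moments and parameter validation", {
  s <- gen_ar1_rr(5000, mean_rr = 800, sd_rr = 50, phi = 0, seed = 51)
  expect_true(sdnn(s) > 46 && sdnn(s) < 54)
  s9 <- gen_ar1_rr(5000, mean_rr = 800, sd_rr = 50, phi = 0.9, seed = 52)
  expect_true(sdnn(s9) > 42 && sdnn(s9) < 58)  # marginal sd preserved
  expect_error(gen_ar1_rr(100, phi = 1), "phi")
  expect_equal(attr(s, "n_resampled"), 0L)
})

test_that("stronger autocorrelation means lower irregularity", {
  wins <- sum(sapply(1:20, function(i) {
    a <- gen_ar1_rr(400, phi = 0.95, seed = 100 + i)
    b <- gen_ar1_rr(400, phi = 0, seed = 200 + i)
    as.numeric(sample_entropy(a)) < as.numeric(sample_entropy(b))
  }))
  expect_gte(wins, 19)
})

test_that("MIX(p) spans periodic to i.i.d. noise with monotone irregularity", {
  p0 <- gen_mix_rr(300, 0, seed = 53)
  se0 <- sample_entropy(p0, entropy_params(r_mode = "absolute", r_abs = 1))
  expect_equal(as.numeric(se0), 0)
  expect_error(gen_mix_rr(100, 1.2), "p")

  wins <- sum(sapply(1:20, function(i) {
    v <- sapply(c(0.1, 0.3, 0.5, 0.9), function(p)
      as.numeric(sample_entropy(gen_mix_rr(500, p, seed = 1000 * p + i))))
    all(diff(v) > 0)
  }))
  expect_gte(wins, 19)
})

test_that("pure RSA modulation is regular with sdnn near amplitude/sqrt(2)", {
  s <- gen_rsa_rr(500, mean_rr = 800, modulation_amplitude = 50,
                  noise_sd = 0, seed = 54)
  expect_equal(sdnn(s), 50 / sqrt(2), tolerance = 0.02)
  se <- sample_entropy(s, entropy_params(r_mode = "absolute", r_abs = 1))
  expect_lt(as.numeric(se), 0.05)
  # added noise raises irregularity
  noisy <- gen_rsa_rr(500, modulation_amplitude = 50, noise_sd = 30,
                      seed = 54)
  expect_gt(as.numeric(sample_entropy(noisy)), as.numeric(sample_entropy(
    gen_rsa_rr(500, modulation_amplitude = 50, noise_sd = 5, seed = 54))))
})

test_that("artifact injection returns an aligned truth mask with exact counts", {
  clean <- gen_ar1_rr(1000, seed = 55)
  inj <- inject_artifacts(clean, rate = 0.005, kind = "spike", seed = 56)
  expect_equal(sum(inj$truth), 5L)
  expect_equal(length(inj$truth), length(inj$series))
  expect_equal(sum(as.numeric(inj$series) != as.numeric(clean)), 5L)

  pair <- inject_artifacts(clean, rate = 0.005, kind = "ectopic_pair",
                           seed = 57)
  expect_equal(sum(pair$truth), 10L)                 # two beats per event
  expect_equal(length(pair$series), 1005L)
  expect_error(inject_artifacts(clean, 0.3, "spike"), "rate")
  expect_error(inject_artifacts(clean, 0.01, "spike", factor = 1.2),
               "factor")
})

test_that("the packaged calibration matches fresh simulation and inverts monotonically", {
  cal <- read.csv(system.file("extdata", "ar1_sampen_calibration_n300.csv",
                              package = "rrsampen"))
  expect_true(all(diff(cal$phi) > 0))
  # spot-check two grid points against fresh simulation
  for (phi in c(0.5, 0.9)) {
    fresh <- mean(sapply(1:60, function(i) as.numeric(
      sample_entropy(gen_ar1_rr(300, phi = phi, seed = 3000 * phi + i)))))
    expect_equal(fresh, cal$sampen_mean[cal$phi == phi], tolerance = 0.05)
  }
  # inverse map: monotone, clamped at the ends
  expect_true(all(diff(sampen_to_phi(c(1.2, 1.0, 0.8, 0.6, 0.4))) > 0))
  expect_equal(sampen_to_phi(2), 0)
  expect_equal(sampen_to_phi(0.01), max(cal$phi))
})

test_that("paired experiments hit their index targets on average", {
  cfg <- experiment_presets("language_paired")
  diffs <- sapply(1:12, function(i) {
    e <- gen_experiment(cfg, seed = 700 + i)
    s <- summarize_experiment(e)
    stats::median(s$sampen[s$condition == "foreign"] -
                  s$sampen[s$condition == "native"])
  })
  # the foreign-condition target sits at the AR(1) dial's i.i.d. ceiling
  # (~1.29 at r = 0.5 x SDNN), so the nominal 0.18 contrast compresses to
  # the generator's realized self-consistency value
  expect_equal(mean(diffs), 0.134, tolerance = 0.03)
  s701 <- summarize_experiment(gen_experiment(cfg, seed = 701))
  meds <- tapply(s701$sampen, s701$condition, stats::median)
  expect_equal(unname(meds["native"]), 1.12, tolerance = 0.06)
  expect_gt(unname(meds["foreign"]), 1.20)
  e <- gen_experiment(cfg, seed = 7)
  expect_equal(length(e$series), 58L)
  expect_equal(nrow(e$manifest), 58L)
  s <- summarize_experiment(e)
  expect_setequal(unique(s$condition), c("native", "foreign"))
  # same subjects appear in both conditions (shared random effects)
  expect_equal(sort(s$subject[s$condition == "native"]),
               sort(s$subject[s$condition == "foreign"]))
})

test_that("timecourse experiments decline in the treated arm only", {
  cfg <- experiment_presets("alcohol_timecourse")
  e <- gen_experiment(cfg, seed = 58)
  s <- summarize_experiment(e)
  expect_setequal(unique(s$condition), c("alcohol", "control"))
  expect_equal(max(s$segment), 6L)
  med <- tapply(s$sampen, list(s$condition, s$segment), stats::median)
  # treated arm ends lower than it starts; arms separate late
  expect_lt(med["alcohol", "6"], med["alcohol", "1"])
  expect_lt(med["alcohol", "6"], med["control", "6"])
})

test_that("learning-onset series dip in variability after the first window", {
  cfg <- experiment_presets("learning_onset")
  e <- gen_experiment(cfg, seed = 59)
  s <- summarize_experiment(e)
  expect_equal(max(s$window), 6L)
  m <- tapply(s$sdnn_ms, s$window, mean)
  expect_gt(m["1"], m["6"])
})
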