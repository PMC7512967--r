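test_that("match counting equals the brute-force oracle on random series", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(30:120, 1)
    x <- random_series(n)
    m <- sample(1:3, 1)
    r <- runif(1, 0.05, 1) * sd(x)
    got <- count_matches(x, m, r)
    want <- oracle_counts(x, m, r)
    expect_identical(got$count_m, as.numeric(want$count_m))
    expect_identical(got$count_m1, as.numeric(want$count_m1))
    expect_equal(got$n_templates, n - m)
  }
})

test_that("tolerance resolution follows the segment SDNN or absolute mode", {
  set.seed(32)
  x <- rnorm(100, 800, 50)
  expect_equal(resolve_tolerance(x), 0.5 * sd(x))
  expect_equal(resolve_tolerance(x, entropy_params(r_coeff = 0.2)),
               0.2 * sd(x))
  expect_equal(resolve_tolerance(x, entropy_params(r_mode = "absolute",
                                                   r_abs = 20)), 20)
  expect_error(resolve_tolerance(rep(700, 10)), "degenerate")
})

test_that("periodic series yield zero entropy; gaps yield the NA sentinel", {
  per <- rep(c(1, 2), 10)
  p_abs <- entropy_params(r_mode = "absolute", r_abs = 0.1)
  se <- sample_entropy(per, p_abs)
  expect_identical(as.numeric(se), 0)
  expect_gt(attr(se, "count_m"), 0)

  nomatch <- sample_entropy(c(1, 10, 100, 1000, 1e4, 1e5),
                            entropy_params(r_mode = "absolute", r_abs = 1))
  expect_true(is.na(nomatch))
  expect_match(attr(nomatch, "reason"), "length m")
  expect_equal(attr(nomatch, "count_m"), 0)

  expect_error(sample_entropy(c(1, 2, 3), entropy_params(m = 2)),
               "at least 4")
})

test_that("entropy is nonnegative and exactly scale-invariant in SDNN mode", {
  set.seed(33)
  for (i in 1:15) {
    x <- pmax(800 + 60 * random_series(sample(50:200, 1)), 1)
    se <- sample_entropy(x)
    if (!is.na(se)) expect_gte(as.numeric(se), 0)
    # power-of-two scalings are exact in floating point
    for (cc in c(0.5, 4)) {
      expect_identical(as.numeric(sample_entropy(cc * x)), as.numeric(se))
    }
  }
})

test_that("entropy agrees with an independently published implementation", {
  skip_if_not_installed("pracma")
  set.seed(34)
  for (i in 1:5) {
    x <- rnorm(150, 800, 40)
    r <- 0.5 * sd(x)
    expect_equal(as.numeric(sample_entropy(x, entropy_params(
      m = 2, r_mode = "absolute", r_abs = r))),
      pracma::sample_entropy(x, edim = 2, r = r, tau = 1))
  }
})

test_that("conditional match probability is m-independent for i.i.d. data", {
  set.seed(35)
  vals <- sapply(1:30, function(i) {
    x <- rnorm(1000)
    sapply(1:2, function(m) as.numeric(sample_entropy(
      x, entropy_params(m = m, r_mode = "absolute", r_abs = 0.5))))
  })
  expect_lt(abs(mean(vals[1, ]) - mean(vals[2, ])), 0.02)
})

test_that("approximate entropy matches its oracle and known fixed points", {
  p_abs <- entropy_params(r_mode = "absolute", r_abs = 5)
  expect_equal(as.numeric(approximate_entropy(rep(700, 30), p_abs)), 0)
  set.seed(36)
  for (i in 1:8) {
    x <- random_series(sample(30:80, 1))
    r <- runif(1, 0.1, 0.8) * sd(x)
    expect_equal(as.numeric(approximate_entropy(
      x, entropy_params(m = 2, r_mode = "absolute", r_abs = r))),
      oracle_apen(x, 2, r))
  }
})

test_that("both entropies rank strongly ordered processes the same way", {
  a <- gen_mix_rr(400, 0.1, seed = 37)
  b <- gen_mix_rr(400, 0.9, seed = 38)
  expect_lt(as.numeric(sample_entropy(a)), as.numeric(sample_entropy(b)))
  expect_lt(as.numeric(approximate_entropy(a)),
            as.numeric(approximate_entropy(b)))
})
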