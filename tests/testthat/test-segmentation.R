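test_that("150 beats under 100/10 windows give the six canonical sections", {
  win <- sliding_windows(rep(800, 150), window_spec(100, 10))
  expect_equal(nrow(win), 6L)
  expect_equal(win$label,
               c("1-100", "11-110", "21-120", "31-130", "41-140", "51-150"))
  expect_equal(nrow(sliding_windows(rep(800, 100))), 1L)
  expect_warning(w0 <- sliding_windows(rep(800, 99)), "shorter")
  expect_equal(nrow(w0), 0L)
})

test_that("window count follows floor((N - L)/S) + 1 on random geometry", {
  set.seed(41)
  for (i in 1:200) {
    L <- sample(2:120, 1)
    S <- sample(1:30, 1)
    n <- L + sample(0:400, 1)
    win <- sliding_windows(rep(800, n), window_spec(L, S))
    expect_equal(nrow(win), floor((n - L) / S) + 1)
    # windows fit inside the series and advance by S
    expect_true(all(win$end <= n))
    if (nrow(win) > 1) expect_true(all(diff(win$start) == S))
    expect_true(all(win$end - win$start + 1 == L))
  }
})

test_that("fixed-duration sections assign beats by elapsed time", {
  seg <- duration_segments(rep(1000, 1800), duration_spec(300))
  expect_equal(nrow(seg), 6L)
  expect_equal(seg$n_beats, rep(300L, 6))

  # 50-beat remainder dropped by default, kept on request
  seg2 <- duration_segments(rep(1000, 1850), duration_spec(300))
  expect_equal(nrow(seg2), 6L)
  seg2k <- duration_segments(rep(1000, 1850), duration_spec(300, "keep"))
  expect_equal(nrow(seg2k), 7L)
  expect_false(seg2k$complete[7])

  # mixed RR summing to 330 s
  x <- c(rep(1100, 273), rep(900, 33))  # 300.3 + 29.7 = 330 s
  expect_equal(nrow(duration_segments(x, duration_spec(300, "keep"))), 2L)
})

test_that("duration segments partition the retained beats", {
  set.seed(42)
  for (i in 1:20) {
    x <- runif(sample(100:1500, 1), 500, 1200)
    spec <- duration_spec(sample(c(60, 120, 300), 1), "keep")
    seg <- duration_segments(x, spec)
    idx <- unlist(lapply(seq_len(nrow(seg)),
                         function(k) seg$start[k]:seg$end[k]))
    expect_identical(idx, seq_along(x))   # every beat exactly once, in order
  }
})

test_that("per-window and per-section summaries use segment-local tolerance", {
  s <- gen_ar1_rr(150, seed = 43)
  hw <- hrv_by_window(s, window_spec(100, 10))
  expect_equal(nrow(hw), 6L)
  first <- as.numeric(unclass(s))[1:100]
  expect_equal(hw$sampen[1], as.numeric(sample_entropy(first)))
  expect_equal(hw$r_ms[1], 0.5 * sdnn(first))

  long <- gen_ar1_rr(1000, mean_rr = 900, seed = 44)
  hs <- hrv_by_segment(long, duration_spec(300))
  expect_equal(nrow(hs), nrow(duration_segments(long, duration_spec(300))))
  expect_true(all(is.finite(hs$sampen)))
})
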