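# Independent brute-force oracles: plain double loops over template pairs,
# sharing no code with the package's counting core.

oracle_counts <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  cm <- 0
  cm1 <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      d <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (d <= r) {
        cm <- cm + 1
        if (abs(x[i + m] - x[j + m]) <= r) cm1 <- cm1 + 1
      }
    }
  }
  list(count_m = cm, count_m1 = cm1)
}

oracle_sampen <- function(x, m, r) {
  cn <- oracle_counts(x, m, r)
  if (cn$count_m == 0 || cn$count_m1 == 0) return(NA_real_)
  -log(cn$count_m1 / cn$count_m)
}

oracle_apen <- function(x, m, r) {
  phi <- function(mm) {
    n <- length(x)
    nt <- n - mm + 1
    tot <- 0
    for (i in 1:nt) {
      c_i <- 0
      for (j in 1:nt) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r)
          c_i <- c_i + 1
      }
      tot <- tot + log(c_i / nt)
    }
    tot / nt
  }
  phi(m) - phi(m + 1)
}

# random test series with mixed marginals and autocorrelation
random_series <- function(n) {
  switch(sample(3, 1),
         rnorm(n),
         runif(n),
         as.numeric(stats::filter(rnorm(n), 0.8, method = "recursive")))
}
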