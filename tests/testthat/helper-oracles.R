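# Independent brute-force oracles used to cross-check the implementation.

# Brute-force circular peak detection with topographic prominence, by naive
# enumeration: rotate the profile so the candidate bin sits first, then scan
# outward bin by bin in each direction for the nearest strictly higher bin,
# taking the minimum over the traversed arc as that side's saddle. Returns
# bin indices and prominences of peaks on the min-max-normalized profile.
oracle_prominent_peaks <- function(profile, threshold) {
  K <- length(profile)
  rng <- max(profile) - min(profile)
  if (rng == 0) return(data.frame(bin = integer(0), prominence = numeric(0)))
  v <- (profile - min(profile)) / rng
  at <- function(j) v[((j - 1) %% K) + 1]
  bins <- integer(0); proms <- numeric(0)
  for (i in seq_len(K)) {
    if (!(at(i) > at(i - 1) && at(i) >= at(i + 1))) next
    side_saddle <- function(dir) {
      lows <- c()
      for (s in 1:(K - 1)) {
        val <- at(i + dir * s)
        if (val > at(i)) break
        lows <- c(lows, val)
      }
      if (length(lows)) min(lows) else at(i)
    }
    prom <- at(i) - max(side_saddle(1), side_saddle(-1))
    if (prom >= threshold) {
      bins <- c(bins, i); proms <- c(proms, prom)
    }
  }
  data.frame(bin = bins, prominence = proms)
}

# Acute angle between two orientations by brute force over all circular
# representations of the difference.
oracle_relative_angle <- function(a, b) {
  min(abs(c(a - b, a - b + 180, a - b - 180, a - b + 360, a - b - 360)))
}

# Otsu threshold by exhaustive search over all candidate cuts: maximize the
# between-class variance of the two populations.
oracle_otsu_threshold <- function(x) {
  xs <- sort(unique(x))
  cuts <- (xs[-1] + xs[-length(xs)]) / 2
  bcv <- vapply(cuts, function(t) {
    lo <- x[x < t]; hi <- x[x >= t]
    length(lo) * length(hi) / length(x)^2 * (mean(hi) - mean(lo))^2
  }, numeric(1))
  cuts[which.max(bcv)]
}

# Random azimuthal profile: baseline plus a random number of wrapped-Gaussian
# bumps at random positions/widths/heights, plus optional noise.
random_profile <- function(K = 24, n_bumps = sample(0:4, 1), noise = 0.05) {
  angles <- seq(0, 360 - 360 / K, by = 360 / K)
  p <- rep(runif(1, 0, 0.5), K)
  for (b in seq_len(n_bumps)) {
    mu <- runif(1, 0, 360)
    sig <- runif(1, 8, 40)
    amp <- runif(1, 0.1, 1)
    d <- ((angles - mu + 180) %% 360) - 180
    p <- p + amp * exp(-d^2 / (2 * sig^2))
  }
  p + rnorm(K, sd = noise)
}

expect_circ_equal <- function(got, want, tol = 1e-6, period = 180) {
  d <- abs(got - want) %% period
  expect_lt(max(pmin(d, period - d)), tol)
}

circ_err <- function(got, want, period = 180) {
  d <- abs(got - want) %% period
  pmin(d, period - d)
}
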