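# Naive re-implementation of the a-trous smoothing (direct indexing loop),
# used as the independent oracle for the transform's detail bands.
naive_starlet_details <- function(x, levels) {
  h <- c(1, 4, 6, 4, 1) / 16
  n <- length(x)
  refl <- function(i) {            # point-symmetric index handling via clamp
    i[i < 1] <- 2 - i[i < 1]
    i[i > n] <- 2 * n - i[i > n]
    i
  }
  a <- x
  d <- matrix(0, levels, n)
  for (j in seq_len(levels)) {
    step <- 2^(j - 1)
    a_next <- numeric(n)
    for (i in seq_len(n)) {
      idx <- refl(i + (-2:2) * step)
      a_next[i] <- sum(h * a[idx])
    }
    d[j, ] <- a - a_next
    a <- a_next
  }
  d
}

test_that("a constant signal yields no modulus-maxima chains", {
  expect_length(wavelet_transform_maxima(rep(3.3, 128), 4), 0)
})

test_that("an isolated impulse is tracked by one chain across every scale", {
  x <- numeric(256)
  x[128] <- 1
  chains <- wavelet_transform_maxima(x, 4)
  spans <- vapply(chains, function(ch) length(ch$scales), integer(1))
  full <- chains[spans == 4L]
  expect_length(full, 1L)
  # positioned at the impulse within the propagation radius at every scale
  expect_true(all(abs(full[[1]]$positions - 128) <=
                    sapply(full[[1]]$scales, function(j) ceiling(2^j / 2))))
  # the remaining maxima are unlinked single-scale sidelobes
  expect_true(all(spans[spans != 4L] == 1L))

  # oracle: per-scale brute-force maxima scan agrees on the tracked positions
  d <- naive_starlet_details(x, 4)
  for (k in seq_along(full[[1]]$scales)) {
    j <- full[[1]]$scales[k]
    av <- abs(d[j, ])
    p <- full[[1]]$positions[k]
    expect_true(av[p] > av[p - 1] && av[p] > av[p + 1])
  }
})

test_that("noise chains mostly decay with scale; smooth structure grows", {
  set.seed(7)
  n_trials <- 5
  frac_neg <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    noise <- rnorm(512, sd = 0.5)
    betas <- vapply(wavelet_transform_maxima(noise, 4), `[[`, numeric(1),
                    "beta_hat")
    frac_neg[i] <- mean(betas < 0)
  }
  expect_true(all(frac_neg > 0.5))  # majority vote, every trial

  # a smooth bump's dominant chain grows with scale
  x <- exp(-((1:512) - 256)^2 / (2 * 20^2))
  chains <- wavelet_transform_maxima(x, 4)
  spans <- vapply(chains, function(ch) length(ch$scales), integer(1))
  mags <- vapply(chains, function(ch) max(ch$magnitudes), numeric(1))
  dom <- chains[[which.max(mags)]]
  expect_gte(dom$beta_hat, 0)
})

test_that("classification partitions chains by the fitted growth exponent", {
  mk <- function(mags, scales = seq_along(mags)) {
    ch <- list(positions = rep(1L, length(mags)), scales = scales,
               magnitudes = mags)
    ch$beta_hat <- if (length(scales) >= 2) {
      lg <- log2(mags)
      sum((scales - mean(scales)) * (lg - mean(lg))) /
        sum((scales - mean(scales))^2)
    } else -Inf
    ch
  }
  doubling <- mk(c(1, 2, 4, 8))   # beta = +1
  halving <- mk(c(8, 4, 2, 1))    # beta = -1
  single <- mk(5, scales = 2L)
  res <- classify_and_prune(list(doubling, halving, single), 0)
  expect_length(res$kept, 1)
  expect_length(res$removed, 2)
  expect_equal(res$kept[[1]]$beta_hat, 1)
  # single-scale chains are classified (as noise), never dropped
  expect_true(any(vapply(res$removed, function(ch) !is.finite(ch$beta_hat),
                         logical(1))))
  empty <- classify_and_prune(list(), 0)
  expect_length(empty$kept, 0)
  expect_length(empty$removed, 0)
})

test_that("keeping all chains reconstructs the signal within 5 percent", {
  t <- seq(0, 1, length.out = 512)
  x <- sin(2 * pi * 3 * t)
  chains <- wavelet_transform_maxima(x, 4)
  y <- reconstruct_from_maxima(chains, x, 4)
  expect_lt(rel_l2(y, x), 0.05)
  expect_identical(denoise_signal(numeric(64), 4), numeric(64))
})

test_that("pruning noise chains reduces RMSE to the clean signal", {
  set.seed(21)
  t <- seq(0, 1, length.out = 1024)
  clean <- sin(2 * pi * 3 * t)
  noisy <- clean + rnorm(1024, sd = 0.3)
  den <- denoise_signal(noisy, 4)
  expect_lt(sqrt(mean((den - clean)^2)), sqrt(mean((noisy - clean)^2)))
})

test_that("denoising does not oscillate and removes bounded energy", {
  set.seed(33)
  t <- seq(0, 1, length.out = 1024)
  clean <- sin(2 * pi * 3 * t)
  noise <- rnorm(1024, sd = 0.3)
  x <- clean + noise
  d1 <- denoise_signal(x, 4)
  d2 <- denoise_signal(d1, 4)
  # second pass changes the output by no more than the first pass did
  expect_lte(sqrt(sum((d2 - d1)^2)), sqrt(sum((d1 - x)^2)))
  # energy removed is bounded by the injected noise energy times a factor
  expect_lte(sum((x - d1)^2), 1.5 * sum(noise^2))
})

test_that("short signals and bad levels are rejected", {
  expect_error(wavelet_transform_maxima(rnorm(8), 4), "shorter")
  expect_error(wavelet_transform_maxima(rnorm(64), 1), ">= 2")
})
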