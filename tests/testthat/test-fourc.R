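test_that("binarization marks any covered fragment", {
  expect_equal(binarize(c(0, 3, 1, 0)), c(0L, 1L, 1L, 0L))
  expect_equal(binarize(rep(0, 5)), rep(0L, 5))
  expect_equal(binarize(1), 1L)
  expect_error(binarize(c(1, -1)), "non-negative")
})

test_that("sliding z-score matches the proportion-test formula", {
  # construct a track where the central w-window has 30/100 covered and
  # the W background (the whole 3000-fragment track at the center) 300/3000
  n <- 3000
  binary <- rep(0L, n)
  center <- 1500
  win <- (center - 49):(center + 50)
  binary[win[1:30]] <- 1L
  outside <- setdiff(seq_len(n), win)
  binary[outside[seq(1, length(outside), length.out = 270)]] <- 1L
  stopifnot(sum(binary) == 300)

  z <- sliding_zscore(binary, fourc_config(w = 100, W = 3000))
  expect_equal(z$p_w[center], 0.3)
  expect_equal(z$p_W[center], 0.1)
  expect_equal(z$z[center], (0.3 - 0.1) / sqrt(0.1 * 0.9 / 100),
               tolerance = 1e-12)
  expect_equal(z$z[center], 6.6667, tolerance = 1e-4)

  # the event this approximates is extreme under the exact binomial too
  expect_lt(pbinom(29, 100, 0.1, lower.tail = FALSE), 1e-7)
})

test_that("normal-approximate window p agrees with the exact binomial tail", {
  # moderate signal where the approximation should be close in absolute
  # terms: 16/100 covered on a 0.1 background
  z <- (0.16 - 0.1) / sqrt(0.1 * 0.9 / 100)
  p_norm <- pnorm(z, lower.tail = FALSE)
  p_exact <- pbinom(15, 100, 0.1, lower.tail = FALSE)
  expect_lt(abs(p_norm - p_exact), 0.02)
})

test_that("edge-truncated windows use the actual window size", {
  withr::with_seed(17, binary <- rbinom(300, 1, 0.3))
  cfg <- fourc_config(w = 10, W = 50)
  z <- sliding_zscore(binary, cfg)
  for (i in c(1, 2, 5, 150, 296, 300)) {
    p_w <- brute_window_fraction(binary, 10, i)
    p_W <- brute_window_fraction(binary, 50, i)
    lo <- max(i - 4, 1)
    hi <- min(i + 5, 300)
    n_w <- hi - lo + 1
    expect_equal(z$p_w[i], p_w, tolerance = 1e-12)
    expect_equal(z$p_W[i], p_W, tolerance = 1e-12)
    expect_equal(z$n_w[i], n_w)
    expected_z <- if (p_W <= 0 || p_W >= 1) 0 else
      (p_w - p_W) / sqrt(p_W * (1 - p_W) / n_w)
    expect_equal(z$z[i], expected_z, tolerance = 1e-12)
  }
  expect_error(sliding_zscore(rep(1L, 5), fourc_config(w = 10, W = 20)),
               "shorter than the window")
})

test_that("degenerate backgrounds give z = 0", {
  z <- sliding_zscore(rep(1L, 500), fourc_config(w = 10, W = 100))
  expect_true(all(z$z == 0))
  z0 <- sliding_zscore(rep(0L, 500), fourc_config(w = 10, W = 100))
  expect_true(all(z0$z == 0))
})

test_that("interaction calling reproduces a by-hand BH step-up", {
  withr::with_seed(41, z_null <- rnorm(1000))
  z <- c(z_null, rep(6.5, 5))
  zt <- tibble::tibble(index = seq_along(z), z = z)
  calls <- call_interactions(zt, mode = "cis", config = fourc_config())
  p <- pnorm(z, lower.tail = FALSE)
  expect_equal(which(calls$significant), bh_reject(p, 0.01))
  # the planted windows are all called
  expect_true(all(calls$significant[1001:1005]))

  # trans calls are a subset of cis calls on the same z vector
  trans <- call_interactions(zt, mode = "trans", config = fourc_config())
  expect_true(all(calls$significant[trans$significant]))
  expect_equal(which(trans$significant), bh_reject(p, 0.005))

  # all-zero z yields no calls
  none <- call_interactions(tibble::tibble(index = 1:100, z = rep(0, 100)),
                            mode = "cis")
  expect_false(any(none$significant))
})

test_that("cis mode masks the viewpoint neighborhood before testing", {
  z <- tibble::tibble(index = 1:1000, z = rep(0, 1000))
  z$z[c(500, 900)] <- 8
  calls <- call_interactions(z, mode = "cis", config = fourc_config(),
                             viewpoint_index = 500)
  expect_false(500 %in% calls$index)
  expect_true(calls$significant[calls$index == 900])
  # trans mode has no viewpoint on the chromosome: nothing masked
  trans <- call_interactions(z, mode = "trans", config = fourc_config(),
                             viewpoint_index = 500)
  expect_true(500 %in% trans$index)
})

test_that("monotonicity: covering more fragments never lowers z", {
  withr::with_seed(3, binary <- rbinom(2000, 1, 0.1))
  cfg <- fourc_config(w = 50, W = 500)
  z1 <- sliding_zscore(binary, cfg)
  i <- which(binary == 0)[100]
  binary2 <- binary
  binary2[i] <- 1L
  z2 <- sliding_zscore(binary2, cfg)
  expect_gte(z2$z[i], z1$z[i])
})

test_that("significant windows merge into maximal runs with coordinates", {
  calls <- tibble::tibble(index = 1:10, z = 0, p = 1, q = 1,
                          significant = FALSE)
  calls$significant[c(2, 3, 4, 7, 9, 10)] <- TRUE
  calls$z[calls$significant] <- 5
  calls$q[calls$significant] <- 0.001
  track <- tibble::tibble(chrom = "chr17", start = (0:9) * 100,
                          end = (1:10) * 100, count = 1)
  runs <- merge_interaction_calls(calls, track)
  expect_equal(runs$from, c(2, 7, 9))
  expect_equal(runs$to, c(4, 7, 10))
  expect_equal(runs$start, c(100, 600, 800))
  expect_equal(runs$end, c(400, 700, 1000))
})

test_that("smoothing is a shrinking centered moving average, per million", {
  track <- tibble::tibble(chrom = "chr17", start = (0:99) * 500,
                          end = (1:100) * 500, count = 7)
  sm <- smooth_track(track, fourc_config(smooth_k = 21),
                     library_size = 1e6)
  expect_equal(sm$value, rep(7, 100))

  # single covered fragment spreads into a 21-fragment plateau of 21/21
  spike <- dplyr::mutate(track, count = ifelse(dplyr::row_number() == 50,
                                               21, 0))
  sm <- smooth_track(spike, fourc_config(smooth_k = 21),
                     library_size = 1e6)
  expect_equal(sum(sm$value > 0), 21)
  expect_equal(sm$value[40:60], rep(1, 21))

  # edge windows shrink: first fragment averages over 11 fragments
  edge <- dplyr::mutate(track, count = ifelse(dplyr::row_number() == 1,
                                              22, 0))
  sm <- smooth_track(edge, fourc_config(smooth_k = 21),
                     library_size = 1e6)
  expect_equal(sm$value[1], 2)

  expect_error(smooth_track(track, library_size = 0), "positive")
})

test_that("domainogram cells equal brute-force recounts", {
  withr::with_seed(29, binary <- rbinom(200, 1, 0.4))
  sizes <- c(1, 5, 21, 50)
  dg <- domainogram(binary, sizes)
  expect_true(all(dg$fraction >= 0 & dg$fraction <= 1))
  # size-1 row is the binary signal itself
  expect_equal(dg$fraction[dg$window_size == 1], as.numeric(binary))
  for (k in sizes) {
    row <- dg$fraction[dg$window_size == k]
    brute <- vapply(1:200, function(i) brute_window_fraction(binary, k, i),
                    numeric(1))
    expect_equal(row, brute, tolerance = 1e-12)
  }
  # all-ones signal gives fraction 1 everywhere
  ones <- domainogram(rep(1L, 50), c(3, 9))
  expect_true(all(ones$fraction == 1))
  # the w-sized row reproduces sliding_zscore's p_w exactly
  z <- sliding_zscore(binary, fourc_config(w = 21, W = 100))
  expect_equal(dg$fraction[dg$window_size == 21], z$p_w)
})
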