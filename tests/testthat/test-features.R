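test_that("power spectrum satisfies the discrete Parseval identity", {
  withr::with_seed(11, {
    x <- matrix(rnorm(64, 100, 20), 8, 8)
  })
  sp <- power_spectrum(x)
  n <- length(x)
  expect_equal(sum(sp$power), n * sum(x^2), tolerance = 1e-12)
  nondc <- sum(sp$power) - sp$power[sp$freq_radius == 0]
  expect_equal(nondc, n * sum((x - mean(x))^2), tolerance = 1e-9)

  # constant frame: everything in the DC bin
  spc <- power_spectrum(matrix(128, 8, 8))
  expect_equal(spc$power[spc$freq_radius > 0], rep(0, 63))
  expect_equal(sum(spc$freq_radius == 0), 1)

  expect_error(power_spectrum(matrix(1, 2, 2)), "too small")
})

test_that("power spectrum is invariant under circular shifts", {
  withr::with_seed(12, x <- matrix(rnorm(32 * 24), 32, 24))
  sp0 <- power_spectrum(x)$power
  for (sh in list(c(1, 0), c(0, 5), c(7, 11))) {
    xs <- x[((seq_len(32) - 1 + sh[1]) %% 32) + 1,
            ((seq_len(24) - 1 + sh[2]) %% 24) + 1]
    expect_equal(power_spectrum(xs)$power, sp0, tolerance = 1e-9)
  }
})

test_that("shell integration matches brute-force annulus bookkeeping", {
  # impulse image: flat power, so shells are proportional to bin counts
  imp <- matrix(0, 16, 16); imp[5, 9] <- 1
  f <- shell_integrate(power_spectrum(imp), n_shells = 100)
  breaks <- 0.5 * (0:100) / 100
  counts <- numeric(100)
  for (u in -8:7) for (v in -8:7) {
    r <- sqrt((u / 16)^2 + (v / 16)^2)
    if (r > 0 && r <= 0.5 + 1e-12) {
      k <- which(r <= breaks[-1] + 1e-12)[1]
      counts[k] <- counts[k] + 1
    }
  }
  expect_equal(as.numeric(f), counts / sum(counts), tolerance = 1e-12)
  expect_equal(sum(f), 1, tolerance = 1e-12)

  # all non-DC power in one bin at radius 0.26 lands in shell 52
  n <- 100
  s <- 0:(n - 1); s[s >= 50] <- s[s >= 50] - n; s <- sort(s)
  r <- sqrt(outer((s / n)^2, (s / n)^2, "+"))
  pw <- matrix(0, n, n)
  pw[which(s == 10), which(s == 24)] <- 5  # sqrt(0.01 + 0.0576) = 0.26
  spec <- structure(list(power = pw, freq_radius = r, dim = c(n, n)),
                    class = "centered_spectrum")
  f2 <- as.numeric(shell_integrate(spec, n_shells = 100))
  expect_equal(which(f2 > 0), 52L)
  expect_equal(f2[52], 1)

  # zero retained power gives the all-zero profile
  fz <- shell_integrate(power_spectrum(matrix(77, 12, 12)))
  expect_equal(as.numeric(fz), rep(0, 100))
  expect_equal(attr(fz, "retained_power"), 0)
})

test_that("features are rotation, shift and brightness invariant and normalized", {
  rot90 <- function(m) t(m)[, nrow(m):1]
  for (seed in 1:5) {
    withr::with_seed(seed, x <- matrix(rnorm(48 * 48, 120, 25), 48, 48))
    f0 <- as.numeric(extract_features(x))
    expect_true(all(f0 >= 0))
    expect_equal(sum(f0), 1, tolerance = 1e-9)
    r90 <- rot90(x); r180 <- rot90(r90); r270 <- rot90(r180)
    for (xr in list(r90, r180, r270))
      expect_equal(as.numeric(extract_features(xr)), f0, tolerance = 1e-9)
    xs <- x[c(9:48, 1:8), c(30:48, 1:29)]
    expect_equal(as.numeric(extract_features(xs)), f0, tolerance = 1e-9)
    expect_equal(as.numeric(extract_features(x + 17)), f0, tolerance = 1e-9)
  }
})

test_that("high-frequency intensity sums the shells above the cutoff", {
  expect_equal(as.numeric(high_frequency_intensity(rep(0.01, 100))), 0.7)
  low_only <- c(rep(1 / 30, 30), rep(0, 70))
  expect_equal(as.numeric(high_frequency_intensity(low_only)), 0)
  one_hot31 <- replace(rep(0, 100), 31, 1)
  expect_equal(as.numeric(high_frequency_intensity(one_hot31)), 1)
  expect_error(high_frequency_intensity(rep(0.01, 100), cutoff = 100), "1..99")
  expect_error(high_frequency_intensity(rep(0.01, 100), cutoff = 0), "1..99")
})

test_that("shell profiles are comparable across image sizes at fixed pixel pitch", {
  # per-pixel frequencies chosen to complete whole cycles at both sizes
  pattern <- function(n) {
    i <- matrix(seq_len(n) - 1, n, n)
    j <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
    2 * sin(2 * pi * (16 / 128) * i) + cos(2 * pi * (33 / 128) * j) +
      0.7 * sin(2 * pi * ((24 / 128) * i + (18 / 128) * j))
  }
  f128 <- as.numeric(extract_features(pattern(128)))
  f256 <- as.numeric(extract_features(pattern(256)))
  expect_equal(which.max(f128), which.max(f256))
  expect_equal(which.max(f128), 25L)  # radius 0.125 -> shell 25
  expect_gt(cor(f128, f256), 0.9)
})

test_that("white-noise shell weights are proportional to annulus bin counts", {
  n_rep <- 100
  acc <- numeric(100)
  for (i in seq_len(n_rep)) {
    withr::with_seed(1000 + i, x <- matrix(rnorm(64 * 64), 64, 64))
    acc <- acc + as.numeric(extract_features(x))
  }
  mean_profile <- acc / n_rep
  sp <- power_spectrum(matrix(0:(64 * 64 - 1), 64, 64))
  r <- sp$freq_radius
  keep <- r > 0 & r <= 0.5
  idx <- pmax(1L, as.integer(ceiling(r[keep] / 0.005 - 1e-9)))
  counts <- tabulate(idx, 100)
  expected <- counts / sum(counts)
  big <- counts >= 20
  expect_gt(cor(mean_profile[big], expected[big]), 0.995)
  expect_lt(max(abs(mean_profile[big] - expected[big]) / expected[big]), 0.1)
})

test_that("batch extraction keeps metadata and reports failures", {
  cfg <- small_cfg()
  ds <- generate_dataset(cfg)
  tab <- batch_extract(ds$images[1:3])
  expect_equal(nrow(tab), 3)
  expect_length(shell_columns(tab), 100)
  expect_true(all(c("well_id", "day", "position", "myf5_pct") %in% names(tab)))
  expect_equal(tab$well_id, vapply(ds$images[1:3], `[[`, "", "well_id"))

  # one unreadable file among readable ones: skipped with a warning
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.png"); p2 <- file.path(dir, "b.png")
  write_image_png(ds$images[[1]], p1)
  write_image_png(ds$images[[2]], p2)
  bad <- file.path(dir, "missing.png")
  expect_warning(tab2 <- batch_extract(c(p1, bad, p2)), "skipped")
  expect_equal(nrow(tab2), 2)
  expect_length(attr(tab2, "failures"), 1)

  expect_error(batch_extract(list()), "non-empty")
})
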