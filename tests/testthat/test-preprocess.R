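test_that("resampling is the identity on-grid and interpolates triangles", {
  grid <- standard_grid()
  expect_equal(length(grid), (500 - 50) / 0.0005 + 1)
  expect_equal(grid[2] - grid[1], 0.0005)

  # a scan already on the grid is reproduced exactly
  sub <- 100000:100100
  scan <- list(mz = grid[sub], intensity = sin(seq_along(sub)))
  expect_equal(resample_spectrum(scan)[sub], scan$intensity)

  # analytic triangle: apex recovered within one grid step
  apex <- 150.00013   # deliberately off-grid
  mzs <- c(apex - 0.01, apex, apex + 0.01)
  r <- resample_spectrum(list(mz = mzs, intensity = c(0, 100, 0)))
  expect_lt(abs(grid[which.max(r)] - apex), 0.0005 + 1e-12)

  # empty scan -> all zeros; unsorted input is a data error
  expect_true(all(resample_spectrum(list(mz = numeric(),
                                         intensity = numeric())) == 0))
  expect_error(resample_spectrum(list(mz = c(2, 1), intensity = c(0, 0))),
               "ascending")
})

test_that("exhalation detection finds square-wave plateaus with correct bounds", {
  # 3 plateaus of 12 scans (6 s) over baseline, breaks of 20 scans
  tic <- rep(10, 120)
  starts <- c(21, 53, 85)
  for (s in starts) tic[s:(s + 11)] <- 1000
  tic <- tic + rep_len(c(-.1, .1), 120)        # avoid zero MAD pathologies
  seg <- detect_exhalations(tic, scan_period = 0.5)$segments
  expect_equal(nrow(seg), 3)
  expect_true(all(abs(seg$start - starts) <= 1))
  expect_true(all(abs(seg$end - (starts + 12)) <= 1))

  # constant TIC: nothing exceeds median + k*MAD
  expect_equal(nrow(detect_exhalations(rep(5, 50), 0.5)$segments), 0)

  # a single long plateau (minority duty cycle) spans one segment
  tic1 <- c(rep(10, 40), rep(800, 25), rep(10, 40))
  seg1 <- detect_exhalations(tic1, 0.5)
  expect_equal(nrow(seg1$segments), 1)
  expect_equal(seg1$segments$start, 41)
  expect_equal(seg1$segments$end, 66)
  expect_true(seg1$warn_few)                   # fewer than 3 -> flagged

  expect_error(detect_exhalations(rep(1, 10), 0.5), "20 scans")
})

test_that("averaging exhalation scans is a pointwise mean", {
  grid <- seq(100, 101, by = 0.0005)
  mk <- function(v, t) list(time = t, mz = grid, intensity = rep(v, length(grid)))
  ser <- structure(list(scans = list(mk(2, 0), mk(4, 0.5), mk(99, 1)),
                        polarity = "pos", sample_id = "s"),
                   class = "scan_series")
  seg <- data.frame(start = 1, end = 3)        # scans 1-2 only
  avg <- average_exhalation_spectrum(ser, seg, grid)
  expect_equal(unique(avg), 3)                 # (2+4)/2, scan 3 excluded
})

test_that("peak picking recovers analytic Gaussian areas and apexes", {
  grid <- seq(100, 110, by = 0.0005)
  A <- 5000; mu <- 104.2; sig <- 0.004
  spec <- A * dnorm(grid, mu, sig)
  pk <- pick_peaks(spec, grid)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$area, A, tolerance = 0.01)   # analytic area oracle
  expect_lt(abs(pk$apex_mz - mu), 0.0005 + 1e-12)

  # flat baseline: no peaks
  expect_equal(nrow(pick_peaks(rep(3, length(grid)), grid)), 0)

  # two Gaussians > 4 sigma apart resolve into two peaks
  mu2 <- mu + 6 * sig
  spec2 <- A * dnorm(grid, mu, sig) + 0.7 * A * dnorm(grid, mu2, sig)
  pk2 <- pick_peaks(spec2, grid)
  expect_equal(nrow(pk2), 2)
  expect_lt(abs(pk2$apex_mz[1] - mu), 0.001)
  expect_lt(abs(pk2$apex_mz[2] - mu2), 0.001)
})

test_that("trapezoid equals analytic area for on-grid triangles", {
  grid <- seq(50, 51, by = 0.0005)
  apex_i <- 1001
  half_w <- 200                                 # grid points per side
  tri <- pmax(0, 1 - abs(seq_along(grid) - apex_i) / half_w) * 80
  pk <- pick_peaks(tri, grid)
  analytic <- 0.5 * (2 * half_w * 0.0005) * 80  # base x height / 2
  expect_equal(pk$area, analytic, tolerance = 1e-9)
})

test_that("feature alignment merges within tolerance and applies presence filter", {
  pt <- function(mz, area = 100) data.frame(apex_mz = mz, left_mz = mz - .01,
                                            right_mz = mz + .01, area = area,
                                            apex_intensity = area)
  # identical tables: feature count equals peak count, nothing imputed
  tabs <- list(a = pt(c(100, 200, 300)), b = pt(c(100, 200, 300)))
  al <- align_features(tabs, tol_ppm = 10, presence_fraction = 0.7)
  expect_equal(length(al$feature_mz), 3)
  expect_false(anyNA(al$values))

  # 1 ppm apart with 10 ppm tolerance: merged into one feature
  tabs2 <- list(a = pt(200), b = pt(200 * (1 + 1e-6)))
  al2 <- align_features(tabs2, tol_ppm = 10)
  expect_equal(length(al2$feature_mz), 1)
  # consensus is the intensity-weighted mean
  expect_equal(al2$feature_mz,
               weighted.mean(c(200, 200 * (1 + 1e-6)), c(100, 100)))

  # presence 1/10 below fraction 0.7: dropped
  tabs3 <- c(list(pt(c(100, 150))), replicate(9, pt(100), simplify = FALSE))
  names(tabs3) <- sprintf("s%02d", 1:10)
  al3 <- align_features(tabs3, tol_ppm = 10, presence_fraction = 0.7)
  expect_equal(length(al3$feature_mz), 1)

  expect_error(align_features(tabs, tol_ppm = 0), "tol_ppm")
})

test_that("TIC normalization, imputation and log2 behave as specified", {
  al <- list(values = matrix(c(2, 3, 5,
                               4, 6, 10), 2, 3, byrow = TRUE,
                             dimnames = list(c("a", "b"), NULL)),
             feature_mz = c(100, 200, 300), sample_ids = c("a", "b"))
  bp <- normalize_and_log(al)
  expect_equal(2^bp$values[1, ], c(0.2, 0.3, 0.5), ignore_attr = TRUE)
  expect_equal(sum(2^bp$values[1, ]), 1)
  # doubling a sample's raw areas changes nothing (scale invariance, exact)
  expect_equal(bp$values[1, ], bp$values[2, ], ignore_attr = TRUE)

  # missing cells get half the smallest positive normalized value
  al$values[1, 2] <- NA
  bp2 <- normalize_and_log(al)
  norm_row <- c(2, 5) / 7
  expect_equal(2^bp2$values[1, 2], min(norm_row) / 2, ignore_attr = TRUE)
})

test_that("end-to-end: noiseless synthetic recordings recover planted features", {
  cfg <- tiny_raw_config(noise_floor = 0, scan_jitter_sd = 0,
                         noise_sd_log2 = 0.2)
  coh <- simulate_cohort(cfg)
  n <- nrow(coh$abundances)
  recs <- lapply(seq_len(n), function(i) simulate_raw_sample(coh, i, cfg))
  res <- preprocess_cohort(recs, presence_fraction = 0.7)
  prof <- res$profile
  expect_true(all(res$qc$n_exhalations == 3))
  # >= 99% of planted features recovered within 5 ppm
  hit <- vapply(coh$truth$feature_mz, function(m)
    any(abs(prof$feature_mz - m) / m * 1e6 < 5), TRUE)
  expect_gte(mean(hit), 0.99)
  # log2 profile monotone in planted abundance within a sample: compare
  # ranks of matched features (satellite isotopes of skipped parents aside)
  j <- vapply(coh$truth$feature_mz, function(m)
    which.min(abs(prof$feature_mz - m)), 1L)
  planted <- coh$abundances[1, ]
  recovered <- prof$values[1, j]
  expect_gt(cor(planted, recovered, method = "spearman"), 0.95)
  # TIC-normalization scale invariance on raw recordings, exact
  rec_scaled <- recs[[1]]
  for (s in seq_along(rec_scaled$scans))
    rec_scaled$scans[[s]]$intensity <- rec_scaled$scans[[s]]$intensity * 7
  p1 <- process_recording(recs[[1]])$peaks
  p2 <- process_recording(rec_scaled)$peaks
  expect_equal(p2$area / p1$area, rep(7, nrow(p1)))
  expect_equal(p1$area / sum(p1$area), p2$area / sum(p2$area))
})
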