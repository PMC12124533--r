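test_that("m/z rounding merges channels half-up and conserves ion count", {
  rc <- RawChromatogram(1:3, c(23.6, 23.7), matrix(c(1, 2, 3, 4, 5, 6), 3))
  b <- roundMz(rc)
  expect_equal(mzValues(b), 24)
  expect_equal(as.numeric(intensities(b)), c(5, 7, 9))  # summed
  expect_equal(sum(intensities(b)), sum(intensities(rc)))

  ## integer axis is the identity
  rc2 <- RawChromatogram(1:2, c(50, 51), matrix(1:4, 2))
  expect_identical(intensities(roundMz(rc2)), intensities(rc2))

  ## half-up tie rule: 23.5 -> 24, independent of parity
  rc3 <- RawChromatogram(1:2, c(23.5, 24.5), matrix(1, 2, 2))
  expect_equal(mzValues(roundMz(rc3)), c(24, 25))

  ## conservation on a random fixture with many collisions
  set.seed(3)
  mz <- sort(runif(40, 50, 60))
  rc4 <- RawChromatogram(1:5, mz, matrix(rpois(200, 30), 5))
  expect_equal(sum(intensities(roundMz(rc4))), sum(intensities(rc4)))
})

test_that("TIC sums each timestep over all m/z bins", {
  b <- BinnedChromatogram(1:2, c(50, 51), matrix(c(1, 3, 2, 4), 2))
  expect_equal(computeTic(b)$total, c(3, 7))
  z <- BinnedChromatogram(1:3, 50, matrix(0, 3, 1))
  expect_equal(computeTic(z)$total, rep(0, 3))
  one <- BinnedChromatogram(1:3, 50, matrix(c(5, 6, 7), 3, 1))
  expect_equal(computeTic(one)$total, c(5, 6, 7))
})

test_that("time segmentation uses the ceiling rule and tiles the run", {
  g <- segmentTime(41, 1.5)
  expect_equal(nSegments(g), 28L)
  widths <- g@boundaries[, 2] - g@boundaries[, 1]
  expect_equal(round(widths[1], 1), 1.5)   # 41/28 = 1.464...
  expect_true(all(abs(widths - 41 / 28) < 1e-12))

  g2 <- segmentTime(3, 1.5)
  expect_equal(unname(g2@boundaries[, 1]), c(0, 1.5))
  expect_equal(unname(g2@boundaries[, 2]), c(1.5, 3))

  expect_error(segmentTime(-1, 1.5), "tTotal")
  expect_error(segmentTime(41, 0), "dt")
})

test_that("quantile noise correction matches the worked subtraction rule", {
  ## one segment, one channel whose 15th percentile is 400
  vals <- c(1000, 390, seq(400, 800, length.out = 18))
  q15 <- unname(quantile(vals, 0.15, type = 7))
  b <- BinnedChromatogram(seq(0.1, 2, length.out = 20), 50,
                          matrix(vals, 20, 1))
  g <- segmentTime(2, 2)
  out <- intensities(quantileNoiseCorrect(b, g, 0.15))
  expect_equal(out[1, 1], 1000 - q15)
  expect_equal(out[2, 1], 0)               # 390 clamps at 0
})

test_that("quantile threshold agrees with a sorted-interpolation oracle", {
  ## brute-force oracle: sort, take rank (n-1)q with linear interpolation
  oracle <- function(x, q) {
    s <- sort(x)
    r <- (length(x) - 1) * q
    lo <- floor(r); hi <- ceiling(r)
    s[lo + 1] + (r - lo) * (s[hi + 1] - s[lo + 1])
  }
  vals <- seq(0, 1900, by = 100)
  expect_equal(lerpQuantile <- scentpipe:::lerpQuantile(vals, 0.15),
               oracle(vals, 0.15))
  set.seed(8)
  for (i in 1:10) {
    x <- rgamma(sample(5:40, 1), 2, 0.01)
    q <- runif(1)
    expect_equal(scentpipe:::lerpQuantile(x, q), oracle(x, q))
  }
})

test_that("quantile correction contract: nonnegative, zero cell quantile, idempotent, order-preserving", {
  ## 21 timesteps per cell so the type-7 rank (n-1)*0.15 = 3 is integral
  ## and the corrected cell's 15th percentile is exactly 0 (between order
  ## statistics the interpolated quantile is merely near 0)
  g <- segmentTime(2, 0.5)
  for (seed in 1:20) {
    set.seed(seed)
    T <- 84L; M <- 3L
    b <- BinnedChromatogram((seq_len(T) - 0.5) * 2 / T,   # segment centres
                            c(50L, 51L, 52L),
                            matrix(rgamma(T * M, 2, 0.01), T, M))
    out <- quantileNoiseCorrect(b, g, 0.15)
    I <- intensities(out)
    expect_true(all(I >= 0))
    ## the 15th percentile of every corrected cell is 0
    seg <- scentpipe:::segmentIndex(scanTimes(out), g)
    expect_true(all(table(seg) == 21L))
    for (s in unique(seg)) for (m in 1:M) {
      expect_equal(unname(quantile(I[seg == s, m], 0.15, type = 7)), 0)
    }
    ## idempotent
    out2 <- quantileNoiseCorrect(out, g, 0.15)
    expect_equal(intensities(out2), I)
    ## relative order within cells preserved: no strict inversions
    raw <- intensities(b)
    for (s in unique(seg)) for (m in 1:M) {
      r <- raw[seg == s, m]; c <- I[seg == s, m]
      expect_false(any(outer(r, r, "<") & outer(c, c, ">")))
    }
  }

  ## constant cell collapses to zero
  cst <- BinnedChromatogram(seq(0.1, 1, length.out = 10), 50,
                            matrix(7, 10, 1))
  expect_true(all(intensities(
    quantileNoiseCorrect(cst, segmentTime(1, 1), 0.15)) == 0))
})

test_that("baseline correction removes polynomials and keeps peak heights", {
  times <- seq(0, 2, length.out = 200)
  ## pure degree-2 baseline, no peaks -> output ~ 0
  base <- 100 + 50 * times - 10 * times^2
  b <- BinnedChromatogram(times, 50, matrix(base, ncol = 1))
  out <- intensities(baselineDriftCorrect(b, degree = 2L))
  expect_lt(max(abs(out)), 1e-6 * max(base))

  ## linear ramp + Gaussian peak: recovered height within 5%
  h <- 1000
  sig <- h * exp(-0.5 * ((times - 1) / 0.05)^2)
  ramp <- 20 + 80 * times
  b2 <- BinnedChromatogram(times, 50, matrix(ramp + sig, ncol = 1))
  out2 <- intensities(baselineDriftCorrect(b2, degree = 2L))
  expect_lt(abs(max(out2) - h) / h, 0.05)

  ## all-zero input stays zero
  z <- BinnedChromatogram(times, 50, matrix(0, 200, 1))
  expect_true(all(intensities(baselineDriftCorrect(z)) == 0))

  ## TIC mode also removes a shared ramp
  b3 <- BinnedChromatogram(times, c(50, 51),
                           cbind(ramp / 2 + sig, ramp / 2))
  out3 <- baselineDriftCorrect(b3, degree = 2L, mode = "tic")
  expect_lt(abs(max(rowSums(intensities(out3))) - h) / h, 0.10)
})

test_that("Mirex normalization equalizes internal-standard areas", {
  mk <- function(amp) {
    times <- seq(29, 30.2, length.out = 120)
    I <- matrix(0, 120, 2)
    I[, 2] <- amp * exp(-0.5 * ((times - 29.6) / 0.05)^2)
    BinnedChromatogram(times, c(270L, 272L), I)
  }
  a <- mirexNormalize(mk(2000), reference = 1)
  b <- mirexNormalize(mk(4000), reference = 1)
  expect_true(a$detected && b$detected)
  expect_equal(b$area / a$area, 2, tolerance = 1e-6)
  ## post-normalization areas identical at the reference
  areaOf <- function(x) windowPeakArea(x, c(29.4, 29.8))$area
  expect_equal(areaOf(a$chromatogram), 1, tolerance = 1e-9)
  expect_equal(areaOf(b$chromatogram), 1, tolerance = 1e-9)

  ## already at reference -> unchanged
  again <- mirexNormalize(a$chromatogram, reference = 1)
  expect_equal(intensities(again$chromatogram),
               intensities(a$chromatogram), tolerance = 1e-9)

  ## dropout: flat noise floor in the window -> fallback scale and warning
  set.seed(1)
  times <- seq(29, 30.2, length.out = 120)
  flat <- BinnedChromatogram(times, c(270L, 272L),
                             matrix(runif(240, 90, 110), 120, 2))
  expect_warning(nd <- mirexNormalize(flat, fallback.scale = 0.5),
                 "not detected")
  expect_false(nd$detected)
  expect_equal(nd$scale, 0.5)
})

test_that("full preprocessing stack runs, toggles, and is near-idempotent", {
  sim <- smallSim(seed = 9L, n_per_cell = 1L)
  ch <- chromatograms(sim$dataset)[[1]]

  ## all stages disabled: identity on the binned chromatogram
  cfg0 <- preprocessConfig(stages = character(0))
  same <- runPreprocess(roundMz(ch), cfg0)$chromatogram
  expect_identical(intensities(same), intensities(roundMz(ch)))

  ## synthetic contamination removed: stripes -> 0 median, Mirex at reference
  cfg <- preprocessConfig(dt_minutes = 1.5, mirex_reference = 1)
  res <- runPreprocess(ch, cfg, tTotal = 41)
  expect_true(res$mirex$detected)
  out <- res$chromatogram
  expect_equal(windowPeakArea(out, cfg$mirex_window)$area, 1,
               tolerance = 1e-9)
  ## noise floor suppressed: ~15% of cells hit zero and the median level
  ## (on the pre-normalization scale) drops to a fraction of the raw one
  expect_gte(mean(intensities(out) == 0), 0.14)
  expect_lt(median(intensities(out)) / res$mirex$scale,
            0.5 * median(intensities(roundMz(ch))))

  ## re-application changes little (fresh Mirex scale aside, signal stable)
  res2 <- runPreprocess(out, cfg, tTotal = 41)
  v1 <- intensities(out); v2 <- intensities(res2$chromatogram)
  expect_lt(sum(abs(v2 - v1)) / max(sum(v1), 1), 0.01)
})

test_that("dataset-level preprocessing applies batch-median fallback scales", {
  sim <- smallSim(seed = 21L, n_per_cell = 2L,
                  mirex = list(window = c(29.4, 29.8), amp = 5e4,
                               sigma = 0.05, dropout = 0))
  ## force one sample's Mirex away by zeroing its window
  ds <- sim$dataset
  ch <- ds@chromatograms[[1]]
  sel <- ch@times >= 29 & ch@times <= 30.2
  ch@intensity[sel, ] <- 0
  ds@chromatograms[[1]] <- ch
  expect_warning(out <- preprocessDataset(ds), "undetected")
  rec <- attr(out, "mirex")
  expect_false(rec$detected[1])
  expect_true(all(rec$detected[-1]))
  mates <- rec$detected & sampleMeta(ds)$source == sampleMeta(ds)$source[1]
  expect_equal(rec$scale[1], median(rec$scale[mates]))
})
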