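# Shared in-code fixtures: tiny chromatograms and datasets built at test
# time (no stored data files).

tinyChrom <- function(T = 6L, M = 3L, mz = c(50.3, 50.6, 52.1),
                      fill = seq_len(T * M)) {
  RawChromatogram(times = seq(0.1, by = 0.1, length.out = T),
                  mz = mz,
                  intensity = matrix(fill, T, M))
}

## one Gaussian peak on a flat chromatogram; returns chromatogram + truth
peakChrom <- function(T = 200L, M = 4L, rt = 1.0, sigma = 0.05,
                      height = 1000, tmax = 2, baseline = 0) {
  times <- seq(0, tmax, length.out = T)
  I <- matrix(baseline, T, M)
  I[, 2L] <- I[, 2L] + height * exp(-0.5 * ((times - rt) / sigma)^2)
  BinnedChromatogram(times, seq(50L, by = 1L, length.out = M), I)
}

tinyDatasetCsv <- function(dir, n = 3L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(sample_id = paste0("S", seq_len(n)),
                     source = rep(c("SiteA", "SiteB"), length.out = n),
                     risk = rep(riskLevels(), length.out = n))
  data.table::fwrite(meta, file.path(dir, "manifest.csv"))
  for (i in seq_len(n))
    writeChromatogram(tinyChrom(fill = i * seq_len(18L)),
                      file.path(dir, paste0("S", i, ".csv")))
  meta
}

## small simulated dataset shared across tests (desk scale, fast)
smallSim <- function(seed = 5L, n_per_cell = 2L, ...) {
  generateDataset(simConfig(n_per_cell = n_per_cell, n_timesteps = 300L,
                            n_mz = 16L, seed = seed, ...))
}
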