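## Synthetic GC-MS dataset generator.
##
## Emulates the statistical structure the pipeline assumes: Gaussian peaks
## in retention time with separable m/z fragment fingerprints, per-risk
## amplitude multipliers on designated signature peaks, per-source
## multiplicative (gamma) and additive (normal) batch effects, polynomial
## baseline drift, a truncated-normal noise floor with persistent
## per-channel "stripe" artifacts, and an internal-standard (Mirex) peak
## near 29.4-29.8 min with configurable dropout. Ground truth for every
## drawn quantity is returned so parameter recovery is testable.

rngSnapshot <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
rngRestore <- function(s) {
  if (is.null(s)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", s, envir = globalenv())
}

#' Build a random peak library
#'
#' @param n_peaks number of compound peaks.
#' @param n_mz number of m/z channels in the grid.
#' @param tTotal run length (minutes); retention times are drawn inside
#'   `[0.05, 0.92] * tTotal` to stay clear of the run edges and the Mirex
#'   window tail.
#' @param amp.range log10 range of base amplitudes (ion counts).
#' @param width.range Gaussian sigma range in minutes (chromatographic
#'   peaks are a few seconds wide).
#' @param seed integer; fixes the library.
#' @return data.frame-free list: per peak retention time `rt`, width
#'   `sigma`, base amplitude `amp`, and a fingerprint (named weights over
#'   channel indices summing to 1).
#' @export
makePeakLibrary <- function(n_peaks = 30L, n_mz = 64L, tTotal = 41,
                            amp.range = c(3.3, 4.7),
                            width.range = c(0.04, 0.1), seed = 1L) {
  old <- rngSnapshot(); on.exit(rngRestore(old))
  set.seed(seed)
  lapply(seq_len(n_peaks), function(i) {
    nfrag <- min(sample(3:8, 1L), n_mz)
    frag <- sample.int(n_mz, nfrag)
    w <- stats::rexp(nfrag) + 0.15
    list(rt = stats::runif(1L, 0.05 * tTotal, 0.92 * tTotal),
         sigma = stats::runif(1L, width.range[1L], width.range[2L]),
         amp = 10^stats::runif(1L, amp.range[1L], amp.range[2L]),
         frag = frag, weights = w / sum(w))
  })
}

#' Simulation configuration
#'
#' Defaults describe the desk-scale study conditions: a 41-minute run on a
#' 1000-timestep x 64-channel grid (the full-resolution 7300 x 480 grid is
#' available by raising `n_timesteps`/`n_mz`), four source sites whose
#' multiplicative batch factors follow source-specific gamma priors and
#' whose additive shifts follow source-specific normal priors, three risk
#' classes expressed as amplitude multipliers on designated signature
#' peaks, quadratic baseline drift, a truncated-normal noise floor with
#' stripe artifacts, and a Mirex internal standard at 29.6 min.
#'
#' @param n_per_cell samples per (source, risk) cell: a scalar or an
#'   `n_sources x 3` matrix (rows = sources, columns = [riskLevels()]).
#' @param n_sources number of source sites (default 4).
#' @param tTotal run length in minutes (default 41).
#' @param n_timesteps timesteps per run (default 1000; full scale 7300).
#' @param n_mz m/z channels (default 64; full scale 480).
#' @param mz_start first raw m/z value; channels sit at
#'   `mz_start + 0:(n_mz-1) + 0.3` (non-integer, as instruments report).
#' @param peaks peak library from [makePeakLibrary()]; default built from
#'   `peak_seed`.
#' @param peak_seed seed for the default peak library.
#' @param n_signature number of peaks carrying class signal (default 6).
#' @param class_effect per-risk amplitude multipliers on signature peaks,
#'   named after [riskLevels()] (default 1, 1.7, 2.6).
#' @param class_source_consistency in `[0, 1]`: 1 = the class signal is the
#'   same in every source; lower values attenuate/perturb signature
#'   multipliers per source, mimicking center-specific peak panels.
#' @param batch_mult_mean per-source means of the multiplicative factor
#'   gamma priors (default `c(0.7, 1, 1.45, 2.1)` recycled).
#' @param batch_mult_shape gamma shape (default 25; CV = 20%). Factor for a
#'   sample from source s is drawn `Gamma(shape, shape / mean_s)`.
#' @param batch_add_mean per-source means of the additive shift priors
#'   (counts added to every cell; default `c(0, 40, 80, 120)` recycled).
#' @param batch_add_sd additive prior SD (default 8).
#' @param drift_range list of `c(min, max)` for quadratic drift
#'   coefficients `b0 + b1 * tau + b2 * tau^2`, `tau` = normalized time.
#' @param noise_mean,noise_sd truncated-normal noise floor parameters.
#' @param n_stripes persistent per-channel stripe artifacts per sample.
#' @param stripe_amp stripe amplitude (counts).
#' @param mirex list: `window` (minutes), `amp` (peak amplitude), `sigma`
#'   (width), `dropout` (probability the standard is absent).
#' @param seed integer master seed; fixes the full dataset.
#' @return a `SimConfig` list.
#' @export
simConfig <- function(n_per_cell = 5L, n_sources = 4L, tTotal = 41,
                      n_timesteps = 1000L, n_mz = 64L, mz_start = 50,
                      peaks = NULL, peak_seed = 99L, n_signature = 6L,
                      class_effect = c(Control = 1, LowRisk = 2.5,
                                       HighRisk = 4.5),
                      class_source_consistency = 1,
                      batch_mult_mean = c(0.7, 1, 1.45, 2.1),
                      batch_mult_shape = 25,
                      batch_add_mean = c(0, 40, 80, 120),
                      batch_add_sd = 8,
                      drift_range = list(b0 = c(0, 20), b1 = c(-5, 25),
                                         b2 = c(-10, 15)),
                      noise_mean = 25, noise_sd = 10,
                      n_stripes = 2L, stripe_amp = 150,
                      mirex = list(window = c(29.4, 29.8), amp = 5e4,
                                   sigma = 0.05, dropout = 0.05),
                      seed = 1L) {
  if (n_sources < 1L) stop("degenerate config: n_sources must be >= 1")
  if (is.null(peaks))
    peaks <- makePeakLibrary(n_mz = n_mz, tTotal = tTotal, seed = peak_seed)
  if (!length(peaks)) stop("degenerate config: empty peak library")
  if (any(class_effect < 0)) stop("amplitudes must be >= 0")
  rt <- vapply(peaks, `[[`, numeric(1L), "rt")
  if (any(rt < 0 | rt > tTotal)) stop("peak retention times outside run")
  cfg <- list(n_per_cell = n_per_cell, n_sources = n_sources,
              tTotal = tTotal, n_timesteps = n_timesteps, n_mz = n_mz,
              mz_start = mz_start, peaks = peaks,
              n_signature = min(n_signature, length(peaks)),
              class_effect = class_effect,
              class_source_consistency = class_source_consistency,
              batch_mult_mean = rep_len(batch_mult_mean, n_sources),
              batch_mult_shape = batch_mult_shape,
              batch_add_mean = rep_len(batch_add_mean, n_sources),
              batch_add_sd = batch_add_sd,
              drift_range = drift_range,
              noise_mean = noise_mean, noise_sd = noise_sd,
              n_stripes = n_stripes, stripe_amp = stripe_amp,
              mirex = mirex, seed = seed)
  class(cfg) <- "SimConfig"
  cfg
}

#' Generate a synthetic dataset with ground truth
#'
#' Each chromatogram is built as
#' `clip0( factor * (sum of class-scaled peaks + Mirex) + shift + drift +
#' noise )`
#' where `factor` is the sample's gamma-distributed multiplicative batch
#' factor, `shift` its normal additive batch shift, `drift` a per-sample
#' quadratic polynomial in time added to every channel, and `noise` a
#' truncated-normal floor plus persistent per-channel stripe artifacts.
#' Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [simConfig()] list.
#' @return list with `dataset` (a [ScentDataset-class] of
#'   [RawChromatogram-class]) and `truth` (data.frame: sample_id, source,
#'   risk, mult_factor, add_shift, b0, b1, b2, mirex_present).
#' @export
generateDataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  old <- rngSnapshot(); on.exit(rngRestore(old))
  set.seed(cfg$seed)

  sources <- paste0("Site", LETTERS[seq_len(cfg$n_sources)])
  risks <- riskLevels()
  ncell <- cfg$n_per_cell
  if (is.matrix(ncell)) {
    stopifnot(nrow(ncell) == cfg$n_sources, ncol(ncell) == 3L)
  } else {
    ncell <- matrix(ncell, cfg$n_sources, 3L)
  }
  times <- seq(0, cfg$tTotal, length.out = cfg$n_timesteps)
  mz <- cfg$mz_start + seq_len(cfg$n_mz) - 1 + 0.3
  tau <- times / cfg$tTotal

  ## peak time profiles and fingerprints are sample-independent
  nsig <- cfg$n_signature
  sig.idx <- seq_len(nsig)
  profiles <- lapply(cfg$peaks, function(p)
    p$amp * exp(-0.5 * ((times - p$rt) / p$sigma)^2))
  ## per-source signature multipliers (source-inconsistent class signal)
  cons <- cfg$class_source_consistency
  sig.mult <- array(1, dim = c(cfg$n_sources, 3L, nsig))
  for (s in seq_len(cfg$n_sources)) {
    pert <- if (cons >= 1) rep(1, nsig) else
      stats::runif(nsig, cons, 1) * (stats::runif(nsig) < (cons + 1) / 2)
    for (k in seq_len(3L))
      sig.mult[s, k, ] <- 1 + (cfg$class_effect[risks[k]] - 1) * pert
  }
  mirex.rt <- mean(cfg$mirex$window)
  mirex.prof <- cfg$mirex$amp *
    exp(-0.5 * ((times - mirex.rt) / cfg$mirex$sigma)^2)
  mirex.frag <- c(cfg$n_mz, max(1L, cfg$n_mz - 5L))
  mirex.w <- c(0.7, 0.3)

  chroms <- list(); truth <- list(); meta <- list(); idx <- 0L
  for (s in seq_len(cfg$n_sources)) for (k in seq_len(3L)) {
    for (r in seq_len(ncell[s, k])) {
      idx <- idx + 1L
      id <- sprintf("%s_%s_%03d", sources[s], risks[k], r)
      factor <- stats::rgamma(1L, shape = cfg$batch_mult_shape,
                              rate = cfg$batch_mult_shape /
                                cfg$batch_mult_mean[s])
      shift <- max(0, stats::rnorm(1L, cfg$batch_add_mean[s],
                                   cfg$batch_add_sd))
      b <- vapply(cfg$drift_range, function(rg)
        stats::runif(1L, rg[1L], rg[2L]), numeric(1L))
      drift <- pmax(b[1L] + b[2L] * tau + b[3L] * tau^2, 0)
      mirex.present <- stats::runif(1L) >= cfg$mirex$dropout

      S <- matrix(0, cfg$n_timesteps, cfg$n_mz)
      for (p in seq_along(cfg$peaks)) {
        pk <- cfg$peaks[[p]]
        cls <- if (p %in% sig.idx) sig.mult[s, k, match(p, sig.idx)] else 1
        S[, pk$frag] <- S[, pk$frag] +
          outer(profiles[[p]] * cls, pk$weights)
      }
      if (mirex.present)
        S[, mirex.frag] <- S[, mirex.frag] + outer(mirex.prof, mirex.w)
      noise <- matrix(pmax(stats::rnorm(length(S), cfg$noise_mean,
                                        cfg$noise_sd), 0),
                      cfg$n_timesteps, cfg$n_mz)
      if (cfg$n_stripes > 0L) for (st in seq_len(cfg$n_stripes)) {
        ch <- sample.int(cfg$n_mz, 1L)
        t0 <- stats::runif(1L, 0, cfg$tTotal * 0.8)
        len <- stats::runif(1L, 2, 6)  # minutes
        rows <- times >= t0 & times <= t0 + len
        noise[rows, ch] <- noise[rows, ch] + cfg$stripe_amp
      }
      I <- pmax(factor * S + shift + drift + noise, 0)
      chroms[[idx]] <- RawChromatogram(times, mz, I)
      meta[[idx]] <- data.frame(sample_id = id, source = sources[s],
                                risk = risks[k])
      truth[[idx]] <- data.frame(sample_id = id, source = sources[s],
                                 risk = risks[k], mult_factor = factor,
                                 add_shift = shift, b0 = b[1L], b1 = b[2L],
                                 b2 = b[3L], mirex_present = mirex.present)
    }
  }
  meta <- do.call(rbind, meta)
  truth <- do.call(rbind, truth)
  rownames(meta) <- rownames(truth) <- NULL
  list(dataset = ScentDataset(chroms, meta, sources), truth = truth)
}

#' Summarize injected bias per source
#'
#' @param d the generated [ScentDataset-class].
#' @param gt the matching ground-truth data.frame.
#' @return data.frame per source: `n`, `mean_tic` (mean per-timestep total
#'   ion count), `mean_factor`, `mean_shift`.
#' @export
summarizeBias <- function(d, gt) {
  stopifnot(is(d, "ScentDataset"))
  if (nrow(gt) != nrow(d@meta) ||
      !all(gt$sample_id == d@meta$sample_id))
    stop("dataset and ground truth do not match")
  tics <- vapply(d@chromatograms, function(ch) mean(rowSums(ch@intensity)),
                 numeric(1L))
  out <- lapply(split(seq_len(nrow(gt)), gt$source), function(i)
    data.frame(source = gt$source[i[1L]], n = length(i),
               mean_tic = mean(tics[i]),
               mean_factor = mean(gt$mult_factor[i]),
               mean_shift = mean(gt$add_shift[i])))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[match(sourceLabels(d)[sourceLabels(d) %in% res$source], res$source), ,
      drop = FALSE]
}
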