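## Per-sample correction stack:
##   1. round m/z channels to integer bins (half-up) and merge
##   2. segment the run into equal-width time frames
##   3. per-(segment, m/z) quantile noise subtraction, clamped at 0
##   4. per-channel iterative polynomial baseline drift correction
##   5. internal-standard (Mirex) area normalization

#' Round raw m/z channels to integer bins
#'
#' Each raw m/z value is rounded half-up to the nearest integer
#' (`floor(mz + 0.5)`); channels sharing a rounded bin are summed, so the
#' total ion count is conserved exactly.
#'
#' @param c a [RawChromatogram-class] (a [BinnedChromatogram-class] passes
#'   through unchanged up to class).
#' @param tie.rule tie-breaking rule; only `"half_up"` is defined, pinned so
#'   x.5 always bins upward regardless of parity.
#' @return a [BinnedChromatogram-class] on a strictly increasing integer
#'   m/z grid.
#' @examples
#' rc <- RawChromatogram(1:3, c(23.6, 23.7), matrix(1:6, 3))
#' mzValues(roundMz(rc))  # both channels merge into bin 24
#' @export
roundMz <- function(c, tie.rule = "half_up") {
  stopifnot(is(c, "RawChromatogram") || is(c, "BinnedChromatogram"))
  tie.rule <- match.arg(tie.rule, "half_up")
  bins <- floor(c@mz + 0.5)
  ubins <- sort(unique(bins))
  if (length(ubins) == length(bins) && all(bins == c@mz)) {
    return(BinnedChromatogram(c@times, bins, c@intensity))
  }
  ## sum columns sharing a bin: group by bin via matrix multiply
  grp <- match(bins, ubins)
  M <- matrix(0, nrow = length(bins), ncol = length(ubins))
  M[cbind(seq_along(bins), grp)] <- 1
  BinnedChromatogram(c@times, ubins, c@intensity %*% M)
}

#' Total ion chromatogram
#'
#' Sums each timestep over all m/z bins, collapsing the matrix to the
#' 1-dimensional total-ion-count time series.
#'
#' @param c a [RawChromatogram-class] or [BinnedChromatogram-class].
#' @return data.frame with columns `time` (minutes) and `total`.
#' @export
computeTic <- function(c) {
  stopifnot(is(c, "RawChromatogram") || is(c, "BinnedChromatogram"))
  data.frame(time = c@times, total = rowSums(c@intensity))
}

#' Segment a run into equal-width time frames
#'
#' `N = ceiling(tTotal / dt)` segments of equal width `tTotal / N` tile
#' `[0, tTotal]`. The canonical 41-minute run at `dt = 1.5` gives N = 28
#' frames of ~1.46 min (1.5 at one decimal).
#'
#' @param tTotal run length in minutes (> 0).
#' @param dt target frame width in minutes (> 0).
#' @return a [SegmentGrid-class].
#' @export
segmentTime <- function(tTotal, dt) {
  if (!is.numeric(tTotal) || tTotal <= 0) stop("tTotal must be > 0")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  n <- ceiling(tTotal / dt)
  edges <- seq(0, tTotal, length.out = n + 1L)
  new("SegmentGrid",
      boundaries = cbind(start = edges[-(n + 1L)], end = edges[-1L]),
      tTotal = tTotal)
}

#' @rdname segmentTime
#' @param g a [SegmentGrid-class].
#' @return `nSegments()`: the number of segments.
#' @export
nSegments <- function(g) {
  stopifnot(is(g, "SegmentGrid"))
  nrow(g@boundaries)
}

#' Assign timesteps to segments
#' @noRd
segmentIndex <- function(times, g) {
  idx <- findInterval(times, g@boundaries[, 1L],
                      left.open = FALSE, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(g@boundaries)] <- nrow(g@boundaries)
  idx
}

## quantile by sorted linear interpolation at rank (n-1)*q (stats type 7)
lerpQuantile <- function(x, q) {
  stats::quantile(x, probs = q, type = 7, names = FALSE)
}

#' Segmented quantile noise subtraction
#'
#' Within each (time frame, m/z bin) cell, the `q`-quantile of intensity
#' (sorted linear interpolation at rank `(n-1) q`) is taken as the local
#' baseline-noise threshold and subtracted from every value in the cell,
#' clamped at 0: `I_corr = max(I - Q_q, 0)`. Relative peak order within a
#' cell is preserved, and re-application is the identity.
#'
#' @param c a [BinnedChromatogram-class].
#' @param g a [SegmentGrid-class] covering the run's time span.
#' @param q quantile level, default 0.15 (the lowest 15th percentile).
#' @return the corrected [BinnedChromatogram-class].
#' @export
quantileNoiseCorrect <- function(c, g, q = 0.15) {
  stopifnot(is(c, "BinnedChromatogram"), is(g, "SegmentGrid"))
  if (q < 0 || q > 1) stop("q must lie in [0, 1]")
  if (max(c@times) > g@tTotal + 1e-9)
    stop("segment grid does not cover the chromatogram's time span")
  seg <- segmentIndex(c@times, g)
  present <- seq_len(nSegments(g)) %in% seg
  ## segments overlapping the run must contain timesteps
  span <- g@boundaries[, 1L] < max(c@times) & g@boundaries[, 2L] > min(c@times)
  if (any(span & !present))
    stop("configuration error: segment ",
         which(span & !present)[1L], " contains no timesteps")
  I <- c@intensity
  for (s in unique(seg)) {
    rows <- which(seg == s)
    thr <- apply(I[rows, , drop = FALSE], 2L, lerpQuantile, q = q)
    I[rows, ] <- pmax(sweep(I[rows, , drop = FALSE], 2L, thr, "-"), 0)
  }
  BinnedChromatogram(c@times, c@mz, I)
}

#' Iterative polynomial baseline estimate (modified polyfit)
#'
#' Fits a degree-`degree` polynomial to `y` over normalized time, then
#' iteratively refits with values above the current fit replaced by the fit
#' (peak stripping), until the baseline change falls below `tol` or
#' `max.iter` is reached.
#'
#' @param y numeric signal.
#' @param x abscissa (any scale; internally centred/scaled).
#' @param degree polynomial degree (>= 1).
#' @param max.iter,tol iteration controls.
#' @return numeric baseline estimate, same length as `y`.
#' @export
polyBaseline <- function(y, x = seq_along(y), degree = 2L,
                         max.iter = 50L, tol = 1e-6) {
  if (degree < 1L) stop("degree must be >= 1")
  xs <- as.numeric(scale(x))
  if (all(is.nan(xs))) xs <- rep(0, length(x))  # constant abscissa
  X <- outer(xs, 0:degree, "^")
  qrX <- qr(X)
  w <- y
  scl <- max(abs(y), 1e-12)
  base <- rep(0, length(y))
  for (i in seq_len(max.iter)) {
    base <- as.numeric(qr.fitted(qrX, w))
    wnew <- pmin(w, base)
    if (max(abs(wnew - w)) < tol * scl) { w <- wnew; break }
    w <- wnew
  }
  base
}

#' Polynomial baseline drift correction
#'
#' Estimates a slowly varying baseline per m/z channel (or on the TIC) by
#' iterative polynomial fitting with peak stripping, subtracts it, and
#' clamps at zero.
#'
#' @param c a [BinnedChromatogram-class].
#' @param degree polynomial degree, default 2.
#' @param mode `"per_channel"` (default) fits every m/z channel
#'   independently; `"tic"` fits the baseline on the TIC and subtracts each
#'   channel's proportional share of it.
#' @param max.iter,tol passed to [polyBaseline()].
#' @return the corrected [BinnedChromatogram-class]. A channel whose fit
#'   fails is left unchanged with a warning.
#' @export
baselineDriftCorrect <- function(c, degree = 2L,
                                 mode = c("per_channel", "tic"),
                                 max.iter = 50L, tol = 1e-6) {
  stopifnot(is(c, "BinnedChromatogram"))
  mode <- match.arg(mode)
  if (degree < 1L) stop("degree must be >= 1")
  if (length(c@times) < degree + 2L)
    stop("not enough timesteps to fit a degree-", degree, " baseline")
  I <- c@intensity
  if (mode == "tic") {
    tic <- rowSums(I)
    base <- polyBaseline(tic, c@times, degree, max.iter, tol)
    share <- I / pmax(tic, 1e-12)   # channel's fraction of each timestep
    I <- pmax(I - share * pmax(base, 0), 0)
  } else {
    for (j in seq_len(ncol(I))) {
      y <- I[, j]
      if (all(y == 0)) next
      base <- tryCatch(polyBaseline(y, c@times, degree, max.iter, tol),
                       error = function(e) {
                         warning("baseline fit failed on m/z ", c@mz[j],
                                 "; channel left unchanged", call. = FALSE)
                         NULL
                       })
      if (!is.null(base)) I[, j] <- pmax(y - pmax(base, 0), 0)
    }
  }
  BinnedChromatogram(c@times, c@mz, I)
}

#' Locate the dominant TIC peak in a time window and measure its area
#'
#' Restricts the TIC to `window`, splits it into contiguous above-zero runs,
#' and returns the trapezoidal area of the run with the largest area.
#'
#' @param c a [BinnedChromatogram-class].
#' @param window length-2 numeric time window (minutes).
#' @return list with `area` (trapezoidal integral, minutes x counts) and
#'   `apex` (time of the run's maximum), both 0/NA if the window is flat.
#' @export
windowPeakArea <- function(c, window) {
  stopifnot(is(c, "BinnedChromatogram"), length(window) == 2L)
  sel <- which(c@times >= window[1L] & c@times <= window[2L])
  if (length(sel) < 2L) return(list(area = 0, apex = NA_real_))
  t <- c@times[sel]
  y <- rowSums(c@intensity[sel, , drop = FALSE])
  pos <- y > 0
  if (!any(pos)) return(list(area = 0, apex = NA_real_))
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- list(area = 0, apex = NA_real_)
  for (r in which(runs$values)) {
    i0 <- max(starts[r] - 1L, 1L); i1 <- min(ends[r] + 1L, length(t))
    idx <- i0:i1
    a <- trapz(t[idx], y[idx])
    if (a > best$area)
      best <- list(area = a, apex = t[idx][which.max(y[idx])])
  }
  best
}

trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)

#' Internal-standard (Mirex) normalization
#'
#' Measures the Mirex peak area as the trapezoidal integral of the
#' maximum-area contiguous TIC peak inside `window` and rescales all
#' intensities by `reference / area`, so every detected sample ends at the
#' same internal-standard area. If the area falls below
#' `threshold.mult` times the window's median-level area (the noise-floor
#' area `median(TIC in window) * width`), the standard is declared
#' undetected and `fallback.scale` (e.g. the batch-median scale factor of
#' detected samples) is applied instead, with a warning.
#'
#' @param c a [BinnedChromatogram-class].
#' @param window Mirex retention window in minutes, default `c(29.4, 29.8)`.
#' @param reference target peak area after normalization (default 1).
#' @param threshold.mult detection threshold as a multiple of the window's
#'   median-level area, default 5.
#' @param fallback.scale scale factor applied when undetected (default 1,
#'   i.e. leave the sample unscaled); batch pipelines pass the median scale
#'   factor of that sample's detected batch mates.
#' @return list with `chromatogram` (scaled [BinnedChromatogram-class]),
#'   `area` (measured Mirex area), `scale` (factor applied) and `detected`
#'   (logical).
#' @export
mirexNormalize <- function(c, window = c(29.4, 29.8), reference = 1,
                           threshold.mult = 5, fallback.scale = 1) {
  stopifnot(is(c, "BinnedChromatogram"))
  if (length(window) != 2L || window[1L] >= window[2L])
    stop("invalid Mirex window")
  pk <- windowPeakArea(c, window)
  ## noise-floor area: the window's 15th-percentile TIC level (the peak
  ## occupies much of the window, so a median would be peak-contaminated)
  sel <- c@times >= window[1L] & c@times <= window[2L]
  floor.area <- if (any(sel))
    lerpQuantile(rowSums(c@intensity[sel, , drop = FALSE]), 0.15) *
      (window[2L] - window[1L]) else 0
  detected <- pk$area > .Machine$double.eps &&
    pk$area >= threshold.mult * floor.area
  if (detected) {
    scl <- reference / pk$area
  } else {
    warning("internal standard not detected in window [",
            window[1L], ", ", window[2L], "]; applying fallback scale ",
            signif(fallback.scale, 4), call. = FALSE)
    scl <- fallback.scale
  }
  list(chromatogram = BinnedChromatogram(c@times, c@mz, c@intensity * scl),
       area = pk$area, scale = scl, detected = detected)
}

#' Default preprocessing configuration
#'
#' @param dt_minutes segment width target, default 1.5.
#' @param quantile noise quantile, default 0.15.
#' @param poly_degree baseline polynomial degree, default 2.
#' @param baseline_mode `"per_channel"` or `"tic"`.
#' @param mirex_window Mirex retention window, default `c(29.4, 29.8)`.
#' @param mirex_reference target Mirex area, default 1.
#' @param stages character vector naming the stages to run, in order.
#'   Default follows the numbered correction sequence: rounding, quantile
#'   noise subtraction, baseline drift correction, Mirex normalization
#'   (segmentation is implicit in the quantile stage). Any stage may be
#'   dropped or reordered.
#' @return list of configuration values for [runPreprocess()].
#' @export
preprocessConfig <- function(dt_minutes = 1.5, quantile = 0.15,
                             poly_degree = 2L,
                             baseline_mode = "per_channel",
                             mirex_window = c(29.4, 29.8),
                             mirex_reference = 1,
                             stages = c("round", "quantile", "baseline",
                                        "mirex")) {
  list(dt_minutes = dt_minutes, quantile = quantile,
       poly_degree = poly_degree, baseline_mode = baseline_mode,
       mirex_window = mirex_window, mirex_reference = mirex_reference,
       stages = stages)
}

#' Run the full per-sample correction stack
#'
#' Applies, in the configured order, m/z rounding, segmented quantile noise
#' subtraction, polynomial baseline drift correction and Mirex
#' normalization. Each stage can be toggled off via `cfg$stages`.
#'
#' @param c a [RawChromatogram-class] or [BinnedChromatogram-class].
#' @param cfg configuration list from [preprocessConfig()].
#' @param tTotal run length in minutes; default the last scan time.
#' @param fallback.scale passed to [mirexNormalize()].
#' @return list with `chromatogram` (the corrected
#'   [BinnedChromatogram-class]) and `mirex` (the [mirexNormalize()] record,
#'   or NULL if the stage was disabled).
#' @export
runPreprocess <- function(c, cfg = preprocessConfig(),
                          tTotal = NULL, fallback.scale = 1) {
  ## raw input is m/z-binned up front: the working container requires an
  ## integer grid, so rounding is implied for RawChromatogram input even
  ## when the "round" stage is toggled off
  x <- if (is(c, "BinnedChromatogram")) c else roundMz(c)
  mirex <- NULL
  if (is.null(tTotal)) tTotal <- max(c@times)
  for (st in cfg$stages) {
    x <- switch(st,
      round = x,
      quantile = {
        g <- segmentTime(tTotal, cfg$dt_minutes)
        quantileNoiseCorrect(x, g, cfg$quantile)
      },
      baseline = baselineDriftCorrect(x, cfg$poly_degree,
                                      cfg$baseline_mode),
      mirex = {
        m <- mirexNormalize(x, cfg$mirex_window, cfg$mirex_reference,
                            fallback.scale = fallback.scale)
        mirex <- m[c("area", "scale", "detected")]
        m$chromatogram
      },
      stop("unknown stage: ", st))
  }
  list(chromatogram = x, mirex = mirex)
}

#' Preprocess every sample of a dataset
#'
#' Runs [runPreprocess()] on each record. Samples whose internal standard is
#' undetected are rescaled by the median Mirex scale factor of detected
#' samples from the same source batch (falling back to the global median,
#' then 1).
#'
#' @param d a [ScentDataset-class].
#' @param cfg configuration from [preprocessConfig()].
#' @param tTotal run length in minutes (default: per-sample last scan time).
#' @return a [ScentDataset-class] of corrected chromatograms, with a
#'   `mirex` attribute data.frame (sample_id, area, scale, detected).
#' @export
preprocessDataset <- function(d, cfg = preprocessConfig(), tTotal = NULL) {
  stopifnot(is(d, "ScentDataset"))
  n <- length(d@chromatograms)
  out <- vector("list", n)
  rec <- data.frame(sample_id = d@meta$sample_id, area = NA_real_,
                    scale = NA_real_, detected = NA)
  ## first pass: everything except Mirex
  pre.stages <- setdiff(cfg$stages, "mirex")
  cfg1 <- cfg; cfg1$stages <- pre.stages
  for (i in seq_len(n))
    out[[i]] <- runPreprocess(d@chromatograms[[i]], cfg1, tTotal)$chromatogram
  if ("mirex" %in% cfg$stages) {
    areas <- vapply(out, function(x)
      windowPeakArea(x, cfg$mirex_window)$area, numeric(1L))
    floors <- vapply(out, function(x) {
      sel <- x@times >= cfg$mirex_window[1L] & x@times <= cfg$mirex_window[2L]
      if (!any(sel)) return(0)
      lerpQuantile(rowSums(x@intensity[sel, , drop = FALSE]), 0.15) *
        diff(cfg$mirex_window)
    }, numeric(1L))
    detected <- areas > .Machine$double.eps & areas >= 5 * floors
    scales <- ifelse(detected, cfg$mirex_reference / areas, NA_real_)
    batch <- as.character(d@meta$source)
    for (i in which(!detected)) {
      mates <- detected & batch == batch[i]
      scales[i] <- if (any(mates)) stats::median(scales[mates])
        else if (any(detected)) stats::median(scales[detected]) else 1
    }
    for (i in seq_len(n)) {
      x <- out[[i]]
      out[[i]] <- BinnedChromatogram(x@times, x@mz, x@intensity * scales[i])
      if (!detected[i])
        warning("sample ", d@meta$sample_id[i],
                ": internal standard undetected; batch-median scale applied",
                call. = FALSE)
    }
    rec$area <- areas; rec$scale <- scales; rec$detected <- detected
  }
  res <- ScentDataset(out, d@meta, d@sources)
  attr(res, "mirex") <- rec
  res
}
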