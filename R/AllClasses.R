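#' @import methods
NULL

#' RawChromatogram: a single GC-MS run as a time x m/z intensity matrix
#'
#' The raw 3D signal of one sample: retention time in minutes, the
#' instrument's (possibly non-integer) m/z axis, and nonnegative ion counts
#' \eqn{I(t, m/z)}.
#'
#' @slot times numeric, strictly increasing retention times (minutes), length T.
#' @slot mz numeric raw m/z values, length M; non-integer values are preserved.
#' @slot intensity T x M numeric matrix of nonnegative ion counts.
#'
#' @seealso [readChromatogram()], [roundMz()]
#' @export
setClass("RawChromatogram",
  representation(times = "numeric", mz = "numeric", intensity = "matrix"))

setValidity("RawChromatogram", function(object) {
  msg <- chromValidity(object@times, object@mz, object@intensity)
  if (is.null(msg)) TRUE else msg
})

## shared validity for raw/binned chromatograms
chromValidity <- function(times, mz, intensity, integer.mz = FALSE) {
  if (length(times) != nrow(intensity))
    return(sprintf("length(times) [%d] != nrow(intensity) [%d]",
                   length(times), nrow(intensity)))
  if (length(mz) != ncol(intensity))
    return(sprintf("length(mz) [%d] != ncol(intensity) [%d]",
                   length(mz), ncol(intensity)))
  if (length(times) > 1L && any(diff(times) <= 0))
    return("times must be strictly increasing")
  if (anyNA(intensity))
    return("intensity contains NA/NaN")
  if (any(intensity < 0))
    return("intensity contains negative values")
  if (integer.mz) {
    if (any(mz != round(mz))) return("mz bins must be integers")
    if (length(mz) > 1L && any(diff(mz) <= 0))
      return("mz bins must be strictly increasing")
  }
  NULL
}

#' BinnedChromatogram: chromatogram on an integer m/z grid
#'
#' Result of rounding raw m/z channels to the nearest integer and summing
#' channels that share a bin; the working representation for all downstream
#' correction stages.
#'
#' @slot times numeric retention times (minutes), strictly increasing.
#' @slot mz integer-valued m/z bins, strictly increasing.
#' @slot intensity T x M' numeric matrix of nonnegative intensities.
#'
#' @seealso [roundMz()], [runPreprocess()]
#' @export
setClass("BinnedChromatogram",
  representation(times = "numeric", mz = "numeric", intensity = "matrix"))

setValidity("BinnedChromatogram", function(object) {
  msg <- chromValidity(object@times, object@mz, object@intensity,
                       integer.mz = TRUE)
  if (is.null(msg)) TRUE else msg
})

#' SegmentGrid: equal-width time frames tiling a run
#'
#' @slot boundaries N x 2 matrix of `[start, end)` minute intervals that tile
#'   `[0, tTotal]` without gaps or overlap.
#' @slot tTotal run length in minutes.
#'
#' @seealso [segmentTime()]
#' @export
setClass("SegmentGrid",
  representation(boundaries = "matrix", tTotal = "numeric"))

setValidity("SegmentGrid", function(object) {
  b <- object@boundaries
  if (ncol(b) != 2L) return("boundaries must have two columns")
  if (nrow(b) < 1L) return("need at least one segment")
  if (abs(b[1L, 1L]) > 1e-9) return("first segment must start at 0")
  if (abs(b[nrow(b), 2L] - object@tTotal) > 1e-9)
    return("last segment must end at tTotal")
  if (nrow(b) > 1L && max(abs(b[-1L, 1L] - b[-nrow(b), 2L])) > 1e-9)
    return("segments must tile without gaps or overlap")
  TRUE
})

#' ScentDataset: chromatograms plus their sample manifest
#'
#' @slot chromatograms named list of [RawChromatogram-class] or
#'   [BinnedChromatogram-class] objects, one per sample.
#' @slot meta data.frame with columns `sample_id`, `source`, `risk` and
#'   optionally `age`, `psa`; one row per sample, same order as
#'   `chromatograms`.
#' @slot sources character, the ordered set of declared batch labels.
#' @export
setClass("ScentDataset",
  representation(chromatograms = "list", meta = "data.frame",
                 sources = "character"))

setValidity("ScentDataset", function(object) {
  m <- object@meta
  need <- c("sample_id", "source", "risk")
  if (!all(need %in% names(m)))
    return(paste("meta must contain columns:", paste(need, collapse = ", ")))
  if (nrow(m) != length(object@chromatograms))
    return("one meta row per chromatogram required")
  if (anyDuplicated(m$sample_id))
    return("duplicate sample_id in meta")
  if (!all(m$source %in% object@sources))
    return("meta$source contains labels not in declared sources")
  bad <- setdiff(unique(m$risk), riskLevels())
  if (length(bad))
    return(paste("unknown risk label(s):", paste(bad, collapse = ", ")))
  TRUE
})

#' The declared three-level risk label set
#'
#' Risk groups follow biopsy Gleason grading: `Control` (biopsy negative),
#' `LowRisk` (Gleason 6 and below), `HighRisk` (Gleason 7 and above).
#'
#' @return character vector of the three risk labels, in canonical order.
#' @export
riskLevels <- function() c("Control", "LowRisk", "HighRisk")

#' FeatureMatrix: samples x features intensity table with batch labels
#'
#' Carrier for the empirical-Bayes batch-correction stage. Features are
#' either per-(segment, m/z bin) aggregate intensities or raw TIC timesteps.
#'
#' @slot values numeric samples x features matrix, no NA.
#' @slot batch factor of per-sample source (batch) labels.
#' @slot risk factor of per-sample risk labels (may be length 0 if unknown).
#' @slot sampleIds character sample identifiers (rownames of `values`).
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", batch = "factor", risk = "factor",
                 sampleIds = "character"))

setValidity("FeatureMatrix", function(object) {
  if (anyNA(object@values)) return("values contains NA")
  if (length(object@batch) != nrow(object@values))
    return("one batch label per sample row required")
  if (length(object@sampleIds) != nrow(object@values))
    return("one sampleId per sample row required")
  if (length(object@risk) && length(object@risk) != nrow(object@values))
    return("risk, when present, must have one label per sample")
  TRUE
})

#' EBModel: fitted empirical-Bayes batch-effect model
#'
#' Per-feature grand location/scale, per-(batch, feature) naive and posterior
#' (shrunken) additive shifts and multiplicative factors, and the per-batch
#' hyperpriors: Normal(mu, sigma^2) over additive shifts and Gamma(shape,
#' rate) over multiplicative factors.
#'
#' @slot grandLoc numeric per-feature grand location.
#' @slot grandScale numeric per-feature pooled scale (floored).
#' @slot batches character batch labels the model knows.
#' @slot gammaHat,deltaHat numeric batch x feature matrices of naive
#'   estimates.
#' @slot gammaStar,deltaStar numeric batch x feature matrices of posterior
#'   means; `deltaStar > 0`.
#' @slot normHyper numeric batch x 2 matrix (columns `mu`, `sd`).
#' @slot gammaHyper numeric batch x 2 matrix (columns `shape`, `rate`).
#' @slot nPerBatch integer samples per batch at fit time.
#' @seealso [fitEB()], [applyEB()]
#' @export
setClass("EBModel",
  representation(grandLoc = "numeric", grandScale = "numeric",
                 batches = "character",
                 gammaHat = "matrix", deltaHat = "matrix",
                 gammaStar = "matrix", deltaStar = "matrix",
                 normHyper = "matrix", gammaHyper = "matrix",
                 nPerBatch = "integer"))

setValidity("EBModel", function(object) {
  if (any(object@deltaStar <= 0)) return("deltaStar must be > 0")
  if (!all(is.finite(object@normHyper)) || !all(is.finite(object@gammaHyper)))
    return("hyperparameters must be finite")
  nb <- length(object@batches)
  for (s in c("gammaHat", "deltaHat", "gammaStar", "deltaStar"))
    if (nrow(slot(object, s)) != nb)
      return(sprintf("%s must have one row per batch", s))
  TRUE
})

#' ScentImage: fixed-size 8-bit image encoding of a chromatogram
#'
#' @slot pixels 256 x 256 x 3 integer array with values in `[0, 255]`.
#' @slot sampleId character provenance tag.
#' @slot window numeric length-2 time window (minutes) the image covers.
#' @slot mode character, `"heatmap"` or `"peaks"`.
#' @seealso [toHeatmapImage()], [toPeakProjectionImage()]
#' @export
setClass("ScentImage",
  representation(pixels = "array", sampleId = "character",
                 window = "numeric", mode = "character"))

setValidity("ScentImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || !all(d == c(256L, 256L, 3L)))
    return("pixels must be a 256 x 256 x 3 array")
  if (anyNA(object@pixels) ||
      min(object@pixels) < 0 || max(object@pixels) > 255)
    return("pixel values must lie in [0, 255]")
  if (any(object@pixels != round(object@pixels)))
    return("pixel values must be integers (8-bit)")
  TRUE
})

#' TrainedModel: domain-adversarial classifier state
#'
#' @slot params list of backbone, disease-head and source-head parameters.
#' @slot history data.frame with per-epoch columns `epoch`, `l0`, `lq`,
#'   `ltotal` (and `lambda`); `ltotal = l0 - lambda * lq` at every row.
#' @slot config list, the [advConfig()] used for training.
#' @slot classes character disease class labels (3-level).
#' @slot sources character source labels seen in training.
#' @export
setClass("TrainedModel",
  representation(params = "list", history = "data.frame", config = "list",
                 classes = "character", sources = "character"))

setValidity("TrainedModel", function(object) {
  h <- object@history
  if (!all(c("epoch", "l0", "lq", "ltotal") %in% names(h)))
    return("history must have columns epoch, l0, lq, ltotal")
  if (nrow(h) && !all(is.finite(unlist(h[c("l0", "lq", "ltotal")]))))
    return("all logged losses must be finite")
  TRUE
})

#' EvalReport: confusion matrix and per-class metrics
#'
#' @slot confusion K x K integer matrix, rows = truth, columns = predicted.
#' @slot perClass data.frame with per-class precision, recall, f1, support.
#' @slot macro named numeric: macro-averaged precision, recall, f1.
#' @slot accuracy overall accuracy (trace / total).
#' @slot merged list with the two-class (Control vs PCa+) confusion,
#'   per-class metrics and accuracy, or empty if not computed.
#' @slot zeroDivision logical flag: TRUE if any precision/recall had an empty
#'   denominator and was reported as 0.
#' @export
setClass("EvalReport",
  representation(confusion = "matrix", perClass = "data.frame",
                 macro = "numeric", accuracy = "numeric", merged = "list",
                 zeroDivision = "logical"))

## ---- show methods -------------------------------------------------------

setMethod("show", "RawChromatogram", function(object) {
  cat(sprintf("RawChromatogram: %d timesteps x %d m/z channels\n",
              length(object@times), length(object@mz)))
  cat(sprintf("  time: %.3f .. %.3f min; m/z: %.1f .. %.1f\n",
              min(object@times), max(object@times),
              min(object@mz), max(object@mz)))
})

setMethod("show", "BinnedChromatogram", function(object) {
  cat(sprintf("BinnedChromatogram: %d timesteps x %d integer m/z bins\n",
              length(object@times), length(object@mz)))
  cat(sprintf("  time: %.3f .. %.3f min; m/z: %d .. %d\n",
              min(object@times), max(object@times),
              as.integer(min(object@mz)), as.integer(max(object@mz))))
})

setMethod("show", "SegmentGrid", function(object) {
  cat(sprintf("SegmentGrid: %d segments tiling [0, %.3g] min (width %.3f)\n",
              nrow(object@boundaries), object@tTotal,
              object@boundaries[1L, 2L] - object@boundaries[1L, 1L]))
})

setMethod("show", "ScentDataset", function(object) {
  cat(sprintf("ScentDataset: %d samples, %d sources\n",
              nrow(object@meta), length(object@sources)))
  print(table(source = object@meta$source, risk = object@meta$risk))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d samples x %d features, %d batches\n",
              nrow(object@values), ncol(object@values),
              nlevels(object@batch)))
})

setMethod("show", "EBModel", function(object) {
  cat(sprintf("EBModel: %d batches x %d features\n",
              length(object@batches), length(object@grandLoc)))
  cat("  additive shift prior  N(mu, sd):\n")
  print(round(object@normHyper, 4))
  cat("  multiplicative factor prior Gamma(shape, rate):\n")
  print(round(object@gammaHyper, 4))
})

setMethod("show", "ScentImage", function(object) {
  cat(sprintf("ScentImage [%s]: 256 x 256 x 3 (8-bit), window %.2f-%.2f min%s\n",
              object@mode, object@window[1L], object@window[2L],
              if (length(object@sampleId) && nzchar(object@sampleId))
                paste0(", sample ", object@sampleId) else ""))
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel: %s backbone, lambda = %.2f, %d epochs\n",
              object@config$backbone, object@config$lambda,
              nrow(object@history)))
  cat(sprintf("  classes: %s | sources: %s\n",
              paste(object@classes, collapse = ", "),
              paste(object@sources, collapse = ", ")))
  if (nrow(object@history)) {
    h <- object@history[nrow(object@history), ]
    cat(sprintf("  final losses: l0 = %.4f, lq = %.4f, ltotal = %.4f\n",
                h$l0, h$lq, h$ltotal))
  }
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  cat(sprintf("  accuracy: %.4f\n", object@accuracy))
  print(object@confusion)
  print(cbind(round(object@perClass[, c("precision", "recall", "f1")], 2),
              support = object@perClass$support))
  if (length(object@merged))
    cat(sprintf("  merged 2-class accuracy: %.4f\n", object@merged$accuracy))
})

## ---- accessors ----------------------------------------------------------

#' @rdname accessors
#' @export
setGeneric("scanTimes", function(x) standardGeneric("scanTimes"))
#' @rdname accessors
#' @export
setGeneric("mzValues", function(x) standardGeneric("mzValues"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' Accessors for chromatogram objects
#'
#' `scanTimes()` returns the retention-time axis in minutes, `mzValues()` the
#' m/z axis, and `intensities()` the time x m/z intensity matrix.
#'
#' @param x a [RawChromatogram-class] or [BinnedChromatogram-class].
#' @return numeric vector or matrix as described.
#' @name accessors
#' @aliases scanTimes mzValues intensities
NULL

for (cl in c("RawChromatogram", "BinnedChromatogram")) {
  setMethod("scanTimes", cl, function(x) x@times)
  setMethod("mzValues", cl, function(x) x@mz)
  setMethod("intensities", cl, function(x) x@intensity)
}

#' @rdname datasetAccessors
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))
#' @rdname datasetAccessors
#' @export
setGeneric("chromatograms", function(x) standardGeneric("chromatograms"))
#' @rdname datasetAccessors
#' @export
setGeneric("sourceLabels", function(x) standardGeneric("sourceLabels"))

#' Accessors for ScentDataset and FeatureMatrix
#'
#' @param x a [ScentDataset-class] or [FeatureMatrix-class].
#' @return `sampleMeta()` the manifest data.frame; `chromatograms()` the list
#'   of per-sample chromatograms; `sourceLabels()` the declared batch label
#'   set; `featureValues()` the samples x features matrix; `batchLabels()`
#'   the per-sample batch factor.
#' @name datasetAccessors
NULL

setMethod("sampleMeta", "ScentDataset", function(x) x@meta)
setMethod("chromatograms", "ScentDataset", function(x) x@chromatograms)
setMethod("sourceLabels", "ScentDataset", function(x) x@sources)

#' @rdname datasetAccessors
#' @export
featureValues <- function(x) {
  stopifnot(is(x, "FeatureMatrix"))
  x@values
}

#' @rdname datasetAccessors
#' @export
batchLabels <- function(x) {
  stopifnot(is(x, "FeatureMatrix"))
  x@batch
}

#' @rdname imageAccessors
#' @export
imagePixels <- function(x) {
  stopifnot(is(x, "ScentImage"))
  x@pixels
}

#' Accessors for ScentImage and TrainedModel
#'
#' @param x a [ScentImage-class] or [TrainedModel-class].
#' @return `imagePixels()` the 256 x 256 x 3 integer array;
#'   `trainingHistory()` the per-epoch loss data.frame.
#' @name imageAccessors
NULL

#' @rdname imageAccessors
#' @export
trainingHistory <- function(x) {
  stopifnot(is(x, "TrainedModel"))
  x@history
}

## ---- constructors (light wrappers used across modules) ------------------

#' Construct a RawChromatogram
#'
#' @param times,mz,intensity see [RawChromatogram-class].
#' @return a validated [RawChromatogram-class].
#' @export
RawChromatogram <- function(times, mz, intensity) {
  intensity <- unname(as.matrix(intensity))
  storage.mode(intensity) <- "double"
  new("RawChromatogram", times = as.numeric(times), mz = as.numeric(mz),
      intensity = intensity)
}

#' Construct a BinnedChromatogram
#'
#' @param times,mz,intensity see [BinnedChromatogram-class].
#' @return a validated [BinnedChromatogram-class].
#' @export
BinnedChromatogram <- function(times, mz, intensity) {
  intensity <- unname(as.matrix(intensity))
  storage.mode(intensity) <- "double"
  new("BinnedChromatogram", times = as.numeric(times), mz = as.numeric(mz),
      intensity = intensity)
}

#' Construct a ScentDataset
#'
#' @param chromatograms list of chromatogram objects (one per manifest row).
#' @param meta manifest data.frame (`sample_id`, `source`, `risk`, ...).
#' @param sources declared source label set; defaults to the labels present.
#' @return a validated [ScentDataset-class].
#' @export
ScentDataset <- function(chromatograms, meta, sources = NULL) {
  if (is.null(sources)) sources <- unique(as.character(meta$source))
  names(chromatograms) <- meta$sample_id
  new("ScentDataset", chromatograms = chromatograms,
      meta = as.data.frame(meta), sources = as.character(sources))
}

#' Construct a FeatureMatrix
#'
#' @param values samples x features numeric matrix.
#' @param batch per-sample batch labels (coerced to factor).
#' @param risk optional per-sample risk labels.
#' @param sampleIds sample identifiers; default rownames or S1..Sn.
#' @return a validated [FeatureMatrix-class].
#' @export
FeatureMatrix <- function(values, batch, risk = character(), sampleIds = NULL) {
  values <- as.matrix(values)
  if (is.null(sampleIds))
    sampleIds <- rownames(values) %||% paste0("S", seq_len(nrow(values)))
  rownames(values) <- sampleIds
  new("FeatureMatrix", values = values, batch = as.factor(batch),
      risk = as.factor(risk), sampleIds = as.character(sampleIds))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
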