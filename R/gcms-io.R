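## Chromatogram and manifest IO.
##
## On-disk CSV matrix dialect: first column = retention time (minutes),
## header row = raw m/z values, remaining cells = ion counts. This is the
## package's own lossless carrier for the time x m/z x intensity signal;
## vendor-native formats are out of scope. mzML is supported optionally
## through mzR.

#' Read a chromatogram from disk
#'
#' Parses the package's CSV matrix dialect (first column retention time in
#' minutes, header row of raw m/z values, cells of nonnegative ion counts),
#' or an mzML file through the optional mzR backend.
#'
#' @param path path to the file.
#' @param format `"csv_matrix"` (default) or `"mzml"`.
#' @param mz.grid for mzML only: optional numeric vector of raw m/z values
#'   defining the channel grid. Peaks are assigned to the nearest grid value;
#'   absent channels stay 0. Default: integer grid spanning the observed m/z
#'   range.
#' @return a validated [RawChromatogram-class]; non-integer m/z values are
#'   preserved untouched.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("time,50,51.3", "0.1,10,0", "0.2,5,2"), f)
#' readChromatogram(f)
#' @export
readChromatogram <- function(path, format = c("csv_matrix", "mzml"),
                             mz.grid = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (format == "mzml") return(readMzml(path, mz.grid))

  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L)
    stop("malformed header in ", path,
         ": need a time column plus at least one m/z column", call. = FALSE)
  mz <- suppressWarnings(as.numeric(names(dt)[-1L]))
  if (anyNA(mz)) {
    bad <- which(is.na(mz))[1L] + 1L
    stop("malformed header in ", path, ": column ", bad,
         " ('", names(dt)[bad], "') is not a numeric m/z value",
         call. = FALSE)
  }
  times <- suppressWarnings(as.numeric(dt[[1L]]))
  if (anyNA(times))
    stop("non-numeric retention time at row ",
         which(is.na(times))[1L], " of ", path, call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0)) {
    r <- which(diff(times) <= 0)[1L] + 1L
    stop("non-monotone time axis in ", path, ": row ", r,
         " (", times[r], " follows ", times[r - 1L], ")", call. = FALSE)
  }
  intens <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(intens) <- "double"
  if (anyNA(intens)) {
    idx <- which(is.na(intens), arr.ind = TRUE)[1L, ]
    stop("non-numeric or missing intensity at row ", idx[1L],
         ", m/z column ", mz[idx[2L]], " of ", path, call. = FALSE)
  }
  if (any(intens < 0)) {
    idx <- which(intens < 0, arr.ind = TRUE)[1L, ]
    stop("negative intensity at row ", idx[1L], ", m/z column ",
         mz[idx[2L]], " of ", path, call. = FALSE)
  }
  RawChromatogram(times, mz, intens)
}

#' Write a chromatogram in the CSV matrix dialect
#'
#' Inverse of [readChromatogram()]; integer ion counts round-trip exactly.
#'
#' @param x a [RawChromatogram-class] or [BinnedChromatogram-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeChromatogram <- function(x, path) {
  stopifnot(is(x, "RawChromatogram") || is(x, "BinnedChromatogram"))
  ## 17 significant digits so the time and m/z axes round-trip bit-exactly
  df <- data.frame(time = sprintf("%.17g", x@times), x@intensity,
                   check.names = FALSE)
  names(df) <- c("time", sprintf("%.17g", x@mz))
  data.table::fwrite(df, path)
  invisible(path)
}

readMzml <- function(path, mz.grid = NULL) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("mzML input requires the mzR package", call. = FALSE)
  h <- NULL
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::header(ms)
  pk <- mzR::peaks(ms)
  if (is.matrix(pk)) pk <- list(pk)
  times <- hdr$retentionTime / 60  # mzR reports seconds
  o <- order(times)
  times <- times[o]
  pk <- pk[o]
  if (is.null(mz.grid)) {
    rng <- range(unlist(lapply(pk, function(p) p[, 1L])), na.rm = TRUE)
    mz.grid <- seq(floor(rng[1L]), ceiling(rng[2L]))
  }
  intens <- matrix(0, nrow = length(times), ncol = length(mz.grid))
  for (i in seq_along(pk)) {
    p <- pk[[i]]
    if (!nrow(p)) next
    j <- findInterval(p[, 1L], mz.grid + c(diff(mz.grid) / 2, Inf)) + 1L
    j[j > length(mz.grid)] <- length(mz.grid)
    agg <- rowsum(p[, 2L], j)
    intens[i, as.integer(rownames(agg))] <- agg[, 1L]
  }
  RawChromatogram(times, mz.grid, intens)
}

#' Read a sample manifest
#'
#' Expects a CSV with required columns `sample_id`, `source`, `risk` and
#' optional `age`, `psa`. Risk labels must come from [riskLevels()].
#'
#' @param path manifest CSV path.
#' @return data.frame of validated sample metadata.
#' @export
readManifest <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  m <- data.table::fread(path, header = TRUE, data.table = FALSE,
                         colClasses = list(character = "sample_id"))
  need <- c("sample_id", "source", "risk")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(m$sample_id)) {
    d <- m$sample_id[duplicated(m$sample_id)][1L]
    stop("duplicate sample_id in manifest: '", d, "'", call. = FALSE)
  }
  bad <- setdiff(unique(m$risk), riskLevels())
  if (length(bad))
    stop("unknown risk label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(riskLevels(), collapse = ", "),
         call. = FALSE)
  m$source <- as.character(m$source)
  m$risk <- as.character(m$risk)
  m
}

#' Read a full dataset directory
#'
#' Loads `manifest.csv` plus one `<sample_id>.csv` chromatogram per manifest
#' row from `dir`.
#'
#' @param dir directory containing the CSV-dialect files.
#' @param manifest optional manifest path (default `file.path(dir,
#'   "manifest.csv")`).
#' @return a [ScentDataset-class].
#' @export
readDataset <- function(dir, manifest = file.path(dir, "manifest.csv")) {
  meta <- readManifest(manifest)
  chroms <- lapply(meta$sample_id, function(id)
    readChromatogram(file.path(dir, paste0(id, ".csv"))))
  ScentDataset(chroms, meta)
}

#' Write a dataset directory
#'
#' @param d a [ScentDataset-class].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(d, dir) {
  stopifnot(is(d, "ScentDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(d@meta, file.path(dir, "manifest.csv"))
  for (i in seq_along(d@chromatograms))
    writeChromatogram(d@chromatograms[[i]],
                      file.path(dir, paste0(d@meta$sample_id[i], ".csv")))
  invisible(dir)
}

#' Validate a dataset against the pipeline's assumptions
#'
#' Report-only screen mirroring the rejection of corrupted runs: flags empty
#' matrices, NaN/negative intensities, non-monotone time axes and time-axis
#' gaps above `gap.factor` times the median sampling interval. The input is
#' never modified; NaNs are treated as corruption, not imputed.
#'
#' @param d a [ScentDataset-class] (records need not pass class validity;
#'   raw list/meta input is screened as-is via [ScentDataset()] fields).
#' @param gap.factor flag a record whose largest time step exceeds this
#'   multiple of its median time step (default 10).
#' @return a list with `kept`, `rejected` counts and a data.frame `report`
#'   (sample_id, ok, reason).
#' @export
validateDataset <- function(d, gap.factor = 10) {
  stopifnot(is(d, "ScentDataset"))
  screen <- function(ch) {
    t <- ch@times; I <- ch@intensity
    if (length(t) == 0L || nrow(I) == 0L || ncol(I) == 0L) return("empty")
    if (anyNA(I)) return("NaN intensity")
    if (any(I < 0)) return("negative intensity")
    if (length(t) > 1L) {
      dt <- diff(t)
      if (any(dt <= 0)) return("non-monotone time axis")
      if (max(dt) > gap.factor * stats::median(dt)) return("time-axis gap")
    }
    "ok"
  }
  reasons <- vapply(d@chromatograms, screen, character(1L))
  report <- data.frame(sample_id = d@meta$sample_id,
                       ok = reasons == "ok",
                       reason = ifelse(reasons == "ok", "", reasons),
                       stringsAsFactors = FALSE)
  list(kept = sum(report$ok), rejected = sum(!report$ok), report = report)
}
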