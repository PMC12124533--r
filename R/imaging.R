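## Fixed-size 8-bit image encodings of chromatograms for CNN input.
##
## Heatmap mode: time on the x axis (256 columns), m/z on the y axis (256
## rows, row 1 = lowest bin), log1p + per-image min-max intensity scaling,
## and a fixed monotone colormap so pixel ordering follows intensity
## ordering. Peak-projection mode: a deterministic oblique painter's-order
## rendering of per-channel traces. Both produce exactly 256 x 256 x 3
## arrays of 8-bit values.

IMG_SIZE <- 256L

## fixed monotone-lightness colormap: every channel nondecreasing in v,
## anchored at black so zero signal maps to zero pixels
scentColormap <- function() {
  anchors <- rbind(c(0, 0, 0),
                   c(40, 15, 70),
                   c(110, 45, 115),
                   c(185, 95, 130),
                   c(230, 170, 150),
                   c(255, 235, 205))
  pos <- seq(0, 1, length.out = nrow(anchors))
  v <- seq(0, 1, length.out = 256L)
  lut <- sapply(1:3, function(ch)
    round(stats::approx(pos, anchors[, ch], xout = v)$y))
  storage.mode(lut) <- "integer"
  lut
}

## area-weighted 1-D resampling matrix: n_tgt x n_src, rows sum to 1
resampleMatrix <- function(n_src, n_tgt) {
  es <- seq(0, 1, length.out = n_src + 1L)
  et <- seq(0, 1, length.out = n_tgt + 1L)
  lo <- outer(et[-length(et)], es[-length(es)], pmax)
  hi <- outer(et[-1L], es[-1L], pmin)
  W <- pmax(hi - lo, 0)
  W / rowSums(W)
}

windowSlice <- function(c, window) {
  if (is.null(window)) return(seq_along(c@times))
  sel <- which(c@times >= window[1L] & c@times <= window[2L])
  if (!length(sel)) stop("empty window: no timesteps in [",
                         window[1L], ", ", window[2L], "]")
  sel
}

#' Heatmap image encoding
#'
#' Resamples the (optionally windowed) chromatogram to a 256 x 256 grid by
#' area-weighted binning (time columns, m/z rows with row 1 = lowest bin),
#' maps intensity by `log1p` followed by per-image min-max scaling to
#' `[0, 255]`, and colors through a fixed monotone lookup table, so the
#' pixel map is monotone nondecreasing in input intensity.
#'
#' @param c a [BinnedChromatogram-class] (or [RawChromatogram-class]).
#' @param window optional length-2 time window in minutes; default the full
#'   run.
#' @param sampleId provenance tag stored on the image.
#' @param global.max optional dataset-level maximum of `log1p` intensity for
#'   global (rather than per-image) normalization.
#' @return a [ScentImage-class].
#' @export
toHeatmapImage <- function(c, window = NULL, sampleId = "",
                           global.max = NULL) {
  sel <- windowSlice(c, window)
  I <- c@intensity[sel, , drop = FALSE]
  Wt <- resampleMatrix(nrow(I), IMG_SIZE)   # 256 x T
  Wm <- resampleMatrix(ncol(I), IMG_SIZE)   # 256 x M
  ## rows = m/z, cols = time
  v <- Wm %*% t(Wt %*% I)
  v <- log1p(pmax(v, 0))
  vmax <- if (is.null(global.max)) max(v) else global.max
  u <- if (vmax > 0) pmin(v / vmax, 1) else v * 0
  q <- matrix(as.integer(round(u * 255)), IMG_SIZE, IMG_SIZE)
  lut <- scentColormap()
  px <- array(0L, dim = c(IMG_SIZE, IMG_SIZE, 3L))
  for (ch in 1:3) px[, , ch] <- lut[q + 1L, ch]
  w <- if (is.null(window)) range(c@times) else as.numeric(window)
  new("ScentImage", pixels = px, sampleId = sampleId, window = w,
      mode = "heatmap")
}

#' Pseudo-3D peak-projection image
#'
#' Renders each m/z channel's time trace as a filled silhouette on an
#' oblique grid, painted back (highest m/z) to front (lowest m/z), so
#' nearer channels occlude farther ones. Rendering is pure array
#' arithmetic: identical input yields identical bytes.
#'
#' @inheritParams toHeatmapImage
#' @return a [ScentImage-class] with `mode = "peaks"`.
#' @export
toPeakProjectionImage <- function(c, window = NULL, sampleId = "") {
  sel <- windowSlice(c, window)
  I <- c@intensity[sel, , drop = FALSE]
  M <- ncol(I)
  ## oblique layout: channel j shifts right by dx and up by dy
  dx.total <- 60L; dy.total <- 80L; h.max <- 130
  width <- IMG_SIZE - dx.total
  Wt <- resampleMatrix(nrow(I), width)
  traces <- t(Wt %*% I)                     # M x width
  traces <- log1p(pmax(traces, 0))
  tmax <- max(traces)
  if (tmax > 0) traces <- traces / tmax
  canvas <- matrix(0, IMG_SIZE, IMG_SIZE)   # rows = y (1 = top)
  lut <- scentColormap()
  for (j in M:1) {                          # back to front
    off <- (j - 1) / max(M - 1, 1)
    x0 <- round(off * dx.total)
    ybase <- IMG_SIZE - round((1 - off) * dy.total) - 1L
    h <- round(traces[j, ] * h.max)
    fill <- 0.25 + 0.35 * off
    for (x in seq_len(width)) {
      if (h[x] <= 0) next
      ytop <- max(ybase - h[x], 1L)
      col <- x0 + x
      canvas[ytop:ybase, col] <- fill
      canvas[ytop, col] <- min(fill + 0.45, 1)  # bright ridge line
    }
  }
  q <- matrix(as.integer(round(canvas * 255)), IMG_SIZE, IMG_SIZE)
  px <- array(0L, dim = c(IMG_SIZE, IMG_SIZE, 3L))
  for (ch in 1:3) px[, , ch] <- lut[q + 1L, ch]
  w <- if (is.null(window)) range(c@times) else as.numeric(window)
  new("ScentImage", pixels = px, sampleId = sampleId, window = w,
      mode = "peaks")
}

#' Zoom-window image tiles
#'
#' One heatmap image per segment of `g`; the tiles' windows exactly tile
#' the run (28 tiles for the canonical 41-minute grid).
#'
#' @param c a chromatogram.
#' @param g a [SegmentGrid-class].
#' @param sampleId provenance tag.
#' @param mode `"heatmap"` or `"peaks"`.
#' @return list of [ScentImage-class], one per segment.
#' @export
tileZoomWindows <- function(c, g, sampleId = "", mode = "heatmap") {
  stopifnot(is(g, "SegmentGrid"))
  lapply(seq_len(nSegments(g)), function(i) {
    w <- g@boundaries[i, ]
    if (mode == "heatmap") toHeatmapImage(c, w, sampleId)
    else toPeakProjectionImage(c, w, sampleId)
  })
}

#' Information compression ratio of the image encoding
#'
#' `(n_values * bits_per_value) / (H * W * C * bits)`. The canonical run
#' (about 3.5e6 32-bit values) against a 256 x 256 x 3 x 8-bit image gives
#' about 71.2.
#'
#' @param n_values number of raw values.
#' @param bits_per_value bits per raw value.
#' @param image_dims length-4 numeric `(H, W, C, bits_per_channel)`.
#' @return the compression ratio.
#' @export
compressionRatio <- function(n_values, bits_per_value,
                             image_dims = c(256, 256, 3, 8)) {
  if (n_values <= 0 || bits_per_value <= 0)
    stop("n_values and bits_per_value must be positive")
  denom <- prod(image_dims)
  if (denom <= 0) stop("image dimensions give a zero-size image")
  (n_values * bits_per_value) / denom
}

#' Write a ScentImage as an 8-bit RGB PNG
#'
#' @param img a [ScentImage-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScentImage <- function(img, path) {
  stopifnot(is(img, "ScentImage"))
  png::writePNG(img@pixels / 255, path)
  invisible(path)
}

#' Encode a dataset as images
#'
#' @param d a [ScentDataset-class].
#' @param mode `"heatmap"` or `"peaks"`.
#' @param window optional time window.
#' @param global.norm if TRUE, heatmaps share one dataset-level intensity
#'   scale instead of per-image min-max.
#' @return named list of [ScentImage-class], one per sample.
#' @export
imagifyDataset <- function(d, mode = c("heatmap", "peaks"), window = NULL,
                           global.norm = FALSE) {
  stopifnot(is(d, "ScentDataset"))
  mode <- match.arg(mode)
  gm <- NULL
  if (global.norm && mode == "heatmap")
    gm <- max(vapply(d@chromatograms, function(ch)
      log1p(max(ch@intensity)), numeric(1L)))
  out <- lapply(seq_along(d@chromatograms), function(i) {
    ch <- d@chromatograms[[i]]
    id <- d@meta$sample_id[i]
    if (mode == "heatmap") toHeatmapImage(ch, window, id, global.max = gm)
    else toPeakProjectionImage(ch, window, id)
  })
  names(out) <- d@meta$sample_id
  out
}
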