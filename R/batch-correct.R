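## Empirical-Bayes source-batch correction.
##
## Template: per-feature standardization, naive per-(batch, feature)
## location/scale estimates, batch-level hyperpriors fitted across features,
## and shrunken posterior estimates used to adjust the data. The additive
## shift carries a Normal(mu, sigma^2) prior; the multiplicative factor a
## Gamma(shape, rate) prior, both fitted by maximum likelihood with
## method-of-moments initialization. The gamma posterior mean is computed by
## numerical quadrature (the gamma prior on a normal scale parameter is not
## conjugate).

#' Build a feature matrix from a dataset
#'
#' Default features are per-(segment, m/z bin) summed intensities — 28 x M'
#' features for the canonical 41-minute grid — which keeps the
#' batch-effects-stable-in-time assumption explicit. `mode = "tic"` uses raw
#' TIC timesteps as features instead.
#'
#' @param d a [ScentDataset-class]; raw chromatograms are m/z-binned first.
#' @param grid a [SegmentGrid-class]; default `segmentTime(tmax, 1.5)`.
#' @param mode `"segment"` (default) or `"tic"`.
#' @return a [FeatureMatrix-class] with the dataset's source labels as
#'   batches and risk labels attached.
#' @export
segmentFeatures <- function(d, grid = NULL, mode = c("segment", "tic")) {
  stopifnot(is(d, "ScentDataset"))
  mode <- match.arg(mode)
  chroms <- lapply(d@chromatograms, function(ch)
    if (is(ch, "BinnedChromatogram")) ch else roundMz(ch))
  mz0 <- chroms[[1L]]@mz
  if (!all(vapply(chroms, function(ch)
    identical(ch@mz, mz0), logical(1L))))
    stop("all samples must share one m/z bin grid")
  if (mode == "tic") {
    vals <- t(vapply(chroms, function(ch) rowSums(ch@intensity),
                     numeric(length(chroms[[1L]]@times))))
    colnames(vals) <- paste0("t", seq_len(ncol(vals)))
  } else {
    tmax <- max(chroms[[1L]]@times)
    if (is.null(grid)) grid <- segmentTime(tmax, 1.5)
    seg <- segmentIndex(chroms[[1L]]@times, grid)
    vals <- t(vapply(chroms, function(ch)
      as.numeric(rowsum(ch@intensity, seg)),
      numeric(length(unique(seg)) * length(mz0))))
    colnames(vals) <- as.character(outer(sort(unique(seg)), mz0,
                                         function(s, m)
                                           sprintf("seg%02d_mz%d", s, m)))
  }
  FeatureMatrix(vals, batch = d@meta$source, risk = d@meta$risk,
                sampleIds = d@meta$sample_id)
}

gammaMLE <- function(x) {
  x <- x[is.finite(x) & x > 0]
  m <- mean(x); v <- stats::var(x)
  if (!length(x) || m <= 0) return(c(shape = 1, rate = 1))
  if (!is.finite(v) || v <= 1e-12 * m^2)          # near-degenerate spread
    return(c(shape = 1e6, rate = 1e6 / m))
  start <- list(shape = m^2 / v, rate = m / v)    # method of moments
  fit <- tryCatch(
    fitdistrplus::fitdist(x, "gamma", method = "mle", start = start),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$estimate)))
    return(c(shape = start$shape, rate = start$rate))
  c(shape = unname(fit$estimate["shape"]), rate = unname(fit$estimate["rate"]))
}

## posterior mean of delta under Gamma(shape, rate) prior and
## within-batch sum of squares S on df degrees of freedom:
##   log p(delta | S) = (shape - 1 - df) log delta - rate*delta - S/(2 delta^2)
## computed by quadrature on a log-spaced grid, vectorized over features.
gammaPosteriorMean <- function(shape, rate, S, df, delta.hat) {
  prior.mean <- shape / rate
  lo <- pmax(pmin(delta.hat, prior.mean) / 20, 1e-6)
  hi <- pmax(delta.hat, prior.mean) * 20
  n.grid <- 400L
  out <- numeric(length(S))
  for (j in seq_along(S)) {
    lg <- seq(log(lo[j]), log(hi[j]), length.out = n.grid)
    d <- exp(lg)
    lp <- (shape - df[j]) * lg - rate * d - S[j] / (2 * d^2)
    ## integrate in log space: p(delta) d(delta) = p(e^l) e^l dl;
    ## the extra e^l folds into (shape - 1 - df + 1) = shape - df above
    lp <- lp - max(lp)
    w <- exp(lp)
    out[j] <- sum(w * d) / sum(w)
  }
  out
}

#' Fit the empirical-Bayes batch-effect model
#'
#' Estimates per-feature grand location and pooled within-batch scale, naive
#' per-(batch, feature) additive shifts (batch mean minus grand location)
#' and multiplicative factors (within-batch SD over pooled SD), then fits
#' per-batch hyperpriors across features — Normal for shifts, Gamma (MLE,
#' method-of-moments start) for factors — and computes shrunken posterior
#' estimates `gammaStar` (normal-normal posterior mean) and `deltaStar`
#' (gamma-prior posterior mean by quadrature).
#'
#' An additive shift common to every batch is not identifiable from the data
#' (the grand location absorbs it); supply `grandLoc`/`grandScale` when an
#' external baseline is known (e.g. simulation truth or a spike-in anchor).
#'
#' @param X a [FeatureMatrix-class], or a samples x features matrix if
#'   `batch` is given.
#' @param batch per-sample batch labels (ignored when `X` is a
#'   [FeatureMatrix-class]).
#' @param grandLoc optional known per-feature grand location.
#' @param grandScale optional known per-feature scale.
#' @param var.floor variance floor on the per-feature pooled scale
#'   (default 1e-8).
#' @param min.batch minimum samples per batch (default 3; relaxable to 1
#'   for degenerate single-batch checks).
#' @return an [EBModel-class].
#' @export
fitEB <- function(X, batch = NULL, grandLoc = NULL, grandScale = NULL,
                  var.floor = 1e-8, min.batch = 3L) {
  if (is(X, "FeatureMatrix")) {
    batch <- X@batch
    X <- X@values
  }
  X <- as.matrix(X)
  batch <- as.factor(batch)
  if (anyNA(X)) stop("feature matrix contains NA")
  nb <- nlevels(batch)
  tab <- table(batch)
  if (any(tab < min.batch))
    stop("each batch needs at least ", min.batch, " samples")
  if (ncol(X) < 2L) stop("need at least 2 features")

  alpha <- if (!is.null(grandLoc)) rep_len(grandLoc, ncol(X)) else colMeans(X)
  bmeans <- rowsum(X, batch) / as.vector(tab)          # nb x features
  ## within-batch variances
  wvar <- (rowsum(X^2, batch) - as.vector(tab) * bmeans^2) /
    pmax(as.vector(tab) - 1L, 1L)
  wvar <- pmax(wvar, 0)
  if (any(rowSums(wvar) == 0 & tab > 1L))
    stop("degenerate batch: zero variance across all features in batch '",
         levels(batch)[which(rowSums(wvar) == 0 & tab > 1L)[1L]], "'")
  pooled <- if (!is.null(grandScale)) rep_len(grandScale, ncol(X))^2 else
    colSums(wvar * pmax(as.vector(tab) - 1L, 1L)) /
      max(sum(pmax(tab - 1L, 1L)), 1L)
  pooled <- pmax(pooled, var.floor)
  sigma <- sqrt(pooled)

  gammaHat <- sweep(bmeans, 2L, alpha, "-")
  deltaHat <- sweep(sqrt(wvar), 2L, sigma, "/")
  deltaHat <- pmax(deltaHat, 1e-6)

  normHyper <- matrix(NA_real_, nb, 2L,
                      dimnames = list(levels(batch), c("mu", "sd")))
  gammaHyper <- matrix(NA_real_, nb, 2L,
                       dimnames = list(levels(batch), c("shape", "rate")))
  gammaStar <- gammaHat
  deltaStar <- deltaHat
  for (b in seq_len(nb)) {
    g <- gammaHat[b, ]
    normHyper[b, ] <- c(mean(g), stats::sd(g))
    gh <- gammaMLE(deltaHat[b, ])
    gammaHyper[b, ] <- gh
    n_b <- as.integer(tab[b])
    ## normal-normal shrinkage for the additive shift
    v <- wvar[b, ] / max(n_b, 1L)                 # var of the batch mean
    tau2 <- max(normHyper[b, 2L]^2, 1e-12)
    gammaStar[b, ] <- (g / pmax(v, 1e-12) + normHyper[b, 1L] / tau2) /
      (1 / pmax(v, 1e-12) + 1 / tau2)
    ## gamma-prior posterior mean for the multiplicative factor
    df <- rep(max(n_b - 1L, 1L), ncol(X))
    S <- df * deltaHat[b, ]^2                     # standardized SSQ
    deltaStar[b, ] <- gammaPosteriorMean(gh["shape"], gh["rate"],
                                         S, df, deltaHat[b, ])
  }
  deltaStar <- pmax(deltaStar, 1e-6)
  new("EBModel", grandLoc = alpha, grandScale = sigma,
      batches = levels(batch),
      gammaHat = gammaHat, deltaHat = deltaHat,
      gammaStar = gammaStar, deltaStar = deltaStar,
      normHyper = normHyper, gammaHyper = gammaHyper,
      nPerBatch = as.integer(tab))
}

#' Apply a fitted empirical-Bayes correction
#'
#' Adjusts each sample by its batch's posterior shift and factor:
#' `x_adj = (x - alpha_g - gammaStar_bg) / deltaStar_bg + alpha_g`.
#'
#' @param X a [FeatureMatrix-class] (or matrix with `batch`).
#' @param m a fitted [EBModel-class] on a compatible feature space.
#' @param batch per-sample batch labels when `X` is a bare matrix. Labels
#'   unseen at fit time are an error — no silent pass-through.
#' @param clamp if TRUE, clamp the adjusted values at 0 (count-like data).
#' @return object of the same kind as `X`, adjusted.
#' @export
applyEB <- function(X, m, batch = NULL, clamp = FALSE) {
  stopifnot(is(m, "EBModel"))
  fm <- NULL
  if (is(X, "FeatureMatrix")) {
    fm <- X; batch <- X@batch; X <- X@values
  }
  X <- as.matrix(X)
  if (ncol(X) != length(m@grandLoc))
    stop("feature space does not match the fitted model")
  batch <- as.character(batch)
  unseen <- setdiff(unique(batch), m@batches)
  if (length(unseen))
    stop("batch label(s) not seen at fit time: ",
         paste(unseen, collapse = ", "))
  b <- match(batch, m@batches)
  adj <- (X - rep(m@grandLoc, each = nrow(X)) - m@gammaStar[b, , drop = FALSE]) /
    m@deltaStar[b, , drop = FALSE] + rep(m@grandLoc, each = nrow(X))
  if (clamp) adj <- pmax(adj, 0)
  dimnames(adj) <- dimnames(X)
  if (!is.null(fm))
    FeatureMatrix(adj, fm@batch, as.character(fm@risk), fm@sampleIds)
  else adj
}

## exact maximum-accuracy cluster -> label assignment (permutation search)
matchedAccuracy <- function(cluster, label) {
  cluster <- as.integer(as.factor(cluster))
  label <- as.integer(as.factor(label))
  k <- max(cluster, label)
  if (k > 8L)
    stop("exact assignment matching implemented for k <= 8")
  tab <- matrix(0L, k, k)
  for (i in seq_along(cluster))
    tab[cluster[i], label[i]] <- tab[cluster[i], label[i]] + 1L
  perms <- permuteAll(k)
  best <- max(apply(perms, 1L, function(p)
    sum(tab[cbind(seq_len(k), p)])))
  best / length(label)
}

permuteAll <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permuteAll(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

#' k-means source-clustering audit
#'
#' How well does unsupervised k-means recover the source labels? Runs
#' k-means with `nstart` restarts under a fixed seed, matches clusters to
#' labels by exact maximum-accuracy assignment, and returns the matched
#' accuracy — high before debiasing, near chance after.
#'
#' @param X a [FeatureMatrix-class] (or matrix with `batch`).
#' @param k number of clusters; default the number of batches.
#' @param batch labels when `X` is a bare matrix.
#' @param nstart k-means restarts (default 20).
#' @param seed RNG seed (default 1).
#' @param scale. standardize features to unit variance first (default TRUE).
#' @return matched accuracy fraction in `[0, 1]`.
#' @export
sourceClusteringAudit <- function(X, k = NULL, batch = NULL, nstart = 20L,
                                  seed = 1L, scale. = TRUE) {
  if (is(X, "FeatureMatrix")) {
    batch <- X@batch; X <- X@values
  }
  batch <- as.factor(batch)
  if (is.null(k)) k <- nlevels(batch)
  if (k < 2L) stop("k must be >= 2")
  if (k > nrow(X)) stop("k exceeds the number of samples")
  V <- as.matrix(X)
  if (scale.) {
    sds <- apply(V, 2L, stats::sd)
    keep <- sds > 0
    V <- sweep(V[, keep, drop = FALSE], 2L, sds[keep], "/")
  }
  old <- rngSnapshot(); on.exit(rngRestore(old))
  set.seed(seed)
  km <- stats::kmeans(V, centers = k, nstart = nstart, iter.max = 50L)
  matchedAccuracy(km$cluster, batch)
}

#' PCA audit of batch structure
#'
#' First two principal-component scores plus a batch-separation statistic:
#' the mean pairwise distance between batch centroids divided by the mean
#' within-batch distance to the own centroid, in PC1-2 space. Degenerate
#' (zero-variance) input reports separation 0.
#'
#' @param X a [FeatureMatrix-class] (or matrix with `batch`).
#' @param batch labels when `X` is a bare matrix.
#' @return list with `scores` (n x 2), `centroids` (batch x 2) and
#'   `separation` (numeric).
#' @export
pcaAudit <- function(X, batch = NULL) {
  if (is(X, "FeatureMatrix")) {
    batch <- X@batch; X <- X@values
  }
  batch <- as.factor(batch)
  V <- as.matrix(X)
  if (nrow(V) < 3L) stop("need at least 3 samples")
  sds <- apply(V, 2L, stats::sd)
  if (all(sds == 0)) {
    scores <- matrix(0, nrow(V), 2L)
    cents <- matrix(0, nlevels(batch), 2L,
                    dimnames = list(levels(batch), NULL))
    return(list(scores = scores, centroids = cents, separation = 0))
  }
  pc <- stats::prcomp(V, center = TRUE, scale. = FALSE, rank. = 2L)
  scores <- pc$x
  if (ncol(scores) < 2L) scores <- cbind(scores, 0)
  cents <- rowsum(scores, batch) / as.vector(table(batch))
  within <- mean(sqrt(rowSums((scores - cents[as.integer(batch), ,
                                              drop = FALSE])^2)))
  dd <- as.matrix(stats::dist(cents))
  between <- mean(dd[upper.tri(dd)])
  sep <- if (!is.finite(within) || within <= 1e-12) {
    if (between > 1e-12) Inf else 0
  } else between / within
  list(scores = scores, centroids = cents, separation = sep)
}
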