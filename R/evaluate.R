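## Stratified cross-validation, confusion matrices, per-class metrics and
## the three-class -> two-class (Control vs PCa+) merge.

#' Stratified k-fold plan
#'
#' Deterministic given `seed`: within each risk class, samples are shuffled
#' and dealt round-robin across folds, so every fold's test set holds each
#' class's proportion within one sample of the global proportion and the
#' test sets partition the dataset.
#'
#' @param meta data.frame with a `risk` column (the stratification key).
#' @param n_folds number of folds (default 5: stratified 20% test sets).
#' @param seed RNG seed.
#' @return list of folds, each `list(train = idx, test = idx)`.
#' @export
makeFolds <- function(meta, n_folds = 5L, seed = 1L) {
  y <- as.character(meta$risk)
  tab <- table(y)
  small <- names(tab)[tab < n_folds]
  if (length(small))
    stop("class(es) smaller than n_folds: ", paste(small, collapse = ", "))
  old <- rngSnapshot(); on.exit(rngRestore(old))
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in names(tab)) {
    i <- sample(which(y == cl))
    fold[i] <- rep_len(seq_len(n_folds), length(i))
  }
  lapply(seq_len(n_folds), function(f)
    list(train = which(fold != f), test = which(fold == f)))
}

#' Confusion matrix and classification report
#'
#' Precision = TP / (TP + FP), recall = TP / (TP + FN),
#' F1 = 2PR / (P + R); macro averages are unweighted class means; support
#' is the number of true instances per class. An empty precision/recall
#' denominator reports the metric as 0 and raises the `zeroDivision` flag.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param classes declared class labels (row/column order of the matrix).
#'   Predictions outside this set are an error.
#' @return an [EvalReport-class].
#' @export
confusionAndReport <- function(y_true, y_pred, classes = riskLevels()) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("label vectors must have equal length")
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad))
    stop("label(s) outside declared classes: ", paste(bad, collapse = ", "))
  cm <- table(factor(y_true, classes), factor(y_pred, classes))
  cm <- unclass(as.matrix(cm))
  names(dimnames(cm)) <- c("true", "predicted")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  zdiv <- any(tp + fp == 0) || any(tp + fn == 0)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  per <- data.frame(class = classes, precision = prec, recall = rec,
                    f1 = f1, support = rowSums(cm), row.names = NULL)
  new("EvalReport", confusion = cm, perClass = per,
      macro = c(precision = mean(prec), recall = mean(rec), f1 = mean(f1)),
      accuracy = sum(tp) / max(sum(cm), 1L),
      merged = list(), zeroDivision = zdiv)
}

#' Merge the risk classes into a two-class report
#'
#' LowRisk and HighRisk collapse to `PCa+` in truth and prediction (so
#' cross-risk confusions vanish) and the metrics are recomputed for
#' Control vs PCa+.
#'
#' @param y_true,y_pred 3-class label vectors, or an [EvalReport-class]
#'   whose confusion matrix is merged directly.
#' @return list with `confusion` (2 x 2), `perClass`, `macro`, `accuracy`.
#' @export
mergeTwoClass <- function(y_true, y_pred = NULL) {
  merge1 <- function(y) ifelse(y == "Control", "Control", "PCa+")
  if (is(y_true, "EvalReport")) {
    cm3 <- y_true@confusion
    stopifnot(all(rownames(cm3) == riskLevels()))
    grp <- merge1(rownames(cm3))
    cm <- t(rowsum(t(rowsum(cm3, grp)), grp))  # rows = true, cols = pred
    cm <- cm[c("Control", "PCa+"), c("Control", "PCa+")]
    names(dimnames(cm)) <- c("true", "predicted")
  } else {
    yt <- merge1(as.character(y_true)); yp <- merge1(as.character(y_pred))
    cm <- unclass(as.matrix(table(factor(yt, c("Control", "PCa+")),
                                  factor(yp, c("Control", "PCa+")))))
    names(dimnames(cm)) <- c("true", "predicted")
  }
  tp <- diag(cm); fp <- colSums(cm) - tp; fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(confusion = cm,
       perClass = data.frame(class = rownames(cm), precision = prec,
                             recall = rec, f1 = f1, support = rowSums(cm),
                             row.names = NULL),
       macro = c(precision = mean(prec), recall = mean(rec), f1 = mean(f1)),
       accuracy = sum(tp) / max(sum(cm), 1L))
}

#' Cross-validated evaluation of the adversarial classifier
#'
#' Runs [makeFolds()] stratified 5-fold cross-validation: per fold, trains
#' [trainAdversarial()] on the training split, predicts the test split, and
#' pools the confusion counts across folds before computing pooled metrics
#' (per-fold accuracies are also reported with mean and SD). The two-class
#' merge is attached to the pooled report.
#'
#' @param images image list.
#' @param meta data.frame with `risk` and `source`.
#' @param cfg an [advConfig()].
#' @param n_folds number of folds (default 5).
#' @param seed fold-plan seed.
#' @return an [EvalReport-class] with `merged` filled in and a `folds`
#'   attribute (per-fold accuracy data.frame).
#' @export
crossValidate <- function(images, meta, cfg = advConfig(), n_folds = 5L,
                          seed = 1L) {
  folds <- makeFolds(meta, n_folds, seed)
  yt <- character(); yp <- character()
  fold.acc <- numeric(length(folds))
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    m <- trainAdversarial(images[tr], meta[tr, , drop = FALSE], cfg)
    P <- predictRisk(m, images[te])
    pred <- m@classes[max.col(P, ties.method = "first")]
    truth <- as.character(meta$risk[te])
    yt <- c(yt, truth); yp <- c(yp, pred)
    fold.acc[f] <- mean(pred == truth)
  }
  rep <- confusionAndReport(yt, yp)
  rep@merged <- mergeTwoClass(yt, yp)
  attr(rep, "folds") <- data.frame(fold = seq_along(folds),
                                   accuracy = fold.acc)
  rep
}

#' Serialize / deserialize an EvalReport as JSON
#'
#' @param r an [EvalReport-class].
#' @param path output JSON path.
#' @return `readEvalReport()` reconstructs the [EvalReport-class];
#'   `writeEvalReport()` returns `path` invisibly.
#' @export
writeEvalReport <- function(r, path) {
  stopifnot(is(r, "EvalReport"))
  obj <- list(classes = rownames(r@confusion),
              confusion = unname(r@confusion),
              perClass = r@perClass, macro = as.list(r@macro),
              accuracy = r@accuracy, zeroDivision = r@zeroDivision,
              merged = if (length(r@merged))
                list(classes = rownames(r@merged$confusion),
                     confusion = unname(r@merged$confusion),
                     perClass = r@merged$perClass,
                     macro = as.list(r@merged$macro),
                     accuracy = r@merged$accuracy) else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeEvalReport
#' @export
readEvalReport <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  mkcm <- function(cmat, cls) {
    cm <- as.matrix(cmat)
    dimnames(cm) <- list(true = cls, predicted = cls)
    cm
  }
  merged <- list()
  if (!is.null(o$merged))
    merged <- list(confusion = mkcm(o$merged$confusion, o$merged$classes),
                   perClass = as.data.frame(o$merged$perClass),
                   macro = unlist(o$merged$macro),
                   accuracy = o$merged$accuracy)
  new("EvalReport", confusion = mkcm(o$confusion, o$classes),
      perClass = as.data.frame(o$perClass), macro = unlist(o$macro),
      accuracy = o$accuracy, merged = merged,
      zeroDivision = isTRUE(o$zeroDivision))
}
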