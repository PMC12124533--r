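test_that("stratified folds partition the data with balanced test classes", {
  meta <- data.frame(risk = rep(c("Control", "LowRisk"), c(50, 50)))
  f <- makeFolds(meta, 5L, seed = 3L)
  expect_length(f, 5L)
  tests <- lapply(f, `[[`, "test")
  expect_setequal(unlist(tests), 1:100)
  expect_equal(anyDuplicated(unlist(tests)), 0L)
  for (fd in f) {
    expect_equal(sum(meta$risk[fd$test] == "Control"), 10L)
    expect_equal(sum(meta$risk[fd$test] == "LowRisk"), 10L)
    expect_setequal(c(fd$train, fd$test), 1:100)
  }

  ## deterministic given seed
  expect_identical(makeFolds(meta, 5L, seed = 3L), f)

  ## 365 samples in the clinical proportions -> 73-sample test folds
  meta365 <- data.frame(risk = rep(riskLevels(), c(125, 133, 107)))
  f365 <- makeFolds(meta365, 5L, seed = 1L)
  sizes <- vapply(f365, function(x) length(x$test), integer(1))
  expect_true(all(abs(sizes - 73) <= 2))
  expect_equal(sum(sizes), 365L)

  expect_error(makeFolds(data.frame(risk = c("Control", "Control",
                                             "LowRisk")), 5L),
               "smaller than n_folds")
})

test_that("classification report matches hand-counted metrics", {
  ## worked example: 111 of 180 true Control correct -> recall 0.62
  yt <- c(rep("Control", 180), rep("LowRisk", 20))
  yp <- c(rep("Control", 111), rep("LowRisk", 69), rep("LowRisk", 20))
  r <- confusionAndReport(yt, yp)
  expect_equal(round(r@perClass$recall[1], 2), 0.62)
  expect_equal(r@confusion["Control", "Control"], 111)

  ## perfect predictions
  rp <- confusionAndReport(yt, yt)
  expect_true(all(rp@perClass$precision[rp@perClass$support > 0] == 1))
  expect_equal(rp@accuracy, 1)

  ## constructed 3x3 matrix vs hand-counted TP/FP/FN
  cm <- rbind(c(5, 1, 0), c(2, 6, 2), c(0, 3, 7))
  yt2 <- rep(riskLevels(), rowSums(cm))
  yp2 <- unlist(lapply(1:3, function(i) rep(riskLevels(), cm[i, ])))
  r2 <- confusionAndReport(yt2, yp2)
  expect_equal(unname(r2@confusion), cm, ignore_attr = TRUE)
  ## hand counts: e.g. LowRisk TP=6, FP=1+3, FN=2+2
  expect_equal(r2@perClass$precision[2], 6 / 10)
  expect_equal(r2@perClass$recall[2], 6 / 10)
  expect_equal(r2@perClass$f1[2], 0.6)
  expect_equal(r2@perClass$support, rowSums(cm), ignore_attr = TRUE)
  expect_equal(r2@accuracy, sum(diag(cm)) / sum(cm))
  expect_equal(unname(r2@macro["precision"]),
               mean(diag(cm) / colSums(cm)))

  ## zero-division flag
  yt3 <- c("Control", "Control")
  yp3 <- c("Control", "Control")
  expect_true(confusionAndReport(yt3, yp3)@zeroDivision)

  expect_error(confusionAndReport("Control", "Benign"),
               "outside declared classes")
  expect_error(confusionAndReport(c("Control", "LowRisk"), "Control"),
               "equal length")
})

test_that("two-class merge collapses cross-risk confusions", {
  ## all correct at 3 classes -> 2-class accuracy 1
  yt <- riskLevels()
  expect_equal(mergeTwoClass(yt, yt)$accuracy, 1)

  ## cross-risk confusions vanish
  m <- mergeTwoClass(c("Control", "LowRisk", "HighRisk"),
                     c("Control", "HighRisk", "LowRisk"))
  expect_equal(m$accuracy, 1)

  ## constructed counts vs hand computation
  yt2 <- c(rep("Control", 10), rep("LowRisk", 6), rep("HighRisk", 4))
  yp2 <- c(rep("Control", 7), rep("LowRisk", 3),    # 3 C -> PCa+
           rep("Control", 2), rep("HighRisk", 4),   # 2 L -> C
           rep("LowRisk", 4))
  m2 <- mergeTwoClass(yt2, yp2)
  expect_equal(unname(m2$confusion), rbind(c(7, 3), c(2, 8)),
               ignore_attr = TRUE)
  expect_equal(m2$perClass$recall[2], 0.8)
  expect_equal(m2$perClass$precision[2], 8 / 11)
  expect_equal(m2$accuracy, 15 / 20)

  ## merging an EvalReport's confusion matrix agrees with label merging
  r <- confusionAndReport(yt2, yp2)
  m3 <- mergeTwoClass(r)
  expect_equal(m3$confusion, m2$confusion)

  ## merged accuracy can only improve on 3-class accuracy
  set.seed(4)
  yr <- sample(riskLevels(), 60, TRUE)
  pr <- sample(riskLevels(), 60, TRUE)
  expect_gte(mergeTwoClass(yr, pr)$accuracy,
             confusionAndReport(yr, pr)@accuracy)
})

test_that("cross-validated evaluation pools confusion counts over folds", {
  ## tiny end-to-end run: deterministic images, fast config
  set.seed(6)
  mk <- function(blk) {
    px <- matrix(0.1, 256, 256)
    px[97:160, 97:160] <- px[97:160, 97:160] + blk
    px <- pmin(px + matrix(runif(256 * 256, 0, 0.05), 256), 1)
    array(as.integer(round(px * 255)), c(256, 256, 3))
  }
  meta <- data.frame(risk = rep(riskLevels(), each = 10),
                     source = rep(c("S1", "S2"), 15))
  blk <- c(Control = 0, LowRisk = 0.25, HighRisk = 0.5)
  imgs <- lapply(seq_len(30), function(i) mk(blk[meta$risk[i]]))
  rep <- crossValidate(imgs, meta,
                       advConfig(lambda = 0, epochs = 10L,
                                 channels = c(4L, 6L), batch_size = 12L),
                       n_folds = 5L, seed = 2L)
  expect_s4_class(rep, "EvalReport")
  expect_equal(sum(rep@confusion), 30)              # pooled over all folds
  folds <- attr(rep, "folds")
  expect_equal(nrow(folds), 5L)
  expect_equal(rep@accuracy,
               sum(diag(rep@confusion)) / sum(rep@confusion))
  expect_length(rep@merged, 4L)                     # two-class merge attached
})

test_that("report JSON serialization round-trips", {
  set.seed(5)
  yt <- sample(riskLevels(), 40, TRUE)
  yp <- sample(riskLevels(), 40, TRUE)
  r <- confusionAndReport(yt, yp)
  r@merged <- mergeTwoClass(yt, yp)
  f <- tempfile(fileext = ".json")
  writeEvalReport(r, f)
  back <- readEvalReport(f)
  expect_equal(back@confusion, r@confusion)
  expect_equal(back@perClass$f1, r@perClass$f1)
  expect_equal(back@macro, r@macro)
  expect_equal(back@accuracy, r@accuracy)
  expect_equal(back@merged$confusion, r@merged$confusion)
})
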