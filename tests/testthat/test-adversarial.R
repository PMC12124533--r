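# Domain-adversarial classifier: loss arithmetic, analytic gradients vs a
# numerical oracle, the gradient-reversal sign, training contracts, and the
# residual-bias probe. Heavier end-to-end debiasing behaviour lives in the
# acceptance tests.

## small deterministic image set: class = brightness of a centre block,
## source = global brightness offset
toyImages <- function(n.rep = 4L, noise = 0.05, seed = 42L) {
  set.seed(seed)
  mk <- function(off, blk) {
    px <- matrix(off, 256, 256)
    px[97:160, 97:160] <- px[97:160, 97:160] + blk
    px <- pmin(px + matrix(runif(256 * 256, 0, noise), 256), 1)
    array(as.integer(round(px * 255)), c(256, 256, 3))
  }
  meta <- expand.grid(rep = seq_len(n.rep), source = c("S1", "S2"),
                      risk = riskLevels(), stringsAsFactors = FALSE)
  offv <- c(S1 = 0.1, S2 = 0.4)
  blkv <- c(Control = 0, LowRisk = 0.2, HighRisk = 0.4)
  imgs <- lapply(seq_len(nrow(meta)), function(i)
    mk(offv[meta$source[i]], blkv[meta$risk[i]]))
  list(imgs = imgs, meta = meta)
}

fastCfg <- function(lambda = 0, epochs = 8L, seed = 1L, ...) {
  advConfig(lambda = lambda, epochs = epochs, seed = seed,
            channels = c(4L, 6L), batch_size = 12L, ...)
}

test_that("the tug-of-war total loss is l0 - lambda * lq", {
  expect_equal(totalLoss(0.9, 123, 0), 0.9)
  expect_equal(totalLoss(0.7, 0.5, 1), 0.2)
  expect_equal(totalLoss(1.0, 0.4, 0.5), 0.8)
  expect_error(totalLoss(1, 1, 1.5), "lambda")
  expect_error(totalLoss(Inf, 1, 0.5), "finite")
})

test_that("analytic gradients match a finite-difference oracle", {
  set.seed(7)
  cfg <- advConfig(lambda = 0.7, channels = c(2L, 3L))
  stem.size <- 8L; n <- 4L
  params <- scentpipe:::initParams(cfg, 3L, 2L, stem.size)
  X <- matrix(runif(n * stem.size^2 * 3), n * stem.size^2, 3)
  y.d <- c(1L, 2L, 3L, 2L); y.s <- c(1L, 2L, 1L, 2L)
  lam <- 0.7
  res <- scentpipe:::advBatchGrad(params, X, y.d, y.s, lam, n, stem.size)
  eps <- 1e-6
  numgrad <- function(set1) {
    r1 <- scentpipe:::advBatchGrad(set1(eps), X, y.d, y.s, lam, n, stem.size)
    r2 <- scentpipe:::advBatchGrad(set1(-eps), X, y.d, y.s, lam, n, stem.size)
    ((r1$l0 - lam * r1$lq) - (r2$l0 - lam * r2$lq)) / (2 * eps)
  }
  ## every conv parameter of both layers against d(Ltotal)
  for (l in 1:2) {
    for (i in seq_along(params$conv[[l]]$W)) {
      g <- numgrad(function(e) {
        p <- params; p$conv[[l]]$W[i] <- p$conv[[l]]$W[i] + e; p
      })
      expect_lt(abs(g - res$grads$conv[[l]]$W[i]), 1e-4)
    }
    for (i in seq_along(params$conv[[l]]$b)) {
      g <- numgrad(function(e) {
        p <- params; p$conv[[l]]$b[i] <- p$conv[[l]]$b[i] + e; p
      })
      expect_lt(abs(g - res$grads$conv[[l]]$b[i]), 1e-4)
    }
  }
})

test_that("the source branch enters the backbone as minus lambda times its gradient", {
  set.seed(8)
  cfg <- advConfig(lambda = 0.6, channels = c(2L, 3L))
  stem.size <- 8L; n <- 4L
  params <- scentpipe:::initParams(cfg, 3L, 2L, stem.size)
  X <- matrix(runif(n * stem.size^2 * 3), n * stem.size^2, 3)
  y.d <- c(1L, 2L, 3L, 2L); y.s <- c(1L, 2L, 1L, 2L)
  gAt <- function(lam) scentpipe:::advBatchGrad(params, X, y.d, y.s, lam,
                                                n, stem.size)
  diffW <- gAt(0.6)$grads$conv[[1]]$W - gAt(0)$grads$conv[[1]]$W
  ## numerical gradient of Lq alone w.r.t. the same weights
  eps <- 1e-6
  for (i in seq_len(12)) {
    pp <- params; pp$conv[[1]]$W[i] <- pp$conv[[1]]$W[i] + eps
    pm <- params; pm$conv[[1]]$W[i] <- pm$conv[[1]]$W[i] - eps
    gq <- (scentpipe:::advBatchGrad(pp, X, y.d, y.s, 0, n, stem.size)$lq -
             scentpipe:::advBatchGrad(pm, X, y.d, y.s, 0, n, stem.size)$lq) /
      (2 * eps)
    expect_lt(abs(diffW[i] - (-0.6) * gq), 1e-4)
  }
})

test_that("training logs the exact loss identity and is seed-deterministic", {
  toy <- toyImages(n.rep = 2L)
  m <- trainAdversarial(toy$imgs, toy$meta, fastCfg(lambda = 0.5))
  h <- trainingHistory(m)
  expect_equal(nrow(h), 8L)
  expect_identical(h$ltotal, h$l0 - h$lambda * h$lq)  # exact arithmetic
  expect_true(all(is.finite(unlist(h[, c("l0", "lq", "ltotal")]))))

  m2 <- trainAdversarial(toy$imgs, toy$meta, fastCfg(lambda = 0.5))
  expect_identical(trainingHistory(m2), h)
  expect_identical(m2@params$conv[[1]]$W, m@params$conv[[1]]$W)

  m3 <- trainAdversarial(toy$imgs, toy$meta, fastCfg(lambda = 0.5, seed = 2L))
  expect_false(identical(m3@params$conv[[1]]$W, m@params$conv[[1]]$W))
})

test_that("at lambda = 0 the source branch leaves the backbone untouched", {
  toy <- toyImages(n.rep = 2L)
  a <- trainAdversarial(toy$imgs, toy$meta,
                        fastCfg(lambda = 0, source_steps = 0L))
  b <- trainAdversarial(toy$imgs, toy$meta,
                        fastCfg(lambda = 0, source_steps = 5L))
  ## extra source-head training must not alter the backbone or the
  ## disease trajectory when the reversal is off
  expect_identical(a@params$conv, b@params$conv)
  expect_identical(trainingHistory(a)$l0, trainingHistory(b)$l0)
})

test_that("configuration errors are caught", {
  toy <- toyImages(n.rep = 2L)
  single <- toy$meta; single$source <- "S1"
  expect_error(trainAdversarial(toy$imgs, single, fastCfg(lambda = 0.5)),
               "single-source")
  expect_error(trainAdversarial(toy$imgs, toy$meta,
                                fastCfg(backbone = "resnet18")),
               "resnet18")
  expect_error(advConfig(lambda = 1.2), "lambda")
})

test_that("prediction is a deterministic softmax over the risk classes", {
  toy <- toyImages(n.rep = 2L)
  m <- trainAdversarial(toy$imgs, toy$meta, fastCfg())
  P <- predictRisk(m, toy$imgs)
  expect_equal(rowSums(P), rep(1, length(toy$imgs)), tolerance = 1e-6)
  expect_equal(colnames(P), riskLevels())
  ## duplicated input -> identical rows
  P2 <- predictRisk(m, toy$imgs[c(1, 1)])
  expect_identical(P2[1, ], P2[2, ])
})

test_that("a separable toy task is learned well above chance", {
  toy <- toyImages(n.rep = 8L, noise = 0.03)
  n <- length(toy$imgs)
  set.seed(2)
  te <- unlist(lapply(split(seq_len(n), toy$meta$risk),
                      function(i) sample(i, 4)))
  tr <- setdiff(seq_len(n), te)
  m <- trainAdversarial(toy$imgs[tr], toy$meta[tr, ],
                        fastCfg(epochs = 30L))
  acc <- mean(m@classes[max.col(predictRisk(m, toy$imgs[te]))] ==
                toy$meta$risk[te])
  expect_gte(acc, 1 / 3 + 0.2)
})

test_that("the residual-bias probe calibrates at its extremes", {
  src <- rep(paste0("S", 1:4), each = 12)
  ## constant features -> chance
  Fc <- matrix(1, 48, 6)
  m <- new("TrainedModel", params = list(), history = data.frame(
    epoch = integer(), l0 = numeric(), lq = numeric(), ltotal = numeric()),
    config = list(), classes = riskLevels(), sources = unique(src))
  pc <- residualBiasProbe(m, Fc, src)
  expect_lte(abs(pc$accuracy - pc$chance), 0.15)
  ## one-hot source features -> perfect
  Fo <- model.matrix(~ 0 + factor(src))
  po <- residualBiasProbe(m, Fo, src)
  expect_gte(po$accuracy, 0.95)
})

test_that("latent features are finite with the configured dimension", {
  toy <- toyImages(n.rep = 2L)
  m <- trainAdversarial(toy$imgs, toy$meta, fastCfg())
  F <- latentFeatures(m, toy$imgs)
  expect_equal(nrow(F), length(toy$imgs))
  expect_equal(ncol(F), m@params$fdim)
  expect_true(all(is.finite(F)))
})
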