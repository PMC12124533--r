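# Empirical-Bayes batch correction: naive estimates, hyperprior fits,
# posterior shrinkage, and the clustering/PCA audits.

simFeatureMatrix <- function(seed, nf = 200L, nb = 4L, ns = 10L,
                             gam.mu = 0.5, gam.sd = 0.1,
                             del.shape = 4, del.rate = 4, sigma = 0.5) {
  set.seed(seed)
  alpha <- runif(nf, 10, 20)
  X <- matrix(0, nb * ns, nf)
  batch <- rep(paste0("B", seq_len(nb)), each = ns)
  truth <- list()
  for (b in seq_len(nb)) {
    gam <- rnorm(nf, gam.mu, gam.sd)
    del <- rgamma(nf, del.shape, del.rate)
    eps <- matrix(rnorm(ns * nf, 0, sigma), ns, nf)
    X[(b - 1) * ns + seq_len(ns), ] <-
      rep(alpha, each = ns) + rep(gam, each = ns) + rep(del, each = ns) * eps
    truth[[b]] <- list(gam = gam, del = del)
  }
  list(X = X, batch = batch, alpha = alpha, sigma = rep(sigma, nf),
       truth = truth)
}

test_that("segmentFeatures aggregates per (segment, m/z) with labels attached", {
  sim <- smallSim(seed = 41L)
  fm <- segmentFeatures(sim$dataset)
  expect_s4_class(fm, "FeatureMatrix")
  expect_equal(nrow(featureValues(fm)), nrow(sampleMeta(sim$dataset)))
  expect_equal(ncol(featureValues(fm)), 28L * 16L)
  expect_equal(as.character(batchLabels(fm)),
               sampleMeta(sim$dataset)$source)
  ## total ion count is conserved by the aggregation
  tot <- sum(intensities(roundMz(chromatograms(sim$dataset)[[1]])))
  expect_equal(sum(featureValues(fm)[1, ]), tot)

  fmt <- segmentFeatures(sim$dataset, mode = "tic")
  expect_equal(ncol(featureValues(fmt)), 300L)
})

test_that("single batch yields near-null correction", {
  sim <- simFeatureMatrix(2L, nf = 80L, nb = 1L, ns = 12L,
                          gam.mu = 0, gam.sd = 0, del.shape = 1e6,
                          del.rate = 1e6)
  m <- fitEB(sim$X, sim$batch, min.batch = 1L)
  expect_lt(max(abs(m@gammaStar)), 0.5)       # shifts ~ 0
  expect_lt(max(abs(m@deltaStar - 1)), 0.35)  # factors ~ 1
  adj <- applyEB(sim$X, m, batch = sim$batch)
  expect_lt(mean(abs(adj - sim$X)), 0.25)
})

test_that("hyperprior recovery: gamma factors and normal shifts", {
  sim <- simFeatureMatrix(3L, nf = 500L, nb = 4L, ns = 30L)
  m <- fitEB(sim$X, sim$batch, grandLoc = sim$alpha,
             grandScale = sim$sigma)
  ## gamma mean shape/rate ~ 1 within 10%
  expect_lt(abs(mean(m@gammaHyper[, "shape"] / m@gammaHyper[, "rate"]) - 1),
            0.1)
  ## normal location within 0.05 of 0.5
  expect_lt(max(abs(m@normHyper[, "mu"] - 0.5)), 0.05)
  ## posterior factors shrink toward the prior: spread no larger than naive
  expect_lte(sd(m@deltaStar), sd(m@deltaHat))
  expect_true(all(m@deltaStar > 0))
})

test_that("apply_eb contract: identity, mean alignment, shape preserved", {
  sim <- simFeatureMatrix(5L, nf = 120L, nb = 2L, ns = 15L)
  m <- fitEB(sim$X, sim$batch)

  ## delta*=1, gamma*=0 -> identity
  id <- m
  id@gammaStar[] <- 0; id@deltaStar[] <- 1
  expect_equal(applyEB(sim$X, id, batch = sim$batch), sim$X,
               ignore_attr = TRUE)

  ## two batches offset by +10 everywhere -> post-correction means equal ~1%
  set.seed(6)
  n <- 100L
  base <- matrix(rnorm(2 * n * 60, 50, 1), 2 * n, 60)
  Xoff <- base
  Xoff[(n + 1):(2 * n), ] <- Xoff[(n + 1):(2 * n), ] + 10
  bt <- rep(c("A", "B"), each = n)
  mo <- fitEB(Xoff, bt)
  adj <- applyEB(Xoff, mo, batch = bt)
  mA <- colMeans(adj[seq_len(n), ]); mB <- colMeans(adj[-seq_len(n), ])
  expect_lt(max(abs(mA - mB) / mA), 0.01)

  ## dims preserved; unseen batch refused; clamp respects nonnegativity
  expect_equal(dim(adj), dim(Xoff))
  expect_error(applyEB(Xoff, mo, batch = rep("C", 2 * n)),
               "not seen at fit")
  expect_true(all(applyEB(Xoff, mo, batch = bt, clamp = TRUE) >= 0))

  ## feature-constant contamination never flips within-sample ordering of
  ## clearly separated features (near-ties may reorder by the estimation
  ## noise of the per-feature correction)
  for (i in 1:5) {
    r <- Xoff[i, 1:20]; c <- adj[i, 1:20]
    expect_false(any(outer(r, r, "-") > 1 & outer(c, c, "<")))
  }

  ## adjustment magnitude shrinks with n for identically distributed batches
  magAt <- function(ns) {
    set.seed(7)
    X <- matrix(rnorm(2 * ns * 40, 20, 3), 2 * ns, 40)
    bt <- rep(c("A", "B"), each = ns)
    m <- fitEB(X, bt)
    mean(abs(applyEB(X, m, batch = bt) - X))
  }
  expect_lt(magAt(200L), magAt(20L))
})

test_that("fitEB rejects degenerate inputs", {
  X <- matrix(5, 10, 20)
  bt <- rep(c("A", "B"), each = 5)
  expect_error(fitEB(X, bt), "degenerate batch")
  expect_error(fitEB(matrix(rnorm(4), 2, 2), rep("A", 2), min.batch = 3L),
               "at least")
})

test_that("k-means source audit: one-hot, chance, and matched accuracy", {
  ## one-hot encoding of source -> perfect recovery
  src <- rep(paste0("S", 1:4), each = 10)
  X <- model.matrix(~ 0 + factor(src))
  expect_equal(sourceClusteringAudit(X, batch = src), 1.0)

  ## pure-noise features, 4 equal batches -> near chance, inside the
  ## permutation-null 95% band
  set.seed(11)
  Xn <- matrix(rnorm(40 * 30), 40, 30)
  acc <- sourceClusteringAudit(Xn, batch = src, seed = 2L)
  null <- replicate(200, {
    perm <- sample(src)
    km <- kmeans(Xn, 4, nstart = 5)
    scentpipe:::matchedAccuracy(km$cluster, perm)
  })
  expect_lte(acc, quantile(null, 0.975) + 0.05)

  expect_error(sourceClusteringAudit(Xn, k = 100L, batch = src), "exceeds")
  ## exact matching oracle on a tiny labelled case
  expect_equal(scentpipe:::matchedAccuracy(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(scentpipe:::matchedAccuracy(c(1, 2, 1, 2), c(1, 1, 2, 2)), 0.5)
})

test_that("PCA audit: degenerate input reports 0; separation drops after EB", {
  X <- matrix(3, 9, 5)
  pa <- pcaAudit(X, batch = rep(c("A", "B", "C"), 3))
  expect_equal(pa$separation, 0)

  ## two well-separated clouds -> ratio > 1
  set.seed(12)
  X2 <- rbind(matrix(rnorm(50, 0), 10), matrix(rnorm(50, 8), 10))
  pa2 <- pcaAudit(X2, batch = rep(c("A", "B"), each = 10))
  expect_gt(pa2$separation, 1)

  ## paired pre/post comparison on biased synthetic features
  sim <- simFeatureMatrix(13L, nf = 150L, nb = 3L, ns = 12L,
                          gam.mu = 3, gam.sd = 1)
  m <- fitEB(sim$X, sim$batch)
  adj <- applyEB(sim$X, m, batch = sim$batch)
  expect_lt(pcaAudit(adj, batch = sim$batch)$separation,
            pcaAudit(sim$X, batch = sim$batch)$separation)
})
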