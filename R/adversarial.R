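## Domain-adversarial classifier.
##
## A small convolutional backbone compresses each image into a latent
## feature vector; a disease head classifies the risk group and a source
## head classifies the batch site. The source branch is connected to the
## backbone through a gradient-reversal layer: identity in the forward
## pass, gradient negated and scaled by lambda in the backward pass. The
## source head itself descends its own cross-entropy L_q while the backbone
## receives -lambda * dL_q, so the tug-of-war total objective seen by the
## backbone is L_total = L_0 - lambda * L_q.
##
## The network is implemented directly with im2col convolutions in base R:
## analytic gradients (including the reversal sign) are validated against a
## finite-difference oracle in the test suite.

#' The adversarial total loss
#'
#' `L_total = L_0 - lambda * L_q`: the disease loss minus the
#' lambda-weighted source loss, the quantity the backbone descends.
#'
#' @param l0 disease classification loss (finite).
#' @param lq source classification loss (finite).
#' @param lambda reversal strength in `[0, 1]`.
#' @return `l0 - lambda * lq`.
#' @export
totalLoss <- function(l0, lq, lambda) {
  if (!is.finite(l0) || !is.finite(lq)) stop("losses must be finite")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  l0 - lambda * lq
}

#' Adversarial training configuration
#'
#' @param lambda gradient-reversal strength in `[0, 1]` (default 0.5).
#' @param backbone `"small_cnn"` (default; a 4-conv-block network sized for
#'   desk-scale training) or `"resnet18"` (not bundled: requires an
#'   external deep-learning runtime and pretrained weights, so selecting it
#'   raises an informative error).
#' @param epochs training epochs (default 12).
#' @param batch_size minibatch size (default 32).
#' @param lr Adam learning rate (default 0.003).
#' @param momentum retained for API stability; the Adam moment decay is
#'   fixed at (0.9, 0.999).
#' @param seed integer; fixes initialization and batch order.
#' @param channels conv-block output channels (default `c(8, 12, 16, 16)`).
#' @param stem_pool input average-pooling factor before the conv blocks
#'   (default 8: 256 -> 32 pixels).
#' @param lambda_schedule `"warmup"` (default: reversal off for the first
#'   third of training, ramped over the middle third, full strength after
#'   — lets the disease task establish itself before the tug-of-war),
#'   `"constant"`, or `"ramp"` (linear 0 -> lambda).
#' @param feature_mode latent embedding from the last feature map:
#'   `"flatten"` (default; positions x channels) or `"gap"` (global average
#'   pool, channels only).
#' @param source_steps extra source-head-only updates per minibatch
#'   (default 5). Keeping the source adversary near-optimal is what makes
#'   the reversed gradient remove source information rather than merely
#'   fool a stale head.
#' @param disease_steps extra disease-head-only updates per minibatch
#'   (default 5); keeps the disease head near-optimal on the evolving
#'   features, which shortens training substantially.
#' @param normalize latent-feature normalization before the heads:
#'   `"center"` (default: per-feature mean subtraction plus one global RMS
#'   scalar — conditions the heads without re-amplifying directions the
#'   reversed gradient suppresses), `"sphere"` (per-sample unit norm),
#'   `"batch"` (classical batch normalization), `"static"` (affine frozen
#'   from the initial forward pass) or `"none"`.
#' @param adv_cap cap the source branch's feature gradient at the task
#'   gradient's norm before the reversal scaling (default TRUE), so lambda
#'   acts as a relative strength and the tug-of-war stays bounded. The
#'   uncapped pure-reversal contract is what the gradient oracle tests
#'   validate.
#' @param class_weights inverse-frequency class weights in the disease
#'   loss (default FALSE).
#' @return an `AdvConfig` list.
#' @export
advConfig <- function(lambda = 0.5, backbone = c("small_cnn", "resnet18"),
                      epochs = 30L, batch_size = 32L, lr = 0.003,
                      momentum = 0.9, seed = 1L,
                      channels = c(8L, 12L, 16L, 16L), stem_pool = 8L,
                      lambda_schedule = c("warmup", "constant", "ramp"),
                      feature_mode = c("flatten", "gap"),
                      source_steps = 5L,
                      disease_steps = 5L,
                      normalize = c("center", "sphere", "batch", "static",
                                    "none"),
                      adv_cap = TRUE,
                      class_weights = FALSE) {
  backbone <- match.arg(backbone)
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  cfg <- list(lambda = lambda, backbone = backbone, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size), lr = lr,
              momentum = momentum, seed = as.integer(seed),
              channels = as.integer(channels),
              stem_pool = as.integer(stem_pool),
              lambda_schedule = match.arg(lambda_schedule),
              feature_mode = match.arg(feature_mode),
              source_steps = as.integer(source_steps),
              disease_steps = as.integer(disease_steps),
              normalize = match.arg(normalize),
              adv_cap = isTRUE(adv_cap),
              class_weights = isTRUE(class_weights))
  class(cfg) <- "AdvConfig"
  cfg
}

## ---- low-level network machinery ----------------------------------------

## neighbor gather indices for a 3x3 same-padded convolution on an H x W
## grid replicated across n images; 0 marks padding (maps to a zero row)
convContext <- function(H, W, n) {
  HW <- H * W
  ys <- rep(seq_len(H), W); xs <- rep(seq_len(W), each = H)
  idx <- list()
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    yy <- ys + dy; xx <- xs + dx
    ok <- yy >= 1L & yy <= H & xx >= 1L & xx <= W
    one <- ifelse(ok, (xx - 1L) * H + yy, 0L)
    g <- rep(one, n) + rep((seq_len(n) - 1L) * HW, each = HW)
    g[rep(one, n) == 0L] <- 0L
    idx[[k]] <- g
  }
  ## 2x2 average-pool groups
  H2 <- H %/% 2L; W2 <- W %/% 2L
  p2 <- (ceiling(xs / 2) - 1L) * H2 + ceiling(ys / 2)
  grp <- rep(p2, n) + rep((seq_len(n) - 1L) * (H2 * W2), each = HW)
  list(idx = idx, pool = grp, H = H, W = W, n = n)
}

im2col <- function(X, ctx) {
  X0 <- rbind(0, X)
  do.call(cbind, lapply(ctx$idx, function(g) X0[g + 1L, , drop = FALSE]))
}

col2im <- function(dXcol, ctx, Cin, nrowX) {
  dX0 <- matrix(0, nrowX + 1L, Cin)
  for (k in seq_along(ctx$idx)) {
    blk <- dXcol[, ((k - 1L) * Cin + 1L):(k * Cin), drop = FALSE]
    g <- ctx$idx[[k]] + 1L
    keep <- g > 1L
    dX0[g[keep], ] <- dX0[g[keep], ] + blk[keep, , drop = FALSE]
  }
  dX0[-1L, , drop = FALSE]
}

softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

## mean cross-entropy and softmax gradient; y: integer class index per row
ceLoss <- function(P, y, w = NULL) {
  n <- nrow(P)
  if (is.null(w)) w <- rep(1, max(y))
  wi <- w[y]
  p <- pmax(P[cbind(seq_len(n), y)], 1e-12)
  loss <- sum(-wi * log(p)) / sum(wi)
  G <- P
  G[cbind(seq_len(n), y)] <- G[cbind(seq_len(n), y)] - 1
  G <- G * (wi / sum(wi))
  list(loss = loss, grad = G)
}

initParams <- function(cfg, n.classes, n.sources, stem.size) {
  ch <- c(3L, cfg$channels)
  conv <- list()
  for (l in seq_along(cfg$channels)) {
    fan <- 9L * ch[l]
    conv[[l]] <- list(
      W = matrix(stats::rnorm(fan * ch[l + 1L], 0, sqrt(2 / fan)),
                 fan, ch[l + 1L]),
      b = rep(0, ch[l + 1L]))
  }
  L <- length(cfg$channels)
  hwL <- (stem.size %/% 2L^L)^2
  if (hwL < 1L) stop("too many conv blocks for the stem size")
  fdim <- if ((cfg$feature_mode %||% "flatten") == "flatten")
    hwL * cfg$channels[L] else cfg$channels[L]
  list(conv = conv,
       bn = list(gamma = rep(1, fdim), beta = rep(0, fdim),
                 rmu = rep(0, fdim), rvar = rep(1, fdim),
                 enabled = (cfg$normalize %||% "center") %in%
                   c("batch", "static")),
       head_d = list(W = matrix(stats::rnorm(fdim * n.classes, 0,
                                             sqrt(1 / fdim)),
                                fdim, n.classes),
                     b = rep(0, n.classes)),
       head_s = list(W = matrix(stats::rnorm(fdim * n.sources, 0,
                                             sqrt(1 / fdim)),
                                fdim, n.sources),
                     b = rep(0, n.sources)),
       fdim = fdim, stem.size = stem.size)
}

## forward through the conv backbone; X: (n*HW) x 3 stacked stem outputs.
## Returns latent features (n x fdim) and, if keep = TRUE, the per-layer
## caches needed for the backward pass.
backboneForward <- function(params, X, n, stem.size, ctxs = NULL,
                            keep = FALSE, fmode = "flatten") {
  L <- length(params$conv)
  H <- stem.size
  if (is.null(ctxs)) {
    ctxs <- list()
    h <- H
    for (l in seq_len(L)) { ctxs[[l]] <- convContext(h, h, n); h <- h %/% 2L }
  }
  cache <- list()
  A <- X
  for (l in seq_len(L)) {
    ctx <- ctxs[[l]]
    Xcol <- im2col(A, ctx)
    Z <- Xcol %*% params$conv[[l]]$W
    Z <- sweep(Z, 2L, params$conv[[l]]$b, "+")
    R <- pmax(Z, 0)
    P <- rowsum(R, ctx$pool) / 4
    if (keep) cache[[l]] <- list(Xcol = Xcol, mask = Z > 0, ctx = ctx,
                                 nrowA = nrow(A))
    A <- P
  }
  ## embed the last feature map: rows of A are (image, position)
  hw <- nrow(A) / n
  Cl <- ncol(A)
  F <- if (fmode == "flatten")
    matrix(aperm(array(A, c(hw, n, Cl)), c(2L, 1L, 3L)), n, hw * Cl)
  else rowsum(A, rep(seq_len(n), each = hw)) / hw
  list(features = F, cache = cache, hw = hw, Cl = Cl, ctxs = ctxs,
       fmode = fmode)
}

backboneBackward <- function(params, fwd, dF, n) {
  dA <- if (fwd$fmode == "flatten")
    matrix(aperm(array(dF, c(n, fwd$hw, fwd$Cl)), c(2L, 1L, 3L)),
           n * fwd$hw, fwd$Cl)
  else dF[rep(seq_len(n), each = fwd$hw), , drop = FALSE] / fwd$hw
  L <- length(params$conv)
  grads <- vector("list", L)
  for (l in L:1) {
    cc <- fwd$cache[[l]]
    dR <- dA[cc$ctx$pool, , drop = FALSE] / 4
    dZ <- dR * cc$mask
    grads[[l]] <- list(W = crossprod(cc$Xcol, dZ), b = colSums(dZ))
    if (l > 1L) {
      dXcol <- dZ %*% t(params$conv[[l]]$W)
      Cin <- ncol(params$conv[[l - 1L]]$W)
      dA <- col2im(dXcol, cc$ctx, Cin, cc$nrowA)
    }
  }
  grads
}

## feature normalization before the heads.
##
## "sphere" (default): each sample's embedding is projected to the unit
## sphere, y = f / ||f||. A fixed, data-independent map: it conditions the
## optimization like a normalization layer but has no batch statistics, so
## directions the reversed gradient suppresses stay suppressed in the
## space the heads, the residual-bias probe and inference all share.
## "batch": classical batch normalization (batch statistics while
## training, recalibrated running statistics at inference).
sphereForward <- function(F, eps = 1e-8) {
  nr <- sqrt(rowSums(F^2))
  nr <- pmax(nr, eps)
  list(Y = F / nr, nr = nr)
}

sphereBackward <- function(dY, fwd) {
  (dY - fwd$Y * rowSums(fwd$Y * dY)) / fwd$nr
}

## "center" normalization: per-feature mean subtraction plus ONE global
## RMS scalar, y = (f - mu) / s with s = sqrt(mean((f - mu)^2)). Centering
## conditions the heads like batch normalization, but because the rescaling
## is a single scalar the map preserves the relative geometry of feature
## directions: what the reversed gradient shrinks stays shrunk for the
## heads, the probe and inference (per-feature variance division would
## re-amplify it). Batch statistics while training; running statistics,
## recalibrated after training, at inference.
centerForward <- function(F, bn, training = TRUE, eps = 1e-8) {
  if (training && nrow(F) > 1L) {
    mu <- colMeans(F)
    C <- sweep(F, 2L, mu, "-")
    s <- sqrt(mean(C^2) + eps)
  } else {
    mu <- bn$rmu
    C <- sweep(F, 2L, mu, "-")
    s <- sqrt(bn$rvar[1L] + eps)   # rvar[1] stores the global mean square
  }
  list(Y = C / s, s = s, mu = mu, msq = mean(C^2))
}

centerBackward <- function(dY, fwd) {
  t.mean <- mean(dY * fwd$Y)
  dC <- (dY - fwd$Y * t.mean) / fwd$s
  sweep(dC, 2L, colMeans(dC), "-")
}

BN_EPS <- 1e-5

bnForward <- function(F, bn, training = TRUE) {
  if (!isTRUE(bn$enabled))
    return(list(Y = F, xhat = F, s = rep(1, ncol(F)),
                mu = rep(0, ncol(F)), v = rep(1, ncol(F))))
  if (isTRUE(bn$frozen)) training <- FALSE
  if (training && nrow(F) > 1L) {
    mu <- colMeans(F)
    xc <- sweep(F, 2L, mu, "-")
    v <- colMeans(xc^2)
  } else {
    mu <- bn$rmu; v <- bn$rvar
    xc <- sweep(F, 2L, mu, "-")
  }
  s <- sqrt(v + BN_EPS)
  xhat <- sweep(xc, 2L, s, "/")
  Y <- sweep(sweep(xhat, 2L, bn$gamma, "*"), 2L, bn$beta, "+")
  list(Y = Y, xhat = xhat, s = s, mu = mu, v = v)
}

bnBackward <- function(dY, fwd, bn) {
  if (!isTRUE(bn$enabled))
    return(list(dF = dY, dgamma = bn$gamma * 0, dbeta = bn$beta * 0))
  dgamma <- colSums(dY * fwd$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, bn$gamma, "*")
  if (isTRUE(bn$frozen)) {
    ## frozen statistics: BN is a fixed affine map
    dF <- sweep(dxhat, 2L, fwd$s, "/")
  } else {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * fwd$xhat)
    dF <- sweep(sweep(dxhat, 2L, m1, "-") -
                  sweep(fwd$xhat, 2L, m2, "*"), 2L, fwd$s, "/")
  }
  list(dF = dF, dgamma = dgamma, dbeta = dbeta)
}

## full forward + backward for one minibatch.
## Returns losses and gradients for every parameter; the backbone gradient
## is dL0/dtheta - lambda * dLq/dtheta (reversal applied), while the source
## head's own gradient is +dLq/dtheta_s.
## Both heads read the normalized latent embedding; the source branch's
## gradient is negated and scaled by lambda before entering the backbone.
advBatchGrad <- function(params, X, y.d, y.s, lambda, n, stem.size,
                         ctxs = NULL, class.w = NULL, fmode = "flatten",
                         norm = "sphere", adv.cap = FALSE) {
  fwd <- backboneForward(params, X, n, stem.size, ctxs, keep = TRUE,
                         fmode = fmode)
  Fr <- fwd$features
  if (norm == "sphere") {
    nf <- sphereForward(Fr)
    F <- nf$Y
  } else if (norm == "center") {
    nf <- centerForward(Fr, params$bn, training = TRUE)
    F <- nf$Y
  } else if (norm %in% c("batch", "static")) {
    nf <- bnForward(Fr, params$bn, training = (norm == "batch"))
    F <- nf$Y
  } else {
    nf <- NULL
    F <- Fr
  }
  Zd <- sweep(F %*% params$head_d$W, 2L, params$head_d$b, "+")
  Zs <- sweep(F %*% params$head_s$W, 2L, params$head_s$b, "+")
  Pd <- softmaxRows(Zd); Ps <- softmaxRows(Zs)
  ce.d <- ceLoss(Pd, y.d, class.w)
  ce.s <- ceLoss(Ps, y.s)
  g.head_d <- list(W = crossprod(F, ce.d$grad), b = colSums(ce.d$grad))
  g.head_s <- list(W = crossprod(F, ce.s$grad), b = colSums(ce.s$grad))
  dF.d <- ce.d$grad %*% t(params$head_d$W)
  dF.s <- ce.s$grad %*% t(params$head_s$W)
  ## norm-matched reversal (training default): the source branch's feature
  ## gradient is capped at the task gradient's norm before the -lambda
  ## scaling, so lambda keeps its [0, 1] meaning as the relative strength
  ## of the tug-of-war and the adversarial push cannot run away from the
  ## task signal. Disabled for the pure-reversal gradient contract.
  if (adv.cap) {
    nd <- sqrt(sum(dF.d^2)); ns <- sqrt(sum(dF.s^2))
    if (is.finite(ns) && ns > nd && ns > 0) dF.s <- dF.s * (nd / ns)
  }
  dY <- dF.d - lambda * dF.s            # gradient reversal on source branch
  g.bn <- list(gamma = params$bn$gamma * 0, beta = params$bn$beta * 0)
  if (norm == "sphere") {
    dFr <- sphereBackward(dY, nf)
  } else if (norm == "center") {
    dFr <- centerBackward(dY, nf)
  } else if (norm %in% c("batch", "static")) {
    bnb <- bnBackward(dY, nf, params$bn)
    dFr <- bnb$dF
    g.bn <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
  } else {
    dFr <- dY
  }
  g.conv <- backboneBackward(params, fwd, dFr, n)
  list(l0 = ce.d$loss, lq = ce.s$loss,
       grads = list(conv = g.conv, head_d = g.head_d, head_s = g.head_s,
                    bn = g.bn),
       batch.stats = if (norm == "batch")
         list(mu = nf$mu, v = nf$v)
       else if (norm == "center")
         list(mu = nf$mu, v = rep(nf$msq, length(nf$mu))) else NULL,
       F = F, Fd = F,
       ctxs = fwd$ctxs)
}

## extra source-head-only Adam step on fixed (already normalized) features;
## keeps the adversary near-optimal against the current backbone
## extra head-only Adam step on fixed features (cheap: one small matmul);
## keeps each linear head near-optimal for the current backbone. For the
## source head this is what makes the reversed gradient remove source
## information rather than merely fool a stale adversary.
headOnlyStep <- function(params, state, F, y, head, lr, decay = 1e-4,
                         class.w = NULL) {
  Z <- sweep(F %*% params[[head]]$W, 2L, params[[head]]$b, "+")
  ce <- ceLoss(softmaxRows(Z), y, class.w)
  g <- list(W = crossprod(F, ce$grad) + decay * params[[head]]$W,
            b = colSums(ce$grad))
  st <- state[[head]]
  bc1 <- 1 - 0.9^(state$t + 1L)   # reuse the shared step counter loosely
  bc2 <- 1 - 0.999^(state$t + 1L)
  for (s in c("W", "b")) {
    st[[s]]$m <- 0.9 * st[[s]]$m + 0.1 * g[[s]]
    st[[s]]$v <- 0.999 * st[[s]]$v + 0.001 * g[[s]]^2
    params[[head]][[s]] <- params[[head]][[s]] -
      lr * (st[[s]]$m / bc1) / (sqrt(st[[s]]$v / bc2) + 1e-8)
  }
  state[[head]] <- st
  list(params = params, state = state)
}

## Mixed optimizer step: the heads and feature normalization use Adam (fast
## convergence of the classifiers); the convolutional backbone uses
## SGD + momentum, so the -lambda scaling of the reversed source gradient
## keeps its meaning (Adam's per-parameter normalization would rescale it
## away).
adamStep <- function(params, grads, state, lr, bb.lr = NULL,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                     momentum = 0.9, clip = 5, decay = 1e-4) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  ## gradient-norm clipping keeps the adversarial tug-of-war bounded; the
  ## source head is clipped separately so that at lambda = 0 it cannot
  ## influence the backbone's update scale
  gn <- sqrt(sum(unlist(lapply(grads$conv, function(l)
    sum(l$W^2) + sum(l$b^2)))) +
    sum(grads$head_d$W^2) + sum(grads$head_d$b^2) +
    sum(grads$bn$gamma^2) + sum(grads$bn$beta^2))
  cs.main <- if (is.finite(gn) && gn > clip) clip / gn else 1
  gs <- sqrt(sum(grads$head_s$W^2) + sum(grads$head_s$b^2))
  cs.src <- if (is.finite(gs) && gs > clip) clip / gs else 1
  cs <- cs.main
  upd <- function(p, g, mv, wd = 0) {
    g <- cs * g + wd * p
    mv$m <- beta1 * mv$m + (1 - beta1) * g
    mv$v <- beta2 * mv$v + (1 - beta2) * g^2
    p <- p - lr * (mv$m / bc1) / (sqrt(mv$v / bc2) + eps)
    list(p = p, mv = mv)
  }
  for (l in seq_along(params$conv)) for (s in c("W", "b")) {
    if (is.null(bb.lr)) {
      u <- upd(params$conv[[l]][[s]], grads$conv[[l]][[s]],
               state$conv[[l]][[s]], wd = if (s == "W") decay else 0)
      params$conv[[l]][[s]] <- u$p; state$conv[[l]][[s]] <- u$mv
    } else {
      mv <- state$conv[[l]][[s]]
      mv$m <- momentum * mv$m - bb.lr * grads$conv[[l]][[s]]
      params$conv[[l]][[s]] <- params$conv[[l]][[s]] + mv$m
      state$conv[[l]][[s]] <- mv
    }
  }
  for (h in c("head_d", "head_s")) for (s in c("W", "b")) {
    cs <- if (h == "head_s") cs.src else cs.main
    u <- upd(params[[h]][[s]], grads[[h]][[s]], state[[h]][[s]],
             wd = if (s == "W") decay else 0)
    params[[h]][[s]] <- u$p; state[[h]][[s]] <- u$mv
  }
  cs <- cs.main
  for (s in c("gamma", "beta")) {
    u <- upd(params$bn[[s]], grads$bn[[s]], state$bn[[s]])
    params$bn[[s]] <- u$p; state$bn[[s]] <- u$mv
  }
  list(params = params, state = state)
}

zeroLike <- function(params) {
  mv <- function(p) list(m = p * 0, v = p * 0)
  st <- list(conv = lapply(params$conv, function(l)
               list(W = mv(l$W), b = mv(l$b))),
             bn = list(gamma = mv(params$bn$gamma),
                       beta = mv(params$bn$beta)),
             head_d = list(W = mv(params$head_d$W), b = mv(params$head_d$b)),
             head_s = list(W = mv(params$head_s$W), b = mv(params$head_s$b)))
  st$t <- 0L
  st
}

## stem: average-pool a 256 x 256 x 3 image by cfg$stem_pool and return a
## (H*W) x 3 matrix in [0, 1]
stemTransform <- function(img, stem_pool) {
  px <- if (is(img, "ScentImage")) img@pixels else img
  H <- dim(px)[1L] %/% stem_pool
  P <- resampleMatrix(dim(px)[1L], H)
  out <- matrix(0, H * H, 3L)
  for (ch in 1:3)
    out[, ch] <- as.numeric(P %*% (px[, , ch] / 255) %*% t(P))
  out
}

#' Train the domain-adversarial classifier
#'
#' Minibatch training of the tug-of-war objective: the disease head
#' and backbone descend the disease cross-entropy `L0`; the source head
#' descends its own cross-entropy `Lq`; the backbone additionally receives
#' the source branch's gradient negated and scaled by `lambda` (gradient
#' reversal), so the backbone's effective objective is
#' `L_total = L0 - lambda * Lq`. Deterministic given `cfg$seed`.
#'
#' @param images list of [ScentImage-class] (or 256 x 256 x 3 arrays).
#' @param meta data.frame with per-image `risk` and `source` columns
#'   (same order as `images`).
#' @param cfg an [advConfig()].
#' @return a [TrainedModel-class]; its history logs per-epoch `l0`, `lq`,
#'   `lambda` and `ltotal = l0 - lambda * lq`.
#' @export
trainAdversarial <- function(images, meta, cfg = advConfig()) {
  stopifnot(inherits(cfg, "AdvConfig"))
  if (cfg$backbone == "resnet18")
    stop("the resnet18 backbone requires an external deep-learning ",
         "runtime with pretrained weights; use backbone = 'small_cnn'")
  classes <- riskLevels()[riskLevels() %in% unique(as.character(meta$risk))]
  sources <- sort(unique(as.character(meta$source)))
  if (length(classes) < 2L) stop("need at least 2 disease classes")
  if (length(sources) < 2L && cfg$lambda > 0)
    stop("configuration error: single-source dataset with lambda > 0")
  y.d <- match(as.character(meta$risk), classes)
  y.s <- match(as.character(meta$source), sources)
  n <- length(images)
  stopifnot(nrow(meta) == n)

  stem.size <- 256L %/% cfg$stem_pool
  mats <- lapply(images, stemTransform, stem_pool = cfg$stem_pool)

  class.w <- if (cfg$class_weights) {
    tw <- table(factor(y.d, levels = seq_along(classes)))
    as.numeric(length(y.d) / (length(classes) * pmax(tw, 1)))
  } else NULL

  old <- rngSnapshot(); on.exit(rngRestore(old))
  set.seed(cfg$seed)
  params <- initParams(cfg, length(classes), length(sources), stem.size)
  state <- zeroLike(params)
  ctx.cache <- list()
  history <- data.frame()
  ## one full-data pass with the current weights to set the normalization
  ## statistics exactly
  recalibrate <- function(params) {
    Fall <- matrix(0, n, params$fdim)
    ctxs <- NULL
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      sel <- b0:min(b0 + cfg$batch_size - 1L, n)
      X <- do.call(rbind, mats[sel])
      fwd <- backboneForward(params, X, length(sel), stem.size,
                             if (length(sel) == cfg$batch_size) ctxs
                             else NULL,
                             fmode = cfg$feature_mode)
      if (length(sel) == cfg$batch_size) ctxs <- fwd$ctxs
      Fall[sel, ] <- fwd$features
    }
    params$bn$rmu <- colMeans(Fall)
    if (cfg$normalize == "center") {
      C <- sweep(Fall, 2L, params$bn$rmu, "-")
      params$bn$rvar <- rep(mean(C^2), ncol(Fall))
    } else {
      v <- apply(Fall, 2L, stats::var) * (n - 1) / n
      ## variance floor relative to the liveliest feature: keeps the fixed
      ## 1/sd map from amplifying near-dead features' gradients
      params$bn$rvar <- pmax(v, 0.01 * max(v), 1e-8)
    }
    params
  }
  ## static normalization: per-feature affine fixed from the initial
  ## forward pass (conditions the optimization like batch normalization at
  ## the start, but stays a fixed map, so adversarially suppressed
  ## directions are not re-amplified for the heads or the probe)
  if (cfg$normalize == "static") {
    params <- recalibrate(params)
    params$bn$frozen <- TRUE
  }
  for (ep in seq_len(cfg$epochs)) {
    lam <- switch(cfg$lambda_schedule,
      constant = cfg$lambda,
      ramp = cfg$lambda * ep / cfg$epochs,
      ## warmup: task-only for the first third, linear ramp over the middle
      ## third, full strength for the last third
      warmup = cfg$lambda * min(1, max(0, (3 * ep / cfg$epochs) - 1)))
    perm <- sample.int(n)
    bs <- cfg$batch_size
    sum0 <- 0; sumq <- 0; wsum <- 0
    for (b0 in seq(1L, n, by = bs)) {
      sel <- perm[b0:min(b0 + bs - 1L, n)]
      nb <- length(sel)
      X <- do.call(rbind, mats[sel])
      key <- as.character(nb)
      res <- advBatchGrad(params, X, y.d[sel], y.s[sel], lam, nb,
                          stem.size, ctx.cache[[key]], class.w,
                          fmode = cfg$feature_mode,
                          norm = cfg$normalize,
                          adv.cap = isTRUE(cfg$adv_cap %||% TRUE))
      ctx.cache[[key]] <- res$ctxs
      ## once the reversal is active the learning rate is dropped: the
      ## representation is formed during warmup and the adversarial phase
      ## fine-tunes rather than re-learns (large steps there destabilize
      ## the tug-of-war)
      lr.ep <- if (lam > 0) cfg$lr * 0.3 else cfg$lr
      st <- adamStep(params, res$grads, state, lr.ep)
      params <- st$params; state <- st$state
      for (k in seq_len(cfg$source_steps)) {
        st <- headOnlyStep(params, state, res$F, y.s[sel], "head_s", cfg$lr)
        params <- st$params; state <- st$state
      }
      for (k in seq_len(cfg$disease_steps)) {
        st <- headOnlyStep(params, state, res$Fd, y.d[sel], "head_d",
                           cfg$lr, class.w = class.w)
        params <- st$params; state <- st$state
      }
      if (!is.null(res$batch.stats)) {
        params$bn$rmu <- 0.9 * params$bn$rmu + 0.1 * res$batch.stats$mu
        params$bn$rvar <- 0.9 * params$bn$rvar + 0.1 * res$batch.stats$v
      }
      sum0 <- sum0 + res$l0 * nb; sumq <- sumq + res$lq * nb
      wsum <- wsum + nb
    }
    l0 <- sum0 / wsum; lq <- sumq / wsum
    history <- rbind(history,
                     data.frame(epoch = ep, l0 = l0, lq = lq, lambda = lam,
                                ltotal = totalLoss(l0, lq, lam)))
  }
  if (cfg$normalize %in% c("batch", "center"))
    params <- recalibrate(params)
  new("TrainedModel", params = params, history = history,
      config = unclass(cfg), classes = classes, sources = sources)
}

#' Latent features from a trained backbone
#'
#' @param m a [TrainedModel-class].
#' @param images list of [ScentImage-class] or 256 x 256 x 3 arrays.
#' @return n x fdim numeric matrix of backbone embeddings.
#' @export
latentFeatures <- function(m, images) {
  stopifnot(is(m, "TrainedModel"))
  cfg <- m@config
  mats <- lapply(images, stemTransform, stem_pool = cfg$stem_pool)
  stem.size <- 256L %/% cfg$stem_pool
  ## forward in chunks to bound memory
  n <- length(mats)
  out <- matrix(0, n, m@params$fdim)
  ctxs <- NULL
  bs <- cfg$batch_size
  for (b0 in seq(1L, n, by = bs)) {
    sel <- b0:min(b0 + bs - 1L, n)
    X <- do.call(rbind, mats[sel])
    fwd <- backboneForward(m@params, X, length(sel), stem.size,
                           if (length(sel) == bs) ctxs else NULL,
                           fmode = cfg$feature_mode %||% "flatten")
    if (length(sel) == bs) ctxs <- fwd$ctxs
    out[sel, ] <- fwd$features
  }
  switch(cfg$normalize %||% "center",
         sphere = sphereForward(out)$Y,
         center = centerForward(out, m@params$bn, training = FALSE)$Y,
         batch = ,
         static = bnForward(out, m@params$bn, training = FALSE)$Y,
         out)
}

#' Predict risk-class probabilities
#'
#' @param m a [TrainedModel-class].
#' @param images list of images with the training dimensions.
#' @return n x 3 matrix of class probabilities (rows sum to 1), with the
#'   model's class labels as column names.
#' @export
predictRisk <- function(m, images) {
  F <- latentFeatures(m, images)
  Z <- sweep(F %*% m@params$head_d$W, 2L, m@params$head_d$b, "+")
  P <- softmaxRows(Z)
  colnames(P) <- m@classes
  P
}

#' Residual source-bias probe on frozen features
#'
#' Freezes the backbone, extracts the latent embeddings, and trains a fresh
#' source classifier — a softmax head of the same form as the in-training
#' source branch, from zero initialization, full-batch Adam for
#' `probe.epochs` epochs — on a stratified training split. Its held-out
#' source accuracy is the package's quantitative measure of how much source
#' information survives debiasing (the analogue of re-training a network
#' for extra epochs to hunt for the source site).
#'
#' @param m a [TrainedModel-class].
#' @param images image list.
#' @param sources per-image source labels.
#' @param probe.epochs training epochs for the probe head (default 200).
#' @param lr probe Adam learning rate (default 0.01).
#' @param train.frac stratified training fraction (default 0.7).
#' @param seed split RNG seed (default 1).
#' @return list with `accuracy` (held-out), `n_test`, and `chance` (the
#'   held-out majority-class share).
#' @export
residualBiasProbe <- function(m, images, sources, probe.epochs = 200L,
                              lr = 0.01, train.frac = 0.7, seed = 1L) {
  F <- if (is.matrix(images)) images else latentFeatures(m, images)
  src <- as.factor(as.character(sources))
  old <- rngSnapshot(); on.exit(rngRestore(old))
  set.seed(seed)
  tr <- unlist(lapply(split(seq_along(src), src), function(i)
    sample(i, max(1L, round(train.frac * length(i))))))
  te <- setdiff(seq_along(src), tr)
  K <- nlevels(src)
  ## one global scale factor so the probe's learning rate is meaningful on
  ## any feature magnitude; relative geometry (including adversarially
  ## shrunken directions) is preserved
  scl <- mean(sqrt(rowSums(F^2)))
  if (scl > 0) F <- F / scl
  X <- F[tr, , drop = FALSE]
  y <- as.integer(src[tr])
  W <- matrix(0, ncol(X), K); b <- rep(0, K)
  mW <- W; vW <- W; mb <- b; vb <- b
  for (t in seq_len(probe.epochs)) {
    Z <- sweep(X %*% W, 2L, b, "+")
    ce <- ceLoss(softmaxRows(Z), y)
    gW <- crossprod(X, ce$grad); gb <- colSums(ce$grad)
    mW <- 0.9 * mW + 0.1 * gW; vW <- 0.999 * vW + 0.001 * gW^2
    W <- W - lr * (mW / (1 - 0.9^t)) / (sqrt(vW / (1 - 0.999^t)) + 1e-8)
    mb <- 0.9 * mb + 0.1 * gb; vb <- 0.999 * vb + 0.001 * gb^2
    b <- b - lr * (mb / (1 - 0.9^t)) / (sqrt(vb / (1 - 0.999^t)) + 1e-8)
  }
  Zte <- sweep(F[te, , drop = FALSE] %*% W, 2L, b, "+")
  acc <- mean(levels(src)[max.col(Zte, ties.method = "first")] ==
                as.character(src[te]))
  list(accuracy = acc, n_test = length(te),
       chance = max(table(src[te])) / length(te))
}
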