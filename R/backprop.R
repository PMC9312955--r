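# Batched forward pass and exact backpropagation for the multi-channel
# vision transformer. Token sequences of a minibatch are stacked row-wise
# into (B*L) x D matrices so layer norms, projections and MLPs are single
# matrix products; the L x L attention is computed per sample and head.
# Gradients are derived analytically and verified against finite differences
# in the test suite.

lnForward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  invstd <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * invstd
  list(y = sweep(xhat, 2L, g, `*`) + rep(b, each = nrow(x)),
       xhat = xhat, invstd = invstd)
}

lnBackward <- function(dy, cache, g) {
  dxhat <- sweep(dy, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  list(dx = cache$invstd * (dxhat - m1 - cache$xhat * m2),
       dg = colSums(dy * cache$xhat), db = colSums(dy))
}

dropoutMask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((runif(nr * nc) >= p) / (1 - p), nr, nc)
}

applyMask <- function(x, mask) if (is.null(mask)) x else x * mask

# Forward pass over a batch.
# x: (B, N, H, W) array. Returns probs (B x nClasses) and, if keepCache,
# everything backpropagation needs. Dropout masks are drawn from the current
# RNG state only when train = TRUE and cfg@dropout > 0.
mvitForwardBatch <- function(x, params, cfg, train = FALSE, keepCache = FALSE) {
  B <- dim(x)[1]
  L <- nTokens(cfg)
  D <- cfg@embedDim
  p <- if (train) cfg@dropout else 0
  idx <- patchIndex(cfg@imageShape[1], cfg@imageShape[2],
                    cfg@patchShape[1], cfg@patchShape[2])
  grp <- rep(seq_len(B), each = L)
  posRep <- rep(seq_len(L), B)
  dh <- D %/% cfg@nHeads
  Fcat <- matrix(0, B, cfg@nBranches * D)
  caches <- if (keepCache) vector("list", cfg@nBranches) else NULL

  for (b in seq_len(cfg@nBranches)) {
    bi <- if (cfg@shareBranchWeights) 1L else b
    br <- params$branches[[bi]]
    Xp <- matrix(0, B * L, prod(cfg@patchShape))
    for (i in seq_len(B)) {
      m <- x[i, b, , ][idx]
      Xp[((i - 1L) * L + 1L):(i * L), ] <- m
    }
    Tok <- addRowVec(Xp %*% br$Wp, br$bp) + br$pos[posRep, , drop = FALSE]
    maskEmb <- dropoutMask(nrow(Tok), D, p)
    Tok <- applyMask(Tok, maskEmb)
    layerCaches <- if (keepCache) vector("list", cfg@depth) else NULL

    for (l in seq_len(cfg@depth)) {
      lp <- br$layers[[l]]
      Tin <- Tok
      c1 <- lnForward(Tin, lp$ln1g, lp$ln1b)
      Q <- addRowVec(c1$y %*% lp$Wq, lp$bq)
      K <- addRowVec(c1$y %*% lp$Wk, lp$bk)
      V <- addRowVec(c1$y %*% lp$Wv, lp$bv)
      O <- matrix(0, B * L, D)
      attn <- if (keepCache) array(0, c(L, L, cfg@nHeads, B)) else NULL
      for (i in seq_len(B)) {
        ri <- ((i - 1L) * L + 1L):(i * L)
        for (h in seq_len(cfg@nHeads)) {
          ch <- ((h - 1L) * dh + 1L):(h * dh)
          A <- softmaxRows(tcrossprod(Q[ri, ch, drop = FALSE],
                                      K[ri, ch, drop = FALSE]) / sqrt(dh))
          O[ri, ch] <- A %*% V[ri, ch, drop = FALSE]
          if (keepCache) attn[, , h, i] <- A
        }
      }
      U <- addRowVec(O %*% lp$Wo, lp$bo)
      maskAttn <- dropoutMask(nrow(U), D, p)
      Tmid <- Tin + applyMask(U, maskAttn)
      c2 <- lnForward(Tmid, lp$ln2g, lp$ln2b)
      Z1 <- addRowVec(c2$y %*% lp$W1, lp$b1)
      Pz1 <- pnorm(Z1)
      M <- Z1 * Pz1
      maskMlp <- dropoutMask(nrow(M), ncol(M), p)
      Md <- applyMask(M, maskMlp)
      Tok <- Tmid + addRowVec(Md %*% lp$W2, lp$b2)
      if (keepCache)
        layerCaches[[l]] <- list(Tin = Tin, c1 = c1, Q = Q, K = K, V = V,
                                 attn = attn, O = O, maskAttn = maskAttn,
                                 Tmid = Tmid, c2 = c2, Z1 = Z1, Pz1 = Pz1,
                                 Md = Md, maskMlp = maskMlp)
    }
    Fcat[, ((b - 1L) * D + 1L):(b * D)] <- rowsum(Tok, grp) / L
    if (keepCache)
      caches[[b]] <- list(Xp = Xp, maskEmb = maskEmb, layers = layerCaches)
  }

  Z <- addRowVec(Fcat %*% params$head$Wh1, params$head$bh1)
  Pz <- pnorm(Z)
  Hh <- Z * Pz
  maskHead <- dropoutMask(nrow(Hh), ncol(Hh), p)
  Hd <- applyMask(Hh, maskHead)
  logits <- addRowVec(Hd %*% params$head$Wh2, params$head$bh2)
  probs <- softmaxRows(logits)
  if (!all(is.finite(probs))) stopData("non-finite network output")
  list(probs = probs,
       cache = if (keepCache) list(branches = caches, Fcat = Fcat, Z = Z,
                                   Pz = Pz, Hd = Hd,
                                   maskHead = maskHead) else NULL)
}

zeroLike <- function(p) {
  if (is.list(p)) lapply(p, zeroLike) else p * 0
}

# Class-weighted cross-entropy loss and its exact gradient for a minibatch.
# y: integer class ids (1 = interictal, 2 = preictal); w: per-sample weights;
# smooth: label-smoothing mass (targets (1 - smooth) one-hot + smooth / 2).
mvitLossGrad <- function(x, y, w, params, cfg, train = TRUE, smooth = 0) {
  B <- dim(x)[1]
  L <- nTokens(cfg)
  D <- cfg@embedDim
  dh <- D %/% cfg@nHeads
  grp <- rep(seq_len(B), each = L)
  fw <- mvitForwardBatch(x, params, cfg, train = train, keepCache = TRUE)
  probs <- fw$probs
  cache <- fw$cache
  Tq <- matrix(smooth / 2, B, 2)
  Tq[cbind(seq_len(B), y)] <- 1 - smooth / 2
  loss <- -sum(w * rowSums(Tq * log(pmax(probs, 1e-300)))) / B

  g <- zeroLike(params)
  dlogits <- (probs - Tq) * (w / B)

  hd <- params$head
  g$head$Wh2 <- crossprod(cache$Hd, dlogits)
  g$head$bh2 <- colSums(dlogits)
  dHd <- tcrossprod(dlogits, hd$Wh2)
  dHh <- applyMask(dHd, cache$maskHead)
  dZ <- dHh * geluGradFromPnorm(cache$Z, cache$Pz)
  g$head$Wh1 <- crossprod(cache$Fcat, dZ)
  g$head$bh1 <- colSums(dZ)
  dF <- tcrossprod(dZ, hd$Wh1)

  for (b in seq_len(cfg@nBranches)) {
    bi <- if (cfg@shareBranchWeights) 1L else b
    br <- params$branches[[bi]]
    bc <- cache$branches[[b]]
    dT <- dF[grp, ((b - 1L) * D + 1L):(b * D), drop = FALSE] / L

    for (l in rev(seq_len(cfg@depth))) {
      lp <- br$layers[[l]]
      lc <- bc$layers[[l]]
      gl <- g$branches[[bi]]$layers[[l]]
      # MLP sub-block: Tok = Tmid + (Md %*% W2 + b2)
      gl$W2 <- gl$W2 + crossprod(lc$Md, dT)
      gl$b2 <- gl$b2 + colSums(dT)
      dMd <- tcrossprod(dT, lp$W2)
      dM <- applyMask(dMd, lc$maskMlp)
      dZ1 <- dM * geluGradFromPnorm(lc$Z1, lc$Pz1)
      gl$W1 <- gl$W1 + crossprod(lc$c2$y, dZ1)
      gl$b1 <- gl$b1 + colSums(dZ1)
      r2 <- lnBackward(tcrossprod(dZ1, lp$W1), lc$c2, lp$ln2g)
      gl$ln2g <- gl$ln2g + r2$dg
      gl$ln2b <- gl$ln2b + r2$db
      dTmid <- dT + r2$dx
      # attention sub-block: Tmid = Tin + mask * (O %*% Wo + bo)
      dU <- applyMask(dTmid, lc$maskAttn)
      gl$Wo <- gl$Wo + crossprod(lc$O, dU)
      gl$bo <- gl$bo + colSums(dU)
      dO <- tcrossprod(dU, lp$Wo)
      dQ <- matrix(0, B * L, D)
      dK <- matrix(0, B * L, D)
      dV <- matrix(0, B * L, D)
      for (i in seq_len(B)) {
        ri <- ((i - 1L) * L + 1L):(i * L)
        for (h in seq_len(cfg@nHeads)) {
          ch <- ((h - 1L) * dh + 1L):(h * dh)
          A <- lc$attn[, , h, i]
          dOi <- dO[ri, ch, drop = FALSE]
          dA <- tcrossprod(dOi, lc$V[ri, ch, drop = FALSE])
          dV[ri, ch] <- crossprod(A, dOi)
          dS <- A * (dA - rowSums(dA * A))
          dQ[ri, ch] <- dS %*% lc$K[ri, ch, drop = FALSE] / sqrt(dh)
          dK[ri, ch] <- crossprod(dS, lc$Q[ri, ch, drop = FALSE]) / sqrt(dh)
        }
      }
      gl$Wq <- gl$Wq + crossprod(lc$c1$y, dQ)
      gl$bq <- gl$bq + colSums(dQ)
      gl$Wk <- gl$Wk + crossprod(lc$c1$y, dK)
      gl$bk <- gl$bk + colSums(dK)
      gl$Wv <- gl$Wv + crossprod(lc$c1$y, dV)
      gl$bv <- gl$bv + colSums(dV)
      dA1 <- tcrossprod(dQ, lp$Wq) + tcrossprod(dK, lp$Wk) +
        tcrossprod(dV, lp$Wv)
      r1 <- lnBackward(dA1, lc$c1, lp$ln1g)
      gl$ln1g <- gl$ln1g + r1$dg
      gl$ln1b <- gl$ln1b + r1$db
      g$branches[[bi]]$layers[[l]] <- gl
      dT <- dTmid + r1$dx
    }
    dT0 <- applyMask(dT, bc$maskEmb)
    gb <- g$branches[[bi]]
    gb$pos <- gb$pos + rowsum(dT0, rep(seq_len(L), B))
    gb$Wp <- gb$Wp + crossprod(bc$Xp, dT0)
    gb$bp <- gb$bp + colSums(dT0)
    g$branches[[bi]] <- gb
  }
  list(loss = loss, grads = g, probs = probs)
}

flattenParams <- function(p) unlist(p, use.names = FALSE)

relistParams <- function(vec, skeleton) {
  pos <- 0L
  fill <- function(p) {
    if (is.list(p)) return(lapply(p, fill))
    n <- length(p)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    attributes(out) <- attributes(p)
    out
  }
  fill(skeleton)
}

# Preictal probabilities for an (B, N, H, W) array, evaluated in chunks.
predictProbs <- function(x, params, cfg, chunk = 256L) {
  B <- dim(x)[1]
  out <- numeric(B)
  for (s in seq(1L, B, by = chunk)) {
    e <- min(s + chunk - 1L, B)
    out[s:e] <- mvitForwardFast(x[s:e, , , , drop = FALSE], params,
                                cfg)[, 2L]
  }
  out
}

# ---- compiled path ----------------------------------------------------------
# Training and bulk prediction go through the RcppArmadillo implementation
# (src/mvit.cpp), an operation-for-operation mirror of the R reference path
# above; the test suite asserts both paths agree to float precision. Dropout
# masks are drawn from R's RNG on both paths, so runs remain reproducible
# under set.seed() (though the two paths consume the RNG differently and are
# only compared with dropout disabled).

# Per-branch patch matrices: list of (B*L) x P, rows grouped by sample.
prepPatches <- function(x, cfg) {
  B <- dim(x)[1]
  L <- nTokens(cfg)
  idx <- patchIndex(cfg@imageShape[1], cfg@imageShape[2],
                    cfg@patchShape[1], cfg@patchShape[2])
  lapply(seq_len(dim(x)[2]), function(b) {
    Xp <- matrix(0, B * L, prod(cfg@patchShape))
    for (i in seq_len(B))
      Xp[((i - 1L) * L + 1L):(i * L), ] <- x[i, b, , ][idx]
    Xp
  })
}

mvitLossGradFast <- function(x, y, w, params, cfg, train = TRUE, smooth = 0) {
  .mvitLossGradCpp(prepPatches(x, cfg), as.integer(y), as.numeric(w), params,
                   dim(x)[1], nTokens(cfg), cfg@embedDim, cfg@nHeads,
                   cfg@depth, cfg@nBranches, cfg@shareBranchWeights,
                   cfg@dropout, train, TRUE, smooth)
}

mvitForwardFast <- function(x, params, cfg) {
  .mvitLossGradCpp(prepPatches(x, cfg), rep(1L, dim(x)[1]),
                   rep(1, dim(x)[1]), params,
                   dim(x)[1], nTokens(cfg), cfg@embedDim, cfg@nHeads,
                   cfg@depth, cfg@nBranches, cfg@shareBranchWeights,
                   0, FALSE, FALSE, 0)$probs
}
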