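test_that("patchify enumerates row-major patches losslessly", {
  # whole-image patch: one row, equal to the row-major flattened image
  m <- matrix(rnorm(12), 3, 4)
  p1 <- patchify(m, c(3, 4))
  expect_identical(dim(p1), c(1L, 12L))
  expect_equal(as.numeric(p1), as.numeric(t(m)))

  # 6x4 image, 2x2 patches: compare against brute-force window enumeration
  img <- matrix(seq_len(24), 6, 4)
  got <- patchify(img, c(2, 2))
  expect_identical(dim(got), c(6L, 4L))
  l <- 0
  for (gr in 1:3) for (gc in 1:2) { # row-major over the 3x2 patch grid
    l <- l + 1
    block <- img[(2 * gr - 1):(2 * gr), (2 * gc - 1):(2 * gc)]
    flat <- c(block[1, 1], block[1, 2], block[2, 1], block[2, 2]) # row-major
    expect_equal(got[l, ], flat, ignore_attr = TRUE)
  }

  # inverse round-trip and divisibility errors
  x <- matrix(rnorm(32 * 64), 32, 64)
  expect_identical(unpatchify(patchify(x, c(8, 8)), c(32, 64), c(8, 8)), x)
  expect_error(patchify(x, c(7, 8)), class = "mvitConfigError")

  # token-count law over a grid of configs
  for (hw in list(c(32, 64), c(16, 16), c(8, 24))) {
    for (pp in list(c(8, 8), c(4, 8), c(2, 2))) {
      cfg <- mvitConfig(nBranches = 1, imageShape = hw, patchShape = pp,
                        embedDim = 8, depth = 1, nHeads = 2, mlpHidden = 8)
      expect_identical(nTokens(cfg), as.integer(prod(hw) %/% prod(pp)))
      expect_identical(nrow(patchify(matrix(0, hw[1], hw[2]), pp)),
                       nTokens(cfg))
    }
  }
  expect_error(mvitConfig(nBranches = 1, imageShape = c(32, 64),
                          patchShape = c(8, 8), embedDim = 9, nHeads = 2),
               class = "mvitConfigError")
})

test_that("patch embedding adds projections and position embeddings", {
  cfg <- smallModelCfg()
  par <- initMViTParams(cfg, seed = 4)
  pats <- patchify(matrix(rnorm(16 * 32), 16, 32), cfg@patchShape)

  # zero projection and bias: tokens equal the branch position embeddings
  par0 <- par
  par0$branches[[1]]$Wp[] <- 0
  expect_identical(embedPatches(pats, par0, 1), par0$branches[[1]]$pos)

  # with positions zeroed, permuting patches permutes tokens identically
  parP <- par
  parP$branches[[2]]$pos[] <- 0
  perm <- sample(nrow(pats))
  expect_equal(embedPatches(pats, parP, 2)[perm, ],
               embedPatches(pats[perm, ], parP, 2), tolerance = 1e-12)

  # identity projection on a single patch
  parI <- initMViTParams(mvitConfig(nBranches = 1, imageShape = c(1, 2),
                                    patchShape = c(1, 2), embedDim = 2,
                                    depth = 1, nHeads = 1, mlpHidden = 4,
                                    dropout = 0), seed = 1)
  parI$branches[[1]]$Wp <- diag(2)
  parI$branches[[1]]$bp[] <- 0
  parI$branches[[1]]$pos[] <- 0
  expect_equal(embedPatches(matrix(c(1, 2), 1, 2), parI, 1),
               matrix(c(1, 2), 1, 2), ignore_attr = TRUE)
})

test_that("multi-head self-attention matches a loop-level oracle", {
  # L = 1: softmax over a single key is 1, so output = Wo(V(token))
  cfg1 <- mvitConfig(nBranches = 1, imageShape = c(2, 2), patchShape = c(2, 2),
                     embedDim = 4, depth = 1, nHeads = 2, mlpHidden = 4,
                     dropout = 0)
  lp <- initMViTParams(cfg1, seed = 2)$branches[[1]]$layers[[1]]
  tok <- matrix(rnorm(4), 1, 4)
  v <- tok %*% lp$Wv + matrix(lp$bv, 1, 4)
  expect_equal(as.matrix(msa(tok, lp, 2)), v %*% lp$Wo + matrix(lp$bo, 1, 4),
               tolerance = 1e-12, ignore_attr = TRUE)

  # attention weights are row-stochastic for any input
  cfg <- smallModelCfg()
  lp2 <- initMViTParams(cfg, seed = 3)$branches[[1]]$layers[[1]]
  out <- msa(matrix(rnorm(8 * 16), 8, 16), lp2, 2)
  for (A in attr(out, "attn"))
    expect_equal(rowSums(A), rep(1, 8), tolerance = 1e-12)

  # L = 3, embedDim = 2, one head: explicit loops over queries and keys
  cfg3 <- mvitConfig(nBranches = 1, imageShape = c(2, 3), patchShape = c(2, 3),
                     embedDim = 2, depth = 1, nHeads = 1, mlpHidden = 4,
                     dropout = 0)
  lp3 <- initMViTParams(cfg3, seed = 5)$branches[[1]]$layers[[1]]
  lp3$Wq <- matrix(c(1, 0, 1, 2), 2, 2) / 2
  lp3$Wk <- matrix(c(0, 1, 1, 0), 2, 2)
  lp3$Wv <- matrix(c(2, 0, 0, 1), 2, 2) / 2
  lp3$Wo <- matrix(c(1, 1, 0, 1), 2, 2)
  tk <- matrix(c(1, 2, 3, 0.5, -1, 2), 3, 2)
  Q <- tk %*% lp3$Wq; K <- tk %*% lp3$Wk; V <- tk %*% lp3$Wv
  oracle <- matrix(0, 3, 2)
  for (i in 1:3) {
    sc <- numeric(3)
    for (j in 1:3) sc[j] <- sum(Q[i, ] * K[j, ]) / sqrt(2)
    a <- exp(sc - max(sc)); a <- a / sum(a)
    for (j in 1:3) oracle[i, ] <- oracle[i, ] + a[j] * V[j, ]
  }
  oracle <- oracle %*% lp3$Wo
  lp3$bq[] <- 0; lp3$bk[] <- 0; lp3$bv[] <- 0; lp3$bo[] <- 0
  expect_lt(max(abs(as.matrix(msa(tk, lp3, 1)) - oracle)), 1e-6)
})

test_that("encoder block is pre-norm residual and reduces to identity with
           zero output projections", {
  cfg <- smallModelCfg()
  lp <- initMViTParams(cfg, seed = 6)$branches[[1]]$layers[[1]]
  lp$Wo[] <- 0; lp$bo[] <- 0; lp$W2[] <- 0; lp$b2[] <- 0
  tok <- matrix(rnorm(8 * 16), 8, 16)
  expect_identical(encoderBlock(tok, lp, 2), tok) # pure residual path

  # shape preservation with live weights
  lp2 <- initMViTParams(cfg, seed = 7)$branches[[1]]$layers[[1]]
  expect_identical(dim(encoderBlock(tok, lp2, 2)), dim(tok))

  # step-by-step oracle on a tiny block (L = 2, embedDim = 2, 1 head),
  # written with explicit scalar arithmetic
  ln <- function(x, g, b) {
    t(apply(x, 1, function(r) {
      mu <- mean(r); v <- mean((r - mu)^2)
      (r - mu) / sqrt(v + 1e-5) * g + b
    }))
  }
  cfg2 <- mvitConfig(nBranches = 1, imageShape = c(2, 2), patchShape = c(2, 2),
                     embedDim = 2, depth = 1, nHeads = 1, mlpHidden = 3,
                     dropout = 0)
  lp3 <- initMViTParams(cfg2, seed = 8)$branches[[1]]$layers[[1]]
  tok2 <- matrix(c(0.3, -1, 2, 0.7), 2, 2)
  a1 <- ln(tok2, lp3$ln1g, lp3$ln1b)
  Q <- a1 %*% lp3$Wq + matrix(lp3$bq, 2, 2, byrow = TRUE)
  K <- a1 %*% lp3$Wk + matrix(lp3$bk, 2, 2, byrow = TRUE)
  V <- a1 %*% lp3$Wv + matrix(lp3$bv, 2, 2, byrow = TRUE)
  att <- matrix(0, 2, 2)
  for (i in 1:2) {
    sc <- c(sum(Q[i, ] * K[1, ]), sum(Q[i, ] * K[2, ])) / sqrt(2)
    a <- exp(sc - max(sc)); a <- a / sum(a)
    att[i, ] <- a[1] * V[1, ] + a[2] * V[2, ]
  }
  u <- tok2 + att %*% lp3$Wo + matrix(lp3$bo, 2, 2, byrow = TRUE)
  a2 <- ln(u, lp3$ln2g, lp3$ln2b)
  z <- a2 %*% lp3$W1 + matrix(lp3$b1, 2, 3, byrow = TRUE)
  gz <- z * pnorm(z)
  oracle <- u + gz %*% lp3$W2 + matrix(lp3$b2, 2, 2, byrow = TRUE)
  expect_lt(max(abs(encoderBlock(tok2, lp3, 1) - oracle)), 1e-6)
})

test_that("forward pass yields a softmax pair with independent branches", {
  cfg <- smallModelCfg(nBranches = 3)
  par <- initMViTParams(cfg, seed = 9)
  x <- array(rnorm(3 * 16 * 32), c(3, 16, 32))
  p <- mvitForward(x, par, cfg)
  expect_named(p, c("interictal", "preictal"))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))

  # perturbing channel 2 leaves the other branches' features bit-identical
  f0 <- attr(p, "features")
  x2 <- x
  x2[2, , ] <- x2[2, , ] + 1
  f2 <- attr(mvitForward(x2, par, cfg), "features")
  expect_identical(f0[1, ], f2[1, ])
  expect_identical(f0[3, ], f2[3, ])
  expect_false(identical(f0[2, ], f2[2, ]))
  expect_error(mvitForward(x[1:2, , ], par, cfg), class = "mvitConfigError")

  # N = 1: forward equals the manual composition of the exported operations
  cfg1 <- smallModelCfg(nBranches = 1)
  par1 <- initMViTParams(cfg1, seed = 10)
  img <- matrix(rnorm(16 * 32), 16, 32)
  tok <- embedPatches(patchify(img, cfg1@patchShape), par1, 1)
  for (lp in par1$branches[[1]]$layers) tok <- encoderBlock(tok, lp, cfg1@nHeads)
  f <- colMeans(tok)
  h <- f %*% par1$head$Wh1 + matrix(par1$head$bh1, 1)
  h <- h * pnorm(h)
  logit <- h %*% par1$head$Wh2 + matrix(par1$head$bh2, 1)
  e <- exp(logit - max(logit))
  expect_equal(as.numeric(mvitForward(list(img), par1, cfg1)),
               as.numeric(e / sum(e)), tolerance = 1e-10)
})

test_that("reference R batch path, compiled path, and per-sample forward all
           agree", {
  cfg <- smallModelCfg(nBranches = 2)
  par <- initMViTParams(cfg, seed = 11)
  x <- array(rnorm(5 * 2 * 16 * 32), c(5, 2, 16, 32))
  pb <- SeizureMViT:::mvitForwardBatch(x, par, cfg)$probs
  pc <- SeizureMViT:::mvitForwardFast(x, par, cfg)
  ps <- t(vapply(1:5, function(i) as.numeric(mvitForward(x[i, , , ], par, cfg)),
                 numeric(2)))
  expect_equal(pb, pc, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(pb, ps, tolerance = 1e-12, ignore_attr = TRUE)

  y <- c(1L, 2L, 1L, 2L, 1L)
  w <- runif(5, 0.5, 1.5)
  rR <- SeizureMViT:::mvitLossGrad(x, y, w, par, cfg, train = FALSE,
                                   smooth = 0.1)
  rC <- SeizureMViT:::mvitLossGradFast(x, y, w, par, cfg, train = FALSE,
                                       smooth = 0.1)
  expect_equal(rR$loss, rC$loss, tolerance = 1e-12)
  expect_equal(SeizureMViT:::flattenParams(rR$grads),
               SeizureMViT:::flattenParams(rC$grads), tolerance = 1e-10)
})

test_that("analytic gradients match finite differences to 1e-4 relative", {
  cfg <- gradCheckCfg()
  par <- initMViTParams(cfg, seed = 12)
  set.seed(13)
  x <- array(rnorm(3 * 2 * 4 * 4), c(3, 2, 4, 4))
  y <- c(1L, 2L, 2L)
  w <- c(1, 0.8, 1.2)
  th <- SeizureMViT:::flattenParams(par)
  gA <- SeizureMViT:::flattenParams(
    SeizureMViT:::mvitLossGrad(x, y, w, par, cfg, train = FALSE)$grads)
  eps <- 1e-5
  lossAt <- function(v) SeizureMViT:::mvitLossGrad(
    x, y, w, SeizureMViT:::relistParams(v, par), cfg, train = FALSE)$loss
  idx <- seq_along(th) # full sweep: the config is tiny
  gN <- vapply(idx, function(i) {
    tp <- th; tp[i] <- tp[i] + eps
    tm <- th; tm[i] <- tm[i] - eps
    (lossAt(tp) - lossAt(tm)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(gN - gA[idx])) / max(abs(gN)), 1e-4)
})
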