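#' MViTConfig: multi-channel vision transformer architecture
#'
#' One transformer-encoder branch per EEG channel: each branch patch-embeds
#' its channel's H x W scalogram into L = H*W / (Ph*Pw) tokens of dimension
#' `embedDim`, adds learned position embeddings, and applies `depth` pre-norm
#' encoder blocks (multi-head self-attention + MLP, each wrapped in a
#' residual connection). Branch features (mean over tokens) are concatenated
#' in channel order and classified by an MLP head.
#'
#' @slot nBranches number of branches N (= EEG channels).
#' @slot imageShape integer(2) (H, W) of the input scalogram images.
#' @slot patchShape integer(2) (Ph, Pw); must divide (H, W). Rectangular
#'   patches generalize square P x P patches for non-square images.
#' @slot embedDim token dimension; divisible by `nHeads`.
#' @slot depth encoder blocks per branch.
#' @slot nHeads attention heads.
#' @slot mlpHidden hidden width of the encoder MLPs.
#' @slot headHidden hidden width of the classification head MLP.
#' @slot dropout dropout rate used during training (0 disables).
#' @slot nClasses number of classes (2: interictal, preictal).
#' @slot shareBranchWeights logical; if TRUE all branches share one weight
#'   set (position embeddings included).
#'
#' @exportClass MViTConfig
setClass("MViTConfig",
  representation(
    nBranches = "integer", imageShape = "integer", patchShape = "integer",
    embedDim = "integer", depth = "integer", nHeads = "integer",
    mlpHidden = "integer", headHidden = "integer", dropout = "numeric",
    nClasses = "integer", shareBranchWeights = "logical"
  )
)

setValidity("MViTConfig", function(object) {
  msg <- character()
  if (object@nBranches < 1L) msg <- c(msg, "nBranches must be >= 1")
  if (any(object@imageShape %% object@patchShape != 0L))
    msg <- c(msg, "patchShape must divide imageShape")
  if (object@embedDim %% object@nHeads != 0L)
    msg <- c(msg, "embedDim must be divisible by nHeads")
  if (prod(object@imageShape) / prod(object@patchShape) < 1)
    msg <- c(msg, "need at least one patch (L >= 1)")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (object@nClasses != 2L) msg <- c(msg, "only binary classification is supported")
  if (length(msg)) msg else TRUE
})

#' Construct an MViTConfig
#'
#' @param nBranches number of EEG channels / branches.
#' @param imageShape,patchShape,embedDim,depth,nHeads,mlpHidden,headHidden,dropout,shareBranchWeights
#'   see [MViTConfig-class]. `headHidden` defaults to `mlpHidden`.
#' @return a validated [MViTConfig-class].
#' @export
mvitConfig <- function(nBranches, imageShape = c(64, 256),
                       patchShape = c(8, 8), embedDim = 64, depth = 4,
                       nHeads = 4, mlpHidden = 128, headHidden = mlpHidden,
                       dropout = 0.1, shareBranchWeights = FALSE) {
  tryCatch(
    new("MViTConfig", nBranches = as.integer(nBranches),
        imageShape = as.integer(imageShape),
        patchShape = as.integer(patchShape),
        embedDim = as.integer(embedDim), depth = as.integer(depth),
        nHeads = as.integer(nHeads), mlpHidden = as.integer(mlpHidden),
        headHidden = as.integer(headHidden),
        dropout = as.numeric(dropout), nClasses = 2L,
        shareBranchWeights = isTRUE(shareBranchWeights)),
    error = function(e) stopConfig(conditionMessage(e)))
}

#' Number of tokens per branch
#' @param cfg an [MViTConfig-class].
#' @return L = H*W / (Ph*Pw).
#' @export
nTokens <- function(cfg) as.integer(prod(cfg@imageShape) %/% prod(cfg@patchShape))

setMethod("show", "MViTConfig", function(object) {
  cat(sprintf(paste0("MViTConfig: %d branch(es), image %dx%d, patch %dx%d ",
                     "(L=%d)\n  embed %d, depth %d, heads %d, mlp %d, ",
                     "dropout %g, shared=%s\n"),
              object@nBranches, object@imageShape[1], object@imageShape[2],
              object@patchShape[1], object@patchShape[2], nTokens(object),
              object@embedDim, object@depth, object@nHeads, object@mlpHidden,
              object@dropout, object@shareBranchWeights))
})

# ---- elementary ops ---------------------------------------------------------

#' Split an image into flattened non-overlapping patches
#'
#' Patches are enumerated row-major over the patch grid and each patch is
#' flattened row-major, so the mapping is lossless ([unpatchify()] inverts
#' it).
#'
#' @param image numeric H x W matrix.
#' @param patch integer(2) (Ph, Pw) dividing (H, W).
#' @return L x (Ph*Pw) matrix, L = H*W / (Ph*Pw).
#' @export
patchify <- function(image, patch) {
  idx <- patchIndex(nrow(image), ncol(image), patch[1], patch[2])
  out <- image[idx]
  dim(out) <- dim(idx)
  out
}

# L x P matrix of column-major linear indices into an H x W matrix; row l is
# patch l (row-major grid order), columns are the row-major flattening of the
# patch.
patchIndex <- function(H, W, Ph, Pw) {
  if (H %% Ph != 0L || W %% Pw != 0L)
    stopConfig("patch shape must divide the image shape")
  gh <- H %/% Ph; gw <- W %/% Pw
  l <- seq_len(gh * gw)
  gr <- (l - 1L) %/% gw            # 0-based grid row
  gc <- (l - 1L) %% gw             # 0-based grid col
  p <- seq_len(Ph * Pw)
  pr <- (p - 1L) %/% Pw            # 0-based row within patch (row-major flatten)
  pc <- (p - 1L) %% Pw
  row <- outer(gr * Ph, pr, `+`) + 1L
  col <- outer(gc * Pw, pc, `+`) + 1L
  (col - 1L) * H + row
}

#' Reassemble an image from its patches
#' @param patches L x (Ph*Pw) matrix as produced by [patchify()].
#' @param imageShape integer(2) (H, W).
#' @param patch integer(2) (Ph, Pw).
#' @return the H x W image.
#' @export
unpatchify <- function(patches, imageShape, patch) {
  idx <- patchIndex(imageShape[1], imageShape[2], patch[1], patch[2])
  img <- matrix(0, imageShape[1], imageShape[2])
  img[idx] <- patches
  img
}

# Gaussian-error-linear unit and its derivative (exact form). The backward
# pass reuses the forward pnorm via geluGradFromPnorm; dnorm is inlined as
# exp(-x^2/2)/sqrt(2*pi).
gelu <- function(x) x * pnorm(x)
geluGrad <- function(x) pnorm(x) + x * dnorm(x)
geluGradFromPnorm <- function(x, px) px + x * (exp(-x * x / 2) * 0.3989422804014327)

softmaxRows <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / rowSums(E)
}

# Row-wise layer normalization y = xhat * g + b, xhat = (x - mu) / sqrt(v + eps).
layerNorm <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  invstd <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * invstd
  sweep(xhat, 2L, g, `*`) + rep(b, each = nrow(x))
}

addRowVec <- function(M, v) M + rep(v, each = nrow(M))

#' Embed patches into the token sequence of a branch
#'
#' tokens = patches %*% W + b + position embeddings of the branch.
#'
#' @param patches L x P matrix from [patchify()].
#' @param params an [initMViTParams()] parameter list.
#' @param branch branch index (1-based); ignored when branch weights are
#'   shared.
#' @return L x embedDim token matrix.
#' @export
embedPatches <- function(patches, params, branch = 1L) {
  br <- params$branches[[min(branch, length(params$branches))]]
  if (ncol(patches) != nrow(br$Wp))
    stopConfig("patch width does not match the projection matrix")
  addRowVec(patches %*% br$Wp, br$bp) + br$pos
}

#' Multi-head self-attention over one token sequence
#'
#' Standard scaled dot-product attention: per head, softmax over the key axis
#' of Q K^T / sqrt(embedDim / nHeads), applied to V; head outputs are
#' concatenated and passed through the output projection. Attention weights
#' are attached as attribute `"attn"` (a list of per-head L x L matrices,
#' each row summing to 1).
#'
#' @param tokens L x embedDim matrix.
#' @param lp layer parameter list with Wq/bq, Wk/bk, Wv/bv, Wo/bo.
#' @param nHeads number of heads (must divide embedDim).
#' @return L x embedDim matrix.
#' @export
msa <- function(tokens, lp, nHeads) {
  D <- ncol(tokens)
  if (D %% nHeads != 0L) stopConfig("embedDim must be divisible by nHeads")
  dh <- D %/% nHeads
  Q <- addRowVec(tokens %*% lp$Wq, lp$bq)
  K <- addRowVec(tokens %*% lp$Wk, lp$bk)
  V <- addRowVec(tokens %*% lp$Wv, lp$bv)
  O <- matrix(0, nrow(tokens), D)
  attn <- vector("list", nHeads)
  for (h in seq_len(nHeads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    A <- softmaxRows(tcrossprod(Q[, cols, drop = FALSE],
                                K[, cols, drop = FALSE]) / sqrt(dh))
    O[, cols] <- A %*% V[, cols, drop = FALSE]
    attn[[h]] <- A
  }
  out <- addRowVec(O %*% lp$Wo, lp$bo)
  if (!all(is.finite(out))) stopData("non-finite attention output")
  structure(out, attn = attn)
}

#' Pre-norm transformer encoder block
#'
#' `u = tokens + MSA(LN(tokens)); out = u + MLP(LN(u))` with
#' MLP = linear -> GELU -> linear. Layer normalization precedes each
#' sub-block and residual connections wrap both.
#'
#' @param tokens L x embedDim matrix.
#' @param lp layer parameter list (ln1/ln2 gains and offsets, attention and
#'   MLP weights).
#' @param nHeads attention heads.
#' @return L x embedDim matrix.
#' @export
encoderBlock <- function(tokens, lp, nHeads) {
  a <- msa(layerNorm(tokens, lp$ln1g, lp$ln1b), lp, nHeads)
  attr(a, "attn") <- NULL
  u <- tokens + a
  z <- addRowVec(layerNorm(u, lp$ln2g, lp$ln2b) %*% lp$W1, lp$b1)
  out <- u + addRowVec(gelu(z) %*% lp$W2, lp$b2)
  if (!all(is.finite(out))) stopData("non-finite encoder block output")
  out
}

# ---- parameters -------------------------------------------------------------

truncNorm <- function(n, sd = 0.02) {
  x <- rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

newLayerParams <- function(D, mlpHidden) {
  list(
    ln1g = rep(1, D), ln1b = rep(0, D),
    Wq = matrix(truncNorm(D * D), D, D), bq = rep(0, D),
    Wk = matrix(truncNorm(D * D), D, D), bk = rep(0, D),
    Wv = matrix(truncNorm(D * D), D, D), bv = rep(0, D),
    Wo = matrix(truncNorm(D * D), D, D), bo = rep(0, D),
    ln2g = rep(1, D), ln2b = rep(0, D),
    W1 = matrix(truncNorm(D * mlpHidden), D, mlpHidden), b1 = rep(0, mlpHidden),
    W2 = matrix(truncNorm(mlpHidden * D), mlpHidden, D), b2 = rep(0, D)
  )
}

#' Initialize MViT parameters
#'
#' Truncated-normal (sd 0.02, clipped at 2 sd) initialization for projection
#' matrices and position embeddings; zeros for biases and layer-norm offsets;
#' ones for layer-norm gains. Fully determined by `seed`.
#'
#' @param cfg an [MViTConfig-class].
#' @param seed integer seed.
#' @return a nested parameter list (`branches`, `head`).
#' @export
initMViTParams <- function(cfg, seed = 1L) {
  L <- nTokens(cfg)
  P <- prod(cfg@patchShape)
  D <- cfg@embedDim
  nb <- if (cfg@shareBranchWeights) 1L else cfg@nBranches
  localSeed(seed, {
    branches <- lapply(seq_len(nb), function(b) {
      list(Wp = matrix(truncNorm(P * D), P, D), bp = rep(0, D),
           pos = matrix(truncNorm(L * D), L, D),
           layers = lapply(seq_len(cfg@depth), function(l)
             newLayerParams(D, cfg@mlpHidden)))
    })
    head <- list(
      Wh1 = matrix(truncNorm(cfg@nBranches * D * cfg@headHidden),
                   cfg@nBranches * D, cfg@headHidden),
      bh1 = rep(0, cfg@headHidden),
      Wh2 = matrix(truncNorm(cfg@headHidden * cfg@nClasses),
                   cfg@headHidden, cfg@nClasses),
      bh2 = rep(0, cfg@nClasses))
    list(branches = branches, head = head)
  })
}

# ---- forward pass (single sample) ------------------------------------------

stackToArray <- function(stack, cfg) {
  imgs <- if (is(stack, "ScalogramStack")) stack@images else stack
  if (is.array(imgs) && length(dim(imgs)) == 3L)
    imgs <- lapply(seq_len(dim(imgs)[1]), function(b) imgs[b, , ])
  if (length(imgs) != cfg@nBranches)
    stopConfig("stack has ", length(imgs), " channels but config expects ",
               cfg@nBranches)
  if (!all(dim(imgs[[1]]) == cfg@imageShape))
    stopConfig("image shape does not match config")
  imgs
}

#' MViT forward pass for one scalogram stack (evaluation mode)
#'
#' Each branch patch-embeds its channel image and runs `depth` encoder
#' blocks; its feature is the mean over the L output tokens. Features are
#' concatenated in channel order and classified by the MLP head with a
#' softmax output. Dropout is disabled (evaluation mode).
#'
#' @param stack a [ScalogramStack-class], a list of N H x W matrices, or an
#'   N x H x W array.
#' @param params parameters from [initMViTParams()] or [trainMViT()].
#' @param cfg the matching [MViTConfig-class].
#' @return named numeric(2) of class probabilities (`interictal`,
#'   `preictal`), summing to 1, with the N x embedDim matrix of
#'   pre-aggregation branch features attached as attribute `"features"`.
#' @export
mvitForward <- function(stack, params, cfg) {
  imgs <- stackToArray(stack, cfg)
  feats <- matrix(0, cfg@nBranches, cfg@embedDim)
  for (b in seq_len(cfg@nBranches)) {
    tok <- embedPatches(patchify(imgs[[b]], cfg@patchShape), params, b)
    bi <- if (cfg@shareBranchWeights) 1L else b
    for (lp in params$branches[[bi]]$layers)
      tok <- encoderBlock(tok, lp, cfg@nHeads)
    feats[b, ] <- colMeans(tok)
  }
  f <- as.vector(t(feats)) # concatenated in channel order
  h <- gelu(drop(f %*% params$head$Wh1) + params$head$bh1)
  logits <- drop(h %*% params$head$Wh2) + params$head$bh2
  e <- exp(logits - max(logits))
  p <- e / sum(e)
  structure(setNames(p, c("interictal", "preictal")), features = feats)
}
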