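# Minimal neural-network primitives with hand-written backpropagation.
#
# Feature maps live as plain matrices of shape (B*H*W) x C, rows ordered
# batch-major with the within-image pixel index column-major (R order).
# Convolutions are evaluated as an im2col gather followed by one BLAS
# matrix multiplication; the adjoint of the gather is an indexed
# scatter-add, so no compiled code is needed. All layers return their
# forward value plus a cache consumed by the matching *_bwd function.

.rs_idx_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (is.null(.rs_idx_cache[[key]])) .rs_idx_cache[[key]] <- builder()
  .rs_idx_cache[[key]]
}

# 3x3 conv gather indices for geometry (B, H, W) and stride 1 or 2.
# Kernel offsets are enumerated k = 1..9 over (dj, di) in -1..1 (di
# fastest); negating an offset maps k -> 10 - k, which the stride-1
# backward pass exploits to express the adjoint as another convolution.
# Weight matrices use row layout (ci - 1) * 9 + k so that the gathered
# im2col block reshapes into position without any transposition.
# Returns list(idx = list of 9 index vectors into rows of X with
# n_pad = B*H*W + 1 marking the zero row; idxall = their concatenation;
# Ho, Wo, n_out).
conv_indices <- function(B, H, W, stride = 1L) {
  key <- paste("conv", B, H, W, stride, sep = "_")
  out <- cache_get(key, function() {
    oi <- seq(1L, H, by = stride); oj <- seq(1L, W, by = stride)
    Ho <- length(oi); Wo <- length(oj)
    n_in <- H * W
    pad <- B * n_in + 1L
    gi <- rep(oi, Wo); gj <- rep(oj, each = Ho)
    idx <- vector("list", 9L)
    k <- 0L
    for (dj in -1:1) for (di in -1:1) {
      k <- k + 1L
      si <- gi + di; sj <- gj + dj
      base <- si + (sj - 1L) * H
      bad <- si < 1L | si > H | sj < 1L | sj > W
      full <- rep(base, B) + rep((seq_len(B) - 1L) * n_in, each = Ho * Wo)
      full[rep(bad, B)] <- pad
      idx[[k]] <- full
    }
    idxall <- unlist(idx)
    safe <- idxall
    bad <- which(idxall == pad)
    safe[bad] <- 1L
    list(idx = idx, idxall = idxall, safe = safe, bad = bad,
         Ho = Ho, Wo = Wo, n_out = B * Ho * Wo)
  })
  out$key <- key
  out
}

# linear indices of the out-of-field entries of the reshaped im2col
# matrix, for a given channel count (cached per geometry x channels)
im2col_zeropos <- function(ci, C, key) {
  cache_get(paste0(key, "_z", C), function() {
    if (length(ci$bad) == 0L) return(integer(0))
    n9 <- 9L * ci$n_out
    as.vector(outer(ci$bad, (seq_len(C) - 1L) * n9, `+`))
  })
}

# im2col: one clamped gather, a free reshape into (n_out) x (9 * C),
# then zeroing of the out-of-field positions
im2col <- function(X, ci) {
  Xcat <- X[ci$safe, , drop = FALSE]
  dim(Xcat) <- c(ci$n_out, 9L * ncol(X))
  zp <- im2col_zeropos(ci, ncol(X), ci$key)
  if (length(zp)) Xcat[zp] <- 0
  Xcat
}

# rearrange conv weights for the adjoint convolution:
# Wback[(co-1)*9 + k, ci] = W[(ci-1)*9 + (10-k), co]
flip_weights <- function(W, Cin, Cout) {
  A <- W
  dim(A) <- c(9L, Cin, Cout)
  A <- A[9:1, , , drop = FALSE]
  A <- aperm(A, c(1L, 3L, 2L))
  dim(A) <- c(9L * Cout, Cin)
  A
}

# nearest-neighbour 2x upsampling indices: output (B, 2H, 2W) -> input rows
upsample_indices <- function(B, H, W) {
  key <- paste("up", B, H, W, sep = "_")
  cache_get(key, function() {
    Ho <- 2L * H; Wo <- 2L * W
    gi <- rep(seq_len(Ho), Wo); gj <- rep(seq_len(Wo), each = Ho)
    base <- ceiling(gi / 2) + (ceiling(gj / 2) - 1L) * H
    rep(base, B) + rep((seq_len(B) - 1L) * H * W, each = Ho * Wo)
  })
}

# window-partition permutation for (shifted) windowed attention.
# perm groups rows so that each consecutive run of ws^2 rows is one
# window; a cyclic shift by `sft` pixels along both axes is folded into
# the permutation (shifted windows wrap around, no attention mask).
win_perm <- function(B, H, W, ws, sft = 0L) {
  key <- paste("win", B, H, W, ws, sft, sep = "_")
  cache_get(key, function() {
    n_in <- H * W
    perm <- integer(B * n_in)
    pos <- 0L
    for (b in seq_len(B)) {
      off <- (b - 1L) * n_in
      for (wj in seq_len(W / ws)) for (wi in seq_len(H / ws)) {
        for (jj in seq_len(ws)) for (ii in seq_len(ws)) {
          i <- ((wi - 1L) * ws + ii - 1L + sft) %% H + 1L
          j <- ((wj - 1L) * ws + jj - 1L + sft) %% W + 1L
          pos <- pos + 1L
          perm[pos] <- off + i + (j - 1L) * H
        }
      }
    }
    inv <- integer(length(perm))
    inv[perm] <- seq_along(perm)
    list(perm = perm, inv = inv)
  })
}

add_bias <- function(Y, b) Y + rep(b, each = nrow(Y))

## ---- dense -----------------------------------------------------------

linear_fwd <- function(X, W, b) {
  list(out = add_bias(X %*% W, b), X = X)
}
linear_bwd <- function(dY, W, cache) {
  list(dX = dY %*% t(W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

## ---- SiLU ------------------------------------------------------------

silu_fwd <- function(X) {
  s <- 1 / (1 + exp(-X))
  list(out = X * s, X = X, s = s)
}
silu_bwd <- function(dY, cache) {
  dY * (cache$s * (1 + cache$X * (1 - cache$s)))
}

## ---- 3x3 convolution (stride 1 or 2, zero padding) -------------------

conv_fwd <- function(X, W, b, B, H, W_img, stride = 1L) {
  ci <- conv_indices(B, H, W_img, stride)
  Xcat <- im2col(X, ci)
  list(out = add_bias(Xcat %*% W, b), Xcat = Xcat, ci = ci,
       n_in = nrow(X), Cin = ncol(X), B = B, H = H, W_img = W_img,
       stride = stride)
}
conv_bwd <- function(dY, W, cache) {
  dW <- crossprod(cache$Xcat, dY)
  db <- colSums(dY)
  Cin <- cache$Cin
  Cout <- ncol(dY)
  if (cache$stride == 1L) {
    # stride-1 adjoint is itself a 3x3 convolution with flipped kernels
    dX <- im2col(dY, cache$ci) %*% flip_weights(W, Cin, Cout)
  } else {
    dXcat <- dY %*% t(W)
    dX <- matrix(0, cache$n_in, Cin)
    for (k in seq_len(9L)) {
      ix <- cache$ci$idx[[k]]
      ok <- ix <= cache$n_in
      sub <- dXcat[, (seq_len(Cin) - 1L) * 9L + k, drop = FALSE]
      # within one kernel offset the output->input map is injective
      dX[ix[ok], ] <- dX[ix[ok], , drop = FALSE] + sub[ok, , drop = FALSE]
    }
  }
  list(dX = dX, dW = dW, db = db)
}

## ---- nearest-neighbour 2x upsampling ---------------------------------

upsample_fwd <- function(X, B, H, W_img) {
  ix <- upsample_indices(B, H, W_img)
  list(out = X[ix, , drop = FALSE], ix = ix, n_in = nrow(X))
}
upsample_bwd <- function(dY, cache) {
  rs <- rowsum(dY, cache$ix) # groups cover 1..n_in, returned sorted
  rs
}

## ---- layer norm over channels (per pixel row) ------------------------

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- Xc * istd
  list(out = add_bias(xhat * rep(g, each = nrow(X)), b),
       xhat = xhat, istd = istd)
}
layernorm_bwd <- function(dY, g, cache) {
  n <- nrow(dY); C <- ncol(dY)
  dxhat <- dY * rep(g, each = n)
  xhat <- cache$xhat
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) *
    cache$istd
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

## ---- FiLM modulation from the time embedding -------------------------
# h * (1 + scale) + shift, with (scale, shift) per sample and channel.

film_fwd <- function(H_feat, scale, shift, rowsmap) {
  S <- scale[rowsmap, , drop = FALSE]
  list(out = H_feat * (1 + S) + shift[rowsmap, , drop = FALSE],
       H_feat = H_feat, S = S, rowsmap = rowsmap)
}
film_bwd <- function(dY, cache) {
  list(dH = dY * (1 + cache$S),
       dscale = rowsum(dY * cache$H_feat, cache$rowsmap),
       dshift = rowsum(dY, cache$rowsmap))
}

## ---- windowed multi-head self-attention block ------------------------
# pre-norm transformer block: x + MSA(LN(x)), then + MLP(LN(x)).
# Windows are ws x ws tiles; `sft` = ws/2 gives the shifted variant
# (cyclic, no mask). Parameters: ln1 g/b, Wqkv/bqkv, Wproj/bproj,
# ln2 g/b, Wm1/bm1, Wm2/bm2.

attn_fwd <- function(X, p, B, H, W_img, ws, sft, heads) {
  C <- ncol(X)
  dh <- C %/% heads
  wp <- win_perm(B, H, W_img, ws, sft)
  M <- ws * ws
  nwin <- nrow(X) %/% M
  scl <- 1 / sqrt(dh)

  ln1 <- layernorm_fwd(X, p$g1, p$b1)
  Xw <- ln1$out[wp$perm, , drop = FALSE]
  QKV <- Xw %*% p$Wqkv
  O <- matrix(0, nrow(X), C)
  A_list <- vector("list", nwin * heads)
  for (w in seq_len(nwin)) {
    r <- ((w - 1L) * M + 1L):(w * M)
    for (h in seq_len(heads)) {
      cq <- ((h - 1L) * dh + 1L):(h * dh)
      Q <- QKV[r, cq, drop = FALSE]
      K <- QKV[r, C + cq, drop = FALSE]
      V <- QKV[r, 2L * C + cq, drop = FALSE]
      S <- tcrossprod(Q, K) * scl
      S <- S - S[cbind(seq_len(M), max.col(S, ties.method = "first"))]
      E <- exp(S)
      A <- E / rowSums(E)
      O[r, cq] <- A %*% V
      A_list[[(w - 1L) * heads + h]] <- A
    }
  }
  proj <- linear_fwd(O, p$Wproj, p$bproj)
  X1 <- X + proj$out[wp$inv, , drop = FALSE]

  ln2 <- layernorm_fwd(X1, p$g2, p$b2)
  m1 <- linear_fwd(ln2$out, p$Wm1, p$bm1)
  act <- silu_fwd(m1$out)
  m2 <- linear_fwd(act$out, p$Wm2, p$bm2)
  out <- X1 + m2$out

  list(out = out,
       cache = list(ln1 = ln1, Xw = Xw, QKV = QKV, A_list = A_list,
                    O = O, proj = proj, X1 = X1, ln2 = ln2, m1 = m1,
                    act = act, m2 = m2, wp = wp, M = M, nwin = nwin,
                    heads = heads, dh = dh, scl = scl, C = C))
}

attn_bwd <- function(dOut, p, cache) {
  C <- cache$C
  g <- list()

  # MLP branch
  b2 <- linear_bwd(dOut, p$Wm2, cache$m2)
  g$Wm2 <- b2$dW; g$bm2 <- b2$db
  dact <- silu_bwd(b2$dX, cache$act)
  b1 <- linear_bwd(dact, p$Wm1, cache$m1)
  g$Wm1 <- b1$dW; g$bm1 <- b1$db
  ln2b <- layernorm_bwd(b1$dX, p$g2, cache$ln2)
  g$g2 <- ln2b$dg; g$b2 <- ln2b$db
  dX1 <- dOut + ln2b$dX

  # attention branch
  dProjOut <- dX1[cache$wp$perm, , drop = FALSE]
  pb <- linear_bwd(dProjOut, p$Wproj, cache$proj)
  g$Wproj <- pb$dW; g$bproj <- pb$db
  dO <- pb$dX
  QKV <- cache$QKV
  dQKV <- matrix(0, nrow(dO), 3L * C)
  M <- cache$M; heads <- cache$heads; dh <- cache$dh; scl <- cache$scl
  for (w in seq_len(cache$nwin)) {
    r <- ((w - 1L) * M + 1L):(w * M)
    for (h in seq_len(heads)) {
      cq <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$A_list[[(w - 1L) * heads + h]]
      Q <- QKV[r, cq, drop = FALSE]
      K <- QKV[r, C + cq, drop = FALSE]
      V <- QKV[r, 2L * C + cq, drop = FALSE]
      dOh <- dO[r, cq, drop = FALSE]
      dA <- tcrossprod(dOh, V)
      dV <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ <- (dS %*% K) * scl
      dK <- crossprod(dS, Q) * scl
      dQKV[r, cq] <- dQ
      dQKV[r, C + cq] <- dK
      dQKV[r, 2L * C + cq] <- dV
    }
  }
  g$Wqkv <- crossprod(cache$Xw, dQKV)
  dXw <- dQKV %*% t(p$Wqkv)
  dLn1 <- dXw[cache$wp$inv, , drop = FALSE]
  ln1b <- layernorm_bwd(dLn1, p$g1, cache$ln1)
  g$g1 <- ln1b$dg; g$b1 <- ln1b$db

  list(dX = dX1 + ln1b$dX, grads = g)
}

## ---- parameter initialisation ----------------------------------------

init_conv <- function(Cin, Cout, gain = 1) {
  sd <- gain * sqrt(2 / (9 * Cin))
  list(W = matrix(stats::rnorm(9 * Cin * Cout, sd = sd), 9 * Cin, Cout),
       b = numeric(Cout))
}
init_linear <- function(Cin, Cout, gain = 1) {
  sd <- gain * sqrt(2 / Cin)
  list(W = matrix(stats::rnorm(Cin * Cout, sd = sd), Cin, Cout),
       b = numeric(Cout))
}
init_attn <- function(C, mlp_ratio = 4) {
  qkv <- init_linear(C, 3L * C)
  proj <- init_linear(C, C, gain = 0.5)
  m1 <- init_linear(C, mlp_ratio * C)
  m2 <- init_linear(mlp_ratio * C, C, gain = 0.5)
  # no qkv bias: a K bias is softmax-invariant and a V bias is absorbed
  # exactly by the projection bias, so only Q would ever use one
  list(g1 = rep(1, C), b1 = numeric(C),
       Wqkv = qkv$W, Wproj = proj$W, bproj = proj$b,
       g2 = rep(1, C), b2 = numeric(C),
       Wm1 = m1$W, bm1 = m1$b, Wm2 = m2$W, bm2 = m2$b)
}

## ---- flatten/unflatten parameter trees (for Adam and grad checks) ----

flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- if (prefix == "") nm else paste(prefix, nm, sep = ".")
    if (is.list(p[[nm]])) out <- c(out, flatten_params(p[[nm]], key))
    else out[[key]] <- p[[nm]]
  }
  out
}

assign_flat <- function(p, flat) {
  for (key in names(flat)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    p[[path]] <- flat[[key]]
  }
  p
}

## ---- Adam optimizer ---------------------------------------------------

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       step = 0L)
}

adam_update <- function(flat, grads, state, lr = 1e-3,
                        beta1 = 0.9, beta2 = 0.99, eps = 1e-8) {
  state$step <- state$step + 1L
  t <- state$step
  for (k in names(flat)) {
    gk <- grads[[k]]
    if (is.null(gk)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gk
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gk^2
    mhat <- state$m[[k]] / (1 - beta1^t)
    vhat <- state$v[[k]] / (1 - beta2^t)
    flat[[k]] <- flat[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}
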