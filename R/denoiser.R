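#' Denoiser architecture specification
#'
#' A U-shaped encoder/decoder over \code{depth} resolution levels with
#' channel widths \code{base_channels * 2^(level-1)}. Each level holds a
#' residual convolution block modulated by the noise-level embedding
#' (FiLM); the two lowest-resolution levels additionally carry a pair of
#' windowed self-attention blocks (an unshifted and a cyclically shifted
#' window partition), the places where attention conventionally sits in
#' diffusion U-nets. The network takes the noisy state \eqn{x_t} and the
#' corrupted image \eqn{y} as a 2-channel stack plus a continuous noise
#' level, and predicts the clean image \eqn{\hat x} directly
#' (x0-prediction), parameterised as \eqn{y} plus a learned correction.
#'
#' Two presets are shipped: \code{"tiny"} (base 16, depth 3, window 4 —
#' under one million parameters, the test and desk-scale default) and
#' \code{"paper"} (base 64, depth 4, window 8), a conventional full-scale
#' profile.
#'
#' @param base_channels Channels at the top resolution.
#' @param depth Number of resolution levels (input edge must be
#'   divisible by \code{2^(depth-1)}).
#' @param swin_window Attention window edge in pixels.
#' @param n_heads Attention heads (must divide the channel width at the
#'   attention levels).
#' @param time_embed_dim Width of the noise-level embedding.
#' @param preset \code{"tiny"} or \code{"paper"}; when given, overrides
#'   the other arguments.
#' @return An object of class \code{"rs_denoiser_spec"}.
#' @export
#' @examples
#' denoiser_spec("tiny")$base_channels
denoiser_spec <- function(preset = NULL, base_channels = 16L, depth = 3L,
                          swin_window = 4L, n_heads = 2L,
                          time_embed_dim = 64L) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("tiny", "paper"))
    if (preset == "tiny") {
      base_channels <- 16L; depth <- 3L; swin_window <- 4L
      n_heads <- 2L; time_embed_dim <- 64L
    } else {
      base_channels <- 64L; depth <- 4L; swin_window <- 8L
      n_heads <- 4L; time_embed_dim <- 256L
    }
  }
  spec <- list(base_channels = as.integer(base_channels),
               depth = as.integer(depth),
               swin_window = as.integer(swin_window),
               n_heads = as.integer(n_heads),
               time_embed_dim = as.integer(time_embed_dim),
               preset = preset %||% "custom")
  if (spec$depth < 2L) stop("`depth` must be >= 2", call. = FALSE)
  if (spec$time_embed_dim %% 2L != 0L)
    stop("`time_embed_dim` must be even", call. = FALSE)
  ch <- spec$base_channels * 2L^(seq_len(spec$depth) - 1L)
  if (any(ch[attn_levels(spec)] %% spec$n_heads != 0L))
    stop("`n_heads` must divide the attention-level channel widths",
         call. = FALSE)
  structure(spec, class = "rs_denoiser_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

attn_levels <- function(spec) c(spec$depth - 1L, spec$depth)

channels_at <- function(spec, l) spec$base_channels * 2L^(l - 1L)

#' Build a denoiser model with randomly initialised weights
#'
#' @param spec An \code{\link{denoiser_spec}}.
#' @param seed Integer seed for weight initialisation.
#' @return An object of class \code{"rs_denoiser"} holding the parameter
#'   tree and the spec.
#' @export
build_denoiser <- function(spec = denoiser_spec("tiny"), seed = 1L) {
  stopifnot(inherits(spec, "rs_denoiser_spec"))
  withr::local_seed(as.integer(seed))
  Dt <- spec$time_embed_dim
  al <- attn_levels(spec)

  res_params <- function(Cin, Cout) {
    list(conv1 = init_conv(Cin, Cout),
         film = init_linear(Dt, 2L * Cout, gain = 0.1),
         conv2 = init_conv(Cout, Cout, gain = 0.5),
         skip = if (Cin != Cout) init_linear(Cin, Cout) else NULL)
  }

  p <- list(
    temb = list(l1 = init_linear(Dt, Dt), l2 = init_linear(Dt, Dt)),
    stem = init_conv(2L, channels_at(spec, 1L))
  )
  for (l in seq_len(spec$depth)) {
    C <- channels_at(spec, l)
    blk <- list(res = res_params(C, C))
    if (l %in% al) {
      blk$attn1 <- init_attn(C)
      blk$attn2 <- init_attn(C)
    }
    p[[paste0("enc", l)]] <- blk
    if (l < spec$depth)
      p[[paste0("down", l)]] <- init_conv(C, channels_at(spec, l + 1L))
  }
  for (l in rev(seq_len(spec$depth - 1L))) {
    C <- channels_at(spec, l)
    blk <- list(upconv = init_conv(channels_at(spec, l + 1L), C),
                res = res_params(2L * C, C))
    if (l %in% al) {
      blk$attn1 <- init_attn(C)
      blk$attn2 <- init_attn(C)
    }
    p[[paste0("dec", l)]] <- blk
  }
  # small head initialisation: the model starts close to the identity
  # mapping x-hat = y, which the learned correction then refines
  p$head <- init_conv(channels_at(spec, 1L), 1L, gain = 0.02)

  structure(list(spec = spec, params = p), class = "rs_denoiser")
}

#' @export
print.rs_denoiser <- function(x, ...) {
  cat(sprintf(
    "<rs_denoiser> preset %s: base %d, depth %d, window %d, %d heads; %d parameters\n",
    x$spec$preset, x$spec$base_channels, x$spec$depth, x$spec$swin_window,
    x$spec$n_heads, n_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param model An \code{"rs_denoiser"}.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(flatten_params(model$params), length, integer(1)))
}

check_grid <- function(spec, H, W) {
  f <- 2L^(spec$depth - 1L)
  if (H %% f != 0L || W %% f != 0L)
    stop(sprintf("grid edge must be divisible by %d for depth %d",
                 f, spec$depth), call. = FALSE)
  for (l in attn_levels(spec)) {
    hl <- H %/% 2L^(l - 1L); wl <- W %/% 2L^(l - 1L)
    if (hl %% spec$swin_window != 0L || wl %% spec$swin_window != 0L)
      stop(sprintf(
        "grid at level %d (%dx%d) not divisible by window %d",
        l, hl, wl, spec$swin_window), call. = FALSE)
  }
  invisible(TRUE)
}

# sinusoidal embedding of the log-scaled noise level, one row per sample
sinusoidal_embedding <- function(level, dim) {
  half <- dim %/% 2L
  freqs <- exp(seq(0, log(100), length.out = half))
  u <- log(pmax(level, 1e-8))
  ang <- outer(u, freqs)
  cbind(sin(ang), cos(ang))
}

res_fwd <- function(X, p, temb, B, H, W_img, rowsmap) {
  a <- silu_fwd(X)
  c1 <- conv_fwd(a$out, p$conv1$W, p$conv1$b, B, H, W_img)
  fl <- linear_fwd(temb, p$film$W, p$film$b)
  Cout <- ncol(c1$out)
  fm <- film_fwd(c1$out, fl$out[, seq_len(Cout), drop = FALSE],
                 fl$out[, Cout + seq_len(Cout), drop = FALSE], rowsmap)
  a2 <- silu_fwd(fm$out)
  c2 <- conv_fwd(a2$out, p$conv2$W, p$conv2$b, B, H, W_img)
  if (is.null(p$skip)) {
    skip <- X; sk <- NULL
  } else {
    sk <- linear_fwd(X, p$skip$W, p$skip$b)
    skip <- sk$out
  }
  list(out = skip + c2$out,
       cache = list(a = a, c1 = c1, fl = fl, fm = fm, a2 = a2, c2 = c2,
                    sk = sk, Cout = Cout))
}

res_bwd <- function(dOut, p, cache) {
  g <- list()
  c2b <- conv_bwd(dOut, p$conv2$W, cache$c2)
  g$conv2 <- list(W = c2b$dW, b = c2b$db)
  da2 <- silu_bwd(c2b$dX, cache$a2)
  fmb <- film_bwd(da2, cache$fm)
  dfl <- cbind(fmb$dscale, fmb$dshift)
  flb <- linear_bwd(dfl, p$film$W, cache$fl)
  g$film <- list(W = flb$dW, b = flb$db)
  dtemb <- flb$dX
  c1b <- conv_bwd(fmb$dH, p$conv1$W, cache$c1)
  g$conv1 <- list(W = c1b$dW, b = c1b$db)
  da <- silu_bwd(c1b$dX, cache$a)
  if (is.null(cache$sk)) {
    dX <- da + dOut
  } else {
    skb <- linear_bwd(dOut, p$skip$W, cache$sk)
    g$skip <- list(W = skb$dW, b = skb$db)
    dX <- da + skb$dX
  }
  list(dX = dX, grads = g, dtemb = dtemb)
}

attn_pair_fwd <- function(X, blk, B, H, W_img, spec) {
  ws <- spec$swin_window
  a1 <- attn_fwd(X, blk$attn1, B, H, W_img, ws, 0L, spec$n_heads)
  a2 <- attn_fwd(a1$out, blk$attn2, B, H, W_img, ws, ws %/% 2L,
                 spec$n_heads)
  list(out = a2$out, cache = list(a1 = a1$cache, a2 = a2$cache))
}

attn_pair_bwd <- function(dOut, blk, cache) {
  b2 <- attn_bwd(dOut, blk$attn2, cache$a2)
  b1 <- attn_bwd(b2$dX, blk$attn1, cache$a1)
  list(dX = b1$dX, grads = list(attn1 = b1$grads, attn2 = b2$grads))
}

# full forward pass; xt, y are (B*H*W) x 1 column matrices (batch-major
# stacked), level a length-B vector. Returns prediction and cache.
denoiser_forward <- function(model, xt_vec, y_vec, level, B, H, W_img) {
  spec <- model$spec
  p <- model$params
  cache <- list(B = B, H = H, W = W_img)

  emb <- sinusoidal_embedding(level, spec$time_embed_dim)
  t1 <- linear_fwd(emb, p$temb$l1$W, p$temb$l1$b)
  ta <- silu_fwd(t1$out)
  t2 <- linear_fwd(ta$out, p$temb$l2$W, p$temb$l2$b)
  temb <- t2$out
  cache$temb <- list(emb = emb, t1 = t1, ta = ta, t2 = t2)

  X <- cbind(xt_vec, y_vec)
  st <- conv_fwd(X, p$stem$W, p$stem$b, B, H, W_img)
  cache$stem <- st
  h <- st$out

  skips <- list()
  dims <- list()
  for (l in seq_len(spec$depth)) {
    Hl <- H %/% 2L^(l - 1L); Wl <- W_img %/% 2L^(l - 1L)
    dims[[l]] <- c(Hl, Wl)
    rowsmap <- rep(seq_len(B), each = Hl * Wl)
    blk <- p[[paste0("enc", l)]]
    r <- res_fwd(h, blk$res, temb, B, Hl, Wl, rowsmap)
    cache[[paste0("enc", l, ".res")]] <- r$cache
    h <- r$out
    if (!is.null(blk$attn1)) {
      ap <- attn_pair_fwd(h, blk, B, Hl, Wl, spec)
      cache[[paste0("enc", l, ".attn")]] <- ap$cache
      h <- ap$out
    }
    skips[[l]] <- h
    if (l < spec$depth) {
      dn <- conv_fwd(h, p[[paste0("down", l)]]$W, p[[paste0("down", l)]]$b,
                     B, Hl, Wl, stride = 2L)
      cache[[paste0("down", l)]] <- dn
      h <- dn$out
    }
  }

  for (l in rev(seq_len(spec$depth - 1L))) {
    Hl <- dims[[l]][1]; Wl <- dims[[l]][2]
    rowsmap <- rep(seq_len(B), each = Hl * Wl)
    blk <- p[[paste0("dec", l)]]
    up <- upsample_fwd(h, B, Hl %/% 2L, Wl %/% 2L)
    uc <- conv_fwd(up$out, blk$upconv$W, blk$upconv$b, B, Hl, Wl)
    cache[[paste0("dec", l, ".up")]] <- list(up = up, uc = uc)
    h <- cbind(uc$out, skips[[l]])
    r <- res_fwd(h, blk$res, temb, B, Hl, Wl, rowsmap)
    cache[[paste0("dec", l, ".res")]] <- r$cache
    h <- r$out
    if (!is.null(blk$attn1)) {
      ap <- attn_pair_fwd(h, blk, B, Hl, Wl, spec)
      cache[[paste0("dec", l, ".attn")]] <- ap$cache
      h <- ap$out
    }
  }

  hd <- conv_fwd(h, p$head$W, p$head$b, B, H, W_img)
  cache$head <- hd
  list(out = y_vec + hd$out, cache = cache)
}

# full backward pass; dOut is (B*H*W) x 1. Returns nested grads tree.
# The decoder ran l = depth-1, ..., 1 forward, so its backward runs
# l = 1, ..., depth-1: each iteration's upsample-input gradient is the
# output gradient of the next decoder level (or, last, of the encoder
# bottleneck). Skip-connection gradients are stashed and added when the
# encoder backward reaches the matching level.
denoiser_backward <- function(model, cache, dOut) {
  spec <- model$spec
  p <- model$params
  g <- list()
  dtemb_acc <- 0

  hb <- conv_bwd(dOut, p$head$W, cache$head)
  g$head <- list(W = hb$dW, b = hb$db)
  dh <- hb$dX

  dskips <- vector("list", spec$depth)
  for (l in seq_len(spec$depth - 1L)) {
    blk <- p[[paste0("dec", l)]]
    gb <- list()
    if (!is.null(blk$attn1)) {
      ab <- attn_pair_bwd(dh, blk, cache[[paste0("dec", l, ".attn")]])
      gb$attn1 <- ab$grads$attn1; gb$attn2 <- ab$grads$attn2
      dh <- ab$dX
    }
    rb <- res_bwd(dh, blk$res, cache[[paste0("dec", l, ".res")]])
    gb$res <- rb$grads
    dtemb_acc <- dtemb_acc + rb$dtemb
    C <- ncol(rb$dX) %/% 2L
    d_uc <- rb$dX[, seq_len(C), drop = FALSE]
    dskips[[l]] <- rb$dX[, C + seq_len(C), drop = FALSE]
    upc <- cache[[paste0("dec", l, ".up")]]
    ucb <- conv_bwd(d_uc, blk$upconv$W, upc$uc)
    gb$upconv <- list(W = ucb$dW, b = ucb$db)
    dh <- upsample_bwd(ucb$dX, upc$up)
    g[[paste0("dec", l)]] <- gb
  }

  d <- dh # gradient w.r.t. the encoder bottleneck output
  for (l in rev(seq_len(spec$depth))) {
    blk <- p[[paste0("enc", l)]]
    gb <- list()
    if (!is.null(blk$attn1)) {
      ab <- attn_pair_bwd(d, blk, cache[[paste0("enc", l, ".attn")]])
      gb$attn1 <- ab$grads$attn1; gb$attn2 <- ab$grads$attn2
      d <- ab$dX
    }
    rb <- res_bwd(d, blk$res, cache[[paste0("enc", l, ".res")]])
    gb$res <- rb$grads
    dtemb_acc <- dtemb_acc + rb$dtemb
    d <- rb$dX
    g[[paste0("enc", l)]] <- gb
    if (l > 1L) {
      dn <- conv_bwd(d, p[[paste0("down", l - 1L)]]$W,
                     cache[[paste0("down", l - 1L)]])
      g[[paste0("down", l - 1L)]] <- list(W = dn$dW, b = dn$db)
      d <- dn$dX + dskips[[l - 1L]]
    }
  }

  stb <- conv_bwd(d, p$stem$W, cache$stem)
  g$stem <- list(W = stb$dW, b = stb$db)

  tc <- cache$temb
  t2b <- linear_bwd(dtemb_acc, p$temb$l2$W, tc$t2)
  dta <- silu_bwd(t2b$dX, tc$ta)
  t1b <- linear_bwd(dta, p$temb$l1$W, tc$t1)
  g$temb <- list(l1 = list(W = t1b$dW, b = t1b$db),
                 l2 = list(W = t2b$dW, b = t2b$db))
  g
}

#' Evaluate the denoiser
#'
#' Deterministic x0-prediction \eqn{\hat x = f_\theta(x_t, y,
#' \mathrm{level})}. Accepts a single image pair (matrices) and a scalar
#' noise level in (0, 1].
#'
#' @param model An \code{"rs_denoiser"} (or, for oracle testing, any
#'   function \code{f(x_t, y, level)} returning an image).
#' @param x_t Noisy state at the queried step (matrix).
#' @param y Motion-corrupted conditioning image (same dimensions).
#' @param level Continuous noise level \eqn{\sqrt{\beta_t}}.
#' @return Predicted motion-free image, same dimensions.
#' @export
denoise <- function(model, x_t, y, level) {
  if (is.function(model)) return(model(x_t, y, level))
  stopifnot(inherits(model, "rs_denoiser"), all(dim(x_t) == dim(y)))
  H <- nrow(x_t); W_img <- ncol(x_t)
  check_grid(model$spec, H, W_img)
  fw <- denoiser_forward(model, matrix(as.vector(x_t), ncol = 1),
                         matrix(as.vector(y), ncol = 1),
                         level, 1L, H, W_img)
  out <- matrix(fw$out, H, W_img)
  if (!all(is.finite(out)))
    stop("denoiser produced non-finite output", call. = FALSE)
  out
}
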