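# ---------------------------------------------------------------------------
# The registration network: linear patch embedding, pair fusion, shifted-
# window multi-head self-attention block pairs, patch merging, dilated
# convolutional blocks and per-stage affine heads, cascaded over a three-
# level image pyramid. Forward and backward passes are written by hand
# (list-of-arrays parameters, analytic gradients); correctness is pinned by
# finite-difference checks in the test suite.
# ---------------------------------------------------------------------------

#' Token grid container
#'
#' A sequence of feature vectors with its attached 3D grid shape. Token
#' order is array (column-major) order of the grid; `nrow(tokens)` always
#' equals `prod(grid)`.
#'
#' @param tokens numeric matrix, one row per token.
#' @param grid integer triple (h, w, d).
#' @export
token_grid <- function(tokens, grid) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3, nrow(tokens) == prod(grid))
  structure(list(tokens = tokens, grid = grid), class = "token_grid")
}

#' @export
print.token_grid <- function(x, ...) {
  cat(sprintf("token grid %d x %d x %d, width %d\n",
              x$grid[1], x$grid[2], x$grid[3], ncol(x$tokens)))
  invisible(x)
}

#' Stage configuration for the registration network
#'
#' @param preset `"default"` (embed width 64, block pairs 1/2/2 with a patch
#'   merge inside the deeper stages) or `"tiny"` (width 16, one pair per
#'   stage) for CPU-scale experiments.
#' @param C embed width; `pairs` attention block-pair count per stage;
#'   `windows` per-stage window size (patch embedding and attention);
#'   `heads` attention heads; `mlp_ratio` hidden-width multiplier;
#'   `dilations` dilation rates of the two conv layers.
#' @return list of class `stage_config`.
#' @export
stage_config <- function(preset = c("default", "tiny"), C = NULL,
                         pairs = NULL, windows = c(2L, 4L, 8L),
                         heads = 2L, mlp_ratio = 4, dilations = c(1L, 2L)) {
  preset <- match.arg(preset)
  if (is.null(C)) C <- if (preset == "tiny") 16L else 64L
  if (is.null(pairs)) pairs <- if (preset == "tiny") c(1L, 1L, 1L) else c(1L, 2L, 2L)
  if (C %% heads != 0) stop("heads must divide the embed width")
  structure(list(preset = preset, C = as.integer(C), pairs = as.integer(pairs),
                 windows = as.integer(windows), heads = as.integer(heads),
                 mlp_ratio = mlp_ratio, dilations = as.integer(dilations),
                 n_stages = length(windows), shift = as.integer(windows %/% 2)),
            class = "stage_config")
}

# --- primitive layers ------------------------------------------------------

rmat <- function(n, m, sd = 0.02) matrix(stats::rnorm(n * m, sd = sd), n, m)

linear_fwd <- function(x, p) {
  out <- x %*% p$W
  out <- sweep(out, 2, p$b, `+`)
  list(out = out, x = x)
}
linear_bwd <- function(dout, cache, p) {
  list(dx = dout %*% t(p$W),
       dp = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

layernorm_fwd <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(xhat * 1, 2, p$g, `*`)
  out <- sweep(out, 2, p$b, `+`)
  list(out = out, xhat = xhat, inv = inv)
}
layernorm_bwd <- function(dout, cache, p) {
  xhat <- cache$xhat
  dxhat <- sweep(dout, 2, p$g, `*`)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dx = dx, dp = list(g = colSums(dout * xhat), b = colSums(dout)))
}

gelu_fwd <- function(x) x * stats::pnorm(x)
gelu_bwd <- function(dout, x) dout * (stats::pnorm(x) + x * stats::dnorm(x))

mlp_fwd <- function(x, p) {
  l1 <- linear_fwd(x, list(W = p$W1, b = p$b1))
  a <- gelu_fwd(l1$out)
  l2 <- linear_fwd(a, list(W = p$W2, b = p$b2))
  list(out = l2$out, l1 = l1, a_in = l1$out, l2 = l2)
}
mlp_bwd <- function(dout, cache, p) {
  b2 <- linear_bwd(dout, cache$l2, list(W = p$W2, b = p$b2))
  da <- gelu_bwd(b2$dx, cache$a_in)
  b1 <- linear_bwd(da, cache$l1, list(W = p$W1, b = p$b1))
  list(dx = b1$dx, dp = list(W1 = b1$dp$W, b1 = b1$dp$b,
                             W2 = b2$dp$W, b2 = b2$dp$b))
}

# BatchNorm over tokens (batch-size-1 regime: statistics are taken over the
# spatial positions of the single volume). `use_batch` selects per-sample
# vs running statistics; running stats are updated via the returned `stats`
# field only when `update_running`.
batchnorm_fwd <- function(x, p, use_batch = TRUE, momentum = 0.1,
                          eps = 1e-5, update_running = use_batch) {
  if (use_batch) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colMeans(xc^2)
    inv <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, inv, `*`)
    if (update_running) {
      new_rm <- (1 - momentum) * p$rm + momentum * mu
      new_rv <- (1 - momentum) * p$rv + momentum * v * nrow(x) / max(nrow(x) - 1, 1)
    } else { new_rm <- p$rm; new_rv <- p$rv }
  } else {
    inv <- 1 / sqrt(p$rv + eps)
    xhat <- sweep(sweep(x, 2, p$rm), 2, inv, `*`)
    new_rm <- p$rm; new_rv <- p$rv
  }
  out <- sweep(sweep(xhat, 2, p$g, `*`), 2, p$b, `+`)
  list(out = out, xhat = xhat, inv = inv,
       stats = list(rm = new_rm, rv = new_rv))
}
batchnorm_bwd <- function(dout, cache, p) {
  xhat <- cache$xhat
  dxhat <- sweep(dout, 2, p$g, `*`)
  n <- nrow(dout)
  dx <- sweep(dxhat - rep(colMeans(dxhat), each = n) -
                xhat * rep(colMeans(dxhat * xhat), each = n),
              2, cache$inv, `*`)
  list(dx = dx, dp = list(g = colSums(dout * xhat), b = colSums(dout)))
}

# --- window attention plans ------------------------------------------------

.plan_cache <- new.env(parent = emptyenv())

# everything index-related for one (grid, window, shifted) combination
attention_plan <- function(grid, win, shifted) {
  key <- paste(c(grid, win, as.integer(shifted)), collapse = "_")
  if (!is.null(.plan_cache[[key]])) return(.plan_cache[[key]])
  gp <- as.integer(ceiling(grid / win) * win)      # padded grid
  npad <- prod(gp)
  # positions of original tokens inside the padded grid (1-based linear)
  gx <- seq_len(grid[1]) - 1L
  gy <- seq_len(grid[2]) - 1L
  gz <- seq_len(grid[3]) - 1L
  pad_pos <- 1L + rep(gx, times = grid[2] * grid[3]) +
    gp[1] * (rep(rep(gy, each = grid[1]), times = grid[3]) +
               gp[2] * rep(gz, each = grid[1] * grid[2]))
  # coordinates of padded-grid tokens
  x <- (seq_len(npad) - 1L) %% gp[1]
  y <- ((seq_len(npad) - 1L) %/% gp[1]) %% gp[2]
  z <- (seq_len(npad) - 1L) %/% (gp[1] * gp[2])
  s <- if (shifted) win %/% 2L else 0L
  # cyclic roll: shifted token i takes the value of source index shift_src[i]
  if (s > 0) {
    xs <- (x + s) %% gp[1]; ys <- (y + s) %% gp[2]; zs <- (z + s) %% gp[3]
    shift_src <- 1L + xs + gp[1] * (ys + gp[2] * zs)
  } else shift_src <- seq_len(npad)
  # window partition on the (shifted) grid
  wx <- x %/% win; ox <- x %% win
  wy <- y %/% win; oy <- y %% win
  wz <- z %/% win; oz <- z %% win
  nw <- gp %/% win
  Tn <- win^3
  wid <- wx + nw[1] * (wy + nw[2] * wz)
  off <- ox + win * (oy + win * oz)
  perm <- order(wid * Tn + off)
  nW <- prod(nw)
  # relative-position index (within-window, same ordering for all windows)
  po <- cbind(ox, oy, oz)[perm[seq_len(Tn)], , drop = FALSE]
  rel <- function(a) outer(po[, a], po[, a], `-`) + win - 1L
  rel_idx <- matrix(1L + rel(1) + (2L * win - 1L) *
                      (rel(2) + (2L * win - 1L) * rel(3)), Tn, Tn)
  # masks for shifted windows: region labels rolled with the features
  masks <- NULL
  if (s > 0) {
    seg <- function(v, n) ifelse(v < n - win, 0L, ifelse(v < n - s, 1L, 2L))
    lab <- seg(x, gp[1]) + 3L * seg(y, gp[2]) + 9L * seg(z, gp[3])
    lab <- lab[shift_src]
    lab <- lab[perm]
    masks <- vector("list", nW)
    for (k in seq_len(nW)) {
      ids <- lab[((k - 1L) * Tn + 1L):(k * Tn)]
      masks[[k]] <- outer(ids, ids, `!=`)
    }
  }
  plan <- list(grid = grid, gp = gp, npad = npad, pad_pos = pad_pos,
               shift_src = shift_src, perm = perm, iperm = order(perm),
               ishift = order(shift_src), nW = nW, Tn = Tn,
               rel_idx = rel_idx, masks = masks, win = win)
  .plan_cache[[key]] <- plan
  plan
}

# --- windowed multi-head self-attention ------------------------------------

#' Windowed (shifted) multi-head self-attention
#'
#' Per-window scaled dot-product attention with a learned relative position
#' bias indexed by 3D token offsets; in shifted mode the token grid is
#' cyclically rolled by half a window per axis with cross-boundary attention
#' masked, then rolled back. The grid is zero-padded on the high side to a
#' window multiple.
#'
#' @param tg `token_grid`.
#' @param p parameter list (`Wqkv`, `bqkv`, `Wo`, `bo`, `bias` with one row
#'   per head and one column per relative offset).
#' @param window window size; `heads` must divide the token width.
#' @param shifted logical.
#' @return `token_grid` of identical shape.
#' @export
window_attention <- function(tg, p, window, heads = 2L, shifted = FALSE) {
  window_attention_fwd(tg, p, window, heads, shifted)$out
}

window_attention_fwd <- function(tg, p, window, heads, shifted) {
  C <- ncol(tg$tokens)
  if (C %% heads != 0) stop("heads must divide the token width")
  Dh <- C %/% heads
  plan <- attention_plan(tg$grid, window, shifted)
  xp <- matrix(0, plan$npad, C)
  xp[plan$pad_pos, ] <- tg$tokens
  xp <- xp[plan$shift_src, , drop = FALSE]
  xw <- xp[plan$perm, , drop = FALSE]
  qkv <- sweep(xw %*% p$Wqkv, 2, p$bqkv, `+`)
  Tn <- plan$Tn
  out <- matrix(0, plan$npad, C)
  wcache <- vector("list", plan$nW)
  scale <- 1 / sqrt(Dh)
  for (k in seq_len(plan$nW)) {
    rows <- ((k - 1L) * Tn + 1L):(k * Tn)
    hc <- vector("list", heads)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * Dh + 1L):(h * Dh)
      Q <- qkv[rows, cols, drop = FALSE]
      K <- qkv[rows, C + cols, drop = FALSE]
      V <- qkv[rows, 2L * C + cols, drop = FALSE]
      sc <- tcrossprod(Q, K) * scale +
        matrix(p$bias[h, plan$rel_idx], Tn, Tn)
      if (!is.null(plan$masks)) sc[plan$masks[[k]]] <- -1e9
      sc <- sc - apply(sc, 1, max)
      e <- exp(sc)
      P <- e / rowSums(e)
      out[rows, cols] <- P %*% V
      hc[[h]] <- list(Q = Q, K = K, V = V, P = P)
    }
    wcache[[k]] <- hc
  }
  proj <- sweep(out %*% p$Wo, 2, p$bo, `+`)
  # undo windowing, shift and padding
  res <- proj[plan$iperm, , drop = FALSE]
  res <- res[plan$ishift, , drop = FALSE]
  res <- res[plan$pad_pos, , drop = FALSE]
  list(out = token_grid(res, tg$grid),
       plan = plan, xw = xw, attn_in = out, wcache = wcache,
       heads = heads, Dh = Dh, C = C)
}

window_attention_bwd <- function(dout, cache, p) {
  plan <- cache$plan
  C <- cache$C; Dh <- cache$Dh; heads <- cache$heads
  Tn <- plan$Tn
  dres <- matrix(0, plan$npad, C)
  dres[plan$pad_pos, ] <- dout
  dres <- dres[order(plan$ishift), , drop = FALSE]   # redo shift
  dres <- dres[order(plan$iperm), , drop = FALSE]    # back to window order
  dWo <- crossprod(cache$attn_in, dres)
  dbo <- colSums(dres)
  dattn <- dres %*% t(p$Wo)
  dqkv <- matrix(0, plan$npad, 3L * C)
  dbias <- matrix(0, nrow(p$bias), ncol(p$bias))
  scale <- 1 / sqrt(Dh)
  for (k in seq_len(plan$nW)) {
    rows <- ((k - 1L) * Tn + 1L):(k * Tn)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * Dh + 1L):(h * Dh)
      cc <- cache$wcache[[k]][[h]]
      dO <- dattn[rows, cols, drop = FALSE]
      dP <- tcrossprod(dO, cc$V)
      dV <- crossprod(cc$P, dO)
      dS <- cc$P * (dP - rowSums(dP * cc$P))
      if (!is.null(plan$masks)) dS[plan$masks[[k]]] <- 0
      dbias[h, ] <- dbias[h, ] +
        as.vector(Matrix::sparseMatrix(i = as.vector(plan$rel_idx),
                                       j = rep(1L, Tn * Tn),
                                       x = as.vector(dS),
                                       dims = c(ncol(p$bias), 1L)))
      dQ <- (dS %*% cc$K) * scale
      dK <- crossprod(dS, cc$Q) * scale
      dqkv[rows, cols] <- dQ
      dqkv[rows, C + cols] <- dK
      dqkv[rows, 2L * C + cols] <- dV
    }
  }
  dWqkv <- crossprod(cache$xw, dqkv)
  dbqkv <- colSums(dqkv)
  dxw <- dqkv %*% t(p$Wqkv)
  dxp <- dxw[plan$iperm, , drop = FALSE]
  dxp <- dxp[plan$ishift, , drop = FALSE]
  dx <- dxp[plan$pad_pos, , drop = FALSE]
  list(dx = dx, dp = list(Wqkv = dWqkv, bqkv = dbqkv, Wo = dWo, bo = dbo,
                          bias = dbias))
}

# --- Swin block pair -------------------------------------------------------

#' One regular + shifted attention block pair
#'
#' Four residual sub-steps in order: LN -> W-MSA -> add, LN -> MLP -> add,
#' LN -> SW-MSA -> add, LN -> MLP -> add. Zeroing all sub-module weights
#' reduces the pair to the identity map (pure residual path).
#'
#' @param tg `token_grid`; `p` the pair's parameter list; `window`,
#'   `heads` as in [window_attention()].
#' @return `token_grid`.
#' @export
swin_block_pair <- function(tg, p, window, heads = 2L) {
  swin_block_pair_fwd(tg, p, window, heads)$out
}

swin_block_pair_fwd <- function(tg, p, window, heads) {
  g <- tg$grid
  ln1 <- layernorm_fwd(tg$tokens, p$ln1)
  at1 <- window_attention_fwd(token_grid(ln1$out, g), p$attn1, window,
                              heads, shifted = FALSE)
  x1 <- tg$tokens + at1$out$tokens
  ln2 <- layernorm_fwd(x1, p$ln2)
  m1 <- mlp_fwd(ln2$out, p$mlp1)
  x2 <- x1 + m1$out
  ln3 <- layernorm_fwd(x2, p$ln3)
  at2 <- window_attention_fwd(token_grid(ln3$out, g), p$attn2, window,
                              heads, shifted = TRUE)
  x3 <- x2 + at2$out$tokens
  ln4 <- layernorm_fwd(x3, p$ln4)
  m2 <- mlp_fwd(ln4$out, p$mlp2)
  list(out = token_grid(x3 + m2$out, g),
       ln1 = ln1, at1 = at1, ln2 = ln2, m1 = m1,
       ln3 = ln3, at2 = at2, ln4 = ln4, m2 = m2)
}

swin_block_pair_bwd <- function(dout, cache, p) {
  dm2 <- mlp_bwd(dout, cache$m2, p$mlp2)
  dln4 <- layernorm_bwd(dm2$dx, cache$ln4, p$ln4)
  dx3 <- dout + dln4$dx
  dat2 <- window_attention_bwd(dx3, cache$at2, p$attn2)
  dln3 <- layernorm_bwd(dat2$dx, cache$ln3, p$ln3)
  dx2 <- dx3 + dln3$dx
  dm1 <- mlp_bwd(dx2, cache$m1, p$mlp1)
  dln2 <- layernorm_bwd(dm1$dx, cache$ln2, p$ln2)
  dx1 <- dx2 + dln2$dx
  dat1 <- window_attention_bwd(dx1, cache$at1, p$attn1)
  dln1 <- layernorm_bwd(dat1$dx, cache$ln1, p$ln1)
  list(dx = dx1 + dln1$dx,
       dp = list(ln1 = dln1$dp, attn1 = dat1$dp, ln2 = dln2$dp,
                 mlp1 = dm1$dp, ln3 = dln3$dp, attn2 = dat2$dp,
                 ln4 = dln4$dp, mlp2 = dm2$dp))
}

# --- patch embedding / fusion / merging ------------------------------------

# linear indices (with 0 for implicit zero padding) of the win^3 voxels of
# each patch; volume zero-padded on the high side to a window multiple
patch_plan <- function(shape, win) {
  key <- paste(c("pe", shape, win), collapse = "_")
  if (!is.null(.plan_cache[[key]])) return(.plan_cache[[key]])
  g <- as.integer(ceiling(shape / win))
  tok <- expand.grid(x = seq_len(g[1]) - 1L, y = seq_len(g[2]) - 1L,
                     z = seq_len(g[3]) - 1L)
  offs <- expand.grid(ox = seq_len(win) - 1L, oy = seq_len(win) - 1L,
                      oz = seq_len(win) - 1L)
  n <- nrow(tok)
  idx <- matrix(0L, n, win^3)
  for (j in seq_len(win^3)) {
    vx <- tok$x * win + offs$ox[j]
    vy <- tok$y * win + offs$oy[j]
    vz <- tok$z * win + offs$oz[j]
    ok <- vx < shape[1] & vy < shape[2] & vz < shape[3]
    idx[, j] <- ifelse(ok, 1L + vx + shape[1] * (vy + shape[2] * vz), 0L)
  }
  plan <- list(grid = g, idx = idx)
  .plan_cache[[key]] <- plan
  plan
}

#' Linear patch embedding of a volume
#'
#' Flattens non-overlapping `window^3` patches of a single-channel volume
#' (vector length 8, 64 or 512 for the three stage windows) and maps them to
#' width-`C` tokens with a learned linear layer. The volume is zero-padded
#' on the high side to a window multiple.
#'
#' @param vol 3D array; `p` list with `W` (`window^3 x C`) and `b`.
#' @param window patch/window size.
#' @return `token_grid` with grid `ceiling(dim(vol) / window)`.
#' @export
patch_embed <- function(vol, p, window) {
  plan <- patch_plan(dim(vol), window)
  v0 <- c(0, as.vector(vol))
  patches <- matrix(v0[plan$idx + 1L], nrow(plan$idx), ncol(plan$idx))
  token_grid(sweep(patches %*% p$W, 2, p$b, `+`), plan$grid)
}

# forward keeping the patch matrix for the weight gradient
patch_embed_fwd <- function(vol, p, window) {
  plan <- patch_plan(dim(vol), window)
  v0 <- c(0, as.vector(vol))
  patches <- matrix(v0[plan$idx + 1L], nrow(plan$idx), ncol(plan$idx))
  list(out = token_grid(sweep(patches %*% p$W, 2, p$b, `+`), plan$grid),
       patches = patches)
}
patch_embed_bwd <- function(dout, cache) {
  list(dp = list(W = crossprod(cache$patches, dout), b = colSums(dout)))
}

#' Fuse the fixed-image and moving-image token grids
#'
#' Feature-wise concatenation (width 2C) followed by a learned linear map
#' back to width C. Swapping the two inputs changes the output unless the
#' weights happen to be symmetric.
#'
#' @param tf,tm `token_grid`s of identical shape and width.
#' @param p list with `W` (`2C x C`) and `b`.
#' @return fused `token_grid`.
#' @export
fuse_pair <- function(tf, tm, p) {
  if (!all(tf$grid == tm$grid) || ncol(tf$tokens) != ncol(tm$tokens))
    stop("token grids to fuse must match in shape and width")
  token_grid(sweep(cbind(tf$tokens, tm$tokens) %*% p$W, 2, p$b, `+`),
             tf$grid)
}
fuse_pair_fwd <- function(tf, tm, p) {
  xcat <- cbind(tf$tokens, tm$tokens)
  list(out = token_grid(sweep(xcat %*% p$W, 2, p$b, `+`), tf$grid),
       xcat = xcat)
}
fuse_pair_bwd <- function(dout, cache) {
  list(dp = list(W = crossprod(cache$xcat, dout), b = colSums(dout)))
}

merge_plan <- function(grid) {
  key <- paste(c("pm", grid), collapse = "_")
  if (!is.null(.plan_cache[[key]])) return(.plan_cache[[key]])
  if (any(grid %% 2L != 0L)) stop("patch merging requires even grid dimensions")
  g2 <- grid %/% 2L
  tok <- expand.grid(x = seq_len(g2[1]) - 1L, y = seq_len(g2[2]) - 1L,
                     z = seq_len(g2[3]) - 1L)
  offs <- expand.grid(ox = 0:1, oy = 0:1, oz = 0:1)
  idx <- matrix(0L, nrow(tok), 8L)
  for (j in 1:8) {
    idx[, j] <- 1L + (tok$x * 2L + offs$ox[j]) +
      grid[1] * ((tok$y * 2L + offs$oy[j]) +
                   grid[2] * (tok$z * 2L + offs$oz[j]))
  }
  plan <- list(grid2 = g2, idx = idx)
  .plan_cache[[key]] <- plan
  plan
}

#' Merge 2x2x2 token neighbourhoods
#'
#' Concatenates the 8 neighbouring tokens of each even-aligned 2x2x2 block
#' (width 8C) and projects to width 2C, halving the grid per axis (token
#' count divides by 8).
#'
#' @param tg `token_grid` with even grid dimensions.
#' @param p list with `W` (`8C x 2C`).
#' @return merged `token_grid`.
#' @export
patch_merge <- function(tg, p) {
  patch_merge_fwd(tg, p)$out
}
patch_merge_fwd <- function(tg, p) {
  plan <- merge_plan(tg$grid)
  C <- ncol(tg$tokens)
  n2 <- nrow(plan$idx)
  gath <- tg$tokens[as.vector(plan$idx), , drop = FALSE]  # (8 n2) x C, j-major
  xcat <- matrix(0, n2, 8L * C)
  for (j in 1:8)
    xcat[, ((j - 1L) * C + 1L):(j * C)] <-
      gath[((j - 1L) * n2 + 1L):(j * n2), , drop = FALSE]
  list(out = token_grid(xcat %*% p$W, plan$grid2),
       xcat = xcat, plan = plan, C = C)
}
patch_merge_bwd <- function(dout, cache, p) {
  plan <- cache$plan; C <- cache$C
  n2 <- nrow(plan$idx)
  dxcat <- dout %*% t(p$W)
  dx <- matrix(0, n2 * 8L, C)
  for (j in 1:8)
    dx[((j - 1L) * n2 + 1L):(j * n2), ] <-
      dxcat[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
  dxs <- rowsum(dx, group = as.vector(plan$idx))
  dtok <- matrix(0, prod(plan$grid2 * 2L), C)
  dtok[as.integer(rownames(dxs)), ] <- dxs
  list(dx = dtok, dp = list(W = crossprod(cache$xcat, dout)))
}

# --- dilated convolutional block -------------------------------------------

conv_plan <- function(grid, dil) {
  key <- paste(c("cv", grid, dil), collapse = "_")
  if (!is.null(.plan_cache[[key]])) return(.plan_cache[[key]])
  tok <- expand.grid(x = seq_len(grid[1]) - 1L, y = seq_len(grid[2]) - 1L,
                     z = seq_len(grid[3]) - 1L)
  offs <- expand.grid(ox = c(-dil, 0L, dil), oy = c(-dil, 0L, dil),
                      oz = c(-dil, 0L, dil))
  idx <- matrix(0L, nrow(tok), 27L)
  for (j in 1:27) {
    vx <- tok$x + offs$ox[j]; vy <- tok$y + offs$oy[j]; vz <- tok$z + offs$oz[j]
    ok <- vx >= 0L & vx < grid[1] & vy >= 0L & vy < grid[2] &
      vz >= 0L & vz < grid[3]
    idx[, j] <- ifelse(ok, 1L + vx + grid[1] * (vy + grid[2] * vz), 0L)
  }
  .plan_cache[[key]] <- idx
  idx
}

# im2col over the token grid (27-tap kernel with dilation), zero padding
im2col_tokens <- function(x, grid, dil) {
  idx <- conv_plan(grid, dil)
  C <- ncol(x)
  n <- nrow(x)
  xp <- rbind(0, x)
  gath <- xp[as.vector(idx) + 1L, , drop = FALSE]   # (27 n) x C, j-major
  xb <- matrix(0, n, 27L * C)
  for (j in 1:27)
    xb[, ((j - 1L) * C + 1L):(j * C)] <-
      gath[((j - 1L) * n + 1L):(j * n), , drop = FALSE]
  xb
}
im2col_tokens_bwd <- function(dxb, grid, dil, C) {
  idx <- conv_plan(grid, dil)
  n <- nrow(dxb)
  dg <- matrix(0, 27L * n, C)
  for (j in 1:27)
    dg[((j - 1L) * n + 1L):(j * n), ] <-
      dxb[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
  sums <- rowsum(dg, group = as.vector(idx))
  dx <- matrix(0, n + 1L, C)
  dx[as.integer(rownames(sums)) + 1L, ] <- sums
  dx[-1L, , drop = FALSE]
}

#' Dilated convolutional block over a token grid
#'
#' Reshapes the tokens to a spatial feature map and applies two 3x3x3
#' convolutions (dilation 1 then 2) each followed by BatchNorm and ReLU,
#' then reshapes back. Symmetric zero padding preserves the spatial shape;
#' the stacked dilations give an effective receptive field of 7 voxels per
#' axis.
#'
#' @param tg `token_grid`; `p` parameter list; `training` updates BatchNorm
#'   running statistics; `bn_mode` chooses per-sample (`"instance"`, the
#'   default — statistics over the spatial positions of the one volume being
#'   processed, identical at training and inference) or stored running
#'   statistics (`"running"`).
#' @return `token_grid` with the same grid and width.
#' @export
dilated_conv_block <- function(tg, p, training = FALSE,
                               bn_mode = c("instance", "running")) {
  dilated_conv_block_fwd(tg, p, training, bn_mode = match.arg(bn_mode))$out
}

dilated_conv_block_fwd <- function(tg, p, training = FALSE,
                                   dilations = c(1L, 2L),
                                   bn_mode = "instance") {
  g <- tg$grid
  C <- ncol(tg$tokens)
  use_batch <- training || bn_mode == "instance"
  xb1 <- im2col_tokens(tg$tokens, g, dilations[1])
  c1 <- sweep(xb1 %*% p$W1, 2, p$b1, `+`)
  bn1 <- batchnorm_fwd(c1, p$bn1, use_batch, update_running = training)
  r1 <- pmax(bn1$out, 0)
  xb2 <- im2col_tokens(r1, g, dilations[2])
  c2 <- sweep(xb2 %*% p$W2, 2, p$b2, `+`)
  bn2 <- batchnorm_fwd(c2, p$bn2, use_batch, update_running = training)
  r2 <- pmax(bn2$out, 0)
  list(out = token_grid(r2, g), xb1 = xb1, bn1 = bn1, r1 = r1,
       xb2 = xb2, bn2 = bn2, r2 = r2, C = C, g = g, dilations = dilations)
}

dilated_conv_block_bwd <- function(dout, cache, p) {
  g <- cache$g; C <- cache$C
  d2 <- dout * (cache$r2 > 0)
  dbn2 <- batchnorm_bwd(d2, cache$bn2, p$bn2)
  dW2 <- crossprod(cache$xb2, dbn2$dx)
  db2 <- colSums(dbn2$dx)
  dxb2 <- dbn2$dx %*% t(p$W2)
  dr1 <- im2col_tokens_bwd(dxb2, g, cache$dilations[2], C)
  d1 <- dr1 * (cache$r1 > 0)
  dbn1 <- batchnorm_bwd(d1, cache$bn1, p$bn1)
  dW1 <- crossprod(cache$xb1, dbn1$dx)
  db1 <- colSums(dbn1$dx)
  dxb1 <- dbn1$dx %*% t(p$W1)
  dx <- im2col_tokens_bwd(dxb1, g, cache$dilations[1], C)
  list(dx = dx, dp = list(W1 = dW1, b1 = db1, bn1 = dbn1$dp,
                          W2 = dW2, b2 = db2, bn2 = dbn2$dp))
}

# --- affine head -----------------------------------------------------------

#' Affine parameter head
#'
#' Mean over tokens, then two linear layers with a tanh in between,
#' producing the raw (unconstrained) 12-vector. The final layer is
#' zero-initialized so an untrained network emits the identity transform.
#'
#' @param tg `token_grid`; `p` parameter list (`W1`, `b1`, `W2`, `b2`).
#' @return numeric 12-vector.
#' @export
affine_head <- function(tg, p) {
  affine_head_fwd(tg, p)$raw
}
affine_head_fwd <- function(tg, p) {
  m <- colMeans(tg$tokens)
  pre <- as.vector(m %*% p$W1) + p$b1
  hsig <- tanh(pre)
  raw <- as.vector(hsig %*% p$W2) + p$b2
  list(raw = raw, m = m, hsig = hsig, n = nrow(tg$tokens))
}
affine_head_bwd <- function(draw, cache, p) {
  dW2 <- outer(cache$hsig, draw)
  db2 <- draw
  dh <- as.vector(p$W2 %*% draw) * (1 - cache$hsig^2)
  dW1 <- outer(cache$m, dh)
  db1 <- dh
  dm <- as.vector(p$W1 %*% dh)
  dx <- matrix(dm / cache$n, cache$n, length(dm), byrow = TRUE)
  list(dx = dx, dp = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# --- model construction ----------------------------------------------------

#' Initialize the registration network
#'
#' @param config `stage_config`.
#' @param seed integer seed for the weight initialization.
#' @return model list (`config` plus per-stage parameter lists).
#' @export
init_network <- function(config = stage_config("default"), seed = 1L) {
  set.seed(seed)
  C <- config$C
  heads <- config$heads
  mk_attn <- function(width, win) list(
    Wqkv = rmat(width, 3L * width), bqkv = numeric(3L * width),
    Wo = rmat(width, width), bo = numeric(width),
    bias = matrix(0, heads, (2L * win - 1L)^3))
  mk_ln <- function(width) list(g = rep(1, width), b = numeric(width))
  mk_mlp <- function(width) {
    hw <- round(width * config$mlp_ratio)
    list(W1 = rmat(width, hw), b1 = numeric(hw),
         W2 = rmat(hw, width), b2 = numeric(width))
  }
  mk_pair <- function(width, win) list(
    ln1 = mk_ln(width), attn1 = mk_attn(width, win), ln2 = mk_ln(width),
    mlp1 = mk_mlp(width), ln3 = mk_ln(width), attn2 = mk_attn(width, win),
    ln4 = mk_ln(width), mlp2 = mk_mlp(width))
  mk_bn <- function(width) list(g = rep(1, width), b = numeric(width),
                                rm = numeric(width), rv = rep(1, width))
  stages <- vector("list", config$n_stages)
  for (i in seq_len(config$n_stages)) {
    win <- config$windows[i]
    npair <- config$pairs[i]
    merge_here <- npair > 1L
    blocks <- vector("list", npair)
    width <- C
    for (b in seq_len(npair)) {
      blocks[[b]] <- mk_pair(width, win)
      if (merge_here && b == 1L) width <- 2L * C
    }
    w_out <- width
    # fusion initialized as difference + context channels: the first half
    # of the output responds to (F - M) token mismatch (zero at perfect
    # alignment, first order in the residual misalignment), the second half
    # to the shared anatomical context; both remain fully trainable
    ch <- C %/% 2L
    Wd <- rmat(C, ch, sd = 0.3)
    Wc <- rmat(C, C - ch, sd = 0.15)
    stages[[i]] <- list(
      embed = list(W = rmat(win^3, C, sd = 0.1), b = numeric(C)),
      fuse = list(W = rbind(cbind(Wd, Wc), cbind(-Wd, Wc)), b = numeric(C)),
      blocks = blocks,
      merge = if (merge_here) list(W = rmat(8L * C, 2L * C)) else NULL,
      conv = list(W1 = rmat(27L * w_out, w_out), b1 = numeric(w_out),
                  bn1 = mk_bn(w_out),
                  W2 = rmat(27L * w_out, w_out), b2 = numeric(w_out),
                  bn2 = mk_bn(w_out)),
      head = list(W1 = rmat(w_out, w_out, sd = 0.05),
                  b1 = numeric(w_out),
                  # near-zero output layer: the untrained cascade starts at
                  # (almost) the identity transform but gradient still
                  # reaches the layers below from the first step
                  W2 = rmat(w_out, 12L, sd = 0.01), b2 = numeric(12L)))
  }
  list(config = config, stages = stages)
}

#' Build a trilinear image pyramid
#'
#' Level `i` of `levels` has scale `0.5^(levels - i)`; the last level is the
#' input itself.
#'
#' @param vol 3D array; `levels` pyramid depth (>= 1).
#' @return list of volumes, coarse to fine.
#' @export
build_pyramid <- function(vol, levels = 3L) {
  stopifnot(levels >= 1)
  out <- vector("list", levels)
  for (i in seq_len(levels)) {
    sc <- 0.5^(levels - i)
    sh <- pmax(2L, as.integer(round(dim(vol) * sc)))
    out[[i]] <- if (i == levels) vol else resize_volume(vol, sh)
  }
  out
}

# one stage of the cascade: embed both volumes, fuse, attention blocks
# (with a merge inside deeper stages), dilated conv, head
stage_forward <- function(st, f_lvl, m_lvl, win, config, training = FALSE) {
  ef <- patch_embed_fwd(f_lvl, st$embed, win)
  em <- patch_embed_fwd(m_lvl, st$embed, win)
  fu <- fuse_pair_fwd(ef$out, em$out, st$fuse)
  x <- fu$out
  bcaches <- vector("list", length(st$blocks))
  mcache <- NULL
  for (b in seq_along(st$blocks)) {
    bc <- swin_block_pair_fwd(x, st$blocks[[b]], win, config$heads)
    x <- bc$out
    bcaches[[b]] <- bc
    if (!is.null(st$merge) && b == 1L) {
      mcache <- patch_merge_fwd(x, st$merge)
      x <- mcache$out
    }
  }
  cv <- dilated_conv_block_fwd(x, st$conv, training, config$dilations)
  hd <- affine_head_fwd(cv$out, st$head)
  list(raw = hd$raw, ef = ef, em = em, fu = fu, bcaches = bcaches,
       mcache = mcache, cv = cv, hd = hd)
}

stage_backward <- function(draw, cache, st, config) {
  dh <- affine_head_bwd(draw, cache$hd, st$head)
  dc <- dilated_conv_block_bwd(dh$dx, cache$cv, st$conv)
  dx <- dc$dx
  dblocks <- vector("list", length(st$blocks))
  dmerge <- NULL
  for (b in rev(seq_along(st$blocks))) {
    if (!is.null(st$merge) && b == 1L) {
      dm <- patch_merge_bwd(dx, cache$mcache, st$merge)
      dmerge <- dm$dp
      dx <- dm$dx
    }
    bb <- swin_block_pair_bwd(dx, cache$bcaches[[b]], st$blocks[[b]])
    dx <- bb$dx
    dblocks[[b]] <- bb$dp
  }
  dfu <- fuse_pair_bwd(dx, cache$fu)
  C <- config$C
  def <- patch_embed_bwd(dx %*% t(st$fuse$W[seq_len(C), , drop = FALSE]),
                         cache$ef)
  dem <- patch_embed_bwd(dx %*% t(st$fuse$W[C + seq_len(C), , drop = FALSE]),
                         cache$em)
  # shared embedding weights: gradients from both branches add
  demb <- list(W = def$dp$W + dem$dp$W, b = def$dp$b + dem$dp$b)
  list(dp = list(embed = demb, fuse = dfu$dp, blocks = dblocks,
                 merge = dmerge, conv = dc$dp, head = dh$dp))
}

#' Run the full registration cascade
#'
#' Builds the image pyramid for both inputs, optionally folds in a
#' centre-of-mass pre-alignment, and for each stage warps the original
#' moving image by the accumulated transform, downsamples it to the stage
#' level, and estimates a residual transform. The final transform is the
#' accumulation of all stages (the moving image is resampled once).
#'
#' @param model from [init_network()] or [train_network()].
#' @param fixed,moving volumes of identical shape, intensities in `[0, 1]`.
#' @param com_init fold in centre-of-mass pre-alignment (default TRUE).
#' @param training use training-mode BatchNorm statistics and keep caches.
#' @return list with `transform` (`affine_transform`), `stages` (per-stage
#'   raw vector, `geometric_params` and `affine_transform`) and, when
#'   `training = TRUE`, the caches the backward pass needs.
#' @export
network_forward <- function(model, fixed, moving, com_init = TRUE,
                            training = FALSE) {
  if (!all(dim(fixed) == dim(moving)))
    stop("fixed and moving volumes must share a shape")
  cfg <- model$config
  nlev <- cfg$n_stages
  f_pyr <- build_pyramid(fixed, nlev)
  pivot <- normalize_coord(center_of_mass(pmax(moving, 0)), dim(moving))
  acc <- if (com_init) com_align(fixed, moving) else identity_transform()
  init <- acc
  stages <- vector("list", nlev)
  caches <- if (training) vector("list", nlev) else NULL
  mats <- list()
  for (i in seq_len(nlev)) {
    # sample the original moving image directly on the level grid through
    # the accumulated transform (single resample, no interpolation stacking)
    m_lvl <- warp_volume(moving, acc, shape = dim(f_pyr[[i]]))
    sc <- stage_forward(model$stages[[i]], f_pyr[[i]], m_lvl,
                        cfg$windows[i], cfg, training)
    params <- constrain_params(sc$raw)
    a_i <- compose_affine(params, center = pivot)
    stages[[i]] <- list(raw = sc$raw, params = params, transform = a_i)
    mats[[i]] <- a_i
    acc <- affine_transform(acc$mat %*% a_i$mat)
    if (training) caches[[i]] <- sc
  }
  out <- list(transform = acc, stages = stages, init = init, pivot = pivot)
  if (training) out$caches <- caches
  out
}

#' Register a moving volume to a fixed volume
#'
#' Convenience wrapper around [network_forward()] returning the estimated
#' transform, the decomposed parameters of the final matrix and the warped
#' moving image.
#'
#' @inheritParams network_forward
#' @param interpolation interpolation for the returned warped volume.
#' @export
register_pair <- function(model, fixed, moving, com_init = TRUE,
                          interpolation = "trilinear") {
  fw <- network_forward(model, fixed, moving, com_init)
  list(transform = fw$transform,
       stages = fw$stages,
       decomposition = decompose_affine(fw$transform, center = fw$pivot),
       warped = warp_volume(moving, fw$transform, interpolation))
}

#' Decompose an affine matrix into translation, rotation, scale and shear
#'
#' Inverts the ordered composition `T (C R S H C^-1)`: the linear block is
#' factored as rotation times upper-triangular (positive diagonal), giving
#' Euler angles (x-y-z order), scales and shears; the translation is
#' recovered given the pivot `center`.
#'
#' @param a `affine_transform`; `center` pivot in normalized coordinates.
#' @return list with `t`, `r`, `s`, `h` triples.
#' @export
decompose_affine <- function(a, center = c(0, 0, 0)) {
  L <- a$mat[1:3, 1:3]
  qrd <- qr(L)
  Q <- qr.Q(qrd); R <- qr.R(qrd)
  sgn <- sign(diag(R)); sgn[sgn == 0] <- 1
  Q <- Q %*% diag(sgn); R <- diag(sgn) %*% R
  s <- diag(R)
  h <- c(R[1, 2] / s[1], R[1, 3] / s[1], R[2, 3] / s[2])
  rx <- atan2(-Q[2, 3], Q[3, 3])
  ry <- asin(max(-1, min(1, Q[1, 3])))
  rz <- atan2(-Q[1, 2], Q[1, 1])
  t <- a$mat[1:3, 4] - center + L %*% center
  list(t = as.vector(t), r = c(rx, ry, rz), s = s, h = h)
}
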