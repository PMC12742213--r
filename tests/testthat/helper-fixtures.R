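# Shared fixtures, all generated in code.

# smooth volume that is non-constant in every local window (background-free),
# used for closed-form NCC checks
smooth_field <- function(shape, seed = 1) {
  set.seed(seed)
  m <- msaffine:::norm_mesh(shape)
  a <- rnorm(6)
  v <- array(0.5 + 0.2 * sin(3 * m[1, ] + a[1]) * cos(2 * m[2, ] + a[2]) +
               0.15 * sin(2.5 * m[3, ] + a[3]) +
               0.1 * m[1, ] * m[2, ] + 0.05 * m[3, ], shape)
  v + array(rnorm(prod(shape), sd = 0.01), shape)
}

random_inrange_params <- function(seed = 1, mild = FALSE) {
  set.seed(seed)
  f <- if (mild) 0.3 else 0.9
  geometric_params(t = runif(3, -0.5, 0.5) * f,
                   r = runif(3, -pi, pi) * f,
                   s = 1 + runif(3, -0.5, 0.5) * f,
                   h = runif(3, -pi, pi) * f)
}

mat_of <- function(p, center = c(0, 0, 0)) compose_affine(p, center)$mat

# dense reference attention: every token pair scored, window / shift
# structure imposed through explicit masks; mirrors the definition, not the
# batched windowed implementation
dense_attention_oracle <- function(tg, p, win, heads, shifted) {
  g <- tg$grid
  C <- ncol(tg$tokens)
  Dh <- C / heads
  gp <- ceiling(g / win) * win
  np <- prod(gp)
  pos <- cbind((seq_len(np) - 1) %% gp[1],
               ((seq_len(np) - 1) %/% gp[1]) %% gp[2],
               (seq_len(np) - 1) %/% (gp[1] * gp[2]))
  orig_lin <- rep(NA_integer_, np)
  inside <- pos[, 1] < g[1] & pos[, 2] < g[2] & pos[, 3] < g[3]
  orig_lin[inside] <- 1 + pos[inside, 1] + g[1] * (pos[inside, 2] +
                                                     g[2] * pos[inside, 3])
  xp <- matrix(0, np, C)
  xp[inside, ] <- tg$tokens[orig_lin[inside], ]
  s <- if (shifted) win %/% 2 else 0
  src <- 1 + ((pos[, 1] + s) %% gp[1]) +
    gp[1] * (((pos[, 2] + s) %% gp[2]) + gp[2] * ((pos[, 3] + s) %% gp[3]))
  xs <- xp[src, , drop = FALSE]
  wid <- (pos[, 1] %/% win) + (gp[1] %/% win) *
    ((pos[, 2] %/% win) + (gp[2] %/% win) * (pos[, 3] %/% win))
  seg <- function(v, n) ifelse(v < n - win, 0, ifelse(v < n - s, 1, 2))
  src_pos <- cbind((pos[, 1] + s) %% gp[1], (pos[, 2] + s) %% gp[2],
                   (pos[, 3] + s) %% gp[3])
  lab <- seg(src_pos[, 1], gp[1]) + 3 * seg(src_pos[, 2], gp[2]) +
    9 * seg(src_pos[, 3], gp[3])
  allowed <- outer(wid, wid, `==`)
  if (s > 0) allowed <- allowed & outer(lab, lab, `==`)
  off <- pos %% win
  out <- matrix(0, np, C)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * Dh + 1):(h * Dh)
    Q <- xs %*% p$Wqkv[, cols, drop = FALSE] +
      matrix(p$bqkv[cols], np, Dh, byrow = TRUE)
    K <- xs %*% p$Wqkv[, C + cols, drop = FALSE] +
      matrix(p$bqkv[C + cols], np, Dh, byrow = TRUE)
    V <- xs %*% p$Wqkv[, 2 * C + cols, drop = FALSE] +
      matrix(p$bqkv[2 * C + cols], np, Dh, byrow = TRUE)
    sc <- (Q %*% t(K)) / sqrt(Dh)
    for (i in seq_len(np)) for (j in seq_len(np)) {
      d <- off[i, ] - off[j, ] + win - 1
      sc[i, j] <- sc[i, j] + p$bias[h, 1 + d[1] + (2 * win - 1) *
                                      (d[2] + (2 * win - 1) * d[3])]
    }
    sc[!allowed] <- -Inf
    P <- exp(sc - apply(sc, 1, max))
    P <- P / rowSums(P)
    out[, cols] <- P %*% V
  }
  proj <- out %*% p$Wo + matrix(p$bo, np, C, byrow = TRUE)
  res <- matrix(0, np, C)
  res[src, ] <- proj
  res[inside, , drop = FALSE][order(orig_lin[inside]), , drop = FALSE]
}

rand_attn <- function(C, win, heads, seed) {
  set.seed(seed)
  list(Wqkv = matrix(rnorm(C * 3 * C, sd = 0.3), C),
       bqkv = rnorm(3 * C, sd = 0.1),
       Wo = matrix(rnorm(C * C, sd = 0.3), C),
       bo = rnorm(C, sd = 0.1),
       bias = matrix(rnorm(heads * (2 * win - 1)^3, sd = 0.2), heads))
}

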