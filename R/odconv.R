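# Omni-dimensional dynamic convolution: a bank of N kernels aggregated per
# sample with four attention sets (spatial k x k, input channel, output
# filter, kernel index) predicted from the globally pooled input. The
# aggregated kernel K = (a_s (x) a_c (x) a_f) .* sum_i a_wi W_i is applied
# as a standard convolution, followed by BN + SiLU like any backbone conv.

#' ODConv layer configuration
#'
#' @param in_channels,out_channels Channel counts.
#' @param kernel_size Spatial kernel size (odd).
#' @param n_kernels Number of kernels `N` in the dynamic bank (>= 1).
#' @param reduction Reduction ratio of the attention hidden width:
#'   `hidden = max(in_channels / reduction, floor)`.
#' @param floor Minimum attention hidden width.
#' @param stride,pad Convolution stride and zero padding (`pad = NULL` keeps
#'   spatial size at stride 1).
#' @param kernel_gate `"sigmoid"` (all four branches sigmoid-normalised) or
#'   `"softmax"` for the kernel-index branch.
#' @return A config list used by `layer_odconv_bn_act()`.
#' @export
odconv_config <- function(in_channels, out_channels, kernel_size = 3,
                          n_kernels = 4, reduction = 16, floor = 16,
                          stride = 1, pad = NULL, kernel_gate = "sigmoid") {
  stopifnot(n_kernels >= 1, in_channels >= 1, out_channels >= 1)
  kernel_gate <- match.arg(kernel_gate, c("sigmoid", "softmax"))
  list(cin = in_channels, cout = out_channels, k = kernel_size,
       n_kernels = n_kernels,
       hidden = max(floor, as.integer(in_channels / reduction)),
       stride = stride, pad = pad %||% (kernel_size %/% 2),
       kernel_gate = kernel_gate)
}

layer_odconv_bn_act <- function(cfg, act = "silu") {
  ly <- new_layer("odconv_bn_act", cin = cfg$cin, cout = cfg$cout, k = cfg$k,
                  n_kernels = cfg$n_kernels, hidden = cfg$hidden,
                  stride = cfg$stride, pad = cfg$pad,
                  kernel_gate = cfg$kernel_gate, act = act)
  k <- cfg$k; cin <- cfg$cin; cout <- cfg$cout; h <- cfg$hidden
  sd_fc <- sqrt(2 / cin)
  sd_h <- sqrt(1 / h)
  bn <- bn_init(cout)
  ly$par <- c(list(
    w = array(stats::rnorm(k * k * cin * cout * cfg$n_kernels,
                           sd = sqrt(2 / (k * k * cin))),
              dim = c(k, k, cin, cout, cfg$n_kernels)),
    fc_w = matrix(stats::rnorm(cin * h, sd = sd_fc), cin, h),
    fc_b = rep(0, h),
    s_w = matrix(stats::rnorm(h * k * k, sd = sd_h), h, k * k),
    s_b = rep(0, k * k),
    c_w = matrix(stats::rnorm(h * cin, sd = sd_h), h, cin),
    c_b = rep(0, cin),
    f_w = matrix(stats::rnorm(h * cout, sd = sd_h), h, cout),
    f_b = rep(0, cout),
    k_w = matrix(stats::rnorm(h * cfg$n_kernels, sd = sd_h), h, cfg$n_kernels),
    k_b = rep(0, cfg$n_kernels)
  ), bn$par)
  ly$state <- bn$state
  ly$decay <- c(w = TRUE, fc_w = TRUE, fc_b = FALSE, s_w = TRUE, s_b = FALSE,
                c_w = TRUE, c_b = FALSE, f_w = TRUE, f_b = FALSE,
                k_w = TRUE, k_b = FALSE, gamma = FALSE, beta = FALSE)
  ly
}

# Attention forward for a batch: returns per-branch matrices with one
# column per sample.
odconv_att_fw <- function(ly, x) {
  d <- dim(x); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  xm <- x; dim(xm) <- c(hw, C * N)
  P <- colSums(xm) / hw; dim(P) <- c(C, N)     # global average pool
  hpre <- crossprod(ly$par$fc_w, P) + ly$par$fc_b
  h <- pmax(hpre, 0)                           # ReLU
  pre_s <- crossprod(ly$par$s_w, h) + ly$par$s_b
  pre_c <- crossprod(ly$par$c_w, h) + ly$par$c_b
  pre_f <- crossprod(ly$par$f_w, h) + ly$par$f_b
  pre_k <- crossprod(ly$par$k_w, h) + ly$par$k_b
  a_s <- sigmoid(pre_s); a_c <- sigmoid(pre_c); a_f <- sigmoid(pre_f)
  if (ly$kernel_gate == "softmax") {
    e <- exp(sweep(pre_k, 2, apply(pre_k, 2, max)))
    a_w <- sweep(e, 2, colSums(e), "/")
  } else {
    a_w <- sigmoid(pre_k)
  }
  list(P = P, hpre = hpre, h = h, a_s = a_s, a_c = a_c, a_f = a_f, a_w = a_w)
}

#' Compute the four ODConv attention sets for a batch of feature maps
#'
#' Global-average-pools the input, maps it through a shared bottleneck FC +
#' ReLU, and emits four gated heads: spatial (`k*k`), input-channel,
#' output-channel, and kernel-index weights, one set per batch sample.
#'
#' @param layer An ODConv layer created by `layer_odconv_bn_act()`.
#' @param x Feature map array of dim `(H, W, C, N)`.
#' @return A list with matrices `alpha_s` (`k*k` x N), `alpha_c`, `alpha_f`,
#'   `alpha_w`, columns indexing batch samples.
#' @export
odconv_attention <- function(layer, x) {
  if (dim(x)[3] != layer$cin) stop("channel mismatch with ODConv config", call. = FALSE)
  a <- odconv_att_fw(layer, x)
  list(alpha_s = a$a_s, alpha_c = a$a_c, alpha_f = a$a_f, alpha_w = a$a_w)
}

# Aggregate the kernel bank for one sample given its attention column.
odconv_aggregate <- function(w, a_s, a_c, a_f, a_w) {
  d <- dim(w) # (k, k, cin, cout, N)
  wm <- w; dim(wm) <- c(prod(d[1:4]), d[5])
  S <- wm %*% a_w  # sum_i a_wi W_i
  mask <- as.vector(outer(as.vector(outer(a_s, a_c)), a_f))
  K <- S * mask
  dim(K) <- d[1:4]
  K
}

fw_odconv_bn_act <- function(ly, x, train) {
  d <- dim(x); N <- d[4]
  att <- odconv_att_fw(ly, x)
  zs <- vector("list", N)
  Ks <- vector("list", N)
  for (n in seq_len(N)) {
    K <- odconv_aggregate(ly$par$w, att$a_s[, n], att$a_c[, n],
                          att$a_f[, n], att$a_w[, n])
    Ks[[n]] <- K
    xn <- x[, , , n, drop = FALSE]
    zs[[n]] <- conv2d_fw(xn, K, NULL, ly$stride, ly$pad)
  }
  z <- abind_batch(zs)
  b <- bn_fw(z, ly$par[c("gamma", "beta")], ly$state, train)
  ly$state <- b$state
  y <- if (ly$act == "silu") silu_fw(b$y) else b$y
  ly$cache <- list(x = x, att = att, Ks = Ks, bn = b)
  y
}

bw_odconv_bn_act <- function(ly, gy) {
  gb <- if (ly$act == "silu") silu_bw(ly$cache$bn$y, gy) else gy
  bb <- bn_bw(gb, ly$cache$bn, ly$par[c("gamma", "beta")])
  ly$grad$gamma <- ly$grad$gamma + bb$dgamma
  ly$grad$beta <- ly$grad$beta + bb$dbeta
  x <- ly$cache$x; att <- ly$cache$att
  d <- dim(x); hw <- d[1] * d[2]; cin <- d[3]; N <- d[4]
  k <- ly$k; cout <- ly$cout; nk <- ly$n_kernels
  wd <- dim(ly$par$w)
  wm <- ly$par$w; dim(wm) <- c(prod(wd[1:4]), nk)
  gx <- array(0, dim = d)
  gpre_s <- matrix(0, k * k, N); gpre_c <- matrix(0, cin, N)
  gpre_f <- matrix(0, cout, N); ga_w <- matrix(0, nk, N)
  gwm <- matrix(0, prod(wd[1:4]), nk)
  for (n in seq_len(N)) {
    xn <- x[, , , n, drop = FALSE]
    gzn <- bb$gx[, , , n, drop = FALSE]
    cb <- conv2d_bw(xn, ly$cache$Ks[[n]], gzn, ly$stride, ly$pad, FALSE)
    gx[, , , n] <- cb$gx
    a_s <- att$a_s[, n]; a_c <- att$a_c[, n]; a_f <- att$a_f[, n]
    a_w <- att$a_w[, n]
    maskv <- as.vector(outer(as.vector(outer(a_s, a_c)), a_f))
    gK <- as.vector(cb$gw)
    gS <- gK * maskv
    gwm <- gwm + gS %*% t(a_w)
    ga_w[, n] <- crossprod(wm, gS)
    Sv <- as.vector(wm %*% a_w)
    gmask <- gK * Sv
    # contract gmask over the axes not owned by each attention branch
    gm <- gmask; dim(gm) <- c(k * k, cin * cout)
    gpre_s_raw <- gm %*% as.vector(outer(a_c, a_f))
    tmp <- gmask * rep(a_s, times = cin * cout)          # weight spatial axis
    dim(tmp) <- c(k * k, cin, cout)
    t2 <- colSums(tmp)                                    # (cin, cout)
    gac_raw <- t2 %*% a_f
    gaf_raw <- crossprod(t2, a_c)
    gpre_s[, n] <- gpre_s_raw * a_s * (1 - a_s)
    gpre_c[, n] <- gac_raw * a_c * (1 - a_c)
    gpre_f[, n] <- gaf_raw * a_f * (1 - a_f)
  }
  ly$grad$w <- ly$grad$w + array(gwm, dim = wd)
  if (ly$kernel_gate == "softmax") {
    gpre_k <- att$a_w * sweep(ga_w, 2, colSums(ga_w * att$a_w))
  } else {
    gpre_k <- ga_w * att$a_w * (1 - att$a_w)
  }
  h <- att$h
  ly$grad$s_w <- ly$grad$s_w + h %*% t(gpre_s)
  ly$grad$s_b <- ly$grad$s_b + rowSums(gpre_s)
  ly$grad$c_w <- ly$grad$c_w + h %*% t(gpre_c)
  ly$grad$c_b <- ly$grad$c_b + rowSums(gpre_c)
  ly$grad$f_w <- ly$grad$f_w + h %*% t(gpre_f)
  ly$grad$f_b <- ly$grad$f_b + rowSums(gpre_f)
  ly$grad$k_w <- ly$grad$k_w + h %*% t(gpre_k)
  ly$grad$k_b <- ly$grad$k_b + rowSums(gpre_k)
  gh <- ly$par$s_w %*% gpre_s + ly$par$c_w %*% gpre_c +
    ly$par$f_w %*% gpre_f + ly$par$k_w %*% gpre_k
  gh <- gh * (att$hpre > 0)
  ly$grad$fc_w <- ly$grad$fc_w + att$P %*% t(gh)
  ly$grad$fc_b <- ly$grad$fc_b + rowSums(gh)
  gP <- ly$par$fc_w %*% gh / hw                           # (cin, N)
  gx <- gx + array(rep(as.vector(gP), each = hw), dim = d)
  gx
}

# concatenate per-sample (H,W,C,1) arrays along the batch axis
abind_batch <- function(xs) {
  d <- dim(xs[[1]])
  out <- array(0, dim = c(d[1], d[2], d[3], length(xs)))
  for (n in seq_along(xs)) out[, , , n] <- xs[[n]]
  out
}

#' Apply an ODConv layer to a batch of feature maps
#'
#' Convenience wrapper around the layer object: computes the four attention
#' sets, aggregates the kernel bank per sample, and applies the resulting
#' convolution (without the trailing BN/activation).
#'
#' @param layer An ODConv layer (`layer_odconv_bn_act()`).
#' @param x Input array `(H, W, C, N)`.
#' @param attention Optional precomputed attention (as from
#'   [odconv_attention()]); useful for forcing degenerate attentions in
#'   equivalence checks.
#' @return Output feature map array.
#' @export
odconv_forward <- function(layer, x, attention = NULL) {
  a <- attention %||% odconv_attention(layer, x)
  N <- dim(x)[4]
  zs <- vector("list", N)
  for (n in seq_len(N)) {
    K <- odconv_aggregate(layer$par$w, a$alpha_s[, n], a$alpha_c[, n],
                          a$alpha_f[, n], a$alpha_w[, n])
    zs[[n]] <- conv2d_fw(x[, , , n, drop = FALSE], K, NULL,
                         layer$stride, layer$pad)
  }
  abind_batch(zs)
}
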