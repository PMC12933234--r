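# Minimal training-capable layer framework. Feature maps are numeric arrays
# with dim (H, W, C, N); conv weights have dim (k, k, Cin, Cout). Each layer
# is an environment holding parameters, their gradients, and a forward cache;
# node_forward()/node_backward() dispatch on ly$type. Backward passes are
# hand-derived adjoints of the forwards.

sigmoid <- function(x) 1 / (1 + exp(-x))

silu_fw <- function(x) x * sigmoid(x)
silu_bw <- function(x, gy) {
  s <- sigmoid(x)
  gy * s * (1 + x * (1 - s))
}

# Replicate a per-channel vector over an (H,W,C,N) array's layout.
chan_expand <- function(v, hw, n) rep(rep(v, each = hw), times = n)

new_layer <- function(type, ...) {
  ly <- new.env(parent = emptyenv())
  ly$type <- type
  ly$par <- list()
  ly$grad <- list()
  ly$state <- list()
  extra <- list(...)
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = ly)
  ly
}

init_conv_weight <- function(k, cin, cout, rng) {
  sd <- sqrt(2 / (k * k * cin))
  array(stats::rnorm(k * k * cin * cout, sd = sd), dim = c(k, k, cin, cout))
}

zero_grads <- function(ly) {
  ly$grad <- lapply(ly$par, function(p) array(0, dim = dim(p) %||% length(p)))
  invisible(ly)
}

# --- batch norm ---------------------------------------------------------

bn_init <- function(c) {
  list(par = list(gamma = rep(1, c), beta = rep(0, c)),
       state = list(rmean = rep(0, c), rvar = rep(1, c), momentum = 0.03,
                    eps = 1e-5))
}

bn_fw <- function(x, par, state, train) {
  d <- dim(x); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  if (train) {
    xm <- x; dim(xm) <- c(hw, C * N)
    cs <- colSums(xm); dim(cs) <- c(C, N)
    mu <- rowSums(cs) / (hw * N)
    cs2 <- colSums(xm^2); dim(cs2) <- c(C, N)
    var <- rowSums(cs2) / (hw * N) - mu^2
    state$rmean <- (1 - state$momentum) * state$rmean + state$momentum * mu
    state$rvar <- (1 - state$momentum) * state$rvar + state$momentum * var
  } else {
    mu <- state$rmean; var <- state$rvar
  }
  inv <- 1 / sqrt(var + state$eps)
  xhat <- (x - chan_expand(mu, hw, N)) * chan_expand(inv, hw, N)
  y <- xhat * chan_expand(par$gamma, hw, N) + chan_expand(par$beta, hw, N)
  dim(y) <- d
  list(y = y, xhat = xhat, inv = inv, state = state)
}

bn_bw <- function(gy, cache, par) {
  d <- dim(gy); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  m <- hw * N
  gym <- gy; dim(gym) <- c(hw, C * N)
  xh <- cache$xhat; dim(xh) <- c(hw, C * N)
  s1 <- colSums(gym); dim(s1) <- c(C, N); dbeta <- rowSums(s1)
  s2 <- colSums(gym * xh); dim(s2) <- c(C, N); dgamma <- rowSums(s2)
  ginv <- chan_expand(par$gamma * cache$inv, hw, N)
  gx <- ginv * (c(gy) - chan_expand(dbeta / m, hw, N) -
                  c(cache$xhat) * chan_expand(dgamma / m, hw, N))
  dim(gx) <- d
  list(gx = gx, dgamma = dgamma, dbeta = dbeta)
}

# --- conv + BN + activation (the YOLOv5 "Conv" unit) --------------------

layer_conv_bn_act <- function(cin, cout, k = 1, stride = 1, pad = NULL,
                              act = "silu", rng = NULL) {
  pad <- pad %||% (k %/% 2)
  bn <- bn_init(cout)
  ly <- new_layer("conv_bn_act", cin = cin, cout = cout, k = k,
                  stride = stride, pad = pad, act = act)
  ly$par <- c(list(w = init_conv_weight(k, cin, cout, rng)), bn$par)
  ly$state <- bn$state
  ly$decay <- c(w = TRUE, gamma = FALSE, beta = FALSE)
  ly
}

fw_conv_bn_act <- function(ly, x, train) {
  z <- conv2d_fw(x, ly$par$w, NULL, ly$stride, ly$pad)
  b <- bn_fw(z, ly$par[c("gamma", "beta")], ly$state, train)
  ly$state <- b$state
  y <- if (ly$act == "silu") silu_fw(b$y) else b$y
  ly$cache <- list(x = x, z = z, bn = b)
  y
}

bw_conv_bn_act <- function(ly, gy) {
  gb <- if (ly$act == "silu") silu_bw(ly$cache$bn$y, gy) else gy
  bb <- bn_bw(gb, ly$cache$bn, ly$par[c("gamma", "beta")])
  ly$grad$gamma <- ly$grad$gamma + bb$dgamma
  ly$grad$beta <- ly$grad$beta + bb$dbeta
  cb <- conv2d_bw(ly$cache$x, ly$par$w, bb$gx, ly$stride, ly$pad, FALSE)
  ly$grad$w <- ly$grad$w + cb$gw
  cb$gx
}

# --- depthwise conv + BN + activation (GSConv's second half) ------------

layer_dwconv_bn_act <- function(c, k = 5, stride = 1, act = "silu") {
  ly <- new_layer("dwconv_bn_act", cin = c, cout = c, k = k, stride = stride,
                  pad = k %/% 2, act = act)
  bn <- bn_init(c)
  sd <- sqrt(2 / (k * k))
  ly$par <- c(list(w = array(stats::rnorm(k * k * c, sd = sd),
                             dim = c(k, k, 1, c))), bn$par)
  ly$state <- bn$state
  ly$decay <- c(w = TRUE, gamma = FALSE, beta = FALSE)
  ly
}

fw_dwconv_bn_act <- function(ly, x, train) {
  z <- dwconv_fw(x, ly$par$w, ly$stride, ly$pad)
  b <- bn_fw(z, ly$par[c("gamma", "beta")], ly$state, train)
  ly$state <- b$state
  y <- if (ly$act == "silu") silu_fw(b$y) else b$y
  ly$cache <- list(x = x, bn = b)
  y
}

bw_dwconv_bn_act <- function(ly, gy) {
  gb <- if (ly$act == "silu") silu_bw(ly$cache$bn$y, gy) else gy
  bb <- bn_bw(gb, ly$cache$bn, ly$par[c("gamma", "beta")])
  ly$grad$gamma <- ly$grad$gamma + bb$dgamma
  ly$grad$beta <- ly$grad$beta + bb$dbeta
  db <- dwconv_bw(ly$cache$x, ly$par$w, bb$gx, ly$stride, ly$pad)
  ly$grad$w <- ly$grad$w + db$gw
  db$gx
}

# --- plain conv with bias (detection head 1x1) --------------------------

layer_conv_bias <- function(cin, cout, k = 1, stride = 1, bias_init = NULL) {
  ly <- new_layer("conv_bias", cin = cin, cout = cout, k = k, stride = stride,
                  pad = k %/% 2)
  b <- bias_init %||% rep(0, cout)
  ly$par <- list(w = init_conv_weight(k, cin, cout, NULL), b = b)
  ly$decay <- c(w = TRUE, b = FALSE)
  ly
}

fw_conv_bias <- function(ly, x, train) {
  ly$cache <- list(x = x)
  conv2d_fw(x, ly$par$w, ly$par$b, ly$stride, ly$pad)
}

bw_conv_bias <- function(ly, gy) {
  cb <- conv2d_bw(ly$cache$x, ly$par$w, gy, ly$stride, ly$pad, TRUE)
  ly$grad$w <- ly$grad$w + cb$gw
  ly$grad$b <- ly$grad$b + cb$gb
  cb$gx
}

# --- parameter-free nodes ----------------------------------------------

layer_maxpool <- function(k = 5, stride = 1) {
  new_layer("maxpool", k = k, stride = stride, pad = k %/% 2)
}

layer_upsample2 <- function() new_layer("upsample2")

layer_add <- function() new_layer("add")

layer_concat <- function() new_layer("concat")

# channel shuffle: interleave the two halves (GSConv mixing step)
layer_shuffle <- function(c) {
  half <- c %/% 2
  perm <- as.vector(rbind(seq_len(half), half + seq_len(half)))
  new_layer("shuffle", perm = perm, inv = order(perm))
}

# weighted fast-normalized fusion over >= 2 inputs
layer_wfusion <- function(n_inputs, eps = 1e-4) {
  ly <- new_layer("wfusion", n_inputs = n_inputs, eps = eps)
  ly$par <- list(w = rep(1, n_inputs))
  ly$decay <- c(w = FALSE)
  ly
}

#' Fast normalized feature fusion
#'
#' Combines feature maps of identical shape with learnable nonnegative
#' scalar weights: `out = sum_i (u_i / (eps + sum_j u_j)) * x_i` with
#' `u = max(w, 0)` (ReLU projection keeps the weights nonnegative). The
#' normalized coefficients lie in `[0, 1)` and sum to strictly less
#' than 1 for `eps > 0`.
#'
#' @param inputs A list of arrays with identical `dim`.
#' @param weights Numeric vector, one weight per input.
#' @param eps Stabiliser added to the weight sum (default `1e-4`).
#' @return An array with the common input shape.
#' @export
fast_normalized_fusion <- function(inputs, weights, eps = 1e-4) {
  stopifnot(length(inputs) >= 2, length(weights) == length(inputs))
  d <- dim(inputs[[1]])
  for (x in inputs) {
    if (!identical(dim(x), d)) stop("fusion inputs must share a shape", call. = FALSE)
  }
  u <- pmax(weights, 0)
  coef <- u / (eps + sum(u))
  out <- array(0, dim = d)
  for (i in seq_along(inputs)) out <- out + coef[i] * inputs[[i]]
  out
}

fw_wfusion <- function(ly, xs, train) {
  u <- pmax(ly$par$w, 0)
  s <- ly$eps + sum(u)
  coef <- u / s
  out <- coef[1] * xs[[1]]
  for (i in seq_along(xs)[-1]) out <- out + coef[i] * xs[[i]]
  ly$cache <- list(xs = xs, u = u, s = s, coef = coef)
  out
}

bw_wfusion <- function(ly, gy) {
  xs <- ly$cache$xs
  gcoef <- vapply(xs, function(x) sum(gy * x), numeric(1))
  s <- ly$cache$s; u <- ly$cache$u
  # d coef_i / d u_j = (delta_ij * s - u_i) / s^2
  gu <- (gcoef * s - sum(gcoef * u)) / s^2
  ly$grad$w <- ly$grad$w + gu * as.numeric(ly$par$w > 0)
  lapply(ly$cache$coef, function(ci) NULL) # no-op placeholder
  gxs <- vector("list", length(xs))
  for (i in seq_along(xs)) gxs[[i]] <- ly$cache$coef[i] * gy
  gxs
}

# --- generic dispatch ---------------------------------------------------

node_forward <- function(ly, xs, train) {
  switch(ly$type,
    input = xs[[1]],
    conv_bn_act = fw_conv_bn_act(ly, xs[[1]], train),
    dwconv_bn_act = fw_dwconv_bn_act(ly, xs[[1]], train),
    conv_bias = fw_conv_bias(ly, xs[[1]], train),
    odconv_bn_act = fw_odconv_bn_act(ly, xs[[1]], train),
    maxpool = {
      r <- maxpool_fw(xs[[1]], ly$k, ly$stride, ly$pad)
      ly$cache <- list(idx = r$idx, xdim = dim(xs[[1]]))
      r$y
    },
    upsample2 = upsample2_fw(xs[[1]]),
    add = { ly$cache <- list(n = length(xs)); Reduce(`+`, xs) },
    concat = {
      ly$cache <- list(cs = vapply(xs, function(x) dim(x)[3], numeric(1)))
      abind_ch(xs)
    },
    shuffle = {
      x <- xs[[1]]
      x[, , ly$perm, , drop = FALSE]
    },
    wfusion = fw_wfusion(ly, xs, train),
    stop("unknown layer type: ", ly$type)
  )
}

# Returns a list of gradients, one per input of the node.
node_backward <- function(ly, gy) {
  switch(ly$type,
    input = list(gy),
    conv_bn_act = list(bw_conv_bn_act(ly, gy)),
    dwconv_bn_act = list(bw_dwconv_bn_act(ly, gy)),
    conv_bias = list(bw_conv_bias(ly, gy)),
    odconv_bn_act = list(bw_odconv_bn_act(ly, gy)),
    maxpool = list(maxpool_bw(gy, ly$cache$idx, ly$cache$xdim)),
    upsample2 = list(upsample2_bw(gy)),
    add = rep(list(gy), ly$cache$n),
    concat = split_ch(gy, ly$cache$cs),
    shuffle = list(gy[, , ly$inv, , drop = FALSE]),
    wfusion = bw_wfusion(ly, gy),
    stop("unknown layer type: ", ly$type)
  )
}

# concatenate along the channel axis (3rd)
abind_ch <- function(xs) {
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], numeric(1))
  out <- array(0, dim = c(d[1], d[2], sum(cs), d[4]))
  at <- 0
  for (x in xs) {
    c <- dim(x)[3]
    out[, , at + seq_len(c), ] <- x
    at <- at + c
  }
  out
}

split_ch <- function(x, cs) {
  out <- vector("list", length(cs))
  at <- 0
  for (i in seq_along(cs)) {
    out[[i]] <- x[, , at + seq_len(cs[i]), , drop = FALSE]
    at <- at + cs[i]
  }
  out
}
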