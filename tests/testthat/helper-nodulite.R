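# Shared helpers for the test suite.

# deterministic random boxes (cx, cy in [lo, hi]; w, h in [wmin, wmax])
random_boxes <- function(n, seed, lo = 10, hi = 100, wmin = 2, wmax = 40) {
  set.seed(seed)
  tibble::tibble(cx = runif(n, lo, hi), cy = runif(n, lo, hi),
                 w = runif(n, wmin, wmax), h = runif(n, wmin, wmax))
}

# tiny model config used throughout the suite (fast to build and run)
tiny_config <- function(...) {
  model_config(input_size = 64, width_multiple = 0.25, ...)
}

# stack a list of per-image box tibbles into one truth tibble
stack_boxes <- function(box_list) {
  dplyr::bind_rows(lapply(seq_along(box_list), function(i) {
    b <- box_list[[i]]
    if (nrow(b)) b$image <- i
    b
  }))
}

# naive direct-loop 2-D convolution oracle (x: (H,W,Cin,N),
# w: (k,k,Cin,Cout)), zero padding, cross-correlation convention
naive_conv2d <- function(x, w, stride = 1, pad = 0) {
  d <- dim(x); k <- dim(w)[1]; cout <- dim(w)[4]
  H <- d[1]; W <- d[2]; cin <- d[3]; N <- d[4]
  xp <- array(0, dim = c(H + 2 * pad, W + 2 * pad, cin, N))
  xp[pad + seq_len(H), pad + seq_len(W), , ] <- x
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  y <- array(0, dim = c(Ho, Wo, cout, N))
  for (n in seq_len(N)) for (co in seq_len(cout)) {
    for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
      r <- (i - 1) * stride; cc <- (j - 1) * stride
      patch <- xp[r + seq_len(k), cc + seq_len(k), , n]
      y[i, j, co, n] <- sum(patch * w[, , , co])
    }
  }
  y
}

# numeric 2-Wasserstein distance between the Gaussian embeddings of two
# boxes, computed directly from the mean/covariance definition as an
# independent oracle (diagonal covariances commute, so the Bures term
# reduces to the Frobenius norm of the sqrt difference).
oracle_w2 <- function(a, b) {
  mu_d2 <- (a$cx - b$cx)^2 + (a$cy - b$cy)^2
  s_a <- c(a$w, a$h) / 2
  s_b <- c(b$w, b$h) / 2
  sqrt(mu_d2 + sum((s_a - s_b)^2))
}
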