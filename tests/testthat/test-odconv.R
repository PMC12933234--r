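# Omni-dimensional dynamic convolution: attention heads, per-sample
# kernel aggregation, equivalence oracles, and gradient flow.

make_odc_layer <- function(cin, cout, k = 3, n_kernels = 2, reduction = 4,
                           floor = 2, kernel_gate = "sigmoid", seed = 1) {
  set.seed(seed)
  nodulite:::layer_odconv_bn_act(
    odconv_config(cin, cout, kernel_size = k, n_kernels = n_kernels,
                  reduction = reduction, floor = floor,
                  kernel_gate = kernel_gate))
}

test_that("attention heads have the right shapes and ranges", {
  ly <- make_odc_layer(6, 8, k = 3, n_kernels = 4)
  set.seed(2)
  x <- array(rnorm(5 * 5 * 6 * 3), dim = c(5, 5, 6, 3))
  a <- odconv_attention(ly, x)
  expect_equal(dim(a$alpha_s), c(9, 3))
  expect_equal(dim(a$alpha_c), c(6, 3))
  expect_equal(dim(a$alpha_f), c(8, 3))
  expect_equal(dim(a$alpha_w), c(4, 3))
  for (m in a) expect_true(all(m > 0 & m < 1))
  # per-sample: attentions must differ between different inputs
  expect_false(isTRUE(all.equal(a$alpha_s[, 1], a$alpha_s[, 2])))
  expect_error(odconv_attention(ly, array(0, dim = c(5, 5, 3, 1))),
               "channel mismatch")
})

test_that("softmax kernel gate normalises the kernel weights", {
  ly <- make_odc_layer(4, 4, n_kernels = 3, kernel_gate = "softmax")
  set.seed(3)
  x <- array(rnorm(4 * 4 * 4 * 2), dim = c(4, 4, 4, 2))
  a <- odconv_attention(ly, x)
  expect_equal(colSums(a$alpha_w), c(1, 1), tolerance = 1e-12)
  expect_true(all(a$alpha_w > 0))
})

test_that("attention hidden width follows max(floor, cin/reduction)", {
  expect_equal(odconv_config(64, 64, reduction = 16, floor = 16)$hidden, 16)
  expect_equal(odconv_config(256, 64, reduction = 16, floor = 16)$hidden, 16)
  expect_equal(odconv_config(256, 64, reduction = 4, floor = 16)$hidden, 64)
  expect_equal(odconv_config(8, 8, reduction = 2, floor = 2)$hidden, 4)
})

test_that("odconv_forward matches the brute-force aggregation oracle", {
  set.seed(10)
  for (trial in 1:20) {
    cin <- sample(2:6, 1); cout <- sample(2:6, 1)
    k <- sample(c(1, 3), 1); nk <- sample(1:4, 1)
    H <- sample(4:6, 1); N <- sample(1:3, 1)
    gate <- sample(c("sigmoid", "softmax"), 1)
    ly <- make_odc_layer(cin, cout, k = k, n_kernels = nk,
                         kernel_gate = gate, seed = 100 + trial)
    x <- array(rnorm(H * H * cin * N), dim = c(H, H, cin, N))
    got <- odconv_forward(ly, x)
    a <- odconv_attention(ly, x)
    want <- array(0, dim = dim(got))
    for (n in seq_len(N)) {
      # brute-force kernel: K[i,j,c,f] = a_s[ij] a_c[c] a_f[f] sum_m a_w[m] W_m
      K <- array(0, dim = c(k, k, cin, cout))
      for (ki in seq_len(k)) for (kj in seq_len(k)) {
        for (c in seq_len(cin)) for (f in seq_len(cout)) {
          s <- 0
          for (m in seq_len(nk)) s <- s + a$alpha_w[m, n] * ly$par$w[ki, kj, c, f, m]
          K[ki, kj, c, f] <- a$alpha_s[(kj - 1) * k + ki, n] *
            a$alpha_c[c, n] * a$alpha_f[f, n] * s
        }
      }
      want[, , , n] <- naive_conv2d(x[, , , n, drop = FALSE], K,
                                    stride = 1, pad = k %/% 2)
    }
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("unit attentions with one kernel reduce to a plain convolution", {
  cin <- 3; cout <- 4; k <- 3
  ly <- make_odc_layer(cin, cout, k = k, n_kernels = 1, seed = 5)
  set.seed(6)
  x <- array(rnorm(6 * 6 * cin * 2), dim = c(6, 6, cin, 2))
  ones <- list(alpha_s = matrix(1, k * k, 2), alpha_c = matrix(1, cin, 2),
               alpha_f = matrix(1, cout, 2), alpha_w = matrix(1, 1, 2))
  got <- odconv_forward(ly, x, attention = ones)
  w <- array(ly$par$w, dim = c(k, k, cin, cout))
  want <- naive_conv2d(x, w, stride = 1, pad = 1)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("scaling one channel's attention scales its contribution", {
  # output-filter attention acts multiplicatively per filter
  cin <- 3; cout <- 2; k <- 1
  ly <- make_odc_layer(cin, cout, k = k, n_kernels = 1, seed = 7)
  set.seed(8)
  x <- array(rnorm(4 * 4 * cin), dim = c(4, 4, cin, 1))
  base <- list(alpha_s = matrix(1, 1, 1), alpha_c = matrix(1, cin, 1),
               alpha_f = matrix(1, cout, 1), alpha_w = matrix(1, 1, 1))
  half <- base
  half$alpha_f[2, 1] <- 0.5
  y0 <- odconv_forward(ly, x, attention = base)
  y1 <- odconv_forward(ly, x, attention = half)
  expect_equal(y1[, , 1, ], y0[, , 1, ])
  expect_equal(y1[, , 2, ], 0.5 * y0[, , 2, ])
})

test_that("gradients flow through all ODConv parameter groups", {
  ly <- make_odc_layer(3, 4, k = 3, n_kernels = 2, seed = 9)
  set.seed(11)
  x <- array(rnorm(6 * 6 * 3 * 2), dim = c(6, 6, 3, 2))
  gy <- array(rnorm(6 * 6 * 4 * 2), dim = c(6, 6, 4, 2))
  y <- nodulite:::fw_odconv_bn_act(ly, x, train = TRUE)
  nodulite:::zero_grads(ly)
  gx <- nodulite:::bw_odconv_bn_act(ly, gy)
  expect_equal(dim(gx), dim(x))
  for (nm in c("w", "fc_w", "s_w", "c_w", "f_w", "k_w", "gamma", "beta")) {
    expect_gt(max(abs(ly$grad[[nm]])), 0)
  }
  # finite-difference check on a weight-bank entry (loss = sum(y * gy))
  eps <- 1e-4
  idx <- c(2, 2, 1, 1, 1)
  num <- local({
    lyp <- make_odc_layer(3, 4, k = 3, n_kernels = 2, seed = 9)
    lyp$par$w[2, 2, 1, 1, 1] <- lyp$par$w[2, 2, 1, 1, 1] + eps
    yp <- nodulite:::fw_odconv_bn_act(lyp, x, train = TRUE)
    lym <- make_odc_layer(3, 4, k = 3, n_kernels = 2, seed = 9)
    lym$par$w[2, 2, 1, 1, 1] <- lym$par$w[2, 2, 1, 1, 1] - eps
    ym <- nodulite:::fw_odconv_bn_act(lym, x, train = TRUE)
    (sum(yp * gy) - sum(ym * gy)) / (2 * eps)
  })
  expect_equal(ly$grad$w[2, 2, 1, 1, 1], num, tolerance = 1e-3)
})

test_that("GSConv halves the dense conv and shuffle interleaves channels", {
  g <- nodulite:::new_graph()
  set.seed(12)
  out <- nodulite:::add_gsconv(g, integer(0), 8, 8, k = 1, s = 1, dwk = 5)
  types <- vapply(g$nodes, function(nd) nd$ly$type, character(1))
  expect_equal(types, c("conv_bn_act", "dwconv_bn_act", "concat", "shuffle"))
  # dense half: 8 -> 4 channels only
  expect_equal(dim(g$nodes[[1]]$ly$par$w)[3:4], c(8, 4))
  # depthwise: one k x k filter per channel
  expect_equal(dim(g$nodes[[2]]$ly$par$w), c(5, 5, 1, 4))
  # interleaving shuffle: [a1 b1 a2 b2 ...] and its inverse
  perm <- g$nodes[[4]]$ly$perm
  expect_equal(perm, c(1, 5, 2, 6, 3, 7, 4, 8))
  expect_equal(order(perm), g$nodes[[4]]$ly$inv)
  expect_error(nodulite:::add_gsconv(g, out, 8, 7), "even")
})

test_that("GSConv uses fewer parameters than the plain convolution", {
  count_pars <- function(g) {
    sum(vapply(g$nodes, function(nd) {
      sum(vapply(nd$ly$par, length, numeric(1)))
    }, numeric(1)))
  }
  g1 <- nodulite:::new_graph()
  nodulite:::add_gsconv(g1, integer(0), 64, 64, k = 3, s = 1, dwk = 5)
  g2 <- nodulite:::new_graph()
  nodulite:::add_conv(g2, integer(0), 64, 64, 3, 1)
  expect_lt(count_pars(g1), count_pars(g2))
})
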