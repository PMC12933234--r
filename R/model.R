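# Detector assembly. A detector is a flat DAG of primitive layer nodes
# (see nn_core.R); composite blocks (C3, SPPF, GSConv, fusion nodes) are
# expanded into primitives at build time, which keeps forward/backward and
# the parameter/FLOP accounting uniform.

make_divisible <- function(x, d = 8) max(d, as.integer(ceiling(x / d) * d))

new_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g
}

g_add <- function(g, ly, from) {
  g$nodes[[length(g$nodes) + 1]] <- list(ly = ly, from = as.integer(from))
  length(g$nodes)
}

add_conv <- function(g, from, cin, cout, k = 1, s = 1, pad = NULL) {
  g_add(g, layer_conv_bn_act(cin, cout, k, s, pad), from)
}

#' Append a GSConv unit to a detector graph
#' @noRd
add_gsconv <- function(g, from, cin, cout, k = 1, s = 1, dwk = 5) {
  if (cout %% 2 != 0) stop("gsconv: output channels must be even", call. = FALSE)
  half <- cout %/% 2
  a <- add_conv(g, from, cin, half, k, s)
  b <- g_add(g, layer_dwconv_bn_act(half, k = dwk), a)
  cc <- g_add(g, layer_concat(), c(a, b))
  g_add(g, layer_shuffle(cout), cc)
}

add_bottleneck <- function(g, from, c1, c2, shortcut = TRUE, odc = NULL) {
  ch <- c2 %/% 1
  target <- if (is.null(odc)) "none" else odc$target
  b1 <- if (target == "both") {
    g_add(g, layer_odconv_bn_act(odconv_config(
      c1, ch, kernel_size = 1, n_kernels = odc$n_kernels,
      reduction = odc$reduction, floor = odc$floor,
      kernel_gate = odc$kernel_gate)), from)
  } else add_conv(g, from, c1, ch, 1, 1)
  b2 <- if (target %in% c("conv2", "both")) {
    g_add(g, layer_odconv_bn_act(odconv_config(
      ch, c2, kernel_size = 3, n_kernels = odc$n_kernels,
      reduction = odc$reduction, floor = odc$floor,
      kernel_gate = odc$kernel_gate)), b1)
  } else add_conv(g, b1, ch, c2, 3, 1)
  if (shortcut && c1 == c2) g_add(g, layer_add(), c(from, b2)) else b2
}

# YOLOv5 C3 block; `odc` non-NULL swaps the bottleneck convs for ODConv
# (the C3_ODC variant).
add_c3 <- function(g, from, c1, c2, n = 1, shortcut = TRUE, odc = NULL,
                   e = 0.5) {
  ch <- as.integer(c2 * e)
  cv1 <- add_conv(g, from, c1, ch, 1, 1)
  cv2 <- add_conv(g, from, c1, ch, 1, 1)
  m <- cv1
  for (i in seq_len(n)) m <- add_bottleneck(g, m, ch, ch, shortcut, odc)
  cc <- g_add(g, layer_concat(), c(m, cv2))
  add_conv(g, cc, 2 * ch, c2, 1, 1)
}

# C3-style fuse block built from GSConv units (used inside the GS-BiFPN).
add_gsc3 <- function(g, from, c1, c2, n = 1, dwk = 5, e = 0.5) {
  ch <- as.integer(c2 * e)
  cv1 <- add_conv(g, from, c1, ch, 1, 1)
  cv2 <- add_conv(g, from, c1, ch, 1, 1)
  m <- cv1
  for (i in seq_len(n)) {
    m <- add_gsconv(g, m, ch, ch, 1, 1, dwk)
    m <- add_gsconv(g, m, ch, ch, 3, 1, dwk)
  }
  cc <- g_add(g, layer_concat(), c(m, cv2))
  add_conv(g, cc, 2 * ch, c2, 1, 1)
}

add_sppf <- function(g, from, c1, c2, k = 5) {
  ch <- c1 %/% 2
  cv1 <- add_conv(g, from, c1, ch, 1, 1)
  p1 <- g_add(g, layer_maxpool(k, 1), cv1)
  p2 <- g_add(g, layer_maxpool(k, 1), p1)
  p3 <- g_add(g, layer_maxpool(k, 1), p2)
  cc <- g_add(g, layer_concat(), c(cv1, p1, p2, p3))
  add_conv(g, cc, 4 * ch, c2, 1, 1)
}

default_anchors <- function() {
  list(p3 = matrix(c(10, 13, 16, 30, 33, 23), 3, 2, byrow = TRUE),
       p4 = matrix(c(30, 61, 62, 45, 59, 119), 3, 2, byrow = TRUE),
       p5 = matrix(c(116, 90, 156, 198, 373, 326), 3, 2, byrow = TRUE))
}

#' Detector configuration
#'
#' Controls the architecture toggles of the single-class CSP detector: the
#' baseline uses standard C3 backbone blocks and a PANet neck; `use_c3_odc`
#' swaps the backbone bottleneck convolutions for ODConv, and
#' `use_gs_bifpn` replaces the neck with the weighted bidirectional
#' GSConv fusion neck. All 8 toggle combinations (including `loss_mode`)
#' are valid, mirroring the ablation grid.
#'
#' @param depth_multiple,width_multiple CSP scaling multipliers (the "s"
#'   model: 0.33 / 0.50).
#' @param num_classes Number of object classes (1 for nodules).
#' @param input_size Square input size in pixels, divisible by 32.
#' @param use_c3_odc,use_gs_bifpn Architecture toggles.
#' @param loss_mode `"ciou"` (stock box loss) or `"f_nwd"`.
#' @param anchors List of per-level 3x2 anchor matrices (pixels at
#'   `input_size` scale).
#' @param odconv ODConv calibration: `n_kernels`, `reduction`, `floor`,
#'   `target` (`"conv2"` replaces only the 3x3 bottleneck conv, `"both"`
#'   also the 1x1), `kernel_gate`, and `stages` (which of the four backbone
#'   C3 stages are converted).
#' @param gsconv_dw_kernel Depthwise kernel size inside GSConv.
#' @param gsc3_repeats Repeats of the GSConv bottleneck inside each neck
#'   fuse block, one per fuse node (length 1 recycles).
#' @return A list of class `nodulite_model_config`.
#' @export
model_config <- function(depth_multiple = 0.33, width_multiple = 0.50,
                         num_classes = 1, input_size = 640,
                         use_c3_odc = FALSE, use_gs_bifpn = FALSE,
                         loss_mode = c("ciou", "f_nwd"),
                         anchors = default_anchors(),
                         odconv = list(),
                         gsconv_dw_kernel = 7,
                         gsc3_repeats = c(1, 2, 1, 1)) {
  if (input_size %% 32 != 0) stop("input_size must be divisible by 32", call. = FALSE)
  od <- utils::modifyList(list(n_kernels = 1, reduction = 2, floor = 16,
                               target = "conv2", kernel_gate = "sigmoid",
                               stages = 1:4), odconv)
  structure(list(depth_multiple = depth_multiple,
                 width_multiple = width_multiple,
                 num_classes = num_classes, input_size = input_size,
                 use_c3_odc = use_c3_odc, use_gs_bifpn = use_gs_bifpn,
                 loss_mode = match.arg(loss_mode), anchors = anchors,
                 odconv = od, gsconv_dw_kernel = gsconv_dw_kernel,
                 gsc3_repeats = gsc3_repeats),
            class = "nodulite_model_config")
}

#' Build the nodule detector
#'
#' Assembles the single-class detector: CSP backbone (stem + four C3
#' stages + SPPF), a neck (PANet baseline or GS-BiFPN), and a three-level
#' anchor head at strides 8/16/32. Architecture toggles come from
#' [model_config()].
#'
#' @param cfg A [model_config()].
#' @param seed Optional integer seed for weight initialisation.
#' @return A detector object (class `nodulite_detector`).
#' @export
build_detector <- function(cfg = model_config(), seed = NULL) {
  stopifnot(inherits(cfg, "nodulite_model_config"))
  if (!is.null(seed)) set.seed(seed)
  wm <- cfg$width_multiple; dm <- cfg$depth_multiple
  ch <- function(x) make_divisible(x * wm, 8)
  dep <- function(n) max(1L, as.integer(round(n * dm)))
  nc <- cfg$num_classes
  no <- 3 * (5 + nc)
  odc <- if (cfg$use_c3_odc) cfg$odconv else NULL
  odc_for <- function(stage) {
    if (!is.null(odc) && stage %in% odc$stages) odc else NULL
  }
  g <- new_graph()
  x0 <- g_add(g, new_layer("input"), integer(0))
  # backbone
  b1 <- add_conv(g, x0, 3, ch(64), 6, 2, pad = 2)          # /2
  b2 <- add_conv(g, b1, ch(64), ch(128), 3, 2)             # /4
  b3 <- add_c3(g, b2, ch(128), ch(128), dep(3), TRUE, odc_for(1))
  b4 <- add_conv(g, b3, ch(128), ch(256), 3, 2)            # /8
  p3b <- add_c3(g, b4, ch(256), ch(256), dep(6), TRUE, odc_for(2))
  b6 <- add_conv(g, p3b, ch(256), ch(512), 3, 2)           # /16
  p4b <- add_c3(g, b6, ch(512), ch(512), dep(9), TRUE, odc_for(3))
  b8 <- add_conv(g, p4b, ch(512), ch(1024), 3, 2)          # /32
  b9 <- add_c3(g, b8, ch(1024), ch(1024), dep(3), TRUE, odc_for(4))
  p5b <- add_sppf(g, b9, ch(1024), ch(1024))
  c3w <- ch(256); c4w <- ch(512); c5w <- ch(1024)
  if (!cfg$use_gs_bifpn) {
    # stock PANet neck
    n10 <- add_conv(g, p5b, c5w, c4w, 1, 1)
    n11 <- g_add(g, layer_upsample2(), n10)
    n12 <- g_add(g, layer_concat(), c(n11, p4b))
    n13 <- add_c3(g, n12, 2 * c4w, c4w, dep(3), FALSE)
    n14 <- add_conv(g, n13, c4w, c3w, 1, 1)
    n15 <- g_add(g, layer_upsample2(), n14)
    n16 <- g_add(g, layer_concat(), c(n15, p3b))
    n17 <- add_c3(g, n16, 2 * c3w, c3w, dep(3), FALSE)     # N3
    n18 <- add_conv(g, n17, c3w, c3w, 3, 2)
    n19 <- g_add(g, layer_concat(), c(n18, n14))
    n20 <- add_c3(g, n19, 2 * c3w, c4w, dep(3), FALSE)     # N4
    n21 <- add_conv(g, n20, c4w, c4w, 3, 2)
    n22 <- g_add(g, layer_concat(), c(n21, n10))
    n23 <- add_c3(g, n22, 2 * c4w, c5w, dep(3), FALSE)     # N5
    outs <- c(n17, n20, n23)
  } else {
    dwk <- cfg$gsconv_dw_kernel
    rep4 <- rep(cfg$gsc3_repeats, length.out = 4)
    # top-down pass
    t1 <- add_gsconv(g, p5b, c5w, c4w, 1, 1, dwk)
    t1u <- g_add(g, layer_upsample2(), t1)
    f4 <- g_add(g, layer_wfusion(2), c(t1u, p4b))
    p4td <- add_gsc3(g, f4, c4w, c4w, rep4[1], dwk)
    t2 <- add_gsconv(g, p4td, c4w, c3w, 1, 1, dwk)
    t2u <- g_add(g, layer_upsample2(), t2)
    f3 <- g_add(g, layer_wfusion(2), c(t2u, p3b))
    n3 <- add_gsc3(g, f3, c3w, c3w, rep4[2], dwk)          # N3
    # bottom-up pass; P4 gets the same-level skip edge
    d1 <- add_gsconv(g, n3, c3w, c4w, 3, 2, dwk)
    f4b <- g_add(g, layer_wfusion(3), c(d1, p4td, p4b))
    n4 <- add_gsc3(g, f4b, c4w, c4w, rep4[3], dwk)         # N4
    d2 <- add_gsconv(g, n4, c4w, c5w, 3, 2, dwk)
    f5 <- g_add(g, layer_wfusion(2), c(d2, p5b))
    n5 <- add_gsc3(g, f5, c5w, c5w, rep4[4], dwk)          # N5
    outs <- c(n3, n4, n5)
  }
  strides <- c(8, 16, 32)
  head_ids <- integer(3)
  head_ch <- c(c3w, c4w, c5w)
  for (i in 1:3) {
    bias <- rep(0, no)
    for (a in 0:2) {
      bias[a * (5 + nc) + 5] <- log(8 / (cfg$input_size / strides[i])^2)
      if (nc > 0) bias[a * (5 + nc) + 5 + seq_len(nc)] <- log(0.6 / max(nc - 0.99, 0.01))
    }
    head_ids[i] <- g_add(g, layer_conv_bias(head_ch[i], no, 1, bias_init = bias),
                         outs[i])
  }
  model <- structure(list(nodes = g$nodes, head_ids = head_ids,
                          strides = strides, cfg = cfg, nc = nc,
                          anchors = cfg$anchors),
                     class = "nodulite_detector")
  for (nd in model$nodes) zero_grads(nd$ly)
  model
}

#' @export
print.nodulite_detector <- function(x, ...) {
  cfg <- x$cfg
  cat("<nodulite_detector> ", length(x$nodes), " nodes | backbone: ",
      if (cfg$use_c3_odc) "C3_ODC" else "C3", " | neck: ",
      if (cfg$use_gs_bifpn) "GS-BiFPN" else "PANet", " | loss: ",
      cfg$loss_mode, "\n", sep = "")
  cat(sprintf("  params: %.2fM | FLOPs @%d: %.1fG\n",
              count_params(x) / 1e6, cfg$input_size,
              count_flops(x, cfg$input_size) / 1e9))
  invisible(x)
}

# --- forward / backward over the DAG ------------------------------------

detector_forward <- function(model, x, train = FALSE) {
  outs <- vector("list", length(model$nodes))
  for (i in seq_along(model$nodes)) {
    nd <- model$nodes[[i]]
    xs <- if (length(nd$from) == 0) list(x) else outs[nd$from]
    outs[[i]] <- node_forward(nd$ly, xs, train)
  }
  if (train) model$.outs <- outs
  list(heads = outs[model$head_ids], outs = outs)
}

detector_backward <- function(model, outs, head_grads) {
  n <- length(model$nodes)
  grads <- vector("list", n)
  for (i in seq_along(model$head_ids)) {
    grads[[model$head_ids[i]]] <- head_grads[[i]]
  }
  for (i in rev(seq_len(n))) {
    nd <- model$nodes[[i]]
    if (is.null(grads[[i]]) || length(nd$from) == 0) next
    gxs <- node_backward(nd$ly, grads[[i]])
    for (j in seq_along(nd$from)) {
      f <- nd$from[j]
      grads[[f]] <- if (is.null(grads[[f]])) gxs[[j]] else grads[[f]] + gxs[[j]]
    }
    grads[[i]] <- NULL # free
  }
  invisible(NULL)
}

# --- accounting ---------------------------------------------------------

#' Count trainable parameters of a detector
#'
#' Sums the lengths of every trainable array in the model (convolution and
#' attention weights, biases, batch-norm scale/shift, fusion weights);
#' batch-norm running statistics are state, not parameters.
#'
#' @param model A detector from [build_detector()].
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  tot <- 0
  for (nd in model$nodes) tot <- tot + sum(vapply(nd$ly$par, length, numeric(1)))
  as.integer(tot)
}

# Propagate (H, W) through the graph; channel bookkeeping is implicit in
# the layer configs.
infer_shapes <- function(model, input_size) {
  hw <- vector("list", length(model$nodes))
  for (i in seq_along(model$nodes)) {
    nd <- model$nodes[[i]]
    ly <- nd$ly
    s <- if (length(nd$from) == 0) c(input_size, input_size) else hw[[nd$from[1]]]
    hw[[i]] <- switch(ly$type,
      conv_bn_act = ,
      dwconv_bn_act = ,
      odconv_bn_act = ,
      conv_bias = floor((s + 2 * ly$pad - ly$k) / ly$stride) + 1,
      maxpool = floor((s + 2 * ly$pad - ly$k) / ly$stride) + 1,
      upsample2 = 2 * s,
      s)
  }
  hw
}

#' Count forward-pass FLOPs of a detector
#'
#' Analytic count over convolution and linear layers at the given square
#' input size, using the 2-FLOPs-per-multiply-accumulate convention
#' (ODConv attention FC branches included; pooling, normalisation,
#' activations and elementwise fusions excluded).
#'
#' @param model A detector from [build_detector()].
#' @param input_size Square input size in pixels (default: the model's
#'   configured size).
#' @return Total FLOPs (raw count; divide by 1e9 for GFLOPs).
#' @export
count_flops <- function(model, input_size = model$cfg$input_size) {
  hw <- infer_shapes(model, input_size)
  tot <- 0
  for (i in seq_along(model$nodes)) {
    ly <- model$nodes[[i]]$ly
    o <- hw[[i]]
    px <- prod(o)
    tot <- tot + switch(ly$type,
      conv_bn_act = 2 * ly$k^2 * ly$cin * ly$cout * px,
      conv_bias = 2 * ly$k^2 * ly$cin * ly$cout * px + ly$cout * px,
      dwconv_bn_act = 2 * ly$k^2 * ly$cout * px,
      odconv_bn_act = 2 * ly$k^2 * ly$cin * ly$cout * px +
        2 * (ly$cin * ly$hidden +
               ly$hidden * (ly$k^2 + ly$cin + ly$cout + ly$n_kernels)),
      0)
  }
  tot
}

# iterate over (node, parameter name) pairs for the optimizer
for_each_param <- function(model, f) {
  for (i in seq_along(model$nodes)) {
    ly <- model$nodes[[i]]$ly
    for (nm in names(ly$par)) f(ly, nm)
  }
  invisible(NULL)
}
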