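# Minimal 2D convolutional network engine used by the translation model.
# Layers are plain lists; convolution kernels run in C++ (src/ops.cpp), the
# graph bookkeeping, activations and optimizers live here. Patches are
# (H, W, C) arrays.

act_fwd <- function(pre, act) {
  switch(act,
    linear = pre,
    relu = pre * (pre > 0),
    lrelu = pre * (pre > 0) + 0.2 * pre * (pre <= 0),
    tanh = tanh(pre),
    stop("unknown activation ", act))
}

act_bwd <- function(g, pre, act) {
  switch(act,
    linear = g,
    relu = g * (pre > 0),
    lrelu = g * ((pre > 0) + 0.2 * (pre <= 0)),
    tanh = g * (1 - tanh(pre)^2),
    stop("unknown activation ", act))
}

init_conv_w <- function(kh, kw, cin, cout, gain = 1) {
  w <- array(rnorm(kh * kw * cin * cout, 0, gain * sqrt(2 / (kh * kw * cin))),
             dim = c(kh, kw, cin, cout))
  w
}

layer_conv <- function(kh, cin, cout, stride = 1L, pad = 1L, act = "relu",
                       gain = 1) {
  list(type = "conv", w = init_conv_w(kh, kh, cin, cout, gain),
       b = numeric(cout), stride = as.integer(stride), pad = as.integer(pad),
       act = act)
}

layer_res <- function(ch) {
  list(type = "res",
       w1 = init_conv_w(3, 3, ch, ch), b1 = numeric(ch),
       w2 = init_conv_w(3, 3, ch, ch), b2 = numeric(ch))
}

layer_up <- function() list(type = "up")

up_fwd <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]
  x[rep(seq_len(h), each = 2), rep(seq_len(w), each = 2), , drop = FALSE]
}

up_bwd <- function(gy) {
  h2 <- dim(gy)[1]; w2 <- dim(gy)[2]
  g1 <- gy[seq(1, h2, 2), , , drop = FALSE] + gy[seq(2, h2, 2), , , drop = FALSE]
  g1[, seq(1, w2, 2), , drop = FALSE] + g1[, seq(2, w2, 2), , drop = FALSE]
}

net_forward <- function(layers, x, keep = FALSE) {
  caches <- if (keep) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      pre <- .conv2d_fwd(x, l$w, l$b, l$stride, l$pad)
      y <- act_fwd(pre, l$act)
      if (keep) caches[[i]] <- list(x = x, pre = pre)
    } else if (l$type == "res") {
      pre1 <- .conv2d_fwd(x, l$w1, l$b1, 1L, 1L)
      a1 <- act_fwd(pre1, "relu")
      h2 <- .conv2d_fwd(a1, l$w2, l$b2, 1L, 1L)
      y <- x + h2
      if (keep) caches[[i]] <- list(x = x, pre1 = pre1, a1 = a1)
    } else if (l$type == "up") {
      y <- up_fwd(x)
      if (keep) caches[[i]] <- list()
    } else stop("unknown layer type")
    x <- y
  }
  list(y = x, caches = caches)
}

net_backward <- function(layers, caches, gy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    cc <- caches[[i]]
    if (l$type == "conv") {
      gpre <- act_bwd(gy, cc$pre, l$act)
      bw <- .conv2d_bwd(cc$x, l$w, gpre, l$stride, l$pad)
      grads[[i]] <- list(w = bw$gw, b = bw$gb)
      gy <- bw$gx
    } else if (l$type == "res") {
      bw2 <- .conv2d_bwd(cc$a1, l$w2, gy, 1L, 1L)
      gpre1 <- act_bwd(bw2$gx, cc$pre1, "relu")
      bw1 <- .conv2d_bwd(cc$x, l$w1, gpre1, 1L, 1L)
      grads[[i]] <- list(w1 = bw1$gw, b1 = bw1$gb, w2 = bw2$gw, b2 = bw2$gb)
      gy <- gy + bw1$gx
    } else if (l$type == "up") {
      grads[[i]] <- list()
      gy <- up_bwd(gy)
    }
  }
  list(gx = gy, grads = grads)
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (i in seq_along(b))
    for (nm in names(b[[i]]))
      a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  a
}

make_opt_state <- function(layers) {
  lapply(layers, function(l) {
    pn <- setdiff(names(l), c("type", "stride", "pad", "act"))
    st <- list()
    for (nm in pn) st[[nm]] <- list(m = l[[nm]] * 0, v = l[[nm]] * 0)
    st
  })
}

opt_update <- function(layers, grads, state, opt) {
  t <- opt$t
  for (i in seq_along(layers)) {
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      if (opt$kind == "sgd") {
        layers[[i]][[nm]] <- layers[[i]][[nm]] - opt$lr * g
      } else {  # adam
        s <- state[[i]][[nm]]
        s$m <- opt$beta1 * s$m + (1 - opt$beta1) * g
        s$v <- opt$beta2 * s$v + (1 - opt$beta2) * g^2
        mh <- s$m / (1 - opt$beta1^t)
        vh <- s$v / (1 - opt$beta2^t)
        layers[[i]][[nm]] <- layers[[i]][[nm]] - opt$lr * mh / (sqrt(vh) + opt$eps)
        state[[i]][[nm]] <- s
      }
    }
  }
  list(layers = layers, state = state)
}
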