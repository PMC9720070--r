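# Minimal reverse-mode autodiff tape over 3D feature maps (H x W x C).
# Operations: convolution (GEMM kernels in src/), batch normalization
# (batch of one: statistics over the spatial plane; running averages
# used at inference), ReLU, add, channel concat, 2x2 max pool, 2x2
# stride-2 transposed convolution, and binary cross-entropy with
# logits. Parameters live in an environment and are created lazily on
# the first (seeded) forward pass, so the architecture definition and
# its initialization cannot drift apart.

new_tape <- function(params, bn_state, training = TRUE, init = FALSE) {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$params <- params        # environment name -> array
  t$bn <- bn_state          # environment name -> list(mean, var)
  t$training <- training
  t$init <- init
  t
}

push_node <- function(tape, op, val, parents = integer(0), extra = NULL) {
  # force arguments before claiming an id: evaluating them may push
  # nested nodes onto the tape
  force(val); force(parents); force(extra)
  id <- length(tape$nodes) + 1L
  tape$nodes[[id]] <- list(op = op, val = val, parents = parents,
                           extra = extra)
  id
}

node_val <- function(tape, id) {
  force(id)  # id may be an un-forced node-producing call; push it first
  tape$nodes[[id]]$val
}

init_param <- function(tape, name, dim, fan_in = NULL) {
  if (!is.null(tape$params[[name]])) return(invisible())
  stop_if_not(tape$init, "unknown parameter '%s' on a non-init tape", name)
  if (is.null(fan_in)) {
    tape$params[[name]] <- array(0, dim)         # biases, BN beta
  } else if (is.na(fan_in)) {
    tape$params[[name]] <- array(1, dim)         # BN gamma
  } else {
    lim <- sqrt(6 / fan_in)                      # He-uniform
    tape$params[[name]] <- array(stats::runif(prod(dim), -lim, lim), dim)
  }
  invisible()
}

tv_input <- function(tape, x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  push_node(tape, "input", x)
}

tv_conv <- function(tape, xid, name, cout, k = 3L) {
  x <- node_val(tape, xid)
  cin <- dim(x)[3]
  pad <- (k - 1L) %/% 2L
  init_param(tape, paste0(name, ".W"), c(k * k * cin, cout),
             fan_in = k * k * cin)
  init_param(tape, paste0(name, ".b"), cout)
  W <- tape$params[[paste0(name, ".W")]]
  b <- tape$params[[paste0(name, ".b")]]
  y <- conv2d_fw(x, W, b, k, pad)
  push_node(tape, "conv", y, xid,
            list(name = name, k = k, pad = pad, cin = cin))
}

tv_upconv <- function(tape, xid, name, cout) {
  x <- node_val(tape, xid)
  cin <- dim(x)[3]
  init_param(tape, paste0(name, ".W"), c(4L * cin, cout), fan_in = 4 * cin)
  init_param(tape, paste0(name, ".b"), cout)
  y <- upconv2_fw(x, tape$params[[paste0(name, ".W")]],
                  tape$params[[paste0(name, ".b")]])
  push_node(tape, "upconv", y, xid, list(name = name))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

tv_bn <- function(tape, xid, name) {
  x <- node_val(tape, xid)
  d <- dim(x)
  C <- d[3]
  init_param(tape, paste0(name, ".gamma"), C, fan_in = NA)
  init_param(tape, paste0(name, ".beta"), C)
  if (is.null(tape$bn[[name]])) {
    stop_if_not(tape$init || !tape$training,
                "unknown BN state '%s'", name)
    tape$bn[[name]] <- list(mean = numeric(C), var = rep(1, C))
  }
  gamma <- tape$params[[paste0(name, ".gamma")]]
  beta <- tape$params[[paste0(name, ".beta")]]
  n <- d[1] * d[2]
  m <- x; dim(m) <- c(n, C)
  if (tape$training) {
    mu <- colMeans(m)
    v <- colMeans(m^2) - mu^2
    st <- tape$bn[[name]]
    tape$bn[[name]] <- list(
      mean = (1 - BN_MOMENTUM) * st$mean + BN_MOMENTUM * mu,
      var = (1 - BN_MOMENTUM) * st$var + BN_MOMENTUM * v)
  } else {
    st <- tape$bn[[name]]
    mu <- st$mean; v <- st$var
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  r <- bn_fw(m, gamma, beta, mu, invstd)
  y <- r$y
  dim(y) <- d
  push_node(tape, "bn", y, xid,
            list(name = name, xhat = r$xhat, invstd = invstd, n = n, C = C))
}

tv_relu <- function(tape, xid) {
  push_node(tape, "relu", relu_fw(node_val(tape, xid)), xid)
}

tv_add <- function(tape, aid, bid) {
  push_node(tape, "add", node_val(tape, aid) + node_val(tape, bid),
            c(aid, bid))
}

tv_concat <- function(tape, ids) {
  vals <- lapply(ids, function(i) node_val(tape, i))
  d <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[3], numeric(1))
  y <- array(0, c(d[1], d[2], sum(cs)))
  at <- 0L
  for (v in vals) {
    y[, , at + seq_len(dim(v)[3])] <- v
    at <- at + dim(v)[3]
  }
  push_node(tape, "concat", y, as.integer(ids), list(channels = cs))
}

tv_maxpool <- function(tape, xid) {
  r <- maxpool2_fw(node_val(tape, xid))
  push_node(tape, "maxpool", r$y, xid, list(idx = r$idx))
}

# Numerically stable BCE-with-logits, mean over pixels.
bce_with_logits <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

tv_bce <- function(tape, zid, target) {
  z <- node_val(tape, zid)
  loss <- bce_with_logits(z, target)
  push_node(tape, "bce", loss, zid, list(target = target))
}

# Reverse pass: returns environment name -> parameter gradient.
tape_backward <- function(tape, loss_id) {
  grads <- vector("list", length(tape$nodes))
  pgrads <- new.env(parent = emptyenv())
  acc_p <- function(name, g) {
    cur <- pgrads[[name]]
    pgrads[[name]] <- if (is.null(cur)) g else cur + g
  }
  acc_n <- function(id, g) {
    grads[[id]] <<- if (is.null(grads[[id]])) g else grads[[id]] + g
  }
  grads[[loss_id]] <- 1
  for (id in rev(seq_len(loss_id))) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- tape$nodes[[id]]
    switch(nd$op,
      input = NULL,
      bce = {
        z <- node_val(tape, nd$parents)
        acc_n(nd$parents, g * (1 / (1 + exp(-z)) - nd$extra$target) /
                length(z))
      },
      conv = {
        W <- tape$params[[paste0(nd$extra$name, ".W")]]
        r <- conv2d_bw(node_val(tape, nd$parents), W, g, nd$extra$k,
                       nd$extra$pad)
        acc_p(paste0(nd$extra$name, ".W"), r$gW)
        acc_p(paste0(nd$extra$name, ".b"), r$gb)
        acc_n(nd$parents, r$gx)
      },
      upconv = {
        x <- node_val(tape, nd$parents)
        W <- tape$params[[paste0(nd$extra$name, ".W")]]
        r <- upconv2_bw(x, W, g)
        acc_p(paste0(nd$extra$name, ".W"), r$gW)
        acc_p(paste0(nd$extra$name, ".b"), r$gb)
        acc_n(nd$parents, r$gx)
      },
      bn = {
        ex <- nd$extra
        gm <- g; dim(gm) <- c(ex$n, ex$C)
        gamma <- tape$params[[paste0(ex$name, ".gamma")]]
        r <- bn_bw(gm, ex$xhat, gamma, ex$invstd, tape$training)
        acc_p(paste0(ex$name, ".beta"), r$gbeta)
        acc_p(paste0(ex$name, ".gamma"), r$ggamma)
        gx <- r$gx
        dim(gx) <- dim(node_val(tape, nd$parents))
        acc_n(nd$parents, gx)
      },
      relu = {
        acc_n(nd$parents, relu_bw(node_val(tape, nd$parents), g))
      },
      add = {
        acc_n(nd$parents[1], g)
        acc_n(nd$parents[2], g)
      },
      concat = {
        at <- 0L
        for (t in seq_along(nd$parents)) {
          ck <- nd$extra$channels[t]
          acc_n(nd$parents[t], g[, , at + seq_len(ck), drop = FALSE])
          at <- at + ck
        }
      },
      maxpool = {
        acc_n(nd$parents, maxpool2_bw(nd$extra$idx, g))
      },
      stop(sprintf("no backward rule for op '%s'", nd$op)))
  }
  pgrads
}

# One Adam update over all parameters with gradients.
adam_step <- function(params, opt, pgrads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- (opt$t %||% 0L) + 1L
  corr1 <- 1 - beta1^opt$t
  corr2 <- 1 - beta2^opt$t
  for (name in ls(pgrads)) {
    # kernels may return n x 1 matrices for vector parameters
    g <- array(as.numeric(pgrads[[name]]), dim(as.array(params[[name]])))
    m <- opt$m[[name]] %||% array(0, dim(as.array(g)))
    v <- opt$v[[name]] %||% array(0, dim(as.array(g)))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    opt$m[[name]] <- m
    opt$v[[name]] <- v
    params[[name]] <- params[[name]] -
      lr * (m / corr1) / (sqrt(v / corr2) + eps)
  }
  invisible()
}
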