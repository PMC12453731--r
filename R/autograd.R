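# Minimal reverse-mode tape for the network core.
#
# Feature maps are dense arrays with dim (C, L, N): channels, positions, batch.
# Pooled/dense activations are (C, N) matrices.  Each op appends a node with
# the forward value and a backward closure mapping the output gradient to the
# gradients of its parents.  Gradients of parameter leaves are accumulated by
# parameter name so the optimizer can address them directly.

tape_new <- function(training = FALSE, grad = training,
                     precision = getOption("cardiofuse.precision", "single")) {
  tp <- new.env(parent = emptyenv())
  tp$parents <- list()
  tp$bw <- list()
  tp$pname <- list()     # parameter name for leaf nodes, else NULL
  tp$n <- 0L
  tp$training <- isTRUE(training)
  tp$grad <- isTRUE(grad)
  tp$single <- identical(precision, "single")
  tp
}

# Node values are NOT retained on the tape: each backward closure captures
# exactly the arrays it needs, so activations nothing captures (e.g. a
# batch-norm output feeding a ReLU) are freed by the GC as the forward pass
# lets go of them.  In no-grad mode nothing at all is retained.
ag_push <- function(tp, val, parents = integer(), bw = NULL, pname = NULL) {
  if (!tp$grad) return(list(id = 0L, val = val))
  i <- tp$n + 1L
  tp$n <- i
  tp$parents[[i]] <- parents
  tp$bw[i] <- list(bw)        # list-assign so NULL entries survive
  tp$pname[i] <- list(pname)
  list(id = i, val = val)
}

ag_input <- function(tp, val) ag_push(tp, val)

ag_param <- function(tp, pe, name) {
  val <- get(name, envir = pe)
  ag_push(tp, val, pname = name)
}

# Backward pass from scalar node `root`; returns named list of parameter
# gradients (missing names have zero gradient).  Node values and closures
# are released as the sweep passes them so peak memory stays near the
# forward-pass activation footprint.
ag_backward <- function(tp, root) {
  grads <- vector("list", tp$n)
  grads[[root$id]] <- 1
  pgrads <- list()
  for (i in seq(root$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nm <- tp$pname[[i]]
    if (!is.null(nm)) {
      pgrads[[nm]] <- if (is.null(pgrads[[nm]])) g else pgrads[[nm]] + g
      grads[[i]] <- NULL
      next
    }
    fn <- tp$bw[[i]]
    if (!is.null(fn)) {
      pg <- fn(g)
      ps <- tp$parents[[i]]
      for (j in seq_along(ps)) {
        p <- ps[j]
        if (p == 0L || is.null(pg[[j]])) next
        grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
      }
    }
    grads[[i]] <- NULL
    tp$bw[i] <- list(NULL)   # release the closure and its captured arrays
  }
  pgrads
}

same_pad <- function(l, k, stride, left_heavy = FALSE) {
  lout <- as.integer(ceiling(l / stride))
  total <- max((lout - 1L) * stride + k - l, 0L)
  pl <- if (left_heavy) as.integer(ceiling(total / 2)) else total %/% 2L
  list(l_out = lout, pad_left = as.integer(pl))
}

ag_conv1d <- function(tp, x, w, b = NULL, stride = 1L, k = NULL,
                      pad_left = NULL) {
  d <- dim(x$val)
  if (is.null(k)) k <- ncol(w$val) / d[1]
  if (is.null(pad_left)) {
    sp <- same_pad(d[2], k, stride)
    pad_left <- sp$pad_left
    l_out <- sp$l_out
  } else l_out <- as.integer(ceiling(d[2] / stride))
  bias <- if (is.null(b)) NULL else b$val
  y <- .conv1d_fw(x$val, w$val, bias, as.integer(stride),
                  as.integer(pad_left), l_out, tp$single)
  xv <- x$val; wv <- w$val
  need_bias <- !is.null(b)
  single <- tp$single
  ag_push(tp, y,
          parents = c(x$id, w$id, if (need_bias) b$id else 0L),
          bw = function(gy) {
            gr <- .conv1d_bw(xv, wv, gy, as.integer(stride),
                             as.integer(pad_left), need_bias, single)
            list(gr$gx, gr$gw, if (need_bias) gr$gb else NULL)
          })
}

ag_relu <- function(tp, x) {
  y <- .relu_fw(x$val)
  ag_push(tp, y, parents = x$id,
          bw = function(gy) list(.relu_bw(y, gy)))
}

ag_sigmoid <- function(tp, x) {
  y <- 1 / (1 + exp(-x$val))
  ag_push(tp, y, parents = x$id, bw = function(gy) list(gy * y * (1 - y)))
}

ag_add <- function(tp, a, b) {
  ag_push(tp, a$val + b$val, parents = c(a$id, b$id),
          bw = function(gy) list(gy, gy))
}

# Batch normalization over (L, N) per channel; `rm`/`rv` are names of running
# statistics inside the state environment `se` (updated in training mode).
ag_bn <- function(tp, x, gamma, beta, se, key, momentum = 0.1, eps = 1e-5) {
  d <- dim(x$val)
  C <- d[1]; M <- prod(d[-1])
  if (!is.null(tp$bn_momentum)) momentum <- tp$bn_momentum
  if (tp$training) {
    st <- .bn_stats(x$val, C)
    m <- st$mean
    v <- st$var
    rmk <- paste0(key, ".rm"); rvk <- paste0(key, ".rv")
    unb <- if (M > 1) M / (M - 1) else 1
    assign(rmk, (1 - momentum) * get(rmk, se) + momentum * m, envir = se)
    assign(rvk, (1 - momentum) * get(rvk, se) + momentum * v * unb, envir = se)
  } else {
    m <- get(paste0(key, ".rm"), se)
    v <- get(paste0(key, ".rv"), se)
  }
  ivar <- 1 / sqrt(v + eps)
  y <- .chan_affine(x$val, gamma$val * ivar, beta$val - gamma$val * ivar * m)
  training <- tp$training
  gv <- gamma$val
  xv <- x$val
  ag_push(tp, y, parents = c(x$id, gamma$id, beta$id),
          bw = function(gy) {
            r <- .bn_bw(xv, gy, m, ivar, gv, training)
            list(r$gx, r$ggamma, r$gbeta)
          })
}

# x: (C, L, N) scaled per-channel by g: (C, N) gate.
ag_scale_channels <- function(tp, x, g) {
  d <- dim(x$val)
  C <- d[1]; L <- d[2]; N <- d[3]
  y <- .mul_chan(x$val, g$val, L)
  xv <- x$val
  gval <- g$val
  ag_push(tp, y, parents = c(x$id, g$id),
          bw = function(gy) {
            list(.mul_chan(gy, gval, L), .sum_mul_over_l(gy, xv, C, L, N))
          })
}

# x: (C, L, N) scaled per-position by m: (1, L, N) map.
ag_scale_positions <- function(tp, x, m) {
  d <- dim(x$val)
  C <- d[1]; L <- d[2]; N <- d[3]
  y <- .mul_pos(x$val, m$val, C)
  xv <- x$val
  mval <- m$val
  ag_push(tp, y, parents = c(x$id, m$id),
          bw = function(gy) {
            gm <- .sum_mul_over_c(gy, xv, C)
            dim(gm) <- c(1L, L, N)
            list(.mul_pos(gy, mval, C), gm)
          })
}

# x: (C, L, N) plus a single-channel signal r: (1, L, N), broadcast over C.
ag_add_bcast_channels <- function(tp, x, r) {
  d <- dim(x$val)
  C <- d[1]; L <- d[2]; N <- d[3]
  y <- .add_pos(x$val, r$val, C)
  ag_push(tp, y, parents = c(x$id, r$id),
          bw = function(gy) {
            gr <- .sum_over_c(gy, C)
            dim(gr) <- c(1L, L, N)
            list(gy, gr)
          })
}

ag_concat_c <- function(tp, a, b) {
  C1 <- dim(a$val)[1]
  C2 <- dim(b$val)[1]
  y <- .concat_rows(a$val, b$val)
  ag_push(tp, y, parents = c(a$id, b$id),
          bw = function(gy) {
            list(.slice_rows(gy, 1L, C1),
                 .slice_rows(gy, C1 + 1L, C1 + C2))
          })
}

ag_slice_c <- function(tp, x, from, to) {
  C <- dim(x$val)[1]
  y <- .slice_rows(x$val, as.integer(from), as.integer(to))
  ag_push(tp, y, parents = x$id,
          bw = function(gy) list(.unslice_rows(gy, as.integer(from), C)))
}

ag_avgpool <- function(tp, x, window) {
  l_in <- dim(x$val)[2]
  y <- .avgpool1d_fw(x$val, as.integer(window))
  ag_push(tp, y, parents = x$id,
          bw = function(gy) list(.avgpool1d_bw(gy, as.integer(window),
                                               as.integer(l_in))))
}

# Global average pool over positions: (C, L, N) -> (C, N).
ag_gap <- function(tp, x) {
  d <- dim(x$val)
  C <- d[1]; L <- d[2]; N <- d[3]
  y <- .avgpool1d_fw(x$val, as.integer(L))
  dim(y) <- c(C, N)
  ag_push(tp, y, parents = x$id,
          bw = function(gy) {
            g3 <- gy
            dim(g3) <- c(C, 1L, N)
            list(.avgpool1d_bw(g3, as.integer(L), as.integer(L)))
          })
}

# Dense layer on (Cin, N) activations: y = W x + b.
ag_dense <- function(tp, x, w, b = NULL) {
  y <- w$val %*% x$val
  if (!is.null(b)) y <- y + b$val
  xv <- x$val; wv <- w$val
  has_b <- !is.null(b)
  ag_push(tp, y, parents = c(x$id, w$id, if (has_b) b$id else 0L),
          bw = function(gy) {
            list(crossprod(wv, gy), tcrossprod(gy, xv),
                 if (has_b) rowSums(gy) else NULL)
          })
}

# Inverted dropout; identity at inference and in stats-only training
# forwards (no grad), so BN recalibration leaves the RNG stream untouched.
ag_dropout <- function(tp, x, p) {
  if (!tp$training || !tp$grad || p <= 0) return(x)
  mask <- (runif(length(x$val)) >= p) / (1 - p)
  dim(mask) <- dim(x$val)
  ag_push(tp, x$val * mask, parents = x$id,
          bw = function(gy) list(gy * mask))
}

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}

# Weighted softmax cross-entropy over a batch.  `y` holds labels in {0, 1}
# (row index y+1 is the true class); `cw` one weight per class, so a balanced
# normalization (all-ones weights) reduces to the plain mean cross-entropy.
ag_softmax_ce <- function(tp, logits, y, cw = c(1, 1)) {
  p <- softmax_cols(logits$val)
  n <- length(y)
  wi <- cw[y + 1L]
  wsum <- sum(wi)
  idx <- cbind(y + 1L, seq_len(n))
  loss <- sum(wi * -log(pmax(p[idx], 1e-12))) / wsum
  node <- ag_push(tp, loss, parents = logits$id,
                  bw = function(gy) {
                    g <- p
                    g[idx] <- g[idx] - 1
                    g <- g * rep(wi, each = nrow(p)) / wsum
                    list(gy * g)
                  })
  node$probs <- p
  node
}

ag_scale <- function(tp, x, s) {
  ag_push(tp, x$val * s, parents = x$id, bw = function(gy) list(gy * s))
}
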