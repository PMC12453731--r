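# Network construction and forward passes for all architecture variants.
#
# A model is a list: variant id, cf_config, a parameter environment (trainable
# arrays addressed by hierarchical names such as "ecg.l2.res1.c1.W"), a state
# environment (batch-norm running statistics), and the attention/injection
# switches the variant implies.  Forward passes are built on the reverse-mode
# tape in autograd.R, so the same code serves inference and training.

he_conv <- function(cout, cin, k) {
  matrix(rnorm(cout * cin * k, 0, sqrt(2 / (cin * k))), cout, cin * k)
}

he_dense <- function(cout, cin) {
  matrix(rnorm(cout * cin, 0, sqrt(2 / cin)), cout, cin)
}

add_conv <- function(pe, name, cin, cout, k, bias = FALSE) {
  assign(paste0(name, ".W"), he_conv(cout, cin, k), envir = pe)
  if (bias) assign(paste0(name, ".b"), numeric(cout), envir = pe)
}

add_bn <- function(pe, se, name, C) {
  assign(paste0(name, ".g"), rep(1, C), envir = pe)
  assign(paste0(name, ".be"), numeric(C), envir = pe)
  assign(paste0(name, ".rm"), numeric(C), envir = se)
  assign(paste0(name, ".rv"), rep(1, C), envir = se)
}

add_dense <- function(pe, name, cin, cout) {
  assign(paste0(name, ".W"), he_dense(cout, cin), envir = pe)
  assign(paste0(name, ".b"), numeric(cout), envir = pe)
}

se_bottleneck <- function(C, ratio) max(C %/% ratio, 1L)

add_res_params <- function(pe, se, name, C, se_ratio) {
  add_conv(pe, paste0(name, ".c1"), C, C, 7L)   # kernel fixed by cfg at fw
  add_bn(pe, se, paste0(name, ".bn1"), C)
  add_conv(pe, paste0(name, ".c2"), C, C, 7L)
  add_bn(pe, se, paste0(name, ".bn2"), C)
  cb <- se_bottleneck(C, se_ratio)
  add_dense(pe, paste0(name, ".se.f1"), C, cb)
  add_dense(pe, paste0(name, ".se.f2"), cb, C)
}

add_encoder_params <- function(pe, se, prefix, cin, cfg) {
  for (lvl in 1:4) {
    C <- cfg$channels[lvl]
    cin_l <- if (lvl == 1) cin else cfg$channels[lvl - 1]
    add_conv(pe, paste0(prefix, ".l", lvl, ".cbr"), cin_l, C, cfg$kernel)
    add_bn(pe, se, paste0(prefix, ".l", lvl, ".cbr.bn"), C)
    add_res_params(pe, se, paste0(prefix, ".l", lvl, ".res1"), C, cfg$se_ratio)
    add_res_params(pe, se, paste0(prefix, ".l", lvl, ".res2"), C, cfg$se_ratio)
  }
}

add_sacmf_params <- function(pe, se, lvl, cfg, with_prev, use_sa, use_ca) {
  C <- cfg$channels[lvl]
  C2in <- 2L * C + if (with_prev) cfg$channels[lvl - 1] else 0L
  p <- paste0("fus.l", lvl)
  if (use_sa) {
    mid <- max((2L * C) %/% cfg$sa_reduce, cfg$sa_min_mid)
    add_conv(pe, paste0(p, ".sa.c1"), 2L * C, mid, 1L, bias = TRUE)
    add_conv(pe, paste0(p, ".sa.c2"), mid, mid, cfg$sa_kernel, bias = TRUE)
    add_conv(pe, paste0(p, ".sa.c3"), mid, 2L, 1L, bias = TRUE)
  }
  if (use_ca) {
    cb <- se_bottleneck(2L * C, cfg$ca_ratio)
    add_dense(pe, paste0(p, ".ca.f1"), 2L * C, cb)
    add_dense(pe, paste0(p, ".ca.f2"), cb, 2L * C)
  }
  add_bn(pe, se, paste0(p, ".c2.bn"), C2in)
  add_conv(pe, paste0(p, ".c2"), C2in, C, cfg$kernel, bias = TRUE)
}

add_head_params <- function(pe, cfg) {
  C <- cfg$channels[4]
  add_conv(pe, "head.conv", C, C, cfg$head_kernel, bias = TRUE)
  cin <- C
  for (i in seq_along(cfg$head_dense)) {
    add_dense(pe, paste0("head.d", i), cin, cfg$head_dense[i])
    cin <- cfg$head_dense[i]
  }
  add_dense(pe, "head.out", cin, 2L)
}

#' Build a fusion-network model
#'
#' Instantiates one of the architecture variants with He-initialized weights.
#' The `"full"` variant is the three-branch network: two modality encoders
#' plus the four-level progressive attention fusion branch and classification
#' head. Ablation variants share the same encoder and head structure; see
#' [cf_variants()].
#'
#' @param variant One of [cf_variants()].
#' @param cfg A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `cf_model`.
#' @export
build_model <- function(variant = "full", cfg = model_config(), seed = 1L) {
  variant <- match.arg(variant, cf_variants())
  pe <- new.env(parent = emptyenv())
  se <- new.env(parent = emptyenv())
  use_sa <- variant %in% c("full", "only_last_sacmf", "sa_only")
  use_ca <- variant %in% c("full", "only_last_sacmf", "ca_only")
  fusion_levels <- if (variant %in% c("full", "concat_only", "sa_only", "ca_only"))
    1:4 else if (variant == "only_last_sacmf") 4L else integer()
  with_seed(seed, {
    if (variant == "early_fusion") {
      add_encoder_params(pe, se, "enc", 2L, cfg)
    } else if (variant == "single_ecg") {
      add_encoder_params(pe, se, "ecg", 1L, cfg)
    } else if (variant == "single_pcg") {
      add_encoder_params(pe, se, "pcg", 1L, cfg)
    } else {
      add_encoder_params(pe, se, "ecg", 1L, cfg)
      add_encoder_params(pe, se, "pcg", 1L, cfg)
    }
    for (lvl in fusion_levels) {
      with_prev <- lvl > 1 && variant != "only_last_sacmf"
      add_sacmf_params(pe, se, lvl, cfg, with_prev, use_sa, use_ca)
    }
    if (variant == "late_fusion") {
      add_conv(pe, "late.proj", 2L * cfg$channels[4], cfg$channels[4],
               cfg$kernel, bias = TRUE)
    }
    add_head_params(pe, cfg)
  })
  structure(list(variant = variant, cfg = cfg, params = pe, state = se,
                 seed = seed, use_sa = use_sa, use_ca = use_ca,
                 raw_injection = TRUE),
            class = "cf_model")
}

#' @export
print.cf_model <- function(x, ...) {
  cat("<cf_model> variant:", x$variant,
      "| input:", x$cfg$input_len, "samples/modality",
      "| parameters:", format(cf_n_params(x), big.mark = ","), "\n")
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `cf_model`.
#' @return Integer count of trainable scalar parameters.
#' @export
cf_n_params <- function(model) {
  sum(vapply(ls(model$params), function(n) length(get(n, model$params)),
             numeric(1)))
}

trace_put <- function(m, key, val) {
  if (!is.null(m$trace)) assign(key, val, envir = m$trace)
}

P <- function(tp, m, name) ag_param(tp, m$params, name)

fw_cbr <- function(tp, m, prefix, x, stride) {
  h <- ag_conv1d(tp, x, P(tp, m, paste0(prefix, ".W")), stride = stride,
                 k = m$cfg$kernel)
  h <- ag_bn(tp, h, P(tp, m, paste0(prefix, ".bn.g")),
             P(tp, m, paste0(prefix, ".bn.be")), m$state, paste0(prefix, ".bn"))
  ag_relu(tp, h)
}

fw_se <- function(tp, m, prefix, x) {
  g <- ag_gap(tp, x)
  g <- ag_relu(tp, ag_dense(tp, g, P(tp, m, paste0(prefix, ".f1.W")),
                            P(tp, m, paste0(prefix, ".f1.b"))))
  g <- ag_sigmoid(tp, ag_dense(tp, g, P(tp, m, paste0(prefix, ".f2.W")),
                               P(tp, m, paste0(prefix, ".f2.b"))))
  trace_put(m, paste0(prefix, ".gate"), g$val)
  ag_scale_channels(tp, x, g)
}

fw_res <- function(tp, m, prefix, x) {
  k <- m$cfg$kernel
  h <- ag_conv1d(tp, x, P(tp, m, paste0(prefix, ".c1.W")), stride = 1L, k = k)
  h <- ag_bn(tp, h, P(tp, m, paste0(prefix, ".bn1.g")),
             P(tp, m, paste0(prefix, ".bn1.be")), m$state, paste0(prefix, ".bn1"))
  h <- ag_relu(tp, h)
  h <- ag_conv1d(tp, h, P(tp, m, paste0(prefix, ".c2.W")), stride = 1L, k = k)
  h <- ag_bn(tp, h, P(tp, m, paste0(prefix, ".bn2.g")),
             P(tp, m, paste0(prefix, ".bn2.be")), m$state, paste0(prefix, ".bn2"))
  h <- fw_se(tp, m, paste0(prefix, ".se"), h)
  ag_relu(tp, ag_add(tp, h, x))
}

# Channel-mean of a possibly multi-channel raw input, pooled to the level
# input length; parameter-free.
pool_raw <- function(tp, x_raw, window) {
  C <- dim(x_raw$val)[1]
  r <- if (C == 1L) x_raw else {
    acc <- ag_slice_c(tp, x_raw, 1L, 1L)
    for (c in 2:C) acc <- ag_add(tp, acc, ag_slice_c(tp, x_raw, c, c))
    ag_scale(tp, acc, 1 / C)
  }
  ag_avgpool(tp, r, window)
}

fw_encoder <- function(tp, m, prefix, x_raw) {
  cfg <- m$cfg
  feats <- vector("list", 4L)
  x <- x_raw
  for (lvl in 1:4) {
    if (lvl >= 3 && isTRUE(m$raw_injection)) {
      pooled <- pool_raw(tp, x_raw, cfg$ap_windows[lvl - 2L])
      x <- ag_add_bcast_channels(tp, x, pooled)
    }
    x <- fw_cbr(tp, m, paste0(prefix, ".l", lvl, ".cbr"), x, cfg$strides[lvl])
    x <- fw_res(tp, m, paste0(prefix, ".l", lvl, ".res1"), x)
    x <- fw_res(tp, m, paste0(prefix, ".l", lvl, ".res2"), x)
    trace_put(m, paste0(prefix, ".l", lvl), x$val)
    feats[[lvl]] <- x
  }
  feats
}

fw_sacmf <- function(tp, m, lvl, fe, fp, fprev) {
  cfg <- m$cfg
  p <- paste0("fus.l", lvl)
  cc <- ag_concat_c(tp, fe, fp)
  if (isTRUE(m$use_sa)) {
    a <- ag_relu(tp, ag_conv1d(tp, cc, P(tp, m, paste0(p, ".sa.c1.W")),
                               P(tp, m, paste0(p, ".sa.c1.b")), k = 1L))
    sp <- same_pad(dim(a$val)[2], cfg$sa_kernel, 1L, left_heavy = TRUE)
    a <- ag_relu(tp, ag_conv1d(tp, a, P(tp, m, paste0(p, ".sa.c2.W")),
                               P(tp, m, paste0(p, ".sa.c2.b")),
                               k = cfg$sa_kernel, pad_left = sp$pad_left))
    a <- ag_sigmoid(tp, ag_conv1d(tp, a, P(tp, m, paste0(p, ".sa.c3.W")),
                                  P(tp, m, paste0(p, ".sa.c3.b")), k = 1L))
    trace_put(m, paste0(p, ".sa.maps"), a$val)
    me <- ag_slice_c(tp, a, 1L, 1L)
    mp <- ag_slice_c(tp, a, 2L, 2L)
    vs <- ag_concat_c(tp, ag_scale_positions(tp, fe, me),
                      ag_scale_positions(tp, fp, mp))
  } else {
    vs <- cc
  }
  trace_put(m, paste0(p, ".vs"), vs$val)
  if (isTRUE(m$use_ca)) {
    g <- ag_gap(tp, vs)
    g <- ag_relu(tp, ag_dense(tp, g, P(tp, m, paste0(p, ".ca.f1.W")),
                              P(tp, m, paste0(p, ".ca.f1.b"))))
    g <- ag_sigmoid(tp, ag_dense(tp, g, P(tp, m, paste0(p, ".ca.f2.W")),
                                 P(tp, m, paste0(p, ".ca.f2.b"))))
    trace_put(m, paste0(p, ".ca.gate"), g$val)
    vc <- ag_scale_channels(tp, vs, g)
  } else {
    vc <- vs
  }
  z <- if (is.null(fprev)) vc else
    ag_concat_c(tp, ag_avgpool(tp, fprev, cfg$prev_pool), vc)
  z <- ag_bn(tp, z, P(tp, m, paste0(p, ".c2.bn.g")),
             P(tp, m, paste0(p, ".c2.bn.be")), m$state, paste0(p, ".c2.bn"))
  z <- ag_conv1d(tp, z, P(tp, m, paste0(p, ".c2.W")),
                 P(tp, m, paste0(p, ".c2.b")), k = cfg$kernel)
  z <- ag_relu(tp, z)
  trace_put(m, paste0("fus.l", lvl, ".out"), z$val)
  z
}

fw_progressive_fusion <- function(tp, m, ecg_feats, pcg_feats) {
  fprev <- NULL
  for (lvl in 1:4)
    fprev <- fw_sacmf(tp, m, lvl, ecg_feats[[lvl]], pcg_feats[[lvl]], fprev)
  fprev
}

fw_head <- function(tp, m, x) {
  cfg <- m$cfg
  h <- ag_conv1d(tp, x, P(tp, m, "head.conv.W"), P(tp, m, "head.conv.b"),
                 stride = cfg$head_stride, k = cfg$head_kernel)
  trace_put(m, "head.conv", h$val)
  h <- ag_gap(tp, h)
  for (i in seq_along(cfg$head_dense)) {
    h <- ag_relu(tp, ag_dense(tp, h, P(tp, m, paste0("head.d", i, ".W")),
                              P(tp, m, paste0("head.d", i, ".b"))))
    h <- ag_dropout(tp, h, cfg$dropout)
  }
  ag_dense(tp, h, P(tp, m, "head.out.W"), P(tp, m, "head.out.b"))
}

as_input <- function(x, len) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  stopifnot(nrow(x) == len)
  array(x, c(1L, nrow(x), ncol(x)))
}

#' Forward pass of a model
#'
#' Runs one batch through the network and returns class probabilities.
#' Waveform inputs are matrices with one column per segment and
#' `cfg$input_len` rows. Single-modality variants require only their own
#' modality; all others require both.
#'
#' @param model A `cf_model`.
#' @param ecg,pcg Waveform matrices (`input_len x n`), or `NULL` for the
#'   modality a single-modality variant does not use.
#' @param training Logical; enables batch-statistics normalization and
#'   dropout (used by the trainer).
#' @param keep_trace Logical; if `TRUE`, attach an environment of named
#'   intermediate activations (`model_forward(...)$trace`) for diagnostics.
#' @return List with `probs` (2 x n matrix of class probabilities, row 2 =
#'   abnormal), `logits`, and optionally `trace`.
#' @export
model_forward <- function(model, ecg = NULL, pcg = NULL, training = FALSE,
                          keep_trace = FALSE, grad = training,
                          bn_momentum = NULL) {
  cfg <- model$cfg
  m <- model
  m$trace <- if (keep_trace) new.env(parent = emptyenv()) else NULL
  tp <- tape_new(training = training, grad = grad)
  tp$bn_momentum <- bn_momentum
  need <- switch(m$variant, single_ecg = "ecg", single_pcg = "pcg", "both")
  if (need %in% c("ecg", "both") && is.null(ecg))
    stop("variant '", m$variant, "' requires an ECG input")
  if (need %in% c("pcg", "both") && is.null(pcg))
    stop("variant '", m$variant, "' requires a PCG input")

  out <- switch(
    m$variant,
    single_ecg = {
      xe <- ag_input(tp, as_input(ecg, cfg$input_len))
      f <- fw_encoder(tp, m, "ecg", xe)
      f[[4]]
    },
    single_pcg = {
      xp <- ag_input(tp, as_input(pcg, cfg$input_len))
      f <- fw_encoder(tp, m, "pcg", xp)
      f[[4]]
    },
    early_fusion = {
      a <- as_input(ecg, cfg$input_len)
      b <- as_input(pcg, cfg$input_len)
      x <- ag_input(tp, array(rbind(matrix(a, 1), matrix(b, 1)) * 1,
                              c(2L, cfg$input_len, dim(a)[3])))
      f <- fw_encoder(tp, m, "enc", x)
      f[[4]]
    },
    late_fusion = {
      xe <- ag_input(tp, as_input(ecg, cfg$input_len))
      xp <- ag_input(tp, as_input(pcg, cfg$input_len))
      fe <- fw_encoder(tp, m, "ecg", xe)
      fp <- fw_encoder(tp, m, "pcg", xp)
      cc <- ag_concat_c(tp, fe[[4]], fp[[4]])
      ag_conv1d(tp, cc, P(tp, m, "late.proj.W"), P(tp, m, "late.proj.b"),
                k = cfg$kernel)
    },
    only_last_sacmf = {
      xe <- ag_input(tp, as_input(ecg, cfg$input_len))
      xp <- ag_input(tp, as_input(pcg, cfg$input_len))
      fe <- fw_encoder(tp, m, "ecg", xe)
      fp <- fw_encoder(tp, m, "pcg", xp)
      fw_sacmf(tp, m, 4L, fe[[4]], fp[[4]], NULL)
    },
    {
      # full / concat_only / sa_only / ca_only: progressive fusion
      xe <- ag_input(tp, as_input(ecg, cfg$input_len))
      xp <- ag_input(tp, as_input(pcg, cfg$input_len))
      fe <- fw_encoder(tp, m, "ecg", xe)
      fp <- fw_encoder(tp, m, "pcg", xp)
      fw_progressive_fusion(tp, m, fe, fp)
    })

  logits <- fw_head(tp, m, out)
  list(tape = tp, logits = logits, probs = softmax_cols(logits$val),
       trace = m$trace, fused = out$val)
}

# One weighted cross-entropy training step's loss and parameter gradients.
model_grad <- function(model, ecg, pcg, y, class_w = c(1, 1)) {
  fwd <- model_forward(model, ecg, pcg, training = TRUE)
  loss <- ag_softmax_ce(fwd$tape, fwd$logits, y, class_w)
  g <- ag_backward(fwd$tape, loss)
  list(loss = loss$val, grads = g, probs = loss$probs)
}

#' Predict abnormal-class probabilities for segments
#'
#' @param model A `cf_model`.
#' @param dataset A `segment_dataset` (see [build_dataset()]).
#' @param idx Integer indices of segments to score (default: all).
#' @param drop Modality to zero at inference: `"none"`, `"ecg"`, or `"pcg"`
#'   (missing-modality protocol: the absent modality's input values are set
#'   to zero, the present one is unchanged).
#' @param batch Evaluation batch size.
#' @return Numeric vector of P(abnormal), one per requested segment.
#' @export
predict_proba <- function(model, dataset, idx = NULL, drop = "none",
                          batch = 128L) {
  drop <- match.arg(drop, c("none", "ecg", "pcg"))
  if (drop != "none" && model$variant %in% c("single_ecg", "single_pcg"))
    stop("modality dropping requires a two-input variant, not '",
         model$variant, "'")
  if (is.null(idx)) idx <- seq_len(nrow(dataset$meta))
  out <- numeric(length(idx))
  for (start in seq(1L, length(idx), by = batch)) {
    take <- idx[start:min(start + batch - 1L, length(idx))]
    xe <- dataset$ecg[, take, drop = FALSE]
    xp <- dataset$pcg[, take, drop = FALSE]
    if (drop == "ecg") xe[] <- 0
    if (drop == "pcg") xp[] <- 0
    fw <- model_forward(model, xe, xp, training = FALSE)
    out[start:(start + length(take) - 1L)] <- fw$probs[2L, ]
    rm(fw)
    gc(FALSE)
  }
  out
}

CF_CHECKPOINT_SCHEMA <- 1L

#' Save / load model checkpoints
#'
#' Checkpoints store the variant, configuration, weights and batch-norm
#' running statistics with a schema version; loading a checkpoint from a
#' newer schema raises an error.
#'
#' @param model A `cf_model`.
#' @param path File path.
#' @return `model_load()` returns the restored `cf_model`.
#' @export
model_save <- function(model, path) {
  obj <- list(schema = CF_CHECKPOINT_SCHEMA, variant = model$variant,
              cfg = unclass(model$cfg), seed = model$seed,
              use_sa = model$use_sa, use_ca = model$use_ca,
              raw_injection = model$raw_injection,
              params = as.list(model$params), state = as.list(model$state))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname model_save
#' @export
model_load <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$schema) || obj$schema > CF_CHECKPOINT_SCHEMA)
    stop("checkpoint schema version ", obj$schema %||% "<missing>",
         " is newer than supported version ", CF_CHECKPOINT_SCHEMA)
  pe <- list2env(obj$params, parent = emptyenv())
  se <- list2env(obj$state, parent = emptyenv())
  structure(list(variant = obj$variant, cfg = structure(obj$cfg,
                                                        class = "cf_config"),
                 params = pe, state = se, seed = obj$seed,
                 use_sa = obj$use_sa, use_ca = obj$use_ca,
                 raw_injection = obj$raw_injection),
            class = "cf_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deep-copy a model.  The parameter/state environments are reference
# objects, and training updates weights in place, so the copies must not
# share array storage with the original.
model_clone <- function(model) {
  dup <- function(e) list2env(lapply(as.list(e), function(a) a + 0),
                              parent = emptyenv())
  model$params <- dup(model$params)
  model$state <- dup(model$state)
  model
}
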