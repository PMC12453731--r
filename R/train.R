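# Training protocol: inverse-frequency class-weighted cross-entropy, Adam
# from lr 0.01, x0.1 plateau decay on the training loss (patience 5 epochs),
# early stopping (patience 20), at most 100 epochs.

#' Training hyperparameters
#'
#' @param max_epochs Maximum training epochs.
#' @param lr Initial Adam learning rate.
#' @param lr_factor Multiplicative learning-rate decay on plateau.
#' @param lr_patience Consecutive non-improving epochs (training loss,
#'   strict decrease) before each decay.
#' @param stop_patience Consecutive non-improving epochs before training
#'   stops; must exceed `lr_patience`.
#' @param batch_train,batch_eval Batch sizes for training and evaluation.
#' @param l2 L2 weight-decay coefficient applied to convolution and dense
#'   weights (not biases or normalization parameters).
#' @param tol Improvement tolerance; 0 means any strict decrease counts.
#' @param seed Seed driving shuffling and dropout.
#' @param bn_recal_batches Batches used to recalibrate batch-norm running
#'   statistics before monitor callbacks and at training end (see
#'   [recalibrate_bn()]); 0 disables recalibration.
#' @return An object of class `cf_train_config`.
#' @export
train_config <- function(max_epochs = 100L, lr = 0.01, lr_factor = 0.1,
                         lr_patience = 5L, stop_patience = 20L,
                         batch_train = 32L, batch_eval = 128L, l2 = 1e-4,
                         tol = 0, seed = 1L, bn_recal_batches = 8L) {
  stopifnot(lr_patience > 0, stop_patience > 0, stop_patience > lr_patience)
  structure(list(max_epochs = as.integer(max_epochs), lr = lr,
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 stop_patience = as.integer(stop_patience),
                 batch_train = as.integer(batch_train),
                 batch_eval = as.integer(batch_eval), l2 = l2, tol = tol,
                 seed = as.integer(seed),
                 bn_recal_batches = as.integer(bn_recal_batches)),
            class = "cf_train_config")
}

#' Inverse-frequency class weights
#'
#' `w_c = N_total / (K * N_c)`, so weights are inversely proportional to the
#' class counts and a balanced dataset yields all-ones weights.
#'
#' @param counts Per-class sample counts (length K, all > 0).
#' @return Numeric weights, same names/order as `counts`.
#' @export
class_weights <- function(counts) {
  if (any(counts <= 0))
    stop("class weights undefined: a class has zero samples")
  sum(counts) / (length(counts) * counts)
}

# Plateau schedule as a pure state machine so the logic is testable against
# injected loss traces.  `streak` counts epochs since the last improvement;
# the lr decays whenever the streak reaches a multiple of `lr_patience`
# (no cooldown), and training stops when it reaches `stop_patience`.
sched_new <- function(lr, factor, lr_patience, stop_patience, tol = 0) {
  list(lr = lr, factor = factor, lr_patience = lr_patience,
       stop_patience = stop_patience, tol = tol, best = Inf, streak = 0L)
}

sched_step <- function(s, loss) {
  decayed <- FALSE
  if (loss < s$best - s$tol) {
    s$best <- loss
    s$streak <- 0L
  } else {
    s$streak <- s$streak + 1L
    if (s$streak %% s$lr_patience == 0L && s$streak < s$stop_patience) {
      s$lr <- s$lr * s$factor
      decayed <- TRUE
    }
  }
  s$decayed <- decayed
  s$stop <- s$streak >= s$stop_patience
  s
}

#' Replay the learning-rate schedule over a loss trace
#'
#' Pure replay of the plateau-decay / early-stopping rules over a given
#' per-epoch training-loss sequence, without any model. Useful to verify
#' schedule behaviour: with defaults, the learning rate first decays after
#' exactly `lr_patience` consecutive non-improving epochs and training stops
#' after `stop_patience`.
#'
#' @param losses Numeric per-epoch training losses.
#' @param cfg A [train_config()].
#' @return Tibble with columns `epoch`, `loss`, `lr` (rate in force after
#'   the epoch's schedule update), `stopped`; rows end at the stopping
#'   epoch.
#' @export
plateau_schedule <- function(losses, cfg = train_config()) {
  s <- sched_new(cfg$lr, cfg$lr_factor, cfg$lr_patience, cfg$stop_patience,
                 cfg$tol)
  rows <- vector("list", length(losses))
  for (e in seq_along(losses)) {
    s <- sched_step(s, losses[e])
    rows[[e]] <- tibble::tibble(epoch = e, loss = losses[e], lr = s$lr,
                                stopped = s$stop)
    if (s$stop) { rows <- rows[seq_len(e)]; break }
  }
  dplyr::bind_rows(rows)
}

adam_new <- function() new.env(parent = emptyenv())

# In-place Adam over the gradient's parameter names.  `pe` must hold
# exclusively owned copies of the weights (train_model deep-copies the model
# before its first step); L2 decay applies to convolution/dense weights only.
adam_step <- function(opt, pe, grads, lr, t, l2 = 0, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    mk <- paste0(nm, ".m"); vk <- paste0(nm, ".v")
    w <- get(nm, pe)
    if (!exists(mk, opt, inherits = FALSE)) {
      assign(mk, numeric(length(w)), opt)
      assign(vk, numeric(length(w)), opt)
    }
    .adam_update(w, get(mk, opt), get(vk, opt), grads[[nm]], lr, beta1,
                 beta2, eps, t, if (endsWith(nm, ".W")) l2 else 0)
  }
}

#' Train a model
#'
#' Weighted cross-entropy (inverse-frequency class weights computed on the
#' training subset unless supplied), Adam from `cfg$lr`, learning-rate decay
#' by `cfg$lr_factor` after `cfg$lr_patience` consecutive epochs without a
#' strict training-loss decrease, early stop after `cfg$stop_patience`, at
#' most `cfg$max_epochs` epochs. Deterministic given `cfg$seed`.
#'
#' @param model A `cf_model` (left unmodified; a trained copy is returned).
#' @param dataset A `segment_dataset`.
#' @param train_idx Integer segment indices to train on (default: all).
#' @param cfg A [train_config()].
#' @param class_w Optional length-2 class weights (normal, abnormal).
#' @param monitor Optional callback `function(epoch, model, history_row)`
#'   returning `TRUE` to request a stop (recorded as reason `"monitor"`),
#'   e.g. for accuracy-targeted experiment budgets.
#' @param monitor_steps If set, the monitor is additionally invoked every
#'   `monitor_steps` optimizer steps (with fractional `epoch`), so large
#'   epochs can be interrupted as soon as a target is reached.
#' @param verbose Print per-epoch progress.
#' @return The trained `cf_model`, with a `history` attribute: a tibble
#'   (epoch, loss, lr) carrying attributes `stop_reason` and `best_epoch`.
#' @export
train_model <- function(model, dataset, train_idx = NULL,
                        cfg = train_config(), class_w = NULL, monitor = NULL,
                        monitor_steps = NULL, verbose = FALSE) {
  m <- model_clone(model)
  if (is.null(train_idx)) train_idx <- seq_len(nrow(dataset$meta))
  y_all <- dataset$meta$label[train_idx]
  if (is.null(class_w)) {
    counts <- c(sum(y_all == 0L), sum(y_all == 1L))
    class_w <- if (all(counts > 0)) class_weights(counts) else c(1, 1)
  }
  opt <- adam_new()
  sch <- sched_new(cfg$lr, cfg$lr_factor, cfg$lr_patience, cfg$stop_patience,
                   cfg$tol)
  history <- list()
  stop_reason <- "max_epochs"
  t_step <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- train_idx[sample(length(train_idx))]
      losses <- c(); sizes <- c()
      for (start in seq(1L, length(ord), by = cfg$batch_train)) {
        take <- ord[start:min(start + cfg$batch_train - 1L, length(ord))]
        xe <- dataset$ecg[, take, drop = FALSE]
        xp <- dataset$pcg[, take, drop = FALSE]
        y <- dataset$meta$label[take]
        gr <- model_grad(m, xe, xp, y, class_w)
        if (!is.finite(gr$loss))
          stop("training diverged (non-finite loss) at epoch ", epoch)
        t_step <- t_step + 1L
        adam_step(opt, m$params, gr$grads, sch$lr, t_step, l2 = cfg$l2)
        losses <- c(losses, gr$loss); sizes <- c(sizes, length(take))
        rm(gr)
        gc(FALSE)   # bound the heap: step buffers are large and short-lived
        if (!is.null(monitor) && !is.null(monitor_steps) &&
            t_step %% monitor_steps == 0L) {
          mm <- if (cfg$bn_recal_batches > 0)
            recalibrate_bn(m, dataset, train_idx, cfg$bn_recal_batches,
                           cfg$batch_train)
          else m
          frac <- epoch - 1 + (start + length(take) - 1) / length(ord)
          row <- tibble::tibble(epoch = frac,
                                loss = sum(losses * sizes) / sum(sizes),
                                lr = sch$lr)
          if (isTRUE(monitor(frac, mm, row))) {
            m <- mm
            stop_reason <- "monitor"
            break
          }
        }
      }
      if (stop_reason == "monitor") break
      epoch_loss <- sum(losses * sizes) / sum(sizes)
      sch <- sched_step(sch, epoch_loss)
      row <- tibble::tibble(epoch = epoch, loss = epoch_loss, lr = sch$lr)
      history[[epoch]] <- row
      if (verbose)
        message(sprintf("epoch %3d  loss %.5f  lr %.5g", epoch, epoch_loss,
                        sch$lr))
      just_checked <- !is.null(monitor_steps) && t_step %% monitor_steps == 0L
      if (!is.null(monitor) && !just_checked) {
        mm <- if (cfg$bn_recal_batches > 0)
          recalibrate_bn(m, dataset, train_idx, cfg$bn_recal_batches,
                         cfg$batch_train)
        else m
        if (isTRUE(monitor(epoch, mm, row))) {
          m <- mm
          stop_reason <- "monitor"
          break
        }
      }
      if (sch$stop) {
        stop_reason <- "early_stop"
        break
      }
    }
  })
  if (stop_reason != "monitor" && cfg$bn_recal_batches > 0)
    m <- recalibrate_bn(m, dataset, train_idx, cfg$bn_recal_batches,
                        cfg$batch_train)
  h <- dplyr::bind_rows(history)
  attr(h, "stop_reason") <- stop_reason
  attr(h, "best_epoch") <- if (nrow(h)) h$epoch[which.min(h$loss)] else NA_integer_
  attr(m, "history") <- h
  m
}

#' Training history of a fitted model
#' @param model A trained `cf_model`.
#' @return Tibble (epoch, loss, lr) with attributes `stop_reason`,
#'   `best_epoch`.
#' @export
train_history <- function(model) attr(model, "history")

#' Run k-fold cross-validation for one variant
#'
#' For every fold f: builds a fresh model (seed derived from `seed` and f),
#' trains on the remaining folds, evaluates on f. The fold assignment is an
#' input, so the identical partition can be pinned across variants.
#'
#' @param dataset A `segment_dataset`.
#' @param folds Integer fold ids per segment (see [make_folds()]).
#' @param variant Model variant (see [cf_variants()]).
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param seed Root seed for per-fold model initialization.
#' @param keep_models Keep the trained per-fold models in the result.
#' @return A `cf_cv` object: per-fold metrics, their mean/sd, and metrics of
#'   the pooled confusion counts.
#' @export
run_cross_validation <- function(dataset, folds, variant = "full",
                                 model_cfg = model_config(),
                                 train_cfg = train_config(), seed = 1L,
                                 keep_models = FALSE) {
  fold_ids <- sort(unique(folds))
  per_fold <- list()
  models <- list()
  for (f in fold_ids) {
    te <- which(folds == f)
    tr <- which(folds != f)
    mdl <- build_model(variant, model_cfg, seed = derive_seed(seed, f, 101L))
    tc <- train_cfg
    tc$seed <- derive_seed(seed, f, 202L)
    fit <- train_model(mdl, dataset, tr, tc)
    met <- evaluate_model(fit, dataset, te)
    per_fold[[length(per_fold) + 1L]] <- dplyr::mutate(met, fold = f,
                                                       .before = 1)
    if (keep_models) models[[as.character(f)]] <- fit
  }
  per_fold <- dplyr::bind_rows(per_fold)
  pooled <- metrics_from_confusion(sum(per_fold$tp), sum(per_fold$fp),
                                   sum(per_fold$tn), sum(per_fold$fn))
  structure(list(variant = variant, per_fold = per_fold, pooled = pooled,
                 models = if (keep_models) models else NULL, seed = seed),
            class = "cf_cv")
}

#' @export
print.cf_cv <- function(x, ...) {
  cat("<cf_cv>", x$variant, "|", nrow(x$per_fold), "folds | mean accuracy",
      sprintf("%.4f", mean(x$per_fold$accuracy)), "±",
      sprintf("%.4f", stats::sd(x$per_fold$accuracy)), "\n")
  invisible(x)
}

#' Recalibrate batch-normalization running statistics
#'
#' On short training schedules the exponentially averaged running statistics
#' can lag far behind the weights (they start from the 0/1 initialization),
#' which degrades inference-mode accuracy even when the fitted weights are
#' good. Recalibration replaces them with the plain average of batch
#' statistics over a few forward passes on training data - a standard
#' practice for small-sample batch-norm models. Weights are not touched.
#'
#' @param model A `cf_model` (modified copy returned).
#' @param dataset A `segment_dataset`.
#' @param idx Training segment indices to draw batches from.
#' @param n_batches Number of forward batches to average.
#' @param batch Batch size.
#' @return The model with refreshed running statistics.
#' @export
recalibrate_bn <- function(model, dataset, idx, n_batches = 8L,
                           batch = 32L) {
  m <- model_clone(model)
  keys <- ls(m$state)
  for (k in keys[endsWith(keys, ".rm")]) assign(k, 0 * get(k, m$state), m$state)
  for (k in keys[endsWith(keys, ".rv")]) assign(k, 0 * get(k, m$state) + 1, m$state)
  n_batches <- min(n_batches, max(1L, length(idx) %/% batch))
  # stride across the index so the statistics see the full population even
  # when segments are ordered by record/class
  use <- idx[unique(round(seq(1, length(idx),
                              length.out = n_batches * batch)))]
  for (i in seq_len(n_batches)) {
    take <- use[((i - 1L) * batch + 1L):min(i * batch, length(use))]
    invisible(model_forward(m, dataset$ecg[, take, drop = FALSE],
                            dataset$pcg[, take, drop = FALSE],
                            training = TRUE, grad = FALSE,
                            bn_momentum = 1 / i))
  }
  m
}
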