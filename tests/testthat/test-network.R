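# Network core: shape contracts, closed-form attention limits, residual/SE
# algebra, raw-injection equivalence, variant construction, checkpointing,
# and an end-to-end finite-difference gradient check in double precision.

zero_params <- function(m, pattern) {
  for (nm in grep(pattern, ls(m$params), value = TRUE))
    assign(nm, 0 * get(nm, m$params), m$params)
  m
}

test_that("encoder levels and fused output obey the shape contract", {
  m <- build_model("full", model_config(), seed = 1)
  x <- rand_waves(2, seed = 1)
  fw <- model_forward(m, x, x, keep_trace = TRUE)
  expected <- list(c(64L, 2000L), c(128L, 400L), c(192L, 80L), c(256L, 16L))
  for (lvl in 1:4) {
    for (mod in c("ecg", "pcg")) {
      d <- dim(get(paste0(mod, ".l", lvl), fw$trace))
      expect_identical(d[1:2], expected[[lvl]])
    }
  }
  expect_identical(dim(fw$fused)[1:2], c(256L, 16L))
  expect_identical(dim(fw$probs), c(2L, 2L))
  expect_equal(colSums(fw$probs), c(1, 1), tolerance = 1e-12)
})

test_that("CBR length arithmetic and non-negativity", {
  tp <- cardiofuse:::tape_new()
  x <- cardiofuse:::ag_input(tp, array(rnorm(3 * 2000 * 2), c(3, 2000, 2)))
  w <- cardiofuse:::ag_input(tp, matrix(rnorm(8 * 3 * 7), 8, 21))
  y5 <- cardiofuse:::ag_conv1d(tp, x, w, stride = 5L, k = 7L)
  expect_identical(dim(y5$val), c(8L, 400L, 2L))
  y1 <- cardiofuse:::ag_conv1d(tp, x, w, stride = 1L, k = 7L)
  expect_identical(dim(y1$val), c(8L, 2000L, 2L))
  r <- cardiofuse:::ag_relu(tp, y1)
  expect_true(all(r$val >= 0))
})

test_that("SE gate collapses to exactly 0.5 with zeroed excitation weights", {
  m <- build_model("single_ecg", small_config(), seed = 2)
  m <- zero_params(m, "res1\\.se\\.")
  x <- rand_waves(2, seed = 2)
  fw <- model_forward(m, ecg = x, keep_trace = TRUE)
  gate <- get("ecg.l1.res1.se.gate", fw$trace)
  expect_equal(unname(as.vector(gate)), rep(0.5, length(gate)),
               tolerance = 1e-15)
  # and gates always live strictly inside (0, 1)
  m2 <- build_model("single_ecg", small_config(), seed = 3)
  fw2 <- model_forward(m2, ecg = x, keep_trace = TRUE)
  g2 <- get("ecg.l2.res2.se.gate", fw2$trace)
  expect_true(all(g2 > 0 & g2 < 1))
})

test_that("residual block with zeroed convs reduces to ReLU(x)", {
  cfg <- small_config()
  m <- build_model("single_ecg", cfg, seed = 4)
  # zero both conv weights of res1 at level 1; BN is identity at inference
  m <- zero_params(m, "^ecg\\.l1\\.res1\\.c[12]\\.W")
  tp <- cardiofuse:::tape_new()
  x <- cardiofuse:::ag_input(tp, array(rnorm(16 * 100 * 2), c(16, 100, 2)))
  out <- cardiofuse:::fw_res(tp, m, "ecg.l1.res1", x)
  expect_equal(out$val, x$val * (x$val > 0), tolerance = 1e-12)
})

test_that("zero raw signal injection equals no injection at levels 3-4", {
  cfg <- small_config()
  m <- build_model("single_ecg", cfg, seed = 5)
  x <- rand_waves(2, seed = 5)
  fw1 <- model_forward(m, ecg = x, keep_trace = TRUE)
  m2 <- m
  m2$raw_injection <- FALSE
  fw2 <- model_forward(m2, ecg = x, keep_trace = TRUE)
  # with a nonzero raw signal the outputs differ...
  expect_false(isTRUE(all.equal(get("ecg.l4", fw1$trace),
                                get("ecg.l4", fw2$trace))))
  # ...with a zero raw signal they agree exactly
  z <- matrix(0, 2000, 2)
  fw3 <- model_forward(m, ecg = z, keep_trace = TRUE)
  fw4 <- model_forward(m2, ecg = z, keep_trace = TRUE)
  expect_equal(get("ecg.l4", fw3$trace), get("ecg.l4", fw4$trace),
               tolerance = 1e-12)
})

test_that("raw-injection pooling windows match level input lengths", {
  cfg <- model_config()
  expect_identical(cfg$input_len / cfg$ap_windows[1], 400)  # level-3 input
  expect_identical(cfg$input_len / cfg$ap_windows[2], 80)   # level-4 input
  tp <- cardiofuse:::tape_new()
  raw <- cardiofuse:::ag_input(tp, array(rnorm(2000 * 2), c(1L, 2000L, 2L)))
  expect_identical(dim(cardiofuse:::ag_avgpool(tp, raw, 5L)$val)[2], 400L)
  expect_identical(dim(cardiofuse:::ag_avgpool(tp, raw, 25L)$val)[2], 80L)
})

test_that("spatial and channel attention collapse to 0.5 with zero weights", {
  m <- build_model("full", small_config(), seed = 6)
  m <- zero_params(m, "^fus\\.l1\\.sa\\.")
  m <- zero_params(m, "^fus\\.l1\\.ca\\.")
  x <- rand_waves(2, seed = 6)
  fw <- model_forward(m, x, x, keep_trace = TRUE)
  maps <- get("fus.l1.sa.maps", fw$trace)
  expect_equal(unname(as.vector(maps)), rep(0.5, length(maps)),
               tolerance = 1e-15)
  gate <- get("fus.l1.ca.gate", fw$trace)
  expect_equal(unname(as.vector(gate)), rep(0.5, length(gate)),
               tolerance = 1e-15)
  # maps have one value per position, in (0,1), for both modalities
  expect_identical(dim(maps), c(2L, 2000L, 2L))

  m2 <- build_model("full", small_config(), seed = 7)
  fw2 <- model_forward(m2, x, x, keep_trace = TRUE)
  maps2 <- get("fus.l2.sa.maps", fw2$trace)
  expect_true(all(maps2 > 0 & maps2 < 1))
})

test_that("all nine variants build, forward, and order parameter counts sanely", {
  cfg <- small_config()
  x <- rand_waves(2, seed = 8)
  n_params <- sapply(cf_variants(), function(v) {
    m <- build_model(v, cfg, seed = 9)
    fw <- model_forward(m,
                        ecg = if (v == "single_pcg") NULL else x,
                        pcg = if (v == "single_ecg") NULL else x)
    expect_identical(dim(fw$probs), c(2L, 2L))
    expect_equal(colSums(fw$probs), c(1, 1), tolerance = 1e-12)
    cf_n_params(m)
  })
  expect_gt(n_params[["full"]], n_params[["single_ecg"]])
  expect_gt(n_params[["full"]], n_params[["sa_only"]])
  expect_gt(n_params[["full"]], n_params[["ca_only"]])
  expect_gt(n_params[["full"]], n_params[["concat_only"]])
  expect_identical(n_params[["single_ecg"]], n_params[["single_pcg"]])
})

test_that("zeroing one modality leaves the other encoder's activations intact", {
  m <- build_model("full", small_config(), seed = 10)
  x <- rand_waves(2, seed = 10)
  fw1 <- model_forward(m, x, x, keep_trace = TRUE)
  fw2 <- model_forward(m, x, matrix(0, 2000, 2), keep_trace = TRUE)
  expect_equal(get("ecg.l4", fw1$trace), get("ecg.l4", fw2$trace),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(get("pcg.l4", fw1$trace),
                                get("pcg.l4", fw2$trace))))
})

test_that("forward passes are deterministic and dropout is inference-inert", {
  m <- build_model("full", small_config(), seed = 11)
  x <- rand_waves(3, seed = 11)
  p1 <- model_forward(m, x, x)$probs
  p2 <- model_forward(m, x, x)$probs
  expect_identical(p1, p2)
})

test_that("checkpoints round-trip and reject newer schema versions", {
  f <- withr::local_tempfile(fileext = ".rds")
  m <- build_model("late_fusion", small_config(), seed = 12)
  model_save(m, f)
  back <- model_load(f)
  x <- rand_waves(2, seed = 12)
  expect_identical(model_forward(back, x, x)$probs,
                   model_forward(m, x, x)$probs)
  obj <- readRDS(f)
  obj$schema <- 99L
  saveRDS(obj, f)
  expect_error(model_load(f), "schema")
})

test_that("full-model gradients agree with finite differences (double path)", {
  withr::local_options(cardiofuse.precision = "double")
  cfg <- tiny_config()
  m <- build_model("full", cfg, seed = 13)
  set.seed(99)
  xe <- matrix(rnorm(250 * 3), 250, 3)
  xp <- matrix(rnorm(250 * 3), 250, 3)
  y <- c(0L, 1L, 1L)
  cw <- c(1.2, 0.8)

  loss_at <- function() {
    fw <- model_forward(m, xe, xp, training = TRUE)
    cardiofuse:::ag_softmax_ce(fw$tape, fw$logits, y, cw)$val
  }
  # analytic gradients (training mode, but dropout off for determinism)
  m$cfg$dropout <- 0
  fw <- model_forward(m, xe, xp, training = TRUE)
  loss <- cardiofuse:::ag_softmax_ce(fw$tape, fw$logits, y, cw)
  grads <- cardiofuse:::ag_backward(fw$tape, loss)
  expect_gt(length(grads), 50)

  eps <- 1e-6
  set.seed(7)
  checked <- 0
  for (nm in sample(names(grads), 12)) {
    w <- get(nm, m$params)
    i <- sample(length(w), 1)
    w2 <- w; w2[i] <- w2[i] + eps
    assign(nm, w2, m$params)
    up <- loss_at()
    w2[i] <- w2[i] - 2 * eps
    assign(nm, w2, m$params)
    dn <- loss_at()
    assign(nm, w, m$params)
    num <- (up - dn) / (2 * eps)
    expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                 label = paste("grad", nm))
    checked <- checked + 1
  }
  expect_equal(checked, 12)
})
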