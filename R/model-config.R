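#' Architecture hyperparameters for the fusion network
#'
#' Holds the structural parameters of the two modality encoders, the
#' progressive cross-modal fusion branch, and the classification head.
#' Defaults correspond to the full-scale architecture operating on one
#' cardiac cycle resampled to 2000 samples: four encoder levels with channel
#' widths 64/128/192/256, kernel size 7, a single stride-5 downsampling per
#' level after the first, squeeze-and-excitation blocks inside every residual
#' unit, and average-pooled raw-signal injection (windows 5 and 25) at the
#' input of levels 3 and 4.
#'
#' @param input_len Samples per segment and modality. Must be divisible by
#'   125 so the level strides (1, 5, 5, 5) produce integer lengths.
#' @param channels Encoder (and fused) channel width at each of the 4 levels.
#' @param kernel Convolution kernel size used throughout encoders and fusion.
#' @param strides Per-level stride applied once in the level's first
#'   (CBR) convolution; the residual convolutions are stride 1.
#' @param se_ratio Squeeze-and-excitation bottleneck reduction ratio.
#' @param ap_windows Average-pooling windows for raw-signal injection at the
#'   inputs of levels 3 and 4; they must match the level input lengths.
#' @param sa_reduce Spatial-attention channel reduction factor for the first
#'   1x1 convolution (intermediate width `max(2C / sa_reduce, sa_min_mid)`).
#' @param sa_min_mid Floor for the spatial-attention intermediate width.
#' @param sa_kernel Spatial-attention mid convolution kernel (even; padded
#'   asymmetrically, one extra sample on the left).
#' @param ca_ratio Channel-attention bottleneck reduction ratio.
#' @param prev_pool Downsampling factor aligning the previous fusion level's
#'   output with the current level before the fusion convolution.
#' @param head_dense Dense-layer widths of the classification head.
#' @param head_kernel,head_stride Conv parameters of the head's downsampling
#'   convolution.
#' @param dropout Dropout probability after each hidden dense layer.
#'
#' @return An object of class `cf_config` (a list of the above).
#' @export
model_config <- function(input_len = 2000L,
                         channels = c(64L, 128L, 192L, 256L),
                         kernel = 7L,
                         strides = c(1L, 5L, 5L, 5L),
                         se_ratio = 16L,
                         ap_windows = c(5L, 25L),
                         sa_reduce = 4L,
                         sa_min_mid = 8L,
                         sa_kernel = 16L,
                         ca_ratio = 16L,
                         prev_pool = 5L,
                         head_dense = c(128L, 64L, 32L),
                         head_kernel = 3L,
                         head_stride = 2L,
                         dropout = 0.5) {
  stopifnot(length(channels) == 4, length(strides) == 4, strides[1] == 1)
  lens <- input_len / cumprod(strides)
  if (any(lens != floor(lens)))
    stop("input_len must be divisible by the cumulative strides")
  lens <- as.integer(lens)
  if (input_len / ap_windows[1] != lens[2] || input_len / ap_windows[2] != lens[3])
    stop("ap_windows must map the raw signal onto the level 3/4 input lengths")
  structure(list(input_len = as.integer(input_len),
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 strides = as.integer(strides), se_ratio = se_ratio,
                 ap_windows = as.integer(ap_windows), sa_reduce = sa_reduce,
                 sa_min_mid = sa_min_mid, sa_kernel = as.integer(sa_kernel),
                 ca_ratio = ca_ratio, prev_pool = as.integer(prev_pool),
                 head_dense = as.integer(head_dense),
                 head_kernel = as.integer(head_kernel),
                 head_stride = as.integer(head_stride),
                 dropout = dropout,
                 level_len = lens),
            class = "cf_config")
}

#' Model variants for the ablation family
#'
#' `cf_variants()` enumerates the closed set of architecture variants:
#' the full progressive-fusion model, the two single-modality branches,
#' early and late fusion baselines, a single fusion module applied only at
#' the deepest level, and attention-reduced fusion modules (concatenation
#' only, spatial attention only, channel attention only).
#'
#' @return Character vector of valid variant identifiers.
#' @export
cf_variants <- function() {
  c("full", "single_ecg", "single_pcg", "early_fusion", "late_fusion",
    "only_last_sacmf", "concat_only", "sa_only", "ca_only")
}
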