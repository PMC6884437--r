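#' Preprocessing configuration
#'
#' The conditioning chain applied before cognitive-load estimation is
#' (1) bandpass filtering to the slow hemodynamic band, (2) linear
#' detrending, and (3) attenuation of skin blood flow (SBF) by removing
#' the leading principal components of the rest-period multichannel
#' activity from the task period.
#'
#' @param low_cut,high_cut bandpass corner frequencies in Hz. The defaults
#'   (0.01 and 0.6) keep the slow hemodynamic band while suppressing drift
#'   and cardiac pulsation.
#' @param filter_order Butterworth order (default 1; a first-order design
#'   has gentle roll-off but minimal passband distortion).
#' @param zero_phase apply the filter forward-backward (default `TRUE`),
#'   giving zero group delay. Set `FALSE` for a causal single pass.
#' @param n_sbf_components number of rest-period principal components
#'   removed from the task period (default 2; 1 and 3 are the commonly
#'   used alternatives).
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(low_cut = 0.01, high_cut = 0.6,
                              filter_order = 1L, zero_phase = TRUE,
                              n_sbf_components = 2L) {
  if (!(low_cut > 0 && low_cut < high_cut))
    stop("need 0 < low_cut < high_cut")
  if (filter_order < 1L) stop("filter_order must be a positive integer")
  if (n_sbf_components < 0L) stop("n_sbf_components must be >= 0")
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 filter_order = as.integer(filter_order),
                 zero_phase = isTRUE(zero_phase),
                 n_sbf_components = as.integer(n_sbf_components)),
            class = "preprocess_config")
}

# Minimum signal length accepted by the filter: three times the slowest
# time constant 1/(2*pi*low_cut).  Shorter inputs are dominated by the
# filter transient and are rejected rather than silently padded.
min_filter_len <- function(fs, cfg) ceiling(3 * fs / (2 * pi * cfg$low_cut))

#' Bandpass filter a signal
#'
#' Butterworth bandpass of order `cfg$filter_order`, applied forward-
#' backward (zero phase) by default.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param cfg a [preprocess_config()].
#' @return filtered vector, same length as `x`.
#' @export
bandpass <- function(x, fs, cfg = preprocess_config()) {
  if (cfg$high_cut >= fs / 2)
    stop("configuration error: high_cut (", cfg$high_cut,
         " Hz) must be below the Nyquist frequency ", fs / 2, " Hz")
  mlen <- min_filter_len(fs, cfg)
  if (length(x) < mlen)
    stop("signal too short for stable filtering: ", length(x),
         " samples < required ", mlen,
         " (3x the ", round(1 / (2 * pi * cfg$low_cut), 1), " s time constant)")
  bf <- signal::butter(cfg$filter_order,
                       c(cfg$low_cut, cfg$high_cut) / (fs / 2),
                       type = "pass")
  if (cfg$zero_phase) zero_phase_filter(bf$b, bf$a, x, pad = mlen)
  else as.numeric(signal::filter(bf, x))
}

# forward-backward filtering with odd-reflection padding; each pass starts
# from the steady state for a constant input at the first padded value, so
# no start-up transient enters the retained segment
zero_phase_filter <- function(b, a, x, pad) {
  n <- length(x)
  p <- min(n - 1L, pad)
  m <- max(length(a), length(b)) - 1L
  dc_gain <- sum(b) / sum(a)
  run <- function(v) as.numeric(
    signal::filter(b, a, v,
                   init.x = rep(v[1L], m),
                   init.y = rep(v[1L] * dc_gain, m)))
  ext <- c(2 * x[1L] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  y <- rev(run(rev(run(ext))))
  y[(p + 1L):(p + n)]
}

#' Remove the least-squares linear trend from a signal
#'
#' @param x numeric vector of length >= 2.
#' @return residuals of the straight-line fit of `x` against sample index;
#'   refitting a line to the output gives slope and intercept zero.
#' @export
detrend_linear <- function(x) {
  if (length(x) < 2L) stop("detrending needs at least 2 samples")
  t <- seq_along(x)
  fit <- stats::.lm.fit(cbind(1, t), x)
  as.numeric(fit$residuals)
}

#' Attenuate skin blood flow via rest-period principal components
#'
#' Channel loadings are computed from the channel-wise-centred rest matrix
#' (channels as variables, time points as observations).  The task matrix,
#' centred with the rest-period channel means, is projected onto the first
#' `cfg$n_sbf_components` loadings and that reconstruction is subtracted.
#' Because the SBF is a superficial systemic signal shared across optodes,
#' it dominates the leading rest-period components; removing them also
#' attenuates common-mode motion artefacts.
#'
#' @param rest,task numeric matrices, time x channel, identical channel sets.
#' @param cfg a [preprocess_config()].
#' @return corrected task matrix, same shape as `task` (rest-mean centred).
#' @export
sbf_attenuate <- function(rest, task, cfg = preprocess_config()) {
  rest <- as.matrix(rest); task <- as.matrix(task)
  if (ncol(rest) != ncol(task))
    stop("rest and task must have identical channel sets")
  k <- cfg$n_sbf_components
  if (k >= ncol(rest))
    stop("configuration error: n_sbf_components (", k,
         ") must be below the channel count (", ncol(rest), ")")
  if (nrow(rest) < ncol(rest) + 1L)
    stop("rest period too short for PCA: need more time samples than channels")
  mu <- colMeans(rest)
  rest_c <- sweep(rest, 2L, mu)
  task_c <- sweep(task, 2L, mu)
  if (k == 0L) return(task_c)
  pc <- stats::prcomp(rest_c, center = FALSE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (rank < k) {
    warning("rest matrix is rank-deficient: using ", rank,
            " component(s) instead of ", k)
    k <- rank
  }
  v <- pc$rotation[, seq_len(k), drop = FALSE]
  task_c - task_c %*% v %*% t(v)
}

#' Apply the full preprocessing chain to a session
#'
#' Each channel of the full recording is bandpass filtered and linearly
#' detrended (rest and task jointly, so the filter sees one continuous
#' series and no boundary transient is introduced at the task onset), the
#' recording is then split at `rest_end`, and SBF components fitted on the
#' rest period are removed from the task period only.  The returned rest
#' segment is centred with the rest channel means so rest and task share
#' one affine frame.
#'
#' @param session a `nirs_session`.
#' @param cfg a [preprocess_config()].
#' @return a new `nirs_session` with identical shape and metadata.
#' @export
preprocess_session <- function(session, cfg = preprocess_config()) {
  stopifnot(inherits(session, "nirs_session"))
  x <- session$samples
  for (j in seq_len(ncol(x)))
    x[, j] <- detrend_linear(bandpass(x[, j], session$fs, cfg))
  ri <- seq_len(session$rest_end)
  rest <- x[ri, , drop = FALSE]
  task <- x[-ri, , drop = FALSE]
  mu <- colMeans(rest)
  task2 <- sbf_attenuate(rest, task, cfg)
  out <- session
  out$samples <- rbind(sweep(rest, 2L, mu), task2)
  colnames(out$samples) <- session$channels$label
  validate_session(out)
}
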