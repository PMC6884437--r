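#' Specification of a synthetic NIRS session
#'
#' The generator emulates the signal environment of a forehead optical
#' topography recording: a band-limited (0.01-0.6 Hz) stochastic
#' hemodynamic component whose task-period amplitude scales with the
#' imposed cognitive load, superimposed cardiac / respiratory / Mayer-wave
#' oscillations with random phases, a shared across-channel skin-blood-flow
#' (SBF) component, linear drift, and white sensor noise.
#'
#' Load is encoded as the standard deviation of the band-limited
#' hemodynamic component during the task period only
#' (`hemo_sigma * load_level`); the rest period keeps a fixed spontaneous
#' amplitude `rest_sigma`.  Encoding load in the slow-band variance is the
#' minimal mechanism a variance/entropy-sensitive estimator should detect,
#' and the band matches the preprocessing passband so the load signal
#' survives preprocessing by construction.  The rest amplitude default
#' (2.0) sits at the top of the canonical task range (low = 1, high = 2):
#' spontaneous low-frequency oscillations in optical recordings are
#' typically as large as task-evoked variability, and a baseline at the
#' upper end of the task amplitude range keeps the baseline-conditioned
#' entropy estimator monotone in load across the whole range.
#'
#' @param fs sampling rate in Hz (default 10).
#' @param rest_s,task_s rest and task durations in seconds (defaults 60
#'   and 70).
#' @param n_channels number of channels (default 4: L1, L3, R1, R3 with
#'   1 / 3 / 1 / 3 cm source-detector distances).
#' @param load_level `"low"` (1), `"high"` (2), or a numeric scalar >= 0.
#' @param hemo_sigma base amplitude (sd) of the task-period hemodynamic
#'   component, multiplied by `load_level`.
#' @param rest_sigma amplitude of the rest-period hemodynamic component
#'   (default 2.0).
#' @param cardiac_hz,resp_hz,mayer_hz artifact frequencies (defaults 1.1,
#'   0.25, 0.10 Hz).
#' @param artifact_amps named amplitudes of the three sinusoidal
#'   artifacts.
#' @param sbf_amp amplitude of the shared low-frequency SBF component
#'   (identical loading on every channel, so it occupies the leading
#'   rest-period principal component).  The default (2.5) makes the
#'   superficial component larger than the cortical fluctuations, as in
#'   real scalp-coupled optical recordings, so rest-period PCA recovers
#'   it cleanly.
#' @param drift_slope linear drift in signal units per second.
#' @param noise_sigma white-noise sd.
#' @param seed RNG seed; identical seed + spec give an identical session.
#' @param subject_id,condition session tags.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(fs = 10, rest_s = 60, task_s = 70, n_channels = 4L,
                           load_level = "low", hemo_sigma = 1.0,
                           rest_sigma = 2.0, cardiac_hz = 1.1,
                           resp_hz = 0.25, mayer_hz = 0.10,
                           artifact_amps = c(cardiac = 0.5, resp = 0.3,
                                             mayer = 0.3),
                           sbf_amp = 2.5, drift_slope = 0.01,
                           noise_sigma = 0.3, seed = 1L,
                           subject_id = "", condition = "") {
  load <- resolve_load(load_level)
  amps <- c(hemo_sigma, rest_sigma, artifact_amps, sbf_amp, noise_sigma)
  if (any(amps < 0)) stop("all amplitudes must be >= 0")
  if (fs <= 2 * cardiac_hz)
    stop("fs must exceed twice the cardiac frequency (", 2 * cardiac_hz, " Hz)")
  structure(list(fs = fs, rest_s = rest_s, task_s = task_s,
                 n_channels = as.integer(n_channels), load_level = load,
                 hemo_sigma = hemo_sigma, rest_sigma = rest_sigma,
                 cardiac_hz = cardiac_hz, resp_hz = resp_hz,
                 mayer_hz = mayer_hz, artifact_amps = artifact_amps,
                 sbf_amp = sbf_amp, drift_slope = drift_slope,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 subject_id = subject_id, condition = condition),
            class = "synthetic_spec")
}

resolve_load <- function(load_level) {
  if (is.character(load_level))
    return(switch(load_level, low = 1, high = 2,
                  stop("load_level must be 'low', 'high' or a number >= 0")))
  if (!is.numeric(load_level) || load_level < 0)
    stop("numeric load_level must be >= 0")
  as.numeric(load_level)
}

# Band-limited unit-sd noise: white noise pushed through the 0.01-0.6 Hz
# first-order Butterworth band (the preprocessing passband), with a
# burn-in dropped to avoid the filter transient.
band_noise <- function(n, fs, low = 0.01, high = 0.6) {
  burn <- 2000L
  bf <- signal::butter(1, c(low, high) / (fs / 2), type = "pass")
  z <- as.numeric(signal::filter(bf, stats::rnorm(n + burn)))[-seq_len(burn)]
  s <- stats::sd(z)
  if (s > 0) z / s else z
}

default_channel_meta <- function(k) {
  if (k == 4L)
    data.frame(label = c("L1", "L3", "R1", "R3"),
               distance = c(1, 3, 1, 3), stringsAsFactors = FALSE)
  else
    data.frame(label = paste0("C", seq_len(k)), distance = 3.0,
               stringsAsFactors = FALSE)
}

#' Generate a synthetic NIRS session
#'
#' @param spec a [synthetic_spec()].
#' @return a `nirs_session`.  The injected shared SBF series is attached
#'   as attribute `"sbf_series"` for diagnostics.
#' @export
generate_session <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  fs <- spec$fs
  n_rest <- round(spec$rest_s * fs)
  n_task <- round(spec$task_s * fs)
  n <- n_rest + n_task
  t <- (seq_len(n) - 1) / fs
  task_idx <- (n_rest + 1L):n
  amp <- rep(spec$rest_sigma, n)
  amp[task_idx] <- spec$hemo_sigma * spec$load_level

  # shared superficial component: slow (< 0.1 Hz) band, identical loading
  sbf <- spec$sbf_amp * band_noise(n, fs, low = 0.005, high = 0.1)

  x <- matrix(0.0, nrow = n, ncol = spec$n_channels)
  freqs <- c(spec$cardiac_hz, spec$resp_hz, spec$mayer_hz)
  for (ch in seq_len(spec$n_channels)) {
    hemo <- amp * band_noise(n, fs)
    phases <- stats::runif(3L, 0, 2 * pi)
    art <- rowSums(vapply(1:3, function(k)
      spec$artifact_amps[[k]] * sin(2 * pi * freqs[k] * t + phases[k]),
      numeric(n)))
    x[, ch] <- hemo + art + sbf + spec$drift_slope * t +
      stats::rnorm(n, sd = spec$noise_sigma)
  }
  s <- nirs_session(x, fs = fs, channels = default_channel_meta(spec$n_channels),
                    rest_end = n_rest, subject_id = spec$subject_id,
                    condition = spec$condition)
  attr(s, "sbf_series") <- sbf
  s
}

#' Generate a paired low/high-load cohort
#'
#' One low-load and one high-load session per subject, with per-subject
#' perturbations around the two template specs: a multiplicative
#' log-normal gain (sdlog 0.2) applied to both the hemodynamic and rest
#' amplitudes (so the within-subject load ratio is preserved), and a
#' Gaussian perturbation (sd 0.005 units/s) of the drift slope.
#' Deterministic under `seed`.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param spec_low,spec_high template [synthetic_spec()]s for the two
#'   conditions.
#' @param seed cohort seed; per-subject session seeds are drawn from it.
#' @return list of length `n_subjects`; each element is
#'   `list(low = session, high = session)`.
#' @export
generate_cohort <- function(n_subjects,
                            spec_low = synthetic_spec(load_level = "low"),
                            spec_high = synthetic_spec(load_level = "high"),
                            seed = 1L) {
  if (n_subjects < 2L) stop("a cohort needs at least 2 subjects")
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n_subjects),
                  ncol = 2L)
  gains <- stats::rlnorm(n_subjects, 0, 0.2)
  dslopes <- stats::rnorm(n_subjects, 0, 0.005)
  lapply(seq_len(n_subjects), function(i) {
    sid <- sprintf("S%02d", i)
    perturb <- function(sp, cond, sd_seed) {
      sp$hemo_sigma <- sp$hemo_sigma * gains[i]
      sp$rest_sigma <- sp$rest_sigma * gains[i]
      sp$drift_slope <- sp$drift_slope + dslopes[i]
      sp$seed <- sd_seed
      sp$subject_id <- sid
      sp$condition <- cond
      sp
    }
    list(low = generate_session(perturb(spec_low, "low", seeds[i, 1L])),
         high = generate_session(perturb(spec_high, "high", seeds[i, 2L])))
  })
}
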