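# small session builders used across test files

make_session <- function(n_rest = 600L, n_task = 700L, n_channels = 4L,
                         fs = 10, seed = 1L) {
  set.seed(seed)
  nirs_session(matrix(rnorm((n_rest + n_task) * n_channels),
                      ncol = n_channels),
               fs = fs, rest_end = n_rest)
}

# session whose every task window (and the baseline) equals one tiled
# 20-s block, so all conditional entropies H(X|B) are exactly zero
make_tiled_session <- function(fs = 10, seed = 3L) {
  set.seed(seed)
  block <- rnorm(round(10 * fs))          # one 10-s block
  col <- rep(block, 13)                   # 60 s rest + 70 s task
  nirs_session(cbind(col, col + rnorm(length(col))), fs = fs,
               rest_end = round(60 * fs))
}

# per-session CL medians for a low/high cohort, one matrix row per subject
cohort_medians <- function(n_subjects, seed, ratio = 2) {
  co <- generate_cohort(n_subjects,
                        synthetic_spec(load_level = 1),
                        synthetic_spec(load_level = ratio),
                        seed = seed)
  t(vapply(co, function(pair) {
    c(low = trace_median(compute_cl_trace(preprocess_session(pair$low))),
      high = trace_median(compute_cl_trace(preprocess_session(pair$high))))
  }, c(low = 0, high = 0)))
}
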