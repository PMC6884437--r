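fs <- 10

test_that("a 70-s task with 20-s windows and 10-s steps yields seven CLs", {
  rest <- rnorm(600); task <- rnorm(700)
  w <- segment_windows(task, rest, fs, window_spec())
  expect_length(w, 7L)
  expect_true(all(lengths(w) == 200L))
  # first window borrows the last 10 s of rest
  expect_identical(w[[1]], c(tail(rest, 100), task[1:100]))
  expect_identical(w[[2]], task[1:200])
  expect_identical(w[[7]], task[501:700])
})

test_that("window counts agree with the enumeration oracle across designs", {
  rest <- rnorm(600)
  for (task_s in seq(20, 180, by = 10)) {
    for (ws in c(10, 20)) {
      for (ss in c(5, 10)) {
        if (ss > ws) next
        for (borrow in c(TRUE, FALSE)) {
          task <- rnorm(task_s * fs)
          got <- length(segment_windows(task, rest, fs,
                                        window_spec(ws, ss, borrow)))
          expect_identical(got, oracle_window_count(task_s, fs, ws, ss, borrow),
                           info = sprintf("task=%ds w=%d s=%d borrow=%d",
                                          task_s, ws, ss, borrow))
          # the closed form floor(task_s / step_s) holds when the window
          # overlap equals the step (the 20 s / 10 s design)
          if (borrow && ws == 2 * ss)
            expect_identical(got, as.integer(task_s %/% ss))
        }
      }
    }
  }
})

test_that("degenerate windowing inputs raise precondition errors", {
  expect_error(segment_windows(rnorm(700), rnorm(50), fs, window_spec()),
               "rest too short")
  expect_error(segment_windows(rnorm(30), rnorm(600), fs, window_spec()),
               "task too short")
  expect_error(window_spec(window_s = 10, step_s = 20), "step_s")
  expect_error(baseline_window(rnorm(150), fs), "baseline window")
})

test_that("per-step CL is the baseline-conditioned entropy", {
  set.seed(31)
  b <- rnorm(200)
  # identical window: no information beyond the baseline
  s_same <- compute_cl_step(b, b, 16)
  expect_equal(s_same$cl_raw, 0, tolerance = 1e-12)
  # independent window: CL approaches the window entropy
  x <- rnorm(5000); b2 <- rnorm(5000)
  s_ind <- compute_cl_step(x, b2, 16)
  expect_equal(s_ind$cl_raw, s_ind$h_x, tolerance = 0.15)
  # fuzz: 0 <= cl_raw <= h_x, and the defining identity is exact
  for (i in 1:200) {
    st <- compute_cl_step(rnorm(150, sd = runif(1, 0.3, 3)), rnorm(150), 16)
    expect_gte(st$cl_raw, 0)
    expect_lte(st$cl_raw, st$h_x + 1e-12)
    expect_equal(st$cl_raw, st$h_x - st$mi_xb, tolerance = 1e-12)
  }
  expect_error(compute_cl_step(rnorm(100), rnorm(200), 16), "equal length")
})

test_that("the update gate takes the direct branch when MI and KL disagree", {
  set.seed(32)
  b <- rnorm(200)
  prev <- compute_cl_step(rnorm(200), b, 16)
  prev$cl_final <- prev$cl_raw; prev$branch <- "first_step"; prev$tau <- 1L
  cur <- compute_cl_step(rnorm(200), b, 16)
  cur$tau <- 2L
  # MI down, KL up: a genuine change, first disjunct
  prev$mi_xb <- 0.5; prev$dkl_xb <- 0.2
  cur$mi_xb <- 0.4; cur$dkl_xb <- 0.3
  out <- constrained_update(prev, cur, rnorm(200), rnorm(200), 16)
  expect_equal(out$branch, "direct")
  expect_equal(out$cl_final, cur$cl_raw)
  # MI up, KL down: second disjunct
  cur$mi_xb <- 0.6; cur$dkl_xb <- 0.1
  out2 <- constrained_update(prev, cur, rnorm(200), rnorm(200), 16)
  expect_equal(out2$branch, "direct")
})

test_that("the averaging branch is a VI-weighted convex combination", {
  set.seed(33)
  b <- rnorm(200)
  xp <- rnorm(200); xc <- 0.7 * xp + rnorm(200, sd = 0.5)
  prev <- compute_cl_step(xp, b, 16)
  prev$cl_final <- prev$cl_raw; prev$branch <- "first_step"
  cur <- compute_cl_step(xc, b, 16)
  # both gates move the same way -> fluctuation suspected -> average
  prev$mi_xb <- 0.4; prev$dkl_xb <- 0.2
  cur$mi_xb <- 0.5; cur$dkl_xb <- 0.3
  out <- constrained_update(prev, cur, xp, xc, 16)
  expect_equal(out$branch, "averaged")
  expect_equal(out$alpha + out$beta, 1, tolerance = 1e-12)
  expect_gte(out$alpha, 0)
  expect_gte(out$cl_final, min(prev$cl_raw, cur$cl_raw) - 1e-12)
  expect_lte(out$cl_final, max(prev$cl_raw, cur$cl_raw) + 1e-12)
  # the weights are the normalised conditional entropies of the pair
  expect_equal(out$alpha,
               conditional_entropy(xp, xc, 16) /
                 variation_of_information(xp, xc, 16),
               tolerance = 1e-9)
  # degenerate VI = 0 (identical windows): equal weights by continuity
  out0 <- constrained_update(prev, cur, xp, xp, 16)
  expect_equal(out0$alpha, 0.5)
  expect_equal(out0$cl_final, mean(c(prev$cl_raw, cur$cl_raw)))
})

test_that("a full trace satisfies the per-step invariants", {
  s <- generate_session(synthetic_spec(seed = 34))
  tr <- compute_cl_trace(preprocess_session(s))
  expect_s3_class(tr, "cl_trace")
  expect_equal(nrow(tr), 7L)
  expect_identical(tr$tau, 1:7)
  expect_equal(tr$branch[1], "first_step")
  expect_equal(tr$cl_final[1], tr$cl_raw[1])
  expect_true(all(tr$cl_final >= 0))
  expect_equal(tr$cl_raw, tr$h_x - tr$mi_xb, tolerance = 1e-12)
  avg <- tr$branch == "averaged"
  if (any(avg)) {
    expect_equal(tr$alpha[avg] + tr$beta[avg], rep(1, sum(avg)),
                 tolerance = 1e-12)
  }
  direct <- tr$branch == "direct"
  expect_equal(tr$cl_final[direct], tr$cl_raw[direct])
  # determinism
  tr2 <- compute_cl_trace(preprocess_session(s))
  expect_identical(as.data.frame(tr), as.data.frame(tr2))
  # the recursive smoothing variant runs and stays within bounds
  trr <- compute_cl_trace(preprocess_session(s), recursive = TRUE)
  expect_true(all(trr$cl_final >= 0))
})

test_that("a task identical to the baseline has zero load throughout", {
  s <- make_tiled_session()
  tr <- compute_cl_trace(s, channel = "C1")
  expect_equal(nrow(tr), 7L)
  expect_equal(tr$cl_raw, rep(0, 7), tolerance = 1e-12)
  expect_equal(trace_median(tr), 0, tolerance = 1e-12)
})

test_that("the trace median is the middle order statistic", {
  mk <- function(v) structure(data.frame(tau = seq_along(v), cl_final = v),
                              class = c("cl_trace", "data.frame"))
  expect_equal(trace_median(mk(c(1, 2, 3))), 2)
  expect_equal(trace_median(mk(c(1, 2, 3, 10))), 2.5)
  expect_equal(trace_median(mk(7)), 7)
  expect_equal(median(mk(c(1, 2, 3))), 2)
})
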