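#' Windowing specification for cognitive-load estimation
#'
#' The task period is cut into overlapping segments; a cognitive-load (CL)
#' value is estimated for each.  With the defaults (20-s windows advancing
#' in 10-s steps) the first window borrows the last 10 s of the resting
#' period, so a 70-s task yields exactly seven CL estimates.
#'
#' @param window_s window length in seconds (default 20).
#' @param step_s step between consecutive windows in seconds (default 10;
#'   must satisfy `0 < step_s <= window_s`).
#' @param first_window_borrows_rest if `TRUE` (default) the first window
#'   spans the last `window_s - step_s` seconds of rest plus the first
#'   `step_s` seconds of task.
#' @return object of class `window_spec`.
#' @export
window_spec <- function(window_s = 20, step_s = 10,
                        first_window_borrows_rest = TRUE) {
  if (!(step_s > 0 && step_s <= window_s))
    stop("need 0 < step_s <= window_s")
  structure(list(window_s = window_s, step_s = step_s,
                 first_window_borrows_rest = isTRUE(first_window_borrows_rest)),
            class = "window_spec")
}

#' Segment a task-period signal into overlapping windows
#'
#' @param task numeric vector, the task-period signal.
#' @param rest numeric vector, the rest-period signal (only its tail is
#'   used, and only when the first window borrows from rest).
#' @param fs sampling rate in Hz.
#' @param spec a [window_spec()].
#' @return list of numeric windows, each of exactly `window_s * fs`
#'   samples.  Windows that would overrun the task end are not emitted.
#'   With rest borrowing the count is `floor(task_seconds / step_s)`.
#' @export
segment_windows <- function(task, rest, fs, spec = window_spec()) {
  wlen <- round(spec$window_s * fs)
  slen <- round(spec$step_s * fs)
  borrow <- wlen - slen
  windows <- list()
  if (spec$first_window_borrows_rest && borrow > 0L) {
    if (length(rest) < borrow)
      stop("rest too short to borrow from: have ", length(rest),
           " samples, need ", borrow)
    if (length(task) < slen)
      stop("task too short: have ", length(task), " samples, need at least ",
           slen, " for the rest-borrowed first window")
    windows[[1L]] <- c(utils::tail(rest, borrow), task[seq_len(slen)])
  }
  start <- 0L
  while (start + wlen <= length(task)) {
    windows[[length(windows) + 1L]] <- task[(start + 1L):(start + wlen)]
    start <- start + slen
  }
  if (length(windows) == 0L)
    stop("task too short: have ", length(task), " samples, need ", wlen,
         " for a full window")
  windows
}

#' Extract the baseline window from the rest period
#'
#' The baseline `B` is the last `window_s` seconds of the resting
#' recording; every task window is conditioned on it.
#'
#' @param rest numeric rest-period vector.
#' @param fs sampling rate in Hz.
#' @param window_s baseline length in seconds (default 20).
#' @return numeric vector of `window_s * fs` samples.
#' @export
baseline_window <- function(rest, fs, window_s = 20) {
  blen <- round(window_s * fs)
  if (length(rest) < blen)
    stop("rest period (", length(rest), " samples) shorter than the ",
         window_s, " s baseline window (", blen, " samples)")
  utils::tail(rest, blen)
}

new_cl_step <- function(tau = NA_integer_, h_x, mi_xb, dkl_xb, cl_raw,
                        cl_final = NA_real_, branch = NA_character_,
                        alpha = NA_real_, beta = NA_real_,
                        vi_prev = NA_real_) {
  structure(list(tau = tau, h_x = h_x, mi_xb = mi_xb, dkl_xb = dkl_xb,
                 cl_raw = cl_raw, cl_final = cl_final, branch = branch,
                 alpha = alpha, beta = beta, vi_prev = vi_prev),
            class = "cl_step")
}

#' Raw cognitive load of one task window
#'
#' The cognitive load of window `x` given baseline `b` is the conditional
#' entropy `CL = H(X|B) = H(X) - MI(X;B)`: the entropy of the task-period
#' activity discounted by the information it shares with the resting
#' baseline, so residual resting activity carried into the task does not
#' inflate the load estimate.  All entropy terms come from one shared
#' joint histogram, so `cl_raw = h_x - mi_xb` holds to machine precision
#' and `0 <= cl_raw <= h_x`.
#'
#' @param x task window (same length as `b`; samples are paired by index).
#' @param b baseline window, see [baseline_window()].
#' @param bins histogram bins (default 16, suited to 200-sample windows).
#' @return a partially filled `cl_step` with `h_x`, `mi_xb`, `dkl_xb`
#'   (the divergence `D(P_X || P_B)`) and `cl_raw`.
#' @export
compute_cl_step <- function(x, b, bins = 16L) {
  if (length(x) != length(b))
    stop("task window and baseline must have equal length (",
         length(x), " vs ", length(b), ")")
  ip <- info_pair(x, b, bins)
  mi <- min(max(ip$mi, 0), ip$hx)
  dkl <- kl_divergence(x, b, bins)
  new_cl_step(h_x = ip$hx, mi_xb = mi, dkl_xb = dkl, cl_raw = ip$hx - mi)
}

#' Constrained update of consecutive cognitive-load estimates
#'
#' Transient fluctuations in the signal can produce spurious jumps in the
#' raw CL.  A change from step `tau-1` to `tau` is accepted as genuine
#' only when the mutual-information and KL-divergence gates move in
#' opposite directions -- an increase in load must be mirrored by a drop
#' in shared information with the baseline and a rise in distributional
#' divergence (or vice versa):
#'
#' \deqn{CL_\tau = H(X_\tau|B)} when
#' (`MI_tau <= MI_{tau-1}` and `DKL_tau > DKL_{tau-1}`) or
#' (`MI_tau > MI_{tau-1}` and `DKL_tau <= DKL_{tau-1}`);
#' otherwise the two raw conditional entropies are averaged with weights
#' from the variation of information of the two windows:
#' \deqn{CL_\tau = \alpha H(X_{\tau-1}|B) + \beta H(X_\tau|B),\quad
#'   \alpha = H(X_{\tau-1}|X_\tau)/VI,\ \beta = H(X_\tau|X_{\tau-1})/VI.}
#'
#' The weights are convex (`alpha + beta = 1` by the VI identity); in the
#' degenerate case `VI = 0` (identical consecutive windows) both are set
#' to 1/2 by continuity.
#'
#' @param prev completed `cl_step` for `tau-1`.
#' @param cur partial `cl_step` for `tau` from [compute_cl_step()].
#' @param x_prev,x_cur the window signals that produced `prev` and `cur`.
#' @param bins histogram bins.
#' @param recursive if `TRUE` the averaging branch blends the previous
#'   *smoothed* value (`prev$cl_final`) instead of the raw conditional
#'   entropy; default `FALSE`, the literal reading of the update formula.
#' @return completed `cl_step` with `cl_final`, `branch`, `alpha`, `beta`,
#'   `vi_prev`.
#' @export
constrained_update <- function(prev, cur, x_prev, x_cur, bins = 16L,
                               recursive = FALSE) {
  stopifnot(inherits(prev, "cl_step"), inherits(cur, "cl_step"))
  direct <- (cur$mi_xb <= prev$mi_xb && cur$dkl_xb > prev$dkl_xb) ||
            (cur$mi_xb >  prev$mi_xb && cur$dkl_xb <= prev$dkl_xb)
  if (direct) {
    cur$branch <- "direct"
    cur$cl_final <- cur$cl_raw
    return(cur)
  }
  ip <- info_pair(x_prev, x_cur, bins)
  h_prev_given_cur <- ip$hxy - ip$hy   # H(X_{tau-1} | X_tau)
  h_cur_given_prev <- ip$hxy - ip$hx   # H(X_tau | X_{tau-1})
  vi <- h_prev_given_cur + h_cur_given_prev
  if (vi <= 1e-12) {
    alpha <- 0.5
  } else {
    alpha <- h_prev_given_cur / vi
    alpha <- min(max(alpha, 0), 1)
  }
  beta <- 1 - alpha
  prev_val <- if (recursive) prev$cl_final else prev$cl_raw
  cur$branch <- "averaged"
  cur$alpha <- alpha
  cur$beta <- beta
  cur$vi_prev <- max(vi, 0)
  cur$cl_final <- alpha * prev_val + beta * cur$cl_raw
  cur
}

#' Compute the cognitive-load trace of a session channel
#'
#' Runs the full per-step estimator on a (preprocessed) session: the
#' baseline is the last `window_s` seconds of rest, the task period is
#' segmented by `spec`, the first step takes its raw value (it has no
#' predecessor), and every later step passes through
#' [constrained_update()].
#'
#' @param session a preprocessed `nirs_session`.
#' @param channel channel label (default "L3").
#' @param spec a [window_spec()].
#' @param bins histogram bins (default 16).
#' @param recursive passed to [constrained_update()].
#' @return object of class `cl_trace`: a data frame with one row per step
#'   and columns `tau`, `h_x`, `mi_xb`, `dkl_xb`, `cl_raw`, `cl_final`,
#'   `branch`, `alpha`, `beta`, `vi_prev`; attributes `spec`, `bins`,
#'   `channel`.
#' @export
compute_cl_trace <- function(session, channel = "L3", spec = window_spec(),
                             bins = 16L, recursive = FALSE) {
  sig <- select_channel(session, channel)
  b <- baseline_window(sig$rest, session$fs, spec$window_s)
  wins <- segment_windows(sig$task, sig$rest, session$fs, spec)
  steps <- vector("list", length(wins))
  s1 <- compute_cl_step(wins[[1L]], b, bins)
  s1$tau <- 1L
  s1$branch <- "first_step"
  s1$cl_final <- s1$cl_raw
  steps[[1L]] <- s1
  if (length(wins) > 1L) {
    for (tau in 2L:length(wins)) {
      cur <- compute_cl_step(wins[[tau]], b, bins)
      cur$tau <- tau
      steps[[tau]] <- constrained_update(steps[[tau - 1L]], cur,
                                         wins[[tau - 1L]], wins[[tau]],
                                         bins, recursive = recursive)
    }
  }
  df <- do.call(rbind, lapply(steps, function(s)
    data.frame(tau = s$tau, h_x = s$h_x, mi_xb = s$mi_xb, dkl_xb = s$dkl_xb,
               cl_raw = s$cl_raw, cl_final = s$cl_final, branch = s$branch,
               alpha = s$alpha, beta = s$beta, vi_prev = s$vi_prev,
               stringsAsFactors = FALSE)))
  structure(df, spec = spec, bins = bins, channel = channel,
            class = c("cl_trace", "data.frame"))
}

#' Median cognitive load of a trace
#'
#' The per-session summary used for classification: the middle order
#' statistic of the smoothed CL values (mean of the middle two for an
#' even count).
#'
#' @param trace a `cl_trace`.
#' @return median of `cl_final`, in bits.
#' @export
trace_median <- function(trace) {
  stopifnot(inherits(trace, "cl_trace"))
  if (nrow(trace) == 0L) stop("empty trace")
  stats::median(trace$cl_final)
}

#' @export
median.cl_trace <- function(x, na.rm = FALSE, ...) trace_median(x)

#' @export
print.cl_trace <- function(x, ...) {
  cat(sprintf("Cognitive-load trace: channel %s, %d steps, %d bins\n",
              attr(x, "channel"), nrow(x), attr(x, "bins")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  cat(sprintf("median CL: %.4f bits\n", trace_median(x)))
  invisible(x)
}

#' @export
plot.cl_trace <- function(x, ...) {
  graphics::plot(x$tau, x$cl_final, type = "b", pch = 19,
                 xlab = "estimation step", ylab = "CL (bits)",
                 main = paste("Cognitive-load trace,", attr(x, "channel")), ...)
  graphics::points(x$tau, x$cl_raw, pch = 1, col = "grey50")
  graphics::abline(h = trace_median(x), lty = 2)
  graphics::legend("topleft", legend = c("smoothed", "raw", "median"),
                   pch = c(19, 1, NA), lty = c(NA, NA, 2),
                   col = c("black", "grey50", "black"), bty = "n")
  invisible(x)
}
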