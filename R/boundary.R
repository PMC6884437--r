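#' Fit the decision boundary between two cognitive-load populations
#'
#' Determines the scalar threshold separating the CL values of a
#' lower-load condition (`s1`) from a higher-load condition (`s2`) as the
#' midpoint between the values that uniquely belong to each set, i.e.
#' outside their overlapping partition:
#'
#' 1. sort `s1` descending and `s2` ascending;
#' 2. find the smallest element of `s1` inside the `s2` interval (the `s1`
#'    marker) and the largest element of `s2` inside the `s1` interval
#'    (the `s2` marker), which bracket the overlap;
#' 3. take the immediate largest `s1` element strictly below the `s1`
#'    marker and the immediate smallest `s2` element strictly above the
#'    `s2` marker;
#' 4. the boundary `d` is the average of those two neighbours.
#'
#' All elements inside the closed overlap region are discarded from both
#' sets; the refined sets are strictly separated by `d` (asserted).  If
#' the sets are disjoint, `d` is the midpoint of `max(s1)` and `min(s2)`
#' and nothing is discarded.  If a strict neighbour does not exist the
#' set's extreme is used and a warning is raised.  Interval membership is
#' closed (ties on a marker value count as within the opposing interval).
#' Inputs are swapped (and flagged) when `median(s1) > median(s2)`, so the
#' fit is label-agnostic.
#'
#' @param s1 numeric CL values of the lower (e.g. one-back) condition.
#' @param s2 numeric CL values of the higher (e.g. two-back) condition.
#' @return object of class `cl_boundary` with fields `d`, `s1`, `s2`,
#'   `s1_refined`, `s2_refined`, `n_discarded_s1`, `n_discarded_s2`,
#'   `markers`, `swapped`.
#' @seealso [classify_median()], [predict.cl_boundary()]
#' @examples
#' m <- fit_decision_boundary(c(1, 2, 3, 4), c(3, 4, 5, 6))
#' coef(m)                      # boundary at 3.5
#' predict(m, c(1.9, 2.5, 3.6)) # easy, easy, difficult
#' @export
fit_decision_boundary <- function(s1, s2) {
  s1 <- as.numeric(s1); s2 <- as.numeric(s2)
  if (length(s1) < 2L || length(s2) < 2L)
    stop("each CL set needs at least 2 elements")
  if (any(!is.finite(s1)) || any(!is.finite(s2)))
    stop("CL sets must be finite")
  if (length(s1) == length(s2) && all(sort(s1) == sort(s2)))
    stop("the two CL sets are identical; no boundary exists")
  swapped <- FALSE
  if (stats::median(s1) > stats::median(s2)) {
    tmp <- s1; s1 <- s2; s2 <- tmp
    swapped <- TRUE
  }
  s1_sorted <- sort(s1, decreasing = TRUE)
  s2_sorted <- sort(s2)
  r1 <- range(s1); r2 <- range(s2)

  in2 <- s1 >= r2[1L] & s1 <= r2[2L]  # s1 elements within the s2 interval
  in1 <- s2 >= r1[1L] & s2 <= r1[2L]  # s2 elements within the s1 interval
  if (!any(in2) && !any(in1)) {
    # disjoint sets: midpoint of the adjacent extremes, nothing discarded
    d <- mean(c(max(s1), min(s2)))
    markers <- c(s1 = NA_real_, s2 = NA_real_)
    s1_ref <- s1_sorted
    s2_ref <- s2_sorted
  } else {
    m1 <- if (any(in2)) min(s1[in2]) else NA_real_
    m2 <- if (any(in1)) max(s2[in1]) else NA_real_
    markers <- c(s1 = m1, s2 = m2)
    # overlap region: the closed intersection of the two CL ranges
    lo <- max(r1[1L], r2[1L])
    hi <- min(r1[2L], r2[2L])
    if (is.na(m1)) m1 <- lo
    if (is.na(m2)) m2 <- hi
    below <- s1[s1 < m1]
    above <- s2[s2 > m2]
    n1 <- if (length(below)) max(below) else {
      warning("no s1 element strictly below its overlap marker; using min(s1)")
      min(s1)
    }
    n2 <- if (length(above)) min(above) else {
      warning("no s2 element strictly above its overlap marker; using max(s2)")
      max(s2)
    }
    d <- mean(c(n1, n2))
    s1_ref <- s1_sorted[!(s1_sorted >= lo & s1_sorted <= hi)]
    s2_ref <- s2_sorted[!(s2_sorted >= lo & s2_sorted <= hi)]
  }
  if (length(s1_ref) == 0L || length(s2_ref) == 0L)
    stop("boundary fit failed: the overlap refinement discarded every ",
         "element of one set (", length(s1_ref), " low / ", length(s2_ref),
         " high survivors); the CL ranges are too entangled")
  if (any(s1_ref >= d) || any(s2_ref <= d))
    stop("boundary fit failed: d = ", signif(d, 6), " does not strictly ",
         "separate the refined sets (nested CL ranges)")
  structure(list(d = d, s1 = s1_sorted, s2 = s2_sorted,
                 s1_refined = s1_ref, s2_refined = s2_ref,
                 n_discarded_s1 = length(s1) - length(s1_ref),
                 n_discarded_s2 = length(s2) - length(s2_ref),
                 markers = markers, swapped = swapped),
            class = "cl_boundary")
}

#' Classify a session median against a fitted boundary
#'
#' A session whose median CL lies above the boundary is labelled
#' "difficult", below it "easy".  A median exactly on the boundary is
#' labelled "easy" (the tie is reported via a message).
#'
#' @param median_cl finite numeric median CL, in bits.
#' @param model a fitted `cl_boundary`.
#' @return `"easy"` or `"difficult"`.
#' @export
classify_median <- function(median_cl, model) {
  stopifnot(inherits(model, "cl_boundary"))
  if (!is.finite(median_cl)) stop("median CL must be finite")
  if (median_cl == model$d)
    message("median CL exactly on the boundary; labelled 'easy' by the tie rule")
  if (median_cl > model$d) "difficult" else "easy"
}

#' @export
print.cl_boundary <- function(x, ...) {
  cat(sprintf("Cognitive-load decision boundary: d = %.4f bits\n", x$d))
  cat(sprintf("  lower set : n = %d (%d discarded in overlap)\n",
              length(x$s1), x$n_discarded_s1))
  cat(sprintf("  higher set: n = %d (%d discarded in overlap)\n",
              length(x$s2), x$n_discarded_s2))
  if (x$swapped) cat("  note: inputs were swapped so s1 is the lower-median set\n")
  invisible(x)
}

#' @export
summary.cl_boundary <- function(object, ...) {
  cat(sprintf("Decision boundary d = %.4f bits\n", object$d))
  if (!all(is.na(object$markers)))
    cat(sprintf("  overlap markers: s1 = %.4f, s2 = %.4f\n",
                object$markers[["s1"]], object$markers[["s2"]]))
  else
    cat("  sets disjoint; d is the midpoint of the adjacent extremes\n")
  cat(sprintf("  refined lower set : %d of %d kept, range [%.4f, %.4f]\n",
              length(object$s1_refined), length(object$s1),
              min(object$s1_refined), max(object$s1_refined)))
  cat(sprintf("  refined higher set: %d of %d kept, range [%.4f, %.4f]\n",
              length(object$s2_refined), length(object$s2),
              min(object$s2_refined), max(object$s2_refined)))
  invisible(object)
}

#' @export
coef.cl_boundary <- function(object, ...) c(boundary = object$d)

#' Predict perceived-difficulty labels for session medians
#'
#' @param object a fitted `cl_boundary`.
#' @param newdata numeric vector of median CL values.
#' @param ... unused.
#' @return character vector of `"easy"` / `"difficult"` labels.
#' @export
predict.cl_boundary <- function(object, newdata, ...) {
  vapply(as.numeric(newdata), classify_median, "", model = object)
}

#' @export
plot.cl_boundary <- function(x, ...) {
  all_v <- c(x$s1, x$s2)
  graphics::plot(NA, xlim = c(0.5, 2.5), ylim = range(all_v),
                 xaxt = "n", xlab = "", ylab = "CL (bits)",
                 main = "Decision boundary", ...)
  graphics::axis(1, at = c(1, 2), labels = c("lower", "higher"))
  graphics::points(jitter(rep(1, length(x$s1)), amount = 0.08), x$s1,
                   col = "grey60")
  graphics::points(jitter(rep(2, length(x$s2)), amount = 0.08), x$s2,
                   col = "grey60")
  graphics::points(jitter(rep(1, length(x$s1_refined)), amount = 0.08),
                   x$s1_refined, pch = 19, col = "firebrick")
  graphics::points(jitter(rep(2, length(x$s2_refined)), amount = 0.08),
                   x$s2_refined, pch = 19, col = "steelblue")
  graphics::abline(h = x$d, lty = 2)
  invisible(x)
}
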