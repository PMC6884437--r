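#' @name infotheory
#' @title Histogram plug-in information estimators
#' @description
#' All information quantities in this package are plug-in estimates over
#' equal-width histograms, in bits (log base 2).  The plug-in estimator is
#' used, rather than k-NN or kernel estimators, because the cognitive-load
#' update rule relies on exact algebraic identities --
#' `H(X|B) = H(X) - MI(X;B)` and the two equivalent forms of the variation
#' of information -- which hold to machine precision only when every term
#' is derived from one shared joint histogram.
#'
#' For quantities over a pair of signals (MI, conditional entropy, VI, KL)
#' the two inputs share one set of equal-width bin edges spanning their
#' pooled min--max, so both are measured on a common alphabet.  For the
#' entropy of a single window the edges span that window.
NULL

# Equal-width edges over the pooled range of the inputs.  A degenerate
# (constant) pool is widened by +-0.5 so all mass falls in one bin.
shared_edges <- function(x, y = NULL, bins) {
  if (bins < 2L) stop("need at least 2 bins")
  v <- c(x, y)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) { lo <- lo - 0.5; hi <- hi + 0.5 }
  seq(lo, hi, length.out = bins + 1L)
}

# Half-open bins [e_i, e_{i+1}) with the final bin closed; out-of-range
# values are clipped into the terminal bins (with a warning).
bin_index <- function(x, edges, warn = TRUE) {
  nb <- length(edges) - 1L
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  n_out <- sum(idx < 1L | idx > nb)
  if (n_out > 0L) {
    if (warn) warning(n_out, " value(s) outside the histogram range were ",
                      "clipped into the terminal bins")
    idx[idx < 1L] <- 1L
    idx[idx > nb] <- nb
  }
  idx
}

#' Build a histogram model
#'
#' @param x non-empty numeric vector of finite values.
#' @param edges strictly increasing bin edges (>= 2). Bins are half-open
#'   `[e_i, e_{i+1})` with the final bin closed; out-of-range values are
#'   clipped into the nearest terminal bin with a warning.
#' @return object of class `cl_histogram` with fields `edges`, `counts`,
#'   `probs` (probabilities sum to 1).
#' @export
build_histogram <- function(x, edges) {
  if (length(x) == 0L) stop("cannot build a histogram from an empty sample")
  if (any(!is.finite(x))) stop("histogram input must be finite")
  if (length(edges) < 2L || is.unsorted(edges, strictly = TRUE))
    stop("edges must be >= 2 strictly increasing values")
  nb <- length(edges) - 1L
  counts <- tabulate(bin_index(x, edges), nbins = nb)
  structure(list(edges = edges, counts = counts, probs = counts / length(x)),
            class = "cl_histogram")
}

#' Build a joint histogram of two paired samples
#'
#' Both variables are binned with one shared set of equal-width edges
#' spanning their pooled range, so marginals of the joint equal the 1-D
#' histograms built with the same edges by construction.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param bins number of bins per axis (default 16).
#' @return object of class `cl_joint` with fields `edges_x`, `edges_y`
#'   (identical), and `probs` (matrix, rows index `x` bins).
#' @export
build_joint_histogram <- function(x, y, bins = 16L) {
  if (length(x) != length(y))
    stop("joint histogram needs paired samples of equal length (",
         length(x), " vs ", length(y), ")")
  if (length(x) == 0L) stop("empty input")
  edges <- shared_edges(x, y, bins)
  ix <- bin_index(x, edges)
  iy <- bin_index(y, edges)
  counts <- matrix(tabulate((iy - 1L) * bins + ix, nbins = bins * bins),
                   nrow = bins)
  structure(list(edges_x = edges, edges_y = edges,
                 probs = counts / length(x)),
            class = "cl_joint")
}

#' Shannon entropy of a histogram, in bits
#'
#' `-sum(p * log2(p))` over the positive-probability cells; bounded by
#' `log2(number of cells)`.
#'
#' @param h a `cl_histogram` or `cl_joint`.
#' @param base logarithm base (default 2, bits).
#' @return entropy in `log(base)` units.
#' @export
entropy <- function(h, base = 2) UseMethod("entropy")

#' @export
entropy.cl_histogram <- function(h, base = 2) plugin_entropy(h$probs, base)

#' @export
entropy.cl_joint <- function(h, base = 2) plugin_entropy(h$probs, base)

#' @rdname entropy
#' @export
joint_entropy <- function(h, base = 2) {
  stopifnot(inherits(h, "cl_joint"))
  plugin_entropy(h$probs, base)
}

plugin_entropy <- function(p, base = 2) {
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

# All marginal/joint terms from one shared joint histogram, so the
# algebraic identities between them are exact.
info_pair <- function(x, y, bins = 16L) {
  j <- build_joint_histogram(x, y, bins)
  px <- rowSums(j$probs)
  py <- colSums(j$probs)
  hx <- plugin_entropy(px)
  hy <- plugin_entropy(py)
  hxy <- plugin_entropy(j$probs)
  list(hx = hx, hy = hy, hxy = hxy, mi = hx + hy - hxy, joint = j)
}

#' Mutual information between two paired signals, in bits
#'
#' Computed as `H(X) + H(Y) - H(X,Y)` with all three entropies taken from
#' one shared joint histogram (marginals from its margins), so that
#' `MI >= 0` and `MI <= min(H(X), H(Y))` hold up to floating-point error;
#' both bounds are asserted.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param bins bins per axis (default 16).
#' @return mutual information in bits.
#' @export
mutual_information <- function(x, y, bins = 16L) {
  ip <- info_pair(x, y, bins)
  tol <- 1e-9
  stopifnot(ip$mi >= -tol, ip$mi <= min(ip$hx, ip$hy) + tol)
  max(ip$mi, 0)
}

#' Conditional entropy H(X | Y), in bits
#'
#' `H(X|Y) = H(X,Y) - H(Y)`, from the same shared joint as
#' [mutual_information()]; equals `H(X) - MI(X;Y)` exactly.
#'
#' @inheritParams mutual_information
#' @export
conditional_entropy <- function(x, y, bins = 16L) {
  ip <- info_pair(x, y, bins)
  ip$hxy - ip$hy
}

#' Kullback-Leibler divergence between two sample distributions, in bits
#'
#' Histograms are built on shared equal-width edges spanning the pooled
#' range of both samples (the inputs may have different lengths -- this is
#' a distribution-level comparison).  Jeffreys smoothing (+0.5 pseudo-count
#' per bin, then renormalisation) is applied to both histograms, keeping
#' the divergence finite and zero iff the smoothed histograms coincide.
#'
#' @param p_samples,q_samples non-empty numeric vectors; the divergence is
#'   `D(P || Q)` in the printed operand order.
#' @param bins number of bins (default 16).
#' @return `sum(p * log2(p/q)) >= 0`.
#' @export
kl_divergence <- function(p_samples, q_samples, bins = 16L) {
  if (length(p_samples) == 0L || length(q_samples) == 0L)
    stop("KL divergence needs non-empty samples")
  edges <- shared_edges(p_samples, q_samples, bins)
  cp <- tabulate(bin_index(p_samples, edges), nbins = bins) + 0.5
  cq <- tabulate(bin_index(q_samples, edges), nbins = bins) + 0.5
  p <- cp / sum(cp)
  q <- cq / sum(cq)
  sum(p * log2(p / q))
}

#' Variation of information between two paired signals, in bits
#'
#' The metric `VI = H(X) + H(Y) - 2 MI(X;Y)`, equivalently
#' `H(X|Y) + H(Y|X)`.  Both forms are computed from one shared joint
#' histogram and their agreement is asserted; `VI >= 0` and
#' `VI(x, x) = 0`.
#'
#' @inheritParams mutual_information
#' @export
variation_of_information <- function(x, y, bins = 16L) {
  ip <- info_pair(x, y, bins)
  vi_mi <- ip$hx + ip$hy - 2 * ip$mi
  vi_ce <- (ip$hxy - ip$hy) + (ip$hxy - ip$hx)
  stopifnot(abs(vi_mi - vi_ce) < 1e-9)
  max(vi_ce, 0)
}
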