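test_that("histogram construction follows the documented bin conventions", {
  # all mass in one bin
  h <- build_histogram(rep(2.5, 100), edges = c(0, 5, 10))
  expect_equal(h$probs, c(1, 0))
  # {0,0,1,1} with edges {0, .5, 1}: the final bin is closed
  h2 <- build_histogram(c(0, 0, 1, 1), edges = c(0, 0.5, 1))
  expect_equal(h2$probs, c(0.5, 0.5))
  # out-of-range values are clipped into terminal bins, with a warning
  expect_warning(h3 <- build_histogram(c(-1, 0.2, 9), edges = c(0, 0.5, 1)),
                 "clipped")
  expect_equal(h3$counts, c(2L, 1L))
  expect_error(build_histogram(numeric(0), c(0, 1)), "empty")
  expect_error(build_histogram(c(1, NA), c(0, 2)), "finite")
})

test_that("entropy matches hand-computed values", {
  expect_equal(entropy(build_histogram(rep(1, 50), c(0, 2))), 0)
  expect_equal(entropy(build_histogram(c(0, 0, 1, 1), c(0, 0.5, 1))), 1.0)
  # probs (1/2, 1/4, 1/4): -(.5*-1 + 2*.25*-2) = 1.5 bits
  h <- build_histogram(c(1, 1, 2, 3), edges = c(0.5, 1.5, 2.5, 3.5))
  expect_equal(h$probs, c(0.5, 0.25, 0.25))
  expect_equal(entropy(h), 1.5)
})

test_that("joint entropy matches hand values and dominates the marginals", {
  unif <- structure(list(probs = matrix(0.25, 2, 2)), class = "cl_joint")
  expect_equal(joint_entropy(unif), 2.0)
  diagonal <- structure(list(probs = diag(c(0.5, 0.5))), class = "cl_joint")
  expect_equal(joint_entropy(diagonal), 1.0)
  set.seed(5)
  for (i in 1:20) {
    j <- build_joint_histogram(rnorm(150), rnorm(150), bins = 8)
    hx <- -sum(rowSums(j$probs)[rowSums(j$probs) > 0] *
                 log2(rowSums(j$probs)[rowSums(j$probs) > 0]))
    hy <- -sum(colSums(j$probs)[colSums(j$probs) > 0] *
                 log2(colSums(j$probs)[colSums(j$probs) > 0]))
    expect_gte(joint_entropy(j) + 1e-12, max(hx, hy))
  }
})

test_that("mutual information obeys its exact identities", {
  set.seed(6)
  x <- rnorm(400)
  # identity channel: MI(x, x) = H(x) on the shared edges
  j <- build_joint_histogram(x, x, 16)
  hx <- entropy(build_histogram(x, j$edges_x))
  expect_equal(mutual_information(x, x, 16), hx, tolerance = 1e-12)
  # a monotone transform with bin-aligned ranks carries all of H(x):
  # x on levels 1..8, y = x + 8 on levels 9..16; 16 equal-width bins over
  # the pooled range put every level in its own bin, so the joint is a
  # permutation matrix
  xr <- rep(1:8, each = 25)
  yr <- xr + 8
  expect_equal(mutual_information(xr, yr, 16), 3.0, tolerance = 1e-12)
  expect_error(mutual_information(rnorm(10), rnorm(11), 8), "equal length")
})

test_that("MI of independent series stays within estimator bias", {
  set.seed(7)
  n <- 2000L
  x <- runif(n); y <- runif(n)
  mi <- mutual_information(x, y, 16)
  # plug-in bias for a 16x16 table is about (16-1)^2/(2 n ln 2)
  expect_lt(mi, 3 * (15^2) / (2 * n * log(2)))
  # permutation null: observed MI is not extreme among shuffles
  null <- vapply(1:300, function(i) mutual_information(x, sample(y), 16), 0.0)
  expect_lt(mi, quantile(null, 0.95) * 1.5)
})

test_that("conditional entropy is exactly H(X,Y) - H(Y)", {
  set.seed(8)
  x <- rnorm(300); y <- rnorm(300)
  expect_equal(conditional_entropy(x, x, 16), 0, tolerance = 1e-12)
  # algebraic identity H(X|Y) = H(X) - MI(X;Y), same shared joint
  j <- build_joint_histogram(x, y, 16)
  hx <- entropy(build_histogram(x, j$edges_x))
  expect_equal(conditional_entropy(x, y, 16),
               hx - mutual_information(x, y, 16), tolerance = 1e-12)
  # independence: H(x|y) ~ H(x) up to estimator bias
  xl <- runif(3000); yl <- runif(3000)
  jl <- build_joint_histogram(xl, yl, 16)
  hxl <- entropy(build_histogram(xl, jl$edges_x))
  expect_equal(conditional_entropy(xl, yl, 16), hxl, tolerance = 0.15)
})

test_that("KL divergence matches the smoothed closed form", {
  x <- rnorm(200)
  expect_equal(kl_divergence(x, x, 16), 0)
  # all P mass in bin 1, all Q mass in bin 2, 100 samples each, +0.5
  # smoothing: p = (100.5, 0.5)/101, q reversed
  p <- c(100.5, 0.5) / 101
  q <- rev(p)
  expected <- sum(p * log2(p / q))
  expect_equal(kl_divergence(rep(0, 100), rep(1, 100), bins = 2), expected,
               tolerance = 1e-12)
  # Gibbs inequality on fuzzed inputs
  set.seed(9)
  for (i in 1:200) {
    a <- rnorm(sample(20:200, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(20:200, 1), mean = runif(1, -1, 1))
    expect_gte(kl_divergence(a, b, 16), 0)
  }
})

test_that("both printed forms of the variation of information agree", {
  set.seed(10)
  x <- rnorm(250)
  expect_equal(variation_of_information(x, x, 16), 0)
  for (i in 1:100) {
    a <- rnorm(200); b <- a * runif(1, 0, 2) + rnorm(200)
    vi <- variation_of_information(a, b, 16)
    # VI = H(a|b) + H(b|a), from the same joint
    expect_equal(vi, conditional_entropy(a, b, 16) +
                   conditional_entropy(b, a, 16), tolerance = 1e-9)
    expect_gte(vi, 0)
  }
  # independent series: VI ~ H(a) + H(b)
  a <- runif(3000); b <- runif(3000)
  j <- build_joint_histogram(a, b, 16)
  ha <- entropy(build_histogram(a, j$edges_x))
  hb <- entropy(build_histogram(b, j$edges_x))
  expect_equal(variation_of_information(a, b, 16), ha + hb, tolerance = 0.3)
})

test_that("information quantities respect their bounds on fuzzed pairs", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(50:300, 1)
    x <- rnorm(n) * runif(1, 0.2, 3)
    y <- 0.5 * x + rnorm(n)
    bins <- sample(c(8L, 16L, 32L), 1)
    j <- build_joint_histogram(x, y, bins)
    hx <- entropy(build_histogram(x, j$edges_x))
    hy <- entropy(build_histogram(y, j$edges_y))
    mi <- mutual_information(x, y, bins)
    expect_gte(mi, 0)
    expect_lte(mi, min(hx, hy) + 1e-9)
    expect_lte(hx, log2(bins) + 1e-12)
  }
})

test_that("uniform-sample entropy converges to log2(bins) from below", {
  edges <- seq(0, 1, length.out = 17)
  set.seed(14)
  means <- vapply(c(100L, 1000L, 10000L), function(n) {
    mean(vapply(1:30, function(i)
      entropy(build_histogram(runif(n), edges)), 0.0))
  }, 0.0)
  expect_true(all(diff(means) > 0))
  expect_true(all(means < 4))
  expect_equal(means[3], 4, tolerance = 0.01)
})

test_that("Gaussian histogram entropy matches the differential closed form", {
  set.seed(15)
  for (sigma in c(1, 2)) {
    x <- rnorm(10000, sd = sigma)
    edges <- seq(min(x), max(x), length.out = 17)
    h_disc <- entropy(build_histogram(x, edges))
    w <- diff(edges)[1]
    expect_equal(h_disc + log2(w), 0.5 * log2(2 * pi * exp(1) * sigma^2),
                 tolerance = 0.05)
  }
})
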