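# independent brute-force oracles, deliberately written as plain scans so
# they share no code path with the package implementation

# boundary oracle: scan the pooled sorted values for the markers and
# neighbours described by the fitting rule, midpoint of the neighbours
oracle_boundary_d <- function(s1, s2) {
  if (median(s1) > median(s2)) { tmp <- s1; s1 <- s2; s2 <- tmp }
  min1 <- min(s1); max1 <- max(s1)
  min2 <- min(s2); max2 <- max(s2)
  if (max1 < min2) return(mean(c(max1, min2)))      # disjoint
  u1 <- sort(unique(s1))
  u2 <- sort(unique(s2))
  m1 <- NA; m2 <- NA
  for (v in u1) if (v >= min2 && v <= max2) { m1 <- v; break }
  for (v in rev(u2)) if (v >= min1 && v <= max1) { m2 <- v; break }
  if (is.na(m1)) m1 <- max(min1, min2)
  if (is.na(m2)) m2 <- min(max1, max2)
  n1 <- NA; n2 <- NA
  for (v in rev(u1)) if (v < m1) { n1 <- v; break }
  for (v in u2) if (v > m2) { n2 <- v; break }
  if (is.na(n1)) n1 <- min1
  if (is.na(n2)) n2 <- max2
  mean(c(n1, n2))
}

# window-count oracle: enumerate every candidate start offset
oracle_window_count <- function(task_s, fs, window_s, step_s, borrow) {
  n_task <- round(task_s * fs)
  wlen <- round(window_s * fs)
  slen <- round(step_s * fs)
  count <- if (borrow && wlen > slen) 1L else 0L
  start <- 0L
  while (start + wlen <= n_task) {
    count <- count + 1L
    start <- start + slen
  }
  count
}
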