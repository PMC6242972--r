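# Independent oracles used across the suite. These deliberately use naive
# O(n^2) / brute-force formulations so they share no code path with the
# implementations they check.

# connected components of the overlap-or-gap<=max_gap relation, by breadth
# first search over the full pairwise adjacency matrix
closure_components <- function(start, end, max_gap) {
  n <- length(start)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    gap <- pmax(start[i], start[j]) - pmin(end[i], end[j])
    gap <= max_gap
  })
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}

# partition of call ids induced by cluster_se_calls, as a canonical
# set-of-sets (sorted character representation)
canonical_partition <- function(groups, ids) {
  sets <- split(ids, groups)
  sort(unname(vapply(sets, function(s) paste(sort(s), collapse = ","),
                     character(1))), method = "radix")
}

# brute-force centered window fraction with edge truncation
brute_window_fraction <- function(binary, k, i) {
  lo <- max(i - floor((k - 1) / 2), 1)
  hi <- min(i + floor(k / 2), length(binary))
  mean(binary[lo:hi])
}

# by-hand Benjamini-Hochberg step-up: returns the rejection set (indices)
bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  below <- which(sorted <= alpha * seq_len(m) / m)
  if (length(below) == 0) return(integer())
  sort(o[seq_len(max(below))])
}

# explicit O-E / V log-rank computation over distinct event times
hand_logrank <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  oe <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    oe <- oe + d1 - d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  oe^2 / v
}

# tiny fixture writer
write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
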