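# Independent brute-force oracles kept deliberately naive.

# Disjoin by breakpoint enumeration: every input start and end+1 is a
# breakpoint; each inter-breakpoint piece covered by >= 1 input interval
# is an output interval. One chromosome/strand at a time.
bruteForceDisjoin <- function(starts, ends) {
  bp <- sort(unique(c(starts, ends + 1L)))
  out <- NULL
  for (i in seq_len(length(bp) - 1L)) {
    s <- bp[i]; e <- bp[i + 1L] - 1L
    if (any(starts <= s & ends >= e))
      out <- rbind(out, c(s, e))
  }
  out
}

# Textbook step-up BH.
bruteForceBH <- function(p) {
  ok <- !is.na(p)
  m <- sum(ok)
  q <- rep(NA_real_, length(p))
  if (m == 0L) return(q)
  ord <- order(p[ok])
  ranked <- p[ok][ord]
  adj <- ranked * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  q[ok][ord] <- pmin(1, adj)
  q
}

randomIntervalSet <- function(n, maxPos = 500L) {
  starts <- sample.int(maxPos, n, replace = TRUE)
  widths <- sample.int(60L, n, replace = TRUE)
  cbind(starts, starts + widths - 1L)
}
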