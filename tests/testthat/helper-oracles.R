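# Plain-R brute-force match-length oracles, written directly from the
# definitions. These are independent of both the compiled fast path and the
# compiled brute-force reference, and are used to cross-check the latter on
# small random cases.

r_self_lambda <- function(a) {
  n <- length(a)
  vapply(seq_len(n), function(i) {
    cap <- n - i + 1
    L <- 0L
    for (len in seq_len(cap)) {
      found <- FALSE
      jmax <- i - len # match must end at i - 1
      if (jmax >= 1) {
        for (j in seq_len(jmax)) {
          if (all(a[j:(j + len - 1)] == a[i:(i + len - 1)])) {
            found <- TRUE
            break
          }
        }
      }
      if (found) L <- len else break
    }
    L + 1L
  }, integer(1))
}

r_cross_lambda <- function(a, ta, b, tb, time_constrained = TRUE) {
  na <- length(a)
  vapply(seq_len(na), function(i) {
    m <- if (time_constrained) sum(tb < ta[i]) else length(b)
    cap <- na - i + 1
    L <- 0L
    for (len in seq_len(cap)) {
      found <- FALSE
      jmax <- m - len + 1
      if (jmax >= 1) {
        for (j in seq_len(jmax)) {
          if (all(b[j:(j + len - 1)] == a[i:(i + len - 1)])) {
            found <- TRUE
            break
          }
        }
      }
      if (found) L <- len else break
    }
    L + 1L
  }, integer(1))
}
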