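# Independent reference implementations shared across test files.

# naive nested-loop reference for the insulation score
oracle_border_strength <- function(counts, w) {
  n <- nrow(counts)
  raw <- rep(NA_real_, n)
  gm <- mean(counts[counts > 0])
  eps <- 1e-6 * gm
  for (b in seq_len(n)) {
    if (b - w < 1 || b + w > n) next
    up <- (b - w):(b - 1)
    down <- (b + 1):(b + w)
    wu <- 0
    for (i in seq_along(up)) for (j in seq_along(up)) {
      if (i < j) wu <- wu + counts[up[i], up[j]]
    }
    wd <- 0
    for (i in seq_along(down)) for (j in seq_along(down)) {
      if (i < j) wd <- wd + counts[down[i], down[j]]
    }
    bt <- 0
    for (i in up) for (j in down) bt <- bt + counts[i, j]
    raw[b] <- (wu + wd) / max(bt, eps)
  }
  raw
}

# exhaustive enumeration oracle for the hypergeometric upper tail
enum_hyper_tail <- function(N, K, n, k_min) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)      # members of set1 = 1..K
  mean(hits >= k_min)
}
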