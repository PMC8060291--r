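# Independent brute-force oracles used to validate the implementation paths.

# Hamming distance with N counting as a mismatch at every position.
oracle_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sum(av != bv | av == "N" | bv == "N")
}

oracle_correct_umi <- function(obs, whitelist) {
  d <- vapply(whitelist, oracle_hamming, numeric(1), a = obs)
  if (any(d == 0)) return(whitelist[which(d == 0)[1]])
  hits <- whitelist[d == 1]
  if (length(hits) == 1) hits else NA_character_
}

# Two-sided Fisher p by full hypergeometric enumeration over the 2x2 table
# with fixed margins.
oracle_fisher_p <- function(a, b, cc, d) {
  m <- a + cc # margin: tissue-specific genes
  n <- b + d
  k <- a + b # margin: biomarkers
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# BH step-up by direct search for the largest k with p_(k) <= k q / m.
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * q / m)))
  rejected <- rep(FALSE, m)
  if (is.finite(k) && k >= 1) rejected[ord[seq_len(k)]] <- TRUE
  rejected
}

# Exact two-sided rank-sum p by enumeration of group assignments (tie-aware
# via midranks); independent of the package's implementation details.
oracle_ranksum_p <- function(x, y) {
  na <- length(x)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(r), na)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  center <- na * length(y) / 2
  mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
}
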