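# Independent oracles, deliberately implemented apart from the package's
# code paths.

# Exhaustive Dempster combination over k mass assignments on the frame
# {TMH, non}. m is a k x 3 matrix with columns m({T}), m({N}), m(Theta).
# Enumerates all 3^k focal-set products; intersections: any {T} with any
# {N} is empty (conflict), otherwise the intersection is the smallest set
# present.
dempster_oracle <- function(m) {
  k <- nrow(m)
  acc <- c(T = 0, N = 0, Th = 0)
  conflict <- 0
  combos <- expand.grid(rep(list(1:3), k))
  for (r in seq_len(nrow(combos))) {
    sets <- as.integer(combos[r, ])
    w <- prod(m[cbind(seq_len(k), sets)])
    has_t <- any(sets == 1L); has_n <- any(sets == 2L)
    if (has_t && has_n) conflict <- conflict + w
    else if (has_t) acc["T"] <- acc["T"] + w
    else if (has_n) acc["N"] <- acc["N"] + w
    else acc["Th"] <- acc["Th"] + w
  }
  unname(acc / (1 - conflict))
}

# Pignistic TMH probability via the oracle.
oracle_pignistic <- function(m) {
  cm <- dempster_oracle(m)
  cm[1] + cm[3] / 2
}

# Brute-force per-position median by explicit sorting.
median_oracle <- function(v, window) {
  h <- (window - 1) %/% 2
  vapply(seq_along(v), function(i) {
    w <- sort(v[max(1, i - h):min(length(v), i + h)])
    n <- length(w)
    if (n %% 2 == 1) w[(n + 1) / 2] else (w[n / 2] + w[n / 2 + 1]) / 2
  }, numeric(1))
}

# Naive k-nearest-neighbor OET classification: plain loops, tie-inclusive.
oetknn_oracle <- function(ref, y, query, k, alpha0, g_pos, g_neg) {
  d2 <- apply(ref, 1, function(r) sum((r - query)^2))
  kth <- sort(d2)[k]
  idx <- which(d2 <= kth)
  m <- t(vapply(idx, function(i) {
    own <- alpha0 * exp(-(if (y[i] == 1) g_pos else g_neg) * d2[i])
    if (y[i] == 1) c(own, 0, 1 - own) else c(0, own, 1 - own)
  }, numeric(3)))
  oracle_pignistic(m)
}
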