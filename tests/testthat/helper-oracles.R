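# Shared test helpers: independent oracles and fixture builders.

# noiseless oracle: a set is positive iff it contains a planted entity
entity_oracle <- function(entities) {
  entities <- lapply(entities, as.integer)
  function(S) any(vapply(entities, function(e) all(e %in% S), TRUE))
}

# quench model with no background and no noise: calls are driven purely by
# planted entities
noiseless_model <- function() {
  quench_model(background_ksv_log_mean = -20, background_ksv_log_sd = 0,
               readout_noise_sd = 0)
}

# Exact minimum number of k-blocks covering all t-subsets of 1..n, by
# branch-and-bound over bitmasks: branch on the blocks containing the first
# uncovered t-subset. Independent of the package's constructors. Only for
# toy sizes (needs choose(n, t) <= 30).
min_cover_bruteforce <- function(n, k, t = 2) {
  if (k == n) return(1L)
  blocks <- combn(n, k, simplify = FALSE)
  subsets <- combn(n, t, simplify = FALSE)
  np <- length(subsets)
  stopifnot(np <= 30)
  full <- bitwShiftL(1L, np) - 1L
  masks <- vapply(blocks, function(b) {
    m <- 0L
    for (j in seq_len(np))
      if (all(subsets[[j]] %in% b)) m <- bitwOr(m, bitwShiftL(1L, j - 1L))
    m
  }, 0L)
  covering <- lapply(seq_len(np), function(j)
    which(bitwAnd(masks, bitwShiftL(1L, j - 1L)) != 0L))

  best <- length(blocks) # trivial upper bound
  rec <- function(cov, depth) {
    if (cov == full) {
      best <<- min(best, depth)
      return(invisible())
    }
    if (depth + 1L >= best) return(invisible()) # cannot improve
    j <- 1L
    while (bitwAnd(cov, bitwShiftL(1L, j - 1L)) != 0L) j <- j + 1L
    for (b in covering[[j]]) rec(bitwOr(cov, masks[b]), depth + 1L)
    invisible()
  }
  rec(0L, 0L)
  as.integer(best)
}

# uncovered t-subsets counted from scratch (independent of verify_cover)
count_uncovered <- function(blocks, n, t = 2, lam = 1) {
  subsets <- combn(n, t, simplify = FALSE)
  cnt <- vapply(subsets, function(s)
    sum(vapply(blocks, function(b) all(s %in% b), TRUE)), 1)
  sum(cnt < lam)
}
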