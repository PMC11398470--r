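# Independent brute-force oracles used across the suite. These are written
# against the stated contracts, not against the package internals.

# Hamming distance between two equal-length strings.
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Leftmost-best Hamming substring scan: best offset (1-based) of pat in
# seq, or NA if the best distance exceeds max_mm.
oracle_scan <- function(seq, pat, max_mm) {
  n <- nchar(seq); m <- nchar(pat)
  if (m > n) return(NA_integer_)
  best <- NA_integer_; best_mm <- max_mm + 1L
  for (off in seq_len(n - m + 1L)) {
    mm <- oracle_hamming(substr(seq, off, off + m - 1L), pat)
    if (mm < best_mm) { best_mm <- mm; best <- off }
  }
  if (best_mm <= max_mm) best else NA_integer_
}

# O(n^2) directional-network collapse over all pairs: nodes in
# (count desc, sequence asc) order; each absorbed into the root of its best
# already-processed neighbour with Hamming <= max_dist and
# count(a) >= 2*count(b) - 1 (best = highest count, then lexicographically
# smallest sequence).
oracle_directional <- function(seqs, counts, max_dist) {
  n <- length(seqs)
  if (max_dist == 0L || n == 0L) return(setNames(seqs, seqs))
  ch <- do.call(rbind, strsplit(seqs, ""))
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) d[i, ] <- colSums(t(ch) != ch[i, ])
  ord <- order(-counts, seqs)
  root <- integer(n)
  for (k in seq_len(n)) {
    b <- ord[k]
    prev <- ord[seq_len(k - 1L)]
    cand <- prev[d[prev, b] <= max_dist &
                   counts[prev] >= 2 * counts[b] - 1]
    if (length(cand) == 0L) {
      root[b] <- b
    } else {
      best <- cand[order(-counts[cand], seqs[cand])][1L]
      root[b] <- root[best]
    }
  }
  setNames(seqs[root], seqs)
}

# Brute-force median-of-ratios from the definitional formula.
oracle_size_factors <- function(m) {
  pos <- apply(m > 0, 1, all)
  ref <- exp(rowMeans(log(m[pos, , drop = FALSE])))
  s <- apply(sweep(m[pos, , drop = FALSE], 1, ref, "/"), 2, median)
  s / exp(mean(log(s)))
}

# Shared small simulated screen (counts-level) for reuse across tests.
small_screen <- function(seed = 11, n_constructs = 40, depth = 6e4,
                         effects = list(), ...) {
  cfg <- simConfig(n_constructs = n_constructs,
                   n_nontargeting = max(1L, n_constructs %/% 10L),
                   depth = depth, effects = effects, seed = seed, ...)
  simulateScreen(simulateLibrary(cfg), conditions = c("ctrl", "trt"),
                 nReplicates = 3)
}

random_dna_vec <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), "")
}
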