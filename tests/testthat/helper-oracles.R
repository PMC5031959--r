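# Independent oracles used across the suite: exhaustive structure
# enumeration for the folding DP, choose()-based enumeration for the
# Fisher and hypergeometric tails, a re-derived category classifier, and
# an exhaustive adapter-search reference.

oracle_pair_reward <- function(a, b) {
  p <- paste0(a, b)
  if (p %in% c("GC", "CG")) 3
  else if (p %in% c("AU", "UA")) 2
  else if (p %in% c("GU", "UG")) 1
  else 0
}

# all nested structures (lists of pair index matrices) for region i..j,
# minimum hairpin loop 3
oracle_enumerate_structures <- function(s, i = 1L, j = length(s)) {
  if (j - i < 4L) return(list(matrix(integer(0), ncol = 2)))
  out <- oracle_enumerate_structures(s, i + 1L, j)
  for (j2 in (i + 4L):j) {
    if (oracle_pair_reward(s[i], s[j2]) == 0) next
    inner <- oracle_enumerate_structures(s, i + 1L, j2 - 1L)
    rest <- oracle_enumerate_structures(s, j2 + 1L, j)
    for (x in inner) for (y in rest)
      out[[length(out) + 1L]] <- rbind(c(i, j2), x, y)
  }
  out
}

# exhaustive-enumeration optimum of the weighted pairing score
oracle_fold_mfe <- function(sequence) {
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  structs <- oracle_enumerate_structures(s)
  best <- 0
  for (st in structs) {
    if (!nrow(st)) next
    sc <- sum(vapply(seq_len(nrow(st)),
                     function(r) oracle_pair_reward(s[st[r, 1]], s[st[r, 2]]),
                     0))
    best <- max(best, sc)
  }
  -best
}

# two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, probabilities from choose()
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  p_obs <- probs[match(a, xs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# upper-tail hypergeometric by explicit enumeration
oracle_hyper_p <- function(TB, TS, B, S) {
  xs <- S:min(B, TS)
  sum(choose(B, xs) * choose(TB - B, TS - xs)) / choose(TB, TS)
}

# category rules re-derived from scratch on a covered-position profile
oracle_category <- function(site_count, covered_counts) {
  if (site_count == 1) return(4L)
  mx <- max(covered_counts)
  med <- stats::median(covered_counts)
  if (site_count == mx)
    return(if (sum(covered_counts == mx) == 1L) 0L else 1L)
  if (site_count > med && site_count < mx) return(2L)
  3L
}

# exhaustive left-to-right adapter search: first position where the
# adapter matches fully, or runs off the read end with >= min_overlap
oracle_trim <- function(read, adapter, min_overlap = 8L) {
  n <- nchar(read); alen <- nchar(adapter)
  for (p in seq_len(n)) {
    k <- min(alen, n - p + 1L)
    if (substr(read, p, p + k - 1L) != substr(adapter, 1L, k)) next
    if (k == alen || (p + k - 1L == n && k >= min_overlap))
      return(substr(read, 1L, p - 1L))
  }
  NA_character_
}

rand_rna_seq <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
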