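# Independent oracles used by the test suite. Both are deliberately naive
# implementations so they share no code with the package internals.

# Exhaustive maximum-cardinality bipartite matching size: for every red spot
# try leaving it unmatched or matching it to each free blue neighbour.
bf_max_matching_size <- function(red, blue, d_max) {
  nr <- nrow(red); nb <- nrow(blue)
  if (nr == 0 || nb == 0) return(0L)
  d <- sqrt(outer(red[, 1], blue[, 1], "-")^2 +
              outer(red[, 2], blue[, 2], "-")^2)
  adj <- lapply(seq_len(nr), function(i) which(d[i, ] <= d_max))
  rec <- function(i, used) {
    if (i > nr) return(0L)
    best <- rec(i + 1L, used)
    for (j in adj[[i]]) {
      if (!used[j]) {
        used[j] <- TRUE
        cand <- 1L + rec(i + 1L, used)
        used[j] <- FALSE
        if (cand > best) best <- cand
      }
    }
    best
  }
  rec(1L, logical(nb))
}

# Brute-force AUC: mean pairwise concordance with half credit for ties.
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# Uniform random spot coordinates in a box.
rand_spots <- function(n, box) {
  cbind(x = runif(n, 0, box), y = runif(n, 0, box))
}
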