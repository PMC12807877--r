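# Independent oracles used across test files. These are deliberately naive
# O(N) / enumeration implementations, kept separate from the package's code
# paths.

# weighted KS enrichment score by a full running-sum scan over every position
brute_force_es <- function(scores, hit_idx, weight = 1) {
  N <- length(scores)
  is_hit <- logical(N)
  is_hit[hit_idx] <- TRUE
  w <- abs(scores)^weight
  W <- sum(w[is_hit])
  if (W == 0) {
    w[] <- 1
    W <- sum(is_hit)
  }
  miss_step <- 1 / (N - sum(is_hit))
  running <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (is_hit[i]) cur + w[i] / W else cur - miss_step
    running[i] <- cur
  }
  running[which.max(abs(running))]
}

# brute-force pause scan: literal re-statement of the 10x nonzero-mean rule
brute_force_pauses <- function(counts, fold = 10, min_nonzero = 10) {
  nz <- counts[counts > 0]
  if (length(nz) < min_nonzero) return(integer(0))
  out <- integer(0)
  for (i in seq_along(counts)) {
    if (counts[i] >= fold * mean(nz)) out <- c(out, i - 1L)
  }
  out
}

# two-sided Fisher p by explicit enumeration of all tables with the observed
# margins, probabilities from choose()
enumerate_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, r1 - (n - c1)):min(r1, c1)
  prob <- vapply(xs, function(x) {
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  }, numeric(1))
  p_obs <- prob[match(a, xs)]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg by the literal step-up definition
stepup_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
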