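# Independent oracles, deliberately implemented differently from the
# package code paths they check.

# All 0-based starts at which deleting d bases from wt yields mut,
# computed on exploded character vectors.
oracle_del_placements <- function(wt, mut) {
  w <- strsplit(wt, "", fixed = TRUE)[[1L]]
  m <- strsplit(mut, "", fixed = TRUE)[[1L]]
  d <- length(w) - length(m)
  stopifnot(d >= 1)
  hits <- integer(0)
  for (i in 0:length(m)) {
    keep <- c(if (i > 0) w[1:i], if (i + d < length(w)) w[(i + d + 1):length(w)])
    if (length(keep) == length(m) && all(keep == m)) hits <- c(hits, i)
  }
  hits
}

oracle_ins_placements <- function(wt, mut) {
  # insertion into wt <=> deletion from mut
  oracle_del_placements(mut, wt)
}

# Clopper-Pearson endpoints by direct root-finding on the binomial tail
# sums (no qbeta).
oracle_cp_interval <- function(k, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lower <- if (k == 0) 0 else
    uniroot(function(p) sum(dbinom(k:n, n, p)) - a, c(1e-12, 1 - 1e-12),
            tol = 1e-12)$root
  upper <- if (k == n) 1 else
    uniroot(function(p) sum(dbinom(0:k, n, p)) - a, c(1e-12, 1 - 1e-12),
            tol = 1e-12)$root
  c(lower, upper)
}

# Two-sided Fisher exact p by exhaustive hypergeometric enumeration on a
# 2x2 table given in row-major order c(a, b, c, d).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    choose(m, x) * choose(n2, k - x) / choose(m + n2, k)
  }, numeric(1))
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A random wild-type/mutant deletion pair with no engineered structure:
# truth is whatever the brute-force oracle measures.
random_deletion_pair <- function(len = 120, max_size = 12) {
  wt <- random_amplicon(len, gc = runif(1, 0.25, 0.65))
  d <- sample(seq_len(max_size), 1L)
  i <- sample(seq(10L, len - d - 10L), 1L)   # 1-based first deleted base
  mut <- paste0(substr(wt, 1L, i - 1L), substr(wt, i + d, len))
  list(wt = wt, mut = mut, size = d)
}

# Frozen expectations for the packaged junction-pair fixture, computed
# with oracle_del_placements / oracle_ins_placements before the caller
# existed (see test-junction.R for the live re-derivation).
fixture_expected <- data.frame(
  allele_id = c("C-45-hy1", "C-55-hy1", "C-142-hy1", "C(450)-100-gl1",
                "C(450)-150-pid1", "C30-9-gl2", "C30-39-hy1", "C30-74-hy1",
                "C30-106-gl1", "C30-148-amp1", "C30-155-hy1"),
  type = c("Del", "Del", "Del", "Del", "Ins", "Del", "Del", "Del", "Del",
           "Del", "Del"),
  size = c(2L, 3L, 1L, 1L, 1L, 1L, 5L, 2L, 1L, 1L, 4L),
  mh = c(1L, 0L, 0L, 0L, 2L, 1L, 1L, 0L, 1L, 0L, 2L),
  stringsAsFactors = FALSE
)
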