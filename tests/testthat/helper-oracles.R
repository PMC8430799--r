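# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# global alignment score by exhaustive recursion (exponential; n <= 8 only)
brute_align_score <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      best <- max(best, rec(i - 1L, j - 1L) +
                    if (av[i] == bv[j]) match else mismatch)
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(length(av), length(bv))
}

# per-gene distinct-miRNA-partner count straight off a record tibble
brute_degrees <- function(records) {
  pairs <- unique(data.frame(m = species_agnostic_key(records$mirna),
                             g = records$gene))
  tab <- table(pairs$g)
  sort(stats::setNames(as.integer(tab), names(tab)), decreasing = TRUE)
}

# one-way ANOVA F from raw sums of squares
brute_anova_f <- function(groups) {
  all_y <- unlist(groups)
  grand <- mean(all_y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  k <- length(groups)
  (ssb / (k - 1)) / (ssw / (length(all_y) - k))
}

# hypergeometric upper tail P(X >= k) by enumerating all size-n draws
brute_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # genes 1..K are "in the term"
  mean(hits >= k)
}

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}
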