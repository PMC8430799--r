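#' Global alignment of two short RNA sequences
#'
#' Needleman-Wunsch global alignment with linear gap penalty. At mature
#' miRNA lengths (~22 nt) the full dynamic program is exact and instant, so
#' no heuristic search is needed. Traceback ties are broken
#' deterministically: diagonal (match/mismatch) is preferred, then up
#' (consume a base of `a`, gap in `b`), then left.
#'
#' @param a,b Non-empty RNA sequences (DNA `T` is normalized to `U`).
#' @param match,mismatch,gap Column scores; defaults +1 / 0 / -1.
#' @return A list of class `rna_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length gapped strings, `-` for gaps), `score`, `identity`
#'   (percent, identical columns over alignment length) and
#'   `identity_shortest` (identical columns over the shorter input length).
#' @examples
#' global_align("ACGU", "ACGA")$identity  # 75
#' @export
global_align <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  if (length(a) != 1L || length(b) != 1L || !nzchar(a) || !nzchar(b)) {
    stop("both sequences must be single non-empty strings", call. = FALSE)
  }
  a <- normalize_rna(a)
  b <- normalize_rna(b)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)

  f <- matrix(0, n + 1L, m + 1L)
  f[, 1L] <- gap * 0:n
  f[1L, ] <- gap * 0:m
  for (i in seq_len(n)) {
    s <- ifelse(av[i] == bv, match, mismatch)
    for (j in seq_len(m)) {
      f[i + 1L, j + 1L] <- max(f[i, j] + s[j], f[i, j + 1L] + gap, f[i + 1L, j] + gap)
    }
  }

  # traceback, tie preference: diagonal > up > left
  ga <- character(0)
  gb <- character(0)
  i <- n
  j <- m
  while (i > 0L || j > 0L) {
    here <- f[i + 1L, j + 1L]
    if (i > 0L && j > 0L &&
        here == f[i, j] + ifelse(av[i] == bv[j], match, mismatch)) {
      ga <- c(av[i], ga); gb <- c(bv[j], gb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && here == f[i, j + 1L] + gap) {
      ga <- c(av[i], ga); gb <- c("-", gb); i <- i - 1L
    } else {
      ga <- c("-", ga); gb <- c(bv[j], gb); j <- j - 1L
    }
  }

  ident_cols <- sum(ga == gb & ga != "-")
  structure(
    list(
      aligned_a = paste(ga, collapse = ""),
      aligned_b = paste(gb, collapse = ""),
      score = f[n + 1L, m + 1L],
      identity = 100 * ident_cols / length(ga),
      identity_shortest = 100 * ident_cols / min(n, m)
    ),
    class = "rna_alignment"
  )
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  cat(sprintf("score %g, identity %.1f%% (alignment length), %.1f%% (shortest)\n",
              x$score, x$identity, x$identity_shortest))
  invisible(x)
}

#' Percent identity between two sequences
#'
#' @inheritParams global_align
#' @param denominator `"alignment"` (identical columns over alignment
#'   length, including gap columns; default) or `"shortest"` (over the
#'   shorter input's length).
#' @return Percent identity in `[0, 100]` (may exceed 100 only if gaps make
#'   identical columns outnumber the shorter sequence, which the scoring
#'   scheme prevents).
#' @export
percent_identity <- function(a, b, denominator = c("alignment", "shortest"),
                             match = 1, mismatch = 0, gap = -1) {
  denominator <- match.arg(denominator)
  aln <- global_align(a, b, match, mismatch, gap)
  if (denominator == "alignment") aln$identity else aln$identity_shortest
}

#' Match each query miRNA to its best homologue in a subject set
#'
#' For each query the subject with the highest global-alignment percent
#' identity is reported (ties broken alphabetically by subject label),
#' together with whether the two seed sequences are identical. This
#' reproduces the cross-species translation step of a panel discovered in
#' one species to assays in another.
#'
#' @param queries,subjects Mature-miRNA tibbles (see [mature_mirna()] /
#'   [read_mirna_fasta()]); `subjects` must be non-empty.
#' @param denominator Identity convention, see [percent_identity()].
#' @return Tibble with one row per query: `query`, `subject`,
#'   `percent_identity`, `seed_identical`, `aligned_query`,
#'   `aligned_subject`.
#' @export
match_homologues <- function(queries, subjects,
                             denominator = c("alignment", "shortest")) {
  denominator <- match.arg(denominator)
  stopifnot(all(c("label", "sequence", "seed") %in% names(queries)),
            all(c("label", "sequence", "seed") %in% names(subjects)))
  if (nrow(subjects) == 0L) stop("subject set must be non-empty", call. = FALSE)

  one <- function(q_label, q_seq, q_seed) {
    alns <- lapply(subjects$sequence, function(s) global_align(q_seq, s))
    ident <- vapply(alns, function(x) {
      if (denominator == "alignment") x$identity else x$identity_shortest
    }, numeric(1))
    best <- order(-ident, subjects$label)[1L]
    tibble::tibble(
      query = q_label,
      subject = subjects$label[best],
      percent_identity = ident[best],
      seed_identical = identical(q_seed, subjects$seed[best]),
      aligned_query = alns[[best]]$aligned_a,
      aligned_subject = alns[[best]]$aligned_b
    )
  }
  dplyr::bind_rows(Map(one, queries$label, queries$sequence, queries$seed))
}
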