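#' Load a gene-to-term annotation map
#'
#' Reads a tab-delimited file with columns `gene` and `term` (an optional
#' `term_label` column is carried through). Duplicate (gene, term) rows
#' collapse; genes outside the declared background are dropped with a
#' warning stating how many.
#'
#' @param path Tab-delimited annotation file.
#' @param background Optional character vector of background gene symbols.
#'   Default: all genes appearing in the map.
#' @return A list of class `annotation_map`: `term_to_genes` (named list of
#'   character vectors), `background`, `term_labels` (named character, may
#'   be empty).
#' @export
load_annotation <- function(path, background = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (nrow(tab) == 0L) stop("annotation file ", path, " is empty", call. = FALSE)
  if (!all(c("gene", "term") %in% names(tab))) {
    stop("annotation file must have 'gene' and 'term' columns", call. = FALSE)
  }
  annotation_map(tab, background)
}

#' Build an annotation map from a data frame
#'
#' @param ann Data frame with columns `gene`, `term` and optionally
#'   `term_label`.
#' @inheritParams load_annotation
#' @return An `annotation_map`.
#' @export
annotation_map <- function(ann, background = NULL) {
  stopifnot(all(c("gene", "term") %in% names(ann)))
  ann <- unique(ann[, intersect(c("gene", "term", "term_label"), names(ann))])
  if (is.null(background)) {
    background <- sort(unique(ann$gene))
  } else {
    background <- sort(unique(as.character(background)))
    outside <- !(ann$gene %in% background)
    if (any(outside)) {
      warning(sum(outside), " annotation row(s) for genes outside the ",
              "background were dropped", call. = FALSE)
      ann <- ann[!outside, ]
    }
  }
  if (nrow(ann) == 0L) stop("no annotations left after background restriction",
                            call. = FALSE)
  term_to_genes <- lapply(split(ann$gene, ann$term), function(g) sort(unique(g)))
  term_labels <- character()
  if ("term_label" %in% names(ann)) {
    lab <- unique(ann[, c("term", "term_label")])
    term_labels <- stats::setNames(lab$term_label, lab$term)
  }
  structure(list(term_to_genes = term_to_genes,
                 background = background,
                 term_labels = term_labels),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("annotation map:", length(x$term_to_genes), "terms over",
      length(x$background), "background genes\n")
  invisible(x)
}

#' Overrepresentation analysis of a gene list
#'
#' For every term with at least one study gene, computes the upper-tail
#' hypergeometric probability of observing `k` or more annotated study
#' genes given term size `K`, study size `n` and background size `N`
#' (via [stats::phyper()]), the expected count `n * K / N`, the fold
#' enrichment `k / expected`, and a Bonferroni-corrected p-value whose
#' multiplier is the number of terms tested (those with `k >= 1`).
#' Results are sorted by fold enrichment, descending.
#'
#' @param study Character vector of study gene symbols. Genes outside the
#'   background are dropped with a warning.
#' @param ann An [annotation_map()].
#' @return Tibble with columns `term`, `term_label`, `k`, `K`, `n`, `N`,
#'   `expected`, `fold_enrichment`, `raw_p`, `bonferroni_p`.
#' @examples
#' ann <- annotation_map(data.frame(
#'   gene = c(paste0("G", 1:5), paste0("G", 1:10)),
#'   term = rep(c("T1", "ALL"), c(5, 10))))
#' overrepresentation(c("G1", "G2", "G3"), ann)
#' @export
overrepresentation <- function(study, ann) {
  stopifnot(inherits(ann, "annotation_map"))
  study <- unique(as.character(study))
  outside <- setdiff(study, ann$background)
  if (length(outside) > 0L) {
    warning(length(outside), " study gene(s) outside the background dropped",
            call. = FALSE)
    study <- setdiff(study, outside)
  }
  if (length(study) == 0L) {
    stop("no study genes left after background restriction", call. = FALSE)
  }
  n <- length(study)
  N <- length(ann$background)

  k_all <- vapply(ann$term_to_genes, function(g) length(intersect(g, study)),
                  integer(1))
  K_all <- lengths(ann$term_to_genes)
  tested <- k_all >= 1L
  m <- sum(tested)
  term <- names(ann$term_to_genes)[tested]
  k <- unname(k_all[tested])
  K <- unname(K_all[tested])

  res <- tibble::tibble(
    term = term,
    term_label = if (length(ann$term_labels) > 0L) {
      unname(ann$term_labels[term])
    } else NA_character_,
    k = k,
    K = K,
    n = n,
    N = N,
    expected = n * K / N,
    raw_p = stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  )
  res$fold_enrichment <- res$k / res$expected
  res$bonferroni_p <- pmin(1, res$raw_p * m)
  res |>
    dplyr::arrange(dplyr::desc(.data$fold_enrichment), .data$raw_p, .data$term) |>
    dplyr::select("term", "term_label", "k", "K", "n", "N", "expected",
                  "fold_enrichment", "raw_p", "bonferroni_p")
}

#' Top significantly enriched terms
#'
#' The `m` highest-fold-enrichment terms among those significant after
#' Bonferroni correction; ties broken by raw p ascending, then term label.
#'
#' @param results Tibble from [overrepresentation()].
#' @param m Maximum number of terms, default 25.
#' @param alpha Significance level on the Bonferroni-corrected p, default
#'   0.05.
#' @return Subset of `results`, at most `m` rows.
#' @export
top_terms <- function(results, m = 25L, alpha = 0.05) {
  stopifnot(m >= 1L)
  sig <- results[results$bonferroni_p < alpha, ]
  sig <- sig |>
    dplyr::arrange(dplyr::desc(.data$fold_enrichment), .data$raw_p, .data$term)
  utils::head(sig, m)
}
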