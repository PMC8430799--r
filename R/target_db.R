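#' Inclusion thresholds for predicted interaction scores
#'
#' The two predicted-source dialects carry scores on different scales:
#' miRDB-like scores live on 0-100 where higher means stronger support, and
#' mirSVR-like scores are non-positive where more negative means stronger.
#' Records are kept only strictly beyond the thresholds (score > min_score_a
#' for the first dialect, score < max_score_b for the second); curated
#' validated records carry no score and always pass.
#'
#' @param min_score_a Minimum miRDB-like score, strict; default 80.
#' @param max_score_b Maximum mirSVR-like score, strict; default -1.2.
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_score_a = 80.0, max_score_b = -1.2) {
  stopifnot(is.numeric(min_score_a), length(min_score_a) == 1L,
            min_score_a >= 0, min_score_a <= 100,
            is.numeric(max_score_b), length(max_score_b) == 1L,
            max_score_b <= 0)
  structure(list(min_score_a = min_score_a, max_score_b = max_score_b),
            class = "filter_thresholds")
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat("interaction inclusion thresholds: score A >", x$min_score_a,
      "| score B <", x$max_score_b, "\n")
  invisible(x)
}

#' Canonicalize gene symbols to rodent style
#'
#' First letter uppercase, remainder lowercase (`"RICTOR"` -> `"Rictor"`),
#' matching the convention of rat gene symbols.
#'
#' @param gene Character vector of gene symbols.
#' @return Character vector.
#' @export
canonicalize_gene_symbol <- function(gene) {
  gene <- trimws(as.character(gene))
  paste0(toupper(substr(gene, 1, 1)), tolower(substr(gene, 2, nchar(gene))))
}

.dialect_source <- c(mirdb = "predicted_scoreA",
                     mirsvr = "predicted_scoreB",
                     validated = "validated")
.source_score_type <- c(predicted_scoreA = "miRDB-like",
                        predicted_scoreB = "mirSVR-like",
                        validated = "none")

#' Read a miRNA-target interaction table
#'
#' Tab-delimited with a header; required columns `mirna` and `gene`, plus
#' `score` for the two predicted dialects. Gene symbols are canonicalized
#' with [canonicalize_gene_symbol()]; row count and order are preserved.
#'
#' @param path Path to the tab-delimited file.
#' @param dialect One of `"mirdb"` (predicted, 0-100 score), `"mirsvr"`
#'   (predicted, non-positive score) or `"validated"` (curated, score
#'   optional and ignored).
#' @return Tibble of interaction records with columns `mirna`, `gene`,
#'   `source`, `score`, `score_type`.
#' @export
read_interaction_table <- function(path, dialect = c("mirdb", "mirsvr", "validated")) {
  dialect <- match.arg(dialect)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  required <- c("mirna", "gene", if (dialect != "validated") "score")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("interaction table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  source <- .dialect_source[[dialect]]
  if (dialect == "validated") {
    score <- rep(NA_real_, nrow(tab))
  } else {
    score <- suppressWarnings(as.numeric(tab$score))
    bad <- which(is.na(score) & !is.na(tab$score))
    if (length(bad) > 0L) {
      stop("non-numeric score in ", path, " at data line(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  interaction_records(tab$mirna, tab$gene, source, score)
}

#' Build interaction records in memory
#'
#' @param mirna,gene Character vectors (recycled to common length).
#' @param source One of `"predicted_scoreA"`, `"predicted_scoreB"`,
#'   `"validated"`.
#' @param score Numeric scores (`NA` for validated records).
#' @return Tibble of interaction records.
#' @export
interaction_records <- function(mirna, gene, source, score = NA_real_) {
  source <- match.arg(source, names(.source_score_type), several.ok = TRUE)
  rec <- tibble::tibble(
    mirna = as.character(mirna),
    gene = canonicalize_gene_symbol(gene),
    source = source,
    score = as.numeric(score)
  )
  rec$score_type <- unname(.source_score_type[rec$source])
  rec$score[rec$source == "validated"] <- NA_real_
  rec
}

#' Apply inclusion thresholds to interaction records
#'
#' Predicted records survive only strictly beyond their dialect's threshold
#' (miRDB-like: score > `min_score_a`; mirSVR-like: score < `max_score_b`);
#' validated records are always kept. Input order is preserved. Filtering
#' is monotone in the thresholds and idempotent.
#'
#' @param records Tibble of interaction records.
#' @param thresholds A [filter_thresholds()] object.
#' @param strongest_site_only If `TRUE`, mirSVR-like records are first
#'   reduced to the strongest (minimum) score per (miRNA, gene) pair before
#'   thresholding, for inputs carrying one row per predicted target site.
#'   Default `FALSE`: every row is thresholded as-is.
#' @return Filtered tibble of interaction records.
#' @export
filter_interactions <- function(records, thresholds = filter_thresholds(),
                                strongest_site_only = FALSE) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (nrow(records) == 0L) return(records)
  if (strongest_site_only) {
    b <- records$source == "predicted_scoreB"
    if (any(b)) {
      best <- records[b, ] |>
        dplyr::group_by(.data$mirna, .data$gene) |>
        dplyr::slice_min(.data$score, n = 1L, with_ties = FALSE) |>
        dplyr::ungroup()
      records <- dplyr::bind_rows(records[!b, ], best)
    }
  }
  keep <- rep(TRUE, nrow(records))
  a <- records$source == "predicted_scoreA"
  b <- records$source == "predicted_scoreB"
  keep[a] <- records$score[a] > thresholds$min_score_a
  keep[b] <- records$score[b] < thresholds$max_score_b
  records[keep, ]
}

#' Restrict interaction records to a miRNA panel
#'
#' Matching is species-prefix-insensitive: a record for `"rno-miR-139-5p"`
#' matches a panel entry `"miR-139-5p"`.
#'
#' @param records Tibble of interaction records.
#' @param mirna_panel Character vector of miRNA labels (non-empty).
#' @return Records whose miRNA matches the panel, order preserved.
#' @export
restrict_to_mirnas <- function(records, mirna_panel) {
  if (length(mirna_panel) == 0L) {
    stop("mirna_panel must be non-empty", call. = FALSE)
  }
  if (nrow(records) == 0L) return(records)
  panel_keys <- unique(species_agnostic_key(mirna_panel))
  records[species_agnostic_key(records$mirna) %in% panel_keys, ]
}

#' Convert a named list of dialect tables to interaction records
#'
#' Accepts the `tables` element produced by the synthetic generators (or
#' any named list of tibbles with `mirna`, `gene` and, for predicted
#' dialects, `score` columns) and stacks them into one record tibble.
#'
#' @param tables Named list with any of `mirdb`, `mirsvr`, `validated`.
#' @return Tibble of interaction records.
#' @export
as_interaction_records <- function(tables) {
  stopifnot(is.list(tables), all(names(tables) %in% names(.dialect_source)))
  dplyr::bind_rows(lapply(names(tables), function(d) {
    tab <- tables[[d]]
    if (nrow(tab) == 0L) return(NULL)
    interaction_records(tab$mirna, tab$gene, .dialect_source[[d]],
                        if ("score" %in% names(tab)) tab$score else NA_real_)
  }))
}
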