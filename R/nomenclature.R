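#' Parse mature microRNA labels
#'
#' Decomposes labels such as `"rno-miR-188-5p"`, `"miR-125b*"` or `"let-7b"`
#' into a species prefix, a family core and an arm designation. The grammar
#' covers the conventional mature-miRNA naming used by miRBase-style
#' resources: an optional three-letter lowercase species code followed by a
#' hyphen, a family core beginning with `miR`, `let` or `lin` (case is
#' canonicalized), and an optional arm suffix `-5p`/`-3p` or a trailing `*`
#' marking the star (passenger) strand.
#'
#' The legacy pig prefix misspelling `scc` is accepted and normalized to
#' `ssc`.
#'
#' @param label Character vector of miRNA labels.
#' @return A tibble with one row per label and columns `raw_label`,
#'   `species_prefix` (three lowercase letters or `""`), `family_core`
#'   (e.g. `"miR-139"`), `arm` (one of `"5p"`, `"3p"`, `"star"`,
#'   `"unspecified"`) and `canonical` (the re-formatted label).
#' @examples
#' parse_mirna_name(c("rno-miR-188-5p", "miR-125b*", "let-7b"))
#' @export
parse_mirna_name <- function(label) {
  if (length(label) == 0L || any(is.na(label)) || any(!nzchar(label))) {
    stop("miRNA labels must be non-empty strings", call. = FALSE)
  }
  label <- trimws(label)
  if (any(!nzchar(label))) stop("miRNA labels must be non-empty strings", call. = FALSE)

  species <- character(length(label))
  rest <- label
  has_prefix <- grepl("^[A-Za-z]{3}-", label)
  species[has_prefix] <- tolower(sub("^([A-Za-z]{3})-.*$", "\\1", label[has_prefix]))
  # 'scc' is a recurring typo for the pig prefix 'ssc'
  species[species == "scc"] <- "ssc"
  rest[has_prefix] <- sub("^[A-Za-z]{3}-", "", label[has_prefix])

  # some "prefixes" are actually family stems (e.g. a bare "miR-21")
  stem <- grepl("^(mir|let|lin)$", species, ignore.case = TRUE)
  species[stem] <- ""
  rest[stem] <- label[stem]

  arm <- rep("unspecified", length(label))
  star <- grepl("\\*$", rest)
  arm[star] <- "star"
  rest[star] <- sub("\\*$", "", rest[star])
  fivep <- grepl("-5p$", rest)
  threep <- grepl("-3p$", rest)
  arm[fivep] <- "5p"
  arm[threep] <- "3p"
  rest[fivep | threep] <- sub("-[53]p$", "", rest[fivep | threep])

  # canonicalize stem casing: miR-..., let-..., lin-...
  core <- sub("^(?i)mir", "miR", rest, perl = TRUE)
  core <- sub("^(?i)let", "let", core, perl = TRUE)
  core <- sub("^(?i)lin", "lin", core, perl = TRUE)

  parsed <- tibble::tibble(
    raw_label = label,
    species_prefix = species,
    family_core = core,
    arm = arm
  )
  parsed$canonical <- format_mirna_name(parsed)
  parsed
}

#' Format parsed miRNA names back into canonical labels
#'
#' Inverse of [parse_mirna_name()]: parsing a formatted label reproduces the
#' same parts (round-trip fixed point).
#'
#' @param parsed A tibble as returned by [parse_mirna_name()].
#' @return Character vector of canonical labels.
#' @export
format_mirna_name <- function(parsed) {
  stopifnot(all(c("species_prefix", "family_core", "arm") %in% names(parsed)))
  prefix <- ifelse(nzchar(parsed$species_prefix), paste0(parsed$species_prefix, "-"), "")
  suffix <- dplyr::case_match(
    parsed$arm,
    "5p" ~ "-5p",
    "3p" ~ "-3p",
    "star" ~ "*",
    .default = ""
  )
  paste0(prefix, parsed$family_core, suffix)
}

#' Species-agnostic comparison key for miRNA labels
#'
#' Strips the species prefix so that orthologous labels from different
#' species (e.g. `"rno-miR-139-5p"` and `"ssc-miR-139-5p"`) map to the same
#' key. Two labels share a key if and only if they agree on family core and
#' arm.
#'
#' @param label Character vector of miRNA labels (raw or canonical).
#' @return Character vector of keys.
#' @examples
#' species_agnostic_key("rno-miR-139-5p") == species_agnostic_key("ssc-miR-139-5p")
#' @export
species_agnostic_key <- function(label) {
  parsed <- parse_mirna_name(label)
  parsed$species_prefix <- ""
  format_mirna_name(parsed)
}

#' Extract the seed region of a mature miRNA sequence
#'
#' The seed is the 5' region governing target recognition; here nucleotides
#' 2-8 (1-based, inclusive) by default, a 7-mer covering both the 2-7 and
#' 2-8 conventions. Bounds are configurable.
#'
#' @param sequence Character vector of RNA (or DNA; `T` is mapped to `U`)
#'   sequences, each of length >= `seed_end`.
#' @param seed_start,seed_end 1-based positions delimiting the seed.
#' @return Character vector of seed substrings.
#' @examples
#' extract_seed("UAGCUUAUCAGACUGAUGUUGA")  # "AGCUUAU"
#' @export
extract_seed <- function(sequence, seed_start = 2L, seed_end = 8L) {
  stopifnot(seed_start >= 1L, seed_end >= seed_start)
  sequence <- normalize_rna(sequence)
  if (any(nchar(sequence) < seed_end)) {
    stop("sequence shorter than the seed region (positions ", seed_start, "-",
         seed_end, ")", call. = FALSE)
  }
  substr(sequence, seed_start, seed_end)
}

#' @keywords internal
normalize_rna <- function(sequence) {
  sequence <- toupper(sequence)
  sequence <- gsub("T", "U", sequence, fixed = TRUE)
  bad <- grepl("[^ACGU]", sequence)
  if (any(bad)) {
    stop("non-RNA characters in sequence(s): ",
         paste(utils::head(sequence[bad], 3), collapse = ", "), call. = FALSE)
  }
  sequence
}

#' Construct a mature-miRNA table
#'
#' Pairs labels with uppercased, U-normalized RNA sequences and derives the
#' seed. Sequences must be 18-26 nt, the mature miRNA length range.
#'
#' @param label Character vector of miRNA labels.
#' @param sequence Character vector of sequences, same length as `label`.
#' @param seed_start,seed_end Seed bounds passed to [extract_seed()].
#' @return Tibble with columns `label`, `sequence`, `seed`.
#' @export
mature_mirna <- function(label, sequence, seed_start = 2L, seed_end = 8L) {
  stopifnot(length(label) == length(sequence))
  sequence <- normalize_rna(sequence)
  len <- nchar(sequence)
  if (any(len < 18L | len > 26L)) {
    stop("mature miRNA sequences must be 18-26 nt; offending label(s): ",
         paste(utils::head(label[len < 18L | len > 26L], 3), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    label = unname(as.character(label)),
    sequence = unname(sequence),
    seed = unname(extract_seed(sequence, seed_start, seed_end))
  )
}

#' Read mature miRNA sequences from a FASTA file
#'
#' Headers are taken as miRNA labels (first whitespace-delimited token);
#' sequences are uppercased and T is normalized to U.
#'
#' @param path Path to a FASTA file.
#' @inheritParams mature_mirna
#' @return Tibble as from [mature_mirna()].
#' @export
read_mirna_fasta <- function(path, seed_start = 2L, seed_end = 8L) {
  set <- Biostrings::readBStringSet(path)
  labels <- sub("\\s.*$", "", names(set))
  mature_mirna(labels, unname(as.character(set)), seed_start, seed_end)
}

#' Write mature miRNA sequences to a FASTA file
#'
#' @param mirnas Tibble with `label` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mirna_fasta <- function(mirnas, path) {
  stopifnot(all(c("label", "sequence") %in% names(mirnas)))
  set <- Biostrings::BStringSet(normalize_rna(mirnas$sequence))
  names(set) <- mirnas$label
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
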