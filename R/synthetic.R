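#' @title Seeded synthetic-data generators
#' @description Generators for the four input kinds consumed by the
#'   analysis (interaction tables, mature-miRNA FASTA pairs, qPCR Cp
#'   tables, annotation maps), each with planted structure and a ground
#'   truth sufficient to score the downstream stage. All generators are
#'   pure functions of their arguments and a single integer seed; the
#'   global RNG state is left untouched.
#' @details A single seed governs all substreams: the stream consumed by a
#'   generator is derived as `(seed * 2654435761 + stream_index) mod
#'   (2^31 - 1)`, with a fixed stream index per generator. Identical
#'   arguments and seed therefore give byte-identical outputs, and
#'   different generators called with the same seed draw from independent
#'   substreams.
#' @name synthetic
NULL

.stream_index <- c(interactions = 1L, profile = 2L, fasta = 3L, cp = 4L,
                   annotation = 5L)

#' @keywords internal
substream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  idx <- .stream_index[[stream]]
  as.integer((as.numeric(seed) %% 2^31 * 2654435761 + idx) %% (2^31 - 1))
}

.mirna_label <- function(i) sprintf("rno-miR-%d-5p", 100L + i)
.gene_label <- function(i) sprintf("G%04d", i)

#' Simulate three-dialect interaction tables with a planted hub
#'
#' Emulates the union of two score-carrying prediction databases and one
#' curated database. One gene (the planted hub) receives exactly
#' `hub_degree` above-threshold interactions from distinct miRNAs;
#' background edges are drawn independently per (miRNA, gene) pair, a
#' stated fraction of them with scores that fall below the inclusion
#' thresholds so that filtering is exercised. Above-threshold background
#' edges are capped at `hub_degree - 1` distinct miRNAs per gene, so the
#' planted hub is the unique top-degree gene of the filtered network.
#'
#' @param seed Integer seed.
#' @param n_mirnas Number of miRNAs (default 18, the panel size the
#'   analysis was designed around).
#' @param n_genes Number of candidate target genes.
#' @param hub_gene Symbol of the planted hub (default `"Hubx"`).
#' @param hub_degree Planted hub degree `k` (<= `n_mirnas`), default 5.
#' @param background_edge_prob Per-(miRNA, gene) probability of a
#'   background record, default 0.02.
#' @param below_threshold_fraction Fraction of background records drawn
#'   with sub-threshold scores, default 0.4.
#' @param thresholds [filter_thresholds()] the scores straddle.
#' @param out_dir If non-`NULL`, writes `mirdb.tsv`, `mirsvr.tsv`,
#'   `validated.tsv` and `truth_edges.tsv` there.
#' @return List with `tables` (named list of tibbles `mirna`, `gene`,
#'   `score` per dialect), `truth` (tibble of the (miRNA, gene) pairs that
#'   survive filtering) and `hub` (list `gene`, `degree`).
#' @export
simulate_interaction_tables <- function(seed, n_mirnas = 18L, n_genes = 120L,
                                        hub_gene = "Hubx", hub_degree = 5L,
                                        background_edge_prob = 0.02,
                                        below_threshold_fraction = 0.4,
                                        thresholds = filter_thresholds(),
                                        out_dir = NULL) {
  if (hub_degree > n_mirnas) {
    stop("planted hub degree exceeds the number of miRNAs", call. = FALSE)
  }
  hub_gene <- canonicalize_gene_symbol(hub_gene)
  mirnas <- .mirna_label(seq_len(n_mirnas))
  genes <- setdiff(.gene_label(seq_len(n_genes)), hub_gene)

  withr::with_seed(substream_seed(seed, "interactions"), {
    rows <- list()
    hub_mirnas <- sample(mirnas, hub_degree)
    for (mi in hub_mirnas) {
      rows[[length(rows) + 1L]] <- .synthetic_record(mi, hub_gene, above = TRUE,
                                                     thresholds = thresholds)
    }
    surviving <- stats::setNames(rep(0L, length(genes)), genes)
    for (g in genes) {
      for (mi in mirnas) {
        if (stats::runif(1) >= background_edge_prob) next
        above <- stats::runif(1) >= below_threshold_fraction
        if (above && surviving[[g]] >= hub_degree - 1L) above <- FALSE
        rows[[length(rows) + 1L]] <- .synthetic_record(mi, g, above, thresholds)
        if (above) surviving[[g]] <- surviving[[g]] + 1L
      }
    }
    all_rows <- dplyr::bind_rows(rows)
  })

  tables <- lapply(split(all_rows, all_rows$dialect), function(d) {
    tibble::tibble(mirna = d$mirna, gene = d$gene, score = d$score)
  })
  for (d in c("mirdb", "mirsvr", "validated")) {
    if (is.null(tables[[d]])) {
      tables[[d]] <- tibble::tibble(mirna = character(), gene = character(),
                                    score = numeric())
    }
  }
  tables <- tables[c("mirdb", "mirsvr", "validated")]
  truth <- unique(all_rows[all_rows$above, c("mirna", "gene")])

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (d in names(tables)) {
      tab <- tables[[d]]
      if (d == "validated") tab$score <- NULL
      utils::write.table(tab, file.path(out_dir, paste0(d, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(truth, file.path(out_dir, "truth_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(tables = tables, truth = truth,
       hub = list(gene = hub_gene, degree = hub_degree))
}

#' @keywords internal
.synthetic_record <- function(mirna, gene, above, thresholds) {
  dialect <- sample(c("mirdb", "mirsvr", if (above) "validated"), 1L)
  score <- switch(dialect,
    mirdb = if (above) stats::runif(1, thresholds$min_score_a + 0.5, 100)
            else stats::runif(1, 50, thresholds$min_score_a),
    mirsvr = if (above) stats::runif(1, -3, thresholds$max_score_b - 0.1)
             else stats::runif(1, thresholds$max_score_b, -0.3),
    validated = NA_real_
  )
  tibble::tibble(mirna = mirna, gene = gene, dialect = dialect,
                 score = score, above = above)
}

#' Simulate interaction tables realizing an exact degree profile
#'
#' Generates above-threshold records giving every gene an exact planted
#' node degree, drawn from a stated profile, plus sub-threshold noise rows
#' that a correct filter must remove. The default profile mirrors the
#' published scale of the cardioprotective miRNA-target network this
#' package models: 882 target genes of an 18-miRNA panel, of which one has
#' degree 5, 14 have degree 3 and 69 have degree 2 (so 84 genes are
#' targeted by more than one miRNA and 15 by at least three).
#'
#' @param seed Integer seed.
#' @param degree_profile Named integer vector: `names` are degrees,
#'   values are gene counts at that degree.
#' @param n_mirnas Number of miRNAs (>= max degree).
#' @param noise_rows Number of additional sub-threshold rows, default 200.
#' @param thresholds [filter_thresholds()] the scores straddle.
#' @return List with `tables` (tibbles per dialect), `truth` (tibble
#'   `gene`, `degree`).
#' @export
simulate_profile_interactions <- function(seed,
                                          degree_profile = c(`5` = 1L, `3` = 14L,
                                                             `2` = 69L, `1` = 798L),
                                          n_mirnas = 18L, noise_rows = 200L,
                                          thresholds = filter_thresholds()) {
  degrees <- rep(as.integer(names(degree_profile)), degree_profile)
  stopifnot(max(degrees) <= n_mirnas)
  genes <- .gene_label(seq_along(degrees))
  mirnas <- .mirna_label(seq_len(n_mirnas))

  withr::with_seed(substream_seed(seed, "profile"), {
    rows <- vector("list", length(genes))
    for (i in seq_along(genes)) {
      partners <- sample(mirnas, degrees[i])
      rows[[i]] <- dplyr::bind_rows(lapply(partners, .synthetic_record,
                                           gene = genes[i], above = TRUE,
                                           thresholds = thresholds))
    }
    noise <- dplyr::bind_rows(lapply(seq_len(noise_rows), function(i) {
      .synthetic_record(sample(mirnas, 1L), sample(genes, 1L),
                        above = FALSE, thresholds = thresholds)
    }))
    all_rows <- dplyr::bind_rows(c(rows, list(noise)))
  })

  tables <- lapply(split(all_rows, all_rows$dialect), function(d) {
    tibble::tibble(mirna = d$mirna, gene = d$gene, score = d$score)
  })
  for (d in c("mirdb", "mirsvr", "validated")) {
    if (is.null(tables[[d]])) {
      tables[[d]] <- tibble::tibble(mirna = character(), gene = character(),
                                    score = numeric())
    }
  }
  list(tables = tables[c("mirdb", "mirsvr", "validated")],
       truth = tibble::tibble(gene = genes, degree = degrees))
}

#' Simulate a cross-species pair of mature-miRNA FASTA sets
#'
#' Produces a query (rat-prefixed) and subject (pig-prefixed) set:
#' `n_identical` pairs share the full mature sequence, and `n_seed_only`
#' pairs share only the seed (positions 2-8) while the rest of the subject
#' sequence is mutated, under a different family name. The truth table
#' carries the intended percent identity computed with the package's own
#' public identity definition.
#'
#' @param seed Integer seed.
#' @param n_identical Number of fully conserved pairs, default 4.
#' @param n_seed_only Number of seed-only conserved pairs, default 1.
#' @param length Mature sequence length, default 22.
#' @param divergence Per-base mutation probability outside the seed for
#'   seed-only pairs, default 0.5.
#' @param out_dir If non-`NULL`, writes `queries.fa`, `subjects.fa` and
#'   `truth.tsv` there.
#' @return List with `queries`, `subjects` (mature-miRNA tibbles) and
#'   `truth` (tibble `query`, `subject`, `identity`, `seed_identical`).
#' @export
simulate_mirna_fasta_pair <- function(seed, n_identical = 4L, n_seed_only = 1L,
                                      length = 22L, divergence = 0.5,
                                      out_dir = NULL) {
  stopifnot(n_identical + n_seed_only >= 1L, length >= 18L, length <= 26L)
  bases <- c("A", "C", "G", "U")
  n_total <- n_identical + n_seed_only

  withr::with_seed(substream_seed(seed, "fasta"), {
    fams <- sample(100:999, 2L * n_total)
    q_seq <- vapply(seq_len(n_total), function(i) {
      paste(sample(bases, length, replace = TRUE), collapse = "")
    }, character(1))
    q_lab <- sprintf("rno-miR-%d-5p", fams[seq_len(n_total)])
    s_lab <- character(n_total)
    s_seq <- character(n_total)
    for (i in seq_len(n_total)) {
      if (i <= n_identical) {
        s_lab[i] <- sub("^rno-", "ssc-", q_lab[i])
        s_seq[i] <- q_seq[i]
      } else {
        s_lab[i] <- sprintf("ssc-miR-%d", fams[n_total + i])
        sv <- strsplit(q_seq[i], "")[[1]]
        outside <- setdiff(seq_len(length), 2:8)
        for (p in outside) {
          if (stats::runif(1) < divergence) sv[p] <- sample(setdiff(bases, sv[p]), 1L)
        }
        # guarantee at least one difference so identity < 100
        if (paste(sv, collapse = "") == q_seq[i]) {
          sv[1L] <- sample(setdiff(bases, sv[1L]), 1L)
        }
        s_seq[i] <- paste(sv, collapse = "")
      }
    }
  })

  queries <- mature_mirna(q_lab, q_seq)
  subjects <- mature_mirna(s_lab, s_seq)
  truth <- tibble::tibble(
    query = q_lab,
    subject = s_lab,
    identity = mapply(percent_identity, q_seq, s_seq, USE.NAMES = FALSE),
    seed_identical = extract_seed(q_seq) == extract_seed(s_seq)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_mirna_fasta(queries, file.path(out_dir, "queries.fa"))
    write_mirna_fasta(subjects, file.path(out_dir, "subjects.fa"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(queries = queries, subjects = subjects, truth = truth)
}

#' Simulate a qPCR Cp table with planted fold changes
#'
#' Emulates a three-group design (ischemia-reperfusion control plus
#' pre-/postconditioning interventions, unequal n of 4-6) measured for a
#' panel of assays against one housekeeping assay. Per sample, the
#' housekeeping Cp is drawn Normal(`hk_mean`, `cp_noise_sd`); the target
#' Cp is the housekeeping Cp plus `baseline_delta_cp`, minus the planted
#' log2 fold change of its (group, assay), plus Normal(0, `cp_noise_sd`)
#' noise. With zero noise the 2^-ddCp pipeline recovers the planted folds
#' exactly.
#'
#' @param seed Integer seed.
#' @param group_sizes Named integer vector of samples per group; the
#'   defaults mirror the tissue-availability-limited design (control 6,
#'   preconditioning 4, postconditioning 6).
#' @param assays Character vector of target assay names.
#' @param effects Tibble with columns `group`, `assay`, `log2_fold`
#'   (absent combinations default to 0; the reference group must be 0).
#' @param reference Reference group name, default `"Isch"`.
#' @param housekeeping Housekeeping assay name, default `"U6"`.
#' @param cp_noise_sd Gaussian Cp noise, cycles, default 0.3.
#' @param baseline_delta_cp Baseline target-minus-housekeeping Cp, default 5.
#' @param hk_mean Mean housekeeping Cp, default 20.
#' @param out_dir If non-`NULL`, writes `cp.csv` and `truth.tsv` there.
#' @return List with `cp` (a [cp_table()]) and `truth` (the full effects
#'   grid).
#' @export
simulate_cp_table <- function(seed,
                              group_sizes = c(Isch = 6L, IPreC = 4L, IPostC = 6L),
                              assays = c("ssc-miR-139-5p", "ssc-miR-212",
                                         "ssc-miR-320", "ssc-miR-362",
                                         "ssc-miR-503-5p"),
                              effects = NULL, reference = "Isch",
                              housekeeping = "U6", cp_noise_sd = 0.3,
                              baseline_delta_cp = 5, hk_mean = 20,
                              out_dir = NULL) {
  stopifnot(!is.null(names(group_sizes)), reference %in% names(group_sizes))
  grid <- tidyr::expand_grid(group = names(group_sizes), assay = assays)
  grid$log2_fold <- 0
  if (!is.null(effects)) {
    stopifnot(all(c("group", "assay", "log2_fold") %in% names(effects)))
    if (any(effects$group == reference & effects$log2_fold != 0)) {
      stop("planted effects in the reference group must be zero", call. = FALSE)
    }
    hit <- match(paste(grid$group, grid$assay),
                 paste(effects$group, effects$assay))
    grid$log2_fold[!is.na(hit)] <- effects$log2_fold[hit[!is.na(hit)]]
  }

  samples <- tibble::tibble(
    sample = sprintf("%s_%02d", rep(names(group_sizes), group_sizes),
                     unlist(lapply(group_sizes, seq_len))),
    group = rep(names(group_sizes), group_sizes)
  )

  rows <- withr::with_seed(substream_seed(seed, "cp"), {
    hk_cp <- stats::rnorm(nrow(samples), hk_mean, cp_noise_sd)
    hk_rows <- tibble::tibble(sample = samples$sample, group = samples$group,
                              assay = housekeeping, cp = hk_cp)
    target_rows <- lapply(assays, function(a) {
      lf <- grid$log2_fold[match(paste(samples$group, a),
                                 paste(grid$group, grid$assay))]
      tibble::tibble(
        sample = samples$sample, group = samples$group, assay = a,
        cp = hk_cp + baseline_delta_cp - lf +
          stats::rnorm(nrow(samples), 0, cp_noise_sd)
      )
    })
    dplyr::bind_rows(c(list(hk_rows), target_rows))
  })

  cp <- cp_table(rows, housekeeping_assay = housekeeping,
                 reference_group = reference)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rows, file.path(out_dir, "cp.csv"), row.names = FALSE)
    utils::write.table(grid, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(cp = cp, truth = grid)
}

#' Simulate an annotation map with one planted enriched term
#'
#' The background holds the study genes plus filler genes. One term is
#' planted at `enrichment_factor` times its expected study-gene count; all
#' other terms draw their members uniformly from the background, so study
#' genes appear in them at the background rate.
#'
#' @param seed Integer seed.
#' @param study_genes Character vector of study gene symbols.
#' @param background_size Total background size, default 2000.
#' @param n_terms Number of terms, default 50.
#' @param term_size_range Inclusive range of term sizes, default 20-60.
#' @param planted_term_size Size of the planted term, default 40.
#' @param enrichment_factor Planted fold enrichment of the first term,
#'   default 5 (1 plants nothing).
#' @param out_dir If non-`NULL`, writes `annotation.tsv` and `truth.tsv`.
#' @return List with `annotation` (tibble `gene`, `term`), `background`,
#'   `truth` (list `planted_term`, `enrichment_factor`).
#' @export
simulate_annotation <- function(seed, study_genes, background_size = 2000L,
                                n_terms = 50L, term_size_range = c(20L, 60L),
                                planted_term_size = 40L,
                                enrichment_factor = 5, out_dir = NULL) {
  study_genes <- unique(as.character(study_genes))
  n <- length(study_genes)
  stopifnot(n >= 1L, background_size > n, n_terms >= 1L)
  filler <- setdiff(sprintf("B%05d", seq_len(background_size + n)), study_genes)
  background <- sort(c(study_genes, filler[seq_len(background_size - n)]))
  N <- length(background)
  planted_term <- "T001"

  ann <- withr::with_seed(substream_seed(seed, "annotation"), {
    sizes <- sample(term_size_range[1]:term_size_range[2], n_terms, replace = TRUE)
    sizes[1L] <- planted_term_size
    terms <- sprintf("T%03d", seq_len(n_terms))
    member_rows <- lapply(seq_len(n_terms), function(i) {
      K <- sizes[i]
      if (i == 1L && enrichment_factor > 1) {
        k <- min(n, K, max(1L, round(enrichment_factor * n * K / N)))
        members <- c(sample(study_genes, k),
                     sample(setdiff(background, study_genes), K - k))
      } else {
        members <- sample(background, K)
      }
      tibble::tibble(gene = members, term = terms[i])
    })
    dplyr::bind_rows(member_rows)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(ann, file.path(out_dir, "annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(planted_term = planted_term,
                 enrichment_factor = enrichment_factor),
      file.path(out_dir, "truth.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  list(annotation = ann, background = background,
       truth = list(planted_term = planted_term,
                    enrichment_factor = enrichment_factor))
}
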