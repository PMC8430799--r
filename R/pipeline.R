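#' Assemble a pipeline configuration
#'
#' Collects the inputs and tuning parameters for [run_all()]. Stages whose
#' inputs are `NULL` are skipped with a notice: the network half
#' (interactions) can run without the wet-lab half (Cp data) and vice
#' versa.
#'
#' @param interactions Named list of interaction-table paths, any of
#'   `mirdb`, `mirsvr`, `validated`.
#' @param mirna_panel Optional character vector of panel miRNA labels to
#'   restrict to.
#' @param directions Optional named character vector miRNA -> `"up"`/
#'   `"down"`.
#' @param thresholds A [filter_thresholds()].
#' @param min_hub_degree Hub cutoff, default 3.
#' @param query_fasta,subject_fasta Optional FASTA paths for homology
#'   matching.
#' @param cp_file Optional Cp CSV path.
#' @param housekeeping_assay,reference_group Required with `cp_file`.
#' @param target_assays Assays to quantify; default all non-housekeeping
#'   assays in the table.
#' @param annotation_file Optional gene-to-term TSV path; enrichment runs
#'   on the filtered network's target genes.
#' @param alpha Significance level, default 0.05.
#' @param dunnett_method,dunnett_draws,seed Passed to
#'   [dunnett_many_to_one()].
#' @param out_dir Output directory for the report bundle.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(interactions = NULL, mirna_panel = NULL,
                            directions = NULL,
                            thresholds = filter_thresholds(),
                            min_hub_degree = 3L,
                            query_fasta = NULL, subject_fasta = NULL,
                            cp_file = NULL, housekeeping_assay = NULL,
                            reference_group = NULL, target_assays = NULL,
                            annotation_file = NULL,
                            alpha = 0.05,
                            dunnett_method = "montecarlo",
                            dunnett_draws = 1e5, seed = 1L,
                            out_dir = tempfile("mirhub_run_")) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Returns problems as data, not errors; an empty character vector means
#' the configuration is runnable.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of problem descriptions.
#' @export
validate_config <- function(config) {
  problems <- character()
  chk_path <- function(p, what) {
    if (!is.null(p) && !file.exists(p)) {
      paste0("missing ", what, " file: ", p)
    } else character()
  }
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1) {
    problems <- c(problems, "alpha must lie strictly between 0 and 1")
  }
  if (!inherits(config$thresholds, "filter_thresholds")) {
    problems <- c(problems, "thresholds must come from filter_thresholds()")
  }
  if (!is.null(config$interactions)) {
    bad <- setdiff(names(config$interactions), c("mirdb", "mirsvr", "validated"))
    if (length(bad) > 0L) {
      problems <- c(problems, paste0("unknown interaction dialect(s): ",
                                     paste(bad, collapse = ", ")))
    }
    for (d in names(config$interactions)) {
      problems <- c(problems, chk_path(config$interactions[[d]],
                                       paste0(d, " interaction")))
    }
  }
  problems <- c(problems,
                chk_path(config$query_fasta, "query FASTA"),
                chk_path(config$subject_fasta, "subject FASTA"),
                chk_path(config$cp_file, "Cp table"),
                chk_path(config$annotation_file, "annotation"))
  if (!is.null(config$cp_file) &&
      (is.null(config$housekeeping_assay) || is.null(config$reference_group))) {
    problems <- c(problems,
                  "cp_file requires housekeeping_assay and reference_group")
  }
  if (xor(is.null(config$query_fasta), is.null(config$subject_fasta))) {
    problems <- c(problems, "homology needs both query_fasta and subject_fasta")
  }
  if (!is.null(config$annotation_file) && is.null(config$interactions)) {
    problems <- c(problems,
                  "enrichment needs the interaction stage for its study genes")
  }
  problems
}

#' Run the full analysis pipeline
#'
#' Orchestrates read -> filter -> network -> hub ranking, then the
#' downstream validation stages that have inputs: homology matching,
#' 2^-ddCp quantification with Dunnett testing, and overrepresentation of
#' the network's target genes. Stage-level row counts are logged to
#' stderr; results go to files under `config$out_dir` (`report.json`,
#' `hubs.tsv`, `homology.tsv`, `ddcp.json`, `enrichment.tsv`,
#' `network.graphml`). Re-running with identical inputs and seeds yields a
#' byte-identical `report.json`.
#'
#' @param config A [pipeline_config()]; must validate cleanly.
#' @return The report, an invisible list mirroring `report.json`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  problems <- validate_config(config)
  if (length(problems) > 0L) {
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(schema_version = "1.0")
  log <- function(...) message("[mirhub] ", ...)

  net <- NULL
  if (!is.null(config$interactions)) {
    records <- .pipeline_stage("target_db", {
      recs <- dplyr::bind_rows(lapply(names(config$interactions), function(d) {
        read_interaction_table(config$interactions[[d]], dialect = d)
      }))
      log("read ", nrow(recs), " interaction records")
      if (!is.null(config$mirna_panel)) {
        recs <- restrict_to_mirnas(recs, config$mirna_panel)
        log("panel restriction kept ", nrow(recs), " records")
      }
      out <- filter_interactions(recs, config$thresholds)
      log("thresholds kept ", nrow(out), " of ", nrow(recs), " records")
      out
    })

    ranking <- .pipeline_stage("network", {
      if (nrow(records) == 0L) {
        stop("no interaction records survive filtering", call. = FALSE)
      }
      net <- build_network(records, directions = config$directions)
      log("network: ", length(net$mirna_nodes), " miRNAs, ",
          length(net$gene_nodes), " genes, ", nrow(net$edges), " edges")
      compute_degree_ranking(net)
    })
    hubs <- select_hubs(ranking, config$min_hub_degree)
    report$network <- list(
      n_mirnas = length(net$mirna_nodes),
      n_target_genes = length(net$gene_nodes),
      n_edges = nrow(net$edges),
      max_degree = if (nrow(ranking) > 0L) ranking$degree[1L] else 0L,
      multi_target_count = multi_target_count(ranking, 2L),
      hub_min_degree = config$min_hub_degree,
      hubs = lapply(seq_along(hubs), function(i) {
        list(gene = hubs[i],
             degree = ranking$degree[match(hubs[i], ranking$gene)])
      }),
      top_hub = if (nrow(ranking) > 0L) ranking$gene[1L] else NA_character_
    )
    readr::write_tsv(ranking[ranking$gene %in% hubs, ],
                     file.path(config$out_dir, "hubs.tsv"))
    export_network(net, file.path(config$out_dir, "network.graphml"), "graphml")
  }

  if (!is.null(config$query_fasta)) {
    matches <- .pipeline_stage("homology", {
      q <- read_mirna_fasta(config$query_fasta)
      s <- read_mirna_fasta(config$subject_fasta)
      log("homology: ", nrow(q), " queries vs ", nrow(s), " subjects")
      match_homologues(q, s)
    })
    report$homology <- lapply(seq_len(nrow(matches)), function(i) {
      list(query = matches$query[i], subject = matches$subject[i],
           percent_identity = matches$percent_identity[i],
           seed_identical = matches$seed_identical[i])
    })
    readr::write_tsv(matches[, c("query", "subject", "percent_identity",
                                 "seed_identical")],
                     file.path(config$out_dir, "homology.tsv"))
  }

  if (!is.null(config$cp_file)) {
    ddcp <- .pipeline_stage("expression", {
      tab <- read_cp_table(config$cp_file, config$housekeeping_assay,
                           config$reference_group)
      assays <- config$target_assays
      if (is.null(assays)) {
        assays <- setdiff(unique(tab$assay), config$housekeeping_assay)
      }
      log("expression: ", length(assays), " target assays, ",
          dplyr::n_distinct(tab$sample), " samples")
      lapply(stats::setNames(assays, assays), function(a) {
        fc <- delta_delta_cp(tab, a)
        groups <- split(fc$samples$fold_change, fc$samples$group)
        dn <- dunnett_many_to_one(groups, config$reference_group,
                                  alpha = config$alpha,
                                  method = config$dunnett_method,
                                  draws = config$dunnett_draws,
                                  seed = config$seed)
        list(
          group_folds = lapply(seq_len(nrow(fc$groups)), function(i) {
            as.list(fc$groups[i, c("group", "n", "mean_fold", "sd_fold")])
          }),
          anova_f = dn$anova_f, anova_p = dn$anova_p,
          comparisons = lapply(seq_len(nrow(dn$comparisons)), function(i) {
            as.list(dn$comparisons[i, c("group", "mean_diff", "p_adjusted",
                                        "significant")])
          })
        )
      })
    })
    report$expression <- ddcp
    jsonlite::write_json(ddcp, file.path(config$out_dir, "ddcp.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if (!is.null(config$annotation_file)) {
    enr <- .pipeline_stage("enrichment", {
      ann <- load_annotation(config$annotation_file)
      study <- intersect(net$gene_nodes, ann$background)
      log("enrichment: ", length(study), " study genes against ",
          length(ann$term_to_genes), " terms")
      overrepresentation(study, ann)
    })
    sig <- top_terms(enr, m = 25L, alpha = config$alpha)
    report$enrichment <- list(
      n_terms_tested = nrow(enr),
      significant_terms = lapply(seq_len(nrow(sig)), function(i) {
        as.list(sig[i, c("term", "k", "expected", "fold_enrichment",
                         "bonferroni_p")])
      })
    )
    readr::write_tsv(enr, file.path(config$out_dir, "enrichment.tsv"))
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' @keywords internal
.pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}
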