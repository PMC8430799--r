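#' Build a bipartite miRNA-mRNA interaction network
#'
#' Collapses interaction records into a deduplicated bipartite graph:
#' miRNA labels (reduced to their species-agnostic key) on one side, gene
#' symbols on the other. Duplicate (miRNA, gene) pairs across source
#' databases collapse to a single edge whose evidence set is the union of
#' sources. Isolated nodes do not occur by construction.
#'
#' @param records Tibble of interaction records (already filtered).
#' @param directions Optional named character vector mapping miRNA keys (or
#'   labels) to a regulation direction `"up"` or `"down"`, carried as a node
#'   annotation only.
#' @return An object of class `interaction_network`: a list with `edges`
#'   (tibble `mirna`, `gene`, `evidence`, `n_sources`), `mirna_nodes`,
#'   `gene_nodes` and `directions`.
#' @export
build_network <- function(records, directions = NULL) {
  if (nrow(records) == 0L) {
    edges <- tibble::tibble(mirna = character(), gene = character(),
                            evidence = character(), n_sources = integer())
  } else {
    edges <- records |>
      dplyr::mutate(mirna = species_agnostic_key(.data$mirna)) |>
      dplyr::group_by(.data$mirna, .data$gene) |>
      dplyr::summarise(
        evidence = paste(sort(unique(.data$source)), collapse = ","),
        n_sources = dplyr::n_distinct(.data$source),
        .groups = "drop"
      ) |>
      dplyr::arrange(.data$mirna, .data$gene)
  }
  dir <- character()
  if (!is.null(directions)) {
    stopifnot(!is.null(names(directions)), all(directions %in% c("up", "down")))
    dir <- stats::setNames(unname(directions), species_agnostic_key(names(directions)))
  }
  structure(
    list(edges = edges,
         mirna_nodes = unique(edges$mirna),
         gene_nodes = unique(edges$gene),
         directions = dir),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("bipartite miRNA-mRNA interaction network:",
      length(x$mirna_nodes), "miRNAs,",
      length(x$gene_nodes), "genes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Rank target genes by node degree
#'
#' Node degree of a gene is its number of distinct miRNA partners in the
#' deduplicated network (evidence multiplicity does not count). Genes are
#' ordered by descending degree, ties broken alphabetically by symbol.
#'
#' @param net An `interaction_network`.
#' @return Tibble with columns `gene` and `degree`, one row per gene node.
#' @export
compute_degree_ranking <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  net$edges |>
    dplyr::count(.data$gene, name = "degree") |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$gene)
}

#' Select hub genes at a minimum degree
#'
#' @param ranking Degree ranking from [compute_degree_ranking()].
#' @param min_degree Minimum node degree (>= 1); default 3, the customary
#'   hub cutoff for these networks.
#' @return Character vector of hub gene symbols in ranking order.
#' @export
select_hubs <- function(ranking, min_degree = 3L) {
  stopifnot(min_degree >= 1L)
  ranking$gene[ranking$degree >= min_degree]
}

#' Count multi-targeted genes
#'
#' Number of genes with node degree at or above a cutoff (default 2, i.e.
#' genes targeted by more than one miRNA).
#'
#' @inheritParams select_hubs
#' @return Integer count.
#' @export
multi_target_count <- function(ranking, min_degree = 2L) {
  sum(ranking$degree >= min_degree)
}

#' Extract the network neighborhood of hub genes
#'
#' Returns the subnetwork induced by the hubs and the miRNAs adjacent to
#' them; optionally also every other target of those miRNAs (the second
#' shell).
#'
#' @param net An `interaction_network`.
#' @param hubs Character vector of gene symbols present in the network.
#' @param include_cotargets If `TRUE`, keep all targets of the hub-adjacent
#'   miRNAs, not only the hubs themselves. Default `FALSE`.
#' @return An `interaction_network` whose edges are a subset of `net`'s.
#' @export
extract_neighborhood <- function(net, hubs, include_cotargets = FALSE) {
  stopifnot(inherits(net, "interaction_network"))
  unknown <- setdiff(hubs, net$gene_nodes)
  if (length(unknown) > 0L) {
    stop("unknown hub gene symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  adj_mirnas <- unique(net$edges$mirna[net$edges$gene %in% hubs])
  edges <- if (include_cotargets) {
    net$edges[net$edges$mirna %in% adj_mirnas, ]
  } else {
    net$edges[net$edges$gene %in% hubs, ]
  }
  out <- net
  out$edges <- edges
  out$mirna_nodes <- unique(edges$mirna)
  out$gene_nodes <- unique(edges$gene)
  out$directions <- net$directions[names(net$directions) %in% out$mirna_nodes]
  out
}

#' Convert an interaction network to an igraph object
#'
#' Nodes carry a `type` attribute (`"mirna"`/`"gene"`, plus the logical
#' `is_gene` bipartite marker), a `direction` attribute for miRNAs where
#' known, and their degree.
#'
#' @param net An `interaction_network`.
#' @return An undirected bipartite [igraph::graph].
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("mirna", "gene", "evidence")],
    directed = FALSE,
    vertices = data.frame(
      name = c(net$mirna_nodes, net$gene_nodes),
      type = c(rep("mirna", length(net$mirna_nodes)),
               rep("gene", length(net$gene_nodes))),
      stringsAsFactors = FALSE
    )
  )
  igraph::V(g)$is_gene <- igraph::V(g)$type == "gene"
  dirs <- rep("", igraph::vcount(g))
  hit <- match(names(net$directions), igraph::V(g)$name)
  dirs[hit[!is.na(hit)]] <- net$directions[!is.na(hit)]
  igraph::V(g)$direction <- dirs
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' Export an interaction network to SIF or GraphML
#'
#' SIF lines read `mirna<TAB>targets<TAB>gene` (Cytoscape-compatible);
#' GraphML carries node type, direction and degree attributes. Both formats
#' round-trip the edge set exactly through [import_network()].
#'
#' @param net An `interaction_network`.
#' @param path Output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml")) {
  stopifnot(inherits(net, "interaction_network"))
  format <- match.arg(format)
  if (format == "sif") {
    writeLines(paste(net$edges$mirna, "targets", net$edges$gene, sep = "\t"), path)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Re-import a network exported with [export_network()]
#'
#' @param path File path.
#' @param format `"sif"` or `"graphml"`.
#' @return An `interaction_network` (evidence provenance is not recoverable
#'   from SIF and is marked `"imported"`).
#' @export
import_network <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    edges <- tibble::tibble(
      mirna = vapply(parts, `[[`, "", 1L),
      gene = vapply(parts, `[[`, "", 3L),
      evidence = "imported",
      n_sources = NA_integer_
    ) |> dplyr::arrange(.data$mirna, .data$gene)
    dir <- character()
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    vt <- igraph::as_data_frame(g, what = "vertices")
    is_gene_from <- vt$type[match(el$from, vt$name)] == "gene"
    edges <- tibble::tibble(
      mirna = ifelse(is_gene_from, el$to, el$from),
      gene = ifelse(is_gene_from, el$from, el$to),
      evidence = if ("evidence" %in% names(el)) el$evidence else "imported",
      n_sources = NA_integer_
    ) |> dplyr::arrange(.data$mirna, .data$gene)
    known <- vt$type == "mirna" & !is.na(vt$direction) & nzchar(vt$direction)
    dir <- stats::setNames(vt$direction[known], vt$name[known])
  }
  structure(
    list(edges = edges,
         mirna_nodes = unique(edges$mirna),
         gene_nodes = unique(edges$gene),
         directions = dir),
    class = "interaction_network"
  )
}
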