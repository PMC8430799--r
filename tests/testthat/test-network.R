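rictor_records <- function() {
  interaction_records(
    c("miR-139-5p", "miR-320", "miR-212", "miR-503", "miR-188-5p"),
    rep("Rictor", 5), "predicted_scoreA", rep(90, 5))
}

test_that("duplicate pairs across databases collapse into one edge with merged evidence", {
  rec <- dplyr::bind_rows(
    interaction_records("rno-miR-1", "Rictor", "predicted_scoreA", 90),
    interaction_records("rno-miR-1", "Rictor", "validated"),
    interaction_records("rno-miR-2", "Rictor", "predicted_scoreB", -2)
  )
  net <- build_network(rec)
  expect_equal(nrow(net$edges), 2L)
  e <- net$edges[net$edges$mirna == "miR-1", ]
  expect_equal(e$evidence, "predicted_scoreA,validated")
  expect_equal(e$n_sources, 2L)
})

test_that("an empty record set yields an empty network and ranking", {
  net <- build_network(rictor_records()[0, ])
  expect_equal(nrow(net$edges), 0L)
  expect_equal(nrow(compute_degree_ranking(net)), 0L)
})

test_that("a gene targeted by five miRNAs ranks first with degree five", {
  net <- build_network(rictor_records())
  ranking <- compute_degree_ranking(net)
  expect_equal(ranking$gene[1], "Rictor")
  expect_equal(ranking$degree[1], 5L)
})

test_that("degree ranking equals brute-force distinct-partner counts on random networks", {
  set.seed(99)
  for (i in 1:5) {
    rec <- interaction_records(
      sprintf("rno-miR-%d", sample(1:12, 60, TRUE)),
      sprintf("G%d", sample(1:15, 60, TRUE)),
      sample(c("predicted_scoreA", "validated"), 60, TRUE))
    ranking <- compute_degree_ranking(build_network(rec))
    oracle <- brute_degrees(rec)
    expect_equal(stats::setNames(ranking$degree, ranking$gene)[names(oracle)],
                 oracle)
    expect_equal(sum(ranking$degree), nrow(build_network(rec)$edges))
  }
})

test_that("ranking orders by descending degree with alphabetical ties", {
  rec <- interaction_records(
    c("m1", "m2", "m3", "m1", "m2", "m1"),
    c("Zeb1", "Zeb1", "Zeb1", "Abl1", "Abl1", "Mid1"),
    "validated")
  ranking <- compute_degree_ranking(build_network(rec))
  expect_equal(ranking$gene, c("Zeb1", "Abl1", "Mid1"))
  rec2 <- interaction_records(c("m1", "m1"), c("Bb", "Aa"), "validated")
  expect_equal(compute_degree_ranking(build_network(rec2))$gene, c("Aa", "Bb"))
})

test_that("hub selection partitions the gene set at the cutoff", {
  ranking <- tibble::tibble(gene = c("A", "B", "C", "D"),
                            degree = c(5L, 3L, 2L, 1L))
  expect_equal(select_hubs(ranking, 3), c("A", "B"))
  expect_equal(select_hubs(ranking, 1), ranking$gene)
  expect_equal(multi_target_count(ranking, 2), 3L)
  expect_equal(multi_target_count(ranking, 1), 4L)
  expect_setequal(c(select_hubs(ranking, 3),
                    ranking$gene[ranking$degree < 3]), ranking$gene)
})

test_that("planted hubs are recovered as the top-ranked gene", {
  for (seed in 1:5) {
    sim <- simulate_interaction_tables(seed, hub_degree = 5)
    ranking <- compute_degree_ranking(
      build_network(filter_interactions(as_interaction_records(sim$tables))))
    expect_equal(ranking$gene[1], sim$hub$gene)
    expect_equal(ranking$degree[1], 5L)
  }
})

test_that("hub neighborhoods are induced subnetworks, monotone in the hub set", {
  rec <- dplyr::bind_rows(
    rictor_records(),
    interaction_records("miR-139-5p", "Other1", "validated"),
    interaction_records("miR-999", "Lonely", "validated")
  )
  net <- build_network(rec)
  nb <- extract_neighborhood(net, "Rictor")
  expect_equal(nb$gene_nodes, "Rictor")
  expect_equal(length(nb$mirna_nodes), 5L)
  expect_true(all(paste(nb$edges$mirna, nb$edges$gene) %in%
                    paste(net$edges$mirna, net$edges$gene)))
  # second shell pulls in co-targets of the hub-adjacent miRNAs
  nb2 <- extract_neighborhood(net, "Rictor", include_cotargets = TRUE)
  expect_setequal(nb2$gene_nodes, c("Rictor", "Other1"))
  # monotone and identity at the extremes
  expect_equal(nrow(extract_neighborhood(net, net$gene_nodes)$edges),
               nrow(net$edges))
  expect_equal(nrow(extract_neighborhood(net, character(0))$edges), 0L)
  expect_error(extract_neighborhood(net, "Nothere"), "Nothere")
})

test_that("SIF and GraphML exports round-trip the edge set", {
  net <- build_network(
    dplyr::bind_rows(rictor_records(),
                     interaction_records("miR-139-5p", "Other1", "validated")),
    directions = c("miR-139-5p" = "up", "miR-320" = "down"))
  for (fmt in c("sif", "graphml")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_network(net, path, fmt)
    back <- import_network(path, fmt)
    expect_equal(back$edges[, c("mirna", "gene")],
                 net$edges[, c("mirna", "gene")])
  }
  # one edge -> one SIF line
  p <- withr::local_tempfile(fileext = ".sif")
  export_network(build_network(rictor_records()[1, ]), p, "sif")
  expect_length(readLines(p), 1L)
  # graphml carries direction annotations
  p2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, p2, "graphml")
  back <- import_network(p2, "graphml")
  expect_equal(back$directions[["miR-139-5p"]], "up")
  expect_equal(back$directions[["miR-320"]], "down")
})
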