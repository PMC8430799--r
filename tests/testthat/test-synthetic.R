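test_that("generators are deterministic given the seed and leave the RNG alone", {
  set.seed(123)
  before <- .Random.seed
  a <- simulate_interaction_tables(5)
  expect_identical(.Random.seed, before)
  b <- simulate_interaction_tables(5)
  expect_identical(a, b)
  expect_false(identical(a$truth, simulate_interaction_tables(6)$truth))
  expect_identical(simulate_mirna_fasta_pair(5), simulate_mirna_fasta_pair(5))
  expect_identical(simulate_cp_table(5), simulate_cp_table(5))
  s <- sprintf("S%d", 1:50)
  expect_identical(simulate_annotation(5, s), simulate_annotation(5, s))
})

test_that("interaction generator plants the hub at the requested degree", {
  sim <- simulate_interaction_tables(2, hub_degree = 7, background_edge_prob = 0.05)
  truth_deg <- table(sim$truth$gene)
  expect_equal(unname(truth_deg[[sim$hub$gene]]), 7L)
  # no background gene reaches the hub degree
  expect_true(all(truth_deg[names(truth_deg) != sim$hub$gene] < 7))
  # files round-trip through the reader dialects
  d <- withr::local_tempdir()
  simulate_interaction_tables(2, hub_degree = 7, background_edge_prob = 0.05,
                              out_dir = d)
  rec <- dplyr::bind_rows(
    read_interaction_table(file.path(d, "mirdb.tsv"), "mirdb"),
    read_interaction_table(file.path(d, "mirsvr.tsv"), "mirsvr"),
    read_interaction_table(file.path(d, "validated.tsv"), "validated"))
  surv <- filter_interactions(rec)
  expect_setequal(paste(surv$mirna, surv$gene),
                  paste(sim$truth$mirna, sim$truth$gene))
  expect_error(simulate_interaction_tables(1, n_mirnas = 4, hub_degree = 5),
               "exceeds")
})

test_that("sub-threshold records are generated and removed by filtering", {
  sim <- simulate_interaction_tables(3, background_edge_prob = 0.1,
                                     below_threshold_fraction = 0.5)
  rec <- as_interaction_records(sim$tables)
  surv <- filter_interactions(rec)
  expect_lt(nrow(surv), nrow(rec))
  expect_equal(sort(unique(paste(surv$mirna, surv$gene))),
               sort(unique(paste(sim$truth$mirna, sim$truth$gene))))
})

test_that("the degree-profile generator realizes its profile exactly after filtering", {
  prof <- c(`4` = 2L, `2` = 3L, `1` = 10L)
  sim <- simulate_profile_interactions(11, degree_profile = prof, noise_rows = 50)
  ranking <- compute_degree_ranking(
    build_network(filter_interactions(as_interaction_records(sim$tables))))
  expect_equal(nrow(ranking), 15L)
  expect_equal(as.vector(table(factor(ranking$degree, levels = c(1, 2, 4)))),
               c(10L, 3L, 2L))
  got <- stats::setNames(ranking$degree, ranking$gene)[sim$truth$gene]
  expect_equal(unname(got), sim$truth$degree)
})

test_that("FASTA pair generator plants identity structure the homology module reproduces", {
  sim <- simulate_mirna_fasta_pair(9, n_identical = 4, n_seed_only = 1)
  m <- match_homologues(sim$queries, sim$subjects)
  hit <- match(sim$truth$query, m$query)
  expect_equal(m$percent_identity[hit], sim$truth$identity)
  expect_equal(m$percent_identity[hit][1:4], rep(100, 4))
  expect_lt(m$percent_identity[hit][5], 100)
  expect_true(m$seed_identical[hit][5])
  # zero-divergence spec: everything matches at 100%
  sim0 <- simulate_mirna_fasta_pair(9, n_identical = 3, n_seed_only = 0)
  m0 <- match_homologues(sim0$queries, sim0$subjects)
  expect_equal(m0$percent_identity, rep(100, 3))
})

test_that("noiseless Cp tables recover planted folds exactly", {
  sim <- simulate_cp_table(
    4, cp_noise_sd = 0,
    effects = tibble::tibble(group = "IPostC", assay = "ssc-miR-320",
                             log2_fold = 1))
  fc <- delta_delta_cp(sim$cp, "ssc-miR-320")
  gm <- fc$groups
  expect_equal(gm$mean_fold[gm$group == "IPostC"], 2)
  expect_equal(gm$mean_fold[gm$group == "Isch"], 1)
  expect_equal(gm$mean_fold[gm$group == "IPreC"], 1)
  expect_equal(gm$n, c(6L, 4L, 6L)[match(gm$group, c("Isch", "IPreC", "IPostC"))])
})

test_that("planted effects in the reference group are rejected", {
  expect_error(
    simulate_cp_table(1, effects = tibble::tibble(
      group = "Isch", assay = "ssc-miR-320", log2_fold = 1)),
    "reference")
})

test_that("annotation generator writes a loadable map with the planted term", {
  study <- sprintf("S%03d", 1:80)
  d <- withr::local_tempdir()
  sim <- simulate_annotation(13, study, background_size = 1000, out_dir = d)
  ann <- load_annotation(file.path(d, "annotation.tsv"))
  expect_true(sim$truth$planted_term %in% names(ann$term_to_genes))
  expect_true(all(lengths(ann$term_to_genes) >= 20))
  # factor 1 plants nothing: no significant term in most seeds
  nulls <- vapply(1:20, function(seed) {
    s <- simulate_annotation(seed, study, background_size = 1000,
                             enrichment_factor = 1)
    a <- annotation_map(s$annotation, background = s$background)
    res <- overrepresentation(study, a)
    !any(res$bonferroni_p < 0.05)
  }, logical(1))
  expect_gte(sum(nulls), 18L)
})
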