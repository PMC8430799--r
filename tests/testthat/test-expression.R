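toy_cp <- function() {
  # two groups, hand-checkable Cp values; reference mean dCp = 5
  cp_table(data.frame(
    sample = rep(c("c1", "c2", "t1", "t2"), each = 2),
    group = rep(c("Ctl", "Ctl", "Trt", "Trt"), each = 2),
    assay = rep(c("U6", "miR-x"), 4),
    cp = c(20, 25,   # c1: dCp 5
           20, 25,   # c2: dCp 5
           20, 24,   # t1: dCp 4 -> ddCp -1 -> fold 2
           20, 26)   # t2: dCp 6 -> ddCp 1 -> fold 0.5
  ), housekeeping_assay = "U6", reference_group = "Ctl")
}

test_that("fold changes are exactly 2^-ddCp against the reference mean", {
  fc <- delta_delta_cp(toy_cp(), "miR-x")
  expect_equal(fc$samples$delta_cp, c(5, 5, 4, 6))
  expect_equal(fc$samples$fold_change, c(1, 1, 2, 0.5))
  expect_equal(fc$samples$fold_change, 2^(-fc$samples$delta_delta_cp))
  expect_equal(log2(fc$samples$fold_change), -fc$samples$delta_delta_cp)
  # reference-group fold computed from its own mean dCp is 1
  ref <- fc$groups[fc$groups$group == "Ctl", ]
  expect_equal(ref$mean_fold, 1)
})

test_that("cp_table validates housekeeping coverage, duplicates and reference", {
  d <- data.frame(sample = c("s1", "s1", "s2"), group = "G",
                  assay = c("U6", "miR-x", "miR-x"), cp = c(20, 25, 24))
  expect_error(cp_table(d, "U6", "G"), "s2")
  d2 <- data.frame(sample = c("s1", "s1"), group = "G",
                   assay = c("U6", "U6"), cp = c(20, 21))
  expect_error(cp_table(d2, "U6", "G"), "duplicated")
  d3 <- data.frame(sample = "s1", group = "G", assay = "U6", cp = 20)
  expect_error(cp_table(d3, "U6", "Missing"), "reference group")
})

test_that("unknown assays error and assay-missing samples drop with a warning", {
  tab <- toy_cp()
  expect_error(delta_delta_cp(tab, "nope"), "unknown target assay")
  expect_error(delta_delta_cp(tab, "U6"), "housekeeping")
  tab2 <- cp_table(rbind(as.data.frame(tab),
                         data.frame(sample = "t3", group = "Trt",
                                    assay = "U6", cp = 20)),
                   "U6", "Ctl")
  expect_warning(fc <- delta_delta_cp(tab2, "miR-x"), "t3")
  expect_equal(nrow(fc$samples), 4L)
})

test_that("CSV round trip feeds the same quantification", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(toy_cp()), path, row.names = FALSE)
  fc <- delta_delta_cp(read_cp_table(path, "U6", "Ctl"), "miR-x")
  expect_equal(fc$samples$fold_change, c(1, 1, 2, 0.5))
})

test_that("one-way ANOVA matches hand-computed and brute-force sums of squares", {
  res <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(res$f, 1.5)
  expect_equal(c(res$df1, res$df2), c(1, 4))
  set.seed(13)
  for (i in 1:5) {
    groups <- lapply(sample(2:4, sample(2:4, 1), TRUE), rnorm)
    expect_equal(one_way_anova(groups)$f, brute_anova_f(groups))
  }
  # identical groups: F = 0
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$f, 0)
  # two groups: F equals the square of the pooled t statistic
  g <- list(rnorm(5), rnorm(6, 1))
  tt <- stats::t.test(g[[1]], g[[2]], var.equal = TRUE)
  expect_equal(one_way_anova(g)$f, unname(tt$statistic^2))
  expect_error(one_way_anova(list(1, c(1, 2))), "at least two observations")
})

test_that("a single Dunnett comparison reduces to the pooled two-sided t-test", {
  set.seed(19)
  g <- list(Ctl = rnorm(6), Trt = rnorm(6, 1))
  rep <- dunnett_many_to_one(g, "Ctl")
  tt <- stats::t.test(g$Trt, g$Ctl, var.equal = TRUE)
  expect_equal(rep$comparisons$p_adjusted, tt$p.value, tolerance = 1e-6)
  expect_equal(rep$comparisons$p_unadjusted, rep$comparisons$p_adjusted)
})

test_that("Dunnett adjustment is never anti-conservative and bounded by Bonferroni", {
  set.seed(29)
  g <- list(Ctl = rnorm(6), A = rnorm(6, 0.5), B = rnorm(4, 1.5), C = rnorm(5))
  for (method in c("montecarlo", "mvt")) {
    rep <- dunnett_many_to_one(g, "Ctl", method = method, draws = 2e4)
    expect_true(all(rep$comparisons$p_adjusted >= rep$comparisons$p_unadjusted))
    expect_true(all(rep$comparisons$p_adjusted >= 0 &
                      rep$comparisons$p_adjusted <= 1))
    # familywise p never exceeds the Bonferroni bound (up to MC noise)
    expect_true(all(rep$comparisons$p_adjusted <=
                      pmin(1, 3 * rep$comparisons$p_unadjusted) + 0.01))
  }
})

test_that("Dunnett adjusted p agrees with an independent implementation", {
  skip_if_not_installed("multcomp")
  set.seed(37)
  y <- c(rnorm(6), rnorm(5, 1), rnorm(4, 2))
  g <- factor(rep(c("Ctl", "A", "B"), c(6, 5, 4)), levels = c("Ctl", "A", "B"))
  rep <- dunnett_many_to_one(split(y, g)[levels(g)], "Ctl", method = "mvt")
  fit <- stats::aov(y ~ g)
  ref <- summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")),
                 test = multcomp::adjusted("single-step"))
  expect_equal(rep$comparisons$p_adjusted,
               unname(as.numeric(ref$test$pvalues)), tolerance = 5e-3)
})

test_that("group relabeling permutes but does not change the statistics", {
  set.seed(41)
  g <- list(Ctl = rnorm(6), A = rnorm(6, 1), B = rnorm(5, -1))
  r1 <- dunnett_many_to_one(g, "Ctl", method = "mvt")
  r2 <- dunnett_many_to_one(g[c("Ctl", "B", "A")], "Ctl", method = "mvt")
  m1 <- r1$comparisons[order(r1$comparisons$group), ]
  m2 <- r2$comparisons[order(r2$comparisons$group), ]
  expect_equal(m1, m2)
})

test_that("planted log2 fold changes are recovered with shrinking bias as n grows", {
  bias <- vapply(c(4L, 6L, 24L), function(n) {
    errs <- vapply(1:20, function(i) {
      sim <- simulate_cp_table(
        1000 + 37L * i + n,
        group_sizes = c(Isch = n, IPostC = n),
        assays = "ssc-miR-212",
        effects = tibble::tibble(group = "IPostC", assay = "ssc-miR-212",
                                 log2_fold = 1))
      fc <- delta_delta_cp(sim$cp, "ssc-miR-212")
      gm <- fc$groups
      log2(gm$geo_mean_fold[gm$group == "IPostC"]) - 1
    }, numeric(1))
    abs(mean(errs))
  }, numeric(1))
  expect_lt(bias[3], bias[1] + 0.05)
  expect_lt(bias[3], 0.1)
})
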