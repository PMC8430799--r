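#' Construct a validated qPCR crossing-point table
#'
#' Long-format table of Cp (crossing point / Ct) values over samples,
#' groups and assays, with a declared housekeeping assay and reference
#' group. Validates that every (sample, assay) pair is unique, that every
#' sample carries a housekeeping measurement, and that the reference group
#' is present.
#'
#' @param data Data frame with columns `sample`, `group`, `assay`, `cp`.
#' @param housekeeping_assay Name of the housekeeping (normalizer) assay,
#'   e.g. `"U6"` for miRNA panels or `"Actb"` for mRNA assays.
#' @param reference_group Name of the reference (control) group whose mean
#'   delta-Cp anchors the fold changes.
#' @return A tibble of class `cp_table` with attributes
#'   `housekeeping_assay` and `reference_group`.
#' @export
cp_table <- function(data, housekeeping_assay, reference_group) {
  stopifnot(all(c("sample", "group", "assay", "cp") %in% names(data)))
  data <- tibble::as_tibble(data[, c("sample", "group", "assay", "cp")])
  data$cp <- as.numeric(data$cp)
  dup <- duplicated(data[, c("sample", "assay")])
  if (any(dup)) {
    stop("duplicated (sample, assay) measurement(s): ",
         paste(utils::head(paste(data$sample[dup], data$assay[dup], sep = "/"), 3),
               collapse = ", "), call. = FALSE)
  }
  hk_samples <- unique(data$sample[data$assay == housekeeping_assay])
  no_hk <- setdiff(unique(data$sample), hk_samples)
  if (length(no_hk) > 0L) {
    stop("sample(s) without a housekeeping (", housekeeping_assay,
         ") measurement: ", paste(utils::head(no_hk, 5), collapse = ", "),
         call. = FALSE)
  }
  if (!reference_group %in% data$group) {
    stop("reference group '", reference_group, "' not present", call. = FALSE)
  }
  structure(data,
            housekeeping_assay = housekeeping_assay,
            reference_group = reference_group,
            class = c("cp_table", class(data)))
}

#' Read a Cp table from CSV
#'
#' @param path CSV file with columns `sample`, `group`, `assay`, `cp`.
#' @inheritParams cp_table
#' @return A `cp_table`.
#' @export
read_cp_table <- function(path, housekeeping_assay, reference_group) {
  cp_table(readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(cp = readr::col_double(),
                                                   .default = readr::col_character())),
           housekeeping_assay, reference_group)
}

#' Relative quantification by the 2^-ddCp method
#'
#' Per sample, delta-Cp is the target Cp minus the housekeeping Cp;
#' delta-delta-Cp subtracts the reference group's mean delta-Cp; the fold
#' change is `2^-ddCp`. By construction the fold change computed from the
#' reference group's own mean delta-Cp equals 1.
#'
#' Samples lacking the target assay are dropped with a warning (unequal
#' group sizes are common when tissue availability varies).
#'
#' @param table A [cp_table()].
#' @param target_assay Assay to quantify (must not be the housekeeping
#'   assay).
#' @return A list of class `fold_change_result` with `samples` (per-sample
#'   tibble: `sample`, `group`, `delta_cp`, `delta_delta_cp`,
#'   `fold_change`) and `groups` (per-group `n`, `mean_fold`, `sd_fold`,
#'   `geo_mean_fold`), plus `target_assay` and `reference_group`.
#' @export
delta_delta_cp <- function(table, target_assay) {
  stopifnot(inherits(table, "cp_table"))
  hk <- attr(table, "housekeeping_assay")
  ref <- attr(table, "reference_group")
  if (!target_assay %in% table$assay) {
    stop("unknown target assay '", target_assay, "'", call. = FALSE)
  }
  if (identical(target_assay, hk)) {
    stop("target assay equals the housekeeping assay", call. = FALSE)
  }

  hk_cp <- table[table$assay == hk, c("sample", "group", "cp")]
  names(hk_cp)[3] <- "cp_housekeeping"
  tg_cp <- table[table$assay == target_assay, c("sample", "cp")]
  names(tg_cp)[2] <- "cp_target"

  missing <- setdiff(hk_cp$sample, tg_cp$sample)
  if (length(missing) > 0L) {
    warning("dropping sample(s) without assay '", target_assay, "': ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  per <- dplyr::inner_join(hk_cp, tg_cp, by = "sample")
  per$delta_cp <- per$cp_target - per$cp_housekeeping
  ref_mean_dcp <- mean(per$delta_cp[per$group == ref])
  if (is.nan(ref_mean_dcp)) {
    stop("no sample of reference group '", ref, "' carries assay '",
         target_assay, "'", call. = FALSE)
  }
  per$delta_delta_cp <- per$delta_cp - ref_mean_dcp
  per$fold_change <- 2^(-per$delta_delta_cp)

  groups <- per |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_fold = mean(.data$fold_change),
                     sd_fold = stats::sd(.data$fold_change),
                     geo_mean_fold = exp(mean(log(.data$fold_change))),
                     .groups = "drop")

  structure(
    list(samples = tibble::as_tibble(per[, c("sample", "group", "delta_cp",
                                             "delta_delta_cp", "fold_change")]),
         groups = groups,
         target_assay = target_assay,
         reference_group = ref),
    class = "fold_change_result"
  )
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat("2^-ddCp quantification of", x$target_assay, "relative to",
      x$reference_group, "\n")
  print(x$groups)
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition over `k` groups; the F statistic
#' is referred to an F distribution on `(k - 1, N - k)` degrees of freedom.
#' Fitting is delegated to [stats::lm()]/[stats::anova()].
#'
#' @param groups A list of numeric vectors, each of length >= 2, or a named
#'   list.
#' @return List with `f`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, as.numeric)
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(lengths(groups) < 2L)) {
    stop("every group needs at least two observations", call. = FALSE)
  }
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(seq_along(groups), lengths(groups)))
  )
  a <- stats::anova(stats::lm(y ~ g, data = df))
  list(f = unname(a$`F value`[1]), df1 = a$Df[1], df2 = a$Df[2],
       p = unname(a$`Pr(>F)`[1]))
}

#' Dunnett many-to-one comparisons against a reference group
#'
#' Each treatment group is compared with the single reference group using
#' t statistics on the pooled within-group variance (the one-way ANOVA
#' error term, `N - k` degrees of freedom). Familywise adjustment follows
#' the many-to-one multivariate-t distribution with the Dunnett correlation
#' structure, evaluated either with [mvtnorm::pmvt()] (`method = "mvt"`) or
#' by seeded Monte Carlo sampling of the null maximum-|t| distribution
#' (`method = "montecarlo"`, the default, with `draws` draws). With a
#' single comparison group the adjusted p equals the unadjusted pooled
#' two-sided t-test p exactly.
#'
#' @param groups Named list of numeric vectors, one per group.
#' @param reference Name of the reference group (must be in `groups`).
#' @param alpha Familywise significance level, default 0.05.
#' @param method `"montecarlo"` (default) or `"mvt"`.
#' @param draws Monte Carlo sample size, default `1e5`.
#' @param seed Seed for the Monte Carlo draws (and for `pmvt`'s
#'   quasi-random integration), default 1; the local RNG state is restored
#'   afterwards.
#' @return A list of class `dunnett_report`: `comparisons` (tibble `group`,
#'   `mean_diff`, `t`, `p_unadjusted`, `p_adjusted`, `significant`),
#'   `anova_f`, `anova_p`, `df`, `alpha`.
#' @export
dunnett_many_to_one <- function(groups, reference, alpha = 0.05,
                                method = c("montecarlo", "mvt"),
                                draws = 1e5, seed = 1L) {
  method <- match.arg(method)
  stopifnot(is.list(groups), !is.null(names(groups)), alpha > 0, alpha < 1)
  if (!reference %in% names(groups)) {
    stop("reference group '", reference, "' not among the groups", call. = FALSE)
  }
  groups <- lapply(groups, as.numeric)
  if (any(lengths(groups) < 2L)) {
    stop("every group needs at least two observations", call. = FALSE)
  }

  aov_res <- one_way_anova(groups)
  cmp_names <- setdiff(names(groups), reference)
  if (length(cmp_names) == 0L) stop("need at least one comparison group", call. = FALSE)

  n <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  k <- length(groups)
  nn <- sum(n)
  df <- nn - k
  s2 <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1))) / df

  n0 <- n[[reference]]
  ni <- n[cmp_names]
  mean_diff <- means[cmp_names] - means[[reference]]
  se <- sqrt(s2 * (1 / ni + 1 / n0))
  tstat <- mean_diff / se
  p_unadj <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)

  m <- length(cmp_names)
  if (m == 1L) {
    p_adj <- p_unadj
  } else {
    lambda <- sqrt(ni / (ni + n0))
    corr <- tcrossprod(lambda)
    diag(corr) <- 1
    p_adj <- if (method == "mvt") {
      vapply(abs(tstat), function(tt) {
        pr <- withr::with_seed(seed, mvtnorm::pmvt(
          lower = rep(-tt, m), upper = rep(tt, m), df = df, corr = corr,
          algorithm = mvtnorm::GenzBretz(abseps = 1e-5)
        ))
        max(0, 1 - as.numeric(pr))
      }, numeric(1))
    } else {
      max_t <- withr::with_seed(seed, {
        z <- mvtnorm::rmvnorm(draws, sigma = corr)
        w <- sqrt(stats::rchisq(draws, df) / df)
        apply(abs(z / w), 1L, max)
      })
      vapply(abs(tstat), function(tt) mean(max_t >= tt), numeric(1))
    }
    p_adj <- pmin(1, pmax(p_adj, p_unadj))
  }

  structure(
    list(
      comparisons = tibble::tibble(
        group = cmp_names,
        mean_diff = unname(mean_diff),
        t = unname(tstat),
        p_unadjusted = unname(p_unadj),
        p_adjusted = unname(p_adj),
        significant = unname(p_adj < alpha)
      ),
      anova_f = aov_res$f,
      anova_p = aov_res$p,
      df = df,
      alpha = alpha
    ),
    class = "dunnett_report"
  )
}

#' @export
print.dunnett_report <- function(x, ...) {
  cat(sprintf("one-way ANOVA F = %.3f (p = %.4g); Dunnett many-to-one, alpha = %g\n",
              x$anova_f, x$anova_p, x$alpha))
  print(x$comparisons)
  invisible(x)
}
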