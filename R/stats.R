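# Cohort-level statistics: normality-gated group tests with Bonferroni
# correction over the 19 sided comparisons, age-controlled partial
# correlations on the side-averaged markers, and control-based abnormality
# cutoffs with affected-area counting over the 8 facial regions.

#' Kolmogorov-Smirnov normality check
#'
#' Standardizes by the sample mean and SD and runs a one-sample KS test
#' against the standard normal; the sample is called normal when p >= alpha.
#' With estimated parameters the plain KS test is anti-conservative; set
#' `lilliefors = TRUE` for the Lilliefors-corrected variant.
#'
#' @param values numeric vector, n >= 4.
#' @param alpha significance level for the normality decision.
#' @param lilliefors use the Lilliefors correction
#'   ([nortest::lillie.test()]).
#' @return `TRUE` if consistent with normality; zero-variance input returns
#'   `FALSE` by convention.
#' @export
normality_check <- function(values, alpha = 0.05, lilliefors = FALSE) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) stop("need at least 4 values")
  s <- sd(values)
  if (s == 0) return(FALSE)
  p <- if (lilliefors) nortest::lillie.test(values)$p.value
       else suppressWarnings(
         ks.test((values - mean(values)) / s, "pnorm")$p.value)
  p >= alpha
}

#' Two-group difference test with normality gating
#'
#' One-way ANOVA when both groups pass [normality_check()], otherwise the
#' Kruskal-Wallis test (robust to outliers). A zero-variance group under
#' ANOVA falls back to Kruskal-Wallis.
#'
#' @param values numeric marker values.
#' @param labels factor/character with two levels (`HC`, `PD`).
#' @param adjusted_alpha significance threshold used for the
#'   `significant_after_bonferroni` flag (see [bonferroni_alpha()]).
#' @param lilliefors passed to [normality_check()].
#' @return list: `test` (`"ANOVA"` or `"Kruskal-Wallis"`), `statistic`,
#'   `p_value`, `significant_after_bonferroni`.
#' @export
group_difference <- function(values, labels, adjusted_alpha = 0.05 / 19,
                             lilliefors = FALSE) {
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- factor(labels[keep])
  if (nlevels(labels) != 2L || min(table(labels)) < 2L)
    stop("need two groups with at least 2 observations each")
  normal <- vapply(split(values, labels),
                   function(v) length(v) >= 4L && sd(v) > 0 &&
                     normality_check(v, lilliefors = lilliefors),
                   logical(1))
  if (all(normal)) {
    ft <- oneway.test(values ~ labels, var.equal = TRUE)
    res <- list(test = "ANOVA", statistic = unname(ft$statistic),
                p_value = ft$p.value)
  } else {
    kt <- kruskal.test(values, labels)
    res <- list(test = "Kruskal-Wallis", statistic = unname(kt$statistic),
                p_value = kt$p.value)
  }
  res$significant_after_bonferroni <- res$p_value < adjusted_alpha
  res
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level (in (0,1)).
#' @param m number of comparisons (>= 1).
#' @return `alpha / m`; with the full 19-comparison marker catalogue this is
#'   0.05/19 = 0.0026 (4 dp).
#' @export
bonferroni_alpha <- function(alpha = 0.05, m) {
  if (m < 1L) stop("m must be >= 1")
  stopifnot(alpha > 0, alpha < 1)
  alpha / m
}

#' Number of group comparisons implied by a marker catalogue
#'
#' One comparison per midline marker and two (left + right) per bilateral
#' marker: the full catalogue of twelve markers, seven of them bilateral,
#' yields 19.
#'
#' @param catalogue a [marker_catalogue()]-shaped `data.frame` (columns
#'   `marker`, `bilateral`).
#' @return integer comparison count.
#' @export
comparison_count <- function(catalogue = marker_catalogue()) {
  if (!nrow(catalogue)) return(0L)
  sum(ifelse(catalogue$bilateral, 2L, 1L))
}

#' Run the 19 sided group-difference tests
#'
#' @param markers marker table from [marker_table()].
#' @param cohort cohort table with `subject_id` and `group`.
#' @param alpha family-wise significance level.
#' @param lilliefors passed to [normality_check()].
#' @return `data.frame`: one row per sided marker with test, statistic,
#'   p-value and Bonferroni flag (at `alpha /` [comparison_count()]).
#' @export
group_difference_table <- function(markers, cohort, alpha = 0.05,
                                   lilliefors = FALSE) {
  df <- merge(markers, cohort[, c("subject_id", "group")], by = "subject_id")
  adj <- bonferroni_alpha(alpha, comparison_count())
  rows <- lapply(sided_marker_names(), function(m) {
    ok <- is.finite(df[[m]])
    if (sum(ok) < 4L || min(table(df$group[ok])) < 2L)
      return(data.frame(marker = m, test = NA, statistic = NA, p_value = NA,
                        significant_after_bonferroni = NA))
    r <- group_difference(df[[m]][ok], df$group[ok], adjusted_alpha = adj,
                          lilliefors = lilliefors)
    data.frame(marker = m, test = r$test, statistic = r$statistic,
               p_value = r$p_value,
               significant_after_bonferroni = r$significant_after_bonferroni)
  })
  out <- do.call(rbind, rows)
  attr(out, "adjusted_alpha") <- adj
  out
}

#' Pearson partial correlation controlled for age
#'
#' Residualizes `x` and `y` on age by ordinary least squares (with intercept)
#' and correlates the residuals; p-value from
#' `t = r * sqrt((n - 3) / (1 - r^2))` on `n - 3` df, two-sided. Constant age
#' reduces to the plain Pearson correlation with `n - 2` df.
#'
#' @param x,y numeric vectors (complete cases used; n >= 4).
#' @param age numeric covariate.
#' @return list: `r`, `p_value`, `n`.
#' @export
partial_correlation_age <- function(x, y, age) {
  keep <- complete.cases(x, y, age)
  x <- x[keep]; y <- y[keep]; age <- age[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete cases")
  if (sd(age) == 0) {
    r <- cor(x, y); df <- n - 2L
  } else {
    r <- cor(resid(lm(x ~ age)), resid(lm(y ~ age))); df <- n - 3L
  }
  r <- min(max(r, -1), 1)
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(r * sqrt(df / (1 - r^2))), df)
  list(r = r, p_value = p, n = n)
}

#' Age-controlled correlations of averaged markers with covariates
#'
#' @param markers marker table.
#' @param cohort cohort table (needs `age` plus the requested covariates).
#' @param covariates covariate column names present in `cohort`; silently
#'   restricted to those available.
#' @param group restrict to one group (default `PD`, matching the clinical
#'   question); `NULL` uses all subjects.
#' @return long `data.frame`: marker, covariate, r, p_value, n.
#' @export
correlation_table <- function(markers, cohort,
                              covariates = c("perceptual", "mds_updrs_iii",
                                             "brady_rigidity", "pigd", "moca",
                                             "bdi_ii", "caudate_sbr",
                                             "putamen_sbr"),
                              group = "PD") {
  df <- merge(markers, cohort, by = "subject_id")
  if (!is.null(group)) df <- df[df$group %in% group, , drop = FALSE]
  covariates <- intersect(covariates, names(cohort))
  avg <- paste0("avg_", marker_catalogue()$marker)
  rows <- list()
  for (m in avg) for (cv in covariates) {
    ok <- complete.cases(df[[m]], df[[cv]], df$age)
    if (sum(ok) < 4L) next
    r <- partial_correlation_age(df[[m]][ok], df[[cv]][ok], df$age[ok])
    rows[[length(rows) + 1L]] <- data.frame(
      marker = sub("^avg_", "", m), covariate = cv, r = r$r,
      p_value = r$p_value, n = r$n)
  }
  do.call(rbind, rows)
}

#' Control-based abnormality cutoffs
#'
#' Per side-averaged marker, the one-sided 5% extreme cutoff of the control
#' distribution in the direction of impairment. All markers decrease with
#' hypomimia, so the operational cutoff is the 5th percentile of controls and
#' values below it are abnormal (`direction = "lower"`, the default);
#' `direction = "upper"` gives the mirrored 95th-percentile rule. Empirical
#' quantiles use linear interpolation.
#'
#' @param control_markers marker table rows for the control group.
#' @param prob tail probability (default 0.05).
#' @param direction `"lower"` (impairment direction) or `"upper"`.
#' @param min_controls minimum controls required per marker.
#' @return named cutoff vector over the 12 averaged markers, with attributes
#'   `direction` and `prob`.
#' @export
control_cutoffs <- function(control_markers, prob = 0.05,
                            direction = c("lower", "upper"),
                            min_controls = 20L) {
  direction <- match.arg(direction)
  avg <- paste0("avg_", marker_catalogue()$marker)
  cuts <- vapply(avg, function(m) {
    v <- control_markers[[m]]
    v <- v[is.finite(v)]
    if (length(v) < min_controls)
      stop("need at least ", min_controls, " controls for marker ", m)
    unname(quantile(v, if (direction == "lower") prob else 1 - prob, type = 7))
  }, numeric(1))
  names(cuts) <- sub("^avg_", "", avg)
  attr(cuts, "direction") <- direction
  attr(cuts, "prob") <- prob
  cuts
}

#' Flag abnormal facial regions for one subject
#'
#' A region is affected when ANY of its averaged markers is beyond its
#' control-based cutoff (the mouth region pools upper lip, lower lip and
#' mouth corner; the eyebrow region pools its three markers). Regions whose
#' markers are all missing are excluded from the count.
#'
#' @param averaged named averaged marker vector for one subject (over the
#'   catalogue marker names, `avg_` prefix tolerated).
#' @param cutoffs from [control_cutoffs()].
#' @return list: `region_flags` (named logical over the 8 regions, `NA` =
#'   undefined), `affected_region_count`.
#' @export
affected_areas <- function(averaged, cutoffs) {
  names(averaged) <- sub("^avg_", "", names(averaged))
  direction <- attr(cutoffs, "direction") %||% "lower"
  cat <- marker_catalogue()
  abn <- if (direction == "lower") averaged[cat$marker] < cutoffs[cat$marker]
         else averaged[cat$marker] > cutoffs[cat$marker]
  flags <- vapply(unique(cat$region), function(rg) {
    a <- abn[cat$marker[cat$region == rg]]
    if (all(is.na(a))) NA else any(a, na.rm = TRUE)
  }, logical(1))
  list(region_flags = flags,
       affected_region_count = sum(flags, na.rm = TRUE))
}

#' Abnormality profile for a whole cohort
#'
#' @param markers marker table.
#' @param cutoffs from [control_cutoffs()].
#' @return `data.frame`: subject_id, one logical column per region, and
#'   `affected_region_count`.
#' @export
abnormality_profile <- function(markers, cutoffs) {
  avg_cols <- paste0("avg_", marker_catalogue()$marker)
  rows <- lapply(seq_len(nrow(markers)), function(i) {
    v <- unlist(markers[i, avg_cols])
    a <- affected_areas(v, cutoffs)
    cbind(data.frame(subject_id = markers$subject_id[i]),
          as.data.frame(as.list(a$region_flags)),
          data.frame(affected_region_count = a$affected_region_count))
  })
  do.call(rbind, rows)
}
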