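## Group-level statistics: two-sample t-tests, two-way ANOVA with
## Bonferroni post-tests, baseline-normalised time courses, and the
## stats digest that assembles them for reporting.

#' Two-sample t-test with group summaries
#'
#' Two-sided Student's t-test (equal variances by default, matching the
#' Prism-era convention; Welch via `var_equal = FALSE`), or a paired
#' t-test. Degenerate zero-variance inputs are handled explicitly: a zero
#' mean difference gives t = 0, p = 1; a non-zero constant difference
#' gives an infinite t with p = 0.
#'
#' @param a,b numeric samples. For `paired = TRUE` they must have equal
#'   length and matched order.
#' @param paired paired test?
#' @param var_equal pooled-variance Student's form (default) or Welch.
#' @param labels length-2 character, group names for reporting.
#' @return object of class `test_result` with fields `test_name`,
#'   `statistic`, `df`, `p_value`, `groups` (mean, sem, n per group) and
#'   `stars`.
#' @export
#' @examples
#' ttest(c(1, 2, 3), c(1, 2, 3))$statistic   # 0
ttest <- function(a, b, paired = FALSE, var_equal = TRUE,
                  labels = c("a", "b")) {
  a <- as.numeric(a); b <- as.numeric(b)
  assert_that(length(a) >= 2L && length(b) >= 2L,
              "each sample needs at least 2 values", kind = "data")
  if (paired)
    assert_that(length(a) == length(b), "paired samples must match in length",
                kind = "data")

  degenerate <- if (paired) stats::sd(a - b) == 0 else
    (stats::sd(a) == 0 && stats::sd(b) == 0)
  if (degenerate) {
    delta <- mean(a) - mean(b)
    statistic <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else 0
    df <- if (paired) length(a) - 1L else length(a) + length(b) - 2L
  } else {
    ht <- stats::t.test(a, b, paired = paired, var.equal = var_equal)
    statistic <- unname(ht$statistic)
    p <- ht$p.value
    df <- unname(ht$parameter)
  }
  groups <- data.frame(group = labels,
                       mean = c(mean(a), mean(b)),
                       sem = c(sem(a), sem(b)),
                       n = c(length(a), length(b)))
  structure(list(test_name = if (paired) "paired t-test" else
                   if (var_equal) "unpaired t-test" else "Welch t-test",
                 statistic = statistic, df = df, p_value = p,
                 groups = groups, stars = significance_stars(p)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, df = %s, p = %.4g (%s)\n",
              x$test_name, x$statistic,
              paste(signif(x$df, 6), collapse = ", "), x$p_value, x$stars))
  if (!is.null(x$groups)) print(x$groups)
  invisible(x)
}

#' Two-way ANOVA with Bonferroni post-tests
#'
#' Fits `values ~ group * treatment` by [stats::aov()] and reports F with
#' numerator/denominator df for both main effects and the interaction
#' (formatted `F_{df1, df2}` as in standard reporting). Post-tests are
#' pairwise group contrasts within each treatment level, using the pooled
#' residual mean square, with Bonferroni correction across all contrasts
#' (adjusted p = raw p x number of contrasts, capped at 1).
#'
#' When every value is identical the effect mean squares are zero and F
#' is reported as 0 with p = 1 instead of 0/0.
#'
#' @param values numeric response.
#' @param group,treatment factors (coerced) of the two crossed designs.
#' @param posthoc compute Bonferroni post-tests?
#' @return object of class `anova_result`: `effects` data frame (effect,
#'   df1, df2, F, p, label, stars) and optionally `posthoc` data frame.
#' @export
two_way_anova <- function(values, group, treatment, posthoc = TRUE) {
  group <- factor(group); treatment <- factor(treatment)
  assert_that(nlevels(group) >= 2L && nlevels(treatment) >= 2L,
              "each factor needs at least 2 levels", kind = "data")
  assert_that(all(table(group, treatment) > 0), "empty design cell",
              kind = "data")
  assert_that(all(is.finite(values)), "values must be finite", kind = "data")

  ## essentially-constant responses: every effect is exactly null
  degenerate <- stats::sd(values) < 1e-10 * (abs(mean(values)) + 1)

  fit <- stats::aov(values ~ group * treatment)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  df_res <- tab[rn == "Residuals", "Df"]
  ms_res <- tab[rn == "Residuals", "Mean Sq"]
  eff_rows <- rn != "Residuals"
  eff <- data.frame(effect = c("group", "treatment", "interaction"),
                    df1 = tab[eff_rows, "Df"],
                    df2 = df_res,
                    F = tab[eff_rows, "F value"],
                    p = tab[eff_rows, "Pr(>F)"])
  zero_ms <- degenerate | tab[eff_rows, "Mean Sq"] == 0
  eff$F[zero_ms] <- 0
  eff$p[zero_ms] <- 1
  eff$F[!is.finite(eff$F)] <- 0
  eff$p[!is.finite(eff$p)] <- 1
  eff$label <- sprintf("F_%d,%d = %.4g", eff$df1, eff$df2, eff$F)
  eff$stars <- significance_stars(eff$p)

  res <- list(effects = eff, df_residual = df_res, ms_residual = ms_res)
  if (posthoc) {
    gl <- levels(group); tl <- levels(treatment)
    pairs <- utils::combn(gl, 2L, simplify = FALSE)
    k <- length(pairs) * length(tl)
    rows <- list()
    for (tr in tl) for (pr in pairs) {
      x1 <- values[group == pr[1] & treatment == tr]
      x2 <- values[group == pr[2] & treatment == tr]
      se <- sqrt(ms_res * (1 / length(x1) + 1 / length(x2)))
      tval <- if (se > 0) (mean(x1) - mean(x2)) / se else 0
      praw <- if (se > 0) 2 * stats::pt(-abs(tval), df_res) else 1
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = tr, contrast = paste(pr, collapse = " vs "),
        t = tval, df = df_res, p_raw = praw,
        p_bonferroni = min(1, praw * k))
    }
    res$posthoc <- do.call(rbind, rows)
    res$posthoc$stars <- significance_stars(res$posthoc$p_bonferroni)
  }
  structure(res, class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result>\n")
  print(x$effects[, c("effect", "label", "p", "stars")])
  if (!is.null(x$posthoc)) {
    cat("Bonferroni post-tests:\n")
    print(x$posthoc[, c("treatment", "contrast", "t", "p_bonferroni", "stars")])
  }
  invisible(x)
}

#' Baseline-normalised group time course
#'
#' Summarises per-unit relative rates (SR, %) into a group mean +/- SEM
#' per post-injection time bin, with the baseline bin fixed at exactly
#' 100% by construction.
#'
#' @param sr data frame with columns `unit_id`, `bin` (character or
#'   numeric bin label, e.g. 30/60/90 for minutes post-injection) and
#'   `sr_percent`.
#' @param group group label attached to the summary.
#' @param baseline_label label used for the baseline bin row.
#' @return data frame with columns `group`, `bin`, `mean_percent`,
#'   `sem_percent`, `n`; first row is the baseline at 100%.
#' @export
build_timecourse <- function(sr, group = "group",
                             baseline_label = "baseline") {
  assert_that(all(c("unit_id", "bin", "sr_percent") %in% names(sr)),
              "sr needs columns unit_id, bin, sr_percent", kind = "data")
  sr <- sr[!is.na(sr$sr_percent), , drop = FALSE]
  bins <- unique(sr$bin)
  rows <- lapply(bins, function(b) {
    v <- sr$sr_percent[sr$bin == b]
    data.frame(group = group, bin = as.character(b),
               mean_percent = mean(v), sem_percent = sem(v), n = length(v))
  })
  n_base <- length(unique(sr$unit_id))
  rbind(data.frame(group = group, bin = baseline_label, mean_percent = 100,
                   sem_percent = 0, n = n_base),
        do.call(rbind, rows))
}

#' Assemble a statistics digest from test results
#'
#' Flattens a named list of [ttest()] / [two_way_anova()] results (and
#' plain data frames) into one digest table, annotated with the number of
#' units/somas and animals per comparison when supplied.
#'
#' @param tests named list; elements are `test_result` or `anova_result`
#'   objects.
#' @param counts optional data frame with columns `comparison`, `n_units`,
#'   `n_animals` merged onto the digest by comparison name.
#' @return data frame with one row per reported statistic.
#' @export
assemble_report <- function(tests, counts = NULL) {
  assert_that(length(tests) >= 1L, "no test results supplied", kind = "data")
  rows <- list()
  for (nm in names(tests)) {
    x <- tests[[nm]]
    if (inherits(x, "test_result")) {
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = nm, test = x$test_name,
        statistic = x$statistic, df = paste(signif(x$df, 6), collapse = ","),
        p_value = x$p_value, stars = x$stars)
    } else if (inherits(x, "anova_result")) {
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = nm, test = paste("two-way ANOVA:", x$effects$effect),
        statistic = x$effects$F,
        df = paste(x$effects$df1, x$effects$df2, sep = ","),
        p_value = x$effects$p, stars = x$effects$stars)
    } else {
      stop_data(sprintf("unsupported test result type for '%s'", nm))
    }
  }
  digest <- do.call(rbind, rows)
  if (!is.null(counts)) {
    assert_that("comparison" %in% names(counts),
                "counts needs a 'comparison' column", kind = "data")
    digest <- merge(digest, counts, by = "comparison", all.x = TRUE,
                    sort = FALSE)
  }
  rownames(digest) <- NULL
  digest
}
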