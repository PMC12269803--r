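#' Normalize analyte concentrations to total protein
#'
#' Per-sample ratio of analyte to total protein concentration (e.g. BDNF in
#' pg/mL over protein in mg/mL gives pg/mg), removing differences in tissue
#' amount across samples. Nonpositive protein concentrations are a
#' validation error naming the offending samples.
#'
#' @param analyte_conc numeric vector of analyte concentrations.
#' @param protein_conc numeric vector of total protein concentrations
#'   (strictly positive), recycled against `analyte_conc` if scalar.
#' @return Numeric vector `analyte_conc / protein_conc`.
#' @export
normalize_assay <- function(analyte_conc, protein_conc) {
  if (length(protein_conc) == 1L) {
    protein_conc <- rep(protein_conc, length(analyte_conc))
  }
  stopifnot(length(analyte_conc) == length(protein_conc))
  bad <- which(!is.na(protein_conc) & protein_conc <= 0)
  if (length(bad) > 0L) {
    stop("nonpositive protein concentration for sample(s): ",
         paste(bad, collapse = ", "))
  }
  analyte_conc / protein_conc
}

check_groups <- function(value, group, min_groups = 2L) {
  stopifnot(length(value) == length(group))
  ok <- !is.na(value) & !is.na(group)
  value <- value[ok]
  group <- factor(as.character(group[ok]))
  counts <- table(group)
  if (length(counts) < min_groups) {
    stop("need at least ", min_groups, " groups (found ", length(counts), ")")
  }
  small <- names(counts)[counts < 2L]
  if (length(small) > 0L) {
    stop("group(s) with fewer than 2 values: ", paste(small, collapse = ", "))
  }
  list(value = value, group = group)
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Classical fixed-effects one-way ANOVA across groups, followed by Tukey's
#' honestly-significant-difference test on all pairwise group comparisons.
#' Every group must contribute at least 2 values; violations are refused
#' naming the offending group.
#'
#' @param value numeric measurements.
#' @param group group labels (coerced to factor).
#' @return An `anova_tukey` list: `F`, `df_between`, `df_within`, `p`, and
#'   `tukey` (data frame: comparison, diff, lwr, upr, p_adj).
#' @examples
#' d <- simulate_assay(c(10, 12, 15), c(1, 1, 1), c(5, 5, 5), seed = 1)
#' one_way_anova_tukey(d$normalized, d$group)
#' @export
one_way_anova_tukey <- function(value, group) {
  d <- check_groups(value, group)
  fit <- stats::aov(value ~ group, data = d)
  tab <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  structure(list(F = tab["group", "F value"],
                 df_between = tab["group", "Df"],
                 df_within = tab["Residuals", "Df"],
                 p = tab["group", "Pr(>F)"],
                 tukey = tukey),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  print(x$tukey)
  invisible(x)
}

#' Unpaired two-sample t-test
#'
#' Two-sided unpaired Student's t-test with pooled variance (the
#' convention for the group comparisons this package supports); Welch's
#' unequal-variance form is available via `var_equal = FALSE`. When both
#' groups are constant and equal, the statistic is reported as `t = 0`,
#' `p = 1` by convention (logged) instead of failing on zero variance.
#'
#' @param x,y numeric vectors (each with at least 2 values).
#' @return List with `t`, `df`, `p`, and the group means.
#' @param var_equal pool the variances (default TRUE, Student's test).
#' @export
unpaired_t <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      message("zero pooled variance with equal means; p = 1 by convention")
      return(list(t = 0, df = length(x) + length(y) - 2L, p = 1,
                  mean_x = mean(x), mean_y = mean(y)))
    }
    stop("zero variance in both groups with unequal means; t undefined")
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}
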