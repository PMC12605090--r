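#' Two-tailed two-sample Student's t test
#'
#' Classical pooled-variance (equal-variance) two-sample t test, the study
#' default for two-group comparisons; Welch's correction is available behind
#' a flag. Degenerate samples with zero pooled variance return the sentinel
#' conventions `p = 1` (equal means) or `p = 0` (unequal means).
#'
#' @param a,b Numeric samples, each with at least 2 finite values.
#' @param welch Use Welch's unequal-variance test instead.
#' @return A tibble with `method`, `statistic`, `df`, `p_value`.
#' @export
t_test_two_tailed <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  if (var(a) == 0 && var(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble::tibble(method = "student_t_two_tailed",
                          statistic = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                          df = length(a) + length(b) - 2,
                          p_value = if (eq) 1 else 0))
  }
  tt <- t.test(a, b, var.equal = !welch, alternative = "two.sided")
  tibble::tibble(method = if (welch) "welch_t_two_tailed" else "student_t_two_tailed",
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value)
}

.as_group_list <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 1)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  for (g in groups) stopifnot(length(g) >= 2, all(is.finite(g)))
  groups
}

.stack_groups <- function(groups) {
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups)))
}

#' One-way ANOVA
#'
#' F test across three or more groups. When every observation is identical
#' the F statistic is undefined (0/0) and the result is reported with the
#' convention `p = 1`.
#'
#' @param groups Named list of at least 3 numeric samples (each of length
#'   at least 2).
#' @return A tibble with `method`, `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
one_way_anova <- function(groups) {
  groups <- .as_group_list(groups)
  if (length(groups) < 3) {
    stop("one-way ANOVA needs at least 3 groups; use t_test_two_tailed for two",
         call. = FALSE)
  }
  df <- .stack_groups(groups)
  k <- length(groups); n <- nrow(df)
  if (var(df$value) == 0) {
    return(tibble::tibble(method = "one_way_anova", statistic = NA_real_,
                          df1 = k - 1, df2 = n - k, p_value = 1))
  }
  fit <- aov(value ~ group, data = df)
  s <- summary(fit)[[1]]
  tibble::tibble(method = "one_way_anova", statistic = s$`F value`[1],
                 df1 = s$Df[1], df2 = s$Df[2], p_value = s$`Pr(>F)`[1])
}

#' Tukey's honestly significant difference test
#'
#' All pairwise comparisons following a one-way ANOVA, with studentized-range
#' adjusted p-values; pairs are ordered lexicographically.
#'
#' @param groups Named list of at least 3 numeric samples.
#' @return A tibble with `contrast`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  groups <- .as_group_list(groups)
  if (length(groups) < 3) {
    stop("Tukey HSD here follows a one-way ANOVA; needs at least 3 groups",
         call. = FALSE)
  }
  df <- .stack_groups(groups)
  tk <- TukeyHSD(aov(value ~ group, data = df))$group
  out <- tibble::tibble(contrast = rownames(tk), diff = unname(tk[, "diff"]),
                        lwr = unname(tk[, "lwr"]), upr = unname(tk[, "upr"]),
                        p_adj = unname(tk[, "p adj"]))
  out[order(out$contrast), ]
}

#' Two-way ANOVA with type-II sums of squares
#'
#' Generic two-crossed-factor ANOVA (with interaction) using type-II sums
#' of squares.
#'
#' @param data Data frame.
#' @param response,factor_a,factor_b Column names.
#' @return A tibble with one row per term: `term`, `sum_sq`, `df`,
#'   `statistic`, `p_value`.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  stopifnot(all(c(response, factor_a, factor_b) %in% names(data)))
  data[[factor_a]] <- factor(data[[factor_a]])
  data[[factor_b]] <- factor(data[[factor_b]])
  fml <- stats::as.formula(sprintf("%s ~ %s * %s", response, factor_a, factor_b))
  tab <- car::Anova(lm(fml, data = data), type = 2)
  tibble::tibble(term = rownames(tab), sum_sq = tab$`Sum Sq`, df = tab$Df,
                 statistic = tab$`F value`, p_value = tab$`Pr(>F)`)
}

#' Significance label ladder
#'
#' Maps p-values to the study's label ladder with strict inequalities:
#' `****` for p < 0.0001, `***` for p < 0.001, `**` for p < 0.01, `*` for
#' p < 0.05, `#` (trend) for p < 0.1, and `ns` otherwise.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of labels.
#' @examples
#' label_significance(c(0.03, 0.09, 0.10))  # "*", "#", "ns"
#' @export
label_significance <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  cut_labels <- function(x) {
    if (x < 0.0001) "****"
    else if (x < 0.001) "***"
    else if (x < 0.01) "**"
    else if (x < 0.05) "*"
    else if (x < 0.1) "#"
    else "ns"
  }
  vapply(p, cut_labels, character(1))
}
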