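#' Three-group comparison of a regional parameter
#'
#' One-way ANOVA across the study groups with Tukey Honestly Significant
#' Difference pairwise contrasts. Because four regions are evaluated,
#' the omnibus threshold is Bonferroni-corrected to 0.0125; pairwise
#' p-values are reported only when the omnibus test is significant, and
#' pairwise significance is declared at 0.05.
#'
#' @param values numeric vector of per-subject values.
#' @param groups factor/character of group membership (>= 2 groups with
#'   >= 2 values each).
#' @param threshold omnibus significance threshold.
#' @return an `aorta_group_comparison`: `group_stats` (mean, sd, n per
#'   group), `anova_p`, `omnibus_significant`, `pairwise` (data.frame:
#'   contrast, diff, p, significant; `NULL` unless omnibus significant),
#'   `degenerate`.
#' @export
compare_groups <- function(values, groups, threshold = 0.0125) {
  groups <- factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need at least 2 groups with at least 2 values each")
  }
  gs <- data.frame(group = names(tab),
                   n = as.integer(tab),
                   mean = as.numeric(tapply(values, groups, mean)),
                   sd = as.numeric(tapply(values, groups, sd)))
  wvar <- tapply(values, groups, var)
  degenerate <- all(wvar == 0)
  if (degenerate) {
    return(structure(list(group_stats = gs, anova_p = NA_real_,
                          omnibus_significant = FALSE, pairwise = NULL,
                          threshold = threshold, degenerate = TRUE),
                     class = "aorta_group_comparison"))
  }
  fit <- aov(values ~ groups)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  sig <- is.finite(p) && p < threshold
  pw <- NULL
  if (sig) {
    tk <- TukeyHSD(fit)$groups
    pw <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                     p = tk[, "p adj"],
                     significant = tk[, "p adj"] < 0.05,
                     row.names = NULL)
  }
  structure(list(group_stats = gs, anova_p = p,
                 omnibus_significant = sig, pairwise = pw,
                 threshold = threshold, degenerate = FALSE),
            class = "aorta_group_comparison")
}

#' @export
print.aorta_group_comparison <- function(x, ...) {
  cat(sprintf("<group comparison> ANOVA p = %.4g (threshold %.4g)\n",
              x$anova_p, x$threshold))
  print(x$group_stats)
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' Rank-based comparison of abnormal-area percentages
#'
#' Two-sample rank-sum (Mann-Whitney) comparison between the two
#' patient groups, with tie handling, plus Table-style
#' "median (IQR: q1-q3)" summaries. Note: despite sometimes being
#' labelled a signed-rank test in clinical reports, two independent
#' groups of unequal size require the rank-sum form; the variant used is
#' recorded in the result.
#'
#' @param native_values,ars_values numeric vectors (independent
#'   samples).
#' @return list with `p`, `medians`, `iqr_strings`, `test`,
#'   `degenerate`.
#' @export
compare_abnormal_areas <- function(native_values, ars_values) {
  if (length(native_values) == 0 || length(ars_values) == 0) {
    stop("empty group")
  }
  fmt <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
    sprintf("%.3g (IQR: %.3g-%.3g)", q[2], q[1], q[3])
  }
  meds <- c(native = median(native_values), ars = median(ars_values))
  strs <- c(native = fmt(native_values), ars = fmt(ars_values))
  allv <- c(native_values, ars_values)
  if (var(allv) == 0) {
    return(list(p = NA_real_, medians = meds, iqr_strings = strs,
                test = "rank-sum (Mann-Whitney)", degenerate = TRUE))
  }
  ties <- any(duplicated(allv))
  wt <- suppressWarnings(
    wilcox.test(native_values, ars_values, exact = !ties,
                correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1
  list(p = min(p, 1), medians = meds, iqr_strings = strs,
       test = "rank-sum (Mann-Whitney)", degenerate = FALSE)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @return list with `r`, `ci` (95%), `p`, `n`.
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 pairs")
  if (var(x) == 0 || var(y) == 0) stop("zero variance in a variable")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), ci = unname(ct$conf.int),
       p = ct$p.value, n = length(x))
}

#' Univariable logistic regression for abnormality determinants
#'
#' Maximum-likelihood logistic fit of a binary outcome (e.g. abnormally
#' increased proximal-descending displacement) on one predictor. Returns
#' the odds ratio with Wald 95% confidence interval and p-value.
#' Complete separation is flagged and yields no numeric OR.
#'
#' @param outcome binary vector (0/1 or logical) with both classes
#'   present.
#' @param predictor numeric vector.
#' @return list with `or`, `ci`, `p`, `coef`, `separation`.
#' @export
logistic_univariable <- function(outcome, predictor) {
  outcome <- as.integer(outcome)
  if (length(unique(outcome[is.finite(outcome)])) < 2) {
    stop("outcome must contain both classes")
  }
  fit <- suppressWarnings(glm(outcome ~ predictor, family = binomial()))
  b <- coef(fit)[["predictor"]]
  se <- sqrt(vcov(fit)["predictor", "predictor"])
  # complete separation: diverging coefficient / exploding Wald SE
  sep <- !fit$converged || abs(b) > 15 || se > 100 * max(abs(b), 1)
  if (sep) {
    return(list(or = NA_real_, ci = c(NA_real_, NA_real_), p = NA_real_,
                coef = b, separation = TRUE))
  }
  z <- b / se
  list(or = exp(b), ci = exp(b + c(-1, 1) * 1.96 * se),
       p = 2 * pnorm(-abs(z)), coef = b, separation = FALSE)
}

#' Incidence of any abnormal vertex per region
#'
#' Percentage of patients with at least one abnormal vertex per ROI and
#' class, formatted as "97% (31/32)".
#'
#' @param summaries list of per-patient data.frames from
#'   [abnormal_area_percent()].
#' @return data.frame with `roi`, `class`, `count`, `n`, `percent`,
#'   `label`.
#' @export
incidence_table <- function(summaries) {
  if (length(summaries) == 0) stop("need at least 1 patient")
  base <- summaries[[1]][, c("roi", "class")]
  n <- length(summaries)
  cnt <- rowSums(matrix(unlist(lapply(summaries, function(s) {
    as.integer(s$any_abnormal_vertex %in% TRUE)
  })), nrow = nrow(base)))
  pct <- round(100 * cnt / n)
  data.frame(base, count = cnt, n = n, percent = 100 * cnt / n,
             label = sprintf("%d%% (%d/%d)", pct, cnt, n))
}
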