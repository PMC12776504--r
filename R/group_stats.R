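#' Normality gate
#'
#' Decides between parametric and nonparametric testing: parametric iff the
#' Shapiro-Wilk test does not reject normality at the gate level (0.05).
#' Constant samples are degenerate and flagged as such.
#'
#' @param x numeric sample, `n >= 3`
#' @param gate_alpha rejection level for the Shapiro-Wilk gate
#' @return `"parametric"`, `"nonparametric"` or `"degenerate"`
#' @export
normality_gate <- function(x, gate_alpha = 0.05) {
  if (length(x) < 3) stop("normality gate needs n >= 3")
  if (stats::sd(x) == 0) return("degenerate")
  p <- stats::shapiro.test(x)$p.value
  if (p >= gate_alpha) "parametric" else "nonparametric"
}

comparison_result <- function(statistic, p_value, d, test_used, alpha,
                              note = NA_character_) {
  res <- list(statistic = unname(statistic), p_value = unname(p_value),
              effect_size_d = unname(d), test_used = test_used,
              significant = is.finite(p_value) && p_value < alpha,
              alpha = alpha, note = note)
  class(res) <- "comparison_result"
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(x$test_used, ": statistic = ", signif(x$statistic, 4),
      ", p = ", format(x$p_value, digits = 3),
      ", d = ", signif(x$effect_size_d, 4),
      if (x$significant) " *" else "", "\n", sep = "")
  invisible(x)
}

#' Paired two-sided comparison with normality gate
#'
#' Paired t-test when the differences pass the Shapiro-Wilk gate, Wilcoxon
#' signed-rank otherwise. Cohen's d for paired data is
#' `mean(diff) / sd(diff)` with the sample (n-1) standard deviation and is
#' reported on the raw values even under the nonparametric branch. Identical
#' inputs (zero-variance differences) are degenerate: d = 0 and p = 1, with
#' a note.
#'
#' @param x_pre,x_post paired numeric samples of equal length, `n >= 3`
#' @param alpha declaration threshold (default 0.01, the planned-comparison
#'   threshold for connectivity contrasts)
#' @return a `comparison_result`
#' @export
compare_paired <- function(x_pre, x_post, alpha = 0.01) {
  if (length(x_pre) != length(x_post)) stop("paired samples differ in length")
  if (length(x_pre) < 3) stop("need n >= 3 pairs")
  d <- x_post - x_pre
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(comparison_result(0, 1, 0, "t", alpha, note = "zero-variance differences"))
    return(comparison_result(Inf, 0, Inf, "t", alpha,
                             note = "constant non-zero differences"))
  }
  gate <- normality_gate(d)
  cohen_d <- mean(d) / stats::sd(d)
  if (gate == "parametric") {
    tt <- stats::t.test(x_post, x_pre, paired = TRUE)
    comparison_result(tt$statistic, tt$p.value, cohen_d, "t", alpha)
  } else {
    wt <- stats::wilcox.test(x_post, x_pre, paired = TRUE, exact = FALSE)
    comparison_result(wt$statistic, wt$p.value, cohen_d, "wilcoxon", alpha,
                      note = "d reported on raw values under nonparametric branch")
  }
}

#' Unpaired two-sided comparison with normality gate
#'
#' Two-sample t-test (pooled-variance Cohen's d) when both groups pass the
#' Shapiro-Wilk gate, Mann-Whitney otherwise.
#'
#' @param a,b numeric samples, each `n >= 3`
#' @param alpha declaration threshold (default 0.01)
#' @param var_equal use the pooled-variance t-test (default TRUE, matching
#'   the pooled-sd effect size)
#' @return a `comparison_result`
#' @export
compare_unpaired <- function(a, b, alpha = 0.01, var_equal = TRUE) {
  if (length(a) < 3 || length(b) < 3) stop("each group needs n >= 3")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(comparison_result(0, 1, 0, "t", alpha, note = "degenerate groups"))
    return(comparison_result(Inf, 0, Inf, "t", alpha, note = "degenerate groups"))
  }
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  cohen_d <- (mean(a) - mean(b)) / sp
  gate_a <- normality_gate(a); gate_b <- normality_gate(b)
  if (gate_a == "parametric" && gate_b == "parametric") {
    tt <- stats::t.test(a, b, var.equal = var_equal)
    comparison_result(tt$statistic, tt$p.value, cohen_d, "t", alpha)
  } else {
    wt <- stats::wilcox.test(a, b, exact = FALSE)
    comparison_result(wt$statistic, wt$p.value, cohen_d, "mannwhitney", alpha,
                      note = "d reported on raw values under nonparametric branch")
  }
}

#' Correlation between connectivity change and clinical change
#'
#' Pearson correlation (Spearman by option) between the post-minus-pre
#' change in the clinical score and the post-minus-pre change in a region's
#' outward connectivity, matched by subject id.
#'
#' @param fma_table data.frame with `subject_id`, `fma_pre`, `fma_post`
#' @param strength_pre,strength_post named numeric vectors of the region's
#'   out-strength per subject (names are subject ids)
#' @param method `"pearson"` (default) or `"spearman"`
#' @return list with `r`, `p_value`, `n`, `method`
#' @export
delta_correlation <- function(fma_table, strength_pre, strength_post,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ids <- fma_table$subject_id
  if (!all(ids %in% names(strength_pre)) || !all(ids %in% names(strength_post)))
    stop("subject ids in the clinical table are missing from the connectivity inputs")
  d_fma <- fma_table$fma_post - fma_table$fma_pre
  d_conn <- strength_post[ids] - strength_pre[ids]
  ct <- stats::cor.test(d_fma, d_conn, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(ids),
       method = method)
}

#' Load the packaged clinical scores table
#'
#' The 22-patient Fugl-Meyer lower-extremity motor scores (34-point domain)
#' with demographics: group (ER = exoskeleton-assisted rehabilitation,
#' SOC = standard of care), age, lesion side and days since stroke, with
#' pre- and post-intervention scores.
#'
#' @return data.frame with columns `subject_id`, `group`, `gender`, `age`,
#'   `lesion_side`, `time_since_stroke`, `fma_pre`, `fma_post`
#' @export
load_fma_table <- function() {
  path <- system.file("extdata", "fma_scores.csv", package = "pdcnet")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(tab$fma_pre >= 0 & tab$fma_pre <= 34),
            all(tab$fma_post >= 0 & tab$fma_post <= 34))
  tab
}

#' Clinical score summary with paired comparison
#'
#' Sample means and standard deviations (n-1) of the pre- and
#' post-intervention scores, the mean and SD of the change, per-group mean
#' changes, and the gated paired comparison of post vs pre.
#'
#' @param fma_table table as returned by [load_fma_table()]
#' @return list with `n`, `mean_pre`, `sd_pre`, `mean_post`, `sd_post`,
#'   `mean_change`, `sd_change`, `group_changes`, `comparison`
#' @export
fma_summary <- function(fma_table) {
  if (anyNA(fma_table$fma_pre) || anyNA(fma_table$fma_post))
    stop("missing clinical scores")
  ch <- fma_table$fma_post - fma_table$fma_pre
  list(n = nrow(fma_table),
       mean_pre = mean(fma_table$fma_pre), sd_pre = stats::sd(fma_table$fma_pre),
       mean_post = mean(fma_table$fma_post), sd_post = stats::sd(fma_table$fma_post),
       mean_change = mean(ch), sd_change = stats::sd(ch),
       group_changes = tapply(ch, fma_table$group, mean),
       comparison = compare_paired(fma_table$fma_pre, fma_table$fma_post,
                                   alpha = 0.05))
}

#' Two-way mixed (split-plot) ANOVA on the clinical scores
#'
#' Between-subject factor group, within-subject factor time (pre vs post).
#' Returns F and p for the group main effect, the time main effect and the
#' group-by-time interaction.
#'
#' @param fma_table table as returned by [load_fma_table()]
#' @return data.frame with rows `group`, `time`, `group:time` and columns
#'   `F`, `df1`, `df2`, `p_value`
#' @export
mixed_anova <- function(fma_table) {
  if (length(unique(fma_table$group)) < 2) stop("need two groups")
  long <- data.frame(
    subject = factor(rep(fma_table$subject_id, 2)),
    group = factor(rep(fma_table$group, 2)),
    time = factor(rep(c("pre", "post"), each = nrow(fma_table)),
                  levels = c("pre", "post")),
    score = c(fma_table$fma_pre, fma_table$fma_post))
  if (stats::var(long$score) == 0) {
    out <- data.frame(F = c(0, 0, 0), df1 = 1,
                      df2 = nrow(fma_table) - length(unique(fma_table$group)),
                      p_value = 1,
                      row.names = c("group", "time", "group:time"))
    return(out)
  }
  fit <- stats::aov(score ~ group * time + Error(subject), data = long)
  sm <- summary(fit)
  between <- sm[["Error: subject"]][[1]]
  within <- sm[["Error: Within"]][[1]]
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    j <- match("Residuals", trimws(rownames(tab)))
    c(F = tab[i, "F value"], df1 = tab[i, "Df"], df2 = tab[j, "Df"],
      p_value = tab[i, "Pr(>F)"])
  }
  out <- rbind(group = pick(between, "group"),
               time = pick(within, "time"),
               `group:time` = pick(within, "group:time"))
  as.data.frame(out)
}
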