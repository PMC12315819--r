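#' Two-group comparison by Student's t-test
#'
#' Two-sample t statistic and two-sided p value; pooled (equal-variance)
#' Student form by default, Welch optional.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @param equal_var pooled-variance Student test (default) or Welch.
#' @return a list with `t`, `p`, `df`, `method`.
#' @export
#' @examples
#' compare_two_groups(c(1, 2, 3), c(2, 3, 4))
compare_two_groups <- function(a, b, equal_var = TRUE) {
  if (!is.numeric(a) || length(a) < 2) stop_param("a", "need >= 2 values")
  if (!is.numeric(b) || length(b) < 2) stop_param("b", "need >= 2 values")
  res <- tryCatch(t.test(a, b, var.equal = isTRUE(equal_var)),
                  error = function(e)
                    stop_param("a", paste("degenerate variance:",
                                          conditionMessage(e))))
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter), method = res$method)
}

#' Multi-group comparison by one-way ANOVA with Tukey HSD
#'
#' @param groups a list of >= 3 numeric vectors (each n >= 2).
#' @return a list with `F`, `p` and `tukey` (data.frame of pairwise
#'   comparisons with Tukey-adjusted p values).
#' @export
#' @examples
#' compare_multi(list(HC = c(1, 2, 1.5), PD = c(2, 3, 2.5), MSA = c(9, 10, 11)))
compare_multi <- function(groups) {
  if (!is.list(groups) || length(groups) < 3)
    stop_param("groups",
               "need >= 3 groups (use compare_two_groups for two groups)")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop_param("groups", "each group needs n >= 2")
  nm <- names(groups)
  if (is.null(nm) || any(nm == ""))
    nm <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(nm, vapply(groups, length, integer(1))), levels = nm))
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      ci_low = tk[, "lwr"], ci_high = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1], tukey = tukey)
}

auc_rank <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)  # mid-ranks: ties get half credit automatically
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC AUC with stratified bootstrap confidence interval
#'
#' The AUC is the normalized Mann-Whitney statistic: the probability that a
#' random positive (patient) scores above a random negative (control), with
#' half credit for ties; computed via mid-ranks. The confidence interval is
#' a stratified percentile bootstrap (resampling positives and negatives
#' separately), deterministic given `seed`. The direction is never flipped:
#' an AUC below 0.5 is reported as-is.
#'
#' @param scores numeric marker values (e.g. co-aggregate counts).
#' @param labels binary labels; 1 (or `TRUE`) = positive/patient class.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @param conf_level confidence level of the percentile interval.
#' @return an object of class `roc_result`: list with `auc`, `ci_low`,
#'   `ci_high`, `n_boot`, `seed`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc(c(1, 2, 3, 2.5, 3.5), c(0, 0, 0, 1, 1), n_boot = 200, seed = 1)$auc
roc <- function(scores, labels, n_boot = 2000, seed = 1,
                conf_level = 0.95) {
  if (length(scores) != length(labels))
    stop_param("labels", "must have the same length as scores")
  labels <- as.integer(as.logical(labels) | labels == 1)
  if (length(unique(labels)) < 2)
    stop_param("labels", "both classes must be present")
  check_scalar_num(n_boot, "n_boot", lower = 1)
  auc <- auc_rank(scores, labels)
  ipos <- which(labels == 1); ineg <- which(labels == 0)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    sp <- sample(ipos, length(ipos), replace = TRUE)
    sn <- sample(ineg, length(ineg), replace = TRUE)
    auc_rank(scores[c(sp, sn)],
             c(rep(1L, length(sp)), rep(0L, length(sn))))
  }, numeric(1)))
  alpha <- 1 - conf_level
  ci <- unname(quantile(boots, c(alpha / 2, 1 - alpha / 2), type = 7))
  structure(list(auc = auc,
                 ci_low = min(ci[1], auc), ci_high = max(ci[2], auc),
                 n_boot = as.integer(n_boot), seed = seed,
                 n_pos = length(ipos), n_neg = length(ineg)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%.0f%% CI %.3f-%.3f; %d+/%d-; %d bootstrap reps)\n",
              x$auc, 95, x$ci_low, x$ci_high, x$n_pos, x$n_neg, x$n_boot))
  invisible(x)
}

#' Spearman rank correlation with p value
#'
#' Spearman's r on mid-ranks (average ranks for ties). The p value is exact
#' for n <= 9 without ties, and uses the t approximation otherwise,
#' following [stats::cor.test()].
#'
#' @param x,y numeric vectors of equal length, n >= 4.
#' @return an object of class `correlation_result`: list with `r`,
#'   `p_value`, `n`.
#' @export
#' @examples
#' spearman_corr(1:4, c(2, 1, 4, 3))$r
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop_param("y", "must match length of x")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop_param("x", "need n >= 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop_param("x", "correlation undefined for a constant vector")
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  exact <- n <= 9 && !has_ties
  res <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = exact))
  structure(list(r = unname(res$estimate), p_value = res$p.value, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> Spearman r = %.3f, p = %.4g, n = %d\n",
              x$r, x$p_value, x$n))
  invisible(x)
}
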