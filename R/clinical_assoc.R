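#' Kaplan-Meier / log-rank comparison of subtype survival
#'
#' Compares disease-free survival across evolutionary subtypes with the
#' standard log-rank test and returns the Kaplan-Meier step-function
#' estimates for plotting. Delegates to the \pkg{survival} package.
#'
#' @param clinical Clinical table with `patient_id`, `dfs_time`,
#'   `dfs_event`.
#' @param labels Named vector of group labels by patient id (e.g.
#'   `subtype_assignment$labels`).
#' @param groups Optional subset of group labels to compare (default all).
#' @return List with `statistic` (log-rank chi-square), `df`, `p_value`,
#'   `n` and `events` per group, and `fit` (a [survival::survfit] object).
#' @export
km_logrank <- function(clinical, labels, groups = NULL) {
  dat <- clinical[clinical$patient_id %in% names(labels), , drop = FALSE]
  dat$group <- labels[dat$patient_id]
  if (!is.null(groups)) {
    if (any(!groups %in% dat$group))
      stop("group with zero members: ",
           paste(setdiff(groups, dat$group), collapse = ", "))
    dat <- dat[dat$group %in% groups, , drop = FALSE]
  }
  if (length(unique(dat$group)) < 2L) stop("need at least 2 groups")
  if (sum(dat$dfs_event) < 1L) stop("need at least 1 event overall")
  dat$group <- factor(dat$group)
  sv <- survival::Surv(dat$dfs_time, dat$dfs_event)
  sd <- survival::survdiff(sv ~ group, data = dat)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n = stats::setNames(as.vector(sd$n), levels(dat$group)),
       events = stats::setNames(as.vector(sd$obs), levels(dat$group)),
       fit = survival::survfit(sv ~ group, data = dat))
}

#' Mann-Whitney U comparison of a continuous variable between two groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney U) test. Small untied samples
#' (both groups at most 20 observations) use the exact null enumeration;
#' larger or tied samples use the normal approximation with tie and
#' continuity corrections. When every value is tied across both groups the
#' test is vacuous: `p = 1` is returned with a warning.
#'
#' @param x,y Numeric values for the two groups (each non-empty).
#' @return List with `U` (statistic for the first group) and `p_value`.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  if (length(unique(c(x, y))) == 1L) {
    warning("all values tied across both groups; p = 1")
    return(list(U = length(x) * length(y) / 2, p_value = 1))
  }
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && max(length(x), length(y)) <= 20L
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                           correct = TRUE)
  list(U = unname(wt$statistic), p_value = wt$p.value)
}
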