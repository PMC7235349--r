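#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by sqrt(n).
#'
#' @param values numeric vector, length >= 2.
#' @return numeric(1) SEM.
#' @export
sem <- function(values) {
  n <- length(values)
  if (n < 2) stop("sem requires at least 2 values")
  stats::sd(values) / sqrt(n)
}

#' Two-sample Student t-test (pooled variance)
#'
#' Classic pooled-variance two-sided t-test with `df = n_a + n_b - 2`; the
#' p-value comes from the t distribution (regularised incomplete beta). If
#' the pooled variance is zero the result is degenerate: equal means give
#' `t = 0, p = 1`; unequal means give `p = 0` with `degenerate = TRUE`.
#' A Welch-corrected variant is available behind `welch = TRUE`.
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @param welch logical; use the Welch (unequal variance) correction.
#' @return list with `t`, `df`, `p` and `degenerate` (logical).
#' @export
studentsT <- function(groupA, groupB, welch = FALSE) {
  na <- length(groupA); nb <- length(groupB)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  if (!all(is.finite(c(groupA, groupB)))) stop("non-finite values")
  ma <- mean(groupA); mb <- mean(groupB)
  va <- stats::var(groupA); vb <- stats::var(groupB)
  if (welch) {
    seSq <- va / na + vb / nb
    df <- seSq^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    seSq <- sp2 * (1 / na + 1 / nb)
  }
  if (seSq == 0 || (welch && !is.finite(df))) {
    if (ma == mb) return(list(t = 0, df = df, p = 1, degenerate = TRUE))
    return(list(t = sign(ma - mb) * Inf, df = df, p = 0, degenerate = TRUE))
  }
  t <- (ma - mb) / sqrt(seSq)
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Compare WT and KO abundance of one cluster
#'
#' Assembles the two-group summary the abundance histograms report: per-group
#' mean and SEM of the cluster percentage, the KO/WT fold change, and the
#' pooled-variance Student t-test with significance at `p < alpha`.
#'
#' @param table abundance data.frame from [abundanceTable()] (columns
#'   image_id, group, cluster_id, percent).
#' @param clusterId cluster id to compare.
#' @param alpha significance level (default 0.01).
#' @param welch logical; Welch-corrected test instead of pooled variance.
#' @return one-row data.frame: cluster_id, n_wt, n_ko, mean_wt, sem_wt,
#'   mean_ko, sem_ko, fold_change, t_stat, df, p_value, significant, alpha.
#' @export
compareGroups <- function(table, clusterId, alpha = 0.01, welch = FALSE) {
  sub <- table[table$cluster_id == clusterId, , drop = FALSE]
  wt <- sub$percent[sub$group == "WT"]
  ko <- sub$percent[sub$group == "KO"]
  if (length(wt) < 2 || length(ko) < 2)
    stop("both groups need >= 2 images with cluster ", clusterId)
  if (mean(wt) == 0)
    stop("fold change undefined: WT mean abundance of cluster ", clusterId,
         " is zero")
  tt <- studentsT(ko, wt, welch = welch)
  data.frame(cluster_id = as.integer(clusterId),
             n_wt = length(wt), n_ko = length(ko),
             mean_wt = mean(wt), sem_wt = sem(wt),
             mean_ko = mean(ko), sem_ko = sem(ko),
             fold_change = mean(ko) / mean(wt),
             t_stat = tt$t, df = tt$df, p_value = tt$p,
             significant = tt$p < alpha, alpha = alpha)
}

#' Compare all clusters between groups
#'
#' One [compareGroups()] row per cluster id, in increasing id order. No
#' multiplicity adjustment is applied (each cluster is reported at the raw
#' per-test level).
#'
#' @inheritParams compareGroups
#' @return data.frame with one row per cluster.
#' @export
compareAll <- function(table, alpha = 0.01, welch = FALSE) {
  ids <- sort(unique(table$cluster_id))
  do.call(rbind, lapply(ids, function(j)
    compareGroups(table, j, alpha = alpha, welch = welch)))
}
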