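#' Median and MAD summary table
#'
#' LDV measures are generally non-normal (screened with Shapiro-Wilk), so
#' group summaries are reported as median and unscaled median absolute
#' deviation (no 1.4826 consistency factor), in the "median +/- mad" style.
#'
#' @param values numeric vector.
#' @param group grouping vector of the same length.
#' @return Data frame (group, n, median, mad). Empty groups are omitted with
#'   a warning.
#' @export
median_mad_table <- function(values, group = rep("all", length(values))) {
  stopifnot(length(values) == length(group))
  keep <- !is.na(values)
  if (is.factor(group)) {
    empty <- setdiff(levels(group), unique(as.character(group[keep])))
    if (length(empty)) warning("empty groups omitted: ", paste(empty, collapse = ", "))
  }
  sp <- split(values[keep], as.character(group[keep]))
  out <- data.frame(group = names(sp),
                    n = vapply(sp, length, integer(1)),
                    median = vapply(sp, stats::median, numeric(1)),
                    mad = vapply(sp, function(v) stats::mad(v, constant = 1), numeric(1)))
  rownames(out) <- NULL
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) test of two independent samples. When both groups
#' have at most `exact_max` observations the permutation-exact two-sided p
#' value is computed by complete enumeration of all rank assignments
#' (midranks used for ties, so the exact branch remains valid with tied
#' data); larger samples use the normal approximation with tie-corrected
#' variance and continuity correction. A paired alternative (signed-rank) is
#' available via `paired = TRUE`.
#'
#' @param a,b numeric samples (each >= 3 values).
#' @param exact_max largest per-group n for the exact branch (default 8).
#' @param paired if `TRUE`, a paired signed-rank test (delegated to
#'   [stats::wilcox.test()]).
#' @return List with `statistic` (Mann-Whitney U of sample `a`), `p`,
#'   `method` (`"exact"`, `"normal"` or `"signed-rank"`), `n_a`, `n_b`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 8, paired = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3) stop("each sample needs at least 3 values")
  if (paired) {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    return(list(statistic = unname(wt$statistic), p = wt$p.value,
                method = "signed-rank", n_a = length(a), n_b = length(b)))
  }
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both samples")
    return(list(statistic = na * nb / 2, p = 1, method = "degenerate",
                n_a = na, n_b = nb))
  }
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu_u <- na * nb / 2
  if (na <= exact_max && nb <= exact_max) {
    combos <- utils::combn(na + nb, na)
    us <- colSums(matrix(rk[combos], nrow = na)) - na * (na + 1) / 2
    # two-sided permutation p: assignments at least as extreme about the mean
    p <- mean(abs(us - mu_u) >= abs(u_obs - mu_u) - 1e-9)
    return(list(statistic = u_obs, p = p, method = "exact", n_a = na, n_b = nb))
  }
  n <- na + nb
  ties <- table(pooled)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (u_obs - mu_u - sign(u_obs - mu_u) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = u_obs, p = p, method = "normal", n_a = na, n_b = nb)
}

#' Holm step-down adjustment
#'
#' Family-wise error control: p values are sorted ascending, the i-th
#' smallest multiplied by (m - i + 1), a running maximum enforced, capped at
#' 1, and returned in input order.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return Adjusted p values in input order.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate control: p values sorted ascending, the i-th
#' multiplied by m / i, a running minimum enforced from the top, capped at 1,
#' returned in input order.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return Adjusted p values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson chi-squared test on a categorical contingency table
#'
#' Compares category frequencies (mechanical states, fibrillae erection
#' stages, ...) across groups. Expected counts below 5 set a warning flag but
#' the statistic is still computed.
#'
#' @param table matrix of non-negative integer counts, groups in rows,
#'   categories in columns; >= 2 of each.
#' @return List with `statistic`, `dof` = (r-1)(c-1), `p`,
#'   `low_expected` flag.
#' @export
chi_squared <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) stop("need >= 2 groups and >= 2 categories")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0)) stop("a group has zero total count")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), dof = unname(res$parameter),
       p = res$p.value, low_expected = any(res$expected < 5))
}

significance_band <- function(p_adj) {
  cut(p_adj, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"), right = FALSE)
}

#' Run a family-structured comparison plan
#'
#' Executes a list of pairwise group comparisons with [wilcoxon_rank_sum()],
#' applying Holm correction within each measure's family (comparisons sharing
#' a measure form one family, matching per-panel starring of figure tables).
#'
#' @param plan data frame with columns `measure`, `group_a`, `group_b`.
#' @param data data frame with columns `measure`, `group`, `value`.
#' @param unit `"run"` (default) to test run-level values, or `"animal"` to
#'   first take the median per animal (requires an `animal_id` column in
#'   `data`); the animal-level option avoids pseudo-replication at the cost
#'   of power.
#' @return Data frame with one row per plan row: measure, group_a, group_b,
#'   n_a, n_b, statistic, p_raw, p_adj, band.
#' @export
run_comparison_plan <- function(plan, data, unit = c("run", "animal")) {
  unit <- match.arg(unit)
  stopifnot(all(c("measure", "group_a", "group_b") %in% names(plan)),
            all(c("measure", "group", "value") %in% names(data)))
  if (nrow(plan) == 0) {
    return(data.frame(measure = character(0), group_a = character(0),
                      group_b = character(0), n_a = integer(0),
                      n_b = integer(0), statistic = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      band = character(0)))
  }
  if (unit == "animal") {
    stopifnot("animal_id" %in% names(data))
    agg <- stats::aggregate(value ~ measure + group + animal_id, data, stats::median)
    data <- agg
  }
  missing <- character(0)
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    m <- plan$measure[i]
    va <- data$value[data$measure == m & data$group == plan$group_a[i]]
    vb <- data$value[data$measure == m & data$group == plan$group_b[i]]
    if (length(va) == 0) missing <<- c(missing, paste0(m, "/", plan$group_a[i]))
    if (length(vb) == 0) missing <<- c(missing, paste0(m, "/", plan$group_b[i]))
    list(va = va, vb = vb)
  })
  if (length(missing)) {
    stop("plan references missing measure/group combinations: ",
         paste(unique(missing), collapse = ", "))
  }
  res <- lapply(rows, function(r) wilcoxon_rank_sum(r$va, r$vb))
  out <- data.frame(measure = plan$measure, group_a = plan$group_a,
                    group_b = plan$group_b,
                    n_a = vapply(res, function(r) r$n_a, numeric(1)),
                    n_b = vapply(res, function(r) r$n_b, numeric(1)),
                    statistic = vapply(res, function(r) r$statistic, numeric(1)),
                    p_raw = vapply(res, function(r) r$p, numeric(1)))
  out$p_adj <- stats::ave(out$p_raw, out$measure, FUN = holm_adjust)
  out$band <- as.character(significance_band(out$p_adj))
  out
}
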