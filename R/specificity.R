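#' Jensen-Shannon distance between two probability vectors
#'
#' Square root of the Jensen-Shannon divergence with base-2 logarithms,
#' so the distance is a metric on the simplex ranging from 0 (identical)
#' to exactly 1 (disjoint supports). `0 * log 0` is taken as 0.
#'
#' @param p,q nonnegative vectors of equal length, each summing to 1
#'   (within 1e-6).
#' @return the distance, in `[0, 1]`.
#' @export
js_distance <- function(p, q) {
  if (length(p) != length(q)) stop_domain("length mismatch")
  if (any(p < 0) || any(q < 0)) stop_domain("negative entries")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop_domain("inputs must sum to 1")
  }
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * (log2(a[i]) - log2(b[i])))
  }
  d2 <- (kl(p, m) + kl(q, m)) / 2
  sqrt(max(0, min(1, d2)))
}

#' Tissue-specificity scores
#'
#' Averages replicate columns per tissue, normalizes each circRNA's
#' tissue-mean profile to probabilities, and scores each tissue `t` as
#' `S_t = 1 - JSD(profile, e_t)` where `e_t` is the perfectly specific
#' unit profile for `t`. `S` ranges from 0 (no expression in `t`) to 1
#' (expressed exclusively in `t`).
#'
#' @param mat expression matrix (rows = circ_id, columns = samples),
#'   e.g. [expression_matrix()] output.
#' @param tissues character vector assigning each column to a tissue.
#' @return list with
#'   * `scores`: matrix of per-tissue `S_t` (rows = scored circ_id);
#'   * `best`: `data.frame` (`circ_id`, `best_tissue`, `best_score`,
#'     `max_level` = maximum tissue-mean SRPBM);
#'   * `tissue_means`: the averaged matrix (all rows);
#'   * `excluded`: circ_ids dropped for all-zero profiles.
#' @export
specificity_scores <- function(mat, tissues) {
  if (ncol(mat) != length(tissues)) stop_validation("one tissue label per column")
  tlev <- unique(tissues)
  means <- sapply(tlev, function(t) {
    cols <- which(tissues == t)
    if (length(cols) == 1L) mat[, cols] else rowMeans(mat[, cols, drop = FALSE])
  })
  if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                           dimnames = list(rownames(mat), tlev))
  tot <- rowSums(means)
  excluded <- rownames(means)[tot == 0]
  keep <- tot > 0
  prof <- means[keep, , drop = FALSE] / tot[keep]
  scores <- matrix(NA_real_, nrow(prof), length(tlev),
                   dimnames = list(rownames(prof), tlev))
  for (t in seq_along(tlev)) {
    e_t <- as.numeric(seq_along(tlev) == t)
    scores[, t] <- apply(prof, 1L, function(p) 1 - js_distance(p, e_t))
  }
  best_idx <- apply(scores, 1L, which.max)
  best <- data.frame(circ_id = rownames(prof),
                     best_tissue = tlev[best_idx],
                     best_score = scores[cbind(seq_len(nrow(scores)), best_idx)],
                     max_level = apply(means[keep, , drop = FALSE], 1L, max),
                     stringsAsFactors = FALSE)
  rownames(best) <- NULL
  list(scores = scores, best = best, tissue_means = means, excluded = excluded)
}

#' Filter tissue-specific circRNAs
#'
#' Keeps circRNAs whose best specificity score reaches `min_score` and
#' whose maximum tissue-mean SRPBM reaches an expression floor: with
#' `level_rule = "mean+2sd"` the floor is the grand mean plus twice the
#' standard deviation of all circRNA-by-tissue mean SRPBM values; a
#' numeric `level_rule` is used directly as the floor.
#'
#' @param spec result of [specificity_scores()].
#' @param min_score minimum best score (default 0.5).
#' @param level_rule `"mean+2sd"` (default) or a numeric threshold.
#' @return the qualifying rows of `spec$best`.
#' @export
specific_circ_filter <- function(spec, min_score = 0.5, level_rule = "mean+2sd") {
  if (identical(level_rule, "mean+2sd")) {
    v <- as.numeric(spec$tissue_means)
    floor_level <- mean(v) + 2 * sd(v)
  } else {
    floor_level <- as.numeric(level_rule)
  }
  out <- spec$best[spec$best$best_score >= min_score &
                     spec$best$max_level >= floor_level, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Poisson read cutoff
#'
#' Fits a Poisson rate as the mean of the supplied per-circRNA read
#' counts and returns the smallest integer cutoff `c >= 1` such that
#' `P(X < c) >= retain` — the read number that "leaves" a fraction
#' `retain` of the fitted distribution below it.
#'
#' @param read_counts nonnegative counts, at least one positive.
#' @param retain retained mass below the cutoff (default 0.99).
#' @return integer cutoff.
#' @export
poisson_cutoff <- function(read_counts, retain = 0.99) {
  if (any(read_counts < 0)) stop_domain("counts must be nonnegative")
  if (all(read_counts == 0)) stop_domain("all-zero counts: no rate to fit")
  lambda <- mean(read_counts)
  cutoff <- 1L
  while (ppois(cutoff - 1L, lambda) < retain) cutoff <- cutoff + 1L
  cutoff
}

#' Condition-specific circRNAs
#'
#' A circRNA is condition-specific when it has at least `cutoff` unique
#' back-spliced reads in one condition and none at all in the other.
#'
#' @param cancer_counts,normal_counts named integer vectors of per-circRNA
#'   unique back-spliced read counts (names aligned by union).
#' @param cutoff read cutoff (default 4, see [poisson_cutoff()]).
#' @return list with `cancer_specific` and `normal_specific` circ_id sets.
#' @export
condition_specific <- function(cancer_counts, normal_counts, cutoff = 4L) {
  ids <- union(names(cancer_counts), names(normal_counts))
  cc <- setNames(rep(0L, length(ids)), ids)
  nc <- cc
  cc[names(cancer_counts)] <- cancer_counts
  nc[names(normal_counts)] <- normal_counts
  list(cancer_specific = ids[cc >= cutoff & nc == 0L],
       normal_specific = ids[nc >= cutoff & cc == 0L])
}

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Exact p-value by complete enumeration of group labelings when
#' `length(x) + length(y) <= exact_max` (midranks handle ties; the
#' two-sided p is the probability of a rank sum at least as far from its
#' null mean as observed); otherwise the normal approximation with tie
#' and continuity corrections. `U` is reported for `x`.
#'
#' @param x,y nonempty numeric vectors.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact_max sample-size bound for the enumeration branch.
#' @return list with `statistic` (U for x) and `p.value`.
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "less", "greater"),
                          exact_max = 12L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) stop_domain("empty group")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  u_obs <- w_obs - nx * (nx + 1) / 2
  if (n <= exact_max) {
    combs <- combn(n, nx)
    w_all <- colSums(matrix(r[combs], nrow = nx))
    mu <- nx * (n + 1) / 2
    eps <- 1e-9
    p <- switch(alternative,
                two.sided = mean(abs(w_all - mu) >= abs(w_obs - mu) - eps),
                greater = mean(w_all >= w_obs - eps),
                less = mean(w_all <= w_obs + eps))
    return(list(statistic = u_obs, p.value = p, method = "exact enumeration"))
  }
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative,
                exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       method = "normal approximation")
}

#' Pearson correlation with t-distribution p-value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r` and `p.value`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_domain("need equal lengths >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) stop_domain("zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value)
}

#' Differential circRNA abundance between paired samples
#'
#' For each tissue pair, restricts to circRNAs detected (SRPBM above
#' `detect_min` in either member), computes per-circRNA
#' `log2((SRPBM_case + eps) / (SRPBM_control + eps))`, tests case versus
#' control SRPBM vectors with [rank_sum_test()], and reports the median
#' log2 fold-change, its direction, and the p-value.
#'
#' @param mat expression matrix (rows = circ_id, columns = samples).
#' @param pairs `data.frame` with columns `tissue`, `case`, `control`
#'   naming matrix columns.
#' @param eps pseudo-SRPBM guarding zero denominators (default 0.01).
#' @param detect_min detection filter on SRPBM (default 1, strict).
#' @return `data.frame` per tissue: `tissue`, `n_circ`,
#'   `median_log2fc`, `direction` (`"up"`/`"down"`/`"none"`/
#'   `"insufficient"`), `p.value`.
#' @export
differential_abundance <- function(mat, pairs, eps = 0.01, detect_min = 1.0) {
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    ca <- mat[, pairs$case[i]]
    co <- mat[, pairs$control[i]]
    keep <- ca > detect_min | co > detect_min
    if (sum(keep) < 2L) {
      return(data.frame(tissue = pairs$tissue[i], n_circ = sum(keep),
                        median_log2fc = NA_real_, direction = "insufficient",
                        p.value = NA_real_, stringsAsFactors = FALSE))
    }
    lfc <- log2((ca[keep] + eps) / (co[keep] + eps))
    med <- median(lfc)
    rs <- rank_sum_test(ca[keep], co[keep])
    data.frame(tissue = pairs$tissue[i], n_circ = sum(keep),
               median_log2fc = med,
               direction = if (med > 0) "up" else if (med < 0) "down" else "none",
               p.value = rs$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
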