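#' Competition-assay time course
#'
#' @param generations Elapsed generations at each sample; strictly
#'   increasing.
#' @param count_query,count_reference Cells assayed (or frequencies) per
#'   genotype at each sample; positive at every time point.
#' @return A data.frame of class `competition_timecourse`.
#' @export
competition_timecourse <- function(generations, count_query,
                                   count_reference) {
  n <- length(generations)
  if (length(count_query) != n || length(count_reference) != n)
    stop("generations and counts must have equal length", call. = FALSE)
  if (n < 3)
    stop("at least 3 time points required for fitness estimation",
         call. = FALSE)
  if (any(diff(generations) <= 0))
    stop("generations must be strictly increasing", call. = FALSE)
  zero <- which(count_query <= 0 | count_reference <= 0)
  if (length(zero) > 0)
    stop("non-positive count at time point(s) ",
         paste(zero, collapse = ", "),
         " (generation ", paste(generations[zero], collapse = ", "),
         "): log ratio undefined", call. = FALSE)
  structure(data.frame(generations = generations,
                       count_query = count_query,
                       count_reference = count_reference),
            class = c("competition_timecourse", "data.frame"))
}

#' Selection coefficient from a competition assay
#'
#' Ordinary least-squares slope of `ln(count_query / count_reference)`
#' against elapsed generations: the per-generation selection coefficient s.
#' The 95% confidence interval uses the slope's standard error and the
#' t-distribution with (n - 2) degrees of freedom, and is reported only when
#' at least 5 time points were sampled (with fewer points the interval is
#' too unstable to quote).
#'
#' @param tc A [competition_timecourse()], or a data.frame with columns
#'   `generations`, `count_query`, `count_reference`. Frequencies work
#'   identically to counts (the ratio is unchanged).
#' @return A list of class `fitness_estimate`: `s`, `se`, `ci95` (length-2
#'   bounds, `NA` when suppressed), `ci_reported`, `n_points`, `intercept`.
#' @examples
#' tc <- competition_timecourse(c(0, 3, 6, 9, 12, 15),
#'                              0.1 * exp(0.05 * c(0, 3, 6, 9, 12, 15)),
#'                              rep(1, 6))
#' estimate_fitness(tc)$s  # 0.05
#' @export
estimate_fitness <- function(tc) {
  # re-validate regardless of class: simulated extreme time courses can
  # carry zero counts
  tc <- competition_timecourse(tc$generations, tc$count_query,
                               tc$count_reference)
  n <- nrow(tc)
  lr <- log(tc$count_query / tc$count_reference)
  fit <- stats::lm(lr ~ tc$generations)
  s <- unname(stats::coef(fit)[2])
  se <- unname(sqrt(diag(stats::vcov(fit)))[2])
  ci_reported <- n >= 5
  ci95 <- if (ci_reported) {
    tcrit <- stats::qt(0.975, df = n - 2)
    c(s - tcrit * se, s + tcrit * se)
  } else c(NA_real_, NA_real_)
  structure(list(s = s, se = se, ci95 = ci95, ci_reported = ci_reported,
                 n_points = n, intercept = unname(stats::coef(fit)[1])),
            class = "fitness_estimate")
}

#' @export
print.fitness_estimate <- function(x, ...) {
  if (x$ci_reported) {
    cat(sprintf("s = %.4g per generation (95%% CI %.4g to %.4g, n = %d)\n",
                x$s, x$ci95[1], x$ci95[2], x$n_points))
  } else {
    cat(sprintf("s = %.4g per generation (n = %d; * CI not reported, < 5 time points)\n",
                x$s, x$n_points))
  }
  invisible(x)
}

#' Per-gene table of promoter affinity and expression change
#'
#' @param gene Unique gene identifiers.
#' @param affinity Promoter affinity score for the factor (arbitrary units).
#' @param lfc Log2 fold change of expression versus the ancestor.
#' @param is_target Logical: membership in the focal gene set (e.g. the
#'   experimentally confirmed NCR targets).
#' @return A data.frame of class `gene_table`.
#' @export
gene_table <- function(gene, affinity, lfc, is_target) {
  n <- length(gene)
  if (length(affinity) != n || length(lfc) != n || length(is_target) != n)
    stop("all columns must have equal length", call. = FALSE)
  if (anyDuplicated(gene)) stop("duplicated gene ids", call. = FALSE)
  if (sum(is_target) < 3)
    stop("focal gene set must contain at least 3 genes", call. = FALSE)
  structure(data.frame(gene = gene, affinity = affinity, lfc = lfc,
                       is_target = as.logical(is_target)),
            class = c("gene_table", "data.frame"))
}

#' Gene-set permutation test for affinity-expression correlation
#'
#' Computes the correlation between promoter affinity and expression fold
#' change on the focal gene set, then builds a null distribution by drawing
#' `n_perm` random gene sets of the same size (without replacement within
#' each draw) from all genes and recomputing the correlation. The empirical
#' p-value uses the add-one convention,
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`, one-sided toward
#' positive association by default (the hypothesis is that higher affinity
#' goes with higher expression); `alternative = "two.sided"` compares
#' absolute values.
#'
#' @param table A [gene_table()] (or data.frame with columns `affinity`,
#'   `lfc`, `is_target`).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional RNG seed for reproducible draws.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param include_focal Draw null sets from all genes including the focal
#'   genes themselves (default TRUE) or from background genes only.
#' @return A list of class `permutation_result`: `statistic_observed`,
#'   `method`, `null_stats`, `p_value`, `n_perm`, `seed`, `alternative`,
#'   `n_focal`, `n_genes`.
#' @export
correlation_with_permutation <- function(table,
                                         method = c("spearman", "pearson"),
                                         n_perm = 10000, seed = NULL,
                                         alternative = c("greater",
                                                         "two.sided"),
                                         include_focal = TRUE) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  focal <- which(table$is_target)
  m <- length(focal)
  n <- nrow(table)
  if (m < 3) stop("focal gene set must contain at least 3 genes",
                  call. = FALSE)
  if (n <= m) stop("need more genes than the focal set size", call. = FALSE)
  x <- table$affinity; y <- table$lfc
  if (stats::sd(x[focal]) == 0 || stats::sd(y[focal]) == 0)
    stop("zero variance in affinity or fold change on the focal set",
         call. = FALSE)
  obs <- stats::cor(x[focal], y[focal], method = method)
  if (!is.null(seed)) set.seed(seed)
  pool <- if (include_focal) seq_len(n) else setdiff(seq_len(n), focal)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    idx <- sample(pool, m)
    stats::cor(x[idx], y[idx], method = method)
  }, numeric(1))
  exceed <- if (alternative == "greater") sum(null_stats >= obs)
            else sum(abs(null_stats) >= abs(obs))
  p <- (1 + exceed) / (n_perm + 1)
  structure(list(statistic_observed = obs, method = method,
                 null_stats = null_stats, p_value = p, n_perm = n_perm,
                 seed = seed, alternative = alternative, n_focal = m,
                 n_genes = n),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("%s correlation on focal set (%d of %d genes) = %.3f; permutation p = %.4g (%d draws, %s)\n",
              x$method, x$n_focal, x$n_genes, x$statistic_observed,
              x$p_value, x$n_perm, x$alternative))
  invisible(x)
}

#' Normalize GFP reporter intensities by forward scatter
#'
#' Per flow-cytometry event: `log10(gfp / fsc)`. Events with non-positive
#' GFP intensity are dropped (their count recorded in attribute
#' `n_dropped`); non-positive forward scatter is a validation error.
#'
#' @param gfp GFP intensity per event.
#' @param fsc Forward scatter (FSC-A) per event; must be > 0.
#' @return Numeric vector of normalized values with attribute `n_dropped`.
#' @examples
#' normalize_gfp(c(1000, 100), c(100, 100))  # 1, 0
#' @export
normalize_gfp <- function(gfp, fsc) {
  if (length(gfp) != length(fsc))
    stop("gfp and fsc must have equal length", call. = FALSE)
  if (any(fsc <= 0))
    stop("forward scatter values must be strictly positive", call. = FALSE)
  keep <- gfp > 0
  out <- log10(gfp[keep] / fsc[keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}
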