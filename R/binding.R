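#' EMSA dose-response table
#'
#' Bundles a protein dose series with the measured fraction of DNA bound.
#' Fractions slightly outside [0, 1] (gel densitometry noise) are retained
#' and flagged rather than rejected.
#'
#' @param doses Protein amounts (ug), ordered, non-negative.
#' @param fractions Fraction of DNA bound at each dose.
#' @param label Optional motif/protein identifier.
#' @return A data.frame of class `dose_response` with columns `dose_ug` and
#'   `fraction_bound`, attributes `label` and `out_of_bounds` (logical per
#'   row).
#' @export
dose_response <- function(doses, fractions, label = "") {
  if (length(doses) != length(fractions))
    stop("doses and fractions must have equal length", call. = FALSE)
  if (any(!is.finite(doses)) || any(doses < 0))
    stop("doses must be finite and non-negative", call. = FALSE)
  if (is.unsorted(doses)) {
    o <- order(doses)
    doses <- doses[o]; fractions <- fractions[o]
  }
  oob <- fractions < 0 | fractions > 1
  if (any(oob))
    warning(sum(oob), " fraction(s) outside [0, 1] retained and flagged",
            call. = FALSE)
  structure(data.frame(dose_ug = doses, fraction_bound = fractions),
            label = label, out_of_bounds = oob,
            class = c("dose_response", "data.frame"))
}

#' Fraction of DNA bound from gel band intensities
#'
#' The bound fraction is the intensity of the shifted (protein-bound) band
#' over the total intensity of all bands in the lane.
#'
#' @param bound_intensity,unbound_intensity Non-negative band intensities
#'   (vectorised).
#' @return `bound / (bound + unbound)`, in [0, 1].
#' @examples
#' fraction_bound(30, 70)  # 0.3
#' @export
fraction_bound <- function(bound_intensity, unbound_intensity) {
  if (any(bound_intensity < 0) || any(unbound_intensity < 0))
    stop("band intensities must be non-negative", call. = FALSE)
  total <- bound_intensity + unbound_intensity
  if (any(total == 0))
    stop("total band intensity is zero: fraction bound undefined",
         call. = FALSE)
  bound_intensity / total
}

#' Predicted fraction bound under the two-parameter Michaelis-Menten model
#'
#' `Fr = frmax * x / (x + kx)`: saturating binding with upper asymptote
#' `frmax` and half-maximal dose `kx`.
#'
#' @param frmax Upper limit of the fraction bound.
#' @param kx Dose at half-maximal binding (ug); must be > 0.
#' @param doses Protein doses (ug).
#' @return Predicted fractions, monotone non-decreasing in dose and bounded
#'   above by `frmax`.
#' @examples
#' predict_fraction(0.8, 5, c(0, 5, 1e6))
#' @export
predict_fraction <- function(frmax, kx, doses) {
  if (!is.finite(kx) || kx <= 0)
    stop("kx must be a positive finite number", call. = FALSE)
  frmax * doses / (doses + kx)
}

#' Fit the two-parameter Michaelis-Menten binding model to EMSA data
#'
#' Nonlinear least squares for `Fr = Frmax * x / (x + Kx)` via
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]). Standard errors come from the
#' estimated covariance at the optimum; per-parameter p-values from
#' t-statistics on (n - 2) degrees of freedom. Deterministic starting values:
#' `frmax0` = maximum observed fraction, `kx0` = dose nearest half of
#' `frmax0` (no random restarts).
#'
#' @param data A [dose_response()] object, or a data.frame with columns
#'   `dose_ug` and `fraction_bound`.
#' @return A list of class `mm_fit`: `frmax`, `kx`, `se_frmax`, `se_kx`,
#'   `p_frmax`, `p_kx`, `rss`, `fitted`, `df_residual`, `n`,
#'   `out_of_bounds_flagged`.
#' @examples
#' d <- dose_response(c(0, 1, 5, 10, 15, 20), predict_fraction(0.8, 5, c(0, 1, 5, 10, 15, 20)))
#' fit_michaelis_menten(d)
#' @export
fit_michaelis_menten <- function(data) {
  if (!inherits(data, "dose_response"))
    data <- dose_response(data$dose_ug, data$fraction_bound)
  x <- data$dose_ug
  y <- data$fraction_bound
  n <- length(x)
  if (n < 3)
    stop("at least 3 dose points required to fit two parameters",
         call. = FALSE)
  if (all(x == 0))
    stop("at least one dose must be positive", call. = FALSE)
  frmax0 <- max(y)
  if (frmax0 <= 0) frmax0 <- 0.5
  kx0 <- x[which.min(abs(y - frmax0 / 2))]
  if (kx0 <= 0) kx0 <- max(x) / 4
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ frmax * x / (x + kx),
                      start = list(frmax = frmax0, kx = kx0),
                      lower = c(frmax = 0, kx = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("Michaelis-Menten fit failed to converge: ", conditionMessage(e),
           call. = FALSE))
  est <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(diag(vc))
  df <- n - 2L
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), df)
  fitted <- predict_fraction(est[["frmax"]], est[["kx"]], x)
  structure(list(frmax = unname(est[["frmax"]]), kx = unname(est[["kx"]]),
                 se_frmax = unname(se[1]), se_kx = unname(se[2]),
                 p_frmax = unname(pval[1]), p_kx = unname(pval[2]),
                 rss = sum((y - fitted)^2), fitted = fitted,
                 df_residual = df, n = n,
                 out_of_bounds_flagged = any(attr(data, "out_of_bounds")),
                 label = attr(data, "label")),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten binding fit%s (n = %d)\n",
              if (nzchar(x$label %||% "")) paste0(" [", x$label, "]") else "",
              x$n))
  cat(sprintf("  Frmax = %.4g (se %.3g, p = %.3g)\n", x$frmax, x$se_frmax,
              x$p_frmax))
  cat(sprintf("  Kx    = %.4g ug (se %.3g, p = %.3g)\n", x$kx, x$se_kx,
              x$p_kx))
  cat(sprintf("  RSS = %.4g\n", x$rss))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Are both binding parameters significant?
#'
#' Convenience check used when reporting EMSA fits: both `Frmax` and `Kx`
#' must reach significance (default threshold p < 0.02) for the binding curve
#' to count as reliably estimated.
#'
#' @param fit An `mm_fit` object.
#' @param alpha Significance threshold (default 0.02).
#' @return Logical.
#' @export
mm_fit_significant <- function(fit, alpha = 0.02) {
  stopifnot(inherits(fit, "mm_fit"))
  is.finite(fit$p_frmax) && is.finite(fit$p_kx) &&
    fit$p_frmax < alpha && fit$p_kx < alpha
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Position weight matrix from top-scoring k-mers
#'
#' Selects the `top_n` k-mers by score (ties at the boundary broken
#' lexicographically, so selection is deterministic), aligns them ungapped at
#' offset zero against the top-scoring k-mer -- optionally choosing for each
#' k-mer the orientation (forward or reverse complement) with more identical
#' positions -- and tallies per-position base frequencies.
#'
#' @param kmers Character vector of equal-length DNA strings.
#' @param scores Numeric scores (e.g. PBM E-scores), one per k-mer.
#' @param top_n How many k-mers to use (default 10).
#' @param revcomp Consider reverse-complement orientation (default TRUE).
#' @return A list of class `pwm`: `width` and `columns`, a 4 x width matrix
#'   of frequencies over rows A, C, G, T; every column sums to 1.
#' @examples
#' pwm_from_top_kmers(c("AGATAAGA", "AGCTAAGA"), c(0.49, 0.45), top_n = 2)
#' @export
pwm_from_top_kmers <- function(kmers, scores, top_n = 10, revcomp = TRUE) {
  if (length(kmers) == 0) stop("no k-mers supplied", call. = FALSE)
  if (length(kmers) != length(scores))
    stop("kmers and scores must have equal length", call. = FALSE)
  kmers <- toupper(kmers)
  w <- unique(nchar(kmers))
  if (length(w) != 1) stop("k-mers must all have the same length",
                           call. = FALSE)
  if (any(grepl("[^ACGT]", kmers)))
    stop("k-mers must contain only A, C, G, T", call. = FALSE)
  if (length(kmers) < top_n) {
    warning("fewer than top_n = ", top_n, " k-mers available; using all ",
            length(kmers), call. = FALSE)
    top_n <- length(kmers)
  }
  o <- order(-scores, kmers)  # descending score, lexicographic tie-break
  sel <- kmers[o][seq_len(top_n)]
  anchor <- sel[1]
  aligned <- vapply(sel, function(k) {
    if (!revcomp) return(k)
    rc <- reverse_complement(k)
    id_f <- sum(strsplit(k, "")[[1]] == strsplit(anchor, "")[[1]])
    id_r <- sum(strsplit(rc, "")[[1]] == strsplit(anchor, "")[[1]])
    if (id_r > id_f) rc else k  # forward wins ties
  }, character(1), USE.NAMES = FALSE)
  bases <- c("A", "C", "G", "T")
  mat <- matrix(0, nrow = 4, ncol = w, dimnames = list(bases, NULL))
  chars <- do.call(rbind, strsplit(aligned, ""))
  for (j in seq_len(w)) {
    tab <- table(factor(chars[, j], levels = bases))
    mat[, j] <- as.numeric(tab) / top_n
  }
  structure(list(width = w, columns = mat), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM, width", x$width, "\n")
  print(round(x$columns, 3))
  invisible(x)
}
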