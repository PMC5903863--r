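# Synthetic-data generators with known ground truth. Every generator is a
# pure function of its arguments plus `seed`: the same call with the same
# seed returns bit-identical output. Defaults mirror the study conditions
# the analyses assume (six-point EMSA dose series, 42-sequence alignment,
# ~6000-gene background with a 41-gene focal set, 1:9 mixing at depth
# 10,000 cells).

#' Simulate EMSA dose-response tables
#'
#' Fractions bound follow the two-parameter Michaelis-Menten curve
#' `frmax * x / (x + kx)` plus i.i.d. Gaussian measurement noise. Values
#' pushed outside [0, 1] by noise are retained and flagged (as real gel
#' densitometry is), never clipped.
#'
#' @param frmax True upper limit of fraction bound, in (0, 1].
#' @param kx True half-maximal dose (ug), > 0.
#' @param doses Dose series (ug); default the six-point series
#'   0, 1, 5, 10, 15, 20.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param n_replicates Number of independent tables to generate.
#' @param seed Optional RNG seed.
#' @return A list of [dose_response()] objects, one per replicate.
#' @examples
#' gen_emsa_data(0.8, 5, noise_sd = 0)[[1]]
#' @export
gen_emsa_data <- function(frmax, kx, doses = c(0, 1, 5, 10, 15, 20),
                          noise_sd = 0.02, n_replicates = 1, seed = NULL) {
  if (!is.finite(frmax) || frmax <= 0 || frmax > 1)
    stop("frmax must lie in (0, 1]", call. = FALSE)
  if (!is.finite(kx) || kx <= 0) stop("kx must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  truth <- predict_fraction(frmax, kx, doses)
  lapply(seq_len(n_replicates), function(r) {
    fr <- truth + stats::rnorm(length(doses), 0, noise_sd)
    suppressWarnings(dose_response(doses, fr,
                                   label = sprintf("sim_rep%d", r)))
  })
}

random_sense_codon <- function(n) {
  sample(sense_codons(), n, replace = TRUE)
}

syn_neighbors_of <- function(codon) {
  aa <- translate_codon(codon)
  nb <- codon_neighbors(codon)
  nb[vapply(nb, function(x) translate_codon(x) == aa, logical(1))]
}

nonsyn_neighbors_of <- function(codon) {
  aa <- translate_codon(codon)
  nb <- codon_neighbors(codon)
  nb[vapply(nb, function(x) {
    a <- translate_codon(x); a != aa && a != "*"
  }, logical(1))]
}

#' Simulate a codon alignment with a purifying-selection window
#'
#' Builds a random sense-codon ancestor and derives `n_seqs` sequences by an
#' independent, single-hit-per-codon mutation model: for each codon of each
#' sequence, at most one event occurs -- synonymous with probability
#' `syn_rate`, nonsynonymous with probability `nonsyn_rate` (or
#' `window_nonsyn_rate` inside `constrained_window`, emulating a conserved
#' domain such as a DNA binding domain under purifying selection). All
#' mutations are single-base changes to sense codons; stop codons are never
#' introduced. Codons without a synonymous neighbour (ATG, TGG) silently
#' skip synonymous events.
#'
#' @param ancestor_len_codons Alignment length in codons.
#' @param n_seqs Number of sequences (default 42).
#' @param syn_rate Per-codon probability of a synonymous change, in [0, 1).
#' @param nonsyn_rate Per-codon probability of a nonsynonymous change
#'   outside the window, in [0, 1).
#' @param constrained_window Integer range of codon positions (e.g.
#'   `11:30`) where the nonsynonymous rate is replaced; `NULL` for none.
#' @param window_nonsyn_rate Nonsynonymous rate inside the window
#'   (typically much smaller than `nonsyn_rate`).
#' @param seed Optional RNG seed.
#' @return A [codon_alignment()] with attributes `ancestor` (codon vector)
#'   and `constrained_window`.
#' @examples
#' aln <- gen_codon_alignment(30, n_seqs = 6, syn_rate = 0.1,
#'                            nonsyn_rate = 0.1, seed = 1)
#' dnds_profile(aln)[1:3, ]
#' @export
gen_codon_alignment <- function(ancestor_len_codons, n_seqs = 42,
                                syn_rate = 0.05, nonsyn_rate = 0.05,
                                constrained_window = NULL,
                                window_nonsyn_rate = 0, seed = NULL) {
  rates <- c(syn_rate, nonsyn_rate, window_nonsyn_rate)
  if (any(rates < 0) || any(rates >= 1))
    stop("mutation rates must lie in [0, 1)", call. = FALSE)
  if (syn_rate + max(nonsyn_rate, window_nonsyn_rate) >= 1)
    stop("syn_rate + nonsyn_rate must be < 1 (single hit per codon)",
         call. = FALSE)
  if (!is.null(constrained_window) &&
      (min(constrained_window) < 1 ||
       max(constrained_window) > ancestor_len_codons))
    stop("constrained_window must lie within the sequence", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ancestor <- random_sense_codon(ancestor_len_codons)
  in_window <- rep(FALSE, ancestor_len_codons)
  if (!is.null(constrained_window)) in_window[constrained_window] <- TRUE
  seqs <- vapply(seq_len(n_seqs), function(i) {
    cod <- ancestor
    for (p in seq_len(ancestor_len_codons)) {
      ns_rate <- if (in_window[p]) window_nonsyn_rate else nonsyn_rate
      u <- stats::runif(1)
      if (u < syn_rate) {
        syn <- syn_neighbors_of(cod[p])
        if (length(syn) > 0) cod[p] <- sample(syn, 1)
      } else if (u < syn_rate + ns_rate) {
        ns <- nonsyn_neighbors_of(cod[p])
        if (length(ns) > 0) cod[p] <- sample(ns, 1)
      }
    }
    paste(cod, collapse = "")
  }, character(1))
  aln <- codon_alignment(seqs, ids = sprintf("isolate_%02d", seq_len(n_seqs)))
  attr(aln, "ancestor") <- ancestor
  attr(aln, "constrained_window") <- constrained_window
  aln
}

#' Simulate a per-gene affinity/fold-change table
#'
#' Focal-set genes draw (affinity, lfc) pairs from a standard bivariate
#' normal with correlation `true_corr`; background genes are uncorrelated.
#' `noise_sd` adds extra independent Gaussian noise to `lfc` on top of the
#' unit-variance draw (0 keeps the focal correlation exact at
#' `true_corr = 1`).
#'
#' @param n_genes Total gene count (default 6000).
#' @param n_target Focal set size (default 41), 3 <= n_target < n_genes.
#' @param true_corr Correlation of the focal set's generative distribution,
#'   |true_corr| <= 1.
#' @param noise_sd Extra noise on `lfc` (>= 0).
#' @param seed Optional RNG seed.
#' @return A [gene_table()].
#' @export
gen_gene_table <- function(n_genes = 6000, n_target = 41, true_corr = 0.5,
                           noise_sd = 0, seed = NULL) {
  if (abs(true_corr) > 1) stop("|true_corr| must be <= 1", call. = FALSE)
  if (n_target < 3 || n_target >= n_genes)
    stop("need 3 <= n_target < n_genes", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  affinity <- stats::rnorm(n_genes)
  lfc <- stats::rnorm(n_genes)
  focal <- seq_len(n_target)  # ids are arbitrary; first m genes are focal
  lfc[focal] <- true_corr * affinity[focal] +
    sqrt(1 - true_corr^2) * lfc[focal]
  if (noise_sd > 0) lfc <- lfc + stats::rnorm(n_genes, 0, noise_sd)
  gene_table(gene = sprintf("gene_%04d", seq_len(n_genes)),
             affinity = affinity, lfc = lfc,
             is_target = seq_len(n_genes) %in% focal)
}

#' Simulate a competition-assay time course
#'
#' The true genotype ratio follows `init_ratio * exp(s_true * t)`; the query
#' frequency is `ratio / (1 + ratio)`. At finite `depth`, observed counts
#' are binomial draws of `depth` cells per time point; `depth = Inf` is the
#' exact mode returning expected frequencies (no sampling), from which
#' [estimate_fitness()] recovers `s_true` exactly.
#'
#' @param s_true True selection coefficient per generation.
#' @param init_ratio Initial query:reference ratio (default 1/9, the 1:9
#'   mixing convention).
#' @param generation_points Increasing vector of sampled generations.
#' @param depth Cells assayed per time point (default 10000), or `Inf`.
#' @param seed Optional RNG seed.
#' @return A [competition_timecourse()] with attribute `s_true`.
#' @examples
#' tc <- gen_competition(0.1, depth = Inf)
#' estimate_fitness(tc)$s  # exactly 0.1
#' @export
gen_competition <- function(s_true, init_ratio = 1 / 9,
                            generation_points = seq(0, 18, by = 3),
                            depth = 10000, seed = NULL) {
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (any(diff(generation_points) <= 0))
    stop("generation_points must be strictly increasing", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ratio <- init_ratio * exp(s_true * generation_points)
  freq <- ratio / (1 + ratio)
  if (any(freq <= 0) || any(freq >= 1))
    warning("query frequency numerically 0 or 1 at some time point; ",
            "zero counts possible downstream", call. = FALSE)
  if (is.infinite(depth)) {
    q <- freq; r <- 1 - freq
  } else {
    q <- stats::rbinom(length(freq), depth, freq)
    r <- depth - q
  }
  # constructed directly: extreme frequencies may legitimately yield zero
  # counts here (warned above); the estimation path rejects them
  tc <- structure(data.frame(generations = generation_points,
                             count_query = q, count_reference = r),
                  class = c("competition_timecourse", "data.frame"))
  attr(tc, "s_true") <- s_true
  tc
}

#' Simulate a noisy observed trajectory of the I1-FFL
#'
#' Integrates the model and adds Gaussian observation noise to the sampled
#' species levels. Noise affects observations only, never the dynamics.
#'
#' @param params An [ffl_params()] object.
#' @param obs_noise_sd Observation noise standard deviation (>= 0).
#' @param sample_times Non-negative times at which to record the state.
#' @param seed Optional RNG seed.
#' @return A data.frame with columns `time`, `gat1`, `dal80`, `mep2`
#'   (observed) and attribute `truth` (the noise-free table).
#' @export
gen_ffl_timecourse <- function(params, obs_noise_sd = 0,
                               sample_times = seq(0, 10, by = 0.5),
                               seed = NULL) {
  if (any(sample_times < 0))
    stop("sample_times must be non-negative", call. = FALSE)
  if (obs_noise_sd < 0) stop("obs_noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- as_ffl_params(params)
  y0 <- c(gat1 = p$gat1, dal80 = 0, mep2 = 0)
  times <- sort(unique(c(0, sample_times)))
  sol <- deSolve::ode(y = y0, times = times, func = ffl_derivs, parms = p,
                      rtol = 1e-9, atol = 1e-9)
  truth <- as.data.frame(sol)[match(sample_times, times), ]
  rownames(truth) <- NULL
  obs <- truth
  if (obs_noise_sd > 0) {
    k <- nrow(obs)
    for (col in c("gat1", "dal80", "mep2"))
      obs[[col]] <- obs[[col]] + stats::rnorm(k, 0, obs_noise_sd)
  }
  attr(obs, "truth") <- truth
  obs
}
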