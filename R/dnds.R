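# Per-codon dN/dS profiling with Nei-Gojobori-style counting:
# potential sites from one-step mutational neighbourhoods, observed
# substitutions averaged over all single-step pathways between codon pairs
# (pathways through stop codons excluded and the rest re-weighted equally).

.dnds_cache <- new.env(parent = emptyenv())

genetic_code <- function() Biostrings::GENETIC_CODE

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

translate_codon <- function(codon) {
  aa <- unname(genetic_code()[codon])
  if (is.na(aa)) stop("invalid codon '", codon, "'", call. = FALSE)
  aa
}

check_sense_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1 || nchar(codon) != 3)
    stop("codon must be a single 3-character string", call. = FALSE)
  codon <- toupper(codon)
  if (grepl("[^ACGT]", codon))
    stop("codon '", codon, "' contains ambiguity or gap characters",
         call. = FALSE)
  if (translate_codon(codon) == "*")
    stop("codon '", codon, "' is a stop codon", call. = FALSE)
  codon
}

codon_neighbors <- function(codon) {
  bases <- c("A", "C", "G", "T")
  spl <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) for (b in setdiff(bases, spl[pos])) {
    mut <- spl; mut[pos] <- b
    out <- c(out, paste(mut, collapse = ""))
  }
  out
}

#' Potential synonymous and nonsynonymous sites of a codon
#'
#' Enumerates the nine single-nucleotide neighbours of a sense codon under
#' the standard nuclear genetic code. Changes preserving the amino acid are
#' synonymous; all others -- including changes to stop codons -- count as
#' nonsynonymous, so `S + N = 3` exactly.
#'
#' @param codon A sense codon (3-character string over A, C, G, T).
#' @return Named numeric vector `c(S =, N =)`: fractional potential
#'   synonymous and nonsynonymous sites (0--3 each).
#' @examples
#' codon_site_counts("TTT")  # S = 1/3: only TTC stays Phe
#' codon_site_counts("GGG")  # S = 1: third position fully synonymous
#' @export
codon_site_counts <- function(codon) {
  codon <- check_sense_codon(codon)
  key <- paste0("sites_", codon)
  if (!is.null(.dnds_cache[[key]])) return(.dnds_cache[[key]])
  aa <- translate_codon(codon)
  syn <- sum(vapply(codon_neighbors(codon),
                    function(nb) translate_codon(nb) == aa, logical(1)))
  res <- c(S = syn / 3, N = 3 - syn / 3)
  .dnds_cache[[key]] <- res
  res
}

perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  out
}

#' Observed synonymous and nonsynonymous substitutions between two codons
#'
#' Codons differing at k positions are connected by k! single-step mutational
#' pathways. Each step is classified synonymous or nonsynonymous by the
#' standard code; pathways passing through a stop codon are excluded and the
#' remaining pathways weighted equally. Returns the pathway-averaged counts.
#'
#' @param codon_a,codon_b Sense codons.
#' @return Named numeric vector `c(Sd =, Nd =)` (fractional). `Sd + Nd`
#'   equals the number of differing positions whenever no pathway is
#'   stop-blocked. `NA` with a warning if every pathway is blocked.
#' @examples
#' pairwise_codon_substitutions("TTT", "TTC")  # one synonymous difference
#' pairwise_codon_substitutions("TTT", "GTA")  # Sd = 0.5, Nd = 1.5
#' @export
pairwise_codon_substitutions <- function(codon_a, codon_b) {
  codon_a <- check_sense_codon(codon_a)
  codon_b <- check_sense_codon(codon_b)
  key <- paste0("sub_", codon_a, codon_b)
  if (!is.null(.dnds_cache[[key]])) return(.dnds_cache[[key]])
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  diff_pos <- which(a != b)
  if (length(diff_pos) == 0) {
    res <- c(Sd = 0, Nd = 0)
  } else {
    gc <- genetic_code()
    path_counts <- list()
    for (ord in perms(diff_pos)) {
      cur <- a; sd <- 0; nd <- 0; blocked <- FALSE
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- b[pos]
        aa_cur <- unname(gc[paste(cur, collapse = "")])
        aa_nxt <- unname(gc[paste(nxt, collapse = "")])
        if (aa_nxt == "*") { blocked <- TRUE; break }
        if (aa_nxt == aa_cur) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (!blocked) path_counts[[length(path_counts) + 1]] <- c(sd, nd)
    }
    if (length(path_counts) == 0) {
      warning("all mutational pathways between ", codon_a, " and ", codon_b,
              " pass through stop codons", call. = FALSE)
      res <- c(Sd = NA_real_, Nd = NA_real_)
    } else {
      m <- do.call(rbind, path_counts)
      res <- c(Sd = mean(m[, 1]), Nd = mean(m[, 2]))
    }
  }
  .dnds_cache[[key]] <- res
  res
}

#' In-frame codon alignment
#'
#' @param sequences Character vector of equal-length in-frame nucleotide
#'   sequences (length divisible by 3). Gap (`-`) and ambiguity characters
#'   are tolerated here and skipped pairwise during profiling.
#' @param ids Sequence identifiers (default `seq1`, `seq2`, ...).
#' @return A list of class `codon_alignment`: `ids`, `sequences`,
#'   `length_codons`.
#' @export
codon_alignment <- function(sequences, ids = NULL) {
  sequences <- toupper(sequences)
  if (length(sequences) < 1) stop("empty alignment", call. = FALSE)
  lens <- unique(nchar(sequences))
  if (length(lens) != 1)
    stop("all sequences must have the same length", call. = FALSE)
  if (lens %% 3 != 0)
    stop("alignment length must be divisible by 3 (in-frame codons)",
         call. = FALSE)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  if (anyDuplicated(ids)) stop("duplicated sequence ids", call. = FALSE)
  structure(list(ids = ids, sequences = unname(sequences),
                 length_codons = lens %/% 3),
            class = "codon_alignment")
}

#' Read an in-frame codon alignment from aligned FASTA
#'
#' @param path Path to an aligned FASTA file.
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  codon_alignment(as.character(ss), ids = names(ss))
}

#' Write a codon alignment to FASTA
#'
#' @param aln A [codon_alignment()].
#' @param path Output path.
#' @export
write_codon_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "codon_alignment"))
  ss <- Biostrings::DNAStringSet(aln$sequences)
  names(ss) <- aln$ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", length(x$ids), "sequences x", x$length_codons,
      "codons\n")
  invisible(x)
}

#' Per-codon dN and dS profile across an alignment
#'
#' For every codon position, observed substitutions (`Sd`, `Nd`) are
#' accumulated over all unordered sequence pairs via
#' [pairwise_codon_substitutions()], and potential sites (`S`, `N`) as the
#' mean of [codon_site_counts()] of the two codons in each pair. Counts are
#' pooled before dividing: `dN = sum(Nd) / sum(N)`, `dS = sum(Sd) / sum(S)`.
#' These are raw proportions (no multiple-hit correction) and can exceed 1.
#' Pairs where either codon carries a gap, ambiguity character or stop codon
#' are skipped at that position; positions with no usable pair are reported
#' `NA` (undefined, not zero).
#'
#' @param aln A [codon_alignment()] with at least 2 sequences.
#' @return A data.frame of class `dnds_profile`: columns `position_aa`, `dN`,
#'   `dS`, `n_pairs_used`, `n_pairs_skipped`; attribute
#'   `aggregation = "pooled-pairwise"`.
#' @examples
#' aln <- codon_alignment(c("TTTGGG", "TTCGGG"))
#' dnds_profile(aln)  # dS = 3 at position 1 (Sd = 1 over mean S = 1/3)
#' @export
dnds_profile <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  nseq <- length(aln$sequences)
  if (nseq < 2) stop("at least 2 sequences required", call. = FALSE)
  L <- aln$length_codons
  codons <- matrix("", nrow = nseq, ncol = L)
  for (i in seq_len(nseq))
    codons[i, ] <- substring(aln$sequences[i], 3 * seq_len(L) - 2,
                             3 * seq_len(L))
  gc <- genetic_code()
  usable <- matrix(FALSE, nrow = nseq, ncol = L)
  for (i in seq_len(nseq)) {
    ok <- !grepl("[^ACGT]", codons[i, ])
    aa <- rep(NA_character_, L)
    aa[ok] <- unname(gc[codons[i, ok]])
    usable[i, ] <- ok & !is.na(aa) & aa != "*"
  }
  pairs <- utils::combn(nseq, 2)
  dN <- dS <- rep(NA_real_, L)
  n_used <- n_skipped <- integer(L)
  any_invalid_warned <- 0L
  for (p in seq_len(L)) {
    sum_Sd <- sum_Nd <- sum_S <- sum_N <- 0
    used <- 0L; skipped <- 0L
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      if (!usable[i, p] || !usable[j, p]) { skipped <- skipped + 1L; next }
      sub <- pairwise_codon_substitutions(codons[i, p], codons[j, p])
      if (anyNA(sub)) { skipped <- skipped + 1L; next }
      sc_i <- codon_site_counts(codons[i, p])
      sc_j <- codon_site_counts(codons[j, p])
      sum_Sd <- sum_Sd + sub[["Sd"]]; sum_Nd <- sum_Nd + sub[["Nd"]]
      sum_S <- sum_S + (sc_i[["S"]] + sc_j[["S"]]) / 2
      sum_N <- sum_N + (sc_i[["N"]] + sc_j[["N"]]) / 2
      used <- used + 1L
    }
    n_used[p] <- used; n_skipped[p] <- skipped
    if (used > 0) {
      dN[p] <- if (sum_N > 0) sum_Nd / sum_N else NA_real_
      dS[p] <- if (sum_S > 0) sum_Sd / sum_S else NA_real_
    } else {
      any_invalid_warned <- any_invalid_warned + 1L
    }
  }
  if (any_invalid_warned > 0)
    warning(any_invalid_warned,
            " position(s) had no usable codon pair; reported as NA",
            call. = FALSE)
  structure(data.frame(position_aa = seq_len(L), dN = dN, dS = dS,
                       n_pairs_used = n_used, n_pairs_skipped = n_skipped),
            aggregation = "pooled-pairwise",
            class = c("dnds_profile", "data.frame"))
}
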