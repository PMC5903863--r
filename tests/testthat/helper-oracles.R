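# Independent brute-force oracles for codon-level counting, deliberately
# built on seqinr's genetic code (not the package's Biostrings path) and on
# explicit hard-coded permutation lists rather than the package's recursion.

oracle_translate <- function(codon) {
  seqinr::translate(strsplit(tolower(codon), "")[[1]])
}

oracle_sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all3 <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  all3[vapply(all3, oracle_translate, character(1)) != "*"]
}

oracle_site_counts <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa <- oracle_translate(codon)
  spl <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) for (b in bases[bases != spl[pos]]) {
    mut <- spl; mut[pos] <- b
    if (oracle_translate(paste(mut, collapse = "")) == aa) syn <- syn + 1
  }
  c(S = syn / 3, N = 3 - syn / 3)
}

oracle_orderings <- function(k) {
  switch(as.character(k),
         "1" = list(1L),
         "2" = list(c(1L, 2L), c(2L, 1L)),
         "3" = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
}

# returns c(Sd, Nd) averaged over stop-free pathways, plus attr "blocked"
# counting excluded pathways
oracle_pairwise <- function(codon_a, codon_b) {
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  diffs <- which(a != b)
  k <- length(diffs)
  if (k == 0) return(structure(c(Sd = 0, Nd = 0), blocked = 0L))
  valid <- list()
  blocked <- 0L
  for (ord in oracle_orderings(k)) {
    cur <- a; sd <- 0; nd <- 0; ok <- TRUE
    for (idx in ord) {
      pos <- diffs[idx]
      nxt <- cur; nxt[pos] <- b[pos]
      aa1 <- oracle_translate(paste(cur, collapse = ""))
      aa2 <- oracle_translate(paste(nxt, collapse = ""))
      if (aa2 == "*") { ok <- FALSE; break }
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) valid[[length(valid) + 1]] <- c(sd, nd) else blocked <- blocked + 1L
  }
  if (length(valid) == 0)
    return(structure(c(Sd = NA_real_, Nd = NA_real_), blocked = blocked))
  m <- do.call(rbind, valid)
  structure(c(Sd = mean(m[, 1]), Nd = mean(m[, 2])), blocked = blocked)
}
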