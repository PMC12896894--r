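GENETIC_CODE <- Biostrings::GENETIC_CODE  # standard (universal) code

codon_split <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))

translate_cds <- function(cds) {
  codons <- codon_split(cds)
  paste(GENETIC_CODE[codons], collapse = "")
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Expands each aligned residue to its source codon, turning protein gaps
#' into `---`, so Ka/Ks can be computed on the codon alignment implied by a
#' protein MSA. Terminal stop codons on the CDS are stripped before checking
#' that each CDS translates exactly to its (ungapped) protein row.
#'
#' @param protein_msa Named character vector of aligned protein rows (gap `-`).
#' @param cds Named character vector of CDS nucleotide strings covering every
#'   taxon in `protein_msa`.
#' @return Named character vector of equal-length codon-aligned nucleotide
#'   rows.
#' @export
back_translate_alignment <- function(protein_msa, cds) {
  miss <- setdiff(names(protein_msa), names(cds))
  if (length(miss)) stop("no CDS for taxa: ", paste(miss, collapse = ", "))
  out <- vapply(names(protein_msa), function(id) {
    row <- protein_msa[[id]]
    aa <- strsplit(row, "")[[1]]
    ungapped <- aa[aa != "-"]
    s <- cds[[id]]
    if (nchar(s) %% 3L != 0L) stop("CDS length not a multiple of 3 for ", id)
    codons <- codon_split(s)
    if (length(codons) == length(ungapped) + 1L &&
        GENETIC_CODE[codons[length(codons)]] == "*")
      codons <- codons[-length(codons)]
    if (length(codons) != length(ungapped))
      stop("CDS length does not match protein length for ", id)
    trans <- GENETIC_CODE[codons]
    mis <- which(trans != ungapped)
    if (length(mis)) stop("CDS does not translate to protein for ", id,
                          " at residue ", mis[1])
    filled <- rep("---", length(aa))
    filled[aa != "-"] <- codons
    paste(filled, collapse = "")
  }, character(1))
  setNames(out, names(protein_msa))
}

# Fraction of synonymous changes at each position of a codon. Mutations to
# stop codons are disregarded (removed from the denominator); a position with
# no valid change contributes 0 synonymous sites.
ng86_syn_fractions <- function(codon) {
  nts <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1]]
  aa <- GENETIC_CODE[codon]
  vapply(1:3, function(i) {
    alts <- nts[nts != chars[i]]
    muts <- vapply(alts, function(nt) {
      x <- chars; x[i] <- nt
      GENETIC_CODE[paste(x, collapse = "")]
    }, character(1))
    valid <- muts != "*"
    if (!any(valid)) return(0)
    sum(muts[valid] == aa) / sum(valid)
  }, numeric(1))
}

# Average synonymous/nonsynonymous step counts over all mutational pathways
# between two codons, pathways passing through stop codons discarded (all
# pathways used if every one is blocked).
ng86_path_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(pos) else {
    idx <- seq_len(k)
    out <- list()
    permute <- function(cur, rest) {
      if (!length(rest)) out[[length(out) + 1L]] <<- pos[cur]
      else for (r in rest) permute(c(cur, r), setdiff(rest, r))
    }
    permute(integer(), idx)
    out
  }
  bchars <- strsplit(b, "")[[1]]
  res <- lapply(perms, function(order) {
    cur <- strsplit(a, "")[[1]]
    sd <- 0; nd <- 0
    for (p in order) {
      prev_codon <- paste(cur, collapse = "")
      cur[p] <- bchars[p]
      nxt_codon <- paste(cur, collapse = "")
      if (GENETIC_CODE[nxt_codon] == "*" && nxt_codon != b) return(NULL)
      if (GENETIC_CODE[prev_codon] == GENETIC_CODE[nxt_codon]) sd <- sd + 1
      else nd <- nd + 1
    }
    c(sd = sd, nd = nd)
  })
  ok <- !vapply(res, is.null, logical(1))
  if (any(ok)) res <- res[ok]
  else res <- lapply(perms, function(order) {  # all pathways blocked: use all
    cur <- strsplit(a, "")[[1]]
    sd <- 0; nd <- 0
    for (p in order) {
      prev <- GENETIC_CODE[paste(cur, collapse = "")]
      cur[p] <- bchars[p]
      if (prev == GENETIC_CODE[paste(cur, collapse = "")]) sd <- sd + 1 else nd <- nd + 1
    }
    c(sd = sd, nd = nd)
  })
  colMeans(do.call(rbind, res))
}

jc_correct <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - (4 / 3) * p)
}

#' Nei-Gojobori (1986) Ka/Ks for an aligned codon pair
#'
#' Counts synonymous and nonsynonymous sites by averaging per-codon
#' synonymous-site fractions over both sequences (mutations to stop codons
#' disregarded), counts differences by averaging over all mutational pathways
#' for codons differing at multiple positions, and applies the Jukes-Cantor
#' correction `d = -(3/4) ln(1 - (4/3) p)` to both proportions. Codons
#' containing gaps, ambiguity codes, or in-frame stops are skipped.
#'
#' The ratio is `NA` when the correction is undefined (`pS >= 0.75` - the
#' high-divergence exclusion rule - or, by the same singularity, `pN >= 0.75`)
#' or when `ks = 0`; the reason is recorded in `na_reason`.
#'
#' @param seq1,seq2 Aligned codon sequences (equal length, multiple of 3).
#' @return List of class `kaks_result` with `S`, `N`, `sd`, `nd`, `pS`, `pN`,
#'   `ks`, `ka`, `ratio`, `na_reason`, `codons_compared`.
#' @export
ng86_kaks <- function(seq1, seq2) {
  if (nchar(seq1) != nchar(seq2)) stop("sequences differ in length")
  if (nchar(seq1) %% 3L != 0L) stop("length not a multiple of 3")
  c1 <- codon_split(toupper(seq1))
  c2 <- codon_split(toupper(seq2))
  clean <- function(x) grepl("^[ACGT]{3}$", x) & GENETIC_CODE[x] != "*"
  usable <- clean(c1) & clean(c2)
  c1 <- c1[usable]; c2 <- c2[usable]
  ncod <- length(c1)
  if (ncod == 0L) stop("no comparable codons")
  s1 <- vapply(c1, function(x) sum(ng86_syn_fractions(x)), numeric(1))
  s2 <- vapply(c2, function(x) sum(ng86_syn_fractions(x)), numeric(1))
  S <- (sum(s1) + sum(s2)) / 2
  N <- 3 * ncod - S
  diffs <- mapply(function(a, b) ng86_path_diffs(a, b), c1, c2)
  sd_ <- sum(diffs["sd", ])
  nd_ <- sum(diffs["nd", ])
  pS <- if (S > 0) sd_ / S else 0
  pN <- if (N > 0) nd_ / N else 0
  ks <- jc_correct(pS)
  ka <- jc_correct(pN)
  na_reason <- NULL
  if (pS >= 0.75) na_reason <- "pS >= 0.75"
  else if (pN >= 0.75) na_reason <- "pN >= 0.75"
  else if (ks == 0) na_reason <- "ks = 0"
  ratio <- if (is.null(na_reason)) ka / ks else NA_real_
  structure(list(S = S, N = N, sd = sd_, nd = nd_, pS = pS, pN = pN,
                 ks = ks, ka = ka, ratio = ratio,
                 na_reason = if (is.null(na_reason)) NA_character_ else na_reason,
                 codons_compared = ncod),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result> S=%.2f N=%.2f sd=%.2f nd=%.2f pS=%.4f pN=%.4f\n",
              x$S, x$N, x$sd, x$nd, x$pS, x$pN))
  cat(sprintf("  Ks=%s Ka=%s Ka/Ks=%s%s\n",
              format(x$ks), format(x$ka), format(x$ratio),
              if (!is.na(x$na_reason)) paste0(" (N/A: ", x$na_reason, ")") else ""))
  invisible(x)
}

#' Ka/Ks table for homologous gene pairs
#'
#' Back-translates the protein alignment for each pair and runs [ng86_kaks()]
#' on the implied codon alignment.
#'
#' @param pairs Data frame with columns `gene1`, `gene2`.
#' @param protein_msa Named character vector of aligned protein rows covering
#'   all pair members.
#' @param cds Named character vector of CDS strings.
#' @return Data frame with one row per pair: `gene1`, `gene2`, `S`, `N`,
#'   `sd`, `nd`, `pS`, `pN`, `ka`, `ks`, `ratio`, `na_reason`.
#' @export
kaks_table <- function(pairs, protein_msa, cds) {
  codon_msa <- back_translate_alignment(protein_msa, cds)
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    g1 <- pairs$gene1[i]; g2 <- pairs$gene2[i]
    if (!g1 %in% names(codon_msa) || !g2 %in% names(codon_msa))
      stop("pair member missing from alignment: ", g1, " / ", g2)
    k <- ng86_kaks(codon_msa[[g1]], codon_msa[[g2]])
    data.frame(gene1 = g1, gene2 = g2, S = k$S, N = k$N, sd = k$sd, nd = k$nd,
               pS = k$pS, pN = k$pN, ka = k$ka, ks = k$ks, ratio = k$ratio,
               na_reason = k$na_reason, stringsAsFactors = FALSE)
  }))
}
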