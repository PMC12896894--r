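IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

revcomp <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""))
}

# Translate an IUPAC pattern into a per-position regex. A subject N is never
# matched by a non-N pattern code; the pattern code N matches any base
# including N.
iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad)) stop("invalid IUPAC letter(s) in pattern: ", paste(unique(bad), collapse = ","))
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (ch == "N") set <- c(set, "N")
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Extract the upstream promoter region of a gene
#'
#' Returns the `length` bases upstream of the translational start: for a
#' plus-strand gene the bases ending immediately before the gene start, and
#' for a minus-strand gene the reverse complement of the bases beginning
#' immediately after the gene end. In both cases the first base of the result
#' is the most upstream one. The region is truncated (and flagged) at
#' chromosome boundaries.
#'
#' @param genome Named character vector of chromosome sequences (from
#'   [read_dna_fasta()]).
#' @param locus One-row gene locus (needs `chromosome`, `start`, `end`,
#'   `strand`).
#' @param length Promoter length in bp (default 2000).
#' @return Nucleotide string with attributes `truncated` (logical) and
#'   `available` (number of bases returned); empty string with a warning when
#'   no upstream base exists.
#' @export
extract_upstream <- function(genome, locus, length = 2000L) {
  chr <- locus$chromosome
  if (!chr %in% names(genome)) stop("chromosome not in genome: ", chr)
  chrom <- genome[[chr]]
  n <- nchar(chrom)
  if (locus$strand == "+") {
    to <- locus$start - 1L
    from <- max(1L, locus$start - length)
    if (to < 1L) {
      warning("gene ", locus$gene_id %||% "?", " has no upstream bases")
      return(structure("", truncated = TRUE, available = 0L))
    }
    s <- substr(chrom, from, to)
  } else {
    from <- locus$end + 1L
    to <- min(n, locus$end + length)
    if (from > n) {
      warning("gene ", locus$gene_id %||% "?", " has no upstream bases")
      return(structure("", truncated = TRUE, available = 0L))
    }
    s <- revcomp(substr(chrom, from, to))
  }
  structure(s, truncated = nchar(s) < length, available = nchar(s))
}

#' Scan a promoter for IUPAC motifs
#'
#' Finds every position (overlaps included) where each motif pattern matches,
#' on the requested strands. Minus-strand hits are found by matching the
#' pattern against the reverse complement and are reported with the original
#' coordinate of the leftmost base of the matched region. A subject `N` never
#' matches a non-N IUPAC code.
#'
#' @param promoter Nucleotide string over `A,C,G,T,N`.
#' @param dictionary Data frame with columns `name`, `pattern` (IUPAC),
#'   `category` and optionally `subcategory` (see [default_motif_dictionary()]).
#' @param strands `"+"`, `"-"` or `"both"`.
#' @return Data frame with columns `motif_name`, `strand`, `offset` (1-based
#'   position of the leftmost matched base).
#' @export
scan_motifs <- function(promoter, dictionary, strands = c("+", "both", "-")) {
  strands <- match.arg(strands)
  stopifnot(all(c("name", "pattern") %in% names(dictionary)))
  promoter <- toupper(promoter)
  rc <- if (strands != "+") revcomp(promoter) else NULL
  L <- nchar(promoter)
  out <- list()
  for (i in seq_len(nrow(dictionary))) {
    pat <- dictionary$pattern[i]
    rx <- paste0("(?=", iupac_regex(pat), ")")  # lookahead: overlapping matches
    m <- nchar(pat)
    if (strands %in% c("+", "both")) {
      g <- gregexpr(rx, promoter, perl = TRUE)[[1]]
      pos <- g[g > 0]
      if (length(pos)) out[[length(out) + 1L]] <-
          data.frame(motif_name = dictionary$name[i], strand = "+",
                     offset = as.integer(pos), stringsAsFactors = FALSE)
    }
    if (strands %in% c("-", "both")) {
      g <- gregexpr(rx, rc, perl = TRUE)[[1]]
      pos <- g[g > 0]
      if (length(pos)) out[[length(out) + 1L]] <-
          data.frame(motif_name = dictionary$name[i], strand = "-",
                     offset = as.integer(L - pos - m + 2L), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(motif_name = character(), strand = character(),
                      offset = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$motif_name, res$strand, res$offset), , drop = FALSE]
}

#' Scan many promoters and tabulate hits
#'
#' @param promoters Named character vector of promoter sequences (names are
#'   gene ids).
#' @param dictionary Motif dictionary data frame.
#' @param strands Strand mode passed to [scan_motifs()].
#' @return Data frame with columns `gene_id`, `motif_name`, `strand`,
#'   `offset`.
#' @export
scan_promoter_set <- function(promoters, dictionary, strands = "+") {
  out <- lapply(names(promoters), function(g) {
    h <- scan_motifs(promoters[[g]], dictionary, strands = strands)
    if (nrow(h)) cbind(gene_id = g, h, stringsAsFactors = FALSE) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(gene_id = character(), motif_name = character(),
                      strand = character(), offset = integer()))
  do.call(rbind, out)
}

#' Roll up promoter hits by motif and category
#'
#' Builds the gene x motif count matrix, the per-category totals, and each
#' category's percentage of the grand total.
#'
#' @param hits Data frame from [scan_promoter_set()] (columns `gene_id`,
#'   `motif_name`).
#' @param dictionary Motif dictionary with `name` and `category` columns;
#'   every `motif_name` in `hits` must appear in it.
#' @return List with `counts` (gene x motif integer matrix),
#'   `category_totals` (named integer vector over all dictionary categories)
#'   and `category_pct` (percentages of the grand total, 0 with attribute
#'   `empty = TRUE` when there are no hits).
#' @export
count_by_category <- function(hits, dictionary) {
  unknown <- setdiff(hits$motif_name, dictionary$name)
  if (length(unknown)) stop("hits reference unknown motif(s): ",
                            paste(unique(unknown), collapse = ", "))
  cats <- sort(unique(dictionary$category))
  genes <- sort(unique(hits$gene_id))
  counts <- table(factor(hits$gene_id, levels = genes),
                  factor(hits$motif_name, levels = dictionary$name))
  counts <- matrix(as.integer(counts), nrow = length(genes),
                   ncol = nrow(dictionary),
                   dimnames = list(genes, dictionary$name))
  motif_cat <- setNames(dictionary$category, dictionary$name)
  totals <- vapply(cats, function(cc)
    sum(counts[, motif_cat[colnames(counts)] == cc, drop = FALSE]), integer(1))
  grand <- sum(totals)
  pct <- if (grand > 0) 100 * totals / grand else
    structure(setNames(rep(0, length(cats)), cats), empty = TRUE)
  list(counts = counts, category_totals = totals, category_pct = pct)
}

#' Built-in cis-element dictionary
#'
#' A small curated dictionary of named promoter cis-acting elements covering
#' the vocabulary commonly reported for plant gene-family promoter scans
#' (ABA/MeJA/SA/auxin/gibberellin/ethylene-responsive elements, meristem and
#' endosperm expression elements, drought/cold/wound MYB/MYC elements, and a
#' few light-responsive elements), with PlantCARE-style names and IUPAC
#' patterns. TGACG-motif and CGTCA-motif are kept as separate entries even
#' though they are reverse complements, matching the convention of scanning
#' each named element on the plus strand. Users can supply their own
#' dictionary in the same shape (TSV: name, pattern, category, subcategory).
#'
#' @return Data frame with columns `name`, `pattern`, `category`
#'   (`growth_development`, `phytohormone`, `stress`, `light`),
#'   `subcategory`.
#' @export
default_motif_dictionary <- function() {
  path <- system.file("extdata", "cis_element_dictionary.tsv", package = "xylpscan")
  read_table(path, required = c("name", "pattern", "category", "subcategory"))
}
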