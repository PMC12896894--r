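#' Read a protein FASTA file
#'
#' Reads a FASTA file into a data frame of protein records. Sequences are
#' uppercased and terminal `*` stop symbols are stripped. The first
#' whitespace-delimited token of each header is the record id; the remainder
#' (if any) is kept as the description.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `sequence`, `description`, one row
#'   per record.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  aas <- Biostrings::readBStringSet(path)
  if (length(aas) == 0L) stop("empty FASTA file: ", path)
  headers <- names(aas)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(aas))
  seqs <- sub("\\*+$", "", seqs)
  if (any(!nzchar(seqs))) stop("empty sequence for id(s): ",
                               paste(ids[!nzchar(seqs)], collapse = ", "))
  data.frame(id = unname(ids), sequence = unname(seqs),
             description = unname(desc), stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records Data frame with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  desc <- records$description %||% rep("", nrow(records))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene loci from a GFF3 file
#'
#' Parses gene and exon features into a per-gene table. Each gene receives a
#' `rank`: its 1-based order along its chromosome when genes are sorted by
#' start coordinate (strand is ignored for ranking, matching collinearity
#' tooling convention). Exon intervals are attached as a list column, sorted
#' and checked to lie within the gene span.
#'
#' @param gff_path Path to a GFF3 file with `gene` and `exon` features. Exons
#'   are linked to genes through their `Parent`/`ID` attributes (directly or
#'   via an mRNA feature).
#' @return A data frame with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`, `rank` and a list column `exon_intervals` (two-column matrices
#'   of 1-based inclusive start/end).
#' @export
read_gene_loci <- function(gff_path) {
  stopifnot(file.exists(gff_path))
  gff <- rtracklayer::readGFF(gff_path,
                              columns = c("seqid", "type", "start", "end", "strand"),
                              tags = c("ID", "Parent"))
  gff <- as.data.frame(gff)
  gff$Parent <- vapply(gff$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_, "")
  if (any(!gff$strand %in% c("+", "-")))
    stop("unknown strand symbol in GFF: ", paste(unique(gff$strand[!gff$strand %in% c("+", "-")]), collapse = ","))
  genes <- gff[gff$type == "gene", ]
  if (nrow(genes) == 0L) stop("no gene features in ", gff_path)
  # map transcript id -> gene id so exons parented to mRNAs resolve
  tx <- gff[gff$type %in% c("mRNA", "transcript"), ]
  tx_parent <- setNames(tx$Parent, tx$ID)
  exons <- gff[gff$type == "exon", ]
  exon_gene <- ifelse(exons$Parent %in% genes$ID, exons$Parent,
                      unname(tx_parent[exons$Parent]))
  loci <- data.frame(gene_id = genes$ID, chromosome = as.character(genes$seqid),
                     start = genes$start, end = genes$end,
                     strand = as.character(genes$strand),
                     stringsAsFactors = FALSE)
  loci$exon_intervals <- lapply(genes$ID, function(g) {
    ex <- exons[!is.na(exon_gene) & exon_gene == g, c("start", "end"), drop = FALSE]
    m <- as.matrix(ex)
    if (nrow(m)) m <- m[order(m[, 1]), , drop = FALSE]
    gi <- loci[loci$gene_id == g, ]
    if (nrow(m) && (min(m[, 1]) < gi$start || max(m[, 2]) > gi$end))
      stop("exon outside gene span for gene ", g)
    dimnames(m) <- list(NULL, c("start", "end"))
    m
  })
  # rank by start within chromosome
  loci$rank <- NA_integer_
  for (chr in unique(loci$chromosome)) {
    sel <- loci$chromosome == chr
    loci$rank[sel] <- rank(loci$start[sel], ties.method = "first")
  }
  loci[order(loci$chromosome, loci$start), , drop = FALSE]
}

#' Exon/intron counts for one gene locus
#'
#' @param locus A one-row slice of the table from [read_gene_loci()], or any
#'   list with an `exon_intervals` matrix.
#' @return Named integer vector `c(exons =, introns =)` with
#'   `introns = exons - 1`.
#' @export
gene_structure_summary <- function(locus) {
  ex <- locus$exon_intervals
  if (is.list(ex) && !is.matrix(ex)) ex <- ex[[1]]
  n <- if (is.null(ex)) 0L else nrow(ex)
  if (n == 0L) stop("locus has no exons")
  c(exons = n, introns = n - 1L)
}

#' Write a phylogenetic tree to Newick
#'
#' Serializes an `ape` `phylo` object with branch lengths and (if present)
#' integer internal support labels. The written file round-trips through
#' [ape::read.tree()] with topology and branch lengths preserved.
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  bad <- grepl("[(),:;\\[\\]\\s]", tree$tip.label, perl = TRUE)
  if (any(bad)) tree$tip.label[bad] <- paste0("'", tree$tip.label[bad], "'")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read / write typed TSV tables
#'
#' Thin wrappers around tab-separated I/O with a column-presence check, so
#' every tabular interface of the pipeline (Ct tables, motif dictionaries,
#' pair lists, report tables) fails loudly on a malformed file.
#'
#' @param path File path.
#' @param required Character vector of column names that must be present.
#' @return `read_table`: a data frame. `write_table`: invisibly, `path`.
#' @export
read_table <- function(path, required = character()) {
  stopifnot(file.exists(path))
  x <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                  check.names = FALSE, comment.char = "")
  miss <- setdiff(required, names(x))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  x
}

#' @param x Data frame to write.
#' @rdname read_table
#' @export
write_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a nucleotide FASTA (genome or CDS) as a named character vector
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_dna_fasta <- function(path) {
  stopifnot(file.exists(path))
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(x))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  setNames(toupper(as.character(x)), ids)
}

#' Write named nucleotide sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dna_fasta <- function(seqs, path) {
  write_fasta(data.frame(id = names(seqs), sequence = unname(seqs),
                         stringsAsFactors = FALSE), path)
}

#' Read a protein multiple sequence alignment
#'
#' Accepts aligned FASTA or CLUSTAL format and returns the alignment as a
#' named character vector of equal-length gapped rows (gap character `-`).
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"clustal"`; default guesses from the first line.
#' @return Named character vector of aligned rows.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^CLUSTAL", first, ignore.case = TRUE)) "clustal" else "fasta"
  }
  if (format == "fasta") {
    recs <- Biostrings::readBStringSet(path)
    rows <- setNames(toupper(as.character(recs)), sub("\\s.*$", "", names(recs)))
  } else {
    lines <- readLines(path)[-1]
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s", lines)]
    parts <- strsplit(trimws(lines), "\\s+")
    ids <- vapply(parts, `[[`, "", 1L)
    chunk <- vapply(parts, `[[`, "", 2L)
    rows <- vapply(split(chunk, factor(ids, levels = unique(ids))),
                   paste0, "", collapse = "")
    rows <- toupper(rows)
  }
  if (length(unique(nchar(rows))) != 1L) stop("alignment rows differ in length")
  if (anyDuplicated(names(rows))) stop("duplicate taxa in alignment")
  rows
}
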