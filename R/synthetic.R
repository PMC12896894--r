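# Background residue alphabet for the generators: no P/A/S/T (so background
# never forms PAST-rich regions) and no C (so it never completes a cysteine
# scaffold). Uniform draws from this set make planted signal unambiguous.
BG_AA <- c("D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "Q", "R", "V", "W", "Y")

rand_str <- function(n, alphabet) paste(sample(alphabet, n, replace = TRUE), collapse = "")

# a PAST-rich block: >= 3 glycomodules plus mostly-PAST filler, fraction >= 0.5
rand_past_block <- function(min_len = 30L, max_len = 60L) {
  repeat {
    len <- sample(min_len:max_len, 1L)
    glyco <- sample(AG_GLYCOMODULES, 3L, replace = TRUE)
    n_fill <- len - 6L
    fill <- sample(c(PAST_RESIDUES, BG_AA), n_fill, replace = TRUE,
                   prob = c(rep(0.7 / 4, 4), rep(0.3 / 15, 15)))
    # interleave the three glycomodules at random cut points of the filler
    cuts <- sort(sample(0:n_fill, 3L, replace = TRUE))
    parts <- c(substr(paste(fill, collapse = ""), 1, cuts[1]), glyco[1],
               substr(paste(fill, collapse = ""), cuts[1] + 1, cuts[2]), glyco[2],
               substr(paste(fill, collapse = ""), cuts[2] + 1, cuts[3]), glyco[3],
               substr(paste(fill, collapse = ""), cuts[3] + 1, n_fill))
    block <- paste(parts, collapse = "")
    if (past_fraction(block) >= 0.5) return(block)
  }
}

# an eight-cysteine nsLTP scaffold with mid-range spacers so the default
# bounds accept it; fillers avoid C and P (one Pro is planted between C2/C3)
rand_nsltp_scaffold <- function(bounds = default_nsltp_bounds()) {
  mid <- function(b) sample(seq(b[1] + 2L, b[2] - 2L), 1L)
  g1 <- mid(bounds$c1_c2); g2 <- mid(bounds$c2_c3); g4 <- mid(bounds$c4_c5)
  g6 <- mid(bounds$c6_c7); g7 <- mid(bounds$c7_c8)
  fill <- function(n) rand_str(n, setdiff(BG_AA, "P"))
  f2 <- strsplit(fill(g2), "")[[1]]
  f2[sample(seq_along(f2), 1L)] <- "P"
  scaffold <- paste0("C", fill(g1), "C", paste(f2, collapse = ""), "CC",
                     fill(g4), "C", "L", "C", fill(g6), "C", fill(g7), "C")
  cys_rel <- cumsum(c(1L, g1 + 1L, g2 + 1L, 1L, g4 + 1L, 2L, g6 + 1L, g7 + 1L))
  list(sequence = scaffold, cys_rel = cys_rel)
}

#' Generate a synthetic proteome with planted XYLPs and decoys
#'
#' Background proteins are drawn from a PAST- and cysteine-free residue
#' distribution, so they can satisfy none of the XYLP rules. Planted XYLPs
#' carry a PAST block (fraction >= 0.5, length 30-60, >= 3 AG glycomodules)
#' and an eight-cysteine scaffold with mid-range spacers. Each decoy violates
#' exactly one rule: `decoy_past` proteins have the PAST block but no
#' cysteines; `decoy_motif` proteins have the scaffold but no PAST block.
#' Deterministic for a fixed seed.
#'
#' @param seed Integer seed.
#' @param n_background,n_xylp,n_decoy_past,n_decoy_motif Class counts.
#' @return List with `proteome` (data frame as from [read_fasta()], rows in
#'   randomized order) and `truth` (data frame: `id`, `role`, and for planted
#'   XYLPs `region_start`, `region_end`, `cys_start` 1-based coordinates).
#' @export
gen_xylp_proteome <- function(seed, n_background = 50L, n_xylp = 8L,
                              n_decoy_past = 5L, n_decoy_motif = 5L) {
  stopifnot(n_background >= 0, n_xylp >= 0, n_decoy_past >= 0, n_decoy_motif >= 0)
  set.seed(seed)
  recs <- list(); truth <- list()
  add <- function(id, seq, role, rs = NA_integer_, re = NA_integer_, cs = NA_integer_) {
    recs[[length(recs) + 1L]] <<- data.frame(id = id, sequence = seq, description = role,
                                             stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(id = id, role = role, region_start = rs,
                                               region_end = re, cys_start = cs,
                                               stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_background))
    add(sprintf("bg%03d", i), rand_str(sample(120:250, 1L), BG_AA), "background")
  for (i in seq_len(n_xylp)) {
    pre <- rand_str(sample(20:40, 1L), BG_AA)
    block <- rand_past_block()
    link <- rand_str(sample(5:15, 1L), BG_AA)
    sc <- rand_nsltp_scaffold()
    post <- rand_str(sample(10:30, 1L), BG_AA)
    seq <- paste0(pre, block, link, sc$sequence, post)
    add(sprintf("xylp%02d", i), seq, "xylp",
        rs = nchar(pre) + 1L, re = nchar(pre) + nchar(block),
        cs = nchar(pre) + nchar(block) + nchar(link) + sc$cys_rel[1])
  }
  for (i in seq_len(n_decoy_past)) {
    pre <- rand_str(sample(20:40, 1L), BG_AA)
    block <- rand_past_block()
    post <- rand_str(sample(30:60, 1L), BG_AA)
    add(sprintf("decoyP%02d", i), paste0(pre, block, post), "decoy_past")
  }
  for (i in seq_len(n_decoy_motif)) {
    pre <- rand_str(sample(20:40, 1L), BG_AA)
    sc <- rand_nsltp_scaffold()
    post <- rand_str(sample(30:60, 1L), BG_AA)
    add(sprintf("decoyM%02d", i), paste0(pre, sc$sequence, post), "decoy_motif")
  }
  proteome <- do.call(rbind, recs)
  truth <- do.call(rbind, truth)
  if (nrow(proteome)) {
    ord <- sample.int(nrow(proteome))
    proteome <- proteome[ord, , drop = FALSE]
    truth <- truth[ord, , drop = FALSE]
    rownames(proteome) <- rownames(truth) <- NULL
  }
  list(proteome = proteome, truth = truth)
}

SENSE_CODONS <- names(GENETIC_CODE)[GENETIC_CODE != "*"]
FOURFOLD_PREFIX <- c("GC", "GG", "CC", "CG", "CT", "GT", "TC", "AC")

#' Generate an aligned codon pair with known substitution composition
#'
#' Builds an ancestral CDS of `n_codons` sense codons, then applies exactly
#' `syn_subs` synonymous and `nonsyn_subs` nonsynonymous single-nucleotide
#' changes, each at a distinct codon (synonymous changes at the third
#' position of fourfold-degenerate codons; nonsynonymous changes never create
#' stops). Deterministic for a fixed seed.
#'
#' @param seed Integer seed.
#' @param n_codons Number of codons.
#' @param syn_subs,nonsyn_subs Requested substitution counts.
#' @return List with `cds1`, `cds2` (nucleotide strings) and `truth`
#'   (list: `syn_codons`, `nonsyn_codons` - 1-based codon indices).
#' @export
gen_codon_pair <- function(seed, n_codons = 200L, syn_subs = 5L, nonsyn_subs = 5L) {
  if (syn_subs + nonsyn_subs > n_codons)
    stop("infeasible: more substitutions than codons")
  set.seed(seed)
  codons <- sample(SENSE_CODONS, n_codons, replace = TRUE)
  targets <- sample.int(n_codons, syn_subs + nonsyn_subs)
  syn_at <- targets[seq_len(syn_subs)]
  nonsyn_at <- targets[syn_subs + seq_len(nonsyn_subs)]
  nts <- c("A", "C", "G", "T")
  derived <- codons
  for (i in syn_at) {  # force a fourfold codon, then swap its third base
    pre <- sample(FOURFOLD_PREFIX, 1L)
    b3 <- sample(nts, 1L)
    codons[i] <- paste0(pre, b3)
    derived[i] <- paste0(pre, sample(setdiff(nts, b3), 1L))
  }
  for (i in nonsyn_at) {
    repeat {
      cod <- sample(SENSE_CODONS, 1L)
      pos <- sample(1:3, 1L)
      ch <- strsplit(cod, "")[[1]]
      alt <- ch; alt[pos] <- sample(setdiff(nts, ch[pos]), 1L)
      altc <- paste(alt, collapse = "")
      if (GENETIC_CODE[altc] != "*" && GENETIC_CODE[altc] != GENETIC_CODE[cod]) {
        codons[i] <- cod; derived[i] <- altc
        break
      }
    }
  }
  list(cds1 = paste(codons, collapse = ""), cds2 = paste(derived, collapse = ""),
       truth = list(syn_codons = sort(syn_at), nonsyn_codons = sort(nonsyn_at)))
}

#' Simulate a protein alignment along a tree
#'
#' Evolves a uniform-random root sequence down the tree: on each branch every
#' site receives a Poisson(`branch length`) number of substitution events,
#' each replacing the residue with one of the 19 alternatives uniformly.
#' Branch lengths are in expected substitutions per site. Deterministic for a
#' fixed seed.
#'
#' @param seed Integer seed.
#' @param tree `phylo` object with branch lengths.
#' @param n_sites Number of sites (default 500).
#' @return Named character vector of ungapped aligned rows (tip labels as
#'   names).
#' @export
gen_msa_on_tree <- function(seed, tree, n_sites = 500L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  set.seed(seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- sample(AA20, n_sites, replace = TRUE)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    t <- ord$edge.length[e]
    s <- seqs[[parent]]
    k <- stats::rpois(n_sites, t)
    for (site in which(k > 0)) {
      for (ev in seq_len(k[site])) s[site] <- sample(setdiff(AA20, s[site]), 1L)
    }
    seqs[[child]] <- s
  }
  setNames(vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""), ""),
           tree$tip.label)
}

#' Write gene loci to a GFF3 file
#'
#' @param loci Gene locus table (columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand`, list column `exon_intervals`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(loci))) {
    g <- loci$gene_id[i]
    writeLines(paste(loci$chromosome[i], "xylpscan", "gene", loci$start[i],
                     loci$end[i], ".", loci$strand[i], ".",
                     paste0("ID=", g), sep = "\t"), con)
    ex <- loci$exon_intervals[[i]]
    for (j in seq_len(NROW(ex)))
      writeLines(paste(loci$chromosome[i], "xylpscan", "exon", ex[j, 1], ex[j, 2],
                       ".", loci$strand[i], ".",
                       paste0("ID=", g, ".e", j, ";Parent=", g), sep = "\t"), con)
  }
  invisible(path)
}

#' Generate a genome layout with planted duplication structure
#'
#' Lays out `n_chrom` chromosomes of `genes_per_chrom` genes each and plants
#' three kinds of homologous pairs: tandem pairs (adjacent ranks on one
#' chromosome), collinear blocks (`block_size` order-preserving anchors
#' across a chromosome pair; random orientation), and dispersed singleton
#' pairs. Each collinear block and each dispersed pair sits on its own
#' chromosome pair, so planted modes are unambiguous. Deterministic for a
#' fixed seed.
#'
#' @param seed Integer seed.
#' @param n_chrom,genes_per_chrom Layout size.
#' @param n_tandem,n_collinear_blocks,block_size,n_dispersed Planted structure.
#' @return List with `loci` (gene locus table), `pairs` (data frame `gene1`,
#'   `gene2`, randomized order) and `truth` (same rows plus `mode` and
#'   `block`).
#' @export
gen_genome_layout <- function(seed, n_chrom = 5L, genes_per_chrom = 40L,
                              n_tandem = 3L, n_collinear_blocks = 2L,
                              block_size = 6L, n_dispersed = 3L) {
  set.seed(seed)
  chrom_pairs <- utils::combn(n_chrom, 2)
  if (n_collinear_blocks + n_dispersed > ncol(chrom_pairs))
    stop("not enough chromosome pairs for the requested blocks and dispersed pairs")
  loci <- do.call(rbind, lapply(seq_len(n_chrom), function(cc) {
    starts <- seq_len(genes_per_chrom) * 10000L + 1L
    data.frame(gene_id = sprintf("g%02d_%03d", cc, seq_len(genes_per_chrom)),
               chromosome = sprintf("chr%d", cc), start = starts,
               end = starts + 1999L,
               strand = sample(c("+", "-"), genes_per_chrom, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  loci$exon_intervals <- lapply(seq_len(nrow(loci)), function(i) {
    nex <- sample(1:3, 1L)
    bounds <- sort(sample(seq(loci$start[i] + 1L, loci$end[i] - 1L), 2L * (nex - 1L)))
    edges <- c(loci$start[i], bounds, loci$end[i])
    m <- matrix(edges, ncol = 2, byrow = TRUE)
    colnames(m) <- c("start", "end")
    m
  })
  loci$rank <- NA_integer_
  for (chr in unique(loci$chromosome)) {
    sel <- loci$chromosome == chr
    loci$rank[sel] <- rank(loci$start[sel], ties.method = "first")
  }
  gid <- function(cc, r) sprintf("g%02d_%03d", cc, r)
  pair_idx <- sample.int(ncol(chrom_pairs), n_collinear_blocks + n_dispersed)
  truth <- list()
  # collinear blocks
  for (b in seq_len(n_collinear_blocks)) {
    cp <- chrom_pairs[, pair_idx[b]]
    a0 <- sample.int(genes_per_chrom - block_size + 1L, 1L)
    b0 <- sample.int(genes_per_chrom - block_size + 1L, 1L)
    rev_ <- sample(c(FALSE, TRUE), 1L)
    for (i in seq_len(block_size)) {
      ra <- a0 + i - 1L
      rb <- if (rev_) b0 + block_size - i else b0 + i - 1L
      truth[[length(truth) + 1L]] <- data.frame(
        gene1 = gid(cp[1], ra), gene2 = gid(cp[2], rb),
        mode = "segmental", block = paste0("block_", b), stringsAsFactors = FALSE)
    }
  }
  # tandem pairs: adjacent ranks, kept clear of each other
  used_t <- list()
  for (i in seq_len(n_tandem)) {
    repeat {
      cc <- sample.int(n_chrom, 1L)
      r <- sample.int(genes_per_chrom - 1L, 1L)
      key <- paste(cc, r); key2 <- paste(cc, r + 1L)
      prev <- unlist(used_t)
      if (!key %in% prev && !key2 %in% prev) {
        used_t <- c(used_t, key, key2)
        truth[[length(truth) + 1L]] <- data.frame(
          gene1 = gid(cc, r), gene2 = gid(cc, r + 1L),
          mode = "tandem", block = NA_character_, stringsAsFactors = FALSE)
        break
      }
    }
  }
  # dispersed singletons, each on an otherwise unused chromosome pair
  for (i in seq_len(n_dispersed)) {
    cp <- chrom_pairs[, pair_idx[n_collinear_blocks + i]]
    truth[[length(truth) + 1L]] <- data.frame(
      gene1 = gid(cp[1], sample.int(genes_per_chrom, 1L)),
      gene2 = gid(cp[2], sample.int(genes_per_chrom, 1L)),
      mode = "dispersed", block = NA_character_, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  ord <- sample.int(nrow(truth))
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  list(loci = loci, pairs = truth[, c("gene1", "gene2")], truth = truth)
}

instantiate_iupac <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(chars, function(ch) sample(IUPAC_SETS[[ch]], 1L), ""), collapse = "")
}

#' Generate promoters with planted motif counts
#'
#' Builds `n_genes` random promoters of `promoter_length` bp and plants exact-match
#' instances of the requested motifs at recorded, non-overlapping offsets.
#' The background is cleaned so that the planted patterns have no accidental
#' plus-strand matches: any stray match is destroyed by point mutation (or
#' the promoter is redrawn), so a plus-strand scan recovers exactly the
#' planted counts. Deterministic for a fixed seed.
#'
#' @param seed Integer seed.
#' @param n_genes Number of promoters.
#' @param plant_counts Named integer vector: motif name -> planted copies per
#'   promoter. Names must appear in `dictionary`.
#' @param dictionary Motif dictionary (default [default_motif_dictionary()]).
#' @param promoter_length Promoter length in bp.
#' @return List with `promoters` (named character vector) and `truth` (data
#'   frame `gene_id`, `motif_name`, `offset`).
#' @export
gen_promoter_set <- function(seed, n_genes = 10L, plant_counts = c(ABRE = 3L, MBS = 2L),
                             dictionary = default_motif_dictionary(),
                             promoter_length = 2000L) {
  set.seed(seed)
  miss <- setdiff(names(plant_counts), dictionary$name)
  if (length(miss)) stop("unknown motif(s) in plant_counts: ", paste(miss, collapse = ", "))
  pats <- setNames(dictionary$pattern[match(names(plant_counts), dictionary$name)],
                   names(plant_counts))
  if (sum((nchar(pats) + 1L) * plant_counts) > promoter_length)
    stop("infeasible packing: planted motifs do not fit in the promoter")
  planted_dict <- dictionary[dictionary$name %in% names(plant_counts), , drop = FALSE]
  promoters <- character(n_genes)
  truth <- list()
  for (g in seq_len(n_genes)) {
    ok <- FALSE
    for (attempt in 1:100) {
      bg <- strsplit(rand_str(promoter_length, c("A", "C", "G", "T")), "")[[1]]
      # choose non-overlapping planting slots
      slots <- list()
      occupied <- integer()
      feasible <- TRUE
      for (nm in names(plant_counts)) {
        m <- nchar(pats[[nm]])
        for (k in seq_len(plant_counts[[nm]])) {
          placed <- FALSE
          for (try in 1:200) {
            off <- sample.int(promoter_length - m + 1L, 1L)
            span <- off:(off + m - 1L)
            if (!any(span %in% occupied)) {
              occupied <- c(occupied, span)
              slots[[length(slots) + 1L]] <- list(name = nm, offset = off,
                                                  instance = instantiate_iupac(pats[[nm]]))
              placed <- TRUE
              break
            }
          }
          if (!placed) { feasible <- FALSE; break }
        }
        if (!feasible) break
      }
      if (!feasible) next
      for (sl in slots) {
        span <- sl$offset:(sl$offset + nchar(sl$instance) - 1L)
        bg[span] <- strsplit(sl$instance, "")[[1]]
      }
      seq <- paste(bg, collapse = "")
      # destroy accidental matches of the planted patterns
      clean <- FALSE
      for (pass in 1:50) {
        hits <- scan_motifs(seq, planted_dict, strands = "+")
        planted_off <- vapply(slots, `[[`, 1L, "offset")
        planted_nm <- vapply(slots, `[[`, "", "name")
        extra <- hits[!paste(hits$motif_name, hits$offset) %in%
                        paste(planted_nm, planted_off), , drop = FALSE]
        if (nrow(extra) == 0L) { clean <- TRUE; break }
        conflict <- FALSE
        for (e in seq_len(nrow(extra))) {
          m <- nchar(pats[[extra$motif_name[e]]])
          span <- extra$offset[e]:(extra$offset[e] + m - 1L)
          free <- setdiff(span, occupied)
          if (!length(free)) { conflict <- TRUE; break }
          p <- free[sample.int(length(free), 1L)]
          cur <- substr(seq, p, p)
          substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
        }
        if (conflict) break
      }
      if (!clean) next
      promoters[g] <- seq
      gene <- sprintf("pgene%02d", g)
      names(promoters)[g] <- gene
      for (sl in slots)
        truth[[length(truth) + 1L]] <- data.frame(gene_id = gene, motif_name = sl$name,
                                                  offset = sl$offset,
                                                  stringsAsFactors = FALSE)
      ok <- TRUE
      break
    }
    if (!ok) stop("could not construct a clean promoter for gene ", g)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(), motif_name = character(), offset = integer())
  list(promoters = promoters, truth = truth)
}

#' Generate a qRT-PCR Ct table with planted fold changes
#'
#' The reference gene gets a constant baseline Ct plus Gaussian noise; each
#' target gene's Ct in a sample is `base_ct - log2(fold change) + noise`, so
#' the planted fold change (relative to the control sample, whose fold must
#' be 1) is recovered by the 2^-ddCt method up to noise. Deterministic for a
#' fixed seed.
#'
#' @param seed Integer seed.
#' @param fold_changes Genes x samples numeric matrix of planted fold
#'   changes (> 0), gene/sample names as dimnames; the control column should
#'   be 1.
#' @param control_sample Name of the control column.
#' @param reference_gene Reference gene name (default `"AcActin"`).
#' @param noise_sd Ct noise standard deviation in cycles.
#' @param replicates Biological replicates per (gene, sample).
#' @param base_ct,ref_ct Baseline Ct of targets and reference.
#' @return List with `ct` (data frame `gene`, `sample`, `replicate`, `ct`)
#'   and `truth` (the fold-change matrix).
#' @export
gen_ct_table <- function(seed, fold_changes, control_sample,
                         reference_gene = "AcActin", noise_sd = 0.1,
                         replicates = 3L, base_ct = 24, ref_ct = 20) {
  stopifnot(is.matrix(fold_changes), all(fold_changes > 0),
            control_sample %in% colnames(fold_changes))
  set.seed(seed)
  genes <- rownames(fold_changes)
  samples <- colnames(fold_changes)
  rows <- list()
  for (s in samples) for (r in seq_len(replicates)) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene = reference_gene, sample = s, replicate = r,
      ct = ref_ct + stats::rnorm(1, 0, noise_sd), stringsAsFactors = FALSE)
    for (g in genes)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, sample = s, replicate = r,
        ct = base_ct - log2(fold_changes[g, s]) + stats::rnorm(1, 0, noise_sd),
        stringsAsFactors = FALSE)
  }
  list(ct = do.call(rbind, rows), truth = fold_changes)
}
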