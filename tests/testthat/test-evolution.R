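test_that("Poisson distance applies pairwise deletion and the log correction", {
  msa <- c(a = "ACDE", b = "ACDE")
  d <- poisson_distance(msa)
  expect_equal(d["a", "b"], 0)
  # half the sites differ -> d = ln 2
  msa <- c(a = "AAAA", b = "AAGG")
  expect_equal(poisson_distance(msa)["a", "b"], log(2), tolerance = 1e-12)
  # gap column excluded: 3 shared sites, 1 mismatch
  msa <- c(a = "AC-A", b = "ACGA")
  expect_equal(poisson_distance(msa)["a", "b"], 0, tolerance = 1e-12)
  msa <- c(a = "AC-T", b = "ACGA")
  expect_equal(poisson_distance(msa)["a", "b"], -log(1 - 1 / 3), tolerance = 1e-12)
})

test_that("Poisson distance flags saturation and refuses empty overlap", {
  msa <- c(a = "AAAA", b = "CCCC")
  d <- poisson_distance(msa, cap = 7)
  expect_equal(d["a", "b"], 7)
  expect_true(attr(d, "saturated")["a", "b"])
  expect_error(poisson_distance(c(a = "A-", b = "-A")), "no shared")
})

test_that("Poisson correction always stretches the raw proportion", {
  set.seed(10)
  for (i in 1:20) {
    msa <- gen_msa_on_tree(i, ape::rtree(4, br = function(n) runif(n, 0.01, 0.5)),
                           n_sites = 300)
    d <- poisson_distance(msa)
    m <- do.call(rbind, strsplit(msa, ""))
    for (a in 1:3) for (b in (a + 1):4) {
      p <- mean(m[a, ] != m[b, ])
      if (p > 0 && p < 1) expect_gte(d[a, b], p)
    }
  }
})

test_that("NJ reconstructs additive distances exactly", {
  dm <- matrix(4, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dm[cbind(c(1, 2, 3, 4), c(2, 1, 4, 3))] <- 2
  diag(dm) <- 0
  tr <- nj_tree(dm)
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]], dm)
  # internal branch 2, tips 1
  expect_setequal(round(sort(tr$edge.length), 6), c(1, 1, 1, 1, 2))

  # three taxa resolve exactly
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(ape::cophenetic.phylo(nj_tree(d3))[letters[1:3], letters[1:3]], d3)
})

test_that("NJ recovers random additive matrices up to 8 taxa", {
  set.seed(11)
  for (n in c(5, 6, 8)) for (rep in 1:5) {
    tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    dm <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(dm)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), rec)), 0)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-9)
  }
})

test_that("NJ topology is invariant to taxon order and rejects bad input", {
  set.seed(12)
  tr <- ape::rtree(6, br = function(k) runif(k, 0.1, 1))
  dm <- ape::cophenetic.phylo(tr)
  perm <- sample(rownames(dm))
  t1 <- nj_tree(dm)
  t2 <- nj_tree(dm[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
  bad <- dm; bad[1, 2] <- bad[1, 2] + 1
  expect_error(nj_tree(bad), "symmetric")
  expect_error(nj_tree(dm[1:2, 1:2]), ">= 3")
})

test_that("bootstrap support is deterministic and saturates on clean signal", {
  # two well-separated identical-sequence clades
  block1 <- strrep("A", 60); block2 <- strrep("W", 60)
  msa <- c(t1 = paste0(block1, strrep("C", 5)), t2 = paste0(block1, strrep("D", 5)),
           t3 = paste0(block2, strrep("E", 5)), t4 = paste0(block2, strrep("F", 5)))
  tr1 <- bootstrap_support(msa, B = 50, seed = 7)
  tr2 <- bootstrap_support(msa, B = 50, seed = 7)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  supports <- as.integer(tr1$node.label[!is.na(tr1$node.label)])
  expect_true(all(supports == 100))
  # single replicate can only produce 0 or 100
  tr3 <- bootstrap_support(msa, B = 1, seed = 3)
  s3 <- as.integer(tr3$node.label[!is.na(tr3$node.label)])
  expect_true(all(s3 %in% c(0L, 100L)))
  expect_error(bootstrap_support(msa, B = 0), "B")
})

test_that("back-translation expands residues to codons and validates the CDS", {
  msa <- c(x = "M-K", y = "MGK")
  cds <- c(x = "ATGAAA", y = "ATGGGAAAA")
  out <- back_translate_alignment(msa, cds)
  expect_equal(out[["x"]], "ATG---AAA")
  expect_equal(out[["y"]], "ATGGGAAAA")
  # terminal stop is stripped before checking
  out2 <- back_translate_alignment(c(x = "MK"), c(x = "ATGAAATAA"))
  expect_equal(out2[["x"]], "ATGAAA")
  expect_error(back_translate_alignment(c(x = "MV"), c(x = "ATGAAA")), "residue 2")
  expect_error(back_translate_alignment(c(x = "MK"), c(y = "ATGAAA")), "no CDS")
})

test_that("generator codon pairs translate back to their proteins", {
  cp <- gen_codon_pair(13, n_codons = 30, syn_subs = 3, nonsyn_subs = 2)
  p1 <- paste(Biostrings::GENETIC_CODE[substring(cp$cds1, seq(1, 88, 3), seq(3, 90, 3))],
              collapse = "")
  out <- back_translate_alignment(setNames(p1, "a"), c(a = cp$cds1))
  expect_equal(out[["a"]], cp$cds1)
})

test_that("NG86 reproduces the worked single-substitution example", {
  k <- ng86_kaks("GGGGGGAAA", "GGAGGGAAA")
  expect_equal(k$sd, 1); expect_equal(k$nd, 0)
  expect_equal(k$S, 7 / 3, tolerance = 1e-12)
  expect_equal(k$pS, 3 / 7, tolerance = 1e-12)
  expect_equal(k$ks, -0.75 * log(1 - (4 / 3) * (3 / 7)), tolerance = 1e-12)
  expect_equal(k$ka, 0)
  expect_equal(k$ratio, 0)
})

test_that("NG86 honours the N/A rules", {
  ident <- ng86_kaks("ATGAAA", "ATGAAA")
  expect_equal(ident$sd + ident$nd, 0)
  expect_true(is.na(ident$ratio))
  expect_equal(ident$na_reason, "ks = 0")
  hs <- ng86_kaks("GGG", "GGA")
  expect_true(is.na(hs$ratio))
  expect_equal(hs$na_reason, "pS >= 0.75")
})

test_that("NG86 is symmetric and conserves sites", {
  set.seed(14)
  for (i in 1:10) {
    cp <- gen_codon_pair(i + 100, n_codons = 25, syn_subs = 3, nonsyn_subs = 4)
    k12 <- ng86_kaks(cp$cds1, cp$cds2)
    k21 <- ng86_kaks(cp$cds2, cp$cds1)
    expect_equal(k12$S, k21$S, tolerance = 1e-12)
    expect_equal(k12$sd, k21$sd, tolerance = 1e-12)
    expect_equal(k12$nd, k21$nd, tolerance = 1e-12)
    expect_equal(k12$S + k12$N, 3 * k12$codons_compared, tolerance = 1e-12)
  }
  expect_error(ng86_kaks("ATGA", "ATGC"), "multiple of 3")
})

test_that("NG86 per-codon counts match pathway enumeration on sampled codon pairs", {
  set.seed(15)
  pairs <- expand.grid(a = SENSE_CODONS_T, b = SENSE_CODONS_T,
                       stringsAsFactors = FALSE)
  pick <- pairs[sample.int(nrow(pairs), 150), ]
  for (i in seq_len(nrow(pick))) {
    a <- pick$a[i]; b <- pick$b[i]
    k <- ng86_kaks(a, b)
    o <- oracle_ng86(a, b)
    expect_equal(k$S, o$S, tolerance = 1e-10)
    expect_equal(k$sd, o$sd, tolerance = 1e-10)
    expect_equal(k$nd, o$nd, tolerance = 1e-10)
  }
})

test_that("planted substitution composition is recovered", {
  for (seed in 1:5) {
    cp <- gen_codon_pair(seed, n_codons = 50, syn_subs = 6, nonsyn_subs = 2)
    k <- ng86_kaks(cp$cds1, cp$cds2)
    expect_equal(k$sd, 6)
    expect_equal(k$nd, 2)
  }
})

test_that("low-divergence simulations rank ka vs ks by the planted excess", {
  hits <- 0; total <- 30
  for (seed in 1:total) {
    cp <- gen_codon_pair(seed + 500, n_codons = 200, syn_subs = 8, nonsyn_subs = 2)
    k <- ng86_kaks(cp$cds1, cp$cds2)
    if (!is.na(k$ka) && !is.na(k$ks) && k$ka < k$ks) hits <- hits + 1
  }
  expect_gte(hits / total, 0.9)
})

test_that("duplication modes follow the window and chain rules", {
  gl <- gen_genome_layout(21, n_chrom = 4, genes_per_chrom = 30, n_tandem = 2,
                          n_collinear_blocks = 1, block_size = 5, n_dispersed = 2)
  calls <- classify_duplications(gl$loci, gl$pairs)
  expect_equal(calls$mode, gl$truth$mode)
  seg <- calls[calls$mode == "segmental", ]
  expect_true(all(seg$chain_length >= 5))
  expect_equal(length(unique(seg$chain_id)), 1L)
  # unknown gene is rejected
  badp <- data.frame(gene1 = "nope", gene2 = gl$pairs$gene2[1])
  expect_error(classify_duplications(gl$loci, badp), "unknown gene")
})

test_that("tandem window and match size act at their boundaries", {
  loci <- data.frame(gene_id = paste0("g", 1:20),
                     chromosome = rep(c("c1", "c2"), each = 10),
                     start = rep(1:10 * 1000, 2), end = rep(1:10 * 1000 + 500, 2),
                     strand = "+", stringsAsFactors = FALSE)
  loci$exon_intervals <- replicate(20, matrix(c(1, 10), 1), simplify = FALSE)
  loci$rank <- rep(1:10, 2)
  # rank distance 2 is tandem, 3 is not
  p <- data.frame(gene1 = c("g1", "g1"), gene2 = c("g3", "g4"))
  calls <- classify_duplications(loci, p)
  expect_equal(calls$mode[1], "tandem")
  expect_false(calls$mode[2] == "tandem")
  # 5 collinear anchors reach match_size; 4 do not
  p5 <- data.frame(gene1 = paste0("g", 1:5), gene2 = paste0("g", 11:15))
  expect_true(all(classify_duplications(loci, p5)$mode == "segmental"))
  p4 <- p5[1:4, ]
  expect_true(all(classify_duplications(loci, p4)$mode == "dispersed"))
})

test_that("max_gaps bounds the rank gap between consecutive anchors", {
  n <- 80
  loci <- data.frame(gene_id = c(paste0("a", 1:n), paste0("b", 1:n)),
                     chromosome = rep(c("c1", "c2"), each = n),
                     start = rep(1:n * 1000, 2), end = rep(1:n * 1000 + 500, 2),
                     strand = "+", stringsAsFactors = FALSE)
  loci$exon_intervals <- replicate(2 * n, matrix(c(1, 10), 1), simplify = FALSE)
  loci$rank <- rep(1:n, 2)
  mk <- function(xs) data.frame(gene1 = paste0("a", xs), gene2 = paste0("b", xs))
  # gap of exactly 25 intervening ranks still chains (ranks 1 and 27)
  ok <- mk(c(1, 27, 28, 29, 30))
  expect_true(all(classify_duplications(loci, ok)$mode == "segmental"))
  # one more intervening rank breaks the chain below match_size
  broken <- mk(c(1, 28, 29, 30, 31))
  calls <- classify_duplications(loci, broken)
  expect_true(all(calls$mode == "dispersed"))
})

test_that("inverted collinear blocks are chained too", {
  gl <- gen_genome_layout(33, n_chrom = 3, genes_per_chrom = 25, n_tandem = 0,
                          n_collinear_blocks = 2, block_size = 6, n_dispersed = 1)
  calls <- classify_duplications(gl$loci, gl$pairs)
  expect_equal(calls$mode, gl$truth$mode)
})
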