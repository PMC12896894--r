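make_genome <- function(seed = 1, len = 10000) {
  set.seed(seed)
  setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "chr1")
}

test_that("upstream extraction respects strand and window arithmetic", {
  genome <- make_genome()
  plus <- list(gene_id = "gp", chromosome = "chr1", start = 3001, end = 3500, strand = "+")
  up <- extract_upstream(genome, plus, length = 2000)
  expect_equal(as.character(up), substr(genome[["chr1"]], 1001, 3000))
  expect_false(attr(up, "truncated"))

  minus <- list(gene_id = "gm", chromosome = "chr1", start = 4500, end = 5000, strand = "-")
  upm <- extract_upstream(genome, minus, length = 2000)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(substr(genome[["chr1"]], 5001, 7000), "")[[1]]),
                                     collapse = ""))
  expect_equal(as.character(upm), rc)
})

test_that("upstream extraction truncates and warns at chromosome edges", {
  genome <- make_genome()
  near <- list(gene_id = "gn", chromosome = "chr1", start = 500, end = 900, strand = "+")
  up <- extract_upstream(genome, near, length = 2000)
  expect_equal(nchar(up), 499L)
  expect_true(attr(up, "truncated"))
  at_edge <- list(gene_id = "ge", chromosome = "chr1", start = 1, end = 100, strand = "+")
  expect_warning(up0 <- extract_upstream(genome, at_edge), "no upstream")
  expect_equal(as.character(up0), "")
  expect_error(extract_upstream(genome, list(chromosome = "chrX", start = 10,
                                             end = 20, strand = "+", gene_id = "x")),
               "not in genome")
})

test_that("motif scanning matches literal, reverse-complement and IUPAC cases", {
  d <- function(nm, pat) data.frame(name = nm, pattern = pat, stringsAsFactors = FALSE)
  h <- scan_motifs("AATGACGTT", d("TGACG", "TGACG"), strands = "+")
  expect_equal(h$offset, 3L)
  expect_equal(nrow(scan_motifs("AATGACGTT", d("CGTCA", "CGTCA"), strands = "+")), 0L)
  hb <- scan_motifs("AATGACGTT", d("CGTCA", "CGTCA"), strands = "both")
  expect_equal(hb$strand, "-")
  expect_equal(hb$offset, 3L)
  hi <- scan_motifs("GCATTTGC", d("E", "CANNTG"), strands = "+")
  expect_equal(hi$offset, 2L)
  expect_error(scan_motifs("ACGT", d("bad", "CAXTG")), "invalid IUPAC")
})

test_that("subject N only matches the pattern code N", {
  d <- function(nm, pat) data.frame(name = nm, pattern = pat, stringsAsFactors = FALSE)
  expect_equal(nrow(scan_motifs("ACNGT", d("m", "CWG"), strands = "+")), 0L)
  expect_equal(scan_motifs("ACNGT", d("m", "CNG"), strands = "+")$offset, 2L)
})

test_that("scanning equals the exhaustive IUPAC oracle on random sequences", {
  set.seed(41)
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  for (i in 1:12) {
    seqlen <- 2000
    s <- paste(sample(c("A", "C", "G", "T"), seqlen, replace = TRUE), collapse = "")
    pat <- paste(sample(codes, sample(5:8, 1), replace = TRUE,
                        prob = c(rep(3, 4), rep(1, 11))), collapse = "")
    d <- data.frame(name = "m", pattern = pat, stringsAsFactors = FALSE)
    got <- scan_motifs(s, d, strands = "+")
    expect_equal(got$offset, oracle_iupac_scan(s, pat))
  }
})

test_that("minus-strand hits mirror plus-strand hits of the reverse complement", {
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  pat <- "TGACGY"
  d <- data.frame(name = "m", pattern = pat, stringsAsFactors = FALSE)
  minus <- scan_motifs(s, d, strands = "-")
  plus_rc <- scan_motifs(s, data.frame(name = "m", pattern = oracle_revcomp(pat)),
                         strands = "+")
  expect_equal(sort(minus$offset), sort(plus_rc$offset))
})

test_that("category rollup percentages and totals are consistent", {
  dict <- default_motif_dictionary()
  hits <- data.frame(gene_id = c("g1", "g1", "g1", "g2"),
                     motif_name = c("MBS", "MBS", "LTR", "Box 4"),
                     strand = "+", offset = c(5L, 50L, 100L, 7L))
  tab <- count_by_category(hits, dict)
  expect_equal(sum(tab$counts), nrow(hits))
  expect_equal(unname(tab$category_totals[c("stress", "light")]), c(3L, 1L))
  expect_equal(unname(tab$category_pct["stress"]), 75)
  expect_equal(sum(tab$category_pct), 100)
  # degenerate: no hits at all
  none <- count_by_category(hits[0, ], dict)
  expect_true(all(none$category_pct == 0))
  expect_true(isTRUE(attr(none$category_pct, "empty")))
  # unknown motif name rejected
  bad <- data.frame(gene_id = "g", motif_name = "nope", strand = "+", offset = 1L)
  expect_error(count_by_category(bad, dict), "unknown motif")
})

test_that("planted promoter counts are recovered exactly", {
  plant <- c(ABRE = 4L, MBS = 2L, LTR = 1L)
  ps <- gen_promoter_set(43, n_genes = 5, plant_counts = plant)
  dict <- default_motif_dictionary()
  hits <- scan_promoter_set(ps$promoters, dict[dict$name %in% names(plant), ],
                            strands = "+")
  counts <- table(hits$gene_id, hits$motif_name)
  for (g in names(ps$promoters)) for (m in names(plant))
    expect_equal(unname(counts[g, m]), unname(plant[[m]]))
  # offsets match the planted truth
  key_hit <- sort(paste(hits$gene_id, hits$motif_name, hits$offset))
  key_truth <- sort(paste(ps$truth$gene_id, ps$truth$motif_name, ps$truth$offset))
  expect_equal(key_hit, key_truth)
})
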