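test_that("past_fraction counts PAST residues over the window", {
  expect_equal(past_fraction("APSTAPSTAP"), 1.0)
  expect_equal(past_fraction("GGGGGGGGGG"), 0.0)
  expect_equal(past_fraction("GAPSTG", 2, 5), 1.0)
  expect_equal(past_fraction("GAPSTG"), 4 / 6)
  expect_equal(past_fraction("APXX"), 0.5)  # X in the denominator only
  expect_error(past_fraction("AP", 3, 3))
  expect_error(past_fraction("AP", 2, 1))
})

test_that("find_past_regions matches the window-union oracle on planted input", {
  s <- paste0(strrep("G", 30), strrep("APAPSPSTTP", 4), strrep("G", 30))
  got <- find_past_regions(s)
  exp <- oracle_past_regions(s)
  expect_equal(got[, c("start", "end")], exp, ignore_attr = TRUE)
  expect_equal(nrow(got), 1L)
  # the planted block is inside the single reported region
  expect_lte(got$start, 31)
  expect_gte(got$end, 70)
})

test_that("find_past_regions threshold is inclusive and degenerate inputs handled", {
  expect_equal(nrow(find_past_regions(strrep("G", 100))), 0L)
  # exactly 7/20 PAST = 0.35 qualifies
  s <- paste0(strrep("P", 7), strrep("G", 13))
  r <- find_past_regions(s, theta = 0.35, l_min = 20L)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(1L, 20L))
  # 6/20 does not
  expect_equal(nrow(find_past_regions(paste0(strrep("P", 6), strrep("G", 14)))), 0L)
  expect_error(find_past_regions("AAAA", theta = 0), "theta")
  expect_error(find_past_regions("AAAA", theta = 1.2), "theta")
  expect_error(find_past_regions("AAAA", l_min = 1), "l_min")
})

test_that("find_past_regions equals the brute-force oracle on random sequences", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(20:300, 1)
    s <- rand_peptide(n, alphabet = c("P", "A", "S", "T", "G", "L", "K", "D"))
    got <- find_past_regions(s)
    exp <- oracle_past_regions(s)
    expect_equal(got[, c("start", "end")], exp, ignore_attr = TRUE)
  }
})

test_that("find_glycomodules reports overlapping dipeptide starts in order", {
  expect_equal(find_glycomodules("GAPG")$position, 2L)
  expect_equal(find_glycomodules("GAPG")$dipeptide, "AP")
  h <- find_glycomodules("APA")
  expect_equal(h$position, c(1L, 2L))
  expect_equal(h$dipeptide, c("AP", "PA"))
  expect_equal(nrow(find_glycomodules("PPPP")), 0L)
})

test_that("glycomodule hits in a region are invariant to residues outside it", {
  s <- "GGAPSPTPGG"
  base <- find_glycomodules(s, 3, 8)
  extended <- find_glycomodules(paste0(s, "GLKG"), 3, 8)
  expect_equal(base, extended)
})

test_that("nsLTP motif matcher finds the constructed toy assignment", {
  toy <- paste0(strrep("A", 5), "C", strrep("A", 9), "C", strrep("A", 5), "P",
                strrep("A", 8), "CC", strrep("A", 12), "C", "L", "C",
                strrep("A", 20), "C", strrep("A", 8), "C")
  m <- match_nsltp_motif(toy)
  expect_equal(m$cys_positions, oracle_nsltp(toy))
  expect_equal(m$spacer_lengths, c(9L, 14L, 0L, 12L, 1L, 20L, 8L))
  expect_equal(m$inter56_residue, "L")
  expect_true(m$inter56_hydrophobic)
  expect_equal(unname(m$proline_position), 22L)
  # two residues between C5 and C6 break the single-X constraint
  toy2 <- sub("CLC", "CLLC", toy)
  expect_null(match_nsltp_motif(toy2))
  # seven cysteines cannot match
  expect_null(match_nsltp_motif(sub("C$", "A", toy)))
})

test_that("nsLTP matcher agrees with exhaustive assignment search", {
  set.seed(202)
  n_matched <- 0
  for (i in 1:80) {
    ncys <- sample(8:12, 1)
    len <- sample(80:140, 1)
    bg <- strsplit(rand_peptide(len, alphabet = c("A", "G", "L", "P", "K")), "")[[1]]
    pos <- sort(sample(len, ncys))
    bg[pos] <- "C"
    s <- paste(bg, collapse = "")
    got <- match_nsltp_motif(s)
    exp <- oracle_nsltp(s)
    if (is.null(exp)) expect_null(got)
    else {
      expect_equal(got$cys_positions, exp)
      n_matched <- n_matched + 1
    }
  }
  # random scaffolds rarely satisfy the consensus; planted ones always do
  sc <- gen_xylp_proteome(7, n_background = 0, n_xylp = 3, n_decoy_past = 0,
                          n_decoy_motif = 0)
  for (s in sc$proteome$sequence)
    expect_equal(match_nsltp_motif(s)$cys_positions, oracle_nsltp(s))
})

test_that("malformed spacer bounds are rejected", {
  b <- default_nsltp_bounds()
  b$c1_c2 <- c(10L, 5L)
  expect_error(match_nsltp_motif("CCCCCCCC", b), "malformed")
})

test_that("classification verdict is the conjunction of the three rules", {
  g <- gen_xylp_proteome(31, n_background = 5, n_xylp = 2, n_decoy_past = 2,
                         n_decoy_motif = 2)
  calls <- classify_proteome(g$proteome)
  for (i in seq_along(calls)) {
    role <- g$truth$role[i]
    call <- calls[[i]]
    if (role == "xylp") expect_equal(call$verdict, "XYLP")
    else expect_equal(call$verdict, "not_XYLP")
    if (role == "decoy_past") expect_true("no_nsltp_motif" %in% call$reasons)
    if (role == "decoy_motif") expect_true("no_past_region" %in% call$reasons)
  }
})

test_that("candidate naming follows input order", {
  g <- gen_xylp_proteome(5, n_background = 3, n_xylp = 3, n_decoy_past = 0,
                         n_decoy_motif = 0)
  calls <- classify_proteome(g$proteome)
  nm <- name_candidates(calls, "AcXYLP")
  acc <- g$proteome$id[g$truth$role == "xylp"]
  expect_equal(names(nm), acc)
  expect_equal(unname(nm), paste0("AcXYLP", seq_along(acc)))
  none <- classify_proteome(gen_xylp_proteome(6, n_background = 2, n_xylp = 0,
                                              n_decoy_past = 0, n_decoy_motif = 0)$proteome)
  expect_warning(nm0 <- name_candidates(none, "X"), "no accepted")
  expect_length(nm0, 0L)
})

test_that("classification_table flattens calls", {
  g <- gen_xylp_proteome(8, n_background = 2, n_xylp = 1, n_decoy_past = 1,
                         n_decoy_motif = 0)
  tab <- classification_table(classify_proteome(g$proteome))
  expect_equal(nrow(tab), 4L)
  expect_setequal(tab$protein_id, g$proteome$id)
  xy <- tab[tab$verdict == "XYLP", ]
  expect_equal(nrow(xy), 1L)
  expect_gte(xy$n_glycomodules, 3L)
  expect_match(xy$cys_positions, "^[0-9]+(,[0-9]+){7}$")
})
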