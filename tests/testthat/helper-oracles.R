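# Independent brute-force oracles used to validate the optimized scanners and
# counters. These deliberately favour clarity over speed and avoid sharing
# code with the implementation.

PAST4 <- c("P", "A", "S", "T")

# union of all qualifying windows (length >= l_min, fraction >= theta),
# reported as maximal runs of covered positions
oracle_past_regions <- function(sequence, theta = 0.35, l_min = 20L) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  covered <- logical(n)
  if (n >= l_min) {
    for (s in 1:(n - l_min + 1L)) for (e in (s + l_min - 1L):n) {
      if (mean(chars[s:e] %in% PAST4) >= theta) covered[s:e] <- TRUE
    }
  }
  if (!any(covered)) return(data.frame(start = integer(), end = integer()))
  idx <- which(covered)
  breaks <- c(0L, which(diff(idx) > 1L), length(idx))
  do.call(rbind, lapply(seq_len(length(breaks) - 1L), function(k)
    data.frame(start = idx[breaks[k] + 1L], end = idx[breaks[k + 1L]])))
}

# exhaustive search over all 8-subsets of cysteine positions; combn walks the
# subsets in lexicographic order, so the first valid one is the leftmost
oracle_nsltp <- function(sequence, bounds = xylpscan::default_nsltp_bounds()) {
  chars <- strsplit(sequence, "")[[1]]
  cys <- which(chars == "C")
  if (length(cys) < 8L) return(NULL)
  lo <- c(bounds$c1_c2[1], bounds$c2_c3[1], 0L, bounds$c4_c5[1], 1L,
          bounds$c6_c7[1], bounds$c7_c8[1])
  hi <- c(bounds$c1_c2[2], bounds$c2_c3[2], 0L, bounds$c4_c5[2], 1L,
          bounds$c6_c7[2], bounds$c7_c8[2])
  combos <- utils::combn(cys, 8L)
  for (k in seq_len(ncol(combos))) {
    pos <- combos[, k]
    gaps <- diff(pos) - 1L
    if (any(gaps < lo | gaps > hi)) next
    between <- chars[(pos[2] + 1L):(pos[3] - 1L)]
    if (!"P" %in% between) next
    return(pos)
  }
  NULL
}

# position-by-position IUPAC matcher; a subject N only matches the pattern
# code N
oracle_iupac_scan <- function(sequence, pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T", "N"))
  sub <- strsplit(sequence, "")[[1]]
  pat <- strsplit(pattern, "")[[1]]
  m <- length(pat)
  hits <- integer()
  for (s in seq_len(length(sub) - m + 1L)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!sub[s + j - 1L] %in% sets[[pat[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Nei-Gojobori by full enumeration: synonymous-site fractions from the nine
# single-nucleotide mutants of each codon (stop mutants dropped from the
# denominator), differences averaged over every substitution ordering that
# avoids stop intermediates.
oracle_ng86 <- function(cod1, cod2) {
  code <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  site_s <- function(cod) {
    total <- 0
    for (p in 1:3) {
      syn <- 0; valid <- 0
      for (nt in setdiff(nts, substr(cod, p, p))) {
        mut <- cod
        substr(mut, p, p) <- nt
        if (code[mut] == "*") next
        valid <- valid + 1
        if (code[mut] == code[cod]) syn <- syn + 1
      }
      if (valid > 0) total <- total + syn / valid
    }
    total
  }
  all_orders <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in all_orders(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  diffs <- which(strsplit(cod1, "")[[1]] != strsplit(cod2, "")[[1]])
  sd <- 0; nd <- 0
  if (length(diffs)) {
    paths <- list()
    for (ord in all_orders(diffs)) {
      cur <- cod1
      steps <- c(); blocked <- FALSE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cod2, p, p)
        if (code[nxt] == "*" && nxt != cod2) { blocked <- TRUE; break }
        steps <- c(steps, if (code[cur] == code[nxt]) "s" else "n")
        cur <- nxt
      }
      if (!blocked) paths <- c(paths, list(steps))
    }
    if (length(paths)) {
      sd <- mean(vapply(paths, function(s) sum(s == "s"), numeric(1)))
      nd <- mean(vapply(paths, function(s) sum(s == "n"), numeric(1)))
    }
  }
  list(S = (site_s(cod1) + site_s(cod2)) / 2, sd = sd, nd = nd)
}

# 0.001-step grid search for the pI (argmin of |net charge|)
oracle_pi_grid <- function(sequence) {
  grid <- seq(0, 14, by = 0.001)
  q <- xylpscan::net_charge(sequence, grid)
  grid[which.min(abs(q))]
}

# random peptide helper
rand_peptide <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H", "I",
                                         "K", "L", "M", "N", "P", "Q", "R", "S",
                                         "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

SENSE_CODONS_T <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
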