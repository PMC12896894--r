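check_canonical <- function(sequence, what) {
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% AA20)
  if (length(bad))
    stop(what, ": non-canonical residue '", chars[bad[1]], "' at position ", bad[1])
  chars
}

#' Molecular weight of a protein
#'
#' Sum of average (not monoisotopic) residue masses plus one water mass,
#' following the ProtParam convention, reported in kDa.
#'
#' @param sequence Amino-acid string (20 canonical residues).
#' @param digits Decimal places for rounding; `NA` for no rounding.
#' @return Molecular weight in kDa.
#' @export
molecular_weight <- function(sequence, digits = 2L) {
  if (!nzchar(sequence)) stop("empty sequence")
  chars <- check_canonical(sequence, "molecular_weight")
  mw <- (sum(AA_MASS[chars]) + WATER_MASS) / 1000
  if (is.na(digits)) mw else round(mw, digits)
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch net charge over the N-terminus, C-terminus and the
#' ionizable side chains (D, E, C, Y negative; H, K, R positive) with the
#' Bjellqvist pKa set. Strictly decreasing in pH.
#'
#' @param sequence Amino-acid string.
#' @param ph pH value (vectorized).
#' @return Net charge (same length as `ph`).
#' @export
net_charge <- function(sequence, ph) {
  chars <- check_canonical(sequence, "net_charge")
  nterm_pka <- if (chars[1] %in% names(PKA_NTERM)) PKA_NTERM[[chars[1]]] else PKA_NTERM_DEFAULT
  counts <- table(factor(chars, levels = AA20))
  vapply(ph, function(p) {
    pos <- 1 / (1 + 10^(p - nterm_pka)) +
      sum(counts[names(PKA_SIDE_POS)] / (1 + 10^(p - PKA_SIDE_POS)))
    neg <- 1 / (1 + 10^(PKA_CTERM - p)) +
      sum(counts[names(PKA_SIDE_NEG)] / (1 + 10^(PKA_SIDE_NEG - p)))
    pos - neg
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' pH at which the net charge crosses zero, found by bisection on `[0, 14]`
#' to `|charge| < tol`; the net charge is strictly decreasing in pH, so the
#' root is unique.
#'
#' @param sequence Amino-acid string.
#' @param tol Charge tolerance for convergence.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, tol = 1e-4) {
  if (!nzchar(sequence)) stop("empty sequence")
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(sequence, mid)
    if (abs(q) < tol || (hi - lo) < 1e-9) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues; positive values indicate
#' a hydrophobic protein.
#'
#' @param sequence Amino-acid string.
#' @return GRAVY value.
#' @export
gravy <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  chars <- check_canonical(sequence, "gravy")
  mean(KD_SCALE[chars])
}

#' Kyte-Doolittle hydropathy profile
#'
#' Sliding unweighted window means of the Kyte-Doolittle scale (ProtScale
#' default weighting), one value per window center.
#'
#' @param sequence Amino-acid string, length >= `window`.
#' @param window Odd window size (default 9).
#' @return List with `window` and `values` (length `nchar(sequence) - window + 1`).
#' @export
hydropathy_profile <- function(sequence, window = 9L) {
  if (window %% 2L == 0L) stop("window must be odd")
  n <- nchar(sequence)
  if (window > n) stop("window larger than sequence")
  chars <- check_canonical(sequence, "hydropathy_profile")
  cs <- c(0, cumsum(KD_SCALE[chars]))
  starts <- seq_len(n - window + 1L)
  list(window = window, values = unname((cs[starts + window] - cs[starts]) / window))
}

#' Guruprasad instability index
#'
#' `(10 / L) * sum(DIWV(x_i, x_{i+1}))` over the `L - 1` consecutive
#' dipeptides, using the published 400-entry dipeptide weight table. Values
#' above 40 predict an unstable protein.
#'
#' @param sequence Amino-acid string, length >= 2.
#' @return Instability index.
#' @export
instability_index <- function(sequence) {
  chars <- check_canonical(sequence, "instability_index")
  L <- length(chars)
  if (L < 2L) stop("sequence must have >= 2 residues")
  (10 / L) * sum(DIWV[cbind(chars[-L], chars[-1])])
}

#' Aliphatic index
#'
#' `X_Ala + 2.9 * X_Val + 3.9 * (X_Ile + X_Leu)` with X in mole percent:
#' the relative volume occupied by aliphatic side chains.
#'
#' @param sequence Amino-acid string.
#' @return Aliphatic index.
#' @export
aliphatic_index <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  chars <- check_canonical(sequence, "aliphatic_index")
  f <- function(a) 100 * sum(chars == a) / length(chars)
  f("A") + 2.9 * f("V") + 3.9 * (f("I") + f("L"))
}

#' Full physicochemical profile for one protein
#'
#' Computes the characterization row for one protein: length, molecular
#' weight, theoretical pI, GRAVY, instability index, aliphatic index, and the
#' categorical labels alkaline (pI > 7.0), unstable (instability index > 40)
#' and hydrophobic (GRAVY > 0).
#'
#' @param id Protein identifier.
#' @param sequence Amino-acid string.
#' @return One-row data frame with columns `protein_id`, `length`, `mw_kda`,
#'   `pi`, `gravy`, `instability`, `aliphatic`, `is_alkaline`, `is_unstable`,
#'   `is_hydrophobic`.
#' @export
physchem_profile <- function(id, sequence) {
  g <- gravy(sequence)
  ii <- instability_index(sequence)
  pi <- isoelectric_point(sequence)
  data.frame(protein_id = id, length = nchar(sequence),
             mw_kda = molecular_weight(sequence), pi = pi, gravy = g,
             instability = ii, aliphatic = aliphatic_index(sequence),
             is_alkaline = pi > 7.0, is_unstable = ii > 40,
             is_hydrophobic = g > 0, stringsAsFactors = FALSE)
}

#' Physicochemical profiles for a proteome
#'
#' @param proteome Data frame from [read_fasta()].
#' @param sidecar Optional annotation sidecar data frame (external predictor
#'   output, e.g. columns `protein_id`, `signal_peptide`, `gpi_anchor`,
#'   `gpi_likelihood`, `subcellular`) merged onto the profile table by
#'   `protein_id`; never computed here.
#' @return Data frame with one [physchem_profile()] row per protein.
#' @export
physchem_table <- function(proteome, sidecar = NULL) {
  out <- do.call(rbind, Map(physchem_profile, proteome$id, proteome$sequence))
  rownames(out) <- NULL
  if (!is.null(sidecar)) {
    if (!"protein_id" %in% names(sidecar)) stop("sidecar lacks protein_id column")
    unknown <- setdiff(sidecar$protein_id, out$protein_id)
    if (length(unknown)) stop("sidecar references unknown protein id(s): ",
                              paste(unknown, collapse = ", "))
    out <- merge(out, sidecar, by = "protein_id", all.x = TRUE, sort = FALSE)
  }
  out
}
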