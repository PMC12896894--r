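#' PAST fraction of a sequence window
#'
#' Fraction of Pro/Ala/Ser/Thr residues in the window `start..end` (1-based
#' inclusive). `X` residues count in the denominator only.
#'
#' @param sequence Amino-acid string.
#' @param start,end Window bounds, 1-based inclusive; default full span.
#' @return Number in `[0, 1]`.
#' @export
past_fraction <- function(sequence, start = 1L, end = nchar(sequence)) {
  n <- nchar(sequence)
  if (!(start >= 1L && start <= end && end <= n)) stop("invalid window [", start, ",", end, "]")
  win <- strsplit(substr(sequence, start, end), "")[[1]]
  sum(win %in% PAST_RESIDUES) / length(win)
}

#' Find PAST-rich regions
#'
#' Scans for regions of AGP-backbone character: every window of length at
#' least `l_min` whose PAST fraction is at least `theta` is found, and the
#' maximal runs of the union of all such windows are reported left to right.
#' This is the deterministic, oracle-checkable reading of "at least one region
#' with >= 35% PAST residues": any qualifying window is contained in exactly
#' one reported region.
#'
#' @param sequence Amino-acid string.
#' @param theta PAST-fraction threshold, in `(0, 1]`; the threshold is
#'   inclusive (a window at exactly `theta` qualifies).
#' @param l_min Minimum window length (>= 2).
#' @return Data frame with columns `start`, `end` (1-based inclusive),
#'   `length`, `past_fraction` (the fraction over the reported region);
#'   zero rows when no window qualifies.
#' @export
find_past_regions <- function(sequence, theta = 0.35, l_min = 20L) {
  if (!(theta > 0 && theta <= 1)) stop("theta must be in (0, 1]")
  if (l_min < 2L) stop("l_min must be >= 2")
  n <- nchar(sequence)
  if (n < 1L) stop("empty sequence")
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      past_fraction = numeric())
  if (n < l_min) return(empty)
  is_past <- strsplit(sequence, "")[[1]] %in% PAST_RESIDUES
  cs <- c(0L, cumsum(is_past))
  covered <- logical(n)
  # windows of exactly l_min .. n; a longer qualifying window whose sub-windows
  # do not qualify must still be covered, so all lengths are scanned.
  for (L in l_min:n) {
    starts <- seq_len(n - L + 1L)
    frac <- (cs[starts + L] - cs[starts]) / L
    ok <- frac >= theta
    if (any(ok)) for (s in starts[ok]) covered[s:(s + L - 1L)] <- TRUE
  }
  if (!any(covered)) return(empty)
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(start = starts[keep], end = ends[keep])
  out$length <- out$end - out$start + 1L
  out$past_fraction <- mapply(function(s, e) (cs[e + 1L] - cs[s]) / (e - s + 1L),
                              out$start, out$end)
  out
}

#' Find AG glycomodule dipeptides
#'
#' Reports every occurrence (overlaps included) of the six AG glycomodule
#' dipeptides (AP, PA, SP, PS, TP, PT) whose start position lies in the given
#' region.
#'
#' @param sequence Amino-acid string.
#' @param start,end Region bounds for the dipeptide start position, 1-based
#'   inclusive; default full span.
#' @return Data frame with columns `position` (1-based start) and `dipeptide`,
#'   positions ascending.
#' @export
find_glycomodules <- function(sequence, start = 1L, end = nchar(sequence)) {
  n <- nchar(sequence)
  if (!(start >= 1L && end <= n && start <= end)) stop("region out of bounds")
  hi <- min(end, n - 1L)
  out <- data.frame(position = integer(), dipeptide = character())
  if (hi < start) return(out)
  pos <- start:hi
  dip <- substring(sequence, pos, pos + 1L)
  keep <- dip %in% AG_GLYCOMODULES
  data.frame(position = pos[keep], dipeptide = dip[keep], stringsAsFactors = FALSE)
}

#' Default spacer bounds for the nsLTP eight-cysteine motif
#'
#' Inclusive bounds on the number of residues between consecutive cysteines of
#' the C1-X-C2-X-P-X-C3C4-X-C5XC6-X-C7-X-C8 consensus. The C3-C4 (adjacent)
#' and C5-C6 (single residue) spacers and the Pro between C2 and C3 are hard
#' constraints of the consensus and are not configurable here.
#'
#' @return Named list of `c(min, max)` integer pairs.
#' @export
default_nsltp_bounds <- function() {
  list(c1_c2 = c(5L, 15L), c2_c3 = c(8L, 20L), c4_c5 = c(5L, 30L),
       c6_c7 = c(10L, 30L), c7_c8 = c(3L, 20L))
}

HYDROPHOBIC_56 <- c("L", "I", "V", "A", "F", "M")

#' Match the nsLTP eight-cysteine motif
#'
#' Searches for the leftmost assignment of eight cysteines satisfying the
#' consensus C1-X-C2-X-P-X-C3C4-X-C5XC6-X-C7-X-C8: C3 and C4 adjacent, exactly
#' one residue between C5 and C6, at least one proline strictly between C2 and
#' C3, and all remaining spacers within `bounds`. "Leftmost" means smallest C1
#' position, ties broken by smallest C2, then C3, and so on. The residue
#' between C5 and C6 is reported together with whether it is hydrophobic
#' (L/I/V/A/F/M) - typically leucine - but hydrophobicity is never a filter.
#'
#' @param sequence Amino-acid string.
#' @param bounds Spacer bounds as from [default_nsltp_bounds()].
#' @return `NULL` if no assignment exists, otherwise a list with
#'   `cys_positions` (8 increasing positions), `spacer_lengths` (7 integers),
#'   `inter56_residue`, `inter56_hydrophobic`, and `proline_position` (first
#'   Pro between C2 and C3).
#' @export
match_nsltp_motif <- function(sequence, bounds = default_nsltp_bounds()) {
  for (b in bounds) if (b[1] > b[2]) stop("malformed bounds: min > max")
  chars <- strsplit(sequence, "")[[1]]
  cys <- which(chars == "C")
  if (length(cys) < 8L) return(NULL)
  pro <- which(chars == "P")
  # gap bounds between consecutive cysteines C1..C8 (residues strictly between)
  lo <- c(bounds$c1_c2[1], bounds$c2_c3[1], 0L, bounds$c4_c5[1], 1L, bounds$c6_c7[1], bounds$c7_c8[1])
  hi <- c(bounds$c1_c2[2], bounds$c2_c3[2], 0L, bounds$c4_c5[2], 1L, bounds$c6_c7[2], bounds$c7_c8[2])
  # depth-first search in lexicographic order over cysteine positions; the
  # first complete assignment found is the leftmost one.
  assign_next <- function(chosen) {
    k <- length(chosen)
    if (k == 8L) return(chosen)
    cand <- cys[cys > chosen[k]]
    gaps <- cand - chosen[k] - 1L
    cand <- cand[gaps >= lo[k] & gaps <= hi[k]]
    for (p in cand) {
      if (k == 2L && !any(pro > chosen[2] & pro < p)) next
      res <- assign_next(c(chosen, p))
      if (!is.null(res)) return(res)
    }
    NULL
  }
  for (c1 in cys) {
    res <- assign_next(c1)
    if (!is.null(res)) {
      spacers <- diff(res) - 1L
      inter <- chars[res[5] + 1L]
      return(list(cys_positions = res,
                  spacer_lengths = spacers,
                  inter56_residue = inter,
                  inter56_hydrophobic = inter %in% HYDROPHOBIC_56,
                  proline_position = pro[pro > res[2] & pro < res[3]][1]))
    }
  }
  NULL
}

#' Classify one protein as XYLP or not
#'
#' Applies the three-part membership rule for xylogen-like proteins: (i) at
#' least one PAST-rich region, (ii) at least one AG glycomodule starting
#' inside some PAST-rich region, and (iii) a matched eight-cysteine nsLTP
#' motif. The verdict is `"XYLP"` iff all three hold.
#'
#' @param id Protein identifier.
#' @param sequence Amino-acid string.
#' @param theta,l_min PAST-region parameters, see [find_past_regions()].
#' @param bounds nsLTP spacer bounds, see [match_nsltp_motif()].
#' @return A list of class `xylp_call` with `protein_id`, `past_regions`,
#'   `glyco_hits` (hits inside PAST regions), `motif`, `verdict` and `reasons`
#'   (per-rule codes: `past_region_ok`/`no_past_region`,
#'   `glycomodule_ok`/`no_glycomodule_in_region`,
#'   `nsltp_motif_ok`/`no_nsltp_motif`).
#' @export
classify_xylp <- function(id, sequence, theta = 0.35, l_min = 20L,
                          bounds = default_nsltp_bounds()) {
  regions <- find_past_regions(sequence, theta = theta, l_min = l_min)
  hits <- if (nrow(regions)) {
    do.call(rbind, lapply(seq_len(nrow(regions)), function(i)
      find_glycomodules(sequence, regions$start[i], regions$end[i])))
  } else data.frame(position = integer(), dipeptide = character())
  motif <- if (nchar(sequence) >= 8L) match_nsltp_motif(sequence, bounds) else NULL
  reasons <- c(
    if (nrow(regions)) "past_region_ok" else "no_past_region",
    if (nrow(hits)) "glycomodule_ok" else "no_glycomodule_in_region",
    if (!is.null(motif)) "nsltp_motif_ok" else "no_nsltp_motif")
  verdict <- if (nrow(regions) && nrow(hits) && !is.null(motif)) "XYLP" else "not_XYLP"
  structure(list(protein_id = id, past_regions = regions, glyco_hits = hits,
                 motif = motif, verdict = verdict, reasons = reasons),
            class = "xylp_call")
}

#' @export
print.xylp_call <- function(x, ...) {
  cat("<xylp_call>", x$protein_id, "->", x$verdict, "\n")
  cat("  PAST regions:", nrow(x$past_regions),
      "| glycomodules in regions:", nrow(x$glyco_hits),
      "| nsLTP motif:", if (is.null(x$motif)) "absent" else "present", "\n")
  cat("  reasons:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Classify a whole proteome
#'
#' @param proteome Data frame from [read_fasta()].
#' @inheritParams classify_xylp
#' @return List of `xylp_call` objects, one per protein, in input order.
#' @export
classify_proteome <- function(proteome, theta = 0.35, l_min = 20L,
                              bounds = default_nsltp_bounds()) {
  Map(classify_xylp, proteome$id, proteome$sequence,
      MoreArgs = list(theta = theta, l_min = l_min, bounds = bounds))
}

#' Name accepted candidates
#'
#' Assigns family names `prefix1..prefixN` to the accepted proteins in input
#' order (e.g. `AcXYLP1..AcXYLP28`).
#'
#' @param calls List of `xylp_call` objects.
#' @param prefix Name prefix, e.g. `"AcXYLP"`.
#' @return Named character vector mapping protein id to family name; empty
#'   (with a warning) when nothing was accepted.
#' @export
name_candidates <- function(calls, prefix) {
  acc <- vapply(calls, function(x) x$verdict == "XYLP", logical(1))
  ids <- vapply(calls, `[[`, "", "protein_id")[acc]
  if (!length(ids)) {
    warning("no accepted XYLP candidates to name")
    return(setNames(character(), character()))
  }
  setNames(paste0(prefix, seq_along(ids)), ids)
}

#' Tabulate classification calls
#'
#' Flattens a list of [classify_xylp()] calls into the report table written by
#' the pipeline.
#'
#' @param calls List of `xylp_call` objects.
#' @return Data frame with one row per protein: `protein_id`, `verdict`,
#'   `n_past_regions`, `best_region` ("start-end" of the longest region),
#'   `n_glycomodules`, `cys_positions` (comma-separated), `reasons`.
#' @export
classification_table <- function(calls) {
  do.call(rbind, lapply(calls, function(x) {
    best <- if (nrow(x$past_regions)) {
      i <- which.max(x$past_regions$length)
      paste0(x$past_regions$start[i], "-", x$past_regions$end[i])
    } else ""
    data.frame(protein_id = x$protein_id, verdict = x$verdict,
               n_past_regions = nrow(x$past_regions), best_region = best,
               n_glycomodules = nrow(x$glyco_hits),
               cys_positions = if (is.null(x$motif)) "" else
                 paste(x$motif$cys_positions, collapse = ","),
               reasons = paste(x$reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}
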