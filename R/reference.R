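#' Published AcXYLP physicochemical reference table
#'
#' The printed characterization table for the 28 kiwifruit XYLP family
#' members (AcXYLP1-AcXYLP28), bundled as a plain-text fixture: amino-acid
#' length, molecular weight (kDa), theoretical pI, aliphatic index,
#' instability index, GRAVY, and the external GPI-anchor prediction columns.
#' Used for worked-example checks of the categorical labels (alkaline pI >
#' 7.0, unstable instability > 40, hydrophobic GRAVY > 0).
#'
#' @return Data frame with 28 rows and 10 columns (`gene_name`, `gene_id`,
#'   `length`, `mw_kda`, `pi`, `aliphatic`, `instability`, `gravy`,
#'   `gpi_anchored`, `gpi_likelihood`).
#' @export
acxylp_reference_table <- function() {
  path <- system.file("extdata", "acxylp_table1.tsv", package = "xylpscan")
  read_table(path, required = c("gene_name", "length", "mw_kda", "pi",
                                "aliphatic", "instability", "gravy"))
}

#' Recompute categorical labels from a physicochemical table
#'
#' Applies the alkaline/unstable/hydrophobic thresholds to the numeric
#' columns of a profile table (computed or published), yielding the family
#' narrative counts.
#'
#' @param tab Data frame with columns `pi`, `instability`, `gravy`.
#' @return Named integer vector: `n`, `n_alkaline` (pi > 7.0), `n_stable`
#'   (instability < 40), `n_unstable` (instability > 40), `n_hydrophilic`
#'   (gravy < 0).
#' @export
physchem_label_counts <- function(tab) {
  stopifnot(all(c("pi", "instability", "gravy") %in% names(tab)))
  c(n = nrow(tab),
    n_alkaline = sum(tab$pi > 7.0),
    n_stable = sum(tab$instability < 40),
    n_unstable = sum(tab$instability > 40),
    n_hydrophilic = sum(tab$gravy < 0))
}
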