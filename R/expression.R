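#' TPM from raw counts
#'
#' Transcripts-per-million normalization: per-gene count rates
#' (`count / effective length`) scaled so every sample column sums to 1e6.
#'
#' @param counts Gene x sample numeric matrix of read counts (gene ids as
#'   rownames).
#' @param lengths Positive effective lengths, one per gene.
#' @return Matrix of TPM values with the same dimnames; all-zero columns stay
#'   zero with a warning.
#' @export
tpm_from_counts <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("effective lengths must be > 0")
  if (length(lengths) != nrow(counts)) stop("one length per gene required")
  rate <- counts / lengths
  cs <- colSums(rate)
  zero <- cs == 0
  if (any(zero)) {
    warning("all-zero sample column(s): ", paste(colnames(counts)[zero], collapse = ", "))
    cs[zero] <- 1
  }
  sweep(rate, 2, cs, "/") * 1e6
}

#' Hierarchically cluster expression rows for heatmap ordering
#'
#' Agglomerative average-linkage clustering on Euclidean distances between
#' (optionally transformed) gene rows - the standard heatmap ordering for
#' TPM matrices. Rows are pre-sorted by gene name so that merge-order ties
#' resolve deterministically by name.
#'
#' @param matrix Gene x sample numeric matrix (gene ids as rownames).
#' @param transform `"log2"` (cluster `log2(TPM + 1)`, default) or `"raw"`.
#' @return List of class `cluster_result` with `leaf_order` (gene ids in
#'   dendrogram order), `hclust` (the [stats::hclust] object) and `matrix`
#'   (the input rows in leaf order).
#' @export
cluster_rows <- function(matrix, transform = c("log2", "raw")) {
  transform <- match.arg(transform)
  m <- as.matrix(matrix)
  if (nrow(m) < 2L) stop("need >= 2 genes")
  if (any(!is.finite(m))) stop("non-finite values in expression matrix")
  m <- m[order(rownames(m)), , drop = FALSE]
  x <- if (transform == "log2") log2(m + 1) else m
  hc <- hclust(dist(x, method = "euclidean"), method = "average")
  list(leaf_order = rownames(m)[hc$order], hclust = hc,
       matrix = m[hc$order, , drop = FALSE]) |>
    structure(class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", length(x$leaf_order), "genes; leaf order:",
      paste(utils::head(x$leaf_order, 8), collapse = ", "),
      if (length(x$leaf_order) > 8) "..." else "", "\n")
  invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' For every replicate, `dCt = Ct_target - Ct_reference` (replicate-matched
#' reference); `ddCt = dCt - mean(dCt of the control sample)` per gene;
#' `RQ = 2^-ddCt`. Reports the mean and standard deviation of RQ across
#' replicates for every (gene, sample).
#'
#' @param ct Data frame with columns `gene`, `sample`, `replicate`, `ct`.
#' @param reference_gene Name of the reference gene (present in every
#'   sample/replicate).
#' @param control_sample Name of the control (calibrator) sample.
#' @return Data frame with columns `gene`, `sample`, `mean_rq`, `sd_rq`,
#'   `n_replicates`.
#' @export
relative_expression_ddct <- function(ct, reference_gene, control_sample) {
  stopifnot(all(c("gene", "sample", "replicate", "ct") %in% names(ct)))
  if (!reference_gene %in% ct$gene) stop("reference gene not in table: ", reference_gene)
  if (!control_sample %in% ct$sample) stop("control sample not in table: ", control_sample)
  ref <- ct[ct$gene == reference_gene, ]
  ref_key <- paste(ref$sample, ref$replicate)
  ref_ct <- setNames(ref$ct, ref_key)
  targets <- ct[ct$gene != reference_gene, ]
  key <- paste(targets$sample, targets$replicate)
  miss <- unique(key[!key %in% ref_key])
  if (length(miss)) stop("missing reference Ct for sample/replicate: ",
                         paste(miss, collapse = "; "))
  targets$dct <- targets$ct - ref_ct[key]
  out <- list()
  for (g in unique(targets$gene)) {
    tg <- targets[targets$gene == g, ]
    ctrl <- tg$dct[tg$sample == control_sample]
    if (!length(ctrl)) stop("no control-sample rows for gene ", g)
    base <- mean(ctrl)
    for (s in unique(tg$sample)) {
      rq <- 2^-(tg$dct[tg$sample == s] - base)
      out[[length(out) + 1L]] <- data.frame(
        gene = g, sample = s, mean_rq = mean(rq),
        sd_rq = if (length(rq) > 1L) sd(rq) else NA_real_,
        n_replicates = length(rq), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
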