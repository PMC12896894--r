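msa_matrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  if (length(unique(nchar(msa))) != 1L) stop("alignment rows differ in length")
  m <- do.call(rbind, strsplit(msa, ""))
  rownames(m) <- names(msa)
  m
}

#' Poisson-corrected protein distance matrix
#'
#' For each pair of rows, the proportion of mismatches `p` is computed over
#' the columns where both rows are non-gap (pairwise deletion), then
#' corrected as `d = -ln(1 - p)`. Pairs with `p >= 1` are saturated: their
#' distance is set to `cap` and flagged in the `"saturated"` attribute.
#'
#' @param msa Named character vector of equal-length aligned rows (gap `-`),
#'   or a character matrix (taxa x sites).
#' @param cap Distance assigned to saturated pairs.
#' @return Symmetric numeric matrix with zero diagonal, taxa as dimnames, and
#'   a logical `"saturated"` attribute matrix.
#' @export
poisson_distance <- function(msa, cap = 10) {
  m <- msa_matrix(msa)
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 taxa")
  taxa <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  sat <- matrix(FALSE, n, n, dimnames = list(taxa, taxa))
  gap <- m == "-"
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- !gap[i, ] & !gap[j, ]
    ns <- sum(shared)
    if (ns == 0L) stop("no shared non-gap sites for pair ", taxa[i], " / ", taxa[j])
    p <- sum(m[i, shared] != m[j, shared]) / ns
    if (p >= 1) {
      d[i, j] <- d[j, i] <- cap
      sat[i, j] <- sat[j, i] <- TRUE
    } else {
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  attr(d, "saturated") <- sat
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) with negative branch lengths
#' clamped to zero; clamping is flagged in the `"clamped"` attribute of the
#' returned tree.
#'
#' @param dm Symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return An unrooted `phylo` object.
#' @export
nj_tree <- function(dm) {
  if (!isSymmetric(unname(as.matrix(dm)), tol = 1e-8)) stop("distance matrix not symmetric")
  if (nrow(as.matrix(dm)) < 3L) stop("need >= 3 taxa")
  tr <- ape::nj(as.matrix(dm))
  clamped <- any(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Builds the full-data NJ tree from Poisson-corrected distances, then
#' resamples alignment columns with replacement `B` times, rebuilds the tree
#' for each replicate, and records for each internal bipartition of the
#' full-data tree the percentage of replicate trees containing it
#' (MEGA-equivalent procedure). Deterministic for a fixed `seed`.
#'
#' @param msa Named character vector of aligned rows, or character matrix
#'   (>= 4 taxa).
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for column resampling.
#' @param cap Saturation cap passed to [poisson_distance()].
#' @return The full-data `phylo` tree with integer percentage supports in
#'   `$node.label` (root label `NA`) and the seed recorded in the `"seed"`
#'   attribute.
#' @export
bootstrap_support <- function(msa, B = 1000L, seed = 1L, cap = 10) {
  if (B < 1L) stop("B must be >= 1")
  m <- msa_matrix(msa)
  if (nrow(m) < 4L) stop("need >= 4 taxa")
  ref <- nj_tree(poisson_distance(m, cap = cap))
  set.seed(seed)
  reps <- lapply(seq_len(B), function(b) {
    idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
    nj_tree(poisson_distance(m[, idx, drop = FALSE], cap = cap))
  })
  cnt <- ape::prop.clades(ref, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- B  # trivial (root) bipartition is present in every tree
  supp <- round(100 * cnt / B)
  ref$node.label <- as.character(supp)
  ref$node.label[1] <- NA  # root of the unrooted representation carries no split
  attr(ref, "seed") <- seed
  ref
}
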