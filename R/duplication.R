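# Longest collinear chain by dynamic programming over anchors. `xs`, `ys` are
# anchor coordinates (gene ranks on the two chromosome axes); both must
# strictly increase along a chain (`ys` strictly decreases when sign = -1),
# with at most `max_gaps` intervening ranks between consecutive anchors on
# either axis. Returns indices of the longest chain (ties broken by first
# lexicographic occurrence).
longest_chain <- function(xs, ys, max_gaps, sign = 1L) {
  n <- length(xs)
  ord <- order(xs, sign * ys)
  x <- xs[ord]; y <- sign * ys[ord]
  len <- rep(1L, n); prev <- rep(NA_integer_, n)
  for (j in seq_len(n)) for (i in seq_len(j - 1L)) {
    if (x[j] > x[i] && y[j] > y[i] &&
        (x[j] - x[i] - 1L) <= max_gaps && (y[j] - y[i] - 1L) <= max_gaps &&
        len[i] + 1L > len[j]) {
      len[j] <- len[i] + 1L
      prev[j] <- i
    }
  }
  best <- which.max(len)
  chain <- integer()
  k <- best
  while (!is.na(k)) { chain <- c(k, chain); k <- prev[k] }
  ord[chain]
}

#' Classify duplicate gene pairs as tandem, segmental or dispersed
#'
#' A pair is *tandem* when both genes sit on the same chromosome within
#' `tandem_window` ranks of each other. The remaining pairs are treated as
#' collinearity anchors: for each chromosome pair, maximal chains of anchors
#' with strictly increasing ranks on both axes (either orientation) and at
#' most `max_gaps` intervening ranks between consecutive anchors are
#' extracted greedily (longest first); pairs in a chain of at least
#' `match_size` anchors are *segmental*, everything else *dispersed*.
#'
#' @param loci Gene locus table from [read_gene_loci()] (needs `gene_id`,
#'   `chromosome`, `rank`).
#' @param pairs Data frame of homologous pairs with columns `gene1`, `gene2`.
#' @param match_size Minimum anchors per collinear chain (default 5).
#' @param max_gaps Maximum intervening ranks between consecutive anchors
#'   (default 25).
#' @param tandem_window Maximum rank distance for a tandem call (default 2).
#' @return Data frame with columns `gene1`, `gene2`, `mode`
#'   (`tandem`/`segmental`/`dispersed`), `chain_id` (`NA` unless segmental)
#'   and `chain_length`.
#' @export
classify_duplications <- function(loci, pairs, match_size = 5L, max_gaps = 25L,
                                  tandem_window = 2L) {
  idx <- match(c(pairs$gene1, pairs$gene2), loci$gene_id)
  if (anyNA(idx)) {
    bad <- c(pairs$gene1, pairs$gene2)[is.na(idx)]
    stop("unknown gene(s) in pairs: ", paste(unique(bad), collapse = ", "))
  }
  np <- nrow(pairs)
  chr1 <- loci$chromosome[idx[seq_len(np)]]
  chr2 <- loci$chromosome[idx[np + seq_len(np)]]
  r1 <- loci$rank[idx[seq_len(np)]]
  r2 <- loci$rank[idx[np + seq_len(np)]]
  out <- data.frame(gene1 = pairs$gene1, gene2 = pairs$gene2,
                    mode = "dispersed", chain_id = NA_character_,
                    chain_length = NA_integer_, stringsAsFactors = FALSE)
  tandem <- chr1 == chr2 & abs(r1 - r2) <= tandem_window
  out$mode[tandem] <- "tandem"
  # orient each remaining anchor on a canonical chromosome-pair axis
  rest <- which(!tandem)
  if (length(rest)) {
    a_first <- chr1[rest] <= chr2[rest]
    ax_chr <- ifelse(a_first, chr1[rest], chr2[rest])
    ay_chr <- ifelse(a_first, chr2[rest], chr1[rest])
    x <- ifelse(a_first, r1[rest], r2[rest])
    y <- ifelse(a_first, r2[rest], r1[rest])
    same <- ax_chr == ay_chr
    x2 <- ifelse(same, pmin(x, y), x)
    y2 <- ifelse(same, pmax(x, y), y)
    key <- paste(ax_chr, ay_chr, sep = "|")
    chain_no <- 0L
    for (k in unique(key)) {
      members <- rest[key == k]
      xs <- x2[key == k]; ys <- y2[key == k]
      avail <- rep(TRUE, length(members))
      repeat {
        live <- which(avail)
        if (length(live) < match_size) break
        fwd <- longest_chain(xs[live], ys[live], max_gaps, sign = 1L)
        rev_ <- longest_chain(xs[live], ys[live], max_gaps, sign = -1L)
        chain <- if (length(fwd) >= length(rev_)) fwd else rev_
        if (length(chain) < match_size) break
        chain_no <- chain_no + 1L
        sel <- members[live[chain]]
        out$mode[sel] <- "segmental"
        out$chain_id[sel] <- paste0("chain_", chain_no)
        out$chain_length[sel] <- length(chain)
        avail[live[chain]] <- FALSE
      }
    }
  }
  out
}

#' Summarize duplication calls
#'
#' @param calls Output of [classify_duplications()].
#' @return Named integer vector with pair-level counts per mode and the
#'   number of distinct segmental chains.
#' @export
duplication_summary <- function(calls) {
  c(tandem_pairs = sum(calls$mode == "tandem"),
    segmental_pairs = sum(calls$mode == "segmental"),
    dispersed_pairs = sum(calls$mode == "dispersed"),
    segmental_chains = length(unique(calls$chain_id[!is.na(calls$chain_id)])))
}
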