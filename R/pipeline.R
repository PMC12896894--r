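#' Default pipeline configuration
#'
#' Assembles the full parameter set of the workflow with its defaults:
#' classification thresholds (`theta` = 0.35, `l_min` = 20), nsLTP spacer
#' bounds, collinearity parameters (`match_size` = 5, `max_gaps` = 25,
#' `tandem_window` = 2), bootstrap replicate count (`bootstrap` = 1000),
#' promoter window (`promoter_length` = 2000 bp), heatmap transform and seed.
#' Validated before any stage runs and serialized (YAML) into the output
#' directory for reproducibility.
#'
#' @param ... Named overrides of any default.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(theta = 0.35, l_min = 20L, nsltp_bounds = default_nsltp_bounds(),
              name_prefix = "XYLP", match_size = 5L, max_gaps = 25L,
              tandem_window = 2L, bootstrap = 1000L, seed = 1L,
              promoter_length = 2000L, heatmap_transform = "log2",
              motif_strands = "+", reference_gene = "AcActin",
              control_sample = NULL,
              proteome = NULL, cds = NULL, gff = NULL, genome = NULL,
              msa = NULL, pairs = NULL, motifs = NULL, tpm = NULL, ct = NULL,
              sidecar = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$theta > 0, cfg$theta <= 1, cfg$l_min >= 2,
            cfg$match_size >= 1, cfg$max_gaps >= 0, cfg$tandem_window >= 0,
            cfg$bootstrap >= 1, cfg$promoter_length >= 1,
            cfg$heatmap_transform %in% c("log2", "raw"),
            cfg$motif_strands %in% c("+", "-", "both"))
  invisible(cfg)
}

stage_inputs <- list(
  classify = "proteome", physchem = "proteome", phylo = "msa",
  kaks = c("pairs", "msa", "cds"), dupes = c("gff", "pairs"),
  promoters = c("genome", "gff"), expression_cluster = "tpm",
  expression_ddct = c("ct", "control_sample"))

#' Run the full identification and characterization workflow
#'
#' Orchestrates the stages on the inputs named in the configuration: XYLP
#' classification, physicochemical profiling, NJ phylogeny with bootstrap,
#' Ka/Ks, duplication-mode classification, promoter cis-element counting,
#' expression clustering and 2^-ddCt quantification. Stages whose inputs are
#' absent are skipped unless explicitly requested via `only` (then a missing
#' input is an error before anything runs). One subdirectory per stage is
#' written under `out_dir`, with the serialized configuration, a run log and
#' a summary table at the root.
#'
#' @param config A [pipeline_config()]; file-path fields name the inputs.
#' @param out_dir Output directory (created if needed).
#' @param only Optional character vector restricting which stages run.
#' @return Invisibly, a named list of per-stage results.
#' @export
run_pipeline <- function(config, out_dir, only = NULL) {
  validate_config(config)
  stages <- names(stage_inputs)
  if (!is.null(only)) {
    bad <- setdiff(only, stages)
    if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
    stages <- only
  }
  have <- function(f) !is.null(config[[f]])
  runnable <- vapply(stages, function(s) all(vapply(stage_inputs[[s]], have, logical(1))),
                     logical(1))
  if (!is.null(only) && !all(runnable))
    stop("missing input for requested stage(s): ",
         paste(stages[!runnable], collapse = ", "))
  stages <- stages[runnable]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), ...,
                            "\n", file = log_path, append = TRUE)
  cfg_out <- config
  cfg_out$nsltp_bounds <- lapply(cfg_out$nsltp_bounds, as.integer)
  yaml::write_yaml(cfg_out[!vapply(cfg_out, is.null, logical(1))],
                   file.path(out_dir, "config.yaml"))
  logf("xylpscan", as.character(utils::packageVersion("xylpscan")),
       "| seed", config$seed, "| stages:", paste(stages, collapse = ","))
  results <- list()
  summary_rows <- list()
  note <- function(stage, what) summary_rows[[length(summary_rows) + 1L]] <<-
    data.frame(stage = stage, summary = what, stringsAsFactors = FALSE)

  sdir <- function(s) { d <- file.path(out_dir, s); dir.create(d, showWarnings = FALSE); d }

  proteome <- if (have("proteome")) read_fasta(config$proteome)
  loci <- if (have("gff")) read_gene_loci(config$gff)

  if ("classify" %in% stages) {
    logf("stage classify")
    calls <- classify_proteome(proteome, theta = config$theta, l_min = config$l_min,
                               bounds = config$nsltp_bounds)
    tab <- classification_table(calls)
    nm <- suppressWarnings(name_candidates(calls, config$name_prefix))
    tab$family_name <- unname(nm[tab$protein_id])
    write_table(tab, file.path(sdir("classify"), "classification.tsv"))
    results$classify <- list(calls = calls, table = tab, names = nm)
    note("classify", paste0(sum(tab$verdict == "XYLP"), "/", nrow(tab), " accepted"))
  }
  if ("physchem" %in% stages) {
    logf("stage physchem")
    sidecar <- if (have("sidecar")) read_table(config$sidecar, required = "protein_id")
    prof <- physchem_table(proteome, sidecar = sidecar)
    write_table(prof, file.path(sdir("physchem"), "physchem.tsv"))
    results$physchem <- prof
    note("physchem", paste0(nrow(prof), " profiles"))
  }
  if ("phylo" %in% stages) {
    logf("stage phylo")
    msa <- read_msa(config$msa)
    tree <- bootstrap_support(msa, B = config$bootstrap, seed = config$seed)
    write_newick(tree, file.path(sdir("phylo"), "tree.nwk"))
    results$phylo <- tree
    note("phylo", paste0(length(tree$tip.label), " taxa, B=", config$bootstrap))
  }
  if ("kaks" %in% stages) {
    logf("stage kaks")
    pairs <- read_table(config$pairs, required = c("gene1", "gene2"))
    msa <- read_msa(config$msa)
    cds <- read_dna_fasta(config$cds)
    kk <- kaks_table(pairs, msa, cds)
    write_table(kk, file.path(sdir("kaks"), "kaks.tsv"))
    results$kaks <- kk
    note("kaks", paste0(nrow(kk), " pairs, ", sum(!is.na(kk$ratio)), " with ratio"))
  }
  if ("dupes" %in% stages) {
    logf("stage dupes")
    pairs <- read_table(config$pairs, required = c("gene1", "gene2"))
    calls <- classify_duplications(loci, pairs, match_size = config$match_size,
                                   max_gaps = config$max_gaps,
                                   tandem_window = config$tandem_window)
    write_table(calls, file.path(sdir("dupes"), "duplications.tsv"))
    results$dupes <- calls
    sm <- duplication_summary(calls)
    note("dupes", paste(names(sm), sm, sep = "=", collapse = " "))
  }
  if ("promoters" %in% stages) {
    logf("stage promoters")
    genome <- read_dna_fasta(config$genome)
    dict <- if (have("motifs"))
      read_table(config$motifs, required = c("name", "pattern", "category"))
    else default_motif_dictionary()
    proms <- setNames(
      lapply(seq_len(nrow(loci)), function(i)
        extract_upstream(genome, loci[i, ], length = config$promoter_length)),
      loci$gene_id)
    truncated <- vapply(proms, function(p) isTRUE(attr(p, "truncated")), logical(1))
    hits <- scan_promoter_set(vapply(proms, as.character, ""), dict,
                              strands = config$motif_strands)
    rollup <- count_by_category(hits, dict)
    d <- sdir("promoters")
    write_table(hits, file.path(d, "hits.tsv"))
    write_table(as.data.frame(rollup$counts), file.path(d, "counts.tsv"))
    write_table(data.frame(category = names(rollup$category_pct),
                           total = rollup$category_totals,
                           pct = as.numeric(rollup$category_pct)),
                file.path(d, "category_pct.tsv"))
    results$promoters <- c(rollup, list(hits = hits, truncated = names(proms)[truncated]))
    note("promoters", paste0(nrow(hits), " hits in ", length(proms), " promoters"))
  }
  if ("expression_cluster" %in% stages) {
    logf("stage expression_cluster")
    tpm <- read_table(config$tpm)
    m <- as.matrix(tpm[, -1, drop = FALSE])
    rownames(m) <- tpm[[1]]
    cl <- cluster_rows(m, transform = config$heatmap_transform)
    d <- sdir("expression")
    ordered <- data.frame(gene = rownames(cl$matrix), cl$matrix, check.names = FALSE)
    write_table(ordered, file.path(d, "tpm_ordered.tsv"))
    write_newick(ape::as.phylo(cl$hclust), file.path(d, "gene_dendrogram.nwk"))
    results$expression_cluster <- cl
    note("expression_cluster", paste0(nrow(m), " genes clustered"))
  }
  if ("expression_ddct" %in% stages) {
    logf("stage expression_ddct")
    ct <- read_table(config$ct, required = c("gene", "sample", "replicate", "ct"))
    rq <- relative_expression_ddct(ct, config$reference_gene, config$control_sample)
    write_table(rq, file.path(sdir("expression"), "relative_expression.tsv"))
    results$expression_ddct <- rq
    note("expression_ddct", paste0(length(unique(rq$gene)), " genes quantified"))
  }
  if (length(summary_rows))
    write_table(do.call(rbind, summary_rows), file.path(out_dir, "summary.tsv"))
  logf("done")
  invisible(results)
}
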