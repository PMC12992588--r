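# Orchestration layer: run configuration and the commands tying the
# stages into the two analyses (proteome-wide bias ranking; uORF census +
# downstream-gene enrichment). A thin command-line wrapper over these
# functions lives in inst/cli/stallscan.R.

#' Build a run configuration
#'
#' Central defaults for a pipeline run. All thresholds default to the
#' values used throughout the analyses: tetrapeptides (`k = 4`), the
#' strict 300-residue small-protein cap, per-clade subsampling capped at
#' 1000 genomes, and significance at Benjamini-Hochberg adjusted p < 0.01.
#'
#' @param motifs Motif list (default `RAPP, RGPP, RAGP, AAPP, AGPP`).
#' @param k Word length for the bias statistic (default 4).
#' @param length_cap Small-protein cap, strict `<` (default 300).
#' @param subsample_cap Per-clade genome cap (default 1000).
#' @param subsample_seed Seed for the per-clade draw (default 214).
#' @param fisher_alternative Sidedness of the enrichment test
#'   (`"two.sided"` default).
#' @param bh_alpha Adjusted-p significance threshold (default 0.01).
#' @param max_gap Maximum intergenic distance when pairing (default
#'   `Inf`).
#' @param out_dir Output directory for TSV tables, or `NA` to skip
#'   writing.
#' @return list of class `stallscan_config`.
#' @export
run_config <- function(motifs = c("RAPP", "RGPP", "RAGP", "AAPP", "AGPP"),
                       k = 4L, length_cap = 300L,
                       subsample_cap = 1000L, subsample_seed = 214L,
                       fisher_alternative = "two.sided", bh_alpha = 0.01,
                       max_gap = Inf, out_dir = NA_character_) {
  stopifnot(k >= 1L, length_cap >= 1L, subsample_cap >= 1L,
            bh_alpha > 0, bh_alpha <= 1,
            fisher_alternative %in% c("two.sided", "greater", "less"))
  structure(list(motifs = motifs, k = as.integer(k),
                 length_cap = as.integer(length_cap),
                 subsample_cap = as.integer(subsample_cap),
                 subsample_seed = as.integer(subsample_seed),
                 fisher_alternative = fisher_alternative,
                 bh_alpha = bh_alpha, max_gap = max_gap,
                 out_dir = out_dir),
            class = "stallscan_config")
}

#' Write / read a run configuration as a plain-text key-value file
#'
#' One `key = value` line per field; `motifs` is comma-joined. The
#' round-trip `read_run_config(write_run_config(cfg, f))` reproduces the
#' configuration exactly.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config`: `path`, invisibly. `read_run_config`: a
#'   `stallscan_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "stallscan_config"))
  vals <- c(motifs = paste(config$motifs, collapse = ","),
            k = config$k, length_cap = config$length_cap,
            subsample_cap = config$subsample_cap,
            subsample_seed = config$subsample_seed,
            fisher_alternative = config$fisher_alternative,
            bh_alpha = format(config$bh_alpha, digits = 17),
            max_gap = format(config$max_gap, digits = 17),
            out_dir = ifelse(is.na(config$out_dir), "NA", config$out_dir))
  writeLines(paste(names(vals), "=", vals), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  pos <- regexpr("=", lines, fixed = TRUE)
  if (any(pos < 0)) stop("malformed key-value line: ", lines[pos < 0][1L])
  vals <- trimws(substring(lines, pos + 1L))
  names(vals) <- trimws(substr(lines, 1L, pos - 1L))
  run_config(motifs = strsplit(vals[["motifs"]], ",", fixed = TRUE)[[1L]],
             k = as.integer(vals[["k"]]),
             length_cap = as.integer(vals[["length_cap"]]),
             subsample_cap = as.integer(vals[["subsample_cap"]]),
             subsample_seed = as.integer(vals[["subsample_seed"]]),
             fisher_alternative = vals[["fisher_alternative"]],
             bh_alpha = as.numeric(vals[["bh_alpha"]]),
             max_gap = as.numeric(vals[["max_gap"]]),
             out_dir = ifelse(vals[["out_dir"]] == "NA", NA_character_,
                              vals[["out_dir"]]))
}

# TSV writer with '#'-prefixed provenance comments.
write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Short deterministic digest of a configuration, for provenance comments.
# The output location is not part of the analysis identity.
config_digest <- function(config) {
  cfg <- config[setdiff(names(config), "out_dir")]
  s <- paste(vapply(cfg, function(v) paste(format(v), collapse = ","), ""),
             collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% .Machine$integer.max)
}

#' Frequency-bias analysis over a set of proteomes
#'
#' The proteome-wide analysis: per-genome pattern statistics for the
#' configured motifs, per-clade bias summaries (mean/median/fraction-zero/
#' ECDF), and the cross-clade underrepresentation ranking over all `20^k`
#' patterns. Genomes absent from the taxonomy table are skipped with a
#' warning; clades larger than the subsample cap are reduced by the
#' seeded draw.
#'
#' @param proteomes list of [proteome] objects, or a directory path
#'   containing protein FASTA files (`.fa`/`.faa`/`.fasta`; file base
#'   names are the genome ids).
#' @param taxonomy data.frame from [read_taxonomy()] (or a path to one).
#' @param config A [run_config()].
#' @param top_n Patterns to keep in the ranking (default 20).
#' @return list with `pattern_stats` (per genome x motif), `clade_summaries`
#'   (nested list motif -> clade -> [clade_summary()]), `clade_means`
#'   (long data.frame over all patterns), `ranking`, and `genomes_used`.
#'   Tables are also written as TSV when `config$out_dir` is set.
#' @export
cmd_bias <- function(proteomes, taxonomy, config = run_config(),
                     top_n = 20L) {
  stopifnot(inherits(config, "stallscan_config"))
  if (is.character(taxonomy)) taxonomy <- read_taxonomy(taxonomy)
  if (is.character(proteomes)) {
    files <- list.files(proteomes, pattern = "\\.(fa|faa|fasta)$",
                        full.names = TRUE)
    if (!length(files)) stop("no FASTA files in ", proteomes)
    proteomes <- lapply(files, read_protein_fasta)
  }
  ids <- vapply(proteomes, function(p) p$genome_id, "")
  names(proteomes) <- ids
  known <- ids %in% taxonomy$genome_id
  if (!all(known)) {
    warning("skipping genomes missing from the taxonomy table: ",
            paste(ids[!known], collapse = ", "))
    proteomes <- proteomes[known]
    ids <- ids[known]
  }
  if (!length(proteomes)) stop("no genomes left after taxonomy join")
  picked <- subsample_genomes(ids, taxonomy, cap = config$subsample_cap,
                              seed = config$subsample_seed)
  used <- unlist(picked, use.names = FALSE)
  patterns <- aa_kmer_patterns(config$k)
  stats_rows <- list()
  # per-clade accumulators over the full pattern space
  acc <- lapply(picked, function(g)
    list(sum = numeric(length(patterns)), n = integer(length(patterns))))
  per_genome_bias <- list()
  for (clade in names(picked)) {
    for (gid in picked[[clade]]) {
      prot <- proteomes[[gid]]
      prot$clade <- clade
      gv <- genome_bias_vector(prot, k = config$k)
      per_genome_bias[[gid]] <- gv
      defined <- !is.na(gv$bias)
      acc[[clade]]$sum[defined] <- acc[[clade]]$sum[defined] + gv$bias[defined]
      acc[[clade]]$n[defined] <- acc[[clade]]$n[defined] + 1L
      mi <- match(config$motifs, patterns)
      stats_rows[[gid]] <- data.frame(
        genome_id = gid, clade = clade, pattern = config$motifs,
        observed_count = gv$observed_count[mi],
        total_windows = gv$total_windows,
        observed_freq = if (gv$total_windows > 0)
          gv$observed_count[mi] / gv$total_windows else NA_real_,
        expected_freq = gv$expected_freq[mi],
        bias = gv$bias[mi], stringsAsFactors = FALSE)
    }
  }
  pattern_stats <- do.call(rbind, stats_rows)
  rownames(pattern_stats) <- NULL
  clade_summaries <- lapply(setNames(config$motifs, config$motifs),
    function(m) {
      lapply(setNames(names(picked), names(picked)), function(clade) {
        rows <- pattern_stats[pattern_stats$pattern == m &
                              pattern_stats$clade == clade, , drop = FALSE]
        clade_summary(rows, clade = clade, pattern = m)
      })
    })
  clade_means <- do.call(rbind, lapply(names(acc), function(clade) {
    mean_bias <- ifelse(acc[[clade]]$n > 0,
                        acc[[clade]]$sum / acc[[clade]]$n, NA_real_)
    data.frame(clade = clade, pattern = patterns, mean_bias = mean_bias,
               stringsAsFactors = FALSE)
  }))
  ranking <- rank_underrepresented(clade_means, top_n = top_n)
  res <- list(pattern_stats = pattern_stats,
              clade_summaries = clade_summaries,
              clade_means = clade_means, ranking = ranking,
              genomes_used = picked)
  if (!is.na(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- c(paste("stallscan bias; config", config_digest(config)),
              paste("subsample seed", config$subsample_seed,
                    "cap", config$subsample_cap))
    write_tsv_commented(pattern_stats,
                        file.path(config$out_dir, "pattern_stats.tsv"), prov)
    write_tsv_commented(ranking,
                        file.path(config$out_dir, "ranking.tsv"), prov)
    ecdf_rows <- do.call(rbind, lapply(config$motifs, function(m)
      do.call(rbind, lapply(names(picked), function(clade) {
        cs <- clade_summaries[[m]][[clade]]
        data.frame(clade = clade, pattern = m, cs$ecdf_points,
                   stringsAsFactors = FALSE)
      }))))
    write_tsv_commented(ecdf_rows,
                        file.path(config$out_dir, "ecdf_points.tsv"), prov)
    summ_rows <- do.call(rbind, lapply(config$motifs, function(m)
      do.call(rbind, lapply(names(picked), function(clade) {
        cs <- clade_summaries[[m]][[clade]]
        data.frame(clade = clade, pattern = m, n_genomes = cs$n_genomes,
                   n_defined = cs$n_defined, mean_bias = cs$mean_bias,
                   median_bias = cs$median_bias,
                   fraction_zero = cs$fraction_zero,
                   stringsAsFactors = FALSE)
      }))))
    write_tsv_commented(summ_rows,
                        file.path(config$out_dir, "clade_summary.tsv"), prov)
  }
  res
}

#' Motif census over a set of proteomes
#'
#' Scans every proteome for the configured motifs, collapses occurrences
#' with [motif_census()], and classifies the localization of each
#' motif-containing protein.
#'
#' @param proteomes list of [proteome] objects or a FASTA directory (as in
#'   [cmd_bias()]).
#' @param config A [run_config()].
#' @param predictor Localization predictor (default
#'   [hydropathy_predictor()]).
#' @return list with `census` (a [motif_census()]), `localization`
#'   (per-protein classes merged into the census `per_protein` table).
#' @export
cmd_census <- function(proteomes, config = run_config(),
                       predictor = hydropathy_predictor()) {
  stopifnot(inherits(config, "stallscan_config"))
  if (is.character(proteomes)) {
    files <- list.files(proteomes, pattern = "\\.(fa|faa|fasta)$",
                        full.names = TRUE)
    if (!length(files)) stop("no FASTA files in ", proteomes)
    proteomes <- lapply(files, read_protein_fasta)
  }
  occ <- do.call(rbind, lapply(proteomes, scan_motifs,
                               motifs = config$motifs))
  cen <- motif_census(occ, length_cap = config$length_cap)
  pp <- cen$per_protein
  pp$localization <- NA_character_
  for (prot in proteomes) {
    sel <- pp$genome_id == prot$genome_id
    if (!any(sel)) next
    seqs <- prot$proteins$sequence[match(pp$protein_id[sel],
                                         prot$proteins$protein_id)]
    pp$localization[sel] <- vapply(seqs, function(s)
      classify_localization(s, predictor)$class, "")
  }
  if (!is.na(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- paste("stallscan census; config", config_digest(config))
    write_tsv_commented(cen$occurrences,
                        file.path(config$out_dir, "occurrences.tsv"), prov)
    write_tsv_commented(pp,
                        file.path(config$out_dir, "census_proteins.tsv"),
                        prov)
    write_tsv_commented(cen$summary,
                        file.path(config$out_dir, "census_summary.tsv"),
                        prov)
  }
  list(census = cen, localization = pp)
}

#' uORF -> downstream-gene enrichment analysis
#'
#' The genome-neighborhood analysis: for each genome, motif-containing
#' small proteins are matched to their CDS features by `protein_id`,
#' paired with same-strand downstream genes, filtered on annotation, and
#' tested group-by-group for target/control enrichment (default
#' comparisons: RGPP vs AGPP and RAPP vs AAPP).
#'
#' @param genomes list of per-genome lists, each with `features` (from
#'   [read_gff3()]) and `proteome` (a [proteome]); e.g. results of
#'   [generate_annotated_genome()], or built from files.
#' @param config A [run_config()]; `config$motifs` must contain the four
#'   comparison motifs.
#' @param comparisons Named character vector control motif by target
#'   motif (default `c(RGPP = "AGPP", RAPP = "AAPP")`).
#' @return list with `pairs` (filtered gene pairs across genomes, with
#'   `group_key`), `census`, and `enrichment` (one [enrichment_table()]
#'   per comparison, named "target_vs_control").
#' @export
cmd_enrich <- function(genomes, config = run_config(),
                       comparisons = c(RGPP = "AGPP", RAPP = "AAPP")) {
  stopifnot(inherits(config, "stallscan_config"))
  motifs <- unique(c(names(comparisons), unname(comparisons)))
  all_pairs <- list()
  all_occ <- list()
  for (g in genomes) {
    stopifnot(is.data.frame(g$features), is_proteome(g$proteome))
    occ <- scan_motifs(g$proteome, motifs)
    all_occ[[length(all_occ) + 1L]] <- occ
    if (nrow(occ) == 0L) next
    cen <- motif_census(occ, length_cap = config$length_cap)
    pp <- cen$per_protein[cen$per_protein$small, , drop = FALSE]
    if (nrow(pp) == 0L) next
    fid <- g$features$feature_id[match(pp$protein_id,
                                       g$features$protein_id)]
    unmatched <- pp$protein_id[is.na(fid)]
    if (length(unmatched))
      stop("genome '", g$proteome$genome_id,
           "': proteins without a matching CDS feature: ",
           paste(unique(unmatched), collapse = ", "))
    uorf_table <- data.frame(feature_id = fid, motif = pp$motif,
                             protein_length = pp$protein_length,
                             stringsAsFactors = FALSE)
    pr <- build_gene_pairs(g$features, uorf_table, max_gap = config$max_gap)
    if (nrow(pr) == 0L) next
    pr$genome_id <- g$proteome$genome_id
    all_pairs[[length(all_pairs) + 1L]] <- pr
  }
  pairs <- do.call(rbind, all_pairs)
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("no uORF/downstream-gene pairs found")
  pairs <- select_uorfs(pairs, length_cap = config$length_cap)
  pairs$group_key <- normalize_annotation(pairs$downstream_product)
  enr <- lapply(seq_along(comparisons), function(i) {
    enrichment_table(pairs, names(comparisons)[i], comparisons[[i]],
                     alpha = config$bh_alpha,
                     alternative = config$fisher_alternative)
  })
  names(enr) <- paste0(names(comparisons), "_vs_", unname(comparisons))
  cen <- motif_census(do.call(rbind, all_occ),
                      length_cap = config$length_cap)
  if (!is.na(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- paste("stallscan enrich; config", config_digest(config))
    write_tsv_commented(pairs, file.path(config$out_dir, "pairs.tsv"), prov)
    for (nm in names(enr))
      write_tsv_commented(enr[[nm]],
                          file.path(config$out_dir,
                                    paste0("enrichment_", nm, ".tsv")), prov)
  }
  list(pairs = pairs, census = cen, enrichment = enr)
}

#' Load an annotated genome from GFF3 + protein FASTA files
#'
#' Convenience loader producing the per-genome structure [cmd_enrich()]
#' consumes.
#'
#' @param gff3_path GFF3 file.
#' @param faa_path Protein FASTA file.
#' @param genome_id Genome identifier (default: FASTA base name).
#' @return list with `features` and `proteome`.
#' @export
read_annotated_genome <- function(gff3_path, faa_path, genome_id = NULL) {
  list(features = read_gff3(gff3_path),
       proteome = read_protein_fasta(faa_path, genome_id = genome_id))
}

#' Generate and write a synthetic dataset
#'
#' Thin wrapper over the synthetic-data module: builds the requested
#' proteomes and/or annotated genomes, writes them under `dir`, and
#' returns the ground truth.
#'
#' @param dir Output directory.
#' @param proteome_specs Named list of [proteome_spec()] (names are genome
#'   ids); may be empty.
#' @param genome_specs Named list of [genome_spec()]; may be empty.
#' @param taxonomy Optional data.frame (`genome_id`, `clade`) written as
#'   `taxonomy.tsv`.
#' @return list of per-dataset ground truths, invisibly.
#' @export
cmd_simulate <- function(dir, proteome_specs = list(),
                         genome_specs = list(), taxonomy = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truths <- list()
  for (gid in names(proteome_specs)) {
    gen <- generate_proteome(proteome_specs[[gid]], genome_id = gid)
    write_protein_fasta(gen$proteome, file.path(dir, paste0(gid, ".faa")))
    truths[[gid]] <- gen$truth
  }
  for (gid in names(genome_specs)) {
    gen <- generate_annotated_genome(genome_specs[[gid]], genome_id = gid)
    write_annotated_genome(gen, dir, genome_id = gid)
    truths[[gid]] <- gen$truth
  }
  if (!is.null(taxonomy))
    write.table(taxonomy, file.path(dir, "taxonomy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(truths)
}
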