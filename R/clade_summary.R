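# Clade-level aggregation of frequency bias: capped per-clade subsampling,
# ECDF summaries, and the cross-clade underrepresentation ranking.

#' Subsample genomes within clades
#'
#' Clades with at most `cap` genomes are returned whole; larger clades are
#' reduced to `cap` genomes by seeded uniform sampling without replacement.
#' Deterministic for a fixed seed (the default, 214, echoes the GTDB
#' release the taxonomy emulates).
#'
#' @param genome_ids Character vector of genome identifiers.
#' @param clade_map data.frame from [read_taxonomy()] (or any data.frame
#'   with `genome_id` and `clade` columns).
#' @param cap Maximum genomes per clade (default 1000).
#' @param seed Integer RNG seed.
#' @return Named list: clade -> character vector of retained genome ids.
#' @export
subsample_genomes <- function(genome_ids, clade_map, cap = 1000L, seed = 214L) {
  stopifnot(cap >= 1L)
  clade <- clade_map$clade[match(genome_ids, clade_map$genome_id)]
  if (anyNA(clade))
    stop("genomes missing from the taxonomy table: ",
         paste(head(genome_ids[is.na(clade)], 5L), collapse = ", "))
  by_clade <- split(genome_ids, clade)
  by_clade <- by_clade[sort(names(by_clade))]
  withr::with_seed(seed, {
    lapply(by_clade, function(ids) {
      if (length(ids) <= cap) ids else sort(sample(ids, cap))
    })
  })
}

#' Summarize one pattern's frequency bias over a clade's genomes
#'
#' Aggregates per-genome [frequency_bias()] rows for a single pattern into
#' the clade-level view: mean and median bias over genomes where the bias
#' is defined, the fraction of genomes entirely lacking the pattern, and
#' the empirical cumulative distribution function of the defined biases
#' (right-continuous step function).
#'
#' @param genome_stats data.frame with one row per genome: columns
#'   `genome_id`, `observed_count`, `bias` (`NA` where undefined).
#' @param clade Clade label.
#' @param pattern Pattern the rows refer to (stored, not checked).
#' @return Object of class `clade_bias_summary`: list with `clade`,
#'   `pattern`, `n_genomes`, `n_defined`, `mean_bias`, `median_bias`,
#'   `fraction_zero`, and `ecdf_points` (data.frame `bias`, `cum_fraction`).
#' @export
clade_summary <- function(genome_stats, clade, pattern = NA_character_) {
  stopifnot(is.data.frame(genome_stats),
            all(c("genome_id", "observed_count", "bias") %in% names(genome_stats)))
  defined <- !is.na(genome_stats$bias)
  if (!any(defined))
    stop("clade '", clade, "': bias undefined for every genome")
  b <- genome_stats$bias[defined]
  xs <- sort(unique(b))
  fn <- ecdf(b)
  structure(list(clade = clade, pattern = pattern,
                 n_genomes = nrow(genome_stats),
                 n_defined = sum(defined),
                 mean_bias = mean(b),
                 median_bias = median(b),
                 fraction_zero = mean(genome_stats$observed_count == 0L),
                 ecdf_points = data.frame(bias = xs, cum_fraction = fn(xs))),
            class = "clade_bias_summary")
}

#' @export
print.clade_bias_summary <- function(x, ...) {
  cat(sprintf(
    "<clade_bias_summary> %s / %s\n  %d genomes (%d defined)  mean %.4g  median %.4g  fraction zero %.3f\n",
    x$clade, x$pattern, x$n_genomes, x$n_defined, x$mean_bias,
    x$median_bias, x$fraction_zero))
  invisible(x)
}

#' Rank patterns by cross-clade mean frequency bias
#'
#' The underrepresentation ranking behind the lowest-mean heatmap: each
#' pattern's score is the unweighted mean over clades of the clade mean
#' biases (every clade counts once, however many genomes it holds).
#' Patterns are returned in ascending score order, ties broken
#' lexicographically.
#'
#' @param clade_means Either a long data.frame with columns `clade`,
#'   `pattern`, `mean_bias`, or a numeric matrix with patterns as rows and
#'   clades as columns.
#' @param top_n Number of patterns to return (default 20; use 50 for the
#'   extended view, `Inf` for all).
#' @return data.frame `pattern`, `mean_bias` (cross-clade mean), `rank`.
#' @export
rank_underrepresented <- function(clade_means, top_n = 20L) {
  if (is.matrix(clade_means)) {
    pat <- rownames(clade_means)
    if (is.null(pat)) stop("matrix input must have pattern rownames")
    score <- rowMeans(clade_means, na.rm = TRUE)
  } else {
    stopifnot(is.data.frame(clade_means),
              all(c("clade", "pattern", "mean_bias") %in% names(clade_means)))
    if (nrow(clade_means) == 0L) stop("empty clade_means input")
    per_clade <- split(clade_means$pattern, clade_means$clade)
    universe <- per_clade[[1L]]
    same <- vapply(per_clade, function(p) setequal(p, universe), NA)
    if (!all(same))
      stop("clades do not cover the same pattern universe")
    agg <- aggregate(mean_bias ~ pattern, data = clade_means,
                     FUN = mean, na.rm = TRUE, na.action = NULL)
    pat <- agg$pattern
    score <- agg$mean_bias
  }
  if (!length(pat)) stop("empty clade_means input")
  ord <- order(score, pat)
  out <- data.frame(pattern = pat[ord], mean_bias = score[ord],
                    stringsAsFactors = FALSE)
  out <- head(out, top_n)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
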