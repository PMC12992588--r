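# Motif census: occurrence scanning, the small-protein filter, and
# distance-to-C-terminus distributions.

#' Scan a proteome for motif occurrences
#'
#' Reports every occurrence of every motif (overlapping occurrences all
#' count) in the stop-stripped sequences, sorted by (genome, protein,
#' start). Protein coordinates are 1-based inclusive; `distance_to_C` is
#' `protein_length - end`, so a motif ending at the final residue has
#' distance 0.
#'
#' @param prot A [proteome].
#' @param motifs Non-empty character vector of motif strings (e.g.
#'   `c("RAPP", "RGPP")`).
#' @return data.frame with columns `genome_id`, `protein_id`, `motif`,
#'   `start`, `end`, `protein_length`, `distance_to_C`.
#' @examples
#' scan_motifs(proteome("g", c(a = "MRAPP")), "RAPP") # start 2, end 5
#' @export
scan_motifs <- function(prot, motifs) {
  stopifnot(is_proteome(prot))
  motifs <- as.character(motifs)
  if (!length(motifs)) stop("'motifs' must be non-empty")
  aas <- Biostrings::AAStringSet(setNames(prot$proteins$sequence,
                                          prot$proteins$protein_id))
  rows <- lapply(motifs, function(m) {
    hits <- Biostrings::vmatchPattern(m, aas)
    starts <- lapply(hits, Biostrings::start)
    n_hit <- lengths(starts)
    if (sum(n_hit) == 0L) return(NULL)
    data.frame(genome_id = prot$genome_id,
               protein_id = rep(prot$proteins$protein_id, n_hit),
               motif = m,
               start = unlist(starts, use.names = FALSE),
               protein_length = rep(prot$proteins$length, n_hit),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(genome_id = character(), protein_id = character(),
                      motif = character(), start = integer(),
                      end = integer(), protein_length = integer(),
                      distance_to_C = integer(), stringsAsFactors = FALSE))
  out$end <- out$start + nchar(out$motif) - 1L
  out$distance_to_C <- out$protein_length - out$end
  out <- out[order(out$genome_id, out$protein_id, out$start), ,
             drop = FALSE]
  out <- out[, c("genome_id", "protein_id", "motif", "start", "end",
                 "protein_length", "distance_to_C")]
  rownames(out) <- NULL
  out
}

#' Census of motif-containing proteins
#'
#' Collapses raw occurrences into per-motif counts and per-protein
#' summaries. A protein counts once per motif regardless of occurrence
#' multiplicity; the small-protein subset uses a strict `length <
#' length_cap` rule; per-protein distance to the C-terminus is taken at
#' the C-terminal-most occurrence (the full occurrence table is retained
#' for per-occurrence positional views).
#'
#' @param occurrences data.frame from [scan_motifs()] (rows from several
#'   proteomes may be concatenated).
#' @param length_cap Small-protein threshold in residues (strictly below;
#'   default 300).
#' @return list of class `motif_census`: `summary` (per-motif data.frame
#'   with `n_occurrences`, `n_proteins`, `n_small_proteins`),
#'   `per_protein` (one row per motif-containing protein with
#'   `n_occurrences`, C-terminal-most `distance_to_C` and `small` flag),
#'   `occurrences` (the input), `length_cap`.
#' @export
motif_census <- function(occurrences, length_cap = 300L) {
  req <- c("genome_id", "protein_id", "motif", "start", "end",
           "protein_length", "distance_to_C")
  stopifnot(is.data.frame(occurrences), all(req %in% names(occurrences)))
  occ <- occurrences
  if (nrow(occ) == 0L) {
    per_protein <- data.frame(motif = character(), genome_id = character(),
                              protein_id = character(),
                              protein_length = integer(),
                              n_occurrences = integer(),
                              distance_to_C = integer(), small = logical(),
                              stringsAsFactors = FALSE)
    summary <- data.frame(motif = character(), n_occurrences = integer(),
                          n_proteins = integer(),
                          n_small_proteins = integer(),
                          stringsAsFactors = FALSE)
    return(structure(list(summary = summary, per_protein = per_protein,
                          occurrences = occ, length_cap = length_cap),
                     class = "motif_census"))
  }
  key <- interaction(occ$motif, occ$genome_id, occ$protein_id, drop = TRUE)
  split_rows <- split(seq_len(nrow(occ)), key)
  per_protein <- do.call(rbind, lapply(split_rows, function(i) {
    rows <- occ[i, , drop = FALSE]
    data.frame(motif = rows$motif[1L], genome_id = rows$genome_id[1L],
               protein_id = rows$protein_id[1L],
               protein_length = rows$protein_length[1L],
               n_occurrences = nrow(rows),
               distance_to_C = min(rows$distance_to_C),
               stringsAsFactors = FALSE)
  }))
  per_protein$small <- per_protein$protein_length < length_cap
  per_protein <- per_protein[order(per_protein$motif, per_protein$genome_id,
                                   per_protein$protein_id), , drop = FALSE]
  rownames(per_protein) <- NULL
  summary <- do.call(rbind, lapply(split(per_protein, per_protein$motif),
    function(pp) {
      data.frame(motif = pp$motif[1L],
                 n_occurrences = sum(pp$n_occurrences),
                 n_proteins = nrow(pp),
                 n_small_proteins = sum(pp$small),
                 stringsAsFactors = FALSE)
    }))
  rownames(summary) <- NULL
  structure(list(summary = summary, per_protein = per_protein,
                 occurrences = occ, length_cap = length_cap),
            class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  cat("<motif_census> (small-protein cap:", x$length_cap, "residues)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Distance-to-C-terminus ECDF for one motif
#'
#' ECDF of the per-protein (C-terminal-most occurrence) distances for one
#' motif, optionally restricted to the small-protein subset — the
#' plottable form of the positional analysis.
#'
#' @param census A [motif_census()] result.
#' @param motif Motif to extract.
#' @param small_only Restrict to proteins shorter than the census length
#'   cap (default TRUE).
#' @return data.frame `distance_to_C`, `cum_fraction` (non-decreasing,
#'   ending at 1).
#' @export
distance_ecdf <- function(census, motif, small_only = TRUE) {
  stopifnot(inherits(census, "motif_census"))
  pp <- census$per_protein
  pp <- pp[pp$motif == motif & (!small_only | pp$small), , drop = FALSE]
  if (nrow(pp) == 0L)
    stop("no proteins for motif '", motif, "'",
         if (small_only) " in the small-protein subset" else "")
  d <- pp$distance_to_C
  xs <- sort(unique(d))
  data.frame(distance_to_C = xs, cum_fraction = ecdf(d)(xs))
}
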