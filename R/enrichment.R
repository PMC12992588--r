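# uORF -> downstream-gene enrichment: same-strand downstream pairing,
# annotation filtering/grouping, an exact hypergeometric Fisher test, and
# Benjamini-Hochberg adjustment.

#' Find the same-strand downstream gene of a uORF
#'
#' The nearest CDS on the same contig and strand whose translation-
#' direction start follows the uORF's stop: for `+` strand features, the
#' candidate with minimal `start > uorf$end`; for `-` strand, maximal
#' `end < uorf$start`. The intergenic distance is the downstream 5' start
#' minus the uORF 3' end in translation direction.
#'
#' @param features CDS data.frame from [read_gff3()], sorted by
#'   (contig, start).
#' @param uorf One-row data.frame (a row of `features`).
#' @param max_gap Maximum allowed intergenic distance (default `Inf`, i.e.
#'   no cap).
#' @return One-row data.frame (the downstream feature plus
#'   `intergenic_distance`), or `NULL` when no candidate exists.
#' @export
find_downstream <- function(features, uorf, max_gap = Inf) {
  stopifnot(is.data.frame(features), is.data.frame(uorf), nrow(uorf) == 1L)
  cand <- features[features$contig == uorf$contig &
                   features$strand == uorf$strand &
                   features$feature_id != uorf$feature_id, , drop = FALSE]
  if (uorf$strand == "+") {
    cand <- cand[cand$start > uorf$end, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    hit <- cand[which.min(cand$start), , drop = FALSE]
    gap <- hit$start - uorf$end
  } else {
    cand <- cand[cand$end < uorf$start, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    hit <- cand[which.max(cand$end), , drop = FALSE]
    gap <- uorf$start - hit$end
  }
  if (gap > max_gap) return(NULL)
  hit$intergenic_distance <- gap
  rownames(hit) <- NULL
  hit
}

#' Pair motif-encoding uORFs with their downstream genes
#'
#' For each uORF feature, locates the same-strand downstream CDS with
#' [find_downstream()] and assembles the gene-pair table used by the
#' enrichment stage.
#'
#' @param features CDS data.frame from [read_gff3()].
#' @param uorf_table data.frame with one row per motif-containing uORF:
#'   columns `feature_id` (matching `features`), `motif`,
#'   `protein_length`.
#' @param max_gap Maximum intergenic distance passed to
#'   [find_downstream()].
#' @return data.frame of gene pairs: uORF fields (`uorf_id`,
#'   `uorf_product`, `uorf_length`, `motif`), downstream fields
#'   (`downstream_id`, `downstream_product`), `contig`, `strand`,
#'   `intergenic_distance`. uORFs without a downstream candidate are
#'   dropped.
#' @export
build_gene_pairs <- function(features, uorf_table, max_gap = Inf) {
  stopifnot(all(c("feature_id", "motif", "protein_length") %in%
                names(uorf_table)))
  rows <- lapply(seq_len(nrow(uorf_table)), function(i) {
    fid <- uorf_table$feature_id[i]
    u <- features[features$feature_id == fid, , drop = FALSE]
    if (nrow(u) != 1L) return(NULL)
    d <- find_downstream(features, u, max_gap = max_gap)
    if (is.null(d)) return(NULL)
    data.frame(uorf_id = fid,
               motif = uorf_table$motif[i],
               uorf_length = uorf_table$protein_length[i],
               uorf_product = u$product_annotation,
               downstream_id = d$feature_id,
               downstream_product = d$product_annotation,
               contig = u$contig, strand = u$strand,
               intergenic_distance = d$intergenic_distance,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(uorf_id = character(), motif = character(),
                      uorf_length = integer(), uorf_product = character(),
                      downstream_id = character(),
                      downstream_product = character(),
                      contig = character(), strand = character(),
                      intergenic_distance = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter gene pairs on annotation and uORF size
#'
#' Keeps pairs whose uORF is small (`uorf_length < length_cap`) and whose
#' product annotation case-insensitively contains one of "unknown",
#' "hypothetical" or "uncharacterized" (candidate arrest peptides are
#' unannotated leaders), while the downstream annotation is non-empty and
#' does not contain "unknown" (the enrichment question concerns downstream
#' genes with predicted functions).
#'
#' @param pairs data.frame from [build_gene_pairs()].
#' @param length_cap Strict uORF length cap in residues (default 300).
#' @return The filtered pairs data.frame.
#' @export
select_uorfs <- function(pairs, length_cap = 300L) {
  stopifnot(all(c("uorf_length", "uorf_product", "downstream_product") %in%
                names(pairs)))
  keep <- pairs$uorf_length < length_cap &
    grepl("unknown|hypothetical|uncharacterized", pairs$uorf_product,
          ignore.case = TRUE) &
    nzchar(pairs$downstream_product) &
    !grepl("unknown", pairs$downstream_product, ignore.case = TRUE)
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize an annotation string into a group key
#'
#' Lowercases, collapses internal whitespace, and strips trailing
#' punctuation/whitespace. Grouping is exact string matching on the
#' normalized form — no fuzzy matching, so e.g. "TonB-dependent receptor"
#' and "TonB dependent receptor" remain distinct groups.
#'
#' @param x Character vector of annotation strings.
#' @return Character vector of group keys.
#' @export
normalize_annotation <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:space:]]+", " ", x)
  x <- gsub("[[:punct:][:space:]]+$", "", x)
  trimws(x)
}

#' Group gene pairs by normalized downstream annotation
#'
#' @param pairs data.frame from [select_uorfs()].
#' @return Named list: group key -> pairs data.frame (with a `group_key`
#'   column added).
#' @export
group_by_annotation <- function(pairs) {
  stopifnot("downstream_product" %in% names(pairs))
  pairs$group_key <- normalize_annotation(pairs$downstream_product)
  split(pairs, pairs$group_key)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact p-value computed from hypergeometric probabilities in log space.
#' The two-sided p-value uses the minimum-likelihood rule: the sum of the
#' probabilities of all tables with the same margins whose probability
#' does not exceed that of the observed table (with 1e-7 relative slack),
#' matching the classical two-sided definition. One-sided alternatives sum
#' the appropriate tail.
#'
#' @param a,b,c,d Non-negative integer cell counts: rows are target /
#'   control, columns in-group / not-in-group.
#' @param alternative `"two.sided"` (default), `"greater"` (first row
#'   over-represented in the first column) or `"less"`.
#' @return The p-value (numeric scalar in `(0, 1]`).
#' @examples
#' fisher_exact(3, 1, 1, 3) # 34/70
#' @export
fisher_exact <- function(a, b, c, d,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) < 1) stop("the table must contain at least one count")
  m <- a + c          # column-1 margin
  n2 <- b + d         # column-2 margin
  k <- a + b          # row-1 margin
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  logp <- dhyper(support, m, n2, k, log = TRUE)
  lobs <- logp[match(a, support)]
  p <- switch(alternative,
    two.sided = sum(exp(logp[logp <= lobs + log1p(1e-7)])),
    greater = sum(exp(logp[support >= a])),
    less = sum(exp(logp[support <= a])))
  min(p, 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment
#' `q(i) = min_{j >= i} p(j) * m / j` (p sorted ascending, result mapped
#' back to input order, capped at 1); delegated to
#' `stats::p.adjust(method = "BH")`, which implements exactly this
#' formula. Inputs outside `[0, 1]` are rejected.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-annotation-group enrichment of target vs control motif uORFs
#'
#' For every downstream-annotation group present in either motif's pairs,
#' builds the 2x2 table (`a` = target uORFs in group, `b` = target not in
#' group, `c` = control in group, `d` = control not in group), computes
#' the proportion-normalized fold enrichment `(a/(a+b)) / (c/(c+d))`,
#' Fisher's exact p-value, and Benjamini-Hochberg adjusted p-values over
#' all groups of this one comparison. Groups with no control uORF are
#' retained with `fold_enrichment = Inf` and flagged, not dropped or
#' pseudocounted.
#'
#' @param pairs Gene-pair data.frame covering both motifs (after
#'   [select_uorfs()]); a `group_key` column is added if absent.
#' @param target_motif,control_motif Motif strings, e.g. `"RGPP"` and
#'   `"AGPP"`.
#' @param alpha Significance threshold on the adjusted p-value (default
#'   0.01).
#' @param alternative Sidedness passed to [fisher_exact()].
#' @return data.frame sorted by descending fold then ascending adjusted p:
#'   `group_key`, `a`, `b`, `c`, `d`, `fold_enrichment`, `infinite_fold`,
#'   `p_value`, `p_adjusted`, `significant`.
#' @export
enrichment_table <- function(pairs, target_motif, control_motif,
                             alpha = 0.01,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(all(c("motif", "downstream_product") %in% names(pairs)))
  if (!"group_key" %in% names(pairs))
    pairs$group_key <- normalize_annotation(pairs$downstream_product)
  tgt <- pairs[pairs$motif == target_motif, , drop = FALSE]
  ctl <- pairs[pairs$motif == control_motif, , drop = FALSE]
  nt <- nrow(tgt); nc <- nrow(ctl)
  if (nt == 0L) stop("no uORF pairs for target motif '", target_motif, "'")
  if (nc == 0L) stop("no uORF pairs for control motif '", control_motif, "'")
  groups <- sort(unique(c(tgt$group_key, ctl$group_key)))
  a <- vapply(groups, function(g) sum(tgt$group_key == g), 0L)
  c_ <- vapply(groups, function(g) sum(ctl$group_key == g), 0L)
  b <- nt - a
  d <- nc - c_
  fold <- (a / nt) / (c_ / nc)   # Inf when c = 0 (and a > 0)
  p <- vapply(seq_along(groups),
              function(i) fisher_exact(a[i], b[i], c_[i], d[i],
                                       alternative = alternative),
              0)
  padj <- bh_adjust(p)
  out <- data.frame(group_key = groups, a = a, b = b, c = c_, d = d,
                    fold_enrichment = fold, infinite_fold = c_ == 0L,
                    p_value = p, p_adjusted = padj,
                    significant = padj < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fold_enrichment, out$p_adjusted, out$group_key), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
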