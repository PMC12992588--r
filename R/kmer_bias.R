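# Composition-normalized k-mer frequency bias: the package's central
# statistic. A proteome's sliding tetrapeptide windows are counted, the
# frequency of each pattern is divided by the frequency expected from the
# proteome's single-residue composition, and the ratio ("frequency bias")
# measures over-/under-representation; values < 1 indicate avoidance.
#
# Convention fixed here and used everywhere: windows containing any
# non-standard letter (X, B, Z, J, U, O) are excluded from both the pattern
# counts and the window total, and composition is computed over standard
# residues only, so observed frequencies over the 20^k standard patterns
# sum to exactly 1.

# Encode a proteome's residues as base-20 window codes.
# Returns list(code = zero-based codes of valid windows, total = n windows).
window_codes <- function(prot, k) {
  # single space separators make windows spanning protein boundaries
  # invalid automatically (space is not a standard letter)
  s <- paste(prot$proteins$sequence, collapse = " ")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  idx <- match(chars, AA_STANDARD)          # NA for non-standard letters
  n <- length(idx)
  if (n < k) return(list(code = integer(0), total = 0L))
  m <- n - k + 1L
  valid <- !is.na(idx[seq_len(m)])
  code <- idx[seq_len(m)] - 1L
  for (j in seq_len(k - 1L)) {
    nxt <- idx[(1L + j):(m + j)]
    valid <- valid & !is.na(nxt)
    code <- code * 20L + (nxt - 1L)
  }
  list(code = code[valid], total = sum(valid))
}

#' Count sliding-window k-mers in a proteome
#'
#' Every length-`k` window of every protein is examined (overlapping
#' windows all count); windows containing a non-standard letter are
#' excluded from both the counts and the window total. Proteins shorter
#' than `k` contribute no windows.
#'
#' @param prot A [proteome].
#' @param k Word length (default 4; must satisfy `20^k <= 4e6` because the
#'   tally is dense).
#' @return list with `counts` (named integer vector over the patterns that
#'   occur at least once) and `total_windows`.
#' @examples
#' count_kmers(proteome("g", c("ARAPPA", "RAPP")))$counts # ARAP APPA RAPP
#' @export
count_kmers <- function(prot, k = 4L) {
  stopifnot(is_proteome(prot))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (20^k > 4e6) stop("dense k-mer tally limited to 20^k <= 4e6")
  wc <- window_codes(prot, k)
  if (wc$total == 0L)
    return(list(counts = setNames(integer(0), character(0)),
                total_windows = 0L))
  tb <- tabulate(wc$code + 1L, nbins = 20L^k)
  nz <- which(tb > 0L)
  counts <- tb[nz]
  names(counts) <- aa_code_to_pattern(nz - 1L, k)
  list(counts = counts, total_windows = wc$total)
}

#' Amino-acid composition of a proteome
#'
#' Per-letter frequencies over all standard residues of all proteins
#' (non-standard letters are excluded from numerator and denominator),
#' computed with `Biostrings::alphabetFrequency`.
#'
#' @param prot A [proteome].
#' @return Named numeric vector over [AA_STANDARD], summing to 1.
#' @export
composition <- function(prot) {
  stopifnot(is_proteome(prot))
  aas <- Biostrings::AAStringSet(prot$proteins$sequence)
  af <- Biostrings::alphabetFrequency(aas, collapse = TRUE)
  counts <- af[AA_STANDARD]
  total <- sum(counts)
  if (total == 0) stop("proteome '", prot$genome_id, "' has no standard residues")
  counts / total
}

#' Expected k-mer frequency under the composition null
#'
#' The frequency a pattern would have if residues occurred independently
#' with the proteome's single-residue frequencies: the product of the
#' composition entries at the pattern's positions.
#'
#' @param pattern Pattern over the standard letters.
#' @param comp Composition vector from [composition()].
#' @return A single numeric frequency in `[0, 1]`.
#' @export
expected_frequency <- function(pattern, comp) {
  letters <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  if (!all(letters %in% AA_STANDARD))
    stop("pattern '", pattern, "' contains non-standard letters")
  prod(comp[letters])
}

#' Frequency bias of a pattern in a proteome
#'
#' The central statistic: observed sliding-window frequency of `pattern`
#' divided by its composition-expected frequency. Bias is reported as
#' undefined (`NA` with `bias_defined = FALSE`) when the expected frequency
#' is zero or the proteome has no valid windows — never coerced to 0 or
#' infinity. A pattern that simply never occurs has bias 0.
#'
#' @param prot A [proteome].
#' @param pattern Pattern over standard letters (length = `k`).
#' @param k Word length; defaults to `nchar(pattern)`.
#' @param counts Optional precomputed result of `count_kmers(prot, k)`, to
#'   avoid recounting when scoring many patterns.
#' @param mode `"windows"` (default) counts every sliding-window occurrence;
#'   `"proteins"` counts each motif-containing protein once (a sensitivity
#'   mode: the two coincide when no protein has multiple occurrences).
#' @return One-row data.frame: `pattern`, `observed_count`, `total_windows`,
#'   `observed_freq`, `expected_freq`, `bias`, `bias_defined`.
#' @examples
#' frequency_bias(proteome("g", c("AAAA")), "AAAA")$bias # 1
#' @export
frequency_bias <- function(prot, pattern, k = nchar(pattern), counts = NULL,
                           mode = c("windows", "proteins")) {
  stopifnot(is_proteome(prot))
  mode <- match.arg(mode)
  k <- as.integer(k)
  if (nchar(pattern) != k)
    stop("pattern '", pattern, "' does not have length k = ", k)
  if (!is_standard_pattern(pattern))
    stop("pattern '", pattern, "' contains non-standard letters")
  if (is.null(counts)) counts <- count_kmers(prot, k)
  tw <- counts$total_windows
  obs <- if (mode == "windows") {
    v <- counts$counts[pattern]
    if (is.na(v)) 0L else as.integer(v)
  } else {
    sum(vapply(prot$proteins$sequence,
               function(s) grepl(pattern, s, fixed = TRUE), NA))
  }
  comp <- composition(prot)
  ef <- expected_frequency(pattern, comp)
  of <- if (tw > 0L) obs / tw else NA_real_
  defined <- tw > 0L && ef > 0
  bias <- if (defined) of / ef else NA_real_
  data.frame(pattern = pattern, observed_count = obs, total_windows = tw,
             observed_freq = of, expected_freq = ef, bias = bias,
             bias_defined = defined, stringsAsFactors = FALSE)
}

#' Dense per-pattern bias vector for one proteome
#'
#' Computes observed counts and biases for all `20^k` patterns at once
#' (used by the clade-ranking stage, where every pattern must be scored).
#'
#' @param prot A [proteome].
#' @param k Word length (dense; `k <= 5`).
#' @return list with `patterns` (in [aa_kmer_patterns()] order), integer
#'   `observed_count`, `total_windows`, numeric `expected_freq` and `bias`
#'   (`NA` where undefined).
#' @export
genome_bias_vector <- function(prot, k = 4L) {
  stopifnot(is_proteome(prot))
  k <- as.integer(k)
  if (20^k > 4e6) stop("dense bias vector limited to 20^k <= 4e6")
  wc <- window_codes(prot, k)
  tb <- tabulate(wc$code + 1L, nbins = 20L^k)
  comp <- composition(prot)
  # expected frequencies in code order: position 1 varies slowest
  ef <- comp
  for (j in seq_len(k - 1L)) ef <- as.vector(outer(ef, comp))
  bias <- if (wc$total > 0L) ifelse(ef > 0, (tb / wc$total) / ef, NA_real_)
          else rep(NA_real_, length(ef))
  list(patterns = aa_kmer_patterns(k), observed_count = tb,
       total_windows = wc$total, expected_freq = ef, bias = bias)
}
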