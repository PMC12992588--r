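# Amino-acid alphabet constants and k-mer index helpers shared across modules.

#' The 20 standard amino-acid one-letter codes
#'
#' Alphabetical order; this ordering fixes the layout of composition vectors
#' and dense k-mer count vectors throughout the package.
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Non-standard letters that may appear in downloaded translations.
AA_NONSTANDARD <- c("X", "B", "Z", "J", "U", "O")

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values used by the default localization heuristic.
#'
#' @format Named numeric vector over the 20 standard letters.
#' @export
KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

is_standard_pattern <- function(pattern) {
  all(strsplit(pattern, "", fixed = TRUE)[[1L]] %in% AA_STANDARD)
}

#' Enumerate all k-mer patterns over the standard amino-acid alphabet
#'
#' Patterns are returned in base-20 code order (last position varies
#' fastest), the same order used by the dense count vectors produced
#' internally, so `aa_kmer_patterns(4)[i]` names the i-th entry of a dense
#' 160,000-long tetrapeptide vector.
#'
#' @param k Word length (default 4). `20^k` patterns are materialized, so
#'   keep k small; the bias engine only needs dense enumeration for k <= 5.
#' @return Character vector of `20^k` patterns.
#' @examples
#' length(aa_kmer_patterns(2)) # 400
#' @export
aa_kmer_patterns <- function(k = 4L) {
  k <- as.integer(k)
  stopifnot(k >= 1L, 20^k <= 4e6)
  idx <- rep(list(seq_len(20L)), k)
  # expand.grid varies the first factor fastest; feed positions reversed so
  # the LAST residue varies fastest, matching the base-20 encoding.
  grid <- do.call(expand.grid, rev(idx))[, k:1, drop = FALSE]
  do.call(paste0, lapply(seq_len(k), function(j) AA_STANDARD[grid[[j]]]))
}

# Decode zero-based base-20 codes into pattern strings.
aa_code_to_pattern <- function(code, k) {
  out <- matrix("", nrow = length(code), ncol = k)
  for (j in k:1) {
    out[, j] <- AA_STANDARD[(code %% 20L) + 1L]
    code <- code %/% 20L
  }
  apply(out, 1L, paste0, collapse = "")
}
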