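# Protein localization classification (SP / TM / CP) via a pluggable
# predictor. The default predictor is a documented Kyte-Doolittle
# hydropathy heuristic so the pipeline runs offline; an adapter for
# externally produced DeepTMHMM output is provided for users who run the
# real predictor.

#' Hydropathy-based localization predictor (default)
#'
#' Builds a predictor function implementing a transparent heuristic:
#' rolling Kyte-Doolittle hydropathy over 19-residue windows (evaluated at
#' window centers, i.e. residues `10 .. n-9`); a maximal run of centers
#' with mean hydropathy >= 1.6 is a hydrophobic segment. A segment lying
#' fully within residues 1-35 that is preceded by at least one positively
#' charged residue (K/R) is reclassified as a signal segment. The protein
#' is SP if a signal segment exists and no transmembrane segment ends
#' after residue 35, TM if any transmembrane segment ends after residue
#' 35, and CP otherwise. Proteins shorter than the window are classified
#' CP with `short_warning = TRUE`.
#'
#' Non-standard letters get hydropathy 0 (neutral).
#'
#' @param window Rolling window width in residues (odd; default 19).
#' @param threshold Mean-hydropathy threshold for a hydrophobic window
#'   (default 1.6).
#' @param n_region N-terminal span (residues) within which a hydrophobic
#'   segment can be a signal anchor (default 35).
#' @return A function `function(sequence)` returning a localization call:
#'   list with `class` (`"SP"`, `"TM"` or `"CP"`), `evidence` (data.frame
#'   `start`, `end`, `kind` of segments, center coordinates) and
#'   `short_warning`.
#' @export
hydropathy_predictor <- function(window = 19L, threshold = 1.6,
                                 n_region = 35L) {
  window <- as.integer(window)
  stopifnot(window >= 3L, window %% 2L == 1L)
  half <- window %/% 2L
  function(sequence) {
    chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
    n <- length(chars)
    empty <- data.frame(start = integer(), end = integer(),
                        kind = character(), stringsAsFactors = FALSE)
    if (n < window)
      return(list(class = "CP", evidence = empty, short_warning = TRUE))
    h <- KYTE_DOOLITTLE[chars]
    h[is.na(h)] <- 0
    centers <- (half + 1L):(n - half)
    # literal window means (no cumsum trick): threshold comparisons at
    # the boundary must not depend on floating-point summation order
    means <- vapply(centers, function(i)
      mean(h[(i - half):(i + half)]), 0)
    hot <- means >= threshold
    segs <- empty
    if (any(hot)) {
      r <- rle(hot)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      iseg <- which(r$values)
      segs <- data.frame(start = centers[starts[iseg]],
                         end = centers[ends[iseg]],
                         stringsAsFactors = FALSE)
      segs$kind <- "tm"
      for (i in seq_len(nrow(segs))) {
        if (segs$end[i] <= n_region && segs$start[i] > 1L) {
          before <- chars[seq_len(segs$start[i] - 1L)]
          if (any(before %in% c("K", "R"))) segs$kind[i] <- "signal"
        }
      }
    }
    tm_after <- any(segs$kind == "tm" & segs$end > n_region)
    cls <- if (any(segs$kind == "signal") && !tm_after) "SP"
           else if (tm_after) "TM"
           else "CP"
    list(class = cls, evidence = segs, short_warning = FALSE)
  }
}

#' Classify the localization of a protein
#'
#' Applies a localization predictor (default: [hydropathy_predictor()]) to
#' one sequence. Deterministic for a fixed predictor.
#'
#' @param sequence Protein sequence (character scalar), or a one-row slice
#'   of a proteome's `proteins` data.frame.
#' @param predictor A predictor function as returned by
#'   [hydropathy_predictor()] (or a lookup built by [read_deeptmhmm()]).
#' @return list with `class` in `{SP, TM, CP}`, `evidence` segments, and
#'   `short_warning`.
#' @export
classify_localization <- function(sequence, predictor = hydropathy_predictor()) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[[1L]]
  stopifnot(is.character(sequence), length(sequence) == 1L)
  call <- predictor(sequence)
  stopifnot(call$class %in% c("SP", "TM", "CP"))
  call
}

#' Localize every protein of a proteome
#'
#' @param prot A [proteome].
#' @param predictor Localization predictor (default
#'   [hydropathy_predictor()]).
#' @return data.frame `protein_id`, `localization`, `short_warning`.
#' @export
localize_proteome <- function(prot, predictor = hydropathy_predictor()) {
  stopifnot(is_proteome(prot))
  calls <- lapply(prot$proteins$sequence, classify_localization,
                  predictor = predictor)
  data.frame(protein_id = prot$proteins$protein_id,
             localization = vapply(calls, `[[`, "", "class"),
             short_warning = vapply(calls, `[[`, NA, "short_warning"),
             stringsAsFactors = FALSE)
}

#' Read externally produced DeepTMHMM predictions
#'
#' Parses the plain-text 3-line-per-protein dialect (`>id | TYPE` header,
#' sequence line, per-residue label line using S for signal and M for
#' membrane) and returns a predictor function usable wherever
#' [hydropathy_predictor()] is: lookups are by exact sequence match, so
#' the file must cover every protein that will be classified.
#'
#' @param path Path to the prediction file.
#' @return A predictor `function(sequence)`; unknown sequences error.
#' @export
read_deeptmhmm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr <- which(startsWith(lines, ">"))
  if (!length(hdr) || any(diff(hdr) != 3L) || (length(lines) - hdr[length(hdr)]) != 2L)
    stop("'", path, "' is not 3-line-per-protein prediction output")
  table <- new.env(parent = emptyenv())
  for (i in hdr) {
    seq <- toupper(lines[i + 1L])
    lab <- toupper(lines[i + 2L])
    if (nchar(seq) != nchar(lab))
      stop("'", path, "': sequence/label length mismatch at ", lines[i])
    labs <- strsplit(lab, "", fixed = TRUE)[[1L]]
    seg_of <- function(kind, code) {
      r <- rle(labs == code)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      i2 <- which(r$values)
      if (!length(i2)) return(NULL)
      data.frame(start = starts[i2], end = ends[i2], kind = kind,
                 stringsAsFactors = FALSE)
    }
    segs <- rbind(seg_of("signal", "S"), seg_of("tm", "M"))
    if (is.null(segs))
      segs <- data.frame(start = integer(), end = integer(),
                         kind = character(), stringsAsFactors = FALSE)
    cls <- if (any(segs$kind == "tm")) "TM"
           else if (any(segs$kind == "signal")) "SP"
           else "CP"
    assign(seq, list(class = cls, evidence = segs, short_warning = FALSE),
           envir = table)
  }
  function(sequence) {
    key <- toupper(sequence)
    if (!exists(key, envir = table, inherits = FALSE))
      stop("sequence not present in the prediction file")
    get(key, envir = table, inherits = FALSE)
  }
}
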