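# Protein FASTA input/output and the proteome container.

#' Construct a proteome
#'
#' The proteome is the unit over which frequency bias is computed: one
#' genome's predicted protein set plus its clade label (phylum, or class for
#' Pseudomonadota). Sequences are uppercased and a single terminal stop
#' character `*` is stripped, so downloaded translations that retain the
#' stop do not create spurious k-mer windows.
#'
#' @param genome_id Genome identifier (non-empty string).
#' @param proteins Either a character vector of sequences (names used as
#'   protein ids; unnamed sequences get `p1`, `p2`, ...) or a data.frame
#'   with columns `protein_id` and `sequence`.
#' @param clade Clade label; may be left `""` for later joining against a
#'   taxonomy table.
#' @return An object of class `proteome`: a list with `genome_id`, `clade`
#'   and a `proteins` data.frame (`protein_id`, `sequence`, `length`).
#' @examples
#' p <- proteome("g1", c(yhfW = "MRAPP"))
#' p$proteins$length # 5
#' @export
proteome <- function(genome_id, proteins, clade = "") {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  if (is.character(proteins)) {
    ids <- names(proteins)
    if (is.null(ids)) ids <- paste0("p", seq_along(proteins))
    proteins <- data.frame(protein_id = ids, sequence = unname(proteins),
                           stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "sequence") %in% names(proteins)))
  if (nrow(proteins) == 0L) stop("proteome '", genome_id, "' has no proteins")
  seqs <- toupper(proteins$sequence)
  seqs <- sub("\\*$", "", seqs)
  if (any(grepl("[[:space:]]", seqs)))
    stop("protein sequences must not contain whitespace")
  if (any(!nzchar(seqs)))
    stop("zero-length protein sequence in genome '", genome_id, "'")
  dup <- proteins$protein_id[duplicated(proteins$protein_id)]
  if (length(dup))
    stop("duplicate protein identifiers in genome '", genome_id, "': ",
         paste(unique(dup), collapse = ", "))
  structure(list(genome_id = genome_id,
                 clade = clade,
                 proteins = data.frame(protein_id = proteins$protein_id,
                                       sequence = seqs,
                                       length = nchar(seqs),
                                       stringsAsFactors = FALSE)),
            class = "proteome")
}

is_proteome <- function(x) inherits(x, "proteome")

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("<proteome> %s  clade: %s\n  %d proteins, %d residues\n",
              x$genome_id, if (nzchar(x$clade)) x$clade else "<unset>",
              nrow(x$proteins), sum(x$proteins$length)))
  invisible(x)
}

#' Read a protein FASTA file into a proteome
#'
#' One record per FASTA entry, in file order. Identifiers are the first
#' whitespace-delimited token of each header. Terminal `*` is stripped and
#' sequences are uppercased.
#'
#' @param path Path to a protein FASTA file.
#' @param genome_id Genome identifier to attach; defaults to the file name
#'   without extension.
#' @param clade Optional clade label.
#' @return A [proteome] object.
#' @export
read_protein_fasta <- function(path, genome_id = NULL, clade = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(aas))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA identifiers in '", path, "': ",
         paste(unique(dup), collapse = ", "))
  proteome(genome_id,
           data.frame(protein_id = ids, sequence = as.character(aas),
                      stringsAsFactors = FALSE),
           clade = clade)
}

#' Write a proteome to protein FASTA
#'
#' Inverse of [read_protein_fasta()]: identifiers and (stop-stripped,
#' uppercased) sequences round-trip exactly.
#'
#' @param x A [proteome].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(x, path) {
  stopifnot(is_proteome(x))
  aas <- Biostrings::AAStringSet(setNames(x$proteins$sequence,
                                          x$proteins$protein_id))
  Biostrings::writeXStringSet(aas, path, width = 70L)
  invisible(path)
}

#' Read a genome -> clade taxonomy table
#'
#' Two tab-separated columns (`genome_id`, `clade`); `#` comment lines and
#' blank lines are ignored. Mirrors the structure of GTDB representative-
#' genome metadata reduced to the clade used for aggregation.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `genome_id`, `clade`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  if (!length(lines)) stop("taxonomy file '", path, "' has no data rows")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("taxonomy file '", path, "': expected 2 tab-separated columns at ",
         "data row ", bad[1L])
  out <- data.frame(genome_id = vapply(parts, `[[`, "", 1L),
                    clade = vapply(parts, `[[`, "", 2L),
                    stringsAsFactors = FALSE)
  dup <- out$genome_id[duplicated(out$genome_id)]
  if (length(dup))
    stop("taxonomy file '", path, "': duplicated genome_id ",
         paste(unique(dup), collapse = ", "))
  if (any(!nzchar(out$clade)))
    stop("taxonomy file '", path, "': empty clade label")
  out
}
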