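#!/usr/bin/env Rscript
# Reproduces the reference-proteome frequency-bias values on real RefSeq
# annotated proteomes (network required):
#   E. coli K-12 MG1655 (GCF_000005845.2): RGPP bias 0, RAPP ~ 0.073
#     (one protein), RAGP ~ 0.22 (five proteins)
#   B. subtilis 168 (GCF_000009045.1): RAGP bias ~ 0.103 (one protein)
#
# Usage: Rscript scripts/reproduce_worked_values.R [workdir]
# Downloads each proteome's protein FASTA from the NCBI datasets API.

suppressMessages(library(stallscan))

workdir <- commandArgs(trailingOnly = TRUE)
workdir <- if (length(workdir)) workdir[[1L]] else "scratch/worked_values"
dir.create(workdir, showWarnings = FALSE, recursive = TRUE)

fetch_proteome <- function(accession) {
  zip <- file.path(workdir, paste0(accession, ".zip"))
  if (!file.exists(zip)) {
    url <- paste0("https://api.ncbi.nlm.nih.gov/datasets/v2/genome/accession/",
                  accession, "/download?include_annotation_type=PROT_FASTA")
    download.file(url, zip, mode = "wb", quiet = TRUE)
  }
  files <- unzip(zip, list = TRUE)$Name
  faa <- grep("protein\\.faa$", files, value = TRUE)
  if (!length(faa)) stop("no protein FASTA inside ", zip)
  unzip(zip, files = faa, exdir = workdir, overwrite = TRUE)
  read_protein_fasta(file.path(workdir, faa), genome_id = accession)
}

report <- function(accession, motifs) {
  prot <- fetch_proteome(accession)
  cat(sprintf("\n%s: %d proteins, %d residues\n", accession,
              nrow(prot$proteins), sum(prot$proteins$length)))
  counts <- count_kmers(prot, 4L)
  cen <- motif_census(scan_motifs(prot, motifs))
  for (m in motifs) {
    fb <- frequency_bias(prot, m, counts = counts)
    np <- cen$summary$n_proteins[match(m, cen$summary$motif)]
    if (is.na(np)) np <- 0L
    cat(sprintf("  %s: bias %.3g  (%d occurrences, %d proteins)\n",
                m, fb$bias, fb$observed_count, np))
  }
}

report("GCF_000005845.2", c("RGPP", "RAPP", "RAGP"))
report("GCF_000009045.1", c("RGPP", "RAPP", "RAGP"))
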