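# Synthetic proteomes and annotated toy genomes with known ground truth:
# planted composition, motif rates, C-terminal placement bias, depletion
# factors and per-group enrichment factors, all recoverable by the
# analysis stages.

#' A realistic default amino-acid composition
#'
#' Average composition of well-annotated protein databases (approximately
#' the UniProtKB/Swiss-Prot average), normalized to sum to 1. Used as the
#' default composition of synthetic proteomes.
#'
#' @return Named numeric vector over [AA_STANDARD].
#' @export
default_composition <- function() {
  pct <- c(A = 8.25, C = 1.38, D = 5.45, E = 6.72, F = 3.86,
           G = 7.07, H = 2.27, I = 5.96, K = 5.84, L = 9.66,
           M = 2.42, N = 4.06, P = 4.70, Q = 3.93, R = 5.53,
           S = 6.56, T = 5.34, V = 6.87, W = 1.08, Y = 2.92)
  pct[AA_STANDARD] / sum(pct)
}

#' Specify a synthetic proteome
#'
#' Residues are drawn iid from `composition`; protein lengths follow a
#' lognormal law truncated to `[min_length, max_length]` (defaults mirror
#' bacterial proteomes: median about 245 residues). The motif plan plants
#' motifs at a per-protein rate with controllable positional bias and
#' thins background occurrences to a controllable depletion factor.
#'
#' @param n_proteins Number of proteins.
#' @param seed Mandatory integer seed; a fixed seed gives byte-identical
#'   output.
#' @param composition Named frequency vector over [AA_STANDARD]
#'   (normalized internally).
#' @param length_meanlog,length_sdlog Lognormal length parameters
#'   (defaults `log(245)` and 0.55).
#' @param min_length,max_length Truncation bounds in residues (50, 2000).
#' @param motif_plan list of plan entries, each a list with `motif`
#'   (string), `p` (per-protein planting probability), `placement`
#'   (`"uniform"` or `"c_terminal"`), `window` (for C-terminal placement:
#'   the motif end is confined to the last `window` residues; default 1,
#'   i.e. flush with the C-terminus) and `d` (depletion factor in `(0,1]`
#'   applied to background occurrences; default 1 = no thinning).
#' @return An object of class `proteome_spec`.
#' @export
proteome_spec <- function(n_proteins, seed,
                          composition = default_composition(),
                          length_meanlog = log(245), length_sdlog = 0.55,
                          min_length = 50L, max_length = 2000L,
                          motif_plan = list()) {
  stopifnot(n_proteins >= 1L, is.numeric(seed), length(seed) == 1L)
  comp <- composition[AA_STANDARD]
  if (anyNA(comp) || any(comp < 0) || sum(comp) <= 0)
    stop("composition must be a non-negative vector over the 20 standard letters")
  comp <- comp / sum(comp)
  plan <- lapply(motif_plan, function(e) {
    stopifnot(is.list(e), !is.null(e$motif))
    e$p <- if (is.null(e$p)) 0 else e$p
    e$placement <- if (is.null(e$placement)) "uniform" else e$placement
    e$window <- if (is.null(e$window)) 1L else as.integer(e$window)
    e$d <- if (is.null(e$d)) 1 else e$d
    stopifnot(e$p >= 0, e$p <= 1, e$d > 0, e$d <= 1,
              e$placement %in% c("uniform", "c_terminal"),
              is_standard_pattern(e$motif))
    if (nchar(e$motif) > min_length)
      stop("motif '", e$motif, "' is longer than the minimum protein length")
    e
  })
  structure(list(n_proteins = as.integer(n_proteins), seed = as.integer(seed),
                 composition = comp, length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog,
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length), motif_plan = plan),
            class = "proteome_spec")
}

# Truncated-lognormal lengths by rejection.
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(rlnorm(n, meanlog, sdlog))
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# Overlapping occurrence starts of a fixed motif in one sequence.
motif_starts <- function(sequence, motif) {
  m <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Generate a synthetic proteome with planted motif structure
#'
#' Residues are drawn iid from the spec composition. For each motif-plan
#' entry, each protein independently receives one planted copy of the
#' motif with probability `p` (overwriting residues at a uniform position
#' or within the C-terminal window). Background (non-planted) occurrences
#' of each listed motif are then thinned to a factor `d`: each is kept
#' with probability `d`, otherwise one of its residues (chosen uniformly)
#' is resampled from the composition until the window no longer matches.
#' Thinning passes repeat until no untreated background occurrence
#' remains, so resampling cannot silently create new occurrences.
#'
#' @param spec A [proteome_spec()].
#' @param genome_id Genome identifier (default `"synthetic"`).
#' @param clade Clade label (default `""`).
#' @return list with `proteome` (a [proteome]) and `truth`: the spec
#'   composition, and per motif the planted count, planted positions, and
#'   post-thinning occurrence count.
#' @export
generate_proteome <- function(spec, genome_id = "synthetic", clade = "") {
  stopifnot(inherits(spec, "proteome_spec"))
  withr::with_seed(spec$seed, {
    lens <- rlnorm_trunc(spec$n_proteins, spec$length_meanlog,
                         spec$length_sdlog, spec$min_length, spec$max_length)
    seqs <- vapply(lens, function(n)
      paste0(sample(AA_STANDARD, n, replace = TRUE,
                    prob = spec$composition), collapse = ""), "")
    planted <- lapply(spec$motif_plan, function(e) {
      data.frame(protein = integer(), start = integer())
    })
    names(planted) <- vapply(spec$motif_plan, `[[`, "", "motif")
    # plant motifs
    for (ei in seq_along(spec$motif_plan)) {
      e <- spec$motif_plan[[ei]]
      if (e$p <= 0) next
      mlen <- nchar(e$motif)
      hit <- which(runif(spec$n_proteins) < e$p)
      starts <- integer(length(hit))
      for (j in seq_along(hit)) {
        n <- lens[hit[j]]
        last_start <- n - mlen + 1L
        start <- if (e$placement == "uniform") {
          sample.int(last_start, 1L)
        } else {
          lo <- max(1L, last_start - (e$window - 1L))
          if (lo == last_start) last_start
          else sample(lo:last_start, 1L)
        }
        substr(seqs[hit[j]], start, start + mlen - 1L) <- e$motif
        starts[j] <- start
      }
      planted[[ei]] <- data.frame(protein = hit, start = starts)
    }
    # thin background occurrences
    for (ei in seq_along(spec$motif_plan)) {
      e <- spec$motif_plan[[ei]]
      if (e$d >= 1) next
      mlen <- nchar(e$motif)
      for (pi in seq_len(spec$n_proteins)) {
        keep_starts <- planted[[ei]]$start[planted[[ei]]$protein == pi]
        treated <- keep_starts
        repeat {
          occ <- setdiff(motif_starts(seqs[pi], e$motif), treated)
          if (!length(occ)) break
          for (s in occ) {
            treated <- c(treated, s)
            if (runif(1L) < e$d) next
            pos <- s + sample.int(mlen, 1L) - 1L
            repeat {
              substr(seqs[pi], pos, pos) <-
                sample(AA_STANDARD, 1L, prob = spec$composition)
              if (substr(seqs[pi], s, s + mlen - 1L) != e$motif) break
            }
          }
        }
      }
    }
    prot <- proteome(genome_id,
                     data.frame(protein_id = sprintf("%s_p%05d", genome_id,
                                                     seq_len(spec$n_proteins)),
                                sequence = seqs, stringsAsFactors = FALSE),
                     clade = clade)
    truth <- list(
      composition = spec$composition,
      motifs = lapply(seq_along(spec$motif_plan), function(ei) {
        e <- spec$motif_plan[[ei]]
        occ <- sum(vapply(seqs, function(s)
          length(motif_starts(s, e$motif)), 0L))
        list(motif = e$motif, p = e$p, placement = e$placement,
             window = e$window, d = e$d,
             planted_count = nrow(planted[[ei]]),
             planted = planted[[ei]], occurrence_count = occ)
      }))
    list(proteome = prot, truth = truth)
  })
}

#' Specify a synthetic annotated genome
#'
#' Describes a toy genome consisting of uORF/downstream-gene pairs: each
#' pair is a small (< 300 aa) motif-encoding ORF annotated "hypothetical
#' protein" followed in translation direction by a CDS whose annotation is
#' drawn from a group catalog, with per-(motif, group) enrichment factors
#' multiplying the focal group's draw probability (the remaining groups
#' are scaled down to renormalize, so the expected target:control
#' proportion ratio equals the planted factor exactly).
#'
#' @param n_pairs Named integer vector: motif -> number of uORF pairs
#'   (e.g. `c(RGPP = 200, AGPP = 200)`).
#' @param seed Mandatory integer seed.
#' @param groups data.frame with columns `annotation` and `weight`
#'   (baseline multinomial weights; default: 20 equal-weight bacterial
#'   gene products).
#' @param enrichment_plan list of lists with `motif`, `annotation`,
#'   `factor` entries.
#' @param max_gap_nt Upper bound of the uniform intergenic gap law in
#'   nucleotides (default 500).
#' @param uorf_length_range,gene_length_range Protein length ranges
#'   (residues) for uORFs and downstream genes.
#' @param n_decoys Number of opposite-strand decoy genes interleaved
#'   between pairs (default one per 4 pairs).
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(n_pairs, seed, groups = default_group_catalog(),
                        enrichment_plan = list(), max_gap_nt = 500L,
                        uorf_length_range = c(60L, 290L),
                        gene_length_range = c(150L, 600L),
                        n_decoys = NULL) {
  stopifnot(is.numeric(n_pairs), !is.null(names(n_pairs)),
            all(nzchar(names(n_pairs))), all(n_pairs >= 1),
            is.numeric(seed), length(seed) == 1L,
            is.data.frame(groups),
            all(c("annotation", "weight") %in% names(groups)),
            all(groups$weight >= 0), sum(groups$weight) > 0)
  w <- groups$weight / sum(groups$weight)
  for (e in enrichment_plan) {
    stopifnot(all(c("motif", "annotation", "factor") %in% names(e)),
              e$motif %in% names(n_pairs), e$factor > 0)
    gi <- match(e$annotation, groups$annotation)
    if (is.na(gi)) stop("enrichment_plan annotation '", e$annotation,
                        "' not in the group catalog")
    if (e$factor * w[gi] >= 1)
      stop("enrichment factor ", e$factor, " on '", e$annotation,
           "' would exceed probability 1")
  }
  if (is.null(n_decoys)) n_decoys <- ceiling(sum(n_pairs) / 4)
  structure(list(n_pairs = setNames(as.integer(n_pairs), names(n_pairs)),
                 seed = as.integer(seed),
                 groups = data.frame(annotation = groups$annotation,
                                     weight = w, stringsAsFactors = FALSE),
                 enrichment_plan = enrichment_plan,
                 max_gap_nt = as.integer(max_gap_nt),
                 uorf_length_range = as.integer(uorf_length_range),
                 gene_length_range = as.integer(gene_length_range),
                 n_decoys = as.integer(n_decoys)),
            class = "genome_spec")
}

#' Default downstream-gene group catalog
#'
#' Twenty equal-weight annotation strings typical of bacterial GFF product
#' fields.
#'
#' @return data.frame `annotation`, `weight`.
#' @export
default_group_catalog <- function() {
  ann <- c("secD protein-export membrane protein",
           "TonB-dependent receptor",
           "copper-translocating P-type ATPase",
           "ABC transporter permease",
           "MFS transporter",
           "two-component sensor histidine kinase",
           "response regulator transcription factor",
           "cytochrome c oxidase subunit",
           "multidrug efflux RND transporter",
           "peptidase M23 family protein",
           "glycosyltransferase family protein",
           "TetR family transcriptional regulator",
           "outer membrane beta-barrel protein",
           "heavy metal translocating P-type ATPase",
           "signal peptidase I",
           "membrane protein insertase YidC",
           "preprotein translocase subunit SecY",
           "cation diffusion facilitator transporter",
           "LysM peptidoglycan-binding domain protein",
           "siderophore biosynthesis protein")
  data.frame(annotation = ann, weight = rep(1 / length(ann), length(ann)),
             stringsAsFactors = FALSE)
}

# One fixed codon per amino acid (reverse translation for toy genomes).
AA_CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCG", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

reverse_translate <- function(aa_seq) {
  paste0(paste0(AA_CODON[strsplit(aa_seq, "", fixed = TRUE)[[1L]]],
                collapse = ""), "TAA")
}

# Group draw probabilities for one motif under the enrichment plan:
# focal groups get factor * weight; the rest are scaled to renormalize.
motif_group_probs <- function(spec, motif) {
  p <- spec$groups$weight
  focal <- rep(FALSE, length(p))
  for (e in spec$enrichment_plan) {
    if (e$motif != motif) next
    gi <- match(e$annotation, spec$groups$annotation)
    p[gi] <- p[gi] * e$factor
    focal[gi] <- TRUE
  }
  rest <- sum(spec$groups$weight[!focal])
  if (any(focal) && rest > 0)
    p[!focal] <- p[!focal] * (1 - sum(p[focal])) / rest
  p / sum(p)
}

#' Generate an annotated toy genome with planted uORF enrichment
#'
#' Lays uORF/downstream-gene pairs along a single contig: a small
#' motif-encoding ORF (motif flush with the C-terminus, product
#' "hypothetical protein") followed in translation direction, after a
#' uniform(0, `max_gap_nt`) gap, by a downstream CDS whose annotation is
#' drawn from the (possibly enriched) group multinomial. Strands are
#' Bernoulli(0.5); opposite-strand decoy genes are interleaved between
#' pairs (they never intervene in same-strand pairing). Coordinates are
#' internally consistent (CDS spans 3*(aa+1) nucleotides including the
#' stop codon).
#'
#' @param spec A [genome_spec()].
#' @param genome_id Genome identifier (default `"synthgenome"`).
#' @param emit_sequence Also assemble the nucleotide contig sequence
#'   (default TRUE; pairing and enrichment only need features + proteins).
#' @return list with `features` (CDS data.frame in [read_gff3()] layout),
#'   `proteome` (all encoded proteins), `genome_seq` (named character, or
#'   NULL), and `truth` (one row per pair: ids, motif, group, strand,
#'   gap).
#' @export
generate_annotated_genome <- function(spec, genome_id = "synthgenome",
                                      emit_sequence = TRUE) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(spec$seed, {
    motifs <- names(spec$n_pairs)
    probs <- lapply(motifs, function(m) motif_group_probs(spec, m))
    names(probs) <- motifs
    pair_motif <- rep(motifs, spec$n_pairs)
    n_total <- length(pair_motif)
    pair_motif <- sample(pair_motif)          # shuffle order along contig
    feats <- list(); prots <- list(); truth <- list(); seq_parts <- list()
    cursor <- 1L
    contig <- paste0(genome_id, "_c1")
    decoy_every <- if (spec$n_decoys > 0) max(1L, n_total %/% spec$n_decoys)
                   else NA_integer_
    rand_aa <- function(n) paste0(sample(AA_STANDARD, n, replace = TRUE,
                                         prob = default_composition()),
                                  collapse = "")
    emit_cds <- function(id, aa, start, strand, product, protein_id) {
      end <- start + 3L * (nchar(aa) + 1L) - 1L
      feats[[length(feats) + 1L]] <<- data.frame(
        feature_id = id, contig = contig, start = start, end = end,
        strand = strand, product_annotation = product,
        protein_id = protein_id, stringsAsFactors = FALSE)
      prots[[length(prots) + 1L]] <<- data.frame(
        protein_id = protein_id, sequence = aa, stringsAsFactors = FALSE)
      if (emit_sequence) {
        nt <- reverse_translate(aa)
        if (strand == "-")
          nt <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(nt)))
        seq_parts[[length(seq_parts) + 1L]] <<- list(start = start, nt = nt)
      }
      end
    }
    for (i in seq_len(n_total)) {
      m <- pair_motif[i]
      strand <- if (runif(1L) < 0.5) "+" else "-"
      gap <- sample.int(spec$max_gap_nt + 1L, 1L) - 1L
      ulen <- sample(spec$uorf_length_range[1L]:spec$uorf_length_range[2L], 1L)
      glen <- sample(spec$gene_length_range[1L]:spec$gene_length_range[2L], 1L)
      group_i <- sample.int(nrow(spec$groups), 1L, prob = probs[[m]])
      group_ann <- spec$groups$annotation[group_i]
      u_aa <- rand_aa(ulen)
      substr(u_aa, ulen - nchar(m) + 1L, ulen) <- m   # motif flush with C-terminus
      g_aa <- rand_aa(glen)
      uid <- sprintf("%s_u%04d", genome_id, i)
      did <- sprintf("%s_d%04d", genome_id, i)
      if (strand == "+") {
        uend <- emit_cds(uid, u_aa, cursor, "+", "hypothetical protein", uid)
        dend <- emit_cds(did, g_aa, uend + gap + 1L, "+", group_ann, did)
      } else {
        # translation right-to-left: downstream gene sits at lower coords
        dend <- emit_cds(did, g_aa, cursor, "-", group_ann, did)
        uend <- emit_cds(uid, u_aa, dend + gap + 1L, "-",
                         "hypothetical protein", uid)
        dend <- uend
      }
      truth[[i]] <- data.frame(pair_id = i, motif = m, uorf_id = uid,
                               downstream_id = did, group = group_ann,
                               strand = strand, gap_nt = gap,
                               stringsAsFactors = FALSE)
      cursor <- dend + 1000L                  # spacer between pairs
      if (!is.na(decoy_every) && i %% decoy_every == 0L) {
        dlen <- sample(spec$gene_length_range[1L]:spec$gene_length_range[2L], 1L)
        xid <- sprintf("%s_x%04d", genome_id, i)
        # pairs are self-contained (partner gap <= max_gap_nt < the 1000-nt
        # spacer), so a decoy between pairs can never win a pairing search
        dstrand <- if (runif(1L) < 0.5) "+" else "-"
        dend2 <- emit_cds(xid, rand_aa(dlen), cursor, dstrand,
                          "elongation factor Tu", xid)
        cursor <- dend2 + 1000L
      }
    }
    features <- do.call(rbind, feats)
    features <- features[order(features$contig, features$start), ,
                         drop = FALSE]
    rownames(features) <- NULL
    prot <- proteome(genome_id, do.call(rbind, prots))
    genome_seq <- NULL
    if (emit_sequence) {
      total_len <- max(features$end) + 100L
      base <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)
      for (sp in seq_parts) {
        idx <- sp$start:(sp$start + nchar(sp$nt) - 1L)
        base[idx] <- strsplit(sp$nt, "", fixed = TRUE)[[1L]]
      }
      genome_seq <- setNames(paste0(base, collapse = ""), contig)
    }
    list(features = features, proteome = prot, genome_seq = genome_seq,
         truth = do.call(rbind, truth))
  })
}

#' Write a synthetic annotated genome to standard files
#'
#' Emits `<genome_id>.gff3` (CDS features with `ID`, `product`,
#' `protein_id` attributes), `<genome_id>.faa` (protein FASTA),
#' optionally `<genome_id>.fna` (contig FASTA) and
#' `<genome_id>.truth.tsv` (planted ground truth) into a directory.
#'
#' @param genome Result of [generate_annotated_genome()].
#' @param dir Output directory (created if needed).
#' @param genome_id Base name for the files.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_annotated_genome <- function(genome, dir, genome_id = genome$proteome$genome_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- genome$features
  gff <- file.path(dir, paste0(genome_id, ".gff3"))
  attrs <- sprintf("ID=%s;product=%s;protein_id=%s",
                   f$feature_id, f$product_annotation, f$protein_id)
  writeLines(c("##gff-version 3",
               sprintf("%s\tstallscan\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                       f$contig, f$start, f$end, f$strand, attrs)),
             gff)
  faa <- file.path(dir, paste0(genome_id, ".faa"))
  write_protein_fasta(genome$proteome, faa)
  paths <- c(gff3 = gff, faa = faa)
  if (!is.null(genome$genome_seq)) {
    fna <- file.path(dir, paste0(genome_id, ".fna"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(genome$genome_seq), fna, width = 70L)
    paths <- c(paths, fna = fna)
  }
  tr <- file.path(dir, paste0(genome_id, ".truth.tsv"))
  write.table(genome$truth, tr, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paths, truth = tr))
}
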