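# Synthetic-data generators: determinism, composition convergence,
# planted structure, and round-trip recovery through the pipeline stages.

test_that("fixed seeds give byte-identical synthetic outputs", {
  sp <- proteome_spec(30, seed = 5,
                      motif_plan = list(list(motif = "RAPP", p = 0.3,
                                             placement = "c_terminal")))
  a <- generate_proteome(sp)
  b <- generate_proteome(sp)
  expect_identical(a$proteome$proteins, b$proteome$proteins)
  expect_identical(a$truth, b$truth)

  gs <- genome_spec(c(RGPP = 12, AGPP = 12), seed = 6)
  ga <- generate_annotated_genome(gs)
  gb <- generate_annotated_genome(gs)
  expect_identical(ga$features, gb$features)
  expect_identical(ga$genome_seq, gb$genome_seq)
  expect_identical(ga$truth, gb$truth)
  # written files are byte-identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_annotated_genome(ga, d1, "g")
  write_annotated_genome(gb, d2, "g")
  for (f in c("g.gff3", "g.faa", "g.fna", "g.truth.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("generated proteome composition converges to the spec composition", {
  comp <- default_composition()
  sp <- proteome_spec(4000, seed = 17, composition = comp)
  gen <- generate_proteome(sp)
  emp <- composition(gen$proteome)
  expect_gt(sum(gen$proteome$proteins$length), 9e5)
  expect_lt(max(abs(emp - comp)), 0.005)
})

test_that("p = 0 and d = 1 give a null proteome with bias near 1", {
  comp <- default_composition()
  sp <- proteome_spec(1500, seed = 23, composition = comp)
  prot <- generate_proteome(sp)$proteome
  gv <- genome_bias_vector(prot, 4L)
  # frequent patterns only (expected count >= 10): mean bias ~ 1
  sel <- gv$expected_freq * gv$total_windows >= 10
  expect_gt(sum(sel), 100)
  expect_lt(abs(mean(gv$bias[sel]) - 1), 0.05)
})

test_that("p = 1 with flush C-terminal placement puts every motif at distance 0", {
  sp <- proteome_spec(40, seed = 29,
                      motif_plan = list(list(motif = "RGPP", p = 1,
                                             placement = "c_terminal",
                                             window = 1L)))
  gen <- generate_proteome(sp)
  expect_equal(gen$truth$motifs[[1]]$planted_count, 40L)
  cen <- motif_census(scan_motifs(gen$proteome, "RGPP"),
                      length_cap = 10000L)
  expect_equal(cen$summary$n_proteins, 40L)
  expect_true(all(cen$per_protein$distance_to_C == 0L))
})

test_that("census counts of planted motifs follow the Binomial(n, p) law", {
  n <- 10000L; p <- 0.05
  sp <- proteome_spec(n, seed = 37, length_meanlog = log(120),
                      motif_plan = list(list(motif = "RGPP", p = p,
                                             placement = "c_terminal")))
  gen <- generate_proteome(sp)
  cen <- motif_census(scan_motifs(gen$proteome, "RGPP"),
                      length_cap = 10000L)
  # chance (non-planted) occurrences add a small positive rate; planted
  # count itself is Binomial(n, p): check the census count against it
  # within 4 SD plus the expected chance-occurrence allowance
  sd_bin <- sqrt(n * p * (1 - p))
  expect_gt(cen$summary$n_proteins, n * p - 4 * sd_bin)
  chance <- sum(gen$proteome$proteins$length) * 5e-6  # ~ef for RGPP
  expect_lt(cen$summary$n_proteins, n * p + 4 * sd_bin + 10 * chance + 10)
  # ground truth is consistent with a direct rescan of the sequences
  expect_gte(cen$summary$n_proteins, gen$truth$motifs[[1]]$planted_count)
  expect_equal(cen$summary$n_occurrences,
               gen$truth$motifs[[1]]$occurrence_count)
})

test_that("planted depletion factors are recovered by the bias statistic", {
  comp <- default_composition()
  comp[c("R", "A", "P")] <- c(0.25, 0.25, 0.25)
  comp <- comp / sum(comp)
  for (d in c(0.1, 0.5)) {
    sp <- proteome_spec(2500, seed = round(43 + d * 100),
                        composition = comp,
                        motif_plan = list(list(motif = "RAPP", p = 0, d = d)))
    gen <- generate_proteome(sp)
    fb <- frequency_bias(gen$proteome, "RAPP")
    expect_gt(fb$total_windows, 1e5)
    expect_lt(abs(fb$bias - d) / d, 0.2)
  }
})

test_that("annotated toy genomes honor the planted pair structure", {
  gs <- genome_spec(c(RGPP = 30, AGPP = 30), seed = 47)
  gen <- generate_annotated_genome(gs, "tg")
  tr <- gen$truth
  expect_equal(nrow(tr), 60L)
  expect_equal(sort(unique(tr$motif)), c("AGPP", "RGPP"))
  f <- gen$features
  # coordinates internally consistent: CDS length = 3*(aa+1)
  aa_len <- gen$proteome$proteins$length[
    match(f$protein_id, gen$proteome$proteins$protein_id)]
  expect_equal(f$end - f$start + 1L, 3L * (aa_len + 1L))
  # uORFs are small, motif-encoding, annotated hypothetical
  u <- gen$proteome$proteins[match(tr$uorf_id,
                                   gen$proteome$proteins$protein_id), ]
  expect_true(all(u$length < 300L))
  expect_true(all(substr(u$sequence, u$length - 3L, u$length) == tr$motif))
  expect_true(all(f$product_annotation[match(tr$uorf_id, f$feature_id)] ==
                  "hypothetical protein"))
  expect_true(all(f$product_annotation[match(tr$downstream_id, f$feature_id)] ==
                  tr$group))
})

test_that("pairing the emitted GFF3 recovers every planted pair", {
  gs <- genome_spec(c(RGPP = 40, AGPP = 40), seed = 53)
  gen <- generate_annotated_genome(gs, "rt", emit_sequence = FALSE)
  dir <- withr::local_tempdir()
  write_annotated_genome(gen, dir, "rt")
  feats <- read_gff3(file.path(dir, "rt.gff3"))
  expect_equal(nrow(feats), nrow(gen$features))
  tr <- gen$truth
  recovered <- 0L
  for (i in seq_len(nrow(tr))) {
    u <- feats[feats$feature_id == tr$uorf_id[i], ]
    hit <- find_downstream(feats, u)
    if (!is.null(hit) && hit$feature_id == tr$downstream_id[i])
      recovered <- recovered + 1L
  }
  expect_equal(recovered, nrow(tr))
})

test_that("invalid specs are rejected", {
  expect_error(proteome_spec(10, seed = 1, min_length = 3L,
                             motif_plan = list(list(motif = "RAPP"))),
               "longer than the minimum")
  expect_error(proteome_spec(10, seed = 1,
                             motif_plan = list(list(motif = "RAPP", p = 2))))
  expect_error(genome_spec(c(RGPP = 10), seed = 1,
                           enrichment_plan = list(
                             list(motif = "RGPP", annotation = "nope",
                                  factor = 5))),
               "not in the group catalog")
})
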