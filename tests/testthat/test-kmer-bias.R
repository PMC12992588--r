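# The central statistic: sliding-window counting, composition,
# expected frequency, and the frequency-bias ratio.

test_that("count_kmers counts overlapping windows and skips short proteins", {
  expect_equal(count_kmers(proteome("g", "RAPP"))$counts, c(RAPP = 1L))
  expect_equal(count_kmers(proteome("g", "RAPP"))$total_windows, 1L)

  short <- count_kmers(proteome("g", "MRA"))
  expect_equal(length(short$counts), 0L)
  expect_equal(short$total_windows, 0L)

  two <- count_kmers(proteome("g", c("ARAPPA", "RAPP")))
  expect_equal(two$total_windows, 4L)
  expect_equal(two$counts[c("ARAP", "RAPP", "APPA")],
               c(ARAP = 1L, RAPP = 2L, APPA = 1L))
})

test_that("windows containing non-standard letters are excluded from both sides", {
  # AXAPP: both windows (AXAP, XAPP) contain X -> zero valid windows
  res <- count_kmers(proteome("g", "AXAPP"))
  expect_equal(res$total_windows, 0L)
  expect_equal(length(res$counts), 0L)
  # RAPPXRAPP: windows by hand -> RAPP (1), APPX..XRAP invalid, RAPP (5+)
  res2 <- count_kmers(proteome("g", "RAPPXRAPP"))
  expect_equal(res2$total_windows, 2L)
  expect_equal(res2$counts, c(RAPP = 2L))
})

test_that("composition excludes non-standard letters and sums to one", {
  expect_equal(unname(composition(proteome("g", "AAAA"))["A"]), 1)
  cc <- composition(proteome("g", "ACDE"))
  expect_equal(unname(cc[c("A", "C", "D", "E")]), rep(0.25, 4))
  expect_equal(sum(cc), 1)

  # X residues drop out of numerator and denominator
  cx <- composition(proteome("g", "AAXG"))
  expect_equal(unname(cx["A"]), 2 / 3)
  expect_equal(unname(cx["G"]), 1 / 3)

  set.seed(11)
  seqs <- random_seqs(10)
  cc <- composition(proteome("g", seqs))
  chars <- unlist(strsplit(seqs, "", fixed = TRUE))
  hand <- table(factor(chars, levels = AA_STANDARD)) / length(chars)
  expect_equal(as.numeric(cc), as.numeric(hand))
  expect_equal(sum(cc), 1, tolerance = 1e-12)
})

test_that("expected_frequency is the positional product of composition", {
  comp_u <- setNames(rep(0.05, 20), AA_STANDARD)
  expect_equal(expected_frequency("RAPP", comp_u), 0.05^4)
  comp_a <- setNames(c(1, rep(0, 19)), AA_STANDARD)
  expect_equal(expected_frequency("AAAA", comp_a), 1)
  set.seed(3)
  w <- runif(20); comp_r <- setNames(w / sum(w), AA_STANDARD)
  expect_equal(expected_frequency("RAPP", comp_r),
               comp_r["R"] * comp_r["A"] * comp_r["P"] * comp_r["P"],
               ignore_attr = TRUE)
  expect_error(expected_frequency("RAXP", comp_u), "non-standard")
})

test_that("frequency_bias handles identity, absence, and undefined cases", {
  fb <- frequency_bias(proteome("g", "AAAA"), "AAAA")
  expect_equal(fb$observed_freq, 1)
  expect_equal(fb$expected_freq, 1)
  expect_equal(fb$bias, 1)

  # pattern absent but expected > 0: bias exactly 0
  fb0 <- frequency_bias(proteome("g", c("MARA", "PAPA")), "RAPP")
  expect_equal(fb0$bias, 0)
  expect_true(fb0$bias_defined)

  # no valid windows: undefined, flagged, not coerced
  fbu <- frequency_bias(proteome("g", "MRA"), "RAPP")
  expect_false(fbu$bias_defined)
  expect_true(is.na(fbu$bias))

  # expected zero (letter absent from proteome): undefined
  fbw <- frequency_bias(proteome("g", "AAAAGGGG"), "WAAA")
  expect_false(fbw$bias_defined)
  expect_true(is.na(fbw$bias))
})

test_that("frequency_bias equals the naive enumeration oracle on random proteomes", {
  set.seed(101)
  for (rep in 1:25) {
    seqs <- random_seqs(sample(1:12, 1L),
                        alphabet = c(AA_STANDARD, "X", "B"))
    prot <- proteome("g", seqs)
    counts <- count_kmers(prot, 4L)
    # every pattern present, plus absent probes
    pats <- unique(c(names(counts$counts), "RAPP", "WWWW"))
    for (pat in pats) {
      got <- frequency_bias(prot, pat, counts = counts)
      exp <- oracle_bias(prot$proteins$sequence, pat)
      expect_equal(got$observed_count, exp$obs)
      expect_equal(got$total_windows, exp$tw)
      if (is.na(exp$bias)) expect_true(is.na(got$bias))
      else expect_equal(got$bias, exp$bias, tolerance = 1e-12)
    }
  }
})

test_that("window-mode and protein-mode counts differ exactly by multiplicity", {
  prot <- proteome("g", c("RAPPRAPP", "MRAPPA", "GGGG"))
  w <- frequency_bias(prot, "RAPP", mode = "windows")
  p <- frequency_bias(prot, "RAPP", mode = "proteins")
  expect_equal(w$observed_count, 3L)
  expect_equal(p$observed_count, 2L)
})

test_that("observed frequencies sum to 1 and expected frequencies to (sum comp)^4", {
  set.seed(5)
  prot <- proteome("g", random_seqs(20, c(10L, 80L),
                                    alphabet = c(AA_STANDARD, "X")))
  res <- count_kmers(prot, 4L)
  expect_equal(sum(res$counts) / res$total_windows, 1)
  gv <- genome_bias_vector(prot, 4L)
  expect_equal(sum(gv$expected_freq), 1, tolerance = 1e-9)
  expect_equal(sum(gv$observed_count), res$total_windows)
  # dense vector agrees with the sparse map
  nz <- gv$observed_count[match(names(res$counts), gv$patterns)]
  expect_equal(nz, unname(res$counts), ignore_attr = TRUE)
})

test_that("dense expected frequencies match expected_frequency entrywise", {
  set.seed(9)
  prot <- proteome("g", random_seqs(5, c(20L, 60L)))
  gv <- genome_bias_vector(prot, 4L)
  comp <- composition(prot)
  probe <- sample(length(gv$patterns), 50L)
  for (i in probe)
    expect_equal(gv$expected_freq[i],
                 expected_frequency(gv$patterns[i], comp))
})

test_that("k is a genuine parameter: k = 2 and k = 5 behave consistently", {
  prot <- proteome("g", "MRAPPA")
  k2 <- count_kmers(prot, 2L)
  expect_equal(k2$total_windows, 5L)
  expect_equal(k2$counts[["RA"]], 1L)
  k5 <- count_kmers(prot, 5L)
  expect_equal(k5$total_windows, 2L)
  expect_equal(sort(names(k5$counts)), c("MRAPP", "RAPPA"))
})
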