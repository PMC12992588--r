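# Downstream-gene pairing, annotation filtering/grouping, Fisher's exact
# test, BH adjustment, and the enrichment table.

feat <- function(id, start, end, strand, product = "", contig = "c1",
                 protein_id = id) {
  data.frame(feature_id = id, contig = contig, start = start, end = end,
             strand = strand, product_annotation = product,
             protein_id = protein_id, stringsAsFactors = FALSE)
}

test_that("find_downstream picks the nearest same-strand gene in translation direction", {
  feats <- rbind(feat("u", 100L, 400L, "+"),
                 feat("g1", 500L, 900L, "+"),
                 feat("g2", 1500L, 1800L, "+"))
  hit <- find_downstream(feats, feats[1, ])
  expect_equal(hit$feature_id, "g1")
  expect_equal(hit$intergenic_distance, 100L)

  # opposite strand candidates are excluded
  feats2 <- rbind(feat("u", 100L, 400L, "+"), feat("g", 500L, 900L, "-"))
  expect_null(find_downstream(feats2, feats2[1, ]))

  # minus strand: translation-direction downstream lies at lower coordinates
  feats3 <- rbind(feat("g", 200L, 800L, "-"), feat("u", 1000L, 1300L, "-"))
  hit3 <- find_downstream(feats3, feats3[2, ])
  expect_equal(hit3$feature_id, "g")
  expect_equal(hit3$intergenic_distance, 200L)

  # max_gap cap
  expect_null(find_downstream(feats, feats[1, ], max_gap = 50L))
  # different contig never pairs
  feats4 <- rbind(feat("u", 100L, 400L, "+"),
                  feat("g", 500L, 900L, "+", contig = "c2"))
  expect_null(find_downstream(feats4, feats4[1, ]))
})

test_that("select_uorfs applies the annotation and length filters", {
  base <- data.frame(
    uorf_length = c(120L, 120L, 350L, 120L, 120L, 120L),
    uorf_product = c("hypothetical protein", "DNA polymerase",
                     "hypothetical protein", "Uncharacterized protein",
                     "protein of unknown function", "hypothetical protein"),
    downstream_product = c("secD", "secD", "secD", "TonB receptor",
                           "MFS transporter", "unknown"),
    stringsAsFactors = FALSE)
  kept <- select_uorfs(base)
  # hand filter: row 1 (hypothetical/secD), row 4 (uncharacterized/TonB),
  # row 5 ("unknown" in the uORF annotation is an accepted keyword);
  # row 2 annotated uORF, row 3 too long, row 6 unknown downstream
  expect_equal(nrow(kept), 3L)
  expect_setequal(kept$downstream_product,
                  c("secD", "TonB receptor", "MFS transporter"))
})

test_that("annotation grouping normalizes case/whitespace but never fuzzy-matches", {
  expect_equal(normalize_annotation(c("SecD ", "secd", "secD.")),
               rep("secd", 3))
  expect_false(normalize_annotation("TonB-dependent receptor") ==
               normalize_annotation("TonB dependent receptor"))
  pairs <- data.frame(
    motif = "RGPP",
    downstream_product = c("SecD ", "secd", "TonB-dependent receptor",
                           "TonB dependent receptor"),
    stringsAsFactors = FALSE)
  grp <- group_by_annotation(pairs)
  expect_equal(sort(names(grp)),
               sort(c("secd", "tonb-dependent receptor",
                      "tonb dependent receptor")))
  expect_equal(nrow(grp$secd), 2L)
})

test_that("fisher_exact matches hand-enumerated worked tables", {
  expect_equal(fisher_exact(1, 1, 1, 1), 1)
  expect_equal(fisher_exact(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact(0, 10, 10, 0), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_error(fisher_exact(-1, 1, 1, 1), "non-negative")
  # agreement with stats::fisher.test (independent implementation)
  set.seed(8)
  for (i in 1:50) {
    tb <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 fisher.test(tb)$p.value, tolerance = 1e-9)
    expect_equal(
      fisher_exact(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2], "greater"),
      fisher.test(tb, alternative = "greater")$p.value, tolerance = 1e-9)
  }
})

test_that("fisher_exact equals exhaustive enumeration for all tables with total <= 40", {
  worst <- 0
  for (n in 1:40) {
    for (r1 in 0:n) {
      for (c1 in 0:n) {
        lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
        if (lo > hi) next
        for (a in lo:hi) {
          b <- r1 - a; c_ <- c1 - a; d <- n - r1 - c1 + a
          p1 <- fisher_exact(a, b, c_, d)
          p2 <- oracle_fisher(a, b, c_, d)
          worst <- max(worst, abs(p1 - p2))
        }
      }
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("fisher_exact is invariant under simultaneous transposition", {
  set.seed(12)
  for (i in 1:40) {
    x <- rpois(4, 5)
    expect_equal(fisher_exact(x[1], x[2], x[3], x[4]),
                 fisher_exact(x[1], x[3], x[2], x[4]), tolerance = 1e-12)
    expect_equal(fisher_exact(x[1], x[2], x[3], x[4]),
                 fisher_exact(x[4], x[3], x[2], x[1]), tolerance = 1e-12)
  }
})

test_that("bh_adjust reproduces the step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(13)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1L))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    # monotone when sorted by raw p
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15))
  }
})

make_pairs <- function(motif, groups) {
  data.frame(motif = motif, downstream_product = groups,
             stringsAsFactors = FALSE)
}

test_that("enrichment_table builds the 2x2 tables and flags infinite folds", {
  pairs <- rbind(make_pairs("RGPP", rep("secD", 10)),
                 make_pairs("AGPP", rep("tonB", 10)))
  et <- enrichment_table(pairs, "RGPP", "AGPP")
  secd <- et[et$group_key == "secd", ]
  expect_equal(unlist(secd[, c("a", "b", "c", "d")]),
               c(a = 10L, b = 0L, c = 0L, d = 10L))
  expect_true(is.infinite(secd$fold_enrichment))
  expect_true(secd$infinite_fold)
  expect_equal(secd$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  # margins: sums of a and c recover totals per group family
  expect_equal(unique(et$a + et$b), 10L)
  expect_equal(unique(et$c + et$d), 10L)
  expect_equal(sum(et$a), 10L)
  expect_equal(sum(et$c), 10L)
})

test_that("identical target and control distributions give fold 1 and p 1", {
  g <- rep(c("secD", "tonB", "mfs"), times = c(4, 3, 3))
  pairs <- rbind(make_pairs("RAPP", g), make_pairs("AAPP", g))
  et <- enrichment_table(pairs, "RAPP", "AAPP")
  expect_equal(et$fold_enrichment, rep(1, 3))
  expect_equal(et$p_value, rep(1, 3))
  expect_false(any(et$significant))
  expect_error(enrichment_table(pairs, "RGPP", "AAPP"), "RGPP")
})

test_that("null enrichment keeps the adjusted-p<0.01 fraction at the FDR level", {
  set.seed(99)
  n_groups <- 25L
  groups <- paste0("grp", seq_len(n_groups))
  hits <- 0L; total <- 0L
  for (rep in 1:200) {
    gt <- sample(groups, 100, replace = TRUE)
    gc <- sample(groups, 100, replace = TRUE)
    pairs <- rbind(make_pairs("RGPP", gt), make_pairs("AGPP", gc))
    et <- enrichment_table(pairs, "RGPP", "AGPP")
    hits <- hits + sum(et$significant)
    total <- total + nrow(et)
  }
  frac <- hits / total
  se <- sqrt(0.01 * 0.99 / total)
  expect_lte(frac, 0.01 + 3 * se)
})

test_that("planted 5x enrichment is recovered within 25% at 500 uORFs per motif", {
  set.seed(55)
  w <- rep(1 / 20, 20)
  groups <- paste0("grp", 1:20)
  # target probabilities: focal group x5, complement renormalized
  pt <- w; pt[1] <- 5 * w[1]; pt[-1] <- pt[-1] * (1 - pt[1]) / sum(w[-1])
  gt <- sample(groups, 500, replace = TRUE, prob = pt)
  gc <- sample(groups, 500, replace = TRUE, prob = w)
  pairs <- rbind(make_pairs("RGPP", gt), make_pairs("AGPP", gc))
  et <- enrichment_table(pairs, "RGPP", "AGPP")
  focal <- et[et$group_key == "grp1", ]
  expect_equal(et$group_key[1], "grp1")            # top fold
  expect_lt(abs(focal$fold_enrichment - 5) / 5, 0.25)
  expect_lt(focal$p_adjusted, 0.01)
})
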