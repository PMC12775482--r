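test_that("icelogo frequencies sum to one and fold changes are exact ratios", {
  logo <- icelogo(rep("PLGLAGKKRA", 7), normalization = "raw")
  sums <- tapply(logo$frequency, logo$position, sum)
  expect_equal(as.numeric(sums), rep(1, 10), tolerance = 1e-9)
  # all-identical peptides: frequency 1 at each position's residue
  expect_equal(logo$frequency[logo$position == 1 & logo$residue == "P"], 1)
  expect_equal(sum(logo$frequency == 1), 10)
  expect_equal(logo$position_label[logo$position == 3][1], "P3")
  expect_equal(logo$position_label[logo$position == 6][1], "P1'")

  # fold change = frequency / reference, elementwise
  withr::with_seed(1, peps <- random_peptides(100))
  nat <- icelogo(peps, normalization = "natural")
  ref <- pmax(NATURAL_AA_FREQS, 1e-4)
  expect_equal(nat$fold_change,
               nat$frequency / unname(ref[nat$residue]), tolerance = 1e-12)
  # a frequency of 0.2 against reference 0.05 is a 4-fold increase
  bg <- setNames(rep(0.05, 20), AA_ALPHABET)
  custom <- icelogo(c("AAAAA", "ACDEF", "AGHIK", "ALMNP", "AQRST"),
                    normalization = "background", reference = bg)
  expect_equal(custom$fold_change[custom$position == 2 & custom$residue == "C"],
               0.2 / 0.05)
  expect_error(icelogo(c("AAA", "AAAA")), "uniform")
  expect_error(icelogo("AAAA", normalization = "background"), "reference")
  # colour classes are attached per residue
  expect_equal(unique(logo$color_class[logo$residue == "F"]), "hydrophobic_aromatic")
  expect_equal(unique(logo$color_class[logo$residue == "K"]), "basic")
})

test_that("icelogo TSV export round-trips the matrix", {
  withr::with_seed(2, logo <- icelogo(random_peptides(30)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_icelogo(logo, path)
  expect_match(readLines(path, n = 1), "normalization=raw")
  back <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  expect_equal(dim(back), c(10, 21))
  expect_equal(back$A[1], logo$frequency[logo$position == 1 & logo$residue == "A"])
})

test_that("position-wise KL is zero on identity, non-negative, and hand-checkable", {
  withr::with_seed(3, peps <- random_peptides(40, 6))
  self_kl <- position_kl(peps, peps)
  expect_equal(self_kl$per_position$kl, rep(0, 6), tolerance = 1e-12)
  expect_equal(self_kl$mean_kl, 0, tolerance = 1e-12)

  withr::with_seed(4, {
    for (i in 1:100) {
      a <- random_peptides(15, 5)
      b <- random_peptides(15, 5)
      expect_gte(position_kl(a, b)$mean_kl, 0)
    }
  })

  # explicit toy sets, KL computed independently with pseudocount 1
  A <- c("AC", "AC", "AD", "CC")
  B <- c("CC", "CD", "AD", "DD")
  got <- position_kl(A, B, alpha = 1)
  kl_hand <- function(ca, cb) {
    fa <- (ca + 1) / sum(ca + 1)
    fb <- (cb + 1) / sum(cb + 1)
    sum(fa * log(fa / fb))
  }
  ca1 <- table(factor(substr(A, 1, 1), levels = AA_ALPHABET))
  cb1 <- table(factor(substr(B, 1, 1), levels = AA_ALPHABET))
  ca2 <- table(factor(substr(A, 2, 2), levels = AA_ALPHABET))
  cb2 <- table(factor(substr(B, 2, 2), levels = AA_ALPHABET))
  expect_equal(got$per_position$kl, c(kl_hand(ca1, cb1), kl_hand(ca2, cb2)),
               tolerance = 1e-12)
  # position subset averaging
  got1 <- position_kl(A, B, positions = 1)
  expect_equal(got1$mean_kl, got$per_position$kl[1])
})

test_that("k-mer census counts overlaps and matches a sliding-window oracle", {
  expect_equal(kmer_census("AAAAA", 3), tibble::tibble(kmer = "AAA", count = 3L))

  withr::with_seed(5, peps <- random_peptides(200, 10))
  for (k in c(3, 5)) {
    census <- kmer_census(peps, k)
    oracle <- table(unlist(lapply(peps, function(s)
      vapply(1:(10 - k + 1), function(i) substr(s, i, i + k - 1), character(1)))))
    expect_equal(sum(census$count), sum(oracle))
    expect_equal(census$count[match(names(oracle), census$kmer)],
                 as.integer(oracle))
  }
  expect_error(kmer_census("AAA", 5), "exceeds")

  # CDF is non-decreasing and ends at one
  cdf <- kmer_cdf(kmer_census(peps, 4))
  expect_true(all(diff(cdf$cumulative_fraction) >= 0))
  expect_equal(cdf$cumulative_fraction[nrow(cdf)], 1)
})

test_that("shared/unique k-mer breakdown partitions the union", {
  a <- kmer_census(c("AAAAA", "CCCCC"), 3)      # AAA, CCC
  b <- kmer_census(c("DDDDD", "CCCCC"), 3)      # DDD, CCC
  br <- shared_breakdown(a, b)
  expect_equal(sum(br$fractions$fraction), 1)
  expect_equal(br$fractions$n[br$fractions$subset == "shared"], 1)
  # disjoint alphabets share nothing
  br0 <- shared_breakdown(kmer_census("AAAAA", 3), kmer_census("DDDDD", 3))
  expect_equal(br0$fractions$fraction[br0$fractions$subset == "shared"], 0)
  withr::with_seed(6, {
    ca <- kmer_census(random_peptides(50), 5)
    cb <- kmer_census(random_peptides(50), 5)
    brr <- shared_breakdown(ca, cb)
    expect_equal(sum(brr$fractions$fraction), 1, tolerance = 1e-12)
    expect_lte(nrow(brr$top_kmers), 9)
  })
})

test_that("biophysical properties follow their defining formulas", {
  bp <- biophysical_properties(c("AAAAAAAAAA", "GGGGGGGGGG", "ACDEFGHIKL"))
  # poly-alanine: aliphatic index 100; poly-glycine: 0
  expect_equal(bp$aliphatic_index[1], 100)
  expect_equal(bp$aliphatic_index[2], 0)
  # ACDEFGHIKL: fA = fI = fL = 0.1 -> 100 * (0.1 + 3.9 * 0.2) = 88
  expect_equal(bp$aliphatic_index[3], 88)

  # mean hydropathy, recomputed independently
  kd <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
          I = 4.5, K = -3.9, L = 3.8)
  expect_equal(bp$hydrophobicity[3], mean(kd), tolerance = 1e-12)
  expect_equal(bp$hydrophobicity[1], 1.8)

  # charge of free lysine at pH 7 under the EMBOSS-style pKa set, by hand:
  # +: N-term 1/(1+10^(7-8.6)) + K 1/(1+10^(7-10.8)); -: C-term 1/(1+10^(3.6-7))
  bk <- biophysical_properties("K")
  hand <- 1 / (1 + 10^(7 - 8.6)) + 1 / (1 + 10^(7 - 10.8)) - 1 / (1 + 10^(3.6 - 7))
  expect_equal(bk$net_charge, hand, tolerance = 1e-12)

  # the isoelectric point satisfies charge(pI) ~ 0
  withr::with_seed(7, peps <- random_peptides(50, 8))
  bps <- biophysical_properties(peps)
  for (i in seq_along(peps)) {
    aa <- strsplit(peps[i], "")[[1]]
    expect_lt(abs(cleavekit:::peptide_charge(aa, bps$isoelectric_point[i])), 1e-3)
  }
  # acidic peptides have low pI, basic high
  expect_lt(biophysical_properties("DDEEDDEE")$isoelectric_point, 5)
  expect_gt(biophysical_properties("KKRRKKRR")$isoelectric_point, 9)
  expect_error(biophysical_properties(""), "invalid|empty")
})

test_that("activity clustering recovers planted family structure", {
  # identical columns merge at distance zero
  withr::with_seed(8, {
    x <- rnorm(60)
    m <- cbind(A = x, B = x, C = rnorm(60))
  })
  cl <- activity_clustering(m, n_top = 20, k = 2)
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
  expect_equal(cl$groups[["A"]], cl$groups[["B"]])

  # two planted families in the simulator -> two clean groups
  panel <- build_panel(M = 6, L = 10, n_families = 2, seed = 9)
  lib <- suppressMessages(simulate_library(panel, n = 2000, motif_fraction = 0.3,
                                           seed = 10))
  cl2 <- activity_clustering(zscore_matrix(lib), n_top = 25, k = 2)
  expect_equal(length(unique(cl2$groups)), 2)
  agreement <- mclust::adjustedRandIndex(cl2$groups[panel$proteases],
                                         panel$family[panel$proteases])
  expect_equal(agreement, 1)
  expect_match(cl2$newick, "^\\(")

  # constant column is reported by name
  mm <- cbind(A = rnorm(30), B = rep(1, 30))
  expect_error(activity_clustering(mm, n_top = 10), "B")
})
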