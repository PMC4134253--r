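gt_df <- function(...) {
  # build a one-locus genotype table from two-letter strings ("AB", "AA")
  gs <- c(...)
  genotypes(data.frame(
    individual = sprintf("i%02d", seq_along(gs)), locus = "L1",
    allele1 = substr(gs, 1, 1), allele2 = substr(gs, 2, 2)))
}

test_that("allele frequencies count copies among genotyped individuals", {
  f <- allele_frequencies(gt_df("AB"))
  expect_equal(unname(f$L1[c("A", "B")]), c(0.5, 0.5))
  f2 <- allele_frequencies(gt_df("AA", "AB", "BB"))
  expect_equal(unname(f2$L1[c("A", "B")]), c(0.5, 0.5))
  # missing genotypes reduce the per-locus sample size
  g <- gt_df("AA", "AB")
  g$allele1[2] <- NA
  g$allele2[2] <- NA
  f3 <- allele_frequencies(g)
  expect_equal(unname(f3$L1["A"]), 1)
  expect_equal(unname(attr(f3, "n")["L1"]), 1L)
  expect_error(allele_frequencies(g[0, ]), "empty")
})

test_that("estimated frequencies recover the truth within sampling error", {
  freqs <- allele_freq_table(list(X = c(a = 0.6, b = 0.3, c = 0.1)))
  g <- synth_genotypes(freqs, 500, seed = 8)
  est <- allele_frequencies(g)$X
  for (al in names(freqs$X)) {
    se <- sqrt(freqs$X[[al]] * (1 - freqs$X[[al]]) / 1000) # 2n draws
    expect_lt(abs(est[[al]] - freqs$X[[al]]), 3 * se + 1e-9)
  }
})

test_that("observed and unbiased expected heterozygosity follow Nei", {
  h <- heterozygosity(gt_df("AA", "AA", "AA"))
  expect_equal(h$ho, 0)
  expect_equal(h$he, 0)
  expect_true(h$monomorphic)
  h2 <- heterozygosity(gt_df("AB", "AB"))
  expect_equal(h2$ho, 1)
  expect_equal(h2$he, (4 / 3) * 0.5) # 2n/(2n-1) * (1 - sum p^2), n = 2
  # k equifrequent alleles: he = 2n/(2n-1) * (1 - 1/k)
  g <- genotypes(data.frame(individual = sprintf("i%d", 1:2), locus = "L",
                            allele1 = c("A", "C"), allele2 = c("B", "D")))
  expect_equal(heterozygosity(g)$he, (4 / 3) * (1 - 1 / 4))
})

test_that("heterozygosity is invariant under allele relabeling", {
  set.seed(3)
  freqs <- freqs_from_target_he(c(0.3, 0.62))
  g <- synth_genotypes(freqs, 60, missing_rate = 0.2, seed = 4)
  h1 <- heterozygosity(g)
  relabel <- function(a) ifelse(is.na(a), NA, paste0("z", a))
  g2 <- g
  g2$allele1 <- relabel(g2$allele1)
  g2$allele2 <- relabel(g2$allele2)
  h2 <- heterozygosity(genotypes(g2))
  expect_equal(h1$ho, h2$ho)
  expect_equal(h1$he, h2$he)
  expect_true(all(h1$ho <= 1))
})

test_that("exact Hardy-Weinberg test matches brute-force enumeration", {
  expect_equal(as.numeric(hwe_exact_test(rep("A", 10), rep("A", 10))), 1.0)
  # all-homozygote biallelic table (3, 0, 3): hand-enumerated p = 20/924
  p <- hwe_exact_test(rep(c("A", "B"), c(3, 3)), rep(c("A", "B"), c(3, 3)))
  expect_equal(as.numeric(p), 20 / 924, tolerance = 1e-12)
  expect_equal(as.numeric(p), hwe_biallelic_oracle(3, 0, 3),
               tolerance = 1e-12)
  # assorted biallelic tables against the independent oracle
  for (tab in list(c(1, 8, 1), c(5, 2, 5), c(2, 6, 8), c(10, 1, 0))) {
    a1 <- rep(c("A", "A", "B"), tab)
    a2 <- rep(c("A", "B", "B"), tab)
    expect_equal(as.numeric(hwe_exact_test(a1, a2)),
                 hwe_biallelic_oracle(tab[1], tab[2], tab[3]),
                 tolerance = 1e-12)
  }
})

test_that("Monte-Carlo and enumeration paths agree within 3 MC SEs", {
  set.seed(12)
  for (i in 1:3) {
    a1 <- sample(c("A", "B", "C"), 25, TRUE, c(0.5, 0.3, 0.2))
    a2 <- sample(c("A", "B", "C"), 25, TRUE, c(0.5, 0.3, 0.2))
    pe <- as.numeric(hwe_exact_test(a1, a2, method = "enumeration",
                                    max_tables = 1e7))
    pm <- hwe_exact_test(a1, a2, method = "mc", nperm = 20000)
    expect_lt(abs(as.numeric(pm) - pe), 3 * attr(pm, "mc_se") + 1e-6)
  }
})

test_that("exact-test p-values are uniform under the null", {
  set.seed(21)
  ps <- replicate(400, {
    g <- matrix(sample(c("A", "B", "C"), 60, TRUE), ncol = 2)
    as.numeric(hwe_exact_test(g[, 1], g[, 2], method = "enumeration",
                              max_tables = 1e7))
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("haplotype diversity follows the unbiased gene-diversity formula", {
  seqs <- c(a = "ACGT", b = "ACGT", c = "AGGT", d = "AGGT")
  h <- haplotype_diversity(seqs)
  expect_equal(h$hd, (4 / 3) * (1 - 0.5)) # n = 4, two haplotypes 2/2
  expect_equal(h$n_haplotypes, 2L)
  same <- rep("ACGTACGT", 5)
  expect_equal(haplotype_diversity(same)$hd, 0)
  # construction-targeted recovery: exact haplotype frequencies
  m <- synth_sequences(c(0.6, 0.4), n = 10, length = 30,
                       divergence_positions = list(integer(0), c(3L, 9L)),
                       seed = 2)
  counts <- table(attr(m, "haplotype"))
  p <- as.numeric(counts) / 10
  expect_equal(haplotype_diversity(m)$hd, (10 / 9) * (1 - sum(p^2)),
               tolerance = 1e-12)
})

test_that("nucleotide diversity equals the all-pairs average", {
  expect_equal(nucleotide_diversity(rep("ACGTAC", 4))$pi, 0)
  two <- c(paste(rep("A", 100), collapse = ""),
           paste(c(rep("A", 99), "C"), collapse = ""))
  expect_equal(nucleotide_diversity(two)$pi, 0.01)
  # planted differences vs a brute-force oracle
  set.seed(6)
  m <- synth_sequences(c(0.4, 0.35, 0.25), n = 10, length = 60,
                       divergence_positions = list(integer(0), c(5L, 20L),
                                                   c(5L, 33L, 47L)),
                       seed = 6)
  oracle <- {
    tot <- 0
    for (i in 1:9) for (j in (i + 1):10)
      tot <- tot + mean(m[i, ] != m[j, ])
    tot / choose(10, 2)
  }
  expect_equal(nucleotide_diversity(m)$pi, oracle, tolerance = 1e-12)
})

test_that("sequence statistics ignore ordering and reject ragged input", {
  m <- synth_sequences(c(0.5, 0.5), n = 12, length = 40, seed = 9)
  shuffled <- m[sample(nrow(m)), ]
  expect_equal(sequence_stats(m)$pi, sequence_stats(shuffled)$pi)
  expect_equal(sequence_stats(m)$hd, sequence_stats(shuffled)$hd)
  expect_error(nucleotide_diversity(c("ACGT", "ACG")), "ragged")
  # gap-containing sequences are excluded from haplotype calling
  gappy <- rbind(m, matrix(c("A", "-", m[1, 3:40]), nrow = 1))
  expect_message(haplotype_diversity(gappy), "dropped")
})
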