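test_that("observed heterozygosity matches direct counting", {
  # all homozygotes / all heterozygotes
  hom <- array(1L, dim = c(5, 2, 2))
  expect_equal(unique(observed_heterozygosity(toy_table(hom, "p"))$Ho), 0)
  het <- array(c(rep(1L, 10), rep(2L, 10)), dim = c(5, 2, 2))
  expect_equal(unique(observed_heterozygosity(toy_table(het, "p"))$Ho), 1)

  tab <- random_table(n = 40, L = 3, n_alleles = 4, n_pops = 2,
                      missing_rate = 0.1, seed = 21)
  out <- observed_heterozygosity(tab)
  g <- tab$samples$population
  for (r in sample(nrow(out), 6)) {
    idx <- which(g == out$group[r])
    l <- match(out$locus[r], tab$loci)
    a1 <- tab$geno[idx, l, 1]; a2 <- tab$geno[idx, l, 2]
    ok <- !is.na(a1)
    expect_equal(out$Ho[r], sum(a1[ok] != a2[ok]) / sum(ok))
  }
})

test_that("expected heterozygosity follows Nei's unbiased formula", {
  # monomorphic -> 0
  mono <- array(1L, dim = c(4, 1, 2))
  expect_equal(expected_heterozygosity(toy_table(mono, "p"))$He, 0)
  # 2 individuals both A/B: He = (4/3) * 0.5
  ab <- array(c(1L, 1L, 2L, 2L), dim = c(2, 1, 2))
  expect_equal(expected_heterozygosity(toy_table(ab, "p"))$He, 2 / 3)
  # random table vs direct evaluation from tallied frequencies
  tab <- random_table(n = 35, L = 2, n_alleles = 5, n_pops = 2,
                      missing_rate = 0.12, seed = 8)
  out <- expected_heterozygosity(tab)
  g <- tab$samples$population
  for (r in seq_len(nrow(out))) {
    idx <- which(g == out$group[r])
    l <- match(out$locus[r], tab$loci)
    copies <- c(tab$geno[idx, l, 1], tab$geno[idx, l, 2])
    copies <- copies[!is.na(copies)]
    p <- as.numeric(table(copies)) / length(copies)
    ng <- length(copies)
    expect_equal(out$He[r], ng / (ng - 1) * (1 - sum(p^2)))
  }
})

test_that("rarefied richness equals exhaustive subsample enumeration", {
  # N = 6 gene copies with counts {3,2,1}, g = 4: enumerate all C(6,4) draws
  geno <- array(NA_integer_, dim = c(3, 1, 2))
  geno[1, 1, ] <- c(1L, 1L); geno[2, 1, ] <- c(1L, 2L); geno[3, 1, ] <- c(2L, 3L)
  tab <- toy_table(geno, "p")
  out <- allelic_richness(tab, g = 4)
  expect_equal(out$richness, richness_enumerate(c(3, 2, 1), 4))
  # further counts and sizes
  geno2 <- array(NA_integer_, dim = c(4, 1, 2))
  geno2[1, 1, ] <- c(1L, 1L); geno2[2, 1, ] <- c(1L, 1L)
  geno2[3, 1, ] <- c(2L, 3L); geno2[4, 1, ] <- c(3L, 4L)
  tab2 <- toy_table(geno2, "p")
  for (g_size in c(2, 3, 5, 8))
    expect_equal(allelic_richness(tab2, g = g_size)$richness,
                 richness_enumerate(c(4, 1, 2, 1), g_size))
})

test_that("richness boundary behaviour: monomorphic, g = N, monotone in g", {
  mono <- array(5L, dim = c(6, 1, 2))
  expect_equal(allelic_richness(toy_table(mono, "p"), g = 4)$richness, 1)
  tab <- random_table(n = 10, L = 2, n_alleles = 5, n_pops = 1,
                      missing_rate = 0, seed = 13)
  full <- allelic_richness(tab, g = 20)
  nall <- vapply(tab$alleles, length, 0L)
  expect_equal(full$richness, as.numeric(nall))
  vals <- vapply(2:20, function(gg) allelic_richness(tab, g = gg)$richness[1], 0)
  expect_true(all(diff(vals) >= -1e-12))
  expect_error(allelic_richness(tab, g = 1), "at least 2")
})

test_that("WC theta: fixed difference gives 1, duplicated population ~ 0", {
  geno <- array(NA_integer_, dim = c(20, 2, 2))
  geno[1:10, , ] <- 1L; geno[11:20, , ] <- 2L
  tab <- toy_table(geno, rep(c("A", "B"), each = 10))
  expect_equal(wc_fst(tab)$theta, 1)

  one <- random_table(n = 12, L = 3, n_alleles = 4, n_pops = 1,
                      missing_rate = 0, seed = 5)
  dup <- bind_genotype_tables(list(
    one, genotype_table(one$geno,
                        transform(one$samples, id = paste0(id, "b"),
                                  population = "B"))))
  expect_lt(wc_fst(dup)$theta, 1e-10)
})

test_that("WC theta equals an independent ANOVA transcription", {
  for (s in 1:4) {
    tab <- random_table(n = 36, L = 3, n_alleles = 4, n_pops = 3,
                        missing_rate = 0.1, seed = 100 + s)
    g <- tab$samples$population
    expect_equal(wc_fst(tab, g)$theta, wc_theta_anova(tab, g),
                 tolerance = 1e-12)
  }
})

test_that("FST permutation p-values sit on the grid and are reproducible", {
  geno <- array(NA_integer_, dim = c(16, 2, 2))
  geno[1:8, , ] <- 1L; geno[9:16, , ] <- 2L
  tab <- toy_table(geno, rep(c("A", "B"), each = 8))
  r <- fst_permutation_test(tab, n_perm = 99, seed = 4)
  expect_equal(r$p_value, 1 / 100)  # observed exceeds every permutation
  r2 <- fst_permutation_test(tab, n_perm = 99, seed = 4)
  expect_identical(r$p_value, r2$p_value)
  # grid property on an exchangeable table
  tab2 <- random_table(n = 20, L = 2, n_alleles = 3, n_pops = 2,
                       missing_rate = 0, seed = 31)
  p <- fst_permutation_test(tab2, n_perm = 19, seed = 9)$p_value
  expect_true(p %in% ((1:20) / 20))
})

test_that("permutation test is calibrated under the null", {
  # one population split at random: p should be ~uniform; check type-I
  # error at alpha = 0.05 over replicate datasets within binomial error
  n_rep <- 120
  rej <- 0
  for (s in seq_len(n_rep)) {
    tab <- random_table(n = 16, L = 2, n_alleles = 4, n_pops = 1,
                        missing_rate = 0, seed = 500 + s)
    set.seed(9000 + s)
    g <- sample(rep(c("X", "Y"), each = 8))
    p <- fst_permutation_test(tab, g, n_perm = 39, seed = s)$p_value
    if (p <= 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / n_rep - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 1 / 40)
})

test_that("morph percentage table reproduces the rounding convention", {
  rows <- data.frame(population = c("a", "b", "c", "d"),
                     N = c(4, 30, 33, 0),
                     count_androchrome = c(1, 30, 23, 0),
                     count_infuscans = c(1, 0, 9, 0),
                     count_obsoleta = c(2, 0, 1, 0))
  out <- morph_frequency_table(rows)
  expect_equal(out$pct_androchrome[1:3], c(25.0, 100.0, 69.7))
  expect_equal(out$pct_infuscans[1:3], c(25.0, 0.0, 27.3))
  expect_equal(out$pct_obsoleta[1:3], c(50.0, 0.0, 3.0))
  expect_true(out$flagged[4])
  expect_true(is.na(out$pct_androchrome[4]))
  expect_error(morph_frequency_table(transform(rows, count_infuscans = -1)),
               "non-negative")
})

test_that("He is invariant to allele relabeling", {
  tab <- random_table(n = 20, L = 1, n_alleles = 4, n_pops = 1,
                      missing_rate = 0, seed = 17)
  relab <- tab$geno
  relab[] <- c(40L, 10L, 30L, 20L)[relab]  # permute the 4 codes
  tab2 <- toy_table(relab, tab$samples$population)
  expect_equal(expected_heterozygosity(tab)$He,
               expected_heterozygosity(tab2)$He)
})

test_that("Ho tracks He under Hardy-Weinberg sampling", {
  anc <- list(L1 = stats::setNames(rep(0.2, 5), 1:5))
  tab <- simulate_genotypes(anc, n = 4000, seed = 3)
  ho <- attr(observed_heterozygosity(tab), "group_means")
  he <- attr(expected_heterozygosity(tab), "group_means")
  expect_equal(unname(ho), unname(he), tolerance = 0.03)
})

test_that("diversity_table assembles the survey-table shape", {
  sc <- survey_shape_scenario(seed = 2)
  g <- ifelse(sc$genotypes$samples$region == "Spain", "Spain",
              ifelse(sc$genotypes$samples$species == "graellsii",
                     "Iberia-Africa", "Europe"))
  dt <- diversity_table(sc$genotypes, g)
  expect_equal(sort(dt$N), sort(c(220L, 166L, 56L)))
  expect_true(all(dt$Ho >= 0 & dt$Ho <= 1))
  expect_true(all(dt$He >= 0 & dt$He <= 1))
  expect_true(all(dt$richness <= dt$alleles))
})
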