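test_that("structure files round-trip in both dialects", {
  tab <- random_table(n = 12, L = 4, n_alleles = 5, n_pops = 3,
                      missing_rate = 0.15, seed = 7)
  for (one_row in c(TRUE, FALSE)) {
    f <- withr::local_tempfile(fileext = ".str")
    write_structure_file(tab, f, one_row_per_individual = one_row)
    back <- read_structure_file(f, one_row_per_individual = one_row,
                                locus_names = tab$loci)
    expect_identical(back$geno, tab$geno)
    expect_identical(back$samples$id, tab$samples$id)
    expect_identical(back$samples$population, tab$samples$population)
    expect_identical(back$samples$is_reference, tab$samples$is_reference)
    expect_identical(back$alleles, tab$alleles)
  }
})

test_that("smallest two-row structure file parses", {
  f <- withr::local_tempfile(fileext = ".str")
  writeLines(c("ind1 p1 0 120", "ind1 p1 0 122",
               "ind2 p1 0 122", "ind2 p1 0 120"), f)
  tab <- read_structure_file(f, one_row_per_individual = FALSE)
  expect_equal(n_samples(tab), 2)
  expect_equal(n_loci(tab), 1)
  expect_equal(tab$alleles[[1]], c(120L, 122L))
})

test_that("missing-code pairs are stored as missing loci", {
  f <- withr::local_tempfile(fileext = ".str")
  writeLines(c("a p1 0 -9 -9 101 101", "b p1 0 100 102 101 103"), f)
  tab <- read_structure_file(f)
  expect_true(all(is.na(tab$geno[1, 1, ])))
  expect_false(anyNA(tab$geno[2, , ]))
  expect_false(-9L %in% unlist(tab$alleles))
})

test_that("malformed structure input is rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".str")
  writeLines(c("a p1 0 1 2", "b p1 0 1 2 3"), f)
  expect_error(read_structure_file(f), "ragged")
  writeLines(c("a p1 0 1 2 3", "b p1 0 1 2 4"), f)
  expect_error(read_structure_file(f), "even number")
  writeLines(c("a p1 0 1 2", "a p1 0 1 2"), f)
  expect_error(read_structure_file(f), "duplicate")
  # half-missing genotype rejected, not coerced
  writeLines(c("a p1 0 -9 4"), f)
  expect_error(read_structure_file(f), "half-missing")
})

test_that("survey-shaped dataset parses with N = 442, 26 pops, 6 loci", {
  sc <- survey_shape_scenario(seed = 5)
  f <- withr::local_tempfile(fileext = ".str")
  write_structure_file(sc$genotypes, f)
  tab <- read_structure_file(f)
  expect_equal(n_samples(tab), 442)
  expect_equal(length(unique(tab$samples$population)), 26)
  expect_equal(n_loci(tab), 6)
})

test_that("genepop parsing handles pops, homozygotes and missing codes", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy file", "locA", "locB", "Pop",
               "id1 , 0101 0202",
               "id2 , 0102 0000",
               "Pop",
               "id3 , 0101 0102"), f)
  tab <- read_genepop_file(f)
  expect_equal(n_loci(tab), 2)
  expect_equal(unname(tab$geno[1, , 1]), c(1L, 2L))
  expect_equal(unname(tab$geno[1, , 2]), c(1L, 2L))
  expect_true(all(is.na(tab$geno[2, 2, ])))
  expect_equal(unique(tab$samples$population), c("id1", "id3"))
  expect_equal(as.integer(table(tab$samples$population)[c("id1", "id3")]),
               c(2L, 1L))
})

test_that("genepop rejects mixed encodings within a locus", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("t", "locA", "Pop", "a , 0101", "b , 001001"), f)
  expect_error(read_genepop_file(f), "mixed 2/3-digit")
})

test_that("genepop write-read cycle is the identity on genotypes", {
  tab <- random_table(n = 15, L = 3, n_alleles = 6, n_pops = 2,
                      missing_rate = 0.2, seed = 3)
  f <- withr::local_tempfile(fileext = ".gen")
  write_genepop_file(tab, f)
  back <- read_genepop_file(f)
  # the writer groups samples by population; match rows by id
  m <- match(tab$samples$id, back$samples$id)
  expect_false(anyNA(m))
  expect_equal(unname(back$geno[m, , , drop = FALSE]), unname(tab$geno))
})

test_that("allele frequencies match a brute-force tally", {
  tab <- random_table(n = 30, L = 3, n_alleles = 5, n_pops = 3,
                      missing_rate = 0.1, seed = 11)
  af <- allele_frequencies(tab)
  g <- tab$samples$population
  for (p in unique(g)) {
    for (l in seq_len(n_loci(tab))) {
      copies <- c(tab$geno[g == p, l, 1], tab$geno[g == p, l, 2])
      copies <- copies[!is.na(copies)]
      expect_equal(af$gene_counts[p, l], length(copies))
      for (a in tab$alleles[[l]]) {
        expect_equal(af$freq[[p]][[l]][[as.character(a)]],
                     sum(copies == a) / length(copies))
      }
      expect_equal(sum(af$freq[[p]][[l]]), 1)
    }
  }
  # gene counts = 2 x non-missing genotypes
  for (l in seq_len(n_loci(tab)))
    expect_equal(sum(af$gene_counts[, l]),
                 2 * sum(!is.na(tab$geno[, l, 1])))
})

test_that("single heterozygote and fixed groups give 0.5/0.5 and 1.0", {
  geno <- array(c(1L, 2L, 2L, 1L, 2L, 2L), dim = c(3, 1, 2))
  geno[1, 1, ] <- c(1L, 2L); geno[2, 1, ] <- c(2L, 2L); geno[3, 1, ] <- c(2L, 2L)
  tab <- toy_table(geno, c("het", "fix", "fix"))
  af <- allele_frequencies(tab)
  expect_equal(unname(af$freq[["het"]][[1]]), c(0.5, 0.5))
  expect_equal(unname(af$freq[["fix"]][[1]]), c(0, 1))
  expect_error(allele_frequencies(tab, groups = "nosuch"), "unknown group")
})

test_that("sample metadata CSV attaches species and region", {
  tab <- random_table(n = 4, L = 2, seed = 2, missing_rate = 0)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = c("s1", "s3"), species = "graellsii",
                       region = "Iberia-Africa", is_reference = TRUE), f,
            row.names = FALSE)
  tab2 <- read_sample_metadata(tab, f)
  expect_equal(tab2$samples$species[c(1, 3)], rep("graellsii", 2))
  expect_equal(tab2$samples$species[2], "unknown")
  expect_true(all(tab2$samples$is_reference[c(1, 3)]))
})
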