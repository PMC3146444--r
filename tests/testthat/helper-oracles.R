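# Shared fixtures and independent oracles used across test files.

# quick genotype_table from an n x L x 2 array and population labels
toy_table <- function(geno, pops, species = "unknown", ref = FALSE) {
  n <- dim(geno)[1]
  genotype_table(geno, data.frame(id = paste0("s", seq_len(n)),
                                  population = pops, species = species,
                                  is_reference = ref,
                                  stringsAsFactors = FALSE))
}

# random genotype table with optional whole-locus missingness
random_table <- function(n = 25, L = 3, n_alleles = 4, n_pops = 2,
                         missing_rate = 0.1, seed = 1) {
  set.seed(seed)
  geno <- array(sample.int(n_alleles, n * L * 2, TRUE), dim = c(n, L, 2))
  for (i in seq_len(n)) for (l in seq_len(L))
    if (stats::runif(1) < missing_rate) geno[i, l, ] <- NA_integer_
  pops <- sample(LETTERS[seq_len(n_pops)], n, TRUE)
  # make sure every population occurs
  pops[seq_len(n_pops)] <- LETTERS[seq_len(n_pops)]
  toy_table(geno, pops)
}

# independent Weir-Cockerham theta: nested ANOVA sums of squares over
# gene-copy indicator variables (a different derivation route from the
# closed-form variance components used in the package)
wc_theta_anova <- function(tab, g) {
  g <- as.character(g)
  labs <- unique(g)
  num <- den <- 0
  for (l in seq_len(n_loci(tab))) {
    reg <- tab$alleles[[l]]
    if (length(reg) < 2) next
    for (u in reg) {
      x <- list(); het <- list()
      for (p in labs) {
        idx <- which(g == p)
        a1 <- tab$geno[idx, l, 1]; a2 <- tab$geno[idx, l, 2]
        ok <- !is.na(a1); a1 <- a1[ok]; a2 <- a2[ok]
        x[[p]] <- ((a1 == u) + (a2 == u)) / 2
        het[[p]] <- (a1 == u) + (a2 == u) == 1
      }
      n_i <- vapply(x, length, 0L)
      keep <- n_i > 0
      x <- x[keep]; het <- het[keep]; n_i <- n_i[keep]
      r <- length(n_i); N <- sum(n_i)
      if (r < 2) next
      p_i <- vapply(x, mean, 0)
      pbar <- sum(n_i * p_i) / N
      SS1 <- 2 * sum(n_i * (p_i - pbar)^2)
      SS2 <- 2 * sum(unlist(mapply(function(xx, pp) (xx - pp)^2, x, p_i,
                                   SIMPLIFY = FALSE)))
      SS3 <- 0.5 * sum(unlist(het))
      MS1 <- SS1 / (r - 1); MS2 <- SS2 / (N - r); MS3 <- SS3 / N
      nc <- (N - sum(n_i^2) / N) / (r - 1)
      sa <- (MS1 - MS2) / (2 * nc)
      sb <- (MS2 - MS3) / 2
      sc <- MS3
      num <- num + sa; den <- den + sa + sb + sc
    }
  }
  num / den
}

# exhaustive rarefaction: mean number of distinct alleles over every
# possible subsample of g gene copies
richness_enumerate <- function(allele_counts, g) {
  pool <- rep(seq_along(allele_counts), allele_counts)
  combos <- utils::combn(length(pool), g)
  mean(apply(combos, 2, function(ix) length(unique(pool[ix]))))
}

# direct pairwise nucleotide diversity on a sequence character matrix
pi_pairwise <- function(m) {
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(m[i, ] != m[j, ])
  tot / choose(n, 2) / ncol(m)
}

# small balding-nichols two-parent scenario shared by admixture tests
bn_parents <- function(seed = 42, theta = 0.2, n_loci = 6, n_alleles = 10) {
  anc <- lapply(seq_len(n_loci), function(l) {
    p <- rep(1 / n_alleles, n_alleles)
    names(p) <- 100 + 2 * seq_len(n_alleles)
    p
  })
  names(anc) <- paste0("L", seq_len(n_loci))
  balding_nichols_freqs(anc, theta = theta, n_pops = 2, seed = seed)
}
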