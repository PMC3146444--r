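#' Observed heterozygosity per group and locus
#'
#' Ho at a locus is the fraction of non-missing genotypes that are
#' heterozygous; the group-level value is the unweighted mean over loci
#' with data.  Loci with no data in a group are reported as `NA`.
#'
#' @inheritParams allele_frequencies
#' @return a data frame with columns `group`, `locus`, `n`, `Ho`, plus a
#'   `"group_means"` attribute (named vector of per-group means).
#' @export
observed_heterozygosity <- function(table, grouping = "population") {
  g <- resolve_grouping(table, grouping)
  out <- expand.grid(group = unique(g), locus = table$loci,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$Ho <- NA_real_
  for (r in seq_len(nrow(out))) {
    idx <- which(g == out$group[r])
    l <- match(out$locus[r], table$loci)
    a1 <- table$geno[idx, l, 1]; a2 <- table$geno[idx, l, 2]
    ok <- !is.na(a1)
    out$n[r] <- sum(ok)
    out$Ho[r] <- if (any(ok)) mean(a1[ok] != a2[ok]) else NA_real_
  }
  means <- tapply(out$Ho, out$group, mean, na.rm = TRUE)
  attr(out, "group_means") <- means[unique(g)]
  out
}

#' Expected heterozygosity (Nei's unbiased gene diversity) per group and locus
#'
#' `He = (2n / (2n - 1)) * (1 - sum(p^2))` with `n` the number of
#' non-missing diploid genotypes and `p` the allele frequencies.
#'
#' @inheritParams allele_frequencies
#' @return a data frame with columns `group`, `locus`, `n`, `He`, plus a
#'   `"group_means"` attribute.
#' @export
expected_heterozygosity <- function(table, grouping = "population") {
  g <- resolve_grouping(table, grouping)
  af <- allele_frequencies(table, g)
  out <- expand.grid(group = unique(g), locus = table$loci,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$He <- NA_real_
  for (r in seq_len(nrow(out))) {
    p <- af$freq[[out$group[r]]][[out$locus[r]]]
    ng <- af$gene_counts[out$group[r], out$locus[r]]
    out$n[r] <- ng %/% 2L
    if (ng >= 2L)
      out$He[r] <- (ng / (ng - 1)) * (1 - sum(p^2))
  }
  means <- tapply(out$He, out$group, mean, na.rm = TRUE)
  attr(out, "group_means") <- means[unique(g)]
  out
}

#' Rarefied allelic richness per group and locus
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies: `sum_i [1 - choose(N - N_i, g) / choose(N, g)]` where `N` is the
#' group's non-missing gene count at the locus and `N_i` the count of
#' allele `i`.  With `g = N` this equals the observed allele count.
#'
#' @inheritParams allele_frequencies
#' @param g rarefaction size in gene copies; defaults to the minimum
#'   non-missing gene count over all groups and loci (the usual convention
#'   when comparing groups).
#' @return data frame with columns `group`, `locus`, `n_genes`, `richness`,
#'   plus `"group_means"` and `"g"` attributes.
#' @export
allelic_richness <- function(table, grouping = "population", g = NULL) {
  gr <- resolve_grouping(table, grouping)
  af <- allele_frequencies(table, gr)
  if (is.null(g)) g <- min(af$gene_counts)
  g <- as.integer(g)
  if (g < 2L) stop("rarefaction size 'g' must be at least 2")
  if (g > min(af$gene_counts))
    stop("'g' exceeds the smallest non-missing gene count (", min(af$gene_counts), ")")
  out <- expand.grid(group = unique(gr), locus = table$loci,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_genes <- NA_integer_; out$richness <- NA_real_
  for (r in seq_len(nrow(out))) {
    p <- af$freq[[out$group[r]]][[out$locus[r]]]
    N <- af$gene_counts[out$group[r], out$locus[r]]
    cnt <- round(p * N)
    cnt <- cnt[cnt > 0]
    out$n_genes[r] <- N
    # lchoose for numerical stability at large N
    out$richness[r] <- sum(1 - exp(lchoose(N - cnt, g) - lchoose(N, g)))
  }
  means <- tapply(out$richness, out$group, mean, na.rm = TRUE)
  attr(out, "group_means") <- means[unique(gr)]
  attr(out, "g") <- g
  out
}

# Weir & Cockerham (1984) variance components per allele.
# Returns c(a, b, c) summed over alleles of one locus; NA if undefined.
wc_components_locus <- function(dose, het, n_i) {
  # dose: r x A matrix of allele copies per population, het: r x A matrix of
  # heterozygote counts involving each allele, n_i: genotypes per population
  keep <- n_i > 0
  dose <- dose[keep, , drop = FALSE]
  het <- het[keep, , drop = FALSE]
  n_i <- n_i[keep]
  r <- length(n_i)
  if (r < 2L) return(c(0, 0, 0))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  a <- b <- cc <- 0
  A <- ncol(dose)
  for (u in seq_len(A)) {
    p_i <- dose[, u] / (2 * n_i)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(het[, u]) / (r * nbar)
    a <- a + (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- b + (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- cc + hbar / 2
  }
  c(a, b, cc)
}

#' Weir-Cockerham FST (theta)
#'
#' Multilocus theta is the ratio of the summed among-group variance
#' component to the summed total, over alleles and loci (ratio of sums, as
#' is standard).  Loci monomorphic across all groups contribute nothing.
#'
#' @inheritParams allele_frequencies
#' @return an object of class `fst_result`: list with `theta`,
#'   `per_locus_theta`, `p_value` (`NA` here; see
#'   [fst_permutation_test()]), `n_permutations`.
#' @export
wc_fst <- function(table, grouping = "population") {
  g <- resolve_grouping(table, grouping)
  labs <- unique(g)
  if (length(labs) < 2L) stop("need at least 2 groups for FST")
  L <- n_loci(table)
  per_locus <- rep(NA_real_, L)
  names(per_locus) <- table$loci
  tot_a <- tot_abc <- 0
  for (l in seq_len(L)) {
    reg <- table$alleles[[l]]
    A <- length(reg)
    if (A < 2L) next
    dose <- matrix(0, nrow = length(labs), ncol = A)
    het <- matrix(0, nrow = length(labs), ncol = A)
    n_i <- numeric(length(labs))
    for (j in seq_along(labs)) {
      idx <- which(g == labs[j])
      a1 <- table$geno[idx, l, 1]; a2 <- table$geno[idx, l, 2]
      ok <- !is.na(a1)
      a1 <- a1[ok]; a2 <- a2[ok]
      n_i[j] <- length(a1)
      m1 <- match(a1, reg); m2 <- match(a2, reg)
      dose[j, ] <- tabulate(m1, A) + tabulate(m2, A)
      is_het <- m1 != m2
      het[j, ] <- tabulate(m1[is_het], A) + tabulate(m2[is_het], A)
    }
    comp <- wc_components_locus(dose, het, n_i)
    denom <- sum(comp)
    if (is.finite(denom) && denom != 0) per_locus[l] <- comp[1] / denom
    tot_a <- tot_a + comp[1]
    tot_abc <- tot_abc + denom
  }
  theta <- if (tot_abc != 0) tot_a / tot_abc else NA_real_
  structure(list(theta = theta, per_locus_theta = per_locus,
                 p_value = NA_real_, n_permutations = 0L),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("Weir-Cockerham theta =", signif(x$theta, 4))
  if (x$n_permutations > 0)
    cat("  (P =", signif(x$p_value, 4), "from", x$n_permutations, "permutations)")
  cat("\n")
  invisible(x)
}

#' Permutation test for Weir-Cockerham theta
#'
#' Whole multilocus genotypes are permuted among groups (preserving
#' within-individual associations) and theta recomputed each time;
#' `p = (1 + #\{theta_perm >= theta_obs\}) / (n_perm + 1)`.
#'
#' @inheritParams allele_frequencies
#' @param n_perm number of permutations (>= 1)
#' @param seed integer seed for reproducibility
#' @return an `fst_result` with `p_value` and `n_permutations` filled in.
#' @export
fst_permutation_test <- function(table, grouping = "population",
                                 n_perm = 999L, seed = 1L) {
  g <- resolve_grouping(table, grouping)
  if (length(unique(g)) < 2L) stop("need at least 2 groups to permute")
  if (n_perm < 1L) stop("'n_perm' must be >= 1")
  obs <- wc_fst(table, g)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(g)
    th <- wc_fst(table, perm)$theta
    if (!is.na(th) && th >= obs$theta) exceed <- exceed + 1L
  }
  obs$p_value <- (1 + exceed) / (n_perm + 1)
  obs$n_permutations <- as.integer(n_perm)
  obs
}

#' Female colour-morph frequency table
#'
#' Adds per-row percentages (one decimal) of the androchrome and the two
#' gynochrome morphs to a table of raw counts.
#'
#' @param counts data frame with columns `population`, `N`,
#'   `count_androchrome`, `count_infuscans`, `count_obsoleta` (additional
#'   columns such as `species` and `date` pass through).
#' @return the input with `pct_androchrome`, `pct_infuscans`,
#'   `pct_obsoleta` and a logical `flagged` column (`TRUE` where `N = 0`
#'   or counts disagree with `N`; percentages are `NA` there).
#' @export
morph_frequency_table <- function(counts) {
  need <- c("population", "N", "count_androchrome", "count_infuscans",
            "count_obsoleta")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  cnt <- counts[, c("count_androchrome", "count_infuscans", "count_obsoleta")]
  if (any(cnt < 0)) stop("morph counts must be non-negative")
  counts$flagged <- counts$N == 0 | rowSums(cnt) != counts$N
  pct <- function(x) ifelse(counts$flagged, NA_real_, round(100 * x / counts$N, 1))
  counts$pct_androchrome <- pct(counts$count_androchrome)
  counts$pct_infuscans <- pct(counts$count_infuscans)
  counts$pct_obsoleta <- pct(counts$count_obsoleta)
  counts
}

#' Table of per-group diversity summaries
#'
#' Convenience wrapper combining sample size, Ho, He, allele counts and
#' rarefied richness into one row per group (the usual survey-table shape).
#'
#' @inheritParams allelic_richness
#' @return data frame with columns `group`, `N`, `Ho`, `He`, `alleles`,
#'   `richness`.
#' @export
diversity_table <- function(table, grouping = "population", g = NULL) {
  gr <- resolve_grouping(table, grouping)
  labs <- unique(gr)
  ho <- attr(observed_heterozygosity(table, gr), "group_means")
  he <- attr(expected_heterozygosity(table, gr), "group_means")
  ar <- attr(allelic_richness(table, gr, g = g), "group_means")
  af <- allele_frequencies(table, gr)
  nall <- vapply(labs, function(p)
    sum(vapply(af$freq[[p]], function(f) sum(f > 0), 0L)), 0L)
  data.frame(group = labs,
             N = as.integer(table(gr)[labs]),
             Ho = as.numeric(ho[labs]),
             He = as.numeric(he[labs]),
             alleles = as.integer(nall),
             richness = as.numeric(ar[labs]),
             stringsAsFactors = FALSE)
}
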