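#' Population-by-allele frequency matrix
#'
#' One row per population; one column per (locus, allele) pair over the
#' full registry, so the column count equals the total number of distinct
#' alleles in the table.  Within each locus block the row entries sum to 1.
#'
#' @inheritParams allele_frequencies
#' @return numeric matrix with a `"gene_counts"` attribute (population x
#'   locus) and a `"locus"` attribute mapping columns to loci.
#' @export
population_frequency_matrix <- function(table, grouping = "population") {
  g <- resolve_grouping(table, grouping)
  labs <- unique(g)
  if (length(labs) < 2L) stop("need at least 2 populations")
  af <- allele_frequencies(table, g)
  bad <- which(af$gene_counts == 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("population(s) with an all-missing locus: ",
         paste(unique(rownames(af$gene_counts)[bad[, 1]]), collapse = ", "))
  cols <- unlist(lapply(table$loci, function(l)
    paste(l, table$alleles[[l]], sep = ".")))
  X <- matrix(0, nrow = length(labs), ncol = length(cols),
              dimnames = list(labs, cols))
  for (p in labs)
    X[p, ] <- unlist(af$freq[[p]])
  attr(X, "gene_counts") <- af$gene_counts
  attr(X, "locus") <- rep(table$loci, lengths(table$alleles))
  X
}

#' PCA of population allele frequencies
#'
#' Eigendecomposition of the weighted covariance of the centred frequency
#' matrix, with populations weighted by their mean gene counts.  The axis
#' "inertia fractions" are eigenvalues over total inertia, and each axis is
#' assigned a share of the global multilocus Weir-Cockerham theta
#' proportional to its inertia (a reporting convention, not an estimator).
#' Axis signs are fixed by making the largest-magnitude loading positive.
#'
#' @param freq_matrix matrix from [population_frequency_matrix()]
#' @param population_weights positive weights (defaults to the mean gene
#'   count per population from the matrix attributes, or equal weights)
#' @param global_theta optional global multilocus theta used for the
#'   per-axis FST apportionment
#' @param n_axes number of axes to retain (default all with positive
#'   eigenvalue, at most `n_pops - 1`; a larger request is truncated with a
#'   warning)
#' @return an object of class `pca_result`: list with `scores`,
#'   `loadings`, `eigenvalues`, `axis_inertia_fraction`, `axis_fst`,
#'   `axis_p_values` (`NA` until [pca_randomization_test()]),
#'   `n_randomizations`.
#' @export
pca_of_populations <- function(freq_matrix, population_weights = NULL,
                               global_theta = NA_real_, n_axes = NULL) {
  X <- unclass(freq_matrix)
  r <- nrow(X)
  if (r < 2L) stop("need at least 2 populations")
  if (is.null(population_weights)) {
    gc <- attr(freq_matrix, "gene_counts")
    population_weights <- if (!is.null(gc)) rowMeans(gc) else rep(1, r)
  }
  w <- population_weights
  if (any(w <= 0)) stop("population weights must be positive")
  w <- w / sum(w)
  mu <- colSums(X * w)
  Xc <- sweep(X, 2, mu)
  # weighted covariance of populations
  C <- crossprod(Xc * sqrt(w))
  e <- eigen(C, symmetric = TRUE)
  pos <- which(e$values > max(e$values[1], 0) * 1e-12 & e$values > 1e-15)
  max_axes <- min(length(pos), r - 1L)
  if (is.null(n_axes)) n_axes <- max_axes
  if (n_axes > max_axes) {
    warning("only ", max_axes, " axes available; truncating")
    n_axes <- max_axes
  }
  total <- sum(pmax(e$values, 0))
  if (n_axes == 0L || total <= 0) {
    return(structure(list(scores = matrix(0, r, 0, dimnames = list(rownames(X), NULL)),
                          loadings = matrix(0, ncol(X), 0),
                          eigenvalues = numeric(0),
                          axis_inertia_fraction = numeric(0),
                          axis_fst = numeric(0),
                          axis_p_values = numeric(0),
                          n_randomizations = 0L),
                     class = "pca_result"))
  }
  V <- e$values[seq_len(n_axes)]
  U <- e$vectors[, seq_len(n_axes), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(n_axes)) {
    k <- which.max(abs(U[, j]))
    if (U[k, j] < 0) U[, j] <- -U[, j]
  }
  scores <- Xc %*% U
  colnames(scores) <- colnames(U) <- paste0("PC", seq_len(n_axes))
  frac <- V / total
  structure(list(scores = scores, loadings = U, eigenvalues = V,
                 axis_inertia_fraction = frac,
                 axis_fst = global_theta * frac,
                 axis_p_values = rep(NA_real_, n_axes),
                 n_randomizations = 0L),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- length(x$eigenvalues)
  cat("population PCA:", k, "axes\n")
  if (k > 0) {
    df <- data.frame(axis = paste0("PC", seq_len(k)),
                     pct_inertia = round(100 * x$axis_inertia_fraction, 1),
                     axis_fst = signif(x$axis_fst, 3),
                     p = signif(x$axis_p_values, 3))
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Randomization significance for the PCA axes
#'
#' Individuals are permuted among populations, the population frequency
#' matrix rebuilt and the leading eigenvalues recomputed; per-axis
#' `p = (1 + #\{lambda_perm >= lambda_obs\}) / (n_rand + 1)`.
#'
#' @inheritParams allele_frequencies
#' @param n_rand number of randomizations (default 5000)
#' @param n_axes number of leading axes to test (default 4)
#' @param seed integer seed
#' @return a `pca_result` (computed on the observed data, with
#'   `global_theta` from [wc_fst()]) whose `axis_p_values` are filled in.
#' @export
pca_randomization_test <- function(table, grouping = "population",
                                   n_rand = 5000L, n_axes = 4L, seed = 1L) {
  if (n_rand < 1L) stop("'n_rand' must be >= 1")
  g <- resolve_grouping(table, grouping)
  if (length(unique(g)) < 2L) stop("need at least 2 populations to permute")
  theta <- wc_fst(table, g)$theta
  X <- population_frequency_matrix(table, g)
  obs <- pca_of_populations(X, global_theta = theta)
  k <- min(n_axes, length(obs$eigenvalues))
  if (k == 0L) return(obs)
  lam_obs <- obs$eigenvalues[seq_len(k)]
  exceed <- integer(k)
  set.seed(seed)
  for (b in seq_len(n_rand)) {
    perm <- sample(g)
    Xp <- population_frequency_matrix(table, perm)
    ep <- pca_of_populations(Xp)
    lam <- c(ep$eigenvalues, rep(0, k))[seq_len(k)]
    exceed <- exceed + (lam >= lam_obs)
  }
  obs$axis_p_values[seq_len(k)] <- (1 + exceed) / (n_rand + 1)
  obs$n_randomizations <- as.integer(n_rand)
  obs
}
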