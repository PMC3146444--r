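#' Diploid codominant genotype tables
#'
#' A `genotype_table` holds multilocus diploid genotypes (integer allele
#' codes, e.g. microsatellite fragment sizes) together with per-sample
#' grouping metadata.  Genotypes live in an `n x L x 2` integer array with
#' `NA` for missing data; a locus is either fully typed or fully missing in
#' a sample (half-missing genotypes are rejected).  The allele registry of
#' each locus is the sorted set of codes observed anywhere in the table.
#'
#' @param geno integer array of dimension `c(n, L, 2)`; `dimnames[[2]]`
#'   supplies locus names (defaults to `L1..`).  `NA` marks missing data.
#' @param samples data frame with columns `id`, `population` and optionally
#'   `species` (`"elegans"`, `"graellsii"` or `"unknown"`), `region`,
#'   `is_reference`.  Missing optional columns are filled with defaults.
#' @param missing_code integer code representing missing data in
#'   STRUCTURE-format files (default `-9`).
#' @return an object of class `genotype_table` with elements `geno`,
#'   `samples`, `loci` (names), `alleles` (registry list) and
#'   `missing_code`.
#' @export
genotype_table <- function(geno, samples, missing_code = -9L) {
  if (length(dim(geno)) != 3L || dim(geno)[3] != 2L)
    stop("'geno' must be an n x L x 2 array")
  n <- dim(geno)[1]
  L <- dim(geno)[2]
  storage.mode(geno) <- "integer"
  if (!is.data.frame(samples) || nrow(samples) != n)
    stop("'samples' must be a data frame with one row per individual")
  if (is.null(samples$id)) stop("'samples' must have an 'id' column")
  samples$id <- as.character(samples$id)
  if (anyDuplicated(samples$id))
    stop("duplicate sample ids: ",
         paste(unique(samples$id[duplicated(samples$id)]), collapse = ", "))
  if (is.null(samples$population)) stop("'samples' must have a 'population' column")
  samples$population <- as.character(samples$population)
  if (any(is.na(samples$population) | samples$population == ""))
    stop("population labels must be non-empty")
  if (is.null(samples$species)) samples$species <- "unknown"
  samples$species <- as.character(samples$species)
  bad <- setdiff(unique(samples$species), c("elegans", "graellsii", "unknown"))
  if (length(bad) > 0)
    stop("unknown species labels: ", paste(bad, collapse = ", "))
  if (is.null(samples$region)) samples$region <- NA_character_
  if (is.null(samples$is_reference)) samples$is_reference <- FALSE
  samples$is_reference <- as.logical(samples$is_reference)
  rownames(samples) <- NULL

  loci <- dimnames(geno)[[2]]
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  dimnames(geno) <- list(samples$id, loci, NULL)

  # missing code in the array is normalised to NA
  geno[geno == as.integer(missing_code)] <- NA_integer_
  half <- is.na(geno[, , 1, drop = FALSE]) != is.na(geno[, , 2, drop = FALSE])
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)
    stop("half-missing genotype for sample '", samples$id[w[1, 1]],
         "' at locus '", loci[w[1, 2]], "'")
  }
  alleles <- lapply(seq_len(L), function(l) sort(unique(as.vector(geno[, l, ]))))
  names(alleles) <- loci

  structure(list(geno = geno, samples = samples, loci = loci,
                 alleles = alleles, missing_code = as.integer(missing_code)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", n_samples(x), "individuals,", n_loci(x), "loci,",
      sum(lengths(x$alleles)), "alleles,",
      length(unique(x$samples$population)), "populations\n")
  invisible(x)
}

#' @rdname genotype_table
#' @param x a `genotype_table`
#' @export
n_samples <- function(x) unname(dim(x$geno)[1])

#' @rdname genotype_table
#' @export
n_loci <- function(x) unname(dim(x$geno)[2])

# sample() guarded against the length-1 x gotcha
sample_codes <- function(codes, n, prob = NULL) {
  codes[sample.int(length(codes), n, replace = TRUE, prob = prob)]
}

#' Combine genotype tables sharing the same loci
#'
#' @param ... `genotype_table` objects with identical locus names.
#' @return a single `genotype_table`.
#' @export
bind_genotype_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) &&
      !inherits(tabs[[1]], "genotype_table")) tabs <- tabs[[1]]
  loci <- tabs[[1]]$loci
  for (t in tabs) if (!identical(t$loci, loci)) stop("locus mismatch")
  geno <- do.call(abind3, lapply(tabs, function(t) t$geno))
  samples <- do.call(rbind, lapply(tabs, function(t) t$samples))
  dimnames(geno)[[2]] <- loci
  genotype_table(geno, samples, missing_code = tabs[[1]]$missing_code)
}

# rbind for n x L x 2 arrays along the first margin
abind3 <- function(...) {
  parts <- list(...)
  L <- dim(parts[[1]])[2]
  out <- array(NA_integer_, dim = c(sum(vapply(parts, function(p) dim(p)[1], 0L)), L, 2L))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Subset a genotype table by sample index or logical mask
#'
#' @param x a `genotype_table`
#' @param i integer or logical index over samples
#' @return a `genotype_table` with the selected samples.
#' @export
subset_samples <- function(x, i) {
  genotype_table(x$geno[i, , , drop = FALSE], x$samples[i, , drop = FALSE],
                 missing_code = x$missing_code)
}

resolve_grouping <- function(table, grouping) {
  if (is.null(grouping)) grouping <- "population"
  if (length(grouping) == 1L && is.character(grouping) &&
      grouping %in% names(table$samples)) {
    g <- table$samples[[grouping]]
  } else {
    if (length(grouping) != n_samples(table))
      stop("'grouping' must name a sample column or give one label per sample")
    g <- as.character(grouping)
  }
  as.character(g)
}

#' Per-group, per-locus allele frequencies
#'
#' Frequencies are tallied over non-missing gene copies; within each group
#' the frequencies at a locus sum to 1 (empty if the locus is entirely
#' missing in the group).  This is the shared kernel for the diversity,
#' differentiation and PCA computations.
#'
#' @param table a [genotype_table()]
#' @param grouping a sample-metadata column name (default `"population"`)
#'   or a vector of one label per sample.
#' @param groups optional subset of group labels to report; an unknown
#'   label is an error.
#' @return a list with `freq` (`freq[[group]][[locus]]`: named numeric
#'   vector over the locus registry) and `gene_counts` (group x locus
#'   matrix of non-missing gene copies).
#' @export
allele_frequencies <- function(table, grouping = "population", groups = NULL) {
  g <- resolve_grouping(table, grouping)
  labs <- unique(g)
  if (!is.null(groups)) {
    bad <- setdiff(groups, labs)
    if (length(bad) > 0) stop("unknown group label(s): ", paste(bad, collapse = ", "))
    labs <- groups
  }
  L <- n_loci(table)
  gene_counts <- matrix(0L, nrow = length(labs), ncol = L,
                        dimnames = list(labs, table$loci))
  freq <- vector("list", length(labs))
  names(freq) <- labs
  for (p in labs) {
    idx <- which(g == p)
    if (length(idx) == 0L) stop("empty group: ", p)
    freq[[p]] <- vector("list", L)
    names(freq[[p]]) <- table$loci
    for (l in seq_len(L)) {
      reg <- table$alleles[[l]]
      copies <- c(table$geno[idx, l, 1], table$geno[idx, l, 2])
      copies <- copies[!is.na(copies)]
      gene_counts[p, l] <- length(copies)
      cnt <- tabulate(match(copies, reg), nbins = length(reg))
      names(cnt) <- as.character(reg)
      freq[[p]][[l]] <- if (length(copies) > 0) cnt / length(copies) else cnt * NA_real_
    }
  }
  list(freq = freq, gene_counts = gene_counts)
}
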