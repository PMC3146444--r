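#' Hybrid cross types and their expected ancestry
#'
#' The seven simulated cross categories: F1 (*graellsii* x *elegans*), F2
#' (F1 x F1), GB1 (F1 x *graellsii*), and the first to fourth *elegans*
#' backcrosses EB1-EB4.  Expected *elegans* ancestry follows the pedigree
#' recursion `a(child) = (a(parentA) + a(parentB)) / 2` with a(*elegans*)
#' = 1 and a(*graellsii*) = 0.
#'
#' @return data frame with columns `cross`, `parentA`, `parentB`,
#'   `expected_elegans_ancestry`.
#' @export
cross_types <- function() {
  data.frame(
    cross = c("F1", "F2", "GB1", "EB1", "EB2", "EB3", "EB4"),
    parentA = c("graellsii", "F1", "F1", "F1", "EB1", "EB2", "EB3"),
    parentB = c("elegans", "F1", "graellsii", "elegans", "elegans",
                "elegans", "elegans"),
    expected_elegans_ancestry = c(0.5, 0.5, 0.25, 0.75, 0.875, 0.9375,
                                  0.96875),
    stringsAsFactors = FALSE)
}

pool_from_table <- function(x) {
  if (inherits(x, "genotype_table")) list(geno = x$geno, loci = x$loci)
  else x
}

#' Simulate offspring genotypes from two parental pools
#'
#' In `frequency_draw` mode each offspring receives, at every locus, one
#' allele drawn from pool A's allele-frequency distribution and one from
#' pool B's, independently across loci (Hardy-Weinberg / linkage
#' equilibrium within each pool).  In `pedigree` mode one parent
#' individual is drawn uniformly from each pool and transmits one of its
#' two alleles, chosen uniformly, at every locus (preserving parental
#' multilocus associations).
#'
#' @param poolA,poolB [genotype_table()] objects with identical loci
#' @param n number of offspring
#' @param mode `"frequency_draw"` or `"pedigree"`
#' @param seed integer seed
#' @param population population label for the offspring (default "cross")
#' @return a [genotype_table()] of `n` offspring
#' @export
simulate_pool_offspring <- function(poolA, poolB, n,
                                    mode = c("frequency_draw", "pedigree"),
                                    seed = 1L, population = "cross") {
  mode <- match.arg(mode)
  if (!identical(poolA$loci, poolB$loci)) stop("locus mismatch between pools")
  if (n_samples(poolA) == 0L || n_samples(poolB) == 0L) stop("empty parental pool")
  L <- n_loci(poolA)
  set.seed(seed)
  geno <- array(NA_integer_, dim = c(n, L, 2L),
                dimnames = list(NULL, poolA$loci, NULL))
  if (mode == "frequency_draw") {
    for (l in seq_len(L)) {
      for (side in 1:2) {
        pool <- if (side == 1) poolA else poolB
        copies <- c(pool$geno[, l, 1], pool$geno[, l, 2])
        copies <- copies[!is.na(copies)]
        if (length(copies) == 0L)
          stop("pool has only missing data at locus '", poolA$loci[l], "'")
        tab <- table(copies)
        alleles <- as.integer(names(tab))
        geno[, l, side] <- sample_codes(alleles, n, prob = as.numeric(tab))
      }
    }
  } else {
    pa <- sample.int(n_samples(poolA), n, replace = TRUE)
    pb <- sample.int(n_samples(poolB), n, replace = TRUE)
    for (l in seq_len(L)) {
      ca <- sample(1:2, n, replace = TRUE)
      cb <- sample(1:2, n, replace = TRUE)
      a <- poolA$geno[cbind(pa, l, ca)]
      b <- poolB$geno[cbind(pb, l, cb)]
      if (anyNA(a) || anyNA(b))
        stop("pedigree mode cannot transmit missing alleles at locus '",
             poolA$loci[l], "'")
      geno[, l, 1] <- a
      geno[, l, 2] <- b
    }
  }
  samples <- data.frame(id = sprintf("%s_%03d", population, seq_len(n)),
                        population = population, stringsAsFactors = FALSE)
  genotype_table(geno, samples, missing_code = poolA$missing_code)
}

#' Generate the full panel of simulated crosses
#'
#' Builds F1 from (graellsii, elegans), F2 from (F1, F1), GB1 from (F1,
#' graellsii), EB1 from (F1, elegans) and EB2-EB4 by successive
#' backcrossing of the previous panel to *elegans*; each generated panel
#' serves as the parental pool for its dependants.  Each cross uses an
#' independent seed substream derived from `seed`, so adding a cross never
#' perturbs earlier ones.
#'
#' @param graellsii_pool,elegans_pool parental [genotype_table()]s
#' @param n_per_cross offspring per cross (default 50)
#' @param mode passed to [simulate_pool_offspring()]
#' @param seed base integer seed
#' @return a named list of class `cross_panel`: one [genotype_table()] per
#'   cross, with attributes `mode`, `seed` and `expected_ancestry`.
#' @export
generate_cross_panel <- function(graellsii_pool, elegans_pool,
                                 n_per_cross = 50L,
                                 mode = c("frequency_draw", "pedigree"),
                                 seed = 1L) {
  mode <- match.arg(mode)
  ct <- cross_types()
  panels <- list(graellsii = graellsii_pool, elegans = elegans_pool)
  for (j in seq_len(nrow(ct))) {
    cr <- ct$cross[j]
    panels[[cr]] <- simulate_pool_offspring(
      panels[[ct$parentA[j]]], panels[[ct$parentB[j]]],
      n = n_per_cross, mode = mode, seed = seed + 101L * j,
      population = cr)
  }
  out <- panels[ct$cross]
  attr(out, "mode") <- mode
  attr(out, "seed") <- as.integer(seed)
  attr(out, "expected_ancestry") <- stats::setNames(
    ct$expected_elegans_ancestry, ct$cross)
  class(out) <- "cross_panel"
  out
}

#' @export
print.cross_panel <- function(x, ...) {
  cat("cross_panel (", attr(x, "mode"), " mode): ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Bind a cross panel (and optional parental pools) into one table
#'
#' @param panel a `cross_panel`
#' @param parents optional named list of parental [genotype_table()]s to
#'   prepend (e.g. reference pools for a supervised admixture run)
#' @return a single [genotype_table()] whose population labels are the
#'   cross / pool names.
#' @export
bind_cross_panel <- function(panel, parents = NULL) {
  tabs <- c(unname(parents), unname(unclass(panel)))
  bind_genotype_tables(tabs)
}
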