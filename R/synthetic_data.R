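rdirichlet1 <- function(shape) {
  x <- stats::rgamma(length(shape), shape = shape, rate = 1)
  if (sum(x) <= 0) x <- rep(1, length(shape))
  x / sum(x)
}

#' Balding-Nichols population allele frequencies
#'
#' Draws per-population frequencies from
#' `Dirichlet(p_anc * (1 - theta) / theta)` at each locus, the standard
#' model in which `theta` is the expected differentiation (FST) of the
#' populations from a shared ancestral pool.  As `theta -> 0` the draws
#' concentrate on the ancestral values.
#'
#' @param ancestral_freqs list (one element per locus) of named numeric
#'   frequency vectors summing to 1
#' @param theta differentiation parameter in (0, 1)
#' @param n_pops number of populations to draw
#' @param seed integer seed
#' @return list of length `n_pops`; each element a list per locus of
#'   frequency vectors named by allele code.
#' @export
balding_nichols_freqs <- function(ancestral_freqs, theta, n_pops, seed = 1L) {
  if (theta <= 0 || theta >= 1) stop("theta must be in (0, 1)")
  anc <- lapply(ancestral_freqs, function(p) {
    if (any(p == 0)) {
      warning("dropping zero-frequency ancestral allele(s)")
      p <- p[p > 0]
    }
    if (abs(sum(p) - 1) > 1e-8) stop("ancestral frequencies must sum to 1")
    p
  })
  set.seed(seed)
  conc <- (1 - theta) / theta
  lapply(seq_len(n_pops), function(k) {
    lapply(anc, function(p) {
      q <- rdirichlet1(p * conc)
      names(q) <- names(p)
      q
    })
  })
}

#' Sample diploid genotypes under Hardy-Weinberg proportions
#'
#' Each genotype is two independent allele draws from the population's
#' frequencies; whole-locus missing entries are inserted independently at
#' `missing_rate`.
#'
#' @param freqs list per locus of named allele-frequency vectors (names
#'   are integer allele codes)
#' @param n number of individuals
#' @param missing_rate per-genotype probability of a missing locus
#' @param seed integer seed
#' @param population,species,region,is_reference sample metadata applied
#'   to all generated individuals
#' @param id_prefix sample-id prefix
#' @return a [genotype_table()]
#' @export
simulate_genotypes <- function(freqs, n, missing_rate = 0, seed = 1L,
                               population = "pop", species = "unknown",
                               region = NA_character_, is_reference = FALSE,
                               id_prefix = population) {
  n <- as.integer(unname(n))
  L <- length(freqs)
  loci <- if (is.null(names(freqs))) paste0("L", seq_len(L)) else names(freqs)
  set.seed(seed)
  geno <- array(NA_integer_, dim = c(n, L, 2L), dimnames = list(NULL, loci, NULL))
  for (l in seq_len(L)) {
    codes <- as.integer(names(freqs[[l]]))
    geno[, l, 1] <- sample_codes(codes, n, prob = freqs[[l]])
    geno[, l, 2] <- sample_codes(codes, n, prob = freqs[[l]])
    if (missing_rate > 0) {
      drop <- stats::runif(n) < missing_rate
      geno[drop, l, ] <- NA_integer_
    }
  }
  samples <- data.frame(id = sprintf("%s_%04d", id_prefix, seq_len(n)),
                        population = population, species = species,
                        region = region, is_reference = is_reference,
                        stringsAsFactors = FALSE)
  genotype_table(geno, samples)
}

#' Sample admixed genotypes with known ancestry
#'
#' Each gene copy's population of origin is Bernoulli(`true_q`, toward
#' population 1) and its allele is then drawn from that population's
#' frequencies, giving individuals whose true ancestry is known exactly.
#'
#' @param freqs_pop1,freqs_pop2 per-locus frequency lists (population 1 is
#'   the cluster whose ancestry `true_q` measures)
#' @param true_q numeric vector in \[0, 1\]; one individual per entry
#' @param seed integer seed
#' @param population,id_prefix metadata for the generated samples
#' @return list with `table` (a [genotype_table()]) and `truth` (data
#'   frame `id`, `true_q`).
#' @export
simulate_admixed <- function(freqs_pop1, freqs_pop2, true_q, seed = 1L,
                             population = "admixed", id_prefix = population) {
  if (any(true_q < 0 | true_q > 1)) stop("true_q entries must lie in [0, 1]")
  n <- length(true_q)
  L <- length(freqs_pop1)
  loci <- if (is.null(names(freqs_pop1))) paste0("L", seq_len(L)) else names(freqs_pop1)
  set.seed(seed)
  geno <- array(NA_integer_, dim = c(n, L, 2L), dimnames = list(NULL, loci, NULL))
  for (l in seq_len(L)) {
    c1 <- as.integer(names(freqs_pop1[[l]]))
    c2 <- as.integer(names(freqs_pop2[[l]]))
    for (cc in 1:2) {
      from1 <- stats::runif(n) < true_q
      a <- integer(n)
      if (any(from1))
        a[from1] <- sample_codes(c1, sum(from1), prob = freqs_pop1[[l]])
      if (any(!from1))
        a[!from1] <- sample_codes(c2, sum(!from1), prob = freqs_pop2[[l]])
      geno[, l, cc] <- a
    }
  }
  samples <- data.frame(id = sprintf("%s_%04d", id_prefix, seq_len(n)),
                        population = population, species = "unknown",
                        stringsAsFactors = FALSE)
  list(table = genotype_table(geno, samples),
       truth = data.frame(id = samples$id, true_q = true_q,
                          stringsAsFactors = FALSE))
}

#' Synthetic aligned mtDNA panel with a prescribed haplotype configuration
#'
#' Builds a random common haplotype of the requested length and derives
#' variant haplotypes differing from it at the specified site sets, then
#' replicates each haplotype to its count and shuffles the sequence order.
#' This reproduces published haplotype-count configurations exactly.
#'
#' @param counts integer vector: sequences per haplotype (first = common
#'   type)
#' @param variant_sites list (length `length(counts) - 1`) of integer site
#'   vectors where each variant differs from the common haplotype;
#'   overlapping site sets must be declared via `allow_overlap = TRUE`
#' @param length alignment length in bp
#' @param seed integer seed
#' @param allow_overlap permit two variants to mutate the same site
#' @return a [haplo_alignment()]
#' @export
simulate_mtdna_panel <- function(counts, variant_sites = list(),
                                 length = 500L, seed = 1L,
                                 allow_overlap = FALSE) {
  if (any(counts < 1L)) stop("haplotype counts must be >= 1")
  if (length(variant_sites) != length(counts) - 1L)
    stop("need one variant site set per non-common haplotype")
  sites <- unlist(variant_sites)
  if (length(sites) > 0 && max(sites) > length)
    stop("variant sites exceed the alignment length")
  if (!allow_overlap && anyDuplicated(sites))
    stop("overlapping variant site sets; set allow_overlap = TRUE to permit")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  common <- sample(bases, length, replace = TRUE)
  haps <- list(common)
  for (v in seq_along(variant_sites)) {
    h <- common
    for (s in variant_sites[[v]])
      h[s] <- sample(setdiff(bases, h[s]), 1)
    haps[[v + 1L]] <- h
  }
  m <- do.call(rbind, rep(haps, times = counts))
  ord <- sample(nrow(m))
  haplo_alignment(m[ord, , drop = FALSE],
                  ids = sprintf("seq%03d", seq_len(nrow(m))))
}

#' Full synthetic two-species survey scenario
#'
#' Emits everything the downstream pipeline consumes: two strongly
#' differentiated parental gene pools (*graellsii* and non-Spanish
#' *elegans*) and an admixed "Spanish" group, shaped like a 26-population
#' survey of 442 individuals at 6 microsatellite loci (group totals
#' 220 non-Spanish *elegans* / 166 Spanish / 56 *graellsii*); simulated
#' mtDNA panels for five gene fragments matching the published haplotype
#' configurations; and a female morph-count table.  Spanish individuals
#' draw their true ancestry from a mixture of pure (q ~ 0.97),
#' backcross-like (q ~ 0.75) and F1-like (q ~ 0.5) classes with
#' proportions 27/59/14% — a cosmetic choice so report shapes resemble an
#' introgressed survey.
#'
#' @param seed integer seed
#' @param n_loci number of microsatellite loci (default 6)
#' @param alleles_per_locus alleles per locus in the ancestral pool
#'   (default 10)
#' @param target_theta parental differentiation (default 0.2)
#' @param missing_rate per-genotype missing probability (default 0)
#' @return list with `genotypes` (one [genotype_table()] for all 26
#'   populations; references flagged), `truth` (true q for Spanish
#'   individuals), `parent_freqs` (graellsii / elegans per-locus
#'   frequencies), `mtdna` (named list of [haplo_alignment()]s), `morphs`
#'   (count table), `manifest` (list of scenario parameters).
#' @export
survey_shape_scenario <- function(seed = 1L, n_loci = 6L,
                                 alleles_per_locus = 10L,
                                 target_theta = 0.2, missing_rate = 0) {
  set.seed(seed)
  # microsatellite-style allele codes: dinucleotide ladder per locus
  anc <- lapply(seq_len(n_loci), function(l) {
    codes <- 100L + 20L * l + 2L * seq_len(alleles_per_locus)
    p <- rdirichlet1(rep(2, alleles_per_locus))
    names(p) <- codes
    p
  })
  names(anc) <- paste0("L", seq_len(n_loci))
  parents <- balding_nichols_freqs(anc, theta = target_theta, n_pops = 2,
                                   seed = seed + 11L)
  gra_f <- parents[[1]]; ele_f <- parents[[2]]

  # population sizes: group totals 220 / 166 / 56
  ele_sizes <- stats::setNames(c(rep(17L, 12), 16L), paste0("EU", 1:13))
  spa_sizes <- stats::setNames(c(20L, 14L, 15L, 17L, 20L, 20L, 20L, 20L, 20L),
                               paste0("SP", 1:9))
  gra_sizes <- stats::setNames(rep(14L, 4), paste0("GR", 1:4))

  tabs <- list()
  for (j in seq_along(ele_sizes))
    tabs[[length(tabs) + 1L]] <- simulate_genotypes(
      ele_f, ele_sizes[j], missing_rate, seed = seed + 100L + j,
      population = names(ele_sizes)[j], species = "elegans",
      region = "Europe-not-Spain", is_reference = TRUE)
  for (j in seq_along(gra_sizes))
    tabs[[length(tabs) + 1L]] <- simulate_genotypes(
      gra_f, gra_sizes[j], missing_rate, seed = seed + 200L + j,
      population = names(gra_sizes)[j], species = "graellsii",
      region = "Iberia-Africa", is_reference = TRUE)

  # Spanish admixed individuals: known true ancestry toward elegans
  truth <- list()
  for (j in seq_along(spa_sizes)) {
    n <- spa_sizes[j]
    set.seed(seed + 300L + j)
    cls <- sample(c("pure", "backcross", "mixed"), n, replace = TRUE,
                  prob = c(0.27, 0.59, 0.14))
    q <- ifelse(cls == "pure", stats::runif(n, 0.93, 1.0),
                ifelse(cls == "backcross", stats::runif(n, 0.70, 0.90),
                       stats::runif(n, 0.35, 0.65)))
    sim <- simulate_admixed(ele_f, gra_f, q, seed = seed + 400L + j,
                            population = names(spa_sizes)[j],
                            id_prefix = names(spa_sizes)[j])
    sim$table$samples$species <- "elegans"
    sim$table$samples$region <- "Spain"
    sim$table$samples$is_reference <- FALSE
    tabs[[length(tabs) + 1L]] <- genotype_table(sim$table$geno,
                                                sim$table$samples)
    truth[[length(truth) + 1L]] <- sim$truth
  }
  genotypes <- bind_genotype_tables(tabs)
  truth <- do.call(rbind, truth)

  # mtDNA panels: the five published fragment configurations
  mtdna <- list(
    COI = simulate_mtdna_panel(13L, list(), length = 591L, seed = seed + 501L),
    COII = simulate_mtdna_panel(c(9L, 3L), list(10L), length = 673L,
                                seed = seed + 502L),
    CYTB = simulate_mtdna_panel(c(22L, 1L, 1L), list(20L, 40L), length = 457L,
                                seed = seed + 503L),
    `12S` = simulate_mtdna_panel(c(65L, 1L, 1L, 1L), list(11L, 22L, 33L),
                                 length = 370L, seed = seed + 504L),
    ND1 = simulate_mtdna_panel(c(7L, 1L), list(100L), length = 591L,
                               seed = seed + 505L))

  set.seed(seed + 600L)
  n_pops_m <- 8L
  Nf <- sample(15:40, n_pops_m, replace = TRUE)
  a <- stats::rbinom(n_pops_m, Nf, 0.25)
  i <- stats::rbinom(n_pops_m, Nf - a, 0.6)
  morphs <- data.frame(population = paste0("M", seq_len(n_pops_m)),
                       species = rep(c("elegans", "graellsii"), length.out = n_pops_m),
                       date = "synthetic", N = Nf,
                       count_androchrome = a, count_infuscans = i,
                       count_obsoleta = Nf - a - i,
                       stringsAsFactors = FALSE)

  list(genotypes = genotypes, truth = truth,
       parent_freqs = list(graellsii = gra_f, elegans = ele_f),
       mtdna = mtdna, morphs = morphs,
       manifest = list(seed = as.integer(seed), n_loci = as.integer(n_loci),
                       alleles_per_locus = as.integer(alleles_per_locus),
                       target_theta = target_theta,
                       group_sizes = c(elegans_europe = 220L, spain = 166L,
                                       graellsii = 56L),
                       missing_rate = missing_rate))
}

#' Write a scenario bundle to disk as plain-text fixtures
#'
#' Writes the genotype table in STRUCTURE and GENEPOP formats, the sample
#' metadata CSV, one FASTA per mtDNA fragment, the morph-count CSV and a
#' JSON truth manifest.  Rerunning with the same scenario produces
#' byte-identical files.
#'
#' @param scenario output of [survey_shape_scenario()]
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of files written
#' @export
write_scenario_bundle <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- character(0)
  p <- function(x) file.path(dir, x)
  write_structure_file(scenario$genotypes, p("genotypes.str"))
  write_genepop_file(scenario$genotypes, p("genotypes.gen"))
  utils::write.csv(scenario$genotypes$samples, p("samples.csv"),
                   row.names = FALSE)
  utils::write.csv(scenario$truth, p("true_q.csv"), row.names = FALSE)
  utils::write.csv(scenario$morphs, p("morphs.csv"), row.names = FALSE)
  for (g in names(scenario$mtdna))
    write_haplo_alignment(scenario$mtdna[[g]], p(paste0("mtdna_", g, ".fasta")))
  jsonlite::write_json(scenario$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  f <- list.files(dir, full.names = TRUE)
  invisible(f)
}
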