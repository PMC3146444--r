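#' Configuration for the Bayesian admixture sampler
#'
#' Defaults follow common practice for microsatellite surveys: a single
#' Dirichlet admixture parameter `alpha` shared across clusters, updated
#' by Gaussian Metropolis steps with a uniform prior on `(0, alpha_max]`;
#' the correlated-frequencies model with a per-cluster drift parameter
#' `F_k` under a gamma prior (mean `drift_prior_mean`, sd
#' `drift_prior_sd`); `lambda = 1` for the ancestral-frequency prior.  The
#' desk-scale default run length is 5000 burn-in / 20000 sampling sweeps;
#' set `burn_in = 20000, n_sweeps = 1e5` for full-length runs.
#'
#' @param K number of clusters (>= 1)
#' @param burn_in,n_sweeps burn-in and sampling sweeps (>= 1)
#' @param freq_model `"correlated"` or `"independent"`
#' @param lambda Dirichlet hyperparameter for allele frequencies
#' @param alpha_init,alpha_max,alpha_proposal_sd admixture-parameter
#'   controls
#' @param drift_prior_mean,drift_prior_sd,drift_proposal_sd correlated-model
#'   drift controls
#' @param use_reference_labels clamp learning samples (`is_reference`) to
#'   the cluster implied by their species label
#' @param seed integer RNG seed
#' @param thin record every `thin`-th post-burn-in sweep
#' @return a list of class `admixture_config`
#' @export
admixture_config <- function(K = 2L, burn_in = 5000L, n_sweeps = 20000L,
                             freq_model = c("correlated", "independent"),
                             lambda = 1, alpha_init = 1, alpha_max = 10,
                             alpha_proposal_sd = 0.025,
                             drift_prior_mean = 0.01, drift_prior_sd = 0.05,
                             drift_proposal_sd = 0.005,
                             use_reference_labels = FALSE,
                             seed = 1L, thin = 10L) {
  freq_model <- match.arg(freq_model)
  if (K < 1L) stop("K must be >= 1")
  if (burn_in < 1L || n_sweeps < 1L) stop("burn_in and n_sweeps must be >= 1")
  if (alpha_max <= 0) stop("alpha_max must be positive")
  if (thin < 1L || thin > n_sweeps) stop("invalid 'thin'")
  structure(list(K = as.integer(K), burn_in = as.integer(burn_in),
                 n_sweeps = as.integer(n_sweeps), freq_model = freq_model,
                 lambda = lambda, alpha_init = alpha_init,
                 alpha_max = alpha_max, alpha_proposal_sd = alpha_proposal_sd,
                 drift_prior_mean = drift_prior_mean,
                 drift_prior_sd = drift_prior_sd,
                 drift_proposal_sd = drift_proposal_sd,
                 use_reference_labels = isTRUE(use_reference_labels),
                 seed = as.integer(seed), thin = as.integer(thin)),
            class = "admixture_config")
}

# genotype array -> n x 2L matrix of 1-based registry indices (NA missing)
as_allele_index_matrix <- function(table) {
  n <- n_samples(table); L <- n_loci(table)
  out <- matrix(NA_integer_, nrow = n, ncol = 2L * L)
  for (l in seq_len(L)) {
    reg <- table$alleles[[l]]
    out[, 2L * l - 1L] <- match(table$geno[, l, 1], reg)
    out[, 2L * l] <- match(table$geno[, l, 2], reg)
  }
  out
}

# reference-cluster labels from species: graellsii -> 1, elegans -> 2.
reference_clusters <- function(table, K) {
  rc <- integer(n_samples(table))
  ref <- table$samples$is_reference
  if (!any(ref)) stop("use_reference_labels = TRUE but no reference samples")
  sp <- table$samples$species
  cl <- ifelse(sp == "graellsii", 1L, ifelse(sp == "elegans", 2L, NA_integer_))
  if (anyNA(cl[ref]))
    stop("reference samples must have species 'graellsii' or 'elegans'")
  if (K < 2L) stop("reference labels need K >= 2")
  rc[ref] <- cl[ref]
  rc
}

#' Fit the admixture model by Gibbs sampling
#'
#' Runs the MCMC described in [admixture_config()] and returns posterior
#' summaries: per-individual mean ancestry `q_mean` with central 90%
#' credible intervals, posterior-mean cluster allele frequencies, the
#' alpha and log-likelihood traces, and the `ln P(D)` model-choice
#' estimate.  With `use_reference_labels = TRUE`, samples flagged
#' `is_reference` are clamped to the cluster implied by their species
#' (*graellsii* = cluster 1, *elegans* = cluster 2), which anchors the
#' cluster labels across runs.  Runs are bit-reproducible given
#' `config$seed`.
#'
#' @param table a [genotype_table()]
#' @param config an [admixture_config()]
#' @return an object of class `admixture_run`: list with `q_mean`,
#'   `q_ci90` (lower/upper arrays), `p_mean`, `alpha_trace`, `lnL_trace`,
#'   `ln_prob_data`, `config`.
#' @export
run_admixture <- function(table, config = admixture_config()) {
  if (!inherits(config, "admixture_config")) stop("'config' must be an admixture_config")
  if (n_samples(table) == 0L) stop("empty genotype table")
  K <- config$K
  idx <- as_allele_index_matrix(table)
  n_alleles <- lengths(table$alleles)
  rc <- if (config$use_reference_labels) reference_clusters(table, K)
        else integer(n_samples(table))
  set.seed(config$seed)
  raw <- .admix_gibbs_cpp(idx, as.integer(n_alleles), K,
                          config$burn_in, config$n_sweeps, config$thin,
                          config$freq_model == "correlated", config$lambda,
                          config$alpha_init, config$alpha_max,
                          config$alpha_proposal_sd,
                          config$drift_prior_mean, config$drift_prior_sd,
                          config$drift_proposal_sd, 500,
                          as.integer(rc), TRUE)
  n <- n_samples(table)
  qs <- raw$q_samples  # dim (K, n, n_samp)
  lo <- hi <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) {
    for (k in seq_len(K)) {
      v <- qs[k, i, ]
      ci <- stats::quantile(v, c(0.05, 0.95), names = FALSE, type = 7)
      lo[i, k] <- ci[1]; hi[i, k] <- ci[2]
    }
  }
  rownames(raw$q_mean) <- rownames(lo) <- rownames(hi) <- table$samples$id
  names(raw$p_mean) <- table$loci
  for (l in seq_along(raw$p_mean))
    colnames(raw$p_mean[[l]]) <- as.character(table$alleles[[l]])
  if (K > 1 && stats::sd(raw$alpha_trace) < 1e-12)
    warning("alpha trace is flat; the sampler may not be mixing")
  structure(list(q_mean = raw$q_mean,
                 q_ci90 = list(lower = lo, upper = hi),
                 p_mean = raw$p_mean,
                 alpha_trace = as.numeric(raw$alpha_trace),
                 lnL_trace = as.numeric(raw$lnL_trace),
                 ln_prob_data = estimate_ln_prob_data(as.numeric(raw$lnL_trace)),
                 samples = table$samples,
                 config = config),
            class = "admixture_run")
}

#' @export
print.admixture_run <- function(x, ...) {
  cat("admixture_run: K =", x$config$K, ", n =", nrow(x$q_mean),
      ", ln P(D) =", round(x$ln_prob_data, 1), "\n")
  invisible(x)
}

#' Model-choice estimate of ln P(D) from a log-likelihood trace
#'
#' `ln P(D) ~ mean(lnL) - var(lnL) / 2`, the harmonic-style estimator used
#' for cluster-number comparison.  Variance is the sample variance.
#'
#' @param lnL_trace numeric vector of length >= 2
#' @return a single number
#' @export
estimate_ln_prob_data <- function(lnL_trace) {
  if (length(lnL_trace) < 2L) stop("lnL trace must have length >= 2")
  mean(lnL_trace) - stats::var(lnL_trace) / 2
}

#' Group-level posterior ancestry summaries
#'
#' @param run an `admixture_run`
#' @param grouping a column of the run's sample table (default
#'   `"population"`) or a per-individual label vector
#' @return list with `group_means` (group x K matrix of arithmetic means
#'   of member rows) and `individual` (data frame of per-individual
#'   `q_mean` with 90% CI bounds for cluster columns).
#' @export
posterior_summary <- function(run, grouping = "population") {
  g <- if (length(grouping) == 1L && grouping %in% names(run$samples))
    as.character(run$samples[[grouping]]) else as.character(grouping)
  if (length(g) != nrow(run$q_mean)) stop("grouping length mismatch")
  labs <- unique(g)
  K <- ncol(run$q_mean)
  gm <- matrix(NA_real_, length(labs), K,
               dimnames = list(labs, paste0("cluster", seq_len(K))))
  for (p in labs)
    gm[p, ] <- colMeans(run$q_mean[g == p, , drop = FALSE])
  ind <- data.frame(id = rownames(run$q_mean), group = g,
                    stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    ind[[paste0("q", k)]] <- run$q_mean[, k]
    ind[[paste0("q", k, "_lo")]] <- run$q_ci90$lower[, k]
    ind[[paste0("q", k, "_hi")]] <- run$q_ci90$upper[, k]
  }
  list(group_means = gm, individual = ind)
}

#' Evanno delta-K model selection from replicate runs
#'
#' From replicate `ln P(D)` values at each K, computes the mean and sd per
#' K and `deltaK = mean_r |L_r(K-1) - 2 L_r(K) + L_r(K+1)| / sd(L(K))`,
#' pairing replicate runs by index.  DeltaK is defined only at interior K
#' with positive sd.
#'
#' @param lnp_by_k named list (names = K values, consecutive integers) of
#'   numeric vectors of replicate `ln P(D)` values; or a data frame with
#'   columns `K`, `lnP`.
#' @param sd_override optional numeric vector (recycled over K) replacing
#'   the replicate sd, e.g. to evaluate deltaK from single runs.
#' @return data frame of class `k_selection_table` with columns `K`,
#'   `n_runs`, `mean_lnP`, `sd_lnP`, `deltaK` (NA at the ends and where
#'   sd = 0, flagged in `defined`).
#' @export
evanno_delta_k <- function(lnp_by_k, sd_override = NULL) {
  if (is.data.frame(lnp_by_k)) {
    lnp_by_k <- split(lnp_by_k$lnP, lnp_by_k$K)
  }
  Ks <- as.integer(names(lnp_by_k))
  o <- order(Ks)
  Ks <- Ks[o]; lnp_by_k <- lnp_by_k[o]
  if (length(Ks) < 3L) stop("need at least 3 consecutive K values")
  if (any(diff(Ks) != 1L)) stop("K values must be consecutive")
  nr <- lengths(lnp_by_k)
  out <- data.frame(K = Ks, n_runs = nr,
                    mean_lnP = vapply(lnp_by_k, mean, 0),
                    sd_lnP = vapply(lnp_by_k, stats::sd, 0),
                    deltaK = NA_real_, defined = FALSE)
  if (!is.null(sd_override)) out$sd_lnP <- rep_len(sd_override, length(Ks))
  for (j in seq_along(Ks)[-c(1, length(Ks))]) {
    m <- min(nr[j - 1L], nr[j], nr[j + 1L])
    if (m < 1L) next
    sdK <- out$sd_lnP[j]
    if (is.na(sdK) || sdK <= 0) next
    if (is.null(sd_override) && nr[j] < 2L) next
    l2 <- abs(lnp_by_k[[j - 1L]][seq_len(m)] - 2 * lnp_by_k[[j]][seq_len(m)] +
              lnp_by_k[[j + 1L]][seq_len(m)])
    out$deltaK[j] <- mean(l2) / sdK
    out$defined[j] <- TRUE
  }
  class(out) <- c("k_selection_table", "data.frame")
  out
}

#' Replicate admixture runs over a range of K
#'
#' Convenience driver for [evanno_delta_k()]: runs the sampler
#' `n_runs` times for each K (unsupervised), with seeds derived from
#' `seed`, and collects `ln P(D)`.
#'
#' @param table a [genotype_table()]
#' @param K_range integer vector of consecutive K values
#' @param n_runs replicate runs per K (>= 2 for a usable sd)
#' @param config_template an [admixture_config()] whose K and seed are
#'   overridden per run
#' @param seed base seed; run `r` at K uses `seed + 1000 * K + r`
#' @return list with `table` (the [evanno_delta_k()] result) and `lnp`
#'   (the raw replicate values).
#' @export
run_k_selection <- function(table, K_range = 1:5, n_runs = 3L,
                            config_template = admixture_config(),
                            seed = 1L) {
  lnp <- lapply(K_range, function(K) {
    vapply(seq_len(n_runs), function(r) {
      cfg <- config_template
      cfg$K <- as.integer(K)
      cfg$seed <- as.integer(seed + 1000L * K + r)
      cfg$use_reference_labels <- FALSE
      run_admixture(table, cfg)$ln_prob_data
    }, 0)
  })
  names(lnp) <- K_range
  list(table = evanno_delta_k(lnp), lnp = lnp)
}
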