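#' Aligned haploid sequence sets
#'
#' A `haplo_alignment` is a set of equal-length aligned sequences over
#' `{A, C, G, T, -, N}` with optional species and ecology
#' (sympatric/allopatric) labels per sequence.
#'
#' @param sequences character vector of equal-length sequence strings, or
#'   a character matrix (rows = sequences, one base per cell)
#' @param ids sequence identifiers (defaults to `seq1..`)
#' @param species,ecology optional per-sequence labels
#' @return an object of class `haplo_alignment` holding an upper-case
#'   character matrix `seq` and a `meta` data frame.
#' @export
haplo_alignment <- function(sequences, ids = NULL, species = NULL,
                            ecology = NULL) {
  if (is.character(sequences) && !is.matrix(sequences)) {
    if (length(unique(nchar(sequences))) != 1L)
      stop("sequences must have equal aligned length")
    m <- do.call(rbind, strsplit(toupper(sequences), ""))
  } else if (is.matrix(sequences)) {
    m <- toupper(sequences)
  } else stop("'sequences' must be a character vector or matrix")
  if (nrow(m) < 1L) stop("alignment needs at least one sequence")
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad) > 0)
    stop("unexpected alignment characters: ", paste(bad, collapse = ", "))
  n <- nrow(m)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  meta <- data.frame(id = as.character(ids),
                     species = if (is.null(species)) NA_character_ else species,
                     ecology = if (is.null(ecology)) NA_character_ else ecology,
                     stringsAsFactors = FALSE)
  rownames(m) <- meta$id
  structure(list(seq = m, meta = meta), class = "haplo_alignment")
}

#' Read an aligned FASTA file as a haplo_alignment
#'
#' @param path FASTA path (sequences must be pre-aligned)
#' @return a [haplo_alignment()]
#' @export
read_haplo_alignment <- function(path) {
  d <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                     as.matrix = TRUE)
  haplo_alignment(toupper(unname(d)), ids = rownames(d))
}

#' Write a haplo_alignment as FASTA
#'
#' @param aln a [haplo_alignment()]
#' @param path output path
#' @export
write_haplo_alignment <- function(aln, path) {
  seqs <- apply(aln$seq, 1, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", aln$meta$id), seqs)), path)
  invisible(path)
}

#' Collapse an alignment into its haplotype spectrum
#'
#' Under `complete_sites_only` (the default, DnaSP-like) alignment columns
#' containing any gap or N are removed before grouping; under `pairwise`
#' all columns are kept, sequences are grouped on exact identity, and
#' pairwise differences between haplotypes skip sites that are ambiguous
#' in either member of the pair.  Segregating sites S are counted over the
#' retained columns (sites with two or more unambiguous states).
#'
#' @param aln a [haplo_alignment()]
#' @param site_policy `"complete_sites_only"` or `"pairwise"`
#' @return an object of class `haplotype_spectrum`: list with `counts`
#'   (haplotype sizes, decreasing), `n`, `S`, `diff_matrix` (pairwise site
#'   differences between haplotypes), `seq_length` (retained sites),
#'   `membership` (haplotype index per sequence).
#' @export
collapse_haplotypes <- function(aln,
                                site_policy = c("complete_sites_only",
                                                "pairwise")) {
  site_policy <- match.arg(site_policy)
  m <- aln$seq
  if (site_policy == "complete_sites_only") {
    keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
    if (!any(keep)) stop("no complete sites retained")
    m <- m[, keep, drop = FALSE]
  }
  key <- apply(m, 1, paste, collapse = "")
  first <- !duplicated(key)
  hap_key <- key[first]
  membership <- match(key, hap_key)
  counts <- as.integer(table(membership))
  # order haplotypes by decreasing count, ties by first appearance
  o <- order(-counts, seq_along(counts))
  membership <- match(membership, o)
  counts <- counts[o]
  reps <- m[first, , drop = FALSE][o, , drop = FALSE]

  H <- nrow(reps)
  d <- matrix(0L, H, H)
  if (H > 1) {
    for (i in seq_len(H - 1)) {
      for (j in (i + 1):H) {
        a <- reps[i, ]; b <- reps[j, ]
        ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
        d[i, j] <- d[j, i] <- sum(a[ok] != b[ok])
      }
    }
  }
  S <- sum(apply(m, 2, function(col) {
    u <- unique(col[col %in% c("A", "C", "G", "T")])
    length(u) >= 2L
  }))
  structure(list(counts = counts, n = sum(counts), S = as.integer(S),
                 diff_matrix = d, seq_length = ncol(m),
                 membership = membership, site_policy = site_policy),
            class = "haplotype_spectrum")
}

#' @export
print.haplotype_spectrum <- function(x, ...) {
  cat("haplotype_spectrum: n =", x$n, ", haplotypes =", length(x$counts),
      "(", paste(x$counts, collapse = ","), "), S =", x$S,
      ", sites =", x$seq_length, "\n")
  invisible(x)
}

#' Build a haplotype spectrum directly from counts and differences
#'
#' Convenience constructor for configurations known only as haplotype
#' counts plus a difference matrix (e.g. when re-analysing published
#' summaries rather than raw sequences).
#'
#' @param counts integer haplotype sizes
#' @param diff_matrix symmetric integer matrix of pairwise site
#'   differences (defaults: every pair differs at 1 site)
#' @param seq_length alignment length in bp
#' @param S segregating sites (default `max(diff_matrix)` lower bound)
#' @return a `haplotype_spectrum`
#' @export
haplotype_spectrum <- function(counts, diff_matrix = NULL, seq_length = 1L,
                               S = NULL) {
  counts <- as.integer(counts)
  H <- length(counts)
  if (is.null(diff_matrix)) {
    diff_matrix <- matrix(1L, H, H); diag(diff_matrix) <- 0L
  }
  if (is.null(S)) S <- max(diff_matrix)
  structure(list(counts = counts, n = sum(counts), S = as.integer(S),
                 diff_matrix = diff_matrix, seq_length = as.integer(seq_length),
                 membership = rep(seq_len(H), counts),
                 site_policy = "explicit"),
            class = "haplotype_spectrum")
}

#' Nei haplotype (gene) diversity with its sampling standard deviation
#'
#' `h = n (1 - sum p_i^2) / (n - 1)` with `p_i` the haplotype relative
#' frequencies, and Nei's sampling variance
#' `V(h) = 2/(n(n-1)) * { 2(n-2) (sum p^3 - (sum p^2)^2) + sum p^2 -
#' (sum p^2)^2 }`; the reported sd is `sqrt(V(h))`.
#'
#' @param spectrum a `haplotype_spectrum` (n >= 2)
#' @return named numeric vector `c(h = , sd = )`
#' @export
haplotype_diversity <- function(spectrum) {
  n <- spectrum$n
  if (n < 2L) stop("need at least 2 sequences")
  p <- spectrum$counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  h <- n * (1 - s2) / (n - 1)
  v <- (2 / (n * (n - 1))) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  c(h = h, sd = sqrt(max(v, 0)))
}

#' Nei nucleotide diversity per site
#'
#' `pi = [ sum over unordered sequence pairs of their site differences /
#' C(n, 2) ] / L`, computed from the haplotype spectrum as
#' `sum_{i<j} n_i n_j d_ij / (C(n,2) L)`.
#'
#' @param spectrum a `haplotype_spectrum` (n >= 2)
#' @param seq_length sites `L` used as the per-site denominator; defaults
#'   to the spectrum's retained length
#' @return a single number
#' @export
nucleotide_diversity <- function(spectrum, seq_length = NULL) {
  n <- spectrum$n
  if (n < 2L) stop("need at least 2 sequences")
  if (is.null(seq_length)) seq_length <- spectrum$seq_length
  if (seq_length < 1L) stop("'seq_length' must be >= 1")
  cnt <- spectrum$counts
  H <- length(cnt)
  tot <- 0
  if (H > 1)
    for (i in seq_len(H - 1))
      for (j in (i + 1):H)
        tot <- tot + cnt[i] * cnt[j] * spectrum$diff_matrix[i, j]
  tot / choose(n, 2) / seq_length
}

#' Table-style mtDNA diversity summary for several gene fragments
#'
#' @param alignments named list of [haplo_alignment()] objects (one per
#'   gene fragment)
#' @param site_policy passed to [collapse_haplotypes()]
#' @return data frame with columns `gene`, `N`, `bp`, `n_haplotypes`, `S`,
#'   `H`, `H_sd`, `pi` (pi rounded to 5 decimals as conventionally
#'   printed; H and sd to 3).
#' @export
mtdna_diversity_table <- function(alignments,
                                  site_policy = "complete_sites_only") {
  rows <- lapply(names(alignments), function(g) {
    sp <- collapse_haplotypes(alignments[[g]], site_policy)
    hd <- if (sp$n >= 2) haplotype_diversity(sp) else c(h = NA, sd = NA)
    pi <- if (sp$n >= 2) nucleotide_diversity(sp) else NA
    data.frame(gene = g, N = sp$n, bp = sp$seq_length,
               n_haplotypes = length(sp$counts), S = sp$S,
               H = round(unname(hd["h"]), 3), H_sd = round(unname(hd["sd"]), 3),
               pi = round(pi, 5), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
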