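#' Admixture-proportion bins for hybrid classification
#'
#' Named intervals on the *elegans*-ancestry proportion q that partition
#' \[0, 1\].  The default cut points place the boundaries of the
#' conservative assignment groups (pure at >= 90% or <= 10%, *elegans*
#' backcrosses at 68-89%, *graellsii* backcrosses at 11-20%, mixed
#' F1/F2/backcross at 21-67%) at the midpoints between the integer
#' percentages, so every q has exactly one bin.  Intervals are
#' right-open except the last.
#'
#' @param cuts increasing numeric vector of 4 interior boundaries
#'   (default `c(0.105, 0.205, 0.675, 0.90)`)
#' @return character-labelled object of class `admixture_bins`
#' @export
admixture_bins <- function(cuts = c(0.105, 0.205, 0.675, 0.90)) {
  if (length(cuts) != 4L || is.unsorted(cuts, strictly = TRUE) ||
      cuts[1] <= 0 || cuts[4] >= 1)
    stop("'cuts' must be 4 strictly increasing values inside (0, 1)")
  structure(list(cuts = cuts,
                 labels = c("pure_graellsii", "graellsii_backcross",
                            "mixed_F1_F2_BC", "elegans_backcross",
                            "pure_elegans")),
            class = "admixture_bins")
}

#' @export
print.admixture_bins <- function(x, ...) {
  b <- c(0, x$cuts, 1)
  for (j in seq_along(x$labels))
    cat(sprintf("%-20s [%.3f, %.3f%s\n", x$labels[j], b[j], b[j + 1],
                if (j == length(x$labels)) "]" else ")"))
  invisible(x)
}

#' Classify an admixture proportion into a hybrid-category bin
#'
#' @param q_elegans numeric vector of *elegans*-ancestry proportions in
#'   \[0, 1\]
#' @param bins an [admixture_bins()]
#' @return factor of bin labels (ordered from pure_graellsii to
#'   pure_elegans)
#' @export
classify_q <- function(q_elegans, bins = admixture_bins()) {
  if (any(is.na(q_elegans)) || any(q_elegans < 0 | q_elegans > 1))
    stop("q must lie in [0, 1]")
  idx <- findInterval(q_elegans, bins$cuts) + 1L  # right-open at each cut
  factor(bins$labels[idx], levels = bins$labels, ordered = TRUE)
}

#' Per-group counts of individuals in each admixture bin
#'
#' @param q_table data frame with columns `group` and `q` (elegans
#'   ancestry), e.g. built from [posterior_summary()]
#' @param bins an [admixture_bins()]
#' @return data frame of class `assignment_summary`: one row per group
#'   with `N` and one count column per bin; counts sum to `N` by
#'   construction.
#' @export
summarize_assignments <- function(q_table, bins = admixture_bins()) {
  if (!all(c("group", "q") %in% names(q_table)))
    stop("'q_table' needs columns 'group' and 'q'")
  cl <- classify_q(q_table$q, bins)
  tab <- table(q_table$group, cl)
  labs <- unique(as.character(q_table$group))
  out <- data.frame(group = labs, N = as.integer(rowSums(tab)[labs]),
                    stringsAsFactors = FALSE)
  for (b in bins$labels) out[[b]] <- as.integer(tab[labs, b])
  class(out) <- c("assignment_summary", "data.frame")
  out
}

#' Calibrate bins against simulated cross panels
#'
#' Reports, per cross, the min / mean / max posterior q and the bin
#' occupancy, i.e. which assignment intervals each simulated hybrid
#' category actually occupies.  This is the calibration step that
#' justifies reading empirical bin counts as hybrid categories.
#'
#' @param cross_panel_q data frame with columns `cross` and `q` (elegans
#'   ancestry of each simulated individual, from a supervised admixture
#'   run on the panel)
#' @param bins an [admixture_bins()]
#' @return list with `ranges` (per-cross min/mean/max and N) and `counts`
#'   (an [summarize_assignments()] table keyed by cross).
#' @export
calibrate_bins <- function(cross_panel_q, bins = admixture_bins()) {
  if (!all(c("cross", "q") %in% names(cross_panel_q)))
    stop("'cross_panel_q' needs columns 'cross' and 'q'")
  if (nrow(cross_panel_q) == 0L) stop("empty cross panel")
  sp <- split(cross_panel_q$q, cross_panel_q$cross)
  sp <- sp[unique(as.character(cross_panel_q$cross))]
  if (any(lengths(sp) == 0L)) stop("empty cross panel")
  ranges <- data.frame(cross = names(sp),
                       N = lengths(sp),
                       q_min = vapply(sp, min, 0),
                       q_mean = vapply(sp, mean, 0),
                       q_max = vapply(sp, max, 0),
                       stringsAsFactors = FALSE)
  rownames(ranges) <- NULL
  counts <- summarize_assignments(
    data.frame(group = cross_panel_q$cross, q = cross_panel_q$q), bins)
  names(counts)[1] <- "cross"
  list(ranges = ranges, counts = counts)
}
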