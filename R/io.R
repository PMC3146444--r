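#' Read genotypes from a STRUCTURE-format text file
#'
#' Whitespace-delimited, no header.  Each row starts with the sample id,
#' the population label and (if `popflag = TRUE`) a 0/1 learning-sample
#' flag, followed by the genotype columns.  In the one-row dialect each
#' locus occupies two adjacent columns; in the two-row dialect each
#' individual occupies two consecutive rows with one column per locus.
#' Both alleles of a genotype equal to `missing_code` mark a missing locus.
#'
#' @param path file path
#' @param one_row_per_individual logical; `FALSE` selects the two-row dialect
#' @param missing_code integer missing-data code (default `-9`)
#' @param popflag logical; is a popflag column present after the population?
#' @param locus_names optional character vector of locus names
#' @return a [genotype_table()]
#' @export
read_structure_file <- function(path, one_row_per_individual = TRUE,
                                missing_code = -9L, popflag = TRUE,
                                locus_names = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty STRUCTURE file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  nfix <- 2L + as.integer(popflag)
  ncols <- lengths(toks)
  if (length(unique(ncols)) != 1L)
    stop("ragged rows in STRUCTURE file at line ",
         which(ncols != ncols[1])[1])
  ngeno <- ncols[1] - nfix
  if (ngeno < 1L) stop("no genotype columns found")

  if (one_row_per_individual) {
    if (ngeno %% 2L != 0L)
      stop("one-row dialect needs an even number of genotype columns ",
           "(2 per locus); got ", ngeno)
    L <- ngeno %/% 2L
    n <- length(toks)
    ids <- vapply(toks, `[[`, "", 1L)
    pops <- vapply(toks, `[[`, "", 2L)
    flags <- if (popflag) vapply(toks, `[[`, "", 3L) else rep("0", n)
    geno <- array(NA_integer_, dim = c(n, L, 2L))
    for (i in seq_len(n)) {
      v <- suppressWarnings(as.integer(toks[[i]][(nfix + 1L):ncols[1]]))
      if (anyNA(v)) stop("non-integer allele code at line ", i)
      geno[i, , 1] <- v[seq(1L, ngeno, by = 2L)]
      geno[i, , 2] <- v[seq(2L, ngeno, by = 2L)]
    }
  } else {
    if (length(toks) %% 2L != 0L)
      stop("two-row dialect needs an even number of rows; got ", length(toks))
    L <- ngeno
    n <- length(toks) %/% 2L
    ids <- character(n); pops <- character(n); flags <- character(n)
    geno <- array(NA_integer_, dim = c(n, L, 2L))
    for (i in seq_len(n)) {
      r1 <- toks[[2L * i - 1L]]; r2 <- toks[[2L * i]]
      if (r1[1] != r2[1])
        stop("two-row dialect: rows ", 2 * i - 1, "-", 2 * i,
             " have mismatched ids ('", r1[1], "' vs '", r2[1], "')")
      ids[i] <- r1[1]; pops[i] <- r1[2]
      flags[i] <- if (popflag) r1[3] else "0"
      a1 <- suppressWarnings(as.integer(r1[(nfix + 1L):ncols[1]]))
      a2 <- suppressWarnings(as.integer(r2[(nfix + 1L):ncols[1]]))
      if (anyNA(a1) || anyNA(a2)) stop("non-integer allele code near line ", 2 * i)
      geno[i, , 1] <- a1
      geno[i, , 2] <- a2
    }
  }
  if (!is.null(locus_names)) {
    if (length(locus_names) != L) stop("need ", L, " locus names")
    dimnames(geno) <- list(NULL, locus_names, NULL)
  }
  samples <- data.frame(id = ids, population = pops,
                        is_reference = flags == "1",
                        stringsAsFactors = FALSE)
  genotype_table(geno, samples, missing_code = missing_code)
}

#' Write a genotype table in STRUCTURE format
#'
#' @inheritParams read_structure_file
#' @param table a [genotype_table()]
#' @export
write_structure_file <- function(table, path, one_row_per_individual = TRUE,
                                 popflag = TRUE) {
  g <- table$geno
  g[is.na(g)] <- table$missing_code
  n <- n_samples(table); L <- n_loci(table)
  fixed <- cbind(table$samples$id, table$samples$population)
  if (popflag) fixed <- cbind(fixed, as.integer(table$samples$is_reference))
  if (one_row_per_individual) {
    body <- matrix("", nrow = n, ncol = 2L * L)
    body[, seq(1L, 2L * L, 2L)] <- as.character(g[, , 1])
    body[, seq(2L, 2L * L, 2L)] <- as.character(g[, , 2])
    out <- apply(cbind(fixed, body), 1, paste, collapse = " ")
  } else {
    out <- character(2L * n)
    for (i in seq_len(n)) {
      out[2L * i - 1L] <- paste(c(fixed[i, ], g[i, , 1]), collapse = " ")
      out[2L * i] <- paste(c(fixed[i, ], g[i, , 2]), collapse = " ")
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read genotypes from a GENEPOP-format text file
#'
#' Supports the 2- and 3-digit allele encodings; `"00"`/`"000"` decodes to
#' missing.  Population names are taken from the first sample id of each
#' `Pop` block.
#'
#' @param path file path
#' @return a [genotype_table()]
#' @export
read_genepop_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("truncated GENEPOP file: ", path)
  body <- lines[-1]  # drop title line
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no 'Pop' line found in ", path)
  header <- body[seq_len(first_pop - 1L)]
  # locus names: one per line, or a single comma-separated line
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  L <- length(loci)

  ids <- character(); pops <- character(); rows <- list()
  pop_name <- NA_character_
  digit_width <- rep(NA_integer_, L)
  for (ln in body[-seq_len(first_pop - 1L)]) {
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) {
      pop_name <- NA_character_
      next
    }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2L) stop("malformed GENEPOP sample line: ", ln)
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    if (length(codes) != L)
      stop("sample '", id, "' has ", length(codes), " genotype fields; expected ", L)
    if (is.na(pop_name)) pop_name <- id
    pair <- matrix(NA_integer_, nrow = L, ncol = 2L)
    for (l in seq_len(L)) {
      w <- nchar(codes[l]) / 2L
      if (!w %in% c(2L, 3L))
        stop("allele encoding at locus '", loci[l], "' for '", id,
             "' is neither 2- nor 3-digit: ", codes[l])
      if (is.na(digit_width[l])) digit_width[l] <- w
      if (digit_width[l] != w)
        stop("mixed 2/3-digit encoding within locus '", loci[l], "'")
      a1 <- as.integer(substr(codes[l], 1L, w))
      a2 <- as.integer(substr(codes[l], w + 1L, 2L * w))
      if (is.na(a1) || is.na(a2))
        stop("non-numeric genotype '", codes[l], "' for '", id, "'")
      if (a1 != 0L && a2 != 0L) pair[l, ] <- c(a1, a2)
      else if (a1 != 0L || a2 != 0L)
        stop("half-missing genotype '", codes[l], "' for '", id, "'")
    }
    ids <- c(ids, id); pops <- c(pops, pop_name)
    rows[[length(rows) + 1L]] <- pair
  }
  n <- length(rows)
  if (n == 0L) stop("no samples in GENEPOP file: ", path)
  geno <- array(NA_integer_, dim = c(n, L, 2L), dimnames = list(NULL, loci, NULL))
  for (i in seq_len(n)) geno[i, , ] <- rows[[i]]
  samples <- data.frame(id = ids, population = pops, stringsAsFactors = FALSE)
  genotype_table(geno, samples)
}

#' Write a genotype table in GENEPOP format
#'
#' @param table a [genotype_table()]
#' @param path file path
#' @param digits 2 or 3; width of each allele code (default 3)
#' @param title first line of the file
#' @export
write_genepop_file <- function(table, path, digits = 3L,
                               title = "genotype_table export") {
  if (!digits %in% c(2L, 3L)) stop("'digits' must be 2 or 3")
  lim <- 10L^digits - 1L
  rng <- range(unlist(table$alleles))
  if (length(unlist(table$alleles)) > 0 && (rng[1] < 1L || rng[2] > lim))
    stop("allele codes outside 1..", lim, " cannot be written with ",
         digits, "-digit encoding")
  g <- table$geno
  fmt <- function(a) ifelse(is.na(a), strrep("0", digits),
                            formatC(a, width = digits, flag = "0"))
  out <- c(title, table$loci)
  pops <- table$samples$population
  for (p in unique(pops)) {
    out <- c(out, "Pop")
    for (i in which(pops == p)) {
      codes <- paste0(fmt(g[i, , 1]), fmt(g[i, , 2]))
      out <- c(out, paste(table$samples$id[i], ",", paste(codes, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Attach sample metadata from a CSV file
#'
#' The CSV must have an `id` column and any of `population`, `species`,
#' `region`, `is_reference`; matching columns overwrite the table's
#' metadata for the listed samples.
#'
#' @param table a [genotype_table()]
#' @param path CSV path
#' @return the updated [genotype_table()]
#' @export
read_sample_metadata <- function(table, path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(meta$id)) stop("metadata CSV needs an 'id' column")
  m <- match(table$samples$id, as.character(meta$id))
  for (col in intersect(c("population", "species", "region", "is_reference"),
                        names(meta))) {
    hit <- !is.na(m)
    table$samples[[col]][hit] <- meta[[col]][m[hit]]
  }
  genotype_table(table$geno, table$samples, missing_code = table$missing_code)
}
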