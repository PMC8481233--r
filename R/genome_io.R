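#' Read a BED / narrowPeak peak file
#'
#' Coordinates are kept in the file's native 0-based half-open convention,
#' which is the single coordinate convention used throughout the package.
#'
#' @param path Path to a tab-separated file without header.
#' @param dialect One of `"bed3"`, `"bed6"`, `"narrowPeak"` (ENCODE 10-column).
#' @return A tibble of peaks with columns `chrom`, `start`, `end`, `name`,
#'   `score` and (narrowPeak only) `summit_offset`. Input order is preserved.
#' @export
read_bed <- function(path, dialect = c("bed6", "bed3", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  need <- switch(dialect, bed3 = 3L, bed6 = 6L, narrowPeak = 10L)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  name = character(0), score = double(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < need)) {
    abort(sprintf("line %d: expected >= %d columns for %s, found %d",
                  which(nf < need)[1], need, dialect, nf[which(nf < need)[1]]))
  }
  grab <- function(i) vapply(fields, `[[`, character(1), i)
  chrom <- grab(1)
  start <- suppressWarnings(as.integer(grab(2)))
  end <- suppressWarnings(as.integer(grab(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) abort(sprintf("line %d: non-integer coordinates", bad[1]))
  bad <- which(!(start >= 0 & start < end))
  if (length(bad) > 0) {
    abort(sprintf("line %d: invalid interval [%d, %d)", bad[1], start[bad[1]], end[bad[1]]))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  if (dialect == "bed3") {
    out$name <- paste0("peak_", seq_len(nrow(out)))
    out$score <- 0
  } else {
    out$name <- grab(4)
    score <- suppressWarnings(as.numeric(grab(5)))
    if (anyNA(score)) abort(sprintf("line %d: non-numeric score", which(is.na(score))[1]))
    if (any(score < 0)) abort(sprintf("line %d: negative score", which(score < 0)[1]))
    out$score <- score
  }
  if (dialect == "narrowPeak") {
    summit <- suppressWarnings(as.integer(grab(10)))
    summit[!is.na(summit) & summit < 0] <- NA_integer_
    bad <- which(!is.na(summit) & summit >= (end - start))
    if (length(bad) > 0) abort(sprintf("line %d: summit offset beyond peak end", bad[1]))
    out$summit_offset <- summit
  }
  out
}

#' Write peaks as BED6 or narrowPeak
#'
#' @param peaks Peak tibble as produced by [read_bed()].
#' @param path Output path.
#' @param dialect `"bed6"` or `"narrowPeak"`.
#' @export
write_bed <- function(peaks, path, dialect = c("bed6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  check_intervals(peaks, "peak")
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                   format(peaks$score, trim = TRUE, scientific = FALSE), ".")
  if (dialect == "narrowPeak") {
    summit <- if ("summit_offset" %in% names(peaks)) peaks$summit_offset else NA_integer_
    df <- cbind(df, 0, 0, 0, ifelse(is.na(summit), -1L, summit))
  }
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read a BEDPE loop list
#'
#' Anchors are canonicalised so the left anchor precedes the right anchor on
#' the chromosome. Inter-chromosomal rows are rejected when `intra_only` is
#' set (the default for loop lists) and otherwise kept.
#'
#' @param path Path to a whitespace-delimited BEDPE file (>= 6 columns).
#' @param intra_only Reject inter-chromosomal pairs?
#' @return Tibble with columns `chrom`, `start1`, `end1`, `start2`, `end2`,
#'   `name`.
#' @export
read_bedpe <- function(path, intra_only = TRUE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(0), start1 = integer(0), end1 = integer(0),
                  start2 = integer(0), end2 = integer(0), name = character(0)))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6)) abort(sprintf("line %d: BEDPE needs >= 6 columns", which(nf < 6)[1]))
  grab <- function(i) vapply(fields, `[[`, character(1), i)
  chrom1 <- grab(1); chrom2 <- grab(4)
  s1 <- as.integer(grab(2)); e1 <- as.integer(grab(3))
  s2 <- as.integer(grab(5)); e2 <- as.integer(grab(6))
  if (anyNA(c(s1, e1, s2, e2))) abort("non-integer coordinates in BEDPE")
  inter <- chrom1 != chrom2
  if (any(inter) && intra_only) {
    abort(sprintf("line %d: inter-chromosomal pair with intra_only = TRUE", which(inter)[1]))
  }
  swap <- chrom1 == chrom2 & s1 > s2
  out <- tibble(
    chrom = chrom1,
    start1 = ifelse(swap, s2, s1), end1 = ifelse(swap, e2, e1),
    start2 = ifelse(swap, s1, s2), end2 = ifelse(swap, e1, e2),
    name = if (any(nf >= 7)) grab(7) else paste0("loop_", seq_along(chrom1))
  )
  check_intervals(tibble(chrom = out$chrom, start = out$start1, end = out$end1), "left anchor")
  check_intervals(tibble(chrom = out$chrom, start = out$start2, end = out$end2), "right anchor")
  out
}

#' Write a loop list as BEDPE
#' @param loops Loop tibble as produced by [read_bedpe()].
#' @param path Output path.
#' @export
write_bedpe <- function(loops, path) {
  df <- data.frame(loops$chrom, loops$start1, loops$end1,
                   loops$chrom, loops$start2, loops$end2, loops$name)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Construct a binned contact matrix object
#'
#' @param mat Square symmetric numeric matrix of non-negative contact counts.
#' @param chrom Chromosome name.
#' @param resolution Bin width in base pairs.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(mat, chrom, resolution) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (any(mat < 0)) abort("contact matrix entries must be non-negative")
  if (max(abs(mat - t(mat))) > 0) abort("contact matrix must be symmetric")
  structure(list(chrom = chrom, resolution = as.integer(resolution), mat = mat),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins @ %d bp, total %.4g contacts\n",
              x$chrom, nrow(x$mat), x$resolution, sum(x$mat) - sum(diag(x$mat)) / 2))
  invisible(x)
}

#' Read a contact matrix from triplet text
#'
#' Each row is `chrom bin_i bin_j value` (whitespace-delimited, 0-based bin
#' indices). The matrix is filled symmetrically; absent pairs are zero and
#' duplicate triplets accumulate by summation, mirroring raw contact
#' aggregation.
#'
#' @param path Triplet file path.
#' @param chrom Chromosome the file describes (validated against column 1).
#' @param resolution Bin width in bp.
#' @param n_bins Number of bins on the chromosome.
#' @return A [contact_matrix()] object.
#' @export
read_contact_matrix <- function(path, chrom, resolution, n_bins) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("chrom", "i", "j", "value"),
                          colClasses = c("character", "integer", "integer", "numeric"))
  m <- matrix(0, n_bins, n_bins)
  if (nrow(df) > 0) {
    if (any(df$chrom != chrom)) abort("triplet chromosome does not match request")
    if (any(df$i < 0 | df$j < 0 | df$i >= n_bins | df$j >= n_bins)) {
      abort("bin index out of range")
    }
    if (any(df$value < 0)) abort("negative contact value")
    for (k in seq_len(nrow(df))) {
      i <- df$i[k] + 1L; j <- df$j[k] + 1L
      m[i, j] <- m[i, j] + df$value[k]
      if (i != j) m[j, i] <- m[j, i] + df$value[k]
    }
  }
  contact_matrix(m, chrom, resolution)
}

#' Write a contact matrix as triplet text (upper triangle, nonzero entries)
#' @param cm A [contact_matrix()] object.
#' @param path Output path.
#' @export
write_contact_matrix <- function(cm, path) {
  idx <- which(upper.tri(cm$mat, diag = TRUE) & cm$mat != 0, arr.ind = TRUE)
  df <- data.frame(chrom = cm$chrom, i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                   value = cm$mat[idx])
  df <- df[order(df$i, df$j), ]
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read a gene table
#'
#' Expects a TSV with header columns `gene_id`, `chrom`, `tss`, `strand`,
#' `expr_log2fc`, `de_flag`. `de_flag` must be one of up/down/ns
#' (case-insensitive when `normalize_case` is TRUE).
#'
#' @param path TSV path.
#' @param normalize_case Fold `de_flag` tokens to lower case before checking.
#' @return Tibble of gene records; duplicate `gene_id`s are an error.
#' @export
read_gene_table <- function(path, normalize_case = TRUE) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand", "expr_log2fc", "de_flag")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("gene table missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df[need])
  if (anyDuplicated(df$gene_id)) {
    abort(paste0("duplicated gene_id: ", df$gene_id[duplicated(df$gene_id)][1]))
  }
  if (any(df$tss < 0)) abort("negative TSS coordinate")
  if (!all(df$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  flag <- if (normalize_case) tolower(df$de_flag) else df$de_flag
  bad <- setdiff(unique(flag), c("up", "down", "ns"))
  if (length(bad) > 0) abort(paste0("unknown de_flag token: ", bad[1]))
  df$de_flag <- flag
  df
}

#' Write a gene table as TSV
#' @param genes Gene tibble (see [read_gene_table()]).
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  readr::write_tsv(genes, path)
  invisible(path)
}

#' Read a two-column ortholog map
#'
#' @param path TSV with header columns `mouse_id`, `human_id`.
#' @return Tibble with the two id columns.
#' @export
read_ortholog_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("mouse_id", "human_id") %in% names(df))) {
    abort("ortholog map needs columns mouse_id, human_id")
  }
  as_tibble(df[c("mouse_id", "human_id")])
}

#' Read a division-event table
#'
#' @param path TSV with header columns `plane`, `condition`, `animal_id`,
#'   `angle` and optionally `area_um2`.
#' @return Tibble of division events; angles must lie in \[0, 90\] degrees.
#' @export
read_division_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("plane", "condition", "animal_id", "angle")
  if (!all(need %in% names(df))) {
    abort("division table needs columns plane, condition, animal_id, angle")
  }
  if (any(df$angle < 0 | df$angle > 90)) abort("division angles must be in [0, 90]")
  as_tibble(df)
}
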