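#' Counts-per-million normalisation
#'
#' Scales each replicate column to one million, then (optionally) applies
#' `log2(cpm + pseudocount)`.
#'
#' @param counts Tibble with a `region_id` column followed by numeric
#'   replicate columns, or a plain numeric matrix.
#' @param log Return log2-transformed values?
#' @param pseudocount Added before the log transform (default 0.5).
#' @return Same shape as the input, normalised.
#' @export
cpm_normalize <- function(counts, log = TRUE, pseudocount = 0.5) {
  m <- counts_matrix(counts)
  lib <- colSums(m)
  if (any(lib == 0)) {
    abort(paste0("library size is zero for column: ",
                 colnames(m)[which(lib == 0)[1]]))
  }
  cpm <- sweep(m, 2, lib, "/") * 1e6
  if (log) cpm <- log2(cpm + pseudocount)
  counts_restore(cpm, counts)
}

counts_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  m <- as.matrix(counts[setdiff(names(counts), "region_id")])
  rownames(m) <- counts$region_id
  m
}

counts_restore <- function(m, template) {
  if (is.matrix(template)) return(m)
  out <- as_tibble(m)
  out <- tibble(region_id = template$region_id, !!!out)
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  n <- length(p)
  ord <- order(p, decreasing = TRUE)
  ranked <- n / seq(n, 1) * p[ord]
  q <- pmin(1, cummin(ranked))
  q[order(ord)]
}

#' Replicate-level differential signal between conditions
#'
#' A transparent stand-in for count-model differential callers: per region,
#' the log2 fold-change of mean CPM (pseudocount 0.5) and a two-sided Welch
#' t-test on `log2(cpm + 0.5)`, followed by Benjamini-Hochberg adjustment
#' across all regions. Direction is `up`/`down` for regions with
#' `fdr < alpha`, `ns` otherwise. Swapping the two arms negates `log2fc`
#' exactly.
#'
#' @param ctrl,ko Count tables (tibble with `region_id` + replicate columns,
#'   or matrices with matching rows); at least 2 replicates per arm.
#' @param alpha Significance threshold on the FDR (default 0.05).
#' @param pseudocount Pseudocount for the fold-change (default 0.5).
#' @return Tibble with `region_id`, `log2fc` (knockout over control),
#'   `p_value`, `fdr`, `direction`.
#' @export
differential_regions <- function(ctrl, ko, alpha = 0.05, pseudocount = 0.5) {
  mc <- counts_matrix(ctrl)
  mk <- counts_matrix(ko)
  if (ncol(mc) < 2 || ncol(mk) < 2) abort("need at least 2 replicates per arm")
  if (nrow(mc) != nrow(mk)) abort("control and knockout tables differ in regions")
  region_id <- if (!is.matrix(ctrl)) ctrl$region_id else rownames(mc)
  if (is.null(region_id)) region_id <- paste0("region_", seq_len(nrow(mc)))
  cpm_c <- sweep(mc, 2, colSums(mc), "/") * 1e6
  cpm_k <- sweep(mk, 2, colSums(mk), "/") * 1e6
  log2fc <- log2((rowMeans(cpm_k) + pseudocount) / (rowMeans(cpm_c) + pseudocount))
  w <- row_welch(log2(cpm_c + pseudocount), log2(cpm_k + pseudocount))
  fdr <- bh_fdr(w$p_value)
  tibble(
    region_id = region_id,
    log2fc = log2fc,
    p_value = w$p_value,
    fdr = fdr,
    direction = ifelse(fdr < alpha, ifelse(log2fc > 0, "up", "down"), "ns")
  )
}

#' Direction split among significant regions
#'
#' @param results Differential result tibble.
#' @param subset Optional logical vector selecting a subset of rows (e.g.
#'   bound active enhancers).
#' @return Tibble with one row per direction (`down`, `up`), counts and
#'   fractions among significant results; fractions sum to one.
#' @export
direction_fractions <- function(results, subset = NULL) {
  if (!is.null(subset)) results <- results[subset, ]
  sig <- filter(results, .data$direction != "ns")
  if (nrow(sig) == 0) abort("no significant regions in the requested subset")
  tibble(
    direction = c("down", "up"),
    n = c(sum(sig$direction == "down"), sum(sig$direction == "up"))
  ) %>% mutate(fraction = .data$n / sum(.data$n))
}
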