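# Cross-species target-set construction and hypergeometric overlap testing.

#' Map peaks to their nearest target genes
#'
#' Applies the nearest-gene rule of [link_by_tad()]: each peak links to the
#' single nearest gene whose TSS lies within `max_dist` of the peak
#' midpoint, additionally requiring shared TAD membership when a domain
#' list is supplied (the mouse mode); without domains only the distance rule
#' applies (the human mode). Returns the deduplicated set of linked gene
#' ids.
#'
#' @param peaks Peak tibble.
#' @param genes Gene tibble.
#' @param domains Optional non-overlapping domain tibble.
#' @param max_dist Maximum midpoint-to-TSS distance (default 100000).
#' @return Character vector of unique target gene ids.
#' @export
map_targets <- function(peaks, genes, domains = NULL, max_dist = 100000) {
  peaks$element_id <- if ("name" %in% names(peaks)) peaks$name else paste0("pk_", seq_len(nrow(peaks)))
  if (!is.null(domains)) {
    links <- link_by_tad(peaks, genes, domains, max_dist)
    return(sort(unique(links$gene_id)))
  }
  mid <- interval_mid(peaks$start, peaks$end)
  targets <- character(0)
  for (i in seq_len(nrow(peaks))) {
    cand <- which(genes$chrom == peaks$chrom[i] & abs(genes$tss - mid[i]) <= max_dist)
    if (length(cand) == 0) next
    dist <- abs(genes$tss[cand] - mid[i])
    targets <- c(targets, genes$gene_id[cand[order(dist, genes$gene_id[cand])][1]])
  }
  sort(unique(targets))
}

#' Restrict target sets to one-to-one orthologs and count the overlap
#'
#' Both target sets and the universe are restricted to genes present in the
#' ortholog map; human ids are translated to mouse ids. Many-to-many
#' ortholog rows are an error unless `one_to_one = TRUE`, which drops every
#' gene involved in a non-unique mapping first.
#'
#' @param mouse_targets,human_targets Character vectors of gene ids (mouse
#'   and human id space respectively).
#' @param ortholog_map Tibble with `mouse_id`, `human_id` columns.
#' @param universe Character vector of mouse gene ids forming the background
#'   (e.g. all expressed genes).
#' @param one_to_one Silently filter to one-to-one pairs first?
#' @return List with the hypergeometric parameters `k` (overlap), `K`
#'   (mouse set size), `n` (human set size), `N` (universe size).
#' @export
intersect_orthologs <- function(mouse_targets, human_targets, ortholog_map,
                                universe, one_to_one = TRUE) {
  map <- ortholog_map
  dup <- duplicated(map$mouse_id) | duplicated(map$mouse_id, fromLast = TRUE) |
    duplicated(map$human_id) | duplicated(map$human_id, fromLast = TRUE)
  if (any(dup)) {
    if (!one_to_one) abort("ortholog map contains many-to-many rows")
    map <- map[!dup, ]
  }
  universe <- intersect(universe, map$mouse_id)
  mouse_set <- intersect(mouse_targets, universe)
  human_as_mouse <- map$mouse_id[match(human_targets, map$human_id)]
  human_set <- intersect(human_as_mouse[!is.na(human_as_mouse)], universe)
  list(k = length(intersect(mouse_set, human_set)),
       K = length(mouse_set), n = length(human_set), N = length(universe))
}

#' Hypergeometric overlap (enrichment) test
#'
#' Upper-tail probability of drawing at least `k` shared genes when a set of
#' size `n` is drawn without replacement from a universe of `N` genes of
#' which `K` belong to the first set.
#'
#' @param k Observed overlap.
#' @param K Size of set 1.
#' @param n Size of set 2.
#' @param N Universe size.
#' @param alternative `"enrichment"` (upper tail, default) or
#'   `"depletion"` (lower tail).
#' @return Object of class `overlap_result` with the parameters,
#'   `fraction_of_set1 = k / K` and `p_value`.
#' @export
hypergeom_overlap <- function(k, K, n, N, alternative = c("enrichment", "depletion")) {
  alternative <- match.arg(alternative)
  if (k > min(K, n) || K > N || n > N || any(c(k, K, n, N) < 0)) {
    abort("invalid hypergeometric parameters: need k <= min(K, n) and K, n <= N")
  }
  p <- if (alternative == "enrichment") {
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    phyper(k, K, N - K, n, lower.tail = TRUE)
  }
  structure(list(k = k, K = K, n = n, N = N,
                 fraction_of_set1 = if (K > 0) k / K else NA_real_,
                 p_value = p, alternative = alternative),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Hypergeometric overlap: k = %d of K = %d vs n = %d in N = %d\n",
              x$k, x$K, x$n, x$N))
  cat(sprintf("fraction of set 1 shared = %.3f, p (%s) = %.4g\n",
              x$fraction_of_set1, x$alternative, x$p_value))
  invisible(x)
}
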