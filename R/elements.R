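#' Merge peaks reproducible across replicates
#'
#' Pools all replicate peak sets, clusters peaks that share at least
#' `min_overlap` bp, and keeps each cluster supported by peaks from at least
#' `min_support` distinct replicates. The returned interval is the union
#' across the supporting replicates, mirroring the convention of keeping
#' peaks identified in at least two replicate samples.
#'
#' Lowering `min_support` never removes a peak (monotonicity).
#'
#' @param peak_sets List of peak tibbles, one per replicate.
#' @param min_support Minimum number of distinct supporting replicates.
#' @param min_overlap Minimum shared bp for two peaks to co-cluster.
#' @return Peak tibble with columns `chrom`, `start`, `end`, `name`, `score`
#'   (max over cluster members) and `n_replicates`.
#' @export
reproducible_peaks <- function(peak_sets, min_support = 2L, min_overlap = 1L) {
  if (min_support < 1) abort("min_support must be >= 1")
  if (length(peak_sets) < min_support) {
    abort("fewer replicate sets than min_support")
  }
  pooled <- bind_rows(peak_sets, .id = ".replicate")
  if (nrow(pooled) == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  name = character(0), score = double(0), n_replicates = integer(0)))
  }
  if (!"score" %in% names(pooled)) pooled$score <- 0
  gr <- peaks_to_gr(pooled)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  support <- vapply(revmap, function(ix) length(unique(pooled$.replicate[ix])), integer(1))
  keep <- support >= min_support
  red <- red[keep]
  tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    name = paste0("rep_peak_", seq_len(sum(keep))),
    score = vapply(revmap[keep], function(ix) max(pooled$score[ix]), double(1)),
    n_replicates = support[keep]
  )
}

#' Classify regulatory elements by chromatin state
#'
#' Assigns each query element exactly one state by peak overlap, with
#' promoter precedence: an element overlapping an H3K4me3 peak is a
#' `promoter`; otherwise overlap with both H3K4me1 and H3K27ac makes an
#' `active_enhancer`, H3K4me1 alone a `poised_enhancer`, and anything else
#' `other`. Accessibility is overlap with an ATAC peak. Overlap means at
#' least `min_overlap` shared bp.
#'
#' @param elements Peak tibble of elements to classify (e.g. CHD7 binding
#'   sites).
#' @param atac,k4me3,k4me1,k27ac Peak tibbles for ATAC, H3K4me3, H3K4me1 and
#'   H3K27ac.
#' @param min_overlap Minimum shared bp (default 1).
#' @return The element tibble with added columns `element_id`, `state`
#'   (factor: promoter, active_enhancer, poised_enhancer, other) and
#'   `accessible`.
#' @export
classify_elements <- function(elements, atac, k4me3, k4me1, k27ac,
                              min_overlap = 1L) {
  if (nrow(elements) == 0) {
    warn("no elements supplied; returning empty classification")
  }
  has_me3 <- overlaps_any(elements, k4me3, min_overlap)
  has_me1 <- overlaps_any(elements, k4me1, min_overlap)
  has_ac <- overlaps_any(elements, k27ac, min_overlap)
  state <- dplyr::case_when(
    has_me3 ~ "promoter",
    has_me1 & has_ac ~ "active_enhancer",
    has_me1 ~ "poised_enhancer",
    TRUE ~ "other"
  )
  out <- elements
  out$element_id <- if ("name" %in% names(out)) out$name else paste0("el_", seq_len(nrow(out)))
  out$state <- factor(state, levels = element_states())
  out$accessible <- overlaps_any(elements, atac, min_overlap)
  out
}

element_states <- function() c("promoter", "active_enhancer", "poised_enhancer", "other")

#' Class proportions of a classified element set
#'
#' @param elements Output of [classify_elements()].
#' @return Tibble with `state`, `n` and `fraction`; fractions sum to one.
#' @export
class_proportions <- function(elements) {
  if (nrow(elements) == 0) abort("cannot compute proportions of an empty element set")
  counts <- table(factor(elements$state, levels = element_states()))
  tibble(state = names(counts), n = as.integer(counts),
         fraction = as.integer(counts) / nrow(elements))
}

#' Temporal activity states of enhancers
#'
#' Combines the early-timepoint enhancer state with a differential H3K27ac
#' result contrasting the late and early timepoints: early-active enhancers
#' with a significant H3K27ac decrease become `P4_specific`, other
#' early-active enhancers `P4_P22_active`; early-poised enhancers with a
#' significant increase become `P22_specific_active`, the rest
#' `unchanged_poised`. Non-enhancer elements receive `NA`.
#'
#' @param elements Classified elements with `element_id` and `state`.
#' @param k27ac_diff Differential result tibble (see
#'   [differential_regions()]) with a `region_id` column matching
#'   `element_id`.
#' @return `elements` with an added `temporal_state` column.
#' @export
temporal_states <- function(elements, k27ac_diff) {
  is_enh <- elements$state %in% c("active_enhancer", "poised_enhancer")
  missing_ids <- setdiff(elements$element_id[is_enh], k27ac_diff$region_id)
  if (length(missing_ids) > 0) {
    abort(paste0("enhancers missing from differential results: ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  d <- k27ac_diff[match(elements$element_id, k27ac_diff$region_id), ]
  temporal <- rep(NA_character_, nrow(elements))
  active <- elements$state == "active_enhancer"
  poised <- elements$state == "poised_enhancer"
  temporal[active] <- ifelse(d$direction[active] == "down", "P4_specific", "P4_P22_active")
  temporal[poised] <- ifelse(d$direction[poised] == "up", "P22_specific_active", "unchanged_poised")
  elements$temporal_state <- factor(
    temporal,
    levels = c("P4_specific", "P4_P22_active", "P22_specific_active", "unchanged_poised")
  )
  elements
}

#' Annotate RNAPII and CHD7 occupancy and summarise by binding stratum
#'
#' Adds `rnapii_bound` and `chd7_bound` overlap flags, then reports the
#' fraction of RNAPII-positive active enhancers within the bound and unbound
#' strata.
#'
#' @param elements Classified elements.
#' @param rnapii,chd7 Peak tibbles.
#' @param min_overlap Minimum shared bp.
#' @return List with `elements` (annotated tibble) and `summary` (tibble with
#'   one row per CHD7 stratum of active enhancers).
#' @export
annotate_occupancy <- function(elements, rnapii, chd7, min_overlap = 1L) {
  elements$rnapii_bound <- overlaps_any(elements, rnapii, min_overlap)
  elements$chd7_bound <- overlaps_any(elements, chd7, min_overlap)
  active <- filter(elements, .data$state == "active_enhancer")
  summary <- active %>%
    group_by(chd7_bound = .data$chd7_bound) %>%
    summarise(n = n(),
              fraction_rnapii = if (n() > 0) mean(.data$rnapii_bound) else 0,
              .groups = "drop")
  for (stratum in c(TRUE, FALSE)) {
    if (!stratum %in% summary$chd7_bound) {
      summary <- bind_rows(summary,
                           tibble(chd7_bound = stratum, n = 0L, fraction_rnapii = 0))
    }
  }
  list(elements = elements, summary = arrange(summary, dplyr::desc(.data$chd7_bound)))
}
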