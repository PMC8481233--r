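# Hi-C post-processing: domain/loop merging, loop-domain classification,
# observed/expected transforms, intradomain contact change, A/B compartment
# eigenvectors oriented by active-mark density, and E-P loop annotation.

#' Merge contact domains with nearby borders
#'
#' Two domains merge when both corresponding borders lie within `border_tol`
#' of each other (|startA - startB| <= tol AND |endA - endB| <= tol); the
#' merged interval is (min start, max end). Applied to a fixpoint, so the
#' result is idempotent. Merging on a single border would chain unrelated
#' domains, hence the two-border rule.
#'
#' @param domains Domain tibble (`chrom`, `start`, `end`) on one chromosome.
#' @param border_tol Border tolerance in bp (default 20000).
#' @return Merged domain tibble, sorted by start.
#' @export
merge_domains <- function(domains, border_tol = 20000) {
  if (border_tol < 0) abort("border_tol must be non-negative")
  if (length(unique(domains$chrom)) > 1) abort("merge_domains expects one chromosome")
  d <- arrange(domains, .data$start, .data$end)
  repeat {
    merged <- FALSE
    n <- nrow(d)
    if (n < 2) break
    for (i in seq_len(n - 1)) {
      js <- which(abs(d$start - d$start[i]) <= border_tol &
                    abs(d$end - d$end[i]) <= border_tol)
      js <- setdiff(js, i)
      if (length(js) > 0) {
        j <- js[1]
        d$start[i] <- min(d$start[i], d$start[j])
        d$end[i] <- max(d$end[i], d$end[j])
        d <- d[-j, ]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
    d <- arrange(d, .data$start, .data$end)
  }
  d
}

loop_mids <- function(loops) {
  tibble(left = interval_mid(loops$start1, loops$end1),
         right = interval_mid(loops$start2, loops$end2))
}

#' Merge loop lists from two conditions
#'
#' A control loop and a knockout loop merge when both the left-anchor
#' midpoints and the right-anchor midpoints are within `anchor_tol`.
#' Conflicts are resolved greedily by the smallest combined anchor distance;
#' merged anchors are the union of the two anchor intervals. Unmatched loops
#' pass through tagged by their source condition.
#'
#' @param ctrl,ko Loop tibbles (see [read_bedpe()]).
#' @param anchor_tol Anchor midpoint tolerance in bp (default 10000).
#' @return Loop tibble with a `source` column (`both`, `ctrl`, `ko`).
#' @export
merge_loops <- function(ctrl, ko, anchor_tol = 10000) {
  if (anchor_tol < 0) abort("anchor_tol must be non-negative")
  mc <- loop_mids(ctrl); mk <- loop_mids(ko)
  cand <- list()
  for (i in seq_len(nrow(ctrl))) {
    same <- which(ko$chrom == ctrl$chrom[i])
    if (length(same) == 0) next
    dl <- abs(mk$left[same] - mc$left[i])
    dr <- abs(mk$right[same] - mc$right[i])
    ok <- dl <= anchor_tol & dr <= anchor_tol
    if (any(ok)) {
      cand[[length(cand) + 1]] <- tibble(i = i, j = same[ok], d = dl[ok] + dr[ok])
    }
  }
  cand <- if (length(cand) > 0) bind_rows(cand) else tibble(i = integer(0), j = integer(0), d = double(0))
  cand <- arrange(cand, .data$d, .data$i, .data$j)
  used_i <- logical(nrow(ctrl)); used_j <- logical(nrow(ko))
  pairs <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used_i[i] && !used_j[j]) {
      used_i[i] <- TRUE; used_j[j] <- TRUE
      pairs[[length(pairs) + 1]] <- c(i, j)
    }
  }
  merged <- purrr::map(pairs, function(p) {
    i <- p[1]; j <- p[2]
    tibble(
      chrom = ctrl$chrom[i],
      start1 = min(ctrl$start1[i], ko$start1[j]), end1 = max(ctrl$end1[i], ko$end1[j]),
      start2 = min(ctrl$start2[i], ko$start2[j]), end2 = max(ctrl$end2[i], ko$end2[j]),
      name = paste0(ctrl$name[i], "|", ko$name[j]),
      source = "both"
    )
  })
  out <- bind_rows(
    bind_rows(merged),
    mutate(ctrl[!used_i, ], source = "ctrl"),
    mutate(ko[!used_j, ], source = "ko")
  )
  arrange(out, .data$chrom, .data$start1, .data$start2)
}

#' Classify contact domains as loop or compartmental domains
#'
#' A domain is a `loop_domain` when some loop has its left-anchor midpoint
#' within `tol` of the domain's left border and its right-anchor midpoint
#' within `tol` of the right border; all other domains are
#' `compartmental_domain`s, so the two classes partition the input.
#'
#' @param domains Domain tibble.
#' @param loops Loop tibble.
#' @param tol Border-to-anchor tolerance in bp (default 25000).
#' @return `domains` with a `domain_class` column.
#' @export
classify_loop_domains <- function(domains, loops, tol = 25000) {
  if (tol < 0) abort("tol must be non-negative")
  mids <- loop_mids(loops)
  is_loop_domain <- vapply(seq_len(nrow(domains)), function(i) {
    same <- loops$chrom == domains$chrom[i]
    any(same &
          abs(mids$left - domains$start[i]) <= tol &
          abs(mids$right - domains$end[i]) <= tol)
  }, logical(1))
  mutate(domains, domain_class = ifelse(is_loop_domain, "loop_domain", "compartmental_domain"))
}

# Coverage = bins with any off-diagonal signal.
covered_bins <- function(mat) {
  rs <- rowSums(mat) - diag(mat)
  rs > 0
}

#' Observed/expected transform of a contact matrix
#'
#' Expected contact at separation d is the mean over all entries on diagonal
#' d restricted to covered bins (the standard distance-decay expectation).
#' Entries involving uncovered bins, or diagonals with zero mean, are `NA`.
#' The transform is invariant to uniform rescaling of the matrix.
#'
#' @param cm A [contact_matrix()] object.
#' @return A `contact_matrix`-like object of class `oe_matrix` with fields
#'   `mat` (O/E values), `expected` (per-diagonal means) and `covered`.
#' @export
observed_expected <- function(cm) {
  m <- cm$mat
  n <- nrow(m)
  cov <- covered_bins(m)
  sep <- abs(row(m) - col(m))
  both <- outer(cov, cov, "&")
  expected <- rep(NA_real_, n)
  means <- tapply(m[both], sep[both], mean)
  expected[as.integer(names(means)) + 1L] <- as.numeric(means)
  oe <- m / expected[sep + 1L]
  oe[!both] <- NA_real_
  oe[is.infinite(oe)] <- NA_real_
  structure(list(chrom = cm$chrom, resolution = cm$resolution,
                 mat = oe, expected = expected, covered = cov),
            class = "oe_matrix")
}

# Leading eigenvector of a symmetric matrix with a deterministic sign
# (largest-magnitude entry positive) and an eigenvalue-gap warning. This
# step is permutation-equivariant: permuting the matrix permutes the vector.
leading_eigen <- function(cc, gap_warn_ratio = 1.2) {
  eg <- eigen(cc, symmetric = TRUE)
  v <- eg$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  if (eg$values[2] > 0 && eg$values[1] / eg$values[2] < gap_warn_ratio) {
    warn(sprintf("eigenvalue gap ratio %.3f below %.2f: compartment call may be unstable",
                 eg$values[1] / eg$values[2], gap_warn_ratio))
  }
  v
}

domain_bins <- function(domain, resolution, n_bins) {
  lo <- floor(domain$start / resolution) + 1L
  hi <- ceiling(domain$end / resolution)
  seq.int(max(1L, lo), min(n_bins, hi))
}

#' Intradomain contact-frequency change between conditions
#'
#' Mean O/E over all intradomain bin pairs (i < j) per condition, returned
#' as `log2(mean_ko / mean_ctrl)`. Because the O/E transform divides out any
#' global scale, the statistic is invariant to uniform rescaling of either
#' matrix and antisymmetric under swapping conditions.
#'
#' @param m_ko,m_ctrl [contact_matrix()] objects on the same chromosome and
#'   binning.
#' @param domain One-row domain tibble (`chrom`, `start`, `end`).
#' @return The log2 contact-frequency change (a single number).
#' @export
intradomain_change <- function(m_ko, m_ctrl, domain) {
  oe_k <- observed_expected(m_ko)
  oe_c <- observed_expected(m_ctrl)
  intradomain_change_oe(oe_k, oe_c, domain)
}

# Workhorse taking precomputed O/E objects (cheap when scanning many domains).
intradomain_change_oe <- function(oe_k, oe_c, domain) {
  bins <- domain_bins(domain, oe_k$resolution, nrow(oe_k$mat))
  bins_k <- bins[oe_k$covered[bins]]
  bins_c <- bins[oe_c$covered[bins]]
  if (length(bins_k) < 2 || length(bins_c) < 2) {
    abort("domain covers fewer than 2 bins with signal")
  }
  pair_mean <- function(oe, b) {
    sub <- oe$mat[b, b, drop = FALSE]
    mean(sub[upper.tri(sub)], na.rm = TRUE)
  }
  log2(pair_mean(oe_k, bins_k) / pair_mean(oe_c, bins_c))
}

#' Domain-level signal change from peak fold-changes
#'
#' log2 of the mean linear-scale fold-change across peaks whose midpoint
#' lies inside the domain.
#'
#' @param peak_diffs Differential result tibble carrying `chrom`, `start`,
#'   `end` and `log2fc` per peak.
#' @param domain One-row domain tibble.
#' @return The log2 mean fold-change, or `NA` (with a warning) when no peak
#'   midpoint falls in the domain.
#' @export
domain_signal_change <- function(peak_diffs, domain) {
  mid <- interval_mid(peak_diffs$start, peak_diffs$end)
  inside <- peak_diffs$chrom == domain$chrom & mid >= domain$start & mid < domain$end
  if (!any(inside)) {
    warn("no peaks inside domain; returning NA")
    return(NA_real_)
  }
  log2(mean(2^peak_diffs$log2fc[inside]))
}

#' Leading-eigenvector compartment track of a contact matrix
#'
#' Drops zero-coverage bins, applies the O/E transform, computes the Pearson
#' correlation matrix of O/E columns and takes the eigenvector of the
#' largest eigenvalue. Covered-bin values are L2-normalised; the global sign
#' is arbitrary until [orient_eigenvector()] fixes it, but is made
#' deterministic by forcing the largest-magnitude entry positive. A warning
#' is raised when the ratio of the top two eigenvalues falls below
#' `gap_warn_ratio`, indicating an unstable block structure.
#'
#' @param cm A [contact_matrix()] object.
#' @param gap_warn_ratio Eigenvalue-gap warning threshold (default 1.2).
#' @return An `eigen_track` tibble with `chrom`, `bin`, `start`, `end`,
#'   `value` (NA on uncovered bins).
#' @export
compartment_eigenvector <- function(cm, gap_warn_ratio = 1.2) {
  oe <- observed_expected(cm)
  cov <- oe$covered
  if (sum(cov) < 3) abort("need at least 3 covered bins")
  sub <- oe$mat[cov, cov, drop = FALSE]
  sub[is.na(sub)] <- 1  # neutral O/E for missing diagonals
  cc <- suppressWarnings(cor(sub))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  v <- leading_eigen(cc, gap_warn_ratio)
  n <- nrow(cm$mat)
  value <- rep(NA_real_, n)
  value[cov] <- v
  track <- tibble(
    chrom = cm$chrom,
    bin = seq_len(n) - 1L,
    start = (seq_len(n) - 1L) * cm$resolution,
    end = seq_len(n) * cm$resolution,
    value = value
  )
  class(track) <- c("eigen_track", class(track))
  attr(track, "resolution") <- cm$resolution
  track
}

#' Orient an eigenvector track by active-mark density
#'
#' Flips the global sign so the track correlates positively with per-bin
#' H3K4me3 peak counts, anchoring the positive (A, euchromatic) compartment
#' to active-mark-dense bins.
#'
#' @param track `eigen_track` tibble from [compartment_eigenvector()].
#' @param k4me3_counts Numeric vector of H3K4me3 peak counts per bin (same
#'   length as the track).
#' @return The oriented track.
#' @export
orient_eigenvector <- function(track, k4me3_counts) {
  if (length(k4me3_counts) != nrow(track)) {
    abort("k4me3_counts must have one value per bin")
  }
  cov <- !is.na(track$value)
  if (var(k4me3_counts[cov]) == 0) {
    abort("active-mark counts have zero variance; orientation impossible")
  }
  r <- cor(track$value[cov], k4me3_counts[cov])
  if (!is.na(r) && r < 0) track$value <- -track$value
  track
}

#' Call A/B compartments from an oriented eigenvector track
#'
#' @param track Oriented `eigen_track` tibble.
#' @return The track with a `compartment` column: `A` for positive values,
#'   `B` for negative, `NA` on uncovered bins.
#' @export
call_compartments <- function(track) {
  track$compartment <- ifelse(is.na(track$value), NA_character_,
                              ifelse(track$value > 0, "A", "B"))
  track
}

#' Pearson correlation between two eigenvector tracks
#'
#' Computed over bins covered in both tracks.
#'
#' @param a,b `eigen_track` tibbles on the same binning.
#' @return Pearson correlation coefficient.
#' @export
eigen_correlation <- function(a, b) {
  if (nrow(a) != nrow(b)) abort("tracks differ in bin count")
  cov <- !is.na(a$value) & !is.na(b$value)
  if (sum(cov) < 3) abort("fewer than 3 jointly covered bins")
  cor(a$value[cov], b$value[cov])
}

#' Annotate enhancer-promoter loops
#'
#' Retains loops with at least one enhancer-state element in one anchor and
#' at least one promoter peak in the paired anchor, and expands each
#' retained loop into its (enhancer, promoter) pairs.
#'
#' @param loops Loop tibble.
#' @param elements Classified element tibble ([classify_elements()]); only
#'   `active_enhancer`/`poised_enhancer` states count as enhancers.
#' @param promoters Promoter peak tibble whose `name` identifies the gene.
#' @return Tibble with one row per (loop, enhancer, promoter) pair:
#'   loop coordinates plus `element_id`, `promoter_name`, and which anchor
#'   held the enhancer.
#' @export
annotate_ep_loops <- function(loops, elements, promoters) {
  enh <- filter(elements, .data$state %in% c("active_enhancer", "poised_enhancer"))
  anchor <- function(side) {
    s <- if (side == "left") loops$start1 else loops$start2
    e <- if (side == "left") loops$end1 else loops$end2
    tibble(chrom = loops$chrom, start = s, end = e)
  }
  out <- list()
  for (enh_side in c("left", "right")) {
    prom_side <- if (enh_side == "left") "right" else "left"
    he <- overlap_pairs(anchor(enh_side), enh)
    hp <- overlap_pairs(anchor(prom_side), promoters)
    joint <- inner_join(he, hp, by = "query", relationship = "many-to-many",
                        suffix = c("_enh", "_prom"))
    if (nrow(joint) > 0) {
      out[[enh_side]] <- dplyr::bind_cols(
        loops[joint$query, c("chrom", "start1", "end1", "start2", "end2", "name")],
        tibble(
          element_id = enh$element_id[joint$subject_enh],
          promoter_name = promoters$name[joint$subject_prom],
          enhancer_anchor = enh_side
        )
      )
    }
  }
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(chrom = character(0), start1 = integer(0), end1 = integer(0),
                  start2 = integer(0), end2 = integer(0), name = character(0),
                  element_id = character(0), promoter_name = character(0),
                  enhancer_anchor = character(0)))
  }
  distinct(arrange(out, .data$chrom, .data$start1, .data$element_id, .data$promoter_name))
}
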