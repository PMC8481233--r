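# Brute-force oracles and random-instance generators. The oracles use plain
# nested loops over all pairs and never share code with the implementation
# paths they check.

bp_overlap <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 & pmax(s1, s2) < pmin(e1, e2)
}

hits_any <- function(q, i, subject) {
  any(bp_overlap(q$chrom[i], q$start[i], q$end[i],
                 subject$chrom, subject$start, subject$end))
}

oracle_classify <- function(elements, atac, k4me3, k4me1, k27ac) {
  n <- nrow(elements)
  state <- character(n); accessible <- logical(n)
  for (i in seq_len(n)) {
    me3 <- nrow(k4me3) > 0 && hits_any(elements, i, k4me3)
    me1 <- nrow(k4me1) > 0 && hits_any(elements, i, k4me1)
    ac <- nrow(k27ac) > 0 && hits_any(elements, i, k27ac)
    state[i] <- if (me3) "promoter" else if (me1 && ac) "active_enhancer" else
      if (me1) "poised_enhancer" else "other"
    accessible[i] <- nrow(atac) > 0 && hits_any(elements, i, atac)
  }
  list(state = state, accessible = accessible)
}

oracle_link_by_tad <- function(elements, genes, domains, max_dist = 1e5) {
  out <- list()
  for (i in seq_len(nrow(elements))) {
    mid <- (elements$start[i] + elements$end[i]) / 2
    dom <- NA
    for (d in seq_len(nrow(domains))) {
      if (domains$chrom[d] == elements$chrom[i] &&
          mid >= domains$start[d] && mid < domains$end[d]) dom <- d
    }
    if (is.na(dom)) next
    best <- NULL; best_d <- Inf
    for (g in seq_len(nrow(genes))) {
      if (genes$chrom[g] != domains$chrom[dom]) next
      if (!(genes$tss[g] >= domains$start[dom] && genes$tss[g] < domains$end[dom])) next
      dd <- abs(genes$tss[g] - mid)
      if (dd > max_dist) next
      if (dd < best_d || (dd == best_d && genes$gene_id[g] < genes$gene_id[best])) {
        best <- g; best_d <- dd
      }
    }
    if (!is.null(best)) {
      out[[length(out) + 1]] <- data.frame(element_id = elements$element_id[i],
                                           gene_id = genes$gene_id[best],
                                           distance = best_d)
    }
  }
  if (length(out) == 0) {
    return(data.frame(element_id = character(0), gene_id = character(0),
                      distance = double(0)))
  }
  do.call(rbind, out)
}

oracle_ep_loops <- function(loops, elements, promoters) {
  enh <- elements[elements$state %in% c("active_enhancer", "poised_enhancer"), ]
  keys <- character(0)
  for (i in seq_len(nrow(loops))) {
    for (sides in list(c("L", "R"), c("R", "L"))) {
      a_s <- if (sides[1] == "L") loops$start1[i] else loops$start2[i]
      a_e <- if (sides[1] == "L") loops$end1[i] else loops$end2[i]
      p_s <- if (sides[2] == "L") loops$start1[i] else loops$start2[i]
      p_e <- if (sides[2] == "L") loops$end1[i] else loops$end2[i]
      for (e in seq_len(nrow(enh))) {
        if (!bp_overlap(loops$chrom[i], a_s, a_e, enh$chrom[e], enh$start[e], enh$end[e])) next
        for (p in seq_len(nrow(promoters))) {
          if (bp_overlap(loops$chrom[i], p_s, p_e,
                         promoters$chrom[p], promoters$start[p], promoters$end[p])) {
            keys <- c(keys, paste(loops$name[i], enh$element_id[e], promoters$name[p]))
          }
        }
      }
    }
  }
  sort(unique(keys))
}

# Independent greedy re-derivation of the loop-merge rule: repeatedly take
# the globally closest eligible (ctrl, ko) pair by combined midpoint
# distance.
oracle_merge_loops <- function(ctrl, ko, tol = 10000) {
  midl <- function(x) (x$start1 + x$end1) / 2
  midr <- function(x) (x$start2 + x$end2) / 2
  avail_c <- rep(TRUE, nrow(ctrl)); avail_k <- rep(TRUE, nrow(ko))
  pairs <- list()
  repeat {
    best <- NULL; best_d <- Inf
    for (i in which(avail_c)) for (j in which(avail_k)) {
      if (ctrl$chrom[i] != ko$chrom[j]) next
      dl <- abs(midl(ctrl)[i] - midl(ko)[j]); dr <- abs(midr(ctrl)[i] - midr(ko)[j])
      if (dl <= tol && dr <= tol) {
        d <- dl + dr
        if (d < best_d || (d == best_d && (is.null(best) || i < best[1] ||
                                           (i == best[1] && j < best[2])))) {
          best <- c(i, j); best_d <- d
        }
      }
    }
    if (is.null(best)) break
    avail_c[best[1]] <- FALSE; avail_k[best[2]] <- FALSE
    pairs[[length(pairs) + 1]] <- best
  }
  pairs
}

# ---- random instance generators ------------------------------------------

rand_peaks <- function(n, chrom = "chr1", span = 10000, width = c(50, 400),
                       id_prefix = "p") {
  if (n == 0) {
    return(tibble::tibble(chrom = character(0), start = integer(0), end = integer(0),
                          name = character(0), score = double(0)))
  }
  start <- sample.int(span, n, replace = TRUE)
  w <- sample(width[1]:width[2], n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = start, end = start + w,
                 name = paste0(id_prefix, seq_len(n)), score = runif(n, 1, 10))
}

rand_loops <- function(n, chrom = "chr1", span = 1e6, anchor = 5000) {
  s1 <- sample.int(span, n, replace = TRUE)
  gap <- sample(5e4:3e5, n, replace = TRUE)
  tibble::tibble(chrom = chrom, start1 = s1, end1 = s1 + anchor,
                 start2 = s1 + gap, end2 = s1 + gap + anchor,
                 name = paste0("lp", seq_len(n)))
}

rand_domains <- function(n, chrom = "chr1", size = c(3, 10), unit = 1e4) {
  sizes <- sample(size[1]:size[2], n, replace = TRUE) * unit
  start <- cumsum(c(0, sizes[-n]))
  tibble::tibble(chrom = chrom, start = start, end = start + sizes,
                 domain_id = paste0("d", seq_len(n)))
}
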