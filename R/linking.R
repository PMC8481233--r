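# Enhancer-gene linking under TAD/loop constraints and the concordance
# statistics built on those links.

element_domain_index <- function(x_chrom, x_pos, domains) {
  # Index of the half-open domain containing each position, NA when outside
  # every domain. Domains must be non-overlapping.
  idx <- rep(NA_integer_, length(x_pos))
  for (i in seq_len(nrow(domains))) {
    hit <- x_chrom == domains$chrom[i] &
      x_pos >= domains$start[i] & x_pos < domains$end[i]
    idx[hit] <- i
  }
  idx
}

check_nonoverlapping <- function(domains) {
  d <- arrange(domains, .data$chrom, .data$start)
  by_chrom <- split(d, d$chrom)
  for (dd in by_chrom) {
    if (nrow(dd) > 1 && any(dd$start[-1] < dd$end[-nrow(dd)])) {
      abort("domains overlap; run merge_domains first (TAD membership would be ambiguous)")
    }
  }
  invisible(domains)
}

#' Link elements to their nearest gene within the same TAD
#'
#' For each element, candidate genes must have their TSS within `max_dist`
#' of the element midpoint AND inside the same (half-open) domain that
#' contains the midpoint. The single nearest candidate is linked; ties break
#' to the lexicographically smallest `gene_id`. Elements outside all domains
#' or without candidates are left unlinked.
#'
#' @param elements Classified element tibble (needs `element_id`, `chrom`,
#'   `start`, `end`; extra columns such as `chd7_bound` are carried through).
#' @param genes Gene tibble (see [read_gene_table()]).
#' @param domains Non-overlapping domain tibble (after [merge_domains()]).
#' @param max_dist Maximum midpoint-to-TSS distance in bp (default 100000).
#' @return Link tibble: element columns plus `gene_id`, `distance`,
#'   `mode = "tad_nearest"`, `same_tad = TRUE`.
#' @export
link_by_tad <- function(elements, genes, domains, max_dist = 100000) {
  check_nonoverlapping(domains)
  mid <- interval_mid(elements$start, elements$end)
  el_dom <- element_domain_index(elements$chrom, mid, domains)
  gene_dom <- element_domain_index(genes$chrom, genes$tss, domains)
  links <- list()
  for (i in seq_len(nrow(elements))) {
    if (is.na(el_dom[i])) next
    cand <- which(!is.na(gene_dom) & gene_dom == el_dom[i] &
                    abs(genes$tss - mid[i]) <= max_dist)
    if (length(cand) == 0) next
    dist <- abs(genes$tss[cand] - mid[i])
    best <- cand[order(dist, genes$gene_id[cand])][1]
    links[[length(links) + 1]] <- dplyr::bind_cols(
      elements[i, , drop = FALSE],
      tibble(gene_id = genes$gene_id[best],
             distance = abs(genes$tss[best] - mid[i]),
             mode = "tad_nearest", same_tad = TRUE)
    )
  }
  if (length(links) == 0) {
    out <- elements[0, , drop = FALSE]
    out$gene_id <- character(0); out$distance <- double(0)
    out$mode <- character(0); out$same_tad <- logical(0)
    return(out)
  }
  bind_rows(links)
}

#' Links carried by annotated enhancer-promoter loops
#'
#' One link per (enhancer, promoter) pair of a retained E-P loop; the
#' promoter name is taken as the linked gene id.
#'
#' @param ep_loops Output of [annotate_ep_loops()].
#' @param elements Classified element tibble used to annotate the loops
#'   (provides `chd7_bound` and coordinates per `element_id`).
#' @return Link tibble with `element_id`, `gene_id`, `mode = "ep_loop"`.
#' @export
link_by_loop <- function(ep_loops, elements) {
  if (nrow(ep_loops) == 0) {
    out <- elements[0, , drop = FALSE]
    out$gene_id <- character(0); out$mode <- character(0)
    return(out)
  }
  pairs <- distinct(ep_loops, .data$element_id, gene_id = .data$promoter_name)
  out <- inner_join(pairs, elements, by = "element_id", relationship = "many-to-many")
  mutate(out, mode = "ep_loop")
}

#' Concordance of enhancer and linked-gene changes
#'
#' Restricted to links whose enhancer changed significantly
#' (`direction != "ns"`); a pair is concordant when the enhancer log2
#' fold-change and the linked gene's expression log2 fold-change share a
#' sign. Counts are stratified by CHD7 occupancy of the enhancer. Genes with
#' `de_flag = "ns"` still contribute their fold-change sign unless
#' `strict_gene_de` is set, in which case they are excluded.
#'
#' @param links Link tibble with `element_id`, `gene_id`, `chd7_bound`.
#' @param enhancer_diffs Differential result tibble keyed by `region_id`
#'   matching `element_id`.
#' @param genes Gene tibble providing `expr_log2fc` and `de_flag`.
#' @param strict_gene_de Exclude genes not themselves differentially
#'   expressed? (default FALSE)
#' @return Object of class `concordance_result`: list with `table` (2x2
#'   matrix, rows CHD7 bound/unbound, columns concordant/discordant),
#'   `fractions` (per-stratum concordant fraction) and `pairs` (the
#'   per-link tibble).
#' @export
concordance_table <- function(links, enhancer_diffs, genes, strict_gene_de = FALSE) {
  x <- links %>%
    inner_join(select(enhancer_diffs, "region_id", enh_log2fc = "log2fc",
                      enh_direction = "direction"),
               by = c(element_id = "region_id")) %>%
    inner_join(select(genes, "gene_id", gene_log2fc = "expr_log2fc", "de_flag"),
               by = "gene_id") %>%
    filter(.data$enh_direction != "ns")
  if (strict_gene_de) x <- filter(x, .data$de_flag != "ns")
  x <- mutate(x, concordant = sign(.data$enh_log2fc) == sign(.data$gene_log2fc))
  tab <- matrix(0L, 2, 2,
                dimnames = list(chd7 = c("bound", "unbound"),
                                outcome = c("concordant", "discordant")))
  for (row in 1:2) {
    sel <- x$chd7_bound == (row == 1)
    tab[row, 1] <- sum(x$concordant[sel])
    tab[row, 2] <- sum(!x$concordant[sel])
  }
  fractions <- tab[, 1] / pmax(1L, rowSums(tab))
  structure(list(table = tab, fractions = fractions, pairs = as_tibble(x)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("Enhancer-gene concordance (significant enhancers only)\n")
  print(x$table)
  cat(sprintf("concordant fraction: bound %.3f, unbound %.3f\n",
              x$fractions[1], x$fractions[2]))
  invisible(x)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Pearson statistic without continuity correction, df = 1. The one-sided
#' p-value is `p_two / 2` when the observed association matches the stated
#' alternative (first row more concordant than the second), and
#' `1 - p_two / 2` otherwise; a zero statistic gives p = 1. A warning is
#' attached when any expected cell is below 1.
#'
#' @param table 2x2 numeric matrix or a `concordance_result`.
#' @param sided `"one"` or `"two"`.
#' @return Object of class `chi2_test` with `statistic`, `p_value`, `sided`,
#'   `table` and `expected_warning`.
#' @export
chi2_2x2 <- function(table, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (inherits(table, "concordance_result")) table <- table$table
  stopifnot(all(dim(table) == c(2, 2)))
  storage.mode(table) <- "double"  # closed form overflows integer arithmetic
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  n <- a + b + c_ + d
  expected <- outer(rowSums(table), colSums(table)) / n
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  stat <- if (denom == 0) 0 else n * (a * d - b * c_)^2 / denom
  p_two <- pchisq(stat, df = 1, lower.tail = FALSE)
  if (sided == "one") {
    f1 <- if (a + b > 0) a / (a + b) else 0
    f2 <- if (c_ + d > 0) c_ / (c_ + d) else 0
    p <- if (stat == 0) 1 else if (f1 > f2) p_two / 2 else 1 - p_two / 2
  } else {
    p <- p_two
  }
  structure(list(statistic = stat, p_value = p, sided = sided, table = table,
                 expected_warning = any(expected < 1)),
            class = "chi2_test")
}

#' @export
print.chi2_test <- function(x, ...) {
  cat(sprintf("Pearson chi-squared (df = 1, %s-sided): X2 = %.4g, p = %.4g\n",
              x$sided, x$statistic, x$p_value))
  if (x$expected_warning) cat("warning: an expected cell count is < 1\n")
  invisible(x)
}

#' Pearson correlation of enhancer and linked-gene fold-changes
#'
#' @param links Link tibble with `element_id` and `gene_id`.
#' @param enhancer_diffs Differential results keyed by `region_id`.
#' @param genes Gene tibble with `expr_log2fc`.
#' @return Pearson r over the linked pairs.
#' @export
pearson_linked <- function(links, enhancer_diffs, genes) {
  x <- links %>%
    inner_join(select(enhancer_diffs, "region_id", enh_log2fc = "log2fc"),
               by = c(element_id = "region_id")) %>%
    inner_join(select(genes, "gene_id", gene_log2fc = "expr_log2fc"), by = "gene_id")
  if (nrow(x) < 3) abort("need at least 3 linked pairs")
  cor(x$enh_log2fc, x$gene_log2fc)
}

#' Gene expression changes grouped by enhancer accessibility change
#'
#' Significant enhancers are split by sign of their accessibility change,
#' each sign-set is cut into `n_groups` magnitude tertiles (quantile split),
#' and the linked genes' expression fold-changes are compared between the
#' extreme groups with a Welch t-test. Sign-sets with fewer members than
#' groups are collapsed into a single group with a warning.
#'
#' @param links Link tibble.
#' @param enhancer_diffs Differential results keyed by `region_id`.
#' @param genes Gene tibble with `expr_log2fc`.
#' @param n_groups Number of magnitude groups per sign (default 3).
#' @return List with `groups` (per-link tibble with `sign` and `group`) and
#'   `tests` (one Welch test per sign comparing smallest vs largest
#'   magnitude group).
#' @export
group_by_accessibility <- function(links, enhancer_diffs, genes, n_groups = 3) {
  x <- links %>%
    inner_join(select(enhancer_diffs, "region_id", enh_log2fc = "log2fc",
                      enh_direction = "direction"),
               by = c(element_id = "region_id")) %>%
    inner_join(select(genes, "gene_id", gene_log2fc = "expr_log2fc"), by = "gene_id") %>%
    filter(.data$enh_direction != "ns") %>%
    mutate(sign = ifelse(.data$enh_log2fc > 0, "increasing", "decreasing"))
  grouped <- x %>%
    group_by(.data$sign) %>%
    mutate(group = if (n() < .env$n_groups) {
      warn("fewer enhancers than groups in a sign-set; collapsing to one group")
      1L
    } else {
      as.integer(cut(rank(abs(.data$enh_log2fc), ties.method = "first"),
                     breaks = .env$n_groups, labels = FALSE))
    }) %>%
    ungroup()
  tests <- grouped %>%
    group_by(.data$sign) %>%
    dplyr::group_map(function(df, key) {
      if (length(unique(df$group)) < 2) return(NULL)
      lo <- df$gene_log2fc[df$group == min(df$group)]
      hi <- df$gene_log2fc[df$group == max(df$group)]
      if (length(lo) < 2 || length(hi) < 2) return(NULL)
      ht <- t.test(hi, lo)
      tibble(sign = key$sign, statistic = unname(ht$statistic),
             p_value = ht$p.value,
             mean_low_group = mean(lo), mean_high_group = mean(hi))
    }) %>% bind_rows()
  list(groups = grouped, tests = tests)
}
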