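el_tbl <- function(start, end, id = NULL, bound = TRUE, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = start, end = end,
                 element_id = id %||% paste0("e", seq_along(start)),
                 chd7_bound = bound)
}
gene_tbl <- function(tss, id = NULL, lfc = 0, chrom = "chr1") {
  tibble::tibble(gene_id = id %||% paste0("g", seq_along(tss)), chrom = chrom,
                 tss = tss, strand = "+", expr_log2fc = lfc,
                 de_flag = ifelse(lfc == 0, "ns", ifelse(lfc > 0, "up", "down")))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("link_by_tad enforces same-TAD and distance rules with gene-id ties", {
  doms <- tibble::tibble(chrom = "chr1", start = c(0, 1e5), end = c(1e5, 5e5),
                         domain_id = c("d1", "d2"))
  el <- el_tbl(49.8e3, 50.2e3)  # midpoint 50 kb, inside d1
  genes <- gene_tbl(c(60e3, 120e3), id = c("gA", "gB"))
  links <- link_by_tad(el, genes, doms)
  expect_equal(links$gene_id, "gA")
  expect_equal(links$distance, 10e3)
  expect_true(all(links$same_tad))

  # only gene in the other TAD -> unlinked
  expect_equal(nrow(link_by_tad(el, gene_tbl(160e3), doms)), 0)

  # two equidistant same-TAD genes -> lexicographically smallest id
  ties <- gene_tbl(c(40e3, 60e3), id = c("g2", "g1"))
  expect_equal(link_by_tad(el, ties, doms)$gene_id, "g1")

  overlapping <- tibble::tibble(chrom = "chr1", start = c(0, 5e4), end = c(1e5, 2e5),
                                domain_id = c("d1", "d2"))
  expect_error(link_by_tad(el, genes, overlapping), "overlap")
})

test_that("each element yields at most one TAD link within 100 kb", {
  withr::local_seed(51)
  for (i in 1:30) {
    doms <- rand_domains(6, size = c(5, 15), unit = 2e4)
    el <- rand_peaks(12, span = max(doms$end) - 500, width = c(100, 300))
    el$element_id <- el$name
    el$chd7_bound <- TRUE
    genes <- gene_tbl(sample.int(max(doms$end), 15))
    links <- link_by_tad(el, genes, doms)
    expect_lte(max(table(links$element_id), 0), 1)
    if (nrow(links) > 0) expect_true(all(links$distance <= 1e5))
  }
})

test_that("link_by_loop expands enhancer-promoter pairs per loop", {
  loops <- tibble::tibble(chrom = "chr1", start1 = 0, end1 = 1e4,
                          start2 = 2e5, end2 = 2.1e5, name = "l1")
  el <- el_tbl(c(2e3, 6e3), c(3e3, 7e3))
  el$state <- "active_enhancer"
  prom <- tibble::tibble(chrom = "chr1", start = 2.05e5, end = 2.06e5,
                         name = "gA", score = 0)
  ep <- annotate_ep_loops(loops, el, prom)
  links <- link_by_loop(ep, el)
  expect_equal(nrow(links), 2)
  expect_setequal(links$element_id, c("e1", "e2"))
  expect_true(all(links$mode == "ep_loop"))
  expect_equal(nrow(link_by_loop(ep[0, ], el)), 0)
})

test_that("concordance counts sign agreement and is invariant to joint negation", {
  links <- tibble::tibble(element_id = paste0("e", 1:4), gene_id = paste0("g", 1:4),
                          chd7_bound = c(TRUE, TRUE, FALSE, FALSE))
  diffs <- tibble::tibble(region_id = paste0("e", 1:4), log2fc = c(-2, -1, 1, 2),
                          fdr = 0.01, direction = c("down", "down", "up", "up"))
  genes <- gene_tbl(1:4 * 1e4, id = paste0("g", 1:4), lfc = c(-1, -0.5, 0.7, 1))
  conc <- concordance_table(links, diffs, genes)
  expect_equal(unname(conc$fractions), c(1, 1))

  neg_diffs <- diffs
  neg_diffs$log2fc <- -neg_diffs$log2fc
  neg_diffs$direction <- c("up", "up", "down", "down")
  neg_genes <- genes
  neg_genes$expr_log2fc <- -neg_genes$expr_log2fc
  conc_neg <- concordance_table(links, neg_diffs, neg_genes)
  expect_equal(conc_neg$table, conc$table)

  # non-significant enhancers never enter
  diffs_ns <- diffs
  diffs_ns$direction <- "ns"
  expect_equal(sum(concordance_table(links, diffs_ns, genes)$table), 0)
})

test_that("independent random signs give a concordant fraction near one half", {
  withr::local_seed(52)
  n <- 1000
  links <- tibble::tibble(element_id = paste0("e", 1:n), gene_id = paste0("g", 1:n),
                          chd7_bound = rep(c(TRUE, FALSE), n / 2))
  lfc <- rnorm(n)
  diffs <- tibble::tibble(region_id = links$element_id, log2fc = lfc, fdr = 0.01,
                          direction = ifelse(lfc > 0, "up", "down"))
  genes <- gene_tbl(seq_len(n) * 1e3, id = links$gene_id, lfc = rnorm(n))
  conc <- concordance_table(links, diffs, genes)
  overall <- sum(conc$table[, 1]) / sum(conc$table)
  expect_lt(abs(overall - 0.5), 0.04)
})

test_that("chi2_2x2 matches hand-computed values and the closed form", {
  res <- chi2_2x2(matrix(c(30, 10, 10, 30), 2, 2, byrow = TRUE), sided = "one")
  expect_equal(res$statistic, 20)
  expect_equal(res$p_value, 3.8721e-6, tolerance = 1e-4)

  flat <- chi2_2x2(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # swapping rows flips the matched direction: p -> 1 - p
  tab <- matrix(c(30, 10, 10, 30), 2, 2, byrow = TRUE)
  p_fwd <- chi2_2x2(tab, "one")$p_value
  p_rev <- chi2_2x2(tab[2:1, ], "one")$p_value
  expect_equal(p_rev, 1 - p_fwd)

  withr::local_seed(53)
  for (i in 1:50) {
    tab <- matrix(sample(1:80, 4, replace = TRUE), 2, 2)
    ours <- chi2_2x2(tab, "two")
    a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]; n <- sum(tab)
    closed <- n * (a * d - b * cc)^2 / ((a + b) * (cc + d) * (a + cc) * (b + d))
    expect_equal(ours$statistic, closed, tolerance = 1e-9)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("pearson_linked reproduces perfect correlation and anticorrelation", {
  n <- 10
  links <- tibble::tibble(element_id = paste0("e", 1:n), gene_id = paste0("g", 1:n),
                          chd7_bound = TRUE)
  lfc <- seq(-2, 2, length.out = n)
  diffs <- tibble::tibble(region_id = links$element_id, log2fc = lfc, fdr = 0.01,
                          direction = "down")
  expect_equal(pearson_linked(links, diffs, gene_tbl(1:n * 1e3, links$gene_id, lfc)), 1)
  expect_equal(pearson_linked(links, diffs, gene_tbl(1:n * 1e3, links$gene_id, -lfc)), -1)
  expect_error(pearson_linked(links[1:2, ], diffs, gene_tbl(1:n * 1e3, links$gene_id, lfc)),
               "at least 3")
})

test_that("accessibility grouping forms magnitude tertiles and orders dose-response", {
  n <- 9
  links <- tibble::tibble(element_id = paste0("e", 1:n), gene_id = paste0("g", 1:n),
                          chd7_bound = TRUE)
  lfc <- -seq(0.5, 4.5, by = 0.5)
  diffs <- tibble::tibble(region_id = links$element_id, log2fc = lfc, fdr = 0.01,
                          direction = "down")
  genes <- gene_tbl(1:n * 1e3, links$gene_id, lfc = lfc + rnorm(n, 0, 1e-3))
  out <- group_by_accessibility(links, diffs, genes)
  expect_equal(as.vector(table(out$groups$group)), c(3, 3, 3))
  means <- tapply(out$groups$gene_log2fc, out$groups$group, mean)
  expect_true(all(diff(means) < 0))  # stronger enhancer loss, stronger gene loss

  expect_warning(group_by_accessibility(links[1:2, ], diffs, genes), "collapsing")
})
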