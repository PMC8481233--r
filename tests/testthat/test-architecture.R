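dom <- function(start, end, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = start, end = end,
                 domain_id = paste0("d", seq_along(start)))
}

test_that("merge_domains merges on the two-border rule and is idempotent", {
  m <- merge_domains(dom(c(100e3, 110e3), c(500e3, 510e3)), border_tol = 20e3)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(100e3, 510e3))

  # ends 400 kb apart: no merge even though starts coincide
  m2 <- merge_domains(dom(c(100e3, 100e3), c(500e3, 900e3)), border_tol = 20e3)
  expect_equal(nrow(m2), 2)

  exact <- dom(c(0, 0, 5e5), c(4e5, 4e5, 9e5))
  m3 <- merge_domains(exact, border_tol = 0)
  expect_equal(nrow(m3), 2)
  expect_equal(merge_domains(m3, border_tol = 0)[, c("start", "end")],
               m3[, c("start", "end")])

  expect_error(merge_domains(dom(0, 1e5), border_tol = -1), "non-negative")

  withr::local_seed(41)
  for (i in 1:20) {
    d <- dom(start = sort(sample.int(2e6, 8)) * 10, end = NA)
    d$end <- d$start + sample(5e4:5e5, 8, replace = TRUE)
    once <- merge_domains(d, border_tol = 30e3)
    twice <- merge_domains(once, border_tol = 30e3)
    expect_equal(as.data.frame(once[c("start", "end")]),
                 as.data.frame(twice[c("start", "end")]))
  }
})

test_that("merge_loops requires both anchors within tolerance and tags sources", {
  lp <- function(s1, s2, name = "l", chrom = "chr1") {
    tibble::tibble(chrom = chrom, start1 = s1, end1 = s1 + 1e4,
                   start2 = s2, end2 = s2 + 1e4, name = name)
  }
  same <- merge_loops(lp(1e5, 5e5, "a"), lp(1e5, 5e5, "b"))
  expect_equal(nrow(same), 1)
  expect_equal(same$source, "both")

  # left anchors 9 kb apart but right anchors 30 kb apart -> no merge
  far <- merge_loops(lp(1e5, 5e5, "a"), lp(1e5 + 9e3, 5e5 + 3e4, "b"))
  expect_equal(nrow(far), 2)
  expect_setequal(far$source, c("ctrl", "ko"))
})

test_that("loop-domain classification partitions domains by border loops", {
  d <- dom(100e3, 600e3)
  loop_at <- function(lmid, rmid) {
    tibble::tibble(chrom = "chr1", start1 = lmid - 5e3, end1 = lmid + 5e3,
                   start2 = rmid - 5e3, end2 = rmid + 5e3, name = "l1")
  }
  expect_equal(classify_loop_domains(d, loop_at(110e3, 590e3))$domain_class,
               "loop_domain")
  expect_equal(classify_loop_domains(d, loop_at(110e3, 500e3))$domain_class,
               "compartmental_domain")

  withr::local_seed(42)
  many <- dom(start = (0:9) * 3e5, end = (1:10) * 3e5)
  cls <- classify_loop_domains(many, loop_at(1.5e5, 2.9e5))
  expect_equal(sum(cls$domain_class == "loop_domain") +
                 sum(cls$domain_class == "compartmental_domain"), 10)
})

test_that("observed/expected is 1 on diagonal-constant matrices and scale-invariant", {
  m <- matrix(0, 5, 5)
  for (d in 0:4) m[abs(row(m) - col(m)) == d] <- 10 / (d + 1)
  oe <- observed_expected(contact_matrix(m, "c", 1000))
  expect_true(all(abs(oe$mat - 1) < 1e-12))

  m2 <- matrix(c(2, 1, 1, 2), 2, 2)
  oe2 <- observed_expected(contact_matrix(m2, "c", 1000))
  expect_true(all(abs(oe2$mat - 1) < 1e-12))

  withr::local_seed(43)
  r <- matrix(rpois(100, 20), 10, 10); r <- r + t(r)
  oe_a <- observed_expected(contact_matrix(r, "c", 1000))
  oe_b <- observed_expected(contact_matrix(7 * r, "c", 1000))
  expect_equal(oe_a$mat, oe_b$mat, tolerance = 1e-12)
})

test_that("intradomain change is zero under identity/global scaling, antisymmetric", {
  withr::local_seed(44)
  r <- matrix(rpois(400, 30), 20, 20); r <- r + t(r)
  cm <- contact_matrix(r, "chr1", 1e4)
  d <- dom(2e4, 1e5)
  expect_equal(intradomain_change(cm, cm, d), 0)
  cm2 <- contact_matrix(3.5 * r, "chr1", 1e4)
  expect_equal(intradomain_change(cm2, cm, d), 0, tolerance = 1e-12)

  r2 <- matrix(rpois(400, 25), 20, 20); r2 <- r2 + t(r2)
  cmb <- contact_matrix(r2, "chr1", 1e4)
  expect_equal(intradomain_change(cmb, cm, d), -intradomain_change(cm, cmb, d),
               tolerance = 1e-12)

  expect_error(intradomain_change(cm, cm, dom(0, 1e4)), "fewer than 2 bins")
})

test_that("mean and sum conventions give the same intradomain log2 ratio", {
  # the pair count is condition-independent, so it cancels in the ratio
  withr::local_seed(45)
  r <- matrix(rpois(400, 30), 20, 20); r <- r + t(r)
  r2 <- r; r2[3:8, 3:8] <- r2[3:8, 3:8] * 2
  oe_k <- observed_expected(contact_matrix(r2, "chr1", 1e4))
  oe_c <- observed_expected(contact_matrix(r, "chr1", 1e4))
  d <- dom(2e4, 1e5)
  bins <- 3:10
  sum_version <- log2(sum(oe_k$mat[bins, bins][upper.tri(diag(length(bins)))]) /
                        sum(oe_c$mat[bins, bins][upper.tri(diag(length(bins)))]))
  mean_version <- enhancertopo:::intradomain_change_oe(oe_k, oe_c, d)
  expect_equal(mean_version, sum_version, tolerance = 1e-12)
})

test_that("domain_signal_change averages fold-changes on the linear scale", {
  pd <- tibble::tibble(chrom = "chr1", start = c(10e3, 20e3), end = c(11e3, 21e3),
                       log2fc = c(1, 3))  # fold-changes 2 and 8
  expect_equal(domain_signal_change(pd, dom(0, 1e5)), log2(5))
  pd0 <- pd; pd0$log2fc <- 0
  expect_equal(domain_signal_change(pd0, dom(0, 1e5)), 0)
  expect_warning(val <- domain_signal_change(pd, dom(5e5, 6e5)), "no peaks")
  expect_true(is.na(val))
})

make_checkerboard <- function(n_bins = 60, block = 6, strength = 0.5, depth = 80,
                              noise = FALSE) {
  comp <- rep(rep(c("A", "B"), each = block), length.out = n_bins)
  sep <- abs(outer(1:n_bins, 1:n_bins, "-"))
  mu <- depth * (sep + 1)^-1 *
    ifelse(outer(comp, comp, "=="), 1 + strength, 1 - strength)
  if (noise) {
    m <- matrix(0, n_bins, n_bins)
    up <- upper.tri(mu, diag = TRUE)
    m[up] <- rpois(sum(up), mu[up])
    mu <- m + t(m) - diag(diag(m))
  }
  list(cm = contact_matrix(mu, "chr1", 15e4), comp = comp)
}

test_that("the leading eigenvector recovers a planted two-block pattern", {
  withr::local_seed(46)
  cb <- make_checkerboard()
  tr <- compartment_eigenvector(cb$cm)
  signs <- sign(tr$value)
  # block structure up to a global sign
  agree <- mean(signs == ifelse(cb$comp == "A", 1, -1))
  expect_true(agree > 0.95 || agree < 0.05)
  expect_equal(sum(tr$value^2, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_error(compartment_eigenvector(contact_matrix(matrix(1, 2, 2), "c", 1)),
               "at least 3")
})

test_that("the correlation eigenvector step is equivariant under bin permutation", {
  # the distance-decay expectation is tied to bin order, so equivariance is a
  # property of the correlation + eigendecomposition step, which is checked
  # on the correlation matrix directly
  withr::local_seed(47)
  cb <- make_checkerboard(n_bins = 40, noise = TRUE)
  cc <- cor(cb$cm$mat)
  v <- suppressWarnings(enhancertopo:::leading_eigen(cc))
  perm <- sample(40)
  v_perm <- suppressWarnings(enhancertopo:::leading_eigen(cc[perm, perm]))
  back <- numeric(40)
  back[perm] <- v_perm
  if (sum(back * v) < 0) back <- -back
  expect_equal(back, v, tolerance = 1e-8)
})

test_that("orientation flips toward active-mark density and correlation behaves", {
  withr::local_seed(48)
  cb <- make_checkerboard()
  counts <- ifelse(cb$comp == "A", 5, 0) + rpois(60, 0.2)
  tr <- orient_eigenvector(compartment_eigenvector(cb$cm), counts)
  expect_gt(cor(tr$value, counts), 0)
  flipped <- tr
  flipped$value <- -flipped$value
  re <- orient_eigenvector(flipped, counts)
  expect_equal(re$value, tr$value)
  called <- call_compartments(tr)
  expect_equal(mean(called$compartment == cb$comp), 1)

  expect_equal(eigen_correlation(tr, tr), 1)
  expect_error(orient_eigenvector(tr, rep(2, 60)), "zero variance")
})

test_that("E-P loop annotation keeps enhancer-promoter anchor pairs only", {
  loops <- tibble::tibble(chrom = "chr1", start1 = 0, end1 = 1e4,
                          start2 = 5e5, end2 = 5.1e5, name = "l1")
  enh <- tibble::tibble(chrom = "chr1", start = 5e3, end = 6e3,
                        element_id = "e1", state = "active_enhancer")
  prom <- tibble::tibble(chrom = "chr1", start = 5.05e5, end = 5.06e5,
                         name = "gA", score = 0)
  ep <- annotate_ep_loops(loops, enh, prom)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$element_id, "e1")
  expect_equal(ep$promoter_name, "gA")

  # enhancers in both anchors, no promoter -> dropped
  enh2 <- dplyr::bind_rows(enh, tibble::tibble(chrom = "chr1", start = 5.05e5,
                                               end = 5.06e5, element_id = "e2",
                                               state = "poised_enhancer"))
  expect_equal(nrow(annotate_ep_loops(loops, enh2, prom[0, ])), 0)
})
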