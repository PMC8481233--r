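pk <- function(start, end, chrom = "chr1", name = NULL) {
  tibble::tibble(chrom = chrom, start = start, end = end,
                 name = name %||% paste0("p", seq_along(start)), score = 1)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("reproducible_peaks keeps multi-replicate peaks and unions staggered overlaps", {
  reps <- list(pk(100, 200), pk(100, 200), pk(100, 200))
  expect_equal(nrow(reproducible_peaks(reps, 2)), 1)

  reps <- list(pk(100, 200), pk(5000, 5100), pk(9000, 9100))
  expect_equal(nrow(reproducible_peaks(reps, 2)), 0)

  reps <- list(pk(100, 200), pk(150, 250), pk(5000, 5100))
  out <- reproducible_peaks(reps, 2)
  expect_equal(nrow(out), 1)
  expect_equal(c(out$start, out$end), c(100L, 250L))
  expect_equal(out$n_replicates, 2L)

  expect_error(reproducible_peaks(reps, 0), "min_support")
})

test_that("reproducible_peaks is monotone in min_support", {
  withr::local_seed(11)
  for (rep_i in 1:20) {
    reps <- lapply(1:4, function(i) rand_peaks(sample(3:12, 1), span = 5000))
    sets <- lapply(1:4, function(ms) reproducible_peaks(reps, ms))
    for (ms in 2:4) {
      lower <- sets[[ms - 1]]
      higher <- sets[[ms]]
      # every peak kept at the stricter support is contained in one kept at
      # the looser support
      for (i in seq_len(nrow(higher))) {
        expect_true(any(lower$start <= higher$start[i] & lower$end >= higher$end[i]))
      }
      expect_lte(nrow(higher), nrow(lower))
    }
  }
})

test_that("classify_elements applies promoter precedence and the mark rules", {
  el <- pk(c(100, 1000, 2000, 3000), c(200, 1100, 2100, 3100))
  me3 <- pk(c(150, 1050), c(180, 1080))
  me1 <- pk(c(1000, 2000), c(1100, 2100))
  ac <- pk(1000, 1100)
  atac <- pk(100, 200)
  out <- classify_elements(el, atac, me3, me1, ac)
  # co-marked with H3K4me3 + H3K4me1 + H3K27ac -> promoter wins
  expect_equal(as.character(out$state), c("promoter", "promoter", "poised_enhancer", "other"))
  expect_equal(out$accessible, c(TRUE, FALSE, FALSE, FALSE))

  # active enhancer needs both H3K4me1 and H3K27ac
  out2 <- classify_elements(pk(1000, 1100), atac[0, ], me3[0, ], me1, ac)
  expect_equal(as.character(out2$state), "active_enhancer")

  expect_warning(classify_elements(el[0, ], atac, me3, me1, ac), "no elements")
})

test_that("classification is a partition: every element gets exactly one state", {
  withr::local_seed(12)
  el <- rand_peaks(100, span = 20000)
  out <- classify_elements(el, rand_peaks(30, span = 20000),
                           rand_peaks(30, span = 20000),
                           rand_peaks(30, span = 20000),
                           rand_peaks(30, span = 20000))
  expect_equal(nrow(out), 100)
  expect_false(anyNA(out$state))
  expect_equal(sum(class_proportions(out)$n), 100)
})

test_that("class_proportions sums to one and errors on empty input", {
  el <- tibble::tibble(state = c("promoter", "active_enhancer", rep("poised_enhancer", 2)))
  props <- class_proportions(el)
  expect_equal(props$fraction, c(0.25, 0.25, 0.5, 0))
  expect_equal(sum(props$fraction), 1, tolerance = 1e-12)
  expect_error(class_proportions(el[0, ]), "empty")
})

test_that("planted class proportions are recovered from replicate peak calls", {
  cfg <- sim_config(seed = 21, n_elements = 10000, chrom_sizes = c(chrS = 4e7),
                    class_props = c(promoter = 0.25, active_enhancer = 0.30,
                                    poised_enhancer = 0.35, other = 0.10))
  pc <- simulate_peaks_and_counts(cfg)
  marks <- lapply(pc$peaks, reproducible_peaks, min_support = 2)
  el <- pc$truth
  el$name <- el$element_id
  out <- classify_elements(el[, c("chrom", "start", "end", "name")],
                           marks$atac, marks$k4me3, marks$k4me1, marks$k27ac)
  props <- class_proportions(out)
  planted <- c(promoter = 0.25, active_enhancer = 0.30, poised_enhancer = 0.35)
  for (s in names(planted)) {
    expect_lt(abs(props$fraction[props$state == s] - planted[[s]]), 0.02)
  }
})

test_that("temporal states follow the differential H3K27ac rules", {
  el <- tibble::tibble(element_id = c("a", "b", "c", "d"),
                       state = c("active_enhancer", "active_enhancer",
                                 "poised_enhancer", "poised_enhancer"))
  diffs <- tibble::tibble(region_id = c("a", "b", "c", "d"),
                          log2fc = c(-1.5, 0.1, 2, 0),
                          fdr = c(0.001, 0.8, 0.01, 0.9),
                          direction = c("down", "ns", "up", "ns"))
  out <- temporal_states(el, diffs)
  expect_equal(as.character(out$temporal_state),
               c("P4_specific", "P4_P22_active", "P22_specific_active", "unchanged_poised"))
  expect_error(temporal_states(el, diffs[-1, ]), "missing")
})

test_that("planted temporal transition fractions are recovered", {
  cfg <- sim_config(seed = 22, n_elements = 8000, chrom_sizes = c(chrS = 4e7))
  pc <- simulate_peaks_and_counts(cfg)
  truth <- pc$truth
  # significance calls taken from the planted temporal effects
  diffs <- tibble::tibble(
    region_id = truth$element_id,
    log2fc = truth$temporal_true_log2fc,
    fdr = ifelse(truth$temporal_true_log2fc == 0, 1, 0.001),
    direction = ifelse(truth$temporal_true_log2fc == 0, "ns",
                       ifelse(truth$temporal_true_log2fc > 0, "up", "down"))
  )
  el <- truth
  el$state <- truth$state
  out <- temporal_states(el, diffs)
  act <- out$state == "active_enhancer"
  poi <- out$state == "poised_enhancer"
  expect_lt(abs(mean(out$temporal_state[act] == "P4_specific") - 0.375), 0.03)
  expect_lt(abs(mean(out$temporal_state[poi] == "P22_specific_active") - 0.322), 0.03)
})

test_that("occupancy summary reports RNAPII fractions by CHD7 stratum", {
  withr::local_seed(13)
  el <- rand_peaks(200, span = 5e7)
  el <- classify_elements(el, el[0, ], el[0, ], el, el)  # all active enhancers
  expect_true(all(el$state == "active_enhancer"))
  chd7 <- el[1:100, c("chrom", "start", "end", "name", "score")]
  rnapii <- el[c(1:42, 101:117), c("chrom", "start", "end", "name", "score")]
  occ <- annotate_occupancy(el, rnapii, chd7)
  s <- occ$summary
  expect_equal(s$fraction_rnapii[s$chd7_bound], 0.42, tolerance = 0.03)
  expect_equal(s$fraction_rnapii[!s$chd7_bound], 0.17, tolerance = 0.03)

  occ0 <- annotate_occupancy(el, el[0, ], chd7)
  expect_equal(occ0$summary$fraction_rnapii, c(0, 0))
})

test_that("planted RNAPII occupancy rates are recovered from replicate peaks", {
  cfg <- sim_config(seed = 23, n_elements = 6000, chrom_sizes = c(chrS = 3e7))
  pc <- simulate_peaks_and_counts(cfg)
  marks <- lapply(pc$peaks, reproducible_peaks, min_support = 2)
  el <- pc$truth
  el$name <- el$element_id
  cl <- classify_elements(el[, c("chrom", "start", "end", "name")],
                          marks$atac, marks$k4me3, marks$k4me1, marks$k27ac)
  occ <- annotate_occupancy(cl, marks$rnapii, marks$chd7)
  s <- occ$summary
  expect_lt(abs(s$fraction_rnapii[s$chd7_bound] - 0.42), 0.03)
  expect_lt(abs(s$fraction_rnapii[!s$chd7_bound] - 0.17), 0.03)
})
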