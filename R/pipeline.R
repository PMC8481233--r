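# End-to-end pipeline over synthetic data. Every stage reads its inputs from
# the output directory (written by the simulate stage), so stages can be run
# individually or chained with stage = "all". All randomness flows from the
# configured seed; outputs are deterministic byte-for-byte under a fixed
# seed (no timestamps are written).

#' Pipeline configuration
#'
#' Bundles the simulation config with every analysis-stage parameter at its
#' default: peak reproducibility support 2, FDR threshold 0.05, domain-merge
#' tolerance 20 kb, loop-anchor merge tolerance 10 kb, loop-domain border
#' tolerance 25 kb, 100 kb linking distance, 30/60 degree division cutoffs.
#' Unknown parameter names are rejected.
#'
#' @param sim A [sim_config()].
#' @param ... Overrides for `min_support`, `alpha`, `border_tol`,
#'   `anchor_tol`, `loop_domain_tol`, `link_max_dist`, `horiz_max`,
#'   `vert_min`, `gap_warn_ratio`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), ...) {
  cfg <- list(sim = sim, min_support = 2L, alpha = 0.05,
              border_tol = 20000, anchor_tol = 10000, loop_domain_tol = 25000,
              link_max_dist = 1e5, horiz_max = 30, vert_min = 60,
              gap_warn_ratio = 1.2)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown pipeline_config parameters: ", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  if (cfg$border_tol < 0 || cfg$anchor_tol < 0 || cfg$loop_domain_tol < 0) {
    abort("tolerances must be non-negative")
  }
  structure(cfg, class = "pipeline_config")
}

pipeline_stages <- function() {
  c("simulate", "classify", "diffsig", "architecture", "link", "concordance",
    "crossspecies", "divisions", "all")
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  path
}

#' Run the pipeline
#'
#' `simulate` writes every synthetic input (peaks, counts, matrices,
#' domains, loops, genes, orthologs, divisions) plus truth tables and a
#' config echo; the analysis stages read those files back and write their
#' results as TSV/JSON. `all` chains every stage. On a stage error the
#' stage's partial outputs are removed.
#'
#' @param stage One of `r paste(pipeline_stages(), collapse = ", ")`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param seed Optional integer overriding `config$sim$seed`.
#' @return Invisibly, the list of files the stage wrote.
#' @export
run_pipeline <- function(stage = "all", config = pipeline_config(),
                         out_dir = "enhancertopo_out", seed = NULL) {
  stage <- match.arg(stage, pipeline_stages())
  if (!is.null(seed)) config$sim$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (stage == "all") setdiff(pipeline_stages(), "all") else stage
  written <- character(0)
  for (s in stages) {
    new_files <- tryCatch(
      do.call(paste0("stage_", s), list(config = config, out = out_dir)),
      error = function(e) {
        abort(paste0("stage '", s, "' failed: ", conditionMessage(e)))
      }
    )
    written <- c(written, new_files)
  }
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    paste0("enhancertopo ", as.character(utils::packageVersion("enhancertopo"))),
    paste0("stage: ", stage),
    paste0("seed: ", config$sim$seed),
    paste0("alpha: ", config$alpha),
    paste0("tolerances: border=", config$border_tol, " anchor=", config$anchor_tol,
           " loop_domain=", config$loop_domain_tol)
  ), log_path)
  invisible(c(written, log_path))
}

out_path <- function(out, ...) {
  p <- file.path(out, ...)
  dir.create(dirname(p), showWarnings = FALSE, recursive = TRUE)
  p
}

with_cleanup <- function(expr_fn) {
  files <- character(0)
  track <- function(p) { files <<- c(files, p); p }
  tryCatch(expr_fn(track), error = function(e) {
    unlink(files)
    stop(e)
  })
  files
}

stage_simulate <- function(config, out) {
  cfg <- config$sim
  with_cleanup(function(track) {
    pc <- simulate_peaks_and_counts(cfg)
    for (mark in names(pc$peaks)) {
      for (r in seq_along(pc$peaks[[mark]])) {
        write_bed(pc$peaks[[mark]][[r]],
                  track(out_path(out, "peaks", sprintf("%s_rep%d.bed", mark, r))))
      }
    }
    atlas <- pc$truth[, c("chrom", "start", "end", "element_id")]
    readr::write_tsv(atlas, track(out_path(out, "regions.tsv")))
    readr::write_tsv(pc$atac_counts$ctrl, track(out_path(out, "counts", "atac_ctrl.tsv")))
    readr::write_tsv(pc$atac_counts$ko, track(out_path(out, "counts", "atac_ko.tsv")))
    readr::write_tsv(pc$k27ac_counts$p4, track(out_path(out, "counts", "k27ac_p4.tsv")))
    readr::write_tsv(pc$k27ac_counts$p22, track(out_path(out, "counts", "k27ac_p22.tsv")))
    readr::write_tsv(pc$truth, track(out_path(out, "truth", "elements.tsv")))

    arch <- simulate_architecture(cfg)
    for (chrom in names(arch$matrices$ctrl)) {
      write_contact_matrix(arch$matrices$ctrl[[chrom]],
                           track(out_path(out, "matrices", paste0(chrom, "_ctrl.txt"))))
      write_contact_matrix(arch$matrices$ko[[chrom]],
                           track(out_path(out, "matrices", paste0(chrom, "_ko.txt"))))
    }
    readr::write_tsv(arch$domains, track(out_path(out, "domains.tsv")))
    write_bedpe(arch$loops$ctrl, track(out_path(out, "loops_ctrl.bedpe")))
    write_bedpe(arch$loops$ko, track(out_path(out, "loops_ko.bedpe")))
    k4 <- bind_rows(lapply(names(arch$k4me3_bin_counts), function(ch) {
      tibble(chrom = ch, bin = seq_along(arch$k4me3_bin_counts[[ch]]) - 1L,
             count = arch$k4me3_bin_counts[[ch]])
    }))
    readr::write_tsv(k4, track(out_path(out, "k4me3_bin_counts.tsv")))
    readr::write_tsv(arch$truth$domains, track(out_path(out, "truth", "domains.tsv")))
    readr::write_tsv(arch$truth$compartments, track(out_path(out, "truth", "compartments.tsv")))

    links <- simulate_expression_links(cfg, pc$truth, arch$domains)
    write_gene_table(links$genes, track(out_path(out, "genes.tsv")))
    readr::write_tsv(links$links, track(out_path(out, "links_planted.tsv")))
    readr::write_tsv(links$truth, track(out_path(out, "truth", "links.tsv")))

    orth <- simulate_orthologs(cfg)
    readr::write_tsv(orth$ortholog_map, track(out_path(out, "ortholog_map.tsv")))
    writeLines(orth$mouse_targets, track(out_path(out, "mouse_targets.txt")))
    writeLines(orth$human_targets, track(out_path(out, "human_targets.txt")))
    writeLines(orth$universe, track(out_path(out, "universe.txt")))

    div <- simulate_divisions(cfg)
    readr::write_tsv(div, track(out_path(out, "divisions.tsv")))

    echo <- unclass(cfg)
    echo$division_params <- as.list(as.data.frame(echo$division_params))
    write_json_out(echo, track(out_path(out, "config_echo.json")))
  })
}

read_mark_reps <- function(out, mark) {
  paths <- sort(list.files(file.path(out, "peaks"),
                           pattern = paste0("^", mark, "_rep\\d+\\.bed$"),
                           full.names = TRUE))
  if (length(paths) == 0) abort(paste0("no replicate peak files for mark: ", mark))
  lapply(paths, read_bed, dialect = "bed6")
}

load_elements <- function(out) {
  p <- file.path(out, "elements.tsv")
  if (!file.exists(p)) abort("elements.tsv not found; run the classify stage first")
  readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
}

load_diffs <- function(out, name = "atac_differential.tsv") {
  p <- file.path(out, name)
  if (!file.exists(p)) abort(paste0(name, " not found; run the diffsig stage first"))
  readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
}

stage_classify <- function(config, out) {
  with_cleanup(function(track) {
    rep_peaks <- function(mark) reproducible_peaks(read_mark_reps(out, mark),
                                                   min_support = config$min_support)
    atlas <- readr::read_tsv(file.path(out, "regions.tsv"), show_col_types = FALSE,
                             progress = FALSE)
    atlas$name <- atlas$element_id
    marks <- lapply(c(chd7 = "chd7", atac = "atac", k4me3 = "k4me3",
                      k4me1 = "k4me1", k27ac = "k27ac", rnapii = "rnapii"), rep_peaks)
    el <- classify_elements(atlas, marks$atac, marks$k4me3, marks$k4me1, marks$k27ac)
    occ <- annotate_occupancy(el, marks$rnapii, marks$chd7)
    readr::write_tsv(occ$elements, track(out_path(out, "elements.tsv")))
    props <- class_proportions(occ$elements)
    write_json_out(list(
      n_elements = nrow(occ$elements),
      class_fractions = setNames(as.list(props$fraction), props$state),
      rnapii_fraction_chd7_bound = occ$summary$fraction_rnapii[occ$summary$chd7_bound],
      rnapii_fraction_chd7_unbound = occ$summary$fraction_rnapii[!occ$summary$chd7_bound]
    ), track(out_path(out, "classification_summary.json")))
  })
}

stage_diffsig <- function(config, out) {
  with_cleanup(function(track) {
    rd <- function(f) readr::read_tsv(file.path(out, "counts", f),
                                      show_col_types = FALSE, progress = FALSE)
    atac <- differential_regions(rd("atac_ctrl.tsv"), rd("atac_ko.tsv"),
                                 alpha = config$alpha)
    readr::write_tsv(atac, track(out_path(out, "atac_differential.tsv")))
    k27 <- differential_regions(rd("k27ac_p4.tsv"), rd("k27ac_p22.tsv"),
                                alpha = config$alpha)
    readr::write_tsv(k27, track(out_path(out, "k27ac_temporal_differential.tsv")))
    el <- load_elements(out)
    sub <- el$state == "active_enhancer" & el$chd7_bound
    dirs <- direction_fractions(atac, subset = sub[match(atac$region_id, el$element_id)])
    tmp <- temporal_states(el, k27)
    readr::write_tsv(tmp, track(out_path(out, "elements_temporal.tsv")))
    write_json_out(list(
      n_significant = sum(atac$direction != "ns"),
      bound_active_down_fraction = dirs$fraction[dirs$direction == "down"],
      bound_active_up_fraction = dirs$fraction[dirs$direction == "up"]
    ), track(out_path(out, "diffsig_summary.json")))
  })
}

stage_architecture <- function(config, out) {
  with_cleanup(function(track) {
    domains <- readr::read_tsv(file.path(out, "domains.tsv"), show_col_types = FALSE,
                               progress = FALSE)
    merged <- bind_rows(lapply(split(domains, domains$chrom), merge_domains,
                               border_tol = config$border_tol))
    loops <- merge_loops(read_bedpe(file.path(out, "loops_ctrl.bedpe")),
                         read_bedpe(file.path(out, "loops_ko.bedpe")),
                         anchor_tol = config$anchor_tol)
    classified <- classify_loop_domains(merged, loops, tol = config$loop_domain_tol)
    readr::write_tsv(classified, track(out_path(out, "domains_classified.tsv")))
    readr::write_tsv(loops, track(out_path(out, "loops_merged.tsv")))

    k4 <- readr::read_tsv(file.path(out, "k4me3_bin_counts.tsv"),
                          show_col_types = FALSE, progress = FALSE)
    diffs <- load_diffs(out)
    atlas <- readr::read_tsv(file.path(out, "regions.tsv"), show_col_types = FALSE,
                             progress = FALSE)
    diffs_xy <- inner_join(diffs, atlas, by = c(region_id = "element_id"))

    chroms <- sort(unique(merged$chrom))
    eigen_tracks <- list(); correlations <- c(); dom_rows <- list()
    for (chrom in chroms) {
      n_bins <- max(k4$bin[k4$chrom == chrom]) + 1L
      res <- config$sim$bin_resolution
      read_cm <- function(cond) {
        read_contact_matrix(file.path(out, "matrices", paste0(chrom, "_", cond, ".txt")),
                            chrom, res, n_bins)
      }
      m_ctrl <- read_cm("ctrl"); m_ko <- read_cm("ko")
      counts <- k4$count[k4$chrom == chrom]
      tr_ctrl <- call_compartments(orient_eigenvector(
        compartment_eigenvector(m_ctrl, config$gap_warn_ratio), counts))
      tr_ko <- call_compartments(orient_eigenvector(
        compartment_eigenvector(m_ko, config$gap_warn_ratio), counts))
      correlations[chrom] <- eigen_correlation(tr_ctrl, tr_ko)
      eigen_tracks[[chrom]] <- mutate(tr_ctrl, condition = "ctrl") %>%
        bind_rows(mutate(tr_ko, condition = "ko"))
      oe_k <- observed_expected(m_ko); oe_c <- observed_expected(m_ctrl)
      dm <- filter(merged, .data$chrom == .env$chrom)
      dm$contact_log2fc <- vapply(seq_len(nrow(dm)), function(i) {
        intradomain_change_oe(oe_k, oe_c, dm[i, ])
      }, double(1))
      dm$signal_log2fc <- vapply(seq_len(nrow(dm)), function(i) {
        suppressWarnings(domain_signal_change(diffs_xy, dm[i, ]))
      }, double(1))
      dom_rows[[chrom]] <- dm
    }
    readr::write_tsv(bind_rows(eigen_tracks), track(out_path(out, "eigen_tracks.tsv")))
    dom_changes <- bind_rows(dom_rows)
    readr::write_tsv(dom_changes, track(out_path(out, "domain_changes.tsv")))
    write_json_out(list(
      n_domains = nrow(classified),
      n_loop_domains = sum(classified$domain_class == "loop_domain"),
      n_compartmental_domains = sum(classified$domain_class == "compartmental_domain"),
      n_loops_merged = nrow(loops),
      eigen_correlation_ctrl_ko = unname(mean(correlations))
    ), track(out_path(out, "architecture_summary.json")))
  })
}

stage_link <- function(config, out) {
  with_cleanup(function(track) {
    el <- load_elements(out)
    genes <- read_gene_table(file.path(out, "genes.tsv"))
    merged <- readr::read_tsv(file.path(out, "domains_classified.tsv"),
                              show_col_types = FALSE, progress = FALSE)
    links <- link_by_tad(el, genes, merged, max_dist = config$link_max_dist)
    readr::write_tsv(links, track(out_path(out, "links_tad.tsv")))
    loops <- readr::read_tsv(file.path(out, "loops_merged.tsv"),
                             show_col_types = FALSE, progress = FALSE)
    promoters <- tibble(chrom = genes$chrom,
                        start = pmax(0, genes$tss - 1000), end = genes$tss + 1000,
                        name = genes$gene_id, score = 0)
    ep <- annotate_ep_loops(loops, el, promoters)
    readr::write_tsv(ep, track(out_path(out, "ep_loops.tsv")))
    readr::write_tsv(link_by_loop(ep, el), track(out_path(out, "links_loop.tsv")))
  })
}

stage_concordance <- function(config, out) {
  with_cleanup(function(track) {
    links <- readr::read_tsv(file.path(out, "links_tad.tsv"),
                             show_col_types = FALSE, progress = FALSE)
    diffs <- load_diffs(out)
    genes <- read_gene_table(file.path(out, "genes.tsv"))
    conc <- concordance_table(links, diffs, genes)
    test <- chi2_2x2(conc, sided = "one")
    r <- pearson_linked(links, diffs, genes)
    groups <- group_by_accessibility(links, diffs, genes)
    write_json_out(list(
      table = as.list(setNames(as.vector(conc$table),
                               c("bound_concordant", "unbound_concordant",
                                 "bound_discordant", "unbound_discordant"))),
      concordant_fraction_bound = unname(conc$fractions[1]),
      concordant_fraction_unbound = unname(conc$fractions[2]),
      chi2_statistic = test$statistic,
      chi2_p_one_sided = test$p_value,
      pearson_r = r,
      group_tests = if (nrow(groups$tests) > 0) {
        purrr::transpose(as.list(groups$tests))
      } else list()
    ), track(out_path(out, "concordance.json")))
  })
}

stage_crossspecies <- function(config, out) {
  with_cleanup(function(track) {
    map <- read_ortholog_map(file.path(out, "ortholog_map.tsv"))
    pars <- intersect_orthologs(
      readLines(file.path(out, "mouse_targets.txt")),
      readLines(file.path(out, "human_targets.txt")),
      map, readLines(file.path(out, "universe.txt"))
    )
    res <- hypergeom_overlap(pars$k, pars$K, pars$n, pars$N)
    write_json_out(list(k = res$k, K = res$K, n = res$n, N = res$N,
                        fraction_of_set1 = res$fraction_of_set1,
                        p_value = res$p_value),
                   track(out_path(out, "crossspecies.json")))
  })
}

stage_divisions <- function(config, out) {
  with_cleanup(function(track) {
    ev <- read_division_table(file.path(out, "divisions.tsv"))
    strata <- distinct(ev, .data$plane, .data$condition)
    ratios <- lapply(seq_len(nrow(strata)), function(i) {
      vr <- vh_ratio(ev, strata$plane[i], strata$condition[i],
                     config$horiz_max, config$vert_min)
      list(plane = strata$plane[i], condition = strata$condition[i],
           pooled_ratio = vr$pooled_ratio, mean_ratio = vr$mean_ratio,
           sem_ratio = vr$sem_ratio, n_events = vr$n_events)
    })
    roses <- bind_rows(lapply(seq_len(nrow(strata)), function(i) {
      sub <- filter(ev, .data$plane == strata$plane[i],
                    .data$condition == strata$condition[i])
      mutate(rose_histogram(sub$angle), plane = strata$plane[i],
             condition = strata$condition[i])
    }))
    readr::write_tsv(roses, track(out_path(out, "rose_histograms.tsv")))
    dens <- ev %>%
      group_by(.data$plane, .data$condition, .data$animal_id) %>%
      summarise(density_per_100um2 = division_density(n(), .data$area_um2[1]),
                .groups = "drop")
    readr::write_tsv(dens, track(out_path(out, "division_density.tsv")))
    write_json_out(list(vh_ratios = ratios), track(out_path(out, "divisions.json")))
  })
}
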