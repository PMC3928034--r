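# End-to-end orchestration: one config object drives simulation (or real
# input loading), fragment filtering, annotation, normalization, and every
# statistical contrast, then writes tables, tracks, figures and a
# machine-readable results JSON. All thresholds live in the config; the
# operations themselves carry no hard-coded constants.

#' Default analysis configuration
#'
#' Thresholds default to the values used throughout the quantitative
#' analysis: 100 bp minimum fragment length, 1.5-fold change cutoff,
#' 25-count evidence threshold, log floor 1, usage categories at
#' 0.1/0.3/0.5%, significance levels 0.05/0.01/0.001.
#'
#' @param seed base seed for the synthetic mode.
#' @param sim named list of [sim_params()] overrides.
#' @return Nested config list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1, sim = list()) {
  list(
    mode = "synthetic",
    seed = seed,
    sim = sim,
    thresholds = list(
      min_fragment_length = 100,
      fold = 1.5,
      evidence = 25,
      log_floor = 1,
      usage_bins = c(0.1, 0.3, 0.5),
      alpha_levels = c(0.05, 0.01, 0.001),
      bin_size = 1e5
    ),
    fish = list(
      n_nuclei = 150,
      cell_types = c("preproB_E2aKO", "proB", "preB")
    )
  )
}

#' Read an analysis configuration from YAML
#'
#' Fields present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path YAML file.
#' @return Config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  merge_lists(cfg, user)
}

#' Logical mask of fragments whose region label matches
#'
#' @param map A region-labeled `FragmentMap`.
#' @param region region label.
#' @return Logical vector over fragments.
#' @export
region_mask <- function(map, region) {
  as.character(S4Vectors::mcols(fragments(map))$region) == region
}

#' Per-gene interaction frequencies of a profile
#'
#' Looks up, for every functional Vkappa gene, the normalized frequency of
#' its host fragment (the gene-level view used for inter-viewpoint and
#' usage correlations).
#'
#' @param profile A `NormalizedProfile`.
#' @param map the `FragmentMap`.
#' @param table A `FeatureTable`.
#' @param kind gene kind (default functional genes).
#' @return Named numeric vector, one frequency per gene.
#' @export
gene_frequencies <- function(profile, map, table, kind = "vk_functional") {
  genes <- gene_host_fragments(table, kind)
  hit <- GenomicRanges::findOverlaps(genes, fragments(map),
                                     select = "first")
  setNames(profile$freq[hit], S4Vectors::mcols(genes)$name)
}

#' Run the full viewpoint-analysis pipeline
#'
#' Synthetic mode: simulates a locus, feature annotation, usage table,
#' replicate 3C-seq counts for every viewpoint and condition, and FISH
#' datasets, then runs the complete quantification: RPM normalization and
#' replicate averaging, per-region means and inside/outside ratios,
#' Vkappa+/- and TF-site group comparisons, fold-change classification of
#' the strongest-vs-weakest signaling contrast, inter-viewpoint and
#' usage-category correlations, 100-kb binned tracks, and FISH distance
#' comparisons. All outputs are written under `outdir`; rerunning with the
#' same config and seed reproduces the results JSON byte for byte.
#'
#' @param config config list from [default_config()] or [read_config()].
#' @param outdir output directory (created if missing).
#' @param write_figures also write summary figures (PDF).
#' @return The results list, invisibly. Every number in the results is
#'   produced by one of the package's exported operations.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile(),
                         write_figures = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  if (any(unlist(th[c("min_fragment_length", "fold", "evidence",
                      "log_floor")]) < 0)) {
    stop("thresholds must be non-negative")
  }
  if (!identical(config$mode, "synthetic")) {
    stop("only synthetic mode is config-driven; assemble real-data runs ",
         "from the exported building blocks (see the vignette)")
  }
  sim_args <- config$sim
  if (is.null(sim_args$seed)) sim_args$seed <- config$seed
  params <- do.call(sim_params, sim_args)
  sim <- simulate_locus(params)
  map <- filter_fragments(sim$map, min_length = th$min_fragment_length,
                          exclusion_zones = sim_exclusion_zone(params))
  usage <- simulate_usage(map, sim$table, params)
  features <- attach_usage(sim$features, usage)
  table <- annotate_fragments(map, features)

  mc <- S4Vectors::mcols(fragments(map))
  filter_counts <- table(mc$excl_reason)
  message(sprintf("fragment filters: %s",
                  paste(names(filter_counts), filter_counts, sep = "=",
                        collapse = ", ")))

  vps <- names(viewpoint_positions(params))
  conds <- params$conditions
  wt <- conds[length(conds)]
  dko <- conds[2]

  counts <- lapply(setNames(vps, vps), function(v) {
    lapply(setNames(conds, conds), function(cc) {
      simulate_viewpoint_counts(map, table, v, cc, params)
    })
  })
  profiles <- lapply(counts, function(by_cond) {
    lapply(by_cond, function(reps) {
      average_replicates(lapply(reps, normalize_rpm, map = map))
    })
  })

  in_vk <- region_mask(map, "vkappa")
  usable <- usable_fragments(map)
  vk_pos <- subgroup_mask(table, "vk_functional", map) & in_vk
  vk_neg <- subgroup_mask(table, "!vk_functional & !vk_pseudo", map) & in_vk

  results <- list(config_seed = config$seed,
                  thresholds = th,
                  n_fragments = n_fragments(map),
                  filter_counts = as.list(filter_counts),
                  region_fragment_counts = region_fragment_counts(map))

  # per-region means and inside/outside ratios (gradient panels)
  results$region_summary <- do.call(rbind, lapply(vps, function(v) {
    do.call(rbind, lapply(conds, function(cc) {
      rs <- region_means(profiles[[v]][[cc]], map)
      data.frame(viewpoint = v, condition = cc, rs,
                 inside_outside = attr(rs, "inside_outside_ratio"))
    }))
  }))

  # Vkappa+/- and TF-site contrasts
  comp_row <- function(v, cc, contrast, mask_a, mask_b, labels) {
    cr <- group_comparison(profiles[[v]][[cc]], mask_a, mask_b, labels)
    data.frame(viewpoint = v, condition = cc, contrast = contrast,
               group_a = labels[1], group_b = labels[2],
               mean_a = cr$means[1], mean_b = cr$means[2],
               n_a = cr$n[1], n_b = cr$n[2], U = cr$U, p = cr$p,
               stars = cr$stars, row.names = NULL)
  }
  comps <- list()
  for (v in vps) for (cc in conds) {
    comps[[length(comps) + 1L]] <-
      comp_row(v, cc, "vk", vk_pos, vk_neg, c("Vk+", "Vk-"))
    for (kind in c("ctcf", "ikaros", "e2a", "h3k4me23")) {
      mk <- subgroup_mask(table, kind, map) & in_vk
      comps[[length(comps) + 1L]] <-
        comp_row(v, cc, kind, mk & usable, in_vk & usable & !mk,
                 c(paste0(kind, "+"), paste0(kind, "-")))
    }
    # Ikaros-only vs Ikaros+E2a Vkappa+ fragments (and vs no-Vk)
    ik_only <- subgroup_mask(table, "vk_functional & ikaros & !e2a", map) & in_vk
    ik_e2a <- subgroup_mask(table, "vk_functional & ikaros & e2a", map) & in_vk
    if (any(ik_only) && any(ik_e2a)) {
      comps[[length(comps) + 1L]] <-
        comp_row(v, cc, "ikaros_subgroups", ik_e2a, ik_only,
                 c("Ikaros+E2a Vk+", "Ikaros-only Vk+"))
    }
    pseudo <- subgroup_mask(table, "vk_pseudo", map) & in_vk
    if (any(pseudo)) {
      comps[[length(comps) + 1L]] <-
        comp_row(v, cc, "pseudo_vs_functional", vk_pos, pseudo,
                 c("Vk functional", "Vk pseudo"))
    }
  }
  results$comparisons <- do.call(rbind, comps)

  # fold-change classification, strongest vs weakest signaling pre-B cells
  wt_counts <- lapply(counts, `[[`, wt)
  dko_counts <- lapply(counts, `[[`, dko)
  fc_all <- classify_fold_change(wt_counts, dko_counts, map, mask = vk_pos,
                                 fold_threshold = th$fold,
                                 evidence_threshold = th$evidence)
  results$fold_classes <- fc_all$fractions
  ik_only <- subgroup_mask(table, "vk_functional & ikaros & !e2a", map) & in_vk
  ik_e2a <- subgroup_mask(table, "vk_functional & ikaros & e2a", map) & in_vk
  results$fold_classes_ikaros_only <-
    classify_fold_change(wt_counts, dko_counts, map, mask = ik_only,
                         fold_threshold = th$fold,
                         evidence_threshold = th$evidence)$fractions
  results$fold_classes_ikaros_e2a <-
    classify_fold_change(wt_counts, dko_counts, map, mask = ik_e2a,
                         fold_threshold = th$fold,
                         evidence_threshold = th$evidence)$fractions

  # inter-viewpoint gene-level correlations
  gene_freq <- lapply(profiles, function(by_cond) {
    lapply(by_cond, gene_frequencies, map = map, table = table)
  })
  pairs <- utils::combn(vps, 2, simplify = FALSE)
  results$viewpoint_correlations <- do.call(rbind, lapply(conds, function(cc) {
    do.call(rbind, lapply(pairs, function(pr) {
      vc <- viewpoint_correlation(gene_freq[[pr[1]]][[cc]],
                                  gene_freq[[pr[2]]][[cc]],
                                  floor = th$log_floor)
      data.frame(condition = cc, viewpoint_a = pr[1], viewpoint_b = pr[2],
                 r_squared = vc$r_squared, n = vc$n)
    }))
  }))

  # usage-category correlations
  results$usage_correlations <- do.call(rbind, lapply(vps, function(v) {
    do.call(rbind, lapply(conds, function(cc) {
      uc <- usage_category_correlation(
        usage$usage_percent[match(names(gene_freq[[v]][[cc]]), usage$gene)],
        gene_freq[[v]][[cc]], bin_edges = th$usage_bins)
      data.frame(viewpoint = v, condition = cc, r_squared = uc$r_squared)
    }))
  }))

  # FISH
  fish_sets <- lapply(config$fish$cell_types, simulate_fish,
                      params = params, n_nuclei = config$fish$n_nuclei)
  fish_sum <- compare_cell_types(fish_sets)
  results$fish <- list(medians = as.list(fish_sum$medians),
                       n = as.list(fish_sum$n),
                       p_values = fish_sum$p_values)

  # ---- outputs ----
  write_fragment_map(map, file.path(outdir, "fragments.bed"))
  write_annotation(table, map, file.path(outdir, "annotation.tsv"))
  write.table(usage, file.path(outdir, "usage.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_sim_truth(params, file.path(outdir, "truth.json"))
  write_fish_table(fish_sets, file.path(outdir, "fish_centroids.tsv"))
  for (v in vps) {
    for (cc in conds) {
      write_bedgraph(profiles[[v]][[cc]],
                     file.path(outdir, sprintf("profile_%s_%s.bedGraph",
                                               v, cc)), map = map)
      track <- bin_profile(profiles[[v]][[cc]], map,
                           bin_size = th$bin_size)
      write_bedgraph(track,
                     file.path(outdir, sprintf("binned_%s_%s.bedGraph",
                                               v, cc)))
    }
  }
  write.table(results$region_summary,
              file.path(outdir, "region_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(results$comparisons, file.path(outdir, "comparisons.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(results, file.path(outdir, "results.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "rows")
  if (write_figures) {
    pipeline_figures(results, profiles, gene_freq, fish_sum, map, table,
                     outdir, wt, dko)
  }
  invisible(results)
}

# figure-style report panels on the synthetic data
pipeline_figures <- function(results, profiles, gene_freq, fish_sum, map,
                             table, outdir, wt, dko) {
  pdf(file.path(outdir, "report.pdf"), width = 8, height = 5)
  on.exit(dev.off())
  rs <- results$region_summary
  print(
    ggplot2::ggplot(rs, ggplot2::aes(condition, mean_freq,
                                     fill = region)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::facet_wrap(~viewpoint) +
      ggplot2::labs(title = "Mean interaction frequency per region",
                    y = "mean RPM per fragment") +
      ggplot2::theme_minimal()
  )
  cmp <- results$comparisons
  vkc <- cmp[cmp$contrast == "vk", ]
  long <- rbind(
    data.frame(vkc[c("viewpoint", "condition")], group = "Vk+",
               mean = vkc$mean_a),
    data.frame(vkc[c("viewpoint", "condition")], group = "Vk-",
               mean = vkc$mean_b)
  )
  print(
    ggplot2::ggplot(long, ggplot2::aes(condition, mean,
                                       fill = group)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::facet_wrap(~viewpoint) +
      ggplot2::labs(title = "Vkappa+ vs Vkappa- fragments",
                    y = "mean RPM per fragment") +
      ggplot2::theme_minimal()
  )
  sc <- data.frame(
    wt_a = log10(pmax(gene_freq[[2]][[wt]], 1)),
    wt_b = log10(pmax(gene_freq[[3]][[wt]], 1)),
    dko_a = log10(pmax(gene_freq[[2]][[dko]], 1)),
    dko_b = log10(pmax(gene_freq[[3]][[dko]], 1))
  )
  print(
    ggplot2::ggplot(sc) +
      ggplot2::geom_point(ggplot2::aes(wt_a, wt_b),
                          color = "grey30") +
      ggplot2::geom_point(ggplot2::aes(dko_a, dko_b),
                          color = "orange", alpha = 0.7) +
      ggplot2::labs(title = "Inter-enhancer gene correlation (grey WT, orange low signaling)",
                    x = "log10 freq, enhancer A", y = "log10 freq, enhancer B") +
      ggplot2::theme_minimal()
  )
  fc <- as.data.frame(results$fold_classes)
  fc$viewpoint <- rownames(results$fold_classes)
  fcl <- stats::reshape(fc, direction = "long",
                        varying = fold_class_levels(),
                        v.names = "fraction", timevar = "class",
                        times = fold_class_levels())
  print(
    ggplot2::ggplot(fcl, ggplot2::aes(viewpoint, fraction,
                                      fill = class)) +
      ggplot2::geom_col() +
      ggplot2::labs(title = "Fold-change classes of Vkappa+ fragments (WT vs lowest signaling)") +
      ggplot2::theme_minimal()
  )
  fish_df <- do.call(rbind, lapply(names(fish_sum$distances), function(t) {
    data.frame(cell_type = t, distance = fish_sum$distances[[t]])
  }))
  print(
    ggplot2::ggplot(fish_df, ggplot2::aes(cell_type, distance)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(title = "Inter-probe 3D distances",
                    y = "distance (um)") +
      ggplot2::theme_minimal()
  )
  invisible(NULL)
}
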