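# Synthetic-data generator. One base seed per parameter set; every stochastic
# operation draws from a deterministic sub-stream so any output can be
# regenerated in isolation, bit for bit, without replaying the whole run.

with_substream <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.numeric(seed) * 101 + offset) %% 2147483629)
  force(code)
}

#' Parameters of the synthetic Igkappa-like locus and 3C-seq model
#'
#' Defaults emulate the study conditions of the quantitative Igkappa
#' viewpoint analysis: an 8.4 Mb locus cut into ~2.6 kb restriction
#' fragments partitioned into upstream (~23%), Vkappa (~39%) and downstream
#' regions; 101 functional and 100 pseudo Vkappa genes placed in the central
#' region; three viewpoints (Sis, iEk, 3pEk) near the 3' end of the Vkappa
#' region; five ordered conditions forming a pre-BCR signaling gradient
#' (`proB < BtkSlp65 < Slp65 < Btk < WT`).
#'
#' The expected count of fragment `f` for viewpoint `v` in condition `c` is
#' `lambda_f = reads x w_f / sum(w)`, with
#' `w_f = d_f^-alpha x G_f x flank_leak_c^[outside Vkappa]`, where `d_f` is
#' the fragment midpoint distance to the viewpoint and `G_f` the gene
#' enrichment: for a fragment hosting a Vkappa gene,
#' `G = F_eff x exp(affinity_sd x ln(10) x z x e(F_eff))` with
#' `F_eff = 1 + (focusing - 1) x e2a_bonus^[E2a-marked]` (pseudo genes use
#' `focusing` scaled by `pseudo_weight`), engagement
#' `e(F) = min(1, (F-1)/affinity_ramp)` (so focusing 1 is an exact null),
#' and `z = sqrt(rho_c) z_gene + sqrt(1-rho_c) z_{gene,viewpoint}` a
#' standard-normal affinity shared across viewpoints to degree
#' `coordination` `rho_c`. Counts are negative binomial with the given
#' `dispersion` (Poisson when 0).
#'
#' @param locus_length locus size in bp.
#' @param mean_fragment_length mean restriction-fragment length in bp.
#' @param n_vk_functional,n_vk_pseudo numbers of Vkappa gene segments.
#' @param tf_marking_probabilities per-gene marking probabilities by kind;
#'   E2a/H3K4me2-3/Ctcf marks are drawn as subsets of Ikaros-marked genes so
#'   every otherwise-marked gene also carries Ikaros.
#' @param tf_background_rate per-fragment probability of a TF site on
#'   non-gene Vkappa-region fragments.
#' @param conditions ordered condition names, weakest signaling first.
#' @param decay_exponent power-law distance-decay exponent alpha (> 0).
#' @param decay_scale expected relative reads at 1 bp (cancels in the
#'   library-share normalization; kept for completeness).
#' @param min_distance decay floor distance in bp.
#' @param focusing_strength viewpoints x conditions matrix of Vkappa-gene
#'   enrichment factors.
#' @param flank_leak per-condition weight of fragments outside the Vkappa
#'   region.
#' @param coordination per-condition share `rho` of gene affinity common to
#'   all viewpoints.
#' @param affinity_sd log10 standard deviation of per-gene affinity.
#' @param affinity_ramp engagement ramp width (see above).
#' @param e2a_bonus scaling of `(focusing - 1)` for E2a-marked genes.
#' @param pseudo_weight scaling of `(focusing - 1)` for pseudogenes.
#' @param dispersion negative-binomial overdispersion (variance =
#'   `mu + dispersion x mu^2`); 0 gives Poisson counts.
#' @param replicates replicate libraries per viewpoint/condition.
#' @param library_size total mapped reads per replicate library.
#' @param cis_fraction fraction of the library landing in the mapped locus.
#' @param usage_coupling exponent linking a gene's WT expected frequency to
#'   its repertoire usage (0 decouples them).
#' @param usage_noise_sd log10 sd of multiplicative usage noise.
#' @param fish_contracted_median,fish_noncontracted_median target median
#'   inter-probe distances (micrometers) for contracted and non-contracted
#'   cell types.
#' @param fish_contracted_types cell-type names drawn as contracted.
#' @param seed base seed for all sub-streams.
#' @return A `sim_params` list.
#' @export
sim_params <- function(locus_length = 8.4e6,
                       mean_fragment_length = 2600,
                       n_vk_functional = 101,
                       n_vk_pseudo = 100,
                       tf_marking_probabilities = c(ikaros = 0.95,
                                                    e2a = 0.37,
                                                    h3k4me23 = 0.28,
                                                    ctcf = 0.12),
                       tf_background_rate = c(ikaros = 0.05, e2a = 0.03,
                                              h3k4me23 = 0.05, ctcf = 0.04),
                       conditions = c("proB", "BtkSlp65", "Slp65", "Btk",
                                      "WT"),
                       decay_exponent = 1,
                       decay_scale = 1,
                       min_distance = 1000,
                       focusing_strength = rbind(
                         Sis  = c(1.5, 1.6, 1.9, 2.2, 2.6),
                         iEk  = c(2.3, 2.3, 2.4, 2.5, 2.6),
                         `3pEk` = c(1.0, 1.2, 1.6, 2.0, 2.6)),
                       flank_leak = c(1.0, 0.95, 0.85, 0.75, 0.65),
                       coordination = c(0.25, 0.55, 0.65, 0.75, 0.85),
                       affinity_sd = 0.9,
                       affinity_ramp = 0.5,
                       e2a_bonus = 1.5,
                       pseudo_weight = 0.8,
                       dispersion = 0.1,
                       replicates = 2,
                       library_size = 1e6,
                       cis_fraction = 0.4,
                       usage_coupling = 1,
                       usage_noise_sd = 0.5,
                       fish_contracted_median = 0.4,
                       fish_noncontracted_median = 0.9,
                       fish_contracted_types = c("proB", "preB"),
                       seed = 1) {
  p <- as.list(environment())
  stopifnot(locus_length > 0, mean_fragment_length > 0,
            n_vk_functional >= 0, n_vk_pseudo >= 0,
            all(tf_marking_probabilities >= 0 &
                  tf_marking_probabilities <= 1),
            decay_exponent > 0, min_distance > 0,
            all(focusing_strength >= 0), all(flank_leak > 0),
            all(coordination >= 0 & coordination <= 1),
            affinity_sd >= 0, dispersion >= 0, replicates >= 1,
            library_size > 0, cis_fraction > 0, cis_fraction <= 1,
            usage_coupling >= 0)
  if (fish_contracted_median <= 0 || fish_noncontracted_median <= 0) {
    stop("FISH median parameters must be positive")
  }
  nc <- length(conditions)
  stopifnot(ncol(focusing_strength) == nc, length(flank_leak) == nc,
            length(coordination) == nc)
  colnames(p$focusing_strength) <- conditions
  names(p$flank_leak) <- conditions
  names(p$coordination) <- conditions
  p$chrom <- "chrSim"
  structure(p, class = "sim_params")
}

# region boundaries mirror the study locus proportions
sim_region_bounds <- function(params) {
  L <- params$locus_length
  up_end <- round(0.234 * L)
  vk_end <- up_end + round(0.393 * L)
  c(up_end = up_end, vk_end = vk_end)
}

#' Synthetic region partition and viewpoint positions
#'
#' @param params A `sim_params` object.
#' @return `sim_partition`: named `GRanges` (upstream/vkappa/downstream);
#'   `viewpoint_positions`: named vector of viewpoint midpoints in bp,
#'   placed near the 3' end of the Vkappa region like the kappa regulatory
#'   elements; `sim_exclusion_zone`: `GRanges` covering the
#'   viewpoint-proximal interval dropped from downstream statistics.
#' @export
sim_partition <- function(params) {
  b <- sim_region_bounds(params)
  gr <- GenomicRanges::GRanges(
    params$chrom,
    IRanges::IRanges(start = c(1, b["up_end"] + 1, b["vk_end"] + 1),
                     end = c(b["up_end"], b["vk_end"], params$locus_length))
  )
  names(gr) <- c("upstream", "vkappa", "downstream")
  gr
}

#' @rdname sim_partition
#' @export
viewpoint_positions <- function(params) {
  vk_end <- sim_region_bounds(params)["vk_end"]
  pos <- vk_end - c(40e3, 25e3, 10e3)
  names(pos) <- rownames(params$focusing_strength)
  pos
}

#' @rdname sim_partition
#' @export
sim_exclusion_zone <- function(params) {
  pos <- viewpoint_positions(params)
  GenomicRanges::GRanges(
    params$chrom,
    IRanges::IRanges(start = min(pos) - 8e3, end = max(pos) + 8e3)
  )
}

#' Simulate a restriction-fragment map and its feature annotation
#'
#' Fragment lengths are exponential around `mean_fragment_length` (the
#' length distribution of a random-sequence digest), so a realistic share
#' of sub-100 bp fragments arises naturally. Functional and pseudo Vkappa
#' genes are placed on distinct fragments of the central region; TF and
#' H3K4me2/3 marks are drawn per gene from `tf_marking_probabilities`
#' (non-Ikaros marks as subsets of the Ikaros-marked genes) and laid on the
#' same fragment as the gene, plus sparse background sites on non-gene
#' Vkappa-region fragments.
#'
#' @param params A `sim_params` object.
#' @return List with elements `map` (a region-labeled `FragmentMap`),
#'   `features` (feature `GRanges`), and `table` (the `FeatureTable` from
#'   [annotate_fragments()]).
#' @export
simulate_locus <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  L <- params$locus_length
  with_substream(params$seed, 1L, {
    n_exp <- ceiling(1.5 * L / params$mean_fragment_length) + 10L
    lens <- rexp(n_exp, rate = 1 / params$mean_fragment_length)
    cum <- cumsum(ceiling(lens))
    cuts <- cum[cum < L]
    bounds <- c(0, cuts, L)
    gr <- GenomicRanges::GRanges(
      params$chrom,
      IRanges::IRanges(start = head(bounds, -1) + 1, end = tail(bounds, -1))
    )
    map <- new_fragment_map(gr, enzyme_motif = "AGATCT", cut_offset = 1L)
    map <- assign_regions(map, sim_partition(params))

    fr <- fragments(map)
    vk_region <- which(S4Vectors::mcols(fr)$region == "vkappa" &
                         GenomicRanges::width(fr) >= 500)
    n_genes <- params$n_vk_functional + params$n_vk_pseudo
    if (length(vk_region) < n_genes) {
      stop("locus too short for the requested number of Vkappa genes")
    }
    host <- sample(vk_region, n_genes)
    fun_host <- sort(host[seq_len(params$n_vk_functional)])
    pse_host <- sort(host[params$n_vk_functional + seq_len(params$n_vk_pseudo)])

    gene_interval <- function(idx) {
      s <- GenomicRanges::start(fr)[idx]
      e <- GenomicRanges::end(fr)[idx]
      m <- pmin(s + floor((e - s) / 2), e - 1)
      list(start = m, end = pmin(m + 300, e))
    }
    fi <- gene_interval(fun_host)
    ps <- gene_interval(pse_host)
    f_start <- c(fi$start, ps$start)
    f_end <- c(fi$end, ps$end)
    f_kind <- c(rep("vk_functional", length(fun_host)),
                rep("vk_pseudo", length(pse_host)))
    f_name <- c(sprintf("VkF%03d", seq_along(fun_host)),
                sprintf("VkP%03d", seq_along(pse_host)))

    # per-gene marks: Ikaros first, the rest nested within Ikaros
    pr <- params$tf_marking_probabilities
    nf <- params$n_vk_functional
    ik <- runif(nf) < pr[["ikaros"]]
    nested <- function(kind) {
      cond <- min(1, pr[[kind]] / max(pr[["ikaros"]], 1e-12))
      ik & (runif(nf) < cond)
    }
    marks <- list(ikaros = ik, e2a = nested("e2a"),
                  h3k4me23 = nested("h3k4me23"), ctcf = nested("ctcf"))
    for (kind in names(marks)) {
      sel <- which(marks[[kind]])
      if (length(sel)) {
        f_start <- c(f_start, fi$start[sel] + 10)
        f_end <- c(f_end, fi$end[sel] + 10)
        f_kind <- c(f_kind, rep(kind, length(sel)))
        f_name <- c(f_name, sprintf("%s_Vk%03d", kind, sel))
      }
    }

    # sparse background sites away from genes
    bg_pool <- setdiff(vk_region, host)
    for (kind in names(params$tf_background_rate)) {
      n_bg <- rbinom(1, length(bg_pool), params$tf_background_rate[[kind]])
      if (n_bg > 0) {
        sel <- sample(bg_pool, n_bg)
        s <- GenomicRanges::start(fr)[sel]
        f_start <- c(f_start, s + 5)
        f_end <- c(f_end, s + 155)
        f_kind <- c(f_kind, rep(kind, n_bg))
        f_name <- c(f_name, sprintf("%s_bg%03d", kind, seq_len(n_bg)))
      }
    }
    features <- make_features(params$chrom, f_start, f_end, f_kind, f_name)
    list(map = map, features = features,
         table = annotate_fragments(map, features))
  })
}

# gene hosts in stable (positional) order; functional then pseudo
gene_host_fragments <- function(table, kind) {
  f <- table$features[S4Vectors::mcols(table$features)$kind == kind]
  f[order(GenomicRanges::start(f))]
}

gene_affinity_z <- function(params, n_genes, vp_index, condition) {
  rho <- params$coordination[[condition]]
  z_shared <- with_substream(params$seed, 13L, rnorm(n_genes))
  z_vp <- with_substream(params$seed, 17L + 7L * vp_index, rnorm(n_genes))
  sqrt(rho) * z_shared + sqrt(1 - rho) * z_vp
}

#' Expected interaction weights of one viewpoint profile
#'
#' Deterministic given the parameters (gene affinities come from seeded
#' sub-streams), so the expected-count model can be inspected without
#' sampling noise. Weights are normalized to sum to one over fragments.
#'
#' @param map,table synthetic map and feature table from [simulate_locus()].
#' @param viewpoint viewpoint name (a row of `params$focusing_strength`).
#' @param condition condition name.
#' @param params A `sim_params` object.
#' @return Numeric vector of per-fragment expected library shares.
#' @export
expected_interaction_weights <- function(map, table, viewpoint, condition,
                                         params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$decay_exponent <= 0) stop("decay exponent must be positive")
  vps <- viewpoint_positions(params)
  if (!viewpoint %in% names(vps)) stop("unknown viewpoint: ", viewpoint)
  if (!condition %in% params$conditions) stop("unknown condition: ",
                                              condition)
  vp_index <- match(viewpoint, names(vps))
  fr <- fragments(map)
  mid <- floor((GenomicRanges::start(fr) + GenomicRanges::end(fr)) / 2)
  d <- pmax(abs(mid - vps[[viewpoint]]), params$min_distance)
  w <- params$decay_scale * d^(-params$decay_exponent)

  Fvc <- params$focusing_strength[viewpoint, condition]
  ln10 <- log(10)
  apply_genes <- function(kind, weight_scale, z_offset) {
    genes <- gene_host_fragments(table, kind)
    if (!length(genes)) return()
    hit <- GenomicRanges::findOverlaps(genes, fr, select = "first")
    e2a <- table$matrix[hit, "e2a"]
    bonus <- ifelse(e2a, params$e2a_bonus, 1) * weight_scale
    Feff <- 1 + (Fvc - 1) * bonus
    z <- gene_affinity_z(params, length(genes), vp_index + z_offset,
                         condition)
    eng <- pmin(1, pmax(0, (Feff - 1) / params$affinity_ramp))
    w[hit] <<- w[hit] * Feff * exp(params$affinity_sd * ln10 * z * eng)
  }
  apply_genes("vk_functional", 1, 0L)
  apply_genes("vk_pseudo", params$pseudo_weight, 100L)

  outside <- S4Vectors::mcols(fr)$region != "vkappa"
  w[outside] <- w[outside] * params$flank_leak[[condition]]
  w / sum(w)
}

#' Simulate replicate 3C-seq count profiles for one viewpoint
#'
#' Per-fragment counts are negative binomial around the expected model of
#' [expected_interaction_weights()] scaled to `library_size x cis_fraction`
#' reads; each replicate draws from its own deterministic sub-stream.
#'
#' @inheritParams expected_interaction_weights
#' @param replicates number of replicate libraries (default from params).
#' @return List of `CountProfile` objects, one per replicate.
#' @export
simulate_viewpoint_counts <- function(map, table, viewpoint, condition,
                                      params,
                                      replicates = params$replicates) {
  share <- expected_interaction_weights(map, table, viewpoint, condition,
                                        params)
  lambda <- params$library_size * params$cis_fraction * share
  vp_index <- match(viewpoint, names(viewpoint_positions(params)))
  cond_index <- match(condition, params$conditions)
  lapply(seq_len(replicates), function(rep) {
    counts <- with_substream(
      params$seed,
      100000L + 10000L * vp_index + 100L * cond_index + rep,
      if (params$dispersion <= 0) {
        rpois(length(lambda), lambda)
      } else {
        rnbinom(length(lambda), mu = lambda, size = 1 / params$dispersion)
      }
    )
    new_count_profile(
      viewpoint = viewpoint, condition = condition, replicate = rep,
      counts = counts,
      library_size = max(params$library_size, sum(counts))
    )
  })
}

new_count_profile <- function(viewpoint, condition, replicate, counts,
                              library_size) {
  stopifnot(all(counts >= 0), library_size >= sum(counts))
  structure(
    list(viewpoint = viewpoint, condition = condition,
         replicate = replicate, counts = as.numeric(counts),
         library_size = library_size),
    class = "CountProfile"
  )
}

#' @export
print.CountProfile <- function(x, ...) {
  cat(sprintf(
    "CountProfile: %s / %s replicate %s; %d fragments, %d in-map reads (library %g)\n",
    x$viewpoint, x$condition, x$replicate, length(x$counts),
    round(sum(x$counts)), x$library_size))
  invisible(x)
}

#' Simulate a Vkappa gene-usage table coupled to interaction strength
#'
#' Raw usage is the gene's WT expected frequency (mean over viewpoints)
#' raised to `usage_coupling`, perturbed by lognormal noise, then normalized
#' so that usage sums to 100%. `usage_coupling = 0` decouples usage from
#' interaction strength; `usage_noise_sd = 0` makes the link strictly
#' monotone.
#'
#' @inheritParams expected_interaction_weights
#' @return `data.frame` with columns `gene`, `fragment_id`, `usage_percent`.
#' @export
simulate_usage <- function(map, table, params) {
  genes <- gene_host_fragments(table, "vk_functional")
  if (!length(genes)) stop("no functional Vkappa genes in the table")
  fr <- fragments(map)
  hit <- GenomicRanges::findOverlaps(genes, fr, select = "first")
  wt <- params$conditions[length(params$conditions)]
  vps <- names(viewpoint_positions(params))
  lam <- rowMeans(vapply(
    vps,
    function(v) expected_interaction_weights(map, table, v, wt, params)[hit],
    numeric(length(genes))
  ))
  noise <- with_substream(params$seed, 23L,
                          rnorm(length(genes), sd = params$usage_noise_sd))
  raw <- lam^params$usage_coupling * 10^noise
  data.frame(
    gene = S4Vectors::mcols(genes)$name,
    fragment_id = S4Vectors::mcols(fr)$fragment_id[hit],
    usage_percent = 100 * raw / sum(raw),
    stringsAsFactors = FALSE
  )
}

#' Simulate a 3D DNA-FISH dataset for one cell type
#'
#' Probe A centroids scatter across nuclei; probe B is displaced by an
#' isotropic Gaussian whose scale is chosen so the population median of the
#' inter-probe 3D distance (a Maxwell distribution) equals the contracted
#' or non-contracted target median, depending on the cell type.
#'
#' @param cell_type cell-type name; types listed in
#'   `params$fish_contracted_types` use the contracted median.
#' @param params A `sim_params` object.
#' @param n_nuclei number of nuclei (>= 1).
#' @return A `FishDataset`: list with `cell_type` and a `coords` data frame
#'   of per-nucleus probe centroids (micrometers).
#' @export
simulate_fish <- function(cell_type, params, n_nuclei = 150) {
  stopifnot(inherits(params, "sim_params"), n_nuclei >= 1)
  target <- if (cell_type %in% params$fish_contracted_types) {
    params$fish_contracted_median
  } else {
    params$fish_noncontracted_median
  }
  # |N3(0, sigma^2 I)| is Maxwell; median = sigma * sqrt(qchisq(0.5, 3))
  sigma <- target / sqrt(qchisq(0.5, 3))
  offset <- 31L + sum(utf8ToInt(cell_type))
  with_substream(params$seed, offset, {
    a <- matrix(rnorm(3 * n_nuclei, sd = 2), ncol = 3)
    b <- a + matrix(rnorm(3 * n_nuclei, sd = sigma), ncol = 3)
    coords <- data.frame(
      nucleus = seq_len(n_nuclei),
      ax = a[, 1], ay = a[, 2], az = a[, 3],
      bx = b[, 1], by = b[, 2], bz = b[, 3]
    )
    structure(list(cell_type = cell_type, coords = coords),
              class = "FishDataset")
  })
}

#' @export
print.FishDataset <- function(x, ...) {
  cat(sprintf("FishDataset: %s, %d nuclei, median distance %.3f um\n",
              x$cell_type, nrow(x$coords), median(fish_distances(x))))
  invisible(x)
}

#' Write the planted simulation truth as JSON
#'
#' @param params A `sim_params` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(params, path) {
  p <- unclass(params)
  p$focusing_strength <- as.data.frame(p$focusing_strength)
  jsonlite::write_json(p, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
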