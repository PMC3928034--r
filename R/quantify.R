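#' Normalize a count profile to reads per million
#'
#' `frequency_f = count_f x 1e6 / library_size`, the library-size
#' normalization applied per restriction fragment before any averaging or
#' aggregation. Fragments excluded by [filter_fragments()] carry `NA` so
#' they drop out of every downstream statistic while keeping the vector
#' aligned with the fragment map.
#'
#' @param profile A `CountProfile`.
#' @param map the `FragmentMap` the counts are keyed to.
#' @return A `NormalizedProfile`.
#' @export
normalize_rpm <- function(profile, map) {
  stopifnot(inherits(profile, "CountProfile"), inherits(map, "FragmentMap"))
  if (profile$library_size <= 0) stop("library_size must be positive")
  if (length(profile$counts) != n_fragments(map)) {
    stop("profile and map disagree on fragment count")
  }
  freq <- profile$counts * 1e6 / profile$library_size
  freq[!usable_fragments(map)] <- NA_real_
  new_normalized_profile(profile$viewpoint, profile$condition, freq,
                         replicates = profile$replicate)
}

new_normalized_profile <- function(viewpoint, condition, freq, replicates) {
  stopifnot(all(freq >= 0, na.rm = TRUE))
  structure(
    list(viewpoint = viewpoint, condition = condition, freq = freq,
         replicates = replicates),
    class = "NormalizedProfile"
  )
}

#' @export
print.NormalizedProfile <- function(x, ...) {
  cat(sprintf(
    "NormalizedProfile: %s / %s (%d replicate%s averaged); %d fragments, %d usable\n",
    x$viewpoint, x$condition, length(x$replicates),
    if (length(x$replicates) == 1) "" else "s",
    length(x$freq), sum(!is.na(x$freq))))
  invisible(x)
}

#' Average replicate profiles fragment by fragment
#'
#' Replicates are normalized individually first, then averaged per
#' fragment (arithmetic mean), the order used throughout the analysis.
#'
#' @param profiles list of `NormalizedProfile` objects sharing viewpoint,
#'   condition and fragment map.
#' @return A `NormalizedProfile` recording the replicate ids averaged.
#' @export
average_replicates <- function(profiles) {
  if (inherits(profiles, "NormalizedProfile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, TRUE, "NormalizedProfile")))
  vp <- unique(vapply(profiles, `[[`, "", "viewpoint"))
  cond <- unique(vapply(profiles, `[[`, "", "condition"))
  lens <- unique(vapply(profiles, function(p) length(p$freq), 1L))
  if (length(vp) != 1L || length(cond) != 1L || length(lens) != 1L) {
    stop("replicates must share viewpoint, condition and fragment map")
  }
  freq <- rowMeans(vapply(profiles, `[[`, numeric(lens), "freq"))
  new_normalized_profile(vp, cond, freq,
                         replicates = unlist(lapply(profiles,
                                                    `[[`, "replicates")))
}

#' Per-region mean interaction frequencies and inside/outside ratio
#'
#' The regional summary is the average frequency per usable restriction
#' fragment within each region. The inside/outside ratio divides the mean
#' over Vkappa-region fragments by the mean over the pooled upstream and
#' downstream fragments.
#'
#' @param profile A `NormalizedProfile`.
#' @param map region-labeled `FragmentMap`.
#' @param regions region labels to summarize.
#' @return A `RegionSummary`: data frame of per-region means and fragment
#'   counts, with the inside/outside ratio as attribute
#'   `inside_outside_ratio` (also returned by [inside_outside_ratio()]).
#' @export
region_means <- function(profile, map,
                         regions = c("upstream", "vkappa", "downstream")) {
  stopifnot(inherits(profile, "NormalizedProfile"),
            inherits(map, "FragmentMap"))
  reg <- as.character(S4Vectors::mcols(fragments(map))$region)
  ok <- !is.na(profile$freq)
  out <- data.frame(region = regions, mean_freq = NA_real_,
                    n_fragments = NA_integer_)
  for (i in seq_along(regions)) {
    sel <- ok & reg == regions[i]
    if (!any(sel)) {
      stop("region '", regions[i], "' has no usable fragments")
    }
    out$mean_freq[i] <- mean(profile$freq[sel])
    out$n_fragments[i] <- sum(sel)
  }
  inside <- ok & reg == "vkappa"
  outside <- ok & reg %in% c("upstream", "downstream")
  ratio <- if (any(inside) && any(outside)) {
    mean(profile$freq[inside]) / mean(profile$freq[outside])
  } else {
    NA_real_
  }
  attr(out, "inside_outside_ratio") <- ratio
  class(out) <- c("RegionSummary", "data.frame")
  out
}

#' @rdname region_means
#' @export
inside_outside_ratio <- function(profile, map) {
  attr(region_means(profile, map), "inside_outside_ratio")
}

#' Bin a profile into fixed genomic windows
#'
#' Each bin holds the sum of the frequencies of the usable fragments whose
#' midpoint falls inside it; bins tile the fragment-map extent. This is the
#' per-100-kb track used for locus-wide line graphs.
#'
#' @param profile A `NormalizedProfile`.
#' @param map the `FragmentMap`.
#' @param bin_size bin width in bp (default 100 kb).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `value`
#'   (1-based inclusive coordinates).
#' @export
bin_profile <- function(profile, map, bin_size = 1e5) {
  stopifnot(bin_size > 0)
  fr <- fragments(map)
  lo <- min(GenomicRanges::start(fr)) - 1  # 0-based extent start
  hi <- max(GenomicRanges::end(fr))
  starts0 <- seq(floor(lo / bin_size) * bin_size, hi - 1, by = bin_size)
  mid <- floor((GenomicRanges::start(fr) + GenomicRanges::end(fr)) / 2)
  idx <- floor((mid - 1) / bin_size) - floor(lo / bin_size) + 1
  ok <- !is.na(profile$freq)
  value <- numeric(length(starts0))
  agg <- tapply(profile$freq[ok], idx[ok], sum)
  value[as.integer(names(agg))] <- as.numeric(agg)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(fr))[1],
    start = starts0 + 1,
    end = pmin(starts0 + bin_size, hi),
    value = value
  )
}

#' Export a normalized profile (or binned track) as bedGraph
#'
#' @param profile A `NormalizedProfile` or a binned track data frame from
#'   [bin_profile()].
#' @param map the `FragmentMap` (needed for profiles only).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path, map = NULL) {
  if (inherits(profile, "NormalizedProfile")) {
    stopifnot(!is.null(map))
    fr <- fragments(map)
    ok <- !is.na(profile$freq)
    gr <- GenomicRanges::granges(fr)[ok]
    S4Vectors::mcols(gr)$score <- profile$freq[ok]
  } else {
    gr <- GenomicRanges::GRanges(
      profile$chrom,
      IRanges::IRanges(profile$start, profile$end)
    )
    S4Vectors::mcols(gr)$score <- profile$value
  }
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
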