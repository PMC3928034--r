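#' Parse a "chrom:start-end" region string
#'
#' Commas in the coordinates are ignored, so printed genome-browser style
#' coordinates ("chr6:70,659,392-70,693,183") can be pasted directly.
#' Coordinates are interpreted as 1-based inclusive.
#'
#' @param x character vector of region strings.
#' @return A [GenomicRanges::GRanges] object.
#' @export
#' @examples
#' parse_region("chr6:70,659,392-70,693,183")
parse_region <- function(x) {
  x <- gsub(",", "", x)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed region string(s): ", paste(x[bad], collapse = ", "))
  }
  GenomicRanges::GRanges(
    seqnames = vapply(m, `[`, "", 2L),
    ranges = IRanges::IRanges(
      start = as.numeric(vapply(m, `[`, "", 3L)),
      end = as.numeric(vapply(m, `[`, "", 4L))
    )
  )
}

#' Default Igkappa region partition (mm9)
#'
#' The locus and its flanking sequence are divided into three named parts:
#' a ~2 Mb upstream region, the ~3.2 Mb Vkappa gene region, and a ~3.2 Mb
#' downstream region. Coordinates are the mm9 genome build defaults used
#' throughout the quantitative analysis; pass a different `GRanges` with the
#' same names to [assign_regions()] to override them.
#'
#' @return Named `GRanges` with ranges `upstream`, `vkappa`, `downstream`.
#' @export
igk_partition <- function() {
  gr <- parse_region(c(
    "chr6:65,441,978-67,443,029",
    "chr6:67,443,034-70,801,754",
    "chr6:70,801,759-73,993,074"
  ))
  names(gr) <- c("upstream", "vkappa", "downstream")
  gr
}

#' Default viewpoint-proximal exclusion zone (mm9)
#'
#' Fragments in the immediate vicinity of the kappa regulatory elements
#' (Sis, iEk, 3'Ek) carry high background signal, a characteristic of all
#' 3C-based assays, and are excluded from downstream statistics.
#'
#' @return `GRanges` of length one.
#' @export
igk_exclusion_zone <- function() {
  parse_region("chr6:70,659,392-70,693,183")
}

region_levels <- function() c("upstream", "vkappa", "downstream", "unassigned")

exclusion_reasons <- function() c("none", "too_short", "viewpoint_proximal")

new_fragment_map <- function(gr, enzyme_motif = NA_character_,
                             cut_offset = NA_integer_) {
  if (is.unsorted(GenomicRanges::start(gr))) {
    gr <- GenomicRanges::sort(gr)
  }
  if (length(gr) > 1L &&
      any(GenomicRanges::start(gr)[-1L] <=
            GenomicRanges::end(gr)[-length(gr)])) {
    stop("fragments of a map must be non-overlapping and sorted")
  }
  mc <- S4Vectors::mcols(gr)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    fragment_id = seq_along(gr),
    region = if (is.null(mc$region)) {
      factor(rep("unassigned", length(gr)), region_levels())
    } else mc$region,
    excluded = if (is.null(mc$excluded)) {
      rep(FALSE, length(gr))
    } else mc$excluded,
    excl_reason = if (is.null(mc$excl_reason)) {
      factor(rep("none", length(gr)), exclusion_reasons())
    } else mc$excl_reason
  )
  structure(
    list(fragments = gr, enzyme_motif = enzyme_motif,
         cut_offset = cut_offset),
    class = "FragmentMap"
  )
}

#' @export
print.FragmentMap <- function(x, ...) {
  fr <- x$fragments
  cat(sprintf("FragmentMap: %d fragments on %s", length(fr),
              paste(unique(as.character(GenomicRanges::seqnames(fr))),
                    collapse = ",")))
  if (!is.na(x$enzyme_motif)) {
    cat(sprintf(" (enzyme motif %s, cut offset %d)",
                x$enzyme_motif, x$cut_offset))
  }
  cat("\n")
  cat(sprintf("  excluded: %d (%s)\n", sum(S4Vectors::mcols(fr)$excluded),
              paste(capture_reason_counts(fr), collapse = ", ")))
  reg <- table(S4Vectors::mcols(fr)$region)
  cat("  regions: ", paste(names(reg), reg, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

capture_reason_counts <- function(fr) {
  tab <- table(S4Vectors::mcols(fr)$excl_reason)
  tab <- tab[names(tab) != "none" & tab > 0]
  if (!length(tab)) return("none")
  paste(names(tab), tab, sep = ":")
}

#' Fragments of a map as GRanges
#' @param map A `FragmentMap`.
#' @return `GRanges` with metadata columns `fragment_id`, `region`,
#'   `excluded`, `excl_reason`.
#' @export
fragments <- function(map) {
  stopifnot(inherits(map, "FragmentMap"))
  map$fragments
}

#' @rdname fragments
#' @export
n_fragments <- function(map) length(fragments(map))

#' @rdname fragments
#' @export
fragment_lengths <- function(map) GenomicRanges::width(fragments(map))

#' Logical mask of fragments usable for downstream statistics
#' @param map A `FragmentMap`.
#' @return Logical vector, `TRUE` for non-excluded fragments.
#' @export
usable_fragments <- function(map) !S4Vectors::mcols(fragments(map))$excluded

#' In-silico restriction digest of a nucleotide sequence
#'
#' Scans the sequence for exact, case-insensitive occurrences of the enzyme
#' recognition motif and cuts `cut_offset` bases into each occurrence
#' (BglII, A^GATCT, cuts one base in). Consecutive cut positions delimit the
#' restriction fragments, which tile the sequence exactly. Overlapping motif
#' occurrences are resolved left to right. Only the primary enzyme is
#' modeled; secondary digestion does not change the fragment resolution of
#' the analysis.
#'
#' @param sequence character string or [Biostrings::DNAString] to digest.
#' @param chrom chromosome name given to the resulting fragments.
#' @param motif recognition motif (A/C/G/T only, length >= 4).
#' @param cut_offset cut position within the motif, `0 <= cut_offset <=
#'   nchar(motif)`.
#' @return A `FragmentMap`.
#' @export
#' @examples
#' digest_sequence("GGAGATCTGG", chrom = "chrT")
digest_sequence <- function(sequence, chrom = "chrU", motif = "AGATCT",
                            cut_offset = 1L) {
  if (inherits(sequence, "DNAString")) sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("sequence must be non-empty")
  motif <- toupper(motif)
  if (nchar(motif) < 4L) stop("motif length must be >= 4")
  if (grepl("[^ACGT]", motif)) {
    stop("unsupported motif: ambiguity codes are not allowed")
  }
  if (cut_offset < 0L || cut_offset > nchar(motif)) {
    stop("cut_offset must lie within the motif")
  }
  len <- nchar(sequence)
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(motif),
    Biostrings::DNAString(toupper(sequence))
  )
  # 0-based cut coordinates; drop cuts falling on the sequence boundaries
  cuts <- sort(unique(Biostrings::start(hits) - 1L + cut_offset))
  cuts <- cuts[cuts > 0L & cuts < len]
  bounds <- c(0L, cuts, len)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = head(bounds, -1L) + 1L,
                              end = tail(bounds, -1L))
  )
  new_fragment_map(gr, enzyme_motif = motif,
                   cut_offset = as.integer(cut_offset))
}

#' Flag fragments excluded from downstream statistics
#'
#' Very small fragments (below `min_length`, default 100 bp) are flagged
#' `too_short`; fragments overlapping any exclusion zone are flagged
#' `viewpoint_proximal`. Flagged fragments stay in the map (so coordinates
#' and indices are stable) but carry no frequency downstream. Flags
#' accumulate: a fragment flagged by an earlier call is never unflagged, so
#' the operation is idempotent and monotone in `min_length`.
#'
#' @param map A `FragmentMap`.
#' @param min_length minimum fragment length in bp retained for analysis.
#' @param exclusion_zones `GRanges` or "chrom:start-end" strings; any
#'   overlap excludes the fragment.
#' @return The updated `FragmentMap`.
#' @export
filter_fragments <- function(map, min_length = 100, exclusion_zones = NULL) {
  stopifnot(inherits(map, "FragmentMap"), min_length >= 0)
  fr <- fragments(map)
  mc <- S4Vectors::mcols(fr)
  short <- GenomicRanges::width(fr) < min_length
  prox <- rep(FALSE, length(fr))
  if (!is.null(exclusion_zones)) {
    if (is.character(exclusion_zones)) {
      exclusion_zones <- parse_region(exclusion_zones)
    }
    zone_chrom <- as.character(unique(GenomicRanges::seqnames(exclusion_zones)))
    map_chrom <- as.character(unique(GenomicRanges::seqnames(fr)))
    if (!all(zone_chrom %in% map_chrom)) {
      stop("exclusion zone on unknown chromosome: ",
           paste(setdiff(zone_chrom, map_chrom), collapse = ", "))
    }
    prox <- IRanges::overlapsAny(fr, exclusion_zones)
  }
  reason <- as.character(mc$excl_reason)
  newly_short <- short & !mc$excluded
  reason[newly_short] <- "too_short"
  newly_prox <- prox & !mc$excluded & !newly_short
  reason[newly_prox] <- "viewpoint_proximal"
  mc$excluded <- mc$excluded | short | prox
  mc$excl_reason <- factor(reason, exclusion_reasons())
  S4Vectors::mcols(fr) <- mc
  map$fragments <- fr
  map
}

#' Label fragments with the locus region containing their midpoint
#'
#' Each fragment is assigned to the partition interval that contains its
#' midpoint; fragments whose midpoint falls in no interval are labeled
#' `unassigned`. Midpoint assignment is deterministic and safe for
#' partitions whose printed boundaries nearly abut.
#'
#' @param map A `FragmentMap`.
#' @param partition named `GRanges`, by default [igk_partition()].
#' @return The updated `FragmentMap`.
#' @export
assign_regions <- function(map, partition = igk_partition()) {
  stopifnot(inherits(map, "FragmentMap"))
  if (is.null(names(partition)) || anyDuplicated(names(partition))) {
    stop("partition intervals must carry unique names")
  }
  if (length(IRanges::findOverlaps(partition, drop.self = TRUE,
                                   drop.redundant = TRUE)) > 0) {
    stop("partition intervals must not overlap")
  }
  fr <- fragments(map)
  mids <- floor((GenomicRanges::start(fr) + GenomicRanges::end(fr)) / 2)
  chr <- as.character(GenomicRanges::seqnames(fr))
  lab <- rep("unassigned", length(fr))
  p_chr <- as.character(GenomicRanges::seqnames(partition))
  p_start <- GenomicRanges::start(partition)
  p_end <- GenomicRanges::end(partition)
  for (i in seq_along(partition)) {  # earlier intervals win on overlap
    sel <- lab == "unassigned" & chr == p_chr[i] &
      mids >= p_start[i] & mids <= p_end[i]
    lab[sel] <- names(partition)[i]
  }
  lv <- union(region_levels(), names(partition))
  S4Vectors::mcols(fr)$region <- factor(lab, lv)
  map$fragments <- fr
  map
}

#' Per-region fragment tallies before and after length filtering
#'
#' Reports, for every region label, the total number of fragments and the
#' number passing all exclusion filters, so tallies can be compared with
#' counts produced under either convention.
#'
#' @param map A `FragmentMap` with regions assigned.
#' @return `data.frame` with columns `region`, `n_total`, `n_usable`.
#' @export
region_fragment_counts <- function(map) {
  mc <- S4Vectors::mcols(fragments(map))
  reg <- mc$region
  data.frame(
    region = levels(reg),
    n_total = as.vector(table(reg)),
    n_usable = as.vector(table(reg[!mc$excluded])),
    row.names = NULL
  )
}

#' Read and write fragment maps as BED4
#'
#' The BED name column carries the fragment index. Coordinates follow BED
#' conventions (0-based half-open on disk); conversion is handled by
#' rtracklayer.
#'
#' @param path file path.
#' @param map A `FragmentMap`.
#' @return `read_fragment_map` returns a `FragmentMap`;
#'   `write_fragment_map` returns `path` invisibly.
#' @export
read_fragment_map <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  S4Vectors::mcols(gr) <- NULL
  new_fragment_map(gr)
}

#' @rdname read_fragment_map
#' @export
write_fragment_map <- function(map, path) {
  fr <- fragments(map)
  out <- GenomicRanges::granges(fr)
  S4Vectors::mcols(out)$name <- as.character(S4Vectors::mcols(fr)$fragment_id)
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}
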