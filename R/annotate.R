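#' Closed vocabulary of genomic feature kinds
#'
#' @return Character vector of the feature kinds the annotation matrix
#'   knows about: functional and pseudo Vkappa gene segments, Ctcf, Ikaros
#'   and E2a binding sites, H3K4me2/3-marked intervals, and `other`.
#' @export
feature_kinds <- function() {
  c("vk_functional", "vk_pseudo", "ctcf", "ikaros", "e2a", "h3k4me23",
    "other")
}

#' Construct a feature set
#'
#' Features are genomic intervals of a known kind (see [feature_kinds()]).
#' Functional Vkappa genes may carry a `usage_percent` value, the fraction
#' of the expressed repertoire using that gene.
#'
#' @param chrom,start,end interval coordinates (1-based inclusive).
#' @param kind feature kind, one of [feature_kinds()].
#' @param name feature identifier (gene or peak id).
#' @param usage_percent optional usage values (%); `NA` where unknown.
#' @return `GRanges` with metadata columns `kind`, `name`, `usage_percent`.
#' @export
make_features <- function(chrom, start, end, kind, name = NULL,
                          usage_percent = NA_real_) {
  kind <- as.character(kind)
  bad <- setdiff(unique(kind), feature_kinds())
  if (length(bad)) stop("unknown feature kind(s): ", paste(bad, collapse = ", "))
  n <- max(length(start), length(end))
  if (n == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      kind = character(0), name = character(0),
      usage_percent = numeric(0))
    return(gr)
  }
  if (is.null(name)) name <- sprintf("feat%04d", seq_len(n))
  usage_percent <- rep_len(as.numeric(usage_percent), n)
  if (any(usage_percent < 0, na.rm = TRUE)) {
    stop("usage_percent must be non-negative")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  S4Vectors::mcols(gr)$kind <- rep_len(kind, n)
  S4Vectors::mcols(gr)$name <- rep_len(name, n)
  S4Vectors::mcols(gr)$usage_percent <- usage_percent
  gr
}

#' Read features of one kind from a BED file
#'
#' BED6 input: the name column carries the gene/peak id and, for Vkappa
#' genes, the score column carries usage x 100 (so 0.25% usage is stored as
#' score 25). Usage can instead be joined later from a TSV table with
#' [attach_usage()].
#'
#' @param path BED file path.
#' @param kind feature kind assigned to every interval in the file.
#' @param score_is_usage if `TRUE`, usage_percent is decoded from score/100.
#' @return `GRanges` feature set.
#' @export
read_features <- function(path, kind, score_is_usage = FALSE) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- sprintf("%s%04d", kind, seq_along(gr))
  usage <- NA_real_
  if (score_is_usage && !is.null(S4Vectors::mcols(gr)$score)) {
    usage <- S4Vectors::mcols(gr)$score / 100
  }
  make_features(as.character(GenomicRanges::seqnames(gr)),
                GenomicRanges::start(gr), GenomicRanges::end(gr),
                kind = kind, name = nm, usage_percent = usage)
}

#' Join a gene-usage table onto a feature set
#'
#' @param features feature `GRanges` (from [make_features()]).
#' @param usage `data.frame` with columns `gene` and `usage_percent`, e.g.
#'   read with [read_usage_table()].
#' @return The feature set with `usage_percent` filled in by gene name.
#' @export
attach_usage <- function(features, usage) {
  stopifnot(all(c("gene", "usage_percent") %in% names(usage)))
  idx <- match(S4Vectors::mcols(features)$name, usage$gene)
  hit <- !is.na(idx)
  S4Vectors::mcols(features)$usage_percent[hit] <-
    usage$usage_percent[idx[hit]]
  features
}

#' @rdname attach_usage
#' @param path TSV file with columns `gene`, `usage_percent`.
#' @export
read_usage_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "usage_percent") %in% names(df)))
  df
}

#' Annotate fragments with features by same-fragment colocalization
#'
#' A fragment is marked positive for a feature kind if at least one feature
#' of that kind overlaps it; this is the same-restriction-fragment
#' colocalization rule used throughout the 3C-seq quantification, with no
#' distance window. A feature spanning a cut site marks every fragment it
#' overlaps. Fragments hosting several functional Vkappa genes take the
#' maximum usage value. Features that overlap no fragment (wrong chromosome
#' or outside the map extent) are dropped with a warning.
#'
#' @param map A `FragmentMap`.
#' @param features feature `GRanges` (see [make_features()]).
#' @return A `FeatureTable`: list with elements `features` (the retained
#'   features), `matrix` (fragments x kinds logical annotation matrix),
#'   `usage` (per-fragment usage %, `NA` where no functional Vkappa gene
#'   resides), and `n_dropped`.
#' @export
annotate_fragments <- function(map, features) {
  stopifnot(inherits(map, "FragmentMap"))
  fr <- fragments(map)
  n <- length(fr)
  kinds <- feature_kinds()
  mat <- matrix(FALSE, nrow = n, ncol = length(kinds),
                dimnames = list(NULL, kinds))
  usage <- rep(NA_real_, n)
  n_dropped <- 0L
  if (length(features)) {
    bad <- setdiff(unique(S4Vectors::mcols(features)$kind), kinds)
    if (length(bad)) stop("unknown feature kind(s): ",
                          paste(bad, collapse = ", "))
    hits <- GenomicRanges::findOverlaps(features, fr)
    covered <- seq_along(features) %in% S4Vectors::queryHits(hits)
    n_dropped <- sum(!covered)
    if (n_dropped > 0L) {
      warning(n_dropped,
              " feature(s) outside the fragment map extent were dropped")
      features <- features[covered]
      hits <- GenomicRanges::findOverlaps(features, fr)
    }
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    k <- S4Vectors::mcols(features)$kind[q]
    mat[cbind(s, match(k, kinds))] <- TRUE
    u <- S4Vectors::mcols(features)$usage_percent[q]
    vk <- k == "vk_functional" & !is.na(u)
    if (any(vk)) {
      agg <- tapply(u[vk], s[vk], max)
      usage[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  structure(
    list(features = features, matrix = mat, usage = usage,
         n_dropped = n_dropped),
    class = "FeatureTable"
  )
}

#' @export
print.FeatureTable <- function(x, ...) {
  cat(sprintf("FeatureTable: %d features on %d fragments\n",
              length(x$features), nrow(x$matrix)))
  marks <- colSums(x$matrix)
  marks <- marks[marks > 0]
  if (length(marks)) {
    cat("  marked fragments:",
        paste(names(marks), marks, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fragment mask from a boolean expression over feature kinds
#'
#' Evaluates an R logical expression whose variables are feature kinds
#' (e.g. `"vk_functional & ikaros & !e2a"`) against the annotation matrix,
#' yielding one logical value per fragment. Fragments excluded from the
#' analysis are forced to `FALSE` when `map` is supplied.
#'
#' @param table A `FeatureTable` from [annotate_fragments()].
#' @param spec character scalar: logical expression over [feature_kinds()]
#'   using `&`, `|`, `!` and parentheses.
#' @param map optional `FragmentMap`; if given, excluded fragments are
#'   masked out.
#' @return Logical vector over fragments.
#' @export
#' @examples
#' # the "Ikaros-only" Vkappa+ class:
#' # subgroup_mask(table, "vk_functional & ikaros & !e2a")
subgroup_mask <- function(table, spec, map = NULL) {
  stopifnot(inherits(table, "FeatureTable"), is.character(spec),
            length(spec) == 1L)
  expr <- str2lang(spec)
  vars <- all.vars(expr)
  bad <- setdiff(vars, colnames(table$matrix))
  if (length(bad)) stop("unknown feature kind(s) in mask expression: ",
                        paste(bad, collapse = ", "))
  env <- list2env(as.list(as.data.frame(table$matrix)))
  mask <- eval(expr, envir = env)
  if (!is.logical(mask) || length(mask) != nrow(table$matrix)) {
    stop("mask expression must evaluate to one logical per fragment")
  }
  if (!is.null(map)) mask <- mask & usable_fragments(map)
  mask
}

#' Write the per-fragment annotation matrix as TSV
#'
#' @param table A `FeatureTable`.
#' @param map the `FragmentMap` the table was built on.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(table, map, path) {
  fr <- fragments(map)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(fr)),
    start = GenomicRanges::start(fr),
    end = GenomicRanges::end(fr),
    fragment_id = S4Vectors::mcols(fr)$fragment_id,
    region = as.character(S4Vectors::mcols(fr)$region),
    excluded = S4Vectors::mcols(fr)$excluded,
    table$matrix,
    usage_percent = table$usage
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
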