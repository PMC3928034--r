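#' Euclidean 3D distance between two probe centroids
#'
#' `sqrt((Xa-Xb)^2 + (Ya-Yb)^2 + (Za-Zb)^2)` in micrometers, the
#' inter-probe distance computed per nucleus from the centers of mass of
#' the two hybridization signals.
#'
#' @param a,b numeric length-3 vectors `(X, Y, Z)` in micrometers.
#' @return Distance in micrometers.
#' @export
#' @examples
#' probe_distance(c(0, 0, 0), c(3, 4, 0))  # 5
probe_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == 3, length(b) == 3)
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("probe coordinates must be finite")
  }
  sqrt(sum((a - b)^2))
}

#' Per-nucleus inter-probe distances of a FISH dataset
#'
#' @param dataset A `FishDataset` (see [simulate_fish()] or
#'   [read_fish_table()]).
#' @return Numeric vector of distances (micrometers), one per nucleus.
#' @export
fish_distances <- function(dataset) {
  stopifnot(inherits(dataset, "FishDataset"))
  co <- dataset$coords
  sqrt((co$ax - co$bx)^2 + (co$ay - co$by)^2 + (co$az - co$bz)^2)
}

#' Compare inter-probe distance distributions between cell types
#'
#' Summarizes each cell type by its median inter-probe distance (the
#' headline statistic of locus-contraction FISH panels) and tests every
#' pair of cell types with the two-sided Mann-Whitney U test.
#'
#' @param datasets list of at least two `FishDataset` objects.
#' @return A `DistanceSummary`: list with `distances` (per type), `medians`,
#'   `n`, and `p_values` (symmetric matrix of pairwise two-sided p).
#' @export
compare_cell_types <- function(datasets) {
  if (length(datasets) < 2) stop("need at least two datasets")
  stopifnot(all(vapply(datasets, inherits, TRUE, "FishDataset")))
  types <- vapply(datasets, `[[`, "", "cell_type")
  if (anyDuplicated(types)) {
    types <- make.unique(types)
  }
  dist <- lapply(datasets, fish_distances)
  names(dist) <- types
  p <- matrix(NA_real_, length(types), length(types),
              dimnames = list(types, types))
  for (i in seq_along(types)) {
    for (j in seq_along(types)) {
      if (i < j) {
        p[i, j] <- p[j, i] <- mann_whitney_u(dist[[i]], dist[[j]])$p
      }
    }
  }
  diag(p) <- 1
  structure(
    list(distances = dist,
         medians = vapply(dist, median, numeric(1)),
         n = vapply(dist, length, integer(1)),
         p_values = p),
    class = "DistanceSummary"
  )
}

#' @export
print.DistanceSummary <- function(x, ...) {
  cat("DistanceSummary (median inter-probe distance, um):\n")
  for (t in names(x$medians)) {
    cat(sprintf("  %s: %.3f (n = %d)\n", t, x$medians[[t]], x$n[[t]]))
  }
  cat("pairwise Mann-Whitney p-values:\n")
  print(signif(x$p_values, 3))
  invisible(x)
}

#' Read and write FISH probe-centroid tables
#'
#' Long-format TSV with columns `cell_type`, `nucleus_id`, `probe` (`A` or
#' `B`), `X`, `Y`, `Z` (micrometers); each nucleus carries both probes.
#'
#' @param path TSV file.
#' @return `read_fish_table`: list of `FishDataset`, one per cell type;
#'   `write_fish_table`: `path` invisibly.
#' @export
read_fish_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_type", "nucleus_id", "probe", "X", "Y", "Z")
  if (!all(need %in% names(df))) {
    stop("FISH table must have columns: ", paste(need, collapse = ", "))
  }
  lapply(split(df, df$cell_type), function(d) {
    a <- d[d$probe == "A", ]
    b <- d[d$probe == "B", ]
    m <- match(a$nucleus_id, b$nucleus_id)
    if (anyNA(m)) stop("each nucleus needs both probe A and probe B")
    structure(
      list(cell_type = d$cell_type[1],
           coords = data.frame(nucleus = a$nucleus_id,
                               ax = a$X, ay = a$Y, az = a$Z,
                               bx = b$X[m], by = b$Y[m], bz = b$Z[m])),
      class = "FishDataset"
    )
  })
}

#' @rdname read_fish_table
#' @param datasets list of `FishDataset` objects.
#' @export
write_fish_table <- function(datasets, path) {
  if (inherits(datasets, "FishDataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(d) {
    co <- d$coords
    rbind(
      data.frame(cell_type = d$cell_type, nucleus_id = co$nucleus,
                 probe = "A", X = co$ax, Y = co$ay, Z = co$az),
      data.frame(cell_type = d$cell_type, nucleus_id = co$nucleus,
                 probe = "B", X = co$bx, Y = co$by, Z = co$bz)
    )
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
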