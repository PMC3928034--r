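#' Mann-Whitney U test with midranks, exact small-sample enumeration
#'
#' Computes the rank-sum statistic `U` for the first sample using midranks
#' for ties. When both samples are at most `exact_limit` observations the
#' two-sided p-value is computed exactly by enumerating all
#' `choose(n1 + n2, n1)` group assignments of the pooled (mid)ranks --
#' valid with ties, unlike the classical null tables. Larger samples use
#' the normal approximation with tie correction and a 0.5 continuity
#' correction. `U + U' = n1 * n2` always holds, and `U` is invariant under
#' any strictly monotone transform of the pooled data.
#'
#' @param x,y numeric samples (both non-empty).
#' @param exact_limit largest per-group size for exact enumeration.
#' @return List with `U`, `U_prime`, `p` (two-sided), `method`, `n1`, `n2`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
mann_whitney_u <- function(x, y, exact_limit = 8) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))  # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_limit && n2 <= exact_limit) {
    idx <- combn(n, n1)
    us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tie_term))
    z <- (abs(U - mu) - 0.5) / sigma
    p <- min(1, 2 * pnorm(-max(z, 0)))
    method <- "normal approximation"
  }
  list(U = U, U_prime = n1 * n2 - U, p = p, method = method,
       n1 = n1, n2 = n2)
}

#' Significance stars at the 0.05 / 0.01 / 0.001 levels
#'
#' @param p p-value(s).
#' @param alpha_levels significance cutoffs, largest first.
#' @return Character vector: `"n.s."`, `"*"`, `"**"`, or `"***"`.
#' @export
significance_stars <- function(p, alpha_levels = c(0.05, 0.01, 0.001)) {
  lv <- sort(alpha_levels, decreasing = TRUE)
  vapply(p, function(pp) {
    stars <- sum(pp < lv)
    if (stars == 0) "n.s." else strrep("*", stars)
  }, "")
}

#' Compare interaction frequencies between two fragment classes
#'
#' Reports group means and the Mann-Whitney rank-sum comparison of the
#' frequencies selected by two disjoint fragment masks (e.g. Vkappa+ vs
#' Vkappa- fragments, or TF-site-positive vs -negative fragments).
#'
#' @param profile A `NormalizedProfile`.
#' @param mask_a,mask_b disjoint logical fragment masks (see
#'   [subgroup_mask()]); each must select at least one usable fragment.
#' @param labels group labels for reporting.
#' @param exact_limit passed to [mann_whitney_u()].
#' @return A `ComparisonResult`: list with `labels`, `means`, `n`, `U`,
#'   `p`, `stars`.
#' @export
group_comparison <- function(profile, mask_a, mask_b,
                             labels = c("A", "B"), exact_limit = 8) {
  stopifnot(inherits(profile, "NormalizedProfile"),
            length(mask_a) == length(profile$freq),
            length(mask_b) == length(profile$freq))
  if (any(mask_a & mask_b)) stop("masks must be disjoint")
  a <- profile$freq[mask_a & !is.na(profile$freq)]
  b <- profile$freq[mask_b & !is.na(profile$freq)]
  if (!length(a) || !length(b)) {
    stop("each mask must select at least one usable fragment")
  }
  mw <- mann_whitney_u(a, b, exact_limit = exact_limit)
  structure(
    list(labels = labels, means = setNames(c(mean(a), mean(b)), labels),
         n = setNames(c(length(a), length(b)), labels),
         U = mw$U, p = mw$p, stars = significance_stars(mw$p)),
    class = "ComparisonResult"
  )
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("ComparisonResult: %s (n=%d, mean %.3g) vs %s (n=%d, mean %.3g)\n",
              x$labels[1], x$n[1], x$means[1],
              x$labels[2], x$n[2], x$means[2]))
  cat(sprintf("  Mann-Whitney U = %g, p = %.4g %s\n", x$U, x$p, x$stars))
  invisible(x)
}

fold_class_levels <- function() {
  c("increase", "decrease", "stable", "no_evidence")
}

avg_counts <- function(profiles) {
  rowMeans(vapply(profiles, `[[`, numeric(length(profiles[[1]]$counts)),
                  "counts"))
}

avg_freq <- function(profiles, map) {
  average_replicates(lapply(profiles, normalize_rpm, map = map))$freq
}

#' Classify per-fragment interaction changes between two conditions
#'
#' Fragments whose replicate-averaged raw counts never exceed
#' `evidence_threshold` in either condition at any of the supplied
#' viewpoints are classified `no_evidence`. For the remaining fragments the
#' ratio of averaged normalized frequencies (first condition over second)
#' classifies each fragment per viewpoint: `> fold_threshold` is
#' `increase`, `< 1/fold_threshold` is `decrease`, otherwise `stable`
#' (a ratio of exactly the threshold is `stable`). A zero denominator with
#' signal in the numerator counts as `increase` (infinite ratio).
#'
#' @param wt,mutant named lists (one element per viewpoint) of replicate
#'   `CountProfile` lists, or a single replicate list each for a
#'   one-viewpoint classification.
#' @param map the `FragmentMap`.
#' @param mask logical fragment mask to classify (e.g. Vkappa+ fragments);
#'   defaults to all usable fragments.
#' @param fold_threshold fold-change cutoff (default 1.5).
#' @param evidence_threshold average raw-count evidence cutoff (default
#'   25); set `rpm_evidence = TRUE` to apply it to normalized frequencies
#'   instead.
#' @param rpm_evidence apply the evidence threshold on the RPM scale.
#' @return A `FoldClassification`: list with `classes` (fragments x
#'   viewpoints factor matrix, `NA` outside the mask), `fractions`
#'   (viewpoints x classes, each row summing to 1 over masked fragments),
#'   and the thresholds used.
#' @export
classify_fold_change <- function(wt, mutant, map, mask = NULL,
                                 fold_threshold = 1.5,
                                 evidence_threshold = 25,
                                 rpm_evidence = FALSE) {
  if (fold_threshold < 0 || evidence_threshold < 0) {
    stop("thresholds must be non-negative")
  }
  if (inherits(wt[[1]], "CountProfile")) wt <- list(vp = wt)
  if (inherits(mutant[[1]], "CountProfile")) mutant <- list(vp = mutant)
  stopifnot(length(wt) == length(mutant))
  vps <- names(wt)
  if (is.null(mask)) mask <- usable_fragments(map)
  mask <- mask & usable_fragments(map)
  n <- n_fragments(map)

  evidence_metric <- function(profiles) {
    if (rpm_evidence) avg_freq(profiles, map) else avg_counts(profiles)
  }
  evidence <- rep(FALSE, n)
  for (v in vps) {
    ev <- pmax(evidence_metric(wt[[v]]), evidence_metric(mutant[[v]]),
               na.rm = TRUE)
    evidence <- evidence | (!is.na(ev) & ev > evidence_threshold)
  }

  classes <- matrix(NA_character_, nrow = n, ncol = length(vps),
                    dimnames = list(NULL, vps))
  n_inf <- 0L
  for (v in vps) {
    fa <- avg_freq(wt[[v]], map)
    fb <- avg_freq(mutant[[v]], map)
    r <- fa / fb
    cls <- rep("stable", n)
    cls[which(r > fold_threshold)] <- "increase"
    cls[which(r < 1 / fold_threshold)] <- "decrease"
    inf_up <- which(is.infinite(r))
    cls[inf_up] <- "increase"
    n_inf <- n_inf + sum(inf_up %in% which(mask & evidence))
    cls[which(is.nan(r))] <- "stable"  # 0/0: no change detectable
    cls[!evidence] <- "no_evidence"
    cls[!mask] <- NA_character_
    classes[, v] <- cls
  }
  if (n_inf > 0) {
    message(n_inf, " fragment(s) with zero frequency in the second ",
            "condition classified as increase (infinite ratio)")
  }
  fractions <- t(apply(classes, 2, function(cl) {
    tab <- table(factor(cl, fold_class_levels()))
    as.numeric(tab) / sum(tab)
  }))
  colnames(fractions) <- fold_class_levels()
  structure(
    list(classes = classes, fractions = fractions,
         fold_threshold = fold_threshold,
         evidence_threshold = evidence_threshold),
    class = "FoldClassification"
  )
}

#' @export
print.FoldClassification <- function(x, ...) {
  cat(sprintf("FoldClassification (fold > %g, evidence > %g counts)\n",
              x$fold_threshold, x$evidence_threshold))
  print(round(100 * x$fractions, 1))
  invisible(x)
}

#' Squared correlation of two log-scaled frequency vectors
#'
#' Frequencies below `floor` are set to the floor before the log10
#' transform (so values below 1 enter as 10^0); the result is the squared
#' Pearson correlation of the transformed pairs, the R^2 used for
#' inter-viewpoint gene-interaction correlation plots.
#'
#' @param freq_a,freq_b paired per-gene frequencies (length >= 3).
#' @param floor transform floor (default 1).
#' @return A `CorrelationResult`: list with `r_squared`, `n`, `transform`.
#' @export
viewpoint_correlation <- function(freq_a, freq_b, floor = 1) {
  stopifnot(length(freq_a) == length(freq_b))
  ok <- !is.na(freq_a) & !is.na(freq_b)
  freq_a <- freq_a[ok]; freq_b <- freq_b[ok]
  if (length(freq_a) < 3) stop("need at least 3 paired values")
  la <- log10(pmax(freq_a, floor))
  lb <- log10(pmax(freq_b, floor))
  if (stats::sd(la) == 0 || stats::sd(lb) == 0) {
    stop("correlation undefined: zero variance after transform")
  }
  structure(
    list(r_squared = cor(la, lb)^2, n = length(la),
         transform = sprintf("log10, floor %g", floor)),
    class = "CorrelationResult"
  )
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("CorrelationResult: R^2 = %.3f (n = %d, %s)\n",
              x$r_squared, x$n, x$transform))
  invisible(x)
}

#' Correlation of gene usage categories with interaction frequency
#'
#' Genes are binned into four usage categories (default < 0.1%,
#' 0.1-0.3%, 0.3-0.5%, > 0.5%; bins left-closed on the lower edge) and the
#' mean frequency per occupied category is computed. R^2 is the squared
#' Pearson correlation between category rank (1..4) and category mean
#' frequency.
#'
#' @param usage per-gene usage (% of repertoire).
#' @param freq per-gene interaction frequencies, paired with `usage`.
#' @param bin_edges inner category boundaries (%).
#' @param method `"category_means"` (default) correlates category rank with
#'   category mean frequency; `"genes"` instead correlates usage with
#'   frequency across all genes without binning.
#' @return A `CorrelationResult` with extra elements `category_means` and
#'   `category_counts`.
#' @export
usage_category_correlation <- function(usage, freq,
                                       bin_edges = c(0.1, 0.3, 0.5),
                                       method = c("category_means",
                                                  "genes")) {
  method <- match.arg(method)
  stopifnot(length(usage) == length(freq))
  ok <- !is.na(usage) & !is.na(freq)
  usage <- usage[ok]; freq <- freq[ok]
  if (method == "genes") {
    if (stats::sd(usage) == 0 || stats::sd(freq) == 0) {
      stop("correlation undefined: zero variance")
    }
    return(structure(
      list(r_squared = cor(usage, freq)^2, n = length(usage),
           transform = "per gene, untransformed"),
      class = "CorrelationResult"
    ))
  }
  edges <- c(-Inf, sort(bin_edges), Inf)
  labs <- c(sprintf("<%g%%", bin_edges[1]),
            sprintf("%g-%g%%", head(bin_edges, -1), tail(bin_edges, -1)),
            sprintf(">%g%%", bin_edges[length(bin_edges)]))
  cat_idx <- cut(usage, edges, right = FALSE, labels = FALSE)
  occupied <- sort(unique(cat_idx))
  if (length(occupied) < 2) {
    stop("correlation undefined: all genes fall in one usage category")
  }
  means <- tapply(freq, cat_idx, mean)
  counts <- tapply(freq, cat_idx, length)
  rank <- occupied
  m <- as.numeric(means)
  if (stats::sd(m) == 0) {
    stop("correlation undefined: identical category means")
  }
  structure(
    list(r_squared = cor(rank, m)^2, n = length(usage),
         transform = "category means",
         category_means = setNames(m, labs[occupied]),
         category_counts = setNames(as.numeric(counts), labs[occupied])),
    class = "CorrelationResult"
  )
}
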