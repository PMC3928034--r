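test_that("RPM normalization is count x 1e6 / library size", {
  map <- toy_map()
  cp <- toy_counts(c(2, 8, 0, 0), library_size = 10)
  np <- normalize_rpm(cp, map)
  expect_equal(np$freq, c(200000, 800000, 0, 0))

  # library of exactly one million: frequencies equal counts
  cp2 <- toy_counts(c(5, 7, 1, 2), library_size = 1e6)
  expect_equal(normalize_rpm(cp2, map)$freq, c(5, 7, 1, 2))

  expect_equal(normalize_rpm(toy_counts(c(0, 0, 0, 0), 100), map)$freq,
               rep(0, 4))
  expect_error(normalize_rpm(toy_counts(c(0, 0, 0, 0), 0), map), "positive")
})

test_that("excluded fragments carry no frequency", {
  map <- filter_fragments(toy_map(), min_length = 150)
  np <- normalize_rpm(toy_counts(c(10, 10, 10, 10), 100), map)
  expect_true(is.na(np$freq[1]))
  expect_false(anyNA(np$freq[2:4]))
  # pre-exclusion RPM conservation: in-map reads / library x 1e6
  cp <- toy_counts(c(10, 20, 30, 40), library_size = 200)
  np2 <- normalize_rpm(cp, toy_map())
  expect_equal(sum(np2$freq), 1e6 * sum(cp$counts) / cp$library_size)
})

test_that("replicate averaging is the per-fragment arithmetic mean", {
  a <- toy_profile(c(100, 100, 2, 4))
  b <- toy_profile(c(300, 100, 4, 8))
  avg <- average_replicates(list(a, b))
  expect_equal(avg$freq, c(200, 100, 3, 6))
  expect_equal(average_replicates(list(a, a))$freq, a$freq)
  expect_equal(average_replicates(list(a))$freq, a$freq)
  expect_error(
    average_replicates(list(a, toy_profile(c(1, 2, 3, 4, 5)))),
    "share")
  expect_error(
    average_replicates(list(a, toy_profile(c(1, 2, 3, 4),
                                           condition = "proB"))),
    "share")
})

test_that("normalize-then-average commutes with averaging counts only for equal library sizes", {
  map <- toy_map()
  c1 <- toy_counts(c(10, 20, 30, 40), library_size = 100, replicate = 1L)
  c2 <- toy_counts(c(40, 30, 20, 10), library_size = 100, replicate = 2L)
  norm_first <- average_replicates(lapply(list(c1, c2), normalize_rpm, map))
  pooled <- toy_counts((c1$counts + c2$counts) / 2, library_size = 100)
  expect_equal(norm_first$freq, normalize_rpm(pooled, map)$freq)

  c3 <- toy_counts(c(40, 30, 20, 10), library_size = 400, replicate = 2L)
  norm_first3 <- average_replicates(lapply(list(c1, c3), normalize_rpm, map))
  pooled3 <- toy_counts((c1$counts + c3$counts) / 2,
                        library_size = (100 + 400) / 2)
  expect_false(isTRUE(all.equal(norm_first3$freq,
                                normalize_rpm(pooled3, map)$freq)))
})

region_map <- function() {
  gr <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(start = c(1, 101, 301, 601, 901),
                             end = c(100, 300, 600, 900, 1200))
  )
  map <- kappa3C:::new_fragment_map(gr)
  part <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(start = c(1, 301, 901),
                             end = c(300, 900, 1200)))
  names(part) <- c("upstream", "vkappa", "downstream")
  assign_regions(map, part)
}

test_that("region means average usable fragments and form the inside/outside ratio", {
  map <- region_map()
  np <- toy_profile(c(1, 3, 2, 4, 6))
  rs <- region_means(np, map)
  expect_equal(rs$mean_freq, c(2, 3, 6))  # upstream {1,3}, vk {2,4}, down {6}
  expect_equal(rs$n_fragments, c(2L, 2L, 1L))
  expect_equal(attr(rs, "inside_outside_ratio"), 3 / mean(c(1, 3, 6)))

  flat <- toy_profile(rep(5, 5))
  expect_equal(inside_outside_ratio(flat, map), 1)

  doubled <- toy_profile(2 * np$freq)
  expect_equal(inside_outside_ratio(doubled, map),
               inside_outside_ratio(np, map))

  empty <- toy_profile(c(1, 3, NA, NA, 6))
  expect_error(region_means(empty, map), "no usable fragments")
})

test_that("region means and binning are linear in the profile", {
  map <- region_map()
  a <- toy_profile(c(1, 2, 3, 4, 5))
  b <- toy_profile(c(5, 1, 0, 2, 2))
  lin <- toy_profile(a$freq + 2 * b$freq)
  expect_equal(region_means(lin, map)$mean_freq,
               region_means(a, map)$mean_freq +
                 2 * region_means(b, map)$mean_freq)
  expect_equal(bin_profile(lin, map, 300)$value,
               bin_profile(a, map, 300)$value +
                 2 * bin_profile(b, map, 300)$value)
})

test_that("binning sums fragment frequencies by midpoint and conserves totals", {
  map <- toy_map()  # midpoints 50, 200, 450, 800
  np <- toy_profile(c(5, 7, 11, 13))
  tr <- bin_profile(np, map, bin_size = 250)
  # bins [1,250] [251,500] [501,750] [751,1000]: 5+7, 11, 0, 13
  expect_equal(tr$value, c(12, 11, 0, 13))
  expect_equal(sum(tr$value), sum(np$freq))

  # one fragment per bin reproduces the profile
  tr2 <- bin_profile(np, map, bin_size = 1)
  expect_equal(sum(tr2$value > 0), 4L)
  expect_equal(sort(tr2$value[tr2$value > 0]), sort(np$freq))

  # NA (excluded) fragments do not contribute
  np_na <- toy_profile(c(5, NA, 11, 13))
  expect_equal(sum(bin_profile(np_na, map, 250)$value), 29)
})

test_that("profiles and binned tracks export as bedGraph", {
  map <- toy_map()
  np <- toy_profile(c(1.5, 2, 0, 3))
  p1 <- tempfile(fileext = ".bedGraph")
  write_bedgraph(np, p1, map = map)
  back <- rtracklayer::import(p1, format = "bedGraph")
  expect_equal(S4Vectors::mcols(back)$score, np$freq)

  p2 <- tempfile(fileext = ".bedGraph")
  write_bedgraph(bin_profile(np, map, 500), p2)
  expect_true(file.exists(p2))
})
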