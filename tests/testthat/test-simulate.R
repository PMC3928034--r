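test_that("simulation is bit-for-bit reproducible under a fixed seed", {
  p <- tiny_params(seed = 9)
  s1 <- simulate_locus(p)
  s2 <- simulate_locus(p)
  expect_identical(fragments(s1$map), fragments(s2$map))
  expect_identical(s1$table$matrix, s2$table$matrix)

  c1 <- simulate_viewpoint_counts(s1$map, s1$table, "Sis", "WT", p)
  c2 <- simulate_viewpoint_counts(s2$map, s2$table, "Sis", "WT", p)
  expect_identical(c1[[1]]$counts, c2[[1]]$counts)
  expect_identical(c1[[2]]$counts, c2[[2]]$counts)
  expect_false(identical(c1[[1]]$counts, c1[[2]]$counts))

  u1 <- simulate_usage(s1$map, s1$table, p)
  u2 <- simulate_usage(s2$map, s2$table, p)
  expect_identical(u1, u2)

  f1 <- simulate_fish("proB", p, 50)
  f2 <- simulate_fish("proB", p, 50)
  expect_identical(f1$coords, f2$coords)
})

test_that("zero marking probabilities leave only gene marks", {
  p <- tiny_params(seed = 2,
                   tf_marking_probabilities = c(ikaros = 0, e2a = 0,
                                                h3k4me23 = 0, ctcf = 0),
                   tf_background_rate = c(ikaros = 0, e2a = 0,
                                          h3k4me23 = 0, ctcf = 0))
  sim <- simulate_locus(p)
  marked <- colSums(sim$table$matrix) > 0
  expect_true(all(names(which(marked)) %in% c("vk_functional", "vk_pseudo")))
})

test_that("Ikaros marking rate matches its planted probability", {
  hits <- vapply(1:200, function(s) {
    p <- tiny_params(seed = s, n_vk_functional = 50, n_vk_pseudo = 0)
    sim <- simulate_locus(p)
    genes <- sim$table$features[
      S4Vectors::mcols(sim$table$features)$kind == "vk_functional"]
    fr <- fragments(sim$map)
    hit <- GenomicRanges::findOverlaps(genes, fr, select = "first")
    sum(sim$table$matrix[hit, "ikaros"])
  }, numeric(1))
  rate <- mean(hits) / 50
  # 10,000 Bernoulli(0.95) draws: 99.9% CI half-width ~ 0.007
  expect_gt(rate, 0.94)
  expect_lt(rate, 0.96)
})

test_that("focusing and leak at 1 give a pure distance-decay null", {
  p <- tiny_params(seed = 4, focusing_strength = flat_focusing(1),
                   flank_leak = rep(1, 5))
  sim <- simulate_locus(p)
  w <- expected_interaction_weights(sim$map, sim$table, "Sis", "WT", p)
  fr <- fragments(sim$map)
  mid <- floor((GenomicRanges::start(fr) + GenomicRanges::end(fr)) / 2)
  d <- pmax(abs(mid - viewpoint_positions(p)[["Sis"]]), p$min_distance)
  # residual after removing the decay term is constant for every fragment,
  # marked or not
  resid <- w * d^p$decay_exponent
  expect_lt(diff(range(resid)) / mean(resid), 1e-12)
})

test_that("a steep decay exponent concentrates reads near the viewpoint", {
  # pure decay (no gene enrichment) so the power law is isolated
  p <- tiny_params(seed = 6, decay_exponent = 4,
                   focusing_strength = flat_focusing(1),
                   flank_leak = rep(1, 5))
  sim <- simulate_locus(p)
  w <- expected_interaction_weights(sim$map, sim$table, "iEk", "proB", p)
  fr <- fragments(sim$map)
  mid <- floor((GenomicRanges::start(fr) + GenomicRanges::end(fr)) / 2)
  d <- abs(mid - viewpoint_positions(p)[["iEk"]])
  nearest10 <- order(d)[1:10]
  expect_gte(sum(w[nearest10]), 0.99)
})

test_that("monotone focusing yields a monotone Vk+/Vk- expected ratio", {
  p <- tiny_params(seed = 8)
  sim <- simulate_locus(p)
  vk <- subgroup_mask(sim$table, "vk_functional") &
    region_mask(sim$map, "vkappa")
  bg <- subgroup_mask(sim$table, "!vk_functional & !vk_pseudo") &
    region_mask(sim$map, "vkappa")
  ratios <- vapply(p$conditions, function(cc) {
    w <- expected_interaction_weights(sim$map, sim$table, "3pEk", cc, p)
    mean(w[vk]) / mean(w[bg])
  }, numeric(1))
  expect_true(all(diff(ratios) >= 0))
})

test_that("usage sums to 100% and couples monotonically when noise-free", {
  p <- tiny_params(seed = 3, usage_noise_sd = 0)
  sim <- simulate_locus(p)
  u <- simulate_usage(sim$map, sim$table, p)
  expect_equal(sum(u$usage_percent), 100)
  expect_true(all(u$usage_percent >= 0))

  genes <- sim$table$features[
    S4Vectors::mcols(sim$table$features)$kind == "vk_functional"]
  genes <- genes[order(GenomicRanges::start(genes))]
  fr <- fragments(sim$map)
  hit <- GenomicRanges::findOverlaps(genes, fr, select = "first")
  lam <- rowMeans(vapply(
    c("Sis", "iEk", "3pEk"),
    function(v) expected_interaction_weights(sim$map, sim$table, v, "WT",
                                             p)[hit],
    numeric(length(genes))))
  expect_equal(order(u$usage_percent), order(lam))
})

test_that("decoupled usage is uncorrelated with interaction strength", {
  cors <- vapply(1:30, function(s) {
    p <- tiny_params(seed = s, usage_coupling = 0)
    sim <- simulate_locus(p)
    u <- simulate_usage(sim$map, sim$table, p)
    genes <- sim$table$features[
      S4Vectors::mcols(sim$table$features)$kind == "vk_functional"]
    genes <- genes[order(GenomicRanges::start(genes))]
    fr <- fragments(sim$map)
    hit <- GenomicRanges::findOverlaps(genes, fr, select = "first")
    lam <- expected_interaction_weights(sim$map, sim$table, "3pEk", "WT",
                                        p)[hit]
    cor(log(u$usage_percent), log(lam))
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("FISH medians hit their targets and sizes are respected", {
  p <- tiny_params(seed = 12)
  f <- simulate_fish("proB", p, 1e4)
  expect_equal(median(fish_distances(f)), 0.4, tolerance = 0.05)
  g <- simulate_fish("preproB_E2aKO", p, 1e4)
  expect_equal(median(fish_distances(g)), 0.9, tolerance = 0.05)

  one <- simulate_fish("preB", p, 1)
  expect_equal(length(fish_distances(one)), 1L)
  expect_error(simulate_fish("proB", p, 0), "n_nuclei")
})

test_that("degenerate parameters are rejected", {
  expect_error(tiny_params(decay_exponent = 0), "decay_exponent")
  expect_error(tiny_params(fish_contracted_median = -1), "positive")
  p <- tiny_params()
  sim <- simulate_locus(p)
  expect_error(
    expected_interaction_weights(sim$map, sim$table, "nope", "WT", p),
    "unknown viewpoint")
  expect_error(
    simulate_viewpoint_counts(sim$map, sim$table, "Sis", "nope", p),
    "unknown condition")
  expect_error(
    simulate_locus(tiny_params(locus_length = 2e5, n_vk_functional = 500)),
    "too short")
})
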