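test_that("Mann-Whitney U and exact p match the permutation oracle", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-12)
  expect_equal(mw$U + mw$U_prime, 4)

  # identical multisets: U = n1 n2 / 2
  mw2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw2$U, 4.5)

  set.seed(31)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    # integer draws force ties to exercise the midrank path
    x <- sample(1:5, n1, replace = TRUE)
    y <- sample(1:5, n2, replace = TRUE)
    mw <- mann_whitney_u(x, y)
    expect_equal(mw$U, oracle_u(x, y))
    expect_equal(mw$p, oracle_mwu_p(x, y), tolerance = 1e-12)
  }
})

test_that("the normal approximation tracks the exact p for n = 8 + 8", {
  set.seed(17)
  worst <- 0
  for (rep in 1:100) {
    x <- rnorm(8); y <- rnorm(8, mean = rnorm(1, sd = 0.8))
    exact <- mann_whitney_u(x, y, exact_limit = 8)$p
    approx <- mann_whitney_u(x, y, exact_limit = 0)$p
    worst <- max(worst, abs(exact - approx))
    # cross-check against the independent base-R implementation
    expect_equal(exact, stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  expect_lt(worst, 0.02)
})

test_that("U is invariant under strictly monotone transforms", {
  set.seed(23)
  x <- rexp(10); y <- rexp(12)
  base <- mann_whitney_u(x, y)
  for (f in list(function(v) v^3, exp, function(v) 5 * v - 2)) {
    tr <- mann_whitney_u(f(x), f(y))
    expect_equal(tr$U, base$U)
    expect_equal(tr$p, base$p)
  }
})

test_that("group comparison reports means and is label-symmetric", {
  np <- toy_profile(c(10, 20, 1, 2))
  a <- c(TRUE, TRUE, FALSE, FALSE)
  b <- !a
  cr <- group_comparison(np, a, b, labels = c("hi", "lo"))
  expect_equal(unname(cr$means), c(15, 1.5))
  expect_equal(unname(cr$n), c(2L, 2L))

  sw <- group_comparison(np, b, a, labels = c("lo", "hi"))
  expect_equal(unname(sw$means), rev(unname(cr$means)))
  expect_equal(sw$p, cr$p)

  expect_error(group_comparison(np, a, a), "disjoint")
  expect_error(group_comparison(np, rep(FALSE, 4), b), "at least one")
})

test_that("fold-change classification applies the 1.5-fold and 25-count rules", {
  map <- toy_map()
  wt <- list(toy_counts(c(30, 10, 40, 26), library_size = 1e6,
                        condition = "WT"))
  mut <- list(toy_counts(c(10, 10, 40, 26), library_size = 1e6,
                         condition = "mut"))
  fc <- classify_fold_change(wt, mut, map)
  cls <- fc$classes[, 1]
  expect_equal(cls[1], "increase")      # ratio 3.0
  expect_equal(cls[2], "no_evidence")   # both <= 25 everywhere
  expect_equal(cls[3], "stable")        # ratio 1
  expect_equal(cls[4], "stable")        # 26 = evidence, ratio 1
  expect_equal(sum(fc$fractions[1, ]), 1)

  # a ratio of exactly 1.5 stays stable (strict inequality)
  wt2 <- list(toy_counts(c(45, 60, 30, 30), 1e6, condition = "WT"))
  mut2 <- list(toy_counts(c(30, 40, 45, 90), 1e6, condition = "mut"))
  cls2 <- classify_fold_change(wt2, mut2, map)$classes[, 1]
  # ratios 1.5, 1.5, 1/1.5, 1/3: only the last crosses the strict threshold
  expect_equal(unname(cls2), c("stable", "stable", "stable", "decrease"))

  # evidence threshold zero leaves no fragment unclassified
  fc0 <- classify_fold_change(wt, mut, map, evidence_threshold = 0)
  expect_equal(unname(fc0$fractions[1, "no_evidence"]), 0)

  expect_error(classify_fold_change(wt, mut, map, fold_threshold = -1),
               "non-negative")
})

test_that("evidence is pooled across viewpoints and counts are replicate-averaged", {
  map <- toy_map()
  # two replicates averaging to 30 on fragment 1; second viewpoint gives
  # fragment 2 its evidence even though viewpoint 1 never does
  wt <- list(
    v1 = list(toy_counts(c(40, 5, 1, 1), 1e6, replicate = 1L),
              toy_counts(c(20, 5, 1, 1), 1e6, replicate = 2L)),
    v2 = list(toy_counts(c(1, 80, 1, 1), 1e6, replicate = 1L),
              toy_counts(c(1, 80, 1, 1), 1e6, replicate = 2L))
  )
  mut <- list(
    v1 = list(toy_counts(c(10, 10, 1, 1), 1e6, replicate = 1L),
              toy_counts(c(10, 10, 1, 1), 1e6, replicate = 2L)),
    v2 = list(toy_counts(c(1, 40, 1, 1), 1e6, replicate = 1L),
              toy_counts(c(1, 40, 1, 1), 1e6, replicate = 2L))
  )
  fc <- classify_fold_change(wt, mut, map)
  expect_equal(unname(fc$classes[1, "v1"]), "increase")  # 30 vs 10
  expect_equal(unname(fc$classes[2, "v1"]), "decrease")  # 5 vs 10, evidence via v2
  expect_equal(unname(fc$classes[3, "v1"]), "no_evidence")
  expect_equal(unname(fc$classes[2, "v2"]), "increase")  # 80 vs 40
})

test_that("log-floored correlation matches the sums-of-squares oracle", {
  a <- c(1, 2, 3)
  vc <- viewpoint_correlation(a, a * 10)
  expect_equal(vc$r_squared, 1)

  # values below the floor enter the transform as 10^0
  vc2 <- viewpoint_correlation(c(0.5, 10, 100), c(1, 10, 100))
  expect_equal(vc2$r_squared, 1)

  set.seed(41)
  x <- 10^rnorm(20, 1.5, 0.7)
  y <- x * 10^rnorm(20, 0, 0.3)
  vc3 <- viewpoint_correlation(x, y)
  expect_equal(vc3$r_squared,
               oracle_r_squared(log10(pmax(x, 1)), log10(pmax(y, 1))),
               tolerance = 1e-10)
  # symmetry
  expect_equal(viewpoint_correlation(y, x)$r_squared, vc3$r_squared)

  expect_error(viewpoint_correlation(c(1, 2), c(1, 2)), "at least 3")
  expect_error(viewpoint_correlation(c(0.1, 0.5, 0.9), c(1, 2, 3)),
               "zero variance")
})

test_that("usage categories bin at 0.1/0.3/0.5% and correlate by rank", {
  u <- c(0.05, 0.2, 0.4, 0.7)
  f <- c(10, 20, 30, 40)
  uc <- usage_category_correlation(u, f)
  expect_equal(unname(uc$category_counts), rep(1, 4))
  expect_equal(unname(uc$category_means), f)
  expect_equal(uc$r_squared, 1)  # means affine in rank

  # boundary values are left-closed: 0.1 joins the second bin
  uc2 <- usage_category_correlation(c(0.1, 0.05), c(5, 1))
  expect_equal(names(uc2$category_means), c("<0.1%", "0.1-0.3%"))

  expect_error(usage_category_correlation(c(0.2, 0.25), c(1, 2)),
               "one usage category")

  # unbinned per-gene alternative
  ug <- usage_category_correlation(u, f, method = "genes")
  expect_equal(ug$r_squared, oracle_r_squared(u, f), tolerance = 1e-10)
})

test_that("class fractions and U bounds hold on simulated contrasts", {
  p <- tiny_params(seed = 14)
  sim <- simulate_locus(p)
  map <- filter_fragments(sim$map, 100, sim_exclusion_zone(p))
  vk <- subgroup_mask(sim$table, "vk_functional", map) &
    region_mask(map, "vkappa")
  wt <- lapply(setNames(c("Sis", "iEk", "3pEk"), c("Sis", "iEk", "3pEk")),
               function(v) simulate_viewpoint_counts(map, sim$table, v,
                                                     "WT", p))
  dko <- lapply(setNames(c("Sis", "iEk", "3pEk"), c("Sis", "iEk", "3pEk")),
                function(v) simulate_viewpoint_counts(map, sim$table, v,
                                                      "BtkSlp65", p))
  fc <- classify_fold_change(wt, dko, map, mask = vk)
  expect_equal(unname(rowSums(fc$fractions)), rep(1, 3))

  np <- average_replicates(lapply(wt$Sis, normalize_rpm, map = map))
  bg <- subgroup_mask(sim$table, "!vk_functional & !vk_pseudo", map) &
    region_mask(map, "vkappa")
  cr <- group_comparison(np, vk, bg)
  expect_gte(cr$U, 0)
  expect_lte(cr$U, prod(cr$n))
  expect_gt(cr$p, 0)
  expect_lte(cr$p, 1)
})
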