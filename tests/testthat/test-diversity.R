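test_that("the six indices match hand-evaluated reference cases", {
  even <- compute_indices(c(0.5, 0.5))
  expect_equal(even$S, 2)
  expect_equal(even$H, log(2))
  expect_equal(even$D1, 0.5)
  expect_equal(even$D2, 2)
  expect_equal(even$BP, 0.5)
  expect_equal(even$E, 1)

  mono <- compute_indices(7.0)
  expect_equal(unlist(mono), c(S = 1, H = 0, D1 = 0, D2 = 1, BP = 1, E = 1))

  skew <- compute_indices(c(0.6, 0.3, 0.1))
  expect_equal(skew$H, 0.8979457, tolerance = 1e-6)
  expect_equal(skew$D1, 0.54)
  expect_equal(skew$D2, 2.173913, tolerance = 1e-6)
  expect_equal(skew$BP, 0.6)
  expect_equal(skew$E, 0.7246377, tolerance = 1e-6)
})

test_that("degenerate abundance input is rejected with a traceable error", {
  expect_error(compute_indices(numeric()), "empty")
  expect_error(compute_indices(c(0, 0), context = "plot p1, group plant"),
               "all-zero.*plot p1")
  expect_error(compute_indices(c(1, -2)), "negative")
})

test_that("Hill numbers hit their closed-form special cases", {
  v <- c(0.6, 0.3, 0.1)
  expect_equal(hill_number(v, 0), 3)
  expect_equal(hill_number(v, 1), exp(0.8979457), tolerance = 1e-6)
  expect_equal(hill_number(v, 2), 1 / sum((v / sum(v))^2))
  expect_equal(hill_number(v, Inf), 1 / 0.6)
  # the a = 1 singularity is removable: nearby powers agree with the limit
  expect_equal(hill_number(v, 1 + 1e-10), hill_number(v, 1))
  expect_error(hill_number(v, -0.5), "powers")
})

test_that("Hill profiles are non-increasing and flat only for even communities", {
  grid <- c(0, 0.5, 1, 2, 4, Inf)
  prof <- hill_profile(rep(1, 5), grid)
  expect_equal(prof$N, rep(5, length(grid)))

  prof2 <- hill_profile(c(0.6, 0.3, 0.1), c(0, 1, 2, Inf))
  expect_equal(prof2$N, c(3, 2.454556, 2.173913, 1.666667),
               tolerance = 1e-6)

  geom <- 0.5^(1:10)
  prof3 <- hill_profile(geom, grid)
  expect_true(all(diff(prof3$N) < 0))
  expect_error(hill_profile(geom, 1), "grid")
})

test_that("indices are invariant to order, scale, and zero-padding", {
  withr::with_seed(42, {
    for (i in 1:50) {
      x <- random_abundance()
      base <- compute_indices(x)
      expect_equal(compute_indices(sample(x)), base)
      expect_equal(compute_indices(x * runif(1, 0.01, 100)), base)
      expect_equal(compute_indices(c(x, rep(0, 5))), base)
    }
  })
})

test_that("vectorized computation agrees with a looped hand-coded oracle", {
  withr::with_seed(7, {
    for (i in 1:200) {
      x <- random_abundance()
      expect_equal(unlist(compute_indices(x)), oracle_indices(x),
                   tolerance = 1e-12)
      a <- runif(1, 0, 5)
      expect_equal(hill_number(x, a), oracle_hill(x, a), tolerance = 1e-10)
    }
  })
})

test_that("per-plot aggregation is the arithmetic mean of focal-unit indices", {
  one <- tibble::tibble(plot = "p1", S = 4, H = 1.2, D1 = 0.6, D2 = 2.5,
                        BP = 0.5, E = 0.625)
  expect_equal(aggregate_per_plot(one), one)

  two <- tibble::tibble(plot = "p1", focal_unit = 1:2,
                        S = c(2, 4), H = c(log(2), 0), D1 = c(0.5, 0),
                        D2 = c(2, 1), BP = c(0.5, 1), E = c(1, 0.25))
  agg <- aggregate_per_plot(two)
  expect_equal(agg$S, 3)
  expect_equal(agg$H, log(2) / 2, tolerance = 1e-7)
  # E is the mean of per-sample ratios, not recomputed from mean D2 / mean S
  expect_equal(agg$E, 0.625)
  expect_false(isTRUE(all.equal(agg$E, agg$D2 / agg$S)))
})

test_that("diversity_table averages focal units and flags empty samples", {
  abund <- tibble::tibble(
    plot = rep("p1", 5),
    focal_unit = c(1, 1, 2, 2, 3),
    group = "plant",
    taxon_id = c("a", "b", "a", "c", "a"),
    abundance = c(1, 1, 3, 1, 0)
  )
  div <- diversity_table(abund)
  # unit 3 is all-zero: excluded from the mean, plot still reported
  expect_equal(nrow(div), 1)
  expect_false(div$empty)
  u1 <- compute_indices(c(1, 1))
  u2 <- compute_indices(c(3, 1))
  expect_equal(div$H, (u1$H + u2$H) / 2)
  expect_equal(div$S, 2)

  all_zero <- tibble::tibble(plot = "p9", group = "plant",
                             taxon_id = "a", abundance = 0)
  div0 <- diversity_table(all_zero)
  expect_true(div0$empty)
  expect_true(is.na(div0$H))

  expect_error(diversity_table(dplyr::mutate(abund, abundance = -abundance)),
               "negative")
})

test_that("diversity_table Hill columns match hill_number per sample", {
  abund <- tibble::tibble(plot = "p1", group = "g",
                          taxon_id = letters[1:3], abundance = c(6, 3, 1))
  div <- diversity_table(abund, hill_powers = c(0, 1, 2, Inf))
  expect_equal(div$N_0, 3)
  expect_equal(div$N_1, hill_number(c(6, 3, 1), 1))
  expect_equal(div$N_inf, hill_number(c(6, 3, 1), Inf))
})

test_that("molecular indices average per-locus values across loci", {
  one <- molecular_diversity(tibble::tibble(
    plot = "p1", locus = "L1", allele = c("a", "b"),
    frequency = c(0.5, 0.5)))
  expect_equal(one$D1, 0.5)  # expected heterozygosity, biallelic 50/50

  two <- molecular_diversity(tibble::tibble(
    plot = "p1", locus = c("L1", "L2", "L2"), allele = c("a", "a", "b"),
    frequency = c(1, 0.5, 0.5)))
  expect_equal(two$D1, 0.25)
  expect_equal(two$D2, 1.5)

  mono <- molecular_diversity(tibble::tibble(
    plot = "p1", locus = "L1", allele = "a", frequency = 1))
  expect_equal(mono$D1, 0)
  expect_equal(mono$D2, 1)
})

test_that("allele frequencies off unity fail unless renormalization is opted in", {
  bad <- tibble::tibble(plot = "p1", locus = "L1",
                        allele = c("a", "b"), frequency = c(0.6, 0.2))
  expect_error(molecular_diversity(bad), "sum to")
  ok <- molecular_diversity(bad, renormalize = TRUE)
  expect_equal(ok$D1, compute_indices(c(0.6, 0.2))$D1)
})
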