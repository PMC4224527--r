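small_scn <- function(...) {
  scenario(n_plots = 15, focal_units = 3, chem = list(n_features = 80), ...)
}

test_that("scenario validation catches impossible parameters", {
  expect_error(scenario(groups = list(plant = list(S_min = 0L))), "S_min")
  expect_error(scenario(groups = list(arth = list(S_max = 99L))), "pool")
  expect_error(scenario(groups = list(AMF = list(k_min = 0))), "k_min")
  expect_error(scenario(beta_lui = -0.9, exog_cov = 0.9), "exog_cov")
  expect_error(
    scenario(coefficients = c("a->b" = 0.2, "b->a" = 0.1)), "cycle")
})

test_that("the full bundle is a deterministic function of scenario and seed", {
  scn <- small_scn()
  a <- generate_study(scn, seed = 33)
  b <- generate_study(scn, seed = 33)
  expect_identical(a$abundance, b$abundance)
  expect_identical(a$molecular, b$molecular)
  expect_identical(a$chem, b$chem)
  expect_identical(a$land_use, b$land_use)
  expect_identical(a$ground_truth$z, b$ground_truth$z)
  c <- generate_study(scn, seed = 34)
  expect_false(identical(a$abundance, c$abundance))
})

test_that("zero couplings yield mutually independent latents", {
  coefs <- c("plant->chem" = 0, "plant->AMF" = 0, "plant->arth" = 0,
             "chem->arth" = 0, "mol->arth" = 0, "AMF->arth" = 0)
  scn <- scenario(n_plots = 400, coefficients = coefs, beta_lui = 0,
                  exog_cov = 0)
  gt <- generate_latents(scn, seed = 10)
  Z <- as.matrix(gt$z[, c("z_mol", "z_plant", "z_chem", "z_AMF", "z_arth")])
  R <- cor(Z)
  off <- R[upper.tri(R)]
  expect_true(all(abs(off) < 4 / sqrt(400)))
})

test_that("generating equations give unit-variance latents with the stated couplings", {
  scn <- scenario(n_plots = 2000)
  gt <- generate_latents(scn, seed = 2)
  Z <- gt$z
  # population identities, checked at Monte-Carlo precision
  expect_lt(abs(stats::sd(Z$z_plant) - 1), 0.08)
  expect_lt(abs(stats::sd(Z$z_arth) - 1), 0.08)
  expect_lt(abs(cor(Z$LUI_z, Z$z_plant) - (-0.38)), 0.07)
  expect_lt(abs(cor(Z$z_mol, Z$z_plant) - 0.2), 0.08)
  # implied covariance bookkeeping matches the generating recursion
  expect_equal(unname(gt$sigma_pop["plant", "chem"]), -0.4)
})

test_that("communities respond to the latent score as designed", {
  params <- list(S_min = 20, S_max = 20, k_min = 1e-4, k_max = 0.6,
                 sample_size = 1e5)
  # deep sampling at high z with k near zero: close to perfectly even
  cts <- community_from_latent(8, params, seed = 1)
  idx <- compute_indices(cts)
  expect_equal(idx$S, 20)
  expect_gt(idx$E, 0.95)

  # exhaustive sampling observes the whole local pool
  params2 <- list(S_min = 12, S_max = 12, k_min = 0.3, k_max = 0.3,
                  sample_size = 1e6)
  cts2 <- community_from_latent(0, params2, seed = 2)
  expect_equal(sum(cts2 > 0), 12)

  # identical (z, seed) reproduce identical counts; counts sum to the draw
  expect_identical(community_from_latent(0.5, params2, seed = 9),
                   community_from_latent(0.5, params2, seed = 9))
  expect_equal(sum(community_from_latent(0.5, params2, seed = 9)), 1e6)

  # realized Shannon diversity increases with z on average
  params3 <- list(S_min = 5, S_max = 40, k_min = 0.08, k_max = 0.6,
                  sample_size = 150)
  withr::with_seed(3, {
    h_lo <- replicate(100, compute_indices(
      community_from_latent(-1.5, params3))$H)
    h_hi <- replicate(100, compute_indices(
      community_from_latent(1.5, params3))$H)
  })
  expect_gt(mean(h_hi), mean(h_lo) + 0.5)
})

test_that("both SAD families generate valid studies with monotone Hill profiles", {
  for (fam in c("geometric", "lognormal")) {
    scn <- scenario(n_plots = 6, focal_units = 2, sad_family = fam,
                    chem = list(n_features = 40))
    # 6 plots can leave a region without fertilized plots: warning expected
    st <- suppressWarnings(generate_study(scn, seed = 4))
    samples <- split(st$abundance$abundance,
                     interaction(st$abundance$plot, st$abundance$focal_unit,
                                 st$abundance$group, drop = TRUE))
    for (x in samples) {
      prof <- hill_profile(x, c(0, 0.5, 1, 2, 4, Inf))
      expect_true(all(diff(prof$N) <= 1e-10))
    }
  }
})

test_that("generated land use standardizes to unit regional means", {
  scn <- small_scn()
  lu <- generate_land_use(scn, seed = 6)
  expect_equal(nrow(lu), 15 * 3)
  expect_true(any(lu$F == 0) || any(lu$G == 0))
  lui <- compute_lui(lu, years = scn$years)
  by_region <- split(lui, lui$region)
  for (d in by_region) {
    for (comp in c("F_std", "M_std", "G_std")) {
      if (!all(is.na(d[[comp]]))) {
        expect_equal(mean(d[[comp]]), 1, tolerance = 1e-10)
      }
    }
  }
})

test_that("the allele-frequency layer is valid and tracks the molecular latent", {
  scn <- scenario(n_plots = 80, focal_units = 1,
                  chem = list(n_features = 20))
  st <- generate_study(scn, seed = 12)
  sums <- st$molecular |>
    dplyr::group_by(plot, locus) |>
    dplyr::summarise(s = sum(frequency), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
  mdiv <- molecular_diversity(st$molecular)
  j <- dplyr::inner_join(mdiv, st$ground_truth$z, by = "plot")
  expect_gt(cor(j$D1, j$z_mol), 0.3)
})

test_that("the chemical layer has no cross-plot singletons and degenerate SEs", {
  st <- generate_study(small_scn(), seed = 21)
  inc <- incidence_from_abundance(st$chem, group = "chem")
  expect_true(all(inc$f == inc$N))  # every feature in every plot
  er <- estimate_richness(inc, B = 150, seed = 1)
  expect_true(all(is.na(er$se)))
  expect_true(all(grepl("degenerate_se", er$flag)))
  expect_equal(er$S_hat, rep(er$S_obs[1], 3))
})

test_that("written bundles round-trip through the pipeline readers", {
  st <- generate_study(small_scn(), seed = 9)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  ab <- read_abundance(file.path(dir, "abundance.tsv"))
  expect_equal(nrow(ab), nrow(st$abundance))
  expect_equal(sort(unique(ab$group)), sort(unique(st$abundance$group)))
  lu <- read_land_use(file.path(dir, "land_use.tsv"))
  expect_equal(compute_lui(lu)$LUI, st$lui$LUI, tolerance = 1e-9)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$beta_lui, -0.38)
  # diversity computation runs cleanly on the re-read tables
  expect_s3_class(diversity_table(ab), "tbl_df")
})
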