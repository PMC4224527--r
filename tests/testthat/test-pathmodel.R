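test_that("degrees of freedom come from moment counting", {
  # saturated three-variable chain: all pairs connected
  sat <- path_spec(c("x -> y", "x -> z", "y -> z"))
  expect_equal(model_df(sat), 0)

  expect_equal(model_df(default_path_spec()), 3)

  chain <- path_spec(c("x -> y", "y -> z"))
  expect_equal(model_df(chain), 1)

  # property: df = p(p+1)/2 - t over random DAGs
  withr::with_seed(55, {
    for (i in 1:40) {
      p <- sample(4:7, 1)
      vars <- paste0("v", 1:p)
      edges <- NULL
      for (a in 1:(p - 1)) {
        for (b in (a + 1):p) {
          if (runif(1) < 0.4) edges <- rbind(edges, c(vars[a], vars[b]))
        }
      }
      if (is.null(edges)) next
      spec <- path_spec(data.frame(from = edges[, 1], to = edges[, 2]),
                        variables = vars)
      t_hand <- nrow(edges) + length(spec$exogenous) +
        length(spec$endogenous)
      expect_equal(model_df(spec), p * (p + 1) / 2 - t_hand)
    }
  })
})

test_that("cycles and under-identified specs are rejected", {
  expect_error(path_spec(c("a -> b", "b -> c", "c -> a")), "cycle")
  expect_error(path_spec(c("a -> a")), "self-loop")
  expect_error(path_spec(c("a -> b"), covariances = "a ~~ b"),
               "exogenous")
})

test_that("plain-text specs round-trip through the parser", {
  txt <- c("# hypothesized couplings", "plant -> chem", "plant -> AMF",
           "plant -> arth", "chem -> arth", "mol -> arth", "AMF -> arth",
           "", "mol ~~ plant")
  spec <- read_path_spec(text = txt)
  expect_equal(model_df(spec), 3)
  expect_setequal(spec$exogenous, c("mol", "plant"))
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(txt, f)
  expect_equal(model_df(read_path_spec(f)), 3)
})

test_that("the saturated model reproduces the observed moments exactly", {
  withr::with_seed(1, {
    d <- tibble::as_tibble(matrix(rnorm(200 * 3), 200, 3),
                           .name_repair = ~ c("x", "y", "z"))
    fit <- fit_path_model(d, path_spec(c("x -> y", "x -> z", "y -> z")))
    expect_equal(fit$chi2, 0, tolerance = 1e-8)
    expect_equal(fit$df, 0)
    expect_equal(fit$Sigma, fit$S, tolerance = 1e-10)
  })
})

test_that("a noiseless child recovers its generating coefficients exactly", {
  withr::with_seed(2, {
    x <- rnorm(80); w <- rnorm(80)
    y <- 0.7 * x - 0.4 * w  # no disturbance
    d <- tibble::tibble(x = x, w = w, y = y)
    expect_warning(
      fit <- fit_path_model(d, path_spec(c("x -> y", "w -> y"),
                                         covariances = "x ~~ w")),
      "singular")
    cf <- tidy(fit)
    # standardized scale: coefficients are b * sd(parent) / sd(child)
    expect_equal(cf$estimate[cf$from == "x"], 0.7 * sd(x) / sd(y),
                 tolerance = 1e-10)
    expect_equal(cf$estimate[cf$from == "w"], -0.4 * sd(w) / sd(y),
                 tolerance = 1e-10)
    expect_lt(fit$residual_variances[["y"]], 1e-12)
  })
})

test_that("equation-wise least squares minimizes the ML discrepancy", {
  withr::with_seed(3, {
    n <- 150
    x <- rnorm(n)
    y <- 0.6 * x + rnorm(n, sd = 0.8)
    z <- -0.5 * y + rnorm(n, sd = 0.9)
    d <- tibble::tibble(x = x, y = y, z = z)
    spec <- path_spec(c("x -> y", "y -> z"))
    fit <- fit_path_model(d, spec)

    # independent numeric minimization of F_ML over all five parameters
    S <- cov(scale(as.matrix(d)))
    fml <- function(th) {
      bxy <- th[1]; byz <- th[2]
      vx <- exp(th[3]); py <- exp(th[4]); pz <- exp(th[5])
      vy <- bxy^2 * vx + py
      Sg <- matrix(0, 3, 3)
      Sg[1, 1] <- vx
      Sg[1, 2] <- Sg[2, 1] <- bxy * vx
      Sg[2, 2] <- vy
      Sg[1, 3] <- Sg[3, 1] <- byz * bxy * vx
      Sg[2, 3] <- Sg[3, 2] <- byz * vy
      Sg[3, 3] <- byz^2 * vy + pz
      log(det(Sg)) - log(det(S)) + sum(diag(S %*% solve(Sg))) - 3
    }
    opt <- optim(c(0.5, -0.5, 0, 0, 0), fml, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 2000))
    cf <- tidy(fit)
    expect_equal(cf$estimate[cf$from == "x"], opt$par[1], tolerance = 1e-5)
    expect_equal(cf$estimate[cf$from == "y"], opt$par[2], tolerance = 1e-5)
    expect_equal(fit$chi2, (n - 1) * opt$value, tolerance = 1e-4)
  })
})

test_that("fit indices follow their defining formulas", {
  # exact fit reductions
  fi <- fit_indices(3, 3, 60, chi2_null = 80, df_null = 10)
  expect_equal(fi$rmsea, 0)
  expect_equal(fi$tlnnfi, 1)

  # hand evaluation at the poor-fit reference point
  fi2 <- fit_indices(6.39, 3, 59, chi2_null = 80, df_null = 10)
  expect_equal(fi2$rmsea, sqrt(3.39 / (3 * 58)), tolerance = 1e-12)
  expect_equal(round(fi2$rmsea, 2), 0.14)

  expect_equal(fit_indices(0, 3, 10, 50, 10)$rmsea, 0)
  # null no better than 1 per df: TLNNFI undefined
  expect_true(is.na(fit_indices(2, 3, 50, chi2_null = 9,
                                df_null = 10)$tlnnfi))
  expect_error(fit_indices(2, 0, 50, 9, 10), "df")
})

test_that("the independence null has p(p-1)/2 degrees of freedom", {
  withr::with_seed(4, {
    d <- tibble::as_tibble(matrix(rnorm(60 * 5), 60, 5),
                           .name_repair = ~ default_path_spec()$variables)
    fit <- fit_path_model(d, default_path_spec())
    expect_equal(fit$df_null, 10)
    expect_equal(fit$df, 3)
    expect_true(fit$p_chi2 >= 0 && fit$p_chi2 <= 1)
  })
})

test_that("missing variables error; collinear data lose their fit statistics", {
  d <- tibble::tibble(x = rnorm(30), y = rnorm(30))
  expect_error(fit_path_model(d, path_spec(c("x -> y", "q -> y"))),
               "lacks model variable")
  # perfectly collinear parents cannot be separated
  d2 <- tibble::tibble(x = rnorm(30))
  d2$y <- 2 * d2$x
  d2$z <- d2$x + rnorm(30)
  expect_error(
    suppressWarnings(fit_path_model(d2, path_spec(c("x -> z", "y -> z")))),
    "collinear")
})

test_that("multi-index runs share the spec and tolerate degenerate indices", {
  withr::with_seed(8, {
    vars <- default_path_spec()$variables
    div <- purrr::map_dfr(vars, function(g) {
      tibble::tibble(plot = sprintf("p%02d", 1:40), group = g,
                     S = rnorm(40), H = rnorm(40))
    })
    # identical data under two index names: identical results
    div$H <- div$S
    run <- multi_index_run(div, default_path_spec(), indices = c("S", "H"))
    expect_equal(run$fits$S$chi2, run$fits$H$chi2)
    expect_equal(run$fit_stats$df, c(3, 3))
    expect_equal(tidy(run$fits$S), tidy(run$fits$H))

    # zero-variance variable for one index: reported, not fatal
    div2 <- div
    div2$H[div2$group == "chem"] <- 1
    run2 <- multi_index_run(div2, default_path_spec(),
                            indices = c("S", "H"))
    expect_true(is.na(run2$fit_stats$chi2[run2$fit_stats$index == "H"]))
    expect_match(run2$fit_stats$note[run2$fit_stats$index == "H"], "chem")
    expect_false(is.na(run2$fit_stats$chi2[run2$fit_stats$index == "S"]))
  })
})

test_that("couplings carried by rare species surface in S but not BP", {
  # evenness frozen (k_min = k_max): the plant -> arth coupling moves only
  # pool sizes, i.e. rare-species structure; dominance-based indices
  # should stay blind to it. Run on a chem-free spec since the saturated
  # chemical layer has no richness variation at all.
  coefs <- c("plant->chem" = 0, "plant->AMF" = 0, "plant->arth" = 0.6,
             "chem->arth" = 0, "mol->arth" = 0, "AMF->arth" = 0)
  scn <- scenario(
    n_plots = 60, focal_units = 3, coefficients = coefs, beta_lui = 0,
    groups = list(
      plant = list(k_min = 0.35, k_max = 0.35),
      arth = list(k_min = 0.35, k_max = 0.35, S_min = 4L, S_max = 16L,
                  pool = 35L)
    ),
    chem = list(n_features = 120)
  )
  st <- generate_study(scn, seed = 42)
  div <- diversity_table(st$abundance)
  mol <- molecular_diversity(st$molecular)
  mol$group <- "mol"
  div <- dplyr::bind_rows(div, mol)
  spec <- path_spec(c("plant -> AMF", "plant -> arth", "AMF -> arth",
                      "mol -> arth"), covariances = "mol ~~ plant")
  run <- multi_index_run(div, spec, indices = c("S", "BP"))
  pa <- run$paths[run$paths$from == "plant" & run$paths$to == "arth", ]
  expect_lt(pa$p_value[pa$index == "S"], 0.05)
  expect_gt(pa$p_value[pa$index == "BP"], 0.05)
})
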