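#' Define a synthetic study scenario
#'
#' Describes a ground-truthed multi-group community study emulating a
#' grassland design: plots spread over regions, focal subsamples per plot,
#' a managed land-use gradient, latent diversity scores coupled through a
#' recursive path structure, and per-group species-abundance distributions
#' (SADs) sampled multinomially so that rare species are sometimes missed
#' and richness extrapolation has real work to do.
#'
#' The default scenario follows the emulated design: 60 plots in 3 regions,
#' 10 focal units per plot, three count-based layers (plants, mycorrhizal
#' fingerprints, arthropods), a five-locus allele-frequency layer, a dense
#' high-richness chemical layer with no cross-plot singleton features, a
#' land-use effect of -0.38 on the plant diversity latent, and standardized
#' coupling coefficients of magnitude 0.2 or 0.4 along the default path
#' topology.
#'
#' @param n_plots,n_regions,focal_units Study dimensions.
#' @param years Years of land-use records to simulate.
#' @param beta_lui Standardized effect of (standardized) LUI on the plant
#'   diversity latent.
#' @param coefficients Named vector of generating standardized path
#'   coefficients, names of the form `"from->to"`.
#' @param exog_cov Generating covariance between the exogenous molecular
#'   and plant latents.
#' @param sad_family `"geometric"` (default) or `"lognormal"` rank-abundance
#'   shape for the count-based groups.
#' @param groups Per-group SAD parameter lists (`pool`, `S_min`, `S_max`,
#'   `k_min`, `k_max`, `pool_decay`, `sdlog_min`, `sdlog_max`,
#'   `sample_size`).
#' @param mol Molecular-layer parameters (`n_loci`, `n_alleles`,
#'   `evenness_b`, `detect`).
#' @param chem Chemical-layer parameters (`n_features`, `evenness_b`,
#'   `sdlog`, `decay`).
#' @return An object of class `hillpath_scenario`.
#' @export
scenario <- function(n_plots = 60L, n_regions = 3L, focal_units = 10L,
                     years = 2006:2008,
                     beta_lui = -0.38,
                     coefficients = c("plant->chem" = -0.4,
                                      "plant->AMF" = 0.4,
                                      "plant->arth" = 0.2,
                                      "chem->arth" = 0.4,
                                      "mol->arth" = -0.2,
                                      "AMF->arth" = 0.2),
                     exog_cov = 0.2,
                     sad_family = c("geometric", "lognormal"),
                     groups = NULL, mol = NULL, chem = NULL) {
  sad_family <- match.arg(sad_family)
  defaults <- list(
    plant = list(pool = 160L, S_min = 10L, S_max = 45L,
                 k_min = 0.08, k_max = 0.55, pool_decay = 0.06,
                 sdlog_min = 0.6, sdlog_max = 2.2, sample_size = 150L),
    AMF = list(pool = 90L, S_min = 6L, S_max = 28L,
               k_min = 0.10, k_max = 0.60, pool_decay = 0.12,
               sdlog_min = 0.6, sdlog_max = 2.2, sample_size = 120L),
    arth = list(pool = 35L, S_min = 3L, S_max = 12L,
                k_min = 0.15, k_max = 0.70, pool_decay = 0.25,
                sdlog_min = 0.6, sdlog_max = 2.2, sample_size = 40L)
  )
  if (!is.null(groups)) {
    for (g in names(groups)) {
      defaults[[g]] <- utils::modifyList(defaults[[g]], groups[[g]])
    }
  }
  mol_def <- list(n_loci = 5L, n_alleles = c(10L, 8L, 6L, 12L, 9L),
                  evenness_b = 0.7, detect = 0.01)
  if (!is.null(mol)) mol_def <- utils::modifyList(mol_def, mol)
  chem_def <- list(n_features = 1000L, evenness_b = 0.5, sdlog = 0.3,
                   decay = 0.008)
  if (!is.null(chem)) chem_def <- utils::modifyList(chem_def, chem)

  for (g in names(defaults)) {
    gp <- defaults[[g]]
    if (gp$S_min < 1L) stop("S_min must be >= 1 for group ", g,
                            call. = FALSE)
    if (gp$S_max > gp$pool) stop("S_max exceeds pool size for group ", g,
                                 call. = FALSE)
    if (gp$k_min <= 0 || gp$k_max >= 1 || gp$k_min > gp$k_max) {
      stop("need 0 < k_min <= k_max < 1 for group ", g, call. = FALSE)
    }
  }
  if (abs(exog_cov) / sqrt(1 - beta_lui^2) >= 1) {
    stop("exog_cov too large relative to beta_lui", call. = FALSE)
  }
  # generating couplings must form a DAG
  gen_spec <- path_spec(edges = sub("->", " -> ", names(coefficients)))

  structure(
    list(n_plots = as.integer(n_plots), n_regions = as.integer(n_regions),
         focal_units = as.integer(focal_units), years = years,
         beta_lui = beta_lui, coefficients = coefficients,
         exog_cov = exog_cov, sad_family = sad_family,
         groups = defaults, mol = mol_def, chem = chem_def,
         gen_spec = gen_spec),
    class = "hillpath_scenario"
  )
}

#' @export
print.hillpath_scenario <- function(x, ...) {
  cat("Synthetic study scenario:", x$n_plots, "plots /", x$n_regions,
      "regions,", x$focal_units, "focal units per plot\n")
  cat("  SAD family:", x$sad_family,
      "; LUI effect on plant latent:", x$beta_lui, "\n")
  cat("  couplings:", paste(names(x$coefficients), "=",
                            x$coefficients, collapse = ", "), "\n")
  invisible(x)
}

maybe_seeded <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

gen_land_use_ <- function(scn) {
  n <- scn$n_plots
  plots <- sprintf("P%03d", seq_len(n))
  regions <- paste0("R", rep_len(seq_len(scn$n_regions), n))
  type <- sample(c("meadow", "pasture", "mixed"), n, replace = TRUE,
                 prob = c(0.4, 0.35, 0.25))
  F_base <- ifelse(stats::runif(n) < ifelse(type == "meadow", 0.75, 0.35),
                   stats::rgamma(n, shape = 2, scale = 18), 0)
  M_base <- ifelse(type == "pasture", 0L,
                   sample(1:3, n, replace = TRUE, prob = c(0.5, 0.35, 0.15)))
  G_base <- ifelse(type == "meadow", 0,
                   stats::rgamma(n, shape = 2, scale = 0.6))
  purrr::map_dfr(scn$years, function(yr) {
    tibble::tibble(
      plot = plots, region = regions, year = yr,
      F = F_base * ifelse(F_base > 0, stats::runif(n, 0.8, 1.25), 1),
      M = M_base,
      G = G_base * ifelse(G_base > 0, stats::runif(n, 0.8, 1.25), 1)
    )
  })
}

#' Simulate land-use records for a scenario
#'
#' Three years of fertilization, mowing and grazing per plot, with
#' management archetypes (meadow/pasture/mixed) producing realistic exact
#' zeros (unfertilized pastures, unmown meadows).
#'
#' @param scn A [scenario()].
#' @param seed Integer seed; identical seed gives identical records.
#' @return A land-use tibble (`plot`, `region`, `year`, `F`, `M`, `G`).
#' @export
generate_land_use <- function(scn, seed = NULL) {
  maybe_seeded(seed, gen_land_use_(scn))
}

gen_latents_ <- function(scn, lui = NULL) {
  n <- scn$n_plots
  if (is.null(lui)) {
    plots <- sprintf("P%03d", seq_len(n))
    L <- stats::rnorm(n)
  } else {
    lui <- lui[order(lui$plot), ]
    plots <- lui$plot
    if (length(plots) != n) {
      stop("LUI table has ", length(plots), " plots but scenario has ", n,
           call. = FALSE)
    }
    L <- as.numeric(scale(lui$LUI))
  }
  beta <- scn$beta_lui
  rho_u <- scn$exog_cov / sqrt(1 - beta^2)

  vars <- scn$gen_spec$variables
  stopifnot(all(c("mol", "plant") %in% vars))
  Zm <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))
  Sig <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  Zm[, "mol"] <- stats::rnorm(n)
  u <- rho_u * Zm[, "mol"] + sqrt(1 - rho_u^2) * stats::rnorm(n)
  Zm[, "plant"] <- beta * L + sqrt(1 - beta^2) * u
  Sig["mol", "mol"] <- 1
  Sig["plant", "plant"] <- 1
  Sig["mol", "plant"] <- Sig["plant", "mol"] <- scn$exog_cov

  done <- c("mol", "plant")
  for (y in setdiff(vars, done)) {
    pa <- scn$gen_spec$parents[[y]]
    b <- vapply(pa, function(p) {
      unname(scn$coefficients[paste0(p, "->", y)])
    }, numeric(1))
    expl <- drop(t(b) %*% Sig[pa, pa, drop = FALSE] %*% b)
    psi <- 1 - expl
    if (psi <= 0.02) {
      stop("generating coefficients leave no residual variance for ", y,
           call. = FALSE)
    }
    Zm[, y] <- Zm[, pa, drop = FALSE] %*% b + sqrt(psi) * stats::rnorm(n)
    for (v in done) Sig[y, v] <- Sig[v, y] <- drop(Sig[v, pa] %*% b)
    Sig[y, y] <- 1
    done <- c(done, y)
  }
  z <- tibble::as_tibble(Zm)
  names(z) <- paste0("z_", names(z))
  z <- dplyr::bind_cols(tibble::tibble(plot = plots, LUI_z = L), z)
  list(z = z, coefficients = scn$coefficients, beta_lui = beta,
       exog_cov = scn$exog_cov, sigma_pop = Sig)
}

#' Draw latent diversity scores realizing the coupling structure
#'
#' Gaussian structural equations over the group-level latents: molecular
#' and plant latents are exogenous (correlated by `exog_cov`; the plant
#' latent additionally carries the `beta_lui` effect of standardized LUI),
#' every other latent is a linear function of its parents plus a residual
#' sized so that all latents have unit population variance — the generating
#' coefficients are therefore standardized path coefficients.
#'
#' @param scn A [scenario()].
#' @param lui Optional LUI table from [compute_lui()]; if `NULL`, a
#'   standard-normal land-use gradient is drawn internally.
#' @param seed Integer seed.
#' @return A ground-truth list: `z` (tibble of per-plot latent scores),
#'   `coefficients`, `beta_lui`, `exog_cov`, `sigma_pop` (population
#'   covariance of the latents).
#' @export
generate_latents <- function(scn, lui = NULL, seed = NULL) {
  maybe_seeded(seed, gen_latents_(scn, lui))
}

sad_proportions <- function(S, z, params, family) {
  w <- stats::pnorm(z)
  if (family == "geometric") {
    k <- params$k_max + (params$k_min - params$k_max) * w
    p <- k * (1 - k)^(seq_len(S) - 1)
  } else {
    sdl <- params$sdlog_max + (params$sdlog_min - params$sdlog_max) * w
    p <- exp(sdl * stats::qnorm(seq_len(S) / (S + 1)))
    p <- sort(p, decreasing = TRUE)
  }
  p / sum(p)
}

#' Sample one community from a latent diversity score
#'
#' The latent score sets both the local species-pool size,
#' `S = round(S_min + (S_max - S_min) * pnorm(z))`, and the evenness of the
#' rank-abundance curve (geometric parameter `k(z)` decreasing in `z`, so
#' higher latent diversity means a more even community). Counts are drawn
#' multinomially at the given sampling depth, so rare species are sometimes
#' unobserved.
#'
#' @param z Latent diversity score.
#' @param params SAD parameter list (`S_min`, `S_max`, `k_min`, `k_max`,
#'   `sdlog_min`, `sdlog_max`, `pool`, `sample_size`).
#' @param sample_size Number of individuals to draw.
#' @param family `"geometric"` or `"lognormal"`.
#' @param pool_taxa Optional global taxon labels (length >= `S_max`); the
#'   local community occupies a random subset, giving between-plot
#'   turnover. Defaults to rank labels local to the call.
#' @param seed Optional integer seed.
#' @return Named integer vector of counts over the local pool (zeros =
#'   present in the local pool but unsampled).
#' @export
community_from_latent <- function(z, params, sample_size = params$sample_size,
                                  family = "geometric", pool_taxa = NULL,
                                  seed = NULL) {
  if (params$S_min < 1L) stop("S_min must be >= 1", call. = FALSE)
  if (sample_size < 1L) stop("sample_size must be >= 1", call. = FALSE)
  maybe_seeded(seed, {
    S <- max(1L, round(params$S_min +
                         (params$S_max - params$S_min) * stats::pnorm(z)))
    p <- sad_proportions(S, z, params, family)
    taxa <- if (is.null(pool_taxa)) {
      sprintf("sp%03d", seq_len(S))
    } else {
      # heavy-tailed global weights: low-rank pool members rarely enter any
      # local community, so the regional pool is never fully observed
      dec <- params$pool_decay %||% 0
      w <- (1 - dec)^(seq_along(pool_taxa) - 1)
      sample(pool_taxa, S, prob = w)
    }
    counts <- as.integer(stats::rmultinom(1L, sample_size, p))
    stats::setNames(counts, taxa)
  })
}

gen_group_abundance_ <- function(scn, gt, group) {
  params <- scn$groups[[group]]
  zcol <- paste0("z_", group)
  pool_taxa <- sprintf("%s_sp%03d", group, seq_len(params$pool))
  rows <- purrr::map_dfr(seq_len(scn$n_plots), function(i) {
    z <- gt$z[[zcol]][i]
    purrr::map_dfr(seq_len(scn$focal_units), function(fu) {
      counts <- community_from_latent(z, params, family = scn$sad_family,
                                      pool_taxa = pool_taxa)
      counts <- counts[counts > 0]
      tibble::tibble(plot = gt$z$plot[i], focal_unit = fu, group = group,
                     taxon_id = names(counts),
                     abundance = as.numeric(counts))
    })
  })
  rows
}

gen_molecular_ <- function(scn, gt) {
  mp <- scn$mol
  # global per-locus allele weights give alleles a stable identity
  base_w <- lapply(seq_len(mp$n_loci), function(l) {
    w <- stats::rgamma(mp$n_alleles[l], shape = 1.2)
    w / sum(w)
  })
  purrr::map_dfr(seq_len(scn$n_plots), function(i) {
    z <- gt$z$z_mol[i]
    temp <- exp(mp$evenness_b * z)  # >1 flattens: more even at high z
    purrr::map_dfr(seq_len(mp$n_loci), function(l) {
      w <- base_w[[l]]
      f <- (w * exp(0.3 * stats::rnorm(length(w))))^(1 / temp)
      f <- f / sum(f)
      f[f < mp$detect] <- 0  # alleles below detection are unscored
      f <- f / sum(f)
      keep <- f > 0
      tibble::tibble(plot = gt$z$plot[i], group = "mol",
                     locus = paste0("L", l),
                     allele = sprintf("L%d_a%02d", l, which(keep)),
                     frequency = f[keep])
    })
  })
}

gen_chem_ <- function(scn, gt) {
  cp <- scn$chem
  n <- scn$n_plots
  nf <- cp$n_features
  base <- (1 - cp$decay)^(seq_len(nf) - 1)  # rank-abundance backbone
  feat <- sprintf("chem_f%04d", seq_len(nf))
  zc <- gt$z$z_chem
  # aligned fingerprinting: every feature has a positive intensity in every
  # plot, so the layer has no cross-plot singletons and incidence-based
  # resampling SEs go degenerate; the chemical signal lives in evenness
  purrr::map_dfr(seq_len(n), function(i) {
    temp <- exp(cp$evenness_b * zc[i])  # >1 flattens: more even at high z
    inten <- (base^(1 / temp)) * exp(cp$sdlog * stats::rnorm(nf))
    inten <- 1e6 * inten / sum(inten)
    tibble::tibble(plot = gt$z$plot[i], group = "chem",
                   taxon_id = feat, abundance = inten)
  })
}

#' Generate a full ground-truthed synthetic study
#'
#' Runs the whole generator under one seed: land-use records, the LUI
#' gradient, coupled latent diversity scores, focal-unit count communities
#' for the plant, mycorrhizal and arthropod layers, a five-locus
#' allele-frequency layer, a dense chemical peak-intensity layer, and the
#' ground-truth record of everything that generated them.
#'
#' @param scn A [scenario()].
#' @param seed Integer master seed; the whole bundle is a deterministic
#'   function of (scenario, seed).
#' @return A list: `abundance` (long counts for plant/AMF/arth),
#'   `molecular` (allele frequencies), `chem` (peak intensities),
#'   `land_use`, `lui`, `ground_truth`, `scenario`.
#' @export
generate_study <- function(scn, seed = 1L) {
  withr::with_seed(seed, {
    lu <- gen_land_use_(scn)
    lui <- compute_lui(lu, years = scn$years)
    gt <- gen_latents_(scn, lui)
    abundance <- dplyr::bind_rows(
      gen_group_abundance_(scn, gt, "plant"),
      gen_group_abundance_(scn, gt, "AMF"),
      gen_group_abundance_(scn, gt, "arth")
    )
    molecular <- gen_molecular_(scn, gt)
    chem <- gen_chem_(scn, gt)
    gt$pools <- vapply(scn$groups, function(g) g$pool, integer(1))
    list(abundance = abundance, molecular = molecular, chem = chem,
         land_use = lu, lui = lui, ground_truth = gt, scenario = scn,
         seed = seed)
  })
}

#' Write a generated study bundle to disk
#'
#' Emits the standard pipeline input files: `abundance.tsv`,
#' `molecular.tsv`, `chem.tsv`, `land_use.tsv`, plus
#' `ground_truth.json` (latent scores, generating coefficients, pools,
#' seed).
#'
#' @param study A bundle from [generate_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv_out(study$abundance, file.path(dir, "abundance.tsv"))
  write_tsv_out(study$molecular, file.path(dir, "molecular.tsv"))
  write_tsv_out(study$chem, file.path(dir, "chem.tsv"))
  write_tsv_out(study$land_use, file.path(dir, "land_use.tsv"))
  gt <- study$ground_truth
  jsonlite::write_json(
    list(z = gt$z, coefficients = as.list(gt$coefficients),
         beta_lui = gt$beta_lui, exog_cov = gt$exog_cov,
         pools = as.list(gt$pools), seed = study$seed),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
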