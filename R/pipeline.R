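#' Assemble a pipeline run configuration
#'
#' Collects everything one full analysis needs: either a synthetic
#' [scenario()] or paths to input files, the Hill power grid, significance
#' level, PCA retention rule, path-model spec, bootstrap replicates and the
#' master seed. Referenced files are checked at validation time.
#'
#' @param scenario A [scenario()] to simulate from (mutually exclusive with
#'   `inputs`).
#' @param inputs Named list of file paths: `abundance`, `land_use`, and
#'   optionally `molecular`, `chem`.
#' @param groups Optional subset of groups to analyze.
#' @param hill_powers Power grid for the Hill profile columns.
#' @param alpha Family-wise error rate for the batteries and path tests.
#' @param retain PCA axis retention rule (`"kaiser"`, `"all"`, `"first2"`).
#' @param path_model A `path_spec`, or path to a plain-text spec file.
#' @param richness_B Bootstrap replicates for richness SEs.
#' @param seed Master seed; every stage derives its randomness from it.
#' @param out_dir Output directory for [run_all()].
#' @return A `run_config` list.
#' @export
run_config <- function(scenario = NULL, inputs = NULL, groups = NULL,
                       hill_powers = c(0, 0.5, 1, 2, 4, Inf),
                       alpha = 0.05, retain = "kaiser",
                       path_model = default_path_spec(),
                       richness_B = 200L, seed = 1L, out_dir = NULL) {
  if (is.null(scenario) == is.null(inputs)) {
    stop("supply exactly one of `scenario` or `inputs`", call. = FALSE)
  }
  if (!is.null(inputs)) {
    needed <- c("abundance", "land_use")
    missing_in <- setdiff(needed, names(inputs))
    if (length(missing_in)) {
      stop("inputs lack: ", paste(missing_in, collapse = ", "),
           call. = FALSE)
    }
    for (f in unlist(inputs)) {
      if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
    }
  }
  if (is.character(path_model)) path_model <- read_path_spec(path_model)
  stopifnot(inherits(path_model, "path_spec"))
  structure(
    list(scenario = scenario, inputs = inputs, groups = groups,
         hill_powers = hill_powers, alpha = alpha, retain = retain,
         path_model = path_model, richness_B = as.integer(richness_B),
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

log_line <- function(lines, ..., quiet = FALSE) {
  msg <- paste0(...)
  if (!quiet) message(msg)
  c(lines, msg)
}

#' Run the full diversity-comparison pipeline
#'
#' Orchestrates every stage on one dataset: simulate or ingest, per-plot
#' diversity tables for all groups, incidence-based richness extrapolation,
#' the LUI gradient, the Bonferroni-corrected correlation and regression
#' batteries, per-group correlation PCAs with importance values, and the
#' multi-index path-model run. When `out_dir` is set, all tables are
#' written as TSV, path fits as JSON, and a human-readable summary lists
#' which paths and regressions were significant per index, alongside a log
#' recording seeds and row counts at each stage.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (overrides the config's).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with every stage's result: `data`, `div`,
#'   `richness`, `lui`, `correlations`, `regressions`, `importance`,
#'   `path_run`, `log`.
#' @export
run_all <- function(config, out_dir = config$out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  lg <- character()
  lg <- log_line(lg, "pipeline seed: ", config$seed, quiet = quiet)

  # --- stage 1: data ---------------------------------------------------
  if (!is.null(config$scenario)) {
    data <- generate_study(config$scenario, seed = config$seed)
    lg <- log_line(lg, "simulated study: ", config$scenario$n_plots,
                   " plots, ", nrow(data$abundance), " abundance rows",
                   quiet = quiet)
  } else {
    data <- list(
      abundance = read_abundance(config$inputs$abundance),
      land_use = read_land_use(config$inputs$land_use),
      molecular = if (!is.null(config$inputs$molecular)) {
        read_table_auto(config$inputs$molecular)
      },
      chem = if (!is.null(config$inputs$chem)) {
        read_abundance(config$inputs$chem)
      }
    )
    data$lui <- compute_lui(data$land_use)
    lg <- log_line(lg, "read ", nrow(data$abundance), " abundance rows",
                   quiet = quiet)
  }

  # --- stage 2: diversity tables --------------------------------------
  div <- diversity_table(data$abundance, hill_powers = config$hill_powers)
  if (!is.null(data$chem)) {
    div <- dplyr::bind_rows(
      div, diversity_table(data$chem, hill_powers = config$hill_powers))
  }
  if (!is.null(data$molecular)) {
    mol_div <- molecular_diversity(data$molecular)
    mol_div$group <- "mol"
    div <- dplyr::bind_rows(div, mol_div)
  }
  if (!is.null(config$groups)) div <- div[div$group %in% config$groups, ]
  lg <- log_line(lg, "diversity table: ", nrow(div), " plot x group rows (",
                 paste(unique(div$group), collapse = ", "), ")",
                 quiet = quiet)

  # --- stage 3: richness extrapolation --------------------------------
  rich_inputs <- data$abundance
  if (!is.null(data$chem)) rich_inputs <- dplyr::bind_rows(rich_inputs,
                                                           data$chem)
  rich <- purrr::map_dfr(unique(rich_inputs$group), function(g) {
    inc <- incidence_from_abundance(rich_inputs, group = g)
    estimate_richness(inc, B = config$richness_B,
                      seed = config$seed + 101L)
  })
  if (!is.null(data$molecular)) {
    mol_long <- tibble::tibble(
      plot = data$molecular$plot,
      group = paste0("mol_", data$molecular$locus),
      taxon_id = data$molecular$allele,
      abundance = data$molecular$frequency
    )
    rich <- dplyr::bind_rows(rich, purrr::map_dfr(
      unique(mol_long$group), function(g) {
        inc <- incidence_from_abundance(mol_long, group = g)
        estimate_richness(inc, B = config$richness_B,
                          seed = config$seed + 101L)
      }))
  }
  lg <- log_line(lg, "richness estimates: ", nrow(rich), " rows",
                 quiet = quiet)

  # --- stage 4: LUI ----------------------------------------------------
  lui <- data$lui
  lg <- log_line(lg, "LUI range: ", paste(signif(range(lui$LUI), 4),
                                          collapse = " - "), quiet = quiet)

  # --- stage 5: batteries ---------------------------------------------
  correlations <- pearson_battery(div, alpha = config$alpha)
  regressions <- lui_regressions(div, lui, alpha = config$alpha)
  lg <- log_line(lg, "battery: ", sum(correlations$significant),
                 " significant correlations, ",
                 sum(regressions$significant),
                 " significant LUI regressions", quiet = quiet)

  # --- stage 6: site discrimination -----------------------------------
  importance <- purrr::map_dfr(unique(div$group), function(g) {
    wide <- div[div$group == g, c("plot", index_cols())]
    wide <- dplyr::inner_join(wide, lui[, c("plot", "LUI")], by = "plot")
    vars <- index_cols()[vapply(index_cols(), function(v) {
      stats::sd(wide[[v]], na.rm = TRUE) > 0
    }, logical(1))]
    if (length(vars) < length(index_cols())) {
      lg <<- log_line(lg, "PCA ", g, ": dropping zero-variance index(es) ",
                      paste(setdiff(index_cols(), vars), collapse = ", "),
                      quiet = quiet)
    }
    pca <- pca_correlation(wide, vars = vars, passive = "LUI")
    iv <- importance_values(pca, retain = config$retain)
    iv$group <- g
    iv
  })

  # --- stage 7: path models -------------------------------------------
  path_vars <- config$path_model$variables
  path_run <- NULL
  if (all(path_vars %in% unique(div$group))) {
    path_run <- multi_index_run(div[div$group %in% path_vars, ],
                                config$path_model, alpha = config$alpha)
    lg <- log_line(lg, "path models: df = ",
                   path_run$fit_stats$df[1], " for all ",
                   nrow(path_run$fit_stats), " indices", quiet = quiet)
  } else {
    lg <- log_line(lg, "path models skipped: groups ",
                   paste(setdiff(path_vars, unique(div$group)),
                         collapse = ", "), " absent", quiet = quiet)
  }

  out <- list(data = data, div = div, richness = rich, lui = lui,
              correlations = correlations, regressions = regressions,
              importance = importance, path_run = path_run, log = lg)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_tsv_out(div, file.path(out_dir, "diversity.tsv"))
    write_tsv_out(rich, file.path(out_dir, "richness.tsv"))
    write_tsv_out(lui, file.path(out_dir, "lui.tsv"))
    write_tsv_out(correlations, file.path(out_dir, "correlations.tsv"))
    write_tsv_out(regressions, file.path(out_dir, "regressions.tsv"))
    write_tsv_out(importance, file.path(out_dir, "importance.tsv"))
    if (!is.null(path_run)) {
      jsonlite::write_json(
        list(fit_stats = path_run$fit_stats, paths = path_run$paths),
        file.path(out_dir, "path_fits.json"), auto_unbox = TRUE,
        digits = NA)
    }
    writeLines(pipeline_summary(out), file.path(out_dir, "summary.txt"))
    writeLines(c(paste("hillpath", as.character(utils::packageVersion("hillpath"))),
                 paste("R", getRversion()), lg),
               file.path(out_dir, "run_log.txt"))
  }
  invisible(out)
}

pipeline_summary <- function(res) {
  lines <- c("Diversity-index comparison pipeline summary", "")
  lines <- c(lines, "Significant LUI regressions (Bonferroni within group):")
  sig <- res$regressions[res$regressions$significant, ]
  lines <- c(lines, if (nrow(sig)) {
    sprintf("  %s / %s: F = %.2f, p = %.4g, r = %.2f",
            sig$group, sig$index, sig$F, sig$p, sig$r)
  } else "  none")
  if (!is.null(res$path_run)) {
    lines <- c(lines, "", "Path-model fit per index:")
    fs <- res$path_run$fit_stats
    lines <- c(lines, sprintf(
      "  %s: chi2 = %.2f (df %d, p = %.3f), RMSEA = %.4f, TLNNFI = %s",
      fs$index, fs$chi2, fs$df, fs$p_chi2, fs$rmsea,
      ifelse(is.na(fs$tlnnfi), "NA", sprintf("%.3f", fs$tlnnfi))))
    lines <- c(lines, "", "Significant paths per index:")
    ps <- res$path_run$paths[res$path_run$paths$significant, ]
    lines <- c(lines, if (nrow(ps)) {
      sprintf("  %s: %s -> %s (%.2f)", ps$index, ps$from, ps$to,
              ps$estimate)
    } else "  none")
  }
  lines
}
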