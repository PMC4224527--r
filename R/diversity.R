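#' Normalize an abundance vector to proportions
#'
#' Drops zero-abundance entries, validates non-negativity, and rescales to
#' proportions summing to one. Abundances may be counts, percent cover, peak
#' heights/intensities or allele frequencies; after normalization the index
#' arithmetic is identical for all of them.
#'
#' @param x Numeric vector of non-negative abundances.
#' @param context Optional label (e.g. "plot AEG01, group plant") used in
#'   error messages so failures are traceable to their sample.
#' @return Numeric vector of proportions summing to 1, zero entries removed.
#' @keywords internal
as_proportions <- function(x, context = NULL) {
  where <- if (is.null(context)) "" else paste0(" [", context, "]")
  if (length(x) == 0L || all(is.na(x))) {
    stop("empty abundance vector", where, call. = FALSE)
  }
  if (anyNA(x)) stop("NA abundance", where, call. = FALSE)
  if (any(x < 0)) stop("negative abundance", where, call. = FALSE)
  x <- x[x > 0]
  if (length(x) == 0L) {
    stop("all-zero abundance vector", where, call. = FALSE)
  }
  x / sum(x)
}

#' Compute the six standard diversity indices for one community
#'
#' Given one community sample (any non-negative abundance vector), computes
#' richness `S`, Shannon diversity `H = -sum(p_i log p_i)` (natural log),
#' Simpson diversity `D1 = 1 - sum(p_i^2)`, Simpson dominance (inverse
#' Simpson) `D2 = 1 / sum(p_i^2)`, Berger-Parker dominance `BP = max(p_i)`,
#' and Simpson evenness `E = D2 / S`. Zero abundances are dropped before
#' anything is computed, so `S` counts only taxa actually present.
#'
#' @param x Numeric vector of non-negative abundances (at least one positive).
#' @param context Optional sample label for error messages.
#' @return A one-row tibble with columns `S`, `H`, `D1`, `D2`, `BP`, `E`.
#' @examples
#' compute_indices(c(0.6, 0.3, 0.1))
#' compute_indices(c(10, 10))  # uniform: E = 1, H = log(2)
#' @export
compute_indices <- function(x, context = NULL) {
  tibble::as_tibble(as.list(indices_vec(as_proportions(x, context))))
}

# index kernel on a proportion vector (already normalized, all > 0)
indices_vec <- function(p) {
  S <- length(p)
  sp2 <- sum(p^2)
  D2 <- 1 / sp2
  c(S = S, H = -sum(p * log(p)), D1 = 1 - sp2, D2 = D2,
    BP = max(p), E = D2 / S)
}

#' Hill number (effective species number) at power a
#'
#' Evaluates `N_a = (sum p_i^a)^(1/(1-a))`, the effective number of equally
#' abundant species matching the community's generalized entropy at power
#' `a`. Special cases: `N_0` is richness, `N_1 = exp(H)` (the analytic
#' limit, used whenever `|a - 1| < 1e-9`), `N_2` is inverse Simpson, and
#' `N_Inf = 1 / max(p_i)`, the inverse Berger-Parker dominance.
#'
#' @param x Numeric vector of non-negative abundances.
#' @param a Numeric vector of powers, each `>= 0`; `Inf` is allowed.
#' @param context Optional sample label for error messages.
#' @return Numeric vector of effective species numbers, one per power.
#' @examples
#' hill_number(c(0.6, 0.3, 0.1), c(0, 1, 2, Inf))
#' @export
hill_number <- function(x, a, context = NULL) {
  p <- as_proportions(x, context)
  if (anyNA(a) || any(a < 0)) {
    stop("Hill powers must be >= 0 (Inf allowed)", call. = FALSE)
  }
  vapply(a, function(ai) {
    if (is.infinite(ai)) return(1 / max(p))
    if (abs(ai - 1) < 1e-9) return(exp(-sum(p * log(p))))
    sum(p^ai)^(1 / (1 - ai))
  }, numeric(1))
}

#' Continuous Hill-number diversity profile
#'
#' Evaluates the effective species number over a grid of powers, producing
#' the diversity profile that runs from richness (`a = 0`, sensitive to rare
#' species) to inverse Berger-Parker dominance (`a = Inf`, sensitive only to
#' the most abundant species). The profile is non-increasing in `a`, and is
#' flat exactly when the community is perfectly even.
#'
#' @param x Numeric vector of non-negative abundances.
#' @param powers Numeric grid of at least two powers (`Inf` allowed).
#' @param context Optional sample label for error messages.
#' @return A tibble of class `hill_profile` with columns `a` and `N`.
#' @examples
#' hill_profile(c(0.6, 0.3, 0.1), c(0, 0.5, 1, 2, 4, Inf))
#' @export
hill_profile <- function(x, powers, context = NULL) {
  if (length(powers) < 2L) stop("need a grid of >= 2 powers", call. = FALSE)
  powers <- sort(powers)
  out <- tibble::tibble(a = powers, N = hill_number(x, powers, context))
  class(out) <- c("hill_profile", class(out))
  out
}

index_cols <- function() c("S", "H", "D1", "D2", "BP", "E")

#' Average focal-unit diversity indices up to the plot level
#'
#' Takes a table of per-sampling-unit index values and returns the
#' arithmetic mean of each index per plot (and per group, if present).
#' The evenness identity `E = D2 / S` is deliberately *not* re-imposed on
#' the means: each index is computed per sample and then averaged, so the
#' plot-level values are means of ratios.
#'
#' @param idx A data frame with a `plot` column, optionally `group`, and
#'   numeric index columns (any of `S`, `H`, `D1`, `D2`, `BP`, `E`, and/or
#'   Hill-number columns `N_*`).
#' @return A tibble with one row per plot (x group), index columns averaged.
#' @export
aggregate_per_plot <- function(idx) {
  stopifnot(is.data.frame(idx), "plot" %in% names(idx))
  if (nrow(idx) == 0L) stop("no rows to aggregate", call. = FALSE)
  keys <- intersect(c("plot", "group"), names(idx))
  vals <- setdiff(names(idx), c(keys, "focal_unit"))
  vals <- vals[vapply(idx[vals], is.numeric, logical(1))]
  idx |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(vals), ~ mean(.x)),
      .groups = "drop"
    )
}

#' Build a plot x group diversity table from a long abundance table
#'
#' The central exchange format of the pipeline: indices are computed per
#' sampling unit (focal unit if the column is present, otherwise the whole
#' plot) and then averaged per plot within each group. Samples with no
#' positive abundance are flagged in the `empty` column rather than silently
#' dropped; their index columns are `NA`.
#'
#' @param abund Long-format data frame with columns `plot`, `group`,
#'   `taxon_id`, `abundance`, and optionally `focal_unit`.
#' @param hill_powers Optional numeric grid of Hill powers; if given, a
#'   column `N_<a>` per power is appended (computed per sample, averaged like
#'   the other indices).
#' @return A tibble with one row per (plot, group): columns `plot`, `group`,
#'   `S`, `H`, `D1`, `D2`, `BP`, `E`, optional `N_*` columns, and `empty`.
#' @examples
#' abund <- tibble::tibble(
#'   plot = rep(c("p1", "p2"), each = 3),
#'   group = "plant",
#'   taxon_id = rep(c("a", "b", "c"), 2),
#'   abundance = c(5, 3, 2, 9, 1, 0)
#' )
#' diversity_table(abund)
#' @export
diversity_table <- function(abund, hill_powers = NULL) {
  needed <- c("plot", "group", "taxon_id", "abundance")
  missing_cols <- setdiff(needed, names(abund))
  if (length(missing_cols)) {
    stop("abundance table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keys <- c("plot", "group")
  if ("focal_unit" %in% names(abund)) keys <- c(keys, "focal_unit")
  if (anyNA(abund$abundance) || any(abund$abundance < 0)) {
    bad <- which(is.na(abund$abundance) | abund$abundance < 0)[1L]
    stop("negative or missing abundance at plot ", abund$plot[bad],
         ", group ", abund$group[bad], call. = FALSE)
  }

  hill_names <- if (is.null(hill_powers)) character() else
    paste0("N_", sub("Inf", "inf", format(hill_powers, trim = TRUE)))
  nv <- 6L + length(hill_names)

  key <- do.call(paste, c(unname(abund[keys]), sep = "\r"))
  idx <- split(seq_len(nrow(abund)), key)
  vals <- vapply(idx, function(i) {
    x <- abund$abundance[i]
    x <- x[x > 0]
    if (length(x) == 0L) return(c(rep(NA_real_, nv), 1))
    p <- x / sum(x)
    hv <- if (is.null(hill_powers)) numeric() else hill_number(p, hill_powers)
    c(indices_vec(p), hv, 0)
  }, numeric(nv + 1L))
  first <- vapply(idx, `[`, integer(1), 1L)
  per_unit <- dplyr::bind_cols(
    abund[first, keys],
    tibble::as_tibble(stats::setNames(
      as.data.frame(t(vals)),
      c(index_cols(), hill_names, "empty")))
  )
  per_unit$empty <- per_unit$empty > 0

  # empty focal units are excluded from the plot mean; a plot is flagged
  # empty only when every unit was
  per_unit |>
    dplyr::select(-dplyr::any_of("focal_unit")) |>
    dplyr::group_by(.data$plot, .data$group) |>
    dplyr::summarise(
      dplyr::across(dplyr::where(is.numeric), ~ {
        m <- mean(.x, na.rm = TRUE)
        if (is.nan(m)) NA_real_ else m
      }),
      empty = all(.data$empty),
      .groups = "drop"
    )
}

#' Diversity indices for multilocus allele-frequency data
#'
#' For molecular (e.g. microsatellite) data, abundance is the allele
#' frequency at each locus: each index is computed per locus and then
#' averaged across loci within a plot. Per locus, `D1` equals the expected
#' heterozygosity `1 - sum(p_i^2)` and `D2` the effective number of alleles.
#' Frequencies at a locus must sum to 1 within `1e-6`; renormalization is
#' opt-in, not silent.
#'
#' @param freqs Data frame with columns `plot`, `locus`, `allele`,
#'   `frequency` (and optionally `group`, carried through).
#' @param renormalize If `TRUE`, frequencies at each locus are rescaled to
#'   sum to 1 instead of erroring on drift beyond tolerance.
#' @param tol Tolerance on `|sum(freq) - 1|` per locus (default `1e-6`).
#' @return A tibble with one row per plot: `plot` (+ `group` if supplied)
#'   and the six index columns, each the across-locus mean.
#' @examples
#' freqs <- tibble::tibble(
#'   plot = "p1", locus = rep(c("L1", "L2"), c(1, 2)),
#'   allele = c("a", "a", "b"), frequency = c(1, 0.5, 0.5)
#' )
#' molecular_diversity(freqs)  # D1 = mean(0, 0.5) = 0.25
#' @export
molecular_diversity <- function(freqs, renormalize = FALSE, tol = 1e-6) {
  needed <- c("plot", "locus", "allele", "frequency")
  missing_cols <- setdiff(needed, names(freqs))
  if (length(missing_cols)) {
    stop("allele-frequency table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keys <- intersect(c("plot", "group"), names(freqs))

  per_locus <- freqs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "locus")))) |>
    dplyr::group_modify(function(d, g) {
      ctx <- paste0("plot ", g$plot, ", locus ", g$locus)
      f <- d$frequency
      tot <- sum(f[f > 0])
      if (abs(tot - 1) > tol) {
        if (!renormalize) {
          stop("allele frequencies sum to ", format(tot), " [", ctx,
               "]; set renormalize = TRUE to rescale", call. = FALSE)
        }
      }
      compute_indices(f, context = ctx)
    }) |>
    dplyr::ungroup()

  per_locus |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(index_cols()), ~ mean(.x)),
      .groups = "drop"
    )
}
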