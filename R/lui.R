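#' Land-use intensity index (LUI)
#'
#' Summarizes grassland management intensity per plot from three equally
#' weighted components — fertilization `F` (kg N ha-1 yr-1), mowing
#' frequency `M` (cuts yr-1) and grazing `G` (livestock units ha-1 yr-1) —
#' each standardized by its mean over all plots of the same region
#' (exploratory), summed and square-root transformed. Standardization by
#' ratios makes the index dimensionless, and the square root improves
#' normality of the resulting gradient.
#'
#' By default the components are first averaged over the requested years,
#' then standardized by the regional means of those multi-year averages,
#' summed and square-rooted (the transform is applied once to the multi-year
#' index). With `yearly_first = TRUE` a yearly index is standardized within
#' each year, averaged across years, and then square-rooted.
#'
#' @param records Data frame with columns `plot`, `region`, `year`, `F`,
#'   `M`, `G`; every plot must cover the same set of years.
#' @param years Optional subset of years to use (default: all present).
#' @param yearly_first Compute a yearly standardized index and average it,
#'   instead of standardizing the multi-year component means.
#' @return A tibble: `plot`, `region`, standardized components `F_std`,
#'   `M_std`, `G_std` (NA for a component dropped as all-zero in a region),
#'   and `LUI`. Within each region the mean of each retained standardized
#'   component equals 1.
#' @examples
#' rec <- tibble::tibble(
#'   plot = c("p1", "p2"), region = "A", year = 2006,
#'   F = c(30, 0), M = c(2, 0), G = c(1, 1)
#' )
#' compute_lui(rec)
#' @export
compute_lui <- function(records, years = NULL, yearly_first = FALSE) {
  needed <- c("plot", "region", "year", "F", "M", "G")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("land-use records lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.null(years)) records <- records[records$year %in% years, ]
  if (nrow(records) == 0L) stop("no land-use records left", call. = FALSE)
  if (any(records$F < 0 | records$M < 0 | records$G < 0, na.rm = TRUE)) {
    stop("land-use components must be nonnegative", call. = FALSE)
  }

  year_sets <- tapply(records$year, records$plot,
                      function(y) paste(sort(unique(y)), collapse = ","))
  if (length(unique(year_sets)) > 1L) {
    stop("plots differ in year coverage; supply a common `years` set",
         call. = FALSE)
  }
  n_region <- table(unique(records[, c("plot", "region")])$region)
  if (any(n_region < 2L)) {
    stop("each region needs >= 2 plots for standardization", call. = FALSE)
  }

  # divide by the group mean; all-zero components are dropped with a warning
  std <- function(x, comp, where) {
    m <- mean(x)
    if (m == 0) {
      warning("component ", comp, " is all-zero in ", where,
              "; dropped from LUI", call. = FALSE)
      return(rep(NA_real_, length(x)))
    }
    x / m
  }

  if (!yearly_first) {
    out <- records |>
      dplyr::group_by(.data$plot, .data$region) |>
      dplyr::summarise(F = mean(.data$F), M = mean(.data$M),
                       G = mean(.data$G), .groups = "drop") |>
      dplyr::group_by(.data$region) |>
      dplyr::mutate(
        F_std = std(.data$F, "F", paste("region", .data$region[1])),
        M_std = std(.data$M, "M", paste("region", .data$region[1])),
        G_std = std(.data$G, "G", paste("region", .data$region[1]))
      ) |>
      dplyr::ungroup() |>
      dplyr::mutate(
        LUI = sqrt(rowSums(cbind(.data$F_std, .data$M_std, .data$G_std),
                           na.rm = TRUE))
      )
  } else {
    out <- records |>
      dplyr::group_by(.data$region, .data$year) |>
      dplyr::mutate(
        F_std = std(.data$F, "F",
                    paste("region", .data$region[1], "year", .data$year[1])),
        M_std = std(.data$M, "M",
                    paste("region", .data$region[1], "year", .data$year[1])),
        G_std = std(.data$G, "G",
                    paste("region", .data$region[1], "year", .data$year[1]))
      ) |>
      dplyr::ungroup() |>
      dplyr::mutate(
        raw = rowSums(cbind(.data$F_std, .data$M_std, .data$G_std),
                      na.rm = TRUE)
      ) |>
      dplyr::group_by(.data$plot, .data$region) |>
      dplyr::summarise(
        F_std = mean(.data$F_std), M_std = mean(.data$M_std),
        G_std = mean(.data$G_std), LUI = sqrt(mean(.data$raw)),
        .groups = "drop"
      )
  }
  out <- out[order(out$plot), ]
  tibble::as_tibble(out[, c("plot", "region", "F_std", "M_std", "G_std",
                            "LUI")])
}
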