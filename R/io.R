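#' Read a long-format abundance table
#'
#' Expects a UTF-8 TSV or CSV with header columns `plot`, `group`,
#' `taxon_id`, `abundance` and optionally `focal_unit`. The delimiter is
#' inferred from the file extension (`.csv` vs anything else = TSV).
#'
#' @param path Path to the file.
#' @return A tibble in the pipeline's long abundance format.
#' @export
read_abundance <- function(path) {
  tab <- read_table_auto(path)
  needed <- c("plot", "group", "taxon_id", "abundance")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("abundance file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab$abundance <- as.numeric(tab$abundance)
  tab
}

#' Read a land-use table
#'
#' Expects columns `plot`, `region`, `year`, `F` (fertilization,
#' kg N ha-1 yr-1), `M` (mowing frequency, cuts yr-1) and `G` (grazing,
#' livestock units ha-1 yr-1).
#'
#' @param path Path to the TSV/CSV file.
#' @return A tibble of land-use records.
#' @export
read_land_use <- function(path) {
  tab <- read_table_auto(path)
  needed <- c("plot", "region", "year", "F", "M", "G")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("land-use file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab
}

read_table_auto <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Write a table as TSV
#'
#' Thin wrapper used for all pipeline outputs (diversity tables, richness
#' estimates, batteries, loadings): plain UTF-8 TSV with a header row.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_tsv_out <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}
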