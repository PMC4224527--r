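#' PCA of the correlation matrix of diversity indices across plots
#'
#' Standardizes each variable over plots and extracts principal components,
#' i.e. an eigen-analysis of the variable correlation matrix. Loadings are
#' reported as correlations between variables and components
#' (`rotation * sdev`), and each component's sign is fixed so that its
#' largest-magnitude loading is positive, giving a reproducible orientation.
#' A passive variable (e.g. LUI) can be projected onto the axes without
#' influencing them.
#'
#' @param data Data frame of plots x variables (a `plot` column, if present,
#'   is used for score labels and otherwise ignored).
#' @param vars Variables to ordinate (default: all numeric columns except
#'   `plot` and any `passive` variable).
#' @param passive Optional name of a column to project passively: its
#'   loadings (correlations with the scores) are reported, but it does not
#'   enter the decomposition.
#' @return An object of class `pca_cor`: eigenvalues, loadings,
#'   `variance_explained`, scores, `passive_loadings` (or NULL), `n`.
#' @export
pca_correlation <- function(data, vars = NULL, passive = NULL) {
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
    vars <- setdiff(vars, c("plot", passive))
  }
  if (length(vars) < 2L) stop("need >= 2 variables", call. = FALSE)
  d <- data[stats::complete.cases(data[, c(vars, passive)]), , drop = FALSE]
  if (nrow(d) < 3L) stop("need >= 3 complete plots", call. = FALSE)
  X <- as.matrix(d[, vars])
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance variable(s): ",
         paste(vars[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  load <- sweep(pc$rotation, 2L, pc$sdev, `*`)  # variable-component correlations
  # orient each axis so its largest-magnitude loading is positive
  flip <- apply(load, 2L, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2L, flip, `*`)
  scores <- sweep(pc$x, 2L, flip, `*`)
  rownames(scores) <- if ("plot" %in% names(d)) as.character(d$plot) else
    rownames(scores)
  passive_load <- NULL
  if (!is.null(passive)) {
    pv <- as.matrix(d[, passive])
    passive_load <- stats::cor(pv, scores)
    rownames(passive_load) <- passive
  }
  structure(
    list(eigenvalues = eig, loadings = load,
         variance_explained = eig / sum(eig), scores = scores,
         passive_loadings = passive_load, n = nrow(d), vars = vars),
    class = "pca_cor"
  )
}

#' @export
print.pca_cor <- function(x, ...) {
  cat("Correlation-matrix PCA: ", length(x$vars), " variables, ",
      x$n, " plots\n", sep = "")
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Tidy PCA loadings
#'
#' @param x A `pca_cor` object.
#' @param ... Unused.
#' @return A tibble: `variable`, `component`, `loading`, `eigenvalue`,
#'   `variance_explained`.
#' @export
tidy.pca_cor <- function(x, ...) {
  k <- ncol(x$loadings)
  tibble::tibble(
    variable = rep(rownames(x$loadings), k),
    component = rep(seq_len(k), each = nrow(x$loadings)),
    loading = as.vector(x$loadings),
    eigenvalue = rep(x$eigenvalues, each = nrow(x$loadings)),
    variance_explained = rep(x$variance_explained, each = nrow(x$loadings))
  )
}

retained_axes <- function(pca, retain) {
  k <- switch(retain,
              kaiser = which(pca$eigenvalues >= 1),
              all = seq_along(pca$eigenvalues),
              first2 = seq_len(min(2L, length(pca$eigenvalues))),
              stop("unknown retention rule: ", retain, call. = FALSE))
  if (length(k) == 0L) {
    stop("no axes retained under rule '", retain, "'", call. = FALSE)
  }
  k
}

#' Per-variable importance values from a correlation PCA
#'
#' Summarizes how strongly each variable structures the ordination:
#' `IV_j = sum over retained axes k of (lambda_k / sum lambda) * |l_jk|`,
#' the eigenvalue-proportion-weighted absolute loadings. With every axis
#' retained IV is at most 1; with a single axis explaining all variance it
#' reduces to the absolute first-axis loading. Variables with high IV
#' discriminate plots well in the reduced space.
#'
#' @param pca A `pca_cor` object.
#' @param retain Axis retention rule: `"kaiser"` (eigenvalue >= 1, default),
#'   `"all"`, or `"first2"`.
#' @return A tibble: `variable`, `IV`, plus the passive variable's IV if
#'   one was projected.
#' @export
importance_values <- function(pca, retain = c("kaiser", "all", "first2")) {
  retain <- match.arg(retain)
  k <- retained_axes(pca, retain)
  w <- pca$variance_explained[k]
  iv <- as.vector(abs(pca$loadings[, k, drop = FALSE]) %*% w)
  out <- tibble::tibble(variable = rownames(pca$loadings), IV = iv)
  if (!is.null(pca$passive_loadings)) {
    piv <- as.vector(abs(pca$passive_loadings[, k, drop = FALSE]) %*% w)
    out <- dplyr::bind_rows(
      out, tibble::tibble(variable = rownames(pca$passive_loadings),
                          IV = piv))
  }
  out
}
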