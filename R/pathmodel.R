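#' Specify a recursive path model over observed variables
#'
#' A recursive path model is a directed acyclic graph over observed
#' variables: parentless (exogenous) variables get free variances and,
#' where declared, free pairwise covariances; every other variable is
#' endogenous with one structural equation per incoming edge set and a free
#' residual variance. The free-parameter count is
#' `t = #edges + #exogenous variances + #exogenous covariances +
#' #endogenous residual variances`.
#'
#' @param edges Two-column data frame (`from`, `to`) or character vector of
#'   `"parent -> child"` strings.
#' @param covariances Optional free covariances among exogenous variables:
#'   two-column data frame (`a`, `b`) or `"a ~~ b"` strings.
#' @param variables Optional explicit variable ordering; defaults to a
#'   topological order of the graph.
#' @return An object of class `path_spec`.
#' @examples
#' path_spec(c("plant -> chem", "plant -> arth", "chem -> arth"))
#' @export
path_spec <- function(edges, covariances = NULL, variables = NULL) {
  edges <- parse_pairs(edges, "->")
  covs <- if (is.null(covariances)) {
    tibble::tibble(a = character(), b = character())
  } else {
    e <- parse_pairs(covariances, "~~")
    tibble::tibble(a = e$from, b = e$to)
  }
  if (nrow(edges) == 0L) stop("no edges in model spec", call. = FALSE)
  if (any(edges$from == edges$to)) stop("self-loop in edges", call. = FALSE)
  vars <- unique(c(variables, edges$from, edges$to, covs$a, covs$b))
  order <- topo_sort(vars, edges)  # errors on cycles
  vars <- order
  parents <- lapply(stats::setNames(vars, vars),
                    function(v) edges$from[edges$to == v])
  exog <- vars[vapply(parents, length, integer(1)) == 0L]
  endo <- setdiff(vars, exog)
  if (nrow(covs) > 0 && !all(covs$a %in% exog & covs$b %in% exog)) {
    stop("free covariances are only allowed among exogenous variables",
         call. = FALSE)
  }
  t_free <- nrow(edges) + length(exog) + nrow(covs) + length(endo)
  structure(
    list(variables = vars, edges = edges, covariances = covs,
         exogenous = exog, endogenous = endo, parents = parents,
         n_free = t_free),
    class = "path_spec"
  )
}

parse_pairs <- function(x, sep) {
  if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 2L)
    return(tibble::tibble(from = as.character(x[[1L]]),
                          to = as.character(x[[2L]])))
  }
  x <- trimws(x)
  x <- x[nzchar(x) & !grepl("^#", x)]
  parts <- strsplit(x, sep, fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("malformed spec line(s): ",
         paste(x[lengths(parts) != 2L], collapse = "; "), call. = FALSE)
  }
  tibble::tibble(from = trimws(vapply(parts, `[`, "", 1L)),
                 to = trimws(vapply(parts, `[`, "", 2L)))
}

topo_sort <- function(vars, edges) {
  remaining <- vars
  order <- character()
  repeat {
    free <- remaining[vapply(remaining, function(v) {
      !any(edges$to == v & edges$from %in% remaining)
    }, logical(1))]
    if (length(free) == 0L) {
      if (length(remaining) == 0L) break
      stop("model spec contains a cycle involving: ",
           paste(remaining, collapse = ", "), call. = FALSE)
    }
    order <- c(order, free)
    remaining <- setdiff(remaining, free)
    if (length(remaining) == 0L) break
  }
  order
}

#' Parse a plain-text path-model spec
#'
#' One statement per line: `parent -> child` for a directed edge,
#' `a ~~ b` for a free covariance between exogenous variables. Blank lines
#' and `#` comments are ignored.
#'
#' @param path Path to the spec file, or a character vector of lines via
#'   `text`.
#' @param text Optional character vector of statements (overrides `path`).
#' @return A `path_spec`.
#' @export
read_path_spec <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  path_spec(edges = lines[grepl("->", lines, fixed = TRUE)],
            covariances = {
              cv <- lines[grepl("~~", lines, fixed = TRUE)]
              if (length(cv)) cv else NULL
            })
}

#' Default five-variable diversity path model
#'
#' The hypothesized coupling structure between group-level diversities:
#' molecular (`mol`) and herbaceous plant (`plant`) diversity exogenous and
#' correlated; plant diversity drives chemical (`chem`), mycorrhizal
#' (`AMF`) and arthropod (`arth`) diversity; chemical, molecular and AMF
#' diversity each drive arthropod diversity. Six edges, two exogenous
#' variances, one exogenous covariance and three residual variances give
#' twelve free parameters and hence 3 model degrees of freedom.
#'
#' @return A `path_spec`.
#' @export
default_path_spec <- function() {
  path_spec(
    edges = c("plant -> chem", "plant -> AMF", "plant -> arth",
              "chem -> arth", "mol -> arth", "AMF -> arth"),
    covariances = "mol ~~ plant",
    variables = c("mol", "plant", "chem", "AMF", "arth")
  )
}

#' @export
print.path_spec <- function(x, ...) {
  cat("Recursive path model:", length(x$variables), "variables,",
      nrow(x$edges), "edges, df =", model_df(x), "\n")
  cat("  exogenous:", paste(x$exogenous, collapse = ", "), "\n")
  for (i in seq_len(nrow(x$edges))) {
    cat("  ", x$edges$from[i], "->", x$edges$to[i], "\n")
  }
  if (nrow(x$covariances)) {
    for (i in seq_len(nrow(x$covariances))) {
      cat("  ", x$covariances$a[i], "~~", x$covariances$b[i], "\n")
    }
  }
  invisible(x)
}

#' Model degrees of freedom by moment counting
#'
#' `df = p(p+1)/2 - t`: distinct covariance moments among the `p` observed
#' variables minus free parameters.
#'
#' @param spec A `path_spec`.
#' @return Integer degrees of freedom (>= 0).
#' @examples
#' model_df(default_path_spec())  # 3
#' @export
model_df <- function(spec) {
  stopifnot(inherits(spec, "path_spec"))
  p <- length(spec$variables)
  moments <- p * (p + 1) / 2
  if (spec$n_free > moments) {
    stop("model has ", spec$n_free, " free parameters but only ", moments,
         " covariance moments (under-identified)", call. = FALSE)
  }
  as.integer(moments - spec$n_free)
}

#' Fit a recursive path model by equation-wise least squares
#'
#' Variables are standardized to unit variance, so estimates are
#' standardized path coefficients. Each endogenous variable is regressed on
#' its parents by ordinary least squares — for a recursive model with
#' complete data and uncorrelated residuals this is the maximum-likelihood
#' solution. The model-implied covariance is built from the reduced form
#' `Sigma = (I - B)^-1 Psi (I - B)^-T` and compared with the sample
#' covariance `S` through the ML discrepancy
#' `F = log det(Sigma) - log det(S) + tr(S Sigma^-1) - p`, giving
#' `chi^2 = (N - 1) F`. Coefficient p-values use Wald z statistics on the
#' least-squares standard errors. Fit is summarized by chi-square with its
#' p-value, RMSEA, and the Tucker-Lewis non-normed fit index against the
#' independence null.
#'
#' @param data Data frame containing one column per model variable (a
#'   `plot` column is ignored); rows with any missing variable are dropped.
#' @param spec A `path_spec`.
#' @return An object of class `path_fit`; see [tidy.path_fit()] and
#'   [glance.path_fit()].
#' @export
fit_path_model <- function(data, spec) {
  stopifnot(inherits(spec, "path_spec"))
  vars <- spec$variables
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("data lacks model variable(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- data[stats::complete.cases(data[, vars]), vars, drop = FALSE]
  N <- nrow(d)
  p <- length(vars)
  if (N <= p + 1L) stop("too few complete cases (", N, ")", call. = FALSE)
  if (N < 5L * p) {
    warning("only ", N, " complete cases for ", p,
            " variables; estimates may be unstable", call. = FALSE)
  }
  Z <- scale(as.matrix(d))
  colnames(Z) <- vars
  S <- stats::cov(Z)
  # collinear data (e.g. a noiseless structural equation) still identify
  # the regression coefficients, but the ML discrepancy is undefined
  s_singular <- !is.finite(determinant(S)$modulus) ||
    det(S) < .Machine$double.eps^0.75

  B <- matrix(0, p, p, dimnames = list(vars, vars))
  Psi <- matrix(0, p, p, dimnames = list(vars, vars))
  coefs <- list()
  for (y in spec$endogenous) {
    pa <- spec$parents[[y]]
    Sxx <- S[pa, pa, drop = FALSE]
    b <- tryCatch(solve(Sxx, S[pa, y]), error = function(e) {
      stop("parents of ", y, " (", paste(pa, collapse = ", "),
           ") are collinear; coefficients unidentifiable", call. = FALSE)
    })
    B[y, pa] <- b
    Psi[y, y] <- S[y, y] - drop(S[y, pa, drop = FALSE] %*% b)
    # least-squares standard errors on the standardized scale
    resid <- Z[, y] - Z[, pa, drop = FALSE] %*% b
    k <- length(pa)
    sigma2 <- sum(resid^2) / (N - k - 1L)
    se <- sqrt(diag(solve(crossprod(Z[, pa, drop = FALSE]))) * sigma2)
    z <- b / se
    coefs[[y]] <- tibble::tibble(
      from = pa, to = y, estimate = unname(b), se = unname(se),
      z = unname(z), p_value = 2 * stats::pnorm(-abs(unname(z)))
    )
  }
  for (v in spec$exogenous) Psi[v, v] <- S[v, v]
  if (nrow(spec$covariances)) {
    for (i in seq_len(nrow(spec$covariances))) {
      a <- spec$covariances$a[i]; b2 <- spec$covariances$b[i]
      Psi[a, b2] <- Psi[b2, a] <- S[a, b2]
    }
  }
  IB <- diag(p) - B
  IBi <- solve(IB)
  Sigma <- IBi %*% Psi %*% t(IBi)
  dimnames(Sigma) <- dimnames(S)

  df <- model_df(spec)
  df_null <- p * (p - 1) / 2
  if (s_singular) {
    warning("observed covariance matrix is singular; ",
            "fit statistics unavailable", call. = FALSE)
    chi2 <- NA_real_
    p_chi2 <- NA_real_
    chi2_null <- NA_real_
    fi <- list(rmsea = NA_real_, tlnnfi = NA_real_)
  } else {
    F_ml <- as.numeric(
      determinant(Sigma)$modulus - determinant(S)$modulus +
        sum(diag(S %*% solve(Sigma))) - p
    )
    chi2 <- max(0, (N - 1) * F_ml)
    p_chi2 <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else
      NA_real_
    # independence null on the correlation matrix
    R <- stats::cov2cor(S)
    chi2_null <- (N - 1) * (-as.numeric(determinant(R)$modulus))
    fi <- if (df >= 1) {
      fit_indices(chi2, df, N, chi2_null, df_null)
    } else {
      # saturated model: exact reproduction of the moments
      list(rmsea = 0, tlnnfi = NA_real_)
    }
  }

  cov_tbl <- if (nrow(spec$covariances)) {
    tibble::tibble(a = spec$covariances$a, b = spec$covariances$b,
                   estimate = mapply(function(a, b) S[a, b],
                                     spec$covariances$a,
                                     spec$covariances$b))
  } else {
    tibble::tibble(a = character(), b = character(), estimate = numeric())
  }

  structure(
    list(coefficients = dplyr::bind_rows(coefs),
         exog_covariances = cov_tbl,
         residual_variances = stats::setNames(diag(Psi)[spec$endogenous],
                                              spec$endogenous),
         chi2 = chi2, df = df, p_chi2 = p_chi2,
         rmsea = fi$rmsea, tlnnfi = fi$tlnnfi,
         chi2_null = chi2_null, df_null = df_null,
         N = N, spec = spec, S = S, Sigma = Sigma),
    class = "path_fit"
  )
}

#' RMSEA and Tucker-Lewis non-normed fit index
#'
#' `RMSEA = sqrt(max(0, (chi2 - df) / (df * (N - 1))))` — misfit per degree
#' of freedom and observation, 0 whenever chi-square does not exceed its
#' df. `TLNNFI = ((chi2_null/df_null) - (chi2/df)) /
#' ((chi2_null/df_null) - 1)` — how far the model moves from the
#' independence null toward perfect fit, with a parsimony adjustment;
#' undefined (NA) when the null fits no worse than 1 per df.
#'
#' @param chi2,df Target model chi-square and degrees of freedom (df >= 1).
#' @param N Sample size (>= 2).
#' @param chi2_null,df_null Independence-null chi-square and df.
#' @return A list with elements `rmsea` and `tlnnfi`.
#' @examples
#' fit_indices(6.39, 3, 59, 80, 10)
#' @export
fit_indices <- function(chi2, df, N, chi2_null, df_null) {
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  if (N < 2) stop("N must be >= 2", call. = FALSE)
  rmsea <- sqrt(max(0, (chi2 - df) / (df * (N - 1))))
  ratio_null <- chi2_null / df_null
  tlnnfi <- if (!is.finite(ratio_null) || ratio_null <= 1) {
    NA_real_
  } else {
    (ratio_null - chi2 / df) / (ratio_null - 1)
  }
  list(rmsea = rmsea, tlnnfi = tlnnfi)
}

#' @export
print.path_fit <- function(x, ...) {
  cat("Recursive path model fit: N =", x$N, "\n")
  cat(sprintf("  chi2 = %.3f, df = %d, p = %s, RMSEA = %.4f, TLNNFI = %s\n",
              x$chi2, x$df,
              ifelse(is.na(x$p_chi2), "NA", sprintf("%.3f", x$p_chi2)),
              x$rmsea,
              ifelse(is.na(x$tlnnfi), "NA", sprintf("%.3f", x$tlnnfi))))
  print(x$coefficients)
  invisible(x)
}

#' Tidy path-model coefficients
#'
#' @param x A `path_fit`.
#' @param ... Unused.
#' @return A tibble of standardized path coefficients: `from`, `to`,
#'   `estimate`, `se`, `z`, `p_value`.
#' @export
tidy.path_fit <- function(x, ...) x$coefficients

#' One-row fit summary of a path model
#'
#' @param x A `path_fit`.
#' @param ... Unused.
#' @return A tibble: `chi2`, `df`, `p_chi2`, `rmsea`, `tlnnfi`, `N`.
#' @export
glance.path_fit <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, df = x$df, p_chi2 = x$p_chi2,
                 rmsea = x$rmsea, tlnnfi = x$tlnnfi, N = x$N)
}

#' Fit the same path model once per diversity index
#'
#' Pivots a plot x group diversity table into one plot x variable matrix
#' per index (groups become model variables), fits the identical structural
#' model to each, and tabulates fit statistics and a paths x indices
#' coefficient/significance table — a machine-readable version of running
#' one path diagram per diversity index.
#'
#' @param div Diversity table (`plot`, `group`, index columns); the groups
#'   must cover the spec's variables.
#' @param spec A `path_spec`.
#' @param indices Index columns to run (default the six standard ones
#'   present in `div`).
#' @param alpha Significance level for the path-significance table.
#' @return An object of class `multi_path_fit`: list with `fits` (named
#'   list of `path_fit`), `fit_stats` (per-index glance rows) and `paths`
#'   (per path x index estimate, p-value, significance).
#' @export
multi_index_run <- function(div, spec, indices = NULL, alpha = 0.05) {
  if (is.null(indices)) indices <- intersect(index_cols(), names(div))
  fits <- lapply(stats::setNames(indices, indices), function(ix) {
    wide <- div |>
      dplyr::select(dplyr::all_of(c("plot", "group", ix))) |>
      tidyr::pivot_wider(names_from = "group", values_from = dplyr::all_of(ix))
    cc <- wide[stats::complete.cases(wide[, spec$variables]), ]
    degen <- spec$variables[vapply(spec$variables, function(v) {
      stats::sd(cc[[v]]) == 0
    }, logical(1))]
    if (length(degen)) {
      # e.g. richness of a saturated layer: constant across plots, so the
      # index carries no signal for this variable and the model is singular
      structure(list(note = paste0("zero-variance variable(s): ",
                                   paste(degen, collapse = ", "))),
                class = "path_unfit")
    } else {
      fit_path_model(wide, spec)
    }
  })
  fit_stats <- purrr::imap_dfr(fits, function(f, ix) {
    if (inherits(f, "path_unfit")) {
      tibble::tibble(index = ix, chi2 = NA_real_, df = model_df(spec),
                     p_chi2 = NA_real_, rmsea = NA_real_,
                     tlnnfi = NA_real_, N = NA_integer_, note = f$note)
    } else {
      dplyr::bind_cols(tibble::tibble(index = ix), glance.path_fit(f),
                       tibble::tibble(note = ""))
    }
  })
  paths <- purrr::imap_dfr(fits, function(f, ix) {
    if (inherits(f, "path_unfit")) return(NULL)
    dplyr::mutate(f$coefficients, index = ix,
                  significant = .data$p_value < alpha)
  })
  structure(list(fits = fits, fit_stats = fit_stats, paths = paths,
                 alpha = alpha),
            class = "multi_path_fit")
}

#' @export
print.multi_path_fit <- function(x, ...) {
  cat("Path model run across", nrow(x$fit_stats), "diversity indices\n")
  print(x$fit_stats)
  cat("significant paths (alpha =", x$alpha, "):\n")
  sig <- x$paths[x$paths$significant, c("index", "from", "to", "estimate")]
  print(sig)
  invisible(x)
}
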