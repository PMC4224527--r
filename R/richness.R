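#' Build an incidence matrix from a long abundance table
#'
#' Converts abundances to presence/absence across sampling units (plots by
#' default, focal units if requested) for one organism/trait group. Species
#' never observed in any unit are dropped. Incidence-based richness
#' extrapolation needs at least two units.
#'
#' @param abund Long abundance table (`plot`, `group`, `taxon_id`,
#'   `abundance`, optionally `focal_unit`).
#' @param group Which group to use; required if the table holds several.
#' @param unit Sampling unit: `"plot"` (default) or `"focal"` (plot x focal
#'   unit).
#' @return An object of class `incidence_matrix`: a list with the logical
#'   `presence` matrix (units x species), `N` (number of units), `f`
#'   (per-species incidence counts) and `S_obs`.
#' @export
incidence_from_abundance <- function(abund, group = NULL,
                                     unit = c("plot", "focal")) {
  unit <- match.arg(unit)
  groups <- unique(abund$group)
  if (is.null(group)) {
    if (length(groups) > 1L) {
      stop("table holds several groups (", paste(groups, collapse = ", "),
           "); pick one with `group`", call. = FALSE)
    }
    group <- groups
  }
  d <- abund[abund$group == group, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for group ", group, call. = FALSE)
  unit_id <- if (unit == "focal") {
    if (!"focal_unit" %in% names(d)) {
      stop("unit = \"focal\" requires a focal_unit column", call. = FALSE)
    }
    paste(d$plot, d$focal_unit, sep = "/")
  } else {
    as.character(d$plot)
  }
  pres <- tapply(d$abundance > 0, list(unit_id, d$taxon_id), any,
                 default = FALSE)
  pres <- pres[, colSums(pres) > 0, drop = FALSE]
  incidence_matrix(pres, group = group)
}

#' Construct an incidence matrix object
#'
#' @param presence Logical (or 0/1) matrix, sampling units in rows, species
#'   in columns.
#' @param group Optional group label carried into outputs.
#' @return An `incidence_matrix` object.
#' @export
incidence_matrix <- function(presence, group = NULL) {
  presence <- as.matrix(presence) > 0
  if (nrow(presence) < 2L) {
    stop("richness extrapolation needs >= 2 sampling units",
         if (!is.null(group)) paste0(" (group ", group, ")") else "",
         call. = FALSE)
  }
  presence <- presence[, colSums(presence) > 0, drop = FALSE]
  f <- colSums(presence)
  structure(
    list(presence = presence, N = nrow(presence), f = f,
         S_obs = ncol(presence), group = group),
    class = "incidence_matrix"
  )
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat("Incidence matrix: ", x$N, " units x ", x$S_obs, " species",
      if (!is.null(x$group)) paste0(" (", x$group, ")"), "\n", sep = "")
  q1 <- sum(x$f == 1L); q2 <- sum(x$f == 2L)
  cat("  singletons q1 =", q1, "; doubletons q2 =", q2, "\n")
  invisible(x)
}

q_count <- function(inc, k) sum(inc$f == k)

#' Chao incidence-based richness estimate
#'
#' `S_hat = S_obs + ((N-1)/N) * q1^2 / (2 q2)` where `q1`/`q2` are the
#' numbers of species seen in exactly one/two sampling units. When there
#' are no doubletons the bias-corrected fallback
#' `S_obs + ((N-1)/N) * q1 (q1 - 1) / 2` is used and the row is flagged.
#'
#' @param inc An `incidence_matrix`.
#' @return One-row tibble: `estimator`, `S_obs`, `S_hat`, `flag`.
#' @export
chao_richness <- function(inc) {
  q1 <- q_count(inc, 1L); q2 <- q_count(inc, 2L)
  corr <- (inc$N - 1) / inc$N
  if (q2 > 0) {
    s_hat <- inc$S_obs + corr * q1^2 / (2 * q2)
    flag <- ""
  } else {
    s_hat <- inc$S_obs + corr * q1 * (q1 - 1) / 2
    flag <- "chao_bias_corrected"
  }
  tibble::tibble(estimator = "chao", S_obs = inc$S_obs, S_hat = s_hat,
                 flag = flag)
}

#' First-order jackknife richness estimate
#'
#' `S_hat = S_obs + q1 * (N - 1) / N`.
#'
#' @inheritParams chao_richness
#' @return One-row tibble: `estimator`, `S_obs`, `S_hat`, `flag`.
#' @export
jackknife1_richness <- function(inc) {
  tibble::tibble(
    estimator = "jackknife1", S_obs = inc$S_obs,
    S_hat = inc$S_obs + q_count(inc, 1L) * (inc$N - 1) / inc$N,
    flag = ""
  )
}

#' Bootstrap richness estimate
#'
#' `S_hat = S_obs + sum_i (1 - f_i / N)^N`, summing each species'
#' probability of being missed by all `N` units under incidence resampling.
#'
#' @inheritParams chao_richness
#' @return One-row tibble: `estimator`, `S_obs`, `S_hat`, `flag`.
#' @export
bootstrap_richness <- function(inc) {
  tibble::tibble(
    estimator = "bootstrap", S_obs = inc$S_obs,
    S_hat = inc$S_obs + sum((1 - inc$f / inc$N)^inc$N),
    flag = ""
  )
}

richness_fun <- function(name) {
  switch(name,
         chao = chao_richness,
         jackknife1 = jackknife1_richness,
         bootstrap = bootstrap_richness,
         stop("unknown estimator: ", name, call. = FALSE))
}

#' Resampling standard error of a richness estimator
#'
#' Standard deviation of the estimator over `B` seeded resamples of the
#' sampling units (rows, with replacement). When every resample returns the
#' same value — as happens when all species occur in all units, so there is
#' nothing to extrapolate — the SE is undefined and reported as `NA` with a
#' `degenerate_se` flag.
#'
#' @param inc An `incidence_matrix`.
#' @param estimator One of `"chao"`, `"jackknife1"`, `"bootstrap"`.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed; the same seed always gives the same SE.
#' @return A list with `se` (or `NA`) and `flag`.
#' @export
estimator_se <- function(inc, estimator, B = 1000L, seed = 1L) {
  if (B < 100L) stop("B must be >= 100", call. = FALSE)
  fun <- richness_fun(estimator)
  vals <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      rows <- sample.int(inc$N, inc$N, replace = TRUE)
      sub <- inc$presence[rows, , drop = FALSE]
      keep <- colSums(sub) > 0
      sub <- sub[, keep, drop = FALSE]
      fun(structure(list(presence = sub, N = nrow(sub),
                         f = colSums(sub), S_obs = ncol(sub)),
                    class = "incidence_matrix"))$S_hat
    }, numeric(1))
  })
  s <- stats::sd(vals)
  if (!is.finite(s) || s == 0) {
    list(se = NA_real_, flag = "degenerate_se")
  } else {
    list(se = s, flag = "")
  }
}

#' Extrapolated richness with resampling standard errors
#'
#' Runs the Chao, first-order jackknife and bootstrap incidence estimators
#' on one incidence matrix and attaches seeded resampling SEs. All three
#' estimates satisfy `S_hat >= S_obs`.
#'
#' @param inc An `incidence_matrix` (see [incidence_from_abundance()]).
#' @param estimators Which estimators to run.
#' @param se Compute resampling SEs?
#' @param B Bootstrap replicates for the SE.
#' @param seed Integer seed for the SE resampling.
#' @return A tibble: `group`, `estimator`, `S_obs`, `S_hat`, `se`, `flag`.
#' @examples
#' m <- matrix(c(1,1,1,1, 1,1,0,0, 1,0,0,0, 0,0,0,1), 4, 4)
#' estimate_richness(incidence_matrix(m), se = FALSE)
#' @export
estimate_richness <- function(inc,
                              estimators = c("chao", "jackknife1",
                                             "bootstrap"),
                              se = TRUE, B = 1000L, seed = 1L) {
  out <- purrr::map_dfr(estimators, function(est) {
    row <- richness_fun(est)(inc)
    if (se) {
      s <- estimator_se(inc, est, B = B, seed = seed)
      row$se <- s$se
      row$flag <- trimws(paste(row$flag, s$flag))
    } else {
      row$se <- NA_real_
    }
    row
  })
  out$group <- if (is.null(inc$group)) NA_character_ else inc$group
  out[, c("group", "estimator", "S_obs", "S_hat", "se", "flag")]
}
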