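#' Options for rate-constant estimation
#'
#' @param fix_ka,fix_kd Optionally pin one rate constant (nM^-1 s^-1) and
#'   estimate only the other; at most one may be set.
#' @param bounds Lower/upper box for both rates, nM^-1 s^-1.
#' @param n_starts Number of multi-start points on a log-spaced grid within
#'   the bounds (a 5x5 grid for the two-parameter fit by default). The
#'   residual-sum-of-squares surface can be nearly flat along the dominated
#'   rate when one direction is much faster, so a single start is unreliable.
#' @param weighted If `TRUE` and the data carry a replicate SD column,
#'   residuals are inverse-variance weighted. Default unweighted.
#' @return A `fit_options` list.
#' @export
fit_options <- function(fix_ka = NULL, fix_kd = NULL,
                        bounds = c(1e-8, 1), n_starts = 25L,
                        weighted = FALSE) {
  if (!is.null(fix_ka) && !is.null(fix_kd))
    stop_config("at most one of `fix_ka`/`fix_kd` may be fixed")
  if (length(bounds) != 2L || any(bounds <= 0) || bounds[1L] >= bounds[2L])
    stop_config("`bounds` must be positive with lower < upper")
  for (v in c(fix_ka, fix_kd)) if (!is.null(v) && v < 0)
    stop_config("fixed rate constants must be nonnegative")
  structure(list(fix_ka = fix_ka, fix_kd = fix_kd, bounds = bounds,
                 n_starts = as.integer(n_starts), weighted = isTRUE(weighted)),
            class = "fit_options")
}

#' Estimate (ka, kd) from a substitution-ratio time course
#'
#' Minimizes the sum of squared residuals between the observed
#' substitution-ratio course and the exact model progress curve
#' [closed_form_extent()] scaled by the initial invader concentration.
#' Optimization runs in log10 parameter space (the rates span several
#' decades) with Levenberg-Marquardt ([minpack.lm::nls.lm()], step and
#' gradient tolerances 1e-10) from a log-spaced multi-start grid; the best
#' converged start wins. If one rate is fixed via [fit_options()], only the
#' free one is optimized.
#'
#' @param course A data.frame with columns `time_s` and `ratio` (or `mean`,
#'   as produced by [aggregate_replicates()], whose `sd` column supplies
#'   optional weights).
#' @param initial Initial concentrations of the reaction, see
#'   [reaction_state()]. At least 10 time points are required.
#' @param options A [fit_options()].
#' @param theory A [theoretical_rate_table()] used to populate the
#'   ratios-to-theory diagnostics.
#' @param toehold_length Toehold length (nt) to look up in `theory`; `NULL`
#'   skips the ratio computation.
#' @param exclude_before Drop points with `time_s` below this value (seconds);
#'   use to discard the pre-reaction stabilization window.
#' @return A `tmsdr_fit` with elements `ka_hat`, `kd_hat`, `rss`, `converged`,
#'   `n_points`, `ratios_to_theory` (full precision) and a `starts` data.frame
#'   of per-start diagnostics. Non-convergence of every start is reported via
#'   `converged = FALSE`, not an error.
#' @examples
#' sys <- tmsdr_system(ka = 1.74e-4, kd = 8.51e-4)
#' init <- reaction_state(10, 10)
#' tt <- seq(0, 5400, by = 10)
#' course <- data.frame(time_s = tt,
#'                      ratio = closed_form_extent(sys, init, tt) / 10)
#' fit <- fit_rates(course, init)
#' c(fit$ka_hat, fit$kd_hat)
#' @export
fit_rates <- function(course, initial, options = fit_options(),
                      theory = theoretical_rate_table(), toehold_length = 6L,
                      exclude_before = 0) {
  initial <- check_state(initial)
  tt <- course$time_s
  robs <- course$ratio %||% course$mean
  if (is.null(tt) || is.null(robs))
    stop_data("`course` must have columns time_s and ratio (or mean)")
  keep <- tt >= exclude_before
  tt <- tt[keep]; robs <- robs[keep]
  if (length(tt) < 10L)
    stop_data("need at least 10 time points to fit, got %d", length(tt))
  w <- rep(1, length(tt))
  if (options$weighted && !is.null(course$sd)) {
    s <- course$sd[keep]
    s[s <= 0 | !is.finite(s)] <- min(s[s > 0], 1)  # guard exact-zero SDs
    w <- 1 / s
  }
  a <- initial[["x1"]]; b <- initial[["x2"]]
  c0 <- initial[["x3"]]; d0 <- initial[["x4"]]
  free <- c(ka = is.null(options$fix_ka), kd = is.null(options$fix_kd))
  if (!any(free)) stop_config("at most one rate constant may be fixed")
  lb <- log10(options$bounds[1L]); ub <- log10(options$bounds[2L])

  residual <- function(p) {
    ka <- if (free[["ka"]]) 10^p[[1L]] else options$fix_ka
    kd <- if (free[["kd"]]) 10^p[[if (free[["ka"]]) 2L else 1L]] else options$fix_kd
    w * (robs - extent_closed_form_(ka, kd, a, b, c0, d0, tt) / a)
  }

  nfree <- sum(free)
  if (nfree == 2L) {
    g <- seq(lb, ub, length.out = max(2L, ceiling(sqrt(options$n_starts))))
    starts <- as.matrix(expand.grid(lka = g, lkd = g))
  } else {
    starts <- matrix(seq(lb, ub, length.out = max(2L, options$n_starts)), ncol = 1L)
    colnames(starts) <- if (free[["ka"]]) "lka" else "lkd"
  }

  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                     gtol = 1e-10, maxiter = 200L)
  diag_rows <- vector("list", nrow(starts))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = rep(lb, nfree),
                         upper = rep(ub, nfree), fn = residual,
                         control = ctrl),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$info %in% 1:4
    rss <- if (is.null(fit)) NA_real_ else fit$deviance
    diag_rows[[i]] <- data.frame(start = i, rss = rss, converged = ok,
                                 info = if (is.null(fit)) NA_integer_ else fit$info)
    if (ok && (is.null(best) || rss < best$deviance)) best <- fit
  }
  diagnostics <- do.call(rbind, diag_rows)

  if (is.null(best)) {
    return(structure(list(ka_hat = NA_real_, kd_hat = NA_real_, rss = NA_real_,
                          converged = FALSE, n_points = length(tt),
                          ratios_to_theory = c(ka = NA_real_, kd = NA_real_),
                          starts = diagnostics, options = options),
                     class = "tmsdr_fit"))
  }
  p <- best$par
  ka_hat <- if (free[["ka"]]) 10^p[[1L]] else options$fix_ka
  kd_hat <- if (free[["kd"]]) 10^p[[if (free[["ka"]]) 2L else 1L]] else options$fix_kd
  ratios <- c(ka = NA_real_, kd = NA_real_)
  if (!is.null(toehold_length)) {
    ratios <- c(ka = ratio_to_theory(ka_hat, theory, toehold_length, digits = NULL),
                kd = ratio_to_theory(kd_hat, theory, toehold_length, digits = NULL))
  }
  structure(list(ka_hat = ka_hat, kd_hat = kd_hat, rss = best$deviance,
                 converged = TRUE, n_points = length(tt),
                 ratios_to_theory = ratios, starts = diagnostics,
                 options = options),
            class = "tmsdr_fit")
}

#' @export
print.tmsdr_fit <- function(x, ...) {
  cat("TMSDR rate-constant fit\n")
  if (!x$converged) {
    cat("  NOT CONVERGED (", nrow(x$starts), "starts )\n")
    return(invisible(x))
  }
  cat(sprintf("  ka = %.3g nM^-1 s^-1, kd = %.3g nM^-1 s^-1\n", x$ka_hat, x$kd_hat))
  cat(sprintf("  RSS = %.4g over %d points (%d starts, %d converged)\n",
              x$rss, x$n_points, nrow(x$starts), sum(x$starts$converged)))
  if (all(is.finite(x$ratios_to_theory)))
    cat(sprintf("  ratio to theory: ka %.2g, kd %.2g\n",
                x$ratios_to_theory[["ka"]], x$ratios_to_theory[["kd"]]))
  invisible(x)
}

#' Ratio of an estimated rate constant to the theoretical value
#'
#' @param estimate Estimated rate constant, nM^-1 s^-1.
#' @param table A [theoretical_rate_table()].
#' @param toehold_length Toehold length in nt; must be present in `table`.
#' @param digits Significant figures for reporting (default 2, matching the
#'   usual presentation); `NULL` returns full precision.
#' @return The unitless ratio estimate / theory.
#' @examples
#' ratio_to_theory(4.78e-5)  # 0.096
#' ratio_to_theory(4.60e-3)  # 9.2
#' @export
ratio_to_theory <- function(estimate, table = theoretical_rate_table(),
                            toehold_length = 6L, digits = 2L) {
  key <- as.character(toehold_length)
  if (is.null(table[[key]]))
    stop_config("no theoretical rate for toehold length %s nt; supply a table entry",
                key)
  r <- estimate / table[[key]]
  if (is.null(digits)) r else signif(r, digits)
}

#' Tabulate fits across reporter configurations
#'
#' One row per condition with the estimated rates, their ratios to theory
#' (two significant figures), the predicted equilibrium substitution ratio
#' (nearest percent) and fit diagnostics. Accepts either `tmsdr_fit` objects
#' or plain lists with `ka_hat`/`kd_hat` (e.g. reference values).
#'
#' @param fits A list; each element a list with `toehold`, `modification`,
#'   `fit` (a `tmsdr_fit` or list with `ka_hat`, `kd_hat`, optionally `rss`,
#'   `converged`) and optionally `initial` (defaults to 10 nM each reactant,
#'   no products).
#' @param table A [theoretical_rate_table()].
#' @param toehold_length Toehold length in nt for the theory lookup.
#' @return A data.frame with columns `toehold`, `modification`, `ka_nM_s`,
#'   `ka_ratio`, `kd_nM_s`, `kd_ratio`, `equilibrium_substitution_pct`,
#'   `rss`, `converged`.
#' @export
build_report <- function(fits, table = theoretical_rate_table(),
                         toehold_length = 6L) {
  if (length(fits) < 1L) stop_data("`fits` must contain at least one fit")
  rows <- lapply(fits, function(f) {
    fit <- f$fit
    initial <- f$initial %||% reaction_state(10, 10)
    ka <- fit$ka_hat; kd <- fit$kd_hat
    eq_pct <- if (is.finite(ka) && is.finite(kd)) {
      sys <- tmsdr_system(ka = ka, kd = kd)
      round(100 * substitution_ratio(equilibrium_extent(sys, initial),
                                     initial[["x1"]]))
    } else NA_real_
    data.frame(
      toehold = f$toehold, modification = f$modification,
      ka_nM_s = ka,
      ka_ratio = if (is.finite(ka)) ratio_to_theory(ka, table, toehold_length) else NA_real_,
      kd_nM_s = kd,
      kd_ratio = if (is.finite(kd)) ratio_to_theory(kd, table, toehold_length) else NA_real_,
      equilibrium_substitution_pct = eq_pct,
      rss = fit$rss %||% NA_real_,
      converged = fit$converged %||% TRUE,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a report table to CSV
#' @param report Output of [build_report()].
#' @param path File path.
#' @export
write_report_csv <- function(report, path) {
  write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bootstrap confidence intervals for fitted rate constants
#'
#' Nonparametric bootstrap over replicates: replicate time courses are
#' resampled with replacement, re-aggregated and refit. Off the default
#' pipeline path; useful when the replicate-to-replicate spread matters.
#'
#' @param courses List of normalized replicate `substitution_course` objects.
#' @param initial Initial concentrations.
#' @param options A [fit_options()].
#' @param n_boot Number of resamples (default 200).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return A list with the point fit, the bootstrap draws (`ka`, `kd`) and
#'   percentile intervals.
#' @export
bootstrap_rates <- function(courses, initial, options = fit_options(),
                            n_boot = 200L, seed = 1L, level = 0.95) {
  point <- fit_rates(aggregate_replicates(courses), initial, options)
  n <- length(courses)
  draws <- withr::with_seed(seed, {
    t(vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      f <- suppressWarnings(
        fit_rates(aggregate_replicates(courses[idx]), initial, options))
      c(ka = f$ka_hat, kd = f$kd_hat)
    }, numeric(2)))
  })
  alpha <- (1 - level) / 2
  list(point = point, draws = as.data.frame(draws),
       ci = apply(draws, 2L, stats::quantile,
                  probs = c(alpha, 1 - alpha), na.rm = TRUE))
}
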