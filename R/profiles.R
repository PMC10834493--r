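#' Sampling time grid for a dissolution run
#'
#' Validates a vector of sampling times (minutes). A grid must hold at least
#' three strictly increasing, strictly positive times: the similarity factor
#' is defined for any n >= 1, but fewer than three points cannot support a
#' meaningful profile comparison.
#'
#' @param times numeric vector of sampling times in minutes.
#' @return the validated numeric vector, classed `"time_grid"`.
#' @examples
#' time_grid(c(10, 15, 20, 30, 45))
#' @export
time_grid <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 3L)
    stop("a time grid needs at least 3 sampling times, got ", length(times))
  if (anyNA(times) || any(!is.finite(times)))
    stop("sampling times must be finite")
  if (any(times <= 0))
    stop("sampling times must be strictly positive (minutes)")
  if (any(diff(times) <= 0))
    stop("sampling times must be strictly increasing")
  structure(times, class = "time_grid")
}

#' Dissolution profile of one product
#'
#' A profile holds the cumulative % of label claim released at each sampling
#' time, either as a full replicate matrix (one column per vessel) or as
#' summary statistics (mean and SD per time point) when only published
#' summaries are available. Values above 100% are legal (assay and content
#' variability routinely push immediate-release profiles a few percent over
#' label claim); values above 120% are rejected as likely unit errors.
#'
#' @param label product label (e.g. `"Ref"`, `"V-1"`).
#' @param times sampling times in minutes, coerced through [time_grid()].
#' @param replicates numeric matrix of % released, `length(times)` rows and
#'   one column per replicate vessel. Omit for a summary-only profile.
#' @param mean,sd per-time-point mean and SD of % released, for summary-only
#'   profiles. `sd` may be `NA` (e.g. a single replicate).
#' @param n number of replicates the summary was computed from (summary-only).
#' @param max_pct plausibility ceiling on % released (default 120, a guard
#'   against fraction-vs-percent unit errors); raise deliberately to admit
#'   known-implausible data.
#' @return an object of class `"dissolution_profile"`.
#' @examples
#' p <- dissolution_profile("Ref", c(10, 15, 20, 30, 45),
#'                          mean = c(98.53, 98.57, 98.00, 97.10, 96.05),
#'                          sd = c(0.90, 0.94, 0.94, 0.91, 0.97), n = 3)
#' profile_means(p)
#' @export
dissolution_profile <- function(label, times, replicates = NULL,
                                mean = NULL, sd = NULL, n = NULL,
                                max_pct = 120) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  grid <- time_grid(times)
  if (!is.null(replicates)) {
    replicates <- as.matrix(replicates)
    storage.mode(replicates) <- "double"
    if (nrow(replicates) != length(grid))
      stop("replicate matrix has ", nrow(replicates),
           " rows but the grid has ", length(grid), " time points")
    check_pct(replicates, label, max_pct)
    if (is.null(colnames(replicates)))
      colnames(replicates) <- paste0("rep", seq_len(ncol(replicates)))
    obj <- list(label = label, grid = grid, replicates = replicates,
                summary_only = FALSE)
  } else {
    if (is.null(mean))
      stop("supply either a replicate matrix or per-time means")
    mean <- as.numeric(mean)
    if (length(mean) != length(grid))
      stop("summary mean has length ", length(mean),
           " but the grid has ", length(grid), " time points")
    check_pct(mean, label, max_pct)
    if (is.null(sd)) sd <- rep(NA_real_, length(grid))
    sd <- as.numeric(sd)
    if (length(sd) == 1L) sd <- rep(sd, length(grid))
    if (length(sd) != length(grid))
      stop("summary sd has length ", length(sd), ", expected ", length(grid))
    if (any(sd < 0, na.rm = TRUE)) stop("summary SD must be >= 0")
    if (is.null(n)) n <- NA_integer_
    obj <- list(label = label, grid = grid, mean = mean, sd = sd,
                n = as.integer(n), summary_only = TRUE)
  }
  structure(obj, class = "dissolution_profile")
}

check_pct <- function(x, label, max_pct = 120) {
  if (anyNA(x) || any(!is.finite(x)))
    stop("profile '", label, "' contains non-finite % released values")
  if (any(x < 0))
    stop("profile '", label, "' contains negative % released values")
  if (any(x > max_pct))
    stop("profile '", label, "' has % released > ", max_pct,
         "; check units (fraction vs percent)")
  invisible(x)
}

#' @export
print.dissolution_profile <- function(x, ...) {
  kind <- if (x$summary_only) "summary-only" else
    paste0(ncol(x$replicates), " replicates")
  cat("Dissolution profile '", x$label, "' (", kind, ")\n", sep = "")
  print(summary(x), row.names = FALSE)
  invisible(x)
}

#' Per-time-point mean and SD of a dissolution profile
#'
#' For replicate profiles the mean and the sample SD (n - 1 denominator, the
#' pharmaceutical QC convention) are computed per time point; a single
#' replicate yields `NA` SD, not zero. Summary-only profiles return their
#' stored values unchanged.
#'
#' @param object a [dissolution_profile()].
#' @param ... unused.
#' @return a data.frame with columns `time_min`, `mean`, `sd`, `n`.
#' @export
summary.dissolution_profile <- function(object, ...) {
  if (object$summary_only) {
    data.frame(time_min = as.numeric(object$grid), mean = object$mean,
               sd = object$sd, n = object$n)
  } else {
    m <- object$replicates
    nr <- ncol(m)
    data.frame(
      time_min = as.numeric(object$grid),
      mean = rowMeans(m),
      sd = if (nr > 1L) apply(m, 1L, stats::sd) else rep(NA_real_, nrow(m)),
      n = nr
    )
  }
}

#' @rdname summary.dissolution_profile
#' @param profile a [dissolution_profile()].
#' @export
profile_means <- function(profile) {
  if (profile$summary_only) profile$mean else rowMeans(profile$replicates)
}

#' Screen replicate variability before mean-profile comparison
#'
#' Regulatory use of mean-based f2 presupposes acceptably low within-product
#' variability; the conventional bound is a coefficient of variation (CV) of
#' at most 20% at the first sampling time and at most 10% thereafter. The CV
#' is computed as `100 * sd / mean` per time point, from replicates when
#' present or from stored summary SDs otherwise.
#'
#' @param profile a [dissolution_profile()].
#' @param first_cv_max,later_cv_max CV bounds (%) for the first and the
#'   subsequent time points.
#' @return a list of class `"cv_screen"`: `table` (data.frame of `time_min`,
#'   `cv`, `limit`, `pass`), `pass` (overall verdict, `NA` when the SD is
#'   unavailable so the policy is not assessable), and the bounds used.
#' @examples
#' p <- dissolution_profile("A", c(10, 15, 20), replicates =
#'        cbind(c(95, 97, 98), c(96, 98, 99), c(97, 99, 98)))
#' screen_variability(p)
#' @export
screen_variability <- function(profile, first_cv_max = 20, later_cv_max = 10) {
  stopifnot(first_cv_max > 0, later_cv_max > 0)
  s <- summary(profile)
  cv <- 100 * s$sd / s$mean
  limit <- c(first_cv_max, rep(later_cv_max, nrow(s) - 1L))
  pass_each <- cv <= limit
  overall <- if (anyNA(cv)) NA else all(pass_each)
  structure(list(
    table = data.frame(time_min = s$time_min, cv = cv, limit = limit,
                       pass = pass_each),
    pass = overall,
    first_cv_max = first_cv_max, later_cv_max = later_cv_max
  ), class = "cv_screen")
}

#' @export
print.cv_screen <- function(x, ...) {
  cat("Replicate variability screen (CV limits: ", x$first_cv_max,
      "% first point, ", x$later_cv_max, "% thereafter)\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  cat("Overall:", if (is.na(x$pass)) "not assessable (SD unavailable)"
      else if (x$pass) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' Dissolution study: a reference profile and one or more test profiles
#'
#' All profiles must share an identical sampling grid (profile comparison
#' requires matched times) and the reference label must differ from every
#' test label. Method metadata (medium, volume, apparatus, stirring speed,
#' temperature, detection) is carried for reporting only; no computation
#' depends on it.
#'
#' @param reference a [dissolution_profile()] for the reference (innovator)
#'   product.
#' @param tests a list of [dissolution_profile()] objects for test products.
#' @param method optional named list of method metadata, e.g. as read by
#'   [read_method()].
#' @return an object of class `"dissolution_study"`.
#' @export
dissolution_study <- function(reference, tests, method = NULL) {
  stopifnot(inherits(reference, "dissolution_profile"))
  if (inherits(tests, "dissolution_profile")) tests <- list(tests)
  if (length(tests) < 1L) stop("a study needs at least one test profile")
  for (p in tests) {
    if (!inherits(p, "dissolution_profile"))
      stop("all tests must be dissolution_profile objects")
    if (!isTRUE(all.equal(as.numeric(p$grid), as.numeric(reference$grid))))
      stop("profile '", p$label, "' is sampled at (",
           paste(p$grid, collapse = ", "), ") min but the reference at (",
           paste(reference$grid, collapse = ", "), ") min")
    if (identical(p$label, reference$label))
      stop("test label '", p$label, "' duplicates the reference label")
  }
  labels <- vapply(tests, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("duplicated test labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  names(tests) <- labels
  structure(list(reference = reference, tests = tests, method = method),
            class = "dissolution_study")
}

#' @export
print.dissolution_study <- function(x, ...) {
  cat("Dissolution study: reference '", x$reference$label, "' vs ",
      length(x$tests), " test product(s) [",
      paste(names(x$tests), collapse = ", "), "]\n", sep = "")
  cat("Sampling times (min):", paste(x$reference$grid, collapse = ", "), "\n")
  if (!is.null(x$method)) {
    cat("Method:", paste(names(x$method), unlist(x$method),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot all profiles of a study (mean ± SD)
#'
#' Base-graphics release curves, reference drawn heavier.
#'
#' @param x a `"dissolution_study"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.dissolution_study <- function(x, ...) {
  profs <- c(list(x$reference), unname(x$tests))
  times <- as.numeric(x$reference$grid)
  means <- vapply(profs, profile_means, numeric(length(times)))
  labels <- vapply(profs, `[[`, "", "label")
  graphics::matplot(times, means, type = "b", pch = seq_along(profs),
                    lty = c(1, rep(2, length(profs) - 1L)),
                    lwd = c(2, rep(1, length(profs) - 1L)),
                    xlab = "Time (min)", ylab = "% label claim released", ...)
  graphics::legend("bottomright", legend = labels, pch = seq_along(profs),
                   lty = c(1, rep(2, length(profs) - 1L)), cex = 0.8)
  invisible(x)
}
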