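#' Moore-Flanner difference factor f1
#'
#' The percent relative cumulative difference between a reference and a test
#' dissolution curve,
#' \deqn{f_1 = 100 \sum_t |R_t - T_t| / \sum_t R_t,}
#' where \eqn{R_t} and \eqn{T_t} are the mean % released at time t. f1 is 0
#' for identical curves and grows with divergence; the regulatory acceptance
#' band is 0-15. Note f1 is not symmetric in (R, T): the reference
#' normalises the sum.
#'
#' @param ref_means,test_means numeric vectors of mean % released, aligned
#'   on the same time points.
#' @return f1 at full floating precision (round to 2 decimals for
#'   reporting).
#' @examples
#' difference_factor(c(98.53, 98.57, 98.00, 97.10, 96.05),
#'                   c(98.48, 103.41, 102.67, 101.86, 100.97))  # ~3.94
#' @export
difference_factor <- function(ref_means, test_means) {
  check_pair(ref_means, test_means)
  s_ref <- sum(ref_means)
  if (s_ref <= 0)
    stop("f1 is undefined: reference means sum to ", s_ref)
  100 * sum(abs(ref_means - test_means)) / s_ref
}

#' Moore-Flanner similarity factor f2
#'
#' A logarithmic reciprocal-square-root transform of the mean squared
#' difference between two dissolution curves,
#' \deqn{f_2 = 50 \log_{10}\!\left(100 \left[1 + \tfrac{1}{n}\sum_t (R_t -
#'   T_t)^2\right]^{-1/2}\right).}
#' f2 equals 100 for identical curves, decreases as the curves diverge, and
#' falls below 50 when the average point-wise difference exceeds about 10%;
#' the regulatory acceptance band is 50-100. Unlike f1, f2 is symmetric in
#' (R, T).
#'
#' @inheritParams difference_factor
#' @return f2 at full floating precision.
#' @examples
#' similarity_factor(c(98.53, 98.57, 98.00, 97.10, 96.05),
#'                   c(98.48, 103.41, 102.67, 101.86, 100.97))  # ~67.80
#' @export
similarity_factor <- function(ref_means, test_means) {
  check_pair(ref_means, test_means)
  msd <- mean((ref_means - test_means)^2)
  50 * log10(100 / sqrt(1 + msd))
}

check_pair <- function(ref, test) {
  if (length(ref) != length(test))
    stop("profiles compared on different numbers of time points: ",
         length(ref), " vs ", length(test))
  if (length(ref) < 1L) stop("at least one time point is required")
  if (anyNA(ref) || anyNA(test)) stop("profile means contain NA")
  invisible(NULL)
}

#' Select the time points entering the f1/f2 sums
#'
#' Policy `"all"` uses every sampling time. Policy `"until_85_plus_one"`
#' implements the regulatory truncation rule for fast-releasing products:
#' keep time points up to and including the first at which the reference
#' mean reaches 85% released, plus one more if available. The first point is
#' always kept.
#'
#' @param ref_means reference mean % released per time point.
#' @param policy `"all"` (default) or `"until_85_plus_one"`.
#' @return integer vector of selected indices.
#' @examples
#' select_timepoints(c(40, 70, 88, 95, 99), "until_85_plus_one")  # 1:4
#' @export
select_timepoints <- function(ref_means, policy = c("all",
                                                    "until_85_plus_one")) {
  policy <- match.arg(policy)
  n <- length(ref_means)
  if (policy == "all") return(seq_len(n))
  hit <- which(ref_means >= 85)
  last <- if (length(hit)) min(hit[1L] + 1L, n) else n
  seq_len(max(last, 1L))
}

#' Compare test dissolution profiles against a reference
#'
#' The central analysis: for each test product in a study, profiles are
#' aggregated to per-time-point means, the comparison time points are chosen
#' by `policy`, and the Moore-Flanner difference factor f1 and similarity
#' factor f2 are computed with an equivalence verdict against the
#' regulatory bands (defaults f1 <= 15 and f2 >= 50, applied conjunctively;
#' set `rule = "f2_only"` to decide on f2 alone). Verdicts use the
#' unrounded factors.
#'
#' @param study a [dissolution_study()].
#' @param policy time-point selection policy, see [select_timepoints()].
#' @param f1_max,f2_min acceptance thresholds.
#' @param rule `"conjunctive"` (both factors must pass) or `"f2_only"`.
#' @return an object of class `"dissolution_comparison"`: a list with
#'   `results` (data.frame: `test_label`, `f1`, `f2`, `n_used`, `verdict`),
#'   `times_used`, the thresholds, policy and rule, and the study compared.
#'   `as.data.frame()` extracts the results table; `coef()` returns the
#'   f1/f2 matrix.
#' @examples
#' csv <- system.file("extdata", "vildagliptin_profiles.csv",
#'                    package = "dissim")
#' cmp <- compare_dissolution(read_study(csv, reference = "Ref"))
#' cmp
#' @export
compare_dissolution <- function(study, policy = c("all", "until_85_plus_one"),
                                f1_max = 15, f2_min = 50,
                                rule = c("conjunctive", "f2_only")) {
  stopifnot(inherits(study, "dissolution_study"))
  policy <- match.arg(policy)
  rule <- match.arg(rule)
  if (!is.finite(f1_max) || f1_max <= 0) stop("f1_max must be positive")
  if (!is.finite(f2_min) || f2_min <= 0 || f2_min > 100)
    stop("f2_min must lie in (0, 100]")
  ref <- profile_means(study$reference)
  idx <- select_timepoints(ref, policy)
  rows <- lapply(study$tests, function(p) {
    tst <- profile_means(p)
    f1 <- difference_factor(ref[idx], tst[idx])
    f2 <- similarity_factor(ref[idx], tst[idx])
    ok <- if (rule == "f2_only") f2 >= f2_min
          else f1 <= f1_max && f2 >= f2_min
    data.frame(test_label = p$label, f1 = f1, f2 = f2,
               n_used = length(idx),
               verdict = if (ok) "similar" else "not_similar")
  })
  structure(list(
    results = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    times_used = as.numeric(study$reference$grid)[idx],
    f1_max = f1_max, f2_min = f2_min, policy = policy, rule = rule,
    study = study
  ), class = "dissolution_comparison")
}

#' @export
print.dissolution_comparison <- function(x, digits = 2, ...) {
  cat("Dissolution profile comparison (reference: '",
      x$study$reference$label, "')\n", sep = "")
  cat("Time points used (min): ", paste(x$times_used, collapse = ", "),
      "  [policy: ", x$policy, "]\n", sep = "")
  cat("Acceptance: ",
      if (x$rule == "conjunctive")
        paste0("f1 <= ", x$f1_max, " and f2 >= ", x$f2_min)
      else paste0("f2 >= ", x$f2_min, " (f2-only rule)"), "\n\n", sep = "")
  out <- x$results
  out$f1 <- round(out$f1, digits)
  out$f2 <- round(out$f2, digits)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
summary.dissolution_comparison <- function(object, ...) {
  r <- object$results
  cat("Compared", nrow(r), "test product(s) over",
      length(object$times_used), "time points\n")
  cat(sprintf("f1 range: %.2f - %.2f  (limit <= %g)\n",
              min(r$f1), max(r$f1), object$f1_max))
  cat(sprintf("f2 range: %.2f - %.2f  (limit >= %g)\n",
              min(r$f2), max(r$f2), object$f2_min))
  n_sim <- sum(r$verdict == "similar")
  cat(n_sim, "of", nrow(r), "products similar to the reference\n")
  invisible(object)
}

#' @export
as.data.frame.dissolution_comparison <- function(x, ...) x$results

#' @export
coef.dissolution_comparison <- function(object, ...) {
  m <- as.matrix(object$results[, c("f1", "f2")])
  rownames(m) <- object$results$test_label
  m
}

#' @export
plot.dissolution_comparison <- function(x, ...) {
  plot(x$study, main = "Dissolution profiles", ...)
}

#' Tidy per-product plotting data (mean ± SD per time point)
#'
#' Long-format export of every profile in a study, suitable for external
#' plotting tools.
#'
#' @param study a [dissolution_study()].
#' @return data.frame with columns `product`, `time_min`, `mean`, `sd`, `n`.
#' @export
plot_data <- function(study) {
  stopifnot(inherits(study, "dissolution_study"))
  profs <- c(list(study$reference), unname(study$tests))
  do.call(rbind, lapply(profs, function(p) {
    cbind(product = p$label, summary(p))
  }))
}
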