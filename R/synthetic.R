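#' Parametric release-kinetics settings for the study generator
#'
#' The generator draws replicate dissolution curves from a Weibull release
#' model with an optional linear post-peak decline,
#' \deqn{m(t) = f_\infty (1 - e^{-(t/\tau)^\beta}) - d \max(0, t - t_{peak}),}
#' where \eqn{t_{peak}} is the first sampling time at which the Weibull term
#' reaches 95% of \eqn{f_\infty}. `beta = 1` gives first-order release; the
#' decline term mimics the slight late decrease real immediate-release
#' profiles can show (drug degradation or adsorption during the run). The
#' model is a data-generating stand-in for testing, not an inference target.
#'
#' @param f_inf asymptotic % of label claim released, in (0, 110].
#' @param tau release time scale (min).
#' @param beta Weibull shape exponent (> 0; 1 = first-order).
#' @param decay post-peak linear decline rate (% per min, >= 0).
#' @param noise_sd replicate noise SD in % units: a scalar, or one value per
#'   sampling time to copy a heteroscedastic pattern.
#' @param n_reps number of replicate vessels.
#' @return an object of class `"release_params"`.
#' @examples
#' release_params(f_inf = 99, tau = 3, decay = 0.04, noise_sd = 1)
#' @export
release_params <- function(f_inf, tau, beta = 1, decay = 0, noise_sd = 0,
                           n_reps = 3) {
  if (!is.finite(f_inf) || f_inf <= 0 || f_inf > 110)
    stop("f_inf must lie in (0, 110]")
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  if (!is.finite(beta) || beta <= 0) stop("beta must be positive")
  if (!is.finite(decay) || decay < 0) stop("decay must be >= 0")
  if (any(!is.finite(noise_sd)) || any(noise_sd < 0))
    stop("noise_sd must be >= 0")
  if (n_reps < 1L) stop("n_reps must be at least 1")
  structure(list(f_inf = f_inf, tau = tau, beta = beta, decay = decay,
                 noise_sd = as.numeric(noise_sd),
                 n_reps = as.integer(n_reps)),
            class = "release_params")
}

#' Noise-free mean release curve
#'
#' Evaluates the Weibull-with-decline model of [release_params()] on a
#' sampling grid; values are clipped at 0.
#'
#' @param params a [release_params()].
#' @param times sampling times (minutes), coerced through [time_grid()].
#' @return numeric vector of mean % released per time point.
#' @examples
#' mean_curve(release_params(f_inf = 100, tau = 3), c(10, 15, 20, 30, 45))
#' @export
mean_curve <- function(params, times) {
  stopifnot(inherits(params, "release_params"))
  t <- as.numeric(time_grid(times))
  w <- params$f_inf * (1 - exp(-(t / params$tau)^params$beta))
  m <- w
  if (params$decay > 0) {
    peak <- which(w >= 0.95 * params$f_inf)
    if (length(peak)) {
      t_peak <- t[peak[1L]]
      m <- w - params$decay * pmax(0, t - t_peak)
    }
  }
  pmax(m, 0)
}

# run expr with a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a single finite numeric seed is required")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate one replicate dissolution profile
#'
#' Replicates are the mean curve plus independent Gaussian noise with the
#' configured per-time SD, truncated at 0. Deterministic for a fixed seed;
#' the caller's RNG state is left untouched.
#'
#' @param params a [release_params()].
#' @param times sampling times (minutes).
#' @param label product label.
#' @param seed RNG seed (mandatory; there is no hidden global default).
#' @return a [dissolution_profile()] with `params$n_reps` replicates.
#' @export
generate_profile <- function(params, times, label, seed) {
  m <- mean_curve(params, times)
  n_t <- length(m)
  sd_t <- params$noise_sd
  if (length(sd_t) == 1L) sd_t <- rep(sd_t, n_t)
  if (length(sd_t) != n_t)
    stop("noise_sd must be a scalar or one value per time point (",
         n_t, "), got ", length(sd_t))
  reps <- with_seed(seed, {
    matrix(stats::rnorm(n_t * params$n_reps, mean = m, sd = sd_t),
           nrow = n_t, ncol = params$n_reps)
  })
  dissolution_profile(label, times, replicates = pmax(reps, 0))
}

#' Generate a reference-plus-tests dissolution study
#'
#' The reference is drawn from `ref_params`; each test product from a
#' perturbed copy, where a perturbation is a named numeric vector of
#' additive offsets to the kinetic parameters (`f_inf`, `tau`, `beta`,
#' `decay`). Small `tau`/`f_inf` offsets produce "similar" studies
#' (f2 > 50); a uniform shift of more than about 10% flips the verdict,
#' since f2 = 50 log10(100/sqrt(1 + 100)) = 49.98 at a 10% offset. Each
#' profile uses its own sub-seed derived from `seed`, so studies are
#' bit-reproducible.
#'
#' @param ref_params a [release_params()] for the reference product.
#' @param test_deltas named list of perturbation vectors, one per test
#'   product (names become product labels; unnamed entries get `T1`,
#'   `T2`, ...). An empty vector means a perturbation-free copy.
#' @param times sampling times (minutes).
#' @param seed RNG seed (mandatory).
#' @param method optional method metadata for the study.
#' @return a [dissolution_study()].
#' @examples
#' st <- generate_study(release_params(99, 3, decay = 0.04, noise_sd = 1),
#'                      list(A = c(f_inf = 1), B = c(tau = 0.5)),
#'                      c(10, 15, 20, 30, 45), seed = 7)
#' compare_dissolution(st)
#' @export
generate_study <- function(ref_params, test_deltas, times, seed,
                           method = NULL) {
  stopifnot(inherits(ref_params, "release_params"))
  if (!is.list(test_deltas) || length(test_deltas) < 1L)
    stop("test_deltas must be a non-empty list of perturbation vectors")
  labels <- names(test_deltas)
  if (is.null(labels)) labels <- rep("", length(test_deltas))
  labels[labels == ""] <- paste0("T", which(labels == ""))
  ref <- generate_profile(ref_params, times, "Ref", seed = seed %% 2^31)
  tests <- Map(function(delta, label, k) {
    generate_profile(perturb_params(ref_params, delta), times, label,
                     seed = (seed + k) %% 2^31)
  }, test_deltas, labels, seq_along(test_deltas))
  dissolution_study(ref, unname(tests), method = method)
}

perturb_params <- function(params, delta) {
  if (length(delta) == 0L) return(params)
  if (is.null(names(delta)) || any(names(delta) == ""))
    stop("perturbations must be named (f_inf, tau, beta, decay)")
  bad <- setdiff(names(delta), c("f_inf", "tau", "beta", "decay"))
  if (length(bad))
    stop("unknown kinetic parameter(s): ", paste(bad, collapse = ", "))
  upd <- unclass(params)
  for (nm in names(delta)) upd[[nm]] <- upd[[nm]] + delta[[nm]]
  do.call(release_params, upd)
}

#' Load a packaged generator preset
#'
#' Presets bundle a sampling grid, reference kinetics and test perturbations
#' as YAML. The shipped `"vildagliptin50"` preset mimics a fast-releasing
#' BCS class I immediate-release tablet study: grid (10, 15, 20, 30, 45)
#' min, reference near-complete release by 10 min with a slight late
#' decline, heteroscedastic replicate SDs in the 0.6-3.5% range, n = 3, and
#' six mildly perturbed test products.
#'
#' @param name preset name, or a path to a preset YAML file.
#' @return a list with elements `params` ([release_params()]), `times`, and
#'   `test_deltas` (suitable for [generate_study()]).
#' @export
release_preset <- function(name = "vildagliptin50") {
  path <- if (file.exists(name)) name else
    system.file("extdata", "presets", paste0(name, ".yaml"),
                package = "dissim")
  if (!nzchar(path) || !file.exists(path)) {
    avail <- sub("\\.yaml$", "", list.files(
      system.file("extdata", "presets", package = "dissim")))
    stop("unknown preset '", name, "'; available: ",
         paste(avail, collapse = ", "))
  }
  raw <- yaml::read_yaml(path)
  list(params = do.call(release_params, raw$params),
       times = as.numeric(raw$times),
       test_deltas = lapply(raw$test_deltas, unlist))
}

#' Peak-area table consistent with a dissolution profile
#'
#' Inverts [percent_released()]: given a replicate profile and a
#' quantitation config, constructs sample peak areas such that running the
#' forward quantitation on them reproduces the profile (to ~1e-9%). The
#' withdrawal correction is unwound sequentially: the vessel concentration
#' at each time is recovered from the cumulative % after subtracting the
#' mass already removed with earlier aliquots. Used for round-trip testing
#' of the quantitation chain.
#'
#' @param profile a replicate [dissolution_profile()].
#' @param cfg a [quant_config()].
#' @param std_area peak area assigned to the working standard (arbitrary
#'   detector units; sample areas are scaled to it).
#' @return an [area_table()].
#' @export
generate_area_table <- function(profile, cfg, std_area = 1e5) {
  stopifnot(inherits(profile, "dissolution_profile"),
            inherits(cfg, "quant_config"))
  if (profile$summary_only)
    stop("a replicate profile is required to generate peak areas")
  n_t <- length(profile$grid)
  if (cfg$withdrawal_vol_ml * n_t >= cfg$medium_vol_ml)
    stop("total withdrawn volume must stay below the medium volume")
  vol <- vessel_volumes(cfg, n_t)
  w <- cfg$withdrawal_vol_ml
  conc <- apply(profile$replicates, 2L, function(pct) {
    mass <- pct * cfg$label_claim_mg / 100
    ci <- numeric(n_t)
    removed <- 0
    for (i in seq_len(n_t)) {
      ci[i] <- (mass[i] - removed) / vol[i]
      if (ci[i] <= 0)
        stop("profile implies a non-positive vessel concentration at time ",
             profile$grid[i], " min; cannot be produced by this run config")
      removed <- removed + w * ci[i]
    }
    ci
  })
  areas <- std_area * as.matrix(conc) / standard_concentration(cfg)
  area_table(as.numeric(profile$grid), areas, std_area)
}
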