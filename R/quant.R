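#' Quantitation configuration for external-standard dissolution assays
#'
#' Holds the standard-preparation arithmetic (two-step volumetric dilution of
#' a weighed standard) and the dissolution-run constants needed to turn peak
#' areas into cumulative % of label claim released.
#'
#' @param std_mass_mg weighed standard mass (mg).
#' @param std_stock_vol_ml first volumetric flask volume (mL).
#' @param std_aliquot_ml aliquot pipetted from the stock (mL).
#' @param std_final_vol_ml second volumetric flask volume (mL).
#' @param std_purity_frac assigned standard purity as a fraction (default 1).
#' @param label_claim_mg declared drug content per dosage unit (mg).
#' @param medium_vol_ml dissolution medium volume (mL).
#' @param withdrawal_vol_ml aliquot withdrawn at each sampling time (mL).
#' @param replacement `"replaced"` if withdrawn medium is replaced with fresh
#'   medium (the commonest compendial practice, the default) or
#'   `"not_replaced"` if the vessel volume shrinks with each sampling.
#' @return an object of class `"quant_config"`.
#' @examples
#' cfg <- quant_config(std_mass_mg = 12.84, std_stock_vol_ml = 25,
#'                     std_aliquot_ml = 2, std_final_vol_ml = 20,
#'                     label_claim_mg = 50, medium_vol_ml = 1000,
#'                     withdrawal_vol_ml = 10)
#' standard_concentration(cfg)  # 0.05136 mg/mL
#' @export
quant_config <- function(std_mass_mg, std_stock_vol_ml, std_aliquot_ml,
                         std_final_vol_ml, std_purity_frac = 1,
                         label_claim_mg, medium_vol_ml, withdrawal_vol_ml,
                         replacement = c("replaced", "not_replaced")) {
  replacement <- match.arg(replacement)
  vols <- c(std_mass_mg = std_mass_mg, std_stock_vol_ml = std_stock_vol_ml,
            std_aliquot_ml = std_aliquot_ml,
            std_final_vol_ml = std_final_vol_ml,
            label_claim_mg = label_claim_mg, medium_vol_ml = medium_vol_ml)
  bad <- names(vols)[!is.finite(vols) | vols <= 0]
  if (length(bad))
    stop("quantitation constants must be positive: ",
         paste(bad, collapse = ", "))
  if (!is.finite(withdrawal_vol_ml) || withdrawal_vol_ml < 0)
    stop("withdrawal_vol_ml must be >= 0")
  if (std_aliquot_ml > std_stock_vol_ml)
    stop("std_aliquot_ml exceeds std_stock_vol_ml")
  if (!is.finite(std_purity_frac) || std_purity_frac <= 0 ||
      std_purity_frac > 1)
    stop("std_purity_frac must lie in (0, 1]")
  structure(list(std_mass_mg = std_mass_mg,
                 std_stock_vol_ml = std_stock_vol_ml,
                 std_aliquot_ml = std_aliquot_ml,
                 std_final_vol_ml = std_final_vol_ml,
                 std_purity_frac = std_purity_frac,
                 label_claim_mg = label_claim_mg,
                 medium_vol_ml = medium_vol_ml,
                 withdrawal_vol_ml = withdrawal_vol_ml,
                 replacement = replacement),
            class = "quant_config")
}

#' @export
print.quant_config <- function(x, ...) {
  cat("Quantitation config: standard ", x$std_mass_mg, " mg -> ",
      x$std_stock_vol_ml, " mL; ", x$std_aliquot_ml, " mL -> ",
      x$std_final_vol_ml, " mL (purity ", x$std_purity_frac, ")\n",
      "label claim ", x$label_claim_mg, " mg, medium ", x$medium_vol_ml,
      " mL, withdrawal ", x$withdrawal_vol_ml, " mL (", x$replacement,
      ")\n", sep = "")
  cat("Working standard concentration:",
      format(standard_concentration(x), digits = 6), "mg/mL\n")
  invisible(x)
}

#' Read a quantitation config from YAML
#'
#' Flat YAML mapping of the [quant_config()] fields.
#'
#' @param path YAML file path; defaults to the packaged vildagliptin config.
#' @return a `"quant_config"`.
#' @export
read_quant_config <- function(path = system.file("extdata",
                                                 "quant_vildagliptin.yaml",
                                                 package = "dissim")) {
  if (!file.exists(path)) stop("quantitation config not found: ", path)
  do.call(quant_config, yaml::read_yaml(path))
}

#' Working standard concentration (mg/mL)
#'
#' Two-step volumetric dilution: mass (corrected for assigned purity) into
#' the stock flask, then an aliquot into the final flask.
#'
#' @param cfg a [quant_config()].
#' @return concentration of the working standard solution in mg/mL.
#' @export
standard_concentration <- function(cfg) {
  stopifnot(inherits(cfg, "quant_config"))
  cfg$std_mass_mg * cfg$std_purity_frac / cfg$std_stock_vol_ml *
    (cfg$std_aliquot_ml / cfg$std_final_vol_ml)
}

#' Table of detector peak areas from a dissolution run
#'
#' @param times sampling times (minutes), coerced through [time_grid()].
#' @param sample_areas matrix of sample peak areas, one row per time point,
#'   one column per replicate vessel (arbitrary detector units).
#' @param std_area mean peak area of the working standard solution, same
#'   units as `sample_areas`.
#' @return an object of class `"area_table"`.
#' @export
area_table <- function(times, sample_areas, std_area) {
  grid <- time_grid(times)
  sample_areas <- as.matrix(sample_areas)
  storage.mode(sample_areas) <- "double"
  if (nrow(sample_areas) != length(grid))
    stop("sample_areas has ", nrow(sample_areas), " rows but the grid has ",
         length(grid), " time points")
  if (anyNA(sample_areas) || any(sample_areas <= 0))
    stop("all sample peak areas must be positive and finite")
  if (!is.finite(std_area) || std_area <= 0)
    stop("standard peak area must be positive")
  structure(list(grid = grid, sample_areas = sample_areas,
                 std_area = std_area), class = "area_table")
}

#' Cumulative % of label claim released from peak areas
#'
#' Single-point external-standard quantitation with aliquot-withdrawal
#' correction. Per replicate, the drug concentration in the vessel at the
#' i-th sampling time is `C_i = std_conc * A_i / A_std`. The cumulative mass
#' released by then is the mass in the vessel plus the mass already removed
#' with earlier aliquots:
#' \deqn{\%_i = 100 \, (C_i V_i + w \sum_{j<i} C_j) / \mathrm{label\ claim}}
#' where `w` is the withdrawal volume and `V_i` the vessel volume at the
#' i-th sampling: the full medium volume when withdrawn medium is replaced,
#' or the medium volume minus `(i-1) w` when it is not.
#'
#' @param areas an [area_table()].
#' @param cfg a [quant_config()].
#' @param label product label for the resulting profile.
#' @return a [dissolution_profile()] on the same grid. Cells computed above
#'   120% are flagged via a warning (possible unit or standard error), not
#'   rejected.
#' @export
percent_released <- function(areas, cfg, label = "sample") {
  stopifnot(inherits(areas, "area_table"), inherits(cfg, "quant_config"))
  n_t <- length(areas$grid)
  if (cfg$withdrawal_vol_ml * n_t >= cfg$medium_vol_ml)
    stop("total withdrawn volume (", cfg$withdrawal_vol_ml * n_t,
         " mL) must stay below the medium volume (", cfg$medium_vol_ml,
         " mL)")
  conc <- standard_concentration(cfg) * areas$sample_areas / areas$std_area
  pct <- apply(conc, 2L, cumulative_pct, cfg = cfg)
  flagged <- pct > 120
  if (any(flagged))
    warning(sum(flagged), " cell(s) computed above 120% of label claim; ",
            "check units and standard response")
  out <- dissolution_profile(label, as.numeric(areas$grid),
                             replicates = pct, max_pct = Inf)
  attr(out, "implausible") <- flagged
  out
}

# mass-balance accumulation for one replicate's concentration series
cumulative_pct <- function(conc, cfg) {
  w <- cfg$withdrawal_vol_ml
  n_t <- length(conc)
  vol <- vessel_volumes(cfg, n_t)
  removed <- c(0, cumsum(conc * w))[seq_len(n_t)]  # mass lost to aliquots
  100 * (conc * vol + removed) / cfg$label_claim_mg
}

vessel_volumes <- function(cfg, n_t) {
  if (cfg$replacement == "replaced") rep(cfg$medium_vol_ml, n_t)
  else cfg$medium_vol_ml - (seq_len(n_t) - 1L) * cfg$withdrawal_vol_ml
}
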