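#' Run the full comparison pipeline and write a report bundle
#'
#' Loads a study from CSV, screens replicate variability, compares every
#' test product against the reference and writes three artifacts to
#' `output_dir`: `results.csv` (test_label, f1, f2, n_used, verdict),
#' `plot_data.csv` (tidy mean ± SD per product per time point) and
#' `report.txt` (a human-readable report echoing the input file hash, the
#' thresholds, the policy and the time points used, for auditability).
#' Verdicts are data, not errors: a `not_similar` product does not make the
#' run fail.
#'
#' @param input path to a profiles CSV (see [read_study()]).
#' @param reference reference product label.
#' @param output_dir directory for the report bundle (created if needed).
#' @param layout CSV layout passed to [read_study()].
#' @param policy,f1_max,f2_min,rule passed to [compare_dissolution()].
#' @return the `"dissolution_comparison"` object, invisibly.
#' @export
run_compare <- function(input, reference, output_dir = ".",
                        layout = "auto", policy = "all",
                        f1_max = 15, f2_min = 50, rule = "conjunctive") {
  study <- read_study(input, reference = reference, layout = layout)
  cmp <- compare_dissolution(study, policy = policy, f1_max = f1_max,
                             f2_min = f2_min, rule = rule)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  res <- cmp$results
  res$f1 <- round(res$f1, 2)
  res$f2 <- round(res$f2, 2)
  utils::write.csv(res, file.path(output_dir, "results.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(plot_data(study), file.path(output_dir, "plot_data.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(report_text(cmp, input), file.path(output_dir, "report.txt"))
  invisible(cmp)
}

report_text <- function(cmp, input) {
  study <- cmp$study
  lines <- c(
    "Dissolution profile equivalence report",
    strrep("=", 40),
    paste0("Input: ", input, " (md5 ",
           unname(tools::md5sum(input)), ")"),
    paste0("Reference product: ", study$reference$label),
    paste0("Test products: ", paste(names(study$tests), collapse = ", ")),
    paste0("Time-point policy: ", cmp$policy, "; points used (min): ",
           paste(cmp$times_used, collapse = ", ")),
    paste0("Acceptance rule: ", cmp$rule, " (f1 <= ", cmp$f1_max,
           ", f2 >= ", cmp$f2_min, ")"),
    "")
  scr <- replicate_screen_lines(study)
  res <- cmp$results
  body <- sprintf("  %-10s f1 = %6.2f   f2 = %6.2f   n = %d   %s",
                  res$test_label, res$f1, res$f2, res$n_used, res$verdict)
  n_sim <- sum(res$verdict == "similar")
  c(lines, scr, "Similarity factors:", body, "",
    sprintf("Conclusion: %d of %d test product(s) similar to '%s'.",
            n_sim, nrow(res), study$reference$label))
}

replicate_screen_lines <- function(study) {
  profs <- c(list(study$reference), unname(study$tests))
  out <- vapply(profs, function(p) {
    scr <- screen_variability(p)
    status <- if (is.na(scr$pass)) "not assessable"
      else if (scr$pass) "pass" else "FAIL"
    sprintf("  %-10s max CV %s%%  -> %s", p$label,
            if (all(is.na(scr$table$cv))) "NA"
            else format(max(scr$table$cv, na.rm = TRUE), digits = 3),
            status)
  }, "")
  c("Replicate variability screen (CV limits 20% first point, 10% after):",
    out, "")
}

#' Generate a synthetic study and write it in the standard CSV schema
#'
#' Draws a study from a generator preset (or explicit parameters) and writes
#' `study.csv` in the long replicate layout plus `generator.yaml` recording
#' the generating parameters and seed for provenance.
#'
#' @param preset preset name or YAML path for [release_preset()]; ignored
#'   when `params` is given.
#' @param seed RNG seed (mandatory).
#' @param output_dir output directory (created if needed).
#' @param params,test_deltas,times explicit generator settings overriding
#'   the preset.
#' @return the generated [dissolution_study()], invisibly.
#' @export
run_synth <- function(preset = "vildagliptin50", seed, output_dir = ".",
                      params = NULL, test_deltas = NULL, times = NULL) {
  if (is.null(params)) {
    pre <- release_preset(preset)
    params <- pre$params
    if (is.null(test_deltas)) test_deltas <- pre$test_deltas
    if (is.null(times)) times <- pre$times
  }
  study <- generate_study(params, test_deltas, times, seed = seed)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_study(study, file.path(output_dir, "study.csv"))
  prov <- list(params = unclass(params),
               test_deltas = lapply(test_deltas, as.list),
               times = times, seed = seed)
  yaml::write_yaml(prov, file.path(output_dir, "generator.yaml"))
  invisible(study)
}

#' Quantify a peak-area CSV into a dissolution profile CSV
#'
#' Reads an area table (columns `time_min`, `replicate`, `area`), applies
#' [percent_released()] under the given quantitation config, and writes the
#' resulting profile in the long CSV layout.
#'
#' @param areas_csv CSV of sample peak areas.
#' @param quant_yaml YAML with the [quant_config()] fields plus `std_area`,
#'   the working-standard peak area.
#' @param label product label for the output profile.
#' @param output profile CSV path.
#' @return the [dissolution_profile()], invisibly.
#' @export
run_quantify <- function(areas_csv, quant_yaml, label = "sample",
                         output = "profile.csv") {
  raw <- yaml::read_yaml(quant_yaml)
  std_area <- raw$std_area
  if (is.null(std_area)) stop("quantitation YAML must provide std_area")
  cfg <- do.call(quant_config, raw[setdiff(names(raw), "std_area")])
  df <- utils::read.csv(areas_csv, stringsAsFactors = FALSE)
  need_cols(df, c("time_min", "replicate", "area"), areas_csv)
  t_lev <- sort(unique(df$time_min))
  r_lev <- unique(df$replicate)
  m <- matrix(NA_real_, length(t_lev), length(r_lev))
  m[cbind(match(df$time_min, t_lev), match(df$replicate, r_lev))] <- df$area
  if (anyNA(m)) stop("area table is missing cells for some time/replicate")
  prof <- percent_released(area_table(t_lev, m, std_area), cfg, label)
  out <- data.frame(product = label,
                    time_min = rep(t_lev, ncol(m)),
                    replicate = rep(seq_len(ncol(m)), each = length(t_lev)),
                    pct_released = sprintf("%.17g", as.vector(
                      prof$replicates)))
  utils::write.csv(out, output, row.names = FALSE, quote = FALSE)
  invisible(prof)
}
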