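#' Read a dissolution study from CSV
#'
#' Three layouts are understood (auto-detected from the header by default):
#' \describe{
#'   \item{long}{columns `product`, `time_min`, `replicate`, `pct_released`;
#'     one row per vessel per time point.}
#'   \item{summary}{columns `product`, `time_min`, `mean`, `sd`, `n`; one row
#'     per time point, producing summary-only profiles. `sd` may be empty.}
#'   \item{wide}{column `time_min` plus one column per product replicate,
#'     named `<product>.<replicate>` (e.g. `Ref.1`, `Ref.2`) or plainly
#'     `<product>` for a single replicate.}
#' }
#' The CSV dialect is fixed: comma separator, dot decimal, header row,
#' times in minutes.
#'
#' @param path CSV file path.
#' @param reference label of the reference product; never inferred from
#'   label text.
#' @param layout `"auto"` (default), `"long"`, `"summary"` or `"wide"`.
#' @param method optional method metadata list attached to the study.
#' @return a [dissolution_study()].
#' @examples
#' csv <- system.file("extdata", "vildagliptin_profiles.csv",
#'                    package = "dissim")
#' read_study(csv, reference = "Ref")
#' @export
read_study <- function(path, reference,
                       layout = c("auto", "long", "summary", "wide"),
                       method = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, strip.white = TRUE)
  if (nrow(df) == 0L) stop("no profiles parsed from ", path)
  if (layout == "auto") {
    layout <- if (all(c("product", "mean") %in% names(df))) "summary"
      else if ("pct_released" %in% names(df)) "long"
      else "wide"
  }
  profiles <- switch(layout,
    long = parse_long(df, path),
    summary = parse_summary(df, path),
    wide = parse_wide(df, path))
  if (!reference %in% names(profiles))
    stop("reference label not found: '", reference, "' (products: ",
         paste(names(profiles), collapse = ", "), ")")
  dissolution_study(profiles[[reference]],
                    profiles[names(profiles) != reference],
                    method = method)
}

need_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
}

as_num_col <- function(x, col) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !(is.na(x) | x == ""))
  if (length(bad))
    stop("non-numeric value in column '", col, "' at data row ", bad[1L],
         ": '", x[bad[1L]], "'")
  v
}

parse_long <- function(df, path) {
  need_cols(df, c("product", "time_min", "replicate", "pct_released"), path)
  df$time_min <- as_num_col(df$time_min, "time_min")
  df$pct_released <- as_num_col(df$pct_released, "pct_released")
  build_replicate_profiles(df$product, df$time_min,
                           as.character(df$replicate), df$pct_released)
}

parse_summary <- function(df, path) {
  need_cols(df, c("product", "time_min", "mean"), path)
  df$time_min <- as_num_col(df$time_min, "time_min")
  df$mean <- as_num_col(df$mean, "mean")
  df$sd <- if ("sd" %in% names(df)) as_num_col(df$sd, "sd") else NA_real_
  df$n <- if ("n" %in% names(df)) as_num_col(df$n, "n") else NA_real_
  out <- lapply(split(df, factor(df$product, levels = unique(df$product))),
    function(d) {
      d <- d[order(d$time_min), ]
      dissolution_profile(d$product[1L], d$time_min, mean = d$mean,
                          sd = d$sd, n = d$n[1L])
    })
  check_same_grid(out)
  out
}

parse_wide <- function(df, path) {
  need_cols(df, "time_min", path)
  df$time_min <- as_num_col(df$time_min, "time_min")
  df <- df[order(df$time_min), ]
  value_cols <- setdiff(names(df), "time_min")
  if (!length(value_cols)) stop("no product columns found in ", path)
  # column "Ref.2" -> product "Ref", replicate "2"; no dot -> one replicate
  prod_of <- sub("\\.[^.]*$", "", value_cols)
  prod_of[!grepl("\\.", value_cols)] <- value_cols[!grepl("\\.", value_cols)]
  out <- lapply(unique(prod_of), function(p) {
    cols <- value_cols[prod_of == p]
    m <- vapply(cols, function(cl) as_num_col(df[[cl]], cl),
                numeric(nrow(df)))
    dissolution_profile(p, df$time_min, replicates = as.matrix(m))
  })
  names(out) <- unique(prod_of)
  out
}

build_replicate_profiles <- function(product, time_min, replicate, pct) {
  out <- lapply(split(seq_along(product),
                      factor(product, levels = unique(product))),
    function(idx) {
      t_lev <- sort(unique(time_min[idx]))
      r_lev <- unique(replicate[idx])
      m <- matrix(NA_real_, length(t_lev), length(r_lev),
                  dimnames = list(NULL, r_lev))
      m[cbind(match(time_min[idx], t_lev), match(replicate[idx], r_lev))] <-
        pct[idx]
      if (anyNA(m))
        stop("product '", product[idx][1L],
             "' is missing replicate measurements at some time points")
      dissolution_profile(product[idx][1L], t_lev, replicates = m)
    })
  check_same_grid(out)
  out
}

check_same_grid <- function(profiles) {
  grids <- lapply(profiles, function(p) as.numeric(p$grid))
  ok <- vapply(grids, function(g) isTRUE(all.equal(g, grids[[1L]])), TRUE)
  if (!all(ok))
    stop("time grids differ across products: ",
         paste(names(profiles)[!ok], collapse = ", "),
         " do not match ", names(profiles)[1L])
  invisible(profiles)
}

#' Write a dissolution study to CSV
#'
#' Replicate studies are written in the long layout, summary-only studies in
#' the summary layout (see [read_study()]). Numeric cells are written with
#' full double precision so that a read/write round trip is exact.
#'
#' @param study a [dissolution_study()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  profs <- c(list(study$reference), unname(study$tests))
  full <- function(x) sprintf("%.17g", x)
  if (profs[[1L]]$summary_only) {
    rows <- lapply(profs, function(p) {
      s <- summary(p)
      data.frame(product = p$label, time_min = full(s$time_min),
                 mean = full(s$mean),
                 sd = ifelse(is.na(s$sd), "", full(s$sd)), n = s$n)
    })
  } else {
    rows <- lapply(profs, function(p) {
      reps <- colnames(p$replicates)
      data.frame(
        product = p$label,
        time_min = full(rep(as.numeric(p$grid), times = length(reps))),
        replicate = rep(reps, each = length(p$grid)),
        pct_released = full(as.vector(p$replicates)))
    })
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read method metadata (dissolution run parameters)
#'
#' A flat YAML mapping of the compendial run parameters: `medium`,
#' `volume_ml`, `apparatus`, `speed_rpm`, `temp_c`, `detection`. The packaged
#' default describes a USP apparatus 2 (paddle) run: 0.01 N HCl, 1000 mL,
#' 50 rpm, 37 degC, HPLC detection at 210 nm. Metadata only; no computation
#' depends on these fields.
#'
#' @param path YAML file; defaults to the packaged method file.
#' @return a named list.
#' @export
read_method <- function(path = system.file("extdata",
                                           "method_vildagliptin.yaml",
                                           package = "dissim")) {
  if (!file.exists(path)) stop("method file not found: ", path)
  yaml::read_yaml(path)
}
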