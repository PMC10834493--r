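# Published mean +/- SD dissolution profiles of a vildagliptin 50 mg
# reference product and six generics (grid 10/15/20/30/45 min, n = 3);
# also shipped as inst/extdata/vildagliptin_profiles.csv.
vg_times <- c(10, 15, 20, 30, 45)
vg_means <- list(
  Ref   = c(98.53, 98.57, 98.00, 97.10, 96.05),
  `V-1` = c(98.34, 100.01, 99.13, 98.48, 97.45),
  `V-2` = c(98.48, 103.41, 102.67, 101.86, 100.97),
  `V-3` = c(96.78, 99.44, 98.29, 97.16, 96.40),
  `V-4` = c(98.17, 97.77, 96.48, 95.80, 94.92),
  `V-5` = c(97.50, 97.27, 96.10, 95.09, 93.97),
  `V-6` = c(99.26, 98.93, 97.76, 96.91, 95.96))
vg_sds <- list(
  Ref   = c(0.90, 0.94, 0.94, 0.91, 0.97),
  `V-1` = c(3.50, 0.74, 0.79, 0.80, 0.89),
  `V-2` = c(2.20, 1.33, 1.53, 1.52, 1.55),
  `V-3` = c(2.50, 1.09, 1.02, 1.05, 1.03),
  `V-4` = c(0.69, 0.66, 0.64, 0.76, 0.64),
  `V-5` = c(1.48, 1.41, 1.42, 1.49, 1.46),
  `V-6` = c(1.13, 0.77, 0.86, 0.78, 0.87))

# published f1/f2 per product (2 dp print precision)
vg_f1 <- c(`V-1` = 1.13, `V-2` = 3.94, `V-3` = 0.68,
           `V-4` = 1.05, `V-5` = 1.70, `V-6` = 0.33)
vg_f2 <- c(`V-1` = 90.28, `V-2` = 67.80, `V-3` = 93.57,
           `V-4` = 91.39, `V-5` = 85.09, `V-6` = 98.47)

vg_study <- function() {
  profs <- lapply(names(vg_means), function(p)
    dissolution_profile(p, vg_times, mean = vg_means[[p]],
                        sd = vg_sds[[p]], n = 3))
  dissolution_study(profs[[1L]], profs[-1L])
}

vg_fixture_csv <- function() {
  system.file("extdata", "vildagliptin_profiles.csv", package = "dissim")
}

# independent brute-force coding of the Moore-Flanner factors: explicit
# element loops, never shared with the implementation under test
oracle_f1 <- function(R, T_) {
  num <- 0; den <- 0
  for (t in seq_along(R)) {
    num <- num + abs(R[t] - T_[t])
    den <- den + R[t]
  }
  (num / den) * 100
}
oracle_f2 <- function(R, T_) {
  ss <- 0
  for (t in seq_along(R)) ss <- ss + (R[t] - T_[t])^2
  50 * log10((1 + ss / length(R))^(-0.5) * 100)
}

# brute-force mass-balance oracle: % released from vessel concentrations,
# tracking withdrawn mass step by step
oracle_pct <- function(conc, medium_ml, w_ml, label_mg, replaced) {
  n <- length(conc)
  out <- numeric(n)
  removed <- 0
  for (i in seq_len(n)) {
    vol <- if (replaced) medium_ml else medium_ml - (i - 1) * w_ml
    out[i] <- 100 * (conc[i] * vol + removed) / label_mg
    removed <- removed + conc[i] * w_ml
  }
  out
}

# random replicate study for round-trip and property tests
random_study <- function(seed, n_tests = 2, n_reps = 3) {
  set.seed(seed)
  times <- sort(sample(5:60, 4))
  mk <- function(label) {
    base <- runif(1, 60, 95)
    m <- pmin(base + cumsum(runif(4, 0, 8)), 110)
    dissolution_profile(label, times,
      replicates = matrix(pmax(m + rnorm(4 * n_reps, 0, 2), 0), 4, n_reps))
  }
  dissolution_study(mk("Ref"), lapply(paste0("T", seq_len(n_tests)), mk))
}

default_quant <- function(...) {
  args <- utils::modifyList(list(
    std_mass_mg = 12.84, std_stock_vol_ml = 25, std_aliquot_ml = 2,
    std_final_vol_ml = 20, label_claim_mg = 50, medium_vol_ml = 1000,
    withdrawal_vol_ml = 10), list(...))
  do.call(quant_config, args)
}
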