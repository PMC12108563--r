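#' Net mass loss of a wear series
#'
#' Soak correction per the gravimetric joint-simulator convention: the net
#' loss `W_n` after n cycles is the measured specimen loss plus the
#' soak-control mass gain at the same n, removing fluid-absorption /
#' environmental drift common to both.
#'
#' @param series a `wear_series` (fields `n`, `specimen_loss`, `soak_gain`)
#'   as from [simulate_wear_series()] or [read_wear_csv()].
#' @return Numeric vector `W_n` (mg), one value per time point.
#' @export
net_mass_loss <- function(series) {
  if (length(series$specimen_loss) != length(series$soak_gain) ||
      length(series$n) != length(series$specimen_loss))
    stop("series length mismatch between cycles, specimen and soak readings")
  series$specimen_loss + series$soak_gain
}

#' Average wear rate by linear regression
#'
#' Fits the model `W_n = a * n + b` by ordinary least squares; `a` is
#' reported per million cycles. Per-interval rates (`diff(W) / diff(n)`,
#' scaled the same way) mirror the stepwise wear-rate plots of cyclic
#' testing read out in 500,000-cycle steps.
#'
#' @param W net mass losses (mg), e.g. from [net_mass_loss()].
#' @param n cycle counts (>= 2 distinct values).
#' @return A `wear_result`: `rate` (a, mg per 10^6 cycles), `intercept`
#'   (b, mg), `interval_rates` (mg per 10^6 cycles per step),
#'   `interval_cycles` (step right endpoints), `residual_sd`.
#' @export
wear_rate <- function(W, n) {
  if (length(W) != length(n)) stop("W and n must have equal length")
  if (length(n) < 2L) stop("need at least 2 points for a regression")
  if (length(unique(n)) < 2L)
    stop("all cycle counts identical: slope undefined")
  fit <- stats::lm(W ~ n)
  a <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  structure(list(rate = a * 1e6, intercept = b,
                 interval_rates = diff(W) / diff(n) * 1e6,
                 interval_cycles = n[-1],
                 residual_sd = sqrt(mean(stats::residuals(fit)^2))),
            class = "wear_result")
}

#' @export
print.wear_result <- function(x, ...) {
  cat(sprintf("<wear_result> rate %.4g mg/10^6 cycles, intercept %.4g mg\n",
              x$rate, x$intercept))
  invisible(x)
}

#' Convert a gravimetric wear rate to a volumetric one
#'
#' @param rate mass-loss rate in mg per 10^6 cycles.
#' @param density material density in mg/mm^3 (UHMWPE about 0.93,
#'   Ti-6Al-4V about 4.43).
#' @return Volumetric rate in mm^3 per 10^6 cycles.
#' @export
mass_to_volume <- function(rate, density) {
  if (density <= 0) stop("density must be > 0")
  rate / density
}

#' Split a compression-test load between the two condylar supports
#'
#' Mirrors the static test convention of loading 70% on the ipsilateral
#' (defect) side and 30% on the contralateral side.
#'
#' @param total total load (N).
#' @param ipsilateral_fraction fraction on the defect side, in `[0, 1]`.
#' @return Named vector `c(ipsilateral =, contralateral =)` in N.
#' @export
compression_load_split <- function(total, ipsilateral_fraction = 0.7) {
  if (ipsilateral_fraction < 0 || ipsilateral_fraction > 1)
    stop("ipsilateral fraction must be in [0, 1]")
  c(ipsilateral = total * ipsilateral_fraction,
    contralateral = total * (1 - ipsilateral_fraction))
}

#' Read / write a wear series as CSV
#'
#' Columns: `n`, `specimen_loss_mg`, `soak_change_mg` (soak change recorded
#' as mass gain).
#'
#' @param series a `wear_series`.
#' @param path CSV file path.
#' @return `write_wear_csv`: `path` invisibly; `read_wear_csv`: a
#'   `wear_series`.
#' @export
write_wear_csv <- function(series, path) {
  utils::write.csv(data.frame(n = series$n,
                              specimen_loss_mg = series$specimen_loss,
                              soak_change_mg = series$soak_gain),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wear_csv
#' @export
read_wear_csv <- function(path) {
  d <- utils::read.csv(path)
  structure(list(n = d$n, specimen_loss = d$specimen_loss_mg,
                 soak_gain = d$soak_change_mg), class = "wear_series")
}

#' Metadata constants of the wear-test scenario
#'
#' The articulation kinematics and load of the cyclic wear test are stored
#' as scenario metadata (no tribological model is simulated): 5 million
#' cycles at 20 N, a 12 degree rotation, 8.5 mm anterior/posterior and
#' 0.7 mm medial/lateral translation, readings every 500,000 cycles.
#'
#' @return Named list of scenario constants.
#' @export
wear_scenario <- function() {
  list(cycles_total = 5e6, load_N = 20, rotation_deg = 12,
       translation_ap_mm = 8.5, translation_ml_mm = 0.7,
       step_cycles = 5e5,
       density_uhmwpe_mg_mm3 = 0.93, density_ti6al4v_mg_mm3 = 4.43)
}
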