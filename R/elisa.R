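# Plate-level affinity and capacity estimation: kinetic-slope readout,
# Hill fits at two coating densities, and the two-density (Beatty)
# affinity estimator.

#' Kinetic ELISA slope
#'
#' Substrate turnover is linear over the observed hour, so the per-well
#' response is the ordinary least-squares slope of signal against time.
#'
#' @param times_min Read times (min), length >= 2.
#' @param reads Fluorescence reads.
#' @return Slope in signal units per minute.
#' @export
kinetic_slope <- function(times_min, reads) {
  stopifnot(length(times_min) == length(reads), length(times_min) >= 2)
  unname(stats::coef(stats::lm(reads ~ times_min))[2])
}

#' Fit a Hill dose-response curve
#'
#' Least-squares fit of `r = plateau * c^n / (ec50^n + c^n)` with the
#' baseline fixed at zero (wells are blocked and washed). Starting values
#' come from the data (plateau from the top response, EC50 from linear
#' interpolation at half-plateau).
#'
#' @param concentrations_nM Antibody concentrations (nM), >= 4 points.
#' @param responses Per-well responses (e.g. kinetic slopes).
#' @return An object of class `hill_fit` with elements `ec50`, `plateau`,
#'   `hill_n`, `rss` and the underlying `nls` fit.
#' @examples
#' conc <- c(0.5, 1, 2, 5, 10, 30)
#' fit_hill(conc, 1 * conc / (5 + conc))
#' @export
fit_hill <- function(concentrations_nM, responses) {
  if (length(concentrations_nM) != length(responses)) {
    stop("concentrations and responses must have equal length")
  }
  if (length(concentrations_nM) < 4) {
    stop("need >= 4 dose points spanning the EC50 for a Hill fit")
  }
  df <- data.frame(conc = concentrations_nM, r = responses)
  df <- df[df$conc > 0, , drop = FALSE]
  top <- max(df$r)
  half <- top / 2
  above <- which(df$r >= half)
  ec50_0 <- if (length(above)) df$conc[min(above)] else stats::median(df$conc)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ plateau * conc^n / (ec50^n + conc^n), data = df,
      start = list(plateau = top, ec50 = ec50_0, n = 1),
      lower = c(plateau = 0, ec50 = 1e-8, n = 0.1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("Hill fit failed: ", conditionMessage(e),
           " (n points = ", nrow(df), ", response range = ",
           signif(min(df$r), 3), "..", signif(max(df$r), 3), ")")
    })
  cf <- stats::coef(fit)
  structure(list(ec50 = unname(cf["ec50"]), plateau = unname(cf["plateau"]),
                 hill_n = unname(cf["n"]),
                 rss = sum(stats::residuals(fit)^2), fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: EC50 %.3g nM, plateau %.3g, n %.2f (RSS %.3g)\n",
              x$ec50, x$plateau, x$hill_n, x$rss))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(ec50 = object$ec50, plateau = object$plateau, hill_n = object$hill_n)
}

#' @export
predict.hill_fit <- function(object, concentrations_nM, ...) {
  with(object, plateau * concentrations_nM^hill_n /
         (ec50^hill_n + concentrations_nM^hill_n))
}

#' Two-density (Beatty) affinity estimate from paired EC50 values
#'
#' From EC50s fitted at a reference coating density (`ec50_1x`) and at
#' double density (`ec50_2x`), computes the published formula
#' `1 / (2 * (2 * ec50_1x - ec50_2x))` and, alongside it, its reciprocal
#' `2 * (2 * ec50_1x - ec50_2x)` interpreted as K_D app in nM. The
#' printed formula has reciprocal-concentration units (an association
#' constant with bivalent-site bookkeeping); both readings are returned,
#' labelled, so either can be reproduced.
#'
#' @param ec50_1x EC50 (nM) at the lower coating density.
#' @param ec50_2x EC50 (nM) at double coating density.
#' @return List with `beatty_value` (the printed formula, 1/nM) and
#'   `kd_app_nM` (its reciprocal).
#' @examples
#' beatty_kd(ec50_1x = 12.5, ec50_2x = 13)
#' @export
beatty_kd <- function(ec50_1x, ec50_2x) {
  stopifnot(ec50_1x > 0, ec50_2x > 0)
  d <- 2 * ec50_1x - ec50_2x
  if (d <= 0) {
    stop("estimation error: densities too similar or inverted ",
         "(2 * EC50_1x must exceed EC50_2x)")
  }
  list(beatty_value = 1 / (2 * d), kd_app_nM = 2 * d)
}

#' Relative epitope capacity from paired Hill plateaus
#'
#' The Hill plateau is the maximal enzymatic turnover rate, i.e. the
#' largest amount of antibody the well can bind, and so measures the
#' number of binding sites. Doubling the coating should double it.
#'
#' @param fit_low,fit_high `hill_fit` objects at the two coating levels.
#' @return List with both plateaus and their ratio `high / low`.
#' @export
epitope_capacity <- function(fit_low, fit_high) {
  stopifnot(inherits(fit_low, "hill_fit"), inherits(fit_high, "hill_fit"))
  list(plateau_low = fit_low$plateau, plateau_high = fit_high$plateau,
       ratio = fit_high$plateau / fit_low$plateau)
}

#' Run the full two-density ELISA chain on a plate table
#'
#' Computes kinetic slopes per well, fits a Hill curve per coating level,
#' and applies the two-density affinity estimator.
#'
#' @param plates Long-format data frame with columns `coating_level`
#'   (`"1x"`/`"2x"`), `concentration_nM`, `time_min`, `signal`.
#' @return List with `fits` (named `hill_fit`s), `capacity`
#'   ([epitope_capacity()] output) and `kd` ([beatty_kd()] output).
#' @export
analyze_elisa_plates <- function(plates) {
  need <- c("coating_level", "concentration_nM", "time_min", "signal")
  if (!all(need %in% names(plates))) {
    stop("plate table must have columns: ", paste(need, collapse = ", "))
  }
  fits <- lapply(split(plates, plates$coating_level), function(pl) {
    wells <- split(pl, pl$concentration_nM)
    conc <- as.numeric(names(wells))
    slopes <- vapply(wells, function(w) kinetic_slope(w$time_min, w$signal), 0)
    fit_hill(conc, unname(slopes))
  })
  if (!all(c("1x", "2x") %in% names(fits))) {
    stop("both coating levels '1x' and '2x' are required")
  }
  list(fits = fits,
       capacity = epitope_capacity(fits[["1x"]], fits[["2x"]]),
       kd = beatty_kd(fits[["1x"]]$ec50, fits[["2x"]]$ec50))
}
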