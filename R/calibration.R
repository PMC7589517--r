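# Calibration maps: alpha <-> K_D app (log-linear) and y_max <-> epitope
# availability (linear through the origin), plus the two three-way
# classifications used for the repertoire heat maps.

#' Construct a calibration map
#'
#' The affinity side is the log-linear map `alpha = beta0 + beta1 * ln(kd)`
#' inverted as `kd = exp((alpha - beta0) / beta1)`; the capacity side is a
#' linear map through the origin between a reference signal (e.g. maximal
#' ELISA turnover rate) and `y_max - 1`. Classification thresholds for
#' apparent K_D (nM) and for y_max complete the map.
#'
#' @param beta0 Intercept of the alpha map (dimensionless).
#' @param beta1 Slope of the alpha map per ln(nM); must be negative
#'   (higher alpha means stronger binding).
#' @param ymax_slope Slope of `y_max - 1` per unit reference signal.
#' @param ymax_classes Two increasing y_max thresholds separating
#'   low / intermediate / high epitope availability. Default `c(2, 3)`.
#' @param kd_classes Two increasing K_D thresholds (nM) separating
#'   high / intermediate / low affinity. Default `c(10, 50)`.
#' @param provenance `"paper_preset"` or `"refit"`.
#' @param fit Optional `lm` fit kept for inspection when refit.
#' @return An object of class `calibration_map`.
#' @seealso [paper_calibration()], [fit_alpha_map()], [default_calibration()]
#' @export
calibration_map <- function(beta0, beta1, ymax_slope = 0.46,
                            ymax_classes = c(2, 3),
                            kd_classes = c(10, 50),
                            provenance = c("refit", "paper_preset"),
                            fit = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(is.numeric(beta0), is.numeric(beta1), length(beta0) == 1,
            length(beta1) == 1, is.finite(beta0), is.finite(beta1))
  if (beta1 >= 0) stop("beta1 must be negative")
  stopifnot(ymax_slope > 0, length(ymax_classes) == 2,
            length(kd_classes) == 2)
  if (diff(ymax_classes) <= 0 || diff(kd_classes) <= 0) {
    stop("classification thresholds must be strictly increasing")
  }
  structure(
    list(beta0 = unname(beta0), beta1 = unname(beta1),
         ymax_slope = ymax_slope,
         ymax_classes = ymax_classes, kd_classes = kd_classes,
         provenance = provenance, fit = fit),
    class = "calibration_map"
  )
}

#' The published preset calibration
#'
#' The preset constants of the affinity map,
#' `K_D app [nM] = exp((alpha - 0.969) / (-0.014))`, together with the
#' reported y_max/ELISA-signal slopes (0.46 for the ovalbumin system,
#' 0.67 for the heat-killed-bacteria system). The preset alpha scale is
#' tied to the original instrument's unit convention; pipelines on
#' synthetic data should normally refit with [default_calibration()].
#'
#' @param system `"OVA"` or `"HKB"`, selecting the y_max slope.
#' @return A `calibration_map` with provenance `"paper_preset"`.
#' @examples
#' kd_from_alpha(0.969, paper_calibration()) # 1 nM
#' @export
paper_calibration <- function(system = c("OVA", "HKB")) {
  system <- match.arg(system)
  calibration_map(beta0 = 0.969, beta1 = -0.014,
                  ymax_slope = if (system == "OVA") 0.46 else 0.67,
                  provenance = "paper_preset")
}

#' @export
print.calibration_map <- function(x, ...) {
  cat(sprintf("Calibration map (%s)\n", x$provenance))
  cat(sprintf("  alpha = %.4g %+.4g * ln(K_D [nM])\n", x$beta0, x$beta1))
  cat(sprintf("  y_max slope: %.3g per reference-signal unit\n",
              x$ymax_slope))
  cat(sprintf("  K_D classes : high < %g nM <= intermediate <= %g nM < low\n",
              x$kd_classes[1], x$kd_classes[2]))
  cat(sprintf("  y_max classes: low < %g <= intermediate <= %g < high\n",
              x$ymax_classes[1], x$ymax_classes[2]))
  if (!is.null(x$fit)) {
    cat(sprintf("  refit from %d calibrants, R^2 = %.3f\n",
                length(stats::fitted(x$fit)),
                summary(x$fit)$r.squared))
  }
  invisible(x)
}

#' @export
coef.calibration_map <- function(object, ...) {
  c(beta0 = object$beta0, beta1 = object$beta1,
    ymax_slope = object$ymax_slope)
}

#' Apparent dissociation constant from the corrected curve feature alpha
#'
#' `kd = exp((alpha - beta0) / beta1)`; strictly decreasing in alpha.
#'
#' @param alpha Corrected curve feature (vectorised).
#' @param map A [calibration_map()].
#' @return K_D app in nM.
#' @export
kd_from_alpha <- function(alpha, map = paper_calibration()) {
  stopifnot(inherits(map, "calibration_map"))
  exp((alpha - map$beta0) / map$beta1)
}

#' Inverse of [kd_from_alpha()]
#'
#' @param kd_app_nM Apparent dissociation constant in nM (vectorised, > 0).
#' @inheritParams kd_from_alpha
#' @return alpha.
#' @export
alpha_from_kd <- function(kd_app_nM, map = paper_calibration()) {
  stopifnot(inherits(map, "calibration_map"), all(kd_app_nM > 0))
  map$beta0 + map$beta1 * log(kd_app_nM)
}

#' Fit the log-linear alpha calibration from known calibrants
#'
#' Ordinary least squares of measured alpha on `ln(kd)` over a set of
#' calibration antibodies of known affinity, as done once per assay
#' system and then applied to every droplet.
#'
#' @param kd_app_nM Known apparent dissociation constants (nM), at least
#'   3 distinct values.
#' @param alpha Measured alpha for each calibrant.
#' @param ... Passed to [calibration_map()] (e.g. `ymax_slope`).
#' @return A `calibration_map` with provenance `"refit"`; the underlying
#'   `lm` fit (with standard errors and R^2) is kept in `$fit`.
#' @examples
#' kd <- c(0.5, 2, 10, 40)
#' fit_alpha_map(kd, 0.969 - 0.014 * log(kd))
#' @export
fit_alpha_map <- function(kd_app_nM, alpha, ...) {
  if (length(kd_app_nM) != length(alpha)) {
    stop("kd_app_nM and alpha must have equal length")
  }
  keep <- is.finite(kd_app_nM) & is.finite(alpha)
  kd_app_nM <- kd_app_nM[keep]
  alpha <- alpha[keep]
  if (length(unique(kd_app_nM)) < 3) {
    stop("calibration error: need >= 3 calibrants with distinct kd")
  }
  if (any(kd_app_nM <= 0)) stop("calibration error: kd must be positive")
  fit <- stats::lm(alpha ~ log(kd_app_nM))
  b <- stats::coef(fit)
  if (b[2] >= 0) {
    stop("calibration error: fitted slope is non-negative; ",
         "alpha must decrease with kd")
  }
  calibration_map(beta0 = b[1], beta1 = b[2], provenance = "refit",
                  fit = fit, ...)
}

#' Available-epitope concentration from the relocation maximum
#'
#' Inverts the linear-through-origin relation between the reference
#' signal and `y_max - 1`: returns `(y_max - 1) / ymax_slope` in
#' reference-antigen-equivalent units.
#'
#' @param y_max Maximal relocation value(s), >= 1.
#' @inheritParams kd_from_alpha
#' @return Epitope availability in reference-signal units.
#' @export
epitope_from_ymax <- function(y_max, map = paper_calibration()) {
  stopifnot(inherits(map, "calibration_map"))
  if (any(y_max < 1)) stop("y_max must be >= 1")
  (y_max - 1) / map$ymax_slope
}

#' Classify an apparent dissociation constant into affinity classes
#'
#' High affinity: kd below the first threshold; intermediate: in the
#' closed interval between the thresholds; low: above the second.
#' Boundary points belong to the intermediate class.
#'
#' @param kd_app_nM K_D app in nM (vectorised, > 0).
#' @inheritParams kd_from_alpha
#' @return Factor with levels `high`, `intermediate`, `low`.
#' @examples
#' classify_kd(c(5, 10, 30, 100))
#' @export
classify_kd <- function(kd_app_nM, map = paper_calibration()) {
  stopifnot(inherits(map, "calibration_map"), all(kd_app_nM > 0))
  th <- map$kd_classes
  cls <- ifelse(kd_app_nM < th[1], "high",
                ifelse(kd_app_nM <= th[2], "intermediate", "low"))
  factor(cls, levels = c("high", "intermediate", "low"))
}

#' Classify y_max into epitope-availability classes
#'
#' Low availability: y_max below the first threshold; intermediate: in
#' the closed interval between the thresholds; high: above the second.
#'
#' @param y_max Maximal relocation (vectorised, >= 1).
#' @inheritParams kd_from_alpha
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @examples
#' classify_epitope(c(1.5, 2, 2.7, 3.4))
#' @export
classify_epitope <- function(y_max, map = paper_calibration()) {
  stopifnot(inherits(map, "calibration_map"))
  if (any(y_max < 1)) stop("y_max must be >= 1")
  th <- map$ymax_classes
  cls <- ifelse(y_max < th[1], "low",
                ifelse(y_max <= th[2], "intermediate", "high"))
  factor(cls, levels = c("low", "intermediate", "high"))
}

#' Default refit calibration for the synthetic assay system
#'
#' Builds the calibration the default pipeline uses: simulates
#' concentration titrations of the forward model for a log-spaced panel
#' of known affinities, extracts alpha (`y_max / x_max`) from each, and
#' fits the log-linear map. This mirrors how the published map was built
#' from commercial calibration antibodies, but in the unit convention of
#' this package's forward model.
#'
#' @param constants An [assay_constants()] object.
#' @param epitope_total_nM Capacity at which the calibration titrations
#'   are run. Default 2 (mid-range for the synthetic populations).
#' @param kd_grid_nM Affinity panel. Default 8 values log-spaced over
#'   0.5-100 nM, spanning all three affinity classes.
#' @param ... Forwarded to [binding_params()] for the detection-side
#'   parameters.
#' @return A refit `calibration_map`.
#' @export
default_calibration <- function(constants = assay_constants(),
                                epitope_total_nM = 2,
                                kd_grid_nM = 10^seq(log10(0.5), 2,
                                                    length.out = 8),
                                ...) {
  cal <- simulate_calibration_titrations(kd_grid_nM, epitope_total_nM,
                                         constants, ...)
  fit_alpha_map(cal$kd_app_nM, cal$alpha)
}

#' Write / read a calibration map as JSON
#'
#' @param map A `calibration_map`.
#' @param path File path.
#' @return `write_calibration_map` returns `path` invisibly;
#'   `read_calibration_map` returns a `calibration_map`.
#' @export
write_calibration_map <- function(map, path) {
  stopifnot(inherits(map, "calibration_map"))
  obj <- map[c("beta0", "beta1", "ymax_slope", "ymax_classes",
               "kd_classes", "provenance")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_map
#' @export
read_calibration_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_map(beta0 = obj$beta0, beta1 = obj$beta1,
                  ymax_slope = obj$ymax_slope,
                  ymax_classes = obj$ymax_classes,
                  kd_classes = obj$kd_classes,
                  provenance = obj$provenance)
}
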