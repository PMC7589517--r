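#' @keywords internal
"_PACKAGE"

## Avogadro constant (1/mol), CODATA exact value
.N_AVOGADRO <- 6.02214076e23

#' Physical constants of a droplet assay run
#'
#' Bundles the fixed physical parameters of a droplet screen: droplet
#' volume, the total concentration of the fluorescent detection probe
#' (anti-Ig reporter antibody), the imaging schedule, and a dimensionless
#' volume-correction scalar applied when converting secretion to
#' concentration.
#'
#' @param droplet_volume_pL Droplet volume in picolitres. Default 50.
#' @param probe_total_nM In-droplet concentration of the labelled detection
#'   antibody in nanomolar. Default 45.
#' @param imaging_times_min Imaging schedule in minutes, strictly
#'   increasing and starting at 0. Default `c(0, 15, 30, 45, 60)`
#'   (five reads, every 15 min for an hour).
#' @param corr Dimensionless volume-correction factor used in the
#'   time-to-concentration conversion. Default 1.
#'
#' @return An object of class `assay_constants`.
#' @examples
#' assay_constants()
#' @export
assay_constants <- function(droplet_volume_pL = 50,
                            probe_total_nM = 45,
                            imaging_times_min = c(0, 15, 30, 45, 60),
                            corr = 1) {
  stopifnot(is.numeric(droplet_volume_pL), length(droplet_volume_pL) == 1,
            droplet_volume_pL > 0)
  stopifnot(is.numeric(probe_total_nM), length(probe_total_nM) == 1,
            probe_total_nM > 0)
  stopifnot(is.numeric(corr), length(corr) == 1, corr > 0)
  if (length(imaging_times_min) < 2 || imaging_times_min[1] != 0 ||
      any(diff(imaging_times_min) <= 0)) {
    stop("imaging_times_min must be strictly increasing and start at 0")
  }
  structure(
    list(droplet_volume_pL = droplet_volume_pL,
         probe_total_nM = probe_total_nM,
         imaging_times_min = imaging_times_min,
         corr = corr),
    class = "assay_constants"
  )
}

#' @export
print.assay_constants <- function(x, ...) {
  cat("Droplet assay constants\n")
  cat(sprintf("  droplet volume : %g pL\n", x$droplet_volume_pL))
  cat(sprintf("  probe total    : %g nM\n", x$probe_total_nM))
  cat(sprintf("  imaging times  : %s min\n",
              paste(x$imaging_times_min, collapse = ", ")))
  cat(sprintf("  volume corr    : %g\n", x$corr))
  invisible(x)
}

#' Binding parameters of one antibody/bactoline pair
#'
#' Parameters of the in-droplet equilibrium binding system: the apparent
#' dissociation constant of the antibody against the bacterial surface,
#' the in-droplet concentration of available epitopes, and the invented
#' detection-side plumbing (probe affinity for antibody, relocation gain,
#' and a surface-avidity factor).
#'
#' The avidity factor models the well-known enhancement of binding on a
#' dense multivalent surface: the effective dissociation constant at the
#' bactoline is `kd_app_nM / avidity`, while `kd_app_nM` remains the
#' solution-scale quantity that calibration maps to. See the methods
#' vignette for the rationale.
#'
#' @param kd_app_nM Apparent dissociation constant (nM) of the
#'   antibody-epitope interaction.
#' @param epitope_total_nM In-droplet concentration of available epitopes
#'   (nM equivalent).
#' @param kd_detect_nM Dissociation constant (nM) of the detection probe
#'   for antibody (assumed identical for free and surface-bound antibody).
#'   Default 1.
#' @param gain Dimensionless relocation gain (local bead-concentration
#'   factor), >= 1. Default 22.
#' @param avidity Dimensionless surface-avidity factor, >= 1. Default 40.
#'
#' @return An object of class `binding_params`.
#' @examples
#' binding_params(kd_app_nM = 1.5, epitope_total_nM = 3)
#' @export
binding_params <- function(kd_app_nM, epitope_total_nM,
                           kd_detect_nM = 1, gain = 22, avidity = 40) {
  vals <- c(kd_app_nM, epitope_total_nM, kd_detect_nM, gain, avidity)
  if (!is.numeric(vals) || length(vals) != 5 || any(!is.finite(vals)) ||
      any(vals <= 0)) {
    stop("all binding parameters must be finite and strictly positive")
  }
  if (gain < 1) stop("gain must be >= 1")
  if (avidity < 1) stop("avidity must be >= 1")
  structure(
    list(kd_app_nM = kd_app_nM, epitope_total_nM = epitope_total_nM,
         kd_detect_nM = kd_detect_nM, gain = gain, avidity = avidity),
    class = "binding_params"
  )
}

#' @export
print.binding_params <- function(x, ...) {
  cat(sprintf(
    "Binding parameters: K_D app %g nM, epitopes %g nM (probe K_D %g nM, gain %g, avidity %g)\n",
    x$kd_app_nM, x$epitope_total_nM, x$kd_detect_nM, x$gain, x$avidity))
  invisible(x)
}

#' Convert a secretion rate and time to an in-droplet concentration
#'
#' Antibody accumulates linearly in a closed droplet:
#' `c(t) = rate * t * corr / (N_A * V)`, expressed in nanomolar.
#'
#' @param rate_per_s Secretion rate in molecules per second (vectorised).
#' @param t_min Elapsed time in minutes (vectorised).
#' @param constants An [assay_constants()] object.
#' @return Concentration in nM.
#' @examples
#' secretion_to_concentration(250, 60) # about 29.9 nM in a 50 pL droplet
#' @export
secretion_to_concentration <- function(rate_per_s, t_min,
                                       constants = assay_constants()) {
  stopifnot(all(rate_per_s >= 0), all(t_min >= 0))
  moles <- rate_per_s * t_min * 60 / .N_AVOGADRO
  vol_L <- constants$droplet_volume_pL * 1e-12
  moles * constants$corr / vol_L * 1e9
}
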