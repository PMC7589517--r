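# Forward equilibrium model of in-droplet fluorescence relocation.
#
# Species: antibody A (secreted), surface epitopes E (on the bactoline),
# detection probe P (labelled anti-Ig). Two independent 1:1 equilibria:
#   A + E  <-> AE   with surface K_D = kd_app / avidity (ligand depletion)
#   P + A  <-> PA   with K_D = kd_detect (probe binds the Fc, so binding is
#                   assumed independent of epitope engagement)
# Probe relocated onto the bactoline is the probe riding on surface-bound
# antibody: POB = PA * (AE / A). Relocation is
#   R = 1 + gain * POB / (P_total - POB).

## stable closed-form bound complex of a 1:1 equilibrium with depletion;
## the sum-form root cancels catastrophically when a*b >> kd, so use the
## product form. Vectorised over `a`.
.bound_complex <- function(a, b, kd) {
  s <- a + b + kd
  2 * a * b / (s + sqrt(s * s - 4 * a * b))
}

#' Equilibrium fluorescence relocation at a given antibody concentration
#'
#' Solves the in-droplet mass-action equilibrium and returns the
#' fluorescence relocation ratio R (bactoline signal over droplet
#' background, baseline 1). The model reproduces the Hook effect: R rises
#' with antibody until the epitopes saturate, then falls because excess
#' free antibody sequesters the detection probe away from the bactoline.
#'
#' @param params A [binding_params()] object.
#' @param constants An [assay_constants()] object (supplies the probe
#'   total concentration).
#' @param antibody_total_nM Total secreted-antibody concentration in nM
#'   (vectorised, >= 0).
#' @return Relocation value(s), dimensionless, >= 1. `R = 1` exactly at
#'   zero antibody.
#' @examples
#' p <- binding_params(kd_app_nM = 1.5, epitope_total_nM = 3)
#' solve_relocation(p, assay_constants(), c(0, 1, 10, 100))
#' @export
solve_relocation <- function(params, constants, antibody_total_nM) {
  stopifnot(inherits(params, "binding_params"),
            inherits(constants, "assay_constants"))
  if (any(!is.finite(antibody_total_nM)) || any(antibody_total_nM < 0)) {
    stop("antibody_total_nM must be finite and >= 0")
  }
  A <- antibody_total_nM
  P <- constants$probe_total_nM
  out <- rep(1, length(A))
  pos <- A > 0
  if (any(pos)) {
    Ap <- A[pos]
    AE <- .bound_complex(Ap, params$epitope_total_nM,
                         params$kd_app_nM / params$avidity)
    PA <- .bound_complex(P, Ap, params$kd_detect_nM)
    pob <- PA * AE / Ap
    if (any(pob >= P)) {
      stop("relocation solver produced probe-on-bead >= probe total; ",
           "inputs: A=", paste(Ap, collapse = ","))
    }
    out[pos] <- 1 + params$gain * pob / (P - pob)
  }
  out
}

#' Construct a relocation curve object
#'
#' @param x Ordered abscissa: concentrations (nM) or times (min),
#'   strictly increasing, length >= 3.
#' @param y Relocation values.
#' @param x_kind Either `"concentration"` or `"time"`.
#' @return A `relocation_curve`: a data frame with columns `x`, `y` and
#'   attribute `x_kind`.
#' @export
relocation_curve <- function(x, y, x_kind = c("concentration", "time")) {
  x_kind <- match.arg(x_kind)
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3")
  }
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  structure(data.frame(x = x, y = y),
            x_kind = x_kind,
            class = c("relocation_curve", "data.frame"))
}

#' @export
print.relocation_curve <- function(x, ...) {
  cat(sprintf("Relocation curve (%s axis, %d points), y in [%.3g, %.3g]\n",
              attr(x, "x_kind"), nrow(x), min(x$y), max(x$y)))
  invisible(x)
}

#' @export
plot.relocation_curve <- function(x, ...) {
  xlab <- if (attr(x, "x_kind") == "time") "time (min)" else
    "antibody concentration (nM)"
  graphics::plot(x$x, x$y, type = "b", xlab = xlab,
                 ylab = "fluorescence relocation", log = if (
                   attr(x, "x_kind") == "concentration") "x" else "", ...)
  invisible(x)
}

#' Relocation titration curve over a set of antibody concentrations
#'
#' @inheritParams solve_relocation
#' @param concentrations_nM Increasing antibody concentrations (nM).
#' @return A [relocation_curve()] with `x_kind = "concentration"`.
#' @examples
#' p <- binding_params(kd_app_nM = 1.5, epitope_total_nM = 3)
#' titration_curve(p, assay_constants(), 10^seq(-1, 2, by = 0.5))
#' @export
titration_curve <- function(params, constants, concentrations_nM) {
  if (any(diff(concentrations_nM) <= 0)) {
    stop("concentrations must be strictly increasing")
  }
  relocation_curve(concentrations_nM,
                   solve_relocation(params, constants, concentrations_nM),
                   x_kind = "concentration")
}

#' Relocation time trace of a secreting cell
#'
#' Under the quasi-equilibrium assumption (binding equilibrates fast
#' relative to the 15-min imaging interval), the trace is the equilibrium
#' relocation evaluated at the accumulated concentration
#' `c(t) = rate * t * corr / (N_A * V)` at each imaging time.
#'
#' @inheritParams solve_relocation
#' @param secretion_rate_per_s Secretion rate in molecules per second.
#' @return A [relocation_curve()] with `x_kind = "time"` over the
#'   imaging schedule in `constants`.
#' @examples
#' p <- binding_params(kd_app_nM = 1.5, epitope_total_nM = 3)
#' trace_from_secretion(p, assay_constants(), 250)
#' @export
trace_from_secretion <- function(params, constants, secretion_rate_per_s) {
  stopifnot(length(secretion_rate_per_s) == 1, secretion_rate_per_s >= 0)
  tt <- constants$imaging_times_min
  cc <- secretion_to_concentration(secretion_rate_per_s, tt, constants)
  relocation_curve(tt, solve_relocation(params, constants, cc),
                   x_kind = "time")
}
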