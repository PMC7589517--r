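# Ground-truth synthetic-data generator: droplet populations with known
# per-cell latents, calibration titrations, two-density ELISA plates and
# rendered pixel-grid droplets.

## log-normal shape parameter from a target median and SD
.lognormal_sdlog <- function(median, sd) {
  if (sd == 0) return(0)
  s2 <- (sd / median)^2
  sqrt(log((1 + sqrt(1 + 4 * s2)) / 2))
}

#' Configuration of a synthetic droplet screen
#'
#' Defines the statistical structure the analysis assumes: Poisson cell
#' occupancy, isotype mix, log-normal single-cell secretion rates
#' (parameterised by median and SD), a 3x3 ground-truth mixture over
#' (affinity class x epitope class) with per-class sampling ranges,
#' bactoline size variability, and measurement noise.
#'
#' @param n_droplets Number of droplets.
#' @param lambda_occupancy Mean cells per droplet (Poisson). Default 0.2.
#' @param isotype_probs Named probabilities for `IgG`, `IgM`, `none`
#'   (a cell that secretes no detectable Ig). Must sum to 1.
#' @param sr_median,sr_sd Named vectors (IgG, IgM) of median and SD of
#'   single-cell secretion rates in molecules/s. Defaults: IgG 250 +/- 150,
#'   IgM 300 +/- 117.
#' @param truth_heatmap 3x3 mixture weights, rows = affinity class
#'   (high, intermediate, low), columns = epitope class (low,
#'   intermediate, high); must sum to 1. The default concentrates half
#'   the mass in the high-affinity/high-epitope bin, as observed for
#'   bacterially immunized mice.
#' @param kd_ranges Per-affinity-class K_D app sampling ranges (nM),
#'   sampled log-uniformly. Defaults sit well inside the class limits
#'   (<10, 10-50, >50 nM).
#' @param epitope_ranges Per-epitope-class capacity sampling ranges in
#'   model nM, sampled uniformly; defaults map onto the y_max
#'   classification bands (<2, 2-3, >3) at the reference bactoline size.
#' @param bacteria_mean,bacteria_sd Bacteria per droplet (truncated
#'   normal > 0). Defaults 164 and 30 (the 2-D imaging estimate).
#' @param noise_cv Multiplicative noise CV applied to `R - 1`. Default
#'   0.05.
#' @param additive_sd Additive baseline jitter SD so empty droplets read
#'   `1 +/- noise`. Default 0.01.
#' @param seed Mandatory integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_droplets = 5000,
                         lambda_occupancy = 0.2,
                         isotype_probs = c(IgG = 0.03, IgM = 0.03,
                                           none = 0.94),
                         sr_median = c(IgG = 250, IgM = 300),
                         sr_sd = c(IgG = 150, IgM = 117),
                         truth_heatmap = matrix(
                           c(0.05, 0.10, 0.50,
                             0.05, 0.10, 0.15,
                             0.01, 0.02, 0.02),
                           nrow = 3, byrow = TRUE,
                           dimnames = list(
                             c("high", "intermediate", "low"),
                             c("low", "intermediate", "high"))),
                         kd_ranges = list(high = c(0.5, 4),
                                          intermediate = c(18, 35),
                                          low = c(80, 250)),
                         epitope_ranges = list(low = c(0.5, 1.6),
                                               intermediate = c(2.4, 3.8),
                                               high = c(4.6, 7)),
                         bacteria_mean = 164, bacteria_sd = 30,
                         noise_cv = 0.05, additive_sd = 0.01,
                         seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_droplets >= 1, lambda_occupancy >= 0)
  if (abs(sum(isotype_probs) - 1) > 1e-8) {
    stop("config error: isotype_probs must sum to 1")
  }
  if (!is.matrix(truth_heatmap) || any(dim(truth_heatmap) != 3) ||
      any(truth_heatmap < 0) || abs(sum(truth_heatmap) - 1) > 1e-8) {
    stop("config error: truth_heatmap must be a non-negative 3x3 matrix summing to 1")
  }
  stopifnot(bacteria_mean > 0, bacteria_sd >= 0, noise_cv >= 0,
            additive_sd >= 0)
  structure(
    list(n_droplets = as.integer(n_droplets),
         lambda_occupancy = lambda_occupancy,
         isotype_probs = isotype_probs,
         sr_median = sr_median, sr_sd = sr_sd,
         truth_heatmap = truth_heatmap,
         kd_ranges = kd_ranges, epitope_ranges = epitope_ranges,
         bacteria_mean = bacteria_mean, bacteria_sd = bacteria_sd,
         noise_cv = noise_cv, additive_sd = additive_sd,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic screen: %d droplets, lambda %.3g, seed %d\n",
    x$n_droplets, x$lambda_occupancy, x$seed))
  invisible(x)
}

#' Simulate a droplet screen with known ground truth
#'
#' Draws cells per droplet from a Poisson distribution, per-cell isotype,
#' secretion rate (log-normal), and (K_D app, epitope capacity) from the
#' configured 3x3 mixture; scales each droplet's capacity by its
#' bactoline size (truncated-normal bacteria count relative to the
#' reference mean); evaluates the forward relocation model on the imaging
#' schedule; and applies multiplicative noise on `R - 1` plus a small
#' additive baseline jitter. Droplets with more than one cell are
#' simulated as a single secreting event (the assay cannot distinguish
#' Poisson doublets).
#'
#' @param config A [synth_config()].
#' @param constants An [assay_constants()].
#' @param params_defaults A [binding_params()] supplying the
#'   detection-side defaults (`kd_detect_nM`, `gain`, `avidity`); its
#'   `kd_app_nM` / `epitope_total_nM` are ignored.
#' @return List with `traces` (long-format data frame: `droplet_id`,
#'   `time_min`, `channel`, `relocation`, `cell_present`) and `truth`
#'   (one row per droplet with every latent variable).
#' @export
simulate_population <- function(config, constants = assay_constants(),
                                params_defaults = binding_params(1, 1)) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_droplets
  tt <- constants$imaging_times_min
  kd_classes <- rownames(config$truth_heatmap)
  ep_classes <- colnames(config$truth_heatmap)

  n_cells <- stats::rpois(n, config$lambda_occupancy)
  cell_present <- n_cells > 0
  isotype <- rep(NA_character_, n)
  isotype[cell_present] <- sample(names(config$isotype_probs),
                                  sum(cell_present), replace = TRUE,
                                  prob = config$isotype_probs)
  secreting <- cell_present & isotype %in% c("IgG", "IgM")

  bacteria <- stats::rnorm(n, config$bacteria_mean, config$bacteria_sd)
  while (any(bacteria <= 0)) {                      # truncate > 0
    bad <- bacteria <= 0
    bacteria[bad] <- stats::rnorm(sum(bad), config$bacteria_mean,
                                  config$bacteria_sd)
  }

  rate <- kd <- epitope <- rep(NA_real_, n)
  kd_class <- ep_class <- rep(NA_character_, n)
  ns <- sum(secreting)
  if (ns > 0) {
    iso_s <- isotype[secreting]
    med <- config$sr_median[iso_s]
    sdl <- vapply(iso_s, function(i)
      .lognormal_sdlog(config$sr_median[[i]], config$sr_sd[[i]]), 0)
    rate[secreting] <- med * exp(stats::rnorm(ns, 0, 1) * sdl)
    bin <- sample(9L, ns, replace = TRUE, prob = as.vector(config$truth_heatmap))
    ki <- (bin - 1L) %% 3L + 1L      # row index (affinity class)
    ei <- (bin - 1L) %/% 3L + 1L     # column index (epitope class)
    kd_class[secreting] <- kd_classes[ki]
    ep_class[secreting] <- ep_classes[ei]
    kd[secreting] <- vapply(seq_len(ns), function(j) {
      r <- config$kd_ranges[[kd_classes[ki[j]]]]
      exp(stats::runif(1, log(r[1]), log(r[2])))
    }, 0)
    epitope[secreting] <- vapply(seq_len(ns), function(j) {
      r <- config$epitope_ranges[[ep_classes[ei[j]]]]
      stats::runif(1, r[1], r[2])
    }, 0)
  }

  nt <- length(tt)
  traces <- data.frame(
    droplet_id = rep(seq_len(n), each = 2 * nt),
    time_min = rep(rep(tt, 2), n),
    channel = rep(rep(c("IgG", "IgM"), each = nt), n),
    relocation = 1,
    cell_present = rep(cell_present, each = 2 * nt),
    stringsAsFactors = FALSE)

  for (i in which(secreting)) {
    p <- binding_params(kd_app_nM = kd[i],
                        epitope_total_nM = epitope[i] *
                          bacteria[i] / config$bacteria_mean,
                        kd_detect_nM = params_defaults$kd_detect_nM,
                        gain = params_defaults$gain,
                        avidity = params_defaults$avidity)
    cc <- secretion_to_concentration(rate[i], tt, constants)
    r <- solve_relocation(p, constants, cc)
    ## rows of droplet i, secreting channel: IgG block first, IgM second
    off <- (i - 1L) * 2L * nt + if (isotype[i] == "IgG") 0L else nt
    traces$relocation[off + seq_len(nt)] <- r
  }
  ## noise: multiplicative on (R - 1) plus additive baseline jitter
  m <- nrow(traces)
  noisy <- 1 + (traces$relocation - 1) *
    (1 + stats::rnorm(m, 0, config$noise_cv)) +
    stats::rnorm(m, 0, config$additive_sd)
  traces$relocation <- pmax(noisy, 0)

  truth <- data.frame(droplet_id = seq_len(n), n_cells = n_cells,
                      cell_present = cell_present, isotype = isotype,
                      rate_per_s = rate, kd_app_nM = kd,
                      epitope_nM = epitope, bacteria = bacteria,
                      kd_class = kd_class, epitope_class = ep_class,
                      stringsAsFactors = FALSE)
  list(traces = traces, truth = truth)
}

#' Simulate calibration titrations for the alpha map
#'
#' Runs noise-free concentration titrations of the forward model for a
#' panel of known affinities at fixed capacity and extracts
#' `alpha = y_max / (x_max * corr)` from each curve, emulating the
#' calibration experiments done with commercial antibodies.
#'
#' @param kds_nM Known apparent dissociation constants (nM).
#' @param epitope_total_nM Capacity of the calibration system.
#' @param constants An [assay_constants()].
#' @param conc_grid_nM Titration grid; default 400 points log-spaced over
#'   0.03-500 nM.
#' @param ... Detection-side parameters passed to [binding_params()].
#' @return Data frame with columns `kd_app_nM`, `alpha`, `y_max`,
#'   `x_max_nM`; alpha is strictly decreasing in kd.
#' @export
simulate_calibration_titrations <- function(kds_nM, epitope_total_nM,
                                            constants = assay_constants(),
                                            conc_grid_nM = 10^seq(
                                              log10(0.03), log10(500),
                                              length.out = 400),
                                            ...) {
  stopifnot(all(kds_nM > 0), epitope_total_nM > 0)
  rows <- lapply(kds_nM, function(kd) {
    p <- binding_params(kd_app_nM = kd,
                        epitope_total_nM = epitope_total_nM, ...)
    cv <- titration_curve(p, constants, conc_grid_nM)
    fe <- extract_features(cv$y, x = cv$x)
    data.frame(kd_app_nM = kd, alpha = fe$y_max / (fe$x_max * constants$corr),
               y_max = fe$y_max, x_max_nM = fe$x_max)
  })
  do.call(rbind, rows)
}

#' Simulate a paired two-density ELISA experiment
#'
#' Plate binding is modelled at equilibrium with ligand depletion;
#' antibodies are bivalent, so the reacting species concentration is
#' twice the antibody concentration. Kinetic reads are linear in time
#' with slope proportional to bound sites; doubling the coating doubles
#' the available sites and hence the plateau.
#'
#' @param kd_app_nM True (per-site) dissociation constant, nM.
#' @param dilutions_nM Antibody dilution series (nM); by default 12
#'   points log-spaced around the expected EC50.
#' @param sites_1x_nM Effective binding-site concentration of the
#'   reference coating (nM). Default 1; the 2x plate doubles it.
#' @param read_times_min Kinetic read schedule; default every 10 min for
#'   an hour.
#' @param noise_cv Multiplicative noise on the per-read signal. Default 0.
#' @param seed Optional seed used when `noise_cv > 0`.
#' @return Long-format plate table for [analyze_elisa_plates()].
#' @export
simulate_elisa <- function(kd_app_nM, dilutions_nM = NULL,
                           sites_1x_nM = 1,
                           read_times_min = seq(0, 60, by = 10),
                           noise_cv = 0, seed = NULL) {
  stopifnot(kd_app_nM > 0, sites_1x_nM > 0)
  if (is.null(dilutions_nM)) {
    ec50_guess <- (kd_app_nM + sites_1x_nM) / 2
    dilutions_nM <- 10^seq(log10(ec50_guess / 30), log10(ec50_guess * 30),
                           length.out = 12)
  }
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (lvl in c("1x", "2x")) {
    L <- sites_1x_nM * if (lvl == "2x") 2 else 1
    sites <- 2 * dilutions_nM            # bivalent IgG
    bound <- .bound_complex(sites, L, kd_app_nM)
    for (j in seq_along(dilutions_nM)) {
      sig <- bound[j] * read_times_min
      if (noise_cv > 0) {
        sig <- sig * (1 + stats::rnorm(length(sig), 0, noise_cv))
      }
      out[[length(out) + 1]] <- data.frame(
        coating_level = lvl, concentration_nM = dilutions_nM[j],
        time_min = read_times_min, signal = sig,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Three independent estimates of bacteria per droplet
#'
#' Method A: the 2-D imaging count (mean, SD, CV) -- a lower limit since
#' the bactoline is three-dimensional. Method B: bactoline volume divided
#' by the volume of one bacterium. Method C: the optical-density drop on
#' immobilisation converted to a count.
#'
#' @param two_d_mean,two_d_sd 2-D estimate, bacteria per droplet.
#'   Defaults 164 and 30.
#' @param bactoline_volume_um3 Measured bactoline volume. Default 2000.
#' @param volume_per_bacterium_um3 Volume of one bacterium. Default 2.
#' @param od_fold_drop Fold decrease of OD600 on immobilisation.
#'   Default 50.
#' @param od_to_count Bacteria per droplet per unit fold-drop. Default 16
#'   (50-fold corresponds to roughly 800 per droplet).
#' @return List with the three estimates: `two_d` (mean, sd, cv),
#'   `volume` (count), `od` (count).
#' @export
bacteria_per_droplet_estimates <- function(two_d_mean = 164, two_d_sd = 30,
                                           bactoline_volume_um3 = 2000,
                                           volume_per_bacterium_um3 = 2,
                                           od_fold_drop = 50,
                                           od_to_count = 16) {
  stopifnot(two_d_mean > 0, two_d_sd >= 0, bactoline_volume_um3 > 0,
            volume_per_bacterium_um3 > 0)
  list(two_d = list(mean = two_d_mean, sd = two_d_sd,
                    cv = two_d_sd / two_d_mean),
       volume = bactoline_volume_um3 / volume_per_bacterium_um3,
       od = od_fold_drop * od_to_count)
}

#' Render a synthetic droplet image pair
#'
#' Fixture factory for the segmentation path: builds a circular droplet
#' mask, an auto-fluorescence grid with a bright bactoline bar (plus an
#' optional detached fragment below half the bactoline area), and a
#' detection-channel grid whose bactoline pixels carry the configured
#' relocation over background.
#'
#' @param relocation Target relocation ratio (>= 1).
#' @param geometry List with `n` (grid side, default 25), `radius`
#'   (droplet radius in pixels, default 10), `bact_rows`, `bact_cols`
#'   (bactoline extent, defaults 2 x 8), `fragment_px` (area of the
#'   detached fragment, default 0 = none).
#' @param noise_sd Multiplicative pixel noise SD. Default 0.
#' @param seed Optional seed for the noise.
#' @return List with matrices `fitc`, `channel`, `droplet_mask`,
#'   `bactoline_mask` (the true mask, before segmentation).
#' @export
render_droplet_image <- function(relocation, geometry = list(),
                                 noise_sd = 0, seed = NULL) {
  stopifnot(relocation >= 1)
  g <- utils::modifyList(list(n = 25, radius = 10, bact_rows = 2,
                              bact_cols = 8, fragment_px = 0), geometry)
  n <- g$n
  ctr <- (n + 1) / 2
  d2 <- outer(seq_len(n), seq_len(n),
              function(r, c) (r - ctr)^2 + (c - ctr)^2)
  droplet <- d2 <= g$radius^2
  bact <- matrix(FALSE, n, n)
  r0 <- floor(ctr - g$bact_rows / 2) + 1
  c0 <- floor(ctr - g$bact_cols / 2) + 1
  bact[r0:(r0 + g$bact_rows - 1), c0:(c0 + g$bact_cols - 1)] <- TRUE
  bact <- bact & droplet
  frag <- matrix(FALSE, n, n)
  if (g$fragment_px > 0) {
    ## detached fragment two rows below the bar, inside the droplet
    fr <- min(r0 + g$bact_rows + 2, n)
    cols <- c0 + seq_len(g$fragment_px) - 1
    frag[fr, cols[cols <= n]] <- TRUE
    frag <- frag & droplet & !bact
  }
  if (!is.null(seed)) set.seed(seed)
  jitter <- function(m) if (noise_sd > 0) {
    m * (1 + stats::rnorm(length(m), 0, noise_sd))
  } else m
  fitc <- matrix(10, n, n)
  fitc[droplet] <- 50
  fitc[bact | frag] <- 200
  channel <- matrix(50, n, n)
  channel[droplet] <- 100
  channel[bact] <- 100 * relocation
  list(fitc = jitter(fitc), channel = jitter(channel),
       droplet_mask = droplet, bactoline_mask = bact)
}
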