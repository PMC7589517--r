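# Per-droplet processing: bactoline segmentation on pixel grids, trace
# feature extraction with the interior-maximum filter, Eq.-style alpha
# computation, K_D app estimation and heat-map bin assignment.

#' Segment the bactoline from a droplet intensity grid
#'
#' Selects the brightest fraction of in-droplet pixels (the bactoline
#' auto-fluorescence), splits the selection into 4-connected components,
#' and discards every component whose area is less than half of the total
#' selected area (removal of free-floating bacteria and noise). Ties in
#' intensity are broken by fixed scan order (column-major), so the result
#' is deterministic and invariant to adding a constant to all intensities.
#'
#' @param intensity_grid Numeric matrix of non-negative pixel intensities.
#' @param droplet_mask Logical matrix of the same shape marking in-droplet
#'   pixels.
#' @param brightest_fraction Fraction of in-droplet pixels to select,
#'   in (0, 1).
#' @return Logical matrix: the bactoline mask.
#' @export
segment_bactoline <- function(intensity_grid, droplet_mask,
                              brightest_fraction) {
  if (!is.matrix(intensity_grid) || !is.matrix(droplet_mask) ||
      !all(dim(intensity_grid) == dim(droplet_mask))) {
    stop("intensity_grid and droplet_mask must be matrices of equal shape")
  }
  stopifnot(brightest_fraction > 0, brightest_fraction < 1)
  idx_in <- which(droplet_mask)
  if (length(idx_in) == 0) stop("droplet_mask is empty")
  k <- max(1L, round(brightest_fraction * length(idx_in)))
  ## stable sort: ties resolved by linear (column-major) scan order
  ord <- idx_in[order(-intensity_grid[idx_in], idx_in)]
  sel <- logical(length(intensity_grid))
  sel[ord[seq_len(k)]] <- TRUE
  sel <- matrix(sel, nrow(intensity_grid))
  comp <- .label_components(sel)
  sizes <- tabulate(comp[comp > 0])
  keep <- which(sizes >= k / 2)
  out <- matrix(FALSE, nrow(sel), ncol(sel))
  out[comp %in% keep & sel] <- TRUE
  out
}

## label 4-connected components of a logical matrix; returns an integer
## matrix, 0 = background. Simple seed-fill; grids here are small.
.label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      r <- (p - 1L) %% nr + 1L
      cc <- (p - 1L) %/% nr + 1L
      for (nb in c(if (r > 1L) p - 1L, if (r < nr) p + 1L,
                   if (cc > 1L) p - nr, if (cc < nc) p + nr)) {
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  lab
}

#' Fluorescence relocation ratio from a masked grid
#'
#' Mean intensity inside the bactoline mask over mean intensity in the
#' rest of the droplet.
#'
#' @param intensity_grid Numeric matrix (the detection channel).
#' @param bactoline_mask Logical matrix from [segment_bactoline()].
#' @param droplet_mask Logical matrix of in-droplet pixels.
#' @return Dimensionless relocation ratio.
#' @export
relocation_value <- function(intensity_grid, bactoline_mask, droplet_mask) {
  stopifnot(all(dim(intensity_grid) == dim(bactoline_mask)),
            all(dim(intensity_grid) == dim(droplet_mask)))
  inside <- bactoline_mask & droplet_mask
  outside <- droplet_mask & !bactoline_mask
  if (!any(inside) || !any(outside)) {
    stop("bactoline mask must be a proper, non-empty subset of the droplet")
  }
  mean(intensity_grid[inside]) / mean(intensity_grid[outside])
}

#' Median secretion-rate summary of a screen
#'
#' @param median_rate Median secretion rate, molecules/s. Defaults to the
#'   reported IgG value 250 (IgM: 300).
#' @param sd_rate Standard deviation of single-cell rates, molecules/s.
#'   Defaults to the reported IgG value 150 (IgM: 117).
#' @return An object of class `secretion_summary`.
#' @export
secretion_summary <- function(median_rate = 250, sd_rate = 150) {
  stopifnot(median_rate > 0, sd_rate >= 0)
  structure(list(median_rate = median_rate, sd_rate = sd_rate),
            class = "secretion_summary")
}

#' @export
print.secretion_summary <- function(x, ...) {
  cat(sprintf("Secretion: median %g +/- %g molecules/s\n",
              x$median_rate, x$sd_rate))
  invisible(x)
}

#' Extract (y_max, x_max) features from a relocation series
#'
#' `y_max` is the maximum of the series; `x_max` is the earliest abscissa
#' achieving it (plateau ties go to the earliest point). The maximum is
#' interior only if it falls strictly between the first and last points;
#' traces whose argmax sits on either end have no defined maximum and are
#' excluded downstream.
#'
#' @param trace Either a long-format droplet trace `data.frame` with
#'   columns `time_min`, `channel`, `relocation` (one droplet), or a
#'   numeric vector of relocation values.
#' @param channel Channel to extract when `trace` is a data frame
#'   (`"IgG"` or `"IgM"`).
#' @param x Abscissa values when `trace` is a numeric vector.
#' @return A list of class `trace_features` with elements `y_max`,
#'   `x_max`, `has_interior_max`.
#' @examples
#' extract_features(c(1.0, 1.5, 2.2, 1.9, 1.6), x = c(0, 15, 30, 45, 60))
#' @export
extract_features <- function(trace, channel = "IgG", x = NULL) {
  if (is.data.frame(trace)) {
    sub <- trace[trace$channel == channel, , drop = FALSE]
    sub <- sub[order(sub$time_min), , drop = FALSE]
    x <- sub$time_min
    y <- sub$relocation
  } else {
    y <- trace
    if (is.null(x)) x <- seq_along(y)
  }
  if (length(y) < 3) stop("need >= 3 points to define a maximum")
  i <- which.max(y)  # which.max returns the earliest maximum
  structure(list(y_max = y[i], x_max = x[i],
                 has_interior_max = i > 1L && i < length(y)),
            class = "trace_features")
}

#' @export
print.trace_features <- function(x, ...) {
  cat(sprintf("y_max %.3f at x = %g (%s maximum)\n", x$y_max, x$x_max,
              if (x$has_interior_max) "interior" else "no interior"))
  invisible(x)
}

#' Corrected curve feature alpha from trace features
#'
#' Converts the time of the relocation maximum into the in-droplet
#' antibody concentration that had accumulated by then (using the median
#' secretion rate, or a per-cell rate in oracle mode) and returns
#' `alpha = y_max / (concentration * corr)`.
#'
#' @param features A `trace_features` object with an interior maximum.
#' @param secretion A [secretion_summary()]; its median rate converts
#'   time to concentration.
#' @param constants An [assay_constants()] object.
#' @param rate_per_s Optional explicit rate overriding the median
#'   (oracle mode with the cell's true rate).
#' @return alpha (dimensionless in the package's nM convention).
#' @export
alpha_from_features <- function(features, secretion = secretion_summary(),
                                constants = assay_constants(),
                                rate_per_s = NULL) {
  stopifnot(inherits(features, "trace_features"))
  if (!features$has_interior_max) {
    stop("alpha is only defined for traces with an interior maximum")
  }
  rate <- if (is.null(rate_per_s)) secretion$median_rate else rate_per_s
  conc <- secretion_to_concentration(rate, features$x_max, constants)
  if (conc <= 0) stop("maximum at time 0: concentration is zero")
  features$y_max / conc
}

#' Build one cell record from a droplet trace
#'
#' Applies the full per-droplet chain: secreting-cell call (cell present
#' and a detectable relocation increase), interior-maximum filter, alpha,
#' K_D app via the calibration map, and the two class assignments.
#' Excluded droplets carry an `excluded_reason` of `"no_cell"`,
#' `"no_increase"` or `"no_interior_max"` and empty estimates.
#'
#' @param trace Long-format data frame for one droplet with columns
#'   `droplet_id`, `time_min`, `channel`, `relocation`, `cell_present`.
#' @param secretion A [secretion_summary()].
#' @param constants An [assay_constants()].
#' @param map A [calibration_map()].
#' @param sr_mode `"median"` (the published approximation) or `"oracle"`
#'   (use `true_rate`, for validation against ground truth).
#' @param true_rate Per-cell secretion rate for oracle mode.
#' @param detect_k Detection threshold multiplier: a channel is called
#'   secreting when final minus initial relocation exceeds
#'   `detect_k * noise_sd`. Default 3.
#' @param noise_sd Baseline relocation noise SD. Default 0.01.
#' @return One-row data frame (a cell record).
#' @export
build_cell_record <- function(trace, secretion = secretion_summary(),
                              constants = assay_constants(),
                              map = paper_calibration(),
                              sr_mode = c("median", "oracle"),
                              true_rate = NULL,
                              detect_k = 3, noise_sd = 0.01) {
  sr_mode <- match.arg(sr_mode)
  id <- trace$droplet_id[1]
  rec <- data.frame(droplet_id = id, isotype = NA_character_,
                    y_max = NA_real_, x_max_min = NA_real_,
                    alpha = NA_real_, kd_app_nM = NA_real_,
                    kd_class = NA_character_, epitope_class = NA_character_,
                    excluded_reason = NA_character_,
                    stringsAsFactors = FALSE)
  if (!any(trace$cell_present)) {
    rec$excluded_reason <- "no_cell"
    return(rec)
  }
  ## secreting-channel call: final minus initial relocation above noise
  channels <- unique(trace$channel)
  rises <- vapply(channels, function(ch) {
    y <- trace$relocation[trace$channel == ch][order(trace$time_min[trace$channel == ch])]
    y[length(y)] - y[1]
  }, 0)
  detected <- channels[rises > detect_k * noise_sd]
  if (length(detected) == 0) {
    rec$excluded_reason <- "no_increase"
    return(rec)
  }
  ch <- detected[which.max(rises[channels %in% detected])]
  fe <- extract_features(trace, channel = ch)
  rec$isotype <- ch
  rec$y_max <- fe$y_max
  rec$x_max_min <- fe$x_max
  if (!fe$has_interior_max) {
    rec$excluded_reason <- "no_interior_max"
    return(rec)
  }
  rate <- if (sr_mode == "oracle") {
    if (is.null(true_rate)) stop("oracle mode requires true_rate")
    true_rate
  } else NULL
  rec$alpha <- alpha_from_features(fe, secretion, constants, rate_per_s = rate)
  rec$kd_app_nM <- kd_from_alpha(rec$alpha, map)
  rec$kd_class <- as.character(classify_kd(rec$kd_app_nM, map))
  rec$epitope_class <- as.character(classify_epitope(rec$y_max, map))
  rec
}

#' Process a whole screen of droplet traces into cell records
#'
#' @param traces Long-format data frame covering many droplets (columns
#'   as in [build_cell_record()]).
#' @param true_rates Optional named vector of per-droplet true secretion
#'   rates (names = droplet ids), required for oracle mode.
#' @inheritParams build_cell_record
#' @return Data frame with one row per droplet.
#' @export
analyze_droplets <- function(traces, secretion = secretion_summary(),
                             constants = assay_constants(),
                             map = paper_calibration(),
                             sr_mode = c("median", "oracle"),
                             true_rates = NULL,
                             detect_k = 3, noise_sd = 0.01) {
  sr_mode <- match.arg(sr_mode)
  groups <- split(traces, factor(traces$droplet_id,
                                 levels = unique(traces$droplet_id)))
  recs <- lapply(groups, function(tr) {
    build_cell_record(tr, secretion, constants, map, sr_mode,
                      true_rate = if (sr_mode == "oracle")
                        unname(true_rates[as.character(tr$droplet_id[1])])
                      else NULL,
                      detect_k = detect_k, noise_sd = noise_sd)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Sensitivity of K_D app to the median-secretion-rate approximation
#'
#' Recomputes the apparent dissociation constant of a record with the
#' secretion rate set to median - 1 SD and median + 1 SD, and reports the
#' fold range under both readings of the sensitivity statement: through
#' the exponential alpha map, and under the linear kd-proportional-to-
#' concentration interpretation.
#'
#' @param record One included cell record (row of [analyze_droplets()]).
#' @inheritParams build_cell_record
#' @return List with `kd_low`, `kd_high` (nM, at median +/- 1 SD),
#'   `fold_map` (max/min through the calibration map),
#'   `fold_linear` (max single-side factor on concentration).
#' @export
sr_sensitivity <- function(record, secretion = secretion_summary(),
                           constants = assay_constants(),
                           map = paper_calibration()) {
  if (is.na(record$alpha)) stop("record was excluded; no alpha available")
  m <- secretion$median_rate
  s <- secretion$sd_rate
  if (s >= m) stop("sd_rate must be below median_rate for a +/- 1 SD sweep")
  rates <- c(low = m - s, mid = m, high = m + s)
  ## alpha scales as 1/rate at fixed (y_max, x_max)
  alphas <- record$alpha * m / rates
  kds <- kd_from_alpha(alphas, map)
  list(kd_low = unname(kds["low"]), kd_high = unname(kds["high"]),
       fold_map = max(kds) / min(kds),
       fold_linear = max(m / (m - s), (m + s) / m))
}

#' Estimate a secretion rate from a calibrated beadline trace
#'
#' Converts each relocation value to an antibody concentration through a
#' supplied inverse calibration, fits concentration against time by
#' ordinary least squares, and converts the slope to molecules per
#' second. Negative fitted slopes are floored at zero with a warning.
#'
#' @param times_min Imaging times (min).
#' @param relocation Relocation values at those times.
#' @param invert Function mapping relocation to concentration (nM); must
#'   be the inverse of the beadline calibration on the ascending branch.
#' @param constants An [assay_constants()].
#' @return Secretion rate in molecules/s.
#' @export
estimate_secretion_rate <- function(times_min, relocation, invert,
                                    constants = assay_constants()) {
  stopifnot(length(times_min) == length(relocation), length(times_min) >= 2)
  conc <- vapply(relocation, invert, 0)
  slope <- stats::coef(stats::lm(conc ~ times_min))[2]  # nM per minute
  if (is.na(slope)) slope <- 0
  if (slope < 0) {
    warning("negative fitted slope; secretion rate floored at 0")
    return(0)
  }
  vol_L <- constants$droplet_volume_pL * 1e-12
  unname(slope * 1e-9 * .N_AVOGADRO * vol_L / 60 / constants$corr)
}
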