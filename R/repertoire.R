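# Cohort-level repertoire statistics: occupancy-based cell counting,
# secreting-cell frequencies, class-switch ratios, cross-reactivity,
# 3x3 heat maps and two-sample tests across mice.

#' Secreting-cell frequencies of one screen
#'
#' The number of screened cells is the number of droplets times the
#' Poisson occupancy lambda; each frequency is the corresponding count
#' over screened cells, in percent.
#'
#' @param n_droplets Droplets screened.
#' @param lambda_occupancy Mean cells per droplet.
#' @param n_igg_sc,n_igm_sc IgG- and IgM-secreting-cell counts.
#' @param n_specific_igg_sc Optional count of antigen-specific IgG-SCs.
#' @return List with `n_cells`, `freq_igg`, `freq_igm`, `freq_ig_total`
#'   and (if supplied) `freq_specific_igg`, all frequencies in percent.
#' @examples
#' screen_frequencies(30000, 0.1, n_igg_sc = 90, n_igm_sc = 60)
#' @export
screen_frequencies <- function(n_droplets, lambda_occupancy,
                               n_igg_sc, n_igm_sc,
                               n_specific_igg_sc = NULL) {
  stopifnot(n_droplets >= 1, lambda_occupancy > 0,
            n_igg_sc >= 0, n_igm_sc >= 0)
  n_cells <- n_droplets * lambda_occupancy
  out <- list(n_cells = n_cells,
              freq_igg = 100 * n_igg_sc / n_cells,
              freq_igm = 100 * n_igm_sc / n_cells)
  out$freq_ig_total <- out$freq_igg + out$freq_igm
  if (!is.null(n_specific_igg_sc)) {
    out$freq_specific_igg <- 100 * n_specific_igg_sc / n_cells
  }
  out
}

#' Class-switch ratio
#'
#' IgG-SC frequency divided by IgM-SC frequency; `NA` (with a warning)
#' when no IgM-SCs were observed.
#'
#' @param freq_igg,freq_igm Frequencies in any common unit.
#' @return Dimensionless ratio.
#' @examples
#' switch_ratio(3.12, 3.2)
#' @export
switch_ratio <- function(freq_igg, freq_igm) {
  stopifnot(freq_igg >= 0, freq_igm >= 0)
  if (freq_igm == 0) {
    warning("IgM frequency is zero; switch ratio undefined")
    return(NA_real_)
  }
  freq_igg / freq_igm
}

#' Fraction of IgG-SCs whose antibody binds the assayed surface
#'
#' @param freq_specific_igg Frequency of surface-binding IgG-SCs.
#' @param freq_total_igg Frequency of all IgG-SCs.
#' @return Dimensionless fraction.
#' @examples
#' specific_fraction(0.68, 3.12)
#' @export
specific_fraction <- function(freq_specific_igg, freq_total_igg) {
  stopifnot(freq_specific_igg >= 0, freq_total_igg >= 0)
  if (freq_total_igg == 0) {
    warning("total IgG frequency is zero; specific fraction undefined")
    return(NA_real_)
  }
  freq_specific_igg / freq_total_igg
}

#' Relative cross-reactive frequency
#'
#' Frequency of IgG-SCs binding a non-immunogen target, relative to the
#' frequency binding the immunogen.
#'
#' @param freq_vs_target Frequency against the probed bacterium.
#' @param freq_vs_immunogen Frequency against the immunizing bacterium.
#' @return Dimensionless relative fraction.
#' @export
crossreactivity <- function(freq_vs_target, freq_vs_immunogen) {
  stopifnot(freq_vs_target >= 0, freq_vs_immunogen >= 0)
  if (freq_vs_immunogen == 0) {
    warning("immunogen frequency is zero; cross-reactivity undefined")
    return(NA_real_)
  }
  freq_vs_target / freq_vs_immunogen
}

#' Cohort summary over individual mice
#'
#' Frequencies are summarised as mean +/- SD, secretion rates as
#' median +/- SD, following the reporting convention of droplet screens.
#' With a single mouse the SD is undefined and returned as `NA` with a
#' warning.
#'
#' @param values Per-mouse values.
#' @param type `"frequency"` (mean) or `"secretion"` (median).
#' @return List with `center`, `sd`, `n`, `type`.
#' @examples
#' cohort_summary(c(1.7, 1.5, 2.1))
#' @export
cohort_summary <- function(values, type = c("frequency", "secretion")) {
  type <- match.arg(type)
  stopifnot(is.numeric(values), length(values) >= 1)
  if (length(values) == 1) {
    warning("single mouse: SD undefined")
    return(list(center = values, sd = NA_real_, n = 1L, type = type))
  }
  list(center = if (type == "frequency") mean(values) else
         stats::median(values),
       sd = stats::sd(values), n = length(values), type = type)
}

#' 3x3 affinity x epitope-density heat map of a record set
#'
#' Relative frequency of included cell records per (affinity class x
#' epitope class) bin, with row and column marginals. The matrix sums to
#' 1 when any included record exists; an empty record set yields an
#' all-zero matrix flagged by the `"empty"` attribute.
#'
#' @param records Cell-record data frame from [analyze_droplets()] (or
#'   any data frame with `kd_class` and `epitope_class` columns);
#'   excluded records are dropped.
#' @return A `repertoire_heatmap`: 3x3 matrix (rows high/intermediate/low
#'   affinity, columns low/intermediate/high epitope availability) with
#'   attributes `row_marginals`, `col_marginals`, `n`, `empty`.
#' @export
repertoire_heatmap <- function(records) {
  kd_lv <- c("high", "intermediate", "low")
  ep_lv <- c("low", "intermediate", "high")
  inc <- records[!is.na(records$kd_class) & !is.na(records$epitope_class), ,
                 drop = FALSE]
  tab <- table(factor(inc$kd_class, levels = kd_lv),
               factor(inc$epitope_class, levels = ep_lv))
  n <- sum(tab)
  m <- if (n > 0) unclass(tab) / n else matrix(0, 3, 3,
                                               dimnames = dimnames(tab))
  m <- matrix(as.numeric(m), 3, 3, dimnames = list(kd_lv, ep_lv))
  structure(m, class = c("repertoire_heatmap", "matrix", "array"),
            row_marginals = rowSums(m), col_marginals = colSums(m),
            n = n, empty = n == 0)
}

#' @export
print.repertoire_heatmap <- function(x, ...) {
  cat(sprintf("Repertoire heat map (n = %d included records%s)\n",
              attr(x, "n"), if (attr(x, "empty")) ", EMPTY" else ""))
  m <- cbind(unclass(x)[, , drop = FALSE], sum = attr(x, "row_marginals"))
  m <- rbind(m, sum = c(attr(x, "col_marginals"), sum(unclass(x))))
  print(round(m, 3))
  invisible(x)
}

#' Signed difference between two repertoire heat maps
#'
#' Entry-wise `a - b`; since both maps sum to 1, the differences sum
#' to 0.
#'
#' @param map_a,map_b `repertoire_heatmap` objects.
#' @return 3x3 numeric matrix of signed differences.
#' @export
heatmap_difference <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "repertoire_heatmap"),
            inherits(map_b, "repertoire_heatmap"))
  unclass(map_a) - unclass(map_b)
}

#' Two-tailed two-sample Student's t-test across mice
#'
#' Pooled-variance Student's t by default, matching the reporting of
#' droplet-screen cohorts; Welch's correction is available behind a
#' flag.
#'
#' @param group_a,group_b Per-mouse values.
#' @param welch Use Welch's unequal-variance t instead. Default `FALSE`.
#' @return List with `t`, `df`, `p`.
#' @examples
#' ttest_two_tailed(c(3.3, 4.1, 2.9), c(1.6, 1.9, 1.8))
#' @export
ttest_two_tailed <- function(group_a, group_b, welch = FALSE) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  ht <- stats::t.test(group_a, group_b, var.equal = !welch,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Round half away from zero at a printed precision
#'
#' Used only when comparing computed values against printed ones;
#' internal values are never rounded.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits.
#' @return Rounded values.
#' @examples
#' round_half_up(1.75, 1) # 1.8
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
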