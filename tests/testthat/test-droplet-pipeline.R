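# Per-droplet processing: segmentation, relocation readout, feature
# extraction, alpha, record assembly and secretion-rate utilities.

cst <- assay_constants()

make_grid <- function(n = 10, bg = 10) matrix(bg, n, n)

test_that("half-area rule removes small fragments but keeps equal blobs", {
  ## one 40 px blob plus a detached 10 px fragment, both brightest
  g <- make_grid(10)
  mask_all <- matrix(TRUE, 10, 10)
  g[2:6, 2:9] <- 200          # 40 px blob
  g[9, 1:10] <- 200           # 10 px fragment (detached row)
  out <- segment_bactoline(g, mask_all, brightest_fraction = 0.5)
  expect_equal(sum(out), 40)
  expect_true(all(out[2:6, 2:9]))
  expect_false(any(out[9, ]))

  ## two equal 25 px blobs: "less than half" removes strictly smaller only
  g2 <- make_grid(12)
  g2[2:6, 2:6] <- 200         # 25 px
  g2[8:12, 8:12] <- 200       # 25 px
  out2 <- segment_bactoline(g2, matrix(TRUE, 12, 12),
                            brightest_fraction = 50 / 144)
  expect_equal(sum(out2), 50)
  expect_true(all(out2[2:6, 2:6]))
  expect_true(all(out2[8:12, 8:12]))
})

test_that("uniform intensities are tie-broken by fixed scan order", {
  g <- make_grid(8, bg = 7)
  mask <- matrix(TRUE, 8, 8)
  out <- segment_bactoline(g, mask, brightest_fraction = 0.25)
  k <- round(0.25 * 64)
  ## column-major scan order: the first k pixels of the grid
  expected <- matrix(FALSE, 8, 8)
  expected[seq_len(k)] <- TRUE
  expect_identical(out, expected)
})

test_that("segmentation is invariant to adding a constant intensity", {
  set.seed(404)
  g <- matrix(runif(144, 0, 100), 12, 12)
  mask <- matrix(TRUE, 12, 12)
  a <- segment_bactoline(g, mask, 0.2)
  b <- segment_bactoline(g + 57.3, mask, 0.2)
  expect_identical(a, b)
})

test_that("segmentation validates inputs", {
  g <- make_grid(5)
  expect_error(segment_bactoline(g, matrix(FALSE, 5, 5), 0.2), "empty")
  expect_error(segment_bactoline(g, matrix(TRUE, 4, 4), 0.2), "shape")
  expect_error(segment_bactoline(g, matrix(TRUE, 5, 5), 1.2))
})

test_that("relocation_value is the in-mask over out-of-mask intensity ratio", {
  g <- make_grid(10, bg = 50)
  droplet <- matrix(TRUE, 10, 10)
  bact <- matrix(FALSE, 10, 10)
  bact[4:5, 3:8] <- TRUE
  expect_equal(relocation_value(g, bact, droplet), 1.0)
  g[bact] <- 100
  expect_equal(relocation_value(g, bact, droplet), 2.0)
  expect_error(relocation_value(g, matrix(FALSE, 10, 10), droplet), "subset")
})

test_that("rendered droplets round-trip their configured relocation", {
  img <- render_droplet_image(2.4, geometry = list(fragment_px = 6))
  n_target <- sum(img$bactoline_mask) + 6
  frac <- n_target / sum(img$droplet_mask)
  seg <- segment_bactoline(img$fitc, img$droplet_mask, frac)
  ## the detached fragment is dropped, the bar survives
  expect_identical(seg, img$bactoline_mask)
  expect_equal(relocation_value(img$channel, seg, img$droplet_mask), 2.4,
               tolerance = 1e-12)
  ## with noise, still close
  img2 <- render_droplet_image(2.4, geometry = list(fragment_px = 6),
                               noise_sd = 0.02, seed = 5)
  seg2 <- segment_bactoline(img2$fitc, img2$droplet_mask, frac)
  expect_equal(relocation_value(img2$channel, seg2, img2$droplet_mask), 2.4,
               tolerance = 0.05)
})

test_that("feature extraction reads y_max, x_max and interiority", {
  fe <- extract_features(c(1.0, 1.5, 2.2, 1.9, 1.6), x = c(0, 15, 30, 45, 60))
  expect_equal(fe$y_max, 2.2)
  expect_equal(fe$x_max, 30)
  expect_true(fe$has_interior_max)

  mono <- extract_features(c(1, 1.2, 1.5, 1.9, 2.4), x = c(0, 15, 30, 45, 60))
  expect_false(mono$has_interior_max)

  plat <- extract_features(c(1, 2, 2, 1.5, 1), x = c(0, 15, 30, 45, 60))
  expect_equal(plat$x_max, 15)  # earliest point of a plateau
  expect_true(plat$has_interior_max)

  expect_error(extract_features(c(1, 2)), "3 points")
})

test_that("alpha matches the hand-computed concentration correction", {
  fe <- structure(list(y_max = 3, x_max = 30, has_interior_max = TRUE),
                  class = "trace_features")
  ## c(30 min, 250/s, 50 pL) = 14.945 nM -> alpha = 3 / 14.945 = 0.2007
  a <- alpha_from_features(fe, secretion_summary(250, 150), cst)
  expect_equal(a, 3 / 14.94485, tolerance = 1e-4)
  ## doubling the rate halves alpha exactly
  a2 <- alpha_from_features(fe, secretion_summary(500, 150), cst)
  expect_equal(a2, a / 2, tolerance = 1e-12)
  ## non-interior maxima are refused
  fe$has_interior_max <- FALSE
  expect_error(alpha_from_features(fe, secretion_summary(), cst), "interior")
})

one_trace <- function(y, id = 1L, cell = TRUE, igm = rep(1, length(y))) {
  tt <- c(0, 15, 30, 45, 60)
  data.frame(droplet_id = id, time_min = rep(tt, 2),
             channel = rep(c("IgG", "IgM"), each = 5),
             relocation = c(y, igm), cell_present = cell)
}

test_that("record assembly is exhaustive and exclusive over exclusion reasons", {
  map <- paper_calibration()
  r_nocell <- build_cell_record(one_trace(rep(1, 5), cell = FALSE), map = map)
  expect_equal(r_nocell$excluded_reason, "no_cell")
  expect_true(is.na(r_nocell$kd_class))

  r_flat <- build_cell_record(one_trace(rep(1, 5)), map = map)
  expect_equal(r_flat$excluded_reason, "no_increase")

  r_edge <- build_cell_record(one_trace(c(1, 1.3, 1.7, 2.0, 2.4)), map = map)
  expect_equal(r_edge$excluded_reason, "no_interior_max")
  expect_equal(r_edge$y_max, 2.4)   # features still reported

  r_ok <- build_cell_record(one_trace(c(1, 1.5, 2.2, 1.9, 1.6)), map = map)
  expect_true(is.na(r_ok$excluded_reason))
  expect_equal(r_ok$isotype, "IgG")
  expect_false(any(is.na(c(r_ok$alpha, r_ok$kd_app_nM))))
  expect_false(is.na(r_ok$kd_class) || is.na(r_ok$epitope_class))

  ## exactly one of {bins, excluded_reason} for every trace
  recs <- rbind(r_nocell, r_flat, r_edge, r_ok)
  expect_true(all(xor(is.na(recs$excluded_reason), is.na(recs$kd_class))))
})

test_that("analyze_droplets keeps one row per droplet in input order", {
  tr <- rbind(one_trace(c(1, 1.5, 2.2, 1.9, 1.6), id = 7L),
              one_trace(rep(1, 5), id = 3L, cell = FALSE))
  recs <- analyze_droplets(tr, map = paper_calibration())
  expect_equal(nrow(recs), 2)
  expect_equal(recs$droplet_id, c(7L, 3L))
  expect_equal(recs$excluded_reason, c(NA, "no_cell"))
})

test_that("K_D sensitivity to the median-rate approximation", {
  map <- paper_calibration()
  rec <- build_cell_record(one_trace(c(1, 1.5, 2.2, 1.9, 1.6)), map = map)

  ## no rate dispersion: fold exactly 1
  s0 <- sr_sensitivity(rec, secretion_summary(250, 0), cst, map)
  expect_equal(s0$fold_map, 1.0)
  expect_equal(s0$fold_linear, 1.0)

  ## 250 +/- 150: linear reading gives max single-side factor 250/100 = 2.5
  s1 <- sr_sensitivity(rec, secretion_summary(250, 150), cst, map)
  expect_equal(s1$fold_linear, 2.5)
  expect_gt(s1$fold_map, 1)
  ## map-based kd bounds bracket the point estimate
  expect_true(s1$kd_low < rec$kd_app_nM || s1$kd_high > rec$kd_app_nM)
})

test_that("secretion rates round-trip through an invertible calibration", {
  ## ascending-branch regime: peak far beyond the hour of accumulation
  p <- binding_params(kd_app_nM = 100, epitope_total_nM = 3)
  inv <- ascending_inverse(p, cst)
  tr <- trace_from_secretion(p, cst, 250)
  est <- estimate_secretion_rate(tr$x, tr$y, inv, cst)
  expect_equal(est, 250, tolerance = 0.01)

  expect_equal(estimate_secretion_rate(c(0, 15, 30, 45, 60), rep(1, 5),
                                       inv, cst), 0)
  expect_warning(
    est_neg <- estimate_secretion_rate(c(0, 15, 30), c(3, 2, 1),
                                       function(y) y, cst),
    "floored")
  expect_equal(est_neg, 0)
})
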