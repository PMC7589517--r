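# Forward equilibrium relocation model: baseline, Hook shape, capacity
# and affinity dependences, conservation.

cst <- assay_constants()

test_that("no antibody means no relocation, and the baseline is exact", {
  p <- binding_params(kd_app_nM = 1, epitope_total_nM = 3)
  expect_identical(solve_relocation(p, cst, 0), 1)
  flat <- solve_relocation(p, cst, rep(0, 5))
  expect_identical(flat, rep(1, 5))
  expect_true(all(solve_relocation(p, cst, 10^seq(-2, 4, by = 0.25)) >= 1))
})

test_that("unrelated antibodies produce negligible relocation", {
  related <- binding_params(kd_app_nM = 1, epitope_total_nM = 3)
  unrelated <- binding_params(kd_app_nM = 1e6, epitope_total_nM = 3)
  grid <- seq(0.5, 200, length.out = 80)
  y_max_rel <- max(solve_relocation(related, cst, grid))
  r_unrel <- solve_relocation(unrelated, cst, grid)
  expect_true(all(r_unrel - 1 < 0.05 * y_max_rel))
})

test_that("curves are unimodal with exactly one interior maximum (Hook)", {
  set.seed(101)
  for (i in 1:40) {
    p <- binding_params(kd_app_nM = 10^runif(1, -0.5, 2.3),
                        epitope_total_nM = runif(1, 0.5, 12))
    grid <- 10^seq(-1, 4, length.out = 250)
    y <- solve_relocation(p, cst, grid)
    expect_equal(n_interior_maxima(y), 1L)
    i_max <- which.max(y)
    expect_gt(i_max, 1)
    expect_lt(i_max, length(grid))
  }
})

test_that("y_max increases with epitope capacity, pointwise on the ascent", {
  grid <- 10^seq(-1, 3, length.out = 300)
  lo <- titration_curve(binding_params(1.5, 2), cst, grid)
  hi <- titration_curve(binding_params(1.5, 6), cst, grid)
  i_lo_peak <- which.max(lo$y)
  expect_true(all(hi$y[1:i_lo_peak] >= lo$y[1:i_lo_peak]))
  expect_gt(max(hi$y), max(lo$y))
  ## strict monotonicity of y_max over a capacity ladder
  ymaxes <- vapply(c(0.5, 1, 2, 4, 8), function(E) {
    max(solve_relocation(binding_params(1.5, E), cst, grid))
  }, 0)
  expect_true(all(diff(ymaxes) > 0))
})

test_that("y_max is insensitive to affinity; x_max shifts right with kd", {
  grid <- 10^seq(-1.5, 3, length.out = 1200)
  E <- 10
  kds <- 10^seq(log10(E / 50), log10(2 * E), length.out = 9)
  feats <- vapply(kds, function(kd) {
    y <- solve_relocation(binding_params(kd, E), cst, grid)
    i <- which.max(y)
    c(y[i], grid[i])
  }, c(0, 0))
  ymax <- feats[1, ]
  xmax <- feats[2, ]
  ref <- ymax[which.min(abs(kds - 1))]
  expect_lt(max(abs(ymax - ref) / ref), 0.10)
  expect_true(all(diff(xmax) >= 0))
})

test_that("x_max shifts right with kd while max height is conserved (kd 0.2 vs 24)", {
  grid <- 10^seq(-1.5, 3, length.out = 1500)
  f <- function(kd) {
    y <- solve_relocation(binding_params(kd, 10), cst, grid)
    i <- which.max(y)
    c(ymax = y[i], xmax = grid[i])
  }
  a <- f(0.2); b <- f(24)
  expect_gt(b["xmax"], a["xmax"])
  expect_lt(abs(b["ymax"] - a["ymax"]) / a["ymax"], 0.10)
})

test_that("mass is conserved at every solution (vs fixed-point oracle)", {
  set.seed(202)
  for (i in 1:200) {
    A <- 10^runif(1, -1, 3)
    E <- 10^runif(1, -0.5, 1.5)
    kd_app <- 10^runif(1, -1, 2.5)
    p <- binding_params(kd_app, E)
    kd_surf <- kd_app / p$avidity
    AE <- bactoline:::.bound_complex(A, E, kd_surf)
    PA <- bactoline:::.bound_complex(cst$probe_total_nM, A, p$kd_detect_nM)
    ## closed form vs independent iteration
    expect_equal(AE, fixed_point_complex(A, E, kd_surf), tolerance = 1e-9)
    expect_equal(PA, fixed_point_complex(cst$probe_total_nM, A,
                                         p$kd_detect_nM), tolerance = 1e-9)
    ## conservation: free + bound recover each total
    free_A <- A - AE
    free_E <- E - AE
    expect_equal((free_A + AE) / A, 1, tolerance = 1e-9)
    expect_equal((free_E + AE) / E, 1, tolerance = 1e-9)
    expect_equal(free_A * free_E / AE, kd_surf, tolerance = 1e-6)
    free_P <- cst$probe_total_nM - PA
    expect_equal((free_P + PA) / cst$probe_total_nM, 1, tolerance = 1e-9)
  }
})

test_that("titration_curve validates its grid and propagates the model", {
  p <- binding_params(1.5, 3)
  expect_error(titration_curve(p, cst, c(1, 1, 2)), "increasing")
  cv <- titration_curve(p, cst, c(0.1, 1, 10, 100))
  expect_s3_class(cv, "relocation_curve")
  expect_equal(cv$y, solve_relocation(p, cst, c(0.1, 1, 10, 100)))
})

test_that("secreted concentration accumulates linearly (hand calculation)", {
  ## 250 molecules/s for 60 min in 50 pL:
  ## 250 * 3600 / (6.02214076e23 * 50e-12 L) = 29.89 nM
  expect_equal(secretion_to_concentration(250, 60, cst), 29.8897,
               tolerance = 1e-4)
  expect_equal(secretion_to_concentration(250, 30, cst),
               secretion_to_concentration(250, 60, cst) / 2)
})

test_that("a non-secreting cell gives a flat trace at baseline", {
  p <- binding_params(1.5, 3)
  tr <- trace_from_secretion(p, cst, 0)
  expect_equal(attr(tr, "x_kind"), "time")
  expect_identical(tr$y, rep(1, length(cst$imaging_times_min)))
})

test_that("parameter validation rejects non-positive inputs", {
  expect_error(binding_params(-1, 3), "positive")
  expect_error(binding_params(1, 0), "positive")
  expect_error(binding_params(1, 1, gain = 0.5), "gain")
  expect_error(assay_constants(droplet_volume_pL = 0))
  expect_error(assay_constants(imaging_times_min = c(5, 10)), "start at 0")
  p <- binding_params(1, 1)
  expect_error(solve_relocation(p, cst, -1), "0")
})
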