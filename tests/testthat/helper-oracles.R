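# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

## 1:1 equilibrium with depletion by damped fixed-point iteration on the
## free concentrations (independent of the closed quadratic form)
fixed_point_complex <- function(a_tot, b_tot, kd, tol = 1e-14,
                                max_iter = 10000) {
  fa <- a_tot
  fb <- b_tot
  for (i in seq_len(max_iter)) {
    fa_new <- a_tot / (1 + fb / kd)
    fb_new <- b_tot / (1 + fa_new / kd)
    if (abs(fa_new - fa) < tol * a_tot && abs(fb_new - fb) < tol * b_tot) {
      fa <- fa_new; fb <- fb_new
      break
    }
    fa <- fa_new; fb <- fb_new
  }
  fa * fb / kd
}

## closed-form OLS slope
ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

## textbook pooled-variance Student's t with p through the incomplete
## beta function (not through pt / t.test)
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  p <- pbeta(df / (df + t^2), df / 2, 0.5)
  list(t = t, df = df, p = p)
}

## counts tolerant interior maxima of a sampled curve: sign changes of
## the first difference, ignoring numerically flat steps
n_interior_maxima <- function(y, rel_tol = 1e-9) {
  d <- diff(y)
  scale <- max(abs(y - 1), 1e-12)
  s <- sign(d)
  s[abs(d) < rel_tol * scale] <- 0
  s <- s[s != 0]
  if (length(s) == 0) return(0L)
  sum(s[-length(s)] == 1 & s[-1] == -1) +
    as.integer(s[1] == -1) * 0L
}

## numeric inverse of the ascending branch of a relocation curve
ascending_inverse <- function(params, constants, c_max = 40) {
  cc <- seq(0, c_max, length.out = 2000)
  rr <- solve_relocation(params, constants, cc)
  i_peak <- which.max(rr)
  approxfun(rr[1:i_peak], cc[1:i_peak], rule = 2)
}
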