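#' Fanger predicted mean vote (PMV)
#'
#' Steady-state whole-body thermal-sensation index on the -3..+3 scale,
#' computed with the ISO 7730 formulation: clothing-surface temperature
#' solved by damped fixed-point iteration, convective coefficient
#' `h_c = max(2.38 * |t_cl - t_a|^0.25, 12.1 * sqrt(v))`, water-vapour
#' pressure from relative humidity via the standard saturation exponential.
#' Note the whole-body clothing area factor used here (two-branch ISO form,
#' `1 + 1.29*I_cl` below 0.078 m2.K/W else `1.05 + 0.645*I_cl`) is distinct
#' from the regional factor of [fcl_from_local()]; the two must not be
#' conflated.
#'
#' @param t_op Operative temperature, degC; air and mean radiant temperature
#'   are both set to this value.
#' @param v Air speed, m/s (>= 0).
#' @param rh Relative humidity, % (0–100).
#' @param met Metabolic rate, met (> 0).
#' @param clo Overall clothing insulation, clo (>= 0).
#' @param external_work External work, met (default 0).
#' @param tol Convergence tolerance on the clothing-surface temperature,
#'   degC.
#' @param max_iter Iteration cap; non-convergence raises an error with
#'   diagnostics.
#' @return PMV (unitless scalar; vectorized over `t_op`).
#' @export
#' @examples
#' pmv(26, v = 0.1, rh = 50, met = 1, clo = 0.3)
pmv <- function(t_op, v, rh, met, clo, external_work = 0,
                tol = 1e-4, max_iter = 300L) {
  if (!is.numeric(v) || v < 0) stop("v must be >= 0", call. = FALSE)
  if (rh < 0 || rh > 100) stop("rh must be in [0, 100]", call. = FALSE)
  if (met <= 0) stop("met must be > 0", call. = FALSE)
  check_insulation(clo)
  vapply(t_op, pmv_one, numeric(1), v = v, rh = rh, met = met, clo = clo,
         wme = external_work, tol = tol, max_iter = max_iter)
}

pmv_one <- function(ta, v, rh, met, clo, wme, tol, max_iter) {
  tr <- ta # operative temperature: air = mean radiant
  icl <- 0.155 * clo
  m <- met * 58.15
  w <- wme * 58.15
  mw <- m - w
  fcl <- if (icl <= 0.078) 1 + 1.29 * icl else 1.05 + 0.645 * icl
  pa <- rh * 10 * exp(16.6536 - 4030.183 / (ta + 235)) # Pa
  hcf <- 12.1 * sqrt(v)
  taa <- ta + 273
  tra <- tr + 273
  tcla <- taa + (35.5 - ta) / (3.5 * icl + 0.1) # initial guess
  p1 <- icl * fcl
  p2 <- p1 * 3.96
  p3 <- p1 * 100
  p4 <- p1 * taa
  p5 <- 308.7 - 0.028 * mw + p2 * (tra / 100)^4
  xn <- tcla / 100
  xf <- tcla / 50
  n <- 0L
  hc <- hcf
  # damped fixed point on t_cl/100; tol is in degC on t_cl
  while (abs(100 * (xn - xf)) > tol) {
    xf <- (xf + xn) / 2
    hcn <- 2.38 * abs(100 * xf - taa)^0.25
    hc <- max(hcf, hcn)
    xn <- (p5 + p4 * hc - p2 * xf^4) / (100 + p3 * hc)
    n <- n + 1L
    if (n > max_iter) {
      stop(sprintf(paste0("clothing-surface temperature iteration failed to ",
                          "converge after %d iterations (t_op=%.2f, clo=%.2f, ",
                          "last delta=%.3g degC)"),
                   max_iter, ta, clo, abs(100 * (xn - xf))), call. = FALSE)
    }
  }
  tcl <- 100 * xn - 273
  hl1 <- 3.05e-3 * (5733 - 6.99 * mw - pa)        # skin diffusion
  hl2 <- if (mw > 58.15) 0.42 * (mw - 58.15) else 0 # sweating
  hl3 <- 1.7e-5 * m * (5867 - pa)                  # latent respiration
  hl4 <- 0.0014 * m * (34 - ta)                    # dry respiration
  hl5 <- 3.96 * fcl * (xn^4 - (tra / 100)^4)       # radiation
  hl6 <- fcl * hc * (tcl - ta)                     # convection
  ts <- 0.303 * exp(-0.036 * m) + 0.028
  ts * (mw - hl1 - hl2 - hl3 - hl4 - hl5 - hl6)
}

#' Neutral operative-temperature band
#'
#' Solves the PMV model for the operative temperatures at which PMV equals
#' -0.5 and +0.5 — the band over which the environment is thermally neutral.
#' A bracketing root-finder on [`bracket[1]`, `bracket[2]`] degC is used with
#' a 0.005 degC temperature tolerance; PMV must change sign over the bracket.
#'
#' @inheritParams pmv
#' @param bracket Search interval for the operative temperature, degC. The
#'   default is deliberately wide: heavy clothing combined with high activity
#'   pushes the band's lower endpoint below 10 degC.
#' @return An object of class `neutral_band`: list with `t_lower`, `t_upper`
#'   (degC) and the inputs.
#' @export
#' @examples
#' neutral_band(v = 0.1, rh = 50, met = 1, clo = 0.3) # ~ (25.99, 28.31)
neutral_band <- function(v, rh, met, clo, external_work = 0,
                         bracket = c(0, 45)) {
  f <- function(t, target) pmv(t, v, rh, met, clo, external_work) - target
  solve_one <- function(target) {
    flo <- f(bracket[1L], target)
    fhi <- f(bracket[2L], target)
    if (sign(flo) == sign(fhi)) {
      stop(sprintf("PMV = %+.1f has no root in the bracket [%g, %g] degC",
                   target, bracket[1L], bracket[2L]), call. = FALSE)
    }
    stats::uniroot(f, bracket, target = target, tol = 0.005)$root
  }
  band <- structure(
    list(t_lower = solve_one(-0.5), t_upper = solve_one(0.5),
         v = v, rh = rh, met = met, clo = clo),
    class = "neutral_band")
  stopifnot(band$t_lower < band$t_upper)
  band
}

#' @export
print.neutral_band <- function(x, ...) {
  cat(sprintf(
    "Neutral operative-temperature band (|PMV| <= 0.5)\n  %.2f to %.2f degC  (v=%.2f m/s, rh=%.0f%%, %.2g met, %.2g clo)\n",
    x$t_lower, x$t_upper, x$v, x$rh, x$met, x$clo))
  invisible(x)
}
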