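# Fixed points, stability and invasion analysis of the one-dimensional
# prevalence map. The fixed-point condition step(p) = p is cleared of its
# denominator to a quintic polynomial in p (p = 0 always factors out),
# solved with polyroot(), and backed by a bisection scan in case the
# polynomial route is ill-conditioned.

polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  out
}

# ascending coefficients of N(p), D(p) with k = N/D
recursion_polys <- function(params) {
  a <- (1 - params$mu) * params$F_rel
  d1 <- -(params$s_f + params$s_h)
  d2 <- params$s_h * (1 - params$mu * (1 - params$s_f))
  list(N = c(0, a), D = c(1, d1, d2))
}

polyadd <- function(a, b) {
  n <- max(length(a), length(b))
  c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
}

# step(p) = p  <=>  N*D + w*N*(D - N) - p*D^2 = 0 (after clearing D^2)
fixed_point_poly <- function(params) {
  pp <- recursion_polys(params)
  w <- params$w
  g <- polyadd(
    polyadd(polymul(pp$N, pp$D),
            w * polymul(pp$N, polyadd(pp$D, -pp$N))),
    -polymul(c(0, 1), polymul(pp$D, pp$D)))
  # p = 0 is always a root: drop the (zero) constant term
  stopifnot(abs(g[1]) < 1e-12)
  g[-1]
}

is_degenerate_map <- function(params) {
  params$mu == 0 && params$s_f == 0 && params$s_h == 0 && params$w == 0
}

#' Derivative-based stability classification of a fixed point
#'
#' Evaluates the derivative of the one-generation map at `p_star` by central
#' finite differences (one-sided at the boundaries of `[0, 1]`) and
#' classifies the point as stable (`|derivative| < 1`), unstable
#' (`|derivative| > 1`) or neutral (`|derivative| = 1` within
#' `neutral_tol`).
#'
#' @param p_star Candidate fixed point in `[0, 1]`.
#' @param params A [model_params()] object.
#' @param h Finite-difference step (default `1e-6`).
#' @param fp_tol `p_star` must satisfy `|step(p_star) - p_star| < fp_tol`.
#' @param neutral_tol Half-width of the neutral band around `|derivative| = 1`.
#' @return A one-row data frame with columns `p_star`, `derivative`,
#'   `stability`.
#' @export
stability_of <- function(p_star, params, h = 1e-6, fp_tol = 1e-8,
                         neutral_tol = 1e-6) {
  params <- as_wolb_params(params)
  check_prevalence(p_star, "p_star")
  if (abs(wolb_step(p_star, params) - p_star) > fp_tol)
    stop(sprintf("p = %g is not a fixed point (residual %.3g)", p_star,
                 abs(wolb_step(p_star, params) - p_star)), call. = FALSE)
  lo <- max(0, p_star - h)
  hi <- min(1, p_star + h)
  deriv <- (wolb_step(hi, params) - wolb_step(lo, params)) / (hi - lo)
  stability <- if (abs(abs(deriv) - 1) <= neutral_tol) "neutral"
  else if (abs(deriv) < 1) "stable"
  else "unstable"
  data.frame(p_star = p_star, derivative = deriv, stability = stability,
             stringsAsFactors = FALSE)
}

#' All fixed points of the prevalence recursion in [0, 1]
#'
#' Solves `step(p) = p` by clearing the denominator to a polynomial and
#' taking its real roots in `[0, 1]` (always including the absorbing state
#' `p = 0`), then classifies each root with [stability_of()]. A bisection
#' scan over a fine grid backs the polynomial route up; roots closer than
#' `merge_tol` are merged. The degenerate identity map (`mu = 0`, `F = 1`,
#' `H = 1`, `w = 0`), for which every prevalence is fixed, is flagged rather
#' than enumerated.
#'
#' @param params A [model_params()] object.
#' @param merge_tol Roots closer than this are merged (default `1e-8`).
#' @param residual_tol Retained roots must satisfy
#'   `|step(p) - p| < residual_tol` after Newton polishing.
#' @return A data frame of class `wolb_fixed_points` with columns `p_star`,
#'   `derivative`, `stability` (one of `stable`, `unstable`, `neutral`,
#'   `degenerate`), ordered by `p_star`. Attribute `degenerate` marks the
#'   identity map.
#' @examples
#' fixed_points(model_params(mu = 0.03, H = 0.1))
#' @export
fixed_points <- function(params, merge_tol = 1e-8, residual_tol = 1e-10) {
  params <- as_wolb_params(params)
  if (is_degenerate_map(params)) {
    out <- data.frame(p_star = 0, derivative = 1, stability = "degenerate",
                      stringsAsFactors = FALSE)
    class(out) <- c("wolb_fixed_points", "data.frame")
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  g <- function(p) wolb_step(p, params) - p

  coef <- fixed_point_poly(params)
  nz <- which(abs(coef) > 1e-14)
  coef <- if (length(nz)) coef[seq_len(max(nz))] else numeric(0)
  roots <- numeric(0)
  if (length(coef) >= 2) {
    z <- polyroot(coef)
    roots <- Re(z)[abs(Im(z)) < 1e-8]
    roots <- roots[roots > -1e-10 & roots < 1 + 1e-10]
    roots <- pmin(pmax(roots, 0), 1)
  }
  # fallback / cross-check: sign changes of g on a fine grid
  grid <- seq(0, 1, length.out = 1e4 + 1)
  gv <- vapply(grid, g, numeric(1))
  sgn <- which(gv[-1] * gv[-length(gv)] < 0)
  for (i in sgn)
    roots <- c(roots, stats::uniroot(g, c(grid[i], grid[i + 1]),
                                     tol = 1e-14)$root)
  roots <- c(0, roots)
  # Newton polish with numeric derivative, then filter on residual
  for (j in seq_along(roots)) {
    p <- roots[j]
    for (it in 1:8) {
      h <- 1e-7
      dg <- (g(min(1, p + h)) - g(max(0, p - h))) / (min(1, p + h) - max(0, p - h))
      if (!is.finite(dg) || abs(dg) < 1e-12) break
      p_new <- min(1, max(0, p - g(p) / dg))
      if (abs(p_new - p) < 1e-15) { p <- p_new; break }
      p <- p_new
    }
    roots[j] <- p
  }
  roots <- roots[abs(vapply(roots, g, numeric(1))) < residual_tol]
  roots <- sort(unique(c(0, roots)))
  keep <- c(TRUE, diff(roots) > merge_tol)
  roots <- roots[keep]
  out <- do.call(rbind, lapply(roots, stability_of, params = params,
                               fp_tol = residual_tol * 10))
  class(out) <- c("wolb_fixed_points", "data.frame")
  attr(out, "degenerate") <- FALSE
  out
}

#' Invasion growth factor of a rare infection
#'
#' Linearising the recursion at `p = 0` gives the per-generation growth
#' factor of a rare infection,
#' \deqn{\lambda = (1 + w)(1 - \mu)F,}
#' independent of `H` (incompatibility acts only at second order in `p`).
#' The infection invades from rare iff `lambda > 1`.
#'
#' @param params A [model_params()] object.
#' @return The scalar growth factor `lambda`.
#' @examples
#' invasion_growth_factor(model_params(mu = 0.03, w = 0.06))  # 1.0282
#' @export
invasion_growth_factor <- function(params) {
  params <- as_wolb_params(params)
  (1 + params$w) * (1 - params$mu) * params$F_rel
}

#' Cytoplasmic-incompatibility invasion threshold (no horizontal transmission)
#'
#' With `w = 0` and CI present (`s_h > 0`), cancelling `p` in the
#' fixed-point condition `k(p) = p` leaves the quadratic
#' \deqn{s_h\,[1 - \mu(1-s_f)]\,p^2 - (s_f + s_h)\,p +
#'       1 - (1-\mu)(1-s_f) = 0,}
#' whose smaller root in `[0, 1)` is the unstable interior equilibrium: the
#' prevalence a CI strain must exceed to invade. Returns `NA` when no such
#' root exists. With perfect maternal transmission and no fecundity cost the
#' constant term vanishes and the threshold is 0 (invasion from any
#' frequency).
#'
#' @param params A [model_params()] object with `w = 0` and `H < 1`.
#' @return The threshold prevalence, `0`, or `NA_real_`.
#' @examples
#' ci_threshold(model_params(mu = 0.03, H = 0.1))  # ~0.0345
#' @export
ci_threshold <- function(params) {
  params <- as_wolb_params(params)
  if (params$w != 0)
    stop("ci_threshold requires w = 0; use fixed_points() for w > 0",
         call. = FALSE)
  if (params$s_h <= 0)
    stop("ci_threshold requires cytoplasmic incompatibility (H < 1)",
         call. = FALSE)
  a <- params$s_h * (1 - params$mu * (1 - params$s_f))
  b <- -(params$s_f + params$s_h)
  cc <- 1 - (1 - params$mu) * (1 - params$s_f)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(NA_real_)
  root <- (-b - sqrt(disc)) / (2 * a)
  if (root < 0 || root >= 1) return(NA_real_)
  root
}

#' Sweep equilibria over a grid of horizontal-transmission rates
#'
#' Convenience wrapper for bifurcation-style summaries: runs
#' [fixed_points()] over a grid of `w` and stacks the results.
#'
#' @param mu,F_rel,H Fixed recursion parameters.
#' @param w_grid Values of the horizontal transmission rate to sweep.
#' @return A data frame with columns `mu`, `F`, `H`, `w`, `p_star`,
#'   `stability`.
#' @export
equilibrium_sweep <- function(mu = 0.03, F_rel = 1, H = 1,
                              w_grid = seq(0, 0.1, by = 0.005)) {
  do.call(rbind, lapply(w_grid, function(wi) {
    fp <- fixed_points(model_params(mu = mu, F_rel = F_rel, H = H, w = wi))
    data.frame(mu = mu, F = F_rel, H = H, w = wi,
               p_star = fp$p_star, stability = fp$stability,
               stringsAsFactors = FALSE)
  }))
}
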