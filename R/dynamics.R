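#' One generation of vertical (maternal) transmission
#'
#' Maps adult prevalence `p` to the offspring prevalence `k` expected under
#' imperfect maternal transmission (`mu`), relative fecundity of infected
#' females (`F`) and cytoplasmic incompatibility (relative hatch `H` in
#' incompatible crosses), in a randomly mating population with discrete
#' generations:
#'
#' \deqn{k = \frac{p (1-\mu)(1-s_f)}{1 - s_f p - s_h p (1-p) -
#'           \mu s_h p^2 (1-s_f)}}
#'
#' with `s_f = 1 - F`, `s_h = 1 - H`.
#'
#' @param p Adult prevalence (proportion infected) in `[0, 1]`.
#' @param params A [model_params()] object.
#' @return Offspring prevalence `k` in `[0, 1]`; `k = 0` iff `p = 0`.
#' @examples
#' vertical_step(0.5, model_params(mu = 0.03))  # 0.485
#' @export
vertical_step <- function(p, params) {
  params <- as_wolb_params(params)
  check_prevalence(p)
  num <- p * (1 - params$mu) * (1 - params$s_f)
  den <- 1 - params$s_f * p - params$s_h * p * (1 - p) -
    params$mu * params$s_h * p^2 * (1 - params$s_f)
  if (any(den <= 0))
    stop(sprintf(
      "non-positive denominator in vertical step (mu=%g, F=%g, H=%g, p=%g)",
      params$mu, params$F_rel, params$H, p[which(den <= 0)[1]]),
      call. = FALSE)
  k <- num / den
  pmin(pmax(k, 0), 1)
}

#' One horizontal-transmission step
#'
#' Adds vector-borne ("dirty needle") horizontal transmission to an
#' offspring prevalence `k`: each infected host generates `w` new cases
#' among the remaining uninfected fraction, so
#' \deqn{p_{t+1} = k + w\,k(1-k).}
#' Values that would exceed 1 (possible only for large `w`) are clipped to 1
#' with a warning.
#'
#' @param k Prevalence after vertical transmission, in `[0, 1]`.
#' @inheritParams vertical_step
#' @return The next-generation prevalence; always `>= k`.
#' @examples
#' horizontal_step(0.5, model_params(w = 0.06))  # 0.515
#' @export
horizontal_step <- function(k, params) {
  params <- as_wolb_params(params)
  check_prevalence(k, "k")
  p_next <- k + params$w * k * (1 - k)
  if (any(p_next > 1)) {
    warning("horizontal transmission pushed prevalence above 1; clipped",
            call. = FALSE)
    p_next <- pmin(p_next, 1)
  }
  p_next
}

#' One full generation of the prevalence recursion
#'
#' Composition of [vertical_step()] followed by [horizontal_step()].
#'
#' @inheritParams vertical_step
#' @return Prevalence at the next generation.
#' @export
wolb_step <- function(p, params) {
  params <- as_wolb_params(params)
  horizontal_step(vertical_step(p, params), params)
}

#' Deterministic prevalence trajectory
#'
#' Iterates [wolb_step()] from a starting prevalence. Purely deterministic.
#'
#' @param p0 Starting prevalence in `[0, 1]`.
#' @param params A [model_params()] object.
#' @param generations Number of generations to iterate (`>= 0`).
#' @return An object of class `wolb_trajectory`: a list with `params`,
#'   `generations`, and `p`, the prevalence sequence of length
#'   `generations + 1` (including `p0`). `as.data.frame()` yields columns
#'   `generation` and `prevalence`.
#' @examples
#' tr <- simulate_trajectory(0.01, model_params(mu = 0.03, w = 0.06), 200)
#' tail(tr$p, 1)
#' @export
simulate_trajectory <- function(p0, params, generations) {
  params <- as_wolb_params(params)
  check_prevalence(p0, "p0")
  if (!is.numeric(generations) || length(generations) != 1L ||
      generations < 0 || generations != round(generations))
    stop("'generations' must be a non-negative integer", call. = FALSE)
  p <- numeric(generations + 1)
  p[1] <- p0
  if (generations > 0)
    for (t in seq_len(generations)) p[t + 1] <- wolb_step(p[t], params)
  structure(
    list(params = params, generations = generations, p = p),
    class = "wolb_trajectory"
  )
}

#' @export
as.data.frame.wolb_trajectory <- function(x, ...) {
  data.frame(generation = seq_along(x$p) - 1L, prevalence = x$p)
}

#' @export
print.wolb_trajectory <- function(x, ...) {
  cat(sprintf(
    "Prevalence trajectory: %d generations, p0 = %.4g, final p = %.6g\n",
    x$generations, x$p[1], x$p[length(x$p)]))
  print(x$params)
  invisible(x)
}

#' Standard horizontal-transmission scenarios
#'
#' Runs the three canonical scenarios contrasting no (`w = 0`), low
#' (`w = 0.01`) and moderate (`w = 0.06`) horizontal transmission, each from
#' starting prevalence 0.01 with imperfect maternal transmission
#' `mu = 0.03`:
#' \describe{
#'   \item{`"A"`}{neutral symbiont: no fitness effect, no reproductive
#'     manipulation (`H = 1`, `F = 1`);}
#'   \item{`"B"`}{cytoplasmic incompatibility (`H = 0.1`, `F = 1`);}
#'   \item{`"C"`}{host fitness benefit (`H = 1`, `F = 1.05`).}
#' }
#'
#' @param panel One of `"A"`, `"B"`, `"C"`.
#' @param generations Number of generations to iterate; default 1000.
#' @param w Horizontal transmission rates to contrast.
#' @param p0,mu Shared starting prevalence and maternal transmission
#'   failure rate.
#' @return A named list of `wolb_trajectory` objects, one per value of `w`
#'   (names `"w=0"` etc.).
#' @examples
#' sc <- scenario_trajectories("A", generations = 100)
#' sapply(sc, function(tr) tail(tr$p, 1))
#' @export
scenario_trajectories <- function(panel = c("A", "B", "C"),
                                  generations = 1000,
                                  w = c(0, 0.01, 0.06),
                                  p0 = 0.01, mu = 0.03) {
  panel <- match.arg(panel)
  HF <- switch(panel,
               A = c(H = 1,   F_rel = 1),
               B = c(H = 0.1, F_rel = 1),
               C = c(H = 1,   F_rel = 1.05))
  out <- lapply(w, function(wi) {
    simulate_trajectory(
      p0,
      model_params(mu = mu, F_rel = HF[["F_rel"]], H = HF[["H"]], w = wi),
      generations)
  })
  names(out) <- paste0("w=", w)
  out
}

#' Classify the long-run fate of a trajectory
#'
#' A trajectory is `"lost"` when its final prevalence falls below
#' `loss_tol`, `"converged"` when the last two iterates differ by less than
#' `conv_tol`, otherwise `"transient"`.
#'
#' @param trajectory A `wolb_trajectory`.
#' @param conv_tol Absolute difference between successive iterates taken as
#'   convergence (default `1e-10`).
#' @param loss_tol Prevalence below which the infection is declared lost
#'   (default `1e-6`).
#' @return A list with `fate` and `p_final`.
#' @export
trajectory_fate <- function(trajectory, conv_tol = 1e-10, loss_tol = 1e-6) {
  stopifnot(inherits(trajectory, "wolb_trajectory"))
  p <- trajectory$p
  n <- length(p)
  p_final <- p[n]
  fate <- if (p_final < loss_tol) "lost"
  else if (n >= 2 && abs(p[n] - p[n - 1]) < conv_tol) "converged"
  else "transient"
  list(fate = fate, p_final = p_final)
}
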