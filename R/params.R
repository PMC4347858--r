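#' Parameters of the discrete-generation prevalence recursion
#'
#' Bundles the four parameters governing symbiont dynamics in the host
#' population. Selection coefficients `s_f = 1 - F` and `s_h = 1 - H` are
#' derived on construction and kept consistent with `F` and `H`; they are
#' never stored independently.
#'
#' @param mu Fraction of uninfected ova produced by infected mothers
#'   (imperfect maternal transmission), in `[0, 1)`.
#' @param F_rel Fecundity of infected females relative to uninfected females
#'   (`F`); must be positive. Values above 1 mean the symbiont is beneficial
#'   (negative `s_f`).
#' @param H Relative hatch rate of incompatible crosses (infected male x
#'   uninfected female), in `[0, 1]`. `H = 1` means no cytoplasmic
#'   incompatibility; smaller `H` means stronger CI.
#' @param w Number of new infections generated per generation by horizontal
#'   transmission from a single infected host in an otherwise uninfected
#'   population, discounted by any reduction in vertical transmission among
#'   newly infected hosts. Non-negative.
#'
#' @return An object of class `wolb_params`: a list with elements `mu`,
#'   `F_rel`, `H`, `w`, `s_f`, `s_h`.
#' @examples
#' model_params(mu = 0.03, F_rel = 1, H = 0.1, w = 0.06)
#' @export
model_params <- function(mu = 0, F_rel = 1, H = 1, w = 0) {
  for (nm in c("mu", "F_rel", "H", "w")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (mu < 0 || mu >= 1)
    stop("'mu' must satisfy 0 <= mu < 1", call. = FALSE)
  if (F_rel <= 0)
    stop("'F_rel' must be > 0", call. = FALSE)
  if (H < 0 || H > 1)
    stop("'H' must lie in [0, 1]", call. = FALSE)
  if (w < 0)
    stop("'w' must be >= 0", call. = FALSE)
  structure(
    list(mu = mu, F_rel = F_rel, H = H, w = w,
         s_f = 1 - F_rel, s_h = 1 - H),
    class = "wolb_params"
  )
}

#' @export
print.wolb_params <- function(x, ...) {
  cat("Wolbachia dynamics parameters\n")
  cat(sprintf("  mu (imperfect maternal transmission): %.4g\n", x$mu))
  cat(sprintf("  F  (relative fecundity of infected):  %.4g  (s_f = %.4g)\n",
              x$F_rel, x$s_f))
  cat(sprintf("  H  (relative hatch, incompatible):    %.4g  (s_h = %.4g)\n",
              x$H, x$s_h))
  cat(sprintf("  w  (horizontal transmission rate):    %.4g\n", x$w))
  invisible(x)
}

as_wolb_params <- function(params) {
  if (inherits(params, "wolb_params")) return(params)
  if (is.list(params))
    return(do.call(model_params,
                   params[intersect(names(params),
                                    c("mu", "F_rel", "H", "w"))]))
  stop("'params' must be a wolb_params object or a named list", call. = FALSE)
}

check_prevalence <- function(p, what = "p") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop("'", what, "' must be a prevalence in [0, 1]", call. = FALSE)
  invisible(p)
}
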