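#' Parameters of the stochastic wasp-vector simulation
#'
#' The mechanistic counterpart of the aggregate horizontal-transmission rate
#' `w`: a parasitoid wasp probes whitefly nymphs, its mouthparts and
#' ovipositor pick the symbiont up from infected hosts, and the
#' contamination can infect the next uninfected host probed ("dirty
#' needle").
#'
#' @param n_hosts Number of hosts per generation (`>= 2`).
#' @param visit_prob Probability `v` that a given host is probed by the
#'   vector in a generation.
#' @param infect_prob Probability `tau` that a contaminated vector infects
#'   the uninfected host it probes.
#' @param survive_prob Probability `sigma` that a probed host survives to
#'   reproduce.
#' @param infectious_visits Number of subsequent probes for which the
#'   contamination persists; the default 1 is the next-visit-only ("dirty
#'   needle") assumption. Larger values model longer-lived contamination.
#' @param kill_hosts If `FALSE` (default) the vector never kills its host
#'   and `sigma` discounts the infection probability (an infection only
#'   matters if the host survives to reproduce). If `TRUE`, probed hosts
#'   die with probability `1 - sigma` and are removed before reproduction.
#' @return An object of class `wolb_vector_params`.
#' @export
vector_params <- function(n_hosts = 1e4, visit_prob = 0.3,
                          infect_prob = 0.938, survive_prob = 0.302,
                          infectious_visits = 1, kill_hosts = FALSE) {
  stopifnot(is.numeric(n_hosts), length(n_hosts) == 1L, n_hosts >= 2,
            n_hosts == round(n_hosts))
  for (nm in c("visit_prob", "infect_prob", "survive_prob")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop("'", nm, "' must be a probability in [0, 1]", call. = FALSE)
  }
  stopifnot(infectious_visits >= 1,
            infectious_visits == round(infectious_visits),
            is.logical(kill_hosts), length(kill_hosts) == 1L)
  structure(
    list(n_hosts = as.integer(n_hosts), visit_prob = visit_prob,
         infect_prob = infect_prob, survive_prob = survive_prob,
         infectious_visits = as.integer(infectious_visits),
         kill_hosts = kill_hosts),
    class = "wolb_vector_params"
  )
}

# One transmission phase: the vector probes each host independently with
# probability v, in random order; probing an infected host (re)contaminates
# it for `infectious_visits` subsequent probes; a contaminated probe of an
# uninfected host establishes an infection (tau, discounted by sigma in
# no-kill mode). Each host is probed at most once, so infections created
# during the phase never feed back into it. Returns the updated status
# vector and, in kill mode, which hosts died.
transmission_phase <- function(status, vp) {
  n <- length(status)
  visited <- which(stats::runif(n) < vp$visit_prob)
  dead <- logical(n)
  if (length(visited) >= 2 && vp$infectious_visits == 1L &&
      !vp$kill_hosts) {
    # next-visit-only, no host death: an infection opportunity is exactly an
    # uninfected visit immediately preceded by an infected one, so the walk
    # vectorises (each host is probed at most once; no feedback within the
    # phase). Draw-for-draw identical to the sequential walk below.
    order <- sample(visited)
    s <- status[order]
    opp <- which(!s & c(FALSE, s[-length(s)]))
    if (length(opp)) {
      hit <- stats::runif(length(opp)) <
        vp$infect_prob * vp$survive_prob
      status[order[opp[hit]]] <- TRUE
    }
    return(list(status = status, dead = dead))
  }
  if (length(visited) >= 1) {
    order <- sample(visited)
    contam <- 0L
    for (host in order) {
      if (vp$kill_hosts && stats::runif(1) > vp$survive_prob)
        dead[host] <- TRUE
      if (status[host]) {
        contam <- vp$infectious_visits
      } else {
        if (contam > 0L) {
          p_inf <- if (vp$kill_hosts) vp$infect_prob
          else vp$infect_prob * vp$survive_prob
          if (!dead[host] && stats::runif(1) < p_inf) status[host] <- TRUE
        }
        contam <- max(0L, contam - 1L)
      }
    }
  }
  list(status = status, dead = dead)
}

#' Individual-based simulation of vector-borne symbiont spread
#'
#' Each generation consists of (a) reproduction — the number of infected
#' offspring is drawn `Binomial(n_hosts, k)` around the deterministic
#' vertical-transmission expectation `k` given by [vertical_step()] — and
#' (b) a transmission phase in which a wasp probes hosts at random and
#' carries the symbiont from infected to uninfected individuals. The census
#' (recorded prevalence) is taken at the adult stage after vector exposure,
#' so the mean trajectory is directly comparable with
#' [simulate_trajectory()] run at the effective rate
#' `w = visit_prob * infect_prob * survive_prob`.
#'
#' @param p0 Starting prevalence.
#' @param vparams A [vector_params()] object.
#' @param params A [model_params()] object supplying `mu`, `F`, `H` for the
#'   reproduction step (its `w` is ignored; the mechanism replaces it).
#' @param generations Number of generations.
#' @param replicates Number of independent replicate populations.
#' @param seed Integer seed; the run is reproducible given the seed.
#' @return An object of class `wolb_abm`: list with `prevalence` (a
#'   `(generations + 1) x replicates` matrix, row 1 = `p0`), `params`,
#'   `vparams`, `seed`. In kill mode the census is among survivors.
#' @export
simulate_abm <- function(p0, vparams, params, generations, replicates = 1,
                         seed = 1L) {
  stopifnot(inherits(vparams, "wolb_vector_params"))
  params <- as_wolb_params(params)
  check_prevalence(p0, "p0")
  stopifnot(generations >= 0, replicates >= 1)
  if (as.double(generations) * vparams$n_hosts > 2^31)
    stop("generations * n_hosts too large", call. = FALSE)
  n <- vparams$n_hosts
  prev <- matrix(NA_real_, nrow = generations + 1, ncol = replicates)
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(replicates)) {
      status <- seq_len(n) <= round(p0 * n)
      prev[1, r] <- mean(status)
      if (generations > 0) for (t in seq_len(generations)) {
        k <- vertical_step(mean(status), params)
        n_inf <- stats::rbinom(1, n, k)
        status <- sample(seq_len(n) <= n_inf)
        ph <- transmission_phase(status, vparams)
        status <- ph$status
        if (vparams$kill_hosts && any(ph$dead)) {
          prev[t + 1, r] <- mean(status[!ph$dead])
          status <- status[!ph$dead]
          # population regrows to n next generation via the binomial draw
          status <- c(status, logical(n - length(status)))[seq_len(n)]
        } else {
          prev[t + 1, r] <- mean(status)
        }
      }
    }
  })
  structure(
    list(prevalence = prev, params = params, vparams = vparams,
         seed = as.integer(seed), generations = generations,
         replicates = replicates),
    class = "wolb_abm"
  )
}

#' @export
as.data.frame.wolb_abm <- function(x, ...) {
  data.frame(
    replicate = rep(seq_len(x$replicates), each = x$generations + 1),
    generation = rep(0:x$generations, times = x$replicates),
    prevalence = as.vector(x$prevalence)
  )
}

#' Monte-Carlo estimate of the effective horizontal-transmission rate
#'
#' Seeds a single infected host among `n_hosts - 1` uninfected ones, runs
#' one transmission phase, and counts new infections; the mean over
#' `n_reps` phases estimates `w`, the number of new cases generated by one
#' infected host in an otherwise uninfected population. Under the
#' next-visit-only assumption the closed-form expectation is approximately
#' `visit_prob * infect_prob * survive_prob`.
#'
#' @param vparams A [vector_params()] object.
#' @param n_reps Number of Monte-Carlo replicates (`>= 1`).
#' @param seed Integer seed.
#' @return A list with `w_hat`, `se`, `n_reps`.
#' @examples
#' estimate_w(vector_params(n_hosts = 500), n_reps = 200, seed = 1)
#' @export
estimate_w <- function(vparams, n_reps = 1000, seed = 1L) {
  stopifnot(inherits(vparams, "wolb_vector_params"), n_reps >= 1)
  n <- vparams$n_hosts
  counts <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_reps), function(i) {
      status <- c(TRUE, rep(FALSE, n - 1))
      sum(transmission_phase(status, vparams)$status) - 1L
    }, integer(1))
  })
  list(w_hat = mean(counts),
       se = stats::sd(counts) / sqrt(n_reps),
       n_reps = n_reps)
}

#' Plausibility band for the horizontal-transmission rate
#'
#' Observable quantities bound `w` from above by the parasitism (visit)
#' rate; the point estimate discounts that rate by the probability that a
#' probed host survives and the probability that a contaminated vector
#' infects it.
#'
#' @param parasitism_rate Fraction of hosts visited per generation.
#' @param survive_prob Fraction of probed hosts surviving to adulthood.
#' @param infect_prob Infection probability among surviving probed hosts.
#' @return A list with `point`, `lower` (0) and `upper`
#'   (`parasitism_rate`).
#' @export
plausibility_band_for_w <- function(parasitism_rate, survive_prob,
                                    infect_prob) {
  for (v in c(parasitism_rate, survive_prob, infect_prob))
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop("all arguments must be probabilities in [0, 1]", call. = FALSE)
  list(point = parasitism_rate * survive_prob * infect_prob,
       lower = 0, upper = parasitism_rate)
}
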