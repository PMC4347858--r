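# Seeded generators reproducing the statistical structure of the four
# experiments: behavioural observation of visits, multi-generation
# persistence of infection, decay of vector infectivity with time, and the
# two-arm host fitness comparison. Every generator draws from a single
# seeded stream (withr::with_seed) and leaves the global RNG untouched.

#' Generate visit-outcome counts for a behavioural observation experiment
#'
#' Visited hosts are partitioned by a multinomial draw into died /
#' parasitoid emerged / whitefly emerged; infection among the emerged
#' whitefly is binomial. Defaults mirror a study in which 106 visited
#' nymphs split roughly 35.8% / 34.0% / 30.2% and 93.8% of survivors
#' acquired the symbiont.
#'
#' @param n_visited Number of hosts visited by the vector.
#' @param prob_outcomes Length-3 probability vector (died, parasitoid
#'   emerged, whitefly emerged); must sum to 1.
#' @param infect_prob Probability an emerged whitefly is infected.
#' @param seed Integer seed (required).
#' @return An [outcome_counts()] object.
#' @examples
#' gen_transmission(seed = 42)
#' @export
gen_transmission <- function(n_visited = 106,
                             prob_outcomes = c(died = 0.358,
                                               parasitoid = 0.340,
                                               whitefly = 0.302),
                             infect_prob = 0.938, seed) {
  stopifnot(length(prob_outcomes) == 3, all(prob_outcomes >= 0),
            abs(sum(prob_outcomes) - 1) < 1e-8,
            infect_prob >= 0, infect_prob <= 1, n_visited >= 1)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    split <- as.vector(stats::rmultinom(1, n_visited, prob_outcomes))
    infected <- stats::rbinom(1, split[3], infect_prob)
  })
  outcome_counts(n_visited, split[1], split[2], split[3], infected)
}

#' Generate a multi-generation persistence count table
#'
#' For each generation and replicate lineage, the number infected among
#' `n_tested` sampled individuals is binomial with the generation's
#' prevalence. The default design is 5 generations x 4 replicates x 10
#' individuals at a constant prevalence of 0.875 (the midpoint of an
#' 85-90% range typical of a stably infected matriline).
#'
#' @param n_generations,n_replicates,n_tested Design dimensions.
#' @param prevalence Scalar or per-generation vector of true prevalences.
#' @param seed Integer seed (required).
#' @return A count table (columns `group` = generation, `replicate`,
#'   `infected`, `total`).
#' @export
gen_persistence <- function(n_generations = 5, n_replicates = 4,
                            n_tested = 10, prevalence = 0.875, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(all(prevalence >= 0), all(prevalence <= 1),
            length(prevalence) %in% c(1L, n_generations))
  p_gen <- rep(prevalence, length.out = n_generations)
  tab <- expand.grid(replicate = seq_len(n_replicates),
                     group = seq_len(n_generations))[, 2:1]
  tab$total <- n_tested
  tab$infected <- withr::with_seed(as.integer(seed), {
    stats::rbinom(nrow(tab), n_tested, p_gen[tab$group])
  })
  tab[, c("group", "replicate", "infected", "total")]
}

#' Generate an infectivity-decay count table
#'
#' Transmission success declines with time since the vector was
#' contaminated: counts are binomial with probability
#' `plogis(intercept + slope * hours)`. The default intercept/slope are
#' chosen so that the expected transmission rate is 0.9 at 24 h and 0.1 at
#' 96 h — high in the first two days, low thereafter.
#'
#' @param hours Time points (h since contamination).
#' @param n_replicates,n_tested Replicates per time point and hosts per
#'   replicate.
#' @param intercept,slope Logit-scale parameters; defaults derived from
#'   `p24` and `p96`.
#' @param p24,p96 Expected transmission rates at 24 h and 96 h used to set
#'   the defaults.
#' @param seed Integer seed (required).
#' @return A count table (columns `group` = hours, `replicate`, `infected`,
#'   `total`).
#' @export
gen_decay <- function(hours = c(24, 48, 72, 96), n_replicates = 4,
                      n_tested = 10, intercept = NULL, slope = NULL,
                      p24 = 0.9, p96 = 0.1, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (is.null(slope)) slope <- (stats::qlogis(p96) - stats::qlogis(p24)) / 72
  if (is.null(intercept)) intercept <- stats::qlogis(p24) - 24 * slope
  tab <- expand.grid(replicate = seq_len(n_replicates), group = hours)[, 2:1]
  tab$total <- n_tested
  p <- stats::plogis(intercept + slope * tab$group)
  tab$infected <- withr::with_seed(as.integer(seed), {
    stats::rbinom(nrow(tab), n_tested, p)
  })
  tab[, c("group", "replicate", "infected", "total")]
}

#' Generate a two-arm fitness dataset
#'
#' Emulates a fitness experiment with `n_replicates` cages per infection
#' arm and `n_pairs` host pairs per cage:
#' \itemize{
#'   \item development time (days): Normal around the arm mean plus a
#'     cage-level random effect; infected hosts develop faster by
#'     `dev_effect` days by default;
#'   \item fecundity (eggs): Normal, no arm effect by default;
#'   \item longevity (days): exponential with an infected-arm hazard ratio
#'     below 1 (longer life) and a cage-level log-hazard jitter;
#'   \item immature survival and offspring sex: over-dispersed binomial
#'     counts per pair, the over-dispersion induced by a cage-plus-pair
#'     logit-scale jitter.
#' }
#' Effect-size defaults are realistic placeholders for this host-symbiont
#' system, not measured values.
#'
#' @param n_replicates Cages per arm.
#' @param n_pairs Host pairs per cage.
#' @param dev_mean,dev_effect,dev_rep_sd,dev_resid_sd Development time
#'   (days): uninfected mean, infected effect (negative = faster),
#'   cage SD, residual SD.
#' @param fec_mean,fec_effect,fec_rep_sd,fec_resid_sd Fecundity (eggs).
#' @param long_mean Uninfected mean longevity (days).
#' @param long_hr Infected/uninfected hazard ratio (< 1 = longer life).
#' @param long_rep_sd Cage SD of the log hazard.
#' @param surv_prob,surv_effect,surv_jitter_sd Immature survival:
#'   uninfected probability, infected logit effect, per-pair logit jitter.
#' @param female_prob,sex_effect,sex_jitter_sd Offspring sex ratio
#'   (probability female), analogous.
#' @param n_offspring Offspring scored per pair for the ratio traits.
#' @param seed Integer seed (required).
#' @return A long data frame with columns `arm`, `replicate`, `trait`,
#'   `value`, `trials` (`NA` except for the ratio traits).
#' @examples
#' head(gen_fitness(seed = 7))
#' @export
gen_fitness <- function(n_replicates = 4, n_pairs = 10,
                        dev_mean = 20, dev_effect = -1.5,
                        dev_rep_sd = 0.5, dev_resid_sd = 1,
                        fec_mean = 80, fec_effect = 0,
                        fec_rep_sd = 4, fec_resid_sd = 12,
                        long_mean = 15, long_hr = 0.5, long_rep_sd = 0.2,
                        surv_prob = 0.8, surv_effect = 0,
                        surv_jitter_sd = 0.3,
                        female_prob = 0.6, sex_effect = 0,
                        sex_jitter_sd = 0.3,
                        n_offspring = 10, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(n_replicates >= 2, n_pairs >= 1)
  arms <- c("uninfected", "infected")
  base <- expand.grid(pair = seq_len(n_pairs),
                      replicate = seq_len(n_replicates),
                      arm = arms, stringsAsFactors = FALSE)
  n <- nrow(base)
  inf <- as.numeric(base$arm == "infected")
  rep_id <- paste0(base$arm, "_", base$replicate)
  withr::with_seed(as.integer(seed), {
    gauss_trait <- function(mean0, effect, rep_sd, resid_sd) {
      re <- stats::rnorm(2 * n_replicates, 0, rep_sd)
      names(re) <- unique(rep_id)
      pmax(0, mean0 + effect * inf + re[rep_id] +
             stats::rnorm(n, 0, resid_sd))
    }
    dev <- gauss_trait(dev_mean, dev_effect, dev_rep_sd, dev_resid_sd)
    fec <- gauss_trait(fec_mean, fec_effect, fec_rep_sd, fec_resid_sd)
    log_haz_re <- stats::rnorm(2 * n_replicates, 0, long_rep_sd)
    names(log_haz_re) <- unique(rep_id)
    rate <- exp(log(1 / long_mean) + log(long_hr) * inf +
                  log_haz_re[rep_id])
    lng <- stats::rexp(n, rate)
    ratio_trait <- function(p0, effect, jitter_sd) {
      eta <- stats::qlogis(p0) + effect * inf +
        stats::rnorm(n, 0, jitter_sd)
      stats::rbinom(n, n_offspring, stats::plogis(eta))
    }
    surv <- ratio_trait(surv_prob, surv_effect, surv_jitter_sd)
    sexf <- ratio_trait(female_prob, sex_effect, sex_jitter_sd)
  })
  one <- function(trait, value, trials = NA_real_) {
    data.frame(arm = base$arm, replicate = base$replicate, trait = trait,
               value = value, trials = trials, stringsAsFactors = FALSE)
  }
  rbind(one("development_time", dev),
        one("fecundity", fec),
        one("longevity", lng),
        one("immature_survival", surv, n_offspring),
        one("sex_ratio", sexf, n_offspring))
}
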