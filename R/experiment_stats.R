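# Statistical analyses for the transmission experiments: outcome
# proportions with logit-scale intervals, per-group prevalence estimation,
# binomial likelihood-ratio heterogeneity tests (with a replicate-level
# random intercept where the design supports one), logistic trend tests,
# and replicate-level fitness comparisons.

#' Visit-outcome counts from a behavioural observation experiment
#'
#' Hosts visited (probed) by parasitoids partition into those that died,
#' those from which a parasitoid emerged, and those that completed
#' development to adult; infection is scored among the survivors.
#'
#' @param visited Total hosts probed.
#' @param died,parasitoid_emerged,whitefly_emerged Outcome counts; must sum
#'   to `visited`.
#' @param infected_of_emerged Infected count among `whitefly_emerged`.
#' @return An object of class `wolb_outcome_counts`.
#' @examples
#' outcome_counts(106, 38, 36, 32, 30)
#' @export
outcome_counts <- function(visited, died, parasitoid_emerged,
                           whitefly_emerged, infected_of_emerged) {
  x <- c(visited = visited, died = died,
         parasitoid_emerged = parasitoid_emerged,
         whitefly_emerged = whitefly_emerged,
         infected_of_emerged = infected_of_emerged)
  if (any(x < 0) || any(x != round(x)))
    stop("all counts must be non-negative integers", call. = FALSE)
  if (died + parasitoid_emerged + whitefly_emerged != visited)
    stop("died + parasitoid_emerged + whitefly_emerged must equal visited",
         call. = FALSE)
  if (infected_of_emerged > whitefly_emerged)
    stop("infected_of_emerged cannot exceed whitefly_emerged", call. = FALSE)
  structure(as.list(x), class = "wolb_outcome_counts")
}

# 95% interval for x/n: Wald on the logit scale back-transformed, or exact
# binomial at the boundaries where the logit SE is undefined.
proportion_ci <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (x == 0 || x == n) {
    ci <- stats::binom.test(x, n)$conf.int
    list(lower = ci[1], upper = ci[2], method = "exact")
  } else {
    lg <- log(x / (n - x))
    se <- sqrt(1 / x + 1 / (n - x))
    list(lower = stats::plogis(lg - z * se),
         upper = stats::plogis(lg + z * se),
         method = "logit")
  }
}

#' Outcome proportions with 95% intervals
#'
#' Reports each outcome of a visit experiment as a percentage (rounded to
#' one decimal, matching the reporting convention for such experiments)
#' with a 95% interval computed on the logit scale and back-transformed;
#' boundary counts (0 or `n`) fall back to the exact binomial interval.
#'
#' @param counts An [outcome_counts()] object.
#' @return A data frame with columns `outcome`, `numerator`, `denominator`,
#'   `proportion`, `percent` (one decimal), `lower`, `upper`,
#'   `ci_method`.
#' @examples
#' outcome_proportions(outcome_counts(106, 38, 36, 32, 30))
#' @export
outcome_proportions <- function(counts) {
  stopifnot(inherits(counts, "wolb_outcome_counts"))
  rows <- list(
    c("died", counts$died, counts$visited),
    c("parasitoid_emerged", counts$parasitoid_emerged, counts$visited),
    c("whitefly_emerged", counts$whitefly_emerged, counts$visited),
    c("infected_of_emerged", counts$infected_of_emerged,
      counts$whitefly_emerged)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    x <- as.numeric(r[2]); n <- as.numeric(r[3])
    ci <- proportion_ci(x, n)
    data.frame(outcome = r[1], numerator = x, denominator = n,
               proportion = x / n,
               percent = round(100 * x / n, 1),
               lower = ci$lower, upper = ci$upper, ci_method = ci$method,
               stringsAsFactors = FALSE)
  }))
  out
}

check_count_table <- function(table) {
  need <- c("group", "replicate", "infected", "total")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop("count table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(table) == 0) stop("count table is empty", call. = FALSE)
  if (any(table$total <= 0)) stop("all totals must be positive", call. = FALSE)
  if (any(table$infected < 0 | table$infected > table$total))
    stop("need 0 <= infected <= total", call. = FALSE)
  invisible(table)
}

#' Per-group prevalence on the logit scale
#'
#' Pools replicates within each group and fits a binomial generalized
#' linear model with a separate logit-scale mean per group (the saturated
#' group model); estimates and standard errors are back-transformed to the
#' proportion scale, giving asymmetric intervals. Groups at the boundary
#' (0 or 100% infected) are flagged and reported with exact binomial
#' intervals.
#'
#' @param table A count table (columns `group`, `replicate`, `infected`,
#'   `total`).
#' @return A data frame with columns `group`, `infected`, `total`,
#'   `estimate` (proportion), `logit`, `logit_se`, `lower`, `upper`,
#'   `boundary`.
#' @export
logit_prevalence_fit <- function(table) {
  check_count_table(table)
  agg <- stats::aggregate(cbind(infected, total) ~ group, data = table, sum)
  agg <- agg[order(agg$group), , drop = FALSE]
  boundary <- agg$infected == 0 | agg$infected == agg$total
  # saturated group model: one intercept-only binomial fit per group
  per_group <- lapply(seq_len(nrow(agg)), function(i) {
    if (boundary[i]) return(c(NA_real_, NA_real_))
    fit <- stats::glm(cbind(agg$infected[i], agg$total[i] - agg$infected[i])
                      ~ 1, family = stats::binomial())
    c(unname(stats::coef(fit)), unname(sqrt(diag(stats::vcov(fit)))))
  })
  est_logit <- vapply(per_group, `[`, numeric(1), 1)
  se_logit <- vapply(per_group, `[`, numeric(1), 2)
  out <- data.frame(group = agg$group, infected = agg$infected,
                    total = agg$total,
                    estimate = agg$infected / agg$total,
                    logit = est_logit, logit_se = se_logit,
                    lower = NA_real_, upper = NA_real_,
                    boundary = boundary, stringsAsFactors = FALSE)
  z <- stats::qnorm(0.975)
  for (i in seq_len(nrow(out))) {
    ci <- proportion_ci(out$infected[i], out$total[i])
    if (out$boundary[i]) {
      out$logit[i] <- NA_real_
      out$logit_se[i] <- NA_real_
      out$lower[i] <- ci$lower
      out$upper[i] <- ci$upper
    } else {
      out$lower[i] <- stats::plogis(out$logit[i] - z * out$logit_se[i])
      out$upper[i] <- stats::plogis(out$logit[i] + z * out$logit_se[i])
    }
  }
  out
}

new_test_result <- function(test, statistic, statistic_kind, df, p_value,
                            estimate = NA_real_, se = NA_real_,
                            note = "") {
  data.frame(test = test, statistic = statistic,
             statistic_kind = statistic_kind,
             df = df, p_value = p_value, estimate = estimate, se = se,
             note = note, stringsAsFactors = FALSE)
}

#' Likelihood-ratio test for heterogeneity in prevalence among groups
#'
#' Compares a binomial model with a separate infection probability per
#' group against one with a common probability; the statistic is twice the
#' log-likelihood difference, referred to a chi-square with
#' `(number of groups - 1)` degrees of freedom. When the table contains
#' more than one replicate, both models carry a replicate-level random
#' intercept on the logit scale, integrated by adaptive Gauss-Hermite
#' quadrature (15 nodes, via `lme4::glmer`); if the replicate variance
#' estimates to (numerically) zero, or the mixed fit fails, the test
#' collapses to the fixed-effects binomial GLM, which is the exact
#' likelihood-ratio test between per-group and pooled binomial MLEs.
#'
#' @param table A count table (columns `group`, `replicate`, `infected`,
#'   `total`) with at least 2 groups.
#' @return A one-row data frame (see [new_test_result()] fields) with
#'   `statistic_kind = "chi_square"`; `note` records which likelihood was
#'   used (`"glmm"` or `"fixed"`).
#' @examples
#' tab <- gen_persistence(seed = 1)
#' lrt_heterogeneity(tab)
#' @export
lrt_heterogeneity <- function(table) {
  check_count_table(table)
  groups <- unique(table$group)
  if (length(groups) < 2)
    stop("need at least 2 groups to test heterogeneity", call. = FALSE)
  df <- length(groups) - 1L
  table$group <- factor(table$group)
  table$replicate <- factor(table$replicate)
  use_glmm <- nlevels(table$replicate) > 1
  stat <- NA_real_
  note <- "fixed"
  if (use_glmm) {
    fit <- tryCatch(suppressMessages({
      full <- lme4::glmer(
        cbind(infected, total - infected) ~ group + (1 | replicate),
        family = stats::binomial(), data = table, nAGQ = 15)
      null <- lme4::glmer(
        cbind(infected, total - infected) ~ 1 + (1 | replicate),
        family = stats::binomial(), data = table, nAGQ = 15)
      list(full = full, null = null)
    }), error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      vc <- c(unlist(lme4::VarCorr(fit$full)),
              unlist(lme4::VarCorr(fit$null)))
      if (all(is.finite(vc)) && max(vc) > 1e-6) {
        stat <- 2 * (as.numeric(stats::logLik(fit$full)) -
                       as.numeric(stats::logLik(fit$null)))
        note <- "glmm"
      }
    }
  }
  if (is.na(stat)) {
    full <- stats::glm(cbind(infected, total - infected) ~ group,
                       family = stats::binomial(), data = table)
    null <- stats::glm(cbind(infected, total - infected) ~ 1,
                       family = stats::binomial(), data = table)
    stat <- stats::deviance(null) - stats::deviance(full)
    note <- "fixed"
  }
  stat <- max(stat, 0)
  new_test_result("prevalence_heterogeneity", stat, "chi_square", df,
                  stats::pchisq(stat, df, lower.tail = FALSE), note = note)
}

#' Logistic trend test of infection counts against time
#'
#' Binomial regression of `infected/total` on a numeric covariate (e.g.
#' hours since vector contamination), fitted by iteratively reweighted
#' least squares with relative deviance convergence tolerance `1e-12`
#' (comfortably below the `1e-8` the estimates are contracted to); reports
#' the
#' slope, its standard error, the Wald `z` and a two-sided p-value.
#' Complete separation (fitted probabilities degenerating to 0/1) is
#' flagged in `note` rather than silently returning divergent estimates.
#'
#' @param table A count table whose `group` column is numeric time.
#' @return A one-row data frame with `statistic_kind = "z"`, `estimate` the
#'   slope per unit time and `se` its standard error.
#' @examples
#' logistic_trend(gen_decay(seed = 1))
#' @export
logistic_trend <- function(table) {
  check_count_table(table)
  time <- suppressWarnings(as.numeric(as.character(table$group)))
  if (anyNA(time))
    stop("'group' must be numeric time for a trend test", call. = FALSE)
  if (length(unique(time)) < 2)
    stop("need at least 2 distinct time values", call. = FALSE)
  fit <- suppressWarnings(stats::glm(
    cbind(infected, total - infected) ~ time,
    family = stats::binomial(), data = table,
    control = stats::glm.control(epsilon = 1e-12, maxit = 200)))
  mu <- stats::fitted(fit)
  separated <- any(mu < 1e-7 | mu > 1 - 1e-7)
  est <- unname(stats::coef(fit)["time"])
  se <- unname(sqrt(stats::vcov(fit)["time", "time"]))
  z <- est / se
  new_test_result("transmission_trend", z, "z", NA_integer_,
                  2 * stats::pnorm(-abs(z)), estimate = est, se = se,
                  note = if (separated) "separation" else "")
}

check_fitness_data <- function(data) {
  need <- c("arm", "replicate", "trait", "value")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    stop("fitness data needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(c("infected", "uninfected") %in% unique(data$arm)))
    stop("both arms ('infected', 'uninfected') must be present",
         call. = FALSE)
  if (is.null(data$trials)) data$trials <- NA_real_
  reps <- stats::aggregate(replicate ~ arm, data = data,
                           function(r) length(unique(r)))
  if (any(reps$replicate < 2))
    stop("each arm needs at least 2 replicates", call. = FALSE)
  data
}

#' Compare fitness traits between infected and uninfected arms
#'
#' Per-trait tests honouring the replicate (cage) structure of a
#' two-arm fitness experiment:
#' \describe{
#'   \item{Gaussian traits (`development_time`, `fecundity`)}{replicate
#'     (cage) means are computed and the arm effect is tested by a pooled
#'     two-sample t test on those means; for a balanced design with `r`
#'     cages per arm this is the likelihood-ratio-equivalent of a linear
#'     mixed model with a replicate random effect and gives
#'     `df = 2r - 2` (6 for the 4 + 4 design).}
#'   \item{Ratio traits (`immature_survival`, `sex_ratio`)}{per-pair
#'     success counts (columns `value` = successes, `trials`) fitted by a
#'     binomial GLM with an arm effect and an over-dispersion scale
#'     estimated from the Pearson statistic (quasi-binomial); Wald `z`.}
#'   \item{`longevity`}{proportional-hazards partial likelihood stratified
#'     by replicate (Breslow ties), Wald `z` for the arm effect; no
#'     censoring is assumed. Stratification is a deliberate simplification
#'     of a shared-frailty model.}
#' }
#' The `estimate` column is always infected minus uninfected on the model's
#' scale (days, logit, or log hazard).
#'
#' @param data A fitness dataset: long data frame with columns `arm`
#'   (`"infected"`/`"uninfected"`), `replicate`, `trait`, `value` and, for
#'   ratio traits, `trials`.
#' @return A data frame with one test row per trait present.
#' @examples
#' fitness_compare(gen_fitness(seed = 1))
#' @export
fitness_compare <- function(data) {
  data <- check_fitness_data(data)
  data$arm <- factor(data$arm, levels = c("uninfected", "infected"))
  gaussian_traits <- c("development_time", "fecundity")
  ratio_traits <- c("immature_survival", "sex_ratio")
  out <- list()
  for (trait in intersect(unique(data$trait),
                          c(gaussian_traits, ratio_traits, "longevity"))) {
    d <- data[data$trait == trait, , drop = FALSE]
    if (trait %in% gaussian_traits) {
      means <- stats::aggregate(value ~ arm + replicate, data = d, mean)
      tt <- stats::t.test(value ~ arm, data = means, var.equal = TRUE)
      est <- unname(tt$estimate[2] - tt$estimate[1])  # infected - uninfected
      se <- unname(tt$stderr)
      out[[trait]] <- new_test_result(
        trait, est / se, "t", unname(tt$parameter),
        tt$p.value, estimate = est, se = se, note = "replicate_means_t")
    } else if (trait %in% ratio_traits) {
      if (anyNA(d$trials))
        stop("ratio trait '", trait, "' needs a 'trials' column",
             call. = FALSE)
      fit <- stats::glm(cbind(value, trials - value) ~ arm,
                        family = stats::quasibinomial(), data = d)
      sm <- summary(fit)$coefficients
      est <- sm["arminfected", "Estimate"]
      se <- sm["arminfected", "Std. Error"]
      z <- est / se
      out[[trait]] <- new_test_result(
        trait, z, "z", NA_integer_, 2 * stats::pnorm(-abs(z)),
        estimate = est, se = se, note = "quasibinomial_pearson")
    } else {
      fit <- survival::coxph(
        survival::Surv(value, rep(1, nrow(d))) ~ arm + strata(replicate),
        data = d, ties = "breslow")
      sm <- summary(fit)$coefficients
      est <- sm["arminfected", "coef"]
      se <- sm["arminfected", "se(coef)"]
      z <- sm["arminfected", "z"]
      out[[trait]] <- new_test_result(
        trait, z, "z", NA_integer_, 2 * stats::pnorm(-abs(z)),
        estimate = est, se = se, note = "cox_stratified")
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
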