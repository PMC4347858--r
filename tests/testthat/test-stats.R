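test_that("visit-outcome proportions round to the printed style", {
  op <- outcome_proportions(outcome_counts(106, 38, 36, 32, 30))
  expect_equal(op$percent, c(35.8, 34.0, 30.2, 93.8))
  expect_equal(op$denominator, c(106, 106, 106, 32))
  expect_true(all(op$lower < op$proportion & op$proportion < op$upper))
  expect_true(all(op$ci_method == "logit"))
})

test_that("boundary counts fall back to exact binomial intervals", {
  op <- outcome_proportions(outcome_counts(20, 0, 0, 20, 0))
  inf <- op[op$outcome == "infected_of_emerged", ]
  expect_equal(inf$percent, 0)
  expect_equal(inf$lower, 0)
  expect_equal(inf$ci_method, "exact")
})

test_that("invalid outcome counts are rejected", {
  expect_error(outcome_counts(106, 38, 36, 30, 30), "must equal visited")
  expect_error(outcome_counts(10, 2, 3, 5, 6), "cannot exceed")
  expect_error(outcome_counts(10, -1, 6, 5, 2), "non-negative")
})

test_that("logit-scale prevalence estimates match direct arithmetic", {
  tab <- data.frame(group = 1, replicate = 1, infected = 35, total = 40)
  fit <- logit_prevalence_fit(tab)
  expect_equal(fit$estimate, 35 / 40)
  expect_equal(fit$logit, log(35 / 5), tolerance = 1e-8)
  expect_equal(fit$logit_se, sqrt(1 / 35 + 1 / 5), tolerance = 1e-6)
  # symmetric on the logit scale, asymmetric after back-transformation:
  # above 0.5 the inverse logit compresses the upper tail
  expect_gt(fit$estimate - fit$lower, fit$upper - fit$estimate)
  # replicates pool within group
  tab2 <- data.frame(group = c(1, 1), replicate = c(1, 2),
                     infected = c(10, 8), total = c(10, 10))
  expect_equal(logit_prevalence_fit(tab2)$estimate, 0.9)
  # exchangeability: identical groups get identical estimates
  tab3 <- data.frame(group = c(1, 2), replicate = 1, infected = 7,
                     total = 10)
  f3 <- logit_prevalence_fit(tab3)
  expect_equal(f3$logit[1], f3$logit[2])
  # boundary group flagged with exact interval
  tab4 <- data.frame(group = 1, replicate = 1, infected = 10, total = 10)
  f4 <- logit_prevalence_fit(tab4)
  expect_true(f4$boundary)
  expect_true(is.na(f4$logit))
  expect_lt(f4$lower, 1)
})

test_that("heterogeneity LRT matches direct binomial likelihood
           arithmetic", {
  tab <- data.frame(group = c(1, 2), replicate = 1,
                    infected = c(8, 2), total = c(10, 10))
  res <- lrt_heterogeneity(tab)
  expect_equal(res$df, 1)
  expect_equal(res$statistic,
               oracle_binomial_lrt(tab$infected, tab$total, tab$group),
               tolerance = 1e-8)
  expect_equal(res$statistic, 7.7098, tolerance = 1e-4)
})

test_that("identical counts in every group give a zero statistic and the
           generation design gives df = 4", {
  tab <- expand.grid(group = 1:5, replicate = 1:4)
  tab$infected <- 9; tab$total <- 10
  res <- lrt_heterogeneity(tab)
  expect_equal(res$statistic, 0, tolerance = 1e-8)
  expect_equal(res$df, 4)
  expect_gt(res$p_value, 0.99)
})

test_that("the LRT statistic is non-negative across simulated tables", {
  for (s in 1:20) {
    res <- lrt_heterogeneity(gen_persistence(seed = s))
    expect_gte(res$statistic, 0)
    expect_equal(res$df, 4)
    expect_true(res$p_value >= 0 && res$p_value <= 1)
  }
})

test_that("heterogeneity LRT rejects degenerate designs", {
  expect_error(lrt_heterogeneity(
    data.frame(group = 1, replicate = 1:2, infected = 1, total = 10)),
    "at least 2 groups")
  expect_error(lrt_heterogeneity(
    data.frame(group = 1:2, replicate = 1, infected = 0, total = 0)),
    "positive")
})

test_that("logistic trend slope, SE and z match a direct likelihood
           oracle", {
  tab <- data.frame(group = c(24, 48, 72, 96), replicate = 1,
                    infected = c(9, 7, 4, 2), total = 10)
  res <- logistic_trend(tab)
  orc <- oracle_logistic_fit(tab$infected, tab$total, tab$group)
  expect_lt(res$estimate, 0)
  expect_equal(res$estimate, orc$coef[2], tolerance = 1e-6)
  expect_equal(res$se, orc$se[2], tolerance = 1e-6)
  expect_equal(res$statistic, orc$coef[2] / orc$se[2], tolerance = 1e-6)
  expect_equal(res$note, "")
})

test_that("equal proportions at every time give a null slope", {
  tab <- expand.grid(group = c(24, 48, 72, 96), replicate = 1:4)
  tab$infected <- 6; tab$total <- 10
  res <- logistic_trend(tab)
  expect_lt(abs(res$statistic), 1e-6)
  expect_lt(abs(res$estimate), 1e-8)
})

test_that("complete separation is flagged rather than silently diverging", {
  tab <- expand.grid(group = c(24, 48, 72, 96), replicate = 1:4)
  tab$infected <- 10; tab$total <- 10
  expect_equal(logistic_trend(tab)$note, "separation")
  tab2 <- data.frame(group = c(24, 48, 72, 96), replicate = 1,
                     infected = c(10, 10, 0, 0), total = 10)
  expect_equal(logistic_trend(tab2)$note, "separation")
})

test_that("IRLS estimates equal direct likelihood maximisation on random
           tables", {
  set.seed(17)
  for (i in 1:8) {
    tab <- data.frame(group = c(24, 48, 72, 96), replicate = 1,
                      infected = rbinom(4, 10, runif(4, 0.2, 0.8)),
                      total = 10)
    if (length(unique(tab$infected)) == 1) next
    res <- logistic_trend(tab)
    if (res$note == "separation") next
    orc <- oracle_logistic_fit(tab$infected, tab$total, tab$group)
    expect_equal(res$estimate, orc$coef[2], tolerance = 1e-6)
    expect_equal(res$se, orc$se[2], tolerance = 1e-6)
  }
})

test_that("Gaussian fitness traits use the replicate-means t test with
           df = 2r - 2", {
  dat <- gen_fitness(seed = 3)
  res <- fitness_compare(dat)
  dev <- res[res$test == "development_time", ]
  expect_equal(dev$df, 6)
  expect_equal(dev$statistic_kind, "t")
  # oracle: two-sample t on cage means
  d <- dat[dat$trait == "development_time", ]
  means <- aggregate(value ~ arm + replicate, data = d, mean)
  tt <- t.test(value ~ factor(arm, c("uninfected", "infected")),
               data = means, var.equal = TRUE)
  expect_equal(abs(dev$statistic), abs(unname(tt$statistic)),
               tolerance = 1e-10)
  expect_equal(res[res$test == "fecundity", "df"], 6)
})

test_that("identical replicate means give t = 0", {
  base <- expand.grid(pair = 1:3, replicate = 1:4,
                      arm = c("uninfected", "infected"),
                      stringsAsFactors = FALSE)
  base$trait <- "development_time"
  base$value <- base$replicate + (base$pair - 2) * 0.1
  res <- fitness_compare(base)
  expect_equal(res$statistic, 0)
  expect_equal(res$estimate, 0)
})

test_that("ratio traits use quasi-binomial Wald z and longevity a
           stratified Cox model", {
  res <- fitness_compare(gen_fitness(seed = 5))
  expect_setequal(res$test, c("development_time", "fecundity", "longevity",
                              "immature_survival", "sex_ratio"))
  expect_equal(res[res$test == "immature_survival", "note"],
               "quasibinomial_pearson")
  expect_equal(res[res$test == "longevity", "note"], "cox_stratified")
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # infected arm lives longer by construction: negative log-hazard
  expect_lt(res[res$test == "longevity", "estimate"], 0)
})

test_that("degenerate fitness designs are rejected", {
  dat <- gen_fitness(seed = 1)
  expect_error(fitness_compare(dat[dat$replicate == 1 |
                                     dat$arm == "uninfected", ]),
               "at least 2 replicates")
  one_arm <- dat[dat$arm == "infected", ]
  expect_error(fitness_compare(one_arm), "both arms")
  no_trials <- dat[dat$trait == "immature_survival", ]
  no_trials$trials <- NA_real_
  no_trials <- rbind(no_trials,
                     transform(dat[dat$trait == "development_time", ],
                               trials = NA_real_))
  expect_error(fitness_compare(no_trials), "trials")
})
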