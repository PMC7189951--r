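test_that("partial log-likelihood matches hand values at beta = 0", {
  # two subjects, events at gaps 5 and 9: risk sets of size 2, then 1
  ll <- pwp_loglik(0, time = c(5, 9), status = c(1, 1), x = matrix(c(1, 0)))
  expect_equal(ll$loglik, -log(2))
  # a single subject with one event contributes nothing at any beta
  for (b in c(-2, 0, 1.5))
    expect_equal(pwp_loglik(b, 3, 1, matrix(1))$loglik, 0)
  # at beta = 0 the value is minus the sum of log risk-set sizes
  set.seed(406)
  for (rep in 1:10) {
    d <- random_tiny_gaps()
    ll0 <- pwp_loglik(0, d$time, d$status, d$x)$loglik
    expect_equal(ll0, -sum(vapply(which(d$status == 1), function(i)
      log(sum(d$time >= d$time[i])), numeric(1))))
  }
  expect_error(pwp_loglik(0, c(3, 4), c(0, 0), matrix(1:2)), "no events")
  expect_error(pwp_loglik(c(0, 0), 3, 1, matrix(1)), "length")
})

test_that("likelihood, score and information agree with enumeration oracles", {
  set.seed(407)
  for (rep in 1:40) {
    p <- sample(1:2, 1)
    d <- random_tiny_gaps(p = p)
    beta <- rnorm(p)
    for (ties in c("breslow", "efron")) {
      mine <- pwp_loglik(beta, d$time, d$status, d$x, ties = ties)
      oracle <- if (ties == "breslow")
        naive_breslow_loglik(beta, d$time, d$status, d$x)
      else naive_efron_loglik(beta, d$time, d$status, d$x)
      expect_equal(mine$loglik, oracle, tolerance = 1e-12)
      g_num <- numeric_gradient(function(b)
        pwp_loglik(b, d$time, d$status, d$x, ties = ties)$loglik, beta)
      expect_equal(unname(mine$score), g_num, tolerance = 1e-4)
      h_num <- -vapply(seq_len(p), function(j) numeric_gradient(function(b)
        pwp_loglik(b, d$time, d$status, d$x, ties = ties)$score[j], beta),
        numeric(p))
      expect_equal(unname(mine$information), matrix(h_num, p, p),
                   tolerance = 1e-3)
    }
  }
})

test_that("one-covariate MLE matches brute-force maximisation", {
  coh <- make_fixture("tiny8")
  gaps <- expand_gaps(coh, max_stratum = 2)
  fit <- pwp_gt(~ woman_employment, gaps)
  for (s in c("1", "2")) {
    rows <- gaps$stratum == as.integer(s)
    x <- as.numeric(gaps$woman_employment[rows] == "unemployed")
    brute <- optimize(function(b)
      naive_breslow_loglik(b, gaps$gap_time[rows], gaps$event[rows],
                           matrix(x)), c(-8, 8), maximum = TRUE)
    expect_equal(unname(fit$strata[[s]]$coef), brute$maximum,
                 tolerance = 1e-4)
  }
})

test_that("fits agree with an independent stratified Cox implementation", {
  library(survival)
  coh <- simulate_cohort(sim_config(
    n_women = 600, seed = 31,
    covariate_effects = list(c(woman_employmentunemployed = 0.4,
                               woman_age_at_marriage = -0.03))))
  gaps <- expand_gaps(coh)
  form <- ~ woman_age_at_marriage + woman_education + woman_employment
  for (ties in c("breslow", "efron")) {
    fit <- pwp_gt(form, gaps, ties = ties)
    for (s in names(fit$strata)) {
      sub <- gaps[gaps$stratum == as.integer(s), ]
      cph <- coxph(Surv(gap_time, event) ~ woman_age_at_marriage +
                     woman_education + woman_employment, data = sub,
                   ties = ties, control = coxph.control(eps = 1e-10,
                                                        iter.max = 50))
      expect_equal(unname(fit$strata[[s]]$coef), unname(coef(cph)),
                   tolerance = 1e-6)
      expect_equal(unname(fit$strata[[s]]$se),
                   unname(sqrt(diag(vcov(cph)))), tolerance = 1e-6)
      expect_equal(fit$strata[[s]]$loglik, cph$loglik[2], tolerance = 1e-6)
    }
    shared <- pwp_gt(form, gaps, ties = ties, per_stratum = FALSE)
    cph_s <- coxph(Surv(gap_time, event) ~ woman_age_at_marriage +
                     woman_education + woman_employment + strata(stratum),
                   data = gaps, ties = ties,
                   control = coxph.control(eps = 1e-10, iter.max = 50))
    expect_equal(unname(shared$strata$all$coef), unname(coef(cph_s)),
                 tolerance = 1e-6)
  }
})

test_that("the reported optimum satisfies the first-order conditions", {
  coh <- simulate_cohort(sim_config(n_women = 300, seed = 37))
  fit <- pwp_gt(~ woman_education + income, coh)
  for (s in names(fit$strata)) {
    f <- fit$strata[[s]]
    expect_true(f$converged)
    expect_lt(f$score_norm, fit$tol)
    # inverse observed information is a proper covariance at the optimum
    expect_true(all(diag(f$vcov) > 0))
  }
})

test_that("coefficients are invariant to rescaling all gap times", {
  gaps <- expand_gaps(simulate_cohort(sim_config(n_women = 250, seed = 41)))
  f1 <- pwp_gt(~ woman_employment + woman_age_at_marriage, gaps)
  gaps2 <- gaps
  gaps2$gap_time <- gaps2$gap_time * 2.5
  f2 <- pwp_gt(~ woman_employment + woman_age_at_marriage, gaps2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
})

test_that("unidentifiable columns are dropped with a warning", {
  coh <- simulate_cohort(sim_config(n_women = 120, seed = 43))
  coh$woman_employment <- factor("employed",
                                 levels = c("employed", "unemployed"))
  w <- capture_warnings(fit <- pwp_gt(~ woman_employment, coh,
                                      max_stratum = 2))
  expect_true(length(w) > 0 && all(grepl("unidentifiable", w)))
  f <- fit$strata[["1"]]
  expect_identical(length(f$coef), 0L)
  # baseline-only log likelihood: sum of -log |risk set| over events
  gaps <- suppressWarnings(expand_gaps(coh, 2))
  rows <- gaps$stratum == 1
  expect_equal(f$loglik, naive_breslow_loglik(
    numeric(0), gaps$gap_time[rows], gaps$event[rows],
    matrix(numeric(0), sum(rows), 0)))
})

test_that("separation is detected and flagged", {
  cov <- data.frame(
    woman_age_at_marriage = 20, woman_education = "secondary",
    woman_employment = rep(c("employed", "unemployed"), each = 3),
    husband_age = 25, husband_education = "secondary",
    husband_employment = "employed", stillbirth = "no",
    age_first_pregnancy = ">18", income = "<=135")
  # employed women all give birth sooner than any unemployed woman
  coh <- cohort(letters[1:6], rep(300, 6),
                as.list(c(10, 12, 14, 100, 120, 140)),
                as.list(rep("male", 6)), cov)
  fit <- pwp_gt(~ woman_employment, coh, max_stratum = 1)
  expect_true(fit$strata[["1"]]$monotone)
  expect_false(fit$strata[["1"]]$converged)
})

test_that("empty strata are rejected", {
  coh <- cohort_from_counts(5, c(5, 0, 0, 0))
  gaps <- expand_gaps(coh, max_stratum = 2)
  expect_error(pwp_gt(~ woman_employment, gaps), "no events")
})

test_that("wald table carries reference rows and normal p-values", {
  gaps <- expand_gaps(simulate_cohort(sim_config(n_women = 400, seed = 47)))
  fit <- pwp_gt(~ woman_education + woman_age_at_marriage, gaps)
  tab <- wald_table(fit)
  ref <- tab[tab$reference, ]
  expect_true(all(ref$HR == 1))
  expect_true(all(ref$level == "illiterate/primary"))
  expect_true(all(is.na(ref$SE)))
  est <- tab[!tab$reference & tab$stratum == "1", ]
  expect_equal(est$HR, exp(est$coef))
  expect_equal(est$p, 2 * pnorm(-abs(est$coef / est$SE)))
  # age enters continuously: no reference row for it
  expect_false(any(tab$variable == "woman_age_at_marriage" & tab$reference))
  s <- summary(fit)
  expect_s3_class(s, "summary.pwp_gt")
  expect_output(print(s), "woman_education")
})

test_that("predict returns stratum-specific linear predictors and risks", {
  gaps <- expand_gaps(simulate_cohort(sim_config(n_women = 200, seed = 53)))
  fit <- pwp_gt(~ woman_employment, gaps)
  lp <- predict(fit, gaps)
  expect_identical(length(lp), nrow(gaps))
  expect_equal(predict(fit, gaps, type = "risk"), exp(lp))
  b1 <- fit$strata[["1"]]$coef
  in1 <- gaps$stratum == 1
  expect_equal(lp[in1],
               unname(b1 * (gaps$woman_employment[in1] == "unemployed")))
})
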