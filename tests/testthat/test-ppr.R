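test_that("truncated mean matches hand values and the integration oracle", {
  expect_equal(trunc_mean_interval(c(24, 48, 96), 60), 44)
  expect_equal(trunc_mean_interval(c(24, 48), 60), 36)   # truncation inactive
  expect_equal(trunc_mean_interval(200, 60), 60)         # full truncation
  expect_error(trunc_mean_interval(numeric(0), 60), "no closed")
  expect_error(trunc_mean_interval(c(3, -1), 60), ">= 0")

  set.seed(404)
  for (rep in 1:10) {
    x <- runif(sample(3:40, 1), 1, 150)
    C <- runif(1, 10, 140)
    expect_equal(trunc_mean_interval(x, C),
                 integrate_empirical_survival(x, C), tolerance = 1e-6)
  }
})

test_that("truncated mean is nondecreasing in C and bounded by C and mean", {
  set.seed(405)
  x <- runif(25, 5, 160)
  Cs <- seq(10, 200, by = 10)
  e <- vapply(Cs, function(C) trunc_mean_interval(x, C), numeric(1))
  expect_true(all(diff(e) >= 0))
  expect_true(all(e <= Cs & e <= mean(x)))
})

test_that("point estimator hits its analytic limits exactly", {
  for (C1 in c(6, 12, 18)) {
    for (C in c(60, 84, 120)) {
      for (E_c in c(30, 42.5, 55)) {
        none <- ppr_point(p = C1 / C, E_c = E_c, C1 = C1, C = C)
        expect_identical(none$estimate, 0)
        all_ <- ppr_point(p = C1 / E_c, E_c = E_c, C1 = C1, C = C)
        expect_identical(all_$estimate, 1)
      }
    }
  }
  # worked fraction: p = 0.25, E_c = 36, C1 = 12, C = 60
  expect_equal(ppr_point(0.25, 36, 12, 60)$estimate, 0.5)
  # undefined cells
  expect_true(is.na(ppr_point(0, 40, 12, 60)$estimate))
  expect_true(is.na(ppr_point(NA, 40, 12, 60)$estimate))
  expect_true(is.na(ppr_point(0.5, 60, 12, 60)$estimate))  # E_c = C
  expect_identical(ppr_point(12 / 60, 60, 12, 60)$estimate, 0)
  # out-of-range raw values are clamped but kept
  low <- ppr_point(0.1, 30, 12, 60)   # raw (12-6)/(0.1*(-30)) = -2
  expect_false(low$in_range)
  expect_identical(low$estimate, 0)
  expect_equal(low$raw, -2)
  high <- ppr_point(0.9, 30, 12, 60)  # raw (12-54)/(0.9*(-30)) > 1
  expect_false(high$in_range)
  expect_identical(high$estimate, 1)
  expect_gt(high$raw, 1)
  expect_error(ppr_point(1.2, 30, 12, 60), "0, 1")
  expect_error(ppr_point(0.5, 30, 60, 12), "C1 < C")
})

test_that("the formula inverts the renewal identity of the cure model", {
  # with exact inputs from the occupancy theory (p from the integral of the
  # occupancy survival, E_C by numeric integration of the gap law), the
  # estimator must return the generating progression probability
  E_trunc <- function(C, mlog, sdlog)
    stats::integrate(function(t) 1 - plnorm(t, mlog, sdlog), 0, C,
                     abs.tol = 1e-10)$value
  for (a in c(0.95, 0.85, 0.55, 0.35)) {
    for (C in c(60, 84, 120)) {
      mlog <- log(54)
      EC <- E_trunc(C, mlog, 0.5)
      EC1 <- E_trunc(12, mlog, 0.5)
      p <- ((1 - a) * 12 + a * EC1) / ((1 - a) * C + a * EC)
      expect_equal(ppr_point(p, EC, 12, C)$estimate, a, tolerance = 5e-3)
    }
  }
})

test_that("interval extraction on the hand-checkable fixture", {
  coh <- make_fixture("tiny8")
  # marriage -> first birth: 7 closed first-birth intervals, one childless
  # woman with open interval 240
  iv <- interval_data(coh, 0, C1 = 12, C = 120, open_denominator = "all")
  expect_setequal(iv$closed, c(30, 24, 30, 36, 24, 30, 48))
  expect_identical(iv$open, 240)
  expect_identical(iv$p, 0)          # her open interval exceeds C1
  # within-C denominator: the 240-month open interval is outside the window
  iv_w <- interval_data(coh, 0, C1 = 12, C = 120)
  expect_identical(iv_w$n_denominator, 0L)
  expect_true(is.na(iv_w$p))
  # first -> second: closed gaps of t4..t7; open gaps of t2, t3, t8
  iv1 <- interval_data(coh, 1, C1 = 12, C = 120, open_denominator = "all")
  expect_setequal(iv1$closed, c(54, 60, 48, 48))
  expect_setequal(iv1$open, c(150, 276, 72))
  expect_identical(iv1$n_parity_i, 3L)
})

test_that("degenerate extraction cases", {
  # everyone progressed: no open intervals, p undefined -> missing cell
  coh <- cohort_from_counts(10, c(10, 10, 0, 0))
  iv <- interval_data(coh, 0, C1 = 12, C = 120)
  expect_true(is.na(iv$p))
  tab <- ppr_table(coh, transitions = 0)
  expect_true(all(is.na(tab$estimate)))
  expect_false(tab$median_complete)
  # single woman at parity 1 with a 6-month open interval -> p = 1
  one <- cohort_from_counts(1, c(1, 0, 0, 0))
  one$interview_time <- one$birth_times[[1]][1] + 6
  iv <- interval_data(one, 1, C1 = 12, C = 60)
  expect_identical(iv$p, 1)
  expect_error(interval_data(coh, -1), ">= 0")
  expect_error(interval_data(coh, 0, C1 = 60, C = 12), "C1 < C")
})

test_that("table assembly: shape, medians, flags", {
  coh <- simulate_cohort(sim_config(
    n_women = 1500, progression = c(0.95, 0.85, 0.55, 0.35),
    interview_window = c(0.01, 420), seed = 23))
  tab <- ppr_table(coh)
  expect_identical(dim(tab$estimate), c(4L, 6L))
  expect_identical(rownames(tab$estimate),
                   c("0->1", "1->2", "2->3", "3->4"))
  expect_true(all(tab$estimate >= 0 & tab$estimate <= 1, na.rm = TRUE))
  expect_equal(unname(tab$medians),
               unname(apply(tab$estimate, 1, median, na.rm = TRUE)))
  expect_error(ppr_table(coh, C_grid = c(10, 60)), "exceed C1")
})

test_that("a near-zero progression probability yields a near-zero row", {
  coh <- simulate_cohort(sim_config(
    n_women = 3000, progression = c(0.95, 0.9, 0.03),
    interview_window = c(0.01, 420), seed = 29))
  tab <- ppr_table(coh, transitions = 2)
  expect_lt(tab$medians[["2->3"]], 0.15)
})

test_that("row medians follow the even-count convention", {
  m <- matrix(c(0.307, 0.315, 0.347, 0.351, 0.361, 0.354), 1,
              dimnames = list("3->4", NULL))
  expect_equal(unname(ppr_medians(m)), (0.347 + 0.351) / 2)
  expect_error(ppr_medians(1:3), "matrix")
})
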