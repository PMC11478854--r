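# The reference cohort: 453 patients per arm, 139 vs 67 deaths.
ref_table <- function() contingency_table(453, 139, 453, 67)

test_that("the reference 2x2 table reproduces at printed precision", {
  ct <- ref_table()
  expect_equal(round(risk(ct, 1), 3), 0.307)
  expect_equal(round(risk(ct, 2), 3), 0.148)

  rd <- risk_difference(ct)
  expect_equal(round(rd$estimate, 3), 0.159)
  expect_equal(round(rd$conf_low, 3), 0.105)
  expect_equal(round(rd$conf_high, 3), 0.213)
  expect_equal(round(rd$z, 3), 5.707)
  expect_identical(sprintf("%.3f", rd$p), "0.000")

  rr <- risk_ratio(ct)
  expect_equal(round(rr$estimate, 3), 2.075)
  expect_equal(round(rr$conf_low, 3), 1.598)
  expect_equal(round(rr$conf_high, 3), 2.693)

  or <- odds_ratio(ct)
  expect_equal(round(or$estimate, 3), 2.550)
  expect_equal(round(or$conf_low, 3), 1.838)
  expect_equal(round(or$conf_high, 3), 3.538)
})

test_that("hand-computed toy tables and symmetry cases agree", {
  ct <- contingency_table(10, 5, 10, 2)
  expect_equal(risk_difference(ct)$estimate, 0.3)
  expect_equal(risk_ratio(ct)$estimate, 2.5)
  expect_equal(odds_ratio(ct)$estimate, 4)   # (5/5)/(2/8)

  same <- contingency_table(50, 10, 50, 10)
  expect_equal(risk_difference(same)$estimate, 0)
  expect_equal(risk_difference(same)$z, 0)
  expect_equal(risk_difference(same)$p, 1)
  expect_equal(risk_ratio(same)$estimate, 1)
  expect_equal(odds_ratio(same)$estimate, 1)
  rr <- risk_ratio(same)
  expect_true(rr$conf_low < 1 && rr$conf_high > 1)

  expect_equal(risk(contingency_table(10, 0, 10, 1), 1), 0)
  # RD + risk2 = risk1 exactly
  set.seed(3)
  for (i in 1:20) {
    n1 <- sample(5:200, 1); n2 <- sample(5:200, 1)
    ct2 <- contingency_table(n1, sample(0:n1, 1), n2, sample(0:n2, 1))
    expect_equal(risk_difference(ct2)$estimate + risk(ct2, 2),
                 risk(ct2, 1), tolerance = 1e-14)
  }
})

test_that("degenerate tables are flagged instead of silently mis-scored", {
  allzero <- contingency_table(10, 0, 10, 0)
  expect_true(risk_difference(allzero)$degenerate)
  expect_true(risk_ratio(allzero)$infinite)
  expect_true(odds_ratio(allzero)$zero_cell)
  expect_error(contingency_table(0, 0, 10, 1), ">= 1")
  expect_error(contingency_table(10, 11, 10, 1), "0 <= x <= n")
})

test_that("OR exceeds RR exceeds 1 whenever risk1 > risk2 > 0", {
  set.seed(99)
  checked <- 0
  while (checked < 30) {
    n1 <- sample(10:300, 1); n2 <- sample(10:300, 1)
    x1 <- sample(1:(n1 - 1), 1); x2 <- sample(1:(n2 - 1), 1)
    ct <- contingency_table(n1, x1, n2, x2)
    if (risk(ct, 1) <= risk(ct, 2)) next
    expect_gt(odds_ratio(ct)$estimate, risk_ratio(ct)$estimate)
    expect_gt(risk_ratio(ct)$estimate, 1)
    checked <- checked + 1
  }
})

test_that("Kaplan-Meier matches hand product-limit computation", {
  # times [2, 3+, 5] with events at 2 and 5: S(2)=2/3, S(5)=0
  d <- survival_data(c(2, 3, 5), c(1, 0, 1), rep("g", 3))
  km <- kaplan_meier(d, "g")
  ev <- km$steps[km$steps$n_event > 0, ]
  expect_equal(ev$surv[ev$time == 2], 2 / 3)
  expect_equal(ev$surv[ev$time == 5], 0)

  # no events: S(t) = 1 everywhere
  noev <- kaplan_meier(survival_data(c(1, 2, 3), c(0, 0, 0), rep("g", 3)),
                       horizon = 10)
  expect_true(all(noev$steps$surv == 1))
  expect_equal(noev$surv_at_horizon, 1)

  # all events at t = 1: S(1) = 0
  all1 <- kaplan_meier(survival_data(rep(1, 4), rep(1, 4), rep("g", 4)),
                       horizon = 1)
  expect_equal(all1$surv_at_horizon, 0)

  # without censoring, KM at the last event time = empirical survivor fraction
  d2 <- survival_data(c(1, 2, 2, 4, 7), rep(1, 5), rep("g", 5))
  km2 <- kaplan_meier(d2, horizon = 7)
  expect_equal(km2$surv_at_horizon, 0)
  km3 <- kaplan_meier(d2, horizon = 4)
  expect_equal(km3$surv_at_horizon, 1 / 5)

  expect_error(kaplan_meier(d, "missing-group"), "missing-group")
})

test_that("log-rank matches a hand O-E tabulation on a 6-subject dataset", {
  # groups A: (1,event) (3,event) (5,censored); B: (2,event) (4,event) (6,event)
  d <- survival_data(c(1, 3, 5, 2, 4, 6), c(1, 1, 0, 1, 1, 1),
                     c("A", "A", "A", "B", "B", "B"))
  lr <- log_rank(d)
  # hand tabulation over event times 1,2,3,4,6:
  # t=1: risk 3A/3B, event A -> E_A += 3/6;   t=2: 2A/3B, event B -> 2/5
  # t=3: 2A/2B, event A -> 2/4;  t=4: 1A/2B, event B -> 1/3; t=6: 0A/1B -> 0
  E_A <- 3 / 6 + 2 / 5 + 2 / 4 + 1 / 3 + 0
  O_A <- 2
  expect_equal(lr$observed[1], O_A)
  expect_equal(lr$expected[1], E_A, tolerance = 1e-12)
  # variance of O-E at each time: n1 n2 d (n-d) / (n^2 (n-1)) with d=1
  V <- (3 * 3) / 36 + (2 * 3) / 25 + (2 * 2) / 16 + (1 * 2) / 9 + 0
  expect_equal(lr$chisq, (O_A - E_A)^2 / V, tolerance = 1e-12)
  expect_identical(lr$df, 1L)
  # O/E hazard ratio
  # 5 events total, so O_B = 3 and E_B = 5 - E_A
  expect_equal(lr$hazard_ratio,
               (O_A / E_A) / ((5 - O_A) / (5 - E_A)),
               tolerance = 1e-12)
})

test_that("log-rank symmetry and degenerate cases behave", {
  # two identical groups interleaved: statistic 0, p 1
  d <- survival_data(rep(c(1, 2, 3), 2), rep(1, 6),
                     rep(c("A", "B"), each = 3))
  lr <- log_rank(d)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)
  expect_equal(lr$hazard_ratio, 1, tolerance = 1e-12)

  # no events at all: statistic 0, p 1, flagged
  none <- log_rank(survival_data(c(1, 2, 3, 4), rep(0, 4),
                                 rep(c("A", "B"), 2)))
  expect_equal(none$chisq, 0)
  expect_equal(none$p, 1)
  expect_true(none$degenerate)

  # one group without events: O/E ratio degenerate, flagged
  deg <- log_rank(survival_data(c(1, 1, 5, 5), c(1, 1, 0, 0),
                                c("A", "A", "B", "B")))
  expect_true(deg$degenerate)

  expect_error(log_rank(survival_data(1, 1, "A")), "two groups")
})

test_that("the risk-analysis report formats p-values like the source table", {
  rep_ <- risk_analysis(ref_table())
  expect_identical(rep_$p_formatted[rep_$measure == "risk_difference"],
                   "0.000")
  expect_setequal(rep_$measure,
                  c("risk_cohort1", "risk_cohort2", "risk_difference",
                    "risk_ratio", "odds_ratio"))
})
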