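# deterministic toy model table: dung depends on fix and DW with known
# coefficients, other covariates are noise
toy_table <- function(n_plots = 30, n_weeks = 12, seed = 1,
                      beta_fix = 2, beta_dw = -0.01, sigma = 0.1) {
  set.seed(seed)
  plots <- data.frame(plot_id = seq_len(n_plots),
                      x = runif(n_plots, 0, 600),
                      y = runif(n_plots, 0, 300), radius = 5)
  tab <- expand.grid(plot_id = plots$plot_id, week = seq_len(n_weeks))
  tab$fix <- rpois(nrow(tab), 4)
  tab$fix_resting <- rbinom(nrow(tab), tab$fix, 0.6)
  tab$DW <- rep(runif(n_plots, 0, 600), n_weeks)
  tab$CC <- rep(runif(n_plots, 0, 1), n_weeks)
  tab$SL <- rep(runif(n_plots, 0, 25), n_weeks)
  tab$TA <- rep(runif(n_weeks, 8, 28), each = n_plots)
  tab$dung <- 1 + beta_fix * tab$fix + beta_dw * tab$DW +
    rnorm(nrow(tab), 0, sigma)
  list(tab = tab, plots = plots)
}

test_that("unit aggregation sums counts and averages covariates", {
  tt <- toy_table(n_plots = 8, n_weeks = 4)
  # identity at 1 x 1
  a11 <- aggregate_units(tt$tab, tt$plots, 1, 1)
  expect_equal(sum(a11$table$dung), sum(tt$tab$dung))
  expect_equal(nrow(a11$table), nrow(tt$tab))

  # two weeks of counts 3 and 4 under a 2-week block -> 7
  small <- data.frame(plot_id = 1, week = 1:2, dung = c(3, 4),
                      fix = c(1, 1), DW = c(10, 10))
  p1 <- data.frame(plot_id = 1, x = 0, y = 0, radius = 5)
  a2 <- aggregate_units(small, p1, 1, 2)
  expect_equal(a2$table$dung, 7)
  expect_equal(a2$table$DW, 10)

  # grouped totals equal brute-force sums over the membership lists
  a44 <- aggregate_units(tt$tab, tt$plots, 4, 1)
  gg <- a44$groups
  for (u in unique(gg$unit_id[gg$complete])) {
    members <- gg$plot_id[!is.na(gg$unit_id) & gg$unit_id == u]
    for (w in 1:4) {
      expect_equal(
        a44$table$dung[a44$table$unit_id == u & a44$table$block == w],
        sum(tt$tab$dung[tt$tab$plot_id %in% members & tt$tab$week == w]))
    }
  }
  # groups are disjoint sets of four
  expect_true(all(table(gg$unit_id) == 4))

  # leftover plots form a flagged incomplete group
  a_rem <- aggregate_units(tt$tab[tt$tab$plot_id <= 6, ],
                           tt$plots[1:6, ], 4, 1)
  expect_equal(length(a_rem$dropped_plots), 2)
})

test_that("the OLS core matches the normal equations to machine precision", {
  tt <- toy_table()
  fit <- stepwise_fit(tt$tab, gps = "fix", covariates = c("DW", "CC", "SL"))
  expect_true(all(c("fix", "DW") %in% fit$terms))
  X <- cbind(1, as.matrix(tt$tab[fit$terms]))
  beta <- solve(t(X) %*% X, t(X) %*% tt$tab$dung)
  expect_equal(unname(fit$coefficients[c("(Intercept)", fit$terms)]),
               as.numeric(beta), tolerance = 1e-10)
})

test_that("stepwise recovers a near-noiseless generative model", {
  tt <- toy_table(sigma = 1e-6)
  # near-zero residual variance triggers "essentially perfect fit" notes
  fit <- suppressWarnings(
    stepwise_fit(tt$tab, gps = c("fix", "fix_resting"),
                 covariates = c("DW", "CC", "SL", "TA")))
  expect_equal(fit$gps_used, "fix")
  expect_equal(unname(fit$coefficients["fix"]), 2, tolerance = 1e-4)
  expect_equal(unname(fit$coefficients["DW"]), -0.01, tolerance = 1e-4)
  expect_gt(fit$r2, 0.999)
  # the resting-only variant is blocked once the total enters
  expect_false("fix_resting" %in% fit$terms)
})

test_that("pure noise rarely admits a lone candidate at the entry level", {
  # with a single candidate the entry test is a plain F test at alpha=0.05
  reps <- 60
  picked <- 0
  for (k in seq_len(reps)) {
    set.seed(1000 + k)
    d <- data.frame(dung = rnorm(150), fix = rnorm(150))
    f <- suppressWarnings(stepwise_fit(d, gps = "fix",
                                       covariates = character(0)))
    picked <- picked + !f$intercept_only
  }
  expect_lt(picked / reps, 0.15)

  # with many candidates the family-wise pick-up rate reflects multiplicity
  picked_multi <- 0
  for (k in seq_len(30)) {
    set.seed(2000 + k)
    d <- data.frame(dung = rnorm(150), fix = rnorm(150), DW = rnorm(150),
                    CC = rnorm(150), SL = rnorm(150), TA = rnorm(150))
    f <- suppressWarnings(stepwise_fit(d, gps = "fix",
                                       covariates = c("DW", "CC", "SL",
                                                      "TA")))
    picked_multi <- picked_multi + !f$intercept_only
  }
  expect_lt(picked_multi / 30, 1 - (1 - 0.05)^5 + 0.25)
  expect_equal(suppressWarnings(
    stepwise_fit(data.frame(dung = rnorm(50), fix = rnorm(50)),
                 gps = "fix", covariates = character(0),
                 entry = 1e-12))$intercept_only, TRUE)
})

test_that("70/30 validation splits match the study calendar", {
  tt <- toy_table(n_plots = 20, n_weeks = 19)
  agg <- aggregate_units(tt$tab, tt$plots, 1, 1)
  sv <- split_validate(agg, "temporal", gps = "fix",
                       covariates = c("DW", "CC"))
  expect_equal(sv$split_ids, 1:13)   # weeks 1-13 calibrate, 14-19 validate
  expect_equal(sv$n_cal, 20 * 13)
  expect_equal(sv$n_val, 20 * 6)
  # near-noiseless generative model: both errors tiny and comparable
  expect_lt(sv$mae_val, 1)
  expect_lt(sv$mae_cal, 1)

  sv2 <- split_validate(agg, "spatial", seed = 4, gps = "fix",
                        covariates = c("DW", "CC"))
  expect_equal(length(sv2$split_ids), 14)   # floor(0.7 * 20)
  expect_lt(sv2$mae_val, 1)

  # an empty validation side is an error
  one_week <- aggregate_units(tt$tab[tt$tab$week == 1, ], tt$plots, 1, 1)
  expect_error(split_validate(one_week, "temporal"), "empty")
})

test_that("MAE is normalized per plot and week", {
  tt <- toy_table(n_plots = 40, n_weeks = 24, sigma = 3)
  agg <- aggregate_units(tt$tab, tt$plots, 4, 6)
  expect_equal(agg$plots_per_unit * agg$weeks_per_unit, 24)
  sv <- suppressWarnings(
    split_validate(agg, "temporal", frac = 0.5, gps = "fix",
                   covariates = c("DW", "CC")))
  cal <- agg$table[agg$table$block %in% sv$split_ids, ]
  raw_mae <- mean(abs(cal$dung - predict(sv$fit$model, newdata = cal)))
  expect_equal(sv$mae_cal, raw_mae / 24)
})

test_that("correlation scans behave on identical and noisy pairs", {
  tt <- toy_table(n_plots = 15, n_weeks = 8)
  tab <- tt$tab
  tab$dung <- tab$fix   # identical series
  cs <- correlation_scan(tab, "fix", plots = tt$plots)
  expect_equal(cs$per_week$r, rep(1, 8))
  expect_equal(cs$cumulative$r, rep(1, 8))
  expect_equal(cs$spatial$r, c(1, 1))

  set.seed(77)
  tab$dung <- rnorm(nrow(tab))
  cs2 <- correlation_scan(tab, "fix")
  expect_true(all(abs(cs2$per_week$r) < 0.6))
  expect_lt(abs(cs2$cumulative$r[8]), 0.3)

  # zero-variance side is flagged as NA
  tab$fix <- 1
  cs3 <- correlation_scan(tab, "fix")
  expect_true(all(is.na(cs3$per_week$r)))
})

test_that("hotspot calls apply absolute and relative thresholds", {
  preds <- data.frame(unit_id = 1:5,
                      predicted = c(10, 20, 30, 150, 40))
  hc <- detect_hotspots(preds)
  expect_equal(hc$is_hotspot, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  none <- detect_hotspots(data.frame(unit_id = 1:3,
                                     predicted = c(1, 2, 3)))
  expect_false(any(none$is_hotspot))
  rel <- detect_hotspots(preds, relative = TRUE, rel_factor = 2)
  expect_equal(rel$threshold[1], 2 * 30)
  expect_equal(sum(rel$is_hotspot), 1)
})
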