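test_that("movement distance sums step lengths in km", {
  s <- make_steps(c(1000, 1000), hourly(2))
  expect_equal(movement_distance(s), 2)

  ## closed square loop sampled at its corners
  tr <- segment_bursts(make_traj(c(0, 1000, 1000, 0, 0),
                                 c(0, 0, 1000, 1000, 0), hourly(5)))
  expect_equal(movement_distance(build_step_series(tr)), 4)

  ## stationary animal
  tr0 <- segment_bursts(make_traj(rep(5, 4), rep(5, 4), hourly(4)))
  expect_equal(movement_distance(build_step_series(tr0)), 0)

  expect_true(is.na(movement_distance(make_steps(1, hourly(1))[0, ])))
})

test_that("diurnality index follows the day-minus-night definition", {
  ## all movement starting 06:00-18:00 is exclusively diurnal: +1
  t_day <- as.POSIXct("2016-03-01 06:00", tz = "UTC") + 3600 * (0:11)
  expect_equal(diurnality(make_steps(rep(500, 12), t_day)), 1)

  ## all movement 18:00-06:00 is exclusively nocturnal: -1
  t_night <- as.POSIXct("2016-03-01 18:00", tz = "UTC") + 3600 * (0:11)
  expect_equal(diurnality(make_steps(rep(500, 12), t_night)), -1)

  ## 3 km by day, 1 km by night in one day: (3 - 1) / 4 = 0.5
  tt <- as.POSIXct(c("2016-03-01 10:00", "2016-03-01 20:00"), tz = "UTC")
  expect_equal(diurnality(make_steps(c(3000, 1000), tt)), 0.5)

  ## the index is a mean over days, not a pooled ratio
  t2 <- as.POSIXct(c("2016-03-01 10:00", "2016-03-02 20:00"), tz = "UTC")
  expect_equal(diurnality(make_steps(c(3000, 1000), t2)), 0)  # (+1 + -1)/2

  ## boundary conventions: 18:00 starts are night, 06:00 starts are day
  t3 <- as.POSIXct(c("2016-03-01 06:00", "2016-03-01 18:00"), tz = "UTC")
  expect_equal(diurnality(make_steps(c(1000, 1000), t3)), 0)

  ## zero-distance days are excluded; all-zero windows are missing
  t4 <- as.POSIXct(c("2016-03-01 10:00", "2016-03-02 10:00"), tz = "UTC")
  expect_equal(diurnality(make_steps(c(0, 800), t4)), 1)
  expect_true(is.na(diurnality(make_steps(c(0, 0), t4))))
})

test_that("exploratory proportion counts decoded states", {
  st <- factor(c(rep("exploratory", 3), rep("encamped", 9)),
               levels = c("encamped", "exploratory"))
  expect_equal(exploratory_proportion(st), 0.25)
  expect_equal(exploratory_proportion(st) +
                 mean(st == "encamped"), 1)       # complement partition
  expect_equal(exploratory_proportion(rep(st[1], 5)), 1)
  expect_true(is.na(exploratory_proportion(factor(character(),
                                                  levels = levels(st)))))
})

## deterministic two-month synthetic track: a tight cluster that shifts
## between months, moving mostly by day
fixture_trajs <- function() {
  set.seed(40)
  t <- hourly(24 * (31 + 29), start = "2016-01-01 00:00:00")
  n <- length(t)
  hrs <- as.integer(format(t, "%H"))
  step_len <- ifelse(hrs >= 6 & hrs < 18, 400, 100)
  ang <- runif(n, -pi, pi)
  feb <- format(t, "%m") == "02"
  x <- 5000 + cumsum(step_len * cos(ang)) * 0.05 + feb * 1500
  y <- 5000 + cumsum(step_len * sin(ang)) * 0.05
  list(a = make_traj(x, y, t, id = "a"),
       b = make_traj(x + 20000, y, t, id = "b", sex = "male",
                     region = "r2"))
}

test_that("behavior table applies definitions and inclusion rules", {
  trajs <- lapply(fixture_trajs(), segment_bursts)
  steps <- do.call(rbind, lapply(trajs, build_step_series))
  class(steps) <- c("step_series", "data.frame")
  states <- factor(rep(c("encamped", "exploratory"), length.out = nrow(steps)),
                   levels = c("encamped", "exploratory"))

  tab <- assemble_behavior_table(trajs, steps, states, scale = "monthly")
  expect_equal(nrow(tab), 4L)                     # 2 individuals x 2 months
  expect_equal(sort(unique(tab$window)), c("2016-01", "2016-02"))

  ## fidelity missing at the first step, defined at the second
  expect_true(all(is.na(tab$site_fidelity[tab$window == "2016-01"])))
  expect_true(all(!is.na(tab$site_fidelity[tab$window == "2016-02"])))
  expect_true(all(tab$site_fidelity >= 0 & tab$site_fidelity <= 1,
                  na.rm = TRUE))
  expect_true(all(tab$diurnality > 0))            # day steps are longer
  expect_equal(tab$exploratory_prop,
               rep(0.5, 4), tolerance = 0.01)

  ## distances equal the sum of the per-window step lengths
  jan_a <- steps$individual_id == "a" &
    format(steps$t_start, "%Y-%m") == "2016-01"
  expect_equal(tab$distance_km[tab$individual_id == "a" &
                                 tab$window == "2016-01"],
               sum(steps$step[jan_a]) / 1000)

  ## an individual present for only part of a month is excluded there
  short <- trajs
  keep <- format(short$a$t_local, "%m") == "01" |
    as.integer(format(short$a$t_local, "%d")) <= 5
  short$a <- segment_bursts(short$a[keep, ])
  tab2 <- assemble_behavior_table(short, steps, states, scale = "monthly")
  expect_equal(sum(tab2$individual_id == "a"), 1L)
  excl <- attr(tab2, "exclusions")
  expect_true(any(excl$individual_id == "a" & excl$window == "2016-02"))
})

test_that("monthly distances sum exactly to the annual distance", {
  set.seed(41)
  t <- hourly(24 * 366, start = "2016-01-01 00:00:00")
  x <- cumsum(rnorm(length(t), sd = 300))
  y <- cumsum(rnorm(length(t), sd = 300))
  tr <- segment_bursts(make_traj(x, y, t))
  steps <- build_step_series(tr)
  states <- factor(rep("encamped", nrow(steps)),
                   levels = c("encamped", "exploratory"))
  mon <- assemble_behavior_table(list(tr), steps, states, scale = "monthly",
                                 h = 500)
  ann <- assemble_behavior_table(list(tr), steps, states, scale = "annual",
                                 h = 500)
  expect_equal(nrow(mon), 12L)
  expect_equal(nrow(ann), 1L)
  expect_equal(sum(mon$distance_km), ann$distance_km, tolerance = 1e-12)

  ## a 14-month record gives one annual row and 14 monthly rows
  t14 <- hourly(24 * (366 + 59), start = "2016-01-01 00:00:00")
  x14 <- cumsum(rnorm(length(t14), sd = 300))
  y14 <- cumsum(rnorm(length(t14), sd = 300))
  tr14 <- segment_bursts(make_traj(x14, y14, t14))
  s14 <- build_step_series(tr14)
  st14 <- factor(rep("encamped", nrow(s14)),
                 levels = c("encamped", "exploratory"))
  expect_equal(nrow(assemble_behavior_table(list(tr14), s14, st14,
                                            scale = "monthly", h = 500)), 14L)
  expect_equal(nrow(assemble_behavior_table(list(tr14), s14, st14,
                                            scale = "annual", h = 500)), 1L)
})

test_that("fidelity follows the successive-month rule", {
  ## months Jan, Feb, Apr present: fidelity defined for Feb only
  set.seed(42)
  mk_month <- function(m, days) {
    t <- hourly(24 * days, start = sprintf("2016-%02d-01 00:00:00", m))
    make_traj(cumsum(rnorm(length(t), sd = 200)),
              cumsum(rnorm(length(t), sd = 200)), t)
  }
  parts <- lapply(list(c(1, 31), c(2, 29), c(4, 30)),
                  function(z) mk_month(z[1], z[2]))
  tr <- do.call(rbind, parts)
  class(tr) <- c("trajectory", "data.frame")
  tr <- segment_bursts(tr)
  steps <- build_step_series(tr)
  states <- factor(rep("exploratory", nrow(steps)),
                   levels = c("encamped", "exploratory"))
  tab <- assemble_behavior_table(list(tr), steps, states, scale = "monthly",
                                 h = 400)
  expect_equal(tab$window, c("2016-01", "2016-02", "2016-04"))
  expect_equal(is.na(tab$site_fidelity), c(TRUE, FALSE, TRUE))
  ## bookkeeping identity: defined fidelity records = records - number of
  ## non-successive window starts
  expect_equal(sum(!is.na(tab$site_fidelity)), nrow(tab) - 2L)
})
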