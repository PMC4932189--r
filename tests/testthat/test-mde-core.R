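test_that("HPD bounds round to the closest million with half away from zero", {
  expect_equal(round_interval(2.4, 0.6), data.frame(young = 1L, old = 2L))
  expect_equal(round_interval(5.0, 5.0), data.frame(young = 5L, old = 5L))
  expect_equal(round_interval(3.5, 0.5), data.frame(young = 1L, old = 4L))
  expect_equal(round_interval(c(2.5, 1.49), c(1.5, 0.49)),
               data.frame(young = c(2L, 0L), old = c(3L, 1L)))
  expect_error(round_interval(1, 2), "hpd_young")
})

make_table <- function(old, young) {
  n <- length(old)
  event_table(event_id = sprintf("e%d", seq_len(n)), dataset_id = rep("d", n),
              taxon_group = rep("plant", n), direction = rep("asia_to_india", n),
              hpd_old_ma = old, hpd_young_ma = young)
}

test_that("compute_mde counts interval coverage per 1-Myr slice", {
  empty <- event_table()
  expect_equal(compute_mde(empty, t_max = 10)$value, rep(0, 11))

  one <- make_table(2.4, 0.6)                 # rounds to (1, 2)
  expect_equal(compute_mde(one, t_max = 5)$value, c(0, 1, 1, 0, 0, 0))

  two <- make_table(c(5, 3.2), c(0.2, 2.1))   # (0,5) and (2,3)
  expect_equal(compute_mde(two, t_max = 6)$value, c(1, 1, 2, 2, 1, 1, 0))
})

test_that("events beyond the analysis span are dropped with a warning, straddlers clipped", {
  tab <- make_table(c(80, 75), c(74.6, 65))
  expect_warning(s <- compute_mde(tab, t_max = 70), "dropped.*e1")
  # e1 (75..80) gone; e2 (65..75) clipped to 65..70
  expect_equal(s$value[66:71], rep(1, 6))
  expect_equal(sum(s$value), 6)
  expect_equal(s$n_events, 1L)
})

test_that("compute_mde agrees with the per-event per-slice brute force on random tables", {
  set.seed(31)
  for (rep in 1:50) {
    tab <- random_event_table(sample(1:40, 1))
    t_max <- sample(c(30, 70), 1)
    s <- suppressWarnings(compute_mde(tab, t_max = t_max))
    expect_identical(as.integer(s$value), brute_mde(tab, t_max))
  }
})

test_that("raw MDE mass, bound and shift identities hold", {
  set.seed(32)
  tab <- random_event_table(50)
  t_max <- 70L
  s <- compute_mde(tab, t_max = t_max)
  b <- round_interval(tab$hpd_old_ma, tab$hpd_young_ma)
  keep <- b$young <= t_max
  expect_equal(sum(s$value),
               sum(pmin(b$old[keep], t_max) - pmax(b$young[keep], 0L) + 1L))
  expect_true(all(s$value <= nrow(tab)))

  # adding k Myr to both bounds shifts the series by k slices (up to clipping)
  k <- 4
  shifted <- make_table(tab$hpd_old_ma + k, tab$hpd_young_ma + k)
  s2 <- suppressWarnings(compute_mde(shifted, t_max = t_max))
  expect_equal(s2$value[(k + 1):(t_max - 10)], s$value[1:(t_max - 10 - k)])
})

test_that("sliding-window smoothing has the stated fixed points and edge behaviour", {
  const <- new_series <- compute_mde(make_table(numeric(0), numeric(0)), t_max = 20)
  const$value <- rep(3, 21)
  expect_equal(smooth_series(const, 5)$value, rep(3, 21))
  expect_equal(smooth_series(const, 1)$value, const$value)  # w = 1 identity

  imp <- const
  imp$value <- c(rep(0, 10), 5, rep(0, 10))   # impulse at t = 10
  sm <- smooth_series(imp, 5)
  expect_equal(sm$value[9:13], rep(1, 5))     # t = 8..12
  expect_equal(sm$value[c(1:8, 14:21)], rep(0, 16))
  expect_identical(sm$stage, "smoothed")

  # edge truncation: leading value averages over the 3 available points
  edge <- const
  edge$value <- c(6, rep(0, 20))
  expect_equal(smooth_series(edge, 5)$value[1], 2)

  expect_error(smooth_series(const, 4), "odd")
})

test_that("the avian bias cutoff is the crossing closest to the present", {
  grid_series <- function(v) {
    s <- compute_mde(make_table(numeric(0), numeric(0)), t_max = length(v) - 1L)
    s$value <- v
    smooth_series(s, 1)   # mark as smoothed without altering values
  }
  avian <- grid_series(seq(10, 0, by = -1))      # 10 at present, falling
  non_avian <- grid_series(seq(0, 10, by = 1))   # rising with age
  expect_equal(avian_bias_cutoff(avian, non_avian), 5L)

  below <- grid_series(rep(0, 11))
  above <- grid_series(rep(2, 11))
  expect_equal(avian_bias_cutoff(below, above), 0L)       # never exceeds
  expect_equal(avian_bias_cutoff(above, above), 0L)       # identical: no crossing

  # exact-tie plateau resolves to its youngest point
  av <- grid_series(c(5, 4, 3, 3, 3, 2, 1, 0, 0, 0, 0))
  na <- grid_series(c(0, 1, 3, 3, 3, 4, 5, 6, 7, 8, 9))
  expect_equal(avian_bias_cutoff(av, na), 2L)

  short <- grid_series(rep(1, 5))
  expect_error(avian_bias_cutoff(avian, short), "different time grids")
  raw <- compute_mde(make_table(3, 1), t_max = 10)
  expect_error(avian_bias_cutoff(raw, raw), "smooth")
})

test_that("truncation removes slices younger than the cutoff and records it", {
  set.seed(33)
  s <- compute_mde(random_event_table(20), t_max = 70)
  expect_equal(truncate_series(s, 0)$value, s$value)

  t7 <- truncate_series(s, 7)
  expect_equal(length(t7$value), 64)
  expect_equal(range(t7$age), c(7, 70))
  expect_equal(t7$truncation_age, 7L)
  expect_equal(t7$value, s$value[s$age >= 7])

  tip <- truncate_series(s, 70)
  expect_equal(length(tip$value), 1L)
  expect_error(truncate_series(s, 71), "exceeds")
})

test_that("stratified series conserve the pooled series for any partition", {
  set.seed(34)
  tab <- random_event_table(50)
  pooled <- compute_mde(tab, t_max = 70)
  for (by in c("direction", "taxon_group")) {
    strata <- stratified_mde(tab, t_max = 70, by = by)
    summed <- Reduce(`+`, lapply(strata, `[[`, "value"))
    expect_equal(summed, pooled$value)
  }

  # single-direction table: one active stratum, the other all zero
  one_dir <- filter_events(tab, direction = "asia_to_india")
  st <- stratified_mde(one_dir, t_max = 70, by = "direction")
  expect_equal(st$india_to_asia$value, rep(0, 71))
  expect_equal(st$asia_to_india$value, compute_mde(one_dir, t_max = 70)$value)
})
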