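test_that("energy divergence matches hand evaluation and the naive formula", {
  d <- energy_divergence(c(0, 0), c(1, 1), alpha = 1)
  expect_equal(d$e_hat, 2)
  expect_equal(d$q_hat, 2)

  expect_equal(energy_divergence(c(3, 3, 3), c(3, 3, 3))$e_hat, 0)

  set.seed(41)
  for (alpha in c(0.5, 1, 1.5, 2)) {
    x <- rnorm(7); y <- rnorm(5, mean = 2)
    d <- energy_divergence(x, y, alpha)
    expect_equal(d$e_hat, naive_e_hat(x, y, alpha))
    # symmetry and homogeneity of degree alpha
    expect_equal(energy_divergence(y, x, alpha)$e_hat, d$e_hat)
    expect_equal(energy_divergence(3 * x, 3 * y, alpha)$e_hat, 3^alpha * d$e_hat)
  }

  expect_error(energy_divergence(1, c(1, 2)), "at least 2")
  expect_error(energy_divergence(c(1, 2), c(1, 2), alpha = 2.5), "alpha")
})

test_that("best_split is exhaustive: equals brute-force search on segments up to length 50", {
  set.seed(42)
  for (rep in 1:40) {
    L <- sample(10:50, 1)
    min_size <- sample(2:5, 1)
    alpha <- sample(c(0.5, 1, 2), 1)
    z <- rnorm(L) + rep(c(0, sample(0:3, 1)), times = c(L %/% 2, L - L %/% 2))
    got <- best_split(z, min_size = min_size, alpha = alpha)
    want <- naive_best_split(z, min_size, alpha)
    expect_equal(got$kappa, want$kappa)
    expect_equal(got$q_hat, want$q_hat, tolerance = 1e-10)
  }
})

test_that("best_split boundary behaviour: regime boundary, ties, short segments", {
  two <- c(rep(0, 10), rep(10, 10))
  expect_equal(best_split(two, min_size = 5)$kappa, 10L)

  const <- rep(4, 20)
  bs <- best_split(const, min_size = 5)
  expect_equal(bs$q_hat, 0)
  expect_equal(bs$kappa, 5L)   # smallest admissible kappa on ties

  expect_null(best_split(rnorm(9), min_size = 5))
})

test_that("permutation p-value matches the exhaustive small-case exceedance probability", {
  # 4 zeros then 4 tens: of the choose(8,4)=70 distinct arrangements, only the
  # two perfectly separated ones reach the observed split statistic, so the
  # permutation exceedance probability is exactly 2/70
  z <- c(rep(0, 4), rep(10, 4))
  arrangements <- combn(8, 4)
  obs <- naive_best_split(z, 2, 1)$q_hat
  hits <- 0L
  for (i in seq_len(ncol(arrangements))) {
    v <- rep(0, 8); v[arrangements[, i]] <- 10
    if (naive_best_split(v, 2, 1)$q_hat >= obs - 1e-12) hits <- hits + 1L
  }
  p_exact <- hits / ncol(arrangements)
  expect_equal(p_exact, 2 / 70)

  fit <- e_divisive(z, R = 4000, sig_level = 0.05, min_size = 2, seed = 7)
  expect_equal(fit$k, 1L)
  expect_equal(fit$estimates$index, 5L)
  # add-one Monte-Carlo estimate of the exact exceedance probability
  expect_lt(abs(fit$estimates$p_value - p_exact), 0.012)
})

test_that("e_divisive is deterministic under a fixed seed", {
  set.seed(43)
  z <- c(rpois(20, 2), rpois(25, 8), rpois(20, 2))
  a <- e_divisive(z, R = 199, seed = 99)
  b <- e_divisive(z, R = 199, seed = 99)
  expect_identical(a$estimates, b$estimates)
  expect_identical(a$stop_p, b$stop_p)
})

test_that("a constant series yields no change points", {
  fit <- e_divisive(rep(2, 40), R = 99, seed = 1)
  expect_equal(fit$k, 0L)
  expect_equal(fit$stop_p, 1)   # every permutation ties the observed zero
})

test_that("a strong Poisson rate jump is located at the regime boundary", {
  hits <- 0L
  extra <- 0L
  for (s in 1:40) {
    set.seed(s)
    z <- c(rpois(15, 1), rpois(15, 12))
    fit <- e_divisive(z, R = 299, seed = 1000 + s)
    if (any(abs(fit$estimates$index - 16L) <= 1L)) hits <- hits + 1L
    if (fit$k > 1L) extra <- extra + 1L
  }
  expect_gte(hits, 38L)   # boundary found (within 1 index) in >= 95% of seeds
  expect_lte(extra, 6L)   # spurious second splits stay near the test level
})

test_that("two well-separated noiseless shifts are both recovered, ordered by statistic", {
  z <- rep(c(0, 10, 20), each = 20)
  fit <- e_divisive(z, R = 499, min_size = 5, seed = 5)
  expect_equal(fit$k, 2L)
  expect_setequal(fit$estimates$index, c(21L, 41L))
  # detection order follows statistic magnitude: the global maximum first
  expect_true(fit$estimates$q_hat[1] >= fit$estimates$q_hat[2])
})

test_that("min_size separation is enforced against the series ends and between points", {
  set.seed(44)
  for (rep in 1:5) {
    z <- c(rpois(12, 1), rpois(12, 6), rpois(12, 15), rpois(12, 2))
    fit <- e_divisive(z, R = 199, min_size = 5, seed = rep)
    idx <- sort(fit$estimates$index)
    if (length(idx)) {
      expect_true(all(idx >= 6 & idx <= length(z) - 4))
      if (length(idx) > 1) expect_true(all(diff(idx) >= 5))
    }
  }
})

test_that("detection power is monotone in the size of a single mean shift", {
  rates <- vapply(c(0.3, 1.5, 6), function(shift) {
    found <- 0L
    for (s in 1:15) {
      set.seed(200 + s)
      z <- rnorm(40) + rep(c(0, shift), each = 20)
      fit <- e_divisive(z, R = 199, seed = 300 + s)
      if (fit$k >= 1L) found <- found + 1L
    }
    found / 15
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.9)
})

test_that("mde_series input is analysed oldest-first and ages map back to the grid", {
  # raw counts with a step: high flux in the older half of a 0..39 Ma grid
  tab <- event_table(
    event_id = sprintf("e%d", 1:30), dataset_id = "d", taxon_group = "plant",
    direction = "asia_to_india",
    hpd_old_ma = c(runif(25, 25, 39), runif(5, 2, 10)),
    hpd_young_ma = c(runif(25, 21, 24), runif(5, 0, 2))
  )
  s <- compute_mde(tab, t_max = 39)
  fit <- e_divisive(s, R = 299, seed = 8)
  expect_true(fit$k >= 1L)
  # reported age must sit on the grid and equal the age at the reported index
  expect_true(all(fit$estimates$age_ma %in% s$age))
  expect_equal(fit$estimates$age_ma, rev(s$age)[fit$estimates$index])
  expect_error(e_divisive(rnorm(9), min_size = 5), "too short")
})

test_that("package recursion agrees with an independent naive divisive implementation", {
  cases <- list(
    c(rep(0, 12), rep(9, 12)),
    rep(c(1, 7, 1), each = 15) + seq(0, 0.044, by = 0.001),
    rep(2.5, 30)
  )
  for (i in seq_along(cases)) {
    z <- cases[[i]]
    fit <- e_divisive(z, R = 199, min_size = 5, seed = 17)
    ref <- naive_e_divisive(z, R = 199, sig_level = 0.05, min_size = 5,
                            alpha = 1, seed = 17)
    expect_identical(sort(fit$estimates$index), ref,
                     info = sprintf("case %d", i))
  }
})
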