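test_that("the exponential-decay MLE has its closed form", {
  # single carrier chromosome, one side of 0.01 M: g = k / sum(l) = 100
  a <- estimate_generations(length_observations(0.01, mode = "carrier"))
  expect_equal(a$g_hat, 100)
  expect_true(a$ci_low <= a$g_hat && a$g_hat <= a$ci_high)

  # 7 homozygotes, 14 one-sided lengths summing 0.0225 M: 14/(2*0.0225)
  lens <- rep(0.0225 / 14, 14)
  a2 <- estimate_generations(length_observations(lens, mode = "homozygote"))
  expect_equal(a2$g_hat, 14 / (2 * 0.0225))
  expect_equal(a2$g_hat, 311.1, tolerance = 1e-3)
  expect_equal(a2$years, a2$g_hat * 25)
})

test_that("censored sides add exposure but no event", {
  obs <- length_observations(c(0.01, 0.02), censored = c(FALSE, TRUE),
                             mode = "carrier")
  expect_equal(estimate_generations(obs)$g_hat, 1 / 0.03)
  expect_error(
    estimate_generations(length_observations(c(0.01, 0.02),
                                             censored = c(TRUE, TRUE),
                                             mode = "carrier")),
    "age unidentifiable")
  expect_error(
    estimate_generations(length_observations(c(0, 0), mode = "carrier")),
    "zero")
})

test_that("the exact chi-square CI covers the truth at its nominal rate", {
  withr::local_seed(2026)
  g <- 311
  covered <- logical(2000)
  for (r in seq_len(2000)) {
    lens <- rexp(14, rate = 2 * g)
    a <- estimate_generations(length_observations(lens, mode = "homozygote"))
    covered[r] <- a$ci_low <= g && g <= a$ci_high
  }
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("estimate is scale-homogeneous and monotone in each length", {
  withr::local_seed(99)
  lens <- rexp(10, 500)
  base <- estimate_generations(length_observations(lens, mode = "homozygote"))
  for (s in runif(5, 0.1, 10)) {
    scaled <- estimate_generations(length_observations(lens * s,
                                                       mode = "homozygote"))
    expect_equal(scaled$g_hat, base$g_hat / s)
  }
  for (i in c(1, 5, 10)) {
    longer <- lens; longer[i] <- longer[i] + 0.001
    a <- estimate_generations(length_observations(longer, mode = "homozygote"))
    expect_lt(a$g_hat, base$g_hat)
  }
})

test_that("the MLE recovers known ages across the plausible range", {
  withr::local_seed(123)
  for (g in c(50, 311, 1000)) {
    n_rep <- 2000  # coverage band is +-2%; 2000 reps put MC error well inside
    ghat <- numeric(n_rep); cov <- logical(n_rep)
    for (r in seq_len(n_rep)) {
      lens <- rexp(14, rate = 2 * g)
      a <- estimate_generations(length_observations(lens, mode = "homozygote"))
      ghat[r] <- a$g_hat
      cov[r] <- a$ci_low <= g && g <= a$ci_high
    }
    expect_lt(abs(median(ghat[1:500]) - g) / g, 0.15)
    expect_gte(mean(cov), 0.93)
    expect_lte(mean(cov), 0.97)
  }
})

test_that("generations convert to years by exact multiplication", {
  expect_identical(generations_to_years(311, 25), 7775)
  expect_identical(generations_to_years(0, 25), 0)
  expect_identical(generations_to_years(107, 25), 2675)
  expect_identical(generations_to_years(975, 25), 24375)
  expect_error(generations_to_years(-1, 25), "non-negative")
})

test_that("physical bounds convert to genetic lengths through the map", {
  blocks <- data.frame(sample = "S1",
                       left_bp = 1000000 - 220400, right_bp = 1000000 + 50000,
                       focal_pos = 1000000,
                       left_morgans = NA_real_, right_morgans = NA_real_,
                       left_censored = FALSE, right_censored = FALSE)
  obs <- physical_to_genetic(blocks, map = genetic_map_uniform(1))
  expect_equal(obs$lengths, c(0.002204, 0.0005))
  expect_equal(obs$censored, c(FALSE, FALSE))

  # a bound sitting on the region edge is censored
  obs2 <- physical_to_genetic(blocks, map = genetic_map_uniform(1),
                              region = c(1000000 - 220400, 2e6))
  expect_equal(obs2$censored, c(TRUE, FALSE))
})

test_that("simulator truth lengths match map-converted block lengths", {
  sim <- simulate_cohort(sim_config(seed = 11))
  blocks <- delineate_blocks(sim$genotypes)
  obs_map <- physical_to_genetic(blocks, map = sim$config$map)
  obs_panel <- physical_to_genetic(blocks)
  expect_equal(obs_map$lengths, obs_panel$lengths, tolerance = 1e-9)

  truth <- sim$truth
  gap <- max(diff(sim$genotypes$panel$cm)) / 100
  t_side <- vapply(seq_len(nrow(blocks)), function(i) {
    s <- blocks$sample[i]
    c(min(truth$length_morgans[truth$sample == s & truth$side == "left"]),
      min(truth$length_morgans[truth$sample == s & truth$side == "right"]))
  }, numeric(2))
  d_side <- rbind(blocks$left_morgans, blocks$right_morgans)
  expect_gte(mean(abs(d_side - t_side) <= gap + 1e-12), 0.95)
})
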