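test_that("ZOIB log-density matches closed-form point masses and the uniform case", {
  # mu = 0.5, phi = 2 is Beta(1, 1): log-density 0 at any interior point
  expect_equal(zoib_logdensity(0.5, 0.5, 2, 0, 0), 0)
  expect_equal(zoib_logdensity(0, 0.5, 2, 0.3, 0), log(0.3))
  expect_equal(zoib_logdensity(1, 0.5, 2, 0.4, 0.5), log(0.2))
  expect_error(zoib_logdensity(1.2, 0.5, 2, 0.1, 0.5), "\\[0, 1\\]")
  expect_error(zoib_logdensity(0.5, 0.5, -1, 0.1, 0.5), "positive")
})

test_that("ZOIB total mass is one: point masses plus continuous quadrature", {
  cases <- list(c(mu = 0.3, phi = 5, p01 = 0.25, coi = 0.6),
                c(mu = 0.7, phi = 0.8, p01 = 0.1, coi = 0.9),
                c(mu = 0.5, phi = 2, p01 = 0, coi = 0))
  for (cs in cases) {
    f <- function(y) {
      exp(zoib_logdensity(y, cs["mu"], cs["phi"], cs["p01"], cs["coi"]))
    }
    # split the range so endpoint singularities of U-shaped betas sit at
    # integration limits, where the quadrature handles them
    cont <- stats::integrate(f, 0, 0.5, rel.tol = 1e-10)$value +
      stats::integrate(f, 0.5, 1, rel.tol = 1e-10)$value
    mass0 <- cs["p01"] * (1 - cs["coi"])
    mass1 <- cs["p01"] * cs["coi"]
    expect_equal(unname(cont + mass0 + mass1), 1, tolerance = 1e-8)
    expect_equal(unname(cont), unname(1 - cs["p01"]), tolerance = 1e-8)
  }
})

test_that("rzoib draws match the distribution's moments", {
  set.seed(60)
  y <- rzoib(2e4, mu = 0.4, phi = 3, p01 = 0.2, coi = 0.75)
  expect_lt(abs(mean(y == 1) - 0.15), 0.01)
  expect_lt(abs(mean(y == 0) - 0.05), 0.01)
  expect_lt(abs(mean(y) - (0.2 * 0.75 + 0.8 * 0.4)), 0.01)
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(70)
  ok <- matrix(rnorm(4000), 2000, 2)
  expect_equal(split_rhat(ok), 1, tolerance = 0.01)
  bad <- cbind(rnorm(2000, 0), rnorm(2000, 10))
  expect_gt(split_rhat(bad), 1.5)
  # within-chain drift is caught by the split
  drift <- cbind(c(rnorm(1000, 0), rnorm(1000, 3)),
                 c(rnorm(1000, 0), rnorm(1000, 3)))
  expect_gt(split_rhat(drift), 1.1)
  expect_error(split_rhat(matrix(rnorm(100), 100, 1)), "2 chains")
  expect_equal(as.numeric(split_rhat(matrix(1, 100, 2))), 1)
  expect_true(attr(split_rhat(matrix(1, 100, 2)), "constant"))
})

test_that("Bayesian R-squared hits its analytic endpoints", {
  y <- c(0.2, 0.4, 0.6, 0.8)
  fitted <- matrix(y, 50, 4, byrow = TRUE)
  expect_equal(bayes_r2(fitted, y)$median, 1)
  set.seed(80)
  noise <- matrix(rep(colMeans(matrix(runif(400), 100, 4)), each = 50), 50, 4) +
    matrix(rnorm(200, 0, 1e-3), 50, 4)
  r2n <- bayes_r2(noise, runif(4))
  expect_lt(r2n$median, 0.5)
  expect_error(bayes_r2(matrix(0.5, 10, 4), y), "zero variance")
})

test_that("the sampler is deterministic and calibrated on the conjugate block", {
  set.seed(90)
  y <- rzoib(300, 0.5, 2, 0.3, 0.5)
  X <- matrix(1, 300, 1, dimnames = list(NULL, "(Intercept)"))
  f1 <- zoib_mcmc(y, X, chains = 2, iter = 400, warmup = 200, seed = 4)
  f2 <- zoib_mcmc(y, X, chains = 2, iter = 400, warmup = 200, seed = 4)
  expect_identical(f1$draws, f2$draws)
  expect_equal(dim(f1$draws), c(200, 2, 4))  # retained = chains x (iter-warmup)

  # exact SBC on the conjugate inflation block: the rank of the true p01
  # among posterior draws is uniform across replicates
  S <- 99
  ranks <- vapply(1:60, function(r) {
    set.seed(r)
    p01 <- rbeta(1, 1, 1)
    coi <- rbeta(1, 1, 1)
    yy <- rzoib(50, 0.5, 2, p01, coi)
    n01 <- sum(yy %in% c(0, 1)); n1 <- sum(yy == 1)
    draws <- rbeta(S, 1 + n01, 1 + 50 - n01)
    sum(draws < p01)
  }, numeric(1))
  bins <- table(cut(ranks, breaks = seq(0, S + 1, length.out = 5),
                    include.lowest = TRUE, right = FALSE))
  expect_gt(stats::chisq.test(bins)$p.value, 1e-3)
})

test_that("severity model recovers known trait-category effects", {
  cfg <- synthetic_config(
    n_species = 100, n_impacted_species = 100,
    events_per_period = c(2000), year_range = c(1986L, 1990L),
    severity_effects = list(I = c(a = 1.2)),
    unquantified_rate = 0, seed = 15
  )
  tbl <- generate_trait_table(cfg)
  gen <- generate_mortality_records(tbl, cfg)
  fit <- fit_severity_model(gen$records, "I", tbl, chains = 2, iter = 1500,
                            warmup = 750, seed = 6)
  expect_true(all(fit$fit$rhat <= 1.01))
  sev <- fit$severity_by_category
  expect_equal(sev$category, c("a", "b"))
  expect_gt(sev$mean_percent[sev$category == "a"],
            sev$mean_percent[sev$category == "b"])
  # credible intervals are on the percent scale and contain the mean
  expect_true(all(sev$q2.5_percent >= 0 & sev$q97.5_percent <= 100))
  expect_true(all(sev$mean_percent > sev$q2.5_percent &
                    sev$mean_percent < sev$q97.5_percent))
  # the planted contrast is detected with the right sign (exact-magnitude
  # recovery is not expected from 10%-step discretized records: rounding and
  # the <10% truncation attenuate the coefficient)
  s <- fit$summary
  row <- s[s$parameter == "cat_b", ]
  expect_lt(row$q97.5, 0)

  # single observed category is reported and skipped
  rec_one <- gen$records[tbl$I[match(gen$records$species, tbl$species)] == "a", ]
  class(rec_one) <- c("mortality_records", "data.frame")
  expect_error(fit_severity_model(rec_one, "I", tbl),
               class = "benthovuln_single_category")
})

test_that("null effects give category contrasts straddling zero", {
  cfg <- synthetic_config(
    n_species = 80, n_impacted_species = 80,
    events_per_period = c(1200), year_range = c(1986L, 1990L),
    severity_effects = list(), unquantified_rate = 0, seed = 16
  )
  tbl <- generate_trait_table(cfg)
  gen <- generate_mortality_records(tbl, cfg)
  fit <- fit_severity_model(gen$records, "J", tbl, chains = 2, iter = 1200,
                            warmup = 600, seed = 7)
  s <- fit$summary
  contrast <- s[grepl("^cat_", s$parameter), ]
  expect_true(all(contrast$q2.5 < 0 & contrast$q97.5 > 0))
})

test_that("posterior-mean bias shrinks as the sample grows", {
  bias_at <- function(n, seed) {
    set.seed(seed)
    grp <- sample(c("a", "b"), n, TRUE)
    X <- stats::model.matrix(~factor(grp))
    colnames(X) <- c("(Intercept)", "cat_b")
    mu <- stats::plogis(X %*% c(-0.3, 0.9))
    y <- rzoib(n, mu, 3, 0.15, 0.7)
    fit <- zoib_mcmc(y, X, chains = 2, iter = 800, warmup = 400,
                     seed = seed)
    fl <- benthovuln:::flatten_draws(fit$draws)
    abs(mean(fl[, "cat_b"]) - 0.9)
  }
  b200 <- mean(vapply(1:4, function(s) bias_at(200, s), numeric(1)))
  b2000 <- mean(vapply(1:4, function(s) bias_at(2000, 100 + s), numeric(1)))
  expect_lt(b2000, b200)
  expect_lt(b2000, 0.1)
})

test_that("volume model fits annual fractions against driver FE counts", {
  set.seed(110)
  n <- 35
  counts <- cbind(temp = rpois(n, 6), disease = rpois(n, 3))
  eta <- -2 + 0.15 * counts[, "temp"]
  y <- rzoib(n, stats::plogis(eta), 5, 0.2, 0.05)
  fit <- fit_volume_model(y, counts, seed = 9)   # default plan: 2 x 3000/1000
  expect_true(all(fit$fit$rhat <= 1.01))
  expect_equal(dim(benthovuln:::flatten_draws(fit$fit$draws))[1],
               2 * (3000 - 1000))            # retained = chains x (iter-warmup)
  s <- fit$summary
  row <- s[s$parameter == "temp", ]
  expect_true(row$q2.5 <= 0.15 && 0.15 <= row$q97.5)
  expect_error(fit_volume_model(rep(0, 35), counts), "all-zero")
  expect_error(fit_volume_model(y[1:5], counts[1:5, , drop = FALSE]),
               "at least 10")
})
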