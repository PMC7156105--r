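test_that("Polya-Gamma draws match the analytic mean and variance", {
  set.seed(17)
  n <- 50000L
  for (z in c(0, 0.7, 2.5, 6)) {
    x <- rpg(rep(1L, n), rep(z, n))
    m <- if (z == 0) 0.25 else tanh(z / 2) / (2 * z)
    v <- if (z == 0) 1 / 24 else (sinh(z) - z) / (4 * z^3 * cosh(z / 2)^2)
    expect_lt(abs(mean(x) - m), 5 * sqrt(v / n))
    expect_lt(abs(var(x) - v), 0.05 * v)
  }
  ## integer shapes add: PG(3, z) has 3x the PG(1, z) mean
  y <- rpg(rep(3L, n), rep(1.2, n))
  expect_lt(abs(mean(y) - 3 * tanh(0.6) / 2.4), 6 * sd(y) / sqrt(n))
})

test_that("design matrices encode covariates and incidences correctly", {
  ped <- as_pedigree(data.frame(
    id = c("f1", "m1", "f2", "m2"), dam = NA, sire = NA,
    sex = c("F", "M", "F", "M"),
    immigrant = c(FALSE, TRUE, TRUE, FALSE)))
  q <- compute_q(ped, assign_genetic_groups(ped))
  broods <- data.frame(
    brood_id = c("b1", "b2", "b3"), year = c(2000L, 2001L, 2001L),
    female_id = c("f1", "f1", "f2"), male_id = c("m1", "m1", "m2"),
    male_age = c(2L, 3L, 1L), n_offspring = c(3L, 2L, 4L),
    n_epo = c(1L, 0L, 4L))
  d <- build_design(ped, q, broods, baseline_year = 2000L)
  ## fixed row: intercept, q_female, q_male, centered year, male age
  expect_equal(unname(d$X[1, ]), c(1, 0, 1, 0, 2))
  expect_equal(unname(d$X[3, ]), c(1, 1, 0, 1, 1))
  ## same social pair shares one pair-effect column
  expect_equal(ncol(d$Z_pair), 2L)
  expect_equal(which(as.matrix(d$Z_pair[1, ]) == 1),
               which(as.matrix(d$Z_pair[2, ]) == 1))
  ## animal incidence points at the right a_f / a_m positions
  n <- nrow(ped)
  i_f1 <- which(ped$id == "f1")
  i_m1 <- which(ped$id == "m1")
  expect_equal(which(as.matrix(d$Z_a[1, ]) == 1), c(i_f1, n + i_m1))

  ## unknown individual is rejected
  bad <- broods
  bad$female_id[1] <- "ghost"
  expect_error(build_design(ped, q, bad), "absent")
  ## zero-offspring broods are invalid observations
  bad2 <- broods
  bad2$n_offspring[1] <- 0L
  expect_error(build_design(ped, q, bad2), "n_offspring")
})

test_that("Gaussian reduction reproduces the conjugate posterior", {
  ## intercept-only model, known residual variance, no pedigree information:
  ## posterior is N(sum(y) / (n + s2/tau2), ...) — computed in closed form
  set.seed(61)
  n <- 40L
  y <- rnorm(n, 1.5, 1)
  ped <- as_pedigree(data.frame(
    id = c(paste0("f", 1:2), paste0("m", 1:2)), dam = NA, sire = NA,
    sex = rep(c("F", "M"), each = 2)))
  q <- compute_q(ped, assign_genetic_groups(ped))
  broods <- data.frame(
    brood_id = paste0("b", 1:n), year = 2000L,
    female_id = rep(paste0("f", 1:2), length.out = n),
    male_id = rep(paste0("m", 1:2), length.out = n),
    male_age = 0L, n_offspring = 1L, n_epo = 0L)
  d <- build_design(ped, q, broods)
  s2 <- 1
  tau2 <- 1e8
  pri <- default_priors(fixed_var = tau2)
  fit <- fit_quietly(d, pri, chain = short_chain(4, 6000L, 1000L, 1L),
                     family = "gaussian", gaussian_y = y, fix_residual = s2,
                     include_random = character(0))
  post_prec <- n / s2 + 1 / tau2
  post_mean <- sum(y) / s2 / post_prec
  post_sd <- sqrt(1 / post_prec)
  mu_draws <- fit$draws[, "intercept"]
  ## the intercept is conditionally independent of the (zeroed or
  ## orthogonal) covariates, so the draws are iid from the conjugate
  ## posterior up to the q and age columns being all-zero here
  expect_lt(abs(mean(mu_draws) - post_mean), 6 * post_sd / sqrt(length(mu_draws)))
  expect_lt(abs(sd(mu_draws) - post_sd) / post_sd, 0.1)
  expect_true(all(is.na(fit$draws[, "var_af"])))
})

test_that("with zero-information data the group-effect posterior is the prior", {
  ## all q = 0 makes the g_f column identically zero: its conditional
  ## posterior equals its N(0, fixed_var) prior at every iteration
  set.seed(71)
  ped <- as_pedigree(data.frame(
    id = c("f1", "f2", "m1", "m2"), dam = NA, sire = NA,
    sex = c("F", "F", "M", "M"), immigrant = FALSE))
  q <- compute_q(ped, assign_genetic_groups(ped))
  n <- 30L
  broods <- data.frame(
    brood_id = paste0("b", 1:n), year = 2000L,
    female_id = rep(c("f1", "f2"), length.out = n),
    male_id = rep(c("m1", "m2"), length.out = n),
    male_age = 1L, n_offspring = 1L,
    n_epo = rep(c(0L, 1L), length.out = n))
  d <- build_design(ped, q, broods)
  fv <- 4
  fit <- fit_quietly(d, default_priors(fixed_var = fv),
                     chain = short_chain(2, 3000L, 500L, 1L),
                     save_animal_draws = FALSE)
  g <- fit$draws[, "g_f"]
  ks <- suppressWarnings(ks.test(g / sqrt(fv), "pnorm"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("swapping the sex roles swaps the sex-specific parameters", {
  cfg <- tiny_config(seed = 14)
  prep <- prepared_dataset(cfg)
  fit1 <- fit_quietly(prep$design, chain = short_chain(9, 6000L, 2000L, 2L),
                      save_animal_draws = FALSE)

  ## swapped data: relabel sexes and exchange the brood roles
  ped2 <- prep$ped
  ped2$sex <- c(F = "M", M = "F")[ped2$sex]
  class(ped2) <- c("pedigree", "data.frame")
  br2 <- prep$sim$broods
  tmp <- br2$female_id
  br2$female_id <- br2$male_id
  br2$male_id <- tmp
  d2 <- build_design(ped2, prep$q, br2)
  fit2 <- fit_quietly(d2, chain = short_chain(9, 6000L, 2000L, 2L),
                      save_animal_draws = FALSE)

  m1 <- colMeans(fit1$draws)
  m2 <- colMeans(fit2$draws)
  swap <- c(g_f = "g_m", g_m = "g_f", var_af = "var_am", var_am = "var_af",
            var_pe_f = "var_pe_m", var_pe_m = "var_pe_f")
  for (p in names(swap))
    expect_lt(abs(m1[[p]] - m2[[swap[[p]]]]),
              0.35 * max(1, abs(m1[[p]])))
  for (p in c("intercept", "cov_afam", "var_pair", "var_year",
              "var_residual"))
    expect_lt(abs(m1[[p]] - m2[[p]]), 0.35 * max(1, abs(m1[[p]])))
})

test_that("retained G draws are symmetric positive semidefinite", {
  prep <- prepared_dataset(tiny_config(seed = 44))
  fit <- fit_quietly(prep$design, chain = short_chain(3, 800L, 300L, 1L),
                     save_animal_draws = FALSE)
  d <- fit$draws
  expect_true(all(d[, "var_af"] > 0))
  expect_true(all(d[, "var_am"] > 0))
  expect_true(all(d[, "cov_afam"]^2 <= d[, "var_af"] * d[, "var_am"]))
  expect_true(all(is.finite(d)))
})

test_that("predicted total genetic values obey u = a + g q draw-wise", {
  prep <- prepared_dataset(tiny_config(seed = 12))
  fit <- fit_quietly(prep$design, chain = short_chain(6, 500L, 200L, 1L))
  pv <- predict_genetic_values(fit)
  q <- prep$q$q[pv$id]
  gf_bar <- mean(fit$draws[, "g_f"])
  gm_bar <- mean(fit$draws[, "g_m"])
  expect_equal(pv$u_f, pv$a_f + gf_bar * unname(q), tolerance = 1e-10)
  expect_equal(pv$u_m, pv$a_m + gm_bar * unname(q), tolerance = 1e-10)
  ## individuals with q = 0 have u identical to a
  z <- pv$q == 0
  expect_identical(pv$u_f[z], pv$a_f[z])
  ## with all-zero group-effect draws u would equal a everywhere
  fit0 <- fit
  fit0$draws[, c("g_f", "g_m")] <- 0
  pv0 <- predict_genetic_values(fit0)
  expect_equal(pv0$u_f, pv0$a_f, tolerance = 1e-14)
})

test_that("chain bookkeeping: retained count, thinning, diagnostics", {
  prep <- prepared_dataset(tiny_config(seed = 18))
  fit <- fit_quietly(prep$design, chain = short_chain(8, 600L, 200L, 2L),
                     save_animal_draws = TRUE)
  expect_equal(nrow(fit$draws), 200L)
  expect_equal(fit$chain$n_retained, 200L)
  expect_named(fit$autocorr)
  th <- thin_fit(fit, 2L)
  expect_equal(nrow(th$draws), 100L)
  expect_equal(th$chain$thin, 4L)
  expect_error(fit_mcmc(prep$design, chain = list(n_iter = 100, burn_in = 10,
                                                  thin = 1)),
               "seed")
})
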