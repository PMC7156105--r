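## minimal fit-like object carrying a draw matrix
fake_fit <- function(draws, var_q = 0.04, baseline_year = 2000L) {
  structure(list(draws = draws,
                 design = list(q = list(var_q = var_q),
                               baseline_year = baseline_year)),
            class = "epp_fit")
}

single_draw <- function(g_f = -1.17, g_m = -1.55, var_af = 1.26,
                        var_am = 0.47, cov_afam = -0.37,
                        var_residual = 3.58) {
  m <- matrix(c(-0.67, g_f, g_m, 0.05, -0.19, var_af, var_am, cov_afam,
                0.1, 0.1, 0.1, 0.1, var_residual), nrow = 1)
  colnames(m) <- c("intercept", "g_f", "g_m", "beta_year", "beta_age",
                   "var_af", "var_am", "cov_afam", "var_pe_f", "var_pe_m",
                   "var_pair", "var_year", "var_residual")
  rbind(m, m)  # two identical draws: summaries need >= 2
}

test_that("total-genetic-value algebra matches hand arithmetic", {
  fit <- fake_fit(single_draw(), var_q = 0.04)
  d <- derive_u_covariances(fit, var_q = 0.04)
  expect_equal(unname(d$draws[1, "var_uf"]), 1.26 + 1.3689 * 0.04)  # 1.314756
  expect_equal(unname(d$draws[1, "var_um"]), 0.47 + 1.55^2 * 0.04)
  expect_equal(unname(d$draws[1, "cov_ufum"]), -0.37 + 1.8135 * 0.04)  # -0.29746
  d <- derive_totals(d)
  expect_equal(unname(d$draws[1, "var_aT"]), 0.99)
  expect_equal(unname(d$draws[1, "var_uT"]),
               1.314756 + 2 * (-0.29746) + (0.47 + 1.55^2 * 0.04))
  d <- derive_correlations_and_h2(d)
  expect_equal(unname(d$draws[1, "cor_afam"]), -0.37 / sqrt(1.26 * 0.47),
               tolerance = 1e-12)
  expect_equal(round(unname(d$draws[1, "cor_afam"]), 4), -0.4808)
  ## heritability: additive variance over the sum of all components
  vsum <- 1.26 + 0.47 + 0.1 * 4 + 3.58
  expect_equal(unname(d$draws[1, "h2_f"]), 1.26 / vsum)
})

test_that("degenerate var_q collapses u-quantities onto a-quantities", {
  fit <- fake_fit(single_draw())
  d <- derive_totals(derive_u_covariances(fit, var_q = 0))
  expect_equal(unname(d$draws[, "var_uf"]), unname(fit$draws[, "var_af"]))
  expect_equal(unname(d$draws[, "cov_ufum"]), unname(fit$draws[, "cov_afam"]))
  expect_equal(unname(d$draws[, "delta_varT"]), c(0, 0))

  ## zero group effects likewise
  fit0 <- fake_fit(single_draw(g_f = 0, g_m = 0))
  d0 <- derive_totals(derive_u_covariances(fit0, var_q = 0.04))
  expect_equal(unname(d0$draws[, "var_uT"]), unname(d0$draws[, "var_aT"]))

  expect_error(derive_u_covariances(fit, var_q = -0.1), "nonnegative")
})

test_that("draw-wise identities hold over a random posterior cloud", {
  set.seed(12)
  k <- 500L
  draws <- cbind(intercept = rnorm(k), g_f = rnorm(k), g_m = rnorm(k),
                 beta_year = rnorm(k, 0, 0.1), beta_age = rnorm(k, 0, 0.1),
                 var_af = rgamma(k, 2, 2), var_am = rgamma(k, 2, 2),
                 cov_afam = rnorm(k, 0, 0.2), var_pe_f = rgamma(k, 1, 5),
                 var_pe_m = rgamma(k, 1, 5), var_pair = rgamma(k, 1, 5),
                 var_year = rgamma(k, 1, 5), var_residual = rgamma(k, 4, 1))
  ## keep G PSD draw-wise
  lim <- sqrt(draws[, "var_af"] * draws[, "var_am"])
  draws[, "cov_afam"] <- pmin(pmax(draws[, "cov_afam"], -lim), lim)
  vq <- 0.06
  d <- derive_correlations_and_h2(derive_totals(
    derive_u_covariances(fake_fit(draws), var_q = vq)))
  dd <- d$draws
  src <- d$source
  expect_true(all(dd[, "var_uf"] >= src[, "var_af"]))
  expect_true(all(dd[, "var_um"] >= src[, "var_am"]))
  ## sign law of the covariance shift
  expect_equal(sign(round(dd[, "cov_ufum"] - src[, "cov_afam"], 12)),
               sign(round(src[, "g_f"] * src[, "g_m"] * vq, 12)),
               ignore_attr = TRUE)
  ## the total-variance difference identity
  expect_equal(dd[, "var_uT"] - dd[, "var_aT"],
               (src[, "g_f"] + src[, "g_m"])^2 * vq,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(dd[, "delta_varT"] >= 0))
  expect_true(all(abs(dd[, "cor_afam"]) <= 1))
  expect_true(all(abs(dd[, "cor_ufum"]) <= 1))
  expect_true(all(dd[, "h2_f"] >= 0 & dd[, "h2_f"] <= 1))
})

test_that("logit-normal quadrature matches closed forms and Monte Carlo", {
  ## zero latent variance: plain inverse logit
  expect_equal(logit_normal_mean(0, 0), 0.5)
  expect_equal(logit_normal_mean(-1.3863, 0), plogis(-1.3863))
  expect_equal(round(logit_normal_mean(log(0.25), 0), 3), 0.2)

  ## against antithetic Monte-Carlo integration
  set.seed(10)
  z <- rnorm(5e5)
  z <- c(z, -z)
  for (eta in c(-2, 0, 1.5)) {
    for (s2 in c(0.5, 3)) {
      mc <- mean(plogis(eta + sqrt(s2) * z))
      expect_lt(abs(logit_normal_mean(eta, s2, nodes = 30) - mc), 1e-3)
    }
  }
})

test_that("back-transformation integrates the residual and orders by q", {
  set.seed(2)
  k <- 200L
  base <- single_draw()
  draws <- base[rep(1, k), ]
  draws[, "intercept"] <- rnorm(k, -0.67, 0.2)
  draws[, "var_residual"] <- rgamma(k, 4, 1)
  fit <- fake_fit(draws, baseline_year = 1993L)
  scen <- data.frame(q_value = c(0.37, 0), year = 2004L, male_age = 2.7)
  rates <- back_transform(fit, scen)
  expect_equal(dim(rates), c(k, 2L))
  expect_true(all(rates > 0 & rates < 1))
  ## g_f + g_m < 0: the q = 0.37 scenario has the lower rate, draw-wise
  expect_true(all(rates[, 1] < rates[, 2]))

  ## zero residual variance reduces to the plain inverse logit
  draws0 <- draws
  draws0[, "var_residual"] <- 0
  r0 <- back_transform(fake_fit(draws0, baseline_year = 1993L),
                       data.frame(q_value = 0, year = 1993L, male_age = 0))
  expect_equal(unname(r0[, 1]), unname(plogis(draws0[, "intercept"])),
               tolerance = 1e-9)
})
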