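test_that("simulation is bit-reproducible under a fixed seed", {
  s1 <- simulate_dataset(tiny_config(seed = 3))
  s2 <- simulate_dataset(tiny_config(seed = 3))
  expect_identical(s1$broods, s2$broods)
  expect_identical(as.data.frame(s1$pedigree), as.data.frame(s2$pedigree))
  expect_identical(s1$truth$a, s2$truth$a)
})

test_that("total genetic values satisfy u - a = g q exactly", {
  cfg <- tiny_config(seed = 5)
  sim <- simulate_dataset(cfg)
  expect_equal(sim$truth$u[, "u_f"] - sim$truth$a[, "a_f"],
               cfg$g_f * sim$truth$q, tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(sim$truth$u[, "u_m"] - sim$truth$a[, "a_m"],
               cfg$g_m * sim$truth$q, tolerance = 1e-14, ignore_attr = TRUE)

  ## degenerate case: no group effects collapses u to a
  cfg0 <- tiny_config(seed = 5, g_f = 0, g_m = 0)
  sim0 <- simulate_dataset(cfg0)
  expect_identical(unname(sim0$truth$u[, "u_f"]), unname(sim0$truth$a[, "a_f"]))
})

test_that("without immigration all ancestry traces to founders with q = 0", {
  sim <- simulate_dataset(tiny_config(seed = 9, immigrants_per_year = 0))
  expect_true(all(!sim$pedigree$immigrant))
  expect_true(all(sim$truth$q == 0))
  ## all parentless individuals are year-zero founders
  parentless <- is.na(sim$pedigree$dam) & is.na(sim$pedigree$sire)
  expect_true(all(sim$pedigree$cohort[parentless] == 0L))
})

test_that("brood records are internally consistent with the pedigree", {
  sim <- simulate_dataset(tiny_config(seed = 21))
  b <- sim$broods
  expect_true(all(b$n_epo >= 0 & b$n_epo <= b$n_offspring))
  expect_true(all(b$n_offspring >= 1 & b$n_offspring <= 4))
  expect_true(all(c(b$female_id, b$male_id) %in% sim$pedigree$id))
  sex <- setNames(sim$pedigree$sex, sim$pedigree$id)
  expect_true(all(sex[b$female_id] == "F"))
  expect_true(all(sex[b$male_id] == "M"))
  expect_true(all(b$male_age >= 1))
  ## every immigrant is parentless and flagged
  imm <- sim$pedigree[sim$pedigree$immigrant, ]
  expect_true(all(is.na(imm$dam) & is.na(imm$sire)))
})

test_that("simulated q matches the gene-dropping expectation in the last cohort", {
  cfg <- sim_config(n_years = 25L, n_founder_pairs = 10L, seed = 55)
  sim <- simulate_dataset(cfg)
  ped <- sim$pedigree
  gr <- assign_genetic_groups(ped)
  gd <- gene_drop_q(ped, gr, n_rep = 4000L)
  last <- ped$id[ped$cohort == max(ped$cohort, na.rm = TRUE)]
  mean_q <- mean(sim$truth$q[last])
  mean_hat <- mean(gd$q_hat[last])
  ## SE of the mean across correlated individuals: conservative bound via
  ## averaging per-individual SEs
  se <- mean(gd$se[last])
  expect_lt(abs(mean_q - mean_hat), 3 * se + 1e-12)
})

test_that("founder breeding values reproduce the generative G at large n", {
  cfg <- sim_config(seed = 77)  # Var(a_f)=1.26, Var(a_m)=0.47, cov=-0.37
  ped <- as_pedigree(data.frame(
    id = as.character(1:5000), dam = NA, sire = NA,
    sex = rep(c("F", "M"), length.out = 5000)))
  set.seed(42)
  bv <- simulate_breeding_values(ped, cfg)
  n <- nrow(ped)
  ## 3-SE moment checks (SE of variance ~ sqrt(2/n) * var)
  expect_lt(abs(var(bv$a[, 1]) - 1.26), 3 * sqrt(2 / n) * 1.26)
  expect_lt(abs(var(bv$a[, 2]) - 0.47), 3 * sqrt(2 / n) * 0.47)
  se_cov <- sqrt((1.26 * 0.47 + 0.37^2) / n)
  expect_lt(abs(cov(bv$a[, 1], bv$a[, 2]) - (-0.37)), 3 * se_cov)

  ## independence when cov = 0
  cfg0 <- sim_config(cov_afam = 0, seed = 1)
  set.seed(43)
  bv0 <- simulate_breeding_values(ped, cfg0)
  expect_lt(abs(cor(bv0$a[, 1], bv0$a[, 2])), 0.05)
})

test_that("offspring a-values regress on the parental midpoint with slope ~1", {
  cfg <- tiny_config(seed = 8)
  sim <- simulate_dataset(sim_config(n_years = 15, seed = 8))
  ped <- sim$pedigree
  both <- !is.na(ped$dam) & !is.na(ped$sire)
  mid <- 0.5 * (sim$truth$a[ped$dam[both], "a_f"] +
                  sim$truth$a[ped$sire[both], "a_f"])
  kid <- sim$truth$a[ped$id[both], "a_f"]
  fit <- lm(kid ~ mid)
  slope <- coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(slope - 1), 3 * se)
})

test_that("phenotype simulation hits its analytic limits", {
  cfg <- tiny_config(seed = 2, intercept = 0, g_f = 0, g_m = 0,
                     beta_year = 0, beta_age = 0,
                     var_af = 0, var_am = 0, cov_afam = 0,
                     var_pe_f = 0, var_pe_m = 0, var_pair = 0,
                     var_year = 0, var_residual = 0)
  sim <- simulate_dataset(cfg)
  p <- sum(sim$broods$n_epo) / sum(sim$broods$n_offspring)
  n <- sum(sim$broods$n_offspring)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / n))

  ## strongly negative intercept: no extra-pair offspring at all
  cfg2 <- tiny_config(seed = 2, intercept = -30, g_f = 0, g_m = 0,
                      beta_year = 0, beta_age = 0,
                      var_af = 0, var_am = 0, cov_afam = 0,
                      var_pe_f = 0, var_pe_m = 0, var_pair = 0,
                      var_year = 0, var_residual = 0)
  sim2 <- simulate_dataset(cfg2)
  expect_equal(sum(sim2$broods$n_epo), 0L)
})

test_that("default truth produces realistic EPP rates with overdispersion", {
  sim <- simulate_dataset(sim_config(seed = 99))
  b <- sim$broods
  rate <- sum(b$n_epo) / sum(b$n_offspring)
  expect_gt(rate, 0.1)
  expect_lt(rate, 0.6)
  ## dispersion test against the binomial under the pooled rate: the
  ## Pearson statistic should far exceed its null degrees of freedom
  expected <- b$n_offspring * rate
  X2 <- sum((b$n_epo - expected)^2 / (expected * (1 - rate)))
  df <- nrow(b) - 1
  expect_gt(X2, df + 5 * sqrt(2 * df))
})

test_that("standalone phenotype simulation works over a fixed pedigree", {
  cfg <- tiny_config(seed = 31)
  sim <- simulate_dataset(cfg)
  set.seed(1)
  bv <- simulate_breeding_values(sim$pedigree, cfg)
  ph <- simulate_phenotypes(sim$pedigree, bv, cfg,
                            skeleton = sim$broods[names(sim$broods) != "n_epo"])
  expect_equal(nrow(ph), nrow(sim$broods))
  expect_true(all(ph$n_epo <= ph$n_offspring))
  ## fresh skeleton built from the pedigree alone
  ph2 <- simulate_phenotypes(sim$pedigree, bv, cfg)
  expect_true(nrow(ph2) > 0)
  expect_true(all(ph2$n_epo <= ph2$n_offspring))
})

test_that("impossible configurations are rejected", {
  expect_error(sim_config(var_af = -1), "nonnegative")
  expect_error(sim_config(var_af = 0.1, var_am = 0.1, cov_afam = 0.5),
               "positive semidefinite")
  expect_error(sim_config(brood_size_min = 3, brood_size_max = 2), "brood size")
  expect_error(simulate_dataset(tiny_config(seed = 1, n_founder_pairs = 1L,
                                            adult_survival = 0,
                                            max_pairs = 1L,
                                            brood_size_min = 1L,
                                            brood_size_max = 1L,
                                            mean_broods_per_pair = 0.1,
                                            intercept = -30)),
               "extinct")
})
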