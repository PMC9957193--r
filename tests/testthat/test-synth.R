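test_that("simulated datasets match their configuration and reproduce bit-for-bit", {
  cf <- small_config()
  sim <- simulate_hybrid_data(cf, seed = 21)
  expect_equal(dim(sim$male_markers), c(cf$n_males, cf$n_markers))
  expect_equal(dim(sim$female_markers), c(cf$n_females, cf$n_markers))
  expect_equal(as.integer(table(sim$phenotypes$env)) / length(cf$traits),
               cf$n_hybrids_per_env)
  expect_setequal(unique(sim$phenotypes$trait), cf$traits)
  expect_true(all(sim$male_markers %in% c(0, 2)))  # inbred parents

  sim2 <- simulate_hybrid_data(cf, seed = 21)
  expect_identical(sim, sim2)
  sim3 <- simulate_hybrid_data(cf, seed = 22)
  expect_false(identical(sim$phenotypes$value, sim3$phenotypes$value))
})

test_that("stored effects recombine to the simulated phenotypes exactly", {
  sim <- simulate_hybrid_data(small_config(), seed = 5)
  comp <- sim$truth$components
  rebuilt <- sim$truth$grand_mean + comp$env_eff + comp$gca_male +
    comp$gca_female + comp$sca + comp$gca_male_x_env +
    comp$gca_female_x_env + comp$sca_x_env + comp$residual
  key_c <- paste(comp$hybrid, comp$env, comp$trait)
  key_p <- paste(sim$phenotypes$hybrid, sim$phenotypes$env,
                 sim$phenotypes$trait)
  expect_identical(key_c, key_p)
  expect_equal(rebuilt, sim$phenotypes$value, tolerance = 1e-12)
})

test_that("the additive-only limit makes mid-parent covariates perfect predictors", {
  cf <- small_config(var_comp = c(env = 1, gca_male = 0.5, gca_female = 0.5,
                                  sca = 0, gca_male_x_env = 0,
                                  gca_female_x_env = 0, sca_x_env = 0,
                                  residual = 0.2),
                     parental_noise_var = 0)
  sim <- simulate_hybrid_data(cf, seed = 9)
  comp <- sim$truth$components
  genetic <- comp$gca_male + comp$gca_female
  expect_true(all(comp$sca == 0) && all(comp$sca_x_env == 0))
  covs <- build_covariates(sim$pedigree, sim$parental_phenotypes, "GY",
                           mode = "C", center = FALSE)
  gy <- comp[comp$trait == "GY", ]
  midparent <- covs[gy$hybrid, "GY_add"]
  expect_equal(cor(midparent, (gy$gca_male + gy$gca_female) / 2), 1,
               tolerance = 1e-10)
})

test_that("effect vectors hit their configured variances at scale", {
  # one large environment so every effect has enough replicates
  cf <- synth_config(n_males = 10, n_females = 200, n_markers = 150,
                     n_envs = 1, n_hybrids_per_env = 2000, overlap = 0)
  devs <- sapply(1:3, function(s) {
    sim <- simulate_hybrid_data(cf, seed = 400 + s)
    tr <- sim$truth
    pv <- function(x) mean(x^2) - mean(x)^2
    c(gca_male = pv(tr$gca_male[, "GY"]),
      gca_female = pv(tr$gca_female[, "GY"]),
      sca = pv(tr$sca[, "GY"]),
      sca_x_env = pv(tr$sca_x_env[, 1, "GY"]),
      residual = pv(tr$components$residual[tr$components$trait == "GY"]))
  })
  target <- cf$var_comp[rownames(devs)]
  rel <- rowMeans(devs) / target
  expect_true(all(abs(rel - 1) < 0.15))
})

test_that("generated markers yield kernels satisfying the kernel invariants", {
  sim <- simulate_hybrid_data(small_config(), seed = 13)
  GM <- grm(marker_qc(sim$male_markers))
  GF <- grm(marker_qc(sim$female_markers))
  H <- sca_kernel(sim$pedigree, GM, GF)
  for (K in list(GM, GF, H)) {
    expect_lt(max(abs(K - t(K))), 1e-10)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(abs(ev)))
  }
  expect_lt(abs(mean(diag(GM)) - 1), 1e-10)
})

test_that("raising the residual variance degrades every model's CV accuracy", {
  mse_at <- function(resid_var, s) {
    vc <- c(env = 1, gca_male = 0.4, gca_female = 0.4, sca = 0.2,
            gca_male_x_env = 0.05, gca_female_x_env = 0.05,
            sca_x_env = 0.1, residual = resid_var)
    sim <- simulate_hybrid_data(small_config(var_comp = vc), seed = 600 + s)
    folds <- make_folds(unique(sim$pedigree$hybrid), k = 3, seed = s)
    run_cv(hybrid_model_spec("C", "none", "GY"), sim, folds,
           n_iter = 400, burn_in = 100, thin = 2, seed = s)$global_mse
  }
  low <- sapply(1:3, function(s) mse_at(0.5, s))
  high <- sapply(1:3, function(s) mse_at(4, s))
  expect_gt(mean(high), mean(low))
})

test_that("missing-data corruption is seeded and respects its rate", {
  M <- rand_markers(50, 40, seed = 3)
  M1 <- corrupt_markers(M, rate = 0.1, seed = 8)
  M2 <- corrupt_markers(M, rate = 0.1, seed = 8)
  expect_identical(M1, M2)
  frac <- mean(is.na(M1))
  expect_gt(frac, 0.05); expect_lt(frac, 0.15)
  expect_error(simulate_hybrid_data(small_config(), ), "seed is required")
})
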