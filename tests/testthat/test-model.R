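sim_small <- simulate_hybrid_data(small_config(), seed = 42)

test_that("model families assemble the documented term sets", {
  records <- sim_small$phenotypes[sim_small$phenotypes$trait == "GY",
                                  c("hybrid", "env", "value")]
  GM <- grm(marker_qc(sim_small$male_markers))
  GF <- grm(marker_qc(sim_small$female_markers))
  covs <- build_covariates(sim_small$pedigree, sim_small$parental_phenotypes,
                           "GY", mode = "AC", traits = sim_small$traits)

  # family D: environment block plus exactly two random genetic terms
  tD <- assemble_terms(hybrid_model_spec("D", "none", "GY"), records,
                       sim_small$pedigree, GM, GF)
  expect_identical(names(tD$kernels), c("env", "sca", "sca_x_env"))
  expect_identical(colnames(tD$X), "(Intercept)")

  # family B with AC covariates: six genetic terms and six covariates
  tB <- assemble_terms(hybrid_model_spec("B", "AC", "GY"), records,
                       sim_small$pedigree, GM, GF, covariates = covs)
  expect_identical(names(tB$kernels),
                   c("env", "gca_male", "gca_female", "sca",
                     "gca_male_x_env", "gca_female_x_env", "sca_x_env"))
  expect_equal(ncol(tB$X), 7)  # intercept + 2 columns x 3 traits

  # family A: every kernel is identity-based (0/1 same-entity indicators)
  tA <- assemble_terms(hybrid_model_spec("A", "C", "GY"), records,
                       sim_small$pedigree, covariates = covs[, 1:2])
  male_of <- sim_small$pedigree$male[match(records$hybrid,
                                           sim_small$pedigree$hybrid)]
  expect_equal(unname(tA$kernels$gca_male),
               unname(outer(male_of, male_of, "==") * 1))
  expect_true(all(unlist(tA$kernels) %in% c(0, 1)))

  expect_error(assemble_terms(hybrid_model_spec("B", "none", "GY"),
                              records, sim_small$pedigree),
               "need G_M and G_F")
  expect_error(assemble_terms(hybrid_model_spec("A", "C", "GY"),
                              records, sim_small$pedigree),
               "no covariates supplied")
})

test_that("a constant response is predicted as the constant with collapsing variances", {
  spec <- hybrid_model_spec("A", "none", "GY")
  data2 <- sim_small
  data2$phenotypes$value <- 7
  fit <- fit_hybrid_model(spec, data2,
                          mask_hybrids = unique(data2$pedigree$hybrid)[1:5],
                          n_iter = 8000, burn_in = 2000, thin = 1, seed = 5)
  expect_lt(max(abs(fit$prediction_table$predicted - 7)), 0.05)
  vc <- fit$var_comp
  expect_true(all(vc$variance[vc$term != "residual"] < 0.2))
})

test_that("identical seeds reproduce a fit bit-for-bit", {
  spec <- hybrid_model_spec("D", "C", "GY")
  f1 <- fit_hybrid_model(spec, sim_small, n_iter = 600, burn_in = 200,
                         thin = 2, seed = 31,
                         mask_hybrids = sim_small$pedigree$hybrid[1:4])
  f2 <- fit_hybrid_model(spec, sim_small, n_iter = 600, burn_in = 200,
                         thin = 2, seed = 31,
                         mask_hybrids = sim_small$pedigree$hybrid[1:4])
  expect_identical(f1$fitted, f2$fitted)
  expect_identical(f1$var_comp, f2$var_comp)
  expect_identical(coef(f1), coef(f2))
})

test_that("an all-zero covariate column leaves predictions unchanged within MC error", {
  y <- sim_small$phenotypes$value[sim_small$phenotypes$trait == "GY"]
  n <- length(y)
  K <- rand_psd(n, seed = 8)
  mask <- seq_len(n) <= 6
  base <- kernel_regression(y, list(g = K), mask = mask, n_iter = 6000,
                            burn_in = 1000, thin = 1, seed = 3)
  with0 <- kernel_regression(y, list(g = K),
                             X = cbind(rep(1, n), zero = rep(0, n)),
                             mask = mask,
                             n_iter = 6000, burn_in = 1000, thin = 1, seed = 3)
  # the two chains consume the RNG differently, so they agree only up to
  # Monte-Carlo error
  expect_lt(max(abs(base$predictions - with0$predictions)), 0.1 * sd(y))
})

test_that("degenerate sampler inputs are refused", {
  y <- rnorm(10)
  K <- rand_psd(10, seed = 1)
  expect_error(kernel_regression(y, list(K), mask = rep(TRUE, 10), seed = 1),
               "all records are masked")
  bad <- diag(10); bad[1, 1] <- -2
  expect_error(kernel_regression(y, list(bad), seed = 1), "not positive")
  expect_error(kernel_regression(y, list(K)), "seed is required")
})

test_that("blup oracle reduces to GLS and interpolation in its limits", {
  # all genetic variances zero: prediction is the fixed-effect fit
  y <- c(1, 3, 5, 7, 9, 11)
  K <- rand_psd(6, seed = 2)
  o <- blup_oracle(y, list(g = K), c(g = 0, residual = 1))
  expect_equal(o$prediction, rep(mean(y), 6), tolerance = 1e-6)

  # single training record, intercept only: prediction equals that record
  o1 <- blup_oracle(c(4.2, NA), list(g = diag(2)), c(g = 1, residual = 1),
                    train = c(TRUE, FALSE))
  expect_equal(o1$prediction[1], 4.2, tolerance = 1e-6)
})

test_that("blup oracle equals direct multivariate-normal conditioning", {
  # independent dense oracle: condition the joint Gaussian explicitly
  for (s in 1:5) {
    n <- 20
    K1 <- rand_psd(n, seed = s)
    K2e <- env_block_kernel(rep(c("a", "b"), each = 10))
    dimnames(K1) <- dimnames(K2e)
    vc <- c(k1 = 0.8, k2 = 0.4, residual = 0.7)
    y <- withr::with_seed(s + 30, rnorm(n, 5))
    train <- rep(TRUE, n); train[1:5] <- FALSE

    o <- blup_oracle(y, list(k1 = K1, k2 = K2e), vc, train = train)

    Sig <- vc["k1"] * K1 + vc["k2"] * K2e
    V <- Sig + diag(vc["residual"], n)
    diag(V) <- diag(V) * (1 + 1e-8)
    tr <- which(train); te <- which(!train)
    X1 <- matrix(1, n, 1)
    b <- solve(t(X1[tr, , drop = FALSE]) %*% solve(V[tr, tr]) %*% X1[tr, ],
               t(X1[tr, , drop = FALSE]) %*% solve(V[tr, tr]) %*% y[tr])
    mu <- as.numeric(X1 %*% b)
    cond <- mu[te] + Sig[te, tr] %*% solve(V[tr, tr], y[tr] - mu[tr])
    expect_equal(o$prediction[te], as.numeric(cond), tolerance = 1e-6)
  }
})

test_that("permuting records permutes oracle predictions correspondingly", {
  n <- 15
  K <- rand_psd(n, seed = 11)
  y <- withr::with_seed(1, rnorm(n))
  train <- rep(c(TRUE, TRUE, FALSE), 5)
  o <- blup_oracle(y, list(g = K), c(g = 1, residual = 0.5), train = train)
  perm <- withr::with_seed(2, sample(n))
  Kp <- K[perm, perm]
  op <- blup_oracle(y[perm], list(g = Kp), c(g = 1, residual = 0.5),
                    train = train[perm])
  expect_equal(op$prediction, o$prediction[perm], tolerance = 1e-8)
})

test_that("summary, coef, residuals and predict expose the fit", {
  spec <- hybrid_model_spec("C", "C", "GY")
  fit <- fit_hybrid_model(spec, sim_small,
                          mask_hybrids = sim_small$pedigree$hybrid[1:3],
                          n_iter = 600, burn_in = 200, thin = 2, seed = 2)
  s <- summary(fit)
  expect_s3_class(s, "summary.kernel_fit")
  expect_named(coef(fit)[1], "(Intercept)")
  r <- residuals(fit)
  expect_true(all(is.na(r[fit$mask])) && !anyNA(r[!fit$mask]))
  pt <- predict(fit)
  expect_identical(nrow(pt), sum(fit$mask))
  expect_output(print(fit), "MC_C")
})
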