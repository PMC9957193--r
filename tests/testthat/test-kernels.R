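test_that("grm matches the hand-computed worked example", {
  # columns have means (1,1) and population sd sqrt(2/3); W W'/2 gives
  # +-1.5 for the two informative lines and 0 for the average line
  X <- cbind(m1 = c(0, 2, 1), m2 = c(2, 0, 1))
  rownames(X) <- c("L1", "L2", "L3")
  G <- grm(X)
  expected <- matrix(c(1.5, -1.5, 0, -1.5, 1.5, 0, 0, 0, 0), 3,
                     dimnames = list(rownames(X), rownames(X)))
  expect_equal(G, expected, tolerance = 1e-12)
  expect_equal(mean(diag(G)), 1, tolerance = 1e-12)
})

test_that("grm diagonal averages one and is invariant to column order and allele swap", {
  for (s in 1:4) {
    X <- marker_qc(rand_markers(12, 50, seed = s))
    G <- grm(X)
    expect_lt(abs(mean(diag(G)) - 1), 1e-10)
    expect_lt(max(abs(G - t(G))), 1e-10)
    expect_equal(grm(X[, sample(ncol(X))]), G, tolerance = 1e-10)
    expect_equal(grm(2 - X), G, tolerance = 1e-10)
  }
})

test_that("identical marker rows give identical kernel entries", {
  X <- rand_markers(3, 30, seed = 9)
  X[2, ] <- X[1, ]
  X <- X[, apply(X, 2, var) > 0, drop = FALSE]
  G <- grm(X)
  expect_equal(G[1, 1], G[2, 2])
  expect_equal(G[1, 2], G[1, 1])
})

test_that("monomorphic markers are refused by name", {
  X <- rand_markers(10, 5, seed = 2)
  X[, 3] <- 2
  expect_error(grm(X), "monomorphic.*m3")
})

test_that("sca kernel is the observed-cross Kronecker sub-matrix", {
  # identity factors: crosses sharing a male but not a female decouple
  GM <- identity_kernel(c("m1", "m2"))
  GF <- identity_kernel(c("f1", "f2"))
  ped <- data.frame(hybrid = c("h1", "h2"), male = "m1",
                    female = c("f1", "f2"))
  expect_equal(unname(sca_kernel(ped, GM, GF)), diag(2))

  # entrywise product of the parental entries
  GM2 <- matrix(c(1.2, 0.3, 0.3, 1), 2, dimnames = list(c("m1", "m2"), c("m1", "m2")))
  GF2 <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("f1", "f2"), c("f1", "f2")))
  H <- sca_kernel(ped, GM2, GF2)
  expect_equal(H[1, 2], 1.2 * 0.5)

  # brute-force full Kronecker product as the oracle
  for (s in 1:25) {
    withr::with_seed(s, {
      nm <- sample(3:6, 1); nf <- sample(3:8, 1)
      GM <- rand_psd(nm, paste0("m", 1:nm), seed = s)
      GF <- rand_psd(nf, paste0("f", 1:nf), seed = s + 50)
      nc <- sample(5:15, 1)
      cross <- cbind(sample(nm, nc, TRUE), sample(nf, nc, TRUE))
    })
    ped <- data.frame(hybrid = paste0("h", seq_len(nrow(cross))),
                      male = paste0("m", cross[, 1]),
                      female = paste0("f", cross[, 2]))
    H <- sca_kernel(ped, GM, GF)
    full <- kronecker(GM, GF)  # block (male), within-block (female)
    idx <- (cross[, 1] - 1) * nrow(GF) + cross[, 2]
    expect_equal(unname(H), full[idx, idx], tolerance = 1e-12)
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(abs(ev)))
  }
  expect_error(sca_kernel(data.frame(hybrid = "h", male = "mX", female = "f1"),
                          GM, GF), "mX")
})

test_that("record expansion equals the dense Z K Z' product", {
  K <- identity_kernel(c("h1", "h2", "h3"))
  two <- expand_kernel(K, c("h1", "h1"))
  expect_equal(unname(two), matrix(1, 2, 2))

  K2 <- rand_psd(4, paste0("h", 1:4), seed = 3)
  expect_equal(unname(expand_kernel(K2, paste0("h", 1:4))), unname(K2))

  for (s in 1:15) {
    ents <- withr::with_seed(s, sample(paste0("h", 1:5), 12, TRUE))
    K3 <- rand_psd(5, paste0("h", 1:5), seed = s)
    Z <- outer(ents, paste0("h", 1:5), "==") * 1
    expect_equal(unname(expand_kernel(K3, ents)), Z %*% K3 %*% t(Z),
                 tolerance = 1e-12)
  }
  expect_error(expand_kernel(K, c("h1", "nope")), "nope")
})

test_that("Hadamard interaction kernels zero out cross-environment entries and stay PSD", {
  env <- c("e1", "e2", "e1")
  E <- env_block_kernel(env)
  main <- rand_psd(3, seed = 6)
  dimnames(main) <- dimnames(E)
  V <- interaction_kernel(main, E)
  expect_equal(V[1, 2], 0)          # different environments
  expect_equal(V[1, 3], main[1, 3]) # same environment
  for (s in 1:15) {
    envs <- withr::with_seed(s, sample(paste0("e", 1:3), 15, TRUE))
    E2 <- env_block_kernel(envs)
    M2 <- rand_psd(15, seed = s + 7)
    dimnames(M2) <- dimnames(E2)
    V2 <- interaction_kernel(M2, E2)
    ev <- eigen(V2, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(abs(ev)))
  }
  expect_error(interaction_kernel(main[1:2, 1:2], E), "dimensions")
})
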