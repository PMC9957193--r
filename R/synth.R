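#' Configuration for the synthetic hybrid-breeding data generator
#'
#' Defaults describe a scaled-down two-pool hybrid breeding program:
#' 6 male and 40 female inbred parents, 300 SNP markers, three
#' environments (years) with unbalanced hybrid sets of 70, 65 and 120
#' crosses and roughly a third of each year's hybrids carried over from
#' the previous year, and three genetically correlated traits. Variance
#' components give a per-record heritability of about 0.45 with GCA
#' variance dominating SCA, and parental phenotypes are observed with
#' small noise (reliability about 0.8), as for replicated-trial BLUEs.
#'
#' @param n_males,n_females numbers of inbred parents per pool.
#' @param n_markers number of biallelic SNPs per pool.
#' @param n_envs number of environments (years).
#' @param n_hybrids_per_env integer vector (recycled to `n_envs`) of
#'   hybrids evaluated per environment.
#' @param overlap fraction of an environment's hybrids carried over from
#'   the previous environment.
#' @param traits trait names; the first is conventionally the target.
#' @param trait_cor genetic correlation between traits: a single
#'   off-diagonal value or a full correlation matrix.
#' @param var_comp named numeric vector of variance components: `env`,
#'   `gca_male`, `gca_female`, `sca`, `gca_male_x_env`,
#'   `gca_female_x_env`, `sca_x_env`, `residual`.
#' @param parental_noise_var variance of the measurement noise added to
#'   the parents' own additive values to form parental phenotypes.
#' @param grand_mean intercept of every trait.
#' @param heterozygous if FALSE (default) parents are fully homozygous
#'   inbreds (dosage 0 or 2); if TRUE dosages are Binomial(2, q).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_males = 6, n_females = 40, n_markers = 300,
                         n_envs = 3, n_hybrids_per_env = c(70, 65, 120),
                         overlap = 0.32,
                         traits = c("GY", "DTF", "DTH"),
                         trait_cor = 0.5,
                         var_comp = c(env = 2, gca_male = 0.4,
                                      gca_female = 0.4, sca = 0.2,
                                      gca_male_x_env = 0.05,
                                      gca_female_x_env = 0.05,
                                      sca_x_env = 0.1, residual = 1),
                         parental_noise_var = 0.1,
                         grand_mean = 10, heterozygous = FALSE) {
  n_traits <- length(traits)
  if (is.matrix(trait_cor)) {
    R <- trait_cor
  } else {
    R <- matrix(trait_cor, n_traits, n_traits)
    diag(R) <- 1
  }
  stopifnot(nrow(R) == n_traits, ncol(R) == n_traits,
            all(abs(diag(R) - 1) < 1e-12), all(R == t(R)))
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("trait correlation matrix is not positive semi-definite",
         call. = FALSE)
  need <- c("env", "gca_male", "gca_female", "sca", "gca_male_x_env",
            "gca_female_x_env", "sca_x_env", "residual")
  if (!all(need %in% names(var_comp)))
    stop("var_comp must name: ", paste(need, collapse = ", "), call. = FALSE)
  if (any(var_comp < 0)) stop("variances must be >= 0", call. = FALSE)
  n_hybrids_per_env <- rep_len(n_hybrids_per_env, n_envs)
  if (any(n_hybrids_per_env > n_males * n_females))
    stop("more hybrids per environment than possible crosses", call. = FALSE)
  stopifnot(overlap >= 0, overlap < 1)
  structure(list(
    n_males = n_males, n_females = n_females, n_markers = n_markers,
    n_envs = n_envs, n_hybrids_per_env = n_hybrids_per_env,
    overlap = overlap, traits = traits, trait_cor = R,
    var_comp = var_comp[need], parental_noise_var = parental_noise_var,
    grand_mean = grand_mean, heterozygous = heterozygous),
    class = "synth_config")
}

#' Simulate a hybrid breeding dataset with ground truth
#'
#' Generates, under the model the package fits: homozygous parental
#' genotypes with allele frequencies Uniform(0.1, 0.9); per-trait marker
#' effects drawn jointly across traits with the configured genetic
#' correlation, giving GCA vectors rescaled to the exact configured
#' variances; SCA effects drawn from `N(0, sca * H)` with `H` the
#' Kronecker sub-matrix kernel of the true GRMs; interaction effects
#' drawn per environment from the corresponding kernels; and parental
#' phenotypes equal to each parent's own additive value plus noise (so
#' that mid-parent covariates are informative). Environments have
#' unbalanced, partially overlapping hybrid sets.
#'
#' @param config a [synth_config()].
#' @param seed integer seed; identical config + seed reproduces the
#'   dataset bit-for-bit.
#' @return a list of class `hybrid_sim`: `male_markers`,
#'   `female_markers`, `pedigree`, `phenotypes` (long format),
#'   `parental_phenotypes`, `traits`, `config`, `seed` and `truth`
#'   (entity-level effects, per-record components and the generating
#'   variance components).
#' @export
simulate_hybrid_data <- function(config = synth_config(), seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(as.integer(seed), simulate_impl(config, seed))
}

simulate_impl <- function(cf, seed) {
  vc <- cf$var_comp
  Tt <- length(cf$traits)
  Lr <- t(chol(cf$trait_cor + diag(1e-10, Tt)))

  sim_pool <- function(n, prefix) {
    q <- runif(cf$n_markers, 0.1, 0.9)
    X <- if (cf$heterozygous) {
      matrix(rbinom(n * cf$n_markers, 2, rep(q, each = n)), n, cf$n_markers)
    } else {
      2 * matrix(rbinom(n * cf$n_markers, 1, rep(q, each = n)),
                 n, cf$n_markers)
    }
    dimnames(X) <- list(paste0(prefix, seq_len(n)),
                        paste0("mk", seq_len(cf$n_markers)))
    X
  }
  XM <- sim_pool(cf$n_males, "M")
  XF <- sim_pool(cf$n_females, "F")

  # correlated additive values per pool, rescaled to the exact variance
  gca_values <- function(X, s2) {
    poly <- apply(X, 2L, function(c) stats::var(c) > 0)
    W <- scale(X[, poly, drop = FALSE])  # centered/standardized markers
    alpha <- matrix(rnorm(sum(poly) * Tt), sum(poly), Tt) %*% t(Lr)
    A <- W %*% alpha
    for (t in seq_len(Tt)) {
      v <- mean(A[, t]^2) - mean(A[, t])^2
      A[, t] <- if (s2 > 0 && v > 0) (A[, t] - mean(A[, t])) * sqrt(s2 / v)
                else 0
    }
    colnames(A) <- cf$traits
    A
  }
  gM <- gca_values(XM, vc["gca_male"])
  gF <- gca_values(XF, vc["gca_female"])

  # true GRMs over the polymorphic markers of each pool
  G_true <- function(X) {
    poly <- apply(X, 2L, function(c) stats::var(c) > 0)
    grm(X[, poly, drop = FALSE])
  }
  GM <- G_true(XM); GF <- G_true(XF)

  # unbalanced, overlapping hybrid sets
  all_cross <- expand.grid(male = rownames(XM), female = rownames(XF),
                           stringsAsFactors = FALSE)
  all_cross$hybrid <- paste0(all_cross$male, "x", all_cross$female)
  env_ids <- paste0("E", seq_len(cf$n_envs))
  env_sets <- vector("list", cf$n_envs)
  env_sets[[1]] <- sample(all_cross$hybrid, cf$n_hybrids_per_env[1])
  for (e in seq_len(cf$n_envs)[-1]) {
    n_e <- cf$n_hybrids_per_env[e]
    n_keep <- min(round(cf$overlap * n_e), length(env_sets[[e - 1]]))
    kept <- sample(env_sets[[e - 1]], n_keep)
    pool <- setdiff(all_cross$hybrid, kept)
    if (n_e - n_keep > length(pool))
      stop("infeasible overlap: not enough crosses left", call. = FALSE)
    env_sets[[e]] <- c(kept, sample(pool, n_e - n_keep))
  }
  hybrids <- unique(unlist(env_sets))
  ped <- all_cross[match(hybrids, all_cross$hybrid),
                   c("hybrid", "male", "female")]
  rownames(ped) <- NULL

  # SCA from the model's own kernel (Cholesky over observed crosses)
  Hk <- sca_kernel(ped, GM, GF)
  Lh <- t(chol(Hk + diag(1e-8, nrow(Hk))))
  sca <- matrix(0, nrow(Hk), Tt, dimnames = list(ped$hybrid, cf$traits))
  if (vc["sca"] > 0)
    sca[] <- sqrt(vc["sca"]) * (Lh %*% matrix(rnorm(nrow(Hk) * Tt),
                                              nrow(Hk), Tt))

  # per-environment interaction draws from the main-effect kernels
  draw_env <- function(Kmat, s2) {
    L <- t(chol(Kmat + diag(1e-8, nrow(Kmat))))
    out <- array(0, c(nrow(Kmat), cf$n_envs, Tt),
                 dimnames = list(rownames(Kmat), env_ids, cf$traits))
    if (s2 > 0)
      for (e in seq_len(cf$n_envs)) for (t in seq_len(Tt))
        out[, e, t] <- sqrt(s2) * (L %*% rnorm(nrow(Kmat)))
    out
  }
  uM <- draw_env(GM, vc["gca_male_x_env"])
  uF <- draw_env(GF, vc["gca_female_x_env"])
  uH <- draw_env(Hk, vc["sca_x_env"])

  env_eff <- matrix(rnorm(cf$n_envs * Tt, 0, sqrt(vc["env"])),
                    cf$n_envs, Tt, dimnames = list(env_ids, cf$traits))

  # assemble records
  rec <- do.call(rbind, lapply(seq_len(cf$n_envs), function(e)
    data.frame(hybrid = env_sets[[e]], env = env_ids[e],
               stringsAsFactors = FALSE)))
  im <- match(ped$male[match(rec$hybrid, ped$hybrid)], rownames(XM))
  iff <- match(ped$female[match(rec$hybrid, ped$hybrid)], rownames(XF))
  ih <- match(rec$hybrid, ped$hybrid)
  ie <- match(rec$env, env_ids)

  comp <- list(); pheno <- list()
  for (t in seq_len(Tt)) {
    eps <- rnorm(nrow(rec), 0, sqrt(vc["residual"]))
    d <- data.frame(
      hybrid = rec$hybrid, env = rec$env, trait = cf$traits[t],
      env_eff = env_eff[ie, t],
      gca_male = gM[im, t], gca_female = gF[iff, t], sca = sca[ih, t],
      gca_male_x_env = uM[cbind(im, ie, t)],
      gca_female_x_env = uF[cbind(iff, ie, t)],
      sca_x_env = uH[cbind(ih, ie, t)],
      residual = eps)
    d$value <- cf$grand_mean + d$env_eff + d$gca_male + d$gca_female +
      d$sca + d$gca_male_x_env + d$gca_female_x_env + d$sca_x_env +
      d$residual
    comp[[t]] <- d
    pheno[[t]] <- d[c("hybrid", "env", "trait", "value")]
  }
  components <- do.call(rbind, comp)
  phenotypes <- do.call(rbind, pheno)
  rownames(components) <- rownames(phenotypes) <- NULL

  # parental phenotypes: own additive value + measurement noise
  pnoise <- sqrt(cf$parental_noise_var)
  pp <- rbind(
    data.frame(parent = rep(rownames(XM), Tt),
               trait = rep(cf$traits, each = cf$n_males),
               value = as.numeric(gM) +
                 rnorm(cf$n_males * Tt, 0, pnoise)),
    data.frame(parent = rep(rownames(XF), Tt),
               trait = rep(cf$traits, each = cf$n_females),
               value = as.numeric(gF) +
                 rnorm(cf$n_females * Tt, 0, pnoise)))
  rownames(pp) <- NULL

  structure(list(
    male_markers = XM, female_markers = XF, pedigree = ped,
    phenotypes = phenotypes, parental_phenotypes = pp,
    traits = cf$traits, config = cf, seed = as.integer(seed),
    truth = list(grand_mean = cf$grand_mean, env_effects = env_eff,
                 gca_male = gM, gca_female = gF, sca = sca,
                 gca_male_x_env = uM, gca_female_x_env = uF,
                 sca_x_env = uH, components = components,
                 var_comp = vc, G_M = GM, G_F = GF, H = Hk)),
    class = "hybrid_sim")
}

#' @export
print.hybrid_sim <- function(x, ...) {
  cf <- x$config
  cat("Synthetic hybrid breeding dataset (seed", x$seed, ")\n")
  cat(sprintf("  %d males x %d females, %d markers, %d hybrids\n",
              cf$n_males, cf$n_females, cf$n_markers, nrow(x$pedigree)))
  cat(sprintf("  %d environments, records per env: %s\n", cf$n_envs,
              paste(cf$n_hybrids_per_env, collapse = ", ")))
  cat("  traits:", paste(cf$traits, collapse = ", "), "\n")
  invisible(x)
}

#' Inject missing values into a marker matrix
#'
#' Post-hoc corruption step for exercising the QC pipeline: each cell is
#' set missing independently with probability `rate`.
#'
#' @param markers dosage matrix.
#' @param rate per-cell missingness probability.
#' @param seed integer seed.
#' @export
corrupt_markers <- function(markers, rate = 0.05, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(rate >= 0, rate <= 1)
  withr::with_seed(as.integer(seed), {
    drop <- matrix(runif(length(markers)) < rate, nrow(markers))
    markers[drop] <- NA_real_
    markers
  })
}
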