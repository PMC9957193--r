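#' Specify one of the twelve hybrid prediction models
#'
#' The model families differ in which genetic terms enter the predictor
#' and whether their kernels are genomic:
#' \describe{
#'   \item{A}{environment + male GCA + female GCA + SCA + all three
#'     genotype-by-environment interactions, identity kernels.}
#'   \item{B}{as A, with genomic kernels (parental GRMs, Kronecker SCA
#'     kernel, Hadamard interactions).}
#'   \item{C}{environment + SCA + SCA-by-environment only, identity
#'     kernels.}
#'   \item{D}{as C with genomic kernels.}
#' }
#' Each family can carry no parental covariates (`"none"`), the target
#' trait's mid-parent covariates (`"C"`), or covariates for the target
#' and correlated traits (`"AC"`), giving 12 models; model ids follow the
#' `MA`, `MA_C`, `MA_AC`, ... convention.
#'
#' @param type model family, one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param covariates covariate mode, `"none"`, `"C"` or `"AC"`.
#' @param trait name of the trait to predict.
#' @return an object of class `hybrid_model_spec`.
#' @export
hybrid_model_spec <- function(type = c("B", "A", "C", "D"),
                              covariates = c("none", "C", "AC"),
                              trait) {
  type <- match.arg(type)
  covariates <- match.arg(covariates)
  stopifnot(is.character(trait), length(trait) == 1L)
  structure(
    list(type = type, covariates = covariates, trait = trait,
         genomic = type %in% c("B", "D"),
         id = paste0("M", type,
                     if (covariates == "none") "" else paste0("_", covariates))),
    class = "hybrid_model_spec")
}

#' @export
print.hybrid_model_spec <- function(x, ...) {
  cat("hybrid model spec", x$id, "- trait", x$trait, "\n")
  cat("  family:", x$type,
      if (x$genomic) "(genomic kernels)" else "(identity kernels)", "\n")
  cat("  parental covariates:", x$covariates, "\n")
  invisible(x)
}

#' Assemble the fixed design and random-term kernels of a model
#'
#' Translates a model spec plus data into the fitting engine's inputs:
#' a fixed design (intercept plus centered covariate columns) and a named
#' list of record-level covariance kernels, one per random term,
#' including the environment main effect (treated as a random effect with
#' its own variance) and the Hadamard interaction kernels.
#'
#' @param spec a [hybrid_model_spec()].
#' @param records data frame of phenotype records for the target trait
#'   with columns `hybrid`, `env`, `value`.
#' @param pedigree hybrid pedigree (`hybrid`, `male`, `female`).
#' @param G_M,G_F parental relationship matrices; required for genomic
#'   families (B, D), ignored otherwise unless `literal_uH = TRUE`.
#' @param covariates hybrids x covariates matrix from
#'   [build_covariates()]; required when `spec$covariates != "none"`.
#' @param literal_uH if TRUE, the non-genomic families keep the genomic
#'   SCA kernel inside the hybrid-by-environment interaction term (the
#'   literal reading of the model description); default FALSE uses
#'   identity kernels for every non-genomic term.
#' @return list with `y`, `X` (fixed design), `kernels` (named list of
#'   record-level PSD matrices) and `records`.
#' @export
assemble_terms <- function(spec, records, pedigree, G_M = NULL, G_F = NULL,
                           covariates = NULL, literal_uH = FALSE) {
  stopifnot(inherits(spec, "hybrid_model_spec"))
  records <- as.data.frame(records)
  if (!all(c("hybrid", "env", "value") %in% names(records)))
    stop("records need columns hybrid, env, value", call. = FALSE)
  records$hybrid <- as.character(records$hybrid)
  records$env <- as.character(records$env)
  pedigree <- as_pedigree(pedigree)
  bad <- setdiff(records$hybrid, pedigree$hybrid)
  if (length(bad))
    stop("records reference hybrids absent from pedigree: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)

  ped <- pedigree[pedigree$hybrid %in% records$hybrid, , drop = FALSE]
  idx <- match(records$hybrid, ped$hybrid)
  rec_male <- ped$male[idx]
  rec_female <- ped$female[idx]
  rid <- seq_len(nrow(records))

  if (spec$genomic && (is.null(G_M) || is.null(G_F)))
    stop("genomic model families need G_M and G_F", call. = FALSE)

  if (spec$genomic) {
    K_M <- G_M; K_F <- G_F
    H <- sca_kernel(ped, G_M, G_F)
  } else {
    K_M <- identity_kernel(unique(ped$male))
    K_F <- identity_kernel(unique(ped$female))
    H <- if (literal_uH) {
      if (is.null(G_M) || is.null(G_F))
        stop("literal_uH needs G_M and G_F", call. = FALSE)
      sca_kernel(ped, G_M, G_F)
    } else identity_kernel(ped$hybrid)
    if (literal_uH) H_main <- identity_kernel(ped$hybrid)
  }

  E <- env_block_kernel(records$env, rid)
  sca_main <- if (!spec$genomic && literal_uH) H_main else H
  sca_rec <- expand_kernel(sca_main, records$hybrid, rid)
  sca_int <- expand_kernel(H, records$hybrid, rid)

  kernels <- list(env = E)
  if (spec$type %in% c("A", "B")) {
    gm <- expand_kernel(K_M, rec_male, rid)
    gf <- expand_kernel(K_F, rec_female, rid)
    kernels$gca_male <- gm
    kernels$gca_female <- gf
    kernels$sca <- sca_rec
    kernels$gca_male_x_env <- interaction_kernel(gm, E)
    kernels$gca_female_x_env <- interaction_kernel(gf, E)
    kernels$sca_x_env <- interaction_kernel(sca_int, E)
  } else {
    kernels$sca <- sca_rec
    kernels$sca_x_env <- interaction_kernel(sca_int, E)
  }

  X <- matrix(1, nrow(records), 1L, dimnames = list(rid, "(Intercept)"))
  if (spec$covariates != "none") {
    if (is.null(covariates))
      stop("covariate mode ", spec$covariates,
           " requested but no covariates supplied", call. = FALSE)
    bad <- setdiff(records$hybrid, rownames(covariates))
    if (length(bad))
      stop("covariate matrix misses hybrids: ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    X <- cbind(X, covariates[records$hybrid, , drop = FALSE])
    rownames(X) <- rid
  }

  list(y = as.numeric(records$value), X = X, kernels = kernels,
       records = records)
}

# eigendecompose a kernel, truncating eigenvalues < tol * max
eigen_kernel <- function(K, tol = 1e-10) {
  es <- eigen(K, symmetric = TRUE)
  dmax <- max(es$values, 0)
  keep <- es$values > tol * max(dmax, .Machine$double.eps)
  if (!any(keep))
    stop("kernel has no positive eigenvalues", call. = FALSE)
  if (min(es$values) < -1e-8 * max(dmax, 1))
    stop("kernel is not positive semi-definite", call. = FALSE)
  list(U = es$vectors[, keep, drop = FALSE], d = es$values[keep])
}

#' Bayesian multi-kernel regression via Gibbs sampling
#'
#' Fits `y = X beta + sum_k u_k + e` with `u_k ~ N(0, s2_k K_k)` and
#' `e ~ N(0, s2_e I)` by Gibbs sampling on the eigen-coordinates of each
#' kernel (the computational engine behind [fit_hybrid_model()]).
#' `beta` has a flat prior; every variance component has a scaled
#' inverse-chi-square prior with `df0` degrees of freedom and scale set
#' so that the prior mode assigns half the response variance to the
#' random terms in equal parts (and half to the residual). Records with
#' `mask = TRUE` are treated as missing: they are imputed at each
#' iteration and their posterior-mean fitted value is reported as the
#' prediction.
#'
#' @param y numeric response; masked entries may be `NA`.
#' @param kernels named list of records x records PSD kernel matrices.
#' @param X fixed-effect design matrix; default intercept only. A column
#'   of ones is prepended if absent.
#' @param mask logical vector marking records to hold out (default: the
#'   `NA` entries of `y`).
#' @param n_iter,burn_in,thin Gibbs sampler settings.
#' @param seed integer seed (mandatory; the run is reproducible).
#' @param fix_variances optional named numeric vector of variance
#'   components (one per kernel plus `"residual"`); when supplied the
#'   sampler holds them fixed instead of updating them.
#' @param df0 prior degrees of freedom for every variance component.
#' @param r2 prior proportion of the response variance assigned to the
#'   random terms jointly (default 0.5).
#' @return an object of class `kernel_fit`.
#' @export
kernel_regression <- function(y, kernels, X = NULL, mask = NULL,
                              n_iter = 12000, burn_in = 2000, thin = 5,
                              seed, fix_variances = NULL, df0 = 5, r2 = 0.5) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  n <- length(y)
  stopifnot(is.list(kernels), length(kernels) >= 1L)
  if (is.null(names(kernels)) || any(names(kernels) == ""))
    names(kernels) <- paste0("K", seq_along(kernels))
  if (is.null(mask)) mask <- is.na(y)
  stopifnot(length(mask) == n)
  if (all(mask)) stop("all records are masked", call. = FALSE)
  if (is.null(X)) X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n)
    stop("fixed design has ", nrow(X), " rows for ", n, " records",
         call. = FALSE)
  if (!any(apply(X, 2L, function(c) all(c == c[1]) && c[1] != 0)))
    X <- cbind(`(Intercept)` = 1, X)
  # intercept column first (the sampler initialises it at mean(y))
  ic <- which(apply(X, 2L, function(c) all(c == 1)))[1]
  if (!is.na(ic) && ic != 1L) X <- X[, c(ic, setdiff(seq_len(ncol(X)), ic)),
                                     drop = FALSE]
  for (k in seq_along(kernels)) {
    if (!all(dim(kernels[[k]]) == n))
      stop("kernel ", names(kernels)[k], " has wrong dimensions",
           call. = FALSE)
  }

  eigs <- lapply(kernels, eigen_kernel)
  K <- length(eigs)

  vy <- stats::var(y[!mask])
  if (!is.finite(vy) || vy <= 0) vy <- 1
  # prior scales: mode = S / (df0 + 2)
  S0 <- rep((df0 + 2) * r2 * vy / K, K)
  S0e <- (df0 + 2) * (1 - r2) * vy

  fix <- !is.null(fix_variances)
  if (fix) {
    need <- c(names(kernels), "residual")
    if (!all(need %in% names(fix_variances)))
      stop("fix_variances must name every kernel and 'residual'",
           call. = FALSE)
    s2_init <- as.numeric(fix_variances[names(kernels)])
    s2e_init <- as.numeric(fix_variances[["residual"]])
  } else {
    s2_init <- S0 / (df0 + 2)
    s2e_init <- S0e / (df0 + 2)
  }

  y_in <- y
  y_in[mask] <- 0  # placeholder; sampler re-initialises masked entries

  res <- withr::with_seed(as.integer(seed),
    gibbs_kernel_sampler(y_in, as.integer(mask), X,
                         lapply(eigs, `[[`, "U"), lapply(eigs, `[[`, "d"),
                         as.integer(n_iter), as.integer(burn_in),
                         as.integer(thin),
                         df0, S0, df0, S0e, fix, s2_init, s2e_init))

  nsamp <- res$n_saved
  var_comp <- data.frame(
    term = c(names(kernels), "residual"),
    variance = c(res$s2, res$s2e),
    mc_se = c(res$s2_sd, res$s2e_sd) / sqrt(nsamp),
    row.names = NULL)
  effects <- stats::setNames(res$effects, names(kernels))
  beta <- stats::setNames(as.numeric(res$beta), colnames(X))

  structure(list(
    y = y, mask = mask, X = X, beta = beta, effects = effects,
    fitted = as.numeric(res$fitted),
    fitted_mc_se = as.numeric(res$fitted_sd) / sqrt(nsamp),
    predictions = as.numeric(res$fitted)[mask],
    var_comp = var_comp,
    settings = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                    seed = seed, df0 = df0, r2 = r2,
                    fixed_variances = fix, n_saved = nsamp)),
    class = "kernel_fit")
}

#' Fit a hybrid prediction model
#'
#' The central fitting function: builds kernels and covariates from the
#' data according to the model spec, assembles the predictor and runs
#' the Gibbs sampler. `data` is a list (such as the value of
#' [simulate_hybrid_data()]) with elements `phenotypes` (long format:
#' `hybrid`, `env`, `trait`, `value`), `pedigree`, and, as needed,
#' `male_markers`/`female_markers` (or precomputed `G_M`/`G_F`) and
#' `parental_phenotypes`.
#'
#' @param spec a [hybrid_model_spec()].
#' @param data list, see Details.
#' @param mask_hybrids character vector of hybrid ids whose records (in
#'   every environment) are masked and predicted — the
#'   untested-lines-in-tested-environments scheme.
#' @param qc apply [marker_qc()] to raw marker matrices first? (default
#'   TRUE; ignored when `G_M`/`G_F` are supplied).
#' @param dominance dominance rule passed to [build_covariates()].
#' @param literal_uH see [assemble_terms()].
#' @inheritParams kernel_regression
#' @param ... further arguments passed to [kernel_regression()].
#' @return an object of classes `hybrid_fit`, `kernel_fit`.
#' @export
fit_hybrid_model <- function(spec, data, mask_hybrids = NULL,
                             n_iter = 12000, burn_in = 2000, thin = 5,
                             seed, qc = TRUE,
                             dominance = "half_abs_diff",
                             literal_uH = FALSE, ...) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(inherits(spec, "hybrid_model_spec"))
  prep <- prepare_model(spec, data, qc = qc, dominance = dominance,
                        literal_uH = literal_uH)
  mask <- prep$records$hybrid %in% (mask_hybrids %||% character(0))
  fit <- kernel_regression(prep$y, prep$kernels, X = prep$X, mask = mask,
                           n_iter = n_iter, burn_in = burn_in, thin = thin,
                           seed = seed, ...)
  fit$spec <- spec
  fit$records <- prep$records
  fit$prediction_table <- data.frame(
    hybrid = prep$records$hybrid[mask],
    env = prep$records$env[mask],
    observed = prep$records$value[mask],
    predicted = fit$fitted[mask])
  class(fit) <- c("hybrid_fit", class(fit))
  fit
}

# build covariates + kernels + fixed design once for a spec/data pair
prepare_model <- function(spec, data, qc = TRUE,
                          dominance = "half_abs_diff", literal_uH = FALSE) {
  ph <- as.data.frame(data$phenotypes)
  if (!all(c("hybrid", "env", "trait", "value") %in% names(ph)))
    stop("phenotypes need columns hybrid, env, trait, value", call. = FALSE)
  records <- ph[ph$trait == spec$trait, c("hybrid", "env", "value")]
  if (nrow(records) == 0L)
    stop("no phenotype records for trait ", spec$trait, call. = FALSE)

  G_M <- data$G_M; G_F <- data$G_F
  if (spec$genomic || literal_uH) {
    if (is.null(G_M)) {
      if (is.null(data$male_markers))
        stop("genomic model requested but no male markers / G_M in data",
             call. = FALSE)
      Xm <- data$male_markers
      if (qc) Xm <- marker_qc(Xm)
      G_M <- grm(Xm)
    }
    if (is.null(G_F)) {
      if (is.null(data$female_markers))
        stop("genomic model requested but no female markers / G_F in data",
             call. = FALSE)
      Xf <- data$female_markers
      if (qc) Xf <- marker_qc(Xf)
      G_F <- grm(Xf)
    }
  }

  covs <- NULL
  if (spec$covariates != "none") {
    if (is.null(data$parental_phenotypes))
      stop("covariate mode ", spec$covariates,
           " needs parental phenotypes in data", call. = FALSE)
    ped_obs <- as_pedigree(data$pedigree)
    ped_obs <- ped_obs[ped_obs$hybrid %in% records$hybrid, , drop = FALSE]
    covs <- build_covariates(ped_obs, data$parental_phenotypes,
                             target_trait = spec$trait,
                             mode = spec$covariates,
                             traits = data$traits,
                             dominance = dominance)
  }

  out <- assemble_terms(spec, records, data$pedigree, G_M = G_M, G_F = G_F,
                        covariates = covs, literal_uH = literal_uH)
  out$covariates <- covs
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
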