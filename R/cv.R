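#' Assign hybrids to cross-validation folds
#'
#' Seeded uniform shuffle followed by round-robin assignment, so fold
#' sizes differ by at most one. Folds are defined at the hybrid level:
#' all records of a hybrid (across environments) share its fold, which is
#' what makes the scheme "untested lines in tested environments".
#'
#' @param hybrid_ids character vector of unique hybrid ids.
#' @param k number of folds (default 7).
#' @param seed integer seed.
#' @return named integer vector mapping hybrid id to fold in `1..k`,
#'   with attributes `seed` and `k`.
#' @export
make_folds <- function(hybrid_ids, k = 7, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  hybrid_ids <- as.character(hybrid_ids)
  if (anyDuplicated(hybrid_ids)) stop("duplicate hybrid ids", call. = FALSE)
  n <- length(hybrid_ids)
  stopifnot(k >= 2)
  if (k > n) stop("more folds than hybrids", call. = FALSE)
  shuffled <- withr::with_seed(as.integer(seed), sample(hybrid_ids))
  folds <- stats::setNames(rep_len(seq_len(k), n), shuffled)[hybrid_ids]
  attr(folds, "seed") <- as.integer(seed)
  attr(folds, "k") <- as.integer(k)
  folds
}

# cheap stable hash of a fold assignment (paired-design bookkeeping)
fold_hash <- function(folds) {
  s <- paste(names(folds), folds, sep = ":", collapse = ";")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  sprintf("%010d", h)
}

#' Untested-lines-in-tested-environments cross-validation
#'
#' For each fold, every record of the fold's hybrids is masked in every
#' environment, the model is refit on the remainder, and the masked
#' records are predicted. Squared errors are pooled per environment and
#' globally (record-weighted); the unweighted mean of per-fold MSEs is
#' reported alongside.
#'
#' @param spec a [hybrid_model_spec()].
#' @param data data list as in [fit_hybrid_model()].
#' @param folds fold assignment from [make_folds()].
#' @param n_iter,burn_in,thin sampler settings per fold fit.
#' @param seed integer seed; fold `f` uses `seed + f`.
#' @param predict_fun optional override of the fitting engine, mainly for
#'   testing: a `function(prep, mask)` returning predictions for the
#'   masked records (in record order).
#' @param ... passed to [kernel_regression()].
#' @return an object of class `cv_report`.
#' @export
run_cv <- function(spec, data, folds, n_iter = 12000, burn_in = 2000,
                   thin = 5, seed, predict_fun = NULL, ...) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  prep <- prepare_model(spec, data)
  eigs <- lapply(prep$kernels, eigen_kernel)
  cv_engine(spec, prep, eigs, folds, n_iter = n_iter, burn_in = burn_in,
            thin = thin, seed = seed, predict_fun = predict_fun, ...)
}

# shared CV loop; eigendecompositions are computed once per model and
# reused across folds (the kernels do not depend on the mask)
cv_engine <- function(spec, prep, eigs, folds, n_iter, burn_in, thin, seed,
                      predict_fun = NULL, ...) {
  records <- prep$records
  bad <- setdiff(records$hybrid, names(folds))
  if (length(bad))
    stop("records reference hybrids without a fold: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  rec_fold <- folds[records$hybrid]
  k <- attr(folds, "k") %||% max(folds)

  pred <- rep(NA_real_, nrow(records))
  for (f in seq_len(k)) {
    mask <- rec_fold == f
    if (!any(mask)) next
    left <- table(records$env[!mask])
    gone <- setdiff(unique(records$env), names(left)[left > 0])
    if (length(gone))
      stop("fold ", f, " leaves environment(s) without training records: ",
           paste(gone, collapse = ", "), call. = FALSE)
    if (!is.null(predict_fun)) {
      pred[mask] <- predict_fun(prep, mask)
    } else {
      fit <- kernel_fit_from_eigs(prep$y, eigs, prep$X, mask,
                                  n_iter = n_iter, burn_in = burn_in,
                                  thin = thin, seed = seed + f, ...)
      pred[mask] <- fit$fitted[mask]
    }
  }

  sq <- (pred - records$value)^2
  cell <- stats::aggregate(sq, list(env = records$env, fold = rec_fold), mean)
  names(cell)[3] <- "mse"
  cell$n <- stats::aggregate(sq, list(env = records$env, fold = rec_fold),
                             length)$x
  env_mse <- tapply(sq, records$env, mean)
  fold_mse <- tapply(sq, rec_fold, mean)

  structure(list(
    model = spec$id, trait = spec$trait,
    predictions = data.frame(hybrid = records$hybrid, env = records$env,
                             fold = as.integer(rec_fold),
                             observed = records$value, predicted = pred),
    cell_mse = cell,
    env_mse = data.frame(env = names(env_mse), mse = as.numeric(env_mse),
                         n = as.integer(table(records$env)[names(env_mse)])),
    global_mse = mean(sq),
    fold_mean_mse = mean(fold_mse),
    n_records = nrow(records),
    fold_hash = fold_hash(folds),
    seed = seed), class = "cv_report")
}

# kernel_regression variant taking precomputed eigendecompositions
kernel_fit_from_eigs <- function(y, eigs, X, mask, n_iter, burn_in, thin,
                                 seed, df0 = 5, r2 = 0.5,
                                 fix_variances = NULL) {
  K <- length(eigs)
  vy <- stats::var(y[!mask]); if (!is.finite(vy) || vy <= 0) vy <- 1
  S0 <- rep((df0 + 2) * r2 * vy / K, K)
  S0e <- (df0 + 2) * (1 - r2) * vy
  fix <- !is.null(fix_variances)
  if (fix) {
    s2_init <- as.numeric(fix_variances[names(eigs)])
    s2e_init <- as.numeric(fix_variances[["residual"]])
  } else {
    s2_init <- S0 / (df0 + 2); s2e_init <- S0e / (df0 + 2)
  }
  y_in <- y; y_in[mask] <- 0
  res <- withr::with_seed(as.integer(seed),
    gibbs_kernel_sampler(y_in, as.integer(mask), X,
                         lapply(eigs, `[[`, "U"), lapply(eigs, `[[`, "d"),
                         as.integer(n_iter), as.integer(burn_in),
                         as.integer(thin), df0, S0, df0, S0e,
                         fix, s2_init, s2e_init))
  list(fitted = as.numeric(res$fitted), s2 = res$s2, s2e = res$s2e)
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validation report -", x$model, "on", x$trait, "\n")
  cat(sprintf("  %d records, fold hash %s\n", x$n_records, x$fold_hash))
  print(transform(x$env_mse, mse = signif(mse, 4)), row.names = FALSE)
  cat(sprintf("  global MSE (pooled records): %.4f\n", x$global_mse))
  cat(sprintf("  global MSE (mean of folds):  %.4f\n", x$fold_mean_mse))
  invisible(x)
}

#' Relative efficiency of two models' mean squared errors
#'
#' `RE = mse_reference / mse_candidate`; values above 1 mean the
#' candidate (typically the covariate-augmented model) predicts better.
#' The percent gain is `(RE - 1) * 100`.
#'
#' @param mse_reference,mse_candidate positive mean squared errors.
#' @return list with `re`, `percent_gain` and a `verdict` string.
#' @examples
#' relative_efficiency(2, 1)       # candidate twice as efficient
#' relative_efficiency(1.141, 1)   # RE 1.141 = 14.1% gain
#' @export
relative_efficiency <- function(mse_reference, mse_candidate) {
  if (!is.finite(mse_reference) || !is.finite(mse_candidate) ||
      mse_reference <= 0 || mse_candidate <= 0)
    stop("MSE values must be positive", call. = FALSE)
  re <- mse_reference / mse_candidate
  list(re = re,
       percent_gain = (re - 1) * 100,
       verdict = if (re > 1) "candidate better"
                 else if (re < 1) "reference better"
                 else "equally efficient")
}

#' Run and compare the hybrid model families under shared folds
#'
#' Fits every requested family in its three covariate modes (`none`,
#' `C`, `AC`) with one shared fold assignment (paired design), and
#' tabulates per-environment and global MSE plus the three relative
#' efficiencies per family: plain vs `_C`, plain vs `_AC`, and `_C` vs
#' `_AC`.
#'
#' @param data data list as in [fit_hybrid_model()].
#' @param trait trait to predict.
#' @param families subset of `c("A", "B", "C", "D")`.
#' @param k number of folds (default 7).
#' @param seed master seed: drives fold construction and per-fold
#'   sampler seeds.
#' @param n_iter,burn_in,thin sampler settings.
#' @param ... passed to the engine.
#' @return an object of class `model_comparison` with elements `mse`
#'   (one row per model), `re` (one row per comparison), `reports` and
#'   `fold_hash`.
#' @export
compare_models <- function(data, trait, families = c("A", "B", "C", "D"),
                           k = 7, seed, n_iter = 12000, burn_in = 2000,
                           thin = 5, ...) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  families <- match.arg(families, several.ok = TRUE)
  ph <- as.data.frame(data$phenotypes)
  hybrids <- unique(ph$hybrid[ph$trait == trait])
  folds <- make_folds(hybrids, k = k, seed = seed)

  reports <- list()
  offset <- 0L
  for (fam in families) {
    # kernels are shared by the three covariate modes of a family:
    # eigendecompose once
    spec_ac <- hybrid_model_spec(fam, "AC", trait)
    prep_ac <- prepare_model(spec_ac, data)
    eigs <- lapply(prep_ac$kernels, eigen_kernel)
    n_cov_target <- 2L  # add + dom columns of the target trait
    for (mode in c("none", "C", "AC")) {
      spec <- hybrid_model_spec(fam, mode, trait)
      prep <- prep_ac
      prep$X <- switch(mode,
        none = prep_ac$X[, 1L, drop = FALSE],
        C = prep_ac$X[, seq_len(1L + n_cov_target), drop = FALSE],
        AC = prep_ac$X)
      offset <- offset + 1000L
      reports[[spec$id]] <- cv_engine(spec, prep, eigs, folds,
                                      n_iter = n_iter, burn_in = burn_in,
                                      thin = thin, seed = seed + offset, ...)
    }
  }

  envs <- reports[[1]]$env_mse$env
  mse <- do.call(rbind, lapply(reports, function(r) {
    row <- data.frame(model = r$model, global_mse = r$global_mse,
                      fold_mean_mse = r$fold_mean_mse)
    for (e in envs) row[[paste0("mse_", e)]] <-
      r$env_mse$mse[r$env_mse$env == e]
    row
  }))
  rownames(mse) <- NULL

  re_rows <- list()
  for (fam in families) {
    g <- function(id) reports[[id]]$global_mse
    plain <- paste0("M", fam)
    pairs <- list(c(plain, paste0(plain, "_C")),
                  c(plain, paste0(plain, "_AC")),
                  c(paste0(plain, "_C"), paste0(plain, "_AC")))
    for (p in pairs) {
      r <- relative_efficiency(g(p[1]), g(p[2]))
      re_rows[[length(re_rows) + 1L]] <- data.frame(
        family = fam, reference = p[1], candidate = p[2],
        re = r$re, percent_gain = r$percent_gain)
    }
  }
  re <- do.call(rbind, re_rows)

  structure(list(mse = mse, re = re, reports = reports,
                 fold_hash = reports[[1]]$fold_hash, trait = trait,
                 seed = seed),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison -", x$trait, "- fold hash", x$fold_hash, "\n\n")
  m <- x$mse
  m[-1] <- lapply(m[-1], signif, 4)
  print(m, row.names = FALSE)
  cat("\nRelative efficiencies (global, pooled records):\n")
  r <- x$re
  r$re <- sprintf("%.3f", r$re)
  r$percent_gain <- sprintf("%.1f", r$percent_gain)
  print(r, row.names = FALSE)
  invisible(x)
}

#' Reported global relative efficiencies of the motivating study
#'
#' The across-year (global) relative efficiencies of mean squared error
#' reported by the hybrid wheat study that motivates this package (1888
#' hybrids from 667 female x 18 male crosses, three seasons, traits GY,
#' DTF, DTH), shipped as a plain-text table. Used for arithmetic
#' cross-checks of the study's summary numbers.
#'
#' @return data frame with columns `family`, `trait`, `comparison`
#'   (`plain_vs_C`, `plain_vs_AC`, `C_vs_AC`) and `re`.
#' @export
reported_global_re <- function() {
  path <- system.file("extdata", "reported_global_re_mse.tsv",
                      package = "hybridcov")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Average percent gain of adding parental covariates, per family
#'
#' Summarises a table of global relative efficiencies into one number
#' per model family: the mean percent gain over the plain-vs-`_C` and
#' plain-vs-`_AC` comparisons across traits, i.e. the average of
#' `(RE - 1) * 100`.
#'
#' @param re_table data frame as returned by [reported_global_re()].
#' @param families families to summarise.
#' @return named numeric vector of average percent gains.
#' @export
family_percent_gain <- function(re_table, families = c("A", "B", "C")) {
  keep <- re_table$comparison %in% c("plain_vs_C", "plain_vs_AC") &
    re_table$family %in% families
  tab <- re_table[keep, ]
  gains <- vapply(split(tab$re, tab$family), function(re)
    mean(vapply(re, function(x) relative_efficiency(x, 1)$percent_gain,
                numeric(1))), numeric(1))
  gains[families]
}
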