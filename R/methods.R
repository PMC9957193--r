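#' @export
print.kernel_fit <- function(x, ...) {
  cat("Bayesian multi-kernel regression fit\n")
  cat(sprintf("  %d records (%d masked), %d random terms\n",
              length(x$y), sum(x$mask), nrow(x$var_comp) - 1L))
  cat(sprintf("  sampler: %d iterations, %d burn-in, thin %d, seed %s\n",
              x$settings$n_iter, x$settings$burn_in, x$settings$thin,
              x$settings$seed))
  cat("  variance components (posterior means):\n")
  vc <- x$var_comp
  cat(paste0("    ", format(vc$term, width = 18),
             formatC(vc$variance, digits = 4, format = "g"),
             collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.hybrid_fit <- function(x, ...) {
  cat("Hybrid prediction model", x$spec$id, "- trait", x$spec$trait, "\n")
  NextMethod()
}

#' @export
summary.kernel_fit <- function(object, ...) {
  vc <- object$var_comp
  gen <- vc$variance[vc$term != "residual" & vc$term != "env"]
  out <- list(
    var_comp = vc,
    beta = object$beta,
    n_records = length(object$y),
    n_masked = sum(object$mask),
    prop_residual = vc$variance[vc$term == "residual"] / sum(vc$variance),
    settings = object$settings)
  class(out) <- "summary.kernel_fit"
  out
}

#' @export
print.summary.kernel_fit <- function(x, ...) {
  cat("Multi-kernel mixed model summary\n")
  cat(sprintf("records: %d (masked: %d)\n", x$n_records, x$n_masked))
  cat("\nFixed effects (posterior means):\n")
  print(round(x$beta, 4))
  cat("\nVariance components:\n")
  print(transform(x$var_comp, variance = signif(variance, 4),
                  mc_se = signif(mc_se, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
coef.kernel_fit <- function(object, ...) object$beta

#' @export
fitted.kernel_fit <- function(object, ...) object$fitted

#' @export
residuals.kernel_fit <- function(object, ...) {
  r <- object$y - object$fitted
  r[object$mask] <- NA_real_
  r
}

#' Predictions from a fitted multi-kernel model
#'
#' @param object a `kernel_fit` / `hybrid_fit`.
#' @param which `"masked"` (default) returns the posterior-mean
#'   predictions of the held-out records; `"all"` returns fitted values
#'   for every record.
#' @param ... unused.
#' @export
predict.kernel_fit <- function(object, which = c("masked", "all"), ...) {
  which <- match.arg(which)
  if (which == "all") return(object$fitted)
  if (inherits(object, "hybrid_fit")) return(object$prediction_table)
  object$predictions
}

#' @export
plot.kernel_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4.5, 4.5, 2, 1))
  on.exit(graphics::par(op))
  ok <- !x$mask
  graphics::plot(x$fitted[ok], x$y[ok], xlab = "fitted", ylab = "observed",
                 main = "observed vs fitted", ...)
  graphics::abline(0, 1, lty = 2)
  vc <- x$var_comp
  graphics::barplot(vc$variance, names.arg = vc$term, las = 2,
                    ylab = "posterior mean variance",
                    main = "variance components")
  invisible(x)
}

#' Closed-form BLUP with known variance components
#'
#' Independent of the Gibbs sampler, solves the mixed model in closed
#' form for fixed variance components: generalized least squares for the
#' fixed effects on the training records, then
#' `yhat = X bhat + C[, train] solve(V[train, train], y - X bhat)` with
#' `V = sum_k s2_k K_k + s2_e I` and `C = sum_k s2_k K_k`. A relative
#' jitter of 1e-8 is added to the diagonal of `V` against singularity.
#' Used as the testing oracle for the sampler and as a fast
#' kernel-extrapolation predictor.
#'
#' @param y response (training values used; masked entries ignored).
#' @param kernels named list of record-level kernels over all records.
#' @param var_comp named numeric vector of variance components matching
#'   `names(kernels)` plus `"residual"`; all positive (zeros allowed for
#'   kernel terms).
#' @param X fixed design over all records (default intercept).
#' @param train logical vector of training records (default: all).
#' @return list with `prediction` (length n), `beta`, and `blups` (per
#'   term, over all records).
#' @export
blup_oracle <- function(y, kernels, var_comp, X = NULL, train = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  X <- as.matrix(X)
  if (is.null(train)) train <- rep(TRUE, n)
  stopifnot(length(train) == n, sum(train) >= ncol(X))
  need <- c(names(kernels), "residual")
  if (!all(need %in% names(var_comp)))
    stop("var_comp must name every kernel and 'residual'", call. = FALSE)
  s2e <- var_comp[["residual"]]
  stopifnot(s2e > 0)

  C <- matrix(0, n, n)
  for (k in names(kernels)) C <- C + var_comp[[k]] * kernels[[k]]
  V <- C + diag(s2e, n)
  diag(V) <- diag(V) * (1 + 1e-8)

  tr <- which(train)
  Vtt <- V[tr, tr, drop = FALSE]
  Xt <- X[tr, , drop = FALSE]
  yt <- y[tr]
  Vi <- chol2inv(chol(Vtt))
  XtVi <- crossprod(Xt, Vi)
  beta <- solve(XtVi %*% Xt + diag(1e-10, ncol(Xt)), XtVi %*% yt)
  resid <- yt - Xt %*% beta
  alpha <- Vi %*% resid
  pred <- as.numeric(X %*% beta + C[, tr, drop = FALSE] %*% alpha)

  blups <- lapply(names(kernels), function(k)
    as.numeric(var_comp[[k]] * kernels[[k]][, tr, drop = FALSE] %*% alpha))
  names(blups) <- names(kernels)
  list(prediction = pred, beta = as.numeric(beta), blups = blups)
}
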