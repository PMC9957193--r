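#' Quality control for a parental SNP dosage matrix
#'
#' Applies the three-step marker filter used before building genomic
#' relationship matrices: (1) drop markers whose missing fraction is at
#' or above `max_missing`; (2) mean-impute the remaining missing cells
#' with the column mean of observed dosages; (3) drop markers whose
#' post-imputation minor allele frequency is below `min_maf`. The steps
#' are applied in exactly that order and the set of lines (rows) is never
#' changed.
#'
#' MAF is computed from the post-imputation column mean as
#' `min(q, 1 - q)` with `q = mean(dosage) / 2`. Because mean imputation
#' leaves the column mean unchanged, computing MAF before or after
#' imputation is equivalent; the post-imputation convention is used.
#'
#' @param dosages numeric matrix, lines x markers, values in `[0, 2]` or
#'   `NA`; rows and columns must be named.
#' @param max_missing markers with missing fraction `>= max_missing` are
#'   dropped (strict keep-below rule); must lie in (0, 1).
#' @param min_maf minimum minor allele frequency kept; in `[0, 0.5)`.
#' @return the filtered, fully imputed dosage matrix with a `"qc_summary"`
#'   attribute (markers in, dropped per step, cells imputed, markers out).
#' @examples
#' X <- cbind(m1 = c(0, 2, 1, 1), m2 = c(NA, NA, 1, 1), m3 = c(2, 2, 2, 0))
#' rownames(X) <- paste0("L", 1:4)
#' marker_qc(X, max_missing = 0.15, min_maf = 0.05)
#' @export
marker_qc <- function(dosages, max_missing = 0.15, min_maf = 0.05) {
  if (length(dosages) == 0L || NROW(dosages) == 0L || NCOL(dosages) == 0L)
    stop("no markers", call. = FALSE)
  dosages <- as_dosage_matrix(dosages)
  stopifnot(max_missing > 0, max_missing < 1, min_maf >= 0, min_maf < 0.5)
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosage values must lie in [0, 2]", call. = FALSE)

  n_in <- ncol(dosages)

  # step 1: missingness filter
  miss_frac <- colMeans(is.na(dosages))
  keep1 <- miss_frac < max_missing
  X <- dosages[, keep1, drop = FALSE]
  n_drop_missing <- sum(!keep1)

  # step 2: mean imputation of surviving columns
  n_imputed <- sum(is.na(X))
  if (n_imputed > 0) {
    cm <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- cm[idx[, 2]]
  }

  # step 3: MAF filter on post-imputation column means
  q <- colMeans(X) / 2
  maf <- pmin(q, 1 - q)
  keep3 <- maf >= min_maf
  X <- X[, keep3, drop = FALSE]
  n_drop_maf <- sum(!keep3)

  if (ncol(X) == 0L)
    stop("no markers survive QC", call. = FALSE)

  attr(X, "qc_summary") <- list(
    n_in = n_in,
    n_dropped_missing = n_drop_missing,
    n_cells_imputed = n_imputed,
    n_dropped_maf = n_drop_maf,
    n_out = ncol(X),
    max_missing = max_missing,
    min_maf = min_maf
  )
  X
}

# coerce and validate a dosage matrix with unique row/column names
as_dosage_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x))) rownames(x) <- paste0("line", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("mk", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate line ids", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate marker ids", call. = FALSE)
  x
}
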