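#' Genomic relationship matrix from marker dosages
#'
#' Computes the VanRaden-style GRM `G = W W' / p`, where `W` is the
#' dosage matrix with each column centered by its mean and divided by its
#' standard deviation, and `p` is the number of markers. With the default
#' population (denominator-n) standard deviation the mean of the diagonal
#' of `G` equals 1 exactly.
#'
#' @param dosages complete (no missing values) numeric matrix of dosages,
#'   lines x markers; run [marker_qc()] first.
#' @param sd_type `"population"` (default, denominator n) or `"sample"`
#'   (denominator n - 1) column standard deviation.
#' @return symmetric positive semi-definite lines x lines matrix.
#' @examples
#' X <- cbind(m1 = c(0, 2, 1), m2 = c(2, 0, 1))
#' rownames(X) <- c("L1", "L2", "L3")
#' grm(X)
#' @export
grm <- function(dosages, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  X <- as_dosage_matrix(dosages)
  if (anyNA(X))
    stop("dosage matrix contains missing values; run marker_qc() first",
         call. = FALSE)
  n <- nrow(X)
  p <- ncol(X)
  mu <- colMeans(X)
  v <- colMeans(X^2) - mu^2                 # population variance
  if (sd_type == "sample") v <- v * n / (n - 1)
  mono <- v <= .Machine$double.eps * 4
  if (any(mono))
    stop("monomorphic markers present: ",
         paste(colnames(X)[mono], collapse = ", "), call. = FALSE)
  W <- sweep(sweep(X, 2L, mu, "-"), 2L, sqrt(v), "/")
  G <- tcrossprod(W) / p
  dimnames(G) <- list(rownames(X), rownames(X))
  G
}

#' Specific combining ability kernel for observed crosses
#'
#' The covariance among hybrids implied by `H = G_M %x% G_F` (Kronecker
#' product of the male and female relationship matrices), restricted to
#' the crosses actually observed: `H[i, j] =
#' G_M[male_i, male_j] * G_F[female_i, female_j]`. The full Kronecker
#' product is never materialised.
#'
#' @param pedigree data frame with columns `hybrid`, `male`, `female`.
#' @param G_M,G_F named relationship matrices over the male and female
#'   parent lines (genomic or identity).
#' @return hybrids x hybrids symmetric PSD matrix, rows/cols named by
#'   `pedigree$hybrid`.
#' @export
sca_kernel <- function(pedigree, G_M, G_F) {
  pedigree <- as_pedigree(pedigree)
  bad_m <- setdiff(pedigree$male, rownames(G_M))
  bad_f <- setdiff(pedigree$female, rownames(G_F))
  if (length(bad_m) || length(bad_f))
    stop("parents missing from relationship matrices: ",
         paste(c(bad_m, bad_f), collapse = ", "), call. = FALSE)
  H <- G_M[pedigree$male, pedigree$male, drop = FALSE] *
    G_F[pedigree$female, pedigree$female, drop = FALSE]
  dimnames(H) <- list(pedigree$hybrid, pedigree$hybrid)
  H
}

#' Expand an entity-level kernel to observation records
#'
#' Returns `Z K Z'` for the 0/1 incidence of records on entities, i.e.
#' the records x records matrix with entry `(r, s) = K[entity_r, entity_s]`.
#'
#' @param K named square kernel over entities.
#' @param entities character vector, one entity id per record; all must
#'   appear in `rownames(K)`.
#' @param record_ids optional record names for the result.
#' @export
expand_kernel <- function(K, entities, record_ids = NULL) {
  entities <- as.character(entities)
  bad <- setdiff(entities, rownames(K))
  if (length(bad))
    stop("records map to entities missing from the kernel: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  out <- K[entities, entities, drop = FALSE]
  if (is.null(record_ids)) record_ids <- seq_along(entities)
  dimnames(out) <- list(record_ids, record_ids)
  out
}

#' Hadamard genotype-by-environment interaction kernel
#'
#' Entrywise product of a record-level main-effect kernel and a
#' record-level environment-block kernel; entries linking records in
#' different environments are zero, and the result is PSD by the Schur
#' product theorem.
#'
#' @param main_expanded,env_expanded records x records matrices over the
#'   identical ordered record set.
#' @export
interaction_kernel <- function(main_expanded, env_expanded) {
  if (!identical(dim(main_expanded), dim(env_expanded)))
    stop("kernel dimensions differ", call. = FALSE)
  if (!identical(dimnames(main_expanded), dimnames(env_expanded)))
    stop("kernel record labels differ", call. = FALSE)
  main_expanded * env_expanded
}

#' Environment block kernel `Z_E Z_E'` over records
#'
#' @param env vector of environment labels, one per record.
#' @param record_ids optional record names.
#' @export
env_block_kernel <- function(env, record_ids = NULL) {
  env <- as.character(env)
  out <- outer(env, env, "==") * 1
  if (is.null(record_ids)) record_ids <- seq_along(env)
  dimnames(out) <- list(record_ids, record_ids)
  out
}

#' Identity kernel over a set of entities
#'
#' Used by the non-genomic model types, which replace every genomic
#' relationship matrix by the identity.
#'
#' @param ids entity identifiers.
#' @export
identity_kernel <- function(ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate entity ids", call. = FALSE)
  diag(length(ids)) |> `dimnames<-`(list(ids, ids))
}

# symmetry / PSD validity check used by tests and assemble_terms
check_kernel <- function(K, tol_sym = 1e-10, tol_psd = 1e-8) {
  if (nrow(K) != ncol(K)) return("not square")
  if (max(abs(K - t(K))) > tol_sym * max(1, max(abs(K)))) return("not symmetric")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol_psd * max(abs(ev), 1)) return("not PSD")
  TRUE
}

as_pedigree <- function(x) {
  x <- as.data.frame(x)
  need <- c("hybrid", "male", "female")
  if (!all(need %in% names(x)))
    stop("pedigree needs columns hybrid, male, female", call. = FALSE)
  x[need] <- lapply(x[need], as.character)
  if (anyDuplicated(x$hybrid)) stop("duplicate hybrid ids in pedigree",
                                    call. = FALSE)
  x
}
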