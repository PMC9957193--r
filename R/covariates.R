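#' Mid-parent phenotypic covariates for hybrids
#'
#' Builds the fixed-effect covariate matrix that injects parental
#' phenotypic information into a hybrid prediction model. For each trait
#' two columns are produced: an additive column, the mid-parent value
#' `(P_M + P_F) / 2`, and a dominance column capturing the parental
#' divergence, `|P_M - P_F| / 2` under the default `half_abs_diff` rule
#' (the literal `|P_M + P_F| / 2` is available as `half_abs_sum`).
#' Mode `"C"` emits the two columns of the target trait only; mode
#' `"AC"` emits two columns for every configured trait (so `2 * T`
#' columns for `T` traits, the target trait first). Columns are centered
#' (not scaled) so the intercept absorbs their mean.
#'
#' @param pedigree data frame with columns `hybrid`, `male`, `female`.
#' @param parental_phenotypes data frame with columns `parent`, `trait`,
#'   `value` (at most one value per parent/trait pair).
#' @param target_trait the trait being predicted.
#' @param mode `"C"` (same trait only) or `"AC"` (same trait plus
#'   correlated traits).
#' @param traits trait set used in mode `"AC"`; defaults to all traits in
#'   `parental_phenotypes`, target first.
#' @param dominance dominance-column rule, see Details.
#' @param center center columns? (default TRUE).
#' @return hybrids x covariates numeric matrix; column names are
#'   `<trait>_add` / `<trait>_dom`.
#' @export
build_covariates <- function(pedigree, parental_phenotypes, target_trait,
                             mode = c("C", "AC"), traits = NULL,
                             dominance = c("half_abs_diff", "half_abs_sum"),
                             center = TRUE) {
  mode <- match.arg(mode)
  dominance <- match.arg(dominance)
  pedigree <- as_pedigree(pedigree)
  pp <- as.data.frame(parental_phenotypes)
  if (!all(c("parent", "trait", "value") %in% names(pp)))
    stop("parental phenotypes need columns parent, trait, value",
         call. = FALSE)
  if (anyDuplicated(pp[c("parent", "trait")]))
    stop("duplicate (parent, trait) phenotype entries", call. = FALSE)

  if (mode == "C") {
    traits <- target_trait
  } else {
    if (is.null(traits)) traits <- unique(pp$trait)
    if (!target_trait %in% traits)
      stop("target trait absent from trait list", call. = FALSE)
    traits <- c(target_trait, setdiff(traits, target_trait))
  }

  # parent x trait lookup
  P <- matrix(NA_real_, nrow = length(unique(pp$parent)), ncol = length(traits),
              dimnames = list(unique(pp$parent), traits))
  keep <- pp$trait %in% traits
  P[cbind(match(pp$parent[keep], rownames(P)),
          match(pp$trait[keep], traits))] <- pp$value[keep]

  need_m <- match(pedigree$male, rownames(P))
  need_f <- match(pedigree$female, rownames(P))
  miss <- character(0)
  for (t in traits) {
    bad_m <- is.na(need_m) | is.na(P[ifelse(is.na(need_m), 1, need_m), t])
    bad_f <- is.na(need_f) | is.na(P[ifelse(is.na(need_f), 1, need_f), t])
    if (any(bad_m))
      miss <- c(miss, paste0("(", pedigree$hybrid[bad_m], ", ",
                             pedigree$male[bad_m], ", ", t, ")"))
    if (any(bad_f))
      miss <- c(miss, paste0("(", pedigree$hybrid[bad_f], ", ",
                             pedigree$female[bad_f], ", ", t, ")"))
  }
  if (length(miss))
    stop("missing parental phenotypes for: ",
         paste(utils::head(miss, 10), collapse = "; "),
         if (length(miss) > 10) " ..." else "", call. = FALSE)

  cols <- list()
  for (t in traits) {
    PM <- P[need_m, t]
    PF <- P[need_f, t]
    cols[[paste0(t, "_add")]] <- (PM + PF) / 2
    cols[[paste0(t, "_dom")]] <-
      if (dominance == "half_abs_diff") abs(PM - PF) / 2 else abs(PM + PF) / 2
  }
  X <- do.call(cbind, cols)
  rownames(X) <- pedigree$hybrid
  if (center) X <- sweep(X, 2L, colMeans(X), "-")
  attr(X, "mode") <- mode
  attr(X, "dominance") <- dominance
  X
}
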