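#' Read and write SNP dosage matrices as TSV
#'
#' The dosage format is a tab-separated table whose first row holds
#' marker ids, first column holds line ids, and cells hold dosages in
#' `[0, 2]` (fractional allowed after imputation). Missing cells are the
#' literal `NA` or an empty field. `write_dosage_tsv()` followed by
#' `read_dosage_tsv()` is an identity for any valid matrix.
#'
#' @param path file path.
#' @return `read_dosage_tsv()` returns a lines x markers numeric matrix.
#' @export
read_dosage_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), colClasses = "character")
  if (ncol(tab) < 2L) stop("dosage file needs line ids plus markers",
                           call. = FALSE)
  ids <- tab[[1]]
  if (anyDuplicated(ids)) stop("duplicate line ids", call. = FALSE)
  mk <- colnames(tab)[-1]
  if (anyDuplicated(mk)) stop("duplicate marker ids in header",
                              call. = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- !is.na(vals) & is.na(num)
  if (any(bad))
    stop("non-numeric dosage cell(s), e.g. '", vals[which(bad)[1]], "'",
         call. = FALSE)
  dimnames(num) <- list(ids, mk)
  num
}

#' @param markers lines x markers numeric matrix with dimnames.
#' @rdname read_dosage_tsv
#' @export
write_dosage_tsv <- function(markers, path) {
  markers <- as_dosage_matrix(markers)
  df <- data.frame(line = rownames(markers), markers, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read and write relationship kernels as TSV
#'
#' Square tables with entity ids as both header row and first column.
#'
#' @param path file path.
#' @export
read_kernel_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  K <- as.matrix(tab)
  if (nrow(K) != ncol(K) || !identical(rownames(K), colnames(K)))
    stop("kernel file is not a labelled square matrix", call. = FALSE)
  K
}

#' @param K labelled square matrix.
#' @rdname read_kernel_tsv
#' @export
write_kernel_tsv <- function(K, path) {
  df <- data.frame(id = rownames(K), K, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read long-format phenotypes (hybrids and parents)
#'
#' Expects a CSV with columns `entity_id`, `entity_role` (`hybrid` or
#' `parent`), `environment` (empty for parents), `trait`, `value`.
#' Hybrid records become the phenotype table consumed by the models,
#' parent records the parental phenotype table behind the mid-parent
#' covariates.
#'
#' @param path file path.
#' @param pedigree optional pedigree to validate hybrid ids against.
#' @return list with elements `phenotypes` (`hybrid`, `env`, `trait`,
#'   `value`) and `parental_phenotypes` (`parent`, `trait`, `value`).
#' @export
read_phenotypes <- function(path, pedigree = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  need <- c("entity_id", "entity_role", "environment", "trait", "value")
  if (!all(need %in% names(tab)))
    stop("phenotype file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad_role <- setdiff(unique(tab$entity_role), c("hybrid", "parent"))
  if (length(bad_role))
    stop("unknown entity role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  key <- paste(tab$entity_id, tab$environment, tab$trait, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate phenotype record(s): ", key[duplicated(key)][1],
         call. = FALSE)
  hy <- tab[tab$entity_role == "hybrid", ]
  pa <- tab[tab$entity_role == "parent", ]
  if (any(!is.na(pa$environment)))
    stop("parental records must have an empty environment field",
         call. = FALSE)
  if (any(is.na(hy$environment)))
    stop("hybrid records need an environment", call. = FALSE)
  if (!is.null(pedigree)) {
    ped <- as_pedigree(pedigree)
    bad <- setdiff(hy$entity_id, ped$hybrid)
    if (length(bad))
      stop("hybrid records not in pedigree: ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  list(
    phenotypes = data.frame(hybrid = hy$entity_id, env = hy$environment,
                            trait = hy$trait, value = hy$value,
                            stringsAsFactors = FALSE),
    parental_phenotypes = data.frame(parent = pa$entity_id, trait = pa$trait,
                                     value = pa$value,
                                     stringsAsFactors = FALSE))
}

#' Write hybrid and parental phenotypes to the long-format CSV
#'
#' @param phenotypes hybrid records (`hybrid`, `env`, `trait`, `value`).
#' @param parental_phenotypes parent records (`parent`, `trait`, `value`).
#' @param path file path.
#' @export
write_phenotypes <- function(phenotypes, parental_phenotypes, path) {
  hy <- data.frame(entity_id = phenotypes$hybrid, entity_role = "hybrid",
                   environment = phenotypes$env, trait = phenotypes$trait,
                   value = phenotypes$value)
  pa <- data.frame(entity_id = parental_phenotypes$parent,
                   entity_role = "parent", environment = NA,
                   trait = parental_phenotypes$trait,
                   value = parental_phenotypes$value)
  utils::write.csv(rbind(hy, pa), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a hybrid pedigree CSV
#'
#' Columns `hybrid`, `male`, `female`; one row per hybrid.
#' @param path file path.
#' @export
read_pedigree <- function(path) {
  as_pedigree(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @param pedigree pedigree data frame.
#' @rdname read_pedigree
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.csv(as_pedigree(pedigree), path, row.names = FALSE)
  invisible(path)
}

#' Import SNP dosages from a VCF file
#'
#' Reads the GT field of a VCF 4.x file (via the vcfR package) and
#' returns ALT-allele dosages: `0/0 -> 0`, `0/1 -> 1`, `1|1 -> 2`,
#' `./. -> NA`. Multiallelic records are skipped with a warning carrying
#' their count.
#'
#' @param path path to a (possibly gzipped) VCF file.
#' @return samples x markers dosage matrix; marker ids are the VCF `ID`
#'   field when present, otherwise `CHROM:POS`. The number of skipped
#'   multiallelic records is attached as attribute `"n_multiallelic"`.
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(colnames(v@gt)) || colnames(v@gt)[1] != "FORMAT" ||
      !any(grepl("GT", v@gt[, 1])))
    stop("VCF has no GT format field", call. = FALSE)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi > 0)
    warning(n_multi, " multiallelic record(s) skipped", call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al == "1")
  })
  out <- t(dos)  # samples x markers
  colnames(out) <- ids
  attr(out, "n_multiallelic") <- n_multi
  out
}
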