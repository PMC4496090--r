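#' Construct a genotype matrix of risk-allele counts
#'
#' The central genotype container: a numeric matrix with one row per
#' individual and one column per SNP, each non-missing cell holding the
#' number of risk alleles (0, 1 or 2; non-integer values appear only after
#' mean-count imputation). Missing genotypes are `NA`.
#'
#' @param counts Numeric matrix, individuals x SNPs.
#' @param individuals Character vector of individual identifiers
#'   (defaults to rownames).
#' @param snps Character vector of SNP identifiers (defaults to colnames).
#' @param imputed Logical; set by [impute_missing_mean()].
#' @return A `geno_matrix` object.
#' @export
geno_matrix <- function(counts, individuals = rownames(counts),
                        snps = colnames(counts), imputed = FALSE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(nrow(counts)))
  if (is.null(snps)) stop("SNP identifiers are required", call. = FALSE)
  if (length(individuals) != nrow(counts) || length(snps) != ncol(counts)) {
    stop("identifier lists do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(individuals)) {
    stop("duplicate individual identifiers", call. = FALSE)
  }
  if (anyDuplicated(snps)) stop("duplicate SNP identifiers", call. = FALSE)
  vals <- counts[!is.na(counts)]
  if (!imputed && length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop("non-missing genotype counts must be 0, 1 or 2", call. = FALSE)
  }
  if (imputed && length(vals) && (any(vals < 0) || any(vals > 2))) {
    stop("imputed genotype values must lie in [0, 2]", call. = FALSE)
  }
  dimnames(counts) <- list(individuals, snps)
  structure(counts, class = c("geno_matrix", "matrix"), imputed = imputed)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d SNPs (%d missing cells%s)\n",
              nrow(x), ncol(x), sum(is.na(x)),
              if (isTRUE(attr(x, "imputed"))) ", imputed" else ""))
  invisible(x)
}

# subsetting keeps class and the imputed flag; drops to plain matrix if
# dimensions are dropped
#' @export
`[.geno_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    out <- structure(out, class = c("geno_matrix", "matrix"),
                     imputed = attr(x, "imputed"))
  }
  out
}

#' Read genotypes from an allele-count CSV
#'
#' Expects rows = individuals (first column the identifier), columns =
#' SNPs, cells in \{0, 1, 2\} or empty/`NA` for missing. Counts are assumed
#' to already be risk-allele counts oriented to the supplied panel; columns
#' absent from the panel raise an error so silent panel/genotype drift is
#' caught at ingestion.
#'
#' @param path CSV file path.
#' @param panel A `snp_panel`; column order of the result follows the panel.
#' @return A `geno_matrix`.
#' @export
read_genotypes_csv <- function(path, panel) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "double"
  unknown <- setdiff(colnames(counts), panel$snp_id)
  if (length(unknown)) {
    stop("genotype columns not in panel: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- intersect(panel$snp_id, colnames(counts))
  geno_matrix(counts[, keep, drop = FALSE], individuals = ids, snps = keep)
}

#' Read genotypes from a PLINK .raw-style dosage file
#'
#' Whitespace-separated file with the usual `FID IID PAT MAT SEX PHENOTYPE`
#' leading columns followed by one `<snp_id>_<counted_allele>` column per
#' SNP holding additive dosages. Dosages counted on the panel's risk allele
#' are taken as-is; dosages counted on the other allele are flipped
#' (2 - x). A counted allele matching neither panel allele, or any
#' orientation question on a strand-ambiguous (A/T, C/G) SNP, is a hard
#' error: guessing strand on ambiguous SNPs corrupts a risk score silently.
#'
#' @param path .raw file path.
#' @param panel A `snp_panel`.
#' @return A `geno_matrix`.
#' @export
read_genotypes_raw <- function(path, panel) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  geno_cols <- setdiff(names(df), meta)
  m <- regmatches(geno_cols, regexpr("_[ACGT]$", geno_cols))
  if (length(m) != length(geno_cols)) {
    stop("every genotype column must be named <snp_id>_<counted_allele>",
         call. = FALSE)
  }
  snp_ids <- sub("_[ACGT]$", "", geno_cols)
  counted <- sub("^_", "", m)
  unknown <- setdiff(snp_ids, panel$snp_id)
  if (length(unknown)) {
    stop("genotype columns not in panel: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(snp_ids, panel$snp_id)
  risk <- panel$risk_allele[idx]
  other <- panel$other_allele[idx]
  ambiguous <- is_ambiguous_pair(risk, other)
  if (any(ambiguous)) {
    stop("strand-ambiguous SNP(s) in dosage file; orientation cannot be ",
         "determined: ", paste(snp_ids[ambiguous], collapse = ", "),
         call. = FALSE)
  }
  counts <- as.matrix(df[, geno_cols, drop = FALSE])
  storage.mode(counts) <- "double"
  flip <- counted == other
  mismatch <- counted != risk & counted != other
  if (any(mismatch)) {
    stop("counted allele matches neither panel allele for: ",
         paste(snp_ids[mismatch], collapse = ", "), call. = FALSE)
  }
  counts[, flip] <- 2 - counts[, flip]
  colnames(counts) <- snp_ids
  keep <- intersect(panel$snp_id, snp_ids)
  geno_matrix(counts[, keep, drop = FALSE],
              individuals = as.character(df$IID), snps = keep)
}

#' Read genotypes from a VCF (optional)
#'
#' Requires the `vcfR` package. GT fields are converted to alternate-allele
#' counts and oriented so that cells count the panel's risk allele, using
#' the VCF REF/ALT pair; strand-ambiguous SNPs are a hard error as in
#' [read_genotypes_raw()].
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param panel A `snp_panel`.
#' @return A `geno_matrix`.
#' @export
read_genotypes_vcf <- function(path, panel) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF ingestion requires the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  snp_ids <- fix[, "ID"]
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  keep <- snp_ids %in% panel$snp_id
  if (!any(keep)) stop("no panel SNPs found in VCF", call. = FALSE)
  snp_ids <- snp_ids[keep]; ref <- ref[keep]; alt <- alt[keep]
  gt <- gt[keep, , drop = FALSE]
  idx <- match(snp_ids, panel$snp_id)
  risk <- panel$risk_allele[idx]
  other <- panel$other_allele[idx]
  ambiguous <- is_ambiguous_pair(risk, other)
  if (any(ambiguous)) {
    stop("strand-ambiguous SNP(s) in VCF; orientation cannot be ",
         "determined: ", paste(snp_ids[ambiguous], collapse = ", "),
         call. = FALSE)
  }
  # count ALT alleles from the GT string, then orient to the risk allele
  alt_count <- function(g) {
    ifelse(is.na(g), NA_real_,
           vapply(strsplit(gsub("\\|", "/", g), "/"),
                  function(a) sum(a == "1"), numeric(1)))
  }
  counts <- t(apply(gt, 1, alt_count))
  ok_risk_alt <- risk == alt & other == ref
  ok_risk_ref <- risk == ref & other == alt
  bad <- !(ok_risk_alt | ok_risk_ref)
  if (any(bad)) {
    stop("VCF REF/ALT do not match panel alleles for: ",
         paste(snp_ids[bad], collapse = ", "), call. = FALSE)
  }
  counts[ok_risk_ref, ] <- 2 - counts[ok_risk_ref, , drop = FALSE]
  counts <- t(counts)
  colnames(counts) <- snp_ids
  keep_order <- intersect(panel$snp_id, snp_ids)
  geno_matrix(counts[, keep_order, drop = FALSE],
              individuals = rownames(counts), snps = keep_order)
}

#' Per-SNP call rate
#'
#' The fraction of individuals successfully genotyped at a SNP; low call
#' rates flag assay failure and such SNPs are dropped before scoring.
#'
#' @param matrix A `geno_matrix`.
#' @param snp_id A single SNP identifier present in `matrix`.
#' @return Fraction in \[0, 1\].
#' @export
snp_call_rate <- function(matrix, snp_id) {
  stopifnot(inherits(matrix, "geno_matrix"))
  if (length(snp_id) != 1L || !snp_id %in% colnames(matrix)) {
    stop("unknown snp_id: ", snp_id, call. = FALSE)
  }
  mean(!is.na(matrix[, snp_id]))
}

#' SNP-level quality control by call rate
#'
#' Drops every SNP whose call rate falls below `call_rate_threshold`.
#'
#' @param matrix A `geno_matrix`.
#' @param call_rate_threshold Minimum acceptable call rate, in (0, 1\];
#'   default 0.95.
#' @return A list with `matrix` (the retained SNPs) and `report` (a
#'   `qc_report`, see [qc_report()]).
#' @export
apply_snp_qc <- function(matrix, call_rate_threshold = 0.95) {
  stopifnot(inherits(matrix, "geno_matrix"))
  if (call_rate_threshold <= 0 || call_rate_threshold > 1) {
    stop("call_rate_threshold must be in (0, 1]", call. = FALSE)
  }
  rates <- colMeans(!is.na(unclass(matrix)))
  drop <- rates < call_rate_threshold
  if (all(drop)) {
    stop("all SNPs fall below the call-rate threshold; empty panel",
         call. = FALSE)
  }
  kept <- matrix[, !drop, drop = FALSE]
  rep <- qc_report(
    excluded_snps = data.frame(snp_id = colnames(matrix)[drop],
                               call_rate = unname(rates[drop]),
                               stringsAsFactors = FALSE),
    snp_call_rates = data.frame(snp_id = colnames(matrix),
                                call_rate = unname(rates),
                                stringsAsFactors = FALSE),
    call_rate_threshold = call_rate_threshold
  )
  list(matrix = kept, report = rep)
}

#' Individual-level quality control by genotyping failures
#'
#' Removes individuals whose genotyping failed at `max_failed` or more
#' SNPs; survivors all have fewer missing genotypes than the threshold.
#'
#' @param matrix A `geno_matrix` (typically after [apply_snp_qc()]).
#' @param max_failed Exclusion threshold on the per-individual count of
#'   missing genotypes (excluded when missing >= `max_failed`); default 3.
#' @return A list with `matrix` and `report`.
#' @export
apply_individual_qc <- function(matrix, max_failed = 3) {
  stopifnot(inherits(matrix, "geno_matrix"), max_failed >= 1)
  n_missing <- rowSums(is.na(unclass(matrix)))
  drop <- n_missing >= max_failed
  kept <- matrix[!drop, , drop = FALSE]
  if (nrow(kept) == 0L) {
    warning("individual QC removed every individual", call. = FALSE)
  }
  rep <- qc_report(
    excluded_individuals = data.frame(
      individual = rownames(matrix)[drop],
      n_missing = unname(n_missing[drop]),
      stringsAsFactors = FALSE),
    max_failed = max_failed
  )
  list(matrix = kept, report = rep)
}

#' Mean-count imputation of sporadic missing genotypes
#'
#' Each missing cell for a SNP is replaced by the mean observed risk-allele
#' count of that SNP across the (post individual-QC) analysis set, so that
#' an individual with a sporadic failure still contributes a score. Imputed
#' values are non-integer in general; observed cells are never altered.
#'
#' @param matrix A `geno_matrix` after individual QC.
#' @return A `geno_matrix` with no missing cells and `imputed = TRUE`.
#' @export
impute_missing_mean <- function(matrix) {
  stopifnot(inherits(matrix, "geno_matrix"))
  counts <- unclass(matrix)
  attr(counts, "imputed") <- NULL
  n_obs <- colSums(!is.na(counts))
  if (any(n_obs == 0L)) {
    stop("cannot impute SNP(s) with zero observed calls: ",
         paste(colnames(counts)[n_obs == 0L], collapse = ", "),
         call. = FALSE)
  }
  means <- colMeans(counts, na.rm = TRUE)
  for (j in which(colSums(is.na(counts)) > 0L)) {
    counts[is.na(counts[, j]), j] <- means[j]
  }
  geno_matrix(counts, imputed = TRUE)
}

#' Compute the genetic predisposition score
#'
#' The unweighted score is the per-individual sum of risk-allele counts
#' over the panel; an optional per-SNP weight vector gives a weighted sum
#' (weights default to 1). The matrix must be fully imputed first so every
#' individual is scored over the same SNPs.
#'
#' @param matrix A `geno_matrix` with no missing cells.
#' @param weights Optional named numeric vector of per-SNP weights; names
#'   must cover the matrix SNPs. Default all 1 (plain allele count).
#' @return A data frame with columns `individual`, `gps`, `n_snps_used`.
#' @export
compute_gps <- function(matrix, weights = NULL) {
  stopifnot(inherits(matrix, "geno_matrix"))
  counts <- unclass(matrix)
  if (anyNA(counts)) {
    stop("genotype matrix still has missing cells; run impute_missing_mean()",
         call. = FALSE)
  }
  if (is.null(weights)) {
    w <- rep(1, ncol(counts))
  } else {
    if (is.null(names(weights)) || !all(colnames(counts) %in% names(weights))) {
      stop("weights must be named and cover every SNP", call. = FALSE)
    }
    w <- unname(weights[colnames(counts)])
  }
  data.frame(individual = rownames(counts),
             gps = as.numeric(counts %*% w),
             n_snps_used = ncol(counts),
             stringsAsFactors = FALSE)
}
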