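#' Read a SNP panel definition
#'
#' A panel file lists the variants that make up a genetic predisposition
#' score: one row per SNP with its identifier, locus (gene label), the risk
#' allele (the allele associated with higher disease incidence or higher
#' fasting glucose in discovery GWAS), the other allele, and the source
#' trait the association was reported for. An optional `proxy_r2` column
#' records the linkage-disequilibrium r-squared between a proxy SNP and the
#' lead SNP it stands in for, and an optional `weight` column allows
#' weighted scores (defaults to 1, i.e. a plain allele count).
#'
#' @param path Path to a comma- or tab-separated file with header columns
#'   `snp_id`, `locus`, `risk_allele`, `other_allele`, `source_trait` and
#'   optionally `proxy_r2`, `weight`.
#' @return A `snp_panel` data frame, validated by [validate_snp_panel()].
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("snp_id,locus,risk_allele,other_allele,source_trait",
#'              "rs7903146,TCF7L2,T,C,T2DM"), f)
#' read_snp_panel(f)
read_snp_panel <- function(path) {
  if (!file.exists(path)) {
    stop("panel file not found: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  validate_snp_panel(df)
}

#' Validate a SNP panel definition
#'
#' Checks the structural invariants of a panel: unique SNP identifiers,
#' risk allele distinct from the other allele, valid source traits, and
#' proxy r-squared above 0.9 where present (a proxy in weaker LD would not
#' faithfully tag the lead signal).
#'
#' @param panel A data frame with the columns described in
#'   [read_snp_panel()].
#' @return The panel with class `snp_panel`, a `weight` column (default 1),
#'   and alleles upper-cased.
#' @export
validate_snp_panel <- function(panel) {
  required <- c("snp_id", "locus", "risk_allele", "other_allele",
                "source_trait")
  missing <- setdiff(required, names(panel))
  if (length(missing)) {
    stop("panel is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  panel$snp_id <- as.character(panel$snp_id)
  if (anyDuplicated(panel$snp_id)) {
    stop("duplicate snp_id in panel: ",
         paste(unique(panel$snp_id[duplicated(panel$snp_id)]),
               collapse = ", "), call. = FALSE)
  }
  panel$risk_allele <- toupper(panel$risk_allele)
  panel$other_allele <- toupper(panel$other_allele)
  same <- panel$risk_allele == panel$other_allele
  if (any(same)) {
    stop("risk_allele equals other_allele for: ",
         paste(panel$snp_id[same], collapse = ", "), call. = FALSE)
  }
  ok_trait <- panel$source_trait %in% c("T2DM", "fasting_glucose")
  if (!all(ok_trait)) {
    stop("source_trait must be 'T2DM' or 'fasting_glucose'; offending SNPs: ",
         paste(panel$snp_id[!ok_trait], collapse = ", "), call. = FALSE)
  }
  if ("proxy_r2" %in% names(panel)) {
    bad <- !is.na(panel$proxy_r2) &
      (panel$proxy_r2 <= 0.9 | panel$proxy_r2 > 1)
    if (any(bad)) {
      stop("proxy_r2 must be in (0.9, 1] when present; offending SNPs: ",
           paste(panel$snp_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  if (!"weight" %in% names(panel)) panel$weight <- 1
  if (any(!is.finite(panel$weight))) {
    stop("panel weights must be finite", call. = FALSE)
  }
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' Is an allele pair strand-ambiguous?
#'
#' A/T and C/G SNPs read identically on either DNA strand, so allele counts
#' from an external file cannot be oriented to the panel's risk allele
#' without external frequency information.
#'
#' @param a,b Single-base allele symbols.
#' @return Logical.
#' @keywords internal
is_ambiguous_pair <- function(a, b) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[a]) & comp[a] == b
}
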