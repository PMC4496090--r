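#' Hardy-Weinberg equilibrium likelihood-ratio test
#'
#' Tests the observed genotype counts of a biallelic SNP against the
#' Hardy-Weinberg proportions p^2, 2pq, q^2 evaluated at the
#' maximum-likelihood allele frequency p = (2 n_aa + n_ab) / (2 n). The
#' statistic is the G-statistic 2 * sum O * ln(O / E) over the three
#' genotype classes (zero-count classes contribute 0), referred to a
#' chi-square with 1 degree of freedom. Departures flag genotyping error.
#'
#' A monomorphic SNP (one allele absent) carries no information about
#' equilibrium: the statistic is 0, p-value 1, and `degenerate` is TRUE.
#'
#' @param n_aa,n_ab,n_bb Non-negative genotype counts (homozygous for the
#'   first allele, heterozygous, homozygous for the second).
#' @return A list with `statistic`, `p_value`, `df` (1), `allele_freq`
#'   (MLE frequency of the first allele) and `degenerate`.
#' @export
#' @examples
#' hwe_lrt(25, 50, 25)   # exact HWE proportions: statistic 0
#' hwe_lrt(50, 0, 50)    # total heterozygote deficit: 200 * log(2)
hwe_lrt <- function(n_aa, n_ab, n_bb) {
  counts <- c(n_aa, n_ab, n_bb)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("total genotype count must be positive", call. = FALSE)
  p <- (2 * n_aa + n_ab) / (2 * n)
  degenerate <- p == 0 || p == 1
  if (degenerate) {
    return(list(statistic = 0, p_value = 1, df = 1L,
                allele_freq = p, degenerate = TRUE))
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  terms <- ifelse(counts > 0, counts * log(counts / expected), 0)
  stat <- 2 * sum(terms)
  stat <- max(stat, 0) # guard tiny negative round-off
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, allele_freq = p, degenerate = FALSE)
}

#' Bonferroni-corrected significance cutoff
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_cutoff(0.05, 25) # 0.002
bonferroni_cutoff <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (m < 1 || m != round(m)) {
    stop("m must be a positive integer", call. = FALSE)
  }
  alpha / m
}

#' Linkage disequilibrium r-squared between two SNPs
#'
#' The composite-LD estimator: the squared Pearson correlation between the
#' two allele-count vectors over complete pairs. It requires no haplotype
#' phase, which is unavailable for genotype-count data.
#'
#' @param geno_a,geno_b Numeric allele-count vectors of equal length;
#'   missing values allowed (pairwise-complete analysis).
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(geno_a, geno_b) {
  if (length(geno_a) != length(geno_b)) {
    stop("genotype vectors must have equal length", call. = FALSE)
  }
  ok <- !is.na(geno_a) & !is.na(geno_b)
  if (sum(ok) < 2) stop("fewer than 2 complete pairs", call. = FALSE)
  a <- geno_a[ok]; b <- geno_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("LD undefined: constant genotype vector", call. = FALSE)
  }
  stats::cor(a, b)^2
}

#' Hardy-Weinberg scan over a genotype matrix
#'
#' Runs [hwe_lrt()] per SNP and flags SNPs whose p-value falls below a
#' Bonferroni-corrected cutoff `alpha / m`. Monomorphic SNPs are reported
#' as degenerate, never auto-excluded. The flag is advisory: exclusion is
#' the caller's decision, mirroring panels on which no SNP fails.
#'
#' @param matrix A `geno_matrix`.
#' @param alpha Family-wise level; default 0.05.
#' @param m Number of tests for the correction; defaults to the panel size.
#' @return A data frame with one row per SNP: counts, statistic, p-value,
#'   degenerate flag, the cutoff used, and `flagged`.
#' @export
hwe_scan <- function(matrix, alpha = 0.05, m = ncol(matrix)) {
  stopifnot(inherits(matrix, "geno_matrix"))
  cutoff <- bonferroni_cutoff(alpha, m)
  rows <- lapply(colnames(matrix), function(s) {
    g <- matrix[, s]
    g <- g[!is.na(g)]
    n_aa <- sum(g == 2); n_ab <- sum(g == 1); n_bb <- sum(g == 0)
    h <- hwe_lrt(n_aa, n_ab, n_bb)
    data.frame(snp_id = s, n_aa = n_aa, n_ab = n_ab, n_bb = n_bb,
               statistic = h$statistic, p_value = h$p_value,
               degenerate = h$degenerate, cutoff = cutoff,
               flagged = !h$degenerate & h$p_value < cutoff,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble a genotype QC report
#'
#' Collects the per-stage artefacts of genotype quality control into one
#' printable object; [write_qc_report()] serialises it.
#'
#' @param ... Named report components (data frames or scalars), e.g.
#'   `excluded_snps`, `excluded_individuals`, `hwe_results`, `ld_pairs`.
#' @return A `qc_report` list.
#' @export
qc_report <- function(...) {
  structure(list(...), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.data.frame(v)) {
      cat(sprintf("  %s: %d row(s)\n", nm, nrow(v)))
    } else {
      cat(sprintf("  %s: %s\n", nm, paste(format(v), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Merge QC reports from successive stages
#'
#' @param ... `qc_report` objects.
#' @return A single combined `qc_report`.
#' @export
combine_qc_reports <- function(...) {
  parts <- list(...)
  out <- list()
  for (p in parts) out[names(p)] <- p
  structure(out, class = "qc_report")
}

#' Write a QC report to machine-readable TSV files plus a log
#'
#' Each tabular component becomes `<prefix>_<name>.tsv`; scalars go to a
#' human-readable `<prefix>_log.txt`.
#'
#' @param report A `qc_report`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_qc_report <- function(report, prefix) {
  stopifnot(inherits(report, "qc_report"))
  paths <- character(0)
  log_lines <- character(0)
  for (nm in names(report)) {
    v <- report[[nm]]
    if (is.data.frame(v)) {
      p <- paste0(prefix, "_", nm, ".tsv")
      write_tsv_stable(v, p)
      paths <- c(paths, p)
      log_lines <- c(log_lines, sprintf("%s: %d row(s) -> %s", nm, nrow(v),
                                        basename(p)))
    } else {
      log_lines <- c(log_lines, sprintf("%s: %s", nm,
                                        paste(format(v), collapse = ", ")))
    }
  }
  logp <- paste0(prefix, "_log.txt")
  writeLines(log_lines, logp)
  invisible(c(paths, logp))
}
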