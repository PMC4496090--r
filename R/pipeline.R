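#' Default participant exclusion filters
#'
#' The narrative-order cascade of a two-arm weight-management trial
#' analysis: measured at 12 months, self-reported white-European
#' ancestry (to limit genetic-background heterogeneity), genotype QC
#' pass, and not on glucose-lowering medication. Each entry names a
#' logical column; a leading `!` keeps rows where the column is FALSE.
#'
#' @return Named character vector of filters, applied in order.
#' @export
default_exclusion_filters <- function() {
  c(measured_12m = "measured_12m",
    white_european = "ethnicity_white_european",
    genotype_qc = "geno_qc_pass",
    no_t2dm_medication = "!t2dm_medication")
}

#' Apply an ordered exclusion cascade to a cohort
#'
#' Filters are applied sequentially and the cascade records, per step, the
#' number entering, excluded and retained, so retained + excluded always
#' equals the previous step's retained count.
#'
#' @param cohort Data frame with an `id` column and the flag columns the
#'   filters reference.
#' @param filters Named character vector as in
#'   [default_exclusion_filters()].
#' @param geno_qc_ids Optional character vector of ids passing genotype
#'   QC; when given, a `geno_qc_pass` column is (re)built from it.
#' @return List with `cohort` (retained rows) and `cascade` (an
#'   `exclusion_cascade` data frame).
#' @export
apply_exclusions <- function(cohort, filters = default_exclusion_filters(),
                             geno_qc_ids = NULL) {
  if (!"id" %in% names(cohort)) {
    stop("cohort must have an 'id' column", call. = FALSE)
  }
  if (!is.null(geno_qc_ids)) {
    cohort$geno_qc_pass <- cohort$id %in% geno_qc_ids
  }
  steps <- list()
  for (k in seq_along(filters)) {
    spec <- filters[[k]]
    negate <- startsWith(spec, "!")
    col <- sub("^!", "", spec)
    if (!col %in% names(cohort)) {
      stop("exclusion filter references missing column: ", col,
           call. = FALSE)
    }
    flag <- cohort[[col]]
    if (!is.logical(flag)) {
      stop("exclusion filter column must be logical: ", col, call. = FALSE)
    }
    keep <- if (negate) !flag else flag
    keep[is.na(keep)] <- FALSE
    steps[[k]] <- data.frame(step = k, filter = names(filters)[k],
                             n_before = nrow(cohort),
                             n_excluded = sum(!keep),
                             n_retained = sum(keep),
                             stringsAsFactors = FALSE)
    cohort <- cohort[keep, , drop = FALSE]
  }
  cascade <- if (length(steps)) do.call(rbind, steps) else
    data.frame(step = integer(0), filter = character(0),
               n_before = integer(0), n_excluded = integer(0),
               n_retained = integer(0), stringsAsFactors = FALSE)
  class(cascade) <- c("exclusion_cascade", "data.frame")
  list(cohort = cohort, cascade = cascade)
}

#' @export
print.exclusion_cascade <- function(x, ...) {
  cat("Exclusion cascade:\n")
  print.data.frame(x)
  invisible(x)
}

#' Build a trial roster matching printed marginal exclusion counts
#'
#' Constructs a deterministic enrolment roster whose sequential filter
#' counts reproduce a published exclusion cascade: of `n_enrolled`
#' participants, the first `n_measured` are measured at 12 months; of
#' those, `n_ethnic` are white European; of those, `n_geno_fail` fail
#' genotype QC; of the survivors, `n_medication` are on glucose-lowering
#' medication. Defaults reproduce a 772-enrolled cohort that retains 353.
#'
#' @param n_enrolled,n_measured,n_ethnic,n_geno_fail,n_medication
#'   Marginal counts, applied sequentially.
#' @return Data frame with `id` and the four flag columns used by
#'   [default_exclusion_filters()].
#' @export
make_exclusion_roster <- function(n_enrolled = 772, n_measured = 442,
                                  n_ethnic = 402, n_geno_fail = 32,
                                  n_medication = 17) {
  stopifnot(n_measured <= n_enrolled, n_ethnic <= n_measured,
            n_geno_fail <= n_ethnic,
            n_medication <= n_ethnic - n_geno_fail)
  id <- sprintf("p%04d", seq_len(n_enrolled))
  measured <- seq_len(n_enrolled) <= n_measured
  ethnic <- seq_len(n_enrolled) <= n_ethnic   # subset of measured
  geno_pass <- rep(TRUE, n_enrolled)
  geno_pass[seq_len(n_geno_fail)] <- FALSE    # subset of ethnic
  medication <- rep(FALSE, n_enrolled)
  medication[n_geno_fail + seq_len(n_medication)] <- TRUE
  data.frame(id = id, measured_12m = measured,
             ethnicity_white_european = ethnic,
             geno_qc_pass = geno_pass, t2dm_medication = medication,
             stringsAsFactors = FALSE)
}

#' Default end-to-end pipeline configuration
#'
#' @param selection_alpha,edge_alpha Model-selection and edge-display
#'   thresholds.
#' @param call_rate_threshold,max_failed,hwe_alpha Genotype QC settings.
#' @param insulin_conversion,energy_unit Trait-derivation settings.
#' @param interactions Candidate interaction pairs screened for every
#'   response whose right-hand side contains both members; the default
#'   screens the clinically motivated pairs (weight change with diet
#'   change, treatment with weight or diet change, genetic score with
#'   weight change).
#' @return A `pipeline_config` list; the variable ordering is
#'   [default_ordering()].
#' @export
default_pipeline_config <- function(selection_alpha = 0.05,
                                    edge_alpha = 0.10,
                                    call_rate_threshold = 0.95,
                                    max_failed = 3,
                                    hwe_alpha = 0.05,
                                    insulin_conversion = 6,
                                    energy_unit = "kJ",
                                    interactions = list(
                                      c("d_weight", "d_satfat_pct"),
                                      c("arm", "d_weight"),
                                      c("arm", "d_satfat_pct"),
                                      c("gps", "d_weight"))) {
  structure(list(selection_alpha = selection_alpha,
                 edge_alpha = edge_alpha,
                 call_rate_threshold = call_rate_threshold,
                 max_failed = max_failed, hwe_alpha = hwe_alpha,
                 insulin_conversion = insulin_conversion,
                 energy_unit = energy_unit,
                 interactions = interactions,
                 ordering = default_ordering()),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of [default_pipeline_config()];
#' `ordering` may be given as `boxes` (list of lists) plus `categorical`
#' (mapping of variable to reference level); `interactions` as a list of
#' two-element lists. Unspecified keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  scalar_keys <- c("selection_alpha", "edge_alpha", "call_rate_threshold",
                   "max_failed", "hwe_alpha", "insulin_conversion",
                   "energy_unit")
  for (k in intersect(scalar_keys, names(y))) cfg[[k]] <- y[[k]]
  if (!is.null(y$interactions)) {
    cfg$interactions <- lapply(y$interactions, as.character)
  }
  if (!is.null(y$ordering)) {
    cat_ref <- unlist(y$ordering$categorical)
    cfg$ordering <- chain_ordering(
      boxes = lapply(y$ordering$boxes, as.character),
      categorical = cat_ref,
      modelled = y$ordering$modelled,
      center = y$ordering$center)
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis: read the panel, genotype and
#' phenotype files; apply the participant exclusion cascade and genotype
#' QC (call rate, per-individual failures, Hardy-Weinberg scan, LD check
#' for same-locus SNP pairs); impute sporadic missingness and compute the
#' genetic predisposition score; derive HOMA indices, change scores and
#' log-ratio outcomes; fit the chain-graph model; and write all artefacts
#' (per-model coefficient TSVs, DOT and JSON graph, QC report, exclusion
#' cascade, JSON run report) to `outdir`. The run is deterministic:
#' identical inputs give byte-identical outputs.
#'
#' The phenotype CSV must carry `id`, the raw measurement columns used by
#' [derive_changes()], `age`, `sex`, `country`, `arm`, and (optionally)
#' `ethnicity_white_european` and `t2dm_medication` flags plus a
#' `measured_12m` flag; a missing `measured_12m` is computed from
#' completeness of the 12-month measurement columns.
#'
#' @param phenotype_file CSV of per-participant phenotypes.
#' @param genotype_file Allele-count CSV or PLINK-style `.raw` file.
#' @param panel_file SNP panel definition file.
#' @param config A `pipeline_config`.
#' @param outdir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return A `run_report` list: config snapshot, exclusion cascade, QC
#'   report, per-model tables, the `chain_graph`, and per-model
#'   complete-case sizes.
#' @export
run_pipeline <- function(phenotype_file, genotype_file, panel_file,
                         config = default_pipeline_config(),
                         outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  panel <- stage("panel", read_snp_panel(panel_file))
  geno <- stage("genotypes", {
    if (grepl("\\.raw$", genotype_file)) {
      read_genotypes_raw(genotype_file, panel)
    } else {
      read_genotypes_csv(genotype_file, panel)
    }
  })
  pheno <- stage("phenotypes", {
    df <- utils::read.csv(phenotype_file, stringsAsFactors = FALSE)
    if (!"id" %in% names(df)) stop("phenotype file lacks an 'id' column")
    df$id <- as.character(df$id)
    df
  })
  if (!"measured_12m" %in% names(pheno)) {
    m12 <- c("weight_12", "glucose_12", "insulin_12", "hba1c_12")
    pheno$measured_12m <- stats::complete.cases(pheno[, m12, drop = FALSE])
  }
  if (!"ethnicity_white_european" %in% names(pheno)) {
    pheno$ethnicity_white_european <- TRUE
  }
  if (!"t2dm_medication" %in% names(pheno)) pheno$t2dm_medication <- FALSE

  # genotype QC
  qc1 <- stage("snp_qc", apply_snp_qc(geno, config$call_rate_threshold))
  qc2 <- stage("individual_qc",
               apply_individual_qc(qc1$matrix, config$max_failed))
  hwe <- stage("hwe", hwe_scan(qc2$matrix, alpha = config$hwe_alpha,
                               m = ncol(geno)))
  if (any(hwe$flagged)) {
    qc2$matrix <- qc2$matrix[, !colnames(qc2$matrix) %in%
                               hwe$snp_id[hwe$flagged], drop = FALSE]
  }
  # LD among SNPs sharing a locus (e.g. two independent signals in one
  # region are kept only if effectively uncorrelated)
  ld_pairs <- stage("ld", {
    loci <- panel$locus[match(colnames(qc2$matrix), panel$snp_id)]
    dup <- unique(loci[duplicated(loci)])
    rows <- list()
    for (lc in dup) {
      ids <- colnames(qc2$matrix)[loci == lc]
      pr <- utils::combn(ids, 2)
      for (j in seq_len(ncol(pr))) {
        r2 <- tryCatch(ld_r2(qc2$matrix[, pr[1, j]], qc2$matrix[, pr[2, j]]),
                       error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <-
          data.frame(locus = lc, snp_a = pr[1, j], snp_b = pr[2, j],
                     r2 = r2, stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(locus = character(0), snp_a = character(0),
                 snp_b = character(0), r2 = numeric(0),
                 stringsAsFactors = FALSE)
  })
  qc <- combine_qc_reports(qc1$report, qc2$report,
                           qc_report(hwe_results = hwe, ld_pairs = ld_pairs))

  # exclusion cascade, then scoring on the analysed set
  excl <- stage("exclusions",
                apply_exclusions(pheno,
                                 geno_qc_ids = rownames(qc2$matrix)))
  analysed_ids <- intersect(excl$cohort$id, rownames(qc2$matrix))
  geno_final <- qc2$matrix[analysed_ids, , drop = FALSE]
  imputed <- stage("imputation", impute_missing_mean(geno_final))
  gps <- stage("gps", compute_gps(imputed))
  cohort <- merge(excl$cohort, gps[, c("individual", "gps")],
                  by.x = "id", by.y = "individual", sort = TRUE)

  derived <- stage("traits",
                   derive_changes(cohort,
                                  insulin_conversion =
                                    config$insulin_conversion,
                                  energy_unit = config$energy_unit))
  graph <- stage("chaingraph",
                 fit_chain_graph(derived, config$ordering,
                                 interactions = config$interactions,
                                 selection_alpha = config$selection_alpha,
                                 edge_alpha = config$edge_alpha))
  model_n <- vapply(graph$fits, `[[`, numeric(1), "n")
  r2 <- vapply(graph$fits, variance_explained, numeric(1))

  report <- structure(list(
    version = as.character(utils::packageVersion("chainreg")),
    config = config, cascade = excl$cascade, qc = qc,
    gps = gps, derived = derived, graph = graph,
    model_n = model_n, r_squared = r2), class = "run_report")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_run_report(report, outdir)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("chainreg run report (version", x$version, ")\n")
  print(x$cascade)
  cat("\nPer-model complete-case n and variance explained:\n")
  print(data.frame(response = names(x$model_n), n = unname(x$model_n),
                   r_squared = round(unname(x$r_squared), 4)))
  invisible(x)
}

#' Write run-report artefacts to a directory
#'
#' @param report A `run_report`.
#' @param outdir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_run_report <- function(report, outdir) {
  paths <- character(0)
  p <- file.path(outdir, "exclusion_cascade.tsv")
  write_tsv_stable(as.data.frame(report$cascade), p); paths <- c(paths, p)
  paths <- c(paths, write_qc_report(report$qc, file.path(outdir, "qc")))
  for (resp in names(report$graph$fits)) {
    fit <- report$graph$fits[[resp]]
    tab <- fit$coef_table
    tab <- cbind(tab, response = rep(resp, nrow(tab)))
    p <- file.path(outdir, paste0("model_", resp, ".tsv"))
    write_tsv_stable(tab, p); paths <- c(paths, p)
  }
  p <- file.path(outdir, "graph.dot")
  export_graph_dot(report$graph, p); paths <- c(paths, p)
  p <- file.path(outdir, "graph.json")
  export_graph_json(report$graph, p); paths <- c(paths, p)
  p <- file.path(outdir, "run_report.json")
  meta <- list(version = report$version,
               selection_alpha = report$config$selection_alpha,
               edge_alpha = report$config$edge_alpha,
               model_n = as.list(report$model_n),
               r_squared = as.list(report$r_squared))
  jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Write a synthetic cohort in the pipeline's input dialects
#'
#' Emits the phenotype CSV, genotype allele-count CSV and panel file that
#' [run_pipeline()] ingests, plus the ground truth as JSON.
#'
#' @param sim Result of [generate_cohort()].
#' @param dir Output directory.
#' @return Named character vector of the paths written.
#' @export
write_cohort_files <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pheno_cols <- c("id", "age", "sex", "country", "arm",
                  "ethnicity_white_european", "t2dm_medication",
                  "weight_0", "weight_12", "glucose_0", "glucose_12",
                  "insulin_0", "insulin_12", "hba1c_0", "hba1c_12",
                  "steps_0", "steps_12", "energy_0", "energy_12",
                  "satfat_g_0", "satfat_g_12")
  pheno_path <- file.path(dir, "phenotypes.csv")
  utils::write.csv(sim$cohort[, pheno_cols], pheno_path, row.names = FALSE)
  geno_path <- file.path(dir, "genotypes.csv")
  gdf <- data.frame(id = rownames(sim$genotypes),
                    as.data.frame(unclass(sim$genotypes)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(gdf, geno_path, row.names = FALSE, na = "")
  panel_path <- file.path(dir, "panel.csv")
  n_snps <- ncol(sim$genotypes)
  # synthetic panel: alternating unambiguous allele pairs
  panel <- data.frame(snp_id = colnames(sim$genotypes),
                      locus = sprintf("LOC%02d", seq_len(n_snps)),
                      risk_allele = rep(c("A", "C"), length.out = n_snps),
                      other_allele = rep(c("G", "T"), length.out = n_snps),
                      source_trait = "T2DM", stringsAsFactors = FALSE)
  utils::write.csv(panel, panel_path, row.names = FALSE)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(list(effects = sim$truth$effects,
                            intercepts = sim$truth$intercepts,
                            noise_sd = as.list(sim$truth$noise_sd),
                            centers = sim$truth$centers,
                            true_r2 = as.list(sim$truth$true_r2)),
                       truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  c(phenotypes = pheno_path, genotypes = geno_path, panel = panel_path,
    truth = truth_path)
}

#' Structure- and parameter-recovery experiment
#'
#' Repeatedly generates synthetic cohorts from one configuration, fits the
#' chain-graph model to each, and scores edge recovery against the
#' generating graph plus coverage of the weight-change model's planted
#' coefficients (arm effect, diet slope, activity slope) by their
#' full-model 2-SE intervals.
#'
#' @param n Retained cohort size per replicate.
#' @param replicates Number of replicates.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param effect_scale Multiplier applied to every generating coefficient.
#' @param config Template `synthetic_config`; its seed, size and
#'   retention are overridden per replicate.
#' @param ordering,interactions,selection_alpha,edge_alpha Passed to
#'   [fit_chain_graph()].
#' @return List with `per_edge` (recovery frequency per planted edge),
#'   `tpr`, `fpr`, `coef_rmse` (replicate means), `coverage` (per planted
#'   weight-model coefficient), and `replicates`.
#' @export
recovery_experiment <- function(n = 2000, replicates = 200, seed = 1,
                                effect_scale = 1,
                                config = synthetic_config(seed = seed),
                                ordering = default_ordering(),
                                interactions =
                                  default_pipeline_config()$interactions,
                                selection_alpha = 0.05,
                                edge_alpha = 0.10) {
  eff <- config$effects
  eff$coefficient <- eff$coefficient * effect_scale
  planted <- c(arm_cp = -3.53, d_satfat_pct = 0.20,
               d_steps_k = -0.18) * effect_scale
  edge_hits <- NULL
  tpr <- fpr <- rmse <- numeric(replicates)
  cover <- matrix(NA, nrow = replicates, ncol = 3,
                  dimnames = list(NULL, names(planted)))
  for (r in seq_len(replicates)) {
    cfg <- synthetic_config(seed = seed + r, n_enrolled = n, retention = 1,
                            effects = eff, noise_sd = config$noise_sd,
                            intercepts = config$intercepts,
                            baseline = config$baseline,
                            n_snps = config$n_snps,
                            geno_missing_rate = config$geno_missing_rate,
                            treatment_fraction = config$treatment_fraction)
    sim <- generate_cohort(cfg)
    g <- fit_chain_graph(sim$cohort, ordering, interactions,
                         selection_alpha, edge_alpha)
    tg <- true_graph(sim$truth, ordering = ordering)
    m <- recovery_metrics(g, tg, interactions)
    tpr[r] <- m$tpr; fpr[r] <- m$fpr; rmse[r] <- m$coef_rmse
    true_keys <- edge_key(tg$edges)
    est_keys <- edge_key(g$edges[g$edges$type != "undirected", ,
                                 drop = FALSE])
    hit <- true_keys %in% est_keys
    names(hit) <- true_keys
    edge_hits <- if (is.null(edge_hits)) hit else edge_hits + hit
    # coefficient coverage from the full (pre-selection) weight model,
    # free of selection conditioning
    wf <- fit_full_model("d_weight", ordering, sim$cohort)
    sm <- summary(wf$lm)$coefficients
    est <- c(arm_cp = unname(sm["armCP", 1]),
             d_satfat_pct = unname(sm["d_satfat_pct", 1]),
             d_steps_k = unname(sm["d_steps_k", 1]))
    se <- c(arm_cp = unname(sm["armCP", 2]),
            d_satfat_pct = unname(sm["d_satfat_pct", 2]),
            d_steps_k = unname(sm["d_steps_k", 2]))
    cover[r, ] <- abs(est - planted) <= 2 * se
  }
  list(per_edge = data.frame(edge = names(edge_hits),
                             rate = as.numeric(edge_hits) / replicates,
                             stringsAsFactors = FALSE),
       tpr = mean(tpr), fpr = mean(fpr),
       coef_rmse = mean(rmse, na.rm = TRUE),
       coverage = colMeans(cover), replicates = replicates)
}

#' Benchmark recovery over a grid of conditions
#'
#' @param n_values,effect_scales,replicates Grid of cohort sizes and
#'   effect-size multipliers, replicates per cell.
#' @param seed Base seed; cells use consecutive offsets.
#' @param ... Passed to [recovery_experiment()].
#' @return Data frame with one row per cell: `n`, `effect_scale`, mean
#'   TPR/FPR/RMSE and the minimum per-edge recovery rate.
#' @export
benchmark_recovery <- function(n_values = c(500, 2000),
                               effect_scales = 1, replicates = 20,
                               seed = 1, ...) {
  rows <- list()
  cell <- 0L
  for (n in n_values) {
    for (es in effect_scales) {
      cell <- cell + 1L
      ex <- recovery_experiment(n = n, replicates = replicates,
                                seed = seed + 10000L * cell,
                                effect_scale = es, ...)
      rows[[cell]] <- data.frame(n = n, effect_scale = es,
                                 replicates = replicates,
                                 tpr = ex$tpr, fpr = ex$fpr,
                                 coef_rmse = ex$coef_rmse,
                                 min_edge_rate = min(ex$per_edge$rate),
                                 stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
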