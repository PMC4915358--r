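#' Run the full duplication analysis pipeline
#'
#' Orchestrates validate -> reconcile -> filter -> branch summary ->
#' overlap/parallel detection -> expression statistics -> term enrichment,
#' writes all stage tables as TSV plus a machine-readable JSON run report,
#' and returns the report.  Expression and annotation stages are optional:
#' when their inputs are absent the tree stages still complete and a notice
#' is logged.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{inputs}{either `simulate` (arguments for [sim_config()]) or
#'       `forest_dir` (a directory readable by [read_forest()]).}
#'     \item{criteria}{`min_evidence_species` (default 2),
#'       `require_full_retention` (default `TRUE`).}
#'     \item{focal}{`branch1`, `branch2` (species sets, comma-joined).}
#'     \item{universe}{`"observable"` (default) or `"all"`.}
#'     \item{expression}{optional: `matrix`, `samples` (TSV paths) or
#'       `simulate: true`; plus `species` (classified species),
#'       `alpha` (0.05), `min_fc` (2), `threshold_tpm` (10),
#'       `dominance_branch`, `dominance_species`.}
#'     \item{annotation}{optional TSV path (`orthogroup`, `term`).}
#'     \item{outdir}{output directory.}
#'     \item{seed}{integer seed for simulated inputs.}
#'   }
#' @param quiet suppress progress messages.
#' @return a `run_report` (list), invisibly written to
#'   `file.path(outdir, "report.json")`.
#' @export
run_full_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  log_msg <- function(...) if (!quiet)
    message(format(Sys.time(), "%H:%M:%S"), " [genedup] ", ...)
  outdir <- config$outdir %||% stop("config$outdir is required")
  if (is.null(config$focal$branch1) || is.null(config$focal$branch2))
    stop("config$focal must name branch1 and branch2 before the run starts")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)

  # --- inputs ---------------------------------------------------------------
  sim <- NULL
  if (!is.null(config$inputs$simulate)) {
    log_msg("stage simulate: generating gene forest")
    args <- config$inputs$simulate
    args$seed <- args$seed %||% seed
    if (!is.null(args$planted_parallel))
      args$planted_parallel <- as.list(args$planted_parallel)
    if (!is.null(args$planted_ancestral))
      args$planted_ancestral <- as.list(args$planted_ancestral)
    sim <- simulate_forest(do.call(sim_config, args))
    forest <- sim
  } else if (!is.null(config$inputs$forest_dir)) {
    log_msg("stage validate: reading forest from ", config$inputs$forest_dir)
    forest <- read_forest(config$inputs$forest_dir)
  } else {
    stop("config$inputs must provide 'simulate' or 'forest_dir'")
  }

  # --- reconcile ------------------------------------------------------------
  log_msg("stage reconcile: ", length(forest$orthogroups), " orthogroups")
  catalog <- reconcile_forest(forest)
  write_catalog_tsv(catalog, file.path(outdir, "events.tsv"))

  # --- filter ---------------------------------------------------------------
  crit <- retention_criteria(
    config$criteria$min_evidence_species %||% 2L,
    config$criteria$require_full_retention %||% TRUE)
  fc <- filter_events(catalog, crit)
  cnt <- attr(fc, "counts")
  log_msg("stage filter: ", cnt$total, " events, ", cnt$after_criterion1,
          " pass criterion 1, ", cnt$retained, " fully retained")
  write_catalog_tsv(fc, file.path(outdir, "filtered_events.tsv"))
  bsum <- branch_summary(fc)
  write_catalog_tsv(bsum, file.path(outdir, "branch_summary.tsv"))

  # --- parallel -------------------------------------------------------------
  overlap <- NULL
  parallel <- NULL
  if (!is.null(config$focal)) {
    pair <- focal_branch_pair(forest$species_tree,
                              config$focal$branch1, config$focal$branch2)
    overlap <- overlap_enrichment(fc, pair,
                                  universe = config$universe %||%
                                    "observable")
    parallel <- find_parallel_events(fc, pair)
    log_msg("stage parallel: overlap k = ", overlap$k_obs,
            " (expected ", signif(overlap$expected, 4), "), ",
            sum(parallel$level == "gene"), " same-gene parallels")
    write_catalog_tsv(parallel, file.path(outdir, "parallel_events.tsv"))
    write_catalog_tsv(
      data.frame(branch1 = overlap$branch1, branch2 = overlap$branch2,
                 N = overlap$N, K = overlap$K, n = overlap$n,
                 k_obs = overlap$k_obs, expected = overlap$expected,
                 p_value = overlap$p_value, log10_p = overlap$log10_p),
      file.path(outdir, "overlap.tsv"))
  } else {
    log_msg("stage parallel skipped: no focal branches configured")
  }

  # --- expression -----------------------------------------------------------
  excfg <- config$expression
  calls <- NULL; pref_enrich <- NULL; conc <- NULL; expr_truth <- NULL
  if (!is.null(excfg)) {
    if (isTRUE(excfg$simulate)) {
      if (is.null(sim))
        stop("expression$simulate requires simulated forest inputs")
      log_msg("stage expression: simulating TPM tables")
      xs <- simulate_expression(sim)
      x <- xs$expression
      expr_truth <- xs
    } else {
      log_msg("stage expression: loading TPM tables")
      x <- load_expression(excfg$matrix, excfg$samples)
    }
    sp <- excfg$species %||% forest$species_tree$phy$tip.label[1L]
    calls <- classify_cell_preference(
      x, sp, alpha = excfg$alpha %||% 0.05,
      min_fc = excfg$min_fc %||% 2)
    write_catalog_tsv(calls, file.path(outdir, "preference_calls.tsv"))
    sp_genes <- names(forest$map)[unclass(forest$map) == sp]
    dup_genes <- unique(unlist(strsplit(
      c(fc$clade_a[fc$retained], fc$clade_b[fc$retained]), ";")))
    cohort <- intersect(dup_genes, sp_genes)
    if (length(cohort)) {
      pref_enrich <- preference_enrichment(cohort, calls)
      write_catalog_tsv(pref_enrich,
                        file.path(outdir, "preference_enrichment.tsv"))
    }
    dom <- excfg$dominance
    if (!is.null(dom)) {
      sp12 <- dom$species %||% c("Osativa", "Zmays")
      conc <- dominance_concordance(
        fc, dom$branch, subset_species(x, sp12[1L]),
        subset_species(x, sp12[2L]),
        threshold_tpm = dom$threshold_tpm %||% 10)
      log_msg("stage concordance: ", conc$n_concordant, "/",
              conc$n_assessed, " (",
              ifelse(conc$n_assessed > 0,
                     sprintf("%.1f%%", conc$percentage), "NA"), ")")
      write_catalog_tsv(conc$events, file.path(outdir, "concordance.tsv"))
    }
  } else {
    log_msg("stage expression skipped: no expression inputs configured")
  }

  # --- term enrichment ------------------------------------------------------
  enrich <- NULL
  if (!is.null(config$annotation) && !is.null(overlap)) {
    annot <- .read_tsv(config$annotation, c("orthogroup", "term"))
    enrich <- term_enrichment(overlap$overlap_orthogroups,
                              names(forest$orthogroups), annot)
    write_catalog_tsv(enrich, file.path(outdir, "term_enrichment.tsv"))
    log_msg("stage enrich: ", sum(enrich$significant),
            " significant term(s)")
  }

  report <- structure(list(
    package_version = as.character(utils::packageVersion("genedup")),
    seed = seed,
    n_orthogroups = length(forest$orthogroups),
    n_genes = length(forest$map),
    counts = cnt,
    branch_summary = bsum,
    overlap = if (!is.null(overlap))
      overlap[c("branch1", "branch2", "N", "K", "n", "k_obs",
                "expected", "p_value", "log10_p")],
    n_parallel_orthogroup = if (!is.null(parallel))
      sum(parallel$level == "orthogroup"),
    n_parallel_gene = if (!is.null(parallel))
      sum(parallel$level == "gene"),
    preference_enrichment = pref_enrich,
    concordance = if (!is.null(conc))
      conc[c("n_assessed", "n_concordant", "percentage")],
    n_significant_terms = if (!is.null(enrich)) sum(enrich$significant),
    config = config
  ), class = "run_report")
  jsonlite::write_json(report[names(report) != "config"],
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  log_msg("pipeline complete; report written to ",
          file.path(outdir, "report.json"))
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("genedup run report (seed ", x$seed, ")\n", sep = "")
  cat("  orthogroups: ", x$n_orthogroups, ", genes: ", x$n_genes, "\n",
      sep = "")
  cat("  events: ", x$counts$total, " -> criterion 1: ",
      x$counts$after_criterion1, " -> retained: ", x$counts$retained,
      "\n", sep = "")
  if (!is.null(x$overlap))
    cat(sprintf(
      "  overlap: k = %d of K = %d / n = %d (N = %d), expected %.3f, p %.3g\n",
      x$overlap$k_obs, x$overlap$K, x$overlap$n, x$overlap$N,
      x$overlap$expected, x$overlap$p_value))
  if (!is.null(x$n_parallel_gene))
    cat("  same-gene parallel duplications:", x$n_parallel_gene, "\n")
  if (!is.null(x$concordance))
    cat(sprintf("  dominance concordance: %d/%d (%.1f%%)\n",
                x$concordance$n_concordant, x$concordance$n_assessed,
                x$concordance$percentage))
  invisible(x)
}
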