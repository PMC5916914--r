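#' Build a run configuration
#'
#' Collects inputs and thresholds for [run_pipeline()]. Matrix/sheet
#' arguments accept either in-memory objects or file paths (TSV, read with
#' the package readers). Thresholds not supplied fall back to the built-in
#' defaults; a YAML file (see [read_run_config()]) sits between the two.
#'
#' @param betas_m0,betas_mf beta matrices (or TSV paths), one per
#'   timepoint.
#' @param sheet sample sheet covering both timepoints (or TSV path).
#' @param detection_p,beadcount optional named lists `list(m0=, mf=)` of
#'   QC matrices (or TSV paths).
#' @param annotation optional probe annotation (or TSV path).
#' @param vmp_threshold VMP threshold on the group-median statistic (0.1).
#' @param vmp_mode `"abs_of_median"` or `"median_of_abs"`.
#' @param alpha FDR threshold of the variance scan (0.05).
#' @param dev_threshold epimutation deviation threshold (0.10, strict >).
#' @param list_mode converter-specificity reading: `"between-group"`
#'   (default) or `"longitudinal"` (see [select_candidates()]).
#' @param max_failed_cpgs,p_thresh,beadcount_min,beadcount_frac QC bounds.
#' @param seed integer recorded in the report (the pipeline itself is
#'   deterministic).
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return a `methvar_run_config` list.
#' @export
run_config <- function(betas_m0, betas_mf, sheet,
                       detection_p = NULL, beadcount = NULL,
                       annotation = NULL,
                       vmp_threshold = 0.1,
                       vmp_mode = "abs_of_median",
                       alpha = 0.05, dev_threshold = 0.10,
                       list_mode = c("between-group", "longitudinal"),
                       max_failed_cpgs = 4500, p_thresh = 0.05,
                       beadcount_min = 3, beadcount_frac = 0.05,
                       seed = 1L, out_dir = NULL) {
  list_mode <- match.arg(list_mode)
  stopifnot(vmp_threshold > 0, vmp_threshold < 1,
            alpha > 0, alpha < 1, dev_threshold > 0, dev_threshold < 1)
  structure(list(betas_m0 = betas_m0, betas_mf = betas_mf, sheet = sheet,
                 detection_p = detection_p, beadcount = beadcount,
                 annotation = annotation,
                 vmp_threshold = vmp_threshold, vmp_mode = vmp_mode,
                 alpha = alpha, dev_threshold = dev_threshold,
                 list_mode = list_mode,
                 max_failed_cpgs = max_failed_cpgs, p_thresh = p_thresh,
                 beadcount_min = beadcount_min,
                 beadcount_frac = beadcount_frac,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "methvar_run_config")
}

#' Read a YAML run configuration
#'
#' Reads a YAML file whose keys are the arguments of [run_config()];
#' explicit arguments passed through `...` override the file, which
#' overrides the built-in defaults.
#'
#' @param path YAML file.
#' @param ... overrides, as for [run_config()].
#' @return a `methvar_run_config` list.
#' @export
read_run_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  over <- list(...)
  cfg[names(over)] <- over
  do.call(run_config, cfg)
}

#' Run the full variability pipeline
#'
#' Executes, in order: optional QC (sample filter on detection p-values,
#' then probe filter on detection p / beadcount / annotation flags, both
#' applied jointly to the two timepoints so they keep a common probe set),
#' VMP detection per group, and the epimutation stage (variance scans at
#' M0 and MF, candidate selection, converter-group deviations at both
#' timepoints over candidate probes, strict outlier calling at MF, and
#' the per-subject summary). Every intermediate table is written under
#' `out_dir` when one is configured, together with a JSON run report.
#' Given identical inputs and configuration the outputs are identical
#' (the report's timestamp aside). A stage failure aborts with the stage
#' name in the error.
#'
#' @param config a `methvar_run_config` from [run_config()].
#' @return the run report, an invisible list: per-stage counts, VMP count
#'   per group, candidate count, call count, per-subject histogram, the
#'   thresholds used, seed, package version and config hash; plus a
#'   `tables` element holding the result tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "methvar_run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  as_matrix <- function(x) if (is.character(x)) read_beta_matrix(x) else x
  as_qc <- function(x) if (is.character(x)) read_qc_matrix(x) else x

  b0 <- stage("load", as_matrix(config$betas_m0))
  bf <- stage("load", as_matrix(config$betas_mf))
  sheet <- stage("load", if (is.character(config$sheet))
    read_sample_sheet(config$sheet) else validate_sample_sheet(config$sheet))
  ann <- stage("load", if (is.character(config$annotation))
    read_probe_annotation(config$annotation) else config$annotation)

  qc_reports <- list()
  if (!is.null(config$detection_p)) {
    detp <- lapply(config$detection_p, as_qc)
    fs0 <- stage("qc_samples", filter_samples(b0, detp$m0,
                 config$max_failed_cpgs, config$p_thresh))
    fsf <- stage("qc_samples", filter_samples(bf, detp$mf,
                 config$max_failed_cpgs, config$p_thresh))
    b0 <- fs0$betas; bf <- fsf$betas
    detp <- list(m0 = fs0$detection_p, mf = fsf$detection_p)
    qc_reports$samples_m0 <- fs0$report
    qc_reports$samples_mf <- fsf$report
  } else detp <- NULL
  if (!is.null(detp) || !is.null(config$beadcount) || !is.null(ann)) {
    bead <- if (is.null(config$beadcount)) NULL
            else lapply(config$beadcount, as_qc)
    # drop a probe everywhere if it fails at either timepoint
    fp0 <- stage("qc_probes", filter_probes(
      b0, detp$m0, if (is.null(bead)) NULL else bead$m0[rownames(b0), colnames(b0), drop = FALSE],
      ann, config$p_thresh, config$beadcount_min, config$beadcount_frac))
    fpf <- stage("qc_probes", filter_probes(
      bf, detp$mf, if (is.null(bead)) NULL else bead$mf[rownames(bf), colnames(bf), drop = FALSE],
      ann, config$p_thresh, config$beadcount_min, config$beadcount_frac))
    keep <- intersect(rownames(fp0$betas), rownames(fpf$betas))
    b0 <- b0[keep, , drop = FALSE]
    bf <- bf[keep, , drop = FALSE]
    qc_reports$probes_m0 <- fp0$report
    qc_reports$probes_mf <- fpf$report
  }

  betas_all <- cbind(b0, bf)
  delta <- stage("vmp", compute_delta(betas_all, sheet))
  vmp_tables <- list()
  for (grp in unique(delta$subject_group)) {
    stat <- stage("vmp", group_median_statistic(delta, grp,
                                                mode = config$vmp_mode))
    vmp_tables[[grp]] <- detect_vmps(stat, config$vmp_threshold)
  }

  scan_m0 <- stage("epimutation", scan_variances(b0, sheet, "M0"))
  scan_mf <- stage("epimutation", scan_variances(bf, sheet, "MF"))
  excl <- NULL
  if (config$list_mode == "longitudinal") {
    lng <- stage("epimutation", scan_longitudinal(betas_all, sheet, "nonconverter"))
    excl <- lng$probe_id[!is.na(lng$q) & lng$q < config$alpha]
  }
  cand <- stage("epimutation",
                select_candidates(scan_m0, scan_mf, config$alpha,
                                  nonconverter_exclude = excl))
  cand_probes <- cand$probe_id[cand$is_candidate]
  calls <- data.frame(probe_id = character(0), subject_id = character(0),
                      timepoint = character(0), deviation = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
  dev_m0 <- dev_mf <- NULL
  conv_subjects <- unique(sheet$subject_id[sheet$group == "converter"])
  if (length(cand_probes) > 0) {
    dev_m0 <- stage("epimutation", compute_deviations(
      b0, sheet, "converter", "M0", cand_probes))
    dev_mf <- stage("epimutation", compute_deviations(
      bf, sheet, "converter", "MF", cand_probes))
    calls <- stage("epimutation", call_epimutations(
      dev_mf, config$dev_threshold, strict = TRUE))
  }
  summary <- stage("epimutation", summarize_calls(calls, conv_subjects))

  report <- list(
    package_version = as.character(utils::packageVersion("methvar")),
    seed = config$seed,
    config_hash = config_hash(config),
    thresholds = list(vmp_threshold = config$vmp_threshold,
                      vmp_mode = config$vmp_mode, alpha = config$alpha,
                      dev_threshold = config$dev_threshold,
                      list_mode = config$list_mode),
    n_probes = nrow(b0),
    n_samples = ncol(betas_all),
    n_paired_subjects = ncol(delta$values),
    vmp_count = lapply(vmp_tables, function(t) sum(t$is_vmp)),
    candidate_count = length(cand_probes),
    call_count = summary$n_calls,
    called_probe_count = summary$n_probes,
    per_subject_histogram = as.list(summary$histogram),
    qc = lapply(qc_reports, function(r)
      list(n_probes_retained = r$n_probes_retained,
           n_samples_retained = r$n_samples_retained)))

  tables <- list(vmp = vmp_tables, scan_m0 = scan_m0, scan_mf = scan_mf,
                 candidates = cand, deviations_m0 = dev_m0,
                 deviations_mf = dev_mf, calls = calls, summary = summary,
                 qc_reports = qc_reports)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, f) write.table(df, file.path(config$out_dir, f),
                                      sep = "\t", quote = FALSE, row.names = FALSE)
    for (grp in names(vmp_tables))
      wt(vmp_tables[[grp]], paste0("vmp_", grp, ".tsv"))
    wt(scan_m0, "scan_M0.tsv"); wt(scan_mf, "scan_MF.tsv")
    wt(cand, "candidates.tsv"); wt(calls, "calls.tsv")
    if (!is.null(dev_m0)) {
      write_beta_matrix(dev_m0 + 0, file.path(config$out_dir, "deviations_M0.tsv"))
      write_beta_matrix(dev_mf + 0, file.path(config$out_dir, "deviations_MF.tsv"))
    }
    jsonlite::write_json(c(report, list(timestamp = format(Sys.time()))),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  report$tables <- tables
  invisible(report)
}

#' Worked-example analysis on the packaged deviation fixture
#'
#' Runs the outlier-calling half of the epimutation stage on the packaged
#' 25-CpG x 14-converter deviation fixture (see [load_table3_fixture()]):
#' strict `> threshold` calling on the post-transition block plus the
#' cohort summary, with the probe -> gene annotation joined onto the
#' calls.
#'
#' @param threshold deviation threshold (default 0.10).
#' @return list with `calls` (annotated), `summary`
#'   (see [summarize_calls()]), and `fixture`.
#' @examples
#' res <- run_table3_analysis()
#' res$summary$n_probes   # 12 called CpGs
#' res$summary$n_calls    # 16 calls
#' @export
run_table3_analysis <- function(threshold = 0.10) {
  fx <- load_table3_fixture()
  dev <- fx$after
  attr(dev, "timepoint") <- "MF"
  calls <- call_epimutations(dev, threshold = threshold, strict = TRUE)
  calls$gene <- fx$annotation$gene[match(calls$probe_id, fx$annotation$probe_id)]
  summary <- summarize_calls(calls, colnames(fx$after))
  list(calls = calls, summary = summary, fixture = fx)
}

# content hash of a configuration (inputs included by value when they are
# in-memory objects, by path string otherwise)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(config)[order(names(config))], tmp)
  unname(tools::md5sum(tmp))
}
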