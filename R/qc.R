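#' Sample-level quality filter on detection p-values
#'
#' A sample is excluded when strictly more than `max_failed_cpgs` of its
#' probes have a detection p-value at or above `p_thresh` (the usual
#' ">4500 CpGs (1%) failing at p >= 0.05" rule for ~450k-probe arrays).
#' A sample with exactly `max_failed_cpgs` failures is retained.
#'
#' @param betas beta matrix (probes x samples).
#' @param detection_p matrix of detection p-values, same dimensions and
#'   dimnames as `betas`. Required: passing `NULL` is a configuration
#'   error, never a silent skip.
#' @param max_failed_cpgs failure-count bound (strict `>` for exclusion).
#' @param p_thresh detection p-value threshold (inclusive `>=` counts as
#'   a failure).
#' @return list with `betas` (retained samples), `detection_p` subset the
#'   same way, and `report` (a QC report, see [qc_report()]).
#' @export
filter_samples <- function(betas, detection_p, max_failed_cpgs = 4500,
                           p_thresh = 0.05) {
  validate_beta_matrix(betas)
  if (is.null(detection_p))
    stop("detection p-values are required for sample QC (configuration error)")
  check_qc_dims(betas, detection_p, "detection_p")
  n_failed <- colSums(detection_p >= p_thresh, na.rm = TRUE)
  drop <- n_failed > max_failed_cpgs
  excluded <- data.frame(sample_id = colnames(betas)[drop],
                         reason = rep("detection_p", sum(drop)),
                         n_failed = unname(n_failed[drop]),
                         stringsAsFactors = FALSE)
  keep <- !drop
  report <- qc_report(
    excluded_samples = excluded,
    excluded_probes = data.frame(probe_id = character(0), reason = character(0),
                                 stringsAsFactors = FALSE),
    n_samples_in = ncol(betas), n_probes_in = nrow(betas),
    n_samples_retained = sum(keep), n_probes_retained = nrow(betas),
    thresholds = list(max_failed_cpgs = max_failed_cpgs, p_thresh = p_thresh))
  list(betas = betas[, keep, drop = FALSE],
       detection_p = detection_p[, keep, drop = FALSE],
       report = report)
}

#' Probe-level quality filter
#'
#' Excludes every probe failing any of, in this reason-precedence order:
#' \enumerate{
#'   \item \strong{detection}: detection p-value >= `p_thresh` in at least
#'     one sample (inclusive);
#'   \item \strong{beadcount}: beadcount < `beadcount_min` in at least
#'     `beadcount_frac` of samples (inclusive; the fraction is compared
#'     exactly in rational arithmetic, so 2 low-bead samples out of 40
#'     meets a 5\% bound);
#'   \item \strong{annotation flags}: probe on chrX/chrY, SNP probe, SNP at
#'     the CpG site, or cross-reactive;
#'   \item \strong{unannotated}: probe absent from the annotation table.
#' }
#' Each excluded probe carries exactly one primary reason (the first rule
#' it fails). Sample fractions are computed over the samples present in
#' `betas`, i.e. over the samples retained by any prior sample-level QC.
#' Omitted QC matrices (`NULL`) simply skip their rule.
#'
#' @param betas beta matrix (probes x samples).
#' @param detection_p optional detection p-value matrix matching `betas`.
#' @param beadcount optional beadcount matrix matching `betas`.
#' @param annotation probe annotation data frame
#'   (see [read_probe_annotation()]).
#' @param p_thresh detection p-value threshold (inclusive).
#' @param beadcount_min minimum acceptable beadcount (strict `<` fails).
#' @param beadcount_frac sample fraction at/above which low beadcounts
#'   exclude the probe (inclusive).
#' @return list with `betas` (retained probes) and `report`.
#' @export
filter_probes <- function(betas, detection_p = NULL, beadcount = NULL,
                          annotation = NULL, p_thresh = 0.05,
                          beadcount_min = 3, beadcount_frac = 0.05) {
  validate_beta_matrix(betas)
  n_samples <- ncol(betas)
  reason <- rep(NA_character_, nrow(betas))

  if (!is.null(detection_p)) {
    check_qc_dims(betas, detection_p, "detection_p")
    fail_det <- rowSums(detection_p >= p_thresh, na.rm = TRUE) >= 1
    reason[is.na(reason) & fail_det] <- "detection_p"
  }
  if (!is.null(beadcount)) {
    check_qc_dims(betas, beadcount, "beadcount")
    n_low <- rowSums(beadcount < beadcount_min, na.rm = TRUE)
    # exact rational comparison n_low / n_samples >= beadcount_frac
    frac_ratio <- as_ratio(beadcount_frac)
    fail_bead <- n_low * frac_ratio$den >= n_samples * frac_ratio$num
    reason[is.na(reason) & fail_bead] <- "beadcount"
  }
  if (!is.null(annotation)) {
    idx <- match(rownames(betas), annotation$probe_id)
    flagged <- rep(FALSE, nrow(betas))
    flag_name <- rep(NA_character_, nrow(betas))
    have <- !is.na(idx)
    for (fl in c("sex_chromosome", "snp_probe", "snp_at_cpg", "cross_reactive")) {
      hit <- have & annotation[[fl]][idx] & !flagged
      flagged[hit] <- TRUE
      flag_name[hit] <- fl
    }
    reason[is.na(reason) & flagged] <- flag_name[is.na(reason) & flagged]
    reason[is.na(reason) & !have] <- "unannotated"
  }

  drop <- !is.na(reason)
  report <- qc_report(
    excluded_samples = data.frame(sample_id = character(0), reason = character(0),
                                  stringsAsFactors = FALSE),
    excluded_probes = data.frame(probe_id = rownames(betas)[drop],
                                 reason = reason[drop],
                                 stringsAsFactors = FALSE),
    n_samples_in = n_samples, n_probes_in = nrow(betas),
    n_samples_retained = n_samples, n_probes_retained = sum(!drop),
    thresholds = list(p_thresh = p_thresh, beadcount_min = beadcount_min,
                      beadcount_frac = beadcount_frac))
  list(betas = betas[!drop, , drop = FALSE], report = report)
}

#' Construct a QC report
#'
#' Bookkeeping container for the QC filters; checks that the retained and
#' excluded counts add up to the inputs.
#'
#' @param excluded_samples data frame (sample_id, reason, ...).
#' @param excluded_probes data frame (probe_id, reason).
#' @param n_samples_in,n_probes_in input dimensions.
#' @param n_samples_retained,n_probes_retained retained dimensions.
#' @param thresholds named list of the thresholds applied.
#' @return an object of class `methvar_qc_report`.
#' @export
qc_report <- function(excluded_samples, excluded_probes,
                      n_samples_in, n_probes_in,
                      n_samples_retained, n_probes_retained, thresholds) {
  stopifnot(n_samples_retained + nrow(excluded_samples) == n_samples_in,
            n_probes_retained + nrow(excluded_probes) == n_probes_in)
  structure(list(excluded_samples = excluded_samples,
                 excluded_probes = excluded_probes,
                 n_samples_in = n_samples_in, n_probes_in = n_probes_in,
                 n_samples_retained = n_samples_retained,
                 n_probes_retained = n_probes_retained,
                 thresholds = thresholds),
            class = "methvar_qc_report")
}

#' @export
print.methvar_qc_report <- function(x, ...) {
  cat("QC report:", x$n_samples_retained, "/", x$n_samples_in, "samples,",
      x$n_probes_retained, "/", x$n_probes_in, "probes retained\n")
  if (nrow(x$excluded_probes) > 0) {
    tb <- table(x$excluded_probes$reason)
    cat("probe exclusions:",
        paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  if (nrow(x$excluded_samples) > 0)
    cat("sample exclusions:", nrow(x$excluded_samples), "\n")
  invisible(x)
}

#' Sample-identity check hook
#'
#' Placeholder for raw-array identity checks (reported-vs-inferred sex,
#' genotype concordance between a subject's two samples). These need raw
#' array internals that sit upstream of a beta matrix, so the default hook
#' excludes nothing; pipelines may supply their own implementation with
#' the same signature.
#'
#' @param betas beta matrix.
#' @param sheet sample sheet.
#' @return data frame of excluded samples (empty in the default hook).
#' @export
check_sample_identity <- function(betas, sheet) {
  data.frame(sample_id = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

check_qc_dims <- function(betas, qc, what) {
  if (!is.matrix(qc) || !identical(dim(qc), dim(betas)) ||
      !identical(rownames(qc), rownames(betas)) ||
      !identical(colnames(qc), colnames(betas)))
    stop(what, " matrix must match the beta matrix dimensions and dimnames")
  invisible(TRUE)
}

# small exact-rational helper: represent a decimal threshold as num/den
as_ratio <- function(x, max_den = 10000L) {
  den <- max_den
  num <- round(x * den)
  g <- gcd(num, den)
  list(num = num / g, den = den / g)
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
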