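#' Two-sided F-test for equality of variances
#'
#' Tests the null of equal variances between two samples with the variance
#' ratio \eqn{F = s_x^2 / s_y^2} (unbiased, n-1 denominators) on
#' \eqn{(n_x - 1, n_y - 1)} degrees of freedom. The two-sided p-value is
#' \eqn{2 \min\{P(F_{df} \le F), P(F_{df} \ge F)\}}, capped at 1.
#'
#' Degenerate inputs are flagged rather than erroring: both variances zero
#' gives `F = NA`, `p = 1` (a constant probe carries no evidence against
#' equality); exactly one variance zero gives the limiting `p = 0` with
#' the degenerate flag set, so callers can keep such probes out of an FDR
#' family.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list `F`, `df1`, `df2`, `p`, `degenerate` (logical).
#' @examples
#' variance_ftest(rnorm(14), rnorm(25))
#' @export
variance_ftest <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("variance_ftest needs >= 2 observations per group")
  vx <- stats::var(x); vy <- stats::var(y)
  df1 <- length(x) - 1L; df2 <- length(y) - 1L
  if (vx == 0 && vy == 0)
    return(list(F = NA_real_, df1 = df1, df2 = df2, p = 1, degenerate = TRUE))
  if (vy == 0)
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0, degenerate = TRUE))
  if (vx == 0)
    return(list(F = 0, df1 = df1, df2 = df2, p = 0, degenerate = TRUE))
  F <- vx / vy
  p <- min(1, 2 * min(pf(F, df1, df2), pf(F, df1, df2, lower.tail = FALSE)))
  list(F = F, df1 = df1, df2 = df2, p = p, degenerate = FALSE)
}

#' Genome-wide variance scan at one timepoint
#'
#' For every probe, compares the beta-value variance of converters against
#' non-converters at the given timepoint with the two-sided F-test of
#' [variance_ftest()], then adjusts p-values across probes by
#' Benjamini-Hochberg FDR. Probes that are degenerate (zero variance in a
#' group) or that have any missing beta among the contributing samples are
#' excluded from the FDR family and carry `q = NA` with `degenerate = TRUE`
#' (missingness reason `"missing"` vs `"zero_variance"` in `degenerate_reason`).
#'
#' @param betas beta matrix covering the timepoint's samples.
#' @param sheet sample sheet; both groups need >= 2 samples at `timepoint`.
#' @param timepoint `"M0"` or `"MF"`.
#' @return data frame, one row per probe: `probe_id`, `timepoint`,
#'   `var_converter`, `var_nonconverter`, `F` (converter/nonconverter),
#'   `df1`, `df2`, `p`, `q`, `higher_variance_group`
#'   (`"converter"`/`"nonconverter"`/`"tie"`), `degenerate`,
#'   `degenerate_reason`.
#' @export
scan_variances <- function(betas, sheet, timepoint) {
  validate_beta_matrix(betas)
  validate_sample_sheet(sheet)
  if (!timepoint %in% sheet$timepoint)
    stop("timepoint not present in sample sheet: ", timepoint)
  sel <- sheet[sheet$timepoint == timepoint & sheet$sample_id %in% colnames(betas), ]
  conv <- sel$sample_id[sel$group == "converter"]
  nonc <- sel$sample_id[sel$group == "nonconverter"]
  if (length(conv) < 2 || length(nonc) < 2)
    stop("both groups need >= 2 samples at ", timepoint)
  xc <- betas[, conv, drop = FALSE]
  xn <- betas[, nonc, drop = FALSE]
  vc <- row_var(xc)
  vn <- row_var(xn)
  miss <- rowSums(is.na(xc)) > 0 | rowSums(is.na(xn)) > 0
  df1 <- length(conv) - 1L; df2 <- length(nonc) - 1L
  F <- vc / vn
  p <- pmin(1, 2 * pmin(pf(F, df1, df2), pf(F, df1, df2, lower.tail = FALSE)))
  zero <- !miss & (vc == 0 | vn == 0)
  p[!miss & vc == 0 & vn == 0] <- 1
  p[!miss & xor(vc == 0, vn == 0)] <- 0
  degen <- miss | zero
  q <- rep(NA_real_, nrow(betas))
  q[!degen] <- p.adjust(p[!degen], method = "BH")
  hi <- ifelse(vc > vn, "converter", ifelse(vn > vc, "nonconverter", "tie"))
  data.frame(probe_id = rownames(betas),
             timepoint = timepoint,
             var_converter = unname(vc),
             var_nonconverter = unname(vn),
             F = unname(F), df1 = df1, df2 = df2,
             p = unname(p), q = unname(q),
             higher_variance_group = unname(hi),
             degenerate = unname(degen),
             degenerate_reason = ifelse(miss, "missing",
                                 ifelse(zero, "zero_variance", "")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Within-group longitudinal variance scan
#'
#' Alternative reading of the "significant within a group" probe lists:
#' for one group, an F-test of MF variance against M0 variance per probe,
#' BH-adjusted. Useful to build the non-converter exclusion set under the
#' longitudinal interpretation (see [select_candidates()]).
#'
#' @param betas beta matrix covering both timepoints' samples.
#' @param sheet sample sheet.
#' @param group `"converter"` or `"nonconverter"`.
#' @return data frame like [scan_variances()] but with columns `var_mf`,
#'   `var_m0` and `F = var_mf / var_m0`.
#' @export
scan_longitudinal <- function(betas, sheet, group) {
  validate_beta_matrix(betas)
  validate_sample_sheet(sheet)
  sel <- sheet[sheet$group == group & sheet$sample_id %in% colnames(betas), ]
  smf <- sel$sample_id[sel$timepoint == "MF"]
  sm0 <- sel$sample_id[sel$timepoint == "M0"]
  if (length(smf) < 2 || length(sm0) < 2)
    stop("group ", group, " needs >= 2 samples at each timepoint")
  xf <- betas[, smf, drop = FALSE]
  x0 <- betas[, sm0, drop = FALSE]
  vf <- row_var(xf); v0 <- row_var(x0)
  miss <- rowSums(is.na(xf)) > 0 | rowSums(is.na(x0)) > 0
  df1 <- length(smf) - 1L; df2 <- length(sm0) - 1L
  F <- vf / v0
  p <- pmin(1, 2 * pmin(pf(F, df1, df2), pf(F, df1, df2, lower.tail = FALSE)))
  zero <- !miss & (vf == 0 | v0 == 0)
  p[!miss & vf == 0 & v0 == 0] <- 1
  p[!miss & xor(vf == 0, v0 == 0)] <- 0
  degen <- miss | zero
  q <- rep(NA_real_, nrow(betas))
  q[!degen] <- p.adjust(p[!degen], method = "BH")
  data.frame(probe_id = rownames(betas), group = group,
             var_mf = unname(vf), var_m0 = unname(v0),
             F = unname(F), df1 = df1, df2 = df2,
             p = unname(p), q = unname(q),
             degenerate = unname(degen),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select candidate epimutation probes from the two timepoint scans
#'
#' Combines the M0 and MF between-group variance scans into per-probe
#' candidate calls. A probe is a candidate when all three filters pass:
#' \enumerate{
#'   \item \strong{MF significance}: FDR-adjusted q below `alpha` at MF,
#'     with the converter group showing the higher variance;
#'   \item \strong{variance increase}: converter variance strictly larger
#'     at MF than at M0 (variance grows with time; a raw comparison, not
#'     itself a test);
#'   \item \strong{converter specificity}: the probe is not in the
#'     non-converter significant set. By default that set is every probe
#'     FDR-significant at either timepoint with the non-converter group
#'     showing the higher variance; pass `nonconverter_exclude` to
#'     substitute another reading (e.g. probes significant in a
#'     within-non-converter longitudinal scan, [scan_longitudinal()]).
#' }
#'
#' @param scan_m0,scan_mf data frames from [scan_variances()] over the
#'   same probe set.
#' @param alpha FDR threshold (default 0.05).
#' @param nonconverter_exclude optional character vector of probe ids to
#'   use as the non-converter significant set; `NULL` (default) derives it
#'   from the two scans as described above.
#' @return data frame sorted by MF q ascending: `probe_id`,
#'   `passes_mf_significance`, `passes_variance_increase`,
#'   `passes_converter_specificity`, `is_candidate`, `q_mf`, `q_m0`,
#'   `var_converter_mf`, `var_converter_m0`.
#' @export
select_candidates <- function(scan_m0, scan_mf, alpha = 0.05,
                              nonconverter_exclude = NULL) {
  if (!setequal(scan_m0$probe_id, scan_mf$probe_id))
    stop("the M0 and MF scans must cover the same probe set")
  scan_m0 <- scan_m0[match(scan_mf$probe_id, scan_m0$probe_id), ]
  sig_mf <- !is.na(scan_mf$q) & scan_mf$q < alpha
  pass1 <- sig_mf & scan_mf$higher_variance_group == "converter"
  pass2 <- scan_mf$var_converter > scan_m0$var_converter
  if (is.null(nonconverter_exclude)) {
    sig_m0 <- !is.na(scan_m0$q) & scan_m0$q < alpha
    nonconverter_exclude <- unique(c(
      scan_mf$probe_id[sig_mf & scan_mf$higher_variance_group == "nonconverter"],
      scan_m0$probe_id[sig_m0 & scan_m0$higher_variance_group == "nonconverter"]))
  }
  pass3 <- !(scan_mf$probe_id %in% nonconverter_exclude)
  out <- data.frame(probe_id = scan_mf$probe_id,
                    passes_mf_significance = pass1,
                    passes_variance_increase = pass2,
                    passes_converter_specificity = pass3,
                    is_candidate = pass1 & pass2 & pass3,
                    q_mf = scan_mf$q, q_m0 = scan_m0$q,
                    var_converter_mf = scan_mf$var_converter,
                    var_converter_m0 = scan_m0$var_converter,
                    stringsAsFactors = FALSE)
  out[order(out$q_mf, out$probe_id), , drop = FALSE]
}

#' Per-subject deviations from the group median beta
#'
#' For each requested probe, subtracts the group's median beta-value at
#' the timepoint from every group member's beta:
#' `deviation(probe, subject) = beta - median(group betas)`. By
#' construction the deviations of an odd-sized group have median exactly 0
#' per probe; even-sized groups use the mean-of-middle-two median.
#'
#' @param betas beta matrix covering the timepoint's samples.
#' @param sheet sample sheet; the group needs >= 3 members at `timepoint`.
#' @param group group whose median is the reference (`"converter"` for
#'   the usual private-epimutation table).
#' @param timepoint `"M0"` or `"MF"`.
#' @param probes probe ids to compute (default: all rows of `betas`);
#'   a probe absent from `betas` is an error naming the probe.
#' @return numeric matrix probes x subjects (subject ids as columns) with
#'   attributes `timepoint` and `group`.
#' @export
compute_deviations <- function(betas, sheet, group = "converter",
                               timepoint, probes = rownames(betas)) {
  validate_beta_matrix(betas)
  validate_sample_sheet(sheet)
  absent <- setdiff(probes, rownames(betas))
  if (length(absent) > 0)
    stop("probe(s) absent from beta matrix: ", paste(absent, collapse = ", "))
  sel <- sheet[sheet$group == group & sheet$timepoint == timepoint &
                 sheet$sample_id %in% colnames(betas), ]
  if (nrow(sel) < 3)
    stop("group ", group, " needs >= 3 members at ", timepoint)
  x <- betas[probes, sel$sample_id, drop = FALSE]
  med <- apply(x, 1, median, na.rm = TRUE)
  dev <- x - med
  colnames(dev) <- sel$subject_id
  structure(dev, timepoint = timepoint, group = group)
}

#' Call private epimutations from a deviation matrix
#'
#' Emits one call per (probe, subject) cell whose absolute deviation from
#' the group median exceeds `threshold` — strictly by default, so a
#' deviation of exactly 0.10 is \emph{not} called. Direction is `"hyper"`
#' for positive deviations and `"hypo"` for negative ones.
#'
#' @param deviations probes x subjects matrix from [compute_deviations()]
#'   (or any matrix with probe rownames and subject colnames).
#' @param threshold deviation threshold on the beta scale (default 0.10).
#' @param strict logical; `TRUE` (default) uses `>` and `FALSE` uses `>=`.
#' @return data frame sorted by probe then subject: `probe_id`,
#'   `subject_id`, `timepoint`, `deviation`, `direction`.
#' @export
call_epimutations <- function(deviations, threshold = 0.10, strict = TRUE) {
  stopifnot(is.matrix(deviations))
  tp <- attr(deviations, "timepoint") %||% NA_character_
  hit <- if (strict) abs(deviations) > threshold else abs(deviations) >= threshold
  hit[is.na(hit)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(probe_id = character(0), subject_id = character(0),
                      timepoint = character(0), deviation = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  calls <- data.frame(probe_id = rownames(deviations)[idx[, 1]],
                      subject_id = colnames(deviations)[idx[, 2]],
                      timepoint = tp,
                      deviation = deviations[idx],
                      stringsAsFactors = FALSE)
  calls$direction <- ifelse(calls$deviation > 0, "hyper", "hypo")
  calls <- calls[order(calls$probe_id, calls$subject_id), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Summarise epimutation calls over a cohort
#'
#' Tallies calls per subject (including zero-call subjects), calls per
#' probe, and — for probes carried by two or more subjects — whether all
#' carriers share the same direction of change.
#'
#' @param calls data frame from [call_epimutations()].
#' @param subjects full subject list (must cover every subject in
#'   `calls`); zero-call subjects enter the histogram.
#' @return list with
#'   `n_calls` (total cell-level calls),
#'   `n_probes` (distinct called probes),
#'   `per_subject` (named integer vector over all subjects),
#'   `histogram` (named vector: how many subjects had 0, 1, 2, ... calls),
#'   `multi_carrier` (data frame `probe_id`, `n_carriers`,
#'     `shared_direction`, `direction` for probes with >= 2 carriers).
#' @export
summarize_calls <- function(calls, subjects) {
  if (!all(calls$subject_id %in% subjects))
    stop("calls contain subject(s) not in the subject list: ",
         paste(setdiff(calls$subject_id, subjects), collapse = ", "))
  per_subject <- setNames(integer(length(subjects)), subjects)
  if (nrow(calls) > 0) {
    tb <- table(calls$subject_id)
    per_subject[names(tb)] <- as.integer(tb)
  }
  histogram <- table(per_subject)
  histogram <- setNames(as.integer(histogram), names(histogram))
  multi <- data.frame(probe_id = character(0), n_carriers = integer(0),
                      shared_direction = logical(0), direction = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(calls) > 0) {
    by_probe <- split(calls, calls$probe_id)
    multi_list <- Filter(function(d) nrow(d) >= 2, by_probe)
    if (length(multi_list) > 0) {
      multi <- do.call(rbind, lapply(multi_list, function(d) {
        dirs <- unique(d$direction)
        data.frame(probe_id = d$probe_id[1], n_carriers = nrow(d),
                   shared_direction = length(dirs) == 1,
                   direction = if (length(dirs) == 1) dirs else "mixed",
                   stringsAsFactors = FALSE)
      }))
      rownames(multi) <- NULL
    }
  }
  list(n_calls = nrow(calls),
       n_probes = length(unique(calls$probe_id)),
       per_subject = per_subject,
       histogram = histogram,
       multi_carrier = multi)
}

# unbiased per-row variance, NA-propagating (rows with any NA give NA)
row_var <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}
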