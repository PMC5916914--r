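#' Per-subject longitudinal methylation differences
#'
#' For every subject with exactly one baseline (M0) and one follow-up (MF)
#' sample, computes \eqn{\Delta\beta = \beta(MF) - \beta(M0)} per probe.
#' Subjects lacking one of the two timepoints are skipped with a warning;
#' a subject with duplicate samples at a timepoint is an error (the
#' pairing would be ambiguous). A difference is missing whenever either
#' side is missing.
#'
#' @param betas beta matrix whose columns cover the sheet's samples
#'   (both timepoints in one matrix).
#' @param sheet sample sheet (see [read_sample_sheet()]).
#' @return an object of class `methvar_delta`: list with `values`
#'   (probes x subjects matrix of differences in \[-1, 1\]) and
#'   `subject_group` (named character vector, group per subject column).
#' @export
compute_delta <- function(betas, sheet) {
  validate_beta_matrix(betas)
  validate_sample_sheet(sheet)
  sheet <- sheet[sheet$sample_id %in% colnames(betas), , drop = FALSE]
  subjects <- unique(sheet$subject_id)
  m0 <- mf <- setNames(rep(NA_character_, length(subjects)), subjects)
  for (tp in c("M0", "MF")) {
    sub <- sheet[sheet$timepoint == tp, ]
    if (anyDuplicated(sub$subject_id))
      stop("subject(s) with duplicate ", tp, " samples: ",
           paste(unique(sub$subject_id[duplicated(sub$subject_id)]), collapse = ", "))
    if (tp == "M0") m0[sub$subject_id] <- sub$sample_id
    else mf[sub$subject_id] <- sub$sample_id
  }
  paired <- !is.na(m0) & !is.na(mf)
  if (any(!paired))
    warning("skipping unpaired subject(s): ",
            paste(subjects[!paired], collapse = ", "))
  if (!any(paired)) stop("no paired subject has both M0 and MF samples")
  subjects <- subjects[paired]
  delta <- betas[, mf[subjects], drop = FALSE] - betas[, m0[subjects], drop = FALSE]
  colnames(delta) <- subjects
  grp <- setNames(sheet$group[match(subjects, sheet$subject_id)], subjects)
  structure(list(values = delta, subject_group = grp), class = "methvar_delta")
}

#' @export
print.methvar_delta <- function(x, ...) {
  cat("longitudinal delta matrix:", nrow(x$values), "probes x",
      ncol(x$values), "paired subjects (",
      paste(names(table(x$subject_group)), table(x$subject_group),
            sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Group-median VMP statistic
#'
#' Summarises one group's per-subject longitudinal differences into a
#' single non-negative statistic per probe. Two summaries are offered:
#' \describe{
#'   \item{`abs_of_median`}{\eqn{|median_i(\Delta\beta_i)|} — the absolute
#'     value of the group median (the default).}
#'   \item{`median_of_abs`}{\eqn{median_i(|\Delta\beta_i|)} — the median of
#'     absolute differences.}
#' }
#' The two differ whenever the group's changes are not of one sign; both
#' are exposed because the field's verbal and symbolic descriptions of
#' this statistic do not always agree. Medians over even-sized groups take
#' the mean of the two middle values. A probe's statistic is missing when
#' fewer than 2 group subjects have a value, or when more than
#' `max_missing_frac` of the group's subjects are missing at that probe
#' (a heavily missing probe would otherwise yield a quietly biased
#' median).
#'
#' @param delta a `methvar_delta` object from [compute_delta()].
#' @param group `"converter"` or `"nonconverter"`.
#' @param mode `"abs_of_median"` (default) or `"median_of_abs"`.
#' @param max_missing_frac maximum tolerated fraction of missing subjects
#'   per probe (default 0.2).
#' @return named numeric vector, one statistic per probe (NA = missing),
#'   with attributes `mode`, `group` and `signed_median` (the signed group
#'   median, for reporting direction).
#' @export
group_median_statistic <- function(delta, group,
                                   mode = c("abs_of_median", "median_of_abs"),
                                   max_missing_frac = 0.2) {
  mode <- match.arg(mode)
  stopifnot(inherits(delta, "methvar_delta"))
  if (!group %in% delta$subject_group)
    stop("unknown or empty group: ", group)
  v <- delta$values[, delta$subject_group == group, drop = FALSE]
  n_grp <- ncol(v)
  n_ok <- rowSums(!is.na(v))
  usable <- n_ok >= 2 & (n_grp - n_ok) <= max_missing_frac * n_grp
  med <- apply(v, 1, median, na.rm = TRUE)
  stat <- if (mode == "abs_of_median") abs(med)
          else apply(abs(v), 1, median, na.rm = TRUE)
  stat[!usable] <- NA_real_
  med[!usable] <- NA_real_
  structure(setNames(stat, rownames(v)),
            mode = mode, group = group, signed_median = setNames(med, rownames(v)))
}

#' Threshold the VMP statistic into variably methylated probe calls
#'
#' A probe is a VMP when its statistic is at least `threshold`
#' (inclusive: a statistic of exactly 0.10 is called). Results are sorted
#' by statistic descending, ties broken by probe id.
#'
#' @param statistic named vector from [group_median_statistic()].
#' @param threshold VMP threshold on the beta scale (default 0.1, i.e. a
#'   10-percentage-point methylation difference, the conventional bound
#'   for biologically meaningful array differences).
#' @return data frame `probe_id`, `group`, `mode`, `statistic`,
#'   `signed_median`, `is_vmp`; probes with a missing statistic are
#'   dropped.
#' @export
detect_vmps <- function(statistic, threshold = 0.1) {
  signed <- attr(statistic, "signed_median")
  grp <- attr(statistic, "group") %||% NA_character_
  mode <- attr(statistic, "mode") %||% NA_character_
  keep <- !is.na(statistic)
  res <- data.frame(probe_id = names(statistic)[keep],
                    group = grp, mode = mode,
                    statistic = unname(statistic[keep]),
                    signed_median = if (is.null(signed)) NA_real_
                                    else unname(signed[keep]),
                    stringsAsFactors = FALSE)
  if (any(res$statistic < 0)) stop("VMP statistics must be non-negative")
  res$is_vmp <- res$statistic >= threshold
  res[order(-res$statistic, res$probe_id), , drop = FALSE]
}

#' Distribution summary of a group's VMP statistic
#'
#' Descriptive summary backing a violin/density plot of the statistic's
#' distribution per group: quantiles plus the count of probes at or above
#' the VMP threshold (which equals the number of `is_vmp` calls from
#' [detect_vmps()] at the same threshold).
#'
#' @param statistic named vector from [group_median_statistic()].
#' @param threshold VMP threshold (default 0.1).
#' @param probs quantile probabilities.
#' @return list with `n` (non-missing probes), `quantiles`, and
#'   `count_above` (statistics >= threshold).
#' @export
violin_summary <- function(statistic, threshold = 0.1,
                           probs = c(0, 0.25, 0.5, 0.75, 0.9, 0.99, 1)) {
  s <- statistic[!is.na(statistic)]
  if (length(s) == 0)
    return(list(n = 0L, quantiles = setNames(numeric(0), character(0)),
                count_above = 0L))
  list(n = length(s),
       quantiles = quantile(s, probs = probs, names = TRUE, type = 7),
       count_above = sum(s >= threshold))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
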