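#' Validate a beta-value matrix
#'
#' A beta matrix is a numeric matrix of methylation fractions with probes
#' in rows and samples in columns. Row and column names must be present and
#' unique; every non-missing value must lie in \[0, 1\] (a numerical slack
#' of 1e-9 is tolerated and clamped by the readers).
#'
#' @param betas numeric matrix, probes x samples.
#' @param tol numerical tolerance on the \[0, 1\] bounds.
#' @return `betas`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_beta_matrix <- function(betas, tol = 1e-9) {
  if (!is.matrix(betas) || !is.numeric(betas))
    stop("beta matrix must be a numeric matrix")
  if (is.null(rownames(betas)) || is.null(colnames(betas)))
    stop("beta matrix must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(betas)))
    stop("duplicate probe ids: ",
         paste(unique(rownames(betas)[duplicated(rownames(betas))]), collapse = ", "))
  if (anyDuplicated(colnames(betas)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(betas)[duplicated(colnames(betas))]), collapse = ", "))
  bad <- which(!is.na(betas) & (betas < -tol | betas > 1 + tol), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("beta value out of [0,1]: %.6g at probe '%s', sample '%s'",
                 betas[i, j], rownames(betas)[i], colnames(betas)[j]))
  }
  invisible(betas)
}

#' Read a beta-value matrix from a delimited text file
#'
#' The first column holds probe ids and the header row holds sample ids.
#' Missing values are written/read as `NA`. Values outside \[0, 1\] by more
#' than 1e-9 are rejected with the offending cell named; values inside the
#' tolerance band are clamped to the bounds.
#'
#' @param path path to a TSV or CSV file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return a validated numeric beta matrix (probes x samples).
#' @export
read_beta_matrix <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop("matrix file needs a probe-id column plus >=1 sample column")
  probes <- df[[1]]
  samples <- names(df)[-1]
  # data-frame subsetting would silently uniquify duplicated header names
  if (anyDuplicated(samples))
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(probes))
    stop("duplicate probe ids: ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  body <- df[, -1, drop = FALSE]
  # parse cells ourselves so a bad cell can be reported by (row, column)
  vals <- matrix(NA_real_, nrow(body), ncol(body),
                 dimnames = list(probes, samples))
  for (j in seq_len(ncol(body))) {
    raw <- body[[j]]
    miss <- is.na(raw) | raw == "NA" | raw == ""
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!miss & is.na(num))
    if (length(bad) > 0)
      stop(sprintf("non-numeric cell '%s' at probe '%s', sample '%s'",
                   raw[bad[1]], probes[bad[1]], samples[j]))
    num[miss] <- NA_real_
    vals[, j] <- num
  }
  validate_beta_matrix(vals)
  # clamp the tolerated rounding slack
  vals[!is.na(vals) & vals < 0] <- 0
  vals[!is.na(vals) & vals > 1] <- 1
  vals
}

#' Write a beta-value matrix to a delimited text file
#'
#' Values are printed at a fixed decimal precision so that a write/read
#' round trip is exact at that precision. Missing values are written as
#' `NA`.
#'
#' @param betas beta matrix (probes x samples).
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param digits decimal places to print.
#' @param id_col name of the probe-id column in the header.
#' @export
write_beta_matrix <- function(betas, path, dialect = c("tsv", "csv"),
                              digits = 6, id_col = "probe_id") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  out <- format(round(betas, digits), trim = TRUE, scientific = FALSE)
  out[is.na(betas)] <- "NA"
  df <- data.frame(rownames(betas), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(betas))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and normalise a longitudinal sample sheet
#'
#' Expects columns `sample_id`, `subject_id`, `group`, `timepoint`
#' (matched case-insensitively). Group labels `"converter"`/`"C"` and
#' `"nonconverter"`/`"non-converter"`/`"NC"` are normalised to
#' `"converter"` / `"nonconverter"`; timepoints to `"M0"` / `"MF"`.
#'
#' @param path path to a TSV sample sheet.
#' @return data frame with columns sample_id, subject_id, group, timepoint.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  names(df) <- tolower(names(df))
  need <- c("sample_id", "subject_id", "group", "timepoint")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  sheet <- df[, need]
  sheet$group <- normalize_group(sheet$group)
  sheet$timepoint <- toupper(sheet$timepoint)
  validate_sample_sheet(sheet)
  sheet
}

normalize_group <- function(x) {
  key <- gsub("[-_ ]", "", tolower(x))
  out <- ifelse(key %in% c("converter", "c"), "converter",
         ifelse(key %in% c("nonconverter", "nc"), "nonconverter", NA_character_))
  if (anyNA(out))
    stop("unrecognised group label(s): ", paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Validate a sample sheet
#'
#' Checks uniqueness of sample ids and of (subject, timepoint) pairs,
#' legal group/timepoint levels, and that group is constant within subject.
#'
#' @param sheet data frame with sample_id, subject_id, group, timepoint.
#' @return `sheet`, invisibly.
#' @export
validate_sample_sheet <- function(sheet) {
  stopifnot(is.data.frame(sheet))
  need <- c("sample_id", "subject_id", "group", "timepoint")
  if (!all(need %in% names(sheet)))
    stop("sample sheet lacks column(s): ",
         paste(setdiff(need, names(sheet)), collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample ids in sample sheet")
  if (!all(sheet$timepoint %in% c("M0", "MF")))
    stop("timepoint must be M0 or MF")
  if (!all(sheet$group %in% c("converter", "nonconverter")))
    stop("group must be converter or nonconverter")
  key <- paste(sheet$subject_id, sheet$timepoint)
  if (anyDuplicated(key))
    stop("duplicate (subject, timepoint) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  gs <- tapply(sheet$group, sheet$subject_id, function(g) length(unique(g)))
  if (any(gs > 1))
    stop("group not constant within subject(s): ",
         paste(names(gs)[gs > 1], collapse = ", "))
  invisible(sheet)
}

#' Read a probe annotation table
#'
#' Expects columns `probe_id`, `chrom`, `pos`, `gene` and the flag columns
#' `sex_chromosome`, `snp_probe`, `snp_at_cpg`, `cross_reactive` (0/1 or
#' TRUE/FALSE; absent flag columns default to all-FALSE). The
#' `sex_chromosome` flag is forced consistent with `chrom` being chrX/chrY.
#' Coordinates are 1-based hg19 positions.
#'
#' @param path path to a TSV annotation table.
#' @return data frame with logical flag columns.
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop("annotation lacks column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  if (anyDuplicated(df$probe_id)) stop("duplicate probe ids in annotation")
  df$pos <- as.integer(df$pos)
  if (any(is.na(df$pos) | df$pos < 1)) stop("annotation positions must be integers >= 1")
  if (!"gene" %in% names(df)) df$gene <- ""
  df$gene[is.na(df$gene)] <- ""
  for (fl in c("sex_chromosome", "snp_probe", "snp_at_cpg", "cross_reactive")) {
    if (!fl %in% names(df)) df[[fl]] <- FALSE
    df[[fl]] <- as.logical(as.integer(as.logical(df[[fl]])))
    df[[fl]][is.na(df[[fl]])] <- FALSE
  }
  df$sex_chromosome <- df$chrom %in% c("chrX", "chrY")
  df[, c("probe_id", "chrom", "pos", "gene",
         "sex_chromosome", "snp_probe", "snp_at_cpg", "cross_reactive")]
}

#' Read a QC-metric matrix (detection p-values or beadcounts)
#'
#' Same layout as a beta matrix: probe ids in the first column, sample ids
#' in the header. No \[0,1\] bound is enforced (beadcounts are counts).
#'
#' @param path path to a TSV file.
#' @return numeric matrix, probes x samples.
#' @export
read_qc_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m))) stop("duplicate probe ids in QC matrix")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in QC matrix")
  m
}
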