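#' Packaged worked example: 25 candidate CpGs in 14 converters
#'
#' The package ships, as plain-text fixtures, the published worked example
#' of the private-epimutation caller: a set of 25 candidate CpGs that
#' passed the variance-scan filters in the converter group of a
#' longitudinal ultra-high-risk cohort, together with the per-subject
#' deviations of each converter's beta-value from the converter-group
#' median, before and after the clinical transition. Deviations are stored
#' exactly as printed, at 2 decimal places; comparisons against them
#' should use a 2-decimal tolerance.
#'
#' @return a list with elements
#'   \describe{
#'     \item{before}{25 x 14 numeric matrix of deviations at the
#'       baseline-analog timepoint (probes x subjects).}
#'     \item{after}{25 x 14 numeric matrix at the post-transition
#'       timepoint.}
#'     \item{annotation}{data frame `probe_id`, `p_fdr` (FDR-adjusted
#'       F-test p at follow-up), `gene` (UCSC symbol(s), "" for
#'       intergenic probes).}
#'   }
#' @examples
#' fx <- load_table3_fixture()
#' dim(fx$after)                       # 25 x 14
#' fx$after["cg18404925", "IC01.055"]  # 0.63, the RAC1 outlier
#' @export
load_table3_fixture <- function() {
  dir <- system.file("extdata", package = "methvar")
  read_block <- function(f) {
    df <- read.delim(file.path(dir, f), sep = "\t", header = TRUE,
                     check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    m
  }
  before <- read_block("table3_before.tsv")
  after <- read_block("table3_after.tsv")
  ann <- read.delim(file.path(dir, "table2_candidates.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
  ann$gene[is.na(ann$gene)] <- ""
  stopifnot(identical(rownames(before), ann$probe_id),
            identical(rownames(after), ann$probe_id),
            identical(colnames(before), colnames(after)))
  list(before = before, after = after, annotation = ann)
}
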