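#' Export probe-level results as a BED file
#'
#' Writes one 0-based half-open single-base interval per probe:
#' `chrom  pos-1  pos  probe_id  score`. Annotation positions are 1-based,
#' so a probe annotated at chr8:129702875 yields the interval
#' `chr8 129702874 129702875`. The score column carries `results[[score_col]]`
#' rescaled linearly to \[0, 1000\] (min -> 0, max -> 1000; constant
#' columns map to 0). Probes without an annotation entry are not written
#' and not silently dropped: they go to a `<path>.rejects` sidecar, one
#' probe id per line.
#'
#' @param results data frame with a `probe_id` column and a numeric
#'   statistic column.
#' @param annotation probe annotation data frame (see
#'   [read_probe_annotation()]).
#' @param path output BED path.
#' @param score_col name of the statistic column used for the BED score.
#' @return invisibly, a list with `n_written` and `rejects` (probe ids).
#' @export
export_bed <- function(results, annotation, path, score_col = "statistic") {
  stopifnot(is.data.frame(results), "probe_id" %in% names(results))
  if (nrow(results) == 0) {
    file.create(path)
    return(invisible(list(n_written = 0L, rejects = character(0))))
  }
  if (!score_col %in% names(results))
    stop("no column '", score_col, "' in results")
  idx <- match(results$probe_id, annotation$probe_id)
  rejects <- results$probe_id[is.na(idx)]
  keep <- !is.na(idx)
  res <- results[keep, , drop = FALSE]
  ann <- annotation[idx[keep], , drop = FALSE]
  s <- res[[score_col]]
  rng <- range(s)
  score <- if (diff(rng) == 0) rep(0L, length(s)) else
    as.integer(round(1000 * (s - rng[1]) / diff(rng)))
  bed <- data.frame(chrom = ann$chrom,
                    start = ann$pos - 1L,
                    end = ann$pos,
                    name = res$probe_id,
                    score = score,
                    stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (length(rejects) > 0)
    writeLines(rejects, paste0(path, ".rejects"))
  invisible(list(n_written = nrow(bed), rejects = rejects))
}
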