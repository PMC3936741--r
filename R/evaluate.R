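## Evaluation against a reference annotation: confirmed (exact-match) vs
## novel junction counts across score thresholds, and coding/noncoding
## categorization of junctions relative to annotated CDS.

#' Evaluate scored junctions against annotated introns
#'
#' At each threshold S, the junctions with score strictly greater than S are
#' split into confirmed (exact boundary and strand match to an annotated
#' intron) and novel counts, yielding the points of a non-normalized
#' ROC-style curve. The same machinery applies to depth-ranked junction sets
#' by passing depth as the score.
#'
#' @param scored data.frame with junction key columns and a \code{score}.
#' @param annotated_introns data.frame of annotated introns (\code{seq},
#'   \code{donor_pos}, \code{acceptor_end}, \code{strand}).
#' @param thresholds numeric vector of thresholds (default
#'   \code{seq(0, 1, by = 0.05)}).
#' @return data.frame of class \code{eval_report}: \code{threshold},
#'   \code{confirmed}, \code{novel}; attribute \code{n} holds the candidate
#'   count.
#' @export
evaluate_vs_annotation <- function(scored, annotated_introns,
                                   thresholds = seq(0, 1, by = 0.05)) {
  ann_key <- junction_key(annotated_introns)
  is_conf <- junction_key(scored) %in% ann_key
  thresholds <- sort(thresholds)
  tp <- fp <- integer(length(thresholds))
  for (i in seq_along(thresholds)) {
    sel <- scored$score > thresholds[i]
    tp[i] <- sum(sel & is_conf)
    fp[i] <- sum(sel & !is_conf)
  }
  out <- data.frame(threshold = thresholds, confirmed = tp, novel = fp)
  ## nesting invariant: raising S can only shrink both counts
  stopifnot(all(diff(out$confirmed) <= 0), all(diff(out$novel) <= 0),
            all(out$confirmed + out$novel <= nrow(scored)))
  attr(out, "n") <- nrow(scored)
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report over %d candidates\n", attr(x, "n")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write / read an evaluation report TSV
#'
#' @param report an \code{eval_report}.
#' @param path file path.
#' @export
write_eval_tsv <- function(report, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# candidates\t%d", attr(report, "n")), con)
  write.table(as.data.frame(report), con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eval_tsv
#' @export
read_eval_tsv <- function(path) {
  first <- readLines(path, n = 1)
  d <- read.delim(path, skip = 1, stringsAsFactors = FALSE)
  attr(d, "n") <- as.integer(sub("# candidates\t", "", first, fixed = TRUE))
  class(d) <- c("eval_report", "data.frame")
  d
}

#' Coding / noncoding status of junctions
#'
#' A junction is noncoding only if, in every annotated isoform overlapping
#' it, the exonic bases immediately flanking both splice sites lie outside
#' the CDS; otherwise it is coding. Junctions outside all transcripts are
#' noncoding.
#'
#' @param junctions data.frame with \code{seq}, \code{donor_pos},
#'   \code{acceptor_end}.
#' @param annotation an \code{annotation} (needs \code{exons} and \code{cds}
#'   with a \code{transcript} column, as from \code{\link{parse_annotation}}).
#' @return character vector "coding" / "noncoding".
#' @export
label_coding_status <- function(junctions, annotation) {
  ex <- annotation$exons
  cds <- annotation$cds
  tx_span <- do.call(rbind, lapply(split(ex, ex$transcript), function(e)
    data.frame(transcript = e$transcript[1], seq = e$seq[1],
               start = min(e$start), end = max(e$end), stringsAsFactors = FALSE)))
  out <- character(nrow(junctions))
  for (i in seq_len(nrow(junctions))) {
    p_l <- junctions$donor_pos[i] - 1L
    p_r <- junctions$acceptor_end[i]
    ov <- tx_span[tx_span$seq == junctions$seq[i] &
                    tx_span$start < junctions$acceptor_end[i] &
                    tx_span$end > junctions$donor_pos[i], , drop = FALSE]
    if (!nrow(ov)) { out[i] <- "noncoding"; next }
    coding <- FALSE
    for (tid in ov$transcript) {
      cc <- cds[cds$transcript == tid, , drop = FALSE]
      in_cds <- function(p) any(cc$start <= p & p < cc$end)
      if (nrow(cc) && (in_cds(p_l) || in_cds(p_r))) { coding <- TRUE; break }
    }
    out[i] <- if (coding) "coding" else "noncoding"
  }
  out
}

#' Write the standard output bundle
#'
#' @param alignments alignment table (SAM output).
#' @param scored scored junction table (BED12 + feature TSV).
#' @param report an \code{eval_report} or NULL.
#' @param genome named character vector.
#' @param dir output directory.
#' @param reads optional read sequences for SAM SEQ fields.
#' @return named vector of written paths.
#' @export
write_outputs <- function(alignments, scored, report, genome, dir, reads = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sam = file.path(dir, "alignments.sam"),
             bed = file.path(dir, "junctions.bed"),
             tsv = file.path(dir, "junctions.tsv"),
             eval = file.path(dir, "evaluation.tsv"))
  write_sam(alignments, genome, paths["sam"], reads)
  write_junction_bed(scored, paths["bed"],
                     score = if ("score" %in% names(scored)) scored$score)
  write_feature_tsv(scored, paths["tsv"])
  if (!is.null(report)) write_eval_tsv(report, paths["eval"]) else paths <- paths[1:3]
  paths
}
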