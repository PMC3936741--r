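## The full pipeline in the method's order: ungapped alignment, then
## anchor-and-extend gapped alignment, then pseudo-transcript remapping of
## still-unmapped reads and paired-end filtering, then junction
## featurization, classification and thresholding.

#' Run the complete splice-junction discovery pipeline
#'
#' @param genome named character vector (or a FASTA path).
#' @param reads1 named character vector of reads (or a FASTQ path); ids
#'   should end in "/1" for paired data.
#' @param reads2 optional second-mate reads (or FASTQ path).
#' @param models a \code{splice_models} object (or a parameter-file path).
#' @param predictions a \code{gene_predictions} object (or a GFF3 path of ab
#'   initio predictions).
#' @param annotation optional reference \code{annotation} (or GFF3 path) for
#'   evaluation.
#' @param constraints an \code{\link{sj_constraints}}.
#' @param threshold posterior score threshold S (default 0.5).
#' @param train_size,dev_size,lattice,folds classifier settings, see
#'   \code{\link{fit_junction_classifier}}.
#' @param seed RNG seed for the classifier stage.
#' @return list of class \code{sj_pipeline} with alignments, candidates,
#'   feature table, fitted classifier, scored table, accepted junctions and
#'   (if annotation given) an \code{eval_report}.
#' @export
run_pipeline <- function(genome, reads1, reads2 = NULL, models, predictions,
                         annotation = NULL, constraints = sj_constraints(),
                         threshold = 0.5, train_size = 10000L, dev_size = 5000L,
                         lattice = expand.grid(ln_c = -9:3, ln_gamma = -9:3),
                         folds = 5L, seed = 1L) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- read_genome_fasta(genome)
  genome <- normalize_genome(genome)
  if (is.character(reads1) && length(reads1) == 1 && file.exists(reads1))
    reads1 <- read_fastq(reads1)
  if (is.character(reads2) && length(reads2) == 1 && file.exists(reads2))
    reads2 <- read_fastq(reads2)
  if (is.character(models) && length(models) == 1) models <- read_splice_params(models)
  if (is.character(predictions) && length(predictions) == 1)
    predictions <- as_gene_predictions(parse_annotation(predictions))
  if (is.character(annotation) && length(annotation) == 1)
    annotation <- parse_annotation(annotation)

  paired <- !is.null(reads2)
  if (paired) {
    if (!all(grepl("/1$", names(reads1)))) names(reads1) <- paste0(names(reads1), "/1")
    if (!all(grepl("/2$", names(reads2)))) names(reads2) <- paste0(names(reads2), "/2")
  }
  reads <- c(reads1, reads2)
  cs <- constraints
  L <- max(nchar(reads))
  k <- max(8L, min(20L, min(nchar(reads)) %/% (cs$max_mismatch + 1L)))
  index <- genome_index(genome, k)

  step12 <- align_reads(reads, index, models, cs)
  aln <- step12$alignments
  if (nrow(aln)) aln$source <- "genome"

  ## step 3: pseudo-transcript remapping of still-unmapped reads
  cand0 <- aggregate_junctions(aln, genome)
  remapped <- if (length(step12$unmapped) && nrow(cand0$junctions)) {
    pt <- build_pseudo_transcripts(cand0$junctions, genome, L)
    remap_unmapped(reads[step12$unmapped], pt, cs)
  } else { a <- empty_alignments(); a$source <- character(0); a }
  aln <- rbind(aln, remapped)
  if (paired) aln <- filter_pairs(aln)

  candidates <- aggregate_junctions(aln, genome)
  features <- junction_features(candidates, aln, genome, models, predictions)

  classifier <- fit_junction_classifier(features, predictions$introns,
                                        train_size = train_size, dev_size = dev_size,
                                        lattice = lattice, folds = folds, seed = seed)
  scored <- predict(classifier, features)
  thr <- score_and_threshold(scored, threshold)
  report <- if (!is.null(annotation))
    evaluate_vs_annotation(scored, annotation$introns) else NULL

  structure(list(alignments = aln, unmapped = setdiff(step12$unmapped,
                                                      unique(remapped$read_id)),
                 candidates = candidates, features = features,
                 classifier = classifier, scored = scored,
                 accepted = thr$accepted, report = report,
                 threshold = threshold, constraints = cs), class = "sj_pipeline")
}

#' @export
print.sj_pipeline <- function(x, ...) {
  cat(sprintf(paste0("sj_pipeline: %d alignments (%d spliced), %d unmapped reads\n",
                     "  %d junction candidates -> %d accepted at S = %g\n"),
              nrow(x$alignments), sum(x$alignments$spliced), length(x$unmapped),
              nrow(x$features), nrow(x$accepted), x$threshold))
  if (!is.null(x$report)) {
    at <- which.min(abs(x$report$threshold - x$threshold))
    cat(sprintf("  at S = %g: %d confirmed, %d novel\n", x$report$threshold[at],
                x$report$confirmed[at], x$report$novel[at]))
  }
  invisible(x)
}
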