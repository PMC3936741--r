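## Standard-format I/O. FASTA/FASTQ go through Biostrings; GFF3 import goes
## through rtracklayer; SAM, junction BED12 and the TSV tables are written
## directly (no installed package writes them from plain tables).

#' Read a multi-record FASTA genome
#'
#' @param path FASTA file.
#' @return named character vector, uppercase-normalized.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_genome_fasta
#' @param genome named character vector to write.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read / write FASTQ reads
#'
#' @param path FASTQ file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fastq
#' @param reads named character vector of read sequences.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

gff3_escape <- function(x) gsub(";", "%3B", gsub("=", "%3D", x))

#' Write a truth annotation as GFF3
#'
#' Emits gene, mRNA, exon and CDS features (1-based closed coordinates) with
#' Parent attributes, one isoform per gene.
#'
#' @param annotation list with \code{genes}, \code{exons}, \code{cds}
#'   data.frames in 0-based half-open coordinates.
#' @param path output file.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  lines <- character(0)
  for (i in seq_len(nrow(annotation$genes))) {
    g <- annotation$genes[i, ]
    ex <- annotation$exons[annotation$exons$gene_id == g$gene_id, , drop = FALSE]
    cds <- annotation$cds[annotation$cds$gene_id == g$gene_id, , drop = FALSE]
    span <- c(min(ex$start), max(ex$end))
    tid <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s", g$seq, span[1] + 1, span[2],
              g$strand, gff3_escape(g$gene_id)),
      sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s", g$seq, span[1] + 1,
              span[2], g$strand, gff3_escape(tid), gff3_escape(g$gene_id)),
      sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s", ex$seq, ex$start + 1,
              ex$end, g$strand, gff3_escape(tid)),
      if (nrow(cds)) sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s", cds$seq,
                             cds$start + 1, cds$end, g$strand, gff3_escape(tid)))
  }
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @param predictions a \code{\link{gene_predictions}} object (its CDS exons
#'   are written as both exon and CDS features).
#' @export
write_predictions_gff3 <- function(predictions, path) {
  ann <- list(genes = predictions$genes, exons = predictions$exons,
              cds = predictions$exons)
  write_annotation_gff3(ann, path)
}

#' Parse a GFF3 annotation
#'
#' Derives introns as the gaps between consecutive exons of each transcript
#' (deduplicated across isoforms) and keeps CDS intervals per isoform for
#' coding-status calls. Coordinates are converted to 0-based half-open.
#'
#' @param path GFF3 file with exon (and optionally CDS) features grouped by
#'   transcript via Parent attributes.
#' @return list of class \code{annotation}: \code{genes}, \code{exons},
#'   \code{cds}, \code{introns} data.frames.
#' @export
parse_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  d <- as.data.frame(gr)
  d$Parent <- vapply(as.list(d$Parent %||% rep(NA_character_, nrow(d))),
                     function(p) if (length(p)) as.character(p)[1] else NA_character_, "")
  types <- as.character(d$type)
  tx <- d[types %in% c("mRNA", "transcript"), , drop = FALSE]
  tx_gene <- setNames(tx$Parent, tx$ID)
  ex <- d[types == "exon", , drop = FALSE]
  if (nrow(ex)) {
    orphan <- is.na(ex$Parent) | !nzchar(ex$Parent)
    if (any(orphan))
      stop(sprintf("orphan exon without Parent at feature %d of %s",
                   which(types == "exon")[which(orphan)[1]], basename(path)))
  }
  cds <- d[types == "CDS", , drop = FALSE]
  genes <- d[types == "gene", , drop = FALSE]
  gene_df <- data.frame(gene_id = genes$ID %||% character(0),
                        seq = as.character(genes$seqnames),
                        strand = as.character(genes$strand), stringsAsFactors = FALSE)
  exon_df <- data.frame(transcript = ex$Parent,
                        gene_id = unname(tx_gene[ex$Parent]),
                        seq = as.character(ex$seqnames),
                        start = ex$start - 1L, end = ex$end,
                        strand = as.character(ex$strand), stringsAsFactors = FALSE)
  cds_df <- if (nrow(cds)) data.frame(transcript = cds$Parent,
                                      gene_id = unname(tx_gene[cds$Parent]),
                                      seq = as.character(cds$seqnames),
                                      start = cds$start - 1L, end = cds$end,
                                      strand = as.character(cds$strand),
                                      stringsAsFactors = FALSE)
  else data.frame(transcript = character(0), gene_id = character(0), seq = character(0),
                  start = integer(0), end = integer(0), strand = character(0))
  introns <- list()
  for (tid in unique(exon_df$transcript)) {
    e <- exon_df[exon_df$transcript == tid, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (any(e$start[-1] < e$end[-nrow(e)]))
      stop(sprintf("overlapping exons in transcript %s of %s", tid, basename(path)))
    if (nrow(e) > 1)
      introns[[tid]] <- data.frame(gene_id = e$gene_id[1], seq = e$seq[1],
                                   donor_pos = e$end[-nrow(e)], acceptor_end = e$start[-1],
                                   strand = e$strand[1], stringsAsFactors = FALSE)
  }
  introns <- if (length(introns)) unique(do.call(rbind, introns)) else
    data.frame(gene_id = character(0), seq = character(0), donor_pos = integer(0),
               acceptor_end = integer(0), strand = character(0))
  rownames(introns) <- NULL
  structure(list(genes = gene_df, exons = exon_df, cds = cds_df, introns = introns),
            class = "annotation")
}

#' Convert a parsed annotation into a gene-prediction set
#'
#' Uses the CDS intervals (falling back to exons when no CDS is present) as
#' the predicted coding exons for the indicator features.
#'
#' @param annotation an \code{annotation} from \code{\link{parse_annotation}}
#'   or the simulator.
#' @return a \code{\link{gene_predictions}} object.
#' @export
as_gene_predictions <- function(annotation) {
  ex <- if (nrow(annotation$cds)) annotation$cds else annotation$exons
  gene_predictions(annotation$genes, ex[c("gene_id", "seq", "start", "end")],
                   annotation$introns)
}

#' Write alignments as SAM
#'
#' Emits a minimal valid SAM: header with one SQ line per genome sequence,
#' N CIGAR operations for introns, NM mismatch tags and an XS:A strand tag on
#' spliced records.
#'
#' @param alignments alignment data.frame.
#' @param genome named character vector (for the header and SEQ fields).
#' @param path output file.
#' @param reads optional named character vector of read sequences.
#' @export
write_sam <- function(alignments, genome, path, reads = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)),
               "@PG\tID:splicefinder\tPN:splicefinder"), con)
  if (!nrow(alignments)) return(invisible(path))
  lines <- character(nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    b <- decode_blocks(a$blocks)
    cig <- paste0(b[1, "len"], "M")
    if (nrow(b) > 1) for (j in 2:nrow(b)) {
      gap <- b[j, "start"] - (b[j - 1, "start"] + b[j - 1, "len"])
      cig <- paste0(cig, gap, "N", b[j, "len"], "M")
    }
    mate <- if (grepl("/1$", a$read_id)) 1L else if (grepl("/2$", a$read_id)) 2L else 0L
    flag <- 0L
    if (a$strand == "-") flag <- flag + 16L
    if (mate > 0) flag <- flag + 1L + (if (mate == 1) 64L else 128L)
    sq <- "*"
    if (!is.null(reads) && a$read_id %in% names(reads)) {
      sq <- reads[[a$read_id]]
      if (a$strand == "-") sq <- revcomp(sq)
    }
    tags <- sprintf("NM:i:%d", a$mismatches)
    if (isTRUE(a$spliced)) {
      ji <- blocks_to_introns(a$blocks)
      g <- genome[[a$seq]]
      dn <- substr(g, ji[1, 1] + 1, ji[1, 1] + 2)
      ac <- substr(g, ji[1, 2] - 1, ji[1, 2])
      cls <- classify_dinuc(dn, ac)
      xs <- if (is.na(cls)) "+" else if (cls <= 3) "+" else "-"
      tags <- paste0(tags, "\tXS:A:", xs)
    }
    lines[i] <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\t%s",
                        sub("/[12]$", "", a$read_id), flag, a$seq, b[1, "start"] + 1L,
                        cig, sq, tags)
  }
  writeLines(lines, con)
  invisible(path)
}

#' Write / read a junction BED12
#'
#' Junctions are written TopHat-style with one exonic base on each side as
#' the two blocks; the score column holds \code{round(1000 * score)}.
#'
#' @param junctions data.frame with \code{seq}, \code{donor_pos},
#'   \code{acceptor_end}, \code{strand}.
#' @param path output file.
#' @param score optional numeric scores in [0, 1].
#' @param name optional feature names.
#' @export
write_junction_bed <- function(junctions, path, score = NULL, name = NULL) {
  n <- nrow(junctions)
  sc <- if (is.null(score)) rep(0L, n) else as.integer(round(1000 * score))
  nm <- if (is.null(name)) sprintf("JUNC%05d", seq_len(n)) else name
  start <- junctions$donor_pos - 1L
  end <- junctions$acceptor_end + 1L
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t0,0,0\t2\t1,1\t0,%d",
                   junctions$seq, start, end, nm, sc, junctions$strand,
                   start, end, junctions$acceptor_end - start)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_junction_bed
#' @export
read_junction_bed <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  sizes <- strsplit(d$V11, ",")
  offs <- strsplit(d$V12, ",")
  donor <- d$V2 + as.integer(vapply(sizes, `[`, "", 1))
  acceptor <- d$V2 + as.integer(vapply(offs, `[`, "", 2))
  data.frame(seq = d$V1, donor_pos = donor, acceptor_end = acceptor,
             strand = d$V6, name = d$V4, score = d$V5 / 1000,
             stringsAsFactors = FALSE)
}

#' Write / read the junction feature/score TSV
#'
#' Human-readable coordinates: donor and acceptor columns are the 1-based
#' closed first/last intronic bases.
#'
#' @param features feature table (optionally with decision/score columns).
#' @param path output file.
#' @export
write_feature_tsv <- function(features, path) {
  out <- features
  out$donor <- out$donor_pos + 1L
  out$acceptor <- out$acceptor_end
  out$donor_pos <- out$acceptor_end <- NULL
  first <- c("seq", "donor", "acceptor", "strand")
  out <- out[c(first, setdiff(names(out), first))]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  d$donor_pos <- d$donor - 1L
  d$acceptor_end <- d$acceptor
  d$donor <- d$acceptor <- NULL
  d
}
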