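## Step 1-2 of the pipeline: ungapped alignment against a k-mer genome index,
## then anchor-and-extend gapped alignment of reads whose segments flag a
## splice junction. All genome coordinates are 0-based half-open on the
## forward strand; `strand` is the strand the read aligned to; each intron's
## own strand is implied by its terminal dinucleotides.

#' Alignment constraint set
#'
#' @param min_overhang minimum exonic nt a read must contribute on each side
#'   of a junction (default 8).
#' @param min_intron,max_intron intron length bounds in nt; introns must
#'   satisfy \code{min_intron <= len < max_intron} (defaults 20 and 10000).
#' @param max_mismatch maximum substitutions per read alignment (default 2).
#' @param seg_len read segment length for anchor finding, 18-25 nt (default 25).
#' @param max_hits maximum placements kept per read (default 10).
#' @param allow_semi also accept semi-canonical GC-AG / AT-AC introns
#'   (default TRUE); canonical GT-AG is always accepted.
#' @return a list of class \code{sj_constraints}.
#' @export
sj_constraints <- function(min_overhang = 8L, min_intron = 20L, max_intron = 10000L,
                           max_mismatch = 2L, seg_len = 25L, max_hits = 10L,
                           allow_semi = TRUE) {
  if (seg_len < 18 || seg_len > 25) stop("seg_len must be between 18 and 25 nt")
  if (!max_mismatch %in% 0:2) stop("max_mismatch must be 0, 1 or 2")
  if (max_intron > 10000L) stop("max_intron must be <= 10000 nt")
  structure(list(min_overhang = as.integer(min_overhang), min_intron = as.integer(min_intron),
                 max_intron = as.integer(max_intron), max_mismatch = as.integer(max_mismatch),
                 seg_len = as.integer(seg_len), max_hits = as.integer(max_hits),
                 allow_semi = isTRUE(allow_semi)), class = "sj_constraints")
}

#' Build a k-mer genome index
#'
#' Hash index from every k-mer to its genome positions; minus-strand hits are
#' resolved through reverse-complement lookup.
#'
#' @param genome named character vector of genome sequences.
#' @param k seed length (default 20; must not exceed the shortest sequence).
#' @return object of class \code{genome_index}.
#' @export
genome_index <- function(genome, k = 20L) {
  genome <- normalize_genome(genome)
  if (k < 8) stop("k must be >= 8")
  if (k > min(nchar(genome))) stop("k exceeds the shortest genome sequence")
  structure(list(ptr = cpp_index_build(genome, as.integer(k)),
                 genome = genome, k = as.integer(k)), class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("genome_index: %d sequence(s), %s nt total, k = %d\n",
              length(x$genome), format(sum(nchar(x$genome)), big.mark = ","), x$k))
  invisible(x)
}

#' Look up a k-mer in a genome index
#'
#' @param index a \code{genome_index}.
#' @param kmer character vector of k-mers (length must equal \code{index$k}).
#' @return data.frame with columns \code{kmer}, \code{seq}, \code{pos}
#'   (0-based) and \code{strand}.
#' @export
index_lookup <- function(index, kmer) {
  hits <- cpp_index_lookup(index$ptr, toupper(kmer))
  data.frame(kmer = kmer[hits$query], seq = names(index$genome)[hits$seq],
             pos = hits$pos, strand = hits$strand, stringsAsFactors = FALSE)
}

#' Split a read into non-overlapping segments
#'
#' Consecutive segments of \code{seg_len} nt cover the read; a final remainder
#' shorter than \code{seg_len} is appended to the last segment. A read shorter
#' than \code{seg_len} yields a single whole-read segment.
#'
#' @param read read sequence (single string).
#' @param seg_len segment length, 18-25 nt.
#' @return data.frame with columns \code{offset} (0-based) and \code{length}.
#' @export
segment_read <- function(read, seg_len = 25L) {
  L <- nchar(read)
  if (L <= seg_len) return(data.frame(offset = 0L, length = L))
  n <- L %/% seg_len
  offs <- (seq_len(n) - 1L) * seg_len
  lens <- rep(as.integer(seg_len), n)
  lens[n] <- L - offs[n]
  data.frame(offset = as.integer(offs), length = lens)
}

#' Ungapped read placement
#'
#' Places each full read on the genome with at most \code{max_mismatch}
#' substitutions, on either strand, by exact k-mer seeding plus Hamming
#' verification. Seeding is exhaustive when \code{index$k <=
#' floor(L / (max_mismatch + 1))}.
#'
#' @param reads named character vector of read sequences.
#' @param index a \code{genome_index}.
#' @param max_mismatch 0, 1 or 2 (default 2).
#' @param max_hits maximum placements returned per read (default 10).
#' @return alignment data.frame (columns \code{read_id}, \code{seq},
#'   \code{strand}, \code{blocks}, \code{mismatches}, \code{spliced}).
#' @export
align_ungapped <- function(reads, index, max_mismatch = 2L, max_hits = 10L) {
  if (!max_mismatch %in% 0:2) stop("max_mismatch must be 0, 1 or 2")
  if (any(nchar(reads) < index$k)) stop("reads shorter than index k cannot be seeded")
  hits <- cpp_place(index$ptr, unname(toupper(reads)), as.integer(max_mismatch),
                    as.integer(max_hits))
  if (!nrow(hits)) return(empty_alignments())
  ids <- names(reads) %||% as.character(seq_along(reads))
  L <- nchar(reads)[hits$query]
  data.frame(read_id = ids[hits$query], seq = names(index$genome)[hits$seq],
             strand = hits$strand,
             blocks = paste0(hits$pos, ":", L),
             mismatches = hits$mismatches, spliced = FALSE, stringsAsFactors = FALSE)
}

## flatten PSFM parameters for the C++ tie-break scorer
psfm_cpars <- function(psfm) {
  list(order = psfm$order, width = psfm$width, marg = as.numeric(psfm$marginal),
       cond = if (psfm$order == 1L) as.numeric(psfm$cond) else numeric(0))
}

#' Anchor-and-extend gapped alignment
#'
#' Segments each read, places segments ungapped (the anchors), and searches
#' the anchor-delimited genomic region for intron placements beginning and
#' ending with canonical (GT-AG) or semi-canonical (GC-AG, AT-AC)
#' dinucleotides, whose orientation defines the junction strand. Among
#' equal-mismatch placements, ties are broken by higher donor+acceptor PSFM
#' score, then by smaller intron. Reads whose unaligned portion spans two
#' close junctions stay unmapped and are left to the remapping stage.
#'
#' @param read read sequence(s); a named vector aligns every read.
#' @param index a \code{genome_index}.
#' @param models optional \code{splice_models} used for tie-breaking.
#' @param constraints an \code{\link{sj_constraints}} object.
#' @param read_id identifier(s) used in the output (defaults to names).
#' @return alignment data.frame (0 rows for reads that stay unmapped).
#' @export
anchor_extend <- function(read, index, models = NULL, constraints = sj_constraints(),
                          read_id = NULL) {
  cs <- constraints
  read <- toupper(read)
  read_id <- read_id %||% names(read) %||% as.character(seq_along(read))
  don <- acc <- list()
  bg <- rep(0.25, 4)
  if (!is.null(models)) {
    don <- psfm_cpars(models$donor)
    acc <- psfm_cpars(models$acceptor)
    bg <- as.numeric(models$background$probs)
  }
  hits <- cpp_spliced_align(index$ptr, unname(read), cs$seg_len, cs$max_mismatch,
                            cs$min_intron, cs$max_intron, cs$min_overhang,
                            cs$max_hits, cs$allow_semi, don, acc, bg)
  if (!nrow(hits)) return(empty_alignments())
  data.frame(read_id = read_id[hits$read], seq = names(index$genome)[hits$seq],
             strand = hits$strand, blocks = hits$blocks,
             mismatches = hits$mismatches, spliced = TRUE, stringsAsFactors = FALSE)
}


empty_alignments <- function() {
  data.frame(read_id = character(0), seq = character(0), strand = character(0),
             blocks = character(0), mismatches = integer(0), spliced = logical(0),
             stringsAsFactors = FALSE)
}

#' Align a read set: ungapped first, then anchor-and-extend
#'
#' @param reads named character vector of reads.
#' @param index a \code{genome_index}.
#' @param models optional \code{splice_models} for tie-breaking.
#' @param constraints an \code{\link{sj_constraints}}.
#' @return list with \code{alignments} (ungapped and spliced rows) and
#'   \code{unmapped} (read ids with no placement).
#' @export
align_reads <- function(reads, index, models = NULL, constraints = sj_constraints()) {
  cs <- constraints
  ids <- names(reads) %||% as.character(seq_along(reads))
  names(reads) <- ids
  ung <- align_ungapped(reads, index, cs$max_mismatch, cs$max_hits)
  todo <- setdiff(ids, unique(ung$read_id))
  spl <- if (length(todo)) anchor_extend(reads[todo], index, models, cs, read_id = todo)
         else empty_alignments()
  aln <- rbind(ung, spl)
  list(alignments = aln, unmapped = setdiff(ids, unique(aln$read_id)))
}

#' Introns implied by spliced alignments
#'
#' @param alignments alignment data.frame.
#' @param genome named character vector (to classify terminal dinucleotides).
#' @return data.frame with one row per (alignment, intron): \code{read_id},
#'   \code{seq}, \code{donor_pos}, \code{acceptor_end}, \code{strand} (the
#'   junction strand from the dinucleotides), \code{class}, plus the flanking
#'   block lengths \code{left_overhang}, \code{right_overhang}.
#' @export
alignment_introns <- function(alignments, genome) {
  empty <- data.frame(read_id = character(0), seq = character(0), donor_pos = integer(0),
                      acceptor_end = integer(0), strand = character(0), class = integer(0),
                      left_overhang = integer(0), right_overhang = integer(0))
  spl <- alignments[alignments$spliced, , drop = FALSE]
  if (!nrow(spl)) return(empty)
  parts <- strsplit(spl$blocks, ",", fixed = TRUE)
  nb <- lengths(parts)
  flat <- matrix(as.integer(unlist(strsplit(unlist(parts), ":", fixed = TRUE))),
                 ncol = 2, byrow = TRUE)
  row_of <- rep(seq_len(nrow(spl)), nb)
  ## intron j of an alignment sits between its blocks j and j+1
  last_of_row <- cumsum(nb)
  is_last <- seq_len(nrow(flat)) %in% last_of_row
  left_idx <- which(!is_last)
  if (!length(left_idx)) return(empty)
  right_idx <- left_idx + 1L
  ri <- row_of[left_idx]
  d <- flat[left_idx, 1] + flat[left_idx, 2]
  a <- flat[right_idx, 1]
  g <- genome[spl$seq[ri]]
  dn <- substr(g, d + 1, d + 2)
  ac <- substr(g, a - 1, a)
  cls <- classify_dinuc(dn, ac)
  data.frame(read_id = spl$read_id[ri], seq = spl$seq[ri], donor_pos = d,
             acceptor_end = a,
             strand = ifelse(is.na(cls) | cls <= 3, "+", "-"), class = cls,
             left_overhang = flat[left_idx, 2], right_overhang = flat[right_idx, 2],
             stringsAsFactors = FALSE)
}

classify_dinuc <- function(donor_dn, acceptor_dn) {
  pair <- paste(donor_dn, acceptor_dn)
  cls <- match(pair, c("GT AG", "GC AG", "AT AC", "CT AC", "CT GC", "GT AT"))
  cls
}
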