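## Step 3 of the pipeline: rescue reads that failed both ungapped and
## anchor-and-extend alignment by aligning them to pseudo-transcripts built
## around the junctions predicted so far, then project transcript placements
## back to genome coordinates and apply paired-end consistency filters.

## walk the genome from `from` in direction `dir` (-1 upstream, +1 downstream)
## collecting `need` exonic nt, splicing out the introns given by the
## parallel vectors spl_d (donor_pos) / spl_a (acceptor_end). Returns a
## blocks matrix (start, len).
walk_exonic <- function(seq_len_, from, need, dir, spl_d, spl_a) {
  bs <- bl <- integer(0)
  p <- from
  while (need > 0) {
    if (dir < 0) {
      if (p <= 0) break
      ok <- spl_a <= p
      stop_at <- if (any(ok)) max(spl_a[ok]) else 0L
      start <- max(0L, p - need, stop_at)
      if (p - start > 0) {
        bs <- c(start, bs); bl <- c(p - start, bl)
        need <- need - (p - start)
      }
      if (need > 0 && any(ok) && start == stop_at) {
        p <- spl_d[ok][which.max(spl_a[ok])]
      } else break
    } else {
      if (p >= seq_len_) break
      ok <- spl_d >= p
      stop_at <- if (any(ok)) min(spl_d[ok]) else seq_len_
      end <- min(seq_len_, p + need, stop_at)
      if (end - p > 0) {
        bs <- c(bs, p); bl <- c(bl, end - p)
        need <- need - (end - p)
      }
      if (need > 0 && any(ok) && end == stop_at) {
        p <- spl_a[ok][which.min(spl_d[ok])]
      } else break
    }
  }
  cbind(bs, bl, deparse.level = 0)
}

#' Build pseudo-transcripts around predicted junctions
#'
#' For each junction, concatenates L exonic nt upstream and L exonic nt
#' downstream of the junction (the junction itself always spliced). If n other
#' junctions lie within L nt of the junction's boundaries, all 2^n subsets of
#' them are spliced in or out, giving 2^n transcripts per junction, each of
#' length at most 2L.
#'
#' @param junctions data.frame with columns \code{seq}, \code{donor_pos},
#'   \code{acceptor_end} (0-based half-open introns).
#' @param genome named character vector.
#' @param L read length.
#' @param max_neighbors cap on n; the nearest neighbors are kept (default 8).
#' @return data.frame with one row per pseudo-transcript: \code{junction}
#'   (row index into \code{junctions}), \code{mask}, \code{seq_name},
#'   \code{blocks} (genome blocks string) and \code{sequence}.
#' @export
build_pseudo_transcripts <- function(junctions, genome, L, max_neighbors = 8L) {
  genome <- normalize_genome(genome)
  bad <- junctions$acceptor_end - junctions$donor_pos >= 10000
  if (any(bad)) stop("pseudo-transcripts require intron lengths < 10000 nt")
  out <- list()
  for (sq in unique(junctions$seq)) {
    jn <- junctions[junctions$seq == sq, , drop = FALSE]
    jrow <- which(junctions$seq == sq)
    nb_d <- nb_a <- vector("list", nrow(jn))
    for (i in seq_len(nrow(jn))) {
      self <- jn$donor_pos == jn$donor_pos[i] & jn$acceptor_end == jn$acceptor_end[i]
      dist <- pmin(abs(jn$donor_pos - jn$donor_pos[i]),
                   abs(jn$donor_pos - jn$acceptor_end[i]),
                   abs(jn$acceptor_end - jn$donor_pos[i]),
                   abs(jn$acceptor_end - jn$acceptor_end[i]))
      keep <- which(!self & dist <= L)
      if (length(keep) > max_neighbors)
        keep <- keep[order(dist[keep])[seq_len(max_neighbors)]]
      nb_d[[i]] <- jn$donor_pos[keep]
      nb_a[[i]] <- jn$acceptor_end[keep]
    }
    pt <- cpp_build_pseudo(genome[[sq]], jn$donor_pos, jn$acceptor_end, nb_d, nb_a,
                           as.integer(L))
    if (nrow(pt)) {
      pt$junction <- jrow[pt$junction]
      pt$seq_name <- sq
      out[[length(out) + 1L]] <- pt
    }
  }
  if (!length(out))
    return(data.frame(junction = integer(0), mask = integer(0), seq_name = character(0),
                      blocks = character(0), sequence = character(0)))
  res <- do.call(rbind, out)
  short <- nchar(res$sequence) < 2 * L
  if (any(short))
    warning(sprintf("%d pseudo-transcripts truncated at contig edges", sum(short)))
  res[c("junction", "mask", "seq_name", "blocks", "sequence")]
}

## project a transcript-coordinate interval [pos, pos+len) through a blocks
## map onto genome blocks; returns matrix (start, len) or NULL
project_interval <- function(blocks, pos, len) {
  out <- list()
  toff <- 0L
  for (i in seq_len(nrow(blocks))) {
    b0 <- toff; b1 <- toff + blocks[i, 2]
    lo <- max(pos, b0); hi <- min(pos + len, b1)
    if (hi > lo)
      out[[length(out) + 1L]] <- c(blocks[i, 1] + (lo - b0), hi - lo)
    toff <- b1
  }
  if (!length(out)) return(NULL)
  m <- do.call(rbind, out)
  if (sum(m[, 2]) != len) return(NULL)
  m
}

#' Remap unmapped reads to pseudo-transcripts
#'
#' Reads are placed ungapped on the pseudo-transcript sequences with the same
#' k-mer machinery, and placements are projected through the transcript
#' coordinate maps into genomic spliced alignments. Projected alignments must
#' still satisfy the per-junction overhang rule; duplicates arising from
#' different transcripts are collapsed.
#'
#' @param reads named character vector of unmapped reads.
#' @param transcripts output of \code{\link{build_pseudo_transcripts}}.
#' @param constraints an \code{\link{sj_constraints}}.
#' @param k seed length for the transcript index (defaults to the pipeline's
#'   usual choice given read length and mismatch budget).
#' @return alignment data.frame; remapped rows carry \code{source = "remap"}.
#' @export
remap_unmapped <- function(reads, transcripts, constraints = sj_constraints(), k = NULL) {
  cs <- constraints
  if (!length(reads) || nrow(transcripts) == 0) {
    aln <- empty_alignments(); aln$source <- character(0); return(aln)
  }
  L <- max(nchar(reads))
  k <- k %||% max(8L, min(20L, min(nchar(reads)) %/% (cs$max_mismatch + 1L)))
  ## identical (sequence, blocks) transcripts from different masks or
  ## neighboring junctions are redundant for remapping
  transcripts <- transcripts[!duplicated(paste(transcripts$seq_name, transcripts$blocks)), ,
                             drop = FALSE]
  usable <- nchar(transcripts$sequence) >= k
  transcripts <- transcripts[usable, , drop = FALSE]
  if (!nrow(transcripts)) {
    aln <- empty_alignments(); aln$source <- character(0); return(aln)
  }
  tseqs <- transcripts$sequence
  names(tseqs) <- sprintf("t%d", seq_along(tseqs))
  tidx <- genome_index(tseqs, k)
  hits <- cpp_place(tidx$ptr, unname(toupper(reads)), cs$max_mismatch, 5L * cs$max_hits)
  ids <- names(reads) %||% as.character(seq_along(reads))
  tr_blocks <- lapply(transcripts$blocks, decode_blocks)
  rl_all <- nchar(reads)
  keep <- logical(nrow(hits))
  bstr <- character(nrow(hits))
  spliced <- logical(nrow(hits))
  for (r in seq_len(nrow(hits))) {
    pm <- project_interval(tr_blocks[[hits$seq[r]]], hits$pos[r], rl_all[hits$query[r]])
    if (is.null(pm)) next
    ## overhang rule for every junction crossed
    if (nrow(pm) > 1 && any(pm[, 2] < cs$min_overhang)) next
    gaps <- if (nrow(pm) > 1) pm[-1, 1] - (pm[-nrow(pm), 1] + pm[-nrow(pm), 2]) else integer(0)
    if (any(gaps < cs$min_intron | gaps >= cs$max_intron)) next
    keep[r] <- TRUE
    bstr[r] <- encode_blocks(pm[, 1], pm[, 2])
    spliced[r] <- nrow(pm) > 1
  }
  if (!any(keep)) {
    aln <- empty_alignments(); aln$source <- character(0); return(aln)
  }
  aln <- data.frame(read_id = ids[hits$query[keep]],
                    seq = transcripts$seq_name[hits$seq[keep]],
                    strand = hits$strand[keep], blocks = bstr[keep],
                    mismatches = hits$mismatches[keep], spliced = spliced[keep],
                    stringsAsFactors = FALSE)
  aln <- aln[!duplicated(aln[c("read_id", "seq", "strand", "blocks")]), , drop = FALSE]
  ## keep only best-mismatch placements per read, capped at max_hits
  aln <- aln[aln$mismatches == stats::ave(aln$mismatches, aln$read_id, FUN = min), ,
             drop = FALSE]
  nth <- stats::ave(seq_len(nrow(aln)), aln$read_id, FUN = seq_along)
  aln <- aln[nth <= cs$max_hits, , drop = FALSE]
  rownames(aln) <- NULL
  aln$source <- "remap"
  aln
}

#' Paired-end consistency filter
#'
#' Removes spliced alignments that are not on the opposite strand of a
#' sibling mate's alignment, and spliced alignments violating the coordinate
#' order expected of forward-reverse pairs (the plus-strand mate must start at
#' a lower coordinate than the minus-strand mate). Reads whose mate is
#' unaligned pass unchanged. Applied to a fixpoint, so the filter is
#' idempotent.
#'
#' @param alignments alignment data.frame; read ids must end in "/1" or "/2".
#' @param max_inner_dist maximum allowed mate separation (default 500000,
#'   effectively off for compact genomes).
#' @return the filtered alignment data.frame.
#' @export
filter_pairs <- function(alignments, max_inner_dist = 500000L) {
  if (!nrow(alignments)) return(alignments)
  repeat {
    pair_id <- sub("/[12]$", "", alignments$read_id)
    start <- as.integer(sub(":.*$", "", alignments$blocks))
    keep <- rep(TRUE, nrow(alignments))
    by_pid <- split(seq_len(nrow(alignments)), pair_id)
    for (rows in by_pid) {
      if (length(unique(alignments$read_id[rows])) < 2) next
      spl <- rows[alignments$spliced[rows]]
      for (r in spl) {
        sib <- rows[alignments$read_id[rows] != alignments$read_id[r]]
        ok <- FALSE
        for (s in sib) {
          if (alignments$seq[s] != alignments$seq[r]) next
          if (alignments$strand[s] == alignments$strand[r]) next
          plus <- if (alignments$strand[r] == "+") r else s
          minus <- if (alignments$strand[r] == "+") s else r
          if (start[plus] <= start[minus] &&
              start[minus] - start[plus] <= max_inner_dist) { ok <- TRUE; break }
        }
        if (!ok) keep[r] <- FALSE
      }
    }
    if (all(keep)) break
    alignments <- alignments[keep, , drop = FALSE]
    if (!nrow(alignments)) break
  }
  rownames(alignments) <- NULL
  alignments
}
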