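## Fast independent oracle for the anchor-and-extend aligner: enumerate every
## canonical / semi-canonical gap placement in the anchor-delimited region of
## a read, using Biostrings pattern matching for the anchors and a
## dinucleotide position index for the gaps. Independent of the package's
## k-mer/chaining code path.

DINUC_CLASSES <- data.frame(
  class = 1:6,
  start = c("GT", "GC", "AT", "CT", "CT", "GT"),
  end = c("AG", "AG", "AC", "AC", "GC", "AT"), stringsAsFactors = FALSE)

dinuc_position_index <- function(g) {
  find <- function(d) {
    m <- gregexpr(d, g, fixed = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  }
  sapply(unique(c(DINUC_CLASSES$start, DINUC_CLASSES$end)), find, simplify = FALSE)
}

## mismatches between a piece (raw bytes) and genome substrings starting at
## each of `starts` (0-based)
mm_at <- function(graw, starts, praw) {
  L <- length(praw)
  vapply(starts, function(p) {
    if (p < 0 || p + L > length(graw)) return(99L)
    sum(graw[(p + 1):(p + L)] != praw)
  }, 0L)
}

## enumerate all (mm, score, D) candidates for one gap; kind = "internal"
## (both gl and gr known), "prefix" (gr known) or "suffix" (gl known)
oracle_gap_candidates <- function(gap, kind, gl, gr, g, graw, din, models, cs,
                                  left_ctx, right_ctx) {
  m <- nchar(gap)
  graw_gap <- charToRaw(gap)
  out <- list()
  push <- function(j, istart, D, mm, cls) out[[length(out) + 1L]] <<-
    c(j = j, istart = istart, D = D, mm = mm, cls = cls)
  for (cls in seq_len(nrow(DINUC_CLASSES))) {
    sd <- DINUC_CLASSES$start[cls]; ed <- DINUC_CLASSES$end[cls]
    if (kind == "internal") {
      D <- (gr - gl) - m
      if (D < cs$min_intron || D >= cs$max_intron) next
      for (j in 0:m) {
        if (left_ctx + j < cs$min_overhang || right_ctx + (m - j) < cs$min_overhang) next
        is <- gl + j; ie <- is + D
        if (substr(g, is + 1, is + 2) != sd || substr(g, ie - 1, ie) != ed) next
        mm <- (if (j > 0) mm_at(graw, gl, charToRaw(substr(gap, 1, j))) else 0L) +
          (if (m - j > 0) mm_at(graw, ie, charToRaw(substr(gap, j + 1, m))) else 0L)
        if (mm <= cs$max_mismatch) push(j, is, D, mm, cls)
      }
    } else if (kind == "prefix") {
      for (j in cs$min_overhang:m) {       # j = far (leftmost) piece length
        near <- m - j
        if (near + right_ctx < cs$min_overhang) next
        ie <- gr - near
        if (ie < 2 || substr(g, ie - 1, ie) != ed) next
        near_mm <- if (near > 0) mm_at(graw, ie, charToRaw(substr(gap, j + 1, m))) else 0L
        if (near_mm > cs$max_mismatch) next
        cand <- din[[sd]]
        cand <- cand[cand >= max(j, ie - cs$max_intron + 1) & cand <= ie - cs$min_intron]
        if (!length(cand)) next
        mm <- near_mm + mm_at(graw, cand - j, charToRaw(substr(gap, 1, j)))
        ok <- which(mm <= cs$max_mismatch)
        for (i in ok) push(j, cand[i], ie - cand[i], mm[i], cls)
      }
    } else {                               # suffix: far piece is rightmost
      for (j in cs$min_overhang:m) {
        near <- m - j
        if (near + left_ctx < cs$min_overhang) next
        is <- gl + near
        if (substr(g, is + 1, is + 2) != sd) next
        near_mm <- if (near > 0) mm_at(graw, gl, charToRaw(substr(gap, 1, near))) else 0L
        if (near_mm > cs$max_mismatch) next
        cand <- din[[ed]]                  # positions of the end dinuc (ie - 2)
        cand <- cand[cand >= is + cs$min_intron - 2 & cand <= is + cs$max_intron - 3]
        if (!length(cand)) next
        mm <- near_mm + mm_at(graw, cand + 2, charToRaw(substr(gap, near + 1, m)))
        ok <- which(mm <= cs$max_mismatch)
        for (i in ok) push(j, is, cand[i] + 2 - is, mm[i], cls)
      }
    }
  }
  if (!length(out)) return(NULL)
  as.data.frame(do.call(rbind, out))
}

## best candidate under (mm, donor+acceptor score, intron length); returns
## NULL if the optimum is not unique
oracle_pick <- function(cand, g, models) {
  cand <- cand[cand$mm == min(cand$mm), , drop = FALSE]
  if (nrow(cand) > 1) {
    sc <- vapply(seq_len(nrow(cand)), function(i) {
      strand <- if (cand$cls[i] <= 3) "+" else "-"
      win <- splicefinder:::extract_site_windows(
        data.frame(seq = "g", donor_pos = cand$istart[i],
                   acceptor_end = cand$istart[i] + cand$D[i], strand = strand),
        c(g = g))
      if (is.na(win$donor) || is.na(win$acceptor)) return(-Inf)
      score_splice_site(win$donor, "donor", models) +
        score_splice_site(win$acceptor, "acceptor", models)
    }, 0)
    best <- abs(sc - max(sc)) <= 1e-9
    cand <- cand[best, , drop = FALSE]
    if (nrow(cand) > 1) cand <- cand[cand$D == min(cand$D), , drop = FALSE]
    if (nrow(cand) > 1) return(NULL)       # residual tie: not a unique optimum
  }
  cand
}

## full oracle for one oriented read. Returns NULL when the read is outside
## the oracle's remit (no anchors, ambiguous anchors, >2 total mismatches or
## a non-unique optimum); otherwise list(introns = matrix, mm = total).
oracle_spliced_alignment <- function(q, gdna, g, graw, din, models, cs) {
  segs <- segment_read(q, cs$seg_len)
  anchors <- NULL
  for (i in seq_len(nrow(segs))) {
    s <- substring(q, segs$offset[i] + 1, segs$offset[i] + segs$length[i])
    hits <- Biostrings::matchPattern(s, gdna, max.mismatch = 1, with.indels = FALSE)
    st <- BiocGenerics::start(hits) - 1L
    if (length(st) > 1) return(NULL)       # ambiguous anchor
    if (length(st) == 1) {
      mm <- mm_at(graw, st, charToRaw(s))
      anchors <- rbind(anchors, c(off = segs$offset[i], len = segs$length[i],
                                  gpos = st, mm = mm))
    }
  }
  if (is.null(anchors)) return(NULL)
  anchors <- as.data.frame(anchors)
  ## anchors must be ordered and plausibly spaced
  if (is.unsorted(anchors$gpos, strictly = TRUE)) return(NULL)
  ## an anchor containing a sequencing error could itself be re-split around
  ## an intron; the oracle commits to its anchors, so such reads are outside
  ## its remit
  if (sum(anchors$mm) > 0) return(NULL)
  total_mm <- sum(anchors$mm)
  introns <- NULL
  n <- nrow(anchors)
  resolve <- function(gap, kind, gl, gr, lc, rc) {
    cand <- oracle_gap_candidates(gap, kind, gl, gr, g, graw, din, models, cs, lc, rc)
    ## a contiguous (unspliced) fill competes with the spliced candidates
    m <- nchar(gap)
    plain <- switch(kind,
                    internal = if ((gr - gl) == m) mm_at(graw, gl, charToRaw(gap)) else 99L,
                    prefix = if (gr - m >= 0) mm_at(graw, gr - m, charToRaw(gap)) else 99L,
                    suffix = mm_at(graw, gl, charToRaw(gap)))
    if (is.null(cand)) {
      if (plain <= cs$max_mismatch) return(list(plain = TRUE, mm = plain))
      return(NULL)
    }
    if (plain <= min(cand$mm)) return(list(plain = TRUE, mm = plain))
    best <- oracle_pick(cand, g, models)
    if (is.null(best)) return("tie")
    list(plain = FALSE, mm = best$mm, intron = c(best$istart, best$istart + best$D))
  }
  handle <- function(res) {
    if (is.null(res)) return(FALSE)
    if (identical(res, "tie")) return(NA)
    total_mm <<- total_mm + res$mm
    if (!res$plain) introns <<- rbind(introns, res$intron)
    TRUE
  }
  for (i in seq_len(max(0, n - 1))) {
    r0 <- anchors$off[i] + anchors$len[i]; r1 <- anchors$off[i + 1]
    g0 <- anchors$gpos[i] + anchors$len[i]; g1 <- anchors$gpos[i + 1]
    if (g1 - g0 < r1 - r0) return(NULL)
    ok <- handle(resolve(substr(q, r0 + 1, r1), "internal", g0, g1,
                         anchors$len[i], anchors$len[i + 1]))
    if (!isTRUE(ok)) return(NULL)
  }
  if (anchors$off[1] > 0) {
    ok <- handle(resolve(substr(q, 1, anchors$off[1]), "prefix", NA,
                         anchors$gpos[1], 0L, anchors$len[1]))
    if (!isTRUE(ok)) return(NULL)
  }
  tail_off <- anchors$off[n] + anchors$len[n]
  if (tail_off < nchar(q)) {
    ok <- handle(resolve(substr(q, tail_off + 1, nchar(q)), "suffix",
                         anchors$gpos[n] + anchors$len[n], NA, anchors$len[n], 0L))
    if (!isTRUE(ok)) return(NULL)
  }
  if (total_mm > cs$max_mismatch || is.null(introns)) return(NULL)
  colnames(introns) <- c("donor_pos", "acceptor_end")
  list(introns = introns[order(introns[, 1]), , drop = FALSE], mm = total_mm)
}
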