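## Aggregation of spliced alignments into unique junction candidates and the
## nine per-junction classification features:
##   alignment-derived: coverage skew, depth, entropy, minimal overhang
##   sequence-derived:  donor score, acceptor score, intron length log-likelihood
##   prediction-derived: frameshift indicator, strand concordance indicator

#' Aggregate spliced alignments into junction candidates
#'
#' One candidate per unique (seq, donor_pos, acceptor_end, strand);
#' multi-intron alignments contribute one support per spanned junction, with
#' per-support overhangs restricted to the blocks flanking that junction.
#'
#' @param alignments alignment data.frame (only \code{spliced} rows are used).
#' @param genome named character vector (for dinucleotide classification).
#' @return list of class \code{sj_candidates}: \code{junctions} (one row per
#'   candidate with \code{junction}, key columns, \code{class}, \code{depth})
#'   and \code{supports} (one row per supporting alignment with overhangs and
#'   the left-anchor offset).
#' @export
aggregate_junctions <- function(alignments, genome) {
  ai <- alignment_introns(alignments, genome)
  if (!nrow(ai)) {
    return(structure(list(
      junctions = data.frame(junction = integer(0), seq = character(0),
                             donor_pos = integer(0), acceptor_end = integer(0),
                             strand = character(0), class = integer(0), depth = integer(0)),
      supports = data.frame(junction = integer(0), read_id = character(0),
                            left_overhang = integer(0), right_overhang = integer(0),
                            offset = integer(0))), class = "sj_candidates"))
  }
  key <- paste(ai$seq, ai$donor_pos, ai$acceptor_end, ai$strand)
  uk <- !duplicated(key)
  junctions <- data.frame(junction = seq_len(sum(uk)), seq = ai$seq[uk],
                          donor_pos = ai$donor_pos[uk], acceptor_end = ai$acceptor_end[uk],
                          strand = ai$strand[uk], class = ai$class[uk],
                          stringsAsFactors = FALSE)
  jidx <- match(key, key[uk])
  junctions$depth <- tabulate(jidx, nbins = nrow(junctions))
  supports <- data.frame(junction = jidx, read_id = ai$read_id,
                         left_overhang = ai$left_overhang,
                         right_overhang = ai$right_overhang,
                         offset = ai$donor_pos - ai$left_overhang,  # left-anchor genome offset
                         stringsAsFactors = FALSE)
  structure(list(junctions = junctions, supports = supports), class = "sj_candidates")
}

#' @export
print.sj_candidates <- function(x, ...) {
  cat(sprintf("sj_candidates: %d junctions, %d supporting alignments\n",
              nrow(x$junctions), nrow(x$supports)))
  invisible(x)
}

## counts of ungapped reads crossing each genomic boundary b (i.e. covering
## both b-1 and b); returns a function(seq, b) -> count
ungapped_boundary_counter <- function(alignments) {
  ung <- alignments[!alignments$spliced, , drop = FALSE]
  starts <- as.integer(sub(":.*$", "", ung$blocks))
  lens <- as.integer(sub("^[0-9]+:", "", ung$blocks))
  by_seq <- split(data.frame(s = starts, e = starts + lens), ung$seq)
  by_seq <- lapply(by_seq, function(d) list(s = sort(d$s), e = sort(d$e)))
  function(seq_name, b) {
    d <- by_seq[[seq_name]]
    if (is.null(d)) return(rep(0L, length(b)))
    ## reads with start <= b-1 and end >= b+1
    findInterval(b - 1, d$s) - findInterval(b, d$e)
  }
}

#' Alignment-derived junction features
#'
#' \itemize{
#'   \item depth: number of supporting spliced alignments C
#'   \item entropy: depth-weighted Shannon entropy of left-anchor offsets,
#'     \eqn{-\sum_i c_i \log_2(c_i / C)}
#'   \item min_overhang: the junction's best evidence, the maximum over
#'     supports of each support's shorter overhang
#'   \item skew: \eqn{\log_2((1 + C) / (1 + \max(u_d, u_a)))} where
#'     \eqn{u_d, u_a} count ungapped reads crossing the donor and acceptor
#'     boundaries; strongly negative skew marks junctions weakly supported
#'     relative to local unspliced coverage
#' }
#'
#' @param candidates an \code{sj_candidates} object.
#' @param alignments full alignment table (its unspliced rows provide the
#'   local ungapped coverage).
#' @return data.frame with columns \code{junction}, \code{skew}, \code{depth},
#'   \code{entropy}, \code{min_overhang}.
#' @export
compute_alignment_features <- function(candidates, alignments) {
  jn <- candidates$junctions
  sup <- candidates$supports
  crossing <- ungapped_boundary_counter(alignments)
  ent <- mo <- numeric(nrow(jn))
  sup_split <- split(sup, factor(sup$junction, levels = jn$junction))
  for (i in seq_len(nrow(jn))) {
    s <- sup_split[[i]]
    ci <- table(s$offset)
    C <- sum(ci)
    ent[i] <- -sum(ci * log2(ci / C))
    mo[i] <- max(pmin(s$left_overhang, s$right_overhang))
  }
  ud <- ua <- integer(nrow(jn))
  for (sq in unique(jn$seq)) {
    m <- jn$seq == sq
    ud[m] <- crossing(sq, jn$donor_pos[m])
    ua[m] <- crossing(sq, jn$acceptor_end[m])
  }
  data.frame(junction = jn$junction,
             skew = log2((1 + jn$depth) / (1 + pmax(ud, ua))),
             depth = jn$depth, entropy = ent, min_overhang = mo)
}

#' Sequence-derived junction features
#'
#' Donor and acceptor log-likelihood-ratio scores (bits) from the splice-site
#' PSFMs and the intron-length log-likelihood. Windows that would run off the
#' contig receive a floor value of -50 bits.
#'
#' @param candidates an \code{sj_candidates} object.
#' @param genome named character vector.
#' @param models a \code{splice_models} object.
#' @return data.frame with columns \code{junction}, \code{gap_loglik},
#'   \code{donor_score}, \code{acceptor_score}.
#' @export
compute_sequence_features <- function(candidates, genome, models) {
  jn <- candidates$junctions
  win <- extract_site_windows(jn, genome)
  ds <- as_ <- numeric(nrow(jn))
  for (i in seq_len(nrow(jn))) {
    ds[i] <- if (is.na(win$donor[i])) -50 else score_splice_site(win$donor[i], "donor", models)
    as_[i] <- if (is.na(win$acceptor[i])) -50 else score_splice_site(win$acceptor[i], "acceptor", models)
  }
  if (any(is.na(win$donor) | is.na(win$acceptor)))
    warning("some junction windows run off the contig; scores floored at -50 bits")
  data.frame(junction = jn$junction,
             gap_loglik = intron_length_loglik(jn$acceptor_end - jn$donor_pos,
                                               models$intron_lengths),
             donor_score = ds, acceptor_score = as_)
}

#' Gene-prediction set used by the indicator features
#'
#' @param genes data.frame: \code{gene_id}, \code{seq}, \code{strand}.
#' @param exons data.frame of CDS exons: \code{gene_id}, \code{seq},
#'   \code{start}, \code{end} (0-based half-open).
#' @param introns data.frame of predicted introns: \code{seq},
#'   \code{donor_pos}, \code{acceptor_end}, \code{strand}.
#' @return object of class \code{gene_predictions}.
#' @export
gene_predictions <- function(genes, exons, introns) {
  stopifnot(all(c("gene_id", "seq", "strand") %in% names(genes)),
            all(c("gene_id", "seq", "start", "end") %in% names(exons)),
            all(c("seq", "donor_pos", "acceptor_end", "strand") %in% names(introns)))
  structure(list(genes = genes, exons = exons, introns = introns),
            class = "gene_predictions")
}

## ab initio coding index of genomic position p within a gene's CDS exons:
## number of coding nt preceding p along the coding strand, or NA if p is
## not inside a CDS exon
coding_index <- function(p, exons, strand) {
  hit <- which(exons$start <= p & p < exons$end)
  if (!length(hit)) return(NA_integer_)
  hit <- hit[1]
  if (strand == "+") {
    sum((exons$end - exons$start)[exons$end <= p]) + (p - exons$start[hit])
  } else {
    sum((exons$end - exons$start)[exons$start > p]) + (exons$end[hit] - 1L - p)
  }
}

#' Prediction-derived indicator features
#'
#' \code{frameshift} is 1 iff both splice sites of the candidate fall inside
#' predicted CDS exons of one gene and the reading frame carried across the
#' candidate intron disagrees with the ab initio frame of the downstream exon.
#' \code{strand_discord} is 1 iff the candidate intron overlaps a predicted
#' gene and its strand differs from that gene's strand.
#'
#' @param candidates an \code{sj_candidates} object.
#' @param predictions a \code{\link{gene_predictions}} object.
#' @return data.frame with columns \code{junction}, \code{frameshift},
#'   \code{strand_discord}.
#' @export
compute_indicators <- function(candidates, predictions) {
  jn <- candidates$junctions
  fs <- sd_ <- integer(nrow(jn))
  exons_by_gene <- split(predictions$exons, predictions$exons$gene_id)
  gene_span <- do.call(rbind, lapply(exons_by_gene, function(e)
    data.frame(gene_id = e$gene_id[1], seq = e$seq[1],
               start = min(e$start), end = max(e$end), stringsAsFactors = FALSE)))
  gene_span$strand <- predictions$genes$strand[match(gene_span$gene_id,
                                                     predictions$genes$gene_id)]
  for (i in seq_len(nrow(jn))) {
    p_l <- jn$donor_pos[i] - 1L   # last exonic base left of the intron
    p_r <- jn$acceptor_end[i]     # first exonic base right of the intron
    ov <- gene_span[gene_span$seq == jn$seq[i] &
                      gene_span$start < jn$acceptor_end[i] &
                      gene_span$end > jn$donor_pos[i], , drop = FALSE]
    if (nrow(ov)) {
      if (any(ov$strand != jn$strand[i])) sd_[i] <- 1L
      for (gid in ov$gene_id) {
        ex <- exons_by_gene[[as.character(gid)]]
        strand <- ov$strand[ov$gene_id == gid][1]
        ci_l <- coding_index(p_l, ex, strand)
        ci_r <- coding_index(p_r, ex, strand)
        if (is.na(ci_l) || is.na(ci_r)) next
        up <- if (strand == "+") ci_l else ci_r
        down <- if (strand == "+") ci_r else ci_l
        if ((down - up) %% 3L != 1L) { fs[i] <- 1L; break }
      }
    }
  }
  data.frame(junction = jn$junction, frameshift = fs, strand_discord = sd_)
}

#' Full nine-feature table for junction candidates
#'
#' @param candidates an \code{sj_candidates} object.
#' @param alignments full alignment table (ungapped coverage for skew).
#' @param genome named character vector.
#' @param models a \code{splice_models}.
#' @param predictions a \code{gene_predictions}.
#' @return data.frame: junction key columns plus the nine features.
#' @export
junction_features <- function(candidates, alignments, genome, models, predictions) {
  jn <- candidates$junctions
  af <- compute_alignment_features(candidates, alignments)
  sf <- compute_sequence_features(candidates, genome, models)
  ind <- compute_indicators(candidates, predictions)
  cbind(jn[c("junction", "seq", "donor_pos", "acceptor_end", "strand", "class")],
        af[c("skew", "depth", "entropy", "min_overhang")],
        sf[c("gap_loglik", "donor_score", "acceptor_score")],
        ind[c("frameshift", "strand_discord")])
}
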