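## Synthetic-data generator: compact genomes with multi-exon genes whose
## splice sites are drawn from generating PSFMs, expression-weighted
## transcripts, splicing-noise transcripts using random GT/AG sites, and
## error-bearing paired-end reads with full ground truth.

#' Simulation configuration
#'
#' Defaults describe the package's standard synthetic benchmark: a 100 kb
#' compact genome carrying 200 multi-exon genes, log-normally expressed, with
#' 20 percent of the read mass coming from splicing-noise transcripts spread
#' over many distinct low-support noise junctions (noisy splicing produces a
#' large diversity of individually rare junctions), and 50000 paired-end
#' 75 nt reads with a per-base error rate of 0.02.
#'
#' @param genome_len genome length in nt.
#' @param n_genes number of genes.
#' @param exons_per_gene integer range c(min, max).
#' @param exon_len exon length range in nt (uniform).
#' @param intron_meanlog,intron_sdlog log-normal intron length parameters.
#' @param intron_range truncation range for intron lengths (nt).
#' @param utr_len range of untranslated leader/trailer lengths inside the
#'   first/last exon.
#' @param noise_fraction share of the transcript pool (and hence of read
#'   mass) carried by noise transcripts; in [0, 1).
#' @param noise_per_gene distinct noise transcripts generated per gene.
#' @param read_len read length, one of 50, 75, 100.
#' @param n_pairs number of read pairs.
#' @param frag_mean,frag_sd fragment length distribution (nt).
#' @param error_rate per-base substitution error rate, in [0, 0.2].
#' @param expr_meanlog,expr_sdlog log-normal expression law for genes.
#' @param pred_miss fraction of genes dropped from the emitted ab initio
#'   prediction stand-in.
#' @param seed RNG seed driving every stage.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(genome_len = 100000L, n_genes = 200L, exons_per_gene = c(2L, 4L),
                       exon_len = c(40L, 120L), intron_meanlog = log(80), intron_sdlog = 0.25,
                       intron_range = c(45L, 400L), utr_len = c(10L, 30L),
                       noise_fraction = 0.2, noise_per_gene = 20L,
                       read_len = 75L, n_pairs = 50000L, frag_mean = 160, frag_sd = 20,
                       error_rate = 0.02, expr_meanlog = 0, expr_sdlog = 1,
                       pred_miss = 0.1, seed = 1L) {
  stopifnot(noise_fraction >= 0, noise_fraction < 1, error_rate >= 0, error_rate <= 0.2,
            read_len %in% c(50L, 75L, 100L), frag_mean >= read_len,
            genome_len > 0, intron_range[2] < 10000)
  structure(as.list(environment()), class = "sim_config")
}

## generating splice-site PSFMs: first-order representable with
## position-independent conditionals; donor consensus (C/A)AG|GTAAGT,
## acceptor: pyrimidine-rich tract ending ...YAG|G. GT / AG terminal
## dinucleotides carry probability ~0.997.
default_generating_models <- function(config) {
  bg <- c(A = 0.29, C = 0.21, G = 0.21, T = 0.29)
  near1 <- function(b) { p <- rep(0.001, 4); p[match(b, BASES)] <- 0.997; p }
  mix <- function(...) { p <- c(...); p / sum(p) }
  don <- cbind(mix(A = 0.35, C = 0.35, G = 0.15, T = 0.15),  # exonic -3
               mix(A = 0.60, C = 0.12, G = 0.16, T = 0.12),  # exonic -2
               mix(A = 0.10, C = 0.05, G = 0.78, T = 0.07),  # exonic -1
               near1("G"), near1("T"),                        # intron +1 +2
               mix(A = 0.60, C = 0.08, G = 0.12, T = 0.20),
               mix(A = 0.70, C = 0.08, G = 0.12, T = 0.10),
               mix(A = 0.10, C = 0.08, G = 0.72, T = 0.10),
               mix(A = 0.15, C = 0.15, G = 0.10, T = 0.60))
  pyr <- mix(A = 0.10, C = 0.30, G = 0.10, T = 0.50)
  acc <- cbind(matrix(rep(pyr, 17), nrow = 4),
               mix(A = 0.05, C = 0.70, G = 0.05, T = 0.20),  # Y at -3
               near1("A"), near1("G"),                        # intron -2 -1
               mix(A = 0.25, C = 0.15, G = 0.45, T = 0.15))  # exonic +1
  indep_cond <- function(marg) {
    w <- ncol(marg)
    cond <- array(0, dim = c(4, 4, w))
    for (j in seq_len(w)) cond[, , j] <- matrix(rep(marg[, j], each = 4), 4, 4)
    cond
  }
  donor <- new_psfm("donor", don, indep_cond(don), order = 1L)
  acceptor <- new_psfm("acceptor", acc, indep_cond(acc), order = 1L)
  ## discretized truncated log-normal intron length pmf
  lo <- config$intron_range[1]; hi <- config$intron_range[2]
  bw <- 10L
  breaks <- seq(lo, hi + bw, by = bw)
  mass <- diff(stats::plnorm(breaks, config$intron_meanlog, config$intron_sdlog))
  n_bins <- ceiling((hi - lo + 1) / bw)
  mass <- mass[seq_len(n_bins)]
  il <- new_intron_length_dist(lo, hi, mass / sum(mass), bw, 1e-6)
  new_splice_models(donor, acceptor, new_background(bg), il)
}

sample_bg <- function(n, bg) paste(sample(BASES, n, replace = TRUE, prob = bg), collapse = "")

rtrunc_lnorm <- function(n, meanlog, sdlog, range) {
  out <- round(rlnorm(n, meanlog, sdlog))
  bad <- out < range[1] | out > range[2]
  while (any(bad)) {
    out[bad] <- round(rlnorm(sum(bad), meanlog, sdlog))
    bad <- out < range[1] | out > range[2]
  }
  as.integer(out)
}

#' Simulate a compact genome with multi-exon genes
#'
#' Intergenic sequence is i.i.d. background; genes are placed on both strands
#' without overlap; every functional intron starts GT and ends AG with its
#' flanking windows sampled from the generating PSFMs; intron lengths follow
#' the configured truncated log-normal.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{sim_genome}: \code{genome} (named character),
#'   \code{annotation} (genes/exons/cds/introns data.frames, 0-based
#'   half-open, forward coordinates), \code{models} (the generating
#'   \code{splice_models}) and per-gene local structures used by the
#'   transcript simulator.
#' @export
simulate_genome <- function(config) {
  models <- default_generating_models(config)
  bg <- models$background$probs
  with_seed(config$seed, {
    n <- config$n_genes
    genes <- vector("list", n)
    total_gene_len <- 0L
    for (i in seq_len(n)) {
      n_ex <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1)
      ex_len <- as.integer(round(runif(n_ex, config$exon_len[1], config$exon_len[2])))
      in_len <- if (n_ex > 1)
        rtrunc_lnorm(n_ex - 1, config$intron_meanlog, config$intron_sdlog,
                     config$intron_range) else integer(0)
      ## build gene-local sequence in transcript orientation
      exons <- lapply(ex_len, function(L) sample_bg(L, bg))
      introns <- character(length(in_len))
      don_w <- sample_psfm_windows(models$donor, max(1, length(in_len)))
      acc_w <- sample_psfm_windows(models$acceptor, max(1, length(in_len)))
      for (j in seq_along(in_len)) {
        dw <- don_w[j]; aw <- acc_w[j]
        substr(dw, 4, 5) <- "GT"                        # construction rule
        substr(aw, 19, 20) <- "AG"
        ## donor window: 3 exonic + 6 intronic; acceptor: 20 intronic + 1 exonic
        substr(exons[[j]], ex_len[j] - 2, ex_len[j]) <- substr(dw, 1, 3)
        substr(exons[[j + 1]], 1, 1) <- substr(aw, 21, 21)
        mid <- if (in_len[j] > 26) sample_bg(in_len[j] - 26, bg) else ""
        introns[j] <- paste0(substr(dw, 4, 9), mid, substr(aw, 1, 20))
      }
      pieces <- character(0)
      for (j in seq_along(exons)) {
        pieces <- c(pieces, exons[[j]])
        if (j <= length(introns)) pieces <- c(pieces, introns[j])
      }
      local_seq <- paste(pieces, collapse = "")
      ## local exon intervals (transcript orientation, 0-based half-open)
      starts <- cumsum(c(0L, head(ex_len + c(in_len, 0L), -1)))
      ex_local <- cbind(start = starts, end = starts + ex_len)
      utr5 <- min(sample(seq(config$utr_len[1], config$utr_len[2]), 1), ex_len[1] - 5L)
      utr3 <- min(sample(seq(config$utr_len[1], config$utr_len[2]), 1), ex_len[n_ex] - 5L)
      tlen <- sum(ex_len)
      cds_len <- tlen - utr5 - utr3
      cds_len <- cds_len - cds_len %% 3L
      strand <- if (runif(1) < 0.5) "+" else "-"
      genes[[i]] <- list(gene_id = sprintf("g%03d", i), strand = strand,
                         local_seq = local_seq, glen = nchar(local_seq),
                         ex_local = ex_local,
                         cds_local = c(utr5, utr5 + cds_len))
      total_gene_len <- total_gene_len + nchar(local_seq)
    }
    spare <- config$genome_len - total_gene_len
    if (spare < 20L * (n + 1L))
      stop(sprintf("cannot pack %d genes (%d nt) into %d nt; lower n_genes or gene sizes",
                   n, total_gene_len, config$genome_len))
    gaps <- as.integer(round(spare * (g <- {p <- runif(n + 1); p / sum(p)})))
    gaps[n + 1] <- spare - sum(gaps[seq_len(n)])
    if (gaps[n + 1] < 0) { gaps[which.max(gaps)] <- gaps[which.max(gaps)] + gaps[n + 1]; gaps[n + 1] <- 0L }
    chunks <- character(0)
    pos <- 0L
    for (i in seq_len(n)) {
      chunks <- c(chunks, sample_bg(gaps[i], bg))
      pos <- pos + gaps[i]
      genes[[i]]$g0 <- pos
      gseq <- genes[[i]]$local_seq
      chunks <- c(chunks, if (genes[[i]]$strand == "+") gseq else revcomp(gseq))
      pos <- pos + nchar(gseq)
    }
    chunks <- c(chunks, sample_bg(gaps[n + 1], bg))
    genome <- c(chr1 = paste(chunks, collapse = ""))

    annotation <- build_annotation(genes)
    structure(list(genome = genome, annotation = annotation, models = models,
                   genes = genes, config = config), class = "sim_genome")
  })
}

## map a local (transcript-oriented) interval [s, e) to forward genome coords
local_to_genome <- function(g, s, e) {
  if (g$strand == "+") c(g$g0 + s, g$g0 + e) else c(g$g0 + g$glen - e, g$g0 + g$glen - s)
}

build_annotation <- function(genes) {
  if (!length(genes)) {
    empty_iv <- data.frame(gene_id = character(0), seq = character(0),
                           start = integer(0), end = integer(0))
    return(list(genes = data.frame(gene_id = character(0), seq = character(0),
                                   strand = character(0)),
                exons = empty_iv, cds = empty_iv,
                introns = data.frame(gene_id = character(0), seq = character(0),
                                     donor_pos = integer(0), acceptor_end = integer(0),
                                     strand = character(0))))
  }
  ex <- cds <- intr <- gn <- list()
  for (g in genes) {
    gn[[length(gn) + 1L]] <- data.frame(gene_id = g$gene_id, seq = "chr1",
                                        strand = g$strand, stringsAsFactors = FALSE)
    ne <- nrow(g$ex_local)
    for (j in seq_len(ne)) {
      iv <- local_to_genome(g, g$ex_local[j, 1], g$ex_local[j, 2])
      ex[[length(ex) + 1L]] <- data.frame(gene_id = g$gene_id, seq = "chr1",
                                          start = iv[1], end = iv[2], stringsAsFactors = FALSE)
      ## CDS portion of this exon (intersection with the local CDS interval)
      tstart <- sum((g$ex_local[, 2] - g$ex_local[, 1])[seq_len(j - 1)])
      clo <- max(g$cds_local[1], tstart)
      chi <- min(g$cds_local[2], tstart + (g$ex_local[j, 2] - g$ex_local[j, 1]))
      if (chi > clo) {
        lo_local <- g$ex_local[j, 1] + (clo - tstart)
        hi_local <- g$ex_local[j, 1] + (chi - tstart)
        civ <- local_to_genome(g, lo_local, hi_local)
        cds[[length(cds) + 1L]] <- data.frame(gene_id = g$gene_id, seq = "chr1",
                                              start = civ[1], end = civ[2],
                                              stringsAsFactors = FALSE)
      }
      if (j < ne) {
        iiv <- local_to_genome(g, g$ex_local[j, 2], g$ex_local[j + 1, 1])
        intr[[length(intr) + 1L]] <- data.frame(gene_id = g$gene_id, seq = "chr1",
                                                donor_pos = iiv[1], acceptor_end = iiv[2],
                                                strand = g$strand, stringsAsFactors = FALSE)
      }
    }
  }
  list(genes = do.call(rbind, gn), exons = do.call(rbind, ex),
       cds = do.call(rbind, cds),
       introns = if (length(intr)) do.call(rbind, intr) else
         data.frame(gene_id = character(0), seq = character(0), donor_pos = integer(0),
                    acceptor_end = integer(0), strand = character(0)))
}

## random GT (for a donor) or AG-terminated (for an acceptor) position search
find_dinuc_positions <- function(local_seq, dinuc, lo, hi) {
  if (hi <= lo) return(integer(0))
  sub <- substr(local_seq, lo + 1, hi + 1)
  m <- gregexpr(dinuc, sub, fixed = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m) - 1L + lo
}

#' Simulate an expression-weighted transcript pool with splicing noise
#'
#' Functional transcripts are the annotated isoforms weighted by a log-normal
#' expression law. Noise transcripts are created by replacing the donor, the
#' acceptor, or both splice sites of a sampled intron with a random GT / AG
#' position inside the gene; they share \code{noise_fraction} of the total
#' pool weight, so the expected noise share of sampled reads equals
#' \code{noise_fraction}.
#'
#' @param sim a \code{sim_genome}.
#' @param config the \code{\link{sim_config}} (defaults to the one inside
#'   \code{sim}).
#' @return data.frame pool: \code{id}, \code{gene_id}, \code{label}
#'   (functional/noise), \code{strand}, \code{blocks} (forward-genome exon
#'   blocks), \code{sequence}, \code{weight}, and for noise rows the novel
#'   junction \code{noise_donor}/\code{noise_acceptor} (forward coords).
#' @export
simulate_transcripts <- function(sim, config = sim$config) {
  with_seed(config$seed + 1L, {
    genes <- sim$genes
    n <- length(genes)
    expr <- rlnorm(n, config$expr_meanlog, config$expr_sdlog)
    func <- vector("list", n)
    for (i in seq_len(n)) {
      g <- genes[[i]]
      func[[i]] <- transcript_from_exons(g, g$ex_local, sprintf("t%03d", i), "functional",
                                         expr[i])
    }
    n_noise <- if (config$noise_fraction > 0) as.integer(config$noise_per_gene * n) else 0L
    noise <- vector("list", n_noise)
    made <- 0L
    guard <- 0L
    while (made < n_noise && guard < 50L * n_noise) {
      guard <- guard + 1L
      gi <- sample(n, 1, prob = expr)
      g <- genes[[gi]]
      ne <- nrow(g$ex_local)
      if (ne < 2) next
      j <- if (ne == 2) 1L else sample(ne - 1L, 1)
      d <- g$ex_local[j, 2]; a <- g$ex_local[j + 1, 1]
      mode <- sample(c("donor", "acceptor", "both"), 1, prob = c(0.45, 0.45, 0.1))
      d2 <- d; a2 <- a
      if (mode %in% c("donor", "both")) {
        cand <- find_dinuc_positions(g$local_seq, "GT", g$ex_local[j, 1] + 10L, a - 22L)
        cand <- setdiff(cand, d)
        if (!length(cand)) next
        d2 <- sample(cand, 1)
      }
      if (mode %in% c("acceptor", "both")) {
        ## acceptor_end a2 requires AG at local [a2-2, a2)
        cand <- find_dinuc_positions(g$local_seq, "AG", d2 + 18L, g$ex_local[j + 1, 2] - 12L)
        cand <- setdiff(cand + 2L, a)
        cand <- cand[cand - d2 >= 20 & cand <= g$ex_local[j + 1, 2] - 10L]
        if (!length(cand)) next
        a2 <- sample(cand, 1)
      }
      if (d2 == d && a2 == a) next
      ex2 <- g$ex_local
      ex2[j, 2] <- d2; ex2[j + 1, 1] <- a2
      if (ex2[j, 2] - ex2[j, 1] < 10 || ex2[j + 1, 2] - ex2[j + 1, 1] < 10) next
      made <- made + 1L
      nt <- transcript_from_exons(g, ex2, sprintf("n%05d", made), "noise", 0)
      niv <- local_to_genome(g, d2, a2)
      nt$noise_donor <- niv[1]; nt$noise_acceptor <- niv[2]
      noise[[made]] <- nt
    }
    noise <- noise[seq_len(made)]
    if (made < n_noise)
      warning(sprintf("generated %d of %d requested noise transcripts", made, n_noise))
    pool <- do.call(rbind, c(func, noise))
    if (is.null(pool$noise_donor)) { pool$noise_donor <- NA_integer_; pool$noise_acceptor <- NA_integer_ }
    ## drop transcripts too short to carry a fragment
    pool <- pool[nchar(pool$sequence) >= config$read_len, , drop = FALSE]
    ## weight normalization: functional mass 1 - noise_fraction, noise mass noise_fraction
    fi <- pool$label == "functional"
    pool$weight[fi] <- pool$weight[fi] / sum(pool$weight[fi]) *
      (if (any(!fi)) 1 - config$noise_fraction else 1)
    if (any(!fi)) {
      nw <- rlnorm(sum(!fi), 0, 0.5)
      pool$weight[!fi] <- nw / sum(nw) * config$noise_fraction
    }
    rownames(pool) <- NULL
    pool
  })
}

transcript_from_exons <- function(g, ex_local, id, label, weight) {
  sq <- paste(substring(g$local_seq, ex_local[, 1] + 1, ex_local[, 2]), collapse = "")
  bl <- t(vapply(seq_len(nrow(ex_local)),
                 function(j) local_to_genome(g, ex_local[j, 1], ex_local[j, 2]),
                 numeric(2)))
  bl <- bl[order(bl[, 1]), , drop = FALSE]
  data.frame(id = id, gene_id = g$gene_id, label = label, strand = g$strand,
             blocks = encode_blocks(bl[, 1], bl[, 2] - bl[, 1]),
             sequence = sq, weight = weight,
             noise_donor = NA_integer_, noise_acceptor = NA_integer_,
             stringsAsFactors = FALSE)
}

## transcript-coordinate interval -> forward genome blocks, honouring strand
project_transcript_interval <- function(blocks, strand, pos, len) {
  total <- sum(blocks[, 2])
  if (strand == "-") pos <- total - (pos + len)
  project_interval(blocks, pos, len)
}

add_read_errors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  L <- nchar(seqs)
  nerr <- rbinom(length(seqs), L, rate)
  hit <- which(nerr > 0)
  for (i in hit) {
    pos <- sample(L[i], nerr[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      shift <- sample(3L, 1)
      substr(seqs[i], p, p) <- BASES[((match(cur, BASES) - 1L + shift) %% 4L) + 1L]
    }
  }
  seqs
}

#' Simulate paired-end reads from a transcript pool
#'
#' Fragments are sampled from transcripts proportionally to pool weight;
#' mates are emitted forward-reverse oriented; substitution errors are
#' i.i.d. per base at \code{error_rate}. Per-read truth records the true
#' genomic blocks of each mate.
#'
#' @param pool output of \code{\link{simulate_transcripts}}.
#' @param config a \code{\link{sim_config}}.
#' @return list: \code{reads1}, \code{reads2} (named character vectors, ids
#'   \code{simNNNNN/1|2}) and \code{truth} (per-mate data.frame with
#'   \code{read_id}, \code{seq}, \code{strand}, \code{blocks},
#'   \code{transcript}, \code{label}).
#' @export
simulate_reads <- function(pool, config) {
  with_seed(config$seed + 2L, {
    L <- config$read_len
    n <- config$n_pairs
    ti <- sample(nrow(pool), n, replace = TRUE, prob = pool$weight)
    tlen <- nchar(pool$sequence)[ti]
    flen <- pmin(pmax(as.integer(round(rnorm(n, config$frag_mean, config$frag_sd))), L), tlen)
    fs <- as.integer(floor(runif(n) * (tlen - flen + 1)))
    frag_seq <- substring(pool$sequence[ti], fs + 1, fs + flen)
    r1 <- substr(frag_seq, 1, L)
    r2 <- revcomp(substring(frag_seq, flen - L + 1, flen))
    ids <- sprintf("sim%06d", seq_len(n))
    blocks_list <- lapply(pool$blocks, decode_blocks)
    b1 <- b2 <- character(n)
    strands <- pool$strand[ti]
    for (i in seq_len(n)) {
      bm <- blocks_list[[ti[i]]]
      m1 <- project_transcript_interval(bm, strands[i], fs[i], L)
      m2 <- project_transcript_interval(bm, strands[i], fs[i] + flen[i] - L, L)
      b1[i] <- encode_blocks(m1[, 1], m1[, 2])
      b2[i] <- encode_blocks(m2[, 1], m2[, 2])
    }
    truth <- data.frame(
      read_id = c(paste0(ids, "/1"), paste0(ids, "/2")),
      seq = "chr1",
      strand = c(strands, ifelse(strands == "+", "-", "+")),
      blocks = c(b1, b2),
      transcript = rep(pool$id[ti], 2),
      label = rep(pool$label[ti], 2), stringsAsFactors = FALSE)
    truth <- truth[order(rep(seq_len(n), 2), rep(1:2, each = n)), ]
    rownames(truth) <- NULL
    r1 <- add_read_errors(r1, config$error_rate)
    r2 <- add_read_errors(r2, config$error_rate)
    names(r1) <- paste0(ids, "/1")
    names(r2) <- paste0(ids, "/2")
    list(reads1 = r1, reads2 = r2, truth = truth)
  })
}

#' Ab initio gene-prediction stand-in derived from simulator truth
#'
#' Emulates an ab initio gene finder at realistic sensitivity by dropping a
#' fraction of genes from the truth annotation.
#'
#' @param sim a \code{sim_genome}.
#' @param config the \code{\link{sim_config}}.
#' @return a \code{\link{gene_predictions}} object.
#' @export
simulate_predictions <- function(sim, config = sim$config) {
  ann <- sim$annotation
  with_seed(config$seed + 3L, {
    keep <- sort(sample(nrow(ann$genes), round((1 - config$pred_miss) * nrow(ann$genes))))
    ids <- ann$genes$gene_id[keep]
    gene_predictions(ann$genes[keep, , drop = FALSE],
                     ann$cds[ann$cds$gene_id %in% ids, , drop = FALSE],
                     ann$introns[ann$introns$gene_id %in% ids, , drop = FALSE])
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs genome, transcript, read and prediction simulation under one seed and
#' optionally writes all artifacts (FASTA, GFF3, FASTQ x2, truth junction
#' BED, generating-model parameter file) to a directory.
#'
#' @param config a \code{\link{sim_config}}.
#' @param dir optional output directory.
#' @return list with \code{sim}, \code{pool}, \code{reads}, \code{predictions}
#'   and \code{truth_junctions} (functional and noise junctions with labels).
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  sim <- simulate_genome(config)
  pool <- simulate_transcripts(sim, config)
  reads <- simulate_reads(pool, config)
  predictions <- simulate_predictions(sim, config)
  func <- unique(sim$annotation$introns[c("seq", "donor_pos", "acceptor_end", "strand")])
  func$label <- "functional"
  nz <- pool[pool$label == "noise", , drop = FALSE]
  noise <- unique(data.frame(seq = "chr1", donor_pos = nz$noise_donor,
                             acceptor_end = nz$noise_acceptor, strand = nz$strand,
                             stringsAsFactors = FALSE))
  ## a noise junction coinciding with a functional one keeps the functional label
  if (nrow(noise)) {
    noise <- noise[!junction_key(noise) %in% junction_key(func), , drop = FALSE]
    noise$label <- "noise"
  }
  truth_junctions <- rbind(func, if (nrow(noise)) noise)
  out <- list(sim = sim, pool = pool, reads = reads, predictions = predictions,
              truth_junctions = truth_junctions, config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(sim$genome, file.path(dir, "genome.fa"))
    write_annotation_gff3(sim$annotation, file.path(dir, "annotation.gff3"))
    write_predictions_gff3(predictions, file.path(dir, "predictions.gff3"))
    write_fastq(reads$reads1, file.path(dir, "reads_1.fastq"))
    write_fastq(reads$reads2, file.path(dir, "reads_2.fastq"))
    write_junction_bed(truth_junctions, file.path(dir, "truth_junctions.bed"),
                       name = truth_junctions$label)
    write_splice_params(sim$models, file.path(dir, "params.txt"))
  }
  out
}
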