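## Junction aggregation and the nine classification features.

mk_aln <- function(read_id, blocks, strand = "+", spliced = TRUE, seq = "chr1") {
  data.frame(read_id = read_id, seq = seq, strand = strand, blocks = blocks,
             mismatches = 0L, spliced = spliced, stringsAsFactors = FALSE)
}

## toy genome whose [200, 280) interval is a GT..AG intron
toy_feature_genome <- function() {
  fx <- toy_junction_genome(exon1_len = 50, intron_len = 80, exon2_len = 50)
  fx
}

test_that("aggregation groups alignments by unique junction key", {
  fx <- toy_feature_genome()
  a <- do.call(rbind, lapply(1:5, function(i)
    mk_aln(sprintf("r%d/1", i),
           sprintf("%d:%d,%d:%d", fx$donor_pos - 20 - i, 20 + i, fx$acceptor_end, 30))))
  cand <- aggregate_junctions(a, fx$genome)
  expect_equal(nrow(cand$junctions), 1)
  expect_equal(cand$junctions$depth, 5)
  expect_equal(cand$junctions$donor_pos, fx$donor_pos)
  ## one 3-block alignment contributes to two junctions, each depth 1
  g3 <- two_junction_genome()
  a3 <- mk_aln("r/1", sprintf("%d:20,%d:30,%d:20", g3$j1[1] - 20, g3$j1[2], g3$j2[2]))
  c3 <- aggregate_junctions(a3, g3$genome)
  expect_equal(nrow(c3$junctions), 2)
  expect_equal(c3$junctions$depth, c(1, 1))
  ## middle block overhangs are reported per junction
  expect_equal(c3$supports$right_overhang[1], 30)
  expect_equal(c3$supports$left_overhang[2], 30)
})

test_that("aggregation equals a brute-force group-by on simulated alignments", {
  ds <- small_dataset()
  idx <- genome_index(ds$sim$genome, k = 20)
  reads <- c(ds$reads$reads1, ds$reads$reads2)[1:800]
  st <- align_reads(reads, idx, ds$sim$models, sj_constraints())
  cand <- aggregate_junctions(st$alignments, ds$sim$genome)
  ai <- alignment_introns(st$alignments, ds$sim$genome)
  oracle <- table(paste(ai$seq, ai$donor_pos, ai$acceptor_end, ai$strand))
  got <- setNames(cand$junctions$depth, splicefinder:::junction_key(cand$junctions))
  expect_equal(sort(names(got)), sort(names(oracle)))
  expect_equal(as.integer(got[names(oracle)]), as.integer(oracle))
})

test_that("entropy, overhang and skew follow their stated formulas", {
  fx <- toy_feature_genome()
  d <- fx$donor_pos; a <- fx$acceptor_end
  ## 7 supports at a single offset: entropy 0
  a1 <- do.call(rbind, lapply(1:7, function(i)
    mk_aln(sprintf("r%d/1", i), sprintf("%d:%d,%d:%d", d - 20, 20, a, 30))))
  cand <- aggregate_junctions(a1, fx$genome)
  f <- compute_alignment_features(cand, a1)
  expect_equal(f$entropy, 0)
  expect_equal(f$depth, 7)
  expect_equal(f$min_overhang, 20)
  ## 8 supports uniform over 4 offsets: -sum(2 * log2(2/8)) * 4 = 16 bits
  a2 <- do.call(rbind, lapply(1:8, function(i) {
    off <- 14 + 2 * ((i - 1) %% 4)
    mk_aln(sprintf("q%d/1", i), sprintf("%d:%d,%d:%d", d - off, off, a, 30))
  }))
  cand2 <- aggregate_junctions(a2, fx$genome)
  f2 <- compute_alignment_features(cand2, a2)
  expect_equal(f2$entropy, 16)
  ## skew: 3 junction reads vs 15 ungapped reads crossing the donor boundary
  spliced <- do.call(rbind, lapply(1:3, function(i)
    mk_aln(sprintf("s%d/1", i), sprintf("%d:%d,%d:%d", d - 20 - i, 20 + i, a, 30))))
  ung <- do.call(rbind, lapply(1:15, function(i)
    mk_aln(sprintf("u%d/1", i), sprintf("%d:60", d - 30 - i), spliced = FALSE)))
  cand3 <- aggregate_junctions(spliced, fx$genome)
  f3 <- compute_alignment_features(cand3, rbind(spliced, ung))
  expect_equal(f3$skew, log2(4 / 16))
})

test_that("entropy grows when a support moves to a previously empty offset", {
  fx <- toy_feature_genome()
  d <- fx$donor_pos; a <- fx$acceptor_end
  ent_of <- function(offsets) {
    al <- do.call(rbind, lapply(seq_along(offsets), function(i)
      mk_aln(sprintf("e%d/1", i), sprintf("%d:%d,%d:%d", d - offsets[i], offsets[i], a, 30))))
    compute_alignment_features(aggregate_junctions(al, fx$genome), al)$entropy
  }
  for (C in 2:6) {
    for (occupied in 1:(C - 1)) {
      ## C supports over `occupied` offsets, then move one support to a new offset
      before <- rep(seq(10, by = 2, length.out = occupied), length.out = C)
      after <- before; after[C] <- 10 + 2 * occupied
      if (length(unique(after)) == length(unique(before))) next
      expect_gt(ent_of(after), ent_of(before))
    }
  }
})

test_that("sequence features are strand-symmetric and maximal at the mode", {
  ds <- small_dataset()
  models <- ds$sim$models
  genome <- ds$sim$genome
  intr <- ds$sim$annotation$introns
  plus <- intr[intr$strand == "+", ][1, ]
  ## the same intron represented on the reverse-complemented genome scores
  ## identically with flipped strand
  g <- genome[[1]]; glen <- nchar(g)
  rc_genome <- c(chr1 = revcomp(g))
  rc_intron <- data.frame(seq = "chr1",
                          donor_pos = glen - plus$acceptor_end,
                          acceptor_end = glen - plus$donor_pos, strand = "-")
  w1 <- splicefinder:::extract_site_windows(plus, genome)
  w2 <- splicefinder:::extract_site_windows(rc_intron, rc_genome)
  expect_equal(w1$donor, w2$donor)
  expect_equal(w1$acceptor, w2$acceptor)
  ## PSFM-consistent donors outscore random background windows
  set.seed(55)
  win <- splicefinder:::extract_site_windows(intr, genome)
  real <- vapply(win$donor[!is.na(win$donor)][1:30], score_splice_site,
                 0, site_type = "donor", models = models)
  rand <- vapply(1:1000, function(i)
    score_splice_site(paste(sample(BASES, 9, replace = TRUE, prob = models$background$probs),
                            collapse = ""), "donor", models), 0)
  expect_gt(median(real), median(rand))
  ## gap log-likelihood peaks at the modal simulated length
  il <- models$intron_lengths
  lens <- seq(il$min_len, il$max_len, by = il$bin_width)
  ll <- intron_length_loglik(lens, il)
  modal <- lens[which.max(il$pmf)]
  expect_equal(intron_length_loglik(modal, il), max(ll))
})

test_that("indicator features follow gene predictions", {
  ## toy gene: two CDS exons [100,160) + [240,300) on +, intron [160,240)
  pred <- gene_predictions(
    genes = data.frame(gene_id = "g1", seq = "chr1", strand = "+"),
    exons = data.frame(gene_id = "g1", seq = "chr1", start = c(100, 240), end = c(160, 300)),
    introns = data.frame(seq = "chr1", donor_pos = 160, acceptor_end = 240, strand = "+"))
  cand_of <- function(d, a, strand = "+") {
    structure(list(junctions = data.frame(junction = 1L, seq = "chr1", donor_pos = d,
                                          acceptor_end = a, strand = strand,
                                          class = 1L, depth = 1L),
                   supports = data.frame(junction = 1L, read_id = "r/1",
                                         left_overhang = 20L, right_overhang = 20L,
                                         offset = d - 20L)), class = "sj_candidates")
  }
  ## candidate matching the predicted intron: concordant, frame preserved
  expect_equal(unlist(compute_indicators(cand_of(160, 240), pred)[c("frameshift", "strand_discord")]),
               c(frameshift = 0L, strand_discord = 0L))
  ## opposite strand inside the gene
  expect_equal(compute_indicators(cand_of(160, 240, "-"), pred)$strand_discord, 1L)
  ## codon-walk oracle: intron inside one CDS exon shifts the frame iff its
  ## length is not a multiple of 3
  for (ilen in c(21, 22, 23, 24, 25)) {
    ind <- compute_indicators(cand_of(110, 110 + ilen), pred)
    expect_equal(ind$frameshift, as.integer(ilen %% 3 != 0))
  }
  ## splicing 160 -> 241 skips one coding base: frameshift
  expect_equal(compute_indicators(cand_of(160, 241), pred)$frameshift, 1L)
})

test_that("feature recomputation is bit-identical", {
  ds <- small_dataset()
  idx <- genome_index(ds$sim$genome, k = 20)
  reads <- c(ds$reads$reads1, ds$reads$reads2)[1:600]
  st <- align_reads(reads, idx, ds$sim$models, sj_constraints())
  cand <- aggregate_junctions(st$alignments, ds$sim$genome)
  f1 <- junction_features(cand, st$alignments, ds$sim$genome, ds$sim$models, ds$predictions)
  f2 <- junction_features(cand, st$alignments, ds$sim$genome, ds$sim$models, ds$predictions)
  expect_identical(f1, f2)
})

test_that("true junctions dominate noise junctions on overhang and entropy", {
  b <- benchmark_run()
  feats <- b$pl$features
  tk <- splicefinder:::junction_key(
    b$ds$truth_junctions[b$ds$truth_junctions$label == "functional", ])
  is_true <- splicefinder:::junction_key(feats) %in% tk
  skip_if(sum(is_true) < 100 || sum(!is_true) < 100)
  set.seed(1)
  n <- min(500, sum(is_true), sum(!is_true))
  tv <- feats[is_true, ][sample(sum(is_true), n), ]
  fv <- feats[!is_true, ][sample(sum(!is_true), n), ]
  expect_lt(wilcox.test(tv$min_overhang, fv$min_overhang, alternative = "greater")$p.value, 0.01)
  expect_lt(wilcox.test(tv$entropy, fv$entropy, alternative = "greater")$p.value, 0.01)
})
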