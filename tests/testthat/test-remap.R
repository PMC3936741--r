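## Pseudo-transcript construction, remapping of unmapped reads and the
## paired-end consistency filter.

test_that("pseudo-transcript count is exactly 2^n and lengths at most 2L", {
  fx <- two_junction_genome()
  L <- 60L
  j1 <- data.frame(seq = "chr1", donor_pos = fx$j1[1], acceptor_end = fx$j1[2])
  ## n = 0 neighbors
  pt <- build_pseudo_transcripts(j1, fx$genome, L)
  expect_equal(nrow(pt), 1)
  expect_equal(nchar(pt$sequence), 2 * L)
  ## n = 1: the second junction lies within L of the first
  j2 <- rbind(j1, data.frame(seq = "chr1", donor_pos = fx$j2[1], acceptor_end = fx$j2[2]))
  pt2 <- build_pseudo_transcripts(j2, fx$genome, L)
  expect_equal(as.vector(table(pt2$junction)), c(2, 2))
  expect_true(all(nchar(pt2$sequence) <= 2 * L))
  ## n = 2 around a focal junction gives 4 transcripts for it
  j3 <- rbind(j2, data.frame(seq = "chr1", donor_pos = fx$j2[1] + 2,
                             acceptor_end = fx$j2[2] - 3))
  pt3 <- build_pseudo_transcripts(j3, fx$genome, L)
  expect_equal(sum(pt3$junction == 1), 4)
})

test_that("pseudo-transcript sequences equal splice-by-hand constructions", {
  fx <- two_junction_genome()
  g <- fx$genome[[1]]
  L <- 60L
  jn <- data.frame(seq = "chr1",
                   donor_pos = c(fx$j1[1], fx$j2[1]),
                   acceptor_end = c(fx$j1[2], fx$j2[2]))
  pt <- build_pseudo_transcripts(jn, fx$genome, L)
  f1 <- pt[pt$junction == 1, ]
  sub0 <- function(a, b) substr(g, a + 1, b)  # 0-based half-open
  ## mask 0: neighbor unspliced -> plain L nt on each side of junction 1
  expect_equal(f1$sequence[f1$mask == 0],
               paste0(sub0(fx$j1[1] - L, fx$j1[1]), sub0(fx$j1[2], fx$j1[2] + L)))
  ## mask 1: neighbor (junction 2) spliced out of the downstream walk
  mid <- fx$j2[1] - fx$j1[2]   # middle exon length
  expect_equal(f1$sequence[f1$mask == 1],
               paste0(sub0(fx$j1[1] - L, fx$j1[1]),
                      sub0(fx$j1[2], fx$j2[1]), sub0(fx$j2[2], fx$j2[2] + (L - mid))))
  ## coordinate projection is the identity through the blocks map
  for (i in seq_len(nrow(pt))) {
    bm <- splicefinder:::decode_blocks(pt$blocks[i])
    expect_equal(paste(substring(g, bm[, 1] + 1, bm[, 1] + bm[, 2]), collapse = ""),
                 pt$sequence[i])
    total <- sum(bm[, 2])
    for (pos in c(0, 5, total - 10)) {
      pm <- splicefinder:::project_interval(bm, pos, 5)
      expect_equal(sum(pm[, 2]), 5)
    }
  }
})

test_that("remapping rescues a read spanning two close junctions", {
  fx <- two_junction_genome(mid_len = 30)
  idx <- genome_index(fx$genome, k = 16)
  tlen <- nchar(fx$transcript)
  start <- 81 - 20   # 20 nt in exon1, middle exon, and the rest in exon2
  read <- substr(fx$transcript, start, start + 59)
  cs <- sj_constraints(seg_len = 25L)
  ## the anchor-and-extend stage cannot place it (one intron per gap)
  direct <- anchor_extend(read, idx, constraints = cs)
  expect_true(nrow(direct) == 0 || !any(grepl(",.*,", direct$blocks)))
  jn <- data.frame(seq = "chr1", donor_pos = c(fx$j1[1], fx$j2[1]),
                   acceptor_end = c(fx$j1[2], fx$j2[2]))
  pt <- build_pseudo_transcripts(jn, fx$genome, 60L)
  res <- remap_unmapped(c("r/1" = read), pt, cs)
  expect_gt(nrow(res), 0)
  three <- grepl(",.*,", res$blocks)
  expect_true(any(three))
  ii <- splicefinder:::blocks_to_introns(res$blocks[three][1])
  expect_equal(unname(ii[, "donor_pos"]), c(fx$j1[1], fx$j2[1]))
  expect_equal(unname(ii[, "acceptor_end"]), c(fx$j1[2], fx$j2[2]))
})

test_that("a read matching an unspliced mask projects without introns", {
  fx <- two_junction_genome()
  g <- fx$genome[[1]]
  jn <- data.frame(seq = "chr1", donor_pos = fx$j1[1], acceptor_end = fx$j1[2])
  pt <- build_pseudo_transcripts(jn, fx$genome, 60L)
  ## intronic read: matches only the upstream half of the pseudo-transcript
  read <- substr(g, fx$j1[1] - 59, fx$j1[1])
  res <- remap_unmapped(c("r/1" = read), pt, sj_constraints())
  expect_true(all(!res$spliced))
  expect_true(all(!grepl(",", res$blocks)))
})

test_that("pair filtering enforces opposite strands and coordinate order", {
  base <- data.frame(read_id = c("p1/1", "p1/2"), seq = "chr1",
                     strand = c("+", "-"),
                     blocks = c("100:30,220:30", "400:60"),
                     mismatches = 0L, spliced = c(TRUE, FALSE),
                     stringsAsFactors = FALSE)
  expect_equal(nrow(filter_pairs(base)), 2)          # proper FR pair kept
  bad <- base; bad$strand <- c("+", "+")
  expect_equal(filter_pairs(bad)$read_id, "p1/2")    # spliced same-strand removed
  rev_ord <- base; rev_ord$blocks <- c("500:30,620:30", "100:60")
  expect_equal(filter_pairs(rev_ord)$read_id, "p1/2")  # plus-mate must be left
  single <- base[1, ]
  expect_equal(nrow(filter_pairs(single)), 1)        # singletons pass
})

test_that("deliberately mis-stranded spliced mates are exactly the ones removed", {
  set.seed(29)
  n <- 500
  rows <- list()
  flip <- sort(sample(n, 50))
  for (i in seq_len(n)) {
    s1 <- if (i %in% flip) "-" else "+"
    rows[[2 * i - 1]] <- data.frame(read_id = sprintf("p%03d/1", i), seq = "chr1",
                                    strand = s1, blocks = sprintf("%d:30,%d:30", i * 10, i * 10 + 120),
                                    mismatches = 0L, spliced = TRUE, stringsAsFactors = FALSE)
    rows[[2 * i]] <- data.frame(read_id = sprintf("p%03d/2", i), seq = "chr1",
                                strand = "-", blocks = sprintf("%d:60", i * 10 + 300),
                                mismatches = 0L, spliced = FALSE, stringsAsFactors = FALSE)
  }
  aln <- do.call(rbind, rows)
  out <- filter_pairs(aln)
  removed <- setdiff(aln$read_id, out$read_id)
  expect_equal(removed, sprintf("p%03d/1", flip))
  ## idempotence
  expect_equal(filter_pairs(out), out)
})

test_that("remapped alignments respect aligner invariants on simulated data", {
  ds <- small_dataset()
  idx <- genome_index(ds$sim$genome, k = 20)
  reads <- c(ds$reads$reads1, ds$reads$reads2)[1:1000]
  cs <- sj_constraints()
  st <- align_reads(reads, idx, ds$sim$models, cs)
  cand <- aggregate_junctions(st$alignments, ds$sim$genome)
  skip_if(nrow(cand$junctions) == 0)
  pt <- suppressWarnings(build_pseudo_transcripts(cand$junctions, ds$sim$genome, 75L))
  rm2 <- remap_unmapped(reads[st$unmapped], pt, cs)
  for (i in seq_len(nrow(rm2))) {
    b <- splicefinder:::decode_blocks(rm2$blocks[i])
    expect_equal(sum(b[, "len"]), 75)
    if (nrow(b) > 1) {
      expect_true(all(b[, "len"] >= cs$min_overhang))
      gaps <- b[-1, 1] - (b[-nrow(b), 1] + b[-nrow(b), 2])
      expect_true(all(gaps >= cs$min_intron & gaps < cs$max_intron))
    }
  }
})
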