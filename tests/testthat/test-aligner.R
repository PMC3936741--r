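## Genome index, ungapped placement, read segmentation and the
## anchor-and-extend gapped aligner.

test_that("index lookup returns exactly the occurrence positions", {
  idx <- genome_index(c(chrA = "ACGTACGT"), k = 8)
  expect_error(genome_index(c(chrA = "ACGTACGT"), k = 4), "k must be >= 8")
  ## use an 8-mer index on a longer toy sequence for the classic example
  idx <- genome_index(c(chrA = paste0("ACGTACGT", strrep("A", 20))), k = 8)
  hit <- index_lookup(idx, "CGTACGTA")
  expect_equal(hit$pos[hit$strand == "+"], 1)
  expect_equal(nrow(index_lookup(idx, "GGGGGGGG")), 0)
})

test_that("index lookups equal a naive string-scan on a random genome", {
  set.seed(23)
  g <- paste(sample(BASES, 10000, replace = TRUE), collapse = "")
  idx <- genome_index(c(chr1 = g), k = 12)
  for (i in 1:200) {
    p <- sample(10000 - 12, 1)
    km <- substr(g, p, p + 11)
    hits <- index_lookup(idx, km)
    fwd <- sort(hits$pos[hits$strand == "+"])
    ## oracle: fixed-width scan over every offset
    scan <- which(vapply(1:(10000 - 11), function(o)
      substr(g, o, o + 11) == km, TRUE)) - 1L
    expect_equal(fwd, scan)
    rcscan <- which(vapply(1:(10000 - 11), function(o)
      substr(g, o, o + 11) == revcomp(km), TRUE)) - 1L
    expect_equal(sort(hits$pos[hits$strand == "-"]), rcscan)
  }
})

test_that("ungapped placement matches a full Hamming-scan oracle", {
  set.seed(31)
  g <- paste(sample(BASES, 4000, replace = TRUE), collapse = "")
  genome <- c(chr1 = g)
  idx <- genome_index(genome, k = 16)
  ## exact unique substring: one placement, 0 mismatches
  r0 <- substr(g, 501, 560)
  a0 <- align_ungapped(c(x = r0), idx)
  expect_equal(nrow(a0), 1)
  expect_equal(a0$blocks, "500:60")
  expect_equal(a0$mismatches, 0)
  ## three substitutions exceed the budget
  r3 <- r0
  for (p in c(5, 25, 45)) substr(r3, p, p) <- setdiff(BASES, substr(r3, p, p))[1]
  expect_equal(nrow(align_ungapped(c(x = r3), idx, max_mismatch = 2)), 0)
  ## randomized agreement with the scan oracle
  for (i in 1:60) {
    p <- sample(4000 - 60, 1)
    r <- substr(g, p, p + 59)
    nmm <- sample(0:2, 1)
    if (nmm > 0) for (q in sample(60, nmm))
      substr(r, q, q) <- setdiff(BASES, substr(r, q, q))[sample(3, 1)]
    if (sample(c(TRUE, FALSE), 1)) r <- revcomp(r)
    got <- align_ungapped(c(x = r), idx, max_mismatch = 2, max_hits = 100)
    want <- hamming_scan_oracle(r, genome, 2)
    got_key <- sort(paste(sub(":.*", "", got$blocks), got$strand, got$mismatches))
    want_key <- sort(paste(want$pos, want$strand, want$mismatches))
    expect_equal(got_key, want_key)
  }
})

test_that("read segmentation is non-overlapping, covering, remainder-merged", {
  s <- segment_read(strrep("A", 76), 25)
  expect_equal(s$offset, c(0, 25, 50))
  expect_equal(s$length, c(25, 25, 26))
  s <- segment_read(strrep("A", 50), 25)
  expect_equal(s$length, c(25, 25))
  r <- paste(sample(BASES, 100, replace = TRUE), collapse = "")
  s <- segment_read(r, 18)
  expect_equal(nrow(s), 5)
  expect_equal(s$length[5], 28)
  expect_equal(paste(substring(r, s$offset + 1, s$offset + s$length), collapse = ""), r)
  expect_equal(segment_read("ACGT", 20)$length, 4)
})

test_that("anchor-and-extend recovers a planted junction and honours overhangs", {
  fx <- toy_junction_genome()
  idx <- genome_index(fx$genome, k = 16)
  ## read straddling the junction with 30 nt on each side
  read <- paste0(substr(fx$transcript, 31, 90))
  aln <- anchor_extend(read, idx, constraints = sj_constraints())
  expect_equal(nrow(aln), 1)
  b <- splicefinder:::decode_blocks(aln$blocks)
  expect_equal(nrow(b), 2)
  ii <- splicefinder:::blocks_to_introns(aln$blocks)
  expect_equal(unname(ii[1, "donor_pos"]), fx$donor_pos)
  expect_equal(unname(ii[1, "acceptor_end"]), fx$acceptor_end)
  ## only 5 nt on the right of the junction: the overhang rule forbids it
  read5 <- substr(fx$transcript, 61 - 55, 65)
  expect_equal(nchar(read5), 60)
  aln5 <- anchor_extend(read5, idx, constraints = sj_constraints())
  if (nrow(aln5)) expect_true(all(!grepl(",", aln5$blocks)))
})

test_that("emitted spliced alignments never violate the structural invariants", {
  ds <- small_dataset()
  idx <- genome_index(ds$sim$genome, k = 20)
  reads <- c(ds$reads$reads1[1:400], ds$reads$reads2[1:400])
  res <- align_reads(reads, idx, ds$sim$models, sj_constraints())
  spl <- res$alignments[res$alignments$spliced, ]
  expect_gt(nrow(spl), 50)
  for (i in seq_len(nrow(spl))) {
    b <- splicefinder:::decode_blocks(spl$blocks[i])
    expect_equal(sum(b[, "len"]), nchar(reads[[spl$read_id[i]]]))
    expect_true(all(b[, "len"] >= 8))
    gaps <- b[-1, "start"] - (b[-nrow(b), "start"] + b[-nrow(b), "len"])
    expect_true(all(gaps >= 20 & gaps < 10000))
  }
  ai <- alignment_introns(spl, ds$sim$genome)
  expect_true(all(!is.na(ai$class)))
})

test_that("aligning the reverse complement yields the mirrored placements", {
  fx <- toy_junction_genome()
  idx <- genome_index(fx$genome, k = 16)
  read <- substr(fx$transcript, 31, 90)
  a1 <- anchor_extend(read, idx)
  a2 <- anchor_extend(revcomp(read), idx)
  expect_equal(a1$blocks, a2$blocks)
  expect_equal(nrow(a1), nrow(a2))
  expect_true(all(a1$strand != a2$strand))
})

test_that("anchor-and-extend agrees with the exhaustive gap enumeration oracle", {
  ds <- small_dataset(seed = 13)
  g <- ds$sim$genome[[1]]
  gdna <- Biostrings::DNAString(g)
  graw <- charToRaw(g)
  din <- dinuc_position_index(g)
  idx <- genome_index(ds$sim$genome, k = 16)
  models <- ds$sim$models
  cs <- sj_constraints()
  cfg0 <- ds$config; cfg0$error_rate <- 0
  reads0 <- simulate_reads(ds$pool, cfg0)
  truth <- reads0$truth
  min_block <- vapply(truth$blocks, function(b)
    min(splicefinder:::decode_blocks(b)[, "len"]), 0L, USE.NAMES = FALSE)
  spanning <- which(grepl(",", truth$blocks) & min_block >= cs$min_overhang)
  rd <- c(reads0$reads1, reads0$reads2)
  checked <- 0L
  for (i in spanning[1:150]) {
    id <- truth$read_id[i]
    q0 <- rd[[id]]
    if (nrow(align_ungapped(setNames(q0, id), idx, cs$max_mismatch, 1L))) next
    q <- if (truth$strand[i] == "+") q0 else revcomp(q0)
    oracle <- oracle_spliced_alignment(q, gdna, g, graw, din, models, cs)
    if (is.null(oracle)) next
    aln <- anchor_extend(q0, idx, models, cs, read_id = id)
    expect_gt(nrow(aln), 0)
    expect_equal(min(aln$mismatches), oracle$mm)
    found <- FALSE
    for (r in seq_len(nrow(aln))) {
      ii <- splicefinder:::blocks_to_introns(aln$blocks[r])
      if (nrow(ii) == nrow(oracle$introns) && all(ii == oracle$introns)) found <- TRUE
    }
    expect_true(found)
    checked <- checked + 1L
  }
  expect_gt(checked, 50)
})
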