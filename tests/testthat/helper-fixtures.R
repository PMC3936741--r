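## Shared fixtures. Everything is generated in code at test time; the
## standard synthetic benchmark (100 kb genome, 200 genes, 50k read pairs,
## seed 1) is expensive, so it is built lazily once per test session.

.fixture_env <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")

## toy genome with two introns separated by a short middle exon:
## exon1 - intron1 - middle exon - intron2 - exon2
two_junction_genome <- function(mid_len = 30, seed = 17) {
  set.seed(seed)
  rb <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")
  e1 <- rb(80); em <- rb(mid_len); e2 <- rb(80)
  i1 <- paste0("GTAAGT", rb(40), "TTCTTTTCTTTCTTCTACAG")
  i2 <- paste0("GTAAGT", rb(54), "TTCTTTTCTTTCTTCTACAG")
  genome <- c(chr1 = paste0(rb(120), e1, i1, em, i2, e2, rb(120)))
  d1 <- 120 + 80; a1 <- d1 + nchar(i1)
  d2 <- a1 + mid_len; a2 <- d2 + nchar(i2)
  list(genome = genome, transcript = paste0(e1, em, e2),
       j1 = c(d1, a1), j2 = c(d2, a2))
}

## standard synthetic benchmark dataset + full pipeline run
benchmark_run <- function() {
  if (is.null(.fixture_env$bench)) {
    cfg <- sim_config(seed = 1)
    ds <- simulate_dataset(cfg)
    pl <- suppressWarnings(run_pipeline(
      ds$sim$genome, ds$reads$reads1, ds$reads$reads2,
      models = ds$sim$models, predictions = ds$predictions,
      annotation = ds$sim$annotation, train_size = 600L, dev_size = 600L, seed = 1))
    .fixture_env$bench <- list(ds = ds, pl = pl)
  }
  .fixture_env$bench
}

## small dataset for unit-scale checks
small_dataset <- function(seed = 7) {
  key <- paste0("small", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- sim_config(genome_len = 20000L, n_genes = 30L, n_pairs = 1500L,
                      noise_per_gene = 5L, seed = seed)
    .fixture_env[[key]] <- simulate_dataset(cfg)
  }
  .fixture_env[[key]]
}

## deterministic toy genome with one gene: exon1 - intron (GT..AG) - exon2,
## returns coordinates of the junction
toy_junction_genome <- function(exon1_len = 60, intron_len = 80, exon2_len = 60,
                                seed = 11) {
  set.seed(seed)
  rb <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                                 prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  exon1 <- rb(exon1_len)
  exon2 <- rb(exon2_len)
  intron <- paste0("GTAAGT", rb(intron_len - 26), "TTTTTTTTTTCTTTCACTAG")
  pad1 <- rb(150); pad2 <- rb(150)
  genome <- c(chr1 = paste0(pad1, exon1, intron, exon2, pad2))
  list(genome = genome, donor_pos = 150 + exon1_len,
       acceptor_end = 150 + exon1_len + intron_len,
       exon1 = c(150, 150 + exon1_len),
       exon2 = c(150 + exon1_len + intron_len, 150 + exon1_len + intron_len + exon2_len),
       transcript = paste0(exon1, exon2))
}

## independent brute-force ungapped placement oracle: scans every genome
## offset on both strands counting mismatches by character comparison
hamming_scan_oracle <- function(read, genome, max_mismatch) {
  hits <- list()
  for (sq in names(genome)) {
    g <- strsplit(genome[[sq]], "")[[1]]
    for (strand in c("+", "-")) {
      q <- strsplit(if (strand == "+") read else revcomp(read), "")[[1]]
      L <- length(q)
      for (p in 0:(length(g) - L)) {
        mm <- sum(g[(p + 1):(p + L)] != q)
        if (mm <= max_mismatch)
          hits[[length(hits) + 1L]] <- data.frame(seq = sq, pos = p, strand = strand,
                                                  mismatches = mm)
      }
    }
  }
  if (!length(hits)) return(data.frame(seq = character(0), pos = integer(0),
                                       strand = character(0), mismatches = integer(0)))
  do.call(rbind, hits)
}
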