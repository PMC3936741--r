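## Sequence models: PSFM estimation, splice-site scoring, intron length
## likelihood and parameter-file serialization.

`%+%` <- function(a, b) paste0(a, b)

make_intron_genome <- function(n, donor_exonic = "ACG", seed = 3) {
  ## one contig per intron; donor window is donor_exonic + "GTAAGT"
  set.seed(seed)
  seqs <- character(n)
  introns <- data.frame(seq = sprintf("s%04d", seq_len(n)), donor_pos = 33L,
                        acceptor_end = 0L, strand = "+", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    mid <- paste(sample(BASES, 40, replace = TRUE), collapse = "")
    acc <- paste0(paste(sample(c("T", "C"), 18, replace = TRUE), collapse = ""), "AG")
    pad <- paste(sample(BASES, 30, replace = TRUE), collapse = "")
    seqs[i] <- paste0(pad, donor_exonic, "GTAAGT", mid, acc, "G",
                      paste(sample(BASES, 30, replace = TRUE), collapse = ""))
    introns$acceptor_end[i] <- 33L + 6L + 40L + 20L
  }
  names(seqs) <- introns$seq
  list(genome = seqs, introns = introns)
}

test_that("degenerate estimation puts all mass on a constant donor window", {
  fx <- make_intron_genome(1000)
  m <- estimate_splice_models(fx$introns, fx$genome, pseudocount = 1e-9)
  consensus <- strsplit("ACGGTAAGT", "")[[1]]
  marg <- m$donor$marginal
  for (j in 1:9) expect_gt(marg[consensus[j], j], 0.999)
})

test_that("first-order PSFM estimation recovers the generating marginals", {
  cfg <- sim_config(seed = 5)
  gen <- splicefinder:::default_generating_models(cfg)
  set.seed(41)
  win <- splicefinder:::sample_psfm_windows(gen$donor, 5000)
  est <- splicefinder:::estimate_psfm(win, "donor", order = 1L, pseudocount = 0.5)
  est_marg <- t(vapply(seq_len(9), function(j)
    as.numeric(table(factor(substr(win, j, j), levels = BASES)) / 5000), numeric(4)))
  truth <- splicefinder:::psfm_implied_marginal(gen$donor)
  expect_lt(max(abs(t(est_marg) - truth)), 0.05)
  ## the model's own stored marginals agree with the empirical ones
  expect_lt(max(abs(est$marginal - t(est_marg))), 0.05)
})

test_that("estimation errors shrink with more training introns", {
  cfg <- sim_config(seed = 5)
  gen <- splicefinder:::default_generating_models(cfg)
  truth <- splicefinder:::psfm_implied_marginal(gen$acceptor)
  err <- sapply(c(1000, 5000), function(n) {
    set.seed(100 + n)
    win <- splicefinder:::sample_psfm_windows(gen$acceptor, n)
    emp <- t(vapply(seq_len(21), function(j)
      as.numeric(table(factor(substr(win, j, j), levels = BASES)) / n), numeric(4)))
    max(abs(t(emp) - truth))
  })
  expect_lte(err[2], err[1] + 0.01)
  expect_lt(err[2], 0.05)
})

test_that("too few introns is refused with the count in the message", {
  fx <- make_intron_genome(10)
  expect_error(estimate_splice_models(fx$introns, fx$genome), "too few introns.*10")
})

test_that("a deterministic PSFM against uniform background scores width * 2 bits", {
  eps <- 1e-12
  consensus <- strsplit("ACGGTAAGT", "")[[1]]
  marg <- matrix(eps, 4, 9, dimnames = list(BASES, NULL))
  for (j in 1:9) marg[consensus[j], j] <- 1 - 3 * eps
  models <- new_splice_models(
    new_psfm("donor", marg),
    new_psfm("acceptor", matrix(0.25, 4, 21)),
    new_background(rep(0.25, 4)),
    new_intron_length_dist(60, 159, rep(0.1, 10)))
  expect_equal(score_splice_site("ACGGTAAGT", "donor", models), 9 * log2(4),
               tolerance = 1e-6)
  ## acceptor PSFM identical to background: any window scores 0
  expect_equal(score_splice_site(strrep("ACGT", 5) %+% "A", "acceptor", models), 0)
})

test_that("scores equal a brute-force chained-probability oracle", {
  set.seed(19)
  ## random first-order donor PSFM
  rdir <- function(n) { x <- rgamma(n, 1.5) + 0.05; x / sum(x) }
  marg <- vapply(1:9, function(j) rdir(4), numeric(4))
  cond <- array(0, dim = c(4, 4, 9))
  for (j in 1:9) for (p in 1:4) cond[p, , j] <- rdir(4)
  cond[, , 1] <- 1
  bg <- rdir(4)
  models <- new_splice_models(
    new_psfm("donor", marg, cond, order = 1L),
    new_psfm("acceptor", matrix(0.25, 4, 21)),
    new_background(bg),
    new_intron_length_dist(60, 159, rep(0.1, 10)))
  for (i in 1:1000) {
    w <- paste(sample(BASES, 9, replace = TRUE), collapse = "")
    chars <- match(strsplit(w, "")[[1]], BASES)
    p_model <- marg[chars[1], 1]
    for (j in 2:9) p_model <- p_model * cond[chars[j - 1], chars[j], j]
    p_bg <- prod(bg[chars])
    expect_equal(score_splice_site(w, "donor", models), log2(p_model) - log2(p_bg),
                 tolerance = 1e-9)
  }
})

test_that("windows with N score via the background on both sides", {
  models <- new_splice_models(
    new_psfm("donor", matrix(c(0.7, 0.1, 0.1, 0.1), 4, 9)),
    new_psfm("acceptor", matrix(0.25, 4, 21)),
    new_background(rep(0.25, 4)),
    new_intron_length_dist(60, 159, rep(0.1, 10)))
  full <- score_splice_site("AAAAAAAAA", "donor", models)
  with_n <- score_splice_site("AAAANAAAA", "donor", models)
  ## the N position contributes 0 bits; its successor falls back to the marginal
  expect_lt(with_n, full)
  expect_true(is.finite(with_n))
  expect_error(score_splice_site("AAAA", "donor", models), "width 9")
})

test_that("intron length log-likelihood follows the binned pmf", {
  d <- new_intron_length_dist(60, 159, rep(0.1, 10))
  expect_equal(intron_length_loglik(60, d), log2(0.1))
  expect_equal(intron_length_loglik(123, d), log2(0.1))
  expect_equal(intron_length_loglik(12000, d), log2(1e-6))
  expect_error(intron_length_loglik(0, d), "length")
  ## empirical: the modal bin scores at least as high as every other bin
  set.seed(8)
  lens <- pmin(pmax(round(rlnorm(5000, log(80), 0.3)), 45), 400)
  emp <- splicefinder:::estimate_intron_length_dist(lens)
  ll <- intron_length_loglik(seq(emp$min_len, emp$max_len, by = emp$bin_width), emp)
  modal_len <- emp$min_len + (which.max(emp$pmf) - 1L) * emp$bin_width
  expect_equal(intron_length_loglik(modal_len, emp), max(ll))
})

test_that("parameter files round-trip exactly and fail loudly when malformed", {
  fx <- make_intron_genome(200)
  m <- estimate_splice_models(fx$introns, fx$genome)
  path <- tempfile(fileext = ".txt")
  write_splice_params(m, path)
  m2 <- read_splice_params(path)
  expect_equal(m2$donor$marginal, m$donor$marginal, tolerance = 0)
  expect_equal(m2$donor$cond, m$donor$cond, tolerance = 0)
  expect_equal(m2$acceptor$marginal, m$acceptor$marginal, tolerance = 0)
  expect_equal(m2$background$probs, m$background$probs, tolerance = 0)
  expect_equal(m2$intron_lengths, m$intron_lengths, tolerance = 0)

  ## missing acceptor section
  lines <- readLines(path)
  drop <- grep("^\\[acceptor\\]", lines):(grep("^\\[background\\]", lines) - 1)
  writeLines(lines[-drop], path)
  expect_error(read_splice_params(path), "acceptor")

  ## donor marginal row not summing to 1: error names the position
  write_splice_params(m, path)
  lines <- readLines(path)
  i <- grep("^marginal$", lines)[1] + 3   # donor position 3
  f <- strsplit(lines[i], "\t")[[1]]
  f[2] <- sprintf("%.17g", as.numeric(f[2]) - 0.1)
  lines[i] <- paste(f, collapse = "\t")
  writeLines(lines, path)
  expect_error(read_splice_params(path), "position 3")
})
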