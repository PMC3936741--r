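## Self-labelled set construction, SVM grid search on W = TP - FP, Platt
## posterior calibration and thresholded output.

fake_features <- function(n, seed = 3) {
  set.seed(seed)
  data.frame(junction = seq_len(n), seq = "chr1",
             donor_pos = seq_len(n) * 50L, acceptor_end = seq_len(n) * 50L + 80L,
             strand = "+", class = 1L,
             skew = rnorm(n, 0, 0.3), depth = rpois(n, 20) + 1L,
             entropy = runif(n, 25, 80), min_overhang = sample(21:35, n, TRUE),
             gap_loglik = rnorm(n, -5), donor_score = rnorm(n, 5),
             acceptor_score = rnorm(n, 5), frameshift = 0L, strand_discord = 0L,
             stringsAsFactors = FALSE)
}

test_that("training-set selection enforces the eligibility rules", {
  f <- fake_features(9000)
  ## 1000 clean negatives (low entropy, strong negative skew), ~8000 positives
  f$skew[1:1000] <- -2; f$entropy[1:1000] <- 5
  tr <- suppressWarnings(select_training_set(f, size = 10000, seed = 42))
  expect_equal(sum(tr$label == 1), 5000)       # 5000 drawn from ~8000+ eligible
  tr2 <- suppressWarnings(select_training_set(f, size = 10000, seed = 42))
  expect_identical(tr$junction, tr2$junction)  # seed-reproducible
  tr3 <- suppressWarnings(select_training_set(f, size = 10000, seed = 43))
  expect_false(identical(tr3$junction[tr3$label == 1], tr$junction[tr$label == 1]))
  ## boundary: overhang 21 with entropy 19 is ineligible for positives
  f2 <- fake_features(100)
  f2$min_overhang <- 21L; f2$entropy <- 19
  f2$skew[1:50] <- -2
  expect_error(select_training_set(f2, size = 50), "0 positive-eligible")
  ## a candidate firing both rules lands in neither class
  f3 <- fake_features(100)
  f3$skew[1] <- -3        # positive-eligible otherwise
  f3$skew[2:20] <- -2; f3$entropy[2:20] <- 5
  suppressWarnings(tr5 <- select_training_set(f3, size = 200))
  expect_false(1L %in% tr5$junction[tr5$label == 1])
  expect_false(1L %in% tr5$junction[tr5$label == 0])
  ## empty class aborts with diagnostic counts
  f4 <- fake_features(50)
  expect_error(select_training_set(f4, 100), "negative-eligible")
})

test_that("development set is label-correct, disjoint from training", {
  f <- fake_features(2000)
  f$skew[1:500] <- -2; f$entropy[1:500] <- 5
  tr <- suppressWarnings(select_training_set(f, size = 600, seed = 1))
  pred <- f[seq(1, 2000, by = 3), c("seq", "donor_pos", "acceptor_end", "strand")]
  dev <- suppressWarnings(select_development_set(f, pred, tr, 300, 300, seed = 2))
  expect_equal(length(intersect(dev$junction, tr$junction)), 0)
  ## labels equal a loop-based matching oracle
  for (i in seq_len(nrow(dev))) {
    hit <- any(pred$donor_pos == dev$donor_pos[i] & pred$acceptor_end == dev$acceptor_end[i] &
                 pred$seq == dev$seq[i] & pred$strand == dev$strand[i])
    expect_equal(dev$label[i] == 1, hit)
  }
  expect_error(select_development_set(f, pred[0, ], tr), "empty")
})

make_blob_sets <- function(n = 400, sep = 6, seed = 5) {
  set.seed(seed)
  mk <- function(n, mu, label, origin) {
    d <- fake_features(n, seed + label)
    d$donor_score <- rnorm(n, mu) ; d$acceptor_score <- rnorm(n, mu)
    d$gap_loglik <- rnorm(n, mu); d$depth <- rpois(n, 20) + 1L
    d$label <- label; d$origin <- origin
    d
  }
  train <- rbind(mk(n, sep, 1L, "train"), mk(n, 0, 0L, "train"))
  dev <- rbind(mk(n, sep, 1L, "dev"), mk(n, 0, 0L, "dev"))
  list(train = train, dev = dev)
}

test_that("grid search finds a separating point on separable blobs", {
  b <- make_blob_sets()
  lattice <- expand.grid(ln_c = c(-3, 0, 3), ln_gamma = c(-3, -1))
  gs <- svm_grid_search(b$train, b$dev, lattice)
  expect_equal(max(gs$W$W), sum(b$dev$label == 1))  # perfect W attainable
  ## permuting the lattice order leaves the argmax unchanged
  gs2 <- svm_grid_search(b$train, b$dev, lattice[sample(nrow(lattice)), ])
  expect_equal(c(gs$ln_c, gs$ln_gamma), c(gs2$ln_c, gs2$ln_gamma))
  ## W values equal a hand count of dev predictions
  std <- splicefinder:::standardizer(b$train[splicefinder:::CLASSIFIER_FEATURES])
  xt <- splicefinder:::apply_standardizer(b$train[splicefinder:::CLASSIFIER_FEATURES], std)
  xd <- splicefinder:::apply_standardizer(b$dev[splicefinder:::CLASSIFIER_FEATURES], std)
  for (i in c(1, 4)) {
    fit <- e1071::svm(x = xt, y = factor(b$train$label, levels = c(0, 1)),
                      type = "C-classification", kernel = "radial",
                      cost = exp(lattice$ln_c[i]), gamma = exp(lattice$ln_gamma[i]),
                      scale = FALSE)
    p <- predict(fit, xd) == "1"
    expect_equal(gs$W$W[gs$W$ln_c == lattice$ln_c[i] & gs$W$ln_gamma == lattice$ln_gamma[i]],
                 sum(p & b$dev$label == 1) - sum(p & b$dev$label == 0))
  }
  expect_error(svm_grid_search(b$train[b$train$label == 1, ], b$dev), "single class")
})

test_that("Platt posterior saturates on separated sets and is monotone", {
  b <- make_blob_sets(sep = 10)
  gs <- svm_grid_search(b$train, b$dev, data.frame(ln_c = 0, ln_gamma = -1))
  platt <- fit_posterior(b$train, gs$std, 1, exp(-1), seed = 9)
  s <- splicefinder:::platt_score(platt$decision, platt)
  expect_gte(min(s[b$train$label == 1]), 0.99)
  expect_lte(max(s[b$train$label == 0]), 0.01)
  grid_f <- seq(min(platt$decision), max(platt$decision), length.out = 1000)
  sg <- splicefinder:::platt_score(grid_f, platt)
  expect_true(all(diff(sg) >= 0))
  expect_true(all(sg >= 0 & sg <= 1))
})

test_that("Platt fit recovers the analytic log-odds of two Gaussians", {
  set.seed(77)
  n <- 10000
  mu0 <- -1; mu1 <- 1; sig <- 1
  f <- c(rnorm(n / 2, mu1, sig), rnorm(n / 2, mu0, sig))
  y <- rep(c(1L, 0L), each = n / 2)
  opt <- optim(c(-1, 0), function(p) splicefinder:::platt_nll(p, f, y),
               gr = function(p) splicefinder:::platt_grad(p, f, y), method = "BFGS")
  ## analytic posterior: logit = (mu1 - mu0)/sig^2 * f  => A = -2, B = 0
  A_true <- -(mu1 - mu0) / sig^2
  expect_lt(abs(opt$par[1] - A_true) / abs(A_true), 0.05)
  expect_lt(abs(opt$par[2]), 0.1)
  ## cross-check against glm's logistic ML fit
  g <- glm(y ~ f, family = binomial)
  expect_equal(opt$par[1], -unname(coef(g)[2]), tolerance = 1e-3)
  expect_equal(opt$par[2], -unname(coef(g)[1]), tolerance = 1e-3)
})

test_that("thresholding is a strict filter and nests monotonically", {
  f <- fake_features(300)
  f$score <- runif(300)
  out1 <- score_and_threshold(f, 1.0)
  expect_equal(nrow(out1$accepted), 0)
  out0 <- score_and_threshold(f, 0.0)
  expect_equal(nrow(out0$accepted), sum(f$score > 0))
  out5 <- score_and_threshold(f, 0.5)
  expect_identical(out5$accepted, f[f$score > 0.5, ])
  thr <- sort(runif(10))
  sizes <- vapply(thr, function(S) nrow(score_and_threshold(f, S)$accepted), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("the fitted classifier on the benchmark is reproducible and sane", {
  b <- benchmark_run()
  cl <- b$pl$classifier
  expect_s3_class(cl, "sj_classifier")
  expect_true(all(b$pl$scored$score >= 0 & b$pl$scored$score <= 1))
  ## posterior is monotone in the decision value
  o <- order(b$pl$scored$decision)
  expect_true(all(diff(b$pl$scored$score[o]) >= -1e-12))
  ## bit-for-bit reproducibility of the classifier stage under the same seed
  cl2 <- suppressWarnings(fit_junction_classifier(
    b$pl$features, b$ds$predictions$introns, train_size = 600, dev_size = 600, seed = 1))
  expect_identical(cl2$train$junction, cl$train$junction)
  expect_equal(c(cl2$ln_c, cl2$ln_gamma), c(cl$ln_c, cl$ln_gamma))
  expect_equal(cl2$platt[c("A", "B")], cl$platt[c("A", "B")])
  sc2 <- predict(cl2, b$pl$features)
  expect_identical(sc2$score, b$pl$scored$score)
})
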