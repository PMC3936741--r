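## Step 4: self-labelled training/development sets, RBF-SVM grid search
## maximizing W = TP - FP on the development set, Platt calibration of
## decision values to posterior probabilities, and thresholded junction calls.

CLASSIFIER_FEATURES <- c("donor_score", "acceptor_score", "gap_loglik",
                         "frameshift", "strand_discord", "depth")

#' Heuristic self-labelled training set
#'
#' Positives are sampled from candidates with shorter overhang > 20 nt and
#' entropy > 20; negatives from candidates with coverage skew < -1 or shorter
#' overhang <= 2 nt. The two rules can both fire on one candidate (a junction
#' with many well-overhanging spliced reads that is still dwarfed by local
#' unspliced coverage); such contradictory-evidence candidates are excluded
#' from both classes, the usual resolution when self-labelling a training
#' set. The selection features (overhang, entropy, skew) are not part of the
#' classifier's feature vector.
#'
#' @param features feature table from \code{\link{junction_features}}.
#' @param size total training-set size, split equally (default 10000).
#' @param seed optional RNG seed for reproducible sampling.
#' @return the selected rows with columns \code{label} (1/0) and
#'   \code{origin = "train"} appended.
#' @export
select_training_set <- function(features, size = 10000L, seed = NULL) {
  if (!nrow(features)) stop("empty candidate pool")
  pos_rule <- features$min_overhang > 20 & features$entropy > 20
  neg_rule <- features$skew < -1 | features$min_overhang <= 2
  pos_ok <- pos_rule & !neg_rule
  neg_ok <- neg_rule & !pos_rule
  if (!any(pos_ok) || !any(neg_ok))
    stop(sprintf("cannot build a training set: %d positive-eligible, %d negative-eligible candidates",
                 sum(pos_ok), sum(neg_ok)))
  half <- size %/% 2L
  with_seed(seed, {
    take <- function(idx, n, what) {
      if (length(idx) < n)
        warning(sprintf("only %d %s-eligible candidates for a target of %d; taking all",
                        length(idx), what, n))
      if (length(idx) <= n) idx else sort(sample(idx, n))
    }
    pos <- take(which(pos_ok), half, "positive")
    neg <- take(which(neg_ok), half, "negative")
    out <- rbind(cbind(features[pos, , drop = FALSE], label = 1L),
                 cbind(features[neg, , drop = FALSE], label = 0L))
    out$origin <- "train"
    rownames(out) <- NULL
    out
  })
}

junction_key <- function(d) paste(d$seq, d$donor_pos, d$acceptor_end, d$strand)

#' Development set labelled by ab initio intron predictions
#'
#' Positives are candidates exactly matching a predicted intron (sequence,
#' boundaries and strand); negatives match none. Both are sampled without
#' replacement, disjoint from the training set.
#'
#' @param features feature table.
#' @param predicted_introns data.frame of ab initio introns (\code{seq},
#'   \code{donor_pos}, \code{acceptor_end}, \code{strand}).
#' @param train training set (for disjointness).
#' @param size_pos,size_neg target sizes (default 5000 each).
#' @param seed optional RNG seed.
#' @return selected rows with \code{label} and \code{origin = "dev"}.
#' @export
select_development_set <- function(features, predicted_introns, train,
                                   size_pos = 5000L, size_neg = 5000L, seed = NULL) {
  if (is.null(predicted_introns) || !nrow(predicted_introns))
    stop("empty ab initio intron prediction set")
  pool <- features[!junction_key(features) %in% junction_key(train), , drop = FALSE]
  is_pos <- junction_key(pool) %in% junction_key(predicted_introns)
  with_seed(seed, {
    take <- function(idx, n, what) {
      if (length(idx) < n)
        warning(sprintf("only %d %s candidates available for the development set (target %d)",
                        length(idx), what, n))
      if (length(idx) <= n) idx else sort(sample(idx, n))
    }
    pos <- take(which(is_pos), size_pos, "prediction-matching")
    neg <- take(which(!is_pos), size_neg, "prediction-free")
    out <- rbind(cbind(pool[pos, , drop = FALSE], label = 1L),
                 cbind(pool[neg, , drop = FALSE], label = 0L))
    out$origin <- "dev"
    rownames(out) <- NULL
    out
  })
}

## z-score standardization with train statistics; constant columns untouched
standardizer <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(x, std) {
  scale(as.matrix(x), center = std$center, scale = std$scale)
}

svm_fit <- function(x, y, cost, gamma) {
  e1071::svm(x = x, y = factor(y, levels = c(0, 1)), type = "C-classification",
             kernel = "radial", cost = cost, gamma = gamma, scale = FALSE)
}

## decision values oriented so larger means more positive-like
svm_decision <- function(fit, x, flip) {
  dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")[, 1]
  if (flip) -dv else dv
}

decision_flip <- function(fit, x, y) {
  dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")[, 1]
  mean(dv[y == 1]) < mean(dv[y == 0])
}

#' RBF-SVM grid search on the W = TP - FP development criterion
#'
#' Fits an RBF-SVM on the (standardized) training set for every lattice point
#' (ln c, ln gamma), classifies the development set, and returns the point
#' maximizing W = TP - FP, with ties broken toward smaller gamma then smaller
#' cost, together with the full heat-map-ready W table.
#'
#' @param train,dev labelled sets from the selection functions.
#' @param lattice data.frame with columns \code{ln_c} and \code{ln_gamma}
#'   (default: both over -9..3 step 1).
#' @return list with \code{ln_c}, \code{ln_gamma}, \code{W} (the map as a
#'   data.frame with a \code{W} column) and the shared \code{std}
#'   standardizer.
#' @export
svm_grid_search <- function(train, dev,
                            lattice = expand.grid(ln_c = -9:3, ln_gamma = -9:3)) {
  if (length(unique(train$label)) < 2) stop("training set has a single class")
  if (!nrow(dev)) stop("empty development set")
  std <- standardizer(train[CLASSIFIER_FEATURES])
  xt <- apply_standardizer(train[CLASSIFIER_FEATURES], std)
  xd <- apply_standardizer(dev[CLASSIFIER_FEATURES], std)
  W <- numeric(nrow(lattice))
  for (i in seq_len(nrow(lattice))) {
    fit <- svm_fit(xt, train$label, exp(lattice$ln_c[i]), exp(lattice$ln_gamma[i]))
    pred <- predict(fit, xd) == "1"
    W[i] <- sum(pred & dev$label == 1) - sum(pred & dev$label == 0)
  }
  Wmap <- cbind(lattice, W = W)
  ord <- order(-Wmap$W, Wmap$ln_gamma, Wmap$ln_c)
  best <- Wmap[ord[1], ]
  list(ln_c = best$ln_c, ln_gamma = best$ln_gamma, W = Wmap, std = std)
}

## negative log-likelihood and gradient for s = 1 / (1 + exp(A f + B))
platt_nll <- function(par, f, y) {
  eta <- par[1] * f + par[2]
  ## -log s for y = 1 is log(1 + exp(eta)); -log(1-s) for y = 0 is log(1+exp(-eta))
  sum(ifelse(y == 1, log1p(exp(pmin(eta, 35))) + pmax(eta - 35, 0),
             log1p(exp(pmin(-eta, 35))) + pmax(-eta - 35, 0)))
}

platt_grad <- function(par, f, y) {
  eta <- par[1] * f + par[2]
  p <- 1 / (1 + exp(-eta))          # = 1 - s
  g <- y * p - (1 - y) * (1 - p)
  c(sum(g * f), sum(g))
}

#' Platt calibration of SVM decision values
#'
#' Fits the sigmoid s(f) = k / (1 + exp(A f + B)) by maximum likelihood on
#' (decision value, label) pairs. Decision values are computed out-of-fold by
#' 5-fold cross-validation on the training set so the sigmoid is not fitted to
#' overfitted margins. k defaults to 1 (so s is a proper probability).
#'
#' @param train labelled training set.
#' @param std standardizer from the grid search.
#' @param cost,gamma the selected SVM parameters.
#' @param folds number of CV folds (default 5).
#' @param seed optional RNG seed controlling fold assignment.
#' @return list with \code{A}, \code{B}, \code{k}, \code{folds} and the
#'   out-of-fold \code{decision} values.
#' @export
fit_posterior <- function(train, std, cost, gamma, folds = 5L, seed = NULL) {
  if (length(unique(train$label)) < 2) stop("training set has a single class")
  x <- apply_standardizer(train[CLASSIFIER_FEATURES], std)
  y <- train$label
  n <- length(y)
  fold <- with_seed(seed, {
    f <- integer(n)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      f[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
    f
  })
  dv <- numeric(n)
  for (kf in seq_len(folds)) {
    tr <- fold != kf
    fit <- svm_fit(x[tr, , drop = FALSE], y[tr], cost, gamma)
    flip <- decision_flip(fit, x[tr, , drop = FALSE], y[tr])
    dv[!tr] <- svm_decision(fit, x[!tr, , drop = FALSE], flip)
  }
  init <- c(A = -1, B = log((sum(y == 0) + 1) / (sum(y == 1) + 1)))
  opt <- optim(init, function(p) platt_nll(p, dv, y), gr = function(p) platt_grad(p, dv, y),
               method = "BFGS", control = list(maxit = 200))
  if (opt$convergence != 0) {
    warning("Platt calibration did not converge; refitting from the standard initialization")
    opt <- optim(c(A = 0, B = init[[2]]), function(p) platt_nll(p, dv, y),
                 gr = function(p) platt_grad(p, dv, y),
                 method = "BFGS", control = list(maxit = 500))
  }
  if (opt$par[1] >= 0)
    warning("fitted sigmoid is not increasing in the decision value; scores may be degenerate")
  list(A = unname(opt$par[1]), B = unname(opt$par[2]), k = 1, folds = folds, decision = dv)
}

platt_score <- function(f, platt) platt$k / (1 + exp(platt$A * f + platt$B))

#' Fit the full junction classifier
#'
#' End-to-end classifier fit: heuristic training-set selection, ab
#' initio-labelled development set, RBF-SVM grid search maximizing W = TP -
#' FP, a final SVM on the full training set, and Platt calibration of decision
#' values (out-of-fold over 5-fold CV) to posterior probabilities.
#'
#' @param features feature table from \code{\link{junction_features}}.
#' @param predicted_introns ab initio intron predictions for dev-set labels.
#' @param train_size,dev_size target set sizes (defaults 10000 and 5000+5000).
#' @param lattice SVM parameter lattice (see \code{\link{svm_grid_search}}).
#' @param folds CV folds for calibration (default 5).
#' @param seed optional RNG seed making the whole fit reproducible.
#' @return an object of class \code{sj_classifier}.
#' @export
fit_junction_classifier <- function(features, predicted_introns, train_size = 10000L,
                                    dev_size = 5000L,
                                    lattice = expand.grid(ln_c = -9:3, ln_gamma = -9:3),
                                    folds = 5L, seed = NULL) {
  train <- select_training_set(features, train_size, seed = seed)
  dev <- select_development_set(features, predicted_introns, train,
                                dev_size, dev_size,
                                seed = if (is.null(seed)) NULL else seed + 1L)
  gs <- svm_grid_search(train, dev, lattice)
  x <- apply_standardizer(train[CLASSIFIER_FEATURES], gs$std)
  fit <- svm_fit(x, train$label, exp(gs$ln_c), exp(gs$ln_gamma))
  flip <- decision_flip(fit, x, train$label)
  platt <- fit_posterior(train, gs$std, exp(gs$ln_c), exp(gs$ln_gamma), folds,
                         seed = if (is.null(seed)) NULL else seed + 2L)
  structure(list(svm = fit, flip = flip, std = gs$std, platt = platt,
                 ln_c = gs$ln_c, ln_gamma = gs$ln_gamma, W = gs$W,
                 train = train, dev = dev,
                 features = CLASSIFIER_FEATURES), class = "sj_classifier")
}

#' @export
print.sj_classifier <- function(x, ...) {
  cat(sprintf(paste0("sj_classifier (RBF-SVM + Platt posterior)\n",
                     "  training set: %d (%d positive / %d negative)\n",
                     "  development set: %d; best (ln c, ln gamma) = (%d, %d), W = %d\n",
                     "  sigmoid: A = %.4f, B = %.4f, k = %g\n"),
              nrow(x$train), sum(x$train$label == 1), sum(x$train$label == 0),
              nrow(x$dev), x$ln_c, x$ln_gamma, max(x$W$W),
              x$platt$A, x$platt$B, x$platt$k))
  invisible(x)
}

#' @export
summary.sj_classifier <- function(object, ...) {
  print(object)
  cat("W map quantiles:\n"); print(quantile(object$W$W))
  invisible(object)
}

#' Score junction candidates with a fitted classifier
#'
#' @param object an \code{sj_classifier}.
#' @param newdata feature table with the six classifier features.
#' @param ... unused.
#' @return \code{newdata} with \code{decision} and \code{score} columns
#'   appended; \code{score} is the Platt posterior in [0, 1], monotone in the
#'   decision value.
#' @export
predict.sj_classifier <- function(object, newdata, ...) {
  x <- apply_standardizer(newdata[object$features], object$std)
  dv <- svm_decision(object$svm, x, object$flip)
  newdata$decision <- dv
  newdata$score <- platt_score(dv, object$platt)
  newdata
}

#' Heat map of the grid-search W surface
#'
#' @param x an \code{sj_classifier}.
#' @param ... passed to \code{image}.
#' @export
plot.sj_classifier <- function(x, ...) {
  lc <- sort(unique(x$W$ln_c)); lg <- sort(unique(x$W$ln_gamma))
  z <- matrix(NA_real_, length(lc), length(lg))
  z[cbind(match(x$W$ln_c, lc), match(x$W$ln_gamma, lg))] <- x$W$W
  graphics::image(lc, lg, z, xlab = "ln c", ylab = "ln gamma",
                  main = "W = TP - FP on development set", ...)
  graphics::points(x$ln_c, x$ln_gamma, pch = 4, cex = 2)
  invisible(x)
}

#' Threshold scored junctions
#'
#' @param scored output of \code{predict.sj_classifier}.
#' @param threshold score threshold S; junctions with score strictly greater
#'   than S are emitted (default 0.5, the default operating point).
#' @return list with \code{accepted} (rows with score > S) and \code{scored}
#'   (the full table, retained for ROC construction).
#' @export
score_and_threshold <- function(scored, threshold = 0.5) {
  list(accepted = scored[scored$score > threshold, , drop = FALSE], scored = scored)
}
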