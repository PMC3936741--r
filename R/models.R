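## Sequence models: splice-site position-specific frequency matrices (PSFMs),
## a background nucleotide model and a binned intron length distribution.
## These stand in for the parameters an ab initio gene finder would supply:
## they can be estimated from labelled introns, loaded from a parameter file,
## or taken from the simulator's generating truth.

DONOR_EXONIC <- 3L     # donor window: 3 exonic nt then 6 intronic nt
DONOR_WIDTH  <- 9L
ACC_INTRONIC <- 20L    # acceptor window: 20 intronic nt then 1 exonic nt
ACC_WIDTH    <- 21L

psfm_width <- function(site_type) {
  switch(match.arg(site_type, c("donor", "acceptor")), donor = DONOR_WIDTH, acceptor = ACC_WIDTH)
}

#' Construct a splice-site PSFM
#'
#' A PSFM gives per-position nucleotide probabilities over a fixed window
#' around a splice site (donor: 3 exonic + 6 intronic positions; acceptor:
#' 20 intronic + 1 exonic). A first-order PSFM additionally conditions each
#' position on the preceding nucleotide; the first position is always
#' zero-order.
#'
#' @param site_type "donor" or "acceptor".
#' @param marginal 4 x width matrix of per-position nucleotide probabilities
#'   (rows A, C, G, T; columns sum to 1).
#' @param cond for order 1, a 4 x 4 x width array: \code{cond[prev, cur, pos]}
#'   is P(cur at pos | prev at pos - 1); slice 1 is ignored.
#' @param order 0 or 1.
#' @return an object of class \code{psfm}.
#' @export
new_psfm <- function(site_type, marginal, cond = NULL, order = if (is.null(cond)) 0L else 1L) {
  site_type <- match.arg(site_type, c("donor", "acceptor"))
  w <- psfm_width(site_type)
  marginal <- as.matrix(marginal)
  if (!all(dim(marginal) == c(4L, w)))
    stop(sprintf("%s PSFM marginal must be 4 x %d", site_type, w))
  dimnames(marginal) <- list(BASES, NULL)
  if (any(marginal <= 0)) stop("PSFM probabilities must be > 0 (apply pseudocounts)")
  if (any(abs(colSums(marginal) - 1) > 1e-9)) stop("PSFM marginal columns must each sum to 1")
  if (order == 1L) {
    if (is.null(cond) || !all(dim(cond) == c(4L, 4L, w)))
      stop(sprintf("first-order %s PSFM needs a 4 x 4 x %d conditional array", site_type, w))
    dimnames(cond) <- list(BASES, BASES, NULL)
    if (any(cond[, , -1] <= 0)) stop("PSFM conditional probabilities must be > 0")
    sums <- apply(cond[, , -1, drop = FALSE], c(1, 3), sum)
    if (any(abs(sums - 1) > 1e-9)) stop("PSFM conditional rows must each sum to 1")
  } else cond <- NULL
  structure(list(site_type = site_type, width = w, order = as.integer(order),
                 marginal = marginal, cond = cond), class = "psfm")
}

#' @export
print.psfm <- function(x, ...) {
  cat(sprintf("PSFM (%s site): width %d, order %d\nconsensus: %s\n", x$site_type,
              x$width, x$order, paste(BASES[apply(x$marginal, 2, which.max)], collapse = "")))
  invisible(x)
}

#' Background nucleotide model
#'
#' @param probs length-4 probability vector over A, C, G, T.
#' @param order only order 0 (stationary composition) is currently supported.
#' @return object of class \code{background_model}.
#' @export
new_background <- function(probs, order = 0L) {
  if (order != 0L) stop("only order-0 background models are supported")
  probs <- as.numeric(probs)
  if (length(probs) != 4 || any(probs <= 0) || abs(sum(probs) - 1) > 1e-9)
    stop("background probs must be 4 positive numbers summing to 1")
  structure(list(order = 0L, probs = setNames(probs, BASES)), class = "background_model")
}

#' Binned intron length distribution
#'
#' Lengths are binned at \code{bin_width} nt over \code{[min_len, max_len]};
#' lengths outside the support receive \code{pseudo_mass}.
#'
#' @param min_len,max_len support bounds in nt; \code{max_len} at most 10000.
#' @param pmf probability per bin, summing to 1 within 1e-6.
#' @param bin_width bin width in nt (default 10).
#' @param pseudo_mass probability assigned to any unseen length.
#' @return object of class \code{intron_length_dist}.
#' @export
new_intron_length_dist <- function(min_len, max_len, pmf, bin_width = 10L, pseudo_mass = 1e-6) {
  if (max_len > 10000) stop("max_len must be <= 10000 nt")
  if (min_len < 1 || max_len < min_len) stop("invalid support bounds")
  n_bins <- ceiling((max_len - min_len + 1) / bin_width)
  if (length(pmf) != n_bins) stop(sprintf("pmf must have %d bins", n_bins))
  if (any(pmf < 0) || abs(sum(pmf) - 1) > 1e-6) stop("pmf must sum to 1 within 1e-6")
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 bin_width = as.integer(bin_width), pmf = as.numeric(pmf),
                 pseudo_mass = pseudo_mass), class = "intron_length_dist")
}

#' Bundle of sequence models used throughout the pipeline
#'
#' @param donor,acceptor \code{psfm} objects.
#' @param background \code{background_model}.
#' @param intron_lengths \code{intron_length_dist}.
#' @return object of class \code{splice_models}.
#' @export
new_splice_models <- function(donor, acceptor, background, intron_lengths) {
  stopifnot(inherits(donor, "psfm"), donor$site_type == "donor",
            inherits(acceptor, "psfm"), acceptor$site_type == "acceptor",
            inherits(background, "background_model"),
            inherits(intron_lengths, "intron_length_dist"))
  structure(list(donor = donor, acceptor = acceptor, background = background,
                 intron_lengths = intron_lengths), class = "splice_models")
}

#' @export
print.splice_models <- function(x, ...) {
  cat("Splice sequence models\n")
  print(x$donor); print(x$acceptor)
  cat(sprintf("background: A=%.3f C=%.3f G=%.3f T=%.3f\n", x$background$probs[1],
              x$background$probs[2], x$background$probs[3], x$background$probs[4]))
  cat(sprintf("intron lengths: [%d, %d] nt, %d-nt bins\n", x$intron_lengths$min_len,
              x$intron_lengths$max_len, x$intron_lengths$bin_width))
  invisible(x)
}

## ---- window extraction -----------------------------------------------------

## Extract donor and acceptor windows for introns (0-based half-open
## [donor_pos, acceptor_end) on the forward genome; strand gives the
## transcribed strand). Returns list(donor=, acceptor=) character vectors with
## NA where a window would run off the contig.
extract_site_windows <- function(introns, genome) {
  n <- nrow(introns)
  don <- acc <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- genome[[introns$seq[i]]]
    len <- nchar(s)
    d <- introns$donor_pos[i]; a <- introns$acceptor_end[i]
    if (introns$strand[i] == "+") {
      if (d - DONOR_EXONIC >= 0 && d + 6 <= len)
        don[i] <- substr(s, d - DONOR_EXONIC + 1, d + 6)
      if (a - ACC_INTRONIC >= 0 && a + 1 <= len)
        acc[i] <- substr(s, a - ACC_INTRONIC + 1, a + 1)
    } else {
      if (a + DONOR_EXONIC <= len && a - 6 >= 0)
        don[i] <- revcomp(substr(s, a - 6 + 1, a + DONOR_EXONIC))
      if (d + ACC_INTRONIC <= len && d - 1 >= 0)
        acc[i] <- revcomp(substr(s, d, d + ACC_INTRONIC))
    }
  }
  list(donor = don, acceptor = acc)
}

## ---- estimation ------------------------------------------------------------

window_matrix <- function(windows, width) {
  m <- matrix(unlist(strsplit(windows, "", fixed = TRUE)), ncol = width, byrow = TRUE)
  m
}

estimate_psfm <- function(windows, site_type, order = 1L, pseudocount = 0.5) {
  w <- psfm_width(site_type)
  if (any(nchar(windows) != w)) stop(sprintf("all %s windows must have width %d", site_type, w))
  m <- window_matrix(windows, w)
  marg <- vapply(seq_len(w), function(j) {
    cnt <- table(factor(m[, j], levels = BASES)) + pseudocount
    as.numeric(cnt / sum(cnt))
  }, numeric(4))
  cond <- NULL
  if (order == 1L) {
    cond <- array(NA_real_, dim = c(4, 4, w))
    cond[, , 1] <- 1  # unused slice, kept positive for validation
    for (j in 2:w) {
      tab <- table(factor(m[, j - 1], levels = BASES), factor(m[, j], levels = BASES)) + pseudocount
      cond[, , j] <- as.matrix(tab / rowSums(tab))
    }
  }
  new_psfm(site_type, marg, cond, order)
}

estimate_intron_length_dist <- function(lengths, bin_width = 10L, pseudo_mass = 1e-6,
                                        max_len = 10000L) {
  lengths <- lengths[lengths >= 1 & lengths <= max_len]
  min_len <- min(lengths); mx <- max(lengths)
  n_bins <- ceiling((mx - min_len + 1) / bin_width)
  bin <- pmin(((lengths - min_len) %/% bin_width) + 1L, n_bins)
  cnt <- tabulate(bin, nbins = n_bins)
  new_intron_length_dist(min_len, mx, cnt / sum(cnt), bin_width, pseudo_mass)
}

#' Estimate splice sequence models from labelled introns
#'
#' Builds donor/acceptor PSFMs from the site windows of the supplied introns
#' (add-pseudocount estimation), the intron length distribution from the
#' empirical lengths, and the background model from whole-genome nucleotide
#' composition.
#'
#' @param introns data.frame with columns \code{seq}, \code{donor_pos},
#'   \code{acceptor_end} (0-based half-open intron interval) and \code{strand}.
#' @param genome named character vector of genome sequences.
#' @param pseudocount added per (position, context, letter); must be > 0.
#' @param order PSFM order, 0 or 1 (default 1).
#' @param bin_width,pseudo_mass passed to the intron length distribution.
#' @return a \code{splice_models} object.
#' @export
estimate_splice_models <- function(introns, genome, pseudocount = 0.5, order = 1L,
                                   bin_width = 10L, pseudo_mass = 1e-6) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (nrow(introns) < 50)
    stop(sprintf("too few introns for model estimation: %d supplied, need >= 50", nrow(introns)))
  genome <- normalize_genome(genome)
  win <- extract_site_windows(introns, genome)
  drop <- is.na(win$donor) | is.na(win$acceptor) |
    grepl("N", win$donor) | grepl("N", win$acceptor)
  if (any(drop))
    message(sprintf("skipping %d introns with out-of-bounds or ambiguous windows", sum(drop)))
  if (sum(!drop) < 50)
    stop(sprintf("too few usable introns: %d after window filtering, need >= 50", sum(!drop)))
  donor <- estimate_psfm(win$donor[!drop], "donor", order, pseudocount)
  acceptor <- estimate_psfm(win$acceptor[!drop], "acceptor", order, pseudocount)
  lens <- (introns$acceptor_end - introns$donor_pos)[!drop]
  counts <- colSums(Biostrings::alphabetFrequency(Biostrings::DNAStringSet(genome))[, BASES, drop = FALSE])
  background <- new_background((counts + 1) / (sum(counts) + 4))
  new_splice_models(donor, acceptor, background,
                    estimate_intron_length_dist(lens, bin_width, pseudo_mass))
}

## ---- scoring ---------------------------------------------------------------

## log2 probability of a window under a PSFM; terms touching an N use the
## background probability, recorded separately so the ratio cancels them.
psfm_log2prob <- function(window, psfm, background) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  lp <- 0; lbg <- 0
  for (j in seq_along(chars)) {
    cur <- chars[j]
    if (cur == "N") next  # contributes background to both sides: net 0
    prev <- if (j > 1) chars[j - 1] else ""
    p <- if (j == 1 || psfm$order == 0L) {
      psfm$marginal[cur, j]
    } else if (prev == "N") {
      psfm$marginal[cur, j]  # conditioning base unknown: fall back to marginal
    } else {
      psfm$cond[prev, cur, j]
    }
    lp <- lp + log2(unname(p))
    lbg <- lbg + log2(background$probs[[cur]])
  }
  c(model = unname(lp), background = unname(lbg))
}

#' Log-likelihood-ratio score of a splice-site window
#'
#' Returns log2 P(window | PSFM) - log2 P(window | background), in bits.
#' Positions holding N contribute the background probability to both numerator
#' and denominator, i.e. 0 bits.
#'
#' @param window nucleotide string of exactly the PSFM width (donor 9,
#'   acceptor 21); letters in A/C/G/T/N.
#' @param site_type "donor" or "acceptor".
#' @param models a \code{splice_models} object.
#' @return numeric score in bits.
#' @export
score_splice_site <- function(window, site_type, models) {
  site_type <- match.arg(site_type, c("donor", "acceptor"))
  psfm <- models[[site_type]]
  window <- toupper(window)
  if (nchar(window) != psfm$width)
    stop(sprintf("%s window must have width %d (got %d)", site_type, psfm$width, nchar(window)))
  if (grepl("[^ACGTN]", window)) stop("window letters must be in {A,C,G,T,N}")
  lp <- psfm_log2prob(window, psfm, models$background)
  unname(lp["model"] - lp["background"])
}

#' Log-likelihood of an intron length
#'
#' log2 of the pmf mass of the bin containing \code{length}; lengths outside
#' the support score \code{log2(pseudo_mass)}.
#'
#' @param length intron length in nt (>= 1).
#' @param dist an \code{intron_length_dist}.
#' @return numeric, bits.
#' @export
intron_length_loglik <- function(length, dist) {
  if (any(length <= 0)) stop("intron length must be >= 1")
  out <- rep(log2(dist$pseudo_mass), length(length))
  inside <- length >= dist$min_len & length <= dist$max_len
  if (any(inside)) {
    bin <- ((length[inside] - dist$min_len) %/% dist$bin_width) + 1L
    p <- dist$pmf[bin]
    out[inside] <- ifelse(p > 0, log2(p), log2(dist$pseudo_mass))
  }
  out
}

## ---- sampling (used by the simulator and for property tests) ---------------

## sample n windows from a PSFM by chained conditional draws
sample_psfm_windows <- function(psfm, n) {
  w <- psfm$width
  m <- matrix("", n, w)
  m[, 1] <- sample(BASES, n, replace = TRUE, prob = psfm$marginal[, 1])
  for (j in 2:w) {
    if (psfm$order == 0L) {
      m[, j] <- sample(BASES, n, replace = TRUE, prob = psfm$marginal[, j])
    } else {
      for (b in BASES) {
        idx <- m[, j - 1] == b
        if (any(idx)) m[idx, j] <- sample(BASES, sum(idx), replace = TRUE, prob = psfm$cond[b, , j])
      }
    }
  }
  apply(m, 1, paste, collapse = "")
}

## true per-position marginals implied by a (possibly first-order) PSFM
psfm_implied_marginal <- function(psfm) {
  w <- psfm$width
  out <- matrix(0, 4, w, dimnames = list(BASES, NULL))
  out[, 1] <- psfm$marginal[, 1]
  if (psfm$order == 0L) return(psfm$marginal)
  for (j in 2:w) out[, j] <- as.numeric(t(psfm$cond[, , j]) %*% out[, j - 1])
  out
}
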