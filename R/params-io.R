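## Sectioned plain-text parameter file for splice_models.
##
## Format (tab-separated, '#' comments ignored):
##   [donor] / [acceptor]
##     order <0|1>
##     width <int>
##     marginal            followed by `width` rows: pos pA pC pG pT
##     conditional         (order 1 only) rows: pos prev pA pC pG pT
##   [background]
##     probs pA pC pG pT
##   [intron_lengths]
##     min_len / max_len / bin_width / pseudo_mass <value>
##     pmf                 followed by one row per bin: bin_start mass
## Probabilities are serialized with 17 significant digits so that a
## save -> load cycle reproduces the model exactly.

fmt_p <- function(x) sprintf("%.17g", x)

#' Write splice models to a plain-text parameter file
#'
#' @param models a \code{splice_models} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_splice_params <- function(models, path) {
  stopifnot(inherits(models, "splice_models"))
  con <- file(path, "w"); on.exit(close(con))
  out <- function(...) writeLines(paste(..., sep = "\t"), con)
  writeLines("# splicefinder sequence model parameters", con)
  for (st in c("donor", "acceptor")) {
    p <- models[[st]]
    out(sprintf("[%s]", st))
    out("order", p$order)
    out("width", p$width)
    out("marginal")
    for (j in seq_len(p$width)) out(j, fmt_p(p$marginal[1, j]), fmt_p(p$marginal[2, j]),
                                     fmt_p(p$marginal[3, j]), fmt_p(p$marginal[4, j]))
    if (p$order == 1L) {
      out("conditional")
      for (j in 2:p$width) for (b in BASES)
        out(j, b, fmt_p(p$cond[b, "A", j]), fmt_p(p$cond[b, "C", j]),
            fmt_p(p$cond[b, "G", j]), fmt_p(p$cond[b, "T", j]))
    }
  }
  out("[background]")
  out("probs", fmt_p(models$background$probs[1]), fmt_p(models$background$probs[2]),
      fmt_p(models$background$probs[3]), fmt_p(models$background$probs[4]))
  d <- models$intron_lengths
  out("[intron_lengths]")
  out("min_len", d$min_len); out("max_len", d$max_len)
  out("bin_width", d$bin_width); out("pseudo_mass", fmt_p(d$pseudo_mass))
  out("pmf")
  starts <- d$min_len + (seq_along(d$pmf) - 1L) * d$bin_width
  for (i in seq_along(d$pmf)) out(starts[i], fmt_p(d$pmf[i]))
  invisible(path)
}

#' Read splice models from a parameter file
#'
#' @param path parameter file written by \code{\link{write_splice_params}} (or
#'   hand-authored in the same format).
#' @return a \code{splice_models} object.
#' @export
read_splice_params <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sec_at <- grep("^\\[", lines)
  if (!length(sec_at)) stop("parameter file has no sections")
  sec_names <- gsub("\\[|\\]", "", lines[sec_at])
  sections <- list()
  bounds <- c(sec_at, length(lines) + 1L)
  for (i in seq_along(sec_at))
    sections[[sec_names[i]]] <- lines[seq(sec_at[i] + 1L, bounds[i + 1L] - 1L)] [
      seq_len(max(0L, bounds[i + 1L] - sec_at[i] - 1L))]
  for (need in c("donor", "acceptor", "background", "intron_lengths"))
    if (is.null(sections[[need]])) stop(sprintf("parameter file missing section [%s]", need))

  parse_psfm <- function(rows, site_type) {
    kv <- strsplit(rows, "\t", fixed = TRUE)
    keys <- vapply(kv, `[`, "", 1)
    grab <- function(key) {
      i <- match(key, keys)
      if (is.na(i)) stop(sprintf("[%s] section missing '%s'", site_type, key))
      i
    }
    order <- as.integer(kv[[grab("order")]][2])
    width <- as.integer(kv[[grab("width")]][2])
    if (width != psfm_width(site_type))
      stop(sprintf("[%s] width %d does not match expected %d", site_type, width, psfm_width(site_type)))
    mi <- grab("marginal")
    mrows <- kv[mi + seq_len(width)]
    if (length(mrows) < width || any(vapply(mrows, length, 0L) != 5))
      stop(sprintf("[%s] marginal block must have %d rows of 5 fields", site_type, width))
    marg <- matrix(0, 4, width)
    for (r in mrows) {
      j <- as.integer(r[1]); p <- as.numeric(r[2:5])
      if (abs(sum(p) - 1) > 1e-6)
        stop(sprintf("[%s] marginal row at position %d sums to %.6g, not 1", site_type, j, sum(p)))
      marg[, j] <- p
    }
    cond <- NULL
    if (order == 1L) {
      ci <- grab("conditional")
      crows <- kv[ci + seq_len(4L * (width - 1L))]
      if (any(vapply(crows, length, 0L) != 6))
        stop(sprintf("[%s] conditional block must have %d rows of 6 fields", site_type, 4 * (width - 1)))
      cond <- array(1, dim = c(4, 4, width), dimnames = list(BASES, BASES, NULL))
      for (r in crows) {
        j <- as.integer(r[1]); prev <- r[2]; p <- as.numeric(r[3:6])
        if (abs(sum(p) - 1) > 1e-6)
          stop(sprintf("[%s] conditional row at position %d (prev %s) sums to %.6g, not 1",
                       site_type, j, prev, sum(p)))
        cond[prev, , j] <- p
      }
    }
    new_psfm(site_type, marg, cond, order)
  }

  donor <- parse_psfm(sections$donor, "donor")
  acceptor <- parse_psfm(sections$acceptor, "acceptor")

  bg_kv <- strsplit(sections$background, "\t", fixed = TRUE)
  bi <- match("probs", vapply(bg_kv, `[`, "", 1))
  if (is.na(bi)) stop("[background] section missing 'probs'")
  bp <- as.numeric(bg_kv[[bi]][2:5])
  if (abs(sum(bp) - 1) > 1e-6) stop("[background] probs do not sum to 1")
  background <- new_background(bp / sum(bp))

  il_kv <- strsplit(sections$intron_lengths, "\t", fixed = TRUE)
  il_keys <- vapply(il_kv, `[`, "", 1)
  scalar <- function(key) {
    i <- match(key, il_keys)
    if (is.na(i)) stop(sprintf("[intron_lengths] section missing '%s'", key))
    as.numeric(il_kv[[i]][2])
  }
  min_len <- scalar("min_len"); max_len <- scalar("max_len")
  bin_width <- scalar("bin_width"); pseudo_mass <- scalar("pseudo_mass")
  pi <- match("pmf", il_keys)
  if (is.na(pi)) stop("[intron_lengths] section missing 'pmf'")
  prows <- il_kv[(pi + 1):length(il_kv)]
  pmf <- vapply(prows, function(r) as.numeric(r[2]), 0)
  if (abs(sum(pmf) - 1) > 1e-6)
    stop(sprintf("[intron_lengths] pmf sums to %.6g, not 1", sum(pmf)))
  il <- new_intron_length_dist(min_len, max_len, pmf, bin_width, pseudo_mass)

  new_splice_models(donor, acceptor, background, il)
}
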