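#' @useDynLib splicefinder, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate dnorm optim predict quantile rbinom rlnorm rnorm runif sd setNames
#' @importFrom utils head read.delim write.table
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

## canonical and semi-canonical intron terminal dinucleotide pairs, plus their
## reverse complements (minus-strand junctions seen on the forward genome)
DINUC_PLUS  <- list(c("GT", "AG"), c("GC", "AG"), c("AT", "AC"))
DINUC_MINUS <- list(c("CT", "AC"), c("CT", "GC"), c("GT", "AT"))

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  out <- cpp_revcomp(toupper(x))
  names(out) <- names(x)
  out
}

## run code with a temporarily fixed RNG state; global state restored afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## named character vector -> upper case, validated alphabet
normalize_genome <- function(genome) {
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome sequences must be named")
  g <- toupper(as.character(genome))
  names(g) <- names(genome)
  bad <- grepl("[^ACGTN]", g)
  if (any(bad)) stop("genome contains letters outside {A,C,G,T,N}: ", names(g)[bad][1])
  g
}

## encode blocks matrix (start,len) as "start:len,start:len" (0-based starts)
encode_blocks <- function(starts, lens) paste(paste(starts, lens, sep = ":"), collapse = ",")

decode_blocks <- function(s) {
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  m <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
  colnames(m) <- c("start", "len")
  m
}

## introns implied by a block string: (donor_pos, acceptor_end) 0-based half-open
blocks_to_introns <- function(s) {
  b <- decode_blocks(s)
  if (nrow(b) < 2) return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("donor_pos", "acceptor_end"))))
  ends <- b[, "start"] + b[, "len"]
  cbind(donor_pos = ends[-nrow(b)], acceptor_end = b[-1, "start"])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
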