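#' @include seqio.R
NULL

.charMatrix <- function(x) {
  seqs <- if (is(x, "MarkerSet")) as.character(sequences(x))
          else toupper(as.character(x))
  if (length(unique(nchar(seqs))) > 1L)
    stop("sequences must be aligned (equal lengths)", call. = FALSE)
  do.call(cbind, strsplit(seqs, "", fixed = TRUE))  # L x n
}

#' Pairwise differences between two aligned sequences
#'
#' A site is valid iff both characters are unambiguous bases
#' (\code{A,C,G,T}); gaps and ambiguity codes are treated as missing.
#' Differences are counted over valid sites only.
#'
#' @param a,b Aligned (equal-length, possibly gapped) sequence strings.
#' @return Named integer vector \code{c(differences, valid_sites)}.
#' @examples
#' pairwiseDiff("AC-T", "ACGT")  # 0 differences over 3 valid sites
#' @export
pairwiseDiff <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("sequences must have equal length", call. = FALSE)
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  acgt <- c("A", "C", "G", "T")
  valid <- ca %in% acgt & cb %in% acgt
  c(differences = sum(valid & ca != cb), valid_sites = sum(valid))
}

## Per-pair difference/valid indicator matrices (L x n_pairs) for an
## alignment, under pairwise or complete deletion of missing data.
.pairIndicators <- function(chars, deletion = "pairwise") {
  n <- ncol(chars)
  acgt <- c("A", "C", "G", "T")
  valid <- matrix(chars %in% acgt, nrow = nrow(chars))
  allValid <- rowSums(valid) == n
  pairs <- utils::combn(n, 2L)
  np <- ncol(pairs)
  dmat <- matrix(FALSE, nrow = nrow(chars), ncol = np)
  vmat <- matrix(FALSE, nrow = nrow(chars), ncol = np)
  for (p in seq_len(np)) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    v <- if (deletion == "complete") allValid else valid[, i] & valid[, j]
    vmat[, p] <- v
    dmat[, p] <- v & chars[, i] != chars[, j]
  }
  list(diff = dmat, valid = vmat)
}

#' Nucleotide diversity (pi) of an alignment
#'
#' Pi is the average proportion of nucleotide differences per site between
#' two sequences of the set: the mean over all \code{n(n-1)/2} unordered
#' pairs of \code{differences / valid_sites}, where a site is valid for a
#' pair iff both sequences carry an unambiguous base there. Pairs with
#' zero valid sites are excluded from the mean; if every pair is excluded
#' the result is \code{NaN}.
#'
#' @param x An aligned \code{\linkS4class{MarkerSet}} or character vector
#'   of equal-length sequences (\code{n >= 2}).
#' @param deletion Missing-data rule: \code{"pairwise"} (default; valid
#'   sites are determined per pair) or \code{"complete"} (only columns
#'   unambiguous in every sequence are used for all pairs).
#' @return Numeric pi in \code{[0, 1]} (or \code{NaN}).
#' @examples
#' nucleotideDiversity(c(a = "ACGTACGTAC", b = "ACGAACGTAC"))  # 0.1
#' @export
nucleotideDiversity <- function(x, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  chars <- .charMatrix(x)
  if (ncol(chars) < 2L)
    stop("nucleotide diversity requires at least 2 sequences", call. = FALSE)
  ind <- .pairIndicators(chars, deletion)
  d <- colSums(ind$diff)
  v <- colSums(ind$valid)
  keep <- v > 0L
  if (!any(keep)) return(NaN)
  mean(d[keep] / v[keep])
}

#' Sliding-window nucleotide diversity profile
#'
#' Computes pi in windows of \code{windowSize} alignment columns advanced
#' by \code{step}, the standard sliding-window analysis of population
#' genetics software. Windows start at columns 1, 1 + step, ... as long as
#' the window fits inside the alignment. Windows are defined on alignment
#' columns: gap columns lie inside the window span but are excluded from
#' each pair's valid sites. The reported midpoint is
#' \code{start + midpointOffset} with the default offset
#' \code{windowSize/2 - 1}; \code{n_valid_sites} counts window columns at
#' which at least two sequences carry an unambiguous base.
#'
#' @param x An aligned \code{\linkS4class{MarkerSet}} or character vector
#'   (\code{n >= 2}, length >= \code{windowSize}).
#' @param windowSize Window size in columns (default 100).
#' @param step Step in columns (default 10).
#' @param midpointOffset Offset added to each window start to obtain the
#'   reported midpoint; default \code{windowSize/2 - 1}.
#' @param deletion Missing-data rule, as in
#'   \code{\link{nucleotideDiversity}}.
#' @return A \code{\linkS4class{DiversityProfile}}.
#' @examples
#' aln <- c(a = strrep("ACGT", 30), b = strrep("ACGA", 30))
#' profile <- slidingWindowPi(aln, windowSize = 100, step = 10)
#' diversityPoints(profile)
#' @export
slidingWindowPi <- function(x, windowSize = 100L, step = 10L,
                            midpointOffset = NULL,
                            deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  windowSize <- as.integer(windowSize)
  step <- as.integer(step)
  if (is.null(midpointOffset)) midpointOffset <- windowSize / 2 - 1
  chars <- .charMatrix(x)
  L <- nrow(chars)
  if (ncol(chars) < 2L)
    stop("nucleotide diversity requires at least 2 sequences", call. = FALSE)
  if (L < windowSize)
    stop("alignment shorter than the window size", call. = FALSE)
  ind <- .pairIndicators(chars, deletion)
  cumd <- rbind(0, apply(ind$diff, 2L, cumsum))
  cumv <- rbind(0, apply(ind$valid, 2L, cumsum))
  anyPairCols <- rowSums(ind$valid) > 0L
  cumAny <- c(0, cumsum(anyPairCols))
  starts <- seq.int(1L, L - windowSize + 1L, by = step)
  points <- data.frame(
    window_start = starts,
    window_end = starts + windowSize - 1L,
    midpoint = starts + midpointOffset,
    n_valid_sites = NA_integer_,
    pi = NA_real_)
  for (w in seq_along(starts)) {
    s <- starts[w]; e <- s + windowSize - 1L
    d <- cumd[e + 1L, ] - cumd[s, ]
    v <- cumv[e + 1L, ] - cumv[s, ]
    keep <- v > 0
    points$pi[w] <- if (any(keep)) mean(d[keep] / v[keep]) else NaN
    points$n_valid_sites[w] <- cumAny[e + 1L] - cumAny[s]
  }
  d <- colSums(ind$diff); v <- colSums(ind$valid); keep <- v > 0
  overall <- if (any(keep)) mean(d[keep] / v[keep]) else NaN
  new("DiversityProfile", windowSize = windowSize, step = step,
      points = points, overallPi = overall)
}

#' Points of a diversity profile
#' @param x A \code{\linkS4class{DiversityProfile}}.
#' @return The per-window \code{data.frame}.
#' @export
diversityPoints <- function(x) {
  stopifnot(is(x, "DiversityProfile"))
  x@points
}

#' Overall pi of a diversity profile
#' @param x A \code{\linkS4class{DiversityProfile}}.
#' @return Numeric pi over the full alignment.
#' @export
overallPi <- function(x) {
  stopifnot(is(x, "DiversityProfile"))
  x@overallPi
}

setMethod("show", "DiversityProfile", function(object) {
  cat(sprintf(
    "DiversityProfile: %d windows (size %d, step %d), overall pi = %.4g\n",
    nrow(object@points), object@windowSize, object@step, object@overallPi))
})
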