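#' @include AllClasses.R
NULL

#' Construct a degenerate primer
#'
#' @param name Primer name.
#' @param seq Primer sequence over the IUPAC nucleotide alphabet
#'   (upper-cased on ingest).
#' @return A \code{\linkS4class{DegeneratePrimer}}.
#' @examples
#' degeneratePrimer("gyrA3-F", "GCDGCHGCNATGCGTTAYAC")
#' @export
degeneratePrimer <- function(name, seq) {
  new("DegeneratePrimer", name = as.character(name),
      seq = toupper(as.character(seq)))
}

#' Construct a primer pair with its amplifiability rule
#'
#' @param name Pair name.
#' @param forward,reverse \code{\linkS4class{DegeneratePrimer}} objects or
#'   plain IUPAC strings.
#' @param minMatch Minimum identical bases required at each binding site
#'   (default 18).
#' @param minAmpliconLen,maxAmpliconLen Product length bounds in bp
#'   (defaults 100 and 3000).
#' @return A \code{\linkS4class{PrimerPair}}.
#' @examples
#' gyrA3 <- primerPair("gyrA3",
#'   "GCDGCHGCNATGCGTTAYAC", "ACAAGMTCWGCKATTTTTTC")
#' @export
primerPair <- function(name, forward, reverse, minMatch = 18L,
                       minAmpliconLen = 100L, maxAmpliconLen = 3000L) {
  if (is.character(forward))
    forward <- degeneratePrimer(paste0(name, "-F"), forward)
  if (is.character(reverse))
    reverse <- degeneratePrimer(paste0(name, "-R"), reverse)
  new("PrimerPair", name = as.character(name), forward = forward,
      reverse = reverse, minMatch = as.integer(minMatch),
      minAmpliconLen = as.integer(minAmpliconLen),
      maxAmpliconLen = as.integer(maxAmpliconLen))
}

setMethod("show", "DegeneratePrimer", function(object) {
  cat(sprintf("DegeneratePrimer %s: 5'-%s-3' (%d nt, %d expansions)\n",
              object@name, object@seq, nchar(object@seq),
              degeneracy(object)))
})

setMethod("show", "PrimerPair", function(object) {
  cat(sprintf("PrimerPair %s (minMatch=%d, amplicon %d-%d bp)\n",
              object@name, object@minMatch, object@minAmpliconLen,
              object@maxAmpliconLen))
  cat(sprintf("  F %s: 5'-%s-3'\n", object@forward@name, object@forward@seq))
  cat(sprintf("  R %s: 5'-%s-3'\n", object@reverse@name, object@reverse@seq))
})

#' Number of non-degenerate expansions of a primer
#'
#' The product over positions of each IUPAC code's degeneracy (e.g. R = 2,
#' N = 4).
#'
#' @param primer A \code{\linkS4class{DegeneratePrimer}} or IUPAC string.
#' @return Integer expansion count.
#' @export
degeneracy <- function(primer) {
  seq <- if (is(primer, "DegeneratePrimer")) primer@seq else toupper(primer)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  prod(nchar(Biostrings::IUPAC_CODE_MAP[chars]))
}

#' Expand a degenerate primer into its exact sequences
#'
#' Converts a primer containing IUPAC ambiguity codes into the full set of
#' primers over \code{A,C,G,T} it represents (the mixture actually present
#' in a degenerate primer synthesis). The cardinality equals
#' \code{\link{degeneracy}} of the primer.
#'
#' @param primer A \code{\linkS4class{DegeneratePrimer}} or IUPAC string.
#' @return Character vector of exact sequences, sorted, no duplicates.
#' @examples
#' expandDegenerate("AY")           # "AC" "AT"
#' length(expandDegenerate("GCDGCHGCNATGCGTTAYAC"))  # 72
#' @export
expandDegenerate <- function(primer) {
  seq <- if (is(primer, "DegeneratePrimer")) primer@seq else toupper(primer)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), .DEGENERATE_CODES)
  if (length(bad))
    stop(sprintf("illegal primer character(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP[chars], "", fixed = TRUE)
  grid <- do.call(expand.grid,
                  c(rev(sets), list(stringsAsFactors = FALSE)))
  out <- do.call(paste0, rev(grid))
  sort(unique(out))
}

#' Count identical bases between an exact primer and a target window
#'
#' A position counts as a match only when the two characters are identical
#' and the target character is an unambiguous base (\code{A,C,G,T}):
#' \code{N}, other ambiguity codes and gaps in the target never count.
#'
#' @param variant Exact primer sequence over \code{A,C,G,T}.
#' @param window Target window of equal length.
#' @return Integer match count.
#' @examples
#' matchCount("ACGT", "ACGA")  # 3
#' matchCount("ACGT", "NNNN")  # 0
#' @export
matchCount <- function(variant, window) {
  if (nchar(variant) != nchar(window))
    stop("variant and window must have equal length", call. = FALSE)
  v <- strsplit(toupper(variant), "", fixed = TRUE)[[1L]]
  w <- strsplit(toupper(window), "", fixed = TRUE)[[1L]]
  sum(v == w & w %in% c("A", "C", "G", "T"))
}

#' Reverse complement of an IUPAC sequence
#'
#' @param seq IUPAC nucleotide string (gaps not allowed).
#' @return The reverse complement, with ambiguity codes complemented under
#'   IUPAC semantics (e.g. R <-> Y).
#' @export
reverseComplementSeq <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Primer pairs used in Bacillus marker-gene evaluation
#'
#' Returns the primer pairs evaluated for amplifying the gyrA gene and the
#' 16S rRNA gene of \emph{Bacillus}: the published gyrA1 and gyrA2 pairs,
#' the degenerate gyrA3/gyrA4/gyrA5 pairs designed for amplicon sequencing,
#' the full-length 16S pair 27F/1492R, and the universal V3-V4 pair
#' 338F/806R. All pairs carry the default amplifiability rule of 18
#' identical bases per primer.
#'
#' @return Named list of \code{\linkS4class{PrimerPair}} objects.
#' @examples
#' bacillusPrimers()[["gyrA3"]]
#' @export
bacillusPrimers <- function() {
  list(
    gyrA1 = primerPair("gyrA1",
      degeneratePrimer("gyrA1-F", "CAGTCAGGAAATGCGTACGTCCTT"),
      degeneratePrimer("gyrA1-R", "GTATCCGTTGTGCGTCAGAGTAAC")),
    gyrA2 = primerPair("gyrA2",
      degeneratePrimer("gyrA2-F", "CAGTCAGGAAATGCGTACGTCCTT"),
      degeneratePrimer("gyrA2-R", "CAAGGTAATGCTCCAGGCATTGCT")),
    gyrA3 = primerPair("gyrA3",
      degeneratePrimer("gyrA3-F", "GCDGCHGCNATGCGTTAYAC"),
      degeneratePrimer("gyrA3-R", "ACAAGMTCWGCKATTTTTTC")),
    gyrA4 = primerPair("gyrA4",
      degeneratePrimer("gyrA4-F", "TAYGCRATGAGYRTHATYGT"),
      degeneratePrimer("gyrA4-R", "TTBGTNGCCATHCCDACMGC")),
    gyrA5 = primerPair("gyrA5",
      degeneratePrimer("gyrA5-F", "GCDGCNGCVATGCGTTAYAC"),
      degeneratePrimer("gyrA5-R", "CGNAGRTYBGTAATDCCDTC")),
    full16S = primerPair("full16S",
      degeneratePrimer("27F", "AGAGTTTGATCCTGGCTCAG"),
      degeneratePrimer("1492R", "GGTTACCTTGTTACGACTT"),
      minMatch = 17L),
    v3v4 = primerPair("v3v4",
      degeneratePrimer("338F", "CCTACGGRRBGCASCAGKVRVGAAT"),
      degeneratePrimer("806R", "GGACTACNVGGGTWTCTAATCC"))
  )
}

#' Read primer pairs from a TSV definition file
#'
#' The file has columns \code{pair}, \code{role} (\code{F} or \code{R}),
#' \code{name}, \code{sequence}; each pair must contribute exactly one F
#' and one R row.
#'
#' @param path Path to the primers TSV.
#' @param minMatch,minAmpliconLen,maxAmpliconLen Rule parameters applied to
#'   every pair.
#' @return Named list of \code{\linkS4class{PrimerPair}} objects.
#' @export
readPrimerPairs <- function(path, minMatch = 18L, minAmpliconLen = 100L,
                            maxAmpliconLen = 3000L) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("pair", "role", "name", "sequence")
  if (!all(need %in% names(df)))
    stop("primer TSV must have columns pair, role, name, sequence",
         call. = FALSE)
  out <- list()
  for (p in unique(df$pair)) {
    sub <- df[df$pair == p, , drop = FALSE]
    f <- sub[sub$role == "F", , drop = FALSE]
    r <- sub[sub$role == "R", , drop = FALSE]
    if (nrow(f) != 1L || nrow(r) != 1L)
      stop(sprintf("pair '%s' must have exactly one F and one R row", p),
           call. = FALSE)
    out[[p]] <- primerPair(p,
      degeneratePrimer(f$name, f$sequence),
      degeneratePrimer(r$name, r$sequence),
      minMatch = minMatch, minAmpliconLen = minAmpliconLen,
      maxAmpliconLen = maxAmpliconLen)
  }
  out
}
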