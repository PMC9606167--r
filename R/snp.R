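#' @include seqio.R
NULL

## Round half away from zero at `digits` decimals (printed-table
## convention; 1/480 * 100 renders as 0.21).
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Choose the representative (reference) sequence of an alignment
#'
#' The representative against which all other genomes are compared is the
#' explicitly configured record id if given, else the first record of the
#' collection (deterministic).
#'
#' @param x A non-empty \code{\linkS4class{MarkerSet}}.
#' @param referenceId Optional record id.
#' @return The reference record id.
#' @export
chooseReference <- function(x, referenceId = NULL) {
  ids <- seqIds(x)
  if (!length(ids)) stop("empty collection", call. = FALSE)
  if (is.null(referenceId)) return(ids[[1L]])
  if (!referenceId %in% ids)
    stop(sprintf("reference id '%s' not found in collection", referenceId),
         call. = FALSE)
  referenceId
}

#' Reference-anchored variable-site profile of an alignment region
#'
#' Compares every genome of an aligned collection against the
#' representative sequence over a fixed sub-region. At each region column
#' where both the genome and the reference carry an unambiguous base
#' (\code{A,C,G,T}), a mismatch is recorded iff they differ; columns where
#' either side is gapped or ambiguous are skipped for that genome but do
#' not shrink the fixed region length used as the frequency denominator.
#' A column is a variable site when at least one genome mismatches the
#' reference there.
#'
#' @param x An aligned \code{\linkS4class{MarkerSet}} containing the
#'   reference.
#' @param referenceId Record id of the representative sequence (default:
#'   first record; see \code{\link{chooseReference}}).
#' @param region Integer \code{c(start, end)}, 1-based inclusive alignment
#'   columns (default: the full alignment).
#' @param regionLength Fixed denominator for frequencies, in bp; defaults
#'   to \code{end - start + 1}. Configurable because published region
#'   lengths sometimes reflect a half-open coordinate convention.
#' @param geneLabel,species Labels carried into summary tables.
#' @return A \code{\linkS4class{VariableSiteProfile}}. Per-genome
#'   frequencies are \code{100 * n_mismatches / regionLength} (exact,
#'   pre-rounding); the reference itself is excluded from the comparison.
#' @examples
#' aln <- MarkerSet(c(ref = "ACGTACGTAC", g1 = "ACGAACGTAC"), aligned = TRUE)
#' p <- variableSites(aln, "ref", region = c(1, 10))
#' variableSitePositions(p)  # 4
#' @export
variableSites <- function(x, referenceId = NULL, region = NULL,
                          regionLength = NULL, geneLabel = "marker",
                          species = "unknown") {
  if (!isAligned(x))
    stop("variableSites requires an aligned collection", call. = FALSE)
  referenceId <- chooseReference(x, referenceId)
  chars <- .charMatrix(x)  # L x n
  L <- nrow(chars)
  if (is.null(region)) region <- c(1L, L)
  region <- as.integer(region)
  if (region[1L] < 1L || region[2L] > L || region[1L] > region[2L])
    stop(sprintf("region %d-%d out of range for alignment of %d columns",
                 region[1L], region[2L], L), call. = FALSE)
  if (is.null(regionLength)) regionLength <- region[2L] - region[1L] + 1L
  ids <- seqIds(x)
  refCol <- match(referenceId, ids)
  cols <- region[1L]:region[2L]
  acgt <- c("A", "C", "G", "T")
  ref <- chars[cols, refCol]
  refOk <- ref %in% acgt
  others <- setdiff(seq_along(ids), refCol)
  mism <- matrix(FALSE, nrow = length(cols), ncol = length(others))
  for (k in seq_along(others)) {
    g <- chars[cols, others[k]]
    mism[, k] <- refOk & g %in% acgt & g != ref
  }
  counts <- colSums(mism)
  perGenome <- data.frame(
    genome_id = ids[others],
    n_mismatches = as.integer(counts),
    freq_pct = 100 * counts / regionLength,
    stringsAsFactors = FALSE)
  varCols <- cols[rowSums(mism) > 0L]
  nVar <- sum(counts >= 1L)
  pos <- counts[counts >= 1L]
  new("VariableSiteProfile",
      geneLabel = geneLabel, species = species, region = region,
      regionLength = as.integer(regionLength), referenceId = referenceId,
      variableSites = as.integer(varCols), perGenome = perGenome,
      nGenomesTotal = length(others), nGenomesVariable = as.integer(nVar),
      mismatchRange = if (length(pos)) as.integer(range(pos)) else c(0L, 0L),
      freqRangePct = if (length(pos)) 100 * range(pos) / regionLength
                     else c(0, 0))
}

#' Variable alignment columns of a profile
#' @param x A \code{\linkS4class{VariableSiteProfile}}.
#' @return Sorted integer vector of variable columns.
#' @export
variableSitePositions <- function(x) {
  stopifnot(is(x, "VariableSiteProfile"))
  x@variableSites
}

#' Per-genome mismatch table of a profile
#' @param x A \code{\linkS4class{VariableSiteProfile}}.
#' @return \code{data.frame(genome_id, n_mismatches, freq_pct)}.
#' @export
perGenomeMismatches <- function(x) {
  stopifnot(is(x, "VariableSiteProfile"))
  x@perGenome
}

setMethod("show", "VariableSiteProfile", function(object) {
  cat(sprintf(
    "VariableSiteProfile %s / %s: region %d-%d (%d bp), reference %s\n",
    object@species, object@geneLabel, object@region[1L], object@region[2L],
    object@regionLength, object@referenceId))
  cat(sprintf("  %d variable sites; %d of %d genomes variable\n",
              length(object@variableSites), object@nGenomesVariable,
              object@nGenomesTotal))
})

.fmtRange <- function(lo, hi, digits = NULL) {
  if (is.null(digits))
    sprintf("%d–%d", lo, hi)
  else
    sprintf(paste0("%.", digits, "f–%.", digits, "f"),
            roundHalfUp(lo, digits), roundHalfUp(hi, digits))
}

#' Summarise variable-site profiles into a polymorphism table
#'
#' Produces one row per (species, gene) profile with the gene (region)
#' length, number of variable sites, genome counts, and the mismatch-count
#' and percent-frequency ranges over genomes with at least one mismatch.
#' Frequencies are rendered at 2 decimals (half-up) and ranges with an
#' en-dash, the conventional layout of published polymorphism tables.
#'
#' @param profiles A list of \code{\linkS4class{VariableSiteProfile}}
#'   objects (at least one).
#' @return A \code{data.frame} with columns \code{species}, \code{gene},
#'   \code{gene_length_bp}, \code{n_variable_sites},
#'   \code{n_genomes_total}, \code{n_genomes_variable},
#'   \code{mismatch_range}, \code{freq_range_pct}.
#' @export
summarizeSpecies <- function(profiles) {
  if (is(profiles, "VariableSiteProfile")) profiles <- list(profiles)
  if (!length(profiles)) stop("at least one profile required", call. = FALSE)
  rows <- lapply(profiles, function(p) {
    data.frame(
      species = p@species,
      gene = p@geneLabel,
      gene_length_bp = p@regionLength,
      n_variable_sites = length(p@variableSites),
      n_genomes_total = p@nGenomesTotal,
      n_genomes_variable = p@nGenomesVariable,
      mismatch_range = .fmtRange(p@mismatchRange[1L], p@mismatchRange[2L]),
      freq_range_pct = .fmtRange(p@freqRangePct[1L], p@freqRangePct[2L],
                                 digits = 2L),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
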