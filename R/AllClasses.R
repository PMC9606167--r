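#' @import methods
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#'   readBStringSet writeXStringSet width IUPAC_CODE_MAP
#' @importFrom S4Vectors metadata metadata<-
NULL

## Accepted residue alphabet: IUPAC nucleotide codes plus gap.
.IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N", "-")
.DEGENERATE_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                       "B", "D", "H", "V", "N")

#' MarkerSet: a collection of named marker-gene sequences
#'
#' A \code{MarkerSet} holds an ordered collection of DNA sequences (genomes,
#' genes or amplicons) over the IUPAC nucleotide alphabet plus the gap
#' character \code{-}, together with per-record descriptions and optional
#' taxon (species) labels used for per-species summaries. The \code{aligned}
#' flag marks collections whose sequences form a multiple sequence alignment
#' (all equal length); alignment-only operations such as
#' \code{\link{extractRegion}}, \code{\link{nucleotideDiversity}} and
#' \code{\link{variableSites}} require it.
#'
#' @slot seqs A \code{\link[Biostrings]{DNAStringSet}} whose names are the
#'   record identifiers (unique, non-empty).
#' @slot desc Character vector of free-text descriptions, parallel to
#'   \code{seqs}.
#' @slot taxon Character vector of taxon labels, parallel to \code{seqs};
#'   \code{NA} where no label is known.
#' @slot aligned Logical scalar; if \code{TRUE} all sequences have equal
#'   length and positional (column) operations are meaningful.
#'
#' @seealso \code{\link{readFasta}}, \code{\link{MarkerSet}} (constructor)
#' @export
setClass("MarkerSet",
  slots = c(
    seqs = "DNAStringSet",
    desc = "character",
    taxon = "character",
    aligned = "logical"
  )
)

setValidity("MarkerSet", function(object) {
  ids <- names(object@seqs)
  msgs <- character()
  n <- length(object@seqs)
  if (n > 0L) {
    if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
      msgs <- c(msgs, "all records must have non-empty ids")
    else if (anyDuplicated(ids))
      msgs <- c(msgs, sprintf("duplicated record id(s): %s",
                              paste(unique(ids[duplicated(ids)]),
                                    collapse = ", ")))
  }
  if (length(object@desc) != n)
    msgs <- c(msgs, "desc must be parallel to seqs")
  if (length(object@taxon) != n)
    msgs <- c(msgs, "taxon must be parallel to seqs")
  if (length(object@aligned) != 1L || is.na(object@aligned))
    msgs <- c(msgs, "aligned must be TRUE or FALSE")
  else if (object@aligned && n > 0L &&
           length(unique(Biostrings::width(object@seqs))) > 1L)
    msgs <- c(msgs, "aligned collection must have equal sequence lengths")
  if (length(msgs)) msgs else TRUE
})

#' DegeneratePrimer: an oligonucleotide over IUPAC codes
#'
#' Represents a (possibly degenerate) PCR primer written in the IUPAC
#' nucleotide alphabet, e.g. the forward primer
#' \code{GCDGCHGCNATGCGTTAYAC} where D = A/G/T, H = A/C/T, N = any and
#' Y = C/T. A degenerate primer stands for the mixture of all its exact
#' (non-degenerate) expansions; see \code{\link{expandDegenerate}}.
#'
#' @slot name Primer name (e.g. \code{"gyrA3-F"}).
#' @slot seq Primer sequence, upper case, over
#'   \code{A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N}.
#' @export
setClass("DegeneratePrimer",
  slots = c(name = "character", seq = "character")
)

setValidity("DegeneratePrimer", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msgs <- c(msgs, "name must be a non-empty string")
  if (length(object@seq) != 1L || is.na(object@seq) || !nzchar(object@seq)) {
    msgs <- c(msgs, "seq must be a non-empty string")
  } else {
    chars <- strsplit(object@seq, "", fixed = TRUE)[[1L]]
    bad <- setdiff(unique(chars), .DEGENERATE_CODES)
    if (length(bad))
      msgs <- c(msgs, sprintf("illegal primer character(s): %s",
                              paste(bad, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' PrimerPair: a forward/reverse primer pair with an amplifiability rule
#'
#' Bundles a forward and a reverse \code{\linkS4class{DegeneratePrimer}}
#' with the parameters of the in-silico amplifiability rule: a template is
#' considered amplifiable when both primers find a binding site with at
#' least \code{minMatch} identical bases (best over all non-degenerate
#' expansions, no indels) and the product length falls within
#' \code{[minAmpliconLen, maxAmpliconLen]}.
#'
#' @slot name Pair name (e.g. \code{"gyrA3"}).
#' @slot forward,reverse \code{\linkS4class{DegeneratePrimer}} objects.
#' @slot minMatch Minimum count of identical bases required at each primer
#'   site (default 18).
#' @slot minAmpliconLen,maxAmpliconLen Product length bounds in bp
#'   (defaults 100 and 3000).
#' @seealso \code{\link{primerPair}}, \code{\link{inSilicoPCR}}
#' @export
setClass("PrimerPair",
  slots = c(
    name = "character",
    forward = "DegeneratePrimer",
    reverse = "DegeneratePrimer",
    minMatch = "integer",
    minAmpliconLen = "integer",
    maxAmpliconLen = "integer"
  )
)

setValidity("PrimerPair", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "name must be a non-empty string")
  mm <- object@minMatch
  if (length(mm) != 1L || is.na(mm) || mm <= 0L)
    msgs <- c(msgs, "minMatch must be a positive integer")
  else {
    shortest <- min(nchar(object@forward@seq), nchar(object@reverse@seq))
    if (mm > shortest)
      msgs <- c(msgs, sprintf(
        "minMatch (%d) exceeds the shortest primer length (%d)", mm, shortest))
  }
  lo <- object@minAmpliconLen; hi <- object@maxAmpliconLen
  if (length(lo) != 1L || length(hi) != 1L || is.na(lo) || is.na(hi) ||
      lo <= 0L || lo > hi)
    msgs <- c(msgs, "require 0 < minAmpliconLen <= maxAmpliconLen")
  if (length(msgs)) msgs else TRUE
})

#' DiversityProfile: sliding-window nucleotide diversity
#'
#' Per-window nucleotide diversity (pi) along an alignment, computed by
#' \code{\link{slidingWindowPi}}. Each point carries the window's start and
#' end columns (1-based inclusive), its reported midpoint, the number of
#' pairwise-valid sites and the window pi. \code{overallPi} is pi over the
#' full alignment.
#'
#' @slot windowSize,step Window size and step in alignment columns.
#' @slot points A \code{data.frame} with columns \code{window_start},
#'   \code{window_end}, \code{midpoint}, \code{n_valid_sites}, \code{pi}.
#' @slot overallPi Numeric scalar, pi over all columns.
#' @export
setClass("DiversityProfile",
  slots = c(
    windowSize = "integer",
    step = "integer",
    points = "data.frame",
    overallPi = "numeric"
  )
)

setValidity("DiversityProfile", function(object) {
  msgs <- character()
  p <- object@points
  need <- c("window_start", "window_end", "midpoint", "n_valid_sites", "pi")
  if (!all(need %in% names(p)))
    msgs <- c(msgs, "points must have columns window_start, window_end, midpoint, n_valid_sites, pi")
  else {
    finite <- p$pi[is.finite(p$pi)]
    if (length(finite) && (min(finite) < 0 || max(finite) > 1))
      msgs <- c(msgs, "pi must lie in [0, 1]")
    if (nrow(p) > 1L && length(unique(diff(p$window_start))) > 1L)
      msgs <- c(msgs, "window starts must be equally spaced by step")
  }
  if (length(msgs)) msgs else TRUE
})

#' VariableSiteProfile: reference-anchored variable sites of a region
#'
#' Result of comparing every genome of an aligned collection against a
#' chosen representative (reference) sequence over a fixed sub-region, as
#' produced by \code{\link{variableSites}}. A column is a variable site
#' when at least one genome carries an unambiguous base differing from the
#' reference base there. Per-genome mismatch counts are converted to
#' frequencies against the fixed region length (the denominator does not
#' shrink for gapped or ambiguous columns).
#'
#' @slot geneLabel Marker gene name (e.g. \code{"16S"}, \code{"gyrA"}).
#' @slot species Species label for summary tables.
#' @slot region Integer vector \code{c(start, end)}, 1-based inclusive
#'   alignment columns.
#' @slot regionLength Fixed region length in bp (\code{end - start + 1} by
#'   default, configurable).
#' @slot referenceId Identifier of the representative sequence.
#' @slot variableSites Sorted integer vector of variable alignment columns.
#' @slot perGenome \code{data.frame} with columns \code{genome_id},
#'   \code{n_mismatches}, \code{freq_pct}.
#' @slot nGenomesTotal,nGenomesVariable Genome counts (all genomes compared;
#'   genomes with at least one mismatch).
#' @slot mismatchRange Integer \code{c(min, max)} mismatch count over
#'   genomes with >= 1 mismatch (both 0 when none).
#' @slot freqRangePct Numeric \code{c(min, max)} frequency range in percent
#'   over genomes with >= 1 mismatch.
#' @export
setClass("VariableSiteProfile",
  slots = c(
    geneLabel = "character",
    species = "character",
    region = "integer",
    regionLength = "integer",
    referenceId = "character",
    variableSites = "integer",
    perGenome = "data.frame",
    nGenomesTotal = "integer",
    nGenomesVariable = "integer",
    mismatchRange = "integer",
    freqRangePct = "numeric"
  )
)

setValidity("VariableSiteProfile", function(object) {
  msgs <- character()
  pg <- object@perGenome
  if (!all(c("genome_id", "n_mismatches", "freq_pct") %in% names(pg)))
    msgs <- c(msgs, "perGenome must have genome_id, n_mismatches, freq_pct")
  else {
    expect <- 100 * pg$n_mismatches / object@regionLength
    if (nrow(pg) && max(abs(pg$freq_pct - expect)) > 1e-9)
      msgs <- c(msgs, "freq_pct must equal 100 * n_mismatches / regionLength")
    nv <- sum(pg$n_mismatches >= 1L)
    if (nv != object@nGenomesVariable)
      msgs <- c(msgs, "nGenomesVariable inconsistent with perGenome")
    if (object@nGenomesVariable > object@nGenomesTotal)
      msgs <- c(msgs, "nGenomesVariable cannot exceed nGenomesTotal")
  }
  if (length(object@region) != 2L || object@region[1L] > object@region[2L])
    msgs <- c(msgs, "region must be c(start, end) with start <= end")
  if (length(msgs)) msgs else TRUE
})

#' ResolutionResult: distinguishable units of a mock community
#'
#' Partition of mock-community members into units that share a byte-identical
#' amplicon sequence for a given primer pair, as produced by
#' \code{\link{resolveCommunity}}. Members whose marker sequence yields no
#' in-silico product are collected in \code{unamplified}. \code{nUnits}
#' counts the non-empty amplified groups only.
#'
#' @slot pairName Primer pair name.
#' @slot marker Marker gene name the partition was computed on.
#' @slot units Named list; each element is a character vector of strain ids
#'   sharing one amplicon sequence.
#' @slot unitSeqs Character vector of the shared amplicon (or insert)
#'   sequence per unit, parallel to \code{units}.
#' @slot unamplified Character vector of strain ids with no product.
#' @slot nUnits Integer count of distinguishable amplified units.
#' @slot perUnitReads \code{data.frame(unit, reads)} of pooled read counts
#'   (zero rows until \code{\link{poolAndCount}} is applied).
#' @export
setClass("ResolutionResult",
  slots = c(
    pairName = "character",
    marker = "character",
    units = "list",
    unitSeqs = "character",
    unamplified = "character",
    nUnits = "integer",
    perUnitReads = "data.frame"
  )
)

setValidity("ResolutionResult", function(object) {
  msgs <- character()
  members <- unlist(object@units, use.names = FALSE)
  if (anyDuplicated(c(members, object@unamplified)))
    msgs <- c(msgs, "units and unamplified must be disjoint and non-overlapping")
  if (object@nUnits != sum(lengths(object@units) > 0L))
    msgs <- c(msgs, "nUnits must equal the number of non-empty amplified groups")
  if (length(object@unitSeqs) != length(object@units))
    msgs <- c(msgs, "unitSeqs must be parallel to units")
  if (length(msgs)) msgs else TRUE
})

#' MockCommunity: a defined set of strains with per-marker sequences
#'
#' A defined mixture of known strains, each carrying one sequence per marker
#' gene (e.g. the full 16S rRNA and gyrA genes of eight strains), used to
#' benchmark the resolution of a marker/primer combination.
#'
#' @slot strains Character vector of unique strain identifiers.
#' @slot markers Named list of \code{\link[Biostrings]{DNAStringSet}}
#'   objects, one per marker gene; each set is named by strain id and covers
#'   every strain.
#' @export
setClass("MockCommunity",
  slots = c(strains = "character", markers = "list")
)

setValidity("MockCommunity", function(object) {
  msgs <- character()
  if (anyDuplicated(object@strains))
    msgs <- c(msgs, "strain ids must be unique")
  if (is.null(names(object@markers)) || any(!nzchar(names(object@markers))))
    msgs <- c(msgs, "markers must be a named list")
  for (m in names(object@markers)) {
    s <- object@markers[[m]]
    if (!is(s, "DNAStringSet")) {
      msgs <- c(msgs, sprintf("marker '%s' must be a DNAStringSet", m))
    } else if (!all(object@strains %in% names(s))) {
      msgs <- c(msgs, sprintf("marker '%s' lacks sequences for some strains", m))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' CommunitySpec: parameters of the synthetic community generator
#'
#' Declarative description of a synthetic genus: a star phylogeny in which
#' species ancestors are independent per-site mutants of one genus ancestor
#' (substitution probability \code{interDivergence}) and strains are
#' independent per-site mutants of their species ancestor
#' (\code{intraRate}). Each marker template embeds one exact expansion of a
#' primer pair's binding sites; species can be flagged primer-incompatible,
#' in which case their forward site is scrambled below the match threshold.
#' Mutations are never planted inside primer sites flagged compatible, so
#' the generator's truth table fully determines amplifiability.
#'
#' Use \code{\link{communitySpec}} to construct and validate one.
#'
#' @slot nSpecies,strainsPerSpecies Integer counts.
#' @slot markers Named list of per-marker template descriptions (see
#'   \code{\link{communitySpec}}).
#' @slot interDivergence,intraRate Per-site substitution probabilities in
#'   \code{[0, 1]}.
#' @slot seed Integer seed making generation reproducible.
#' @export
setClass("CommunitySpec",
  slots = c(
    nSpecies = "integer",
    strainsPerSpecies = "integer",
    markers = "list",
    interDivergence = "numeric",
    intraRate = "numeric",
    seed = "integer"
  )
)

setValidity("CommunitySpec", function(object) {
  msgs <- character()
  if (object@nSpecies < 1L || object@strainsPerSpecies < 1L)
    msgs <- c(msgs, "nSpecies and strainsPerSpecies must be >= 1")
  for (p in c(object@interDivergence, object@intraRate))
    if (is.na(p) || p < 0 || p > 1)
      msgs <- c(msgs, "substitution probabilities must lie in [0, 1]")
  if (is.null(names(object@markers)) || !length(object@markers))
    msgs <- c(msgs, "markers must be a non-empty named list")
  for (m in names(object@markers)) {
    mk <- object@markers[[m]]
    pair <- mk$pair
    minlen <- max(nchar(pair@forward@seq), nchar(pair@reverse@seq)) + 50L
    if (mk$length < minlen)
      msgs <- c(msgs, sprintf(
        "marker '%s' length must be >= primer length + 50 (%d)", m, minlen))
  }
  if (length(msgs)) msgs else TRUE
})
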