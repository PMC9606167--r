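#' @include pcr.R
NULL

#' Construct a mock community
#'
#' @param markers Named list of per-marker sequence sets; each element a
#'   \code{\link[Biostrings]{DNAStringSet}} or named character vector whose
#'   names are strain ids.
#' @param strains Optional character vector of strain ids; defaults to the
#'   names of the first marker set.
#' @return A \code{\linkS4class{MockCommunity}}.
#' @examples
#' mc <- mockCommunity(list(
#'   gyrA = c(s1 = strrep("ACGT", 100), s2 = strrep("ACGA", 100))))
#' @export
mockCommunity <- function(markers, strains = NULL) {
  markers <- lapply(markers, function(m) {
    if (is.character(m)) Biostrings::DNAStringSet(toupper(m)) else m
  })
  if (is.null(strains)) strains <- names(markers[[1L]])
  new("MockCommunity", strains = strains, markers = markers)
}

#' Strain identifiers of a mock community
#' @param x A \code{\linkS4class{MockCommunity}}.
#' @return Character vector of strain ids.
#' @export
communityStrains <- function(x) {
  stopifnot(is(x, "MockCommunity"))
  x@strains
}

#' Marker sequences of a mock community
#' @param x A \code{\linkS4class{MockCommunity}}.
#' @param marker Marker gene name.
#' @return A \code{\link[Biostrings]{DNAStringSet}} named by strain.
#' @export
markerSequences <- function(x, marker) {
  stopifnot(is(x, "MockCommunity"))
  if (!marker %in% names(x@markers))
    stop(sprintf("marker '%s' not present in community", marker),
         call. = FALSE)
  x@markers[[marker]][x@strains]
}

setMethod("show", "MockCommunity", function(object) {
  cat(sprintf("MockCommunity of %d strains; markers: %s\n",
              length(object@strains),
              paste(names(object@markers), collapse = ", ")))
})

#' Resolve a mock community with a primer pair
#'
#' Runs \code{\link{inSilicoPCR}} on each member's marker sequence and
#' partitions the members into distinguishable units: members whose
#' amplicons are byte-identical (case-insensitive) share a unit, members
#' with no product form the "unamplified" group. By default identity is
#' judged on the amplicon insert (primer-binding regions trimmed), since
#' reads of degenerate-primer products carry primer-encoded variation that
#' is not biological; \code{keepPrimers = TRUE} compares full amplicons.
#' When a member yields several products, the leftmost is used.
#'
#' @param community A \code{\linkS4class{MockCommunity}}.
#' @param marker Marker gene name.
#' @param pair A \code{\linkS4class{PrimerPair}}.
#' @param keepPrimers Logical; compare full amplicons instead of inserts.
#' @return A \code{\linkS4class{ResolutionResult}}.
#' @examples
#' mc <- mockCommunity(list(m = c(
#'   s1 = paste0(strrep("A", 20), "ACGTACGTACGTACGTACGT",
#'               strrep("C", 120), "ACGTACGTACGTACGTACGT", strrep("A", 20)))))
#' @export
resolveCommunity <- function(community, marker, pair, keepPrimers = FALSE) {
  seqs <- markerSequences(community, marker)
  strains <- community@strains
  key <- setNames(rep(NA_character_, length(strains)), strains)
  for (s in strains) {
    amp <- inSilicoPCR(pair, as.character(seqs[[s]]), id = s)
    if (nrow(amp)) {
      chosen <- amp[1L, ]  # leftmost product
      key[[s]] <- toupper(if (keepPrimers) chosen$seq else chosen$insert)
    }
  }
  unamplified <- strains[is.na(key)]
  amped <- key[!is.na(key)]
  units <- split(names(amped), factor(amped, levels = unique(amped)))
  names(units) <- sprintf("unit%02d", seq_along(units))
  new("ResolutionResult",
      pairName = pair@name, marker = marker,
      units = units, unitSeqs = unique(unname(amped)),
      unamplified = unamplified,
      nUnits = length(units),
      perUnitReads = data.frame(unit = character(), reads = integer(),
                                stringsAsFactors = FALSE))
}

#' @describeIn nUnits Unit count of a resolution result.
#' @export
setMethod("nUnits", "ResolutionResult", function(x) x@nUnits)

#' @describeIn unitMembers Partition of a resolution result.
#' @export
setMethod("unitMembers", "ResolutionResult", function(x) x@units)

#' Strains without any in-silico product
#' @param x A \code{\linkS4class{ResolutionResult}}.
#' @return Character vector of strain ids.
#' @export
unamplifiedStrains <- function(x) {
  stopifnot(is(x, "ResolutionResult"))
  x@unamplified
}

setMethod("show", "ResolutionResult", function(object) {
  cat(sprintf("ResolutionResult: pair %s on %s -> %d unit%s\n",
              object@pairName, object@marker, object@nUnits,
              if (object@nUnits == 1L) "" else "s"))
  for (u in names(object@units))
    cat(sprintf("  %s: %s\n", u, paste(object@units[[u]], collapse = ", ")))
  if (length(object@unamplified))
    cat(sprintf("  unamplified: %s\n",
                paste(object@unamplified, collapse = ", ")))
  if (nrow(object@perUnitReads)) {
    cat("  pooled reads:\n")
    for (i in seq_len(nrow(object@perUnitReads)))
      cat(sprintf("    %s: %d\n", object@perUnitReads$unit[i],
                  object@perUnitReads$reads[i]))
  }
})

#' Annotate denoised amplicon sequences (ZOTUs) to strains
#'
#' Assigns each ZOTU to the reference strain of highest global identity,
#' computed as an ungapped position-wise comparison over the end-trimmed
#' common length (the longer sequence is truncated to the shorter):
#' identity = matches / compared length. Ties for the best identity and
#' identities below \code{minIdentity} yield \code{"unassigned"}.
#'
#' @param zotus A \code{\linkS4class{MarkerSet}},
#'   \code{\link[Biostrings]{DNAStringSet}} or named character vector of
#'   denoised sequences.
#' @param references Named character vector (or \code{DNAStringSet}) of
#'   per-strain amplicon sequences.
#' @param minIdentity Minimum identity fraction for assignment
#'   (default 0.97).
#' @return A \code{data.frame} with columns \code{zotu_id}, \code{strain}
#'   (\code{"unassigned"} where no unique confident hit exists) and
#'   \code{identity} (of the best hit).
#' @export
annotateZotus <- function(zotus, references, minIdentity = 0.97) {
  zs <- if (is(zotus, "MarkerSet")) as.character(sequences(zotus))
        else setNames(toupper(as.character(zotus)), names(zotus))
  refs <- setNames(toupper(as.character(references)), names(references))
  if (!length(refs)) stop("references must be non-empty", call. = FALSE)
  if (is.null(names(refs)) || any(!nzchar(names(refs))))
    stop("references must be named by strain", call. = FALSE)
  ids <- names(zs)
  if (is.null(ids)) ids <- sprintf("zotu%d", seq_along(zs))
  identity1 <- function(a, b) {
    L <- min(nchar(a), nchar(b))
    if (L == 0L) return(0)
    ca <- strsplit(substr(a, 1L, L), "", fixed = TRUE)[[1L]]
    cb <- strsplit(substr(b, 1L, L), "", fixed = TRUE)[[1L]]
    sum(ca == cb) / L
  }
  out <- data.frame(zotu_id = ids, strain = NA_character_,
                    identity = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(zs)) {
    idents <- vapply(refs, identity1, numeric(1L), a = zs[[i]])
    best <- max(idents)
    hits <- names(refs)[idents == best]
    out$identity[i] <- best
    out$strain[i] <- if (best >= minIdentity && length(hits) == 1L)
      hits else "unassigned"
  }
  out
}

#' Pool annotated ZOTU read counts into community units
#'
#' Sums read counts per assigned strain, then merges strains belonging to
#' the same distinguishable unit of a \code{\linkS4class{ResolutionResult}}
#' partition. Reads of unassigned ZOTUs are reported under
#' \code{"unassigned"}; total reads are conserved.
#'
#' @param mapping \code{data.frame(zotu_id, strain)} from
#'   \code{\link{annotateZotus}}.
#' @param readCounts Named integer vector of read counts per zotu_id.
#' @param result A \code{\linkS4class{ResolutionResult}} defining the unit
#'   partition; \code{NULL} keeps strains as their own units.
#' @return The \code{result} with \code{perUnitReads} filled in (or, when
#'   \code{result} is \code{NULL}, a \code{data.frame(unit, reads)}).
#' @export
poolAndCount <- function(mapping, readCounts, result = NULL) {
  if (!all(mapping$zotu_id %in% names(readCounts)))
    stop("every zotu in the mapping must have a read count", call. = FALSE)
  counts <- readCounts[mapping$zotu_id]
  perStrain <- tapply(as.integer(counts), mapping$strain, sum)
  if (is.null(result)) {
    df <- data.frame(unit = names(perStrain),
                     reads = as.integer(perStrain),
                     stringsAsFactors = FALSE)
    rownames(df) <- NULL
    return(df)
  }
  stopifnot(is(result, "ResolutionResult"))
  units <- result@units
  rows <- lapply(names(units), function(u) {
    strains <- units[[u]]
    data.frame(unit = u,
               reads = sum(perStrain[intersect(strains, names(perStrain))],
                           na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  assigned <- unlist(units, use.names = FALSE)
  leftover <- setdiff(names(perStrain), assigned)
  if (length(leftover))
    df <- rbind(df, data.frame(
      unit = ifelse(leftover == "unassigned", "unassigned",
                    paste0("other:", leftover)),
      reads = as.integer(perStrain[leftover]),
      stringsAsFactors = FALSE))
  df$reads <- as.integer(df$reads)
  rownames(df) <- NULL
  result@perUnitReads <- df
  result
}

#' Dereplicate reads into unique sequences with counts
#'
#' Exact-string dereplication after upper-casing; with error-free
#' simulated reads this recovers one unique sequence per distinguishable
#' source. Counts sum to the number of input reads.
#'
#' @param reads A \code{\linkS4class{MarkerSet}},
#'   \code{\link[Biostrings]{DNAStringSet}} or character vector of reads.
#' @return A \code{data.frame} with columns \code{seq} and \code{count},
#'   sorted by descending count then sequence.
#' @export
dereplicateReads <- function(reads) {
  rs <- if (is(reads, "MarkerSet")) as.character(sequences(reads))
        else toupper(as.character(reads))
  if (!length(rs))
    return(data.frame(seq = character(), count = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(rs)
  df <- data.frame(seq = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$seq), , drop = FALSE]
  rownames(df) <- NULL
  df
}
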