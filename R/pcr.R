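#' @include primers.R
NULL

## Per-window best-over-expansions identical-base counts.
##
## Because a degenerate primer's expansions form the full Cartesian product
## of its per-position IUPAC sets, the maximum over expansions of the
## identical-base count at a window equals the number of window positions
## whose (unambiguous) target base lies in the primer's set at that
## position. This makes the scan O(primer length * target length) with no
## expansion loop, and is exactly equivalent to maximising matchCount()
## over expandDegenerate().
.windowMatchCounts <- function(primerSeq, targetChars) {
  k <- nchar(primerSeq)
  L <- length(targetChars)
  if (L < k) return(integer(0))
  nwin <- L - k + 1L
  codes <- match(targetChars, c("A", "C", "G", "T"), nomatch = 0L)
  pc <- strsplit(primerSeq, "", fixed = TRUE)[[1L]]
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP[pc], "", fixed = TRUE)
  comp <- matrix(0L, nrow = 4L, ncol = k)
  for (j in seq_len(k))
    comp[match(sets[[j]], c("A", "C", "G", "T")), j] <- 1L
  counts <- integer(nwin)
  for (j in seq_len(k)) {
    idx <- codes[seq.int(j, j + nwin - 1L)]
    ok <- idx > 0L
    counts[ok] <- counts[ok] + comp[idx[ok] + 4L * (j - 1L)]
  }
  counts
}

## The exact expansion achieving the best count at one window: copy the
## target base where it is compatible, else the first base of the set.
.achievingVariant <- function(primerSeq, windowChars) {
  pc <- strsplit(primerSeq, "", fixed = TRUE)[[1L]]
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP[pc], "", fixed = TRUE)
  out <- character(length(pc))
  for (j in seq_along(pc)) {
    w <- windowChars[j]
    out[j] <- if (w %in% c("A", "C", "G", "T") && w %in% sets[[j]])
      w else sets[[j]][1L]
  }
  paste(out, collapse = "")
}

## Per-position compatibility of one window with the primer's IUPAC sets.
.matchVector <- function(sets, windowChars) {
  vapply(seq_along(sets), function(j) {
    w <- windowChars[j]
    w %in% c("A", "C", "G", "T") && w %in% sets[[j]]
  }, logical(1L))
}

.maxRun <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

.asTargetString <- function(target) {
  if (is(target, "MarkerSet")) {
    if (length(target) != 1L)
      stop("target must be a single sequence", call. = FALSE)
    s <- as.character(target@seqs)[[1L]]
  } else if (is(target, "DNAString")) {
    s <- as.character(target)
  } else {
    s <- toupper(as.character(target))
  }
  if (grepl("-", s, fixed = TRUE))
    stop("target must be ungapped", call. = FALSE)
  s
}

#' Locate primer binding sites under the minimum-identical-base rule
#'
#' Scans every window of primer length on both strands of an ungapped
#' target against all non-degenerate expansions of the primer, and reports
#' windows whose best expansion reaches at least \code{minMatch} identical
#' bases. No indels are permitted within a site; ambiguity codes or
#' \code{N} in the target count as mismatches. Minus-strand sites are
#' reported in plus-strand coordinates.
#'
#' @param primer A \code{\linkS4class{DegeneratePrimer}} or IUPAC string.
#' @param target An ungapped sequence: a single-record
#'   \code{\linkS4class{MarkerSet}}, \code{DNAString} or character string.
#' @param minMatch Minimum identical bases (absolute count).
#' @param id Record id used in the report (default \code{"target"}, or the
#'   record id when \code{target} is a \code{MarkerSet}).
#' @param contiguous Logical; additionally require a contiguous run of at
#'   least \code{minMatch} matching positions (sensitivity analysis; the
#'   default rule counts matches anywhere in the site).
#' @param anchor3 Integer; additionally require the \code{anchor3}
#'   3'-terminal positions of the primer to match (0 disables). Useful to
#'   emulate the polymerase's intolerance of 3' mismatches.
#' @return A \code{data.frame} with columns \code{record_id},
#'   \code{strand}, \code{start}, \code{end}, \code{matched},
#'   \code{variant} (the expansion achieving the match, in primer
#'   orientation), sorted by (start, strand). A target shorter than the
#'   primer yields zero rows.
#' @examples
#' findBindingSites("AY", "GGAT", minMatch = 2)
#' @export
findBindingSites <- function(primer, target, minMatch = 18L, id = NULL,
                             contiguous = FALSE, anchor3 = 0L) {
  pseq <- if (is(primer, "DegeneratePrimer")) primer@seq else toupper(primer)
  if (is.null(id))
    id <- if (is(target, "MarkerSet")) seqIds(target)[1L] else "target"
  tstr <- .asTargetString(target)
  tc <- strsplit(tstr, "", fixed = TRUE)[[1L]]
  k <- nchar(pseq)
  empty <- data.frame(record_id = character(), strand = character(),
                      start = integer(), end = integer(),
                      matched = integer(), variant = character(),
                      stringsAsFactors = FALSE)
  if (length(tc) < k) return(empty)
  rows <- list()
  anchor3 <- as.integer(anchor3)
  scan1 <- function(scanSeq, strand) {
    counts <- .windowMatchCounts(scanSeq, tc)
    hit <- which(counts >= minMatch)
    if (length(hit) && (contiguous || anchor3 > 0L)) {
      pc <- strsplit(scanSeq, "", fixed = TRUE)[[1L]]
      sets <- strsplit(Biostrings::IUPAC_CODE_MAP[pc], "", fixed = TRUE)
      ## on the minus strand the scanned sequence is the primer's reverse
      ## complement, so the primer's 3' end sits at window position 1
      anchorPos <- if (anchor3 > 0L) {
        if (strand == "+") (k - anchor3 + 1L):k else seq_len(anchor3)
      } else integer()
      keep <- vapply(hit, function(i) {
        mv <- .matchVector(sets, tc[i:(i + k - 1L)])
        (!contiguous || .maxRun(mv) >= minMatch) &&
          (anchor3 == 0L || all(mv[anchorPos]))
      }, logical(1L))
      hit <- hit[keep]
    }
    if (!length(hit)) return(NULL)
    variant <- vapply(hit, function(i) {
      v <- .achievingVariant(scanSeq, tc[i:(i + k - 1L)])
      if (strand == "-") reverseComplementSeq(v) else v
    }, character(1L))
    data.frame(record_id = id, strand = strand, start = hit,
               end = hit + k - 1L, matched = counts[hit],
               variant = variant, stringsAsFactors = FALSE)
  }
  rows$plus <- scan1(pseq, "+")
  rows$minus <- scan1(reverseComplementSeq(pseq), "-")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) return(empty)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' In-silico PCR of a primer pair on a template
#'
#' Emits one amplicon per orientation-consistent pair of binding sites
#' within the pair's product length bounds: a forward-primer site on the
#' plus strand combined with a downstream reverse-primer site on the minus
#' strand, and the strand-mirrored case. All coordinates and the amplicon
#' sequence are reported on the plus strand; \code{insert} is the amplicon
#' with both primer-binding regions trimmed. An empty result means the
#' template is not amplifiable under the pair's rule.
#'
#' @param pair A \code{\linkS4class{PrimerPair}}.
#' @param target An ungapped template (single-record
#'   \code{\linkS4class{MarkerSet}}, \code{DNAString} or string).
#' @param id Record id for the report.
#' @param contiguous,anchor3 Optional stricter site rules; see
#'   \code{\link{findBindingSites}}.
#' @return A \code{data.frame} with columns \code{record_id},
#'   \code{pair_name}, \code{strand}, \code{start}, \code{end},
#'   \code{length}, \code{fwd_matched}, \code{rev_matched}, \code{seq},
#'   \code{insert}, ordered by (start, end).
#' @examples
#' pp <- primerPair("toy", "ACGTACGTACGTACGTACGT", "TTTTGGGGCCCCAAAATTTT",
#'                  minAmpliconLen = 50)
#' @export
inSilicoPCR <- function(pair, target, id = NULL, contiguous = FALSE,
                        anchor3 = 0L) {
  if (is.null(id))
    id <- if (is(target, "MarkerSet")) seqIds(target)[1L] else "target"
  tstr <- .asTargetString(target)
  fLen <- nchar(pair@forward@seq)
  rLen <- nchar(pair@reverse@seq)
  fSites <- findBindingSites(pair@forward, tstr, pair@minMatch, id = id,
                             contiguous = contiguous, anchor3 = anchor3)
  rSites <- findBindingSites(pair@reverse, tstr, pair@minMatch, id = id,
                             contiguous = contiguous, anchor3 = anchor3)
  empty <- data.frame(record_id = character(), pair_name = character(),
                      strand = character(), start = integer(),
                      end = integer(), length = integer(),
                      fwd_matched = integer(), rev_matched = integer(),
                      seq = character(), insert = character(),
                      stringsAsFactors = FALSE)
  rows <- list()
  ## plus orientation: forward on +, reverse on - downstream
  fp <- fSites[fSites$strand == "+", , drop = FALSE]
  rm_ <- rSites[rSites$strand == "-", , drop = FALSE]
  if (nrow(fp) && nrow(rm_)) {
    for (i in seq_len(nrow(fp))) for (j in seq_len(nrow(rm_))) {
      if (rm_$start[j] <= fp$end[i]) next
      len <- rm_$end[j] - fp$start[i] + 1L
      if (len < pair@minAmpliconLen || len > pair@maxAmpliconLen) next
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = id, pair_name = pair@name, strand = "+",
        start = fp$start[i], end = rm_$end[j], length = len,
        fwd_matched = fp$matched[i], rev_matched = rm_$matched[j],
        seq = substr(tstr, fp$start[i], rm_$end[j]),
        insert = if (rm_$start[j] - 1L >= fp$end[i] + 1L)
          substr(tstr, fp$end[i] + 1L, rm_$start[j] - 1L) else "",
        stringsAsFactors = FALSE)
    }
  }
  ## minus orientation: reverse on + upstream of forward on -
  fm <- fSites[fSites$strand == "-", , drop = FALSE]
  rp <- rSites[rSites$strand == "+", , drop = FALSE]
  if (nrow(fm) && nrow(rp)) {
    for (i in seq_len(nrow(fm))) for (j in seq_len(nrow(rp))) {
      if (fm$start[i] <= rp$end[j]) next
      len <- fm$end[i] - rp$start[j] + 1L
      if (len < pair@minAmpliconLen || len > pair@maxAmpliconLen) next
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = id, pair_name = pair@name, strand = "-",
        start = rp$start[j], end = fm$end[i], length = len,
        fwd_matched = fm$matched[i], rev_matched = rp$matched[j],
        seq = substr(tstr, rp$start[j], fm$end[i]),
        insert = if (fm$start[i] - 1L >= rp$end[j] + 1L)
          substr(tstr, rp$end[j] + 1L, fm$start[i] - 1L) else "",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- unique(out)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-species amplifiability summary of a sequence database
#'
#' Runs \code{\link{inSilicoPCR}} on every record of a database and
#' summarises per species: a species counts as identified by the pair iff
#' at least one of its sequences yields at least one amplicon.
#'
#' @param db A \code{\linkS4class{MarkerSet}} whose records all carry a
#'   taxon label.
#' @param pair A \code{\linkS4class{PrimerPair}}.
#' @return A list with elements \code{species} (a \code{data.frame} with
#'   columns \code{species}, \code{n_sequences}, \code{n_amplifiable},
#'   \code{amplifiable}), \code{n_sequences_matched} and
#'   \code{n_species_matched}.
#' @export
amplifiabilitySummary <- function(db, pair) {
  taxa <- taxonLabels(db)
  if (anyNA(taxa))
    stop("every record must carry a taxon label", call. = FALSE)
  seqs <- as.character(sequences(db))
  ids <- seqIds(db)
  amp <- vapply(seq_along(seqs), function(i)
    nrow(inSilicoPCR(pair, seqs[[i]], id = ids[i])) > 0L, logical(1L))
  species <- unique(taxa)
  tab <- data.frame(
    species = species,
    n_sequences = vapply(species, function(s) sum(taxa == s), integer(1L)),
    n_amplifiable = vapply(species, function(s) sum(amp[taxa == s]),
                           integer(1L)),
    stringsAsFactors = FALSE)
  tab$amplifiable <- tab$n_amplifiable >= 1L
  rownames(tab) <- NULL
  list(species = tab,
       n_sequences_matched = sum(tab$n_amplifiable),
       n_species_matched = sum(tab$amplifiable))
}

#' Write amplicons to FASTA
#'
#' Headers follow \code{id|start-end|strand}.
#'
#' @param amplicons A \code{data.frame} from \code{\link{inSilicoPCR}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeAmpliconFasta <- function(amplicons, path) {
  hdr <- sprintf("%s|%d-%d|%s", amplicons$record_id, amplicons$start,
                 amplicons$end, amplicons$strand)
  s <- Biostrings::DNAStringSet(amplicons$seq)
  names(s) <- hdr
  Biostrings::writeXStringSet(s, filepath = path)
  invisible(path)
}
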