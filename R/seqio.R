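#' @include AllGenerics.R
NULL

#' Construct a MarkerSet
#'
#' @param seqs A \code{\link[Biostrings]{DNAStringSet}} or named character
#'   vector of sequences; names are the record ids.
#' @param desc Optional character vector of descriptions (default empty
#'   strings).
#' @param taxon Optional character vector of taxon labels (default
#'   \code{NA}).
#' @param aligned Logical; \code{NA} (default) sets the flag to \code{TRUE}
#'   iff all sequences have equal length and at least one contains a gap.
#' @return A \code{\linkS4class{MarkerSet}}.
#' @examples
#' ms <- MarkerSet(c(a = "ACGT", b = "ACGA"))
#' seqIds(ms)
#' @export
MarkerSet <- function(seqs, desc = NULL, taxon = NULL, aligned = NA) {
  if (is.character(seqs)) {
    seqs <- normalizeSeqChars(seqs, names(seqs))
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  n <- length(seqs)
  if (is.null(desc)) desc <- rep("", n)
  if (is.null(taxon)) taxon <- rep(NA_character_, n)
  if (is.na(aligned)) {
    w <- Biostrings::width(seqs)
    aligned <- n > 0L && length(unique(w)) == 1L &&
      any(vapply(as.character(seqs), function(s) grepl("-", s, fixed = TRUE),
                 logical(1L)))
  }
  new("MarkerSet", seqs = seqs, desc = desc, taxon = taxon,
      aligned = as.logical(aligned))
}

## Upper-case, map U->T and the '.' gap alias to '-', and verify the
## alphabet, reporting the record id and the offending character.
normalizeSeqChars <- function(seqs, ids = names(seqs)) {
  seqs <- toupper(seqs)
  seqs <- chartr("U.", "T-", seqs)
  ok <- paste(.IUPAC_CHARS, collapse = "")
  for (i in seq_along(seqs)) {
    bad <- unique(strsplit(gsub(sprintf("[%s]", ok), "", seqs[[i]]), "",
                           fixed = TRUE)[[1L]])
    if (length(bad))
      stop(sprintf("record '%s' contains illegal character(s): %s",
                   if (is.null(ids)) as.character(i) else ids[[i]],
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  seqs
}

#' Read marker-gene sequences from a FASTA file
#'
#' Records are kept in file order and upper-cased on ingest; \code{U} is
#' normalised to \code{T} and the gap alias \code{.} to \code{-}. The record
#' id is the first whitespace-delimited token of the header; the remainder
#' is the description. A taxon label is parsed from the description with
#' \code{taxonPattern} (default: the first two whitespace-separated words,
#' matching binomial species names such as \code{Bacillus subtilis}). The
#' \code{aligned} flag is set \code{TRUE} iff all sequences have equal
#' length and at least one contains a gap.
#'
#' @param path Path to a (multi-record, wrapped or unwrapped) FASTA file.
#' @param taxonPattern Regular expression with one capture group applied to
#'   each description to extract the taxon label; non-matching descriptions
#'   yield \code{NA}.
#' @return A \code{\linkS4class{MarkerSet}}.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 Bacillus subtilis strain X", "ACGTACGT"), fa)
#' ms <- readFasta(fa)
#' taxonLabels(ms)
#' @export
readFasta <- function(path, taxonPattern = "^(\\S+\\s+\\S+)") {
  if (!file.exists(path))
    stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L)
    stop(sprintf("no records in FASTA file: %s", path), call. = FALSE)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(raw)
  names(seqs) <- ids
  seqs <- normalizeSeqChars(seqs, ids)
  taxon <- rep(NA_character_, length(ids))
  has <- nzchar(desc) & grepl(taxonPattern, desc)
  taxon[has] <- sub(paste0(taxonPattern, ".*$"), "\\1", desc[has])
  MarkerSet(Biostrings::DNAStringSet(seqs), desc = desc, taxon = taxon)
}

#' Write a MarkerSet to a FASTA file
#'
#' Headers are \code{id description} (description omitted when empty).
#' Round-tripping through \code{\link{readFasta}} preserves (id, seq) pairs.
#'
#' @param x A \code{\linkS4class{MarkerSet}}.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(x, path, width = 70L) {
  s <- x@seqs
  hdr <- names(s)
  has <- nzchar(x@desc)
  hdr[has] <- paste(hdr[has], x@desc[has])
  names(s) <- hdr
  Biostrings::writeXStringSet(s, filepath = path, width = width)
  invisible(path)
}

#' @describeIn seqIds Ids of a MarkerSet.
#' @export
setMethod("seqIds", "MarkerSet", function(x) names(x@seqs))

#' @describeIn taxonLabels Labels of a MarkerSet.
#' @export
setMethod("taxonLabels", "MarkerSet", function(x) x@taxon)

#' @describeIn taxonLabels-set Replace labels of a MarkerSet.
#' @export
setMethod("taxonLabels<-", "MarkerSet", function(x, value) {
  x@taxon <- rep_len(as.character(value), length(x@seqs))
  validObject(x)
  x
})

#' @describeIn isAligned Alignment flag of a MarkerSet.
#' @export
setMethod("isAligned", "MarkerSet", function(x) x@aligned)

#' @describeIn sequences Sequences of a MarkerSet.
#' @export
setMethod("sequences", "MarkerSet", function(x) x@seqs)

#' @export
setMethod("length", "MarkerSet", function(x) length(x@seqs))

#' Subset a MarkerSet
#' @param x A \code{\linkS4class{MarkerSet}}.
#' @param i Index vector (numeric, logical or record ids).
#' @param j,drop,... Ignored.
#' @return A \code{\linkS4class{MarkerSet}} of the selected records.
#' @export
setMethod("[", "MarkerSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@seqs))
  new("MarkerSet", seqs = x@seqs[i], desc = x@desc[i], taxon = x@taxon[i],
      aligned = x@aligned)
})

setMethod("show", "MarkerSet", function(object) {
  cat(sprintf("MarkerSet of %d sequence%s%s\n", length(object@seqs),
              if (length(object@seqs) == 1L) "" else "s",
              if (object@aligned)
                sprintf(" (aligned, %d columns)",
                        if (length(object@seqs)) Biostrings::width(object@seqs)[1L] else 0L)
              else ""))
  n <- min(5L, length(object@seqs))
  if (n > 0L) {
    w <- Biostrings::width(object@seqs)[seq_len(n)]
    for (i in seq_len(n))
      cat(sprintf("  %s  %d bp  %s\n", names(object@seqs)[i], w[i],
                  ifelse(is.na(object@taxon[i]), "", object@taxon[i])))
    if (length(object@seqs) > n) cat("  ...\n")
  }
})

#' @describeIn extractRegion Trim every record of an aligned collection to
#'   columns \code{[start, end]} (1-based inclusive); the output length is
#'   \code{end - start + 1} for every record and the aligned flag is kept.
#' @examples
#' aln <- MarkerSet(c(a = "ACGTACGT", b = "ACGAAC-T"), aligned = TRUE)
#' as.character(sequences(extractRegion(aln, 3, 6)))
#' @export
setMethod("extractRegion", "MarkerSet", function(x, start, end) {
  if (!x@aligned)
    stop("extractRegion requires an aligned collection", call. = FALSE)
  len <- if (length(x@seqs)) Biostrings::width(x@seqs)[1L] else 0L
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start || end > len)
    stop(sprintf("region %d-%d out of range for alignment of %d columns",
                 start, end, len), call. = FALSE)
  new("MarkerSet",
      seqs = Biostrings::DNAStringSet(x@seqs, start = start, end = end),
      desc = x@desc, taxon = x@taxon, aligned = TRUE)
})

#' Write a tab-separated report
#'
#' Writes rows with a header line, UTF-8, in the given row order. Numeric
#' columns can be rendered at a fixed number of decimals.
#'
#' @param rows A \code{data.frame} (zero rows allowed; the header is still
#'   written).
#' @param path Output path.
#' @param digits Optional integer; if given, every numeric (non-integer)
#'   column is formatted with that many decimals.
#' @return Invisibly, \code{path}.
#' @export
writeTsvReport <- function(rows, path, digits = NULL) {
  stopifnot(is.data.frame(rows))
  out <- rows
  if (!is.null(digits)) {
    for (j in seq_along(out))
      if (is.double(out[[j]]))
        out[[j]] <- formatC(out[[j]], format = "f", digits = digits)
  }
  utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-separated report written by \code{writeTsvReport}
#' @param path Path to the TSV file.
#' @return A \code{data.frame}.
#' @export
readTsvReport <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read an accession manifest
#'
#' A manifest is a TSV file with header
#' \code{accession<TAB>species<TAB>path} listing genome accessions, their
#' species assignment and an optional local file path (the \code{path}
#' column may be absent or empty). It stands in for supplementary accession
#' tables; no downloading is performed.
#'
#' @param path Path to the manifest TSV.
#' @return A \code{data.frame} with columns \code{accession},
#'   \code{species}, \code{path}.
#' @export
readAccessionManifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("manifest not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("accession", "species") %in% names(df)))
    stop("manifest must have columns 'accession' and 'species'", call. = FALSE)
  if (!"path" %in% names(df)) df$path <- NA_character_
  if (any(!nzchar(df$accession)) || anyNA(df$accession))
    stop("manifest accessions must be non-empty", call. = FALSE)
  if (anyDuplicated(df$accession))
    stop(sprintf("duplicated accession(s): %s",
                 paste(unique(df$accession[duplicated(df$accession)]),
                       collapse = ", ")), call. = FALSE)
  df[, c("accession", "species", "path")]
}
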