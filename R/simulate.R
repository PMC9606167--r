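#' @include pcr.R resolution.R
NULL

.ACGT <- c("A", "C", "G", "T")

## Substitute each allowed position independently with probability `rate`,
## drawing the replacement uniformly from the 3 alternative bases.
## Returns list(chars, positions) with the mutated positions.
.mutateChars <- function(chars, allowed, rate) {
  if (rate <= 0 || !length(allowed))
    return(list(chars = chars, positions = integer()))
  sel <- allowed[stats::runif(length(allowed)) < rate]
  if (length(sel)) {
    cur <- match(chars[sel], .ACGT)
    offset <- sample.int(3L, length(sel), replace = TRUE)
    chars[sel] <- .ACGT[((cur - 1L + offset) %% 4L) + 1L]
  }
  list(chars = chars, positions = sort(sel))
}

## Scramble a planted forward-primer site below the match threshold by
## substituting, at positions where the primer's IUPAC set is not N, a base
## outside the set. Each substitution reduces the best-over-expansions
## match count by exactly one.
.breakSite <- function(chars, siteStart, primerSeq, minMatch) {
  pc <- strsplit(primerSeq, "", fixed = TRUE)[[1L]]
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP[pc], "", fixed = TRUE)
  breakable <- which(lengths(sets) < 4L)
  need <- length(pc) - minMatch + 2L  # one below threshold, plus margin
  if (length(breakable) < need)
    stop("primer too degenerate to construct an incompatible site",
         call. = FALSE)
  for (j in breakable[seq_len(need)]) {
    pos <- siteStart + j - 1L
    chars[pos] <- setdiff(.ACGT, sets[[j]])[1L]
  }
  chars
}

#' Describe a synthetic marker template
#'
#' Helper building one entry of the \code{markers} list of
#' \code{\link{communitySpec}}: the marker's template length, the primer
#' pair whose binding sites are embedded, the site layout and the
#' per-species compatibility flags.
#'
#' @param pair A \code{\linkS4class{PrimerPair}}; one exact expansion of
#'   each primer is embedded in the genus ancestor.
#' @param length Template length in bp.
#' @param fwdStart 1-based start of the forward-primer site.
#' @param insertLength Length of the insert between the primer sites; the
#'   expected amplicon length is \code{insertLength} plus both primer
#'   lengths.
#' @param compatible Logical vector of per-species primer compatibility
#'   (recycled to the number of species); incompatible species have their
#'   forward site scrambled below the match threshold.
#' @param copies Number of copies of this marker per genome (multi-copy
#'   rRNA-like loci); copies beyond the first receive extra substitutions
#'   at rate \code{copySnpRate} and ids suffixed \code{|copyN}.
#' @param copySnpRate Per-site substitution probability between intra-genome
#'   copies.
#' @return A named list consumed by \code{\link{communitySpec}}.
#' @export
markerTemplate <- function(pair, length = 1200L, fwdStart = 101L,
                           insertLength = 460L, compatible = TRUE,
                           copies = 1L, copySnpRate = 0) {
  list(pair = pair, length = as.integer(length),
       fwdStart = as.integer(fwdStart),
       insertLength = as.integer(insertLength),
       compatible = compatible, copies = as.integer(copies),
       copySnpRate = copySnpRate)
}

#' Construct and validate a synthetic community specification
#'
#' @param nSpecies Number of species in the genus.
#' @param strainsPerSpecies Strains generated per species.
#' @param markers Named list of \code{\link{markerTemplate}} descriptions.
#' @param interDivergence Per-site substitution probability between the
#'   genus ancestor and each species ancestor.
#' @param intraRate Per-site substitution probability between a species
#'   ancestor and each of its strains.
#' @param seed Integer seed; identical specs generate byte-identical data.
#' @return A \code{\linkS4class{CommunitySpec}}.
#' @examples
#' spec <- communitySpec(3, 4,
#'   markers = list(gyrA = markerTemplate(bacillusPrimers()$gyrA3)),
#'   interDivergence = 0.2, intraRate = 0.01, seed = 1)
#' @export
communitySpec <- function(nSpecies, strainsPerSpecies, markers,
                          interDivergence = 0.2, intraRate = 0.01,
                          seed = 1L) {
  for (m in names(markers)) {
    mk <- markers[[m]]
    fl <- nchar(mk$pair@forward@seq)
    rl <- nchar(mk$pair@reverse@seq)
    revEnd <- mk$fwdStart + fl + mk$insertLength + rl - 1L
    if (revEnd > mk$length)
      stop(sprintf("marker '%s': primer sites (ending %d) exceed length %d",
                   m, revEnd, mk$length), call. = FALSE)
    markers[[m]]$compatible <- rep_len(mk$compatible, nSpecies)
  }
  new("CommunitySpec", nSpecies = as.integer(nSpecies),
      strainsPerSpecies = as.integer(strainsPerSpecies),
      markers = markers, interDivergence = interDivergence,
      intraRate = intraRate, seed = as.integer(seed))
}

setMethod("show", "CommunitySpec", function(object) {
  cat(sprintf(
    "CommunitySpec: %d species x %d strains; markers %s; inter %.3g, intra %.3g, seed %d\n",
    object@nSpecies, object@strainsPerSpecies,
    paste(names(object@markers), collapse = ", "),
    object@interDivergence, object@intraRate, object@seed))
})

#' Generate a synthetic community with known truth
#'
#' Builds, per marker, a genus ancestor sequence with one exact expansion
#' of the template's primer pair embedded at the configured sites, then a
#' star phylogeny: species ancestors are independent per-site mutants of
#' the genus ancestor (probability \code{interDivergence}), strains are
#' independent per-site mutants of their species ancestor
#' (\code{intraRate}), and intra-genome marker copies are mutants of the
#' first copy (\code{copySnpRate}). Mutations are never planted inside
#' primer sites, so compatibility flags fully determine amplifiability;
#' species flagged incompatible have their forward site scrambled below
#' the pair's match threshold. All sequences are gap-free and equal-length
#' per marker, so collections are directly usable as alignments.
#'
#' @param spec A \code{\linkS4class{CommunitySpec}}.
#' @return A list with elements \code{markers} (named list of aligned
#'   \code{\linkS4class{MarkerSet}} collections, one record per genome
#'   copy, taxon labels set to the species), \code{community} (a
#'   \code{\linkS4class{MockCommunity}} over the first copy of each
#'   strain), \code{truth} (a \code{data.frame} with one row per emitted
#'   record: id, marker, species, strain, copy, compatible, planted
#'   mutation positions, expected amplicon coordinates) and \code{spec}.
#' @examples
#' spec <- communitySpec(2, 3,
#'   markers = list(gyrA = markerTemplate(bacillusPrimers()$gyrA3)),
#'   interDivergence = 0.1, intraRate = 0.01, seed = 7)
#' sim <- generateCommunity(spec)
#' sim$markers$gyrA
#' @export
generateCommunity <- function(spec) {
  stopifnot(is(spec, "CommunitySpec"))
  set.seed(spec@seed)
  markers <- list()
  truthRows <- list()
  communitySeqs <- list()
  for (m in names(spec@markers)) {
    mk <- spec@markers[[m]]
    pair <- mk$pair
    fl <- nchar(pair@forward@seq); rl <- nchar(pair@reverse@seq)
    fwdStart <- mk$fwdStart
    fwdEnd <- fwdStart + fl - 1L
    revStart <- fwdEnd + mk$insertLength + 1L
    revEnd <- revStart + rl - 1L
    L <- mk$length
    ancestor <- sample(.ACGT, L, replace = TRUE)
    fwdVar <- expandDegenerate(pair@forward)[1L]
    revVar <- expandDegenerate(pair@reverse)[1L]
    ancestor[fwdStart:fwdEnd] <- strsplit(fwdVar, "", fixed = TRUE)[[1L]]
    ancestor[revStart:revEnd] <-
      strsplit(reverseComplementSeq(revVar), "", fixed = TRUE)[[1L]]
    siteCols <- c(fwdStart:fwdEnd, revStart:revEnd)
    freeCols <- setdiff(seq_len(L), siteCols)
    seqs <- character(); taxa <- character()
    for (sp in seq_len(spec@nSpecies)) {
      spLabel <- sprintf("Species%02d", sp)
      spAnc <- .mutateChars(ancestor, freeCols, spec@interDivergence)$chars
      compatible <- mk$compatible[sp]
      if (!compatible)
        spAnc <- .breakSite(spAnc, fwdStart, pair@forward@seq, pair@minMatch)
      for (st in seq_len(spec@strainsPerSpecies)) {
        strainId <- sprintf("sp%02d_st%02d", sp, st)
        mut <- .mutateChars(spAnc, freeCols, spec@intraRate)
        strainChars <- mut$chars
        for (cp in seq_len(mk$copies)) {
          if (cp == 1L) {
            id <- strainId
            copyChars <- strainChars
            copyPos <- mut$positions
          } else {
            id <- sprintf("%s|copy%d", strainId, cp)
            cmut <- .mutateChars(strainChars, freeCols, mk$copySnpRate)
            copyChars <- cmut$chars
            copyPos <- sort(union(mut$positions, cmut$positions))
          }
          seqs[id] <- paste(copyChars, collapse = "")
          taxa[id] <- spLabel
          truthRows[[length(truthRows) + 1L]] <- data.frame(
            id = id, marker = m, species = spLabel, strain = strainId,
            copy = cp, compatible = compatible,
            planted_positions = paste(copyPos, collapse = ","),
            amp_start = if (compatible) fwdStart else NA_integer_,
            amp_end = if (compatible) revEnd else NA_integer_,
            stringsAsFactors = FALSE)
          if (cp == 1L) communitySeqs[[m]][strainId] <- seqs[id]
        }
      }
    }
    markers[[m]] <- MarkerSet(Biostrings::DNAStringSet(seqs),
                              taxon = unname(taxa), aligned = TRUE)
  }
  truth <- do.call(rbind, truthRows)
  rownames(truth) <- NULL
  community <- mockCommunity(communitySeqs)
  list(markers = markers, community = community, truth = truth, spec = spec)
}

#' Simulate amplicon reads from a mock community
#'
#' For each strain, runs \code{\link{inSilicoPCR}} on the marker sequence
#' and, when a product exists, emits \code{depthPerStrain} full-length
#' copies of the leftmost amplicon with independent per-base substitution
#' errors at \code{errorRate} (uniform over the 3 alternative bases). The
#' truth mapping records the source strain of every read. Strains without
#' a product are recorded with zero reads.
#'
#' @param community A \code{\linkS4class{MockCommunity}}.
#' @param marker Marker gene name.
#' @param pair A \code{\linkS4class{PrimerPair}}.
#' @param depthPerStrain Reads per amplifiable strain.
#' @param errorRate Per-base substitution probability in \code{[0, 0.05]}.
#' @param seed Integer seed.
#' @return A list with \code{reads} (a \code{\linkS4class{MarkerSet}} of
#'   reads), \code{truth} (\code{data.frame(read_id, strain)}) and
#'   \code{amplicons} (named character vector of the error-free amplicon
#'   per amplified strain).
#' @export
generateReads <- function(community, marker, pair, depthPerStrain = 100L,
                          errorRate = 0, seed = 1L) {
  stopifnot(errorRate >= 0, errorRate <= 0.05)
  set.seed(as.integer(seed))
  strains <- communityStrains(community)
  seqs <- markerSequences(community, marker)
  reads <- character(); src <- character(); amps <- character()
  for (s in strains) {
    amp <- inSilicoPCR(pair, as.character(seqs[[s]]), id = s)
    if (!nrow(amp)) next
    ampSeq <- toupper(amp$seq[1L])
    amps[s] <- ampSeq
    if (depthPerStrain < 1L) next
    chars <- strsplit(ampSeq, "", fixed = TRUE)[[1L]]
    for (r in seq_len(depthPerStrain)) {
      rc <- .mutateChars(chars, seq_along(chars), errorRate)$chars
      id <- sprintf("%s_r%04d", s, r)
      reads[id] <- paste(rc, collapse = "")
      src[id] <- s
    }
  }
  readSet <- if (length(reads))
    MarkerSet(Biostrings::DNAStringSet(reads), aligned = FALSE)
  else
    MarkerSet(Biostrings::DNAStringSet(character()), aligned = FALSE)
  list(reads = readSet,
       truth = data.frame(read_id = names(src),
                          strain = unname(src),
                          stringsAsFactors = FALSE),
       amplicons = amps)
}

#' A synthetic eight-strain mock community
#'
#' Constructs a fully synthetic stand-in for a defined eight-strain
#' \emph{Bacillus}-like mock community carrying a 16S rRNA-like gene with
#' 338F/806R (V3-V4) binding sites and a gyrA-like gene with gyrA3 binding
#' sites. The strains are built so that the V3-V4 amplicon collapses three
#' strain pairs (LY1/LY18, LY37/LY43, LY39/LY48) into shared units — five
#' distinguishable units in total — while the gyrA3 amplicon resolves six
#' units (only LY1/LY18 and LY39/LY48 remain identical). Outside the
#' amplified regions every strain is distinct. This mirrors the typical
#' outcome that a faster-evolving protein-coding marker separates strains
#' an rRNA amplicon cannot; the sequences themselves are synthetic, not
#' the strains' true genes.
#'
#' @param seed Integer seed for the backbone and planted variation.
#' @return A \code{\linkS4class{MockCommunity}} with markers \code{"16S"}
#'   and \code{"gyrA"} over strains LY1, LY2, LY18, LY35, LY37, LY39,
#'   LY43, LY48.
#' @examples
#' mc <- syntheticMockCommunity()
#' communityStrains(mc)
#' @export
syntheticMockCommunity <- function(seed = 1L) {
  set.seed(as.integer(seed))
  strains <- c("LY1", "LY2", "LY18", "LY35", "LY37", "LY39", "LY43", "LY48")
  primers <- bacillusPrimers()
  ## group labels: strains sharing a group share the amplicon insert
  groups16S <- c(LY1 = 1, LY18 = 1, LY37 = 2, LY43 = 2, LY39 = 3, LY48 = 3,
                 LY2 = 4, LY35 = 5)
  groupsGyrA <- c(LY1 = 1, LY18 = 1, LY39 = 2, LY48 = 2,
                  LY2 = 3, LY35 = 4, LY37 = 5, LY43 = 6)
  buildMarker <- function(pair, L, fwdStart, insertLength, groups,
                          snpsPerGroup = 8L) {
    fl <- nchar(pair@forward@seq); rl <- nchar(pair@reverse@seq)
    fwdEnd <- fwdStart + fl - 1L
    revStart <- fwdEnd + insertLength + 1L
    revEnd <- revStart + rl - 1L
    stopifnot(revEnd <= L)
    backbone <- sample(.ACGT, L, replace = TRUE)
    backbone[fwdStart:fwdEnd] <-
      strsplit(expandDegenerate(pair@forward)[1L], "", fixed = TRUE)[[1L]]
    backbone[revStart:revEnd] <- strsplit(
      reverseComplementSeq(expandDegenerate(pair@reverse)[1L]),
      "", fixed = TRUE)[[1L]]
    insertCols <- (fwdEnd + 1L):(revStart - 1L)
    outsideCols <- setdiff(seq_len(L), fwdStart:revEnd)
    ## distinct SNP set per group inside the insert
    ngroups <- length(unique(groups))
    groupCols <- matrix(sample(insertCols, ngroups * snpsPerGroup),
                        nrow = ngroups)
    seqs <- character()
    for (s in names(groups)) {
      chars <- backbone
      for (pos in groupCols[groups[[s]], ]) {
        cur <- match(chars[pos], .ACGT)
        chars[pos] <- .ACGT[(cur %% 4L) + 1L]  # deterministic per position
      }
      ## strain-private variation outside the amplicon
      private <- sample(outsideCols, 6L)
      pc <- match(chars[private], .ACGT)
      chars[private] <- .ACGT[((pc - 1L + sample.int(3L, 6L, TRUE)) %% 4L) + 1L]
      seqs[s] <- paste(chars, collapse = "")
    }
    seqs
  }
  markers <- list(
    `16S` = buildMarker(primers$v3v4, L = 1540L, fwdStart = 330L,
                        insertLength = 420L, groups = groups16S),
    gyrA = buildMarker(primers$gyrA3, L = 2450L, fwdStart = 350L,
                       insertLength = 460L, groups = groupsGyrA)
  )
  mockCommunity(markers, strains = strains)
}

#' Write a generated community to disk
#'
#' Emits one FASTA per marker plus the truth table as TSV and a JSON copy,
#' the on-disk layout consumed by the command-line interface.
#'
#' @param sim Result of \code{\link{generateCommunity}}.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
writeCommunity <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (m in names(sim$markers)) {
    p <- file.path(outdir, paste0(m, ".fasta"))
    writeFasta(sim$markers[[m]], p)
    paths <- c(paths, p)
  }
  tsv <- file.path(outdir, "truth.tsv")
  writeTsvReport(sim$truth, tsv)
  js <- file.path(outdir, "truth.json")
  jsonlite::write_json(sim$truth, js, dataframe = "rows")
  invisible(c(paths, tsv, js))
}
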