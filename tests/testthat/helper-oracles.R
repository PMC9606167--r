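# Independent brute-force oracles, deliberately naive and separate from the
# package implementation paths they check.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# Recursive enumeration of all non-degenerate expansions.
oracleExpand <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  out <- ""
  for (ch in chars) {
    alts <- ORACLE_IUPAC[[ch]]
    out <- as.vector(vapply(out, function(pfx) paste0(pfx, alts),
                            character(length(alts))))
  }
  sort(unique(out))
}

# Naive identical-base count: target ambiguity codes never match.
oracleMatchCount <- function(variant, window) {
  v <- strsplit(variant, "", fixed = TRUE)[[1L]]
  w <- strsplit(window, "", fixed = TRUE)[[1L]]
  sum(v == w & w %in% c("A", "C", "G", "T"))
}

# Binding sites by looping every window against every expansion.
oracleBindingSites <- function(primerSeq, target, minMatch) {
  variants <- oracleExpand(primerSeq)
  k <- nchar(primerSeq)
  L <- nchar(target)
  hits <- integer(); best <- integer()
  if (L >= k) for (i in seq_len(L - k + 1L)) {
    win <- substr(target, i, i + k - 1L)
    m <- max(vapply(variants, oracleMatchCount, integer(1L), window = win))
    if (m >= minMatch) { hits <- c(hits, i); best <- c(best, m) }
  }
  data.frame(start = hits, matched = best)
}

# Double-loop nucleotide diversity: mean over pairs of diff/valid.
oraclePi <- function(seqs) {
  n <- length(seqs)
  ratios <- numeric()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- strsplit(toupper(seqs[[i]]), "", fixed = TRUE)[[1L]]
    b <- strsplit(toupper(seqs[[j]]), "", fixed = TRUE)[[1L]]
    d <- 0L; v <- 0L
    for (s in seq_along(a)) {
      if (a[s] %in% c("A", "C", "G", "T") && b[s] %in% c("A", "C", "G", "T")) {
        v <- v + 1L
        if (a[s] != b[s]) d <- d + 1L
      }
    }
    if (v > 0L) ratios <- c(ratios, d / v)
  }
  if (length(ratios)) mean(ratios) else NaN
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# Random gapped/ambiguous alignment for property tests.
randomAlignment <- function(nSeq, nCol, pGap = 0.05, pAmbig = 0.02) {
  vapply(seq_len(nSeq), function(i) {
    chars <- sample(c("A", "C", "G", "T"), nCol, TRUE)
    r <- runif(nCol)
    chars[r < pGap] <- "-"
    chars[r >= pGap & r < pGap + pAmbig] <-
      sample(c("N", "R", "Y", "W"), sum(r >= pGap & r < pGap + pAmbig), TRUE)
    paste(chars, collapse = "")
  }, character(1L))
}

writeTempFasta <- function(records, wrap = FALSE) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  lines <- character()
  for (id in names(records)) {
    lines <- c(lines, paste0(">", id))
    s <- records[[id]]
    if (wrap) {
      starts <- seq(1, nchar(s), by = 17)
      lines <- c(lines, substring(s, starts, pmin(starts + 16, nchar(s))))
    } else lines <- c(lines, s)
  }
  writeLines(lines, path)
  path
}
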