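PRIMER20 <- "ATCGGATCTTGCAAGTCCAG"  # non-palindromic 20-mer probe

mutateAt <- function(seq, pos) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in pos)
    chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1L]
  paste(chars, collapse = "")
}

test_that("an exact embedded site is found with a full match", {
  set.seed(21)
  target <- paste0(randomDna(40), PRIMER20, randomDna(40))
  # guard against chance extra sites in the random pad
  sites <- findBindingSites(PRIMER20, target, minMatch = 18)
  plus <- sites[sites$strand == "+" & sites$start == 41, ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$matched, 20L)
  expect_equal(plus$end, 60L)
  expect_equal(plus$variant, PRIMER20)
})

test_that("the 18-base rule tolerates 2 substitutions but not 3", {
  set.seed(22)
  pad <- randomDna(30)
  for (nmut in 0:3) {
    site <- mutateAt(PRIMER20, seq_len(nmut))
    target <- paste0(pad, site, pad)
    sites <- findBindingSites(PRIMER20, target, minMatch = 18)
    hit <- sites[sites$strand == "+" & sites$start == 31, ]
    if (nmut <= 2) {
      expect_equal(hit$matched, 20L - nmut)
    } else {
      expect_equal(nrow(hit), 0L)
    }
  }
})

test_that("degenerate primers bind via the achieving expansion", {
  sites <- findBindingSites("AY", "GGAT", minMatch = 2)
  plus <- sites[sites$strand == "+", ]
  expect_equal(plus$start, 3L)
  expect_equal(plus$end, 4L)
  expect_equal(plus$variant, "AT")
})

test_that("targets shorter than the primer yield no sites", {
  expect_equal(nrow(findBindingSites(PRIMER20, "ACGT", minMatch = 18)), 0L)
})

test_that("ambiguity codes in the target count as mismatches", {
  target <- paste0(strrep("G", 20), sub("^..", "NN", PRIMER20),
                   strrep("G", 20))
  sites <- findBindingSites(PRIMER20, target, minMatch = 19)
  expect_equal(nrow(sites[sites$start == 21, ]), 0L)
  sites18 <- findBindingSites(PRIMER20, target, minMatch = 18)
  expect_equal(sites18[sites18$start == 21, "matched"], 18L)
})

test_that("window scanning agrees with the brute-force expansion oracle", {
  set.seed(23)
  for (primer in c("ACGTAYSW", "GCDGCHGCNATGCGTTAYAC")) {
    for (rep in 1:20) {
      target <- randomDna(80)
      minMatch <- nchar(primer) - 2L
      got <- findBindingSites(primer, target, minMatch = minMatch)
      got <- got[got$strand == "+", c("start", "matched")]
      rownames(got) <- NULL
      want <- oracleBindingSites(primer, target, minMatch)
      expect_equal(got$start, want$start)
      expect_equal(got$matched, want$matched)
    }
  }
})

test_that("exact degenerate hits agree with Biostrings matchPattern", {
  set.seed(24)
  primer <- "GCDGCHGCNATGCGTTAYAC"
  variant <- expandDegenerate(primer)[37]
  target <- paste0(randomDna(60), variant, randomDna(60))
  got <- findBindingSites(primer, target, minMatch = 20)
  got <- got[got$strand == "+", ]
  ref <- Biostrings::matchPattern(Biostrings::DNAString(primer),
                                  Biostrings::DNAString(target),
                                  max.mismatch = 0, fixed = "subject")
  expect_equal(got$start, BiocGenerics::start(ref))
  expect_equal(got$end, BiocGenerics::end(ref))
})

test_that("a constructed template yields exactly one spanning amplicon", {
  set.seed(25)
  pair <- bacillusPrimers()$gyrA3
  fv <- expandDegenerate(pair@forward)[5]
  rv <- expandDegenerate(pair@reverse)[3]
  target <- paste0(randomDna(100), fv, randomDna(460),
                   reverseComplementSeq(rv), randomDna(100))
  amp <- inSilicoPCR(pair, target)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$start, 101L)
  expect_equal(amp$end, 600L)
  expect_equal(amp$length, 500L)
  expect_equal(amp$seq, substr(target, 101, 600))
  expect_equal(amp$insert, substr(target, 121, 580))
})

test_that("a forward site alone does not amplify", {
  set.seed(26)
  pair <- bacillusPrimers()$gyrA3
  fv <- expandDegenerate(pair@forward)[1]
  target <- paste0(randomDna(50), fv, randomDna(400))
  expect_equal(nrow(inSilicoPCR(pair, target)), 0L)
})

test_that("two forward sites upstream of one reverse site give two amplicons", {
  set.seed(27)
  pair <- primerPair("toy", PRIMER20, "TTGCAGCATCCGGCATCGCA",
                     minAmpliconLen = 50, maxAmpliconLen = 2000)
  rcR <- reverseComplementSeq(pair@reverse@seq)
  target <- paste0(randomDna(30), PRIMER20, randomDna(100), PRIMER20,
                   randomDna(100), rcR, randomDna(30))
  amp <- inSilicoPCR(pair, target)
  plus <- amp[amp$strand == "+", ]
  expect_equal(nrow(plus), 2L)
  expect_equal(sort(plus$start), c(31L, 151L))
  expect_equal(unique(plus$end), 30L + 20L + 100L + 20L + 100L + 20L)
})

test_that("amplicon length bounds are enforced", {
  set.seed(28)
  pair <- primerPair("toy", PRIMER20, "TTGCAGCATCCGGCATCGCA",
                     minAmpliconLen = 300, maxAmpliconLen = 400)
  rcR <- reverseComplementSeq(pair@reverse@seq)
  target <- paste0(randomDna(20), PRIMER20, randomDna(100), rcR,
                   randomDna(20))  # product 140 < 300
  expect_equal(nrow(inSilicoPCR(pair, target)), 0L)
  relaxed <- primerPair("toy", PRIMER20, "TTGCAGCATCCGGCATCGCA",
                        minAmpliconLen = 100, maxAmpliconLen = 400)
  expect_equal(nrow(inSilicoPCR(relaxed, target)), 1L)
})

test_that("in-silico PCR is reverse-complement symmetric", {
  set.seed(29)
  pair <- bacillusPrimers()$gyrA3
  fv <- expandDegenerate(pair@forward)[2]
  rv <- expandDegenerate(pair@reverse)[2]
  for (rep in 1:25) {
    target <- paste0(randomDna(sample(20:80, 1)), fv,
                     randomDna(sample(380:460, 1)),
                     reverseComplementSeq(rv), randomDna(sample(20:80, 1)))
    fwd <- inSilicoPCR(pair, target)
    rcv <- inSilicoPCR(pair, reverseComplementSeq(target))
    expect_equal(nrow(fwd), nrow(rcv))
    if (nrow(fwd)) {
      expect_setequal(vapply(rcv$seq, reverseComplementSeq, character(1)),
                      fwd$seq)
      L <- nchar(target)
      expect_setequal(L - rcv$end + 1L, fwd$start)
      expect_setequal(L - rcv$start + 1L, fwd$end)
    }
  }
})

test_that("lowering minMatch never removes a site; raising maxAmpliconLen never removes an amplicon", {
  set.seed(30)
  pair <- bacillusPrimers()$gyrA3
  fv <- expandDegenerate(pair@forward)[1]
  rv <- expandDegenerate(pair@reverse)[1]
  target <- paste0(randomDna(50), mutateAt(fv, c(3, 9)), randomDna(420),
                   reverseComplementSeq(rv), randomDna(50))
  for (mm in c(20, 19, 18, 16, 14)) {
    hi <- findBindingSites(pair@forward, target, minMatch = mm)
    lo <- findBindingSites(pair@forward, target, minMatch = mm - 1L)
    key <- function(df) paste(df$strand, df$start)
    expect_true(all(key(hi) %in% key(lo)))
  }
  narrow <- primerPair("gyrA3", pair@forward, pair@reverse,
                       maxAmpliconLen = 500L)
  wide <- primerPair("gyrA3", pair@forward, pair@reverse,
                     maxAmpliconLen = 3000L)
  a1 <- inSilicoPCR(narrow, target)
  a2 <- inSilicoPCR(wide, target)
  expect_true(all(paste(a1$start, a1$end) %in% paste(a2$start, a2$end)))
})

test_that("contiguous and 3'-anchored site rules are stricter filters", {
  # 2 substitutions in the middle: 18 matches total but the longest run is
  # only 11, and the 3' end is intact
  midMut <- mutateAt(PRIMER20, c(6, 9))
  target <- paste0(strrep("G", 25), midMut, strrep("G", 25))
  default <- findBindingSites(PRIMER20, target, minMatch = 18)
  expect_equal(default[default$strand == "+", "matched"], 18L)
  contig <- findBindingSites(PRIMER20, target, minMatch = 18,
                             contiguous = TRUE)
  expect_equal(nrow(contig[contig$strand == "+", ]), 0L)
  anchored <- findBindingSites(PRIMER20, target, minMatch = 18, anchor3 = 3)
  expect_equal(nrow(anchored[anchored$strand == "+", ]), 1L)
  # substitutions at the 3' terminus fail the anchored rule but not the
  # default count rule
  endMut <- mutateAt(PRIMER20, c(19, 20))
  target2 <- paste0(strrep("G", 25), endMut, strrep("G", 25))
  default2 <- findBindingSites(PRIMER20, target2, minMatch = 18)
  expect_equal(default2[default2$strand == "+", "matched"], 18L)
  anchored2 <- findBindingSites(PRIMER20, target2, minMatch = 18,
                                anchor3 = 3)
  expect_equal(nrow(anchored2[anchored2$strand == "+", ]), 0L)
  # a contiguous 18-run passes the contiguous rule
  target3 <- paste0(strrep("G", 25), mutateAt(PRIMER20, 1:2),
                    strrep("G", 25))
  contig3 <- findBindingSites(PRIMER20, target3, minMatch = 18,
                              contiguous = TRUE)
  expect_equal(nrow(contig3[contig3$strand == "+", ]), 1L)
})

test_that("identical inputs give byte-identical scan reports", {
  set.seed(31)
  target <- paste0(randomDna(80), PRIMER20, randomDna(80))
  a <- findBindingSites(PRIMER20, target, minMatch = 16)
  b <- findBindingSites(PRIMER20, target, minMatch = 16)
  expect_identical(a, b)
})

test_that("amplifiability summary counts species with >= 1 amplifiable sequence", {
  set.seed(32)
  pair <- bacillusPrimers()$gyrA3
  fv <- expandDegenerate(pair@forward)[1]
  rv <- expandDegenerate(pair@reverse)[1]
  good <- function() paste0(randomDna(30), fv, randomDna(420),
                            reverseComplementSeq(rv), randomDna(30))
  bad <- function() randomDna(520)
  seqs <- c(s1a = good(), s1b = good(), s2a = good(), s3a = bad())
  db <- MarkerSet(seqs, taxon = c("sp1", "sp1", "sp2", "sp3"),
                  aligned = FALSE)
  res <- amplifiabilitySummary(db, pair)
  expect_equal(res$n_species_matched, 2L)
  expect_equal(res$n_sequences_matched, 3L)
  expect_equal(res$species$n_amplifiable[res$species$species == "sp3"], 0L)
  expect_equal(sum(res$species$n_amplifiable), res$n_sequences_matched)
})

test_that("a database with no amplifiable sequence reports zero totals", {
  set.seed(33)
  db <- MarkerSet(c(a = randomDna(300), b = randomDna(300)),
                  taxon = c("sp1", "sp2"), aligned = FALSE)
  res <- amplifiabilitySummary(db, bacillusPrimers()$gyrA3)
  expect_equal(res$n_species_matched, 0L)
  expect_equal(res$n_sequences_matched, 0L)
})
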