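gyrA3 <- bacillusPrimers()$gyrA3

smallSpec <- function(seed = 1L, intra = 0.01, inter = 0.2, nSpecies = 3L,
                      strains = 4L, compatible = TRUE, copies = 1L,
                      copySnpRate = 0) {
  communitySpec(nSpecies, strains,
    markers = list(gyrA = markerTemplate(gyrA3, length = 1200L,
                                         fwdStart = 101L,
                                         insertLength = 460L,
                                         compatible = compatible,
                                         copies = copies,
                                         copySnpRate = copySnpRate)),
    interDivergence = inter, intraRate = intra, seed = seed)
}

test_that("identical seeds generate byte-identical communities", {
  s1 <- generateCommunity(smallSpec(seed = 9))
  s2 <- generateCommunity(smallSpec(seed = 9))
  expect_identical(as.character(sequences(s1$markers$gyrA)),
                   as.character(sequences(s2$markers$gyrA)))
  expect_identical(s1$truth, s2$truth)
  s3 <- generateCommunity(smallSpec(seed = 10))
  expect_false(identical(as.character(sequences(s1$markers$gyrA)),
                         as.character(sequences(s3$markers$gyrA))))
})

test_that("zero intraspecies rate makes conspecific strains identical with zero pi", {
  sim <- generateCommunity(smallSpec(intra = 0, seed = 12))
  ms <- sim$markers$gyrA
  for (sp in unique(taxonLabels(ms))) {
    sub <- as.character(sequences(ms[taxonLabels(ms) == sp]))
    expect_equal(length(unique(sub)), 1L)
    expect_equal(nucleotideDiversity(sub), 0)
  }
})

test_that("planted truth positions match the emitted sequences", {
  sim <- generateCommunity(smallSpec(seed = 13, intra = 0.02))
  ms <- sim$markers$gyrA
  truth <- sim$truth
  seqs <- as.character(sequences(ms))
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    if (row$copy != 1L) next
    spAnc <- NULL  # reconstruct: strain differs from species consensus only
    pos <- if (nzchar(row$planted_positions))
      as.integer(strsplit(row$planted_positions, ",")[[1]]) else integer()
    # mutations never land inside the primer sites
    expect_false(any(pos %in% c(101:120, 581:600)))
  }
})

test_that("compatible strains amplify at the planted coordinates; incompatible never do", {
  sim <- generateCommunity(smallSpec(seed = 14,
                                     compatible = c(TRUE, FALSE, TRUE)))
  ms <- sim$markers$gyrA
  truth <- sim$truth
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    amp <- inSilicoPCR(gyrA3, as.character(sequences(ms))[[row$id]],
                       id = row$id)
    if (row$compatible) {
      expect_gte(nrow(amp), 1L)
      expect_equal(amp$start[1], row$amp_start)
      expect_equal(amp$end[1], row$amp_end)
    } else {
      expect_equal(nrow(amp), 0L)
    }
  }
})

test_that("species-level amplifiability counts follow the construction", {
  compat <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  sim <- generateCommunity(smallSpec(seed = 15, nSpecies = 10L, strains = 2L,
                                     compatible = compat))
  res <- amplifiabilitySummary(sim$markers$gyrA, gyrA3)
  expect_equal(res$n_species_matched, sum(compat))
  expect_equal(res$n_sequences_matched, sum(compat) * 2L)
})

test_that("multi-copy loci get copy-suffixed ids and planted copy SNPs", {
  sim <- generateCommunity(smallSpec(seed = 16, copies = 3L,
                                     copySnpRate = 0.01, nSpecies = 2L,
                                     strains = 2L))
  ms <- sim$markers$gyrA
  expect_equal(length(ms), 2L * 2L * 3L)
  expect_true(all(c("sp01_st01", "sp01_st01|copy2", "sp01_st01|copy3")
                  %in% seqIds(ms)))
  # community holds one sequence per strain (first copy)
  expect_equal(length(communityStrains(sim$community)), 4L)
})

test_that("mean pi over star-topology replicates matches the analytic value", {
  set.seed(17)
  m <- 0.02
  pis <- vapply(1:60, function(r) {
    sim <- generateCommunity(smallSpec(seed = 1000L + r, intra = m,
                                       nSpecies = 1L, strains = 10L))
    # restrict to the mutable region between the invariant primer sites
    nucleotideDiversity(extractRegion(sim$markers$gyrA, 121L, 580L))
  }, numeric(1))
  expected <- 2 * m * (1 - m) + (2 / 3) * m^2
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - expected), 3 * se)
})

test_that("interspecies pi exceeds mean intraspecies pi on generated data", {
  sim <- generateCommunity(smallSpec(seed = 18, inter = 0.2, intra = 0.01))
  ms <- sim$markers$gyrA
  interPi <- nucleotideDiversity(ms)
  intraPis <- vapply(unique(taxonLabels(ms)), function(sp)
    nucleotideDiversity(ms[taxonLabels(ms) == sp]), numeric(1))
  expect_gt(interPi, mean(intraPis))
})

test_that("snp profiling recovers exactly the planted strain mutations", {
  sim <- generateCommunity(smallSpec(seed = 19, intra = 0.01, nSpecies = 1L,
                                     strains = 8L))
  ms <- sim$markers$gyrA
  truth <- sim$truth
  ref <- truth$id[1]
  prof <- variableSites(ms, ref)
  pg <- perGenomeMismatches(prof)
  refPos <- as.integer(strsplit(truth$planted_positions[1], ",")[[1]])
  for (i in 2:nrow(truth)) {
    pos <- if (nzchar(truth$planted_positions[i]))
      as.integer(strsplit(truth$planted_positions[i], ",")[[1]]) else integer()
    # mismatches vs the reference = symmetric difference of the two
    # planted sets, minus positions where both mutated to the same base
    a <- as.character(sequences(ms))[[truth$id[i]]]
    b <- as.character(sequences(ms))[[ref]]
    direct <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(pg$n_mismatches[pg$genome_id == truth$id[i]], direct)
    expect_true(all(which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
                    %in% union(pos, refPos)))
  }
})

test_that("error-free reads dereplicate to one unique per distinguishable unit", {
  sim <- generateCommunity(smallSpec(seed = 20, intra = 0))
  rd <- generateReads(sim$community, "gyrA", gyrA3, depthPerStrain = 20,
                      errorRate = 0, seed = 3)
  derep <- dereplicateReads(rd$reads)
  res <- resolveCommunity(sim$community, "gyrA", gyrA3, keepPrimers = TRUE)
  expect_equal(nrow(derep), nUnits(res))
  expect_equal(sum(derep$count), nrow(rd$truth))
})

test_that("read generation respects depth, seed and the error-rate bound", {
  sim <- generateCommunity(smallSpec(seed = 21, nSpecies = 2L, strains = 2L))
  r0 <- generateReads(sim$community, "gyrA", gyrA3, depthPerStrain = 0,
                      errorRate = 0, seed = 1)
  expect_equal(length(sequences(r0$reads)), 0L)
  r1 <- generateReads(sim$community, "gyrA", gyrA3, depthPerStrain = 10,
                      errorRate = 0.01, seed = 5)
  r2 <- generateReads(sim$community, "gyrA", gyrA3, depthPerStrain = 10,
                      errorRate = 0.01, seed = 5)
  expect_identical(as.character(sequences(r1$reads)),
                   as.character(sequences(r2$reads)))
  expect_equal(nrow(r1$truth), 4L * 10L)
  expect_error(generateReads(sim$community, "gyrA", gyrA3,
                             errorRate = 0.2, seed = 1))
})

test_that("noisy reads annotate back to their source strains", {
  sim <- generateCommunity(smallSpec(seed = 22, intra = 0.02, nSpecies = 2L,
                                     strains = 3L))
  rd <- generateReads(sim$community, "gyrA", gyrA3, depthPerStrain = 50,
                      errorRate = 0.01, seed = 7)
  derep <- dereplicateReads(rd$reads)
  ann <- annotateZotus(setNames(derep$seq, paste0("z", seq_len(nrow(derep)))),
                       rd$amplicons, minIdentity = 0.97)
  # map each unique read back through its exact copies to the true strain
  readSeqs <- as.character(sequences(rd$reads))
  correct <- 0L
  for (i in seq_len(nrow(derep))) {
    srcs <- unique(rd$truth$strain[match(names(readSeqs)[readSeqs == derep$seq[i]],
                                         rd$truth$read_id)])
    if (length(srcs) == 1L && ann$strain[i] == srcs) correct <- correct + 1L
  }
  expect_gte(correct / nrow(derep), 0.99)
})

test_that("the synthetic eight-strain community reproduces the designed collapse", {
  mc <- syntheticMockCommunity(seed = 1)
  primers <- bacillusPrimers()
  r16 <- resolveCommunity(mc, "16S", primers$v3v4)
  expect_equal(nUnits(r16), 5L)
  pairsOf <- function(res) Filter(function(u) length(u) == 2, unitMembers(res))
  collapsed <- lapply(pairsOf(r16), sort)
  expect_setequal(vapply(collapsed, paste, character(1), collapse = "+"),
                  c("LY1+LY18", "LY37+LY43", "LY39+LY48"))
  rg <- resolveCommunity(mc, "gyrA", primers$gyrA3)
  expect_equal(nUnits(rg), 6L)
  expect_equal(length(unamplifiedStrains(rg)), 0L)
})

test_that("writeCommunity emits FASTA and truth files that read back", {
  sim <- generateCommunity(smallSpec(seed = 23, nSpecies = 2L, strains = 2L))
  outdir <- withr::local_tempdir()
  writeCommunity(sim, outdir)
  fa <- readFasta(file.path(outdir, "gyrA.fasta"))
  expect_equal(seqIds(fa), seqIds(sim$markers$gyrA))
  truth <- readTsvReport(file.path(outdir, "truth.tsv"))
  expect_equal(nrow(truth), nrow(sim$truth))
})
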