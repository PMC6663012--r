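smallProteome <- function(n = 4, seed = 55) {
  ProteoRhythm:::withSeed(seed, ProteoRhythm:::randomProteome(n, c(60, 100)))
}

test_that("defect-free genome encodes every digested peptide in its annotated frame", {
  base <- smallProteome()
  g <- makeGenomeWithPlantedErrors(base, 0, 0, 0, 0, seed = 2)
  expect_equal(nrow(truthLabels(g)), 0)
  peps <- unique(unlist(lapply(as.character(base), digestTryptic,
                               lengthRange = c(6, 30))))
  cl <- classifyAgainstGenome(peps[1:10], g)
  expect_true(all(cl$genome_class == "annotated"))
  expect_true(all(cl$same_frame_as_transcript))
})

test_that("an overlap plant maps perfectly inside a transcript in a shifted frame", {
  base <- smallProteome()
  g <- makeGenomeWithPlantedErrors(base, nOverlap = 1, nUncalled = 0,
                                   nWobbly = 0, nGap = 0, seed = 3)
  tr <- truthLabels(g)
  expect_equal(tr$category, "TRANSCRIPT_FRAME_OVERLAP")
  cl <- classifyAgainstGenome(tr$peptide, g)
  expect_equal(cl$genome_class, "TRANSCRIPT_FRAME_OVERLAP")
  expect_equal(cl$n_mismatches, 0)
  expect_true(cl$overlaps_transcript)
  expect_false(cl$same_frame_as_transcript)
})

test_that("planted defects of all four kinds recover their truth labels", {
  base <- smallProteome(n = 6)
  g <- makeGenomeWithPlantedErrors(base, 2, 5, 8, 6, seed = 9)
  tr <- truthLabels(g)
  expect_equal(as.integer(table(tr$category)[ProteoRhythm::GENOME_CLASSES]),
               c(2L, 5L, 8L, 6L))
  cl <- classifyAgainstGenome(tr$peptide, g)
  m <- merge(cl, tr, by = "peptide")
  expect_equal(mean(m$genome_class == m$category), 1)
  # substitution wobblies carry exactly one mismatch
  wob <- m[m$category == "WOBBLY_SCAFFOLD" & m$subtype == "substitution", ]
  expect_true(all(wob$n_mismatches == 1))
  # genome construction is seed-deterministic
  g2 <- makeGenomeWithPlantedErrors(base, 2, 5, 8, 6, seed = 9)
  expect_identical(as.character(scaffolds(g)), as.character(scaffolds(g2)))
})

test_that("empty genome warns and yields NO_HIT; space guard trips", {
  g0 <- new("GenomeSet", scaffolds = Biostrings::DNAStringSet(),
            transcripts = data.frame(), truthLabels = data.frame())
  expect_warning(cl <- classifyAgainstGenome("AAAAAAGGK", g0), "empty genome")
  expect_equal(cl$genome_class, "NO_HIT")
  expect_error(makeGenomeWithPlantedErrors(smallProteome(), 1, 1, 1, 1,
                                           maxGenomeNt = 100, seed = 1),
               "insufficient scaffold space")
})

test_that("proteome collection divergence: identity at 0, binomial at 0.5", {
  base <- Biostrings::AAStringSet(c(p1 = strrep("ACDEFGHAST", 10)))  # 100 aa
  col0 <- makeProteomeCollection(base, nSpecies = 3, taxonSizes = c(1, 1, 1),
                                 divergencePerTaxon = c(0, 0, 0), seed = 5)
  expect_equal(as.character(proteomeEntries(col0[[1]])[[1]]),
               as.character(base[[1]]))
  # divergence 0.5 on 100 residues: substitutions within binomial 99% interval
  n_subs <- vapply(1:40, function(i) {
    cc <- makeProteomeCollection(base, nSpecies = 1, taxonSizes = 1,
                                 divergencePerTaxon = 0.5, seed = i)
    a <- strsplit(as.character(proteomeEntries(cc[[1]])[[1]]), "")[[1]]
    b <- strsplit(as.character(base[[1]]), "")[[1]]
    sum(a != b)
  }, numeric(1))
  ci <- qbinom(c(0.005, 0.995), 100, 0.5)
  expect_true(mean(n_subs >= ci[1] & n_subs <= ci[2]) > 0.9)
  # default collection matches the 39-proteome reference-set cardinality
  col39 <- makeProteomeCollection(smallProteome(2), seed = 1)
  expect_equal(length(col39), 39)
  expect_equal(length(unique(vapply(col39, dbId, character(1)))), 39)
  expect_setequal(unique(vapply(col39, taxonGroup, character(1))),
                  c("Anopheles species", "Other mosquito species",
                    "non-dipteran"))
})

test_that("simulated PSMs share scores across databases and pass thresholds", {
  ent <- Biostrings::AAStringSet(c(e1 = "MAAAPEPTIDEKGGG"))
  dbA <- new("ProteomeDB", dbId = "dbA", species = "a", taxonGroup = "t",
             entries = ent)
  dbB <- new("ProteomeDB", dbId = "dbB", species = "b", taxonGroup = "t",
             entries = ent)
  ps <- simulatePsms("PEPTIDEK", list(dbA, dbB),
                     scoreParams = list(mean = 40, sd = 0, thresholds = 35.6),
                     seed = 3)
  expect_equal(nrow(ps), 2)
  # identical sequence context -> identical scores in both records
  expect_equal(ps$score[1], ps$score[2])
  expect_equal(unique(ps$score), 40)
  expect_true(all(ps$score > ps$identity_threshold))
  expect_true(all(ps$rank == 1))
  # peptide absent from a database yields no record
  none <- simulatePsms("WWWWWWK", list(dbA), seed = 3)
  expect_equal(nrow(none), 0)
})

test_that("empirical PSM pass rate matches the normal tail within 3 SE", {
  set.seed(6)
  peps <- ProteoRhythm:::randomTrypticPeptides(1000, c(8, 12))
  ent <- Biostrings::AAStringSet(setNames(paste0("MA", peps, "GG"),
                                          sprintf("e%04d", seq_along(peps))))
  db <- new("ProteomeDB", dbId = "d", species = "s", taxonGroup = "t",
            entries = ent)
  ps <- simulatePsms(peps, list(db),
                     scoreParams = list(mean = 40, sd = 8, thresholds = 35.6),
                     seed = 11)
  ps1 <- ps[ps$rank == 1 & !duplicated(ps$peptide), ]
  p_hat <- mean(ps1$score > ps1$identity_threshold)
  p_true <- pnorm(35.6, 40, 8, lower.tail = FALSE)
  se <- sqrt(p_true * (1 - p_true) / nrow(ps1))
  expect_lt(abs(p_hat - p_true), 3 * se)
})
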