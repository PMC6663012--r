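psm <- function(peptide, db_id, score, threshold = 35.6, rank = 1,
                accession = "acc1") {
  data.frame(peptide = peptide, db_id = db_id, accession = accession,
             score = score, identity_threshold = threshold, rank = rank)
}

test_that("missing-peptide filter applies threshold, same-score and I/L rules", {
  col <- rbind(
    psm("AAAAGGGGK", "dbA", 40),             # retained: above 35.6, no target hit
    psm("CCCCGGGGK", "dbA", 30),             # below identity threshold
    psm("DDDDGGGGK", "dbA", 44),             # same score in target -> removed
    psm("EEEIGGGGK", "dbA", 50),             # I/L permutation in target -> removed
    psm("FFFFGGGGK", "dbA", 41, rank = 2),   # not rank 1
    psm("HHHHGGGGK", "sda500", 45)           # only hit in excluded db
  )
  tgt <- rbind(psm("DDDDGGGGK", "target", 44, threshold = 19),
               psm("EEELGGGGK", "target", 39, threshold = 19))
  out <- findMissing(tgt, col, exclusions = "sda500")
  expect_equal(out$peptide, "AAAAGGGGK")
  expect_equal(out$db_ids, "dbA")
  # empty collection -> empty result
  expect_equal(nrow(findMissing(tgt, col[0, ])), 0)
})

test_that("fixture with planted cases matches the hand-checked truth list", {
  set.seed(15)
  keep <- replicate(30, paste(c(sample(c("A","C","D","E","F","G","H","S","T","V"),
                                       8, replace = TRUE), "K"), collapse = ""))
  keep <- unique(keep)
  same_score <- c("MMMMMMNNK", "NNNNNNMMK")
  il_perm <- c("TTTTIDDDK", "VVVVLEEEK")      # target holds TTTTLDDDK, VVVVIEEEK
  col <- rbind(
    do.call(rbind, lapply(keep, psm, db_id = "dbA", score = 50)),
    do.call(rbind, lapply(same_score, psm, db_id = "dbA", score = 47)),
    do.call(rbind, lapply(il_perm, psm, db_id = "dbB", score = 52)))
  tgt <- rbind(
    do.call(rbind, lapply(same_score, psm, db_id = "t", score = 47, threshold = 19)),
    psm("TTTTLDDDK", "t", 60, threshold = 19),
    psm("VVVVIEEEK", "t", 60, threshold = 19))
  out <- findMissing(tgt, col)
  expect_setequal(out$peptide, keep)
  # anti-monotone in the target: adding target evidence never adds missing
  tgt2 <- rbind(tgt, psm(keep[1], "t", 50, threshold = 19))
  out2 <- findMissing(tgt2, col)
  expect_true(all(out2$peptide %in% out$peptide))
  expect_false(keep[1] %in% out2$peptide)
})

test_that("containment grouping collapses the worked example to one group", {
  g <- groupContainment(c("ATAQLIESIK", "ATAQLIE", "ATAQL"))
  expect_equal(nrow(g), 1)
  expect_equal(g$representative, "ATAQLIESIK")
  expect_equal(g$n_members, 3)
  g2 <- groupContainment(c("AAAA", "CCCC"))
  expect_equal(nrow(g2), 2)
  # containment respects I/L equivalence
  g3 <- groupContainment(c("PEPTIDEK", "PTLDE"))
  expect_equal(nrow(g3), 1)
  g4 <- groupContainment(c("PEPTIDEK", "PTLDE"), ilEquivalent = FALSE)
  expect_equal(nrow(g4), 2)
})

test_that("grouping equals brute-force union-find, idempotent, order-free", {
  set.seed(23)
  base <- replicate(60, paste(sample(c("A","C","D","E","F","G","I","L","S","K"),
                                     sample(8:14, 1), replace = TRUE),
                              collapse = ""))
  # plant substrings (some with I<->L swaps) of random members
  subs <- vapply(sample(base, 80, replace = TRUE), function(s) {
    a <- sample(nchar(s) - 4, 1)
    frag <- substr(s, a, a + 4)
    chartr("IL", "LI", frag)
  }, character(1))
  peps <- unique(c(base, subs))
  got <- groupContainment(peps)
  want <- bruteGroups(peps)
  expect_equal(nrow(got), length(want))
  got_sets <- sort(vapply(strsplit(got$members, ","), function(v)
    paste(sort(v), collapse = ","), character(1)))
  want_sets <- sort(vapply(want, function(v)
    paste(sort(v), collapse = ","), character(1)))
  expect_equal(got_sets, want_sets)
  # idempotent on representatives and invariant to input order
  expect_equal(groupContainment(sample(peps)), got)
})

test_that("taxon summary counts groups once per taxon and honors exclusions", {
  taxonomy <- data.frame(db_id = c("an1", "an2", "an3", "cx1", "sda"),
                         species = letters[1:5],
                         taxon_group = c("Anopheles", "Anopheles", "Anopheles",
                                         "Culex", "Anopheles"))
  hits <- data.frame(peptide = c("AAAAAK", "CCCCCK", "DDDDDK"),
                     db_ids = c("an1,an2,an3", "cx1,an1", "sda"))
  groups <- groupContainment(hits$peptide)
  out <- taxonSummary(groups, hits, taxonomy, exclusions = "sda")
  expect_equal(unname(out["Anopheles"]), 2L)   # 3 species still one count
  expect_equal(unname(out["Culex"]), 1L)
  # unknown db id is rejected
  bad <- data.frame(peptide = "AAAAAK", db_ids = "nope")
  expect_error(taxonSummary(groups[1, ], bad, taxonomy), "unknown db_id")
})

test_that("six-frame search agrees with the naive translate-everything oracle", {
  set.seed(41)
  scafs <- Biostrings::DNAStringSet(c(
    s1 = paste(sample(c("A","C","G","T"), 900, replace = TRUE), collapse = ""),
    s2 = paste(sample(c("A","C","G","T"), 700, replace = TRUE), collapse = "")))
  peps <- character(0)
  # plant peptides on both strands in random frames
  plant <- function(sc, pos, pep, strand) {
    nt <- ProteoRhythm:::revTranslate(pep)
    if (strand == "-")
      nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    s <- as.character(scafs[[sc]])
    substr(s, pos, pos + nchar(nt) - 1) <- nt
    scafs[[sc]] <<- Biostrings::DNAString(s)
  }
  set.seed(42)
  for (i in 1:4) {
    pep <- ProteoRhythm:::randomTrypticPeptides(1, c(8, 8))
    plant(sample(1:2, 1), sample(100:400, 1), pep, sample(c("+", "-"), 1))
    peps <- c(peps, pep)
  }
  peps <- c(peps, "WWWWHHHH")   # absent
  got <- sixFrameHits(peps, scafs, maxMismatch = 0)
  for (pep in peps) {
    want <- bruteSixFrame(pep, scafs)
    g <- got[got$peptide == pep, c("scaffold_id", "start", "end", "strand")]
    rownames(g) <- NULL
    o <- order(want$scaffold_id, want$start)
    want <- want[o, ]; rownames(want) <- NULL
    o2 <- order(g$scaffold_id, g$start)
    g <- g[o2, ]; rownames(g) <- NULL
    expect_equal(g, want, info = pep)
  }
})
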