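# Brute-force oracles used across tests. These deliberately use the
# dumbest correct algorithm so they stay independent of the implementation.

# partitions of n into exactly k positive parts (non-increasing)
partitionsInto <- function(n, k, maxPart = n) {
  if (k == 1) return(if (n <= maxPart) list(n) else list())
  out <- list()
  for (first in seq_len(min(n - k + 1, maxPart)))
    for (rest in partitionsInto(n - first, k - 1, first))
      out <- c(out, list(c(first, rest)))
  out
}

# all permutations of a vector (n <= 8 only)
allPerms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(allPerms(v[-i]), function(p) c(v[i], p))))
}

# O(n^2) pair-count S statistic
bruteS <- function(series, reference) {
  n <- length(series)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (reference[i] != reference[j])
      s <- s + sign(series[i] - series[j]) * sign(reference[i] - reference[j])
  s
}

# exhaustive permutation pmf of S for a tied reference
brutePmf <- function(reference) {
  n <- length(reference)
  perms <- allPerms(seq_len(n))
  S <- vapply(perms, bruteS, numeric(1), reference = reference)
  tab <- table(S)
  list(S = as.numeric(names(tab)), p = as.numeric(tab) / length(perms))
}

# brute-force tryptic digestion: enumerate all runs of fully-cleaved
# fragments with <= maxMissed internal cleavage sites
bruteDigest <- function(seq, maxMissed = 2, lengthRange = c(6, 50)) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  sites <- integer(0)
  for (i in seq_len(n - 1))
    if (aa[i] %in% c("K", "R") && aa[i + 1] != "P") sites <- c(sites, i)
  bounds <- c(0, sites, n)
  peps <- character(0)
  for (a in seq_len(length(bounds) - 1)) {
    for (b in (a + 1):length(bounds)) {
      if (b - a - 1 > maxMissed) break
      peps <- c(peps, paste(aa[(bounds[a] + 1):bounds[b]], collapse = ""))
    }
  }
  peps <- unique(peps)
  peps[nchar(peps) >= lengthRange[1] & nchar(peps) <= lengthRange[2]]
}

# brute-force containment grouping: all-pairs substring test + transitive
# closure by repeated merging
bruteGroups <- function(peptides, ilEquivalent = TRUE) {
  peptides <- unique(peptides)
  key <- if (ilEquivalent) chartr("IL", "JJ", peptides) else peptides
  n <- length(peptides)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || grp[i] == grp[j]) next
      if (grepl(key[i], key[j], fixed = TRUE) ||
          grepl(key[j], key[i], fixed = TRUE)) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(split(peptides, grp))
}

# naive six-frame search: translate every in-frame window of both strands
bruteSixFrame <- function(pep, scaffoldSeqs) {
  m <- nchar(pep)
  pj <- chartr("IL", "JJ", pep)
  hits <- list()
  for (sc in names(scaffoldSeqs)) {
    x <- scaffoldSeqs[[sc]]
    L <- length(x)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") x else Biostrings::reverseComplement(x)
      schr <- as.character(s)
      for (p0 in 0:(L - 3 * m)) {
        nt <- substr(schr, p0 + 1, p0 + 3 * m)
        aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                                 no.init.codon = TRUE))
        if (grepl("*", aa, fixed = TRUE)) next
        if (chartr("IL", "JJ", aa) == pj) {
          co <- if (strand == "+") c(p0, p0 + 3 * m)
                else c(L - (p0 + 3 * m), L - p0)
          hits[[length(hits) + 1]] <-
            data.frame(scaffold_id = sc, start = co[1], end = co[2],
                       strand = strand)
        }
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(scaffold_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  do.call(rbind, hits)
}

# a small deterministic abundance experiment built directly from a matrix
paxFromMatrix <- function(raw, zt, course = rep(1, length(zt))) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = asinh(raw), raw = raw, detected = raw > 0),
    colData = S4Vectors::DataFrame(
      course = course, elapsed = seq_along(zt), zt = zt,
      row.names = colnames(raw)))
  new("ProteinAbundanceExperiment", se)
}
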