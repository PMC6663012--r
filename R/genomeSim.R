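#' Build a toy genome encoding a proteome, with planted annotation errors
#'
#' Encodes every protein of the input proteome as an annotated transcript
#' (random synonymous codons, one scaffold per gene with random intergenic
#' flanks), then plants four kinds of annotation defects, each carried by a
#' distinct random tryptic-like peptide whose true category is recorded:
#'
#' * `nOverlap` overlap genes: the peptide is encoded inside an annotated
#'   transcript but in a shifted reading frame (overlapping gene models);
#' * `nUncalled` uncalled genes: the peptide is encoded on a scaffold with
#'   no transcript model;
#' * `nWobbly` wobbly genes: the encoded peptide carries exactly one planted
#'   amino-acid substitution or a 1-nt insertion/deletion (split between the
#'   two defect types by `wobblyIndelFrac`);
#' * `nGap` gap genes: the peptide is absent from the scaffolds entirely.
#'
#' @param proteome an [Biostrings::AAStringSet] (or [ProteomeDB-class]) of
#'   annotated proteins.
#' @param nOverlap,nUncalled,nWobbly,nGap planted defect counts (>= 0).
#' @param wobblyIndelFrac fraction of wobbly plants that are 1-nt indels
#'   rather than substitutions (default 0.5).
#' @param peptideLength length of planted peptides (default 12 residues).
#' @param maxGenomeNt guard on total scaffold length; construction is
#'   rejected with an explicit message if exceeded.
#' @param seed integer seed; fully deterministic.
#' @return a [GenomeSet-class]; `truthLabels(x)` maps each planted peptide to
#'   its category.
#' @export
makeGenomeWithPlantedErrors <- function(proteome, nOverlap = 2, nUncalled = 25,
                                        nWobbly = 94, nGap = 120,
                                        wobblyIndelFrac = 0.5,
                                        peptideLength = 12,
                                        maxGenomeNt = 5e6, seed = 1L) {
  if (is(proteome, "ProteomeDB")) proteome <- proteomeEntries(proteome)
  if (length(proteome) == 0) stop("'proteome' must be non-empty")
  counts <- c(nOverlap, nUncalled, nWobbly, nGap)
  if (any(counts < 0)) stop("defect counts must be >= 0")

  withSeed(seed, {
    prot_chr <- as.character(proteome)
    est <- sum(nchar(prot_chr)) * 3 + sum(counts) * (3 * peptideLength + 200) +
      length(proteome) * 200
    if (est > maxGenomeNt)
      stop(sprintf(
        "insufficient scaffold space: construction needs ~%d nt but maxGenomeNt = %g",
        est, maxGenomeNt))

    nPep <- sum(counts)
    peps <- character(0)
    guard <- 0
    prot_il <- ilCollapseInternal(prot_chr)
    while (length(peps) < nPep && guard < 50) {
      guard <- guard + 1
      cand <- randomTrypticPeptides(nPep - length(peps),
                                    lengthRange = rep(peptideLength, 2))
      ok <- !vapply(ilCollapseInternal(cand), function(p)
        any(grepl(p, prot_il, fixed = TRUE)), logical(1))
      peps <- unique(c(peps, cand[ok]))
    }
    if (length(peps) < nPep) stop("could not generate distinct planted peptides")
    cat_of <- rep(GENOME_CLASSES, times = counts)
    names(peps) <- NULL

    scaffolds <- character(0)
    tr <- list()
    addScaffold <- function(name, seq) scaffolds[[name]] <<- seq

    # annotated genes, one scaffold each
    for (i in seq_along(prot_chr)) {
      cds <- revTranslate(prot_chr[i])
      fl5 <- randomNt(sample(60:120, 1)); fl3 <- randomNt(sample(60:120, 1))
      nm <- sprintf("scf_gene%03d", i)
      addScaffold(nm, paste0(fl5, cds, fl3))
      tr[[length(tr) + 1]] <- data.frame(
        transcript_id = sprintf("tx%03d", i), scaffold_id = nm,
        start = nchar(fl5), end = nchar(fl5) + nchar(cds),
        strand = "+", frame = 0L)
    }

    idx <- split(seq_len(nPep), cat_of)
    truth <- data.frame(peptide = peps, category = cat_of)

    # overlap genes: peptide in frame +1 inside a stop-free host transcript
    for (k in seq_along(idx$TRANSCRIPT_FRAME_OVERLAP)) {
      i <- idx$TRANSCRIPT_FRAME_OVERLAP[k]
      reg <- makeOverlapRegion(peps[i])
      fl5 <- randomNt(sample(60:120, 1)); fl3 <- randomNt(sample(60:120, 1))
      nm <- sprintf("scf_ovl%03d", k)
      addScaffold(nm, paste0(fl5, reg, fl3))
      tr[[length(tr) + 1]] <- data.frame(
        transcript_id = sprintf("tx_ovl%03d", k), scaffold_id = nm,
        start = nchar(fl5), end = nchar(fl5) + nchar(reg),
        strand = "+", frame = 0L)
    }

    # uncalled genes: peptide on a transcript-free scaffold
    for (k in seq_along(idx$SCAFFOLD_HIT)) {
      i <- idx$SCAFFOLD_HIT[k]
      addScaffold(sprintf("scf_unc%03d", k),
                  paste0(randomNt(sample(40:90, 1)), revTranslate(peps[i]),
                         randomNt(sample(40:90, 1))))
    }

    # wobbly genes: one substitution or one 1-nt indel; degenerate codon
    # choices can occasionally leave the original peptide encoded exactly,
    # so each plant is verified to admit no perfect six-frame hit
    wob <- idx$WOBBLY_SCAFFOLD
    n_indel <- round(wobblyIndelFrac * length(wob))
    is_indel <- seq_along(wob) <= n_indel
    for (k in seq_along(wob)) {
      i <- wob[k]
      for (try in 1:25) {
        nt <- if (is_indel[k]) plantIndel(peps[i]) else plantSubstitution(peps[i])
        scf <- paste0(randomNt(sample(40:90, 1)), nt,
                      randomNt(sample(40:90, 1)))
        probe <- Biostrings::DNAStringSet(setNames(scf, "w"))
        if (nrow(sixFrameHits(peps[i], probe, maxMismatch = 0)) == 0) break
        if (try == 25) stop("could not plant a wobbly defect without an exact hit")
      }
      addScaffold(sprintf("scf_wob%03d", k), scf)
    }
    # gap genes are never placed

    gs <- new("GenomeSet",
              scaffolds = Biostrings::DNAStringSet(unlist(scaffolds)),
              transcripts = do.call(rbind, tr),
              truthLabels = truth)
    gs
  })
}

randomNt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# amino acid -> random synonymous codon
revTranslate <- function(aaSeq) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  aa <- strsplit(aaSeq, "")[[1]]
  paste(vapply(aa, function(a) sample(by_aa[[a]], 1), character(1)),
        collapse = "")
}

# region whose frame-1 offset encodes the peptide while frame 0 (the
# annotated transcript frame) is stop-free
makeOverlapRegion <- function(pep, maxTries = 500) {
  m <- nchar(pep)
  for (i in seq_len(maxTries)) {
    s1 <- randomNt(3 * sample(4:8, 1) + 1)       # offset 1 mod 3
    need <- (3 - (nchar(s1) + 3 * m) %% 3) %% 3
    s2 <- randomNt(3 * sample(4:8, 1) + need)
    reg <- paste0(s1, revTranslate(pep), s2)
    aa0 <- as.character(suppressWarnings(
      Biostrings::translate(Biostrings::DNAString(reg),
                            no.init.codon = TRUE)))
    if (!grepl("*", aa0, fixed = TRUE)) return(reg)
  }
  stop("could not build a stop-free overlap region")
}

# encode the peptide with exactly one amino-acid substitution
plantSubstitution <- function(pep) {
  aa <- strsplit(pep, "")[[1]]
  m <- length(aa)
  pos <- sample(2:(m - 1), 1)
  # the substituted residue must differ under I/L collapsing too
  repl <- setdiff(AA_STANDARD20, unique(c(aa[pos], if (aa[pos] %in% c("I", "L")) c("I", "L"))))
  aa[pos] <- sample(repl, 1)
  revTranslate(paste(aa, collapse = ""))
}

# encode the peptide, then apply one 1-nt insertion (between codons) or
# deletion (inside a codon), leaving prefix/suffix codons intact
plantIndel <- function(pep) {
  m <- nchar(pep)
  nt <- revTranslate(pep)
  j <- sample(2:(m - 2), 1)                     # split after codon j
  if (runif(1) < 0.5) {
    paste0(substr(nt, 1, 3 * j), randomNt(1), substr(nt, 3 * j + 1, 3 * m))
  } else {
    drop <- 3 * j + sample(1:3, 1)              # a nt of codon j+1
    paste0(substr(nt, 1, drop - 1), substr(nt, drop + 1, 3 * m))
  }
}

#' Derive a multi-species proteome collection from a base proteome
#'
#' Each derived proteome applies i.i.d. residue substitutions to every base
#' protein at its taxon's divergence rate and is labelled with a species name
#' and taxon group. The default emulates a 39-proteome reference collection
#' spanning close congeners, other mosquitoes, and non-dipteran vectors.
#'
#' @param baseProteome an [Biostrings::AAStringSet].
#' @param nSpecies number of derived proteomes (default 39).
#' @param taxonGroups taxon labels in assignment order.
#' @param taxonSizes number of species per taxon (sums to `nSpecies`).
#' @param divergencePerTaxon per-residue substitution rate per taxon, each in
#'   [0, 1).
#' @param seed integer seed.
#' @return list of [ProteomeDB-class] objects.
#' @export
makeProteomeCollection <- function(baseProteome, nSpecies = 39,
                                   taxonGroups = c("Anopheles species",
                                                   "Other mosquito species",
                                                   "non-dipteran"),
                                   taxonSizes = c(6, 10, 23),
                                   divergencePerTaxon = c(0.02, 0.1, 0.25),
                                   seed = 1L) {
  if (nSpecies < 1) stop("'nSpecies' must be >= 1")
  if (sum(taxonSizes) != nSpecies) stop("'taxonSizes' must sum to 'nSpecies'")
  if (any(divergencePerTaxon < 0 | divergencePerTaxon >= 1))
    stop("divergence rates must lie in [0, 1)")
  taxon_of <- rep(taxonGroups, times = taxonSizes)
  div_of <- rep(divergencePerTaxon, times = taxonSizes)
  base <- as.character(baseProteome)
  withSeed(seed, {
    lapply(seq_len(nSpecies), function(i) {
      ent <- vapply(base, mutateProtein, character(1), rate = div_of[i])
      names(ent) <- names(base)
      new("ProteomeDB",
          dbId = sprintf("db%02d", i),
          species = sprintf("species_%02d", i),
          taxonGroup = taxon_of[i],
          entries = Biostrings::AAStringSet(ent))
    })
  })
}

mutateProtein <- function(seq, rate) {
  if (rate == 0) return(seq)
  aa <- strsplit(seq, "")[[1]]
  hit <- runif(length(aa)) < rate
  if (any(hit))
    aa[hit] <- vapply(aa[hit],
                      function(a) sample(setdiff(AA_STANDARD20, a), 1),
                      character(1))
  paste(aa, collapse = "")
}

#' Simulate scored peptide-spectrum matches against a set of databases
#'
#' Each peptide receives one score (shared across all databases, since the
#' spectral evidence is the same) drawn from a truncated normal; a PSM record
#' is emitted for every database in which the peptide occurs as an
#' I/L-equivalent substring of some entry, with the database's identity
#' threshold attached and rank 1 on the top accession.
#'
#' @param peptides character vector (non-empty).
#' @param dbs list of [ProteomeDB-class] objects.
#' @param scoreParams list: `mean` and `sd` of the score distribution
#'   (scores are truncated at 0), `thresholds` — named vector of per-db
#'   identity thresholds (default 35.6), or a single default.
#' @param seed integer seed.
#' @return data.frame: `peptide`, `db_id`, `accession`, `score`,
#'   `identity_threshold`, `rank`.
#' @export
simulatePsms <- function(peptides, dbs,
                         scoreParams = list(mean = 45, sd = 10,
                                            thresholds = 35.6),
                         seed = 1L) {
  if (length(peptides) == 0) stop("'peptides' must be non-empty")
  thr <- scoreParams$thresholds
  withSeed(seed, {
    score <- pmax(0, rnorm(length(peptides), scoreParams$mean, scoreParams$sd))
    names(score) <- peptides
    out <- list()
    for (db in dbs) {
      ents <- ilCollapseInternal(as.character(proteomeEntries(db)))
      accs <- names(proteomeEntries(db))
      t_db <- if (!is.null(names(thr)) && dbId(db) %in% names(thr))
        thr[[dbId(db)]] else thr[[1]]
      for (pi in seq_along(peptides)) {
        hit <- which(grepl(ilCollapseInternal(peptides[pi]), ents, fixed = TRUE))
        if (length(hit) == 0) next
        out[[length(out) + 1]] <- data.frame(
          peptide = peptides[pi], db_id = dbId(db),
          accession = accs[hit],
          score = score[[pi]], identity_threshold = t_db,
          rank = seq_along(hit))
      }
    }
    if (length(out) == 0)
      return(data.frame(peptide = character(0), db_id = character(0),
                        accession = character(0), score = numeric(0),
                        identity_threshold = numeric(0), rank = integer(0)))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
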