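#' Run the full simulate-quantify-detect-rhythm-proteogenomics pipeline
#'
#' Executes every stage on synthetic data with known ground truth: simulate
#' a staggered time-course abundance matrix and peptide features; quantify
#' (charge/top-N filter, median normalization, unique-peptide summing,
#' arcsinh); profile time-of-day detectability; ANOVA-prefilter and test
#' rhythmicity with JTK_CYCLE; and run the proteogenomic missing-peptide
#' workflow on a toy genome with planted annotation errors. Identical
#' config + seed give identical outputs. Per-stage record counts are logged
#' via `message()` so the identification funnel is visible.
#'
#' @param config configuration from [pipelineConfig()].
#' @param outdir optional output directory; when given, all report tables
#'   plus a run manifest are written via [writePipelineTables()].
#' @return list with elements `design`, `truth`, `pax`
#'   (the [ProteinAbundanceExperiment-class]), `detectability` (per-ZT
#'   counts, breadth, peaks), `rhythm` (per-protein results), `missing`,
#'   `groups`, `taxa`, `classes` and `genome`.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = NULL) {
  seed <- config$seed
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    res
  }

  design <- stage("design", makeTimeCourseDesign(
    nCourses = config$design$nCourses, durations = config$design$durations,
    interval = config$design$interval, poolSize = config$design$poolSize))

  sim <- stage("simulate", simulateAbundance(
    design, nProteins = config$simulate$nProteins,
    fracRhythmic = config$simulate$fracRhythmic,
    noiseSd = config$simulate$noiseSd,
    dropout = if (is.null(config$simulate$dropoutScale)) NULL else
      list(midpoint = NA, scale = config$simulate$dropoutScale),
    seed = deriveSeed(seed, 1)))
  feats <- stage("simulate", simulateFeatures(design, sim$raw,
                                              seed = deriveSeed(seed, 2)))
  message(sprintf("simulate: %d proteins, %d feature spectra",
                  nrow(sim$raw), nrow(feats)))

  feats <- stage("quantify", filterFeatures(feats,
    charges = config$quantify$charges, topK = config$quantify$topK))
  feats <- stage("quantify", normalizeFeatures(feats))
  pax <- stage("quantify", proteinAbundance(feats, design,
    minPeptides = config$quantify$minPeptides))
  message(sprintf("quantify: %d quantifiable proteins x %d samples",
                  nrow(pax), ncol(pax)))

  detect <- stage("detectability", list(
    per_zt = perZtDetection(pax),
    breadth = detectionBreadth(pax),
    by_breadth = abundanceByBreadth(pax),
    peaks = peakTimeHistogram(pax)))

  pre <- stage("rhythm", anovaPrefilter(pax,
    alpha = config$rhythm$alphaAnova, minReps = config$rhythm$minReps))
  rhythm <- stage("rhythm", rhythmAnalysis(pax, pre,
    alphaJtk = config$rhythm$alphaJtk, period = config$rhythm$period,
    lagStep = config$rhythm$lagStep))
  message(sprintf("rhythm: %d eligible -> %d ANOVA-retained -> %d rhythmic",
                  sum(pre$eligible), sum(pre$retained), sum(rhythm$rhythmic)))

  pg <- stage("proteogenomics", runProteogenomics(config, seed))
  message(sprintf(
    "proteogenomics: %d missing peptides -> %d groups; classes: %s",
    nrow(pg$missing), nrow(pg$groups),
    paste(sprintf("%s=%d", names(pg$class_counts), pg$class_counts),
          collapse = " ")))

  results <- list(design = design, truth = sim$truth, pax = pax,
                  detectability = detect, rhythm = rhythm,
                  missing = pg$missing, groups = pg$groups, taxa = pg$taxa,
                  classes = pg$classes, genome = pg$genome)
  if (!is.null(outdir)) {
    tables <- list(
      truth = sim$truth,
      design = designSamples(design),
      abundance = as.data.frame(abundanceMatrix(pax)),
      per_zt_detection = detect$per_zt,
      detection_breadth = detect$breadth,
      peak_histogram = detect$peaks$counts,
      rhythm = rhythm,
      missing_peptides = pg$missing,
      peptide_groups = pg$groups,
      taxon_summary = pg$taxa,
      genome_classes = pg$classes,
      scaffolds = scaffolds(pg$genome)
    )
    writePipelineTables(tables, outdir, config)
  }
  invisible(results)
}

# the proteogenomic stage on a planted toy genome: simulate databases and
# PSMs, filter to missing peptides, group, summarize taxa, classify
runProteogenomics <- function(config, seed) {
  pc <- config$proteogenomics
  base <- withSeed(deriveSeed(seed, 3), randomProteome(
    pc$nBaseProteins, pc$baseProteinLength))
  genome <- makeGenomeWithPlantedErrors(
    base, nOverlap = pc$nOverlap, nUncalled = pc$nUncalled,
    nWobbly = pc$nWobbly, nGap = pc$nGap,
    seed = deriveSeed(seed, 4))
  truth <- truthLabels(genome)

  dbs <- makeProteomeCollection(base, seed = deriveSeed(seed, 5))
  # collection species carry the planted genes the target annotation lacks;
  # each planted gene is conserved in a random subset of species (at least
  # one outside the excluded conspecific strain)
  member <- withSeed(deriveSeed(seed, 7), {
    mm <- matrix(runif(length(dbs) * nrow(truth)) < 0.5,
                 nrow = length(dbs))
    ok_rows <- which(!(vapply(dbs, dbId, character(1)) %in% pc$exclusions))
    for (j in which(colSums(mm[ok_rows, , drop = FALSE]) == 0))
      mm[sample(ok_rows, 1), j] <- TRUE
    mm
  })
  dbs <- lapply(seq_along(dbs), function(i) {
    db <- dbs[[i]]
    sel <- which(member[i, ])
    if (length(sel) == 0) return(db)
    extra <- Biostrings::AAStringSet(setNames(
      vapply(truth$peptide[sel], function(p)
        paste0("MAAA", p, "AAAK"), character(1)),
      paste0("planted_", sel)))
    new("ProteomeDB", dbId = dbId(db), species = db@species,
        taxonGroup = taxonGroup(db),
        entries = c(proteomeEntries(db), extra))
  })

  target_peps <- unique(unlist(lapply(as.character(base), digestTryptic,
                                      maxMissed = 2,
                                      lengthRange = pc$peptideLength)))
  all_peps <- c(truth$peptide, target_peps)
  thr <- setNames(rep(pc$thresholdCollection, length(dbs)),
                  vapply(dbs, dbId, character(1)))
  psms_col <- simulatePsms(all_peps, dbs,
    scoreParams = list(mean = 45, sd = 5, thresholds = thr),
    seed = deriveSeed(seed, 6))
  target_db <- new("ProteomeDB", dbId = "target", species = "target species",
                   taxonGroup = "target", entries = base)
  psms_tgt <- simulatePsms(all_peps, list(target_db),
    scoreParams = list(mean = 45, sd = 5,
                       thresholds = c(target = pc$thresholdTarget)),
    seed = deriveSeed(seed, 6))   # same stream: same evidence, same scores

  missing <- findMissing(psms_tgt, psms_col, exclusions = pc$exclusions)
  groups <- groupContainment(missing$peptide)
  taxonomy <- data.frame(
    db_id = vapply(dbs, dbId, character(1)),
    species = vapply(dbs, function(d) d@species, character(1)),
    taxon_group = vapply(dbs, taxonGroup, character(1)))
  taxa <- taxonSummary(groups, missing, taxonomy, exclusions = pc$exclusions)
  classes <- classifyAgainstGenome(groups$representative, genome)
  cc <- table(factor(classes$genome_class, levels = GENOME_CLASSES))
  list(genome = genome, missing = missing, groups = groups,
       taxa = data.frame(taxon_group = names(taxa), n_groups = unname(taxa)),
       classes = classes,
       class_counts = setNames(as.integer(cc), names(cc)))
}

# random well-formed protein sequences (start with M, standard residues)
randomProteome <- function(n, lengthRange) {
  lens <- sample(lengthRange[1]:lengthRange[2], n, replace = TRUE)
  seqs <- vapply(lens, function(l)
    paste0("M", paste(sample(AA_STANDARD20, l - 1, replace = TRUE),
                      collapse = "")), character(1))
  Biostrings::AAStringSet(setNames(seqs, sprintf("prot%03d", seq_len(n))))
}
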