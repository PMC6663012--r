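#' Read a protein or nucleotide FASTA file
#'
#' Thin wrappers over Biostrings readers that tolerate wrapped lines and
#' mixed case; record ids are the first whitespace-delimited token of each
#' header. Empty files yield an empty set with a warning.
#'
#' @param path file path.
#' @return an [Biostrings::AAStringSet] / [Biostrings::DNAStringSet].
#' @export
readProteomeFasta <- function(path) {
  x <- tryCatch(Biostrings::readAAStringSet(path),
                error = function(e) stop("malformed FASTA '", path, "': ",
                                         conditionMessage(e)))
  if (length(x) == 0) warning("empty FASTA file: ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  Biostrings::AAStringSet(toupper(as.character(x)))
}

#' @rdname readProteomeFasta
#' @export
readGenomeFasta <- function(path) {
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("malformed FASTA '", path, "': ",
                                         conditionMessage(e)))
  if (length(x) == 0) warning("empty FASTA file: ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Write / read tab-separated tables with headers
#'
#' @param x data.frame.
#' @param path file path.
#' @export
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write the standard report bundle of a pipeline run
#'
#' Emits one TSV per analysis product plus FASTA sequence files and a JSON
#' run manifest recording the configuration, seed, package version and an
#' md5 checksum of every emitted file (so byte-identical reruns are
#' verifiable).
#'
#' @param results list of data.frames / objects from [runPipeline()].
#' @param outdir output directory (created if needed).
#' @param config the pipeline configuration list.
#' @return invisibly, the manifest list.
#' @export
writePipelineTables <- function(results, outdir, config = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(obj, name) {
    p <- file.path(outdir, name)
    if (is.data.frame(obj)) writeTsv(obj, p)
    else if (is(obj, "XStringSet")) Biostrings::writeXStringSet(obj, p)
    else if (is.numeric(obj)) writeTsv(data.frame(key = names(obj), value = unname(obj)), p)
    p
  }
  files <- character(0)
  for (nm in names(results)) {
    obj <- results[[nm]]
    ext <- if (is(obj, "XStringSet")) ".fasta" else ".tsv"
    files <- c(files, emit(obj, paste0(nm, ext)))
  }
  if (length(config)) yaml::write_yaml(config, file.path(outdir, "config.yaml"))
  manifest <- list(
    package = "ProteoRhythm",
    version = as.character(packageVersion("ProteoRhythm")),
    config = config,
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read and write transcript models as GFF3
#'
#' Transcript models travel internally as a data.frame with 0-based
#' half-open coordinates (`transcript_id`, `scaffold_id`, `start`, `end`,
#' `strand`, `frame`); on disk they are standard 1-based GFF3 `CDS`
#' features whose `phase` column carries the frame, read and written with
#' rtracklayer.
#'
#' @param transcripts transcript data.frame (e.g.
#'   [transcriptModels()] of a [GenomeSet-class]).
#' @param path GFF3 file path.
#' @return `readTranscriptsGff3`: the transcript data.frame.
#' @export
writeTranscriptsGff3 <- function(transcripts, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for GFF3 output")
  gr <- GenomicRanges::GRanges(
    seqnames = transcripts$scaffold_id,
    ranges = IRanges::IRanges(start = transcripts$start + 1,
                              end = transcripts$end),
    strand = transcripts$strand)
  gr$type <- "CDS"
  gr$ID <- transcripts$transcript_id
  gr$phase <- as.integer(transcripts$frame)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname writeTranscriptsGff3
#' @export
readTranscriptsGff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for GFF3 input")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  data.frame(
    transcript_id = as.character(gr$ID),
    scaffold_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    frame = as.integer(gr$phase))
}

#' Default pipeline configuration
#'
#' Collects every tunable constant of the pipeline: the staggered design,
#' simulation model, quantitation thresholds (charges 2-4, top 5 spectra,
#' at least 2 component peptides), rhythm parameters (ANOVA alpha 0.1, JTK
#' alpha 0.1, period 24 h, 2-h phase grid) and proteogenomics thresholds
#' (identity thresholds, exclusions, peptide length bounds). Values can be
#' overridden by a named list or a YAML file.
#'
#' @param overrides named list of overrides (nested lists merged).
#' @param yamlFile optional YAML file of overrides, applied before
#'   `overrides`.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(overrides = list(), yamlFile = NULL) {
  cfg <- list(
    seed = 1L,
    design = list(nCourses = 3, durations = c(44, 36, 28), interval = 4,
                  poolSize = 10),
    simulate = list(nProteins = 400, fracRhythmic = 0.2, noiseSd = 0.25,
                    dropoutScale = 1),
    quantify = list(charges = c(2, 3, 4), topK = 5, minPeptides = 2),
    rhythm = list(alphaAnova = 0.1, alphaJtk = 0.1, period = 24,
                  lagStep = 2, minReps = 2),
    proteogenomics = list(
      nOverlap = 2, nUncalled = 25, nWobbly = 94, nGap = 120,
      nBaseProteins = 30, baseProteinLength = c(120, 250),
      thresholdTarget = 19, thresholdCollection = 35.6,
      exclusions = "db01",                 # the conspecific strain database
      peptideLength = c(6, 50))
  )
  if (!is.null(yamlFile)) cfg <- mergeConfig(cfg, yaml::read_yaml(yamlFile))
  cfg <- mergeConfig(cfg, overrides)
  stopifnot(cfg$rhythm$alphaAnova > 0, cfg$rhythm$alphaAnova < 1,
            cfg$rhythm$alphaJtk > 0, cfg$rhythm$alphaJtk < 1,
            cfg$rhythm$period > 0)
  cfg
}

mergeConfig <- function(base, over) {
  for (nm in names(over)) {
    base[[nm]] <- if (is.list(over[[nm]]) && is.list(base[[nm]]))
      mergeConfig(base[[nm]], over[[nm]]) else over[[nm]]
  }
  base
}
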