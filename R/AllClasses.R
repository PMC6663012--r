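#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @importFrom Biostrings AAStringSet DNAStringSet readAAStringSet
#'   readDNAStringSet writeXStringSet translate vmatchPattern subseq
#'   reverseComplement GENETIC_CODE
#' @importFrom IRanges IRanges start end width
NULL

#' Staggered time-course sampling design
#'
#' Maps every sample of a multi-course collection protocol to its course,
#' elapsed hour, and zeitgeber time (ZT; hours since lights-on, with lights on
#' at ZT0 and off at ZT12 under a 12:12 light:dark cycle).
#'
#' @slot samples data.frame with columns `sample_id`, `course`, `elapsed`
#'   (hours since course start) and `zt` (zeitgeber time of collection).
#' @slot interval sampling interval in hours.
#' @slot lightsOn,lightsOff ZT hours of lights-on (0) and lights-off (12).
#' @slot poolSize number of animals pooled per sample.
#' @exportClass TimeCourseDesign
setClass("TimeCourseDesign",
  representation(
    samples   = "data.frame",
    interval  = "numeric",
    lightsOn  = "numeric",
    lightsOff = "numeric",
    poolSize  = "integer"
  )
)

setValidity("TimeCourseDesign", function(object) {
  s <- object@samples
  need <- c("sample_id", "course", "elapsed", "zt")
  if (!all(need %in% names(s)))
    return(sprintf("samples must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(s$sample_id)) return("duplicate sample_id")
  if (any(s$zt < 0 | s$zt >= 24)) return("zt must lie in [0, 24)")
  if (object@interval <= 0) return("interval must be positive")
  TRUE
})

#' @describeIn TimeCourseDesign number of samples in the design
#' @param x,object a `TimeCourseDesign`
#' @export
setMethod("length", "TimeCourseDesign", function(x) nrow(x@samples))

#' Accessors for TimeCourseDesign
#'
#' `designSamples` returns the per-sample table; `ztBins` the sorted unique
#' ZT bins; `samplingInterval` the spacing in hours; `poolSize` the number of
#' animals pooled per sample.
#'
#' @param design a [TimeCourseDesign-class] object.
#' @return `designSamples`: data.frame; `ztBins`: numeric vector;
#'   `samplingInterval`, `poolSize`: scalars.
#' @export
designSamples <- function(design) design@samples

#' @rdname designSamples
#' @export
ztBins <- function(design) sort(unique(design@samples$zt))

#' @rdname designSamples
#' @export
samplingInterval <- function(design) design@interval

#' @rdname designSamples
#' @export
poolSize <- function(design) design@poolSize

setMethod("show", "TimeCourseDesign", function(object) {
  s <- object@samples
  cat(sprintf(
    "TimeCourseDesign: %d samples, %d courses, every %g h\n",
    nrow(s), length(unique(s$course)), object@interval))
  tab <- table(s$zt)
  cat("  samples per ZT bin: ",
      paste(sprintf("ZT%s=%d", names(tab), as.integer(tab)), collapse = " "),
      "\n", sep = "")
  cat(sprintf("  lights on ZT%g, off ZT%g; pool of %d animals per sample\n",
              object@lightsOn, object@lightsOff, object@poolSize))
})

#' Protein abundance matrix with detection mask and time metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding
#' normalized, inverse-hyperbolic-sine (arcsinh) transformed protein
#' abundances. Assays: `abundance` (arcsinh units), `raw` (summed, normalized
#' peptide ion intensities) and `detected` (logical; `FALSE` exactly where
#' the raw sum is zero — never imputed). `colData` carries `course`,
#' `elapsed` and `zt` per sample; `rowData` carries `n_peptides`, the number
#' of distinct component peptides supporting each protein.
#'
#' @exportClass ProteinAbundanceExperiment
setClass("ProteinAbundanceExperiment", contains = "SummarizedExperiment")

setValidity("ProteinAbundanceExperiment", function(object) {
  an <- names(SummarizedExperiment::assays(object))
  if (!all(c("abundance", "raw", "detected") %in% an))
    return("assays must include 'abundance', 'raw' and 'detected'")
  det <- SummarizedExperiment::assay(object, "detected")
  raw <- SummarizedExperiment::assay(object, "raw")
  if (!identical(dim(det), dim(raw))) return("assay dimensions differ")
  if (any(det != (raw > 0))) return("'detected' must equal raw > 0")
  ab <- SummarizedExperiment::assay(object, "abundance")
  if (any(!is.finite(ab[det]))) return("abundance must be finite where detected")
  if (!all(c("zt", "course", "elapsed") %in% names(SummarizedExperiment::colData(object))))
    return("colData must carry 'course', 'elapsed' and 'zt'")
  TRUE
})

#' Accessors for ProteinAbundanceExperiment
#'
#' `abundanceMatrix` returns the arcsinh-transformed abundances,
#' `detectedMask` the logical detection mask, and `sampleZT` the zeitgeber
#' time of each sample (column).
#'
#' @param x a [ProteinAbundanceExperiment-class].
#' @return matrix, logical matrix, or numeric vector respectively.
#' @export
abundanceMatrix <- function(x) SummarizedExperiment::assay(x, "abundance")

#' @rdname abundanceMatrix
#' @export
detectedMask <- function(x) SummarizedExperiment::assay(x, "detected")

#' @rdname abundanceMatrix
#' @export
sampleZT <- function(x) SummarizedExperiment::colData(x)$zt

setMethod("show", "ProteinAbundanceExperiment", function(object) {
  callNextMethod()
  det <- detectedMask(object)
  cat(sprintf("detected: %.1f%% of entries; %d proteins detected in every sample\n",
              100 * mean(det), sum(rowSums(!det) == 0)))
})

#' Toy genome with annotated transcripts and planted-defect truth labels
#'
#' @slot scaffolds a [Biostrings::DNAStringSet] of scaffold sequences.
#' @slot transcripts data.frame of transcript models: `transcript_id`,
#'   `scaffold_id`, `start`, `end` (0-based half-open nucleotide
#'   coordinates), `strand` (`+`/`-`), `frame` (0/1/2 offset from `start`).
#' @slot truthLabels data.frame `peptide`, `category` recording each planted
#'   peptide's true annotation-error category (or `"annotated"`).
#' @exportClass GenomeSet
setClass("GenomeSet",
  representation(
    scaffolds   = "DNAStringSet",
    transcripts = "data.frame",
    truthLabels = "data.frame"
  )
)

setValidity("GenomeSet", function(object) {
  tr <- object@transcripts
  need <- c("transcript_id", "scaffold_id", "start", "end", "strand", "frame")
  if (nrow(tr) > 0) {
    if (!all(need %in% names(tr)))
      return(sprintf("transcripts must have columns %s", paste(need, collapse = ", ")))
    if (!all(tr$scaffold_id %in% names(object@scaffolds)))
      return("transcript on unknown scaffold")
    wid <- Biostrings::width(object@scaffolds)[match(tr$scaffold_id, names(object@scaffolds))]
    if (any(tr$start < 0 | tr$end > wid | tr$start >= tr$end))
      return("transcript coordinates out of scaffold bounds")
    if (!all(tr$strand %in% c("+", "-"))) return("strand must be + or -")
  }
  tl <- object@truthLabels
  ok <- c(GENOME_CLASSES, "annotated")
  if (nrow(tl) > 0 && !all(tl$category %in% ok))
    return("truth categories must be a genome class or 'annotated'")
  TRUE
})

#' @rdname GenomeSet-class
#' @param x,object a `GenomeSet`
#' @export
scaffolds <- function(x) x@scaffolds

#' @rdname GenomeSet-class
#' @export
transcriptModels <- function(x) x@transcripts

#' @rdname GenomeSet-class
#' @export
truthLabels <- function(x) x@truthLabels

setMethod("show", "GenomeSet", function(object) {
  cat(sprintf("GenomeSet: %d scaffolds (%s nt), %d transcript models, %d truth-labelled peptides\n",
              length(object@scaffolds),
              format(sum(Biostrings::width(object@scaffolds)), big.mark = ","),
              nrow(object@transcripts), nrow(object@truthLabels)))
  if (nrow(object@truthLabels))
    print(table(object@truthLabels$category))
})

#' A predicted proteome database with taxon labels
#'
#' @slot dbId unique database identifier within a collection.
#' @slot species species name.
#' @slot taxonGroup coarse taxonomic group label (e.g. "Anopheles species",
#'   "Other mosquito species", "non-dipteran").
#' @slot entries an [Biostrings::AAStringSet]; names are accessions.
#' @exportClass ProteomeDB
setClass("ProteomeDB",
  representation(
    dbId       = "character",
    species    = "character",
    taxonGroup = "character",
    entries    = "AAStringSet"
  )
)

setValidity("ProteomeDB", function(object) {
  if (length(object@dbId) != 1L || !nzchar(object@dbId)) return("dbId must be a single non-empty string")
  if (length(object@entries)) {
    letters_used <- unique(strsplit(paste(as.character(object@entries), collapse = ""), "")[[1]])
    if (!all(letters_used %in% AA_STANDARD20))
      return("sequences must use the 20 standard residues")
    if (anyDuplicated(names(object@entries))) return("duplicate accession")
  }
  TRUE
})

#' @rdname ProteomeDB-class
#' @param x,object a `ProteomeDB`
#' @export
dbId <- function(x) x@dbId

#' @rdname ProteomeDB-class
#' @export
taxonGroup <- function(x) x@taxonGroup

#' @rdname ProteomeDB-class
#' @export
proteomeEntries <- function(x) x@entries

setMethod("show", "ProteomeDB", function(object) {
  cat(sprintf("ProteomeDB '%s' (%s; %s): %d entries\n",
              object@dbId, object@species, object@taxonGroup,
              length(object@entries)))
})

#' Genome annotation-error categories
#'
#' Precedence order used by [classifyAgainstGenome()]: a perfect full-length
#' hit inside an annotated transcript but in a different frame/strand
#' (`TRANSCRIPT_FRAME_OVERLAP`, overlapping gene models), a perfect hit
#' outside any transcript (`SCAFFOLD_HIT`, uncalled gene), a best hit with
#' exactly one mismatch or a full-length 1-nt frameshift match
#' (`WOBBLY_SCAFFOLD`, SNP/sequencing error/frameshift), and no hit at all
#' (`NO_HIT`, suspected assembly gap).
#' @export
GENOME_CLASSES <- c("TRANSCRIPT_FRAME_OVERLAP", "SCAFFOLD_HIT",
                    "WOBBLY_SCAFFOLD", "NO_HIT")

AA_STANDARD20 <- c("A","C","D","E","F","G","H","I","K","L",
                   "M","N","P","Q","R","S","T","V","W","Y")
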