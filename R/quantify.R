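#' Charge and top-N spectrum filtering of feature records
#'
#' Retains only multiply charged features (2+, 3+ or 4+ by default) and, per
#' feature, only its `topK` most intense spectra.
#'
#' @param features data.frame with columns `feature_id`, `peptide`,
#'   `protein_id`, `charge`, `sample_id`, `intensity` (one row per spectrum).
#' @param charges charges to keep.
#' @param topK spectra retained per feature, ranked by intensity.
#' @return the filtered feature data.frame.
#' @export
filterFeatures <- function(features, charges = c(2, 3, 4), topK = 5) {
  if (nrow(features) == 0) return(features)
  f <- features[features$charge %in% charges, , drop = FALSE]
  if (nrow(f) == 0) return(f)
  ord <- order(f$feature_id, -f$intensity)
  f <- f[ord, , drop = FALSE]
  keep <- ave(seq_len(nrow(f)), f$feature_id, FUN = seq_along) <= topK
  out <- f[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Median normalization of feature intensities across samples
#'
#' Per sample, computes the median of summed feature intensities (all spectra
#' of a feature summed) and rescales every intensity so each sample's median
#' equals the global median of per-sample medians. This equalizes the median
#' feature intensity across samples while preserving the global intensity
#' scale. The operation is idempotent. Samples whose intensities are all
#' zero are flagged with a warning and left unscaled.
#'
#' @param features charge-filtered feature data.frame (see
#'   [filterFeatures()]).
#' @return feature data.frame with normalized `intensity`.
#' @export
normalizeFeatures <- function(features) {
  if (nrow(features) == 0) return(features)
  feat_sum <- tapply(features$intensity,
                     list(features$feature_id, features$sample_id),
                     sum)
  med <- apply(feat_sum, 2, function(col) {
    v <- col[!is.na(col)]
    if (length(v) == 0 || all(v == 0)) NA_real_ else median(v)
  })
  bad <- is.na(med) | med == 0
  if (any(bad))
    warning("sample(s) with all-zero intensities left unscaled: ",
            paste(names(med)[bad], collapse = ", "))
  global <- median(med[!bad])
  scale <- ifelse(bad, 1, global / med)
  features$intensity <- features$intensity *
    scale[match(features$sample_id, names(med))]
  features
}

#' Protein quantitation by unique-peptide intensity summing
#'
#' Per protein and sample, sums the ion intensities of its unique peptides
#' (peptides mapping to exactly one protein in the table; shared peptides are
#' excluded) and transforms the sum with the inverse hyperbolic sine,
#' `arcsinh(x) = log(x + sqrt(x^2 + 1))` — a log-like variance-stabilizing
#' transform that is defined at zero, suiting intensity data with many
#' near-zero values. Proteins supported by fewer than `minPeptides` distinct
#' peptides overall are dropped as not quantifiable. Zero raw sums are kept
#' as 0 with `detected = FALSE`; missing values are never imputed.
#'
#' @param features normalized feature data.frame (see
#'   [normalizeFeatures()]).
#' @param design a [TimeCourseDesign-class] supplying sample metadata.
#' @param minPeptides minimum distinct component peptides for a protein to
#'   be quantifiable (default 2).
#' @return a [ProteinAbundanceExperiment-class].
#' @export
proteinAbundance <- function(features, design, minPeptides = 2) {
  s <- designSamples(design)
  # unique peptides: mapping to exactly one protein
  pp <- unique(features[, c("peptide", "protein_id")])
  n_prot <- table(pp$peptide)
  unique_peps <- names(n_prot)[n_prot == 1]
  f <- features[features$peptide %in% unique_peps, , drop = FALSE]

  pep_count <- tapply(pp$peptide[pp$peptide %in% unique_peps],
                      pp$protein_id[pp$peptide %in% unique_peps],
                      function(x) length(unique(x)))
  keep_prot <- names(pep_count)[pep_count >= minPeptides]
  f <- f[f$protein_id %in% keep_prot, , drop = FALSE]
  keep_prot <- sort(keep_prot)

  raw <- matrix(0, nrow = length(keep_prot), ncol = nrow(s),
                dimnames = list(keep_prot, s$sample_id))
  if (nrow(f)) {
    agg <- tapply(f$intensity, list(f$protein_id, f$sample_id), sum)
    agg[is.na(agg)] <- 0
    raw[rownames(agg), colnames(agg)] <- agg
  }
  ab <- asinh(raw)
  det <- raw > 0
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = ab, raw = raw, detected = det),
    colData = S4Vectors::DataFrame(s[, c("course", "elapsed", "zt")],
                                   row.names = s$sample_id),
    rowData = S4Vectors::DataFrame(
      n_peptides = as.integer(pep_count[keep_prot]),
      row.names = keep_prot)
  )
  new("ProteinAbundanceExperiment", se)
}

#' Target-decoy false discovery rate
#'
#' Estimates the identification FDR as the percentage of decoy-database
#' matches over target-database matches, `100 * n_decoy / n_target`, rounded
#' half-up to two decimals.
#'
#' @param nTarget number of target-database matches above threshold (> 0).
#' @param nDecoy number of decoy-database matches above threshold.
#' @return list with `n_target`, `n_decoy`, `fdr_percent`.
#' @examples
#' computeFdr(11867, 160)$fdr_percent  # 1.35
#' computeFdr(13300, 248)$fdr_percent  # 1.86
#' @export
computeFdr <- function(nTarget, nDecoy) {
  if (!is.finite(nTarget) || nTarget <= 0) stop("'nTarget' must be > 0")
  if (!is.finite(nDecoy) || nDecoy < 0) stop("'nDecoy' must be >= 0")
  list(n_target = nTarget, n_decoy = nDecoy,
       fdr_percent = roundHalfUp(100 * nDecoy / nTarget, 2))
}
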