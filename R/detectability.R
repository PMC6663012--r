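#' Proteins detectable at each time of day
#'
#' A protein counts as detectable at a ZT bin if it was detected (raw
#' abundance > 0) in at least `minReplicates` replicate samples at that bin,
#' pooling replicates across courses.
#'
#' @param pax a [ProteinAbundanceExperiment-class].
#' @param minReplicates detections required per bin (default 1).
#' @return named integer vector: count of detectable proteins per ZT bin.
#' @export
perZtDetection <- function(pax, minReplicates = 1) {
  hits <- detectionByBin(pax) >= minReplicates
  setNames(as.integer(colSums(hits)), colnames(hits))
}

#' Detection breadth: number of ZT bins at which each protein is detected
#'
#' @inheritParams perZtDetection
#' @return named integer vector, one entry per protein, with values in
#'   `0..n_bins`. Its histogram is the "detected at k time points" summary.
#' @export
detectionBreadth <- function(pax, minReplicates = 1) {
  hits <- detectionByBin(pax) >= minReplicates
  setNames(as.integer(rowSums(hits)), rownames(hits))
}

# proteins x ZT-bins matrix of per-bin detection counts
detectionByBin <- function(pax) {
  det <- detectedMask(pax)
  zt <- sampleZT(pax)
  bins <- sort(unique(zt))
  perBinApply(det, zt, bins, rowSums)
}

# apply f over the columns of each ZT bin; always returns a matrix even for
# a single-protein input
perBinApply <- function(mat, zt, bins, f) {
  out <- vapply(bins, function(b) f(mat[, zt == b, drop = FALSE]),
                numeric(nrow(mat)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(mat))
  dimnames(out) <- list(rownames(mat), as.character(bins))
  out
}

#' Abundance distributions segmented by detection breadth
#'
#' Per-protein mean transformed abundance is computed over detected samples
#' only (time points where a protein was not detected do not enter its
#' average), then grouped by the number of ZT bins at which the protein was
#' detected. Empty breadth groups are omitted.
#'
#' @inheritParams perZtDetection
#' @param breadth optional precomputed [detectionBreadth()] result.
#' @return data.frame with `k` (breadth), `n` (proteins in the group),
#'   `median_abundance`, and a list-column `means` of the per-protein mean
#'   abundances.
#' @export
abundanceByBreadth <- function(pax, breadth = detectionBreadth(pax)) {
  ab <- abundanceMatrix(pax)
  det <- detectedMask(pax)
  means <- rowSums(ab * det) / rowSums(det)
  keep <- breadth[rownames(ab)] > 0
  df <- data.frame(k = breadth[rownames(ab)][keep], mean = means[keep])
  ks <- sort(unique(df$k))
  data.frame(
    k = ks,
    n = vapply(ks, function(k) sum(df$k == k), integer(1)),
    median_abundance = vapply(ks, function(k) median(df$mean[df$k == k]),
                              numeric(1)),
    means = I(lapply(ks, function(k) unname(df$mean[df$k == k])))
  )
}

#' Histogram of peak-abundance times of day
#'
#' For each protein detected at least once, the peak ZT bin is the bin with
#' the greatest mean detected abundance. Exact ties are resolved to the
#' earliest ZT and flagged.
#'
#' @inheritParams perZtDetection
#' @return list with `counts` (named integer vector per ZT bin), `peak_zt`
#'   (named vector per protein) and `tied` (logical per protein).
#' @export
peakTimeHistogram <- function(pax) {
  ab <- abundanceMatrix(pax)
  det <- detectedMask(pax)
  zt <- sampleZT(pax)
  bins <- sort(unique(zt))
  n_bin <- perBinApply(det, zt, bins, rowSums)
  s_bin <- perBinApply(ab * det, zt, bins, rowSums)
  bin_mean <- ifelse(n_bin > 0, s_bin / n_bin, NA_real_)

  ever <- rowSums(det) > 0
  bm <- bin_mean[ever, , drop = FALSE]
  peak_idx <- apply(bm, 1, function(r) which.max(r))  # earliest max wins ties
  tied <- apply(bm, 1, function(r) sum(r == max(r, na.rm = TRUE), na.rm = TRUE) > 1)
  peak <- bins[peak_idx]
  counts <- setNames(integer(length(bins)), as.character(bins))
  tab <- table(peak)
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts,
       peak_zt = setNames(peak, rownames(bm)),
       tied = setNames(tied, rownames(bm)))
}
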