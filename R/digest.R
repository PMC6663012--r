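#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P, and returns all
#' peptides with up to `maxMissed` internal missed cleavages, filtered to a
#' length window.
#'
#' @param sequence a protein sequence (single string, standard residues).
#' @param maxMissed maximum internal missed cleavages (default 2).
#' @param lengthRange minimum and maximum peptide length retained
#'   (default 6-50 residues).
#' @return character vector of unique peptides.
#' @examples
#' digestTryptic("AAAAAA", lengthRange = c(1, 50))  # no K/R: the chain itself
#' @export
digestTryptic <- function(sequence, maxMissed = 2, lengthRange = c(6, 50)) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  if (n == 0) return(character(0))
  # cleavage after position i: aa[i] in K/R and aa[i+1] != P
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | aa[cut_after + 1] != "P"]
  bounds <- c(0, cut_after, if (n %in% cut_after) NULL else n)
  # fully cleaved fragments are (bounds[i]+1) .. bounds[i+1]
  nf <- length(bounds) - 1
  out <- character(0)
  for (i in seq_len(nf)) {
    for (j in i:min(nf, i + maxMissed)) {
      pep <- substr(sequence, bounds[i] + 1, bounds[j + 1])
      out <- c(out, pep)
    }
  }
  out <- unique(out)
  len <- nchar(out)
  out[len >= lengthRange[1] & len <= lengthRange[2]]
}

#' Isoleucine/leucine equivalence of peptide sequences
#'
#' I and L are isobaric and indistinguishable by standard MS/MS, so sequence
#' comparisons treat them as one symbol.
#'
#' @param a,b peptide sequences.
#' @return logical: equal after mapping both I and L to a common symbol.
#' @examples
#' ilEquiv("PEPTIDE", "PEPTLDE")  # TRUE
#' @export
ilEquiv <- function(a, b) ilCollapseInternal(a) == ilCollapseInternal(b)

#' @rdname ilEquiv
#' @param x character vector of sequences.
#' @return `ilCollapse`: the sequences with I and L replaced by "J".
#' @export
ilCollapse <- function(x) ilCollapseInternal(x)
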