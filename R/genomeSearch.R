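#' Six-frame peptide-to-genome search
#'
#' Translates every scaffold in all three frames on both strands and locates
#' occurrences of each peptide under I/L equivalence, exactly or with up to
#' one amino-acid mismatch. Candidate windows whose translation contains a
#' stop codon are invalid. Coordinates are 0-based half-open on the forward
#' strand; minus-strand hits report forward-strand intervals with
#' `strand = "-"`.
#'
#' @param peptides character vector of peptide sequences.
#' @param scaffoldSeqs a [Biostrings::DNAStringSet].
#' @param maxMismatch 0 (exact) or 1.
#' @param frameTable precomputed [sixFrameTable] (internal reuse).
#' @return data.frame: `peptide`, `scaffold_id`, `start`, `end`, `strand`,
#'   `frame`, `n_mismatches`.
#' @export
sixFrameHits <- function(peptides, scaffoldSeqs, maxMismatch = 0,
                         frameTable = NULL) {
  fr <- if (is.null(frameTable)) sixFrameTable(scaffoldSeqs) else frameTable
  out <- list()
  for (pep in peptides) {
    pat <- ilCollapseInternal(pep)
    m <- nchar(pat)
    if (m > SIXFRAME_MAX_PEPLEN)
      stop("peptide longer than supported maximum (", SIXFRAME_MAX_PEPLEN, ")")
    starts <- if (maxMismatch == 0) {
      g <- gregexpr(pat, fr$big, fixed = TRUE)[[1]]
      if (g[1] == -1) integer(0) else as.integer(g)
    } else {
      IRanges::start(Biostrings::matchPattern(pat, fr$bigAA,
                                              max.mismatch = maxMismatch,
                                              fixed = TRUE))
    }
    for (p in starts) {
      seg <- segmentOfPosition(fr, p, m)
      if (is.na(seg$k)) next                  # spans a segment boundary
      k <- seg$k; a <- seg$a
      window <- substr(fr$aa[k], a, a + m - 1)
      if (grepl("*", window, fixed = TRUE)) next
      nmm <- sum(strsplit(ilCollapseInternal(window), "")[[1]] !=
                 strsplit(pat, "")[[1]])
      if (nmm > maxMismatch) next
      co <- aaToForwardCoords(a, m, fr$frame[k], fr$strand[k], fr$len[k])
      out[[length(out) + 1]] <- data.frame(
        peptide = pep, scaffold_id = fr$scaffold[k],
        start = co[1], end = co[2],
        strand = fr$strand[k], frame = fr$frame[k], n_mismatches = nmm)
    }
  }
  if (length(out) == 0)
    return(data.frame(peptide = character(0), scaffold_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      n_mismatches = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# upper bound on searchable peptide length; the inter-segment separator is
# longer, so no approximate match can bridge two frame translations
SIXFRAME_MAX_PEPLEN <- 60L

# map a position in the concatenated frame string to (segment, aa offset);
# NA if the m-residue window does not fit inside one segment
segmentOfPosition <- function(fr, p, m) {
  k <- findInterval(p, fr$off)
  if (k < 1 || p + m - 1 > fr$off[k] + fr$seglen[k] - 1) return(list(k = NA))
  list(k = k, a = p - fr$off[k] + 1)
}

# table of the six frame translations of each scaffold (vectorized)
sixFrameTable <- function(scaffoldSeqs) {
  n <- length(scaffoldSeqs)
  L <- Biostrings::width(scaffoldSeqs)
  rc <- Biostrings::reverseComplement(scaffoldSeqs)
  scaffold <- character(0); strand <- character(0); frame <- integer(0)
  len <- numeric(0); pieces <- NULL
  for (str in c("+", "-")) {
    src <- if (str == "+") scaffoldSeqs else rc
    for (f in 0:2) {
      w <- ((L - f) %/% 3) * 3
      keep <- w >= 3
      if (!any(keep)) next
      sub <- Biostrings::subseq(src[keep], f + 1, width = w[keep])
      pieces <- c(pieces, list(sub))
      scaffold <- c(scaffold, names(scaffoldSeqs)[keep])
      strand <- c(strand, rep(str, sum(keep)))
      frame <- c(frame, rep(f, sum(keep)))
      len <- c(len, L[keep])
    }
  }
  aa <- as.character(suppressWarnings(
    Biostrings::translate(do.call(c, pieces), if.fuzzy.codon = "solve",
                          no.init.codon = TRUE)))
  # one concatenated I/L-collapsed search string; separator runs of X longer
  # than any searchable peptide prevent cross-segment matches
  sep <- strrep("X", SIXFRAME_MAX_PEPLEN + 1L)
  collapsed <- ilCollapseInternal(aa)
  seglen <- nchar(aa)
  off <- 1L + c(0L, cumsum(seglen + nchar(sep)))[seq_along(aa)]
  big <- paste(collapsed, collapse = sep)
  list(scaffold = scaffold, strand = strand, frame = frame, len = len,
       aa = aa, seglen = seglen, off = off, big = big,
       bigAA = Biostrings::AAString(chartr("*", "X", big)))
}

# AA-position hit -> forward-strand 0-based half-open nt interval
aaToForwardCoords <- function(aaStart, aaLen, frame, strand, scafLen) {
  s0 <- frame + 3 * (aaStart - 1)
  e0 <- s0 + 3 * aaLen
  if (strand == "+") c(s0, e0) else c(scafLen - e0, scafLen - s0)
}

#' Classify missing peptides against a genome into annotation-error classes
#'
#' Searches each peptide against all six reading frames of all scaffolds
#' under I/L equivalence and assigns one class by precedence:
#' `TRANSCRIPT_FRAME_OVERLAP` (perfect full-length hit lying within an
#' annotated transcript but in a different frame or strand than annotated —
#' an overlapping gene model), `SCAFFOLD_HIT` (perfect hit outside any
#' transcript model — an uncalled gene), `WOBBLY_SCAFFOLD` (best hit has
#' exactly one amino-acid mismatch, or is a full-length match at peptide
#' length plus or minus one arising from a 1-nt frameshift — SNP, sequencing
#' error or frameshift), and `NO_HIT` (suspected assembly gap). A perfect
#' hit inside a transcript in its annotated frame indicates the peptide is
#' not actually missing; it is reported as class `"annotated"` with a
#' consistency flag.
#'
#' @param peptides character vector (typically group representatives).
#' @param genome a [GenomeSet-class].
#' @return data.frame: `peptide`, `genome_class`, `subtype` (`substitution`,
#'   `frameshift_insertion`, `frameshift_deletion` or NA), `scaffold_id`,
#'   `start`, `end`, `strand`, `frame`, `n_mismatches`,
#'   `overlaps_transcript`, `same_frame_as_transcript`.
#' @export
classifyAgainstGenome <- function(peptides, genome) {
  stopifnot(is(genome, "GenomeSet"))
  scafs <- scaffolds(genome)
  tr <- transcriptModels(genome)
  if (length(scafs) == 0) {
    warning("empty genome: all peptides classified NO_HIT")
    return(data.frame(peptide = peptides, genome_class = "NO_HIT",
                      subtype = NA_character_, scaffold_id = NA_character_,
                      start = NA_integer_, end = NA_integer_,
                      strand = NA_character_, frame = NA_integer_,
                      n_mismatches = NA_integer_,
                      overlaps_transcript = FALSE,
                      same_frame_as_transcript = FALSE))
  }
  fr <- sixFrameTable(scafs)
  exact <- sixFrameHits(peptides, scafs, maxMismatch = 0, frameTable = fr)
  need_mm <- setdiff(peptides, exact$peptide)
  mm1 <- if (length(need_mm))
    sixFrameHits(need_mm, scafs, maxMismatch = 1, frameTable = fr) else NULL

  rows <- lapply(peptides, function(pep) {
    ex <- exact[exact$peptide == pep, , drop = FALSE]
    if (nrow(ex)) {
      ann <- annotateHits(ex, tr)
      # precedence among perfect hits: frame-overlap > scaffold > annotated
      pick <- which(ann$overlaps_transcript & !ann$same_frame_as_transcript)
      if (length(pick)) return(mkrow(pep, "TRANSCRIPT_FRAME_OVERLAP", NA, ann[pick[1], ]))
      pick <- which(!ann$overlaps_transcript)
      if (length(pick)) return(mkrow(pep, "SCAFFOLD_HIT", NA, ann[pick[1], ]))
      return(mkrow(pep, "annotated", NA, ann[1, ]))
    }
    sub <- mm1[mm1$peptide == pep & mm1$n_mismatches == 1, , drop = FALSE]
    if (nrow(sub)) {
      ann <- annotateHits(sub, tr)
      return(mkrow(pep, "WOBBLY_SCAFFOLD", "substitution", ann[1, ]))
    }
    fs <- frameshiftHits(pep, scafs, frameTable = fr)
    if (nrow(fs)) {
      ann <- annotateHits(fs, tr)
      return(mkrow(pep, "WOBBLY_SCAFFOLD", fs$subtype[1], ann[1, ]))
    }
    mkrow(pep, "NO_HIT", NA, NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

mkrow <- function(pep, cls, subtype, hit) {
  if (is.null(hit))
    return(data.frame(peptide = pep, genome_class = cls,
                      subtype = NA_character_, scaffold_id = NA_character_,
                      start = NA_integer_, end = NA_integer_,
                      strand = NA_character_, frame = NA_integer_,
                      n_mismatches = NA_integer_, overlaps_transcript = FALSE,
                      same_frame_as_transcript = FALSE))
  data.frame(peptide = pep, genome_class = cls,
             subtype = if (is.na(subtype)) NA_character_ else subtype,
             scaffold_id = hit$scaffold_id,
             start = hit$start, end = hit$end, strand = hit$strand,
             frame = hit$frame, n_mismatches = hit$n_mismatches,
             overlaps_transcript = hit$overlaps_transcript,
             same_frame_as_transcript = hit$same_frame_as_transcript)
}

# add transcript-containment and frame-agreement flags to a hit table
annotateHits <- function(hits, transcripts) {
  hits$overlaps_transcript <- FALSE
  hits$same_frame_as_transcript <- FALSE
  if (nrow(transcripts) == 0) return(hits)
  for (i in seq_len(nrow(hits))) {
    cand <- transcripts[transcripts$scaffold_id == hits$scaffold_id[i] &
                        transcripts$start <= hits$start[i] &
                        transcripts$end >= hits$end[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    hits$overlaps_transcript[i] <- TRUE
    same <- vapply(seq_len(nrow(cand)), function(j) {
      if (cand$strand[j] != hits$strand[i]) return(FALSE)
      if (cand$strand[j] == "+")
        (hits$start[i] - (cand$start[j] + cand$frame[j])) %% 3 == 0
      else
        ((cand$end[j] - cand$frame[j]) - hits$end[i]) %% 3 == 0
    }, logical(1))
    hits$same_frame_as_transcript[i] <- any(same)
  }
  hits
}

# full-length matches interrupted by a single 1-nt insertion or deletion:
# prefix peptide[1..j] intact in one frame, suffix intact in a shifted frame.
# Anchored by exact half-peptide matches in the six-frame translations.
frameshiftHits <- function(pep, scaffoldSeqs, frameTable = NULL) {
  m <- nchar(pep)
  h <- m %/% 2
  if (m < 4) return(emptyFsHits())
  H1 <- substr(pep, 1, h)
  H2 <- substr(pep, h + 1, m)
  fr <- if (is.null(frameTable)) sixFrameTable(scaffoldSeqs) else frameTable

  cand <- list()  # (scaffold, strand, windowStart in strand 0-based coords)
  for (half in c(1, 2)) {
    pat <- ilCollapseInternal(if (half == 1) H1 else H2)
    g <- gregexpr(pat, fr$big, fixed = TRUE)[[1]]
    if (g[1] == -1) next
    for (pos in as.integer(g)) {
      seg <- segmentOfPosition(fr, pos, nchar(pat))
      if (is.na(seg$k)) next
      k <- seg$k
      p <- fr$frame[k] + 3 * (seg$a - 1)      # strand 0-based nt of the half
      ws <- if (half == 1) p else c(p - 3 * h - 1, p - 3 * h + 1)
      for (w in ws)
        cand[[length(cand) + 1]] <- list(sc = fr$scaffold[k],
                                         strand = fr$strand[k], w = w)
    }
  }
  if (length(cand) == 0) return(emptyFsHits())
  seen <- character(0)
  out <- list()
  for (cn in cand) {
    key <- paste(cn$sc, cn$strand, cn$w)
    if (key %in% seen) next
    seen <- c(seen, key)
    x <- scaffoldSeqs[[cn$sc]]
    s <- if (cn$strand == "+") x else Biostrings::reverseComplement(x)
    hit <- tryFrameshiftWindow(s, cn$w, pep)
    if (is.null(hit)) next
    L <- length(x)
    co <- if (cn$strand == "+") c(cn$w, cn$w + hit$ntLen)
          else c(L - (cn$w + hit$ntLen), L - cn$w)
    out[[length(out) + 1]] <- data.frame(
      peptide = pep, scaffold_id = cn$sc, start = co[1], end = co[2],
      strand = cn$strand, frame = cn$w %% 3, n_mismatches = 0L,
      subtype = hit$subtype)
  }
  if (length(out) == 0) return(emptyFsHits())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

emptyFsHits <- function() {
  data.frame(peptide = character(0), scaffold_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             frame = integer(0), n_mismatches = integer(0),
             subtype = character(0))
}

# try all split points / indel polarities for a window starting at 0-based
# strand position w; returns ntLen + subtype on success
tryFrameshiftWindow <- function(strandSeq, w, pep) {
  m <- nchar(pep)
  L <- length(strandSeq)
  if (w < 0 || w + 3 * m - 1 > L) return(NULL)
  winLen <- min(3 * m + 1, L - w)
  win <- as.character(Biostrings::subseq(strandSeq, w + 1, width = winLen))
  pj <- ilCollapseInternal(pep)
  transl <- function(nt) {
    if (nchar(nt) == 0) return("")
    ilCollapseInternal(as.character(suppressWarnings(
      Biostrings::translate(Biostrings::DNAString(nt),
                            no.init.codon = TRUE))))
  }
  for (j in seq_len(m - 1)) {
    pre <- substr(win, 1, 3 * j)
    if (transl(pre) != substr(pj, 1, j)) break  # prefix must be intact up to j
    # insertion of 1 nt after codon j: suffix peptide[j+1..m] at 3j+2
    if (winLen >= 3 * m + 1) {
      suf <- substr(win, 3 * j + 2, 3 * m + 1)
      if (transl(suf) == substr(pj, j + 1, m))
        return(list(ntLen = 3 * m + 1, subtype = "frameshift_insertion"))
    }
    # deletion of 1 nt inside codon j+1: suffix peptide[j+2..m] at 3j+3
    if (j <= m - 2 && winLen >= 3 * m - 1) {
      suf <- substr(win, 3 * j + 3, 3 * m - 1)
      if (transl(suf) == substr(pj, j + 2, m))
        return(list(ntLen = 3 * m - 1, subtype = "frameshift_deletion"))
    }
  }
  NULL
}
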