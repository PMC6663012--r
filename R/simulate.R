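#' Simulate a raw protein abundance time course with known rhythmic truth
#'
#' Generates per-sample raw intensities for `nProteins` proteins over a
#' sampling design. A fraction of proteins carries a 24-h cosine rhythm:
#' the true signal is `baseline * (1 + amplitude * cos(2*pi*(zt - phase)/24))`,
#' observed with multiplicative lognormal noise. Each measurement is then
#' independently censored (set to 0 = not detected) with probability given by
#' a decreasing logistic function of the true intensity, emulating the
#' abundance-dependent dropout of data-dependent LC-MS acquisition: low-
#' abundance proteins vanish at some times of day, high-abundance proteins
#' are seen everywhere.
#'
#' @param design a [TimeCourseDesign-class].
#' @param nProteins number of proteins (default 1525, the scale of a typical
#'   mosquito whole-body label-free experiment).
#' @param fracRhythmic fraction of proteins with a planted 24-h rhythm.
#' @param noiseSd standard deviation of the lognormal measurement noise on
#'   the log scale (0 = noise-free).
#' @param dropout either `NULL` (no dropout) or
#'   `list(midpoint =, scale =)`: the probability of non-detection is
#'   `plogis((log(midpoint) - log(true)) / scale)`, i.e. 50% at the midpoint
#'   intensity and decreasing with abundance. `midpoint = NA` uses the median
#'   simulated baseline.
#' @param amplitudeRange range of relative rhythm amplitudes (uniform draw).
#' @param baselineMeanlog,baselineSdlog lognormal parameters of per-protein
#'   baseline intensity.
#' @param phaseGrid candidate peak phases (ZT hours); default the 2-h grid.
#' @param seed integer seed; the generator is fully deterministic given its
#'   arguments and seed.
#' @return list with `raw` (proteins x samples matrix of raw intensities, 0
#'   where not detected) and `truth` (data.frame: `protein_id`,
#'   `is_rhythmic`, `phase_zt`, `amplitude`, `baseline`).
#' @export
simulateAbundance <- function(design,
                              nProteins = 1525,
                              fracRhythmic = 0.2,
                              noiseSd = 0.25,
                              dropout = list(midpoint = NA, scale = 1),
                              amplitudeRange = c(0.3, 0.8),
                              baselineMeanlog = log(5e5),
                              baselineSdlog = 1.5,
                              phaseGrid = seq(0, 22, by = 2),
                              seed = 1L) {
  stopifnot_scalar_prob(fracRhythmic, "fracRhythmic")
  if (!is.finite(noiseSd) || noiseSd < 0) stop("'noiseSd' must be finite and >= 0")
  if (!is.finite(nProteins) || nProteins < 1) stop("'nProteins' must be >= 1")
  if (!is.null(dropout) &&
      (!is.list(dropout) || !all(c("midpoint", "scale") %in% names(dropout)) ||
       !is.finite(dropout$scale)))
    stop("'dropout' must be NULL or list(midpoint=, scale=) with finite scale")

  s <- designSamples(design)
  n <- as.integer(nProteins)
  withSeed(seed, {
    nR <- round(fracRhythmic * n)
    is_rhythmic <- c(rep(TRUE, nR), rep(FALSE, n - nR))
    baseline  <- rlnorm(n, baselineMeanlog, baselineSdlog)
    amplitude <- ifelse(is_rhythmic,
                        runif(n, amplitudeRange[1], amplitudeRange[2]), 0)
    phase     <- ifelse(is_rhythmic, sample(phaseGrid, n, replace = TRUE), NA_real_)

    zt <- s$zt
    true_signal <- baseline * (1 + outer(amplitude,
      rep(1, length(zt))) * cos(2 * pi * (outer(rep(1, n), zt) -
      outer(ifelse(is.na(phase), 0, phase), rep(1, length(zt)))) / 24))
    noise <- if (noiseSd > 0)
      matrix(exp(rnorm(n * length(zt), 0, noiseSd)), n) else 1
    raw <- true_signal * noise

    if (!is.null(dropout)) {
      mid <- dropout$midpoint
      if (is.null(mid) || is.na(mid)) mid <- median(baseline)
      p_drop <- plogis((log(mid) - log(true_signal)) / dropout$scale)
      raw[matrix(runif(n * length(zt)), n) < p_drop] <- 0
    }

    pid <- sprintf("P%04d", seq_len(n))
    dimnames(raw) <- list(pid, s$sample_id)
    list(
      raw = raw,
      truth = data.frame(
        protein_id = pid,
        is_rhythmic = is_rhythmic,
        phase_zt = phase,
        amplitude = amplitude,
        baseline = baseline
      )
    )
  })
}

#' Expand simulated protein intensities into peptide-level feature records
#'
#' Splits each protein's per-sample raw intensity across a random number of
#' distinct tryptic-like peptides with fixed per-protein proportions, so the
#' quantitation stage (sum of unique peptide intensities per protein) can
#' reconstruct the simulated protein signal. Each peptide yields one
#' feature per sample, carrying `nSpectra` spectrum intensities that sum to
#' the feature's total. A configurable fraction of contaminating charge-1
#' features is added to exercise the charge filter.
#'
#' @param design a [TimeCourseDesign-class].
#' @param raw proteins x samples raw intensity matrix from
#'   [simulateAbundance()].
#' @param peptidesPerProtein range (min, max) of distinct peptides per
#'   protein; default 2 to 6 so every protein is quantifiable.
#' @param nSpectra spectra per feature (default 3).
#' @param fracCharge1 fraction of additional charge-1 decoy features.
#' @param seed integer seed.
#' @return data.frame with `feature_id`, `peptide`, `protein_id`, `charge`,
#'   `sample_id`, `intensity` (one row per spectrum).
#' @export
simulateFeatures <- function(design, raw,
                             peptidesPerProtein = c(2, 6),
                             nSpectra = 3,
                             fracCharge1 = 0.02,
                             seed = 1L) {
  s <- designSamples(design)
  stopifnot(identical(colnames(raw), s$sample_id))
  n <- nrow(raw)
  withSeed(seed, {
    k <- sample(peptidesPerProtein[1]:peptidesPerProtein[2], n, replace = TRUE)
    peps <- randomTrypticPeptides(sum(k))
    prot_of_pep <- rep(seq_len(n), k)
    # fixed per-protein peptide share (Dirichlet via gamma)
    share <- rgamma(sum(k), shape = 2)
    share <- share / ave(share, prot_of_pep, FUN = sum)
    charge <- sample(2:4, sum(k), replace = TRUE)

    ns <- nrow(s)
    pep_idx <- rep(seq_along(peps), each = ns)
    samp_idx <- rep(seq_len(ns), times = length(peps))
    total <- raw[cbind(prot_of_pep[pep_idx], samp_idx)] * share[pep_idx]

    feat <- data.frame(
      feature_id = sprintf("F%05d_%s", pep_idx, s$sample_id[samp_idx]),
      peptide    = peps[pep_idx],
      protein_id = rownames(raw)[prot_of_pep[pep_idx]],
      charge     = charge[pep_idx],
      sample_id  = s$sample_id[samp_idx],
      total      = total
    )
    feat <- feat[feat$total > 0, , drop = FALSE]

    # split feature total into spectrum intensities
    w <- matrix(rgamma(nrow(feat) * nSpectra, shape = 5), ncol = nSpectra)
    w <- w / rowSums(w)
    out <- feat[rep(seq_len(nrow(feat)), each = nSpectra),
                c("feature_id", "peptide", "protein_id", "charge", "sample_id")]
    out$intensity <- as.vector(t(w * feat$total))

    # contaminating singly-charged features, removed by the charge filter
    n1 <- ceiling(fracCharge1 * nrow(feat))
    if (n1 > 0) {
      pick <- sample(nrow(feat), n1, replace = TRUE)
      dec <- feat[pick, c("peptide", "protein_id", "sample_id")]
      dec$feature_id <- sprintf("F1ch%04d_%s", seq_len(n1), dec$sample_id)
      dec$charge <- 1L
      dec$intensity <- rlnorm(n1, log(1e4), 1)
      out <- rbind(out, dec[, names(out)])
    }
    rownames(out) <- NULL
    out
  })
}

# Random tryptic-like peptides (end in K/R, no internal K/R, no P after the
# would-be cleavage site), unique as a set.
randomTrypticPeptides <- function(n, lengthRange = c(8, 15)) {
  inner <- setdiff(AA_STANDARD20, c("K", "R"))
  out <- character(0)
  stopifnot(lengthRange[1] >= 4)
  while (length(out) < n) {
    m <- n - length(out)
    lens <- lengthRange[1]:lengthRange[2]
    len <- lens[sample.int(length(lens), m, replace = TRUE)]
    body <- vapply(len, function(l) {
      first <- sample(setdiff(inner, "P"), 1)  # no P right after upstream K/R
      paste0(first,
             paste(sample(inner, l - 2, replace = TRUE), collapse = ""),
             sample(c("K", "R"), 1))
    }, character(1))
    out <- unique(c(out, body))
  }
  out[seq_len(n)]
}
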