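#' Exact null distribution of the tied-reference Kendall S statistic
#'
#' Under the null that the data are exchangeable continuous values, the
#' concordance count of a series against a tied cosine reference is a
#' Jonckheere-Terpstra statistic over the reference tie groups, whose exact
#' distribution is the convolution of independent Mann-Whitney null
#' distributions: for groups of sizes `t_1..t_g`, `JT = sum_i U(t_i, T_i)`
#' with `T_i = t_{i+1} + ... + t_g`. The S statistic (concordant minus
#' discordant pairs) is `2*JT - P` where `P` is the number of reference-
#' untied pairs. Beyond `exactLimit` observations a normal approximation
#' with continuity correction and the tie-corrected variance is used.
#'
#' @param tieStructure integer vector of reference tie-group sizes (replicate
#'   multiplicities), e.g. `rep(5, 6)` for six time points with five
#'   replicates.
#' @param exactLimit maximum series length for the exact convolution
#'   (default 60).
#' @return an object of class `JtkNull`: list with `n`, `tie_structure`,
#'   `max_s` (the number of reference-untied pairs), and either `S`/`pmf`
#'   (exact support and probabilities, symmetric about 0 and summing to 1)
#'   or `sd` for the normal approximation (`exact = FALSE`).
#' @export
jtkNull <- function(tieStructure, exactLimit = 60) {
  t <- as.integer(tieStructure)
  stopifnot(all(t >= 1))
  n <- sum(t)
  P <- (n^2 - sum(t^2)) / 2L
  if (n <= exactLimit) {
    pmf <- 1  # pmf of JT over support 0..P, built by convolution
    Tn <- n
    for (ti in t[-length(t)]) {
      Tn <- Tn - ti
      pmf <- convolveFree(pmf, mwNullPmf(ti, Tn))
    }
    stopifnot(length(pmf) == P + 1)
    structure(list(n = n, tie_structure = t, max_s = P, exact = TRUE,
                   S = 2 * (0:P) - P, pmf = pmf),
              class = "JtkNull")
  } else {
    v <- (n^2 * (2 * n + 3) - sum(t^2 * (2 * t + 3))) / 72
    structure(list(n = n, tie_structure = t, max_s = P, exact = FALSE,
                   sd = 2 * sqrt(v)),
              class = "JtkNull")
  }
}

#' @export
print.JtkNull <- function(x, ...) {
  cat(sprintf("JtkNull: n=%d, tie structure {%s}, S in [-%d, %d], %s\n",
              x$n, paste(x$tie_structure, collapse = ","), x$max_s, x$max_s,
              if (x$exact) "exact convolution" else "normal approximation"))
  invisible(x)
}

# Null pmf of the Mann-Whitney U count for samples of sizes m and n.
# Counts A(u; m, n) satisfy A(u; m, n) = A(u; m, n-1) + A(u - n; m-1, n):
# condition on whether the overall largest value is in the second or first
# sample (if in the first, it beats all n of the second).
mwNullPmf <- function(m, n) {
  # V[[m'+1]] holds the count vector for U(m', n') over 0..m'*n'
  V <- lapply(0:m, function(mm) 1)           # n' = 0 column: point mass at 0
  for (nn in seq_len(n)) {
    Vnew <- vector("list", m + 1)
    Vnew[[1]] <- 1
    for (mm in seq_len(m)) {
      len <- mm * nn + 1
      a <- numeric(len)
      old <- V[[mm + 1]]                      # (mm, nn-1), support 0..mm*(nn-1)
      a[seq_along(old)] <- old
      shifted <- Vnew[[mm]]                   # (mm-1, nn), shifted by nn
      a[nn + seq_along(shifted)] <- a[nn + seq_along(shifted)] + shifted
      Vnew[[mm + 1]] <- a
    }
    V <- Vnew
  }
  V[[m + 1]] / choose(m + n, m)
}

# open (full) convolution of two pmfs supported on 0..len-1
convolveFree <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  }
  out
}

#' Two-sided exact tail probability of a JTK S statistic
#'
#' @param null a `JtkNull` from [jtkNull()].
#' @param S observed S.
#' @return `P(|S*| >= |S|)` under the null.
#' @export
jtkTailP <- function(null, S) {
  s <- abs(S)
  if (null$exact) {
    p <- sum(null$pmf[abs(null$S) >= s])
  } else {
    if (s == 0) return(1)
    p <- 2 * pnorm(-(s - 1) / null$sd)
  }
  min(1, max(p, .Machine$double.xmin))
}

#' Phased cosine reference ordering for JTK
#'
#' The reference value at time `t` is `cos(2*pi*(t - lag)/period)`;
#' replicates collected at the same time point (and time points whose cosine
#' values coincide) share a reference rank, forming the tie structure of the
#' null.
#'
#' @param timepoints collection times in hours, one per observation
#'   (replicates repeat their time).
#' @param lag reference phase in hours (peak position of the cosine).
#' @param period rhythm period in hours (default 24).
#' @return list with `values` (reference value per observation), `ranks`
#'   (tied ranks) and `tie_structure` (group sizes in reference order).
#' @export
jtkReference <- function(timepoints, lag, period = 24) {
  v <- round(cos(2 * pi * (timepoints - lag) / period), 9)
  r <- rank(v)
  list(values = v, ranks = r, tie_structure = as.integer(table(v)))
}

#' Tied-reference Kendall S statistic
#'
#' Sum over all observation pairs with distinct reference values of the sign
#' agreement between data differences and reference differences; pairs tied
#' in the data contribute zero.
#'
#' @param series numeric observations.
#' @param reference reference values (same length), typically
#'   `jtkReference(...)$values`.
#' @return integer S (concordant minus discordant pairs).
#' @export
jtkStatistic <- function(series, reference) {
  stopifnot(length(series) == length(reference))
  n <- length(series)
  if (n < 2) return(0L)
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- sequence((n - 1):1) + i
  as.integer(sum(sign(series[i] - series[j]) * sign(reference[i] - reference[j])))
}

#' JTK_CYCLE rhythmicity test for one series
#'
#' Scans a grid of phase lags; at each lag, the series is scored against the
#' phased cosine reference ordering with the tied-reference Kendall S
#' statistic and the two-sided exact tail probability `P(|S*| >= |S|)` is
#' computed from the convolution null. The reported p-value is the minimum
#' over lags multiplied by the number of distinct reference orderings
#' (Bonferroni; a reference and its reversal count once since they give
#' identical two-sided tails), capped at 1. The estimated phase is the lag
#' attaining the minimum (ties: largest S, then earliest lag); `tau` is
#' `S / max_S` at that lag.
#'
#' @param series numeric observations (a protein's abundance series).
#' @param timepoints collection times in hours (e.g. ZT), same length.
#' @param period rhythm period in hours (default 24).
#' @param lagStep phase-grid step in hours (default 2, so estimated phases
#'   lie on \{0, 2, ..., period-2\}).
#' @param exactLimit see [jtkNull()].
#' @param nullCache optional environment memoizing nulls across calls.
#' @return list with `jtk_p`, `phase_zt` (NA for a constant series), `tau`,
#'   `n_orderings`, and `per_lag` (data.frame of lag, S, max_s, p).
#' @export
jtkCycle <- function(series, timepoints, period = 24, lagStep = 2,
                     exactLimit = 60, nullCache = NULL) {
  stopifnot(length(series) == length(timepoints))
  lags <- seq(0, period - lagStep, by = lagStep)
  if (is.null(nullCache)) nullCache <- new.env(parent = emptyenv())

  per_lag <- lapply(lags, function(lag) {
    ref <- jtkReference(timepoints, lag, period)
    key <- paste(sort(ref$tie_structure), collapse = ",")
    null <- get0(key, envir = nullCache)
    if (is.null(null)) {
      null <- jtkNull(ref$tie_structure, exactLimit)
      assign(key, null, envir = nullCache)
    }
    S <- jtkStatistic(series, ref$values)
    list(lag = lag, S = S, max_s = null$max_s,
         p = jtkTailP(null, S), ranks = ref$ranks)
  })

  # distinct reference orderings, a reversal pair counting once
  keys <- vapply(per_lag, function(x) {
    a <- paste(x$ranks, collapse = ",")
    b <- paste(length(x$ranks) + 1 - x$ranks, collapse = ",")
    if (a < b) a else b
  }, character(1))
  n_orderings <- length(unique(keys))

  p_lag <- vapply(per_lag, `[[`, numeric(1), "p")
  S_lag <- vapply(per_lag, `[[`, numeric(1), "S")
  max_s <- vapply(per_lag, `[[`, numeric(1), "max_s")

  p_min <- min(p_lag)
  jtk_p <- min(1, n_orderings * p_min)

  if (all(S_lag == 0)) {        # constant (or fully tied) series
    phase <- NA_real_; tau <- 0
  } else {
    cand <- which(p_lag == p_min)
    cand <- cand[S_lag[cand] == max(S_lag[cand])]
    best <- cand[1]
    phase <- lags[best]
    tau <- S_lag[best] / max_s[best]
  }
  list(jtk_p = jtk_p, phase_zt = phase, tau = tau,
       n_orderings = n_orderings,
       per_lag = data.frame(lag = lags, S = S_lag, max_s = max_s, p = p_lag))
}

#' One-way ANOVA prefilter for time-of-day differences
#'
#' Restricts to proteins detected at every ZT bin (with at least `minReps`
#' detected replicates per bin and, optionally, at least
#' `minPeptidesPerSample` distinct peptides behind every detected sample),
#' then computes the fixed-effects one-way F test of transformed abundance
#' across ZT bins, using detected values only. Proteins with zero
#' within-group variance everywhere are degenerate and excluded with a
#' logged reason.
#'
#' @param pax a [ProteinAbundanceExperiment-class].
#' @param alpha retention threshold on the ANOVA p-value (default 0.1).
#' @param minReps detected replicates required per ZT bin (default 2).
#' @param minPeptidesPerSample per-sample distinct-peptide requirement
#'   applied where the `n_peptides_sample` assay is available (default 0 =
#'   off).
#' @return data.frame with `protein_id`, `anova_p`, `eligible`, `retained`,
#'   `reason` (for excluded/degenerate proteins).
#' @export
anovaPrefilter <- function(pax, alpha = 0.1, minReps = 2,
                           minPeptidesPerSample = 0) {
  ab <- abundanceMatrix(pax)
  det <- detectedMask(pax)
  if (minPeptidesPerSample > 0 &&
      "n_peptides_sample" %in% names(SummarizedExperiment::assays(pax))) {
    nps <- SummarizedExperiment::assay(pax, "n_peptides_sample")
    det <- det & (nps >= minPeptidesPerSample)
  }
  zt <- sampleZT(pax)
  bins <- sort(unique(zt))
  k <- length(bins)

  per_bin_n <- perBinApply(det, zt, bins, rowSums)
  eligible <- rowSums(per_bin_n >= minReps) == k

  # vectorized one-way ANOVA over detected values, ZT bin as the factor
  N  <- rowSums(det)
  gs <- perBinApply(ab * det, zt, bins, rowSums)
  tot_ss <- rowSums(ab^2 * det)
  grand  <- rowSums(gs)
  ssb <- rowSums(gs^2 / pmax(per_bin_n, 1)) - grand^2 / N
  ssw <- tot_ss - rowSums(gs^2 / pmax(per_bin_n, 1))
  Fst <- (ssb / (k - 1)) / (ssw / (N - k))
  Fst[!eligible] <- NA_real_
  p <- pf(Fst, k - 1, pmax(N - k, 1), lower.tail = FALSE)
  # zero within-group variance with real between-group signal is a perfect
  # time-of-day effect (F = Inf, p = 0); degenerate means no variance at all
  tol <- .Machine$double.eps * pmax(tot_ss, 1)
  p[eligible & ssw <= tol & ssb > tol] <- 0
  degenerate <- eligible & ssw <= tol & ssb <= tol
  p[!eligible | degenerate] <- NA_real_
  reason <- rep(NA_character_, nrow(ab))
  reason[!eligible] <- "not detected at all ZT bins"
  reason[degenerate] <- "zero within-group variance"
  data.frame(
    protein_id = rownames(ab),
    anova_p = p,
    eligible = eligible & !degenerate,
    retained = !is.na(p) & p < alpha,
    reason = reason,
    row.names = NULL
  )
}

#' Run JTK_CYCLE over the ANOVA-passing proteins and call the rhythmic set
#'
#' @param pax a [ProteinAbundanceExperiment-class].
#' @param prefilter result of [anovaPrefilter()]; computed with defaults if
#'   missing.
#' @param alphaJtk rhythmicity threshold on the (lag-Bonferroni) JTK p-value
#'   (default 0.1).
#' @param period,lagStep,exactLimit passed to [jtkCycle()].
#' @return data.frame with one row per tested protein: `protein_id`,
#'   `anova_p`, `jtk_p`, `q_value` (Benjamini-Hochberg across tested
#'   proteins), `phase_zt`, `tau`, `rhythmic`.
#' @export
rhythmAnalysis <- function(pax, prefilter = anovaPrefilter(pax),
                           alphaJtk = 0.1, period = 24, lagStep = 2,
                           exactLimit = 60) {
  tested <- prefilter$protein_id[prefilter$retained]
  ab <- abundanceMatrix(pax)
  det <- detectedMask(pax)
  zt <- sampleZT(pax)
  cache <- new.env(parent = emptyenv())
  rows <- lapply(tested, function(p) {
    use <- det[p, ]
    r <- jtkCycle(ab[p, use], zt[use], period = period, lagStep = lagStep,
                  exactLimit = exactLimit, nullCache = cache)
    data.frame(protein_id = p,
               anova_p = prefilter$anova_p[prefilter$protein_id == p],
               jtk_p = r$jtk_p, phase_zt = r$phase_zt, tau = r$tau)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(0), anova_p = numeric(0),
               jtk_p = numeric(0), phase_zt = numeric(0), tau = numeric(0))
  callRhythmic(out, alphaJtk = alphaJtk)
}

#' Call the rhythmic set and attach BH q-values
#'
#' A protein is called rhythmic when its JTK p-value is below `alphaJtk`;
#' q-values are Benjamini-Hochberg adjusted across the tested set.
#'
#' @param results data.frame with at least `protein_id` and `jtk_p`.
#' @param alphaJtk threshold (default 0.1).
#' @return `results` with added `q_value` and `rhythmic` columns.
#' @export
callRhythmic <- function(results, alphaJtk = 0.1) {
  stopifnot_scalar_prob(alphaJtk, "alphaJtk")
  if (nrow(results) == 0) {
    results$q_value <- numeric(0); results$rhythmic <- logical(0)
    return(results)
  }
  results$q_value <- p.adjust(results$jtk_p, method = "BH")
  results$rhythmic <- results$jtk_p < alphaJtk
  results
}
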