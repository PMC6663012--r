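mkFeatures <- function(...) {
  df <- data.frame(...)
  names(df) <- c("feature_id", "peptide", "protein_id", "charge",
                 "sample_id", "intensity")[seq_along(df)]
  df
}

test_that("charge filter keeps 2+/3+/4+ and top-5 truncation keeps largest", {
  f <- mkFeatures(
    feature_id = c("a", "b", rep("c", 7)),
    peptide = "PEPTIDEK", protein_id = "P1",
    charge = c(1, 5, rep(3, 7)),
    sample_id = "s1",
    intensity = c(10, 10, 7:1))
  out <- filterFeatures(f)
  expect_false(any(out$charge %in% c(1, 5)))
  cc <- out[out$feature_id == "c", ]
  expect_equal(nrow(cc), 5)
  expect_setequal(cc$intensity, 7:3)          # the five most intense spectra
  expect_equal(nrow(filterFeatures(f[0, ])), 0)
})

test_that("median normalization equalizes sample medians and is idempotent", {
  set.seed(42)
  n_feat <- 40
  samples <- sprintf("s%02d", 1:50)
  offs <- rlnorm(50, 0, 0.8)                  # per-sample scale offsets
  f <- do.call(rbind, lapply(seq_along(samples), function(si)
    mkFeatures(feature_id = sprintf("f%02d_%s", 1:n_feat, samples[si]),
               peptide = sprintf("PEP%02dK", 1:n_feat),
               protein_id = "P1", charge = 2, sample_id = samples[si],
               intensity = rlnorm(n_feat, log(1e5), 1) * offs[si])))
  out <- normalizeFeatures(f)
  med <- tapply(out$intensity, out$sample_id, median)
  expect_lt(sd(med) / mean(med), 1e-12)       # between-sample median CV -> 0
  # grand scale preserved: target is the median of input per-sample medians
  med_in <- tapply(f$intensity, f$sample_id, median)
  expect_equal(unname(med[1]), median(med_in))
  # idempotent
  out2 <- normalizeFeatures(out)
  expect_equal(out2$intensity, out$intensity, tolerance = 1e-12)
})

test_that("all-zero samples are flagged and left unscaled", {
  f <- mkFeatures(feature_id = c("f1", "f2"), peptide = c("AAK", "CCK"),
                  protein_id = "P1", charge = 2,
                  sample_id = c("s1", "s2"), intensity = c(100, 0))
  expect_warning(out <- normalizeFeatures(f), "unscaled")
  expect_equal(out$intensity[out$sample_id == "s2"], 0)
})

test_that("protein abundance sums unique peptides then applies arcsinh", {
  d <- makeTimeCourseDesign(1, 24, 4)
  sid <- designSamples(d)$sample_id
  f <- do.call(rbind, lapply(sid, function(s) mkFeatures(
    feature_id = paste0(c("f1", "f2", "f3", "f4", "f5"), "_", s),
    peptide = c("AAAK", "CCCK", "DDDK", "EEEK", "SHAREDK"),
    protein_id = c("P1", "P1", "P2", "P3", "P1"),
    charge = 2, sample_id = s, intensity = c(1, 10, 100, 5, 1000))))
  # SHAREDK also maps to P2 -> excluded from sums as non-unique
  f2 <- f[f$peptide == "SHAREDK", ]
  f2$protein_id <- "P2"
  pax <- proteinAbundance(rbind(f, f2), d, minPeptides = 2)
  # P2 has peptides DDDK + SHAREDK, but SHAREDK is shared -> 1 unique -> out
  # P3 has a single peptide -> excluded
  expect_equal(rownames(pax), "P1")
  # P1 = arcsinh(1 + 10); matches log(x + sqrt(x^2+1)) evaluated directly
  x <- 11
  expect_equal(unname(abundanceMatrix(pax)[1, 1]), log(x + sqrt(x^2 + 1)))
})

test_that("arcsinh values match the closed form and transform order matters", {
  x <- c(1, 10, 100)
  expect_equal(asinh(x), log(x + sqrt(x^2 + 1)), tolerance = 1e-14)
  # strictly monotone; and sum-then-transform != transform-then-sum
  expect_true(all(diff(asinh(x)) > 0))
  expect_false(isTRUE(all.equal(asinh(sum(x)), sum(asinh(x)))))
})

test_that("zero raw sums are kept as undetected zeros, never imputed", {
  d <- makeTimeCourseDesign(1, 24, 4)
  sid <- designSamples(d)$sample_id
  f <- mkFeatures(feature_id = c("f1", "f2"), peptide = c("AAAK", "CCCK"),
                  protein_id = "P1", charge = 2, sample_id = sid[1],
                  intensity = c(5, 5))
  pax <- proteinAbundance(f, d)
  expect_equal(unname(abundanceMatrix(pax)[1, sid[2]]), 0)
  expect_false(detectedMask(pax)[1, sid[2]])
  expect_true(detectedMask(pax)[1, sid[1]])
  expect_true(validObject(pax))
})

test_that("target-decoy FDR reproduces printed values and is scale-free", {
  expect_equal(computeFdr(11867, 160)$fdr_percent, 1.35)
  expect_equal(computeFdr(13300, 248)$fdr_percent, 1.86)
  expect_equal(computeFdr(5000, 0)$fdr_percent, 0)
  expect_equal(computeFdr(2 * 11867, 2 * 160)$fdr_percent,
               computeFdr(11867, 160)$fdr_percent)
  expect_error(computeFdr(0, 5), "nTarget")
})
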