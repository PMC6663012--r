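#' Build a staggered time-course sampling design
#'
#' Constructs the collection schedule of one or more time courses sampled at
#' a fixed interval. Courses start at configurable zeitgeber times so that
#' pooling across courses yields balanced replication per ZT bin: the default
#' three courses of 44, 36 and 28 h starting at ZT0, ZT0 and ZT16 give 30
#' samples and exactly five biological replicates at each of the six 4-h ZT
#' bins (0, 4, 8, 12, 16, 20).
#'
#' @param nCourses number of courses.
#' @param durations course durations in hours (length `nCourses`); each must
#'   be at least 24 h (otherwise a course cannot cover every ZT bin) and a
#'   multiple of `interval`.
#' @param interval sampling interval in hours (default 4).
#' @param starts ZT of the first collection of each course. Default
#'   `c(0, 0, 16)` for the three-course default; otherwise ZT0 for all.
#' @param lightsOn,lightsOff ZT of lights-on/-off (12:12 LD).
#' @param poolSize animals pooled per sample (default 10).
#' @return a [TimeCourseDesign-class]. Samples are collected at elapsed times
#'   `0, interval, ..., duration`, so a course of duration `d` contributes
#'   `d/interval + 1` samples; `zt = (start + elapsed) mod 24`.
#' @examples
#' d <- makeTimeCourseDesign()
#' table(designSamples(d)$zt)  # five replicates per ZT bin
#' @export
makeTimeCourseDesign <- function(nCourses = 3,
                                 durations = c(44, 36, 28),
                                 interval = 4,
                                 starts = NULL,
                                 lightsOn = 0, lightsOff = 12,
                                 poolSize = 10) {
  if (length(durations) != nCourses)
    stop("'durations' must have length 'nCourses'")
  if (any(durations < 24))
    stop("course durations must be >= 24 h to cover all ZT bins")
  if (any(durations %% interval != 0))
    stop("course durations must be multiples of 'interval'")
  if (is.null(starts)) {
    starts <- if (nCourses == 3 && identical(as.numeric(durations), c(44, 36, 28)) &&
                  interval == 4) c(0, 0, 16) else rep(0, nCourses)
  }
  if (length(starts) != nCourses) stop("'starts' must have length 'nCourses'")

  rows <- do.call(rbind, lapply(seq_len(nCourses), function(ci) {
    elapsed <- seq(0, durations[ci], by = interval)
    data.frame(
      course  = ci,
      elapsed = elapsed,
      zt      = (starts[ci] + elapsed) %% 24
    )
  }))
  rows$sample_id <- sprintf("C%d_T%02d", rows$course, rows$elapsed)
  rows <- rows[, c("sample_id", "course", "elapsed", "zt")]
  rownames(rows) <- NULL
  new("TimeCourseDesign",
      samples = rows, interval = as.numeric(interval),
      lightsOn = lightsOn, lightsOff = lightsOff,
      poolSize = as.integer(poolSize))
}
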