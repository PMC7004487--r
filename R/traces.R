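#' Baseline-normalized responses from an integrated nerve trace
#'
#' For each scheduled stimulus: the baseline `B` is the mean of the signal
#' over the `baseline_s` seconds immediately before onset, the raw response
#' `S` is the mean over the stimulus window, and the reported response is
#' the baseline-normalized `R = (S - B) / B`.  Every stimulus must be
#' preceded by at least `baseline_s` seconds of non-stimulus recording, and
#' a non-positive baseline is an error (the normalization is undefined).
#'
#' @param trace a [trace_recording()] of kind `"nerve"`.
#' @param baseline_s pre-stimulus averaging window (s, default 10).
#' @return list of class `response_table` with `responses`: one row per
#'   stimulus (`label`, `baseline`, `raw_mean`, `R`).
#' @export
nerve_response <- function(trace, baseline_s = 10) {
  stopifnot(inherits(trace, "trace_recording"))
  assert_that(trace$kind == "nerve", "trace is not a nerve recording")
  times <- (seq_along(trace$values) - 1) / trace$sampling_rate
  sch <- trace$schedule
  off <- sch$onset + sch$duration
  rows <- lapply(seq_len(nrow(sch)), function(i) {
    on <- sch$onset[i]
    assert_that(on >= baseline_s,
                "stimulus '%s' has less than %g s of recording before onset",
                sch$label[i], baseline_s)
    if (i > 1) {
      assert_that(on - baseline_s >= off[i - 1],
                  "baseline window of '%s' overlaps the previous stimulus",
                  sch$label[i])
    }
    pre <- times >= (on - baseline_s) & times < on
    win <- times >= on & times < off[i]
    B <- mean(trace$values[pre])
    S <- mean(trace$values[win])
    assert_that(B > 0, "baseline for stimulus '%s' is non-positive (%.4g)",
                sch$label[i], B)
    data.frame(label = sch$label[i], baseline = B, raw_mean = S,
               R = (S - B) / B)
  })
  structure(list(responses = do.call(rbind, rows), kind = "nerve",
                 baseline_s = baseline_s),
            class = "response_table")
}

#' Peak responses from a fura-2 ratio trace
#'
#' The baseline `B` is the mean ratio over the first `baseline_s` seconds of
#' the recording (10-15 s).  For each stimulus, a response is "visible" when
#' the ratio exceeds `B + k * SD` of the baseline segment for at least
#' `sustain` consecutive samples -- requiring the exceedance to be sustained
#' keeps an isolated noise spike (the expected maximum of a 30-sample window
#' routinely crosses 3 SD) from counting as a response, which matches what a
#' by-eye call of "visible" means.  For a visible response the peak `P` is
#' the maximum ratio in the stimulus window; in the absence of one the value
#' is taken 30 s after stimulus onset and flagged.  Reported per stimulus:
#' `dR = P - B` and the normalized value `dR / P`.
#'
#' @param trace a [trace_recording()] of kind `"calcium"`.
#' @param baseline_s baseline segment length in seconds (10 to 15).
#' @param k visible-response criterion in baseline SDs (default 3).
#' @param sustain consecutive samples required above the criterion
#'   (default 2).
#' @param fallback_s where to read the value when no response is visible
#'   (s after onset, default 30).
#' @return list of class `response_table` with `responses`: one row per
#'   stimulus (`label`, `baseline`, `peak`, `dR`, `normalized`,
#'   `no_visible_response`).
#' @export
calcium_response <- function(trace, baseline_s = 10, k = 3, sustain = 2L,
                             fallback_s = 30) {
  stopifnot(inherits(trace, "trace_recording"))
  assert_that(trace$kind == "calcium", "trace is not a calcium recording")
  assert_that(baseline_s >= 10 && baseline_s <= 15,
              "baseline_s must lie in [10, 15] s")
  times <- (seq_along(trace$values) - 1) / trace$sampling_rate
  sch <- trace$schedule
  assert_that(sch$onset[1] >= baseline_s,
              "first stimulus begins before the %g s baseline segment ends",
              baseline_s)
  base_sel <- times < baseline_s
  B <- mean(trace$values[base_sel])
  sd_base <- sd(trace$values[base_sel])
  rows <- lapply(seq_len(nrow(sch)), function(i) {
    on <- sch$onset[i]; off <- on + sch$duration[i]
    win <- times >= on & times <= off
    P <- max(trace$values[win])
    above <- (trace$values[win] - B) > k * sd_base
    runs <- rle(above)
    visible <- any(runs$values & runs$lengths >= sustain)
    if (!visible) {
      t_fb <- on + fallback_s
      assert_that(t_fb <= max(times),
                  "recording ends before the %g s fallback point of '%s'",
                  fallback_s, sch$label[i])
      P <- trace$values[which.min(abs(times - t_fb))]
    }
    data.frame(label = sch$label[i], baseline = B, peak = P, dR = P - B,
               normalized = if (P != 0) (P - B) / P else NA_real_,
               no_visible_response = !visible)
  })
  structure(list(responses = do.call(rbind, rows), kind = "calcium",
                 baseline = B, baseline_sd = sd_base, k = k),
            class = "response_table")
}

#' @export
print.response_table <- function(x, ...) {
  cat(sprintf("<response_table> kind '%s'\n", x$kind))
  print(x$responses)
  invisible(x)
}

#' Re-normalize nerve responses to a reference stimulus
#'
#' Optional alternative presentation of nerve responses: each `R` divided by
#' the `R` of a reference stimulus (conventionally NH4Cl), on top of the
#' baseline normalization.
#'
#' @param rt a nerve `response_table`.
#' @param reference reference stimulus label.
#' @return the table with a `R_relative` column added.
#' @export
normalize_to_reference <- function(rt, reference = "NH4Cl") {
  stopifnot(inherits(rt, "response_table"), rt$kind == "nerve")
  ref <- rt$responses$R[rt$responses$label == reference]
  assert_that(length(ref) == 1, "reference stimulus '%s' not found", reference)
  assert_that(ref != 0, "reference response is zero")
  rt$responses$R_relative <- rt$responses$R / ref
  rt
}
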