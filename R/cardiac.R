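#' Select the correlation template frame
#'
#' Computes pairwise Pearson correlations between all frames in an initial
#' window (frames flattened to pixel vectors) and locates the pair with the
#' lowest correlation: these two frames show the heart in opposite extreme
#' states (end-systole vs end-diastole). Within that pair, the frame with
#' the lower mean correlation to the rest of the window — the rarer,
#' systolic extreme, whose contraction phase is brief — is returned as the
#' template, with ties broken toward the earlier frame. A systolic template
#' makes the correlation trace peak sharply at each beat rather than
#' plateauing through diastole.
#'
#' @param stack A `frame_stack`.
#' @param window Number of initial frames to examine (default 100; all
#'   frames are used if the stack is shorter).
#' @return 1-based template frame index.
#' @export
select_template <- function(stack, window = 100L) {
  stopifnot(inherits(stack, "frame_stack"))
  T_n <- dim(stack$frames)[1]
  stopifnot(T_n >= 2)
  w <- min(window, T_n)
  if (w < 2) stop("window must cover at least 2 frames")
  M <- matrix(stack$frames[seq_len(w), , ], nrow = w)  # frames x pixels
  sds <- apply(M, 1, sd)
  if (all(sds == 0)) stop("degenerate recording: all frames constant")
  C <- suppressWarnings(cor(t(M)))
  C[is.na(C)] <- 0  # zero-variance frames correlate as 0 with everything
  diag(C) <- 1
  Cu <- C
  Cu[lower.tri(Cu, diag = TRUE)] <- Inf
  mn <- min(Cu)
  hits <- which(Cu == mn, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  i <- hits[1, 1]; j <- hits[1, 2]
  mean_i <- mean(C[i, -i]); mean_j <- mean(C[j, -j])
  unname(if (mean_j < mean_i - 1e-12) j else i)
}

#' Correlate every frame with the template
#'
#' @param stack A `frame_stack`.
#' @param template_index 1-based frame index from [select_template()].
#' @return Object of class `correlation_trace`: list with `values`
#'   (per-frame Pearson correlation with the template, in `[-1, 1]`),
#'   `template_index`, `frame_interval`.
#' @export
correlation_trace <- function(stack, template_index) {
  stopifnot(inherits(stack, "frame_stack"))
  T_n <- dim(stack$frames)[1]
  stopifnot(template_index >= 1, template_index <= T_n)
  M <- matrix(stack$frames, nrow = T_n)
  tmpl <- M[template_index, ]
  if (sd(tmpl) == 0) stop("degenerate recording: template frame is constant")
  vals <- suppressWarnings(as.vector(cor(tmpl, t(M))))
  if (anyNA(vals)) {
    warning(sum(is.na(vals)), " zero-variance frame(s); correlation set to 0")
    vals[is.na(vals)] <- 0
  }
  structure(list(values = vals, template_index = template_index,
                 frame_interval = stack$frame_interval),
            class = "correlation_trace")
}

#' @export
print.correlation_trace <- function(x, ...) {
  cat("correlation_trace:", length(x$values), "frames, template",
      x$template_index, "\n")
  invisible(x)
}

# centred moving average with edge replication, window w (odd)
smooth_ma <- function(x, w) {
  if (w <= 1) return(x)
  if (w %% 2 == 0) w <- w + 1
  h <- (w - 1) / 2
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.vector(stats::filter(xp, rep(1 / w, w), sides = 2))[(h + 1):(h + length(x))]
}

# topographic prominence of local maxima at indices `peaks` of series x
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    v <- x[p]
    l <- p - 1; lmin <- v
    while (l >= 1 && x[l] <= v) { lmin <- min(lmin, x[l]); l <- l - 1 }
    # at the series boundary only the interior side defines the base
    left_base <- if (l >= 1) lmin else -Inf
    r <- p + 1; rmin <- v
    n <- length(x)
    while (r <= n && x[r] <= v) { rmin <- min(rmin, x[r]); r <- r + 1 }
    right_base <- if (r <= n) rmin else -Inf
    base <- max(left_base, right_base)
    if (!is.finite(base)) base <- min(lmin, rmin)
    v - base
  }, numeric(1))
}

#' Detect beats as peaks of the correlation trace
#'
#' Smooths the trace with a centred moving average, finds local maxima
#' (plateaus contribute their centre), keeps those with topographic
#' prominence at least `prominence_fraction` of the smoothed trace's range
#' and enforces a refractory separation. Retained peaks are then re-timed on
#' a matched-filter version of the trace (moving average scaled to ~15% of
#' the inter-beat interval) with parabolic sub-frame interpolation, which
#' keeps beat timing stable on broad correlation peaks under pixel noise.
#'
#' @param trace A [correlation_trace()].
#' @param min_separation Minimum separation between peaks, seconds
#'   (default 0.15 s, i.e. a maximum credible 400 beats/min).
#' @param prominence_fraction Required prominence as a fraction of the
#'   smoothed trace range (default 0.3).
#' @param smooth_window Moving-average window, frames (default 5).
#' @return Numeric vector of peak times in seconds (possibly length 0 or 1;
#'   downstream stages flag `too_few_beats`).
#' @export
detect_peaks <- function(trace, min_separation = 0.15,
                         prominence_fraction = 0.3, smooth_window = 5L) {
  stopifnot(inherits(trace, "correlation_trace"), length(trace$values) >= 3)
  x <- smooth_ma(trace$values, smooth_window)
  rng <- max(x) - min(x)
  if (rng == 0) return(numeric(0))
  # local maxima with plateau handling: compress runs of equal values
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  is_max <- vapply(seq_len(k), function(i) {
    left_ok <- i == 1 || r$values[i - 1] < r$values[i]
    right_ok <- i == k || r$values[i + 1] < r$values[i]
    left_ok && right_ok && !(i == 1 && i == k)
  }, logical(1))
  cand <- floor((starts[is_max] + ends[is_max]) / 2)
  if (!length(cand)) return(numeric(0))
  prom <- peak_prominence(x, cand)
  cand <- cand[prom >= prominence_fraction * rng]
  prom <- peak_prominence(x, cand)
  if (!length(cand)) return(numeric(0))
  # enforce refractory separation, keeping higher peaks first
  min_sep_frames <- min_separation / trace$frame_interval
  ord <- order(-x[cand], cand)
  keep <- logical(length(cand))
  for (i in ord) {
    if (!any(keep & abs(cand - cand[i]) < min_sep_frames)) keep[i] <- TRUE
  }
  cand <- sort(cand[keep])
  # two-stage timing: peaks are *detected* on the lightly smoothed trace,
  # then *timed* on a matched-filter trace (moving average scaled to ~15%
  # of the inter-beat interval), which suppresses pixel-noise wobble on
  # broad peaks; the vertex of a 3-point parabola gives sub-frame times
  n <- length(x)
  xs <- x
  half_win <- 1L
  if (length(cand) >= 3) {
    ibi_frames <- median(diff(cand))
    w_match <- max(smooth_window, 2 * floor(0.15 * ibi_frames) + 1)
    xs <- smooth_ma(trace$values, w_match)
    half_win <- max(2L, as.integer(round(0.2 * ibi_frames)))
  }
  times <- vapply(cand, function(p) {
    lo <- max(2, p - half_win); hi <- min(n - 1, p + half_win)
    if (lo > hi) { lo <- max(1, p); hi <- min(n, p) }
    pm <- (lo:hi)[which.max(xs[lo:hi])]
    d <- 0
    if (pm > 1 && pm < n) {
      y0 <- xs[pm - 1]; y1 <- xs[pm]; y2 <- xs[pm + 1]
      den <- y0 - 2 * y1 + y2
      if (abs(den) > 1e-12) d <- max(-1, min(1, 0.5 * (y0 - y2) / den))
    }
    (pm - 1 + d) * trace$frame_interval
  }, numeric(1))
  times <- sort(times)
  times[c(TRUE, diff(times) > 0)]
}

#' Classify inter-beat gaps as sinoatrial pauses or arrests
#'
#' The median inter-beat interval (IBI) is computed over all successive
#' peak differences. Any interval longer than 2 s is a sinoatrial arrest;
#' otherwise any interval longer than 3x the median IBI is a sinoatrial
#' pause (arrest takes precedence). Flagged intervals are removed from the
#' normal-to-normal (NN) set; NN intervals are kept in contiguous segments
#' so that successive-difference statistics never span a gap.
#'
#' @param peak_times Strictly increasing beat times, seconds (>= 2 beats).
#' @param frame_interval Seconds per frame (metadata, carried through).
#' @param pause_multiplier Pause threshold as a multiple of the median IBI.
#' @param arrest_seconds Arrest threshold in seconds.
#' @return Object of class `beat_calls`: list with `peak_times`,
#'   `nn_intervals`, `nn_segments` (list of NN runs between gaps),
#'   `gap_events` (data.frame `start_time`, `length`, `class`),
#'   `median_ibi`, `frame_interval`.
#' @export
classify_gaps <- function(peak_times, frame_interval,
                          pause_multiplier = .bc_defaults$pause_multiplier,
                          arrest_seconds = .bc_defaults$arrest_seconds) {
  stopifnot(length(peak_times) >= 2, all(diff(peak_times) > 0))
  ibi <- diff(peak_times)
  med <- median(ibi)
  cls <- ifelse(ibi > arrest_seconds, "arrest",
                ifelse(ibi > pause_multiplier * med, "pause", "nn"))
  gap_idx <- which(cls != "nn")
  gap_events <- data.frame(start_time = peak_times[gap_idx],
                           length = ibi[gap_idx],
                           class = cls[gap_idx], stringsAsFactors = FALSE)
  seg_id <- cumsum(c(0, cls[-length(cls)] != "nn"))
  keep <- cls == "nn"
  nn_segments <- unname(split(ibi[keep], seg_id[keep]))
  structure(list(peak_times = peak_times,
                 nn_intervals = ibi[keep],
                 nn_segments = nn_segments,
                 gap_events = gap_events,
                 median_ibi = med,
                 frame_interval = frame_interval),
            class = "beat_calls")
}

#' @export
print.beat_calls <- function(x, ...) {
  cat("beat_calls:", length(x$peak_times), "beats,",
      length(x$nn_intervals), "NN intervals,",
      nrow(x$gap_events), "gap event(s)\n")
  invisible(x)
}

# population SD
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Heart-rate and HRV metrics from beat calls
#'
#' Heart rate is 60 / mean(NN) in beats/min; SDNN is the population SD of
#' the NN intervals; RMSSD is the root mean square of successive NN
#' differences, where successive pairs never span a removed pause/arrest
#' gap; the composite HRV is the average of SDNN and RMSSD. SDNN and RMSSD
#' are reported in milliseconds.
#'
#' @param calls A [classify_gaps()] result.
#' @param min_beats Minimum beats required for a rate (default 2);
#'   SDNN/RMSSD additionally require >= 3 NN intervals.
#' @return Object of class `cardiac_phenotype`: list with `heart_rate`
#'   (bpm), `sdnn`, `rmssd`, `hrv` (ms), `n_beats`, `has_pause`,
#'   `has_arrest`, `qc_flag`.
#' @export
compute_phenotype <- function(calls, min_beats = 2L) {
  stopifnot(inherits(calls, "beat_calls"))
  n_beats <- length(calls$peak_times)
  has_pause <- any(calls$gap_events$class == "pause")
  has_arrest <- any(calls$gap_events$class == "arrest")
  nn <- calls$nn_intervals
  out <- list(heart_rate = NA_real_, sdnn = NA_real_, rmssd = NA_real_,
              hrv = NA_real_, n_beats = n_beats, has_pause = has_pause,
              has_arrest = has_arrest, qc_flag = "ok",
              sd_convention = "population")
  if (n_beats < min_beats || length(nn) < 1) {
    out$qc_flag <- "too_few_beats"
    return(structure(out, class = "cardiac_phenotype"))
  }
  out$heart_rate <- 60 / mean(nn)
  if (length(nn) >= 3) {
    out$sdnn <- sd_pop(nn) * 1000
    diffs <- unlist(lapply(calls$nn_segments, function(s)
      if (length(s) >= 2) diff(s) else numeric(0)))
    if (length(diffs) >= 1) {
      out$rmssd <- sqrt(mean(diffs^2)) * 1000
      out$hrv <- (out$sdnn + out$rmssd) / 2
    }
  }
  if (is.na(out$sdnn) || is.na(out$rmssd)) out$qc_flag <- "too_few_beats"
  structure(out, class = "cardiac_phenotype")
}

#' @export
print.cardiac_phenotype <- function(x, ...) {
  cat(sprintf(paste0("cardiac_phenotype: %d beats, %.1f bpm, SDNN %.2f ms, ",
                     "RMSSD %.2f ms, HRV %.2f ms [%s]%s%s\n"),
              x$n_beats, x$heart_rate, x$sdnn, x$rmssd, x$hrv, x$qc_flag,
              if (isTRUE(x$has_pause)) " +pause" else "",
              if (isTRUE(x$has_arrest)) " +arrest" else ""))
  invisible(x)
}

#' Flag recordings where true beats were likely missed
#'
#' A missed beat shows up as an interval near twice the typical one. The
#' flag is `suspect_missed_beat` when any non-gap NN interval lies in
#' `(1.7x, 3x]` the median IBI, or when more than 5% of NN intervals
#' exceed 1.7x the median IBI; otherwise `ok`. Pause/arrest gaps are
#' excluded from the NN set before this check.
#'
#' @param calls A [classify_gaps()] result.
#' @param trace Optional [correlation_trace()] (interface symmetry; unused).
#' @return `"ok"` or `"suspect_missed_beat"`.
#' @export
qc_missed_beats <- function(calls, trace = NULL) {
  stopifnot(inherits(calls, "beat_calls"))
  nn <- calls$nn_intervals
  if (!length(nn)) return("ok")
  med <- calls$median_ibi
  in_band <- nn > 1.7 * med & nn <= 3 * med
  frac_long <- mean(nn > 1.7 * med)
  if (any(in_band) || frac_long > 0.05) "suspect_missed_beat" else "ok"
}

#' Quantify a recording end to end
#'
#' Template selection, correlation trace, peak detection, gap
#' classification, phenotype metrics and missed-beat QC in one call.
#'
#' @param stack A `frame_stack`.
#' @param window,min_separation,prominence_fraction,smooth_window Passed to
#'   the respective stages.
#' @param pause_multiplier,arrest_seconds Gap thresholds.
#' @return A `cardiac_phenotype` with attribute `calls` (the `beat_calls`)
#'   and attribute `trace` (the `correlation_trace`).
#' @export
quantify_stack <- function(stack, window = 100L, min_separation = 0.15,
                           prominence_fraction = 0.3, smooth_window = 5L,
                           pause_multiplier = .bc_defaults$pause_multiplier,
                           arrest_seconds = .bc_defaults$arrest_seconds) {
  tmpl <- select_template(stack, window)
  trace <- correlation_trace(stack, tmpl)
  peaks <- detect_peaks(trace, min_separation, prominence_fraction, smooth_window)
  if (length(peaks) < 2) {
    ph <- structure(list(heart_rate = NA_real_, sdnn = NA_real_,
                         rmssd = NA_real_, hrv = NA_real_,
                         n_beats = length(peaks), has_pause = FALSE,
                         has_arrest = FALSE, qc_flag = "too_few_beats",
                         sd_convention = "population"),
                    class = "cardiac_phenotype")
    attr(ph, "trace") <- trace
    return(ph)
  }
  calls <- classify_gaps(peaks, stack$frame_interval,
                         pause_multiplier, arrest_seconds)
  ph <- compute_phenotype(calls)
  if (ph$qc_flag == "ok") ph$qc_flag <- qc_missed_beats(calls, trace)
  attr(ph, "calls") <- calls
  attr(ph, "trace") <- trace
  ph
}
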