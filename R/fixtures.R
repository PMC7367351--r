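#' Recording specification for synthetic atrium fixtures
#'
#' Bundles the parameters of a simulated 30-s recording of the beating
#' atrium: the mean inter-beat (RR) interval, i.i.d. Gaussian jitter on each
#' RR interval, optional gap events (sinoatrial pauses/arrests), pixel noise
#' and frame geometry.
#'
#' @param mean_rr Mean RR interval in seconds (> 0).
#' @param rr_jitter_sd SD in seconds of the i.i.d. Gaussian perturbation
#'   added to each RR interval (>= 0).
#' @param gap_events List of `c(start_beat_index, gap_length_seconds)` pairs;
#'   the RR interval following the 1-based beat index is replaced by the gap.
#' @param duration Recording length in seconds.
#' @param frame_rate Frames per second.
#' @param noise_sd SD of i.i.d. Gaussian pixel noise, in intensity units
#'   (the rendered pulse has amplitude ~1).
#' @param frame_shape Integer `c(height, width)` in pixels.
#' @param seed Integer seed; fixtures are bit-reproducible under it.
#' @return An object of class `recording_spec`.
#' @export
recording_spec <- function(mean_rr = 0.4, rr_jitter_sd = 0, gap_events = list(),
                           duration = 30, frame_rate = 152, noise_sd = 0,
                           frame_shape = c(40L, 40L), seed = 1L) {
  stopifnot(mean_rr > 0, rr_jitter_sd >= 0, duration > 0, frame_rate > 0,
            noise_sd >= 0, length(frame_shape) == 2, all(frame_shape >= 8))
  for (g in gap_events)
    if (length(g) != 2 || g[2] <= 0)
      stop("each gap event must be c(start_beat_index, gap_length_seconds > 0)")
  structure(list(mean_rr = mean_rr, rr_jitter_sd = rr_jitter_sd,
                 gap_events = gap_events, duration = duration,
                 frame_rate = frame_rate, noise_sd = noise_sd,
                 frame_shape = as.integer(frame_shape), seed = as.integer(seed)),
            class = "recording_spec")
}

#' Simulate ground-truth beat times
#'
#' Draws successive RR intervals as `mean_rr + N(0, rr_jitter_sd^2)`,
#' truncated below at `0.1 * mean_rr` so intervals stay physical, then
#' replaces the RR interval after each named beat with the requested gap
#' length. The first beat is at t = 0 and the schedule is truncated at
#' `duration` (beats in `[0, duration)`).
#'
#' @param spec A [recording_spec()].
#' @return Object of class `beat_schedule`: list with `beat_times` (seconds,
#'   strictly increasing), `duration`, `frame_rate`, and `rr_intervals`
#'   (the realised inter-beat intervals, i.e. `diff(beat_times)`).
#' @export
simulate_beat_times <- function(spec) {
  stopifnot(inherits(spec, "recording_spec"))
  set.seed(spec$seed)
  n_draw <- ceiling(spec$duration / spec$mean_rr * 2) + 50
  rr <- spec$mean_rr + rnorm(n_draw, 0, spec$rr_jitter_sd)
  rr <- pmax(rr, 0.1 * spec$mean_rr)
  beats <- c(0, cumsum(rr))
  n_within <- sum(beats < spec$duration)
  for (g in spec$gap_events) {
    idx <- as.integer(g[1])
    if (idx < 1 || idx >= n_within)
      stop("gap start index ", idx, " is beyond the generated beat count (",
           n_within, ")")
    rr[idx] <- g[2]
  }
  beats <- c(0, cumsum(rr))
  beats <- beats[beats < spec$duration]
  structure(list(beat_times = beats, duration = spec$duration,
                 frame_rate = spec$frame_rate, rr_intervals = diff(beats)),
            class = "beat_schedule")
}

#' @export
print.beat_schedule <- function(x, ...) {
  cat("beat_schedule:", length(x$beat_times), "beats over", x$duration,
      "s @", x$frame_rate, "fps; median RR",
      round(median(x$rr_intervals), 4), "s\n")
  invisible(x)
}

#' Render a beating-atrium frame stack
#'
#' Renders each frame as a filled soft-edged ellipse on a dark background.
#' The ellipse radius follows a raised-cosine contraction pulse of width
#' `0.6 * median RR`, centred on each beat time (radius shrinks at systole),
#' with i.i.d. Gaussian pixel noise added. Frame count is
#' `floor(duration * frame_rate)`.
#'
#' @param schedule A [simulate_beat_times()] result.
#' @param spec The [recording_spec()] used to generate `schedule`.
#' @return Object of class `frame_stack`: list with `frames`
#'   (T x H x W numeric array) and `frame_interval` (seconds).
#' @export
render_frame_stack <- function(schedule, spec) {
  stopifnot(inherits(schedule, "beat_schedule"), inherits(spec, "recording_spec"))
  if (abs(schedule$duration - spec$duration) > 1e-9 ||
      abs(schedule$frame_rate - spec$frame_rate) > 1e-9)
    stop("schedule and spec disagree on duration/frame_rate")
  H <- spec$frame_shape[1]; W <- spec$frame_shape[2]
  n_frames <- floor(spec$duration * spec$frame_rate)
  rr_med <- if (length(schedule$rr_intervals)) median(schedule$rr_intervals)
            else spec$mean_rr
  pulse_w <- 0.6 * rr_med

  r0 <- 0.30 * min(H, W)            # diastolic radius scale, px
  depth <- 0.45                      # fractional radius reduction at systole
  ax0 <- 1.20 * r0; by0 <- 0.85 * r0
  if (ax0 + 2 > W / 2 || by0 + 2 > H / 2)
    stop("frame_shape too small to contain the ellipse")

  t_frames <- (seq_len(n_frames) - 1) / spec$frame_rate
  # contraction phase per frame: nearest beat within half a pulse width
  idx <- findInterval(t_frames, schedule$beat_times)
  d_prev <- ifelse(idx >= 1, t_frames - schedule$beat_times[pmax(idx, 1)], Inf)
  d_next <- ifelse(idx < length(schedule$beat_times),
                   schedule$beat_times[pmin(idx + 1, length(schedule$beat_times))] - t_frames,
                   Inf)
  d <- pmin(abs(d_prev), abs(d_next))
  pulse <- ifelse(d <= pulse_w / 2, 0.5 * (1 + cos(2 * pi * d / pulse_w)), 0)

  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  X <- matrix(rep(seq_len(W), each = H), H, W) - cx
  Y <- matrix(rep(seq_len(H), W), H, W) - cy

  set.seed(spec$seed + 1L)  # sub-stream distinct from the RR draw
  frames <- array(0, dim = c(n_frames, H, W))
  edge <- 1.5  # px, soft-edge half-width
  for (k in seq_len(n_frames)) {
    shrink <- 1 - depth * pulse[k]
    ax <- ax0 * shrink; by <- by0 * shrink
    e <- sqrt((X / ax)^2 + (Y / by)^2)
    img <- pmin(1, pmax(0, (1 - e) * min(ax, by) / edge + 0.5))
    img <- 0.08 + 0.9 * img
    if (spec$noise_sd > 0) img <- img + rnorm(H * W, 0, spec$noise_sd)
    frames[k, , ] <- img
  }
  structure(list(frames = frames, frame_interval = 1 / spec$frame_rate),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat("frame_stack:", d[1], "frames of", d[2], "x", d[3], "px @",
      round(1 / x$frame_interval, 2), "fps\n")
  invisible(x)
}

#' Diploid amplicon read-set specification
#'
#' @param target An [amplicon_target()].
#' @param allele_variants List of length <= 2; each element a data.frame with
#'   columns `pos` (1-based anchor), `ref`, `alt` describing the edits carried
#'   by that allele (empty data.frame or NULL = wildtype allele).
#' @param depth Number of reads to simulate (>= 1).
#' @param error_rate Per-base substitution error probability in `[0, 0.05)`.
#' @param seed Integer seed.
#' @return Object of class `diploid_amplicon_spec`.
#' @export
diploid_amplicon_spec <- function(target, allele_variants = list(NULL, NULL),
                                  depth = 100L, error_rate = 0, seed = 1L) {
  stopifnot(inherits(target, "amplicon_target"), depth >= 1,
            error_rate >= 0, error_rate < 0.05, length(allele_variants) <= 2)
  while (length(allele_variants) < 2) allele_variants <- c(allele_variants, list(NULL))
  for (av in allele_variants) {
    if (is.null(av) || nrow(av) == 0) next
    stopifnot(all(c("pos", "ref", "alt") %in% names(av)))
    if (any(av$pos < 1 | av$pos + nchar(av$ref) - 1 > nchar(target$reference)))
      stop("allele edit lies outside the reference")
    for (i in seq_len(nrow(av)))
      if (substr(target$reference, av$pos[i], av$pos[i] + nchar(av$ref[i]) - 1) != av$ref[i])
        stop("edit ref allele does not match the reference sequence")
  }
  structure(list(target = target, allele_variants = allele_variants,
                 depth = as.integer(depth), error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "diploid_amplicon_spec")
}

# apply a variant table (1-based anchor pos, ref, alt) to a sequence,
# right-to-left so earlier coordinates stay valid
apply_variants <- function(reference, variants) {
  if (is.null(variants) || nrow(variants) == 0) return(reference)
  v <- variants[order(-variants$pos), , drop = FALSE]
  s <- reference
  for (i in seq_len(nrow(v))) {
    before <- substr(s, 1, v$pos[i] - 1)
    after <- substr(s, v$pos[i] + nchar(v$ref[i]), nchar(s))
    s <- paste0(before, v$alt[i], after)
  }
  s
}

#' Simulate merged amplicon reads from a diploid embryo
#'
#' Each read is a full-length copy of one of the two allele haplotypes
#' (allele chosen uniformly), with per-base substitution errors at
#' `error_rate`. Read names encode the true allele (`read<i>|allele<k>`)
#' so tests can use them as oracles. Base qualities are constant.
#'
#' @param spec A [diploid_amplicon_spec()].
#' @return data.frame with columns `read_id`, `sequence`, `allele`
#'   (1 or 2); attribute `haplotypes` holds the two true allele sequences.
#' @export
simulate_amplicon_reads <- function(spec) {
  stopifnot(inherits(spec, "diploid_amplicon_spec"))
  set.seed(spec$seed)
  haps <- vapply(spec$allele_variants,
                 function(av) apply_variants(spec$target$reference, av), "")
  allele <- sample(1:2, spec$depth, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  seqs <- character(spec$depth)
  for (i in seq_len(spec$depth)) {
    s <- strsplit(haps[allele[i]], "")[[1]]
    if (spec$error_rate > 0) {
      err <- which(runif(length(s)) < spec$error_rate)
      for (j in err) s[j] <- sample(setdiff(bases, s[j]), 1)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  out <- data.frame(read_id = sprintf("read%d|allele%d", seq_len(spec$depth), allele),
                    sequence = seqs, allele = allele, stringsAsFactors = FALSE)
  attr(out, "haplotypes") <- haps
  out
}

#' Simulate a screening cohort
#'
#' Draws per-embryo genotypes binomially from per-gene mutant allele
#' frequencies (each mutant allele scored as a HIGH-impact allele, weight 1,
#' so dosage equals the mutant allele count), then generates phenotypes from
#' additive linear models (heart rate and HRV on the z-score scale) and a
#' logistic model for sinoatrial pauses, with batch and time-of-day effects.
#'
#' @param n Number of embryos.
#' @param genes data.frame with columns `gene`, `maf` (mutant allele
#'   frequency), and per-dosage-unit effects `beta_rate`, `beta_hrv`
#'   (SD units) and `logor_pause`.
#' @param n_batches Number of imaging batches (fixed effects).
#' @param baseline_pause Baseline sinoatrial-pause probability at dosage 0
#'   in the reference batch (default 0.10, consistent with the ~13% pause
#'   prevalence observed in a 2-dpf F1 screening cohort once dosage effects
#'   are included).
#' @param batch_sd SD of per-batch shifts on the continuous outcomes.
#' @param seed Integer seed.
#' @return List with `cohort` (one row per embryo: `embryo_id`, dosage
#'   columns `dosage_<gene>`, phenotypes `heart_rate_z`, `hrv_z`,
#'   `has_pause`, covariates `batch`, `time_of_day`, `experiment`) and
#'   `truth` (the generating parameters).
#' @export
make_cohort <- function(n, genes, n_batches = 6, baseline_pause = 0.10,
                        batch_sd = 0.2, seed = 1L) {
  stopifnot(is.data.frame(genes),
            all(c("gene", "maf", "beta_rate", "beta_hrv", "logor_pause") %in% names(genes)))
  if (anyDuplicated(genes$gene)) stop("duplicated gene labels")
  set.seed(seed)
  k <- nrow(genes)
  if (n == 0) {
    cohort <- data.frame(embryo_id = character(0))
    for (g in genes$gene) cohort[[paste0("dosage_", g)]] <- numeric(0)
    cohort$heart_rate_z <- numeric(0); cohort$hrv_z <- numeric(0)
    cohort$has_pause <- integer(0); cohort$batch <- character(0)
    cohort$time_of_day <- numeric(0); cohort$experiment <- character(0)
    return(list(cohort = cohort, truth = genes))
  }
  G <- vapply(genes$maf, function(q) rbinom(n, 2L, q), integer(n))
  if (n == 1) G <- matrix(G, nrow = 1)
  colnames(G) <- genes$gene
  batch <- sample(sprintf("b%d", seq_len(n_batches)), n, replace = TRUE)
  batch_rate <- setNames(rnorm(n_batches, 0, batch_sd), sprintf("b%d", seq_len(n_batches)))
  batch_hrv <- setNames(rnorm(n_batches, 0, batch_sd), sprintf("b%d", seq_len(n_batches)))
  tod <- runif(n, 9, 17)
  tod_c <- tod - 13

  rate <- as.vector(G %*% genes$beta_rate) + batch_rate[batch] +
    0.02 * tod_c + rnorm(n)
  hrv <- as.vector(G %*% genes$beta_hrv) + batch_hrv[batch] +
    0.02 * tod_c + rnorm(n)
  eta <- qlogis(baseline_pause) + as.vector(G %*% genes$logor_pause) +
    0.2 * (batch_rate[batch] / max(batch_sd, 1e-9)) * batch_sd
  pause <- rbinom(n, 1L, plogis(eta))

  cohort <- data.frame(embryo_id = sprintf("e%04d", seq_len(n)),
                       stringsAsFactors = FALSE)
  for (g in genes$gene) cohort[[paste0("dosage_", g)]] <- G[, g]
  cohort$heart_rate_z <- unname(rate)
  cohort$hrv_z <- unname(hrv)
  cohort$has_pause <- pause
  cohort$batch <- batch
  cohort$time_of_day <- tod
  cohort$experiment <- "exp1"
  list(cohort = cohort, truth = genes)
}
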