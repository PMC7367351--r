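#' Efficiency-corrected relative expression (Pfaffl method)
#'
#' `ratio = E_target^(Cq_cal,target - Cq_sample,target) /
#'          E_ref^(Cq_cal,ref - Cq_sample,ref)`
#' where `E` is the amplification efficiency in fold-per-cycle (2 = perfect
#' doubling) and the Cq values are replicate means. The calibrator's
#' self-ratio is exactly 1.
#'
#' @param target_cq_sample,target_cq_calibrator Mean Cq of the gene of
#'   interest in the sample and calibrator condition.
#' @param ref_cq_sample,ref_cq_calibrator Mean Cq of the reference gene.
#' @param E_target,E_ref Amplification efficiencies, in `(1, 2.5]`.
#' @return Expression ratio relative to the calibrator (vectorised);
#'   non-finite Cq inputs yield `NA` with a warning.
#' @export
pfaffl_ratio <- function(target_cq_sample, target_cq_calibrator,
                         ref_cq_sample, ref_cq_calibrator,
                         E_target, E_ref) {
  stopifnot(all(E_target > 1 & E_target <= 2.5),
            all(E_ref > 1 & E_ref <= 2.5))
  bad <- !is.finite(target_cq_sample) | !is.finite(target_cq_calibrator) |
    !is.finite(ref_cq_sample) | !is.finite(ref_cq_calibrator)
  if (any(bad)) warning(sum(bad), " non-finite Cq value(s); ratio set to NA")
  r <- E_target^(target_cq_calibrator - target_cq_sample) /
    E_ref^(ref_cq_calibrator - ref_cq_sample)
  r[bad] <- NA_real_
  r
}

#' Average technical Cq replicates
#'
#' @param cq Matrix or data.frame of Cq replicates (rows = reactions), or a
#'   numeric vector for a single reaction.
#' @param sd_warn Warn when the replicate SD exceeds this many cycles
#'   (default 0.5).
#' @return Numeric vector of replicate means.
#' @export
average_cq <- function(cq, sd_warn = 0.5) {
  m <- as.matrix(cq)
  stopifnot(all(is.na(m) | (m > 0 & m < 45)))
  sds <- apply(m, 1, sd, na.rm = TRUE)
  if (any(sds > sd_warn, na.rm = TRUE))
    warning(sum(sds > sd_warn, na.rm = TRUE),
            " reaction(s) with replicate SD > ", sd_warn, " cycles")
  rowMeans(m, na.rm = TRUE)
}

#' Condition contrasts on expression ratios
#'
#' Linear model of the (by default log-transformed) expression ratio on
#' condition indicators plus a batch fixed effect, returning each
#' condition's contrast against the control level with Wald 95% CI and
#' p-value. With a single batch the batch term is dropped with a warning.
#'
#' @param data data.frame with columns `ratio`, `condition`, `batch`.
#' @param control Control condition level (reference).
#' @param log_scale Model `log(ratio)` (default TRUE; variance-stabilising)
#'   or the raw ratio.
#' @return data.frame with one row per non-control condition: `condition`,
#'   `estimate` (log fold-change if `log_scale`), `ci_low`, `ci_high`,
#'   `p_value`, `n_used`.
#' @export
condition_contrast <- function(data, control, log_scale = TRUE) {
  stopifnot(all(c("ratio", "condition", "batch") %in% names(data)),
            control %in% data$condition)
  conds <- unique(data$condition)
  stopifnot(length(conds) >= 2)
  tab <- table(data$condition)
  if (any(tab < 2)) stop("need >= 2 samples per condition")
  data$condition <- stats::relevel(factor(data$condition), ref = control)
  data$y <- if (log_scale) log(data$ratio) else data$ratio
  use_batch <- length(unique(data$batch)) > 1
  if (!use_batch) warning("single batch: batch term dropped")
  f <- if (use_batch) y ~ condition + factor(batch) else y ~ condition
  fit <- lm(f, data = data)
  cf <- coef(fit); vc <- vcov(fit)
  terms <- paste0("condition", setdiff(levels(data$condition), control))
  rows <- lapply(terms, function(tm) {
    b <- cf[tm]; s <- sqrt(vc[tm, tm])
    data.frame(condition = sub("^condition", "", tm), estimate = unname(b),
               ci_low = unname(b - 1.96 * s), ci_high = unname(b + 1.96 * s),
               p_value = unname(2 * stats::pnorm(-abs(b / s))),
               n_used = stats::nobs(fit), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "scale") <- if (log_scale) "log" else "raw"
  out
}
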