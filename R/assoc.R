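#' Assemble the embryo x target dosage matrix
#'
#' Applies the screening missingness rules: embryos with missing calls at
#' more than `max_missing` of the targeted sites are excluded (count
#' reported via message), and the remaining missing entries are imputed to
#' the per-target mean dosage over successfully called embryos.
#'
#' @param site_calls data.frame with columns `embryo_id`, `target`,
#'   `status` (`"called"`/`"missing"`) and `dosage`.
#' @param max_missing Maximum tolerated missing site calls per embryo
#'   (default 2, matching a nine-target design).
#' @return data.frame, one row per retained embryo: `embryo_id` plus one
#'   `dosage_<target>` column per target (imputed where missing).
#'   Attribute `n_excluded` records the number of dropped embryos.
#' @export
assemble_dosage_matrix <- function(site_calls,
                                   max_missing = .bc_defaults$max_missing_sites) {
  stopifnot(all(c("embryo_id", "target", "status", "dosage") %in% names(site_calls)))
  targets <- unique(site_calls$target)
  embryos <- unique(site_calls$embryo_id)
  wide <- matrix(NA_real_, length(embryos), length(targets),
                 dimnames = list(embryos, targets))
  called <- site_calls$status == "called" & !is.na(site_calls$dosage)
  wide[cbind(match(site_calls$embryo_id[called], embryos),
             match(site_calls$target[called], targets))] <-
    site_calls$dosage[called]
  all_missing <- colSums(!is.na(wide)) == 0
  if (any(all_missing))
    stop("target(s) missing in every embryo: ",
         paste(targets[all_missing], collapse = ", "))
  n_miss <- rowSums(is.na(wide))
  drop <- n_miss > max_missing
  if (any(drop))
    message(sum(drop), " embryo(s) excluded with > ", max_missing,
            " missing site calls")
  wide <- wide[!drop, , drop = FALSE]
  for (j in seq_len(ncol(wide))) {
    m <- is.na(wide[, j])
    if (any(m)) wide[m, j] <- mean(wide[!m, j])
  }
  out <- data.frame(embryo_id = rownames(wide), stringsAsFactors = FALSE)
  for (j in seq_along(targets)) out[[paste0("dosage_", targets[j])]] <- wide[, j]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Rank-based inverse-normal transform
#'
#' Blom variant: `z_i = qnorm((r_i - 3/8) / (n + 1/4))` with ties sharing
#' their average rank, yielding approximately mean 0 and SD 1. Missing
#' values propagate.
#'
#' @param values Numeric vector (>= 3 non-missing values).
#' @return Numeric vector of z-scores.
#' @export
inverse_normal <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 non-missing values")
  if (length(unique(values[ok])) == 1) stop("degenerate distribution: all values identical")
  r <- rank(values[ok], ties.method = "average")
  z <- rep(NA_real_, length(values))
  z[ok] <- qnorm((r - 3 / 8) / (n + 1 / 4))
  z
}

#' Composite HRV endpoint
#'
#' The average of SDNN and RMSSD, in their common unit; missing if either
#' component is missing.
#'
#' @param sdnn,rmssd Numeric vectors (same units).
#' @return `(sdnn + rmssd) / 2`, elementwise.
#' @export
composite_hrv <- function(sdnn, rmssd) (sdnn + rmssd) / 2

# shared model-fitting core: outcome ~ dosages + covariates, Wald CIs.
fit_terms <- function(formula, data, family, terms, model_label,
                      conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  fit <- if (family == "logistic")
    suppressWarnings(glm(formula, data = data, family = binomial()))
  else lm(formula, data = data)
  cf <- coef(fit)
  se <- rep(NA_real_, length(cf))
  vc <- vcov(fit)
  se[match(rownames(vc), names(cf))] <- sqrt(diag(vc))
  dropped <- names(cf)[is.na(cf)]
  if (length(intersect(dropped, terms)))
    warning("term(s) dropped due to multicollinearity: ",
            paste(intersect(dropped, terms), collapse = ", "))
  rows <- lapply(terms, function(tm) {
    if (!tm %in% names(cf) || is.na(cf[tm])) {
      return(data.frame(term = tm, estimate = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        n_used = stats::nobs(fit), model = model_label,
                        note = "dropped_collinear", stringsAsFactors = FALSE))
    }
    b <- cf[tm]; s <- se[which(names(cf) == tm)]
    note <- ""
    if (family == "logistic" && (is.na(s) || s > 10)) note <- "possible_separation"
    pv <- 2 * stats::pnorm(-abs(b / s))
    lo <- b - z * s; hi <- b + z * s
    if (family == "logistic") {
      data.frame(term = tm, estimate = exp(b), ci_low = exp(lo),
                 ci_high = exp(hi), p_value = pv, n_used = stats::nobs(fit),
                 model = model_label, note = note, stringsAsFactors = FALSE)
    } else {
      data.frame(term = tm, estimate = b, ci_low = lo, ci_high = hi,
                 p_value = pv, n_used = stats::nobs(fit), model = model_label,
                 note = note, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "fit") <- fit
  out
}

#' Mutually adjusted additive association model
#'
#' Fits a single multivariable model with the dosage scores of all targeted
#' sites as independent exposures (mutually adjusted) plus time-of-day and
#' batch (and experiment, when present) fixed effects. Linear models report
#' betas in outcome units (z-scores when the outcome was inverse-normal
#' transformed); logistic models report odds ratios. Wald 95% confidence
#' intervals and p-values. Collinear dosage columns are dropped with a
#' warning; logistic fits with implausibly large standard errors are
#' flagged `possible_separation` with the (effectively infinite-bound) CI
#' reported as is.
#'
#' @param outcome Name of the outcome column in `cohort`.
#' @param cohort data.frame with dosage columns (prefix `dosage_`),
#'   the outcome and covariates `time_of_day`, `batch` (and optionally
#'   `experiment`).
#' @param family `"linear"` or `"logistic"`.
#' @param dosage_cols Dosage column names; defaults to every column
#'   starting with `dosage_`.
#' @param extra_adjust Optional extra covariate column names (e.g. the
#'   mutual heart-rate/HRV adjustment).
#' @return data.frame of class `assoc_results` with one row per dosage
#'   term: `term`, `estimate` (beta or OR), `ci_low`, `ci_high`,
#'   `p_value`, `n_used`, `model`, `note`. Attribute `fit` holds the
#'   underlying model object.
#' @export
additive_model <- function(outcome, cohort, family = c("linear", "logistic"),
                           dosage_cols = grep("^dosage_", names(cohort), value = TRUE),
                           extra_adjust = character(0)) {
  family <- match.arg(family)
  stopifnot(outcome %in% names(cohort), length(dosage_cols) >= 1)
  covs <- character(0)
  if ("time_of_day" %in% names(cohort)) covs <- c(covs, "time_of_day")
  for (v in c("batch", "experiment"))
    if (v %in% names(cohort) && length(unique(cohort[[v]])) > 1) {
      cohort[[v]] <- factor(cohort[[v]])
      covs <- c(covs, v)
    }
  covs <- c(covs, extra_adjust)
  rhs <- paste(c(dosage_cols, covs), collapse = " + ")
  f <- stats::as.formula(paste(outcome, "~", rhs))
  res <- fit_terms(f, cohort, family, dosage_cols,
                   model_label = paste0("additive_", family,
                                        "_fixed_batch_effects"))
  class(res) <- c("assoc_results", class(res))
  res
}

#' Compare both-alleles-nonsense embryos with mutation-free embryos
#'
#' The "2 vs 0" design: embryos carrying HIGH-impact (frameshift or
#' stop-gained) variants on both alleles of `gene` are compared with
#' embryos free from induced variants at that site, adjusting for dosage
#' scores of the remaining genes and the covariates. Refuses to fit
#' (status `not_testable`) when fewer than `min_group` embryos carry
#' nonsense variants on both alleles, or when the reference group is empty.
#'
#' @param outcome Outcome column name.
#' @param cohort data.frame as in [additive_model()], additionally holding
#'   logical columns `hi2_<gene>` (both alleles nonsense) and
#'   `wt_<gene>` (no induced variants), e.g. from [nonsense_groups()].
#' @param gene Gene/target label.
#' @param family `"linear"` or `"logistic"`.
#' @param min_group Minimum size of the both-alleles-nonsense group
#'   (default 5).
#' @return data.frame of class `assoc_results` (one row), or a one-row
#'   data.frame with `model = "two_vs_zero"` and `note = "not_testable"`.
#' @export
two_vs_zero <- function(outcome, cohort, gene, family = c("linear", "logistic"),
                        min_group = 5L) {
  family <- match.arg(family)
  g2 <- cohort[[paste0("hi2_", gene)]]
  g0 <- cohort[[paste0("wt_", gene)]]
  if (is.null(g2) || is.null(g0))
    stop("cohort lacks hi2_/wt_ group columns for ", gene)
  not_testable <- function(why) {
    data.frame(term = paste0("hi2_", gene), estimate = NA_real_,
               ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
               n_used = 0L, model = paste0("two_vs_zero_", family),
               note = paste0("not_testable:", why), stringsAsFactors = FALSE)
  }
  if (sum(g2, na.rm = TRUE) < min_group) return(not_testable("fewer_than_5_hi2"))
  if (sum(g0, na.rm = TRUE) == 0) return(not_testable("empty_reference"))
  sub <- cohort[which(g2 | g0), , drop = FALSE]
  sub$group2 <- as.integer(g2[which(g2 | g0)])
  other <- setdiff(grep("^dosage_", names(cohort), value = TRUE),
                   paste0("dosage_", gene))
  covs <- character(0)
  if ("time_of_day" %in% names(sub)) covs <- c(covs, "time_of_day")
  for (v in c("batch", "experiment"))
    if (v %in% names(sub) && length(unique(sub[[v]])) > 1) {
      sub[[v]] <- factor(sub[[v]])
      covs <- c(covs, v)
    }
  f <- stats::as.formula(paste(outcome, "~",
                               paste(c("group2", other, covs), collapse = " + ")))
  res <- fit_terms(f, sub, family, "group2",
                   model_label = paste0("two_vs_zero_", family))
  res$term <- paste0("hi2_", gene)
  class(res) <- c("assoc_results", class(res))
  res
}

#' Derive 2-vs-0 group indicators from site calls
#'
#' @param site_calls List of `site_call` objects (see [call_site()]).
#' @return data.frame with `embryo_id`, `target`, `hi2` (both alleles
#'   carry a HIGH-impact variant) and `wt` (no called variants on either
#'   allele); missing calls yield NA in both.
#' @export
nonsense_groups <- function(site_calls) {
  rows <- lapply(site_calls, function(sc) {
    if (sc$status != "called")
      return(data.frame(embryo_id = sc$embryo_id, target = sc$target,
                        hi2 = NA, wt = NA, stringsAsFactors = FALSE))
    hi <- vapply(sc$alleles, function(a)
      nrow(a$variants) > 0 && any(a$variants$impact == "HIGH"), logical(1))
    anyv <- vapply(sc$alleles, function(a) nrow(a$variants) > 0, logical(1))
    data.frame(embryo_id = sc$embryo_id, target = sc$target,
               hi2 = all(hi), wt = !any(anyv), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square comparing observed genotype counts with
#' the `p^2 : 2pq : q^2` expectation at the observed allele frequency.
#'
#' @param n_00,n_01,n_11 Counts of embryos carrying 0, 1 and 2 mutated
#'   alleles.
#' @return List with `chi_square`, `p_value`, `allele_freq` (mutant).
#' @export
hwe_test <- function(n_00, n_01, n_11) {
  stopifnot(n_00 >= 0, n_01 >= 0, n_11 >= 0)
  n <- n_00 + n_01 + n_11
  if (n == 0) stop("no observations")
  q <- (2 * n_11 + n_01) / (2 * n)
  p <- 1 - q
  if (q == 0 || q == 1)
    return(list(chi_square = 0, p_value = 1, allele_freq = q))
  expd <- n * c(p^2, 2 * p * q, q^2)
  chi <- sum((c(n_00, n_01, n_11) - expd)^2 / expd)
  list(chi_square = chi, p_value = pchisq(chi, df = 1, lower.tail = FALSE),
       allele_freq = q)
}
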