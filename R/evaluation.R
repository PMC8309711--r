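#' Signed percentage error of an estimate
#'
#' `100 * (estimate - actual) / actual`; negative values are
#' underestimates.
#'
#' @param estimateML estimated volume(s), mL.
#' @param actualML true volume(s), mL (> 0); recycled against
#'   `estimateML`.
#' @return percentage error(s).
#' @export
percentageError <- function(estimateML, actualML) {
  if (any(!is.finite(actualML)) || any(actualML <= 0))
    stop("actual volume must be strictly positive")
  100 * (estimateML - actualML) / actualML
}

#' Summarise signed and absolute percentage errors
#'
#' Mean percentage error (MPE, bias) and mean absolute percentage error
#' (MAPE, spread) with their sample standard deviations (n - 1
#' denominator). With a single record the SDs are `NA`.
#'
#' @param pctErrors numeric vector of signed percentage errors, e.g. from
#'   [percentageError()].
#' @return list with `mpe_pct`, `sd_pe_pct`, `mape_pct`, `sd_ape_pct`, `n`.
#' @examples
#' summarizeErrors(c(-10, 10))  # MPE 0, MAPE 10
#' @export
summarizeErrors <- function(pctErrors) {
  if (!length(pctErrors))
    stop("no errors to summarise")
  if (any(!is.finite(pctErrors)))
    stop("percentage errors must be finite")
  n <- length(pctErrors)
  list(mpe_pct   = mean(pctErrors),
       sd_pe_pct = if (n > 1L) sd(pctErrors) else NA_real_,
       mape_pct  = mean(abs(pctErrors)),
       sd_ape_pct = if (n > 1L) sd(abs(pctErrors)) else NA_real_,
       n = n)
}

#' Method-agreement statistics for one estimator
#'
#' The full agreement battery against ground truth: Pearson correlation of
#' estimate vs actual; Bland-Altman analysis of the differences
#' `d = estimate - actual` (mean difference, sample SD, limits of
#' agreement at mean +- 1.96 SD); the coefficient of variation defined as
#' `SD(d) / mean(actual) * 100`; a two-sided paired Student's t-test and
#' two-sided Wilcoxon signed-rank test of the differences against zero.
#'
#' The Wilcoxon test uses the exact distribution for n <= 25 (when the
#' nonzero |d| are tie-free) and the normal approximation with continuity
#' correction otherwise; zero differences are dropped by default
#' (`zeroes = "pratt"` instead ranks them before discarding, the Pratt
#' variant, via a zero-adjusted normal approximation).
#'
#' @param actualML true volumes, mL.
#' @param estimateML estimated volumes, mL, same length (>= 3 for the
#'   correlation; >= 2 suffices for Bland-Altman, in which case the
#'   correlation fields are `NA`).
#' @param zeroes `"drop"` (default) or `"pratt"` handling of zero
#'   differences in the signed-rank test.
#' @return list with `pearson_r`, `r_squared`, `mean_diff_mL`,
#'   `sd_diff_mL`, `loa_lower_mL`, `loa_upper_mL`, `cv_pct`, `t_p`,
#'   `wilcoxon_p`, `n`.
#' @export
agreement <- function(actualML, estimateML, zeroes = c("drop", "pratt")) {
  zeroes <- match.arg(zeroes)
  if (length(actualML) != length(estimateML))
    stop("actual and estimate vectors must have equal length")
  n <- length(actualML)
  if (n < 2L)
    stop("agreement needs at least 2 paired records")
  d <- estimateML - actualML
  if (n >= 3L) {
    if (sd(actualML) == 0 || sd(estimateML) == 0)
      stop("correlation undefined for a constant series")
    r <- cor(actualML, estimateML)
  } else {
    r <- NA_real_
  }
  md <- mean(d)
  sdd <- sd(d)
  list(pearson_r = r,
       r_squared = r^2,
       mean_diff_mL = md,
       sd_diff_mL = sdd,
       loa_lower_mL = md - 1.96 * sdd,
       loa_upper_mL = md + 1.96 * sdd,
       cv_pct = sdd / mean(actualML) * 100,
       t_p = pairedTP(d),
       wilcoxon_p = signedRankP(d, zeroes),
       n = n)
}

# two-sided one-sample t on the paired differences; degenerate cases:
# all-zero differences are perfect agreement (p = 1), a nonzero constant
# difference is detected with certainty (p -> 0).
pairedTP <- function(d) {
  if (sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
  t.test(d, mu = 0, alternative = "two.sided")$p.value
}

signedRankP <- function(d, zeroes = "drop") {
  nz <- d[d != 0]
  if (!length(nz)) return(1)
  if (zeroes == "drop") {
    exact <- length(nz) <= 25L && !anyDuplicated(abs(nz))
    suppressWarnings(
      wilcox.test(nz, mu = 0, alternative = "two.sided",
                  exact = exact, correct = TRUE)$p.value)
  } else {
    # Pratt: rank |d| including zeros, then discard the zero ranks;
    # zero-adjusted normal approximation with tie correction.
    n <- length(d)
    n0 <- n - length(nz)
    rk <- rank(abs(d))
    W <- sum(rk[d > 0])
    mu <- (n * (n + 1) - n0 * (n0 + 1)) / 4
    ties <- table(rk[d != 0])
    v <- n * (n + 1) * (2 * n + 1) / 24 -
      n0 * (n0 + 1) * (2 * n0 + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(v)
    min(1, 2 * pnorm(-abs(z)))
  }
}

#' Stratify records into clinical volume groups
#'
#' Partitions (0, Inf) into left-open right-closed intervals at the given
#' cutpoints -- by default (0,200], (200,400], (400,600], (600,Inf) mL, the
#' conventional small-to-large stratification. A volume exactly on a
#' cutpoint belongs to the lower group.
#'
#' @param actualML true volumes, mL (> 0).
#' @param cutpoints strictly increasing positive cut volumes, mL.
#' @return factor of group labels (`"0-200"`, `"200-400"`, ...,
#'   `">600"`), one per record, with levels in volume order.
#' @examples
#' groupByVolume(c(150, 200, 200.1, 750))
#' @export
groupByVolume <- function(actualML, cutpoints = c(200, 400, 600)) {
  if (any(cutpoints <= 0) || is.unsorted(cutpoints, strictly = TRUE))
    stop("cutpoints must be positive and strictly increasing")
  if (any(actualML <= 0))
    stop("volumes must be strictly positive")
  k <- length(cutpoints)
  labels <- c(paste0(c(0, cutpoints[-k]), "-", cutpoints),
              paste0(">", cutpoints[k]))
  cut(actualML, breaks = c(0, cutpoints, Inf), labels = labels,
      right = TRUE)
}

#' Evaluate every estimator of a cohort, pooled and per volume group
#'
#' For each estimate column (`est_*_mL`) of the cohort, computes the error
#' summary and the agreement battery on the pooled records and within
#' each volume group (groups with fewer than 3 records get the error
#' summary only, since the correlation is not estimable).
#'
#' @param cohort data.frame with `actual_volume_mL` and one or more
#'   `est_*` columns (e.g. from [generateCohort()] or [readCohortCSV()]).
#' @param cutpoints volume-group cutpoints, mL; see [groupByVolume()].
#' @return nested list: `$n`, `$groups` (group sizes), and `$methods`,
#'   one entry per estimate column with `$pooled` (errors + agreement)
#'   and `$by_group`. The cohort's generation config, when present, is
#'   carried through as `$config`.
#' @export
evaluateCohort <- function(cohort, cutpoints = c(200, 400, 600)) {
  if (!"actual_volume_mL" %in% names(cohort))
    stop("cohort must contain 'actual_volume_mL'")
  methods <- grep("^est_", names(cohort), value = TRUE)
  if (!length(methods))
    stop("cohort contains no 'est_*' estimate columns")
  actual <- cohort$actual_volume_mL
  grp <- groupByVolume(actual, cutpoints)
  out <- list(n = nrow(cohort),
              groups = as.list(table(grp)),
              methods = list())
  for (m in methods) {
    est <- cohort[[m]]
    pe <- percentageError(est, actual)
    pooled <- list(errors = summarizeErrors(pe),
                   agreement = agreement(actual, est))
    byGroup <- lapply(levels(grp), function(g) {
      idx <- grp == g
      if (!sum(idx)) return(NULL)
      res <- list(errors = summarizeErrors(pe[idx]))
      if (sum(idx) >= 3L && sd(actual[idx]) > 0 && sd(est[idx]) > 0)
        res$agreement <- agreement(actual[idx], est[idx])
      res
    })
    names(byGroup) <- levels(grp)
    out$methods[[m]] <- list(pooled = pooled,
                             by_group = byGroup[!vapply(byGroup, is.null,
                                                        logical(1L))])
  }
  cfg <- attr(cohort, "config")
  if (!is.null(cfg)) out$config <- cfg
  out
}

#' Write an evaluation report as JSON
#'
#' @param report list from [evaluateCohort()].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
writeReportJSON <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
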