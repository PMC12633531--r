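#' @include AllClasses.R detect.R
NULL

#' Flag kataegis-burden outliers by z-score
#'
#' Single-pass rule: `z = (x - mean(x)) / sd(x)` on the raw burden vector;
#' samples with `z > zThreshold` are flagged. The mean and sd are not
#' recomputed after removals, and a zero-sd cohort flags nothing.
#'
#' @param burdens numeric burden per sample.
#' @param ids sample identifiers (defaults to names or indices).
#' @param zThreshold exclusion threshold (default 3).
#' @return character vector of flagged sample ids (possibly empty).
#' @export
flagOutliers <- function(burdens, ids = NULL, zThreshold = 3) {
  if (length(burdens) < 2L) stop("need at least two samples")
  ids <- ids %||% names(burdens) %||% as.character(seq_along(burdens))
  s <- stats::sd(burdens)
  if (is.na(s) || s == 0) return(character(0))
  z <- (burdens - mean(burdens)) / s
  ids[z > zThreshold]
}

#' Two-group comparison of a continuous variable
#'
#' Two-sided Wilcoxon rank-sum (signed-rank when `paired`). The exact
#' distribution is used when both groups have at most 25 observations and
#' no ties are present; otherwise the normal approximation with
#' continuity and tie correction, for reproducibility across platforms.
#'
#' @param values numeric vector.
#' @param grouping factor/character with exactly two levels (ignored when
#'   `paired`; then `values` and `values2` are the pairs).
#' @param values2 second member of each pair when `paired = TRUE`.
#' @param paired logical.
#' @return list with p, statistic, n1, n2, medians, exact.
#' @export
compareGroups <- function(values, grouping = NULL, values2 = NULL,
                          paired = FALSE) {
  if (paired) {
    stopifnot(length(values) == length(values2))
    x <- values; y <- values2
  } else {
    g <- factor(grouping)
    if (nlevels(g) != 2L) stop("grouping must have exactly two levels")
    x <- values[g == levels(g)[1]]
    y <- values[g == levels(g)[2]]
    if (length(x) == 0L || length(y) == 0L) stop("a group is empty")
  }
  exact <- length(x) <= 25L && length(y) <= 25L &&
    !anyDuplicated(c(x, y)) && (!paired || !any(x == y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                            exact = exact, correct = TRUE))
  list(p = wt$p.value, statistic = unname(wt$statistic),
       n1 = length(x), n2 = length(y),
       medians = c(stats::median(x), stats::median(y)), exact = exact)
}

#' Kataegis/driver-gene co-occurrence
#'
#' Per gene: two-sided Fisher exact test of kataegis positivity against
#' driver-mutation presence, BH-adjusted across genes. Genes mutated in
#' no sample get p = 1 and an `uninformative` flag. Odds ratios use the
#' Haldane correction when a margin is zero.
#'
#' @param positive logical kataegis positivity, named by sample.
#' @param drivers logical sample x gene matrix of mutation presence.
#' @return data.frame with gene, counts, odds_ratio, p, fdr,
#'   uninformative.
#' @export
driverCooccurrence <- function(positive, drivers) {
  stopifnot(is.matrix(drivers) || is.data.frame(drivers))
  drivers <- as.matrix(drivers)
  if (!is.null(rownames(drivers)) && !is.null(names(positive)))
    drivers <- drivers[names(positive), , drop = FALSE]
  rows <- lapply(colnames(drivers), function(gene) {
    mut <- as.logical(drivers[, gene])
    if (!any(mut)) {
      return(data.frame(gene = gene, n_mut_pos = 0L, n_mut_neg = 0L,
                        odds_ratio = NA_real_, p = 1,
                        uninformative = TRUE, stringsAsFactors = FALSE))
    }
    tab <- table(factor(positive, c(FALSE, TRUE)), factor(mut, c(FALSE, TRUE)))
    data.frame(gene = gene,
               n_mut_pos = sum(mut & positive), n_mut_neg = sum(mut & !positive),
               odds_ratio = .oddsRatio(tab),
               p = stats::fisher.test(tab)$p.value,
               uninformative = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Negative-binomial regression of kataegis burden
#'
#' Fits `kataegis_count ~ covariates` with a log link and NB dispersion
#' (suitable for burdens with variance exceeding the mean). Covariates in
#' `logTransform` enter as `log(1 + x)` to tolerate zeros; the rest enter
#' untransformed. Rows with missing covariates and flagged outliers must
#' be removed by the caller.
#'
#' @param cohort cohort table with a `kataegis_count` column.
#' @param covariates character vector of covariate column names (empty
#'   for an intercept-only fit).
#' @param logTransform subset of `covariates` to log(1+x)-transform.
#' @return list with `coefficients` (estimate, se, z, p per term),
#'   `theta` (NB dispersion), `model` (the `glm.nb` fit).
#' @export
nbBurdenRegression <- function(cohort, covariates = character(0),
                               logTransform = character(0)) {
  .assertColumns(cohort, c("kataegis_count", covariates), "cohort table")
  df <- cohort[, c("kataegis_count", covariates), drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  for (cv in logTransform) df[[cv]] <- log1p(df[[cv]])
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("kataegis_count ~", rhs))
  fit <- withCallingHandlers(
    MASS::glm.nb(fml, data = df),
    warning = function(w) {
      # theta estimation hitting its inner limits still returns a usable
      # fit; convergence proper is checked below
      if (grepl("(iteration|alternation) limit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop("negative binomial fit did not converge after ", fit$iter,
         " IWLS iterations")
  sm <- summary(fit)$coefficients
  list(coefficients = data.frame(term = rownames(sm), estimate = sm[, 1],
                                 se = sm[, 2], z = sm[, 3], p = sm[, 4],
                                 row.names = NULL),
       theta = fit$theta, model = fit, n = nrow(df))
}

#' Kaplan-Meier stratification by kataegis state or burden
#'
#' Builds the endpoint (`bcr_or_met`: BCR and/or metastasis; `met_only`:
#' metastasis, with BCR-only patients excluded), stratifies by kataegis
#' positivity or by burden above/below `burdenSplit`, and runs the
#' two-group log-rank test on the product-limit estimates.
#'
#' @param cohort cohort table with kataegis_count, followup_days,
#'   bcr_flag, metastasis_flag (and excluded_flag, honoured when present).
#' @param mode `"positivity"` or `"burden_gt_1"`.
#' @param endpoint `"bcr_or_met"` or `"met_only"`.
#' @param burdenSplit burden cut for `burden_gt_1` (default 1).
#' @return list with `fit` (survfit), `p` (log-rank; NA with a flag when
#'   a stratum has no events), `data`, `n`.
#' @export
survivalStrata <- function(cohort, mode = c("positivity", "burden_gt_1"),
                           endpoint = c("bcr_or_met", "met_only"),
                           burdenSplit = 1) {
  mode <- match.arg(mode); endpoint <- match.arg(endpoint)
  df <- cohort
  if (!is.null(df$excluded_flag)) df <- df[!df$excluded_flag, , drop = FALSE]
  df <- df[!is.na(df$followup_days), , drop = FALSE]
  if (endpoint == "met_only")
    df <- df[!(df$bcr_flag %in% TRUE & !(df$metastasis_flag %in% TRUE)), ,
             drop = FALSE]
  df$status <- if (endpoint == "bcr_or_met")
    as.integer(df$bcr_flag %in% TRUE | df$metastasis_flag %in% TRUE)
  else as.integer(df$metastasis_flag %in% TRUE)
  df$stratum <- if (mode == "positivity")
    ifelse(df$kataegis_count >= 1, "positive", "negative")
  else ifelse(df$kataegis_count > burdenSplit, "multiple", "0-1")
  if (length(unique(df$stratum)) < 2L)
    return(list(fit = NULL, p = NA_real_, data = df, n = nrow(df),
                note = "fewer than two strata"))
  fit <- survival::survfit(survival::Surv(followup_days, status) ~ stratum,
                           data = df)
  note <- NA_character_
  perStratumEvents <- tapply(df$status, df$stratum, sum)
  if (sum(df$status) == 0L) {
    p <- NA_real_
    note <- "no events in any stratum"
  } else {
    sd <- survival::survdiff(survival::Surv(followup_days, status) ~ stratum,
                             data = df)
    p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    if (any(perStratumEvents == 0L)) note <- "a stratum has zero events"
  }
  list(fit = fit, p = p, data = df, n = nrow(df), note = note)
}

#' Assemble the per-sample cohort table
#'
#' Joins kataegis burden (zero for event-free samples), genomic covariates
#' and clinical metadata; sets `positive = kataegis_count >= 1` and flags
#' burden outliers by the single-pass z-score rule with a recorded reason.
#'
#' @param events a [KataegisEvents-class] or event data.frame.
#' @param clinical clinical table ([readClinical()] format).
#' @param covariates optional per-sample covariate data.frame keyed by
#'   sample_id.
#' @param zThreshold outlier threshold (default 3).
#' @return cohort data.frame with excluded_flag and excluded_reason.
#' @export
buildCohortTable <- function(events, clinical, covariates = NULL,
                             zThreshold = 3) {
  ev <- if (is(events, "KataegisEvents")) eventTable(events) else events
  counts <- table(ev$sample_id)
  df <- clinical
  df$kataegis_count <- as.integer(counts[df$sample_id])
  df$kataegis_count[is.na(df$kataegis_count)] <- 0L
  df$positive <- df$kataegis_count >= 1L
  if (!is.null(covariates))
    df <- merge(df, covariates, by = "sample_id", all.x = TRUE, sort = FALSE)
  df <- df[order(df$sample_id), , drop = FALSE]
  out <- if (nrow(df) >= 2L)
    flagOutliers(df$kataegis_count, df$sample_id, zThreshold) else character(0)
  df$excluded_flag <- df$sample_id %in% out
  df$excluded_reason <- ifelse(df$excluded_flag,
                               sprintf("burden z-score > %g", zThreshold),
                               NA_character_)
  rownames(df) <- NULL
  df
}

#' Recompute percentages from a counts table
#'
#' Utility for cohort composition tables: `100 * numerator / denominator`
#' rounded to the number of digits each row specifies (matching the
#' precision a table is printed at).
#'
#' @param counts data.frame with columns numerator, denominator and
#'   optionally digits (default 0).
#' @return the input with a `pct` column appended.
#' @export
#' @examples
#' cohortPercentages(data.frame(numerator = 68, denominator = 166,
#'                              digits = 0))
cohortPercentages <- function(counts) {
  .assertColumns(counts, c("numerator", "denominator"), "counts table")
  digits <- counts$digits %||% 0
  counts$pct <- round(100 * counts$numerator / counts$denominator, digits)
  counts
}
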