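`%||%` <- function(a, b) if (is.null(a)) b else a

.assertColumns <- function(df, cols, what = "input table") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# chromosome ordering: order of appearance in the reference (not lexicographic)
.chromLevels <- function(chrom, genome = NULL) {
  if (!is.null(genome)) chromNames(genome) else unique(as.character(chrom))
}

.orderRecords <- function(df, genome = NULL) {
  lev <- .chromLevels(df$chrom, genome)
  ci <- match(as.character(df$chrom), lev)
  df[order(df$sample_id, ci, df$pos), , drop = FALSE]
}

#' Derive a stage-specific random seed from a global seed
#'
#' Deterministically salts a global integer seed with a stage name so that
#' pipeline stages draw from independent, reproducible random substreams.
#' The result is always a valid 32-bit integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage name used as salt.
#' @return an integer seed.
#' @export
#' @examples
#' saltSeed(17, "simulate")
saltSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  u <- utf8ToInt(stage)
  h <- sum(u * seq_along(u))
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

.isSingleBase <- function(x) {
  is.character(x) & nchar(x) == 1L & x %in% c("A", "C", "G", "T")
}

.complementBase <- function(x) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[x]
}

# Haldane-corrected odds ratio for a 2x2 table when any cell is zero
.oddsRatio <- function(tab) {
  if (any(tab == 0)) {
    ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) /
      ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
  } else {
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  }
}
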