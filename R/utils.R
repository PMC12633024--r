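## Small shared helpers.  Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

#' Area under the ROC curve by the Mann-Whitney rank statistic
#'
#' @param score numeric score, higher = more positive-like.
#' @param truth logical (or 0/1) ground-truth class.
#' @return AUC in \[0, 1\]; `NA` if either class is empty.
#' @export
auc_score <- function(score, truth) {
  truth <- as.logical(truth)
  keep <- !is.na(score) & !is.na(truth)
  score <- score[keep]
  truth <- truth[keep]
  n1 <- sum(truth)
  n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## z-score with a guard for zero variance
zscore <- function(x, center = mean(x), scale = sd(x)) {
  if (!is.finite(scale) || scale == 0) return(rep(0, length(x)))
  (x - center) / scale
}

## weighted mean that tolerates empty input
wmean <- function(x, w) {
  if (length(x) == 0L || sum(w) == 0) return(NA_real_)
  sum(x * w) / sum(w)
}

## Reverse complement of an ACGT string (vectorised)
revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca", vapply(s, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

## percent formatted to one decimal, as the summaries print it
format_pct <- function(x) sprintf("%.1f%%", 100 * x)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
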