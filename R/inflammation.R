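## Inflammation scoring: single-sample GSEA, the four-signature
## Inflammation Score (IS), tumor-type tertile status, within-type
## z-normalisation, and the IS association models.

#' Single-sample GSEA scores
#'
#' Per sample, genes are ranked by expression (descending) and the
#' enrichment score is the integrated difference between the
#' `|rank|^tau`-weighted step CDF of in-set genes and the uniform step
#' CDF of out-of-set genes (the classic single-sample ranked-walk
#' statistic).  With `normalize = "range"` the whole score matrix is
#' divided by its range across samples and sets.
#'
#' @param expr genes x samples numeric matrix (log-scale expected),
#'   unique rownames.
#' @param sets named list of gene-symbol vectors.
#' @param tau rank weight exponent (default 0.25).
#' @param normalize `"range"` (default) or `"none"`.
#' @return sets x samples numeric matrix of scores.
#' @export
ssgsea <- function(expr, sets, tau = 0.25, normalize = c("range", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), tau >= 0)
  if (anyDuplicated(rownames(expr)))
    stop_fmt("expression matrix has duplicated gene symbols")
  n <- nrow(expr)
  for (nm in names(sets))
    if (!any(sets[[nm]] %in% rownames(expr)))
      stop_fmt("gene set '%s' has no overlap with the expression matrix", nm)
  scores <- matrix(0, length(sets), ncol(expr),
                   dimnames = list(names(sets), colnames(expr)))
  R <- apply(expr, 2, rank, ties.method = "average")   # genes x samples
  for (j in seq_len(ncol(expr))) {
    ord <- order(expr[, j], decreasing = TRUE)
    r_ord <- R[ord, j]
    genes_ord <- rownames(expr)[ord]
    w <- abs(r_ord)^tau
    for (k in seq_along(sets)) {
      inset <- genes_ord %in% sets[[k]]
      n_in <- sum(inset)
      p_in <- cumsum(ifelse(inset, w, 0)) / sum(w[inset])
      p_out <- cumsum(!inset) / (n - n_in)
      scores[k, j] <- sum(p_in - p_out)
    }
  }
  if (normalize == "range") {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  scores
}

#' Inflammation Score from four signature gene sets
#'
#' IS = per-sample arithmetic mean of the four ssGSEA signature scores
#' (type-I interferon, chemokine T-cell recruitment, activated
#' cytotoxic CD8, IFN-gamma response in the published analysis; any
#' four sets are accepted).
#'
#' @param expr genes x samples matrix.
#' @param sets named list of exactly four gene sets.
#' @param tau,normalize passed to [ssgsea()].
#' @return data.frame: `sample_id`, one column per signature score,
#'   `is` (their mean).
#' @export
inflammation_score <- function(expr, sets, tau = 0.25, normalize = "range") {
  if (length(sets) != 4L)
    stop_fmt("the Inflammation Score is the mean of exactly 4 signature scores (got %d sets)",
             length(sets))
  s <- ssgsea(expr, sets, tau = tau, normalize = normalize)
  out <- data.frame(sample_id = colnames(expr), t(s),
                    is = colMeans(s), row.names = NULL,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out
}

#' Tumor-type tertile inflammation status and within-type z-score
#'
#' Tertile thresholds T1 < T2 are computed per tumor type from eligible
#' samples only (viral-negative/unknown and hypermutation class MMRP);
#' the resulting thresholds classify every sample of the type,
#' including the excluded ones: hot when IS > T2, cold when IS <= T1,
#' intermediate otherwise (samples exactly at a threshold take the
#' lower status).  `z_is` standardises IS with the eligible samples'
#' mean and sd.  Types with fewer than 3 eligible samples, or with
#' degenerate thresholds (T1 = T2), are flagged; degenerate types get
#' all-intermediate status.
#'
#' @param is_scores data.frame with `sample_id` and `is` (from
#'   [inflammation_score()]).
#' @param annotations annotation table (`tumor_type`, `viral_status`).
#' @param hypermutation optional data.frame `sample_id`, `class`
#'   (MMRP/MMRD/POLE); samples absent from it count as MMRP.
#' @return data.frame: `sample_id`, `tumor_type`, `is`, `eligible`,
#'   `t1`, `t2`, `status`, `z_is`, `flagged`.
#' @export
tertile_status <- function(is_scores, annotations, hypermutation = NULL) {
  annotations <- annotation_table(annotations)
  d <- merge(is_scores[, c("sample_id", "is")],
             annotations[, c("sample_id", "tumor_type", "viral_status")],
             by = "sample_id")
  cls <- rep("MMRP", nrow(d))
  if (!is.null(hypermutation)) {
    m <- hypermutation$class[match(d$sample_id, hypermutation$sample_id)]
    cls[!is.na(m)] <- m[!is.na(m)]
  }
  d$eligible <- d$viral_status != "positive" & cls == "MMRP"
  out <- lapply(split(d, d$tumor_type), function(dt) {
    el <- dt$is[dt$eligible]
    if (length(el) < 3L) {
      warn_fmt("tumor type %s has %d eligible sample(s) (< 3): no inflammation status assigned",
               dt$tumor_type[1], length(el))
      dt$t1 <- dt$t2 <- dt$z_is <- NA_real_
      dt$status <- NA_character_
      dt$flagged <- TRUE
      return(dt)
    }
    qs <- quantile(el, c(1 / 3, 2 / 3), names = FALSE)
    t1 <- qs[1]; t2 <- qs[2]
    degenerate <- t1 == t2
    dt$t1 <- t1; dt$t2 <- t2
    dt$status <- if (degenerate) "intermediate" else
      ifelse(dt$is > t2, "hot", ifelse(dt$is <= t1, "cold", "intermediate"))
    dt$z_is <- zscore(dt$is, mean(el), sd(el))
    dt$flagged <- degenerate
    dt
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(match(out$sample_id, is_scores$sample_id)),
      c("sample_id", "tumor_type", "is", "eligible", "t1", "t2", "status",
        "z_is", "flagged")]
}

#' Welch comparison of (z-scored) IS between HRD and a reference group
#'
#' Two-sample Welch t test with the sign convention t > 0 when the HRD
#' arm is higher.
#'
#' @param z_is numeric IS (usually z-scored within tumor type).
#' @param hrd logical: TRUE = HRD arm, FALSE = reference arm (HRP/MMRP).
#' @return list: `t`, `p`, `n_hrd`, `n_ref`, `flagged` (degenerate arm).
#' @export
compare_is <- function(z_is, hrd) {
  stopifnot(length(z_is) == length(hrd))
  keep <- is.finite(z_is) & !is.na(hrd)
  x <- z_is[keep & hrd]; y <- z_is[keep & !hrd]
  if (length(x) < 2 || length(y) < 2 || sd(x) == 0 && sd(y) == 0)
    return(list(t = NA_real_, p = NA_real_, n_hrd = length(x),
                n_ref = length(y), flagged = TRUE))
  tt <- t.test(x, y)
  list(t = unname(tt$statistic), p = tt$p.value, n_hrd = length(x),
       n_ref = length(y), flagged = FALSE)
}

## shared OLS core with rank diagnostics
.ols <- function(y, X) {
  qrx <- qr(cbind(`(Intercept)` = 1, X))
  if (qrx$rank < ncol(X) + 1) {
    drop_cols <- colnames(cbind(`(Intercept)` = 1, X))[qrx$pivot[-seq_len(qrx$rank)]]
    stop_fmt("design matrix is rank deficient; collinear column(s): %s",
             paste(drop_cols, collapse = ", "))
  }
  fit <- lm(y ~ ., data = as.data.frame(X, check.names = FALSE))
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- stats::confint(fit)
  data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
             t = co[, 3], p = co[, 4], ci_lo = ci[, 1], ci_hi = ci[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multilinear regression of IS on HRD status and TMB
#'
#' Ordinary least squares `z_is ~ hrd + tmb (+ extra covariates)` with
#' intercept; per-coefficient t and p are reported.
#'
#' @param z_is numeric response (z-scored IS).
#' @param hrd logical/0-1 HRD indicator.
#' @param tmb numeric TMB covariate.
#' @param extra optional named data.frame of additional covariates.
#' @return data.frame of coefficients (`term`, `estimate`, `se`, `t`,
#'   `p`, `ci_lo`, `ci_hi`).
#' @export
regress_is <- function(z_is, hrd, tmb, extra = NULL) {
  X <- data.frame(hrd = as.numeric(hrd), tmb = as.numeric(tmb))
  if (!is.null(extra)) X <- cbind(X, extra)
  .ols(as.numeric(z_is), as.matrix(X))
}

#' Regression of IS on regional LOH and oncogene amplification
#'
#' OLS of (within-type z-scored) IS on per-region LOH fractions plus an
#' oncogene-amplification indicator, typically restricted to HRD
#' samples.  Covariate order is preserved in the output.
#'
#' @param z_is numeric response.
#' @param loh_regions data.frame/matrix of per-region LOH covariates
#'   (one column per region).
#' @param og_amp optional logical indicator of amplification in any
#'   configured oncogene.
#' @return coefficient data.frame as in [regress_is()].
#' @export
regress_is_on_genomics <- function(z_is, loh_regions, og_amp = NULL) {
  X <- as.data.frame(loh_regions, check.names = FALSE)
  if (!is.null(og_amp)) X$og_amp <- as.numeric(og_amp)
  X <- as.matrix(X)
  keep <- apply(X, 2, function(col) sd(col) > 0)
  if (!any(keep)) {
    fit <- lm(as.numeric(z_is) ~ 1)
    co <- summary(fit)$coefficients
    return(data.frame(term = "(Intercept)", estimate = co[1, 1],
                      se = co[1, 2], t = co[1, 3], p = co[1, 4],
                      ci_lo = stats::confint(fit)[1], ci_hi = stats::confint(fit)[2],
                      stringsAsFactors = FALSE))
  }
  .ols(as.numeric(z_is), X[, keep, drop = FALSE])
}

#' Default oncogene amplification panel
#'
#' The oncogenes whose amplification defines the OG-amplification
#' indicator used by [regress_is_on_genomics()].
#'
#' @return character vector of gene symbols.
#' @export
default_oncogene_panel <- function() {
  c("BCL11A", "BCL6", "CCND1", "CDK6", "EGFR", "FGFR1", "KRAS", "TERT")
}
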