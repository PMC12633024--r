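## Per-sample mutational features feeding the HRD classifier: SBS96
## catalogs, signature refitting (Bayesian likelihood / cosine / NNLS),
## microhomology-deletion counts, tumor mutational burden, the
## hypermutation triage, and the 8-oxo-G artifact filter.

#' Build SBS96 catalogs per sample
#'
#' Counts every usable SNV into its pyrimidine-strand trinucleotide
#' channel.  Non-SNVs are ignored.  The trinucleotide context comes from
#' the mutation table's `context` column, or, when absent, from the
#' genome build's sequence accessor.  SNVs whose context cannot be
#' resolved are excluded with a warning and tallied in the `excluded`
#' attribute.
#'
#' @param mutations a mutation table (see [mutation_table()]).
#' @param genome optional `genome_build` with a sequence accessor, used
#'   for records lacking a `context` column.
#' @param samples optional sample ids to force into the result (samples
#'   with zero usable SNVs get an all-zero row).
#' @return integer matrix, samples x 96 channels, with attribute
#'   `excluded` = named vector of per-sample exclusion counts.
#' @export
build_catalog <- function(mutations, genome = NULL, samples = NULL) {
  mutations <- mutation_table(mutations)
  snv <- mutations[mutations$variant_class == "SNV", , drop = FALSE]
  ctx <- snv$context
  need <- is.na(ctx)
  if (any(need) && !is.null(genome) && !is.null(genome$sequence)) {
    idx <- which(need)
    ctx[idx] <- vapply(idx, function(i) {
      genome$sequence(snv$chrom[i], snv$pos[i] - 2, snv$pos[i] + 1)
    }, character(1))
  }
  channel <- sbs96_channel_of(snv$ref, snv$alt, ctx)
  bad <- is.na(channel)
  if (any(bad))
    warn_fmt("%d SNV(s) with unresolvable trinucleotide context excluded from catalogs",
             sum(bad))
  ids <- sort(unique(c(snv$sample_id, samples)))
  ch <- sbs96_channels()
  m <- matrix(0L, nrow = length(ids), ncol = 96,
              dimnames = list(ids, ch))
  if (any(!bad)) {
    tab <- table(factor(snv$sample_id[!bad], levels = ids),
                 factor(channel[!bad], levels = ch))
    m <- m + unclass(tab)
  }
  excl <- table(factor(snv$sample_id[bad], levels = ids))
  attr(m, "excluded") <- setNames(as.integer(excl), ids)
  class(m) <- c("catalog96", class(m))
  m
}

## smooth a spectrum with the documented pseudocount and renormalize
.smooth_spectrum <- function(p, eps = 1e-9) {
  p <- p + eps
  p / sum(p)
}

#' Posterior probability that a catalog was drawn from the HRD spectrum
#'
#' Bayesian two-model comparison under multinomial sampling: with prior
#' `prior_pos` on the positive (HRD-like) spectrum, returns
#' `prior * L(c | pos) / (prior * L(c | pos) + (1 - prior) * L(c | neg))`
#' with log-space likelihoods and a 1e-9 pseudocount on both spectra so
#' zero-probability channels cannot annihilate the product.
#'
#' @param catalog numeric vector of 96 channel counts.
#' @param pos,neg positive / negative spectra (96 probabilities).
#' @param prior_pos prior probability of the positive model.
#' @return posterior in \[0, 1\]; a zero-count catalog returns
#'   `prior_pos` (documented convention).
#' @export
sig3_likelihood <- function(catalog, pos, neg, prior_pos = 0.5) {
  stopifnot(length(catalog) == 96L, prior_pos >= 0, prior_pos <= 1)
  assert_spectrum(pos, "pos"); assert_spectrum(neg, "neg")
  if (sum(catalog) == 0) return(prior_pos)
  lp <- sum(catalog * log(.smooth_spectrum(pos)))
  ln <- sum(catalog * log(.smooth_spectrum(neg)))
  ## normalize in log space before exponentiating
  m <- max(lp, ln)
  wp <- prior_pos * exp(lp - m)
  wn <- (1 - prior_pos) * exp(ln - m)
  wp / (wp + wn)
}

#' Cosine similarity between a catalog and a spectrum
#'
#' @param catalog numeric vector of 96 channel counts (sum > 0).
#' @param spectrum a 96-probability spectrum.
#' @return cosine in \[0, 1\].
#' @export
cosine_to <- function(catalog, spectrum) {
  stopifnot(length(catalog) == 96L, length(spectrum) == 96L)
  if (sum(catalog) == 0)
    stop_fmt("cosine similarity is undefined for a zero-count catalog")
  sum(catalog * spectrum) / (sqrt(sum(catalog^2)) * sqrt(sum(spectrum^2)))
}

#' Non-negative least-squares signature exposures
#'
#' Decomposes a catalog over a spectrum panel, minimising
#' `||catalog - panel %*% e||_2` subject to `e >= 0` (Lawson-Hanson
#' active set, via \pkg{pracma}).
#'
#' @param catalog numeric vector of 96 channel counts.
#' @param panel 96 x K matrix of spectra (columns named).
#' @return list with `exposures` (named, mutation units), `fractions`
#'   (exposures / their sum; zero vector if all exposures are 0) and
#'   `residual` (Euclidean norm of the unexplained remainder).
#' @export
nnls_exposures <- function(catalog, panel) {
  stopifnot(length(catalog) == 96L, is.matrix(panel), nrow(panel) == 96L,
            ncol(panel) >= 1L)
  fit <- pracma::lsqnonneg(panel, as.numeric(catalog))
  e <- setNames(fit$x, colnames(panel))
  tot <- sum(e)
  list(exposures = e,
       fractions = if (tot > 0) e / tot else e * 0,
       residual = sqrt(sum((as.numeric(catalog) - panel %*% fit$x)^2)))
}

## deleted sequence of a deletion record: VCF-style (shared prefix
## stripped) or MAF-style (alt "-" means ref is the deleted run)
.deleted_sequence <- function(ref, alt) {
  if (alt %in% c("-", "")) return(toupper(ref))
  ref <- toupper(ref); alt <- toupper(alt)
  k <- 0L
  while (k < nchar(alt) && k < nchar(ref) &&
         substr(ref, k + 1, k + 1) == substr(alt, k + 1, k + 1)) k <- k + 1L
  if (k < nchar(alt)) return(NA_character_)   # not a clean deletion
  substr(ref, k + 1, nchar(ref))
}

## microhomology length: max over (prefix of deleted vs start of 3'
## flank, suffix of deleted vs end of 5' flank), capped below the
## deletion length
.microhomology_length <- function(deleted, flank5, flank3) {
  L <- nchar(deleted)
  mh3 <- 0L
  while (mh3 < L && mh3 < nchar(flank3) &&
         substr(deleted, mh3 + 1, mh3 + 1) == substr(flank3, mh3 + 1, mh3 + 1))
    mh3 <- mh3 + 1L
  mh5 <- 0L
  f5 <- nchar(flank5)
  while (mh5 < L && mh5 < f5 &&
         substr(deleted, L - mh5, L - mh5) == substr(flank5, f5 - mh5, f5 - mh5))
    mh5 <- mh5 + 1L
  min(max(mh3, mh5), L - 1L)
}

#' Count microhomology-mediated deletions per sample
#'
#' Deletions of length >= `min_len` (default 5 bp) are split by whether
#' the deleted sequence carries a microhomology of >= `min_mh` bp
#' (default 2) with an immediate flank: `n_del_mh` (the
#' MMEJ/ID6-linked count) versus `n_del_no_mh` (NHEJ/ID8-linked).
#' Microhomology is the longer of the deleted sequence's prefix match
#' against the 3' flank and suffix match against the 5' flank, capped
#' below the deletion length.  Flanks come from the `flank5`/`flank3`
#' columns or, failing that, from the genome sequence accessor;
#' unresolvable flanks exclude the record with a warning.
#'
#' @param mutations a mutation table.
#' @param genome optional `genome_build` with sequence accessor.
#' @param min_len minimum deletion length counted (bp).
#' @param min_mh microhomology length splitting the two counts (bp).
#' @param samples optional ids to force into the result with zero counts.
#' @return data.frame: `sample_id`, `n_del_mh`, `n_del_no_mh`.
#' @export
count_microhomology_deletions <- function(mutations, genome = NULL,
                                          min_len = 5L, min_mh = 2L,
                                          samples = NULL) {
  mutations <- mutation_table(mutations)
  del <- mutations[mutations$variant_class == "deletion", , drop = FALSE]
  ids <- sort(unique(c(del$sample_id, samples)))
  out <- data.frame(sample_id = ids, n_del_mh = 0L, n_del_no_mh = 0L,
                    stringsAsFactors = FALSE)
  if (!nrow(del)) return(out)
  excluded <- 0L
  for (i in seq_len(nrow(del))) {
    deleted <- .deleted_sequence(del$ref[i], del$alt[i])
    if (is.na(deleted) || nchar(deleted) < min_len) next
    L <- nchar(deleted)
    f5 <- del$flank5[i]; f3 <- del$flank3[i]
    if ((is.na(f5) || is.na(f3)) && !is.null(genome) &&
        !is.null(genome$sequence)) {
      ## deleted run starts one base after the anchored position for
      ## VCF-style records, at pos for MAF-style ("-" alt) records
      anchored <- !(del$alt[i] %in% c("-", ""))
      del_start <- del$pos[i] - 1 + if (anchored) nchar(del$alt[i]) else 0
      f5 <- genome$sequence(del$chrom[i], del_start - L, del_start)
      f3 <- genome$sequence(del$chrom[i], del_start + L, del_start + 2 * L)
    }
    if (is.na(f5) || is.na(f3)) { excluded <- excluded + 1L; next }
    mh <- .microhomology_length(deleted, toupper(f5), toupper(f3))
    j <- match(del$sample_id[i], out$sample_id)
    if (mh >= min_mh) out$n_del_mh[j] <- out$n_del_mh[j] + 1L
    else out$n_del_no_mh[j] <- out$n_del_no_mh[j] + 1L
  }
  if (excluded > 0)
    warn_fmt("%d deletion(s) with unresolvable flanks excluded from microhomology counts",
             excluded)
  out
}

#' Tumor mutational burden
#'
#' Nonsynonymous mutations (truncating plus nonsynonymous consequence
#' classes, SNVs and indels) per megabase of assayed exome.
#'
#' @param mutations a mutation table.
#' @param footprint_mb assayed exome footprint in Mb (default 38).
#' @param samples optional ids to force into the result.
#' @return data.frame: `sample_id`, `n_nonsyn`, `tmb` (per Mb).
#' @export
compute_tmb <- function(mutations, footprint_mb = 38, samples = NULL) {
  if (!is.numeric(footprint_mb) || footprint_mb <= 0)
    stop_fmt("footprint_mb must be positive")
  mutations <- mutation_table(mutations)
  nonsyn <- mutations$consequence %in% c(TRUNCATING_CONSEQUENCES,
                                         NONSYNONYMOUS_CONSEQUENCES)
  ids <- sort(unique(c(mutations$sample_id, samples)))
  n <- table(factor(mutations$sample_id[nonsyn], levels = ids))
  data.frame(sample_id = ids, n_nonsyn = as.integer(n),
             tmb = as.numeric(n) / footprint_mb, stringsAsFactors = FALSE)
}

#' Is a somatic variant pathogenic?
#'
#' A variant counts as pathogenic when it is truncating
#' (Nonsense_Mutation, Frame_Shift_Del/Ins, Translation_Start_Site,
#' Splice_Site); or nonsynonymous with SIFT "deleterious" AND PolyPhen
#' "probably_damaging"; or ClinVar-annotated "pathogenic" /
#' "likely_pathogenic".  A ClinVar "Benign" label vetoes all routes.
#'
#' @param mutations a mutation table (vectorised over rows).
#' @return logical vector, one per row.
#' @export
is_pathogenic <- function(mutations) {
  mutations <- mutation_table(mutations)
  cons <- mutations$consequence
  sift <- tolower(mutations$sift %||% NA)
  poly <- tolower(mutations$polyphen %||% NA)
  clin <- tolower(mutations$clinvar %||% NA)
  truncating <- cons %in% TRUNCATING_CONSEQUENCES
  nonsyn <- cons %in% NONSYNONYMOUS_CONSEQUENCES
  ## SIFT/PolyPhen tokens may carry scores, e.g. "deleterious(0.01)"
  damaging <- nonsyn &
    !is.na(sift) & grepl("^deleterious", sift) &
    !is.na(poly) & grepl("^probably_damaging", poly)
  clin_path <- !is.na(clin) & grepl("^(likely_)?pathogenic", clin)
  benign_veto <- !is.na(clin) & grepl("^benign", clin)
  (truncating | damaging | clin_path) & !benign_veto
}

#' Triage hypermutated samples before HRD classification
#'
#' Classifies every sample as MMRP, MMRD or POLE from MSI score,
#' NNLS signature-exposure fractions and TMB:
#' MMRD when `msi_score >= msi_threshold` OR (MMR-like exposure fraction
#' >= `f_mmr` AND `tmb >= t_hyper`); else POLE when POLE-like exposure
#' fraction >= `f_pole` AND `tmb >= t_pole`; else MMRP.  When the MSI
#' score is missing the MSI branch is skipped (signature-only rule) and
#' a note is emitted.  MMRD/POLE samples are excluded from HRD
#' classification downstream.
#'
#' @param fractions samples x spectra matrix of NNLS exposure fractions.
#' @param msi_score named numeric vector of MSI scores (NA allowed).
#' @param tmb named numeric vector of TMB per Mb.
#' @param mmr_spectrum,pole_spectrum panel column names.
#' @param msi_threshold,f_mmr,f_pole,t_hyper,t_pole rule thresholds.
#' @return data.frame: `sample_id`, `class`, plus the evidence columns
#'   `msi_score`, `mmr_fraction`, `pole_fraction`, `tmb`.
#' @export
triage_hypermutation <- function(fractions, msi_score, tmb,
                                 mmr_spectrum = "mmr_like",
                                 pole_spectrum = "pole_like",
                                 msi_threshold = 3.5, f_mmr = 0.3,
                                 f_pole = 0.3, t_hyper = 10, t_pole = 100) {
  stopifnot(all(c(mmr_spectrum, pole_spectrum) %in% colnames(fractions)))
  ids <- rownames(fractions)
  msi <- msi_score[ids]
  tmb <- tmb[ids]
  if (anyNA(msi))
    message(sprintf("%d sample(s) without MSI score: MMRD call degrades to the signature-only rule",
                    sum(is.na(msi))))
  fm <- fractions[, mmr_spectrum]
  fp <- fractions[, pole_spectrum]
  mmrd <- (!is.na(msi) & msi >= msi_threshold) | (fm >= f_mmr & tmb >= t_hyper)
  pole <- !mmrd & fp >= f_pole & tmb >= t_pole
  cls <- ifelse(mmrd, "MMRD", ifelse(pole, "POLE", "MMRP"))
  data.frame(sample_id = ids, class = cls, msi_score = as.numeric(msi),
             mmr_fraction = fm, pole_fraction = fp, tmb = tmb,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag sequencing-artifact samples by SBS45-like exposure
#'
#' Samples whose artifact-spectrum exposure fraction reaches the
#' threshold are removed from all downstream stages.  The summary
#' reports the exclusion rate as a percentage of all samples.
#'
#' @param fractions samples x spectra matrix of NNLS exposure fractions.
#' @param threshold exposure-fraction cutoff (default 0.2).
#' @param artifact_spectrum panel column name.
#' @return list with `excluded` (sample ids), `n_total`, `rate`
#'   (fraction) and `rate_label` (e.g. `"0.9%"`); printed by its class.
#' @export
filter_artifact_samples <- function(fractions, threshold = 0.2,
                                    artifact_spectrum = "artifact_like") {
  stopifnot(artifact_spectrum %in% colnames(fractions))
  flagged <- rownames(fractions)[fractions[, artifact_spectrum] >= threshold]
  n <- nrow(fractions)
  res <- list(excluded = flagged, n_total = n,
              rate = if (n > 0) length(flagged) / n else 0)
  res$rate_label <- format_pct(res$rate)
  class(res) <- "artifact_filter"
  res
}

#' @export
print.artifact_filter <- function(x, ...) {
  cat(sprintf("artifact filter: %d/%d samples excluded (%s of all samples)\n",
              length(x$excluded), x$n_total, x$rate_label))
  invisible(x)
}
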