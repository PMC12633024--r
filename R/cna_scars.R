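## Allele-specific copy-number analysis: sample baselines, genomic scar
## scores (HRD-LOH, TAI, LST and their sum GIS), 100-kb genome-wide
## LOH/amplification profiles, gene-level calls, group/region
## statistics, differential-region detection and co-occurrence tests.

#' Per-sample copy-number baseline
#'
#' For each chromosome, segment-length-weighted means of minor and major
#' copy number over segments larger than `min_len` (default 100 kb);
#' the sample-level baseline aggregates chromosome means weighted by
#' each chromosome's qualifying coverage.  Chromosomes with no
#' qualifying segment contribute nothing; samples with no qualifying
#' segment anywhere are dropped with a message.
#'
#' @param segments a segment table (0-based half-open).
#' @param min_len minimum segment length (bp) entering the baseline.
#' @return data.frame `sample_id`, `major`, `minor`, `total`, with the
#'   per-chromosome means in attribute `"chromosome"`.
#' @export
compute_baseline <- function(segments, min_len = 1e5) {
  segments <- segment_table(segments)
  seg <- segments[(segments$end - segments$start) > min_len, , drop = FALSE]
  dropped <- setdiff(unique(segments$sample_id), unique(seg$sample_id))
  if (length(dropped))
    message(sprintf("%d sample(s) with no segment > %g bp excluded from baselines: %s",
                    length(dropped), min_len, paste(dropped, collapse = ", ")))
  if (!nrow(seg))
    return(data.frame(sample_id = character(0), major = numeric(0),
                      minor = numeric(0), total = numeric(0)))
  seg$len <- seg$end - seg$start
  by_chrom <- do.call(rbind, lapply(
    split(seg, list(seg$sample_id, seg$chrom), drop = TRUE),
    function(d) data.frame(sample_id = d$sample_id[1], chrom = d$chrom[1],
                           major = wmean(d$major, d$len),
                           minor = wmean(d$minor, d$len),
                           coverage = sum(d$len), stringsAsFactors = FALSE)))
  rownames(by_chrom) <- NULL
  out <- do.call(rbind, lapply(split(by_chrom, by_chrom$sample_id), function(d) {
    data.frame(sample_id = d$sample_id[1],
               major = wmean(d$major, d$coverage),
               minor = wmean(d$minor, d$coverage), stringsAsFactors = FALSE)
  }))
  out$total <- out$major + out$minor
  rownames(out) <- NULL
  attr(out, "chromosome") <- by_chrom
  out
}

## merge maximal runs of flagged, abutting (gap <= tol bp) segments;
## takes sorted start/end vectors, returns a list(start, end) of runs
.merge_flagged_runs <- function(start, end, flag, tol = 1) {
  if (!any(flag)) return(list(start = numeric(0), end = numeric(0)))
  s <- start[flag]; e <- end[flag]
  grp <- cumsum(c(TRUE, s[-1] - e[-length(e)] > tol))
  list(start = as.numeric(tapply(s, grp, min)),
       end = as.numeric(tapply(e, grp, max)))
}

## single left-to-right pass merging equal-CN neighbors with gap < smooth
.merge_equal_cn <- function(start, end, major, minor, smooth) {
  n <- length(start)
  if (n < 2L) return(list(start = start, end = end, major = major,
                          minor = minor))
  out_s <- numeric(n); out_e <- numeric(n)
  out_ma <- numeric(n); out_mi <- numeric(n)
  j <- 1L
  out_s[1] <- start[1]; out_e[1] <- end[1]
  out_ma[1] <- major[1]; out_mi[1] <- minor[1]
  for (i in 2:n) {
    if (start[i] - out_e[j] < smooth && major[i] == out_ma[j] &&
        minor[i] == out_mi[j]) {
      out_e[j] <- end[i]
    } else {
      j <- j + 1L
      out_s[j] <- start[i]; out_e[j] <- end[i]
      out_ma[j] <- major[i]; out_mi[j] <- minor[i]
    }
  }
  list(start = out_s[1:j], end = out_e[1:j], major = out_ma[1:j],
       minor = out_mi[1:j])
}

## LST smoothing: coalesce equal-CN neighbors first (so splits that
## preserve copy-number values cannot change the score), then drop
## sub-smooth segments, then coalesce across the gaps they leave
.lst_smooth_arm <- function(start, end, major, minor, smooth = 3e6) {
  a <- .merge_equal_cn(start, end, major, minor, smooth)
  keep <- (a$end - a$start) >= smooth
  .merge_equal_cn(a$start[keep], a$end[keep], a$major[keep], a$minor[keep],
                  smooth)
}

#' Genomic scar scores per sample
#'
#' Three allele-specific copy-number scar counts and their sum:
#' \describe{
#'   \item{n_loh_segments}{HRD-LOH: merged LOH regions (minor copy
#'     number < 1) longer than `loh_min_len` (15 Mb) that do not span
#'     the whole chromosome.}
#'   \item{n_tai}{telomeric allelic imbalance: merged allelic-imbalance
#'     regions (major != minor) reaching a telomere (within
#'     `telomere_tol` of a chromosome end) without overlapping the
#'     centromere.}
#'   \item{n_lst}{large-scale state transitions: per chromosome arm,
#'     breakpoints between adjacent segments each >= `lst_min_len`
#'     (10 Mb) after smoothing away segments/gaps < `lst_smooth` (3 Mb).}
#'   \item{gis}{genomic instability score, the sum of the three.}
#' }
#' Chromosomes without a centromere annotation are skipped for TAI/LST
#' with a warning.
#'
#' @param segments a segment table.
#' @param genome a `genome_build` with centromeres.
#' @param loh_min_len,lst_min_len,lst_smooth,telomere_tol scar
#'   parameters in bp (defaults follow the scores' original definitions).
#' @return data.frame `sample_id`, `n_loh_segments`, `n_tai`, `n_lst`,
#'   `gis`.
#' @export
compute_scars <- function(segments, genome, loh_min_len = 15e6,
                          lst_min_len = 10e6, lst_smooth = 3e6,
                          telomere_tol = 1e4) {
  segments <- segment_table(segments)
  missing_cen <- character(0)
  key <- paste(segments$sample_id, segments$chrom, sep = "\r")
  idx_by <- split(seq_len(nrow(segments)), key)
  sid_of <- vapply(idx_by, function(i) segments$sample_id[i[1]], character(1))
  chrom_of <- vapply(idx_by, function(i) segments$chrom[i[1]], character(1))
  n_loh_v <- n_tai_v <- n_lst_v <- integer(length(idx_by))
  for (b in seq_along(idx_by)) {
    i <- idx_by[[b]]
    chrom <- chrom_of[b]
    L <- genome$chrom_lengths[chrom]
    if (is.na(L)) next
    o <- i[order(segments$start[i])]
    s <- segments$start[o]; e <- segments$end[o]
    ma <- segments$major[o]; mi <- segments$minor[o]

    ## HRD-LOH: merged LOH runs > 15 Mb, not whole chromosome
    loh <- .merge_flagged_runs(s, e, mi < 1)
    if (length(loh$start)) {
      whole <- loh$start <= telomere_tol & loh$end >= L - telomere_tol
      n_loh_v[b] <- sum((loh$end - loh$start) > loh_min_len & !whole)
    }

    cen <- genome_centromere(genome, chrom)
    if (is.null(cen)) { missing_cen <- union(missing_cen, chrom); next }

    ## TAI: merged AI runs reaching a telomere, not crossing the centromere
    ai <- .merge_flagged_runs(s, e, ma != mi)
    if (length(ai$start)) {
      telo <- ai$start <= telomere_tol | ai$end >= L - telomere_tol
      crosses_cen <- ai$start < cen[["end"]] & ai$end > cen[["start"]]
      n_tai_v[b] <- sum(telo & !crosses_cen)
    }

    ## LST per arm
    n_lst <- 0L
    for (arm in list(c(0, cen[["start"]]), c(cen[["end"]], L))) {
      keep <- e > arm[1] & s < arm[2]
      if (!any(keep)) next
      a <- .lst_smooth_arm(pmax(s[keep], arm[1]), pmin(e[keep], arm[2]),
                           ma[keep], mi[keep], lst_smooth)
      n <- length(a$start)
      if (n < 2L) next
      len <- a$end - a$start
      gap <- a$start[-1] - a$end[-n]
      differs <- a$major[-1] != a$major[-n] | a$minor[-1] != a$minor[-n]
      n_lst <- n_lst + sum(gap < lst_smooth & differs &
                             len[-n] >= lst_min_len & len[-1] >= lst_min_len)
    }
    n_lst_v[b] <- n_lst
  }
  if (length(missing_cen))
    warn_fmt("no centromere for chromosome(s) %s: skipped for TAI/LST",
             paste(sort(missing_cen), collapse = ", "))
  out <- aggregate(cbind(n_loh_segments = n_loh_v, n_tai = n_tai_v,
                         n_lst = n_lst_v),
                   by = list(sample_id = sid_of), FUN = sum)
  out <- out[order(out$sample_id), ]
  rownames(out) <- NULL
  out$gis <- out$n_loh_segments + out$n_tai + out$n_lst
  out
}

#' Genome-wide 100-kb LOH / amplification profiles
#'
#' Divides each chromosome into `binsize` bins and computes
#' overlap-length-weighted minor and major copy number per bin and
#' sample, the LOH call (weighted minor < 1), and the
#' baseline-corrected amplification deviation (weighted major minus the
#' sample's baseline major).  Bins with zero segment coverage are
#' missing (`NA`), not zero.  The Y chromosome is dropped; the X
#' chromosome is profiled only for samples annotated female.
#'
#' @param segments a segment table.
#' @param genome a `genome_build`.
#' @param annotations optional annotation table supplying `sex`;
#'   without it every sample's X bins are missing.
#' @param binsize bin width in bp (default 100 kb).
#' @param baseline optional precomputed [compute_baseline()] result.
#' @return an object of class `bin_profiles`: list with `bins`
#'   (data.frame chrom/start/end), matrices `minor`, `major`,
#'   `coverage`, `amp_dev` and logical matrix `loh` (samples x bins),
#'   and the `baseline` used.
#' @export
bin_profiles <- function(segments, genome, annotations = NULL,
                         binsize = 1e5, baseline = NULL) {
  segments <- segment_table(segments)
  if (is.null(baseline)) baseline <- compute_baseline(segments)
  chroms <- setdiff(names(genome$chrom_lengths), "Y")
  bins <- do.call(rbind, lapply(chroms, function(ch) {
    L <- genome$chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = binsize)
    data.frame(chrom = ch, start = starts, end = pmin(starts + binsize, L),
               stringsAsFactors = FALSE)
  }))
  rownames(bins) <- NULL
  nb <- nrow(bins)
  offset <- c(0, cumsum(table(factor(bins$chrom, levels = chroms))))[seq_along(chroms)]
  names(offset) <- chroms

  ids <- unique(segments$sample_id)
  female <- rep(FALSE, length(ids))
  if (!is.null(annotations)) {
    annotations <- annotation_table(annotations)
    female <- annotations$sex[match(ids, annotations$sample_id)] == "female"
    female[is.na(female)] <- FALSE
  }
  names(female) <- ids

  mk <- function() matrix(NA_real_, length(ids), nb, dimnames = list(ids, NULL))
  minor_m <- mk(); major_m <- mk(); cov_m <- mk()
  for (sid in ids) {
    ss <- segments[segments$sample_id == sid, , drop = FALSE]
    for (ch in intersect(unique(ss$chrom), chroms)) {
      if (ch == "X" && !female[[sid]]) next
      L <- genome$chrom_lengths[[ch]]
      nbin_ch <- ceiling(L / binsize)
      covs <- numeric(nbin_ch); mins <- numeric(nbin_ch); majs <- numeric(nbin_ch)
      seg <- ss[ss$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(seg))) {
        b1 <- floor(seg$start[i] / binsize) + 1
        b2 <- min(ceiling(seg$end[i] / binsize), nbin_ch)
        idx <- b1:b2
        bs <- (idx - 1) * binsize
        be <- pmin(bs + binsize, L)
        ov <- pmin(seg$end[i], be) - pmax(seg$start[i], bs)
        covs[idx] <- covs[idx] + ov
        mins[idx] <- mins[idx] + ov * seg$minor[i]
        majs[idx] <- majs[idx] + ov * seg$major[i]
      }
      gidx <- offset[[ch]] + seq_len(nbin_ch)
      w <- ifelse(covs > 0, covs, NA_real_)
      minor_m[sid, gidx] <- mins / w
      major_m[sid, gidx] <- majs / w
      cov_m[sid, gidx] <- covs / (pmin((seq_len(nbin_ch)) * binsize, L) -
                                    (seq_len(nbin_ch) - 1) * binsize)
    }
  }
  base_major <- baseline$major[match(ids, baseline$sample_id)]
  structure(list(bins = bins, minor = minor_m, major = major_m,
                 coverage = cov_m, loh = minor_m < 1,
                 amp_dev = major_m - base_major, baseline = baseline),
            class = "bin_profiles")
}

#' @export
print.bin_profiles <- function(x, ...) {
  cat(sprintf("bin_profiles: %d samples x %d bins (%d chromosomes)\n",
              nrow(x$minor), nrow(x$bins), length(unique(x$bins$chrom))))
  invisible(x)
}

#' Gene-level copy-number calls
#'
#' Each gene takes the copy-number values of the segment containing its
#' midpoint.  Calls: `relative_amp` (total copy number at least
#' `amp_gain` = 2 copies above the sample baseline total), `focal_amp`
#' (relative amplification on a segment with log10(length) <
#' `focal_log10_len` = 6.5), `loh` (minor < 1), `deep_deletion` (total
#' < `deep_del_total` = 0.5).  Genes with no covering segment are
#' absent from the result.
#'
#' @param segments a segment table.
#' @param gene_coords data.frame `gene`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param baseline optional precomputed baseline.
#' @param amp_gain,focal_log10_len,deep_del_total rule thresholds.
#' @return data.frame: `sample_id`, `gene`, `major`, `minor`, `total`,
#'   `seg_length`, `relative_amp`, `focal_amp`, `loh`, `deep_deletion`.
#' @export
gene_calls <- function(segments, gene_coords, baseline = NULL, amp_gain = 2,
                       focal_log10_len = 6.5, deep_del_total = 0.5) {
  segments <- segment_table(segments)
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(gene_coords)))
  gene_coords$chrom <- normalize_chrom(gene_coords$chrom)
  gene_coords$mid <- floor((gene_coords$start + gene_coords$end) / 2)
  if (is.null(baseline)) baseline <- compute_baseline(segments)
  res <- list()
  for (sid in unique(segments$sample_id)) {
    ss <- segments[segments$sample_id == sid, , drop = FALSE]
    bt <- baseline$total[match(sid, baseline$sample_id)]
    if (is.na(bt)) next
    for (g in seq_len(nrow(gene_coords))) {
      seg <- ss[ss$chrom == gene_coords$chrom[g] &
                  ss$start <= gene_coords$mid[g] &
                  ss$end > gene_coords$mid[g], , drop = FALSE]
      if (!nrow(seg)) next
      tot <- seg$major[1] + seg$minor[1]
      len <- seg$end[1] - seg$start[1]
      rel <- tot >= bt + amp_gain
      res[[length(res) + 1]] <- data.frame(
        sample_id = sid, gene = gene_coords$gene[g], major = seg$major[1],
        minor = seg$minor[1], total = tot, seg_length = len,
        relative_amp = rel, focal_amp = rel && log10(len) < focal_log10_len,
        loh = seg$minor[1] < 1, deep_deletion = tot < deep_del_total,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(sample_id = character(0), gene = character(0),
                      major = numeric(0), minor = numeric(0),
                      total = numeric(0), seg_length = numeric(0),
                      relative_amp = logical(0), focal_amp = logical(0),
                      loh = logical(0), deep_deletion = logical(0))
  rownames(out) <- NULL
  out
}

## per-sample summary of a region from bin profiles
.region_summaries <- function(profiles, region) {
  idx <- which(profiles$bins$chrom == region$chrom &
                 profiles$bins$start < region$end &
                 profiles$bins$end > region$start)
  if (!length(idx)) stop_fmt("region overlaps no bins")
  loh_frac <- rowMeans(profiles$loh[, idx, drop = FALSE], na.rm = TRUE)
  amp <- rowMeans(profiles$amp_dev[, idx, drop = FALSE], na.rm = TRUE)
  data.frame(sample_id = rownames(profiles$loh), loh_frac = loh_frac,
             amp = amp, stringsAsFactors = FALSE)
}

.safe_welch <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    return(list(t = 0, p = 1, flagged = TRUE))
  if (sd(x) == 0 && sd(y) == 0) {
    ## degenerate variance: identical means are uninformative (p = 1);
    ## complete separation is maximally significant
    if (mean(x) == mean(y)) return(list(t = 0, p = 1, flagged = TRUE))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0, flagged = TRUE))
  }
  tt <- t.test(x, y)
  list(t = unname(tt$statistic), p = tt$p.value, flagged = FALSE)
}

.safe_ci <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2 || sd(x) == 0)
    return(c(mean(x), mean(x)))
  as.numeric(t.test(x)$conf.int)
}

#' Per-region LOH / amplification statistics between two groups
#'
#' For each region, summarises every sample's LOH fraction (share of
#' non-missing bins with LOH) and mean baseline-corrected amplification
#' deviation, reports per-group means with 95% one-sample-t confidence
#' intervals, and Welch two-sample t tests between the groups on both
#' variables.  Degenerate variance yields p = 1 with a flag.
#'
#' @param profiles a `bin_profiles` object.
#' @param groups named character/factor vector, sample id -> group
#'   (exactly two groups used, >= 2 samples each).
#' @param regions data.frame `chrom`, `start`, `end` (0-based
#'   half-open), optional `name`.
#' @return data.frame, one row per region, with per-group estimates,
#'   CIs, t statistics and p values for LOH fraction and amplification.
#' @export
group_region_stats <- function(profiles, groups, regions) {
  glev <- unique(na.omit(as.character(groups)))
  if (length(glev) != 2L) stop_fmt("exactly two groups are required")
  out <- lapply(seq_len(nrow(regions)), function(r) {
    region <- regions[r, ]
    s <- .region_summaries(profiles, region)
    g <- as.character(groups[s$sample_id])
    s1 <- s[g %in% glev[1], ]; s2 <- s[g %in% glev[2], ]
    if (nrow(s1) < 2 || nrow(s2) < 2)
      stop_fmt("fewer than 2 samples in a group for region %d", r)
    wl <- .safe_welch(s1$loh_frac, s2$loh_frac)
    wa <- .safe_welch(s1$amp, s2$amp)
    ci1l <- .safe_ci(s1$loh_frac); ci2l <- .safe_ci(s2$loh_frac)
    ci1a <- .safe_ci(s1$amp); ci2a <- .safe_ci(s2$amp)
    data.frame(region = region$name %||% sprintf("%s:%g-%g", region$chrom,
                                                 region$start, region$end),
               chrom = region$chrom, start = region$start, end = region$end,
               group1 = glev[1], group2 = glev[2],
               loh_frac1 = mean(s1$loh_frac, na.rm = TRUE),
               loh_frac1_lo = ci1l[1], loh_frac1_hi = ci1l[2],
               loh_frac2 = mean(s2$loh_frac, na.rm = TRUE),
               loh_frac2_lo = ci2l[1], loh_frac2_hi = ci2l[2],
               loh_t = wl$t, loh_p = wl$p,
               amp1 = mean(s1$amp, na.rm = TRUE),
               amp1_lo = ci1a[1], amp1_hi = ci1a[2],
               amp2 = mean(s2$amp, na.rm = TRUE),
               amp2_lo = ci2a[1], amp2_hi = ci2a[2],
               amp_t = wa$t, amp_p = wa$p,
               flagged = wl$flagged || wa$flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## vectorised per-bin Welch t between two row-subsets of a matrix
.binwise_welch <- function(m1, m2) {
  n1 <- colSums(is.finite(m1)); n2 <- colSums(is.finite(m2))
  mu1 <- colMeans(m1, na.rm = TRUE); mu2 <- colMeans(m2, na.rm = TRUE)
  v1 <- apply(m1, 2, function(x) var(x, na.rm = TRUE))
  v2 <- apply(m2, 2, function(x) var(x, na.rm = TRUE))
  se2 <- v1 / n1 + v2 / n2
  t <- (mu1 - mu2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  ## zero variance in both groups: identical means are uninformative,
  ## complete separation is maximally significant
  sep <- se2 == 0 & !is.na(se2) & mu1 != mu2
  p[sep] <- 0
  t[sep] <- sign(mu1 - mu2)[sep] * Inf
  bad <- (!is.finite(t) & !sep) | (!is.finite(p)) | n1 < 2 | n2 < 2
  p[bad] <- 1
  t[bad] <- 0
  list(t = t, p = p, diff = mu1 - mu2)
}

#' Detect differential LOH / amplification regions between groups
#'
#' Runs a per-bin Welch t test between the two groups (on the 0/1 LOH
#' indicator or on the amplification deviation), adjusts p values by
#' Benjamini-Hochberg across all tested bins, and reports maximal runs
#' of significant bins: runs separated by at most `gap_bins`
#' non-significant bins are merged, and merged runs with fewer than
#' `min_span_bins` significant bins are discarded.  The direction says
#' which group is higher.
#'
#' @param profiles a `bin_profiles` object.
#' @param groups named vector, sample id -> group (two groups).
#' @param variable `"loh"` or `"amp"`.
#' @param alpha BH-adjusted significance level.
#' @param min_span_bins minimum number of significant bins per region.
#' @param gap_bins maximum non-significant gap merged over.
#' @return data.frame `chrom`, `start`, `end`, `n_bins`, `direction`
#'   (`"group1"` or `"group2"`), `mean_diff`; zero rows when nothing is
#'   significant.
#' @export
differential_regions <- function(profiles, groups, variable = c("loh", "amp"),
                                 alpha = 0.05, min_span_bins = 10,
                                 gap_bins = 2) {
  variable <- match.arg(variable)
  glev <- unique(na.omit(as.character(groups)))
  if (length(glev) != 2L) stop_fmt("exactly two groups are required")
  m <- if (variable == "loh") profiles$loh + 0 else profiles$amp_dev
  ids <- rownames(m)
  g <- as.character(groups[ids])
  w <- .binwise_welch(m[g %in% glev[1], , drop = FALSE],
                      m[g %in% glev[2], , drop = FALSE])
  q <- p.adjust(w$p, method = "BH")
  sig <- q <= alpha
  bins <- profiles$bins
  res <- list()
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    s <- sig[idx]
    s[is.na(s)] <- FALSE
    if (!any(s)) next
    r <- rle(s)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    ## merge runs across small gaps
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] - 1 <= gap_bins)
        merged$end[nrow(merged)] <- runs$end[i]
      else merged <- rbind(merged, runs[i, ])
    }
    for (i in seq_len(nrow(merged))) {
      span <- merged$start[i]:merged$end[i]
      nsig <- sum(s[span])
      if (nsig < min_span_bins) next
      d <- mean(w$diff[idx[span]][s[span]], na.rm = TRUE)
      res[[length(res) + 1]] <- data.frame(
        chrom = ch, start = bins$start[idx[merged$start[i]]],
        end = bins$end[idx[merged$end[i]]], n_bins = nsig,
        direction = if (d >= 0) glev[1] else glev[2], mean_diff = d,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_bins = integer(0),
                      direction = character(0), mean_diff = numeric(0))
  rownames(out) <- NULL
  out
}

#' Co-occurrence of two binary sample states
#'
#' Builds the 2x2 table of `statusA` x `statusB`, reports the sample
#' odds ratio `ad/bc` (with the Haldane 0.5 correction when any cell is
#' zero, flagged) and the two-sided Fisher exact p value.  An
#' all-constant vector yields an undefined OR and p = 1, flagged.
#'
#' @param statusA,statusB logical vectors over the same samples.
#' @return list: `or`, `p`, `table`, `haldane`, `flagged`.
#' @export
cooccurrence <- function(statusA, statusB) {
  stopifnot(length(statusA) == length(statusB))
  keep <- !is.na(statusA) & !is.na(statusB)
  a <- as.logical(statusA[keep]); b <- as.logical(statusB[keep])
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                2, 2, byrow = TRUE,
                dimnames = list(A = c("TRUE", "FALSE"),
                                B = c("TRUE", "FALSE")))
  if (length(unique(a)) < 2 || length(unique(b)) < 2)
    return(list(or = NA_real_, p = 1, table = tab, haldane = FALSE,
                flagged = TRUE))
  haldane <- any(tab == 0)
  tc <- if (haldane) tab + 0.5 else tab
  or <- (tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1])
  p <- fisher.test(tab)$p.value
  list(or = or, p = p, table = tab, haldane = haldane, flagged = FALSE)
}
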