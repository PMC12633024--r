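## Synthetic cohort generator.  Emulates the statistical structure of
## the pipeline's inputs -- signature-mixture SNV catalogs,
## HRD-dependent microhomology-deletion and scar rates, group-specific
## regional LOH enrichment, inflammation-linked expression and cell
## fractions -- together with ground-truth labels, so every downstream
## stage is testable without external data.

IS_GENE_SETS_NAMES <- c("type_i_ifn", "chemokine_tcell", "cd8_cytotoxic",
                        "ifng_response")

#' The packaged four inflammation signature gene sets (synthetic)
#'
#' Placeholder gene sets standing in for the published type-I IFN,
#' chemokine T-cell recruitment, activated CD8 and IFN-gamma response
#' signatures; gene symbols are synthetic.  Substitute the published
#' GMTs for real analyses.
#'
#' @param genes_per_set genes per signature (default 30).
#' @return named list of four gene-symbol vectors.
#' @export
is_gene_sets <- function(genes_per_set = 30) {
  pre <- c("T1IFN", "CHEMOK", "CD8ACT", "IFNG")
  setNames(lapply(pre, function(p) sprintf("%s_%03d", p, seq_len(genes_per_set))),
           IS_GENE_SETS_NAMES)
}

#' Gene coordinates on the default synthetic genome
#'
#' BRCA1/2, TP53, a DDR panel and the oncogene amplification panel,
#' each as a 100-kb locus (0-based half-open coordinates).
#'
#' @return data.frame `gene`, `chrom`, `start`, `end`.
#' @export
default_gene_coords <- function() {
  g <- rbind(
    c("BRCA1", "5", 30e6), c("BRCA2", "6", 60e6), c("TP53", "7", 10e6),
    c("PALB2", "1", 20e6), c("RAD51C", "1", 150e6), c("ATM", "2", 25e6),
    c("CHEK2", "2", 140e6), c("BARD1", "4", 15e6), c("BRIP1", "4", 100e6),
    c("FANCA", "7", 70e6), c("XRCC2", "8", 15e6), c("MRE11", "8", 60e6),
    c("BCL11A", "1", 80e6), c("BCL6", "2", 100e6), c("CCND1", "3", 20e6),
    c("CDK6", "3", 120e6), c("EGFR", "4", 60e6), c("FGFR1", "5", 80e6),
    c("KRAS", "6", 20e6), c("TERT", "7", 60e6))
  data.frame(gene = g[, 1], chrom = g[, 2], start = as.numeric(g[, 3]),
             end = as.numeric(g[, 3]) + 1e5, stringsAsFactors = FALSE)
}

#' The DDR gene panel used by the simulator and the enrichment examples
#' @return character vector of gene symbols.
#' @export
default_ddr_genes <- function() {
  c("BRCA1", "BRCA2", "PALB2", "RAD51C", "ATM", "CHEK2", "BARD1", "BRIP1",
    "FANCA", "XRCC2", "MRE11")
}

#' Cohort simulation configuration
#'
#' The defaults define the packaged synthetic study conditions: a
#' 600-sample, three-tumor-type cohort (one type per immunogenomic
#' group pattern) with strong HRD effect sizes on signatures, indels,
#' scars, regional LOH and inflammation.  `zero_effects = TRUE` keeps
#' the cohort structure (prevalences, seeds, sample sizes) but removes
#' every HRD-dependent effect, for null-calibration experiments.
#'
#' @param n_samples named integer vector, samples per tumor type.
#' @param group named character vector, tumor type -> "dHpC" (HRD
#'   hotter) or "dCpH" (HRD colder).
#' @param hrd_prevalence named fractions per type.
#' @param mmrd_rate,pole_rate hypermutator fractions (drawn first; such
#'   samples are never HRD).
#' @param snv_meanlog,snv_sdlog log-normal SNV burden per sample;
#'   hypermutators are scaled by `mmrd_burden_mult` / `pole_burden_mult`.
#' @param sbs45_rate,sbs45_weight fraction of samples dominated by the
#'   8-oxo-G artifact spectrum and its mixture weight there.
#' @param mh_del_mean,nonmh_del_mean Poisson means of >= 5 bp deletions
#'   with / without >= 2 bp microhomology, by HRD status.
#' @param breakpoint_rate per-bp copy-number breakpoint rate by status.
#' @param p_loh,p_amp per-segment probabilities of LOH / amplification.
#' @param p_whole_chrom_loh per-chromosome whole-chromosome LOH rate.
#' @param region_effects data.frame `chrom`, `start`, `end`, `group`,
#'   `p_loh_hrd`, `p_loh_other`: region forced to LOH with the
#'   status-conditional probability in samples of the matching group.
#' @param hrd_is_effect latent inflammation shift of HRD per group
#'   (positive in dHpC, negative in dCpH, in latent sd units).
#' @param region_is_beta,og_amp_is_beta latent IS effects of region LOH
#'   and oncogene amplification.
#' @param p_og_amp probability of a focal oncogene amplification by
#'   HRD status.
#' @param expression_amplitude,expression_noise_sd signal amplitude on
#'   the four IS gene sets and the per-observation Gaussian noise sd.
#' @param n_background_genes,genes_per_set expression matrix geometry.
#' @param cell_tilt log-scale tilt of the "cluster 1" cytotoxic cell
#'   types with latent IS in the Dirichlet cell-fraction model.
#' @param biallelic_brca_fraction fraction of HRD samples given a
#'   biallelic BRCA1/2 loss (the classifier's seed labels).
#' @param monoallelic_brca_rate fraction of HRP samples given a single
#'   (monoallelic) pathogenic BRCA hit as distractors.
#' @param ddr_alt_prob per-gene DDR alteration probability by status.
#' @param tp53_alt_prob TP53 alteration probability by status.
#' @param seed integer random seed; fixed seed gives byte-identical
#'   cohorts.
#' @param genome a `genome_build`.
#' @param zero_effects remove all HRD-dependent effects.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = c(OVX = 250, LUX = 200, GIX = 150),
                          group = c(OVX = "dHpC", LUX = "dCpH", GIX = "dHpC"),
                          hrd_prevalence = c(OVX = 0.35, LUX = 0.25, GIX = 0.15),
                          mmrd_rate = 0.05, pole_rate = 0.02,
                          snv_meanlog = log(80), snv_sdlog = 0.6,
                          mmrd_burden_mult = 15, pole_burden_mult = 150,
                          sbs45_rate = 0.01, sbs45_weight = 0.6,
                          mh_del_mean = c(HRD = 12, HRP = 1),
                          nonmh_del_mean = c(HRD = 6, HRP = 3),
                          breakpoint_rate = c(HRD = 6e-8, HRP = 8e-9),
                          p_loh = c(HRD = 0.35, HRP = 0.04),
                          p_amp = c(HRD = 0.20, HRP = 0.08),
                          p_whole_chrom_loh = c(HRD = 0.04, HRP = 0.005),
                          region_effects = data.frame(
                            chrom = "3", start = 50e6, end = 55e6,
                            group = "dCpH", p_loh_hrd = 0.8,
                            p_loh_other = 0.2, stringsAsFactors = FALSE),
                          hrd_is_effect = c(dHpC = 1.2, dCpH = -1.2),
                          region_is_beta = -0.8, og_amp_is_beta = -0.5,
                          p_og_amp = c(HRD = 0.20, HRP = 0.05),
                          expression_amplitude = 1.0,
                          expression_noise_sd = 0.5,
                          n_background_genes = 380, genes_per_set = 30,
                          cell_tilt = 0.6,
                          biallelic_brca_fraction = 0.5,
                          monoallelic_brca_rate = 0.05,
                          ddr_alt_prob = c(HRD = 0.15, HRP = 0.05),
                          tp53_alt_prob = c(HRD = 0.5, HRP = 0.3),
                          seed = 1, genome = default_genome(),
                          zero_effects = FALSE) {
  cfg <- as.list(environment())
  if (zero_effects) {
    cfg$mh_del_mean["HRD"] <- cfg$mh_del_mean["HRP"]
    cfg$nonmh_del_mean["HRD"] <- cfg$nonmh_del_mean["HRP"]
    cfg$breakpoint_rate["HRD"] <- cfg$breakpoint_rate["HRP"]
    cfg$p_loh["HRD"] <- cfg$p_loh["HRP"]
    cfg$p_amp["HRD"] <- cfg$p_amp["HRP"]
    cfg$p_whole_chrom_loh["HRD"] <- cfg$p_whole_chrom_loh["HRP"]
    cfg$p_og_amp["HRD"] <- cfg$p_og_amp["HRP"]
    cfg$hrd_is_effect[] <- 0
    cfg$region_is_beta <- 0
    cfg$og_amp_is_beta <- 0
    if (nrow(cfg$region_effects))
      cfg$region_effects$p_loh_hrd <- cfg$region_effects$p_loh_other
    cfg$ddr_alt_prob["HRD"] <- cfg$ddr_alt_prob["HRP"]
    cfg$tp53_alt_prob["HRD"] <- cfg$tp53_alt_prob["HRP"]
    cfg$zero_signature_effect <- TRUE
  } else cfg$zero_signature_effect <- FALSE
  probs <- c(cfg$hrd_prevalence, cfg$mmrd_rate, cfg$pole_rate,
             cfg$sbs45_rate, cfg$sbs45_weight, cfg$p_loh, cfg$p_amp,
             cfg$p_whole_chrom_loh, cfg$p_og_amp,
             cfg$biallelic_brca_fraction, cfg$monoallelic_brca_rate,
             cfg$ddr_alt_prob, cfg$tp53_alt_prob)
  if (nrow(cfg$region_effects))
    probs <- c(probs, cfg$region_effects$p_loh_hrd,
               cfg$region_effects$p_loh_other)
  if (any(probs < 0 | probs > 1))
    stop_fmt("all probabilities must lie in [0, 1]")
  if (!identical(sort(names(cfg$n_samples)), sort(names(cfg$group))) ||
      !identical(sort(names(cfg$n_samples)), sort(names(cfg$hrd_prevalence))))
    stop_fmt("n_samples, group and hrd_prevalence must share tumor-type names")
  structure(cfg, class = "cohort_config")
}

## mixture weights over the packaged spectrum panel per condition
.signature_weights <- function(status, artifact, zero_effect) {
  w <- switch(status,
    HRD = c(background_flat = 0.15, clock_like = 0.25, hrd_like = 0.60,
            mmr_like = 0, pole_like = 0, artifact_like = 0),
    HRP = c(background_flat = 0.30, clock_like = 0.70, hrd_like = 0,
            mmr_like = 0, pole_like = 0, artifact_like = 0),
    MMRD = c(background_flat = 0.10, clock_like = 0.20, hrd_like = 0,
             mmr_like = 0.70, pole_like = 0, artifact_like = 0),
    POLE = c(background_flat = 0.10, clock_like = 0.10, hrd_like = 0,
             mmr_like = 0, pole_like = 0.80, artifact_like = 0))
  if (zero_effect && status %in% c("HRD", "HRP"))
    w <- c(background_flat = 0.30, clock_like = 0.70, hrd_like = 0,
           mmr_like = 0, pole_like = 0, artifact_like = 0)
  if (artifact) w <- w * 0.4 + c(background_flat = 0, clock_like = 0,
                                 hrd_like = 0, mmr_like = 0, pole_like = 0,
                                 artifact_like = 0.6)
  w
}

.rand_bases <- function(n, len) {
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i)
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = ""), character(1))
}

## replace [start, end) of one sample's segments on `chrom` with a
## single segment carrying (major, minor)
.splice_region <- function(seg, chrom, start, end, major, minor) {
  on_ch <- seg$chrom == chrom
  keep <- seg[!on_ch, , drop = FALSE]
  ch <- seg[on_ch, , drop = FALSE]
  pieces <- list()
  for (i in seq_len(nrow(ch))) {
    if (ch$end[i] <= start || ch$start[i] >= end) {
      pieces[[length(pieces) + 1]] <- ch[i, ]
    } else {
      if (ch$start[i] < start) {
        left <- ch[i, ]; left$end <- start
        pieces[[length(pieces) + 1]] <- left
      }
      if (ch$end[i] > end) {
        right <- ch[i, ]; right$start <- end
        pieces[[length(pieces) + 1]] <- right
      }
    }
  }
  new <- data.frame(sample_id = seg$sample_id[1], chrom = chrom,
                    start = start, end = end, major = major, minor = minor,
                    stringsAsFactors = FALSE)
  out <- rbind(keep, do.call(rbind, c(pieces, list(new))))
  out[order(out$chrom, out$start), , drop = FALSE]
}

## one sample's background segmentation
.simulate_segments <- function(sid, status_scar, cfg) {
  genome <- cfg$genome
  ch_v <- character(0); s_v <- e_v <- ma_v <- mi_v <- numeric(0)
  for (chrom in names(genome$chrom_lengths)) {
    L <- genome$chrom_lengths[[chrom]]
    if (runif(1) < cfg$p_whole_chrom_loh[[status_scar]]) {
      ch_v <- c(ch_v, chrom); s_v <- c(s_v, 0); e_v <- c(e_v, L)
      ma_v <- c(ma_v, 1); mi_v <- c(mi_v, 0)
      next
    }
    nbp <- rpois(1, L * cfg$breakpoint_rate[[status_scar]])
    bounds <- sort(unique(c(0, floor(runif(nbp) * (L - 2)) + 1, L)))
    ns <- length(bounds) - 1
    u <- runif(ns)
    minor <- ifelse(u < cfg$p_loh[[status_scar]], 0, 1)
    major <- ifelse(u < cfg$p_loh[[status_scar]], 1,
                    ifelse(u < cfg$p_loh[[status_scar]] + cfg$p_amp[[status_scar]],
                           sample(2:3, ns, replace = TRUE), 1))
    ch_v <- c(ch_v, rep(chrom, ns)); s_v <- c(s_v, bounds[-length(bounds)])
    e_v <- c(e_v, bounds[-1]); ma_v <- c(ma_v, major); mi_v <- c(mi_v, minor)
  }
  data.frame(sample_id = sid, chrom = ch_v, start = s_v, end = e_v,
             major = ma_v, minor = mi_v, stringsAsFactors = FALSE)
}

## a batch of mutation rows as plain column vectors (cheap to emit in
## the simulation loop; one data.frame is assembled at the end)
.mut_batch <- function(sid, chrom, pos, ref, alt, variant_class, consequence,
                       sift = NA_character_, polyphen = NA_character_,
                       clinvar = NA_character_, gene = NA_character_,
                       context = NA_character_, flank5 = NA_character_,
                       flank3 = NA_character_) {
  k <- length(pos)
  list(sample_id = rep_len(sid, k), chrom = rep_len(chrom, k), pos = pos,
       ref = rep_len(ref, k), alt = rep_len(alt, k),
       variant_class = rep_len(variant_class, k),
       consequence = rep_len(consequence, k), sift = rep_len(sift, k),
       polyphen = rep_len(polyphen, k), clinvar = rep_len(clinvar, k),
       gene = rep_len(gene, k), context = rep_len(context, k),
       flank5 = rep_len(flank5, k), flank3 = rep_len(flank3, k))
}

.bind_mut_batches <- function(batches) {
  batches <- batches[!vapply(batches, is.null, logical(1))]
  cols <- names(batches[[1]])
  out <- lapply(setNames(cols, cols), function(cn)
    unlist(lapply(batches, `[[`, cn), use.names = FALSE))
  do.call(data.frame, c(out, stringsAsFactors = FALSE))
}

#' Simulate a cohort with ground truth
#'
#' Generates every input of the pipeline -- somatic mutations (SNVs
#' with trinucleotide contexts, microhomology-flagged deletions with
#' inline flanking sequence, pathogenic BRCA/DDR hits), allele-specific
#' copy-number segments with HRD-dependent scar geometries and planted
#' region effects, germline and promoter-silencing calls, expression,
#' cell fractions, annotations with MSI scores -- plus a ground-truth
#' table.  Fixed seed implies byte-identical output.
#'
#' @param config a [cohort_config()].
#' @return object of class `hrd_cohort`: list with `mutations`,
#'   `segments`, `expression`, `cell_fractions`, `annotations`,
#'   `germline`, `silencing`, `truth`, `gene_coords`, `gene_sets`,
#'   `genome`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) stop_fmt("need a cohort_config")
  cfg <- config
  set.seed(cfg$seed)
  types <- rep(names(cfg$n_samples), cfg$n_samples)
  n <- length(types)
  ids <- sprintf("%s_%04d", types, seq_len(n))
  grp <- cfg$group[types]

  ## --- truth assignment ---------------------------------------------
  u <- runif(n)
  hclass <- ifelse(u < cfg$mmrd_rate, "MMRD",
                   ifelse(u < cfg$mmrd_rate + cfg$pole_rate, "POLE", "MMRP"))
  hrd <- hclass == "MMRP" & runif(n) < cfg$hrd_prevalence[types]
  status <- ifelse(hclass != "MMRP", hclass, ifelse(hrd, "HRD", "HRP"))
  artifact <- runif(n) < cfg$sbs45_rate

  brca_status <- rep("WT", n)
  seed_pick <- hrd & runif(n) < cfg$biallelic_brca_fraction
  brca_status[seed_pick] <- sample(c("BRCA1-/-", "BRCA2-/-"),
                                   sum(seed_pick), replace = TRUE)
  mono <- status == "HRP" & runif(n) < cfg$monoallelic_brca_rate

  ## --- mutations ----------------------------------------------------
  panel <- spectrum_panel()
  chan <- sbs96_channels()
  chan_ref <- substr(chan, 3, 3)
  chan_alt <- substr(chan, 5, 5)
  chan_ctx <- paste0(substr(chan, 1, 1), chan_ref, substr(chan, 7, 7))
  chrom_names <- names(cfg$genome$chrom_lengths)
  chrom_prob <- cfg$genome$chrom_lengths / sum(cfg$genome$chrom_lengths)
  scar_status <- ifelse(status %in% c("HRD"), "HRD", "HRP")

  mut_parts <- vector("list", n)
  germ_parts <- list()
  sil_parts <- list()
  og_amp <- rep(FALSE, n)
  og_gene <- rep(NA_character_, n)
  coords <- default_gene_coords()
  ddr_genes <- setdiff(default_ddr_genes(), c("BRCA1", "BRCA2"))
  seg_parts <- vector("list", n)
  n_regions <- nrow(cfg$region_effects)
  region_loh <- matrix(FALSE, n, max(n_regions, 1))

  for (i in seq_len(n)) {
    sid <- ids[i]
    burden_mult <- switch(status[i], MMRD = cfg$mmrd_burden_mult,
                          POLE = cfg$pole_burden_mult, 1)
    n_snv <- max(1L, round(rlnorm(1, cfg$snv_meanlog + log(burden_mult),
                                  cfg$snv_sdlog)))
    w <- .signature_weights(status[i], artifact[i], cfg$zero_signature_effect)
    mix <- as.numeric(panel[, names(w)] %*% w)
    cnt <- rmultinom(1, n_snv, mix)[, 1]
    ci <- rep.int(seq_len(96), cnt)
    ref <- chan_ref[ci]; alt <- chan_alt[ci]; ctx <- chan_ctx[ci]
    flip <- runif(length(ci)) < 0.5
    if (any(flip)) {
      ref[flip] <- chartr("CT", "GA", ref[flip])
      alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
      ctx[flip] <- revcomp(ctx[flip])
    }
    cons <- sample(c("Missense_Mutation", "Silent", "Nonsense_Mutation",
                     "Splice_Site", "3'UTR"), length(ci), replace = TRUE,
                   prob = c(0.50, 0.30, 0.05, 0.02, 0.13))
    sift <- poly <- rep(NA_character_, length(ci))
    mis <- cons == "Missense_Mutation"
    sift[mis] <- sample(c("deleterious", "tolerated"), sum(mis), TRUE,
                        prob = c(0.3, 0.7))
    poly[mis] <- sample(c("probably_damaging", "possibly_damaging", "benign"),
                        sum(mis), TRUE, prob = c(0.3, 0.3, 0.4))
    snv_chrom <- sample(chrom_names, length(ci), TRUE, prob = chrom_prob)
    snv <- .mut_batch(sid, snv_chrom,
                      floor(runif(length(ci)) *
                              (cfg$genome$chrom_lengths[snv_chrom] - 4)) + 2,
                      ref, alt, "SNV", cons, sift = sift, polyphen = poly,
                      context = ctx)

    ## deletions: microhomology-positive and -negative, plus small
    ## (< 5 bp) distractors that must count toward neither feature
    del_status <- if (status[i] %in% c("HRD")) "HRD" else "HRP"
    n_mh <- rpois(1, cfg$mh_del_mean[[del_status]])
    n_nomh <- rpois(1, cfg$nonmh_del_mean[[del_status]])
    n_small <- rpois(1, 1.5)
    mk_del <- function(k, mh) {
      if (k == 0L) return(NULL)
      len <- sample(5:12, k, replace = TRUE)
      deleted <- vapply(len, function(l)
        paste(sample(DNA_BASES, l, replace = TRUE), collapse = ""), character(1))
      flank3 <- character(k); flank5 <- character(k); anchor <- character(k)
      for (j in seq_len(k)) {
        if (mh) {
          mhl <- sample(2:min(4, len[j] - 1), 1)
          tail3 <- paste(sample(DNA_BASES, 10 - mhl, replace = TRUE),
                         collapse = "")
          flank3[j] <- paste0(substr(deleted[j], 1, mhl), tail3)
          anchor[j] <- sample(DNA_BASES, 1)
          flank5[j] <- paste0(.rand_bases(1, 9), anchor[j])
        } else {
          first <- substr(deleted[j], 1, 1)
          last <- substr(deleted[j], len[j], len[j])
          flank3[j] <- paste0(sample(setdiff(DNA_BASES, first), 1),
                              .rand_bases(1, 9))
          anchor[j] <- sample(setdiff(DNA_BASES, last), 1)
          flank5[j] <- paste0(.rand_bases(1, 9), anchor[j])
        }
      }
      ch <- sample(chrom_names, k, TRUE, prob = chrom_prob)
      .mut_batch(sid, ch,
                 floor(runif(k) * (cfg$genome$chrom_lengths[ch] - 30)) + 2,
                 paste0(anchor, deleted), anchor, "deletion",
                 sample(c("Frame_Shift_Del", "In_Frame_Del"), k, TRUE,
                        prob = c(0.8, 0.2)),
                 flank5 = flank5, flank3 = flank3)
    }
    mk_small <- function(k) {
      if (k == 0L) return(NULL)
      len <- sample(2:4, k, replace = TRUE)
      deleted <- vapply(len, function(l)
        paste(sample(DNA_BASES, l, replace = TRUE), collapse = ""), character(1))
      anchor <- .rand_bases(k, 1)
      ch <- sample(chrom_names, k, TRUE, prob = chrom_prob)
      .mut_batch(sid, ch,
                 floor(runif(k) * (cfg$genome$chrom_lengths[ch] - 30)) + 2,
                 paste0(anchor, deleted), anchor, "deletion",
                 "Frame_Shift_Del", flank5 = .rand_bases(k, 10),
                 flank3 = .rand_bases(k, 10))
    }
    parts <- list(snv, mk_del(n_mh, TRUE), mk_del(n_nomh, FALSE),
                  mk_small(n_small))

    ## --- copy-number segments ---------------------------------------
    seg <- .simulate_segments(sid, scar_status[i], cfg)
    if (n_regions > 0) for (r in seq_len(n_regions)) {
      re <- cfg$region_effects[r, ]
      if (grp[i] != re$group) next
      p <- if (hrd[i]) re$p_loh_hrd else re$p_loh_other
      loh_here <- runif(1) < p
      region_loh[i, r] <- loh_here
      seg <- .splice_region(seg, re$chrom, re$start, re$end, 1,
                            if (loh_here) 0 else 1)
    }
    if (runif(1) < cfg$p_og_amp[[ifelse(hrd[i], "HRD", "HRP")]]) {
      og <- coords[coords$gene %in% default_oncogene_panel(), ]
      pick <- og[sample(nrow(og), 1), ]
      seg <- .splice_region(seg, pick$chrom, max(0, pick$start - 2.5e5),
                            pick$end + 2.5e5, 3, 1)
      og_amp[i] <- TRUE
      og_gene[i] <- pick$gene
    }

    ## --- BRCA / DDR alterations -------------------------------------
    brca_hit_rows <- NULL
    add_path_snv <- function(gene, clin = "pathogenic") {
      gc <- coords[match(gene, coords$gene), ]
      .mut_batch(sid, gc$chrom, gc$start + sample(1e5, length(gene)), "C",
                 "T", "SNV", "Nonsense_Mutation", clinvar = clin,
                 gene = gene, context = "ACA")
    }
    brca_loh <- function(gene) {
      gc <- coords[coords$gene == gene, ]
      .splice_region(seg, gc$chrom, max(0, gc$start - 2e6), gc$end + 2e6, 1, 0)
    }
    if (brca_status[i] != "WT") {
      gene <- if (brca_status[i] == "BRCA1-/-") "BRCA1" else "BRCA2"
      mech <- sample(c("somatic_loh", "germline_loh", "silencing_loh",
                       "deep_deletion", "two_somatic"), 1,
                     prob = c(0.45, 0.20, 0.15, 0.10, 0.10))
      if (mech == "silencing_loh" && gene == "BRCA2") mech <- "germline_loh"
      if (mech == "somatic_loh") {
        brca_hit_rows <- add_path_snv(gene)
        seg <- brca_loh(gene)
      } else if (mech == "germline_loh") {
        germ_parts[[length(germ_parts) + 1]] <-
          data.frame(sample_id = sid, gene = gene, stringsAsFactors = FALSE)
        seg <- brca_loh(gene)
      } else if (mech == "silencing_loh") {
        sil_parts[[length(sil_parts) + 1]] <-
          data.frame(sample_id = sid, gene = gene, stringsAsFactors = FALSE)
        seg <- brca_loh(gene)
      } else if (mech == "deep_deletion") {
        gc <- coords[coords$gene == gene, ]
        seg <- .splice_region(seg, gc$chrom, max(0, gc$start - 2.5e5),
                              gc$end + 2.5e5, 0, 0)
      } else {  # two independent somatic hits
        brca_hit_rows <- add_path_snv(c(gene, gene))
      }
    } else if (mono[i]) {
      brca_hit_rows <- add_path_snv(sample(c("BRCA1", "BRCA2"), 1))
    }
    alt_p <- cfg$ddr_alt_prob[[ifelse(hrd[i], "HRD", "HRP")]]
    ddr_alt <- ddr_genes[runif(length(ddr_genes)) < alt_p]
    ddr_rows <- if (length(ddr_alt)) add_path_snv(ddr_alt) else NULL
    tp53_rows <- if (runif(1) < cfg$tp53_alt_prob[[ifelse(hrd[i], "HRD",
                                                          "HRP")]])
      add_path_snv("TP53") else NULL

    mut_parts[[i]] <- c(parts, list(brca_hit_rows, ddr_rows, tp53_rows))
    seg_parts[[i]] <- seg
  }

  mutations <- mutation_table(.bind_mut_batches(do.call(c, mut_parts)))
  segments <- segment_table(do.call(rbind, seg_parts))
  germline <- if (length(germ_parts)) do.call(rbind, germ_parts) else
    data.frame(sample_id = character(0), gene = character(0))
  silencing <- if (length(sil_parts)) do.call(rbind, sil_parts) else
    data.frame(sample_id = character(0), gene = character(0))

  ## --- latent inflammation and expression ---------------------------
  region_effect_term <- if (n_regions > 0)
    cfg$region_is_beta * rowSums(region_loh[, seq_len(n_regions), drop = FALSE])
  else 0
  latent_is <- cfg$hrd_is_effect[grp] * hrd + region_effect_term +
    cfg$og_amp_is_beta * og_amp + rnorm(n)
  latent_is <- as.numeric(latent_is)

  sets <- is_gene_sets(cfg$genes_per_set)
  set_genes <- unlist(sets, use.names = FALSE)
  genes <- c(set_genes, sprintf("BG_%04d", seq_len(cfg$n_background_genes)))
  base_expr <- rnorm(length(genes), 5, 1)
  in_set <- as.numeric(genes %in% set_genes)
  expression <- base_expr +
    outer(in_set, latent_is) * cfg$expression_amplitude +
    matrix(rnorm(length(genes) * n, 0, cfg$expression_noise_sd),
           length(genes), n)
  dimnames(expression) <- list(genes, ids)

  ## --- cell fractions (tilted Dirichlet) ----------------------------
  cell_types <- c("T_CD8", "T_CD4", "NK", "B_cell", "M1_macrophage",
                  "M2_macrophage", "DC", "Treg", "Neutrophil", "Fibroblast",
                  "Endothelial", "Mast")
  cluster1 <- c("T_CD8", "NK", "M1_macrophage", "DC")
  alpha0 <- setNames(c(8, 10, 4, 6, 3, 5, 2, 3, 4, 12, 8, 2), cell_types)
  fractions <- t(vapply(seq_len(n), function(i) {
    a <- alpha0 * ifelse(cell_types %in% cluster1,
                         exp(cfg$cell_tilt * latent_is[i]), 1)
    g <- rgamma(length(a), shape = a, rate = 1)
    g / sum(g)
  }, numeric(length(cell_types))))
  dimnames(fractions) <- list(ids, cell_types)

  ## --- annotations and truth ----------------------------------------
  sex <- ifelse(types == "OVX", "female",
                sample(c("female", "male"), n, replace = TRUE))
  viral <- ifelse(types == "GIX" & runif(n) < 0.25, "positive", "negative")
  msi <- ifelse(hclass == "MMRD", pmax(0, rnorm(n, 10, 2)),
                abs(rnorm(n, 0.4, 0.3)))
  annotations <- annotation_table(data.frame(
    sample_id = ids, tumor_type = types, sex = sex, viral_status = viral,
    subtype = NA_character_, msi_score = msi, stringsAsFactors = FALSE))

  truth <- data.frame(sample_id = ids, tumor_type = types,
                      group = as.character(grp), hrd_status = hrd,
                      hypermutation_class = hclass, brca_status = brca_status,
                      latent_is = latent_is, sbs45_artifact = artifact,
                      og_amp = og_amp, og_gene = og_gene,
                      stringsAsFactors = FALSE)
  if (n_regions > 0)
    for (r in seq_len(n_regions))
      truth[[sprintf("region_loh_%d", r)]] <- region_loh[, r]

  structure(list(mutations = mutations, segments = segments,
                 expression = expression, cell_fractions = fractions,
                 annotations = annotations, germline = germline,
                 silencing = silencing, truth = truth,
                 gene_coords = coords, gene_sets = sets,
                 genome = cfg$genome, config = cfg),
            class = "hrd_cohort")
}

#' @export
print.hrd_cohort <- function(x, ...) {
  cat(sprintf("hrd_cohort: %d samples (%s), %d mutations, %d segments\n",
              nrow(x$truth),
              paste(names(x$config$n_samples), collapse = "/"),
              nrow(x$mutations), nrow(x$segments)))
  invisible(x)
}

#' Write ground-truth tables to TSV
#'
#' @param truth the `truth` data.frame of a simulated cohort.
#' @param dir output directory (created if missing).
#' @return invisibly, the written file path.
#' @export
emit_truth_tables <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "truth.tsv")
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Write every cohort input file to a directory
#'
#' Emits the five pipeline inputs (MAF, segments, expression, cell
#' fractions, annotations) plus germline, silencing, gene sets and the
#' truth tables, all as tab-separated text.
#'
#' @param cohort an `hrd_cohort`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_maf(cohort$mutations, file.path(dir, "mutations.maf"))
  write_segments(cohort$segments, file.path(dir, "segments.tsv"))
  write_matrix_tsv(cohort$expression, file.path(dir, "expression.tsv"),
                   "gene")
  write_matrix_tsv(cohort$cell_fractions, file.path(dir, "cell_fractions.tsv"),
                   "sample")
  write_annotations(cohort$annotations, file.path(dir, "annotations.tsv"))
  write.table(cohort$germline, file.path(dir, "germline.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$silencing, file.path(dir, "silencing.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_gmt(cohort$gene_sets, file.path(dir, "inflammation_sets.gmt"))
  emit_truth_tables(cohort$truth, dir)
  invisible(dir)
}
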