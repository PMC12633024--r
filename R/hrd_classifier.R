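## The HRD classifier: feature assembly, biallelic BRCA/DDR calls,
## neighbor-augmented seed labels, two-step gradient-boosted training
## with stratified 5-fold cross-validation, pan-cancer + tumor-type
## score combination, and final label overrides.

HRD_FEATURE_COLS <- c("sig3_likelihood", "sig3_cosine", "sig3_exposure",
                      "sig3_exposure_fraction", "gis", "n_del_mh",
                      "n_del_no_mh")

#' Assemble the per-sample HRD feature table
#'
#' Computes, for every sample in the cohort: the Sig3 posterior
#' likelihood (HRD-like vs clock/background spectrum), cosine
#' similarity to the HRD-like spectrum, NNLS Sig3 exposure and exposure
#' fraction, the genomic instability score (GIS), the two
#' microhomology-deletion counts, and TMB.  Also runs the
#' hypermutation triage and the SBS45-like artifact filter.
#'
#' @param mutations a mutation table.
#' @param segments a segment table.
#' @param genome a `genome_build`.
#' @param annotations annotation table (for MSI scores).
#' @param panel spectrum panel (default [spectrum_panel()]).
#' @param footprint_mb exome footprint for TMB.
#' @param prior_pos prior for the Sig3 likelihood.
#' @param ... further arguments to [triage_hypermutation()] /
#'   [filter_artifact_samples()] are taken at their defaults.
#' @return list: `features` (data.frame, one row per sample),
#'   `triage` (hypermutation calls), `artifact` (filter result),
#'   `catalog` (SBS96 matrix), `fractions` (NNLS fraction matrix).
#' @export
hrd_features <- function(mutations, segments, genome, annotations,
                         panel = spectrum_panel(), footprint_mb = 38,
                         prior_pos = 0.5, ...) {
  ids <- sort(unique(c(mutations$sample_id, segments$sample_id)))
  catalog <- build_catalog(mutations, genome, samples = ids)
  neg_spectrum <- 0.5 * panel[, "clock_like"] + 0.5 * panel[, "background_flat"]
  nn <- lapply(rownames(catalog), function(s)
    nnls_exposures(catalog[s, ], panel))
  fractions <- do.call(rbind, lapply(nn, `[[`, "fractions"))
  rownames(fractions) <- rownames(catalog)
  feats <- data.frame(
    sample_id = rownames(catalog),
    sig3_likelihood = vapply(rownames(catalog), function(s)
      sig3_likelihood(catalog[s, ], panel[, "hrd_like"], neg_spectrum,
                      prior_pos), numeric(1)),
    sig3_cosine = vapply(rownames(catalog), function(s)
      if (sum(catalog[s, ]) > 0) cosine_to(catalog[s, ], panel[, "hrd_like"])
      else 0, numeric(1)),
    sig3_exposure = vapply(nn, function(x) x$exposures[["hrd_like"]],
                           numeric(1)),
    sig3_exposure_fraction = vapply(nn, function(x)
      x$fractions[["hrd_like"]], numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  scars <- compute_scars(segments, genome)
  mh <- count_microhomology_deletions(mutations, genome, samples = ids)
  tmb <- compute_tmb(mutations, footprint_mb, samples = ids)
  feats <- merge(feats, scars[, c("sample_id", "gis")], all.x = TRUE)
  feats <- merge(feats, mh, all.x = TRUE)
  feats <- merge(feats, tmb[, c("sample_id", "tmb")], all.x = TRUE)
  for (col in c("gis", "n_del_mh", "n_del_no_mh", "tmb"))
    feats[[col]][is.na(feats[[col]])] <- 0
  feats <- feats[match(ids, feats$sample_id), ]
  rownames(feats) <- NULL

  msi <- setNames(annotations$msi_score, annotations$sample_id)[ids]
  triage <- triage_hypermutation(fractions, msi,
                                 setNames(feats$tmb, feats$sample_id))
  artifact <- filter_artifact_samples(fractions)
  list(features = feats, triage = triage, artifact = artifact,
       catalog = catalog, fractions = fractions)
}

#' Biallelic-loss calls per sample and gene
#'
#' Assembles per-(sample, gene) hits -- pathogenic somatic variants
#' (each counted separately), pathogenic germline variants, promoter
#' silencing, deep deletion -- plus the locus LOH state, and calls:
#' `biallelic_loss` for a deep deletion alone, >= 2 independent hits,
#' or one hit plus LOH; `monoallelic` for a single hit without LOH;
#' `intact` otherwise.
#'
#' @param mutations a mutation table.
#' @param germline data.frame `sample_id`, `gene` of pathogenic
#'   germline variants (may be empty).
#' @param gene_cna a [gene_calls()] result covering the genes.
#' @param silencing data.frame `sample_id`, `gene` of silencing calls.
#' @param genes genes to call (default BRCA1/BRCA2).
#' @param samples sample ids to cover (default: all in `gene_cna`).
#' @return data.frame: `sample_id`, `gene`, `n_somatic`, `germline`,
#'   `silenced`, `deep_deletion`, `loh`, `n_hits`, `status`.
#' @export
call_biallelic <- function(mutations, germline, gene_cna, silencing,
                           genes = c("BRCA1", "BRCA2"), samples = NULL) {
  if (is.null(samples)) samples <- unique(gene_cna$sample_id)
  mutations <- mutation_table(mutations)
  path <- is_pathogenic(mutations) & !is.na(mutations$gene)
  som <- mutations[path & mutations$gene %in% genes, , drop = FALSE]
  grid <- expand.grid(sample_id = samples, gene = genes,
                      stringsAsFactors = FALSE)
  key <- function(s, g) paste(s, g, sep = "\r")
  n_som <- table(key(som$sample_id, som$gene))
  grid$n_somatic <- as.integer(n_som[key(grid$sample_id, grid$gene)])
  grid$n_somatic[is.na(grid$n_somatic)] <- 0L
  grid$germline <- key(grid$sample_id, grid$gene) %in%
    key(germline$sample_id, germline$gene)
  grid$silenced <- key(grid$sample_id, grid$gene) %in%
    key(silencing$sample_id, silencing$gene)
  cna_key <- key(gene_cna$sample_id, gene_cna$gene)
  m <- match(key(grid$sample_id, grid$gene), cna_key)
  grid$deep_deletion <- !is.na(m) & gene_cna$deep_deletion[m]
  grid$loh <- !is.na(m) & gene_cna$loh[m]
  grid$n_hits <- grid$n_somatic + grid$germline + grid$silenced +
    grid$deep_deletion
  grid$status <- ifelse(
    grid$deep_deletion | grid$n_hits >= 2 | (grid$n_hits == 1 & grid$loh),
    "biallelic_loss",
    ifelse(grid$n_hits == 1, "monoallelic", "intact"))
  grid
}

## cosine similarity of one standardized feature vector against rows
## of a standardized matrix; identical vectors get similarity 1 even
## at zero norm
.cosine_rows <- function(v, m) {
  nv <- sqrt(sum(v^2))
  nm <- sqrt(rowSums(m^2))
  num <- as.numeric(m %*% v)
  sim <- num / (nv * nm)
  zero <- nv == 0 | nm == 0
  if (any(zero)) {
    same <- apply(m, 1, function(r) isTRUE(all.equal(r, v)))
    sim[zero] <- ifelse(same[zero], 1, 0)
  }
  sim
}

#' Seed labels with nearest-neighbor augmentation
#'
#' BRCA1/2 biallelic-loss samples are labeled positive; for each, the
#' `k` most similar BRCA-wild-type samples (cosine similarity in
#' z-scored feature space) are added as positives, keeping a single
#' instance of samples selected by several seeds.  Everything else is
#' labeled negative for the first training step.
#'
#' @param features feature data.frame with `sample_id` and the columns
#'   in `feature_cols`.
#' @param biallelic a [call_biallelic()] result covering BRCA1/BRCA2.
#' @param k neighbors per seed (default 3).
#' @param feature_cols feature columns used for the similarity.
#' @return list: `labels` (named logical, TRUE = positive), `seeds`,
#'   `neighbors` (augmented sample ids).
#' @export
seed_labels <- function(features, biallelic, k = 3,
                        feature_cols = HRD_FEATURE_COLS) {
  brca <- biallelic[biallelic$gene %in% c("BRCA1", "BRCA2"), ]
  seeds <- unique(brca$sample_id[brca$status == "biallelic_loss"])
  seeds <- intersect(seeds, features$sample_id)
  if (length(seeds) < 2L)
    stop_fmt("training aborted: %d BRCA1/2 biallelic seed(s); at least 2 required",
             length(seeds))
  X <- scale(as.matrix(features[, feature_cols]))
  X[!is.finite(X)] <- 0
  rownames(X) <- features$sample_id
  wt <- setdiff(features$sample_id, seeds)
  neighbors <- unique(unlist(lapply(seeds, function(s) {
    sim <- .cosine_rows(X[s, ], X[wt, , drop = FALSE])
    wt[order(sim, decreasing = TRUE)[seq_len(min(k, length(wt)))]]
  })))
  labels <- setNames(features$sample_id %in% c(seeds, neighbors),
                     features$sample_id)
  list(labels = labels, seeds = seeds, neighbors = neighbors)
}

.default_grid <- function() {
  expand.grid(nrounds = c(100, 300), max_depth = c(2, 3),
              eta = c(0.05, 0.1))
}

## stratified fold assignment
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

.fit_xgb <- function(X, y, params, nrounds) {
  dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y))
  xgboost::xgb.train(
    params = c(params, list(objective = "binary:logistic", nthread = 1,
                            subsample = 1, colsample_bytree = 1)),
    data = dtrain, nrounds = nrounds, verbose = 0)
}

#' One gradient-boosting training step with 5-fold CV model selection
#'
#' Trains a gradient-boosted tree ensemble, choosing trees, depth and
#' learning rate on a grid by stratified cross-validated AUC, then
#' refits the winning configuration on all samples.  Deterministic for
#' a fixed seed (no row/column subsampling).
#'
#' @param X numeric feature matrix (rows = samples, rownames set).
#' @param labels logical vector (TRUE = positive), length nrow(X).
#' @param cv_folds number of folds (default 5).
#' @param grid data.frame of `nrounds`, `max_depth`, `eta` candidates.
#' @param seed integer seed for the fold assignment.
#' @return list: `model` (xgboost handle), `best` (chosen row of the
#'   grid), `cv_auc`, `cv_scores` (out-of-fold scores), `grid_report`,
#'   `scores` (in-sample scores of the refit model).
#' @export
train_step <- function(X, labels, cv_folds = 5, grid = .default_grid(),
                       seed = 1) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stop_fmt("training requires both classes")
  set.seed(seed)
  fold <- .stratified_folds(labels, cv_folds)
  grid_auc <- numeric(nrow(grid))
  oof_all <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    oof <- rep(NA_real_, nrow(X))
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      if (length(unique(labels[tr])) < 2L) next
      m <- .fit_xgb(X[tr, , drop = FALSE], labels[tr],
                    list(max_depth = grid$max_depth[g], eta = grid$eta[g]),
                    grid$nrounds[g])
      oof[!tr] <- predict(m, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE]))
    }
    grid_auc[g] <- auc_score(oof, labels)
    oof_all[[g]] <- oof
  }
  best <- which.max(grid_auc)
  best_scores <- oof_all[[best]]
  model <- .fit_xgb(X, labels,
                    list(max_depth = grid$max_depth[best],
                         eta = grid$eta[best]), grid$nrounds[best])
  scores <- predict(model, xgboost::xgb.DMatrix(X))
  names(scores) <- rownames(X)
  list(model = model, best = grid[best, ], cv_auc = grid_auc[best],
       cv_scores = setNames(best_scores, rownames(X)),
       grid_report = cbind(grid, cv_auc = grid_auc), scores = scores)
}

#' Relabel samples from first-step scores
#'
#' Negatives scoring at or above `theta_hi` become positive; positives
#' scoring below `theta_lo` become negative.
#'
#' @param scores named numeric scores from the first-step model.
#' @param labels named logical labels.
#' @param theta_hi,theta_lo relabeling thresholds (default 0.5 / 0.5).
#' @return list: `labels` (revised), `n_up`, `n_down`.
#' @export
relabel <- function(scores, labels, theta_hi = 0.5, theta_lo = 0.5) {
  scores <- scores[names(labels)]
  up <- !labels & scores >= theta_hi
  down <- labels & scores < theta_lo
  labels[up] <- TRUE
  labels[down] <- FALSE
  list(labels = labels, n_up = sum(up), n_down = sum(down))
}

## full two-step protocol on one sample subset
.two_step <- function(X, init_labels, cv_folds, grid, theta_hi, theta_lo,
                      seed) {
  s1 <- train_step(X, init_labels, cv_folds, grid, seed)
  rl <- relabel(s1$scores, init_labels, theta_hi, theta_lo)
  labels2 <- rl$labels
  if (length(unique(labels2)) < 2L) labels2 <- init_labels  # degenerate flip
  s2 <- train_step(X, labels2, cv_folds, grid, seed + 1L)
  list(step1 = s1, step2 = s2, labels2 = labels2,
       n_up = rl$n_up, n_down = rl$n_down)
}

#' Train the two-step HRD classifier bundle
#'
#' Runs the full protocol: seed labels from BRCA1/2 biallelic losses
#' with 3-nearest-neighbor augmentation, a first gradient-boosted
#' classifier (5-fold CV over the hyperparameter grid), score-based
#' relabeling, and a second classifier trained the same way.  This is
#' done (a) pan-cancer on all samples, (b) per tumor type for types
#' with more than `min_type_seeds` seed-positive training samples and
#' at least `min_type_total` samples (otherwise that type falls to the
#' pooled model, with a warning when the seed count alone qualified),
#' and (c) once for the pooled remaining types.  Hypermutated
#' (MMRD/POLE) and artifact samples must be excluded beforehand.
#'
#' @param features feature data.frame (`sample_id` + feature columns).
#' @param annotations annotation table (`tumor_type`).
#' @param biallelic a [call_biallelic()] result.
#' @param cv_folds,grid,theta_hi,theta_lo,seed training controls.
#' @param min_type_seeds,min_type_total tumor-type model thresholds.
#' @param feature_cols feature columns used by the models.
#' @param fit_type_models set FALSE to train the pan-cancer model only
#'   (tumor-type scores then fall back to the pan score), e.g. for
#'   calibration experiments that assess only the pan score.
#' @return object of class `hrd_bundle`: pan / per-type / pooled
#'   models, the types each serves, thresholds and metadata.
#' @export
train_hrd_classifier <- function(features, annotations, biallelic,
                                 cv_folds = 5, grid = .default_grid(),
                                 theta_hi = 0.5, theta_lo = 0.5, seed = 1,
                                 min_type_seeds = 10, min_type_total = 30,
                                 feature_cols = HRD_FEATURE_COLS,
                                 fit_type_models = TRUE) {
  annotations <- annotation_table(annotations)
  X <- as.matrix(features[, feature_cols])
  rownames(X) <- features$sample_id
  sl <- seed_labels(features, biallelic, feature_cols = feature_cols)
  type <- setNames(annotations$tumor_type,
                   annotations$sample_id)[features$sample_id]

  pan <- .two_step(X, sl$labels, cv_folds, grid, theta_hi, theta_lo, seed)

  type_models <- list()
  pooled_types <- character(0)
  if (!fit_type_models) pooled_types <- unique(type)
  else for (tt in unique(type)) {
    in_type <- which(type == tt)
    n_seed_pos <- sum(sl$labels[in_type])
    if (n_seed_pos > min_type_seeds && length(in_type) >= min_type_total &&
        n_seed_pos < length(in_type)) {
      type_models[[tt]] <- .two_step(X[in_type, , drop = FALSE],
                                     sl$labels[in_type], cv_folds, grid,
                                     theta_hi, theta_lo, seed)
    } else {
      if (n_seed_pos > min_type_seeds)
        warn_fmt("tumor type %s has > %d HRD training samples but < %d samples: served by the pooled model",
                 tt, min_type_seeds, min_type_total)
      pooled_types <- c(pooled_types, tt)
    }
  }
  pooled <- NULL
  if (length(pooled_types) && fit_type_models) {
    in_pool <- which(type %in% pooled_types)
    if (length(unique(sl$labels[in_pool])) == 2L)
      pooled <- .two_step(X[in_pool, , drop = FALSE], sl$labels[in_pool],
                          cv_folds, grid, theta_hi, theta_lo, seed)
  }
  structure(list(pan = pan, type_models = type_models, pooled = pooled,
                 pooled_types = pooled_types, seed_info = sl,
                 feature_cols = feature_cols,
                 metadata = list(cv_folds = cv_folds, grid = grid,
                                 theta_hi = theta_hi, theta_lo = theta_lo,
                                 seed = seed)),
            class = "hrd_bundle")
}

#' @export
print.hrd_bundle <- function(x, ...) {
  cat(sprintf(
    "hrd_bundle: pan-cancer model (CV AUC %.3f), %d tumor-type model(s), %s pooled model\n",
    x$pan$step2$cv_auc, length(x$type_models),
    if (is.null(x$pooled)) "no" else "one"))
  invisible(x)
}

#' Score and label samples with a trained bundle
#'
#' Each sample gets a pan-cancer score and a tumor-type score (its
#' type's model, or the pooled model for remaining/unknown types, or
#' the pan model when no pooled model exists).  Labels: HRD when both
#' scores reach their thresholds, HRP when both are below, HRD_low
#' otherwise.  Samples listed as MMRD/POLE in `hypermutation` pass
#' through with that class, never rescored into HRD.
#'
#' @param features feature data.frame for the samples to classify.
#' @param annotations annotation table.
#' @param bundle a trained `hrd_bundle`.
#' @param theta_pan,theta_type decision thresholds (default 0.5 / 0.5).
#' @param hypermutation optional triage data.frame (`sample_id`,
#'   `class`).
#' @return data.frame: `sample_id`, `tumor_type`, `pan_score`,
#'   `type_score`, `label` (HRD / HRD_low / HRP / MMRD / POLE).
#' @export
classify_hrd <- function(features, annotations, bundle, theta_pan = 0.5,
                         theta_type = 0.5, hypermutation = NULL) {
  annotations <- annotation_table(annotations)
  X <- as.matrix(features[, bundle$feature_cols])
  rownames(X) <- features$sample_id
  dm <- xgboost::xgb.DMatrix(X)
  pan_score <- predict(bundle$pan$step2$model, dm)
  type <- setNames(annotations$tumor_type,
                   annotations$sample_id)[features$sample_id]
  type_score <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    mdl <- bundle$type_models[[type[i]]]
    if (is.null(mdl)) mdl <- bundle$pooled
    type_score[i] <- if (is.null(mdl)) pan_score[i] else
      predict(mdl$step2$model,
              xgboost::xgb.DMatrix(X[i, , drop = FALSE]))
  }
  label <- ifelse(pan_score >= theta_pan & type_score >= theta_type, "HRD",
                  ifelse(pan_score < theta_pan & type_score < theta_type,
                         "HRP", "HRD_low"))
  if (!is.null(hypermutation)) {
    hm <- hypermutation$class[match(features$sample_id,
                                    hypermutation$sample_id)]
    passthrough <- !is.na(hm) & hm %in% c("MMRD", "POLE")
    label[passthrough] <- hm[passthrough]
  }
  data.frame(sample_id = features$sample_id, tumor_type = as.character(type),
             pan_score = pan_score, type_score = type_score, label = label,
             stringsAsFactors = FALSE)
}

#' Override BRCA1/2 biallelic samples into the HRD class
#'
#' Samples with biallelic BRCA1/2 loss that were classified HRD_low or
#' HRP are relabeled HRD with the override flag set; the summary
#' reports the overridden fraction of all final HRD labels.
#'
#' @param labels a [classify_hrd()] result.
#' @param biallelic a [call_biallelic()] result.
#' @return object of class `hrd_labels`: the labels data.frame (with
#'   `override` column) plus `n_override`, `n_hrd`, `override_pct`
#'   (percentage, one decimal as printed).
#' @export
finalize_labels <- function(labels, biallelic) {
  brca <- biallelic[biallelic$gene %in% c("BRCA1", "BRCA2") &
                      biallelic$status == "biallelic_loss", ]
  is_brca <- labels$sample_id %in% brca$sample_id
  override <- is_brca & labels$label %in% c("HRD_low", "HRP")
  labels$label[override] <- "HRD"
  labels$override <- override
  n_hrd <- sum(labels$label == "HRD")
  res <- list(labels = labels, n_override = sum(override), n_hrd = n_hrd,
              override_fraction = if (n_hrd > 0) sum(override) / n_hrd else 0)
  res$override_pct <- round(100 * res$override_fraction, 1)
  class(res) <- "hrd_labels"
  res
}

#' @export
print.hrd_labels <- function(x, ...) {
  tab <- table(x$labels$label)
  cat("final HRD labels:", paste(sprintf("%s=%d", names(tab), tab),
                                 collapse = ", "), "\n")
  cat(sprintf("overridden by BRCA1/2 biallelic status: %d out of %d; %.1f%% of all HRD-labeled cases\n",
              x$n_override, x$n_hrd, x$override_pct))
  invisible(x)
}

#' Run the full HRD classification pipeline on a cohort
#'
#' Convenience wrapper used by the examples and the acceptance script:
#' feature extraction, hypermutation triage, artifact-sample removal,
#' BRCA biallelic calls, two-step classifier training on the eligible
#' (MMRP, non-artifact) samples, classification of every sample, and
#' the BRCA override.
#'
#' @param cohort an `hrd_cohort` (or a list with the same elements).
#' @param seed training seed.
#' @param ... passed to [train_hrd_classifier()].
#' @return list: `features` (the [hrd_features()] result), `biallelic`,
#'   `bundle`, `labels` (an `hrd_labels` object), `eligible` (sample
#'   ids used in training).
#' @export
hrd_pipeline <- function(cohort, seed = 1, ...) {
  fx <- hrd_features(cohort$mutations, cohort$segments, cohort$genome,
                     cohort$annotations)
  gc_brca <- gene_calls(cohort$segments,
                        cohort$gene_coords[cohort$gene_coords$gene %in%
                                             c("BRCA1", "BRCA2"), ])
  biallelic <- call_biallelic(cohort$mutations, cohort$germline, gc_brca,
                              cohort$silencing,
                              samples = fx$features$sample_id)
  mmrp <- fx$triage$sample_id[fx$triage$class == "MMRP"]
  eligible <- setdiff(mmrp, fx$artifact$excluded)
  feats_train <- fx$features[fx$features$sample_id %in% eligible, ]
  bundle <- train_hrd_classifier(feats_train, cohort$annotations,
                                 biallelic, seed = seed, ...)
  keep <- !(fx$features$sample_id %in% fx$artifact$excluded)
  cls <- classify_hrd(fx$features[keep, ], cohort$annotations, bundle,
                      hypermutation = fx$triage)
  labels <- finalize_labels(cls, biallelic)
  list(features = fx, biallelic = biallelic, bundle = bundle,
       labels = labels, eligible = eligible)
}
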