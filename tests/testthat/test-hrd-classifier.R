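bial_row <- function(sample_id, gene = "BRCA1", status = "biallelic_loss") {
  data.frame(sample_id = sample_id, gene = gene, status = status,
             stringsAsFactors = FALSE)
}

fake_features <- function(X, ids = sprintf("S%03d", seq_len(nrow(X)))) {
  df <- data.frame(sample_id = ids, X, stringsAsFactors = FALSE)
  names(df)[-1] <- hrdimmune:::HRD_FEATURE_COLS[seq_len(ncol(X))]
  df
}

test_that("biallelic calls combine hits, LOH and deep deletions", {
  mut <- rbind(
    mut_row("A", gene = "BRCA1", consequence = "Nonsense_Mutation"),
    mut_row("B", gene = "BRCA1", consequence = "Nonsense_Mutation"),
    mut_row("E", gene = "BRCA2", consequence = "Nonsense_Mutation",
            pos = 50),
    mut_row("E", gene = "BRCA2", consequence = "Frame_Shift_Del",
            ref = "CAA", alt = "C", pos = 99))
  cna <- data.frame(sample_id = rep(c("A", "B", "C", "D", "E"), each = 2),
                    gene = rep(c("BRCA1", "BRCA2"), 5),
                    deep_deletion = FALSE, loh = FALSE)
  cna$loh[cna$sample_id == "A" & cna$gene == "BRCA1"] <- TRUE
  cna$deep_deletion[cna$sample_id == "D" & cna$gene == "BRCA2"] <- TRUE
  germ <- data.frame(sample_id = "C", gene = "BRCA1")
  sil <- data.frame(sample_id = character(0), gene = character(0))
  calls <- call_biallelic(mut, germ, cna, sil,
                          samples = c("A", "B", "C", "D", "E"))
  get <- function(s, g) calls$status[calls$sample_id == s & calls$gene == g]
  expect_equal(get("A", "BRCA1"), "biallelic_loss")  # somatic + LOH
  expect_equal(get("B", "BRCA1"), "monoallelic")     # one hit, no LOH
  expect_equal(get("C", "BRCA1"), "monoallelic")     # germline only
  expect_equal(get("D", "BRCA2"), "biallelic_loss")  # deep deletion alone
  expect_equal(get("E", "BRCA2"), "biallelic_loss")  # two somatic hits
  expect_equal(get("A", "BRCA2"), "intact")
})

test_that("seed labels augment each seed with its 3 nearest neighbors", {
  set.seed(101)
  # 10 well-separated seeds and a far cloud of negatives: every seed's
  # neighbors are distinct, so positives = 10 + 30
  X <- rbind(matrix(rnorm(10 * 4, 10, 0.01), 10),
             matrix(rnorm(90 * 4, 0, 1), 90))
  X[11:40, ] <- X[1:10, ][rep(1:10, each = 3), ] +
    matrix(rnorm(120, 0, 0.001), 30)
  f <- fake_features(X)
  bi <- bial_row(f$sample_id[1:10])
  fc <- hrdimmune:::HRD_FEATURE_COLS[1:4]
  sl <- seed_labels(f, bi, feature_cols = fc)
  expect_equal(sum(sl$labels), 40L)
  expect_setequal(sl$neighbors, f$sample_id[11:40])

  # shared nearest neighbors are kept once
  X2 <- rbind(matrix(rnorm(2 * 4, 5, 0.001), 2),
              matrix(5, 1, 4),
              matrix(rnorm(40 * 4, -5, 0.5), 40))
  f2 <- fake_features(X2)
  sl2 <- seed_labels(f2, bial_row(f2$sample_id[1:2]), feature_cols = fc)
  expect_lt(sum(sl2$labels), 2 + 6 + 1)

  # a WT sample identical in features to a seed is its top neighbor
  X3 <- rbind(matrix(rnorm(5 * 4, 0, 1), 5))
  X3 <- rbind(X3, X3[1, , drop = FALSE])
  f3 <- fake_features(X3)
  sl3 <- seed_labels(f3, bial_row(f3$sample_id[c(1, 2)]), k = 1,
                     feature_cols = fc)
  expect_true(f3$sample_id[6] %in% sl3$neighbors)

  expect_error(seed_labels(f, bial_row(f$sample_id[1]), feature_cols = fc),
               "at least 2")
})

test_that("training separates separable classes and is deterministic", {
  set.seed(7)
  n <- 200
  X <- matrix(rnorm(n * 3), n, dimnames = list(sprintf("S%03d", 1:n), NULL))
  y <- X[, 1] + 0.5 * X[, 2] > 0
  small_grid <- data.frame(nrounds = 50, max_depth = 2, eta = 0.1)
  fit <- train_step(X, y, cv_folds = 5, grid = small_grid, seed = 3)
  expect_gte(fit$cv_auc, 0.95)
  fit2 <- train_step(X, y, cv_folds = 5, grid = small_grid, seed = 3)
  expect_identical(fit$scores, fit2$scores)
  expect_identical(fit$cv_scores, fit2$cv_scores)
  expect_error(train_step(X, rep(TRUE, n)), "both classes")
})

test_that("shuffled labels give chance-level cross-validated AUC", {
  set.seed(70)
  n <- 150
  X <- matrix(rnorm(n * 4), n, dimnames = list(sprintf("S%03d", 1:n), NULL))
  small_grid <- data.frame(nrounds = 50, max_depth = 2, eta = 0.1)
  aucs <- vapply(1:12, function(s) {
    y <- sample(rep(c(TRUE, FALSE), c(50, 100)))
    train_step(X, y, cv_folds = 5, grid = small_grid, seed = s)$cv_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("relabeling flips by threshold with sane boundaries", {
  scores <- c(a = 0.95, b = 0.05, c = 0.6, d = 0.4)
  labels <- c(a = FALSE, b = TRUE, c = FALSE, d = TRUE)
  r <- relabel(scores, labels, theta_hi = 0.5, theta_lo = 0.5)
  expect_true(r$labels[["a"]])    # negative with high score flips up
  expect_false(r$labels[["b"]])   # positive with low score flips down
  expect_equal(r$n_up, 2L)
  expect_equal(r$n_down, 2L)
  # theta_hi above 1: no upward flips
  r2 <- relabel(scores, labels, theta_hi = 1 + 1e-9, theta_lo = 0)
  expect_equal(r2$n_up, 0L)
  expect_equal(r2$n_down, 0L)
})

test_that("the trained bundle scores by type and labels by both scores", {
  co <- small_cohort()
  fx <- default_small_fx()
  bi <- small_biallelic(co, fx)
  mmrp <- fx$triage$sample_id[fx$triage$class == "MMRP"]
  feats <- fx$features[fx$features$sample_id %in% mmrp, ]
  bundle <- suppressWarnings(
    train_hrd_classifier(feats, co$annotations, bi, seed = 2))
  cls <- classify_hrd(feats, co$annotations, bundle)
  # the label rule is exactly the two-threshold combination
  want <- ifelse(cls$pan_score >= 0.5 & cls$type_score >= 0.5, "HRD",
                 ifelse(cls$pan_score < 0.5 & cls$type_score < 0.5,
                        "HRP", "HRD_low"))
  expect_equal(cls$label, want)
  # hypermutated samples pass through untouched
  cls2 <- classify_hrd(fx$features, co$annotations, bundle,
                       hypermutation = fx$triage)
  hm <- fx$triage$sample_id[fx$triage$class != "MMRP"]
  expect_true(all(cls2$label[cls2$sample_id %in% hm] %in%
                    c("MMRD", "POLE")))
  # every sample is scored by exactly one type-level route
  expect_true(all(is.finite(cls$type_score)))
})

test_that("tumor types without enough seeds fall to the pooled model", {
  co <- small_cohort()
  fx <- default_small_fx()
  bi <- small_biallelic(co, fx)
  mmrp <- fx$triage$sample_id[fx$triage$class == "MMRP"]
  feats <- fx$features[fx$features$sample_id %in% mmrp, ]
  bundle <- suppressWarnings(
    train_hrd_classifier(feats, co$annotations, bi, seed = 2))
  # the small cohort has too few seeds per type for type-level models
  sl <- seed_labels(feats, bi)
  type <- co$annotations$tumor_type[match(feats$sample_id,
                                          co$annotations$sample_id)]
  per_type <- tapply(sl$labels, type, sum)
  expect_true(all(per_type[setdiff(names(per_type),
                                   names(bundle$type_models))] <= 10 |
                    table(type)[setdiff(names(per_type),
                                        names(bundle$type_models))] < 30))
})

test_that("BRCA overrides finalize labels and report their share", {
  labels <- data.frame(
    sample_id = c("A", "B", "C", "D"),
    tumor_type = "T", pan_score = c(0.9, 0.1, 0.2, 0.1),
    type_score = c(0.9, 0.1, 0.9, 0.1),
    label = c("HRD", "HRP", "HRD_low", "HRP"),
    stringsAsFactors = FALSE)
  bi <- bial_row(c("B", "C"))
  fin <- finalize_labels(labels, bi)
  expect_equal(fin$labels$label, c("HRD", "HRD", "HRD", "HRP"))
  expect_equal(fin$labels$override, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(fin$n_hrd, 3L)
  expect_equal(fin$override_pct, round(100 * 2 / 3, 1))
  # BRCA-WT HRP samples are untouched
  expect_equal(fin$labels$label[4], "HRP")
})
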