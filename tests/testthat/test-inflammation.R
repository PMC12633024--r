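rand_expr <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 5, 2), n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  m
}

test_that("ssGSEA is a rank statistic with the expected monotonicities", {
  expr <- rand_expr(100, 6, 5)
  top <- names(sort(expr[, 1], decreasing = TRUE))[1:10]
  bottom <- names(sort(expr[, 1]))[1:10]
  s <- ssgsea(expr, list(top = top, bottom = bottom), normalize = "none")
  expect_gt(s["top", 1], s["bottom", 1])

  # any strictly monotone transform of one sample leaves it unchanged
  expr2 <- expr
  expr2[, 1] <- exp(expr2[, 1] / 3)
  s2 <- ssgsea(expr2, list(top = top, bottom = bottom), normalize = "none")
  expect_equal(s2[, 1], s[, 1])

  expect_error(ssgsea(expr, list(ghost = c("NOPE1", "NOPE2"))), "ghost")
})

test_that("ssGSEA agrees with an independently coded ranked-walk reference", {
  set.seed(6)
  for (i in 1:20) {
    ng <- sample(40:120, 1)
    expr <- rand_expr(ng, sample(2:5, 1), seed = 100 + i)
    set_size <- sample(5:15, 1)
    set <- sample(rownames(expr), set_size)
    s <- ssgsea(expr, list(S = set), tau = 0.25, normalize = "none")
    for (j in seq_len(ncol(expr))) {
      ref <- oracle_ssgsea_one(expr[, j], rownames(expr), set, tau = 0.25)
      expect_equal(unname(s["S", j]), ref, tolerance = 1e-6)
    }
  }
})

test_that("complement sets move opposite to their sets at tau = 0", {
  expr <- rand_expr(80, 4, 9)
  set <- rownames(expr)[1:20]
  comp <- setdiff(rownames(expr), set)
  s <- ssgsea(expr, list(a = set, b = comp), tau = 0, normalize = "none")
  expect_true(all(sign(s["a", ]) == -sign(s["b", ])))
})

test_that("the Inflammation Score is the mean of four signature scores", {
  expr <- rand_expr(100, 5, 8)
  set <- rownames(expr)[1:12]
  four_same <- list(a = set, b = set, c = set, d = set)
  r <- inflammation_score(expr, four_same)
  expect_equal(r$is, r$a)   # mean of four identical scores
  expect_error(inflammation_score(expr, four_same[1:3]), "4")

  sets <- list(a = rownames(expr)[1:10], b = rownames(expr)[11:20],
               c = rownames(expr)[21:30], d = rownames(expr)[31:40])
  r2 <- inflammation_score(expr, sets)
  expect_equal(r2$is, rowMeans(as.matrix(r2[, c("a", "b", "c", "d")])))
})

test_that("IS recovers the latent inflammation signal of the generator", {
  co <- small_cohort()
  r <- inflammation_score(co$expression, co$gene_sets)
  m <- match(r$sample_id, co$truth$sample_id)
  expect_gt(cor(r$is, co$truth$latent_is[m]), 0.8)
})

test_that("tertile status uses eligible samples only but labels everyone", {
  ann <- data.frame(sample_id = sprintf("S%02d", 1:10), tumor_type = "T",
                    viral_status = c(rep("negative", 9), "positive"))
  is_df <- data.frame(sample_id = ann$sample_id, is = c(1:9, 100))
  r <- tertile_status(is_df, ann)
  el <- r[r$eligible, ]
  expect_equal(as.vector(table(factor(el$status,
                                      c("cold", "intermediate", "hot")))),
               c(3L, 3L, 3L))
  # the viral sample is excluded from thresholds yet labeled hot
  expect_false(r$eligible[10])
  expect_equal(r$status[10], "hot")
  # z is standardized on the eligible samples
  expect_equal(mean(r$z_is[r$eligible]), 0, tolerance = 1e-12)
  expect_equal(sd(r$z_is[r$eligible]), 1, tolerance = 1e-12)

  # degenerate thresholds: everything intermediate, flagged
  is_const <- data.frame(sample_id = ann$sample_id, is = rep(2, 10))
  rc <- tertile_status(is_const, ann)
  expect_true(all(rc$status == "intermediate"))
  expect_true(all(rc$flagged))

  # hypermutated samples excluded from thresholds
  hm <- data.frame(sample_id = c("S08", "S09"), class = "MMRD")
  r2 <- tertile_status(is_df, ann, hm)
  expect_false(any(r2$eligible[8:9]))
  expect_lt(r2$t2[1], r$t2[1])
})

test_that("tertile statuses partition eligible samples near-evenly", {
  set.seed(77)
  for (n in c(9, 10, 14, 23)) {
    ann <- data.frame(sample_id = sprintf("S%02d", 1:n), tumor_type = "T",
                      viral_status = "negative")
    r <- tertile_status(data.frame(sample_id = ann$sample_id,
                                   is = rnorm(n)), ann)
    counts <- table(factor(r$status, c("hot", "intermediate", "cold")))
    expect_lte(max(counts) - min(counts), 1)
  }
})

test_that("IS comparison is a Welch t with HRD-positive sign", {
  x <- c(1, 2, 3); y <- c(1, 2, 3)
  r <- compare_is(c(x, y), rep(c(TRUE, FALSE), each = 3))
  expect_equal(r$t, 0)

  # closed-form Welch on a 6-sample hand example
  a <- c(2.0, 2.5, 3.0); b <- c(1.0, 1.2, 1.1)
  r2 <- compare_is(c(a, b), rep(c(TRUE, FALSE), each = 3))
  tw <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(r2$t, tw)
  expect_gt(r2$t, 0)   # HRD arm higher => positive

  expect_true(compare_is(rep(1, 6), rep(c(TRUE, FALSE), 3))$flagged)
})

test_that("IS regression recovers noise-free coefficients exactly", {
  set.seed(12)
  n <- 60
  hrd <- rbinom(n, 1, 0.4)
  tmb <- rnorm(n)
  z <- 1.0 * hrd - 0.5 * tmb + 0.3
  # noise-free response: lm warns about the perfect fit, by construction
  fit <- suppressWarnings(regress_is(z, hrd, tmb))
  expect_equal(fit$estimate[fit$term == "hrd"], 1.0, tolerance = 1e-8)
  expect_equal(fit$estimate[fit$term == "tmb"], -0.5, tolerance = 1e-8)
  expect_equal(fit$estimate[fit$term == "(Intercept)"], 0.3,
               tolerance = 1e-8)

  # collinearity is an error naming the offending column
  expect_error(regress_is(z, hrd, tmb, extra = data.frame(dup = tmb)),
               "collinear")
})

test_that("genomic IS regression handles degenerate covariates", {
  set.seed(13)
  n <- 50
  loh <- matrix(runif(n * 2), n, dimnames = list(NULL, c("r1", "r2")))
  z <- -0.8 * loh[, 1] + rnorm(n, 0, 0.01)
  fit <- regress_is_on_genomics(z, loh)
  expect_lt(fit$estimate[fit$term == "r1"], 0)

  # all-zero covariates collapse to an intercept-only fit
  fit0 <- regress_is_on_genomics(z, matrix(0, n, 2,
                                           dimnames = list(NULL,
                                                           c("a", "b"))))
  expect_equal(fit0$term, "(Intercept)")

  # duplicated region columns are collinear
  expect_error(regress_is_on_genomics(z, cbind(r1 = loh[, 1],
                                               r1b = loh[, 1])),
               "collinear")
})
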