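test_that("DDR enrichment reproduces exact 2x2 statistics with BH", {
  # gene X altered in 20/100 HRD and 5/100 HRP
  samples <- sprintf("S%03d", 1:200)
  hrd <- setNames(rep(c(TRUE, FALSE), each = 100), samples)
  alt <- matrix(FALSE, 200, 3, dimnames = list(samples, c("X", "Y", "NEVER")))
  alt[1:20, "X"] <- TRUE; alt[101:105, "X"] <- TRUE
  alt[c(1:10, 101:110), "Y"] <- TRUE
  r <- ddr_enrichment(alt, hrd)
  rx <- r[r$gene == "X", ]
  expect_equal(rx$or, (20 * 95) / (80 * 5))   # 4.75
  expect_equal(rx$p, oracle_fisher_p(matrix(c(20, 80, 5, 95), 2,
                                            byrow = TRUE)),
               tolerance = 1e-9)
  # an unaltered gene is flagged with q = 1
  expect_true(r$flagged[r$gene == "NEVER"])
  expect_equal(r$q[r$gene == "NEVER"], 1)
  # equal p values stay equal after BH
  expect_equal(length(unique(r$q[!r$flagged])) <= 2, TRUE)
  expect_warning(ddr_enrichment(alt, hrd, genes = c("X", "GHOST")),
                 "GHOST")
})

test_that("gene-pair epistasis tests the joint-dysfunction indicator", {
  set.seed(41)
  n <- 500
  samples <- sprintf("S%03d", 1:n)
  a <- runif(n) < 0.4; b <- runif(n) < 0.4
  hrd <- setNames(ifelse(a & b, runif(n) < 0.8, runif(n) < 0.1), samples)
  alt <- cbind(A = a, B = b); rownames(alt) <- samples
  r <- pair_epistasis(alt, "A", "B", hrd)
  expect_lt(r$p, 1e-6)
  expect_gt(r$or, 1)

  # a never-altered gene is degenerate
  alt0 <- cbind(A = rep(FALSE, n), B = b); rownames(alt0) <- samples
  r0 <- pair_epistasis(alt0, "A", "B", hrd)
  expect_true(r0$flagged)
  expect_equal(r0$p, 1)
  expect_error(pair_epistasis(alt, "A", "GHOST", hrd), "GHOST")
})

test_that("over-representation p values equal hypergeometric tail sums", {
  universe <- sprintf("U%03d", 1:100)
  sets <- list(hit = universe[1:10], none = universe[91:100])
  gene_list <- c(universe[1:5], universe[40:44])   # 5 of 10 in `hit`
  r <- ora(gene_list, universe, sets)
  expect_equal(r$p[r$set == "hit"],
               phyper(4, 10, 90, 10, lower.tail = FALSE))
  # direct tail-sum oracle
  tail_sum <- sum(vapply(5:10, function(k)
    choose(10, k) * choose(90, 10 - k) / choose(100, 10), numeric(1)))
  expect_equal(r$p[r$set == "hit"], tail_sum, tolerance = 1e-12)

  # list identical to the set is the extreme case
  r2 <- ora(universe[1:10], universe, sets)
  expect_equal(r2$n_hits[r2$set == "hit"], 10L)
  expect_lt(r2$p[r2$set == "hit"], 1e-12)

  # empty intersections everywhere give q = 1
  r3 <- ora(universe[50:59], universe, list(s = universe[1:10]))
  expect_equal(r3$q, 1)
  expect_error(ora(c("ALIEN"), universe, sets), "ALIEN")
})

make_fraction_fixture <- function(n_per = 30, shift = 0, seed = 2024) {
  set.seed(seed)
  samples <- sprintf("S%03d", seq_len(2 * n_per))
  cells <- c("CT1", "CT2", "CT3")
  m <- matrix(abs(rnorm(length(samples) * 3, 1)), ncol = 3,
              dimnames = list(samples, cells))
  m[seq_len(n_per), "CT1"] <- m[seq_len(n_per), "CT1"] + shift
  ann <- data.frame(sample_id = samples, tumor_type = "T")
  groups <- setNames(rep(c("g1", "g2"), each = n_per), samples)
  list(m = m, ann = ann, groups = groups)
}

test_that("delta-Z tables are antisymmetric and centered under the null", {
  fx <- make_fraction_fixture()
  d <- tme_delta(fx$m, fx$ann, fx$groups, comparison = c("g1", "g2"))
  d_swapped <- tme_delta(fx$m, fx$ann, fx$groups,
                         comparison = c("g2", "g1"))
  expect_equal(d$delta_z, -d_swapped$delta_z)

  # identical groups: exactly zero
  m2 <- rbind(fx$m, fx$m)
  rownames(m2) <- c(paste0(rownames(fx$m), "a"), paste0(rownames(fx$m), "b"))
  d0 <- tme_delta(m2,
                  data.frame(sample_id = rownames(m2), tumor_type = "T"),
                  setNames(rep(c("g1", "g2"), each = nrow(fx$m)),
                           rownames(m2)))
  expect_true(all(abs(d0$delta_z) < 1e-12))
})

test_that("a planted one-cell-type shift appears in delta-Z", {
  fx <- make_fraction_fixture(n_per = 200, shift = 1)
  d <- tme_delta(fx$m, fx$ann, fx$groups)
  dz <- d$delta_z[d$cell_type == "CT1"]
  expect_gt(dz, 0.5)
  expect_lt(d$p[d$cell_type == "CT1"], 0.001)
  expect_lt(max(abs(d$delta_z[d$cell_type != "CT1"])), 0.4)
})

test_that("cell-type clustering separates correlated blocks", {
  set.seed(55)
  base1 <- rnorm(40); base2 <- rnorm(40)
  dz <- cbind(A1 = base1, A2 = base1 + rnorm(40, 0, 0.01),
              B1 = base2, B2 = base2 + rnorm(40, 0, 0.01))
  tabs <- data.frame(tumor_type = rep(sprintf("T%02d", 1:40), 4),
                     cell_type = rep(colnames(dz), each = 40),
                     delta_z = as.vector(dz))
  cl <- cluster_celltypes(tabs, k = 2)
  expect_equal(cl[["A1"]], cl[["A2"]])
  expect_equal(cl[["B1"]], cl[["B2"]])
  expect_true(cl[["A1"]] != cl[["B1"]])

  # k = number of cell types: singletons
  cl4 <- cluster_celltypes(tabs, k = 4)
  expect_equal(length(unique(cl4)), 4L)
  expect_error(cluster_celltypes(tabs, k = 10), "exceeds")

  # permuting cell-type order does not change the partition
  tabs_perm <- tabs[order(rev(tabs$cell_type)), ]
  cl_perm <- cluster_celltypes(tabs_perm, k = 2)
  expect_equal(cl_perm[["A1"]] == cl_perm[["A2"]], TRUE)
  expect_true(cl_perm[["A1"]] != cl_perm[["B1"]])
})

test_that("cell-type correlations match closed forms and mask constants", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(1, 3, 2, 4),
             d = rep(5, 4))
  rownames(m) <- sprintf("S%d", 1:4)
  r <- correlate_celltypes(m)
  expect_equal(diag(r$r)[1:3], c(a = 1, b = 1, c = 1))
  expect_equal(r$r["a", "b"], 1)
  expect_equal(r$r["a", "c"], cor(m[, "a"], m[, "c"]))
  expect_true(all(is.na(r$p["d", c("a", "b", "c")])))
  expect_false(any(r$significant["d", ]))
  expect_error(correlate_celltypes(m[1:2, ]), "at least 3")

  # independent columns rarely cross the null bound
  set.seed(66)
  big <- matrix(rnorm(1000 * 8), 1000, 8,
                dimnames = list(NULL, paste0("c", 1:8)))
  rb <- correlate_celltypes(big)
  off <- abs(rb$r[upper.tri(rb$r)])
  expect_gte(mean(off < 0.1), 0.95)
})
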