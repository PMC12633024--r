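seg_df <- function(sample_id, chrom, start, end, major, minor) {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             major = major, minor = minor, stringsAsFactors = FALSE)
}

test_that("baselines are coverage-weighted over segments above 100 kb", {
  # two chromosomes of equal qualifying coverage with majors 2 and 4
  seg <- rbind(seg_df("S1", "1", 0, 50e6, 2, 1),
               seg_df("S1", "2", 0, 50e6, 4, 1))
  b <- compute_baseline(seg)
  expect_equal(b$major, 3)
  expect_equal(b$total, 4)

  b2 <- compute_baseline(seg_df("S1", "1", 0, 1e6, 2, 1))
  expect_equal(c(b2$major, b2$minor, b2$total), c(2, 1, 3))

  # a chromosome holding only a 50-kb segment contributes nothing
  seg3 <- rbind(seg_df("S1", "1", 0, 50e6, 2, 1),
                seg_df("S1", "2", 0, 5e4, 9, 9))
  expect_equal(compute_baseline(seg3)$major, 2)

  expect_message(b4 <- compute_baseline(seg_df("S1", "1", 0, 5e4, 2, 1)),
                 "excluded")
  expect_equal(nrow(b4), 0L)
})

test_that("scar counting follows the HRD-LOH / TAI / LST definitions", {
  g <- genome_build(c("1" = 120e6),
                    data.frame(chrom = "1", start = 54e6, end = 57e6))
  # interstitial 20-Mb LOH on a 120-Mb chromosome
  seg <- rbind(seg_df("S1", "1", 0, 60e6, 1, 1),
               seg_df("S1", "1", 60e6, 80e6, 1, 0),
               seg_df("S1", "1", 80e6, 120e6, 1, 1))
  expect_equal(compute_scars(seg, g)$n_loh_segments, 1L)

  # whole-chromosome LOH is excluded
  expect_equal(compute_scars(seg_df("S1", "1", 0, 120e6, 1, 0),
                             g)$n_loh_segments, 0L)

  # adjacent 12-Mb (1,1) and 15-Mb (2,1) segments on one arm: one LST,
  # and the (2,1) imbalance does not reach a telomere (no TAI)
  seg2 <- rbind(seg_df("S1", "1", 0, 12e6, 1, 1),
                seg_df("S1", "1", 12e6, 27e6, 2, 1),
                seg_df("S1", "1", 27e6, 120e6, 1, 1))
  sc <- compute_scars(seg2, g)
  expect_equal(sc$n_lst, 2L)  # both flanks of the 15-Mb block qualify
  expect_equal(sc$n_tai, 0L)

  # telomeric allelic imbalance not crossing the centromere
  seg3 <- rbind(seg_df("S1", "1", 0, 20e6, 2, 1),
                seg_df("S1", "1", 20e6, 120e6, 1, 1))
  expect_equal(compute_scars(seg3, g)$n_tai, 1L)

  # imbalance spanning the centromere is not TAI
  seg4 <- rbind(seg_df("S1", "1", 0, 60e6, 2, 1),
                seg_df("S1", "1", 60e6, 120e6, 1, 1))
  expect_equal(compute_scars(seg4, g)$n_tai, 0L)

  # missing centromere: TAI/LST skipped with a warning
  g2 <- genome_build(c("1" = 120e6))
  expect_warning(sc2 <- compute_scars(seg2, g2), "centromere")
  expect_equal(sc2$n_lst, 0L)
})

test_that("scar scores match the brute-force definition oracle", {
  g <- default_genome()
  set.seed(17)
  for (i in 1:30) {
    seg <- random_segment_genome(sprintf("S%02d", i), g)
    got <- suppressWarnings(compute_scars(seg, g))
    want <- oracle_scars_sample(seg, g)
    expect_equal(got$n_loh_segments, unname(want["n_loh_segments"]))
    expect_equal(got$n_tai, unname(want["n_tai"]))
    expect_equal(got$n_lst, unname(want["n_lst"]))
    expect_equal(got$gis, sum(want))
  }
})

test_that("gis is invariant under value-preserving segment splits", {
  g <- default_genome()
  set.seed(23)
  for (i in 1:10) {
    seg <- random_segment_genome("S1", g)
    before <- compute_scars(seg, g)
    # split every segment longer than 2 bp at its midpoint
    split_at_mid <- function(d) {
      mid <- floor((d$start + d$end) / 2)
      ok <- mid > d$start & mid < d$end
      rbind(transform(d[ok, ], end = mid[ok]),
            transform(d[ok, ], start = mid[ok]),
            d[!ok, ])
    }
    after <- compute_scars(split_at_mid(seg), g)
    expect_equal(after$gis, before$gis)
  }
})

test_that("bin profiles weight by overlap and respect sex chromosomes", {
  g <- genome_build(c("1" = 3e5, "X" = 2e5),
                    data.frame(chrom = c("1", "X"), start = c(1e5, 5e4),
                               end = c(1.2e5, 7e4)))
  seg <- rbind(seg_df("F1", "1", 0, 6e4, 2, 1),     # 60 kb at minor 1
               seg_df("F1", "1", 6e4, 3e5, 2, 0),   # then minor 0
               seg_df("F1", "X", 0, 2e5, 1, 1),
               seg_df("M1", "1", 0, 3e5, 2, 1),
               seg_df("M1", "X", 0, 2e5, 1, 0),
               seg_df("FL", "1", 0, 3e5, 2, 1))     # flat (2,1) genome
  ann <- data.frame(sample_id = c("F1", "M1", "FL"), tumor_type = "T",
                    sex = c("female", "male", "male"))
  bp <- bin_profiles(seg, g, ann)
  b1 <- which(bp$bins$chrom == "1")[1]
  expect_equal(unname(bp$minor["F1", b1]), 0.6)  # 60 kb * 1 + 40 kb * 0
  expect_true(bp$loh["F1", b1])           # weighted minor < 1
  expect_false(bp$loh["M1", b1])          # fully minor 1
  xbin <- which(bp$bins$chrom == "X")[1]
  expect_false(is.na(bp$minor["F1", xbin]))
  expect_true(is.na(bp$minor["M1", xbin]))  # male X is missing

  # a flat (2,1) genome has zero amplification deviation everywhere:
  # the baseline correction is exact in the trivial limit
  expect_true(all(abs(bp$amp_dev["FL", bp$bins$chrom == "1"]) < 1e-12))
})

test_that("bin LOH fraction matches segment-level LOH coverage", {
  g <- default_genome()
  set.seed(31)
  seg <- random_segment_genome("S1", g)
  seg <- seg[seg$chrom != "X", ]
  bp <- bin_profiles(seg, g)
  auto <- bp$bins$chrom != "X"
  bin_frac <- mean(bp$loh["S1", auto], na.rm = TRUE)
  seg_frac <- sum((seg$end - seg$start)[seg$minor < 1]) /
    sum(seg$end - seg$start)
  expect_equal(bin_frac, seg_frac, tolerance = 0.01)
})

test_that("gene-level calls follow the amplification and deletion rules", {
  genes <- data.frame(gene = c("GAIN_F", "GAIN_B", "LOH_G", "DEL_G"),
                      chrom = c("1", "2", "3", "4"),
                      start = c(1e6, 1e6, 1e6, 1e6), end = c(1.1e6, 1.1e6,
                                                             1.1e6, 1.1e6))
  seg <- rbind(
    seg_df("S1", "1", 0.8e6, 0.8e6 + 10^6.4, 5, 1),  # focal gain
    seg_df("S1", "2", 0, 1e7, 5, 1),                 # broad gain
    seg_df("S1", "3", 0, 2e6, 2, 0),                 # LOH
    seg_df("S1", "4", 0.9e6, 1.4e6, 0, 0),           # deep deletion
    # long flat background keeps the baseline total near 3
    seg_df("S1", "5", 0, 100e6, 2, 1),
    seg_df("S1", "6", 0, 100e6, 2, 1))
  calls <- gene_calls(seg, genes)
  rownames(calls) <- calls$gene
  expect_true(calls["GAIN_F", "focal_amp"])
  expect_true(calls["GAIN_B", "relative_amp"])
  expect_false(calls["GAIN_B", "focal_amp"])   # log10(length) >= 6.5
  expect_true(calls["LOH_G", "loh"])
  expect_false(calls["LOH_G", "relative_amp"])
  expect_true(calls["DEL_G", "deep_deletion"])
  # focal_amp implies relative_amp on every call
  expect_true(all(!calls$focal_amp | calls$relative_amp))
})

test_that("co-occurrence odds ratios and Fisher p values are exact", {
  a <- rep(c(TRUE, FALSE), c(100, 100))
  b <- c(rep(c(TRUE, FALSE), c(30, 70)), rep(c(TRUE, FALSE), c(10, 90)))
  cc <- cooccurrence(a, b)
  expect_equal(cc$or, (30 * 90) / (70 * 10))  # 3.857...
  expect_equal(cc$p, fisher.test(cc$table)$p.value)

  ind <- cooccurrence(rep(c(TRUE, FALSE), each = 50),
                      rep(c(TRUE, FALSE, TRUE, FALSE), each = 25))
  expect_equal(ind$or, 1)
  expect_equal(ind$p, 1)

  const <- cooccurrence(rep(TRUE, 10), rep(c(TRUE, FALSE), 5))
  expect_true(const$flagged)
  expect_equal(const$p, 1)

  zero <- cooccurrence(c(TRUE, TRUE, FALSE, FALSE),
                       c(TRUE, TRUE, TRUE, FALSE))
  expect_true(zero$haldane)
})

test_that("region statistics separate planted group differences", {
  g <- genome_build(c("1" = 1e7), data.frame(chrom = "1", start = 4.5e6,
                                             end = 4.7e6))
  mk <- function(id, loh) seg_df(id, "1", c(0, 2e6, 4e6), c(2e6, 4e6, 1e7),
                                 1, c(1, if (loh) 0 else 1, 1))
  seg <- do.call(rbind, c(lapply(sprintf("A%02d", 1:5), mk, loh = TRUE),
                          lapply(sprintf("B%02d", 1:5), mk, loh = FALSE)))
  bp <- bin_profiles(seg, g)
  groups <- setNames(rep(c("A", "B"), each = 5),
                     sprintf("%s%02d", rep(c("A", "B"), each = 5), 1:5))
  rs <- group_region_stats(bp, groups, data.frame(chrom = "1", start = 2e6,
                                                  end = 4e6))
  expect_equal(rs$loh_frac1, 1)
  expect_equal(rs$loh_frac2, 0)
  expect_lt(rs$loh_p, 1e-6)

  # identical groups: t ~ 0, p ~ 1 (flagged degenerate variance)
  rs2 <- group_region_stats(bp, setNames(rep(c("A", "B"), 5),
                                         names(groups)[c(1, 6, 2, 7, 3, 8,
                                                         4, 9, 5, 10)]),
                            data.frame(chrom = "1", start = 6e6, end = 8e6))
  expect_equal(rs2$loh_t, 0)
  expect_equal(rs2$loh_p, 1)
})

test_that("differential region detection needs a wide-enough span", {
  g <- genome_build(c("1" = 1e7), data.frame(chrom = "1", start = 4.5e6,
                                             end = 4.7e6))
  mk <- function(id, loh) seg_df(id, "1", c(0, 2e6, 4e6), c(2e6, 4e6, 1e7),
                                 1, c(1, if (loh) 0 else 1, 1))
  seg <- do.call(rbind, c(lapply(sprintf("A%02d", 1:8), mk, loh = TRUE),
                          lapply(sprintf("B%02d", 1:8), mk, loh = FALSE)))
  bp <- bin_profiles(seg, g)
  groups <- setNames(rep(c("A", "B"), each = 8), rownames(bp$loh))
  hit <- differential_regions(bp, groups, min_span_bins = 5)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$direction, "A")
  expect_lt(abs(hit$start - 2e6), 2e5)
  expect_lt(abs(hit$end - 4e6), 2e5)
  # a span requirement larger than the genome yields nothing
  expect_equal(nrow(differential_regions(bp, groups,
                                         min_span_bins = 1e5)), 0L)
})
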