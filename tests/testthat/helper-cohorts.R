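# Shared simulated cohorts, built once per test run.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, config) {
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- simulate_cohort(config)
  .cohort_cache[[key]]
}

# the packaged default study cohort (n = 600, strong effects, seed 1)
default_cohort <- function() cached_cohort("default", cohort_config(seed = 1))

# a small cohort for unit tests
small_cohort <- function() {
  cached_cohort("small", cohort_config(
    n_samples = c(OVX = 50, LUX = 40, GIX = 30),
    seed = 421))
}

# features/triage for the default cohort, computed once
default_features <- function() {
  if (is.null(.cohort_cache$default_fx)) {
    co <- default_cohort()
    .cohort_cache$default_fx <- suppressWarnings(
      hrd_features(co$mutations, co$segments, co$genome, co$annotations))
  }
  .cohort_cache$default_fx
}

# features/triage for the small cohort, computed once
default_small_fx <- function() {
  if (is.null(.cohort_cache$small_fx)) {
    co <- small_cohort()
    .cohort_cache$small_fx <- suppressWarnings(
      hrd_features(co$mutations, co$segments, co$genome, co$annotations))
  }
  .cohort_cache$small_fx
}

# BRCA biallelic calls for a cohort
small_biallelic <- function(co, fx) {
  gcb <- gene_calls(co$segments,
                    co$gene_coords[co$gene_coords$gene %in%
                                     c("BRCA1", "BRCA2"), ])
  call_biallelic(co$mutations, co$germline, gcb, co$silencing,
                 samples = fx$features$sample_id)
}

# a mutation table prefilled with the optional columns
mut_row <- function(sample_id = "S1", chrom = "1", pos = 100, ref = "C",
                    alt = "T", consequence = "Missense_Mutation",
                    sift = NA, polyphen = NA, clinvar = NA, gene = NA,
                    context = NA, flank5 = NA, flank3 = NA,
                    variant_class = NA) {
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, variant_class = variant_class,
             consequence = consequence, sift = sift, polyphen = polyphen,
             clinvar = clinvar, gene = gene, context = context,
             flank5 = flank5, flank3 = flank3, stringsAsFactors = FALSE)
}
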