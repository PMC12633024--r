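## Associations between genomic state and the tumor microenvironment:
## DDR-gene and gene-pair enrichment, generic over-representation
## analysis, and the cell-fraction delta-Z / clustering / correlation
## analyses.

#' Build a sample x gene alteration ("dysfunctional") matrix
#'
#' A gene is dysfunctional in a sample when it carries a pathogenic
#' somatic variant (see [is_pathogenic()]), a pathogenic germline
#' variant, a deep deletion, or promoter silencing (OR combination).
#'
#' @param mutations a mutation table.
#' @param genes character vector of genes to include (columns).
#' @param samples character vector of sample ids (rows).
#' @param germline optional data.frame `sample_id`, `gene` of pathogenic
#'   germline variants.
#' @param gene_cna optional [gene_calls()] result (for deep deletions).
#' @param silencing optional data.frame `sample_id`, `gene` of promoter
#'   silencing calls.
#' @return logical matrix, samples x genes, no NA.
#' @export
alteration_matrix <- function(mutations, genes, samples, germline = NULL,
                              gene_cna = NULL, silencing = NULL) {
  m <- matrix(FALSE, length(samples), length(genes),
              dimnames = list(samples, genes))
  mark <- function(sid, g) {
    keep <- sid %in% samples & g %in% genes
    if (any(keep)) m[cbind(sid[keep], g[keep])] <<- TRUE
  }
  if (!is.null(mutations) && nrow(mutations)) {
    mutations <- mutation_table(mutations)
    path <- is_pathogenic(mutations) & !is.na(mutations$gene)
    mark(mutations$sample_id[path], mutations$gene[path])
  }
  if (!is.null(germline) && nrow(germline))
    mark(germline$sample_id, germline$gene)
  if (!is.null(gene_cna) && nrow(gene_cna)) {
    dd <- gene_cna[gene_cna$deep_deletion, , drop = FALSE]
    mark(dd$sample_id, dd$gene)
  }
  if (!is.null(silencing) && nrow(silencing))
    mark(silencing$sample_id, silencing$gene)
  m
}

#' Per-gene enrichment of dysfunction in HRD versus HRP
#'
#' For each gene, a 2x2 Fisher exact test of dysfunction against the
#' HRD/HRP split, with Benjamini-Hochberg adjustment across tested
#' genes.  Samples can be restricted by `background_mask` (e.g. to
#' exclude BRCA1/2 biallelic samples).  Genes altered in no sample get
#' an undefined OR and q = 1, flagged.
#'
#' @param alterations logical samples x genes matrix.
#' @param hrd named logical vector (TRUE = HRD, FALSE = HRP); NA
#'   samples are ignored.
#' @param genes genes to test (default: all columns).
#' @param background_mask optional logical vector over samples.
#' @return data.frame: `gene`, `n_alt_hrd`, `n_alt_hrp`, `or`, `p`,
#'   `q`, `flagged`.
#' @export
ddr_enrichment <- function(alterations, hrd, genes = colnames(alterations),
                           background_mask = NULL) {
  ids <- rownames(alterations)
  hrd <- hrd[ids]
  keep <- !is.na(hrd)
  if (!is.null(background_mask)) keep <- keep & background_mask[ids]
  missing <- setdiff(genes, colnames(alterations))
  if (length(missing)) {
    warn_fmt("gene(s) absent from the alteration matrix skipped: %s",
             paste(missing, collapse = ", "))
    genes <- setdiff(genes, missing)
  }
  rows <- lapply(genes, function(g) {
    alt <- alterations[keep, g]
    h <- hrd[keep]
    cc <- cooccurrence(alt, h)
    data.frame(gene = g, n_alt_hrd = sum(alt & h), n_alt_hrp = sum(alt & !h),
               or = cc$or, p = cc$p, flagged = cc$flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$q[out$flagged] <- 1
  rownames(out) <- NULL
  out[, c("gene", "n_alt_hrd", "n_alt_hrp", "or", "p", "q", "flagged")]
}

#' Gene-pair ("epistatic") enrichment against HRD
#'
#' Tests whether HRD is enriched when both genes are dysfunctional:
#' Fisher exact test of the `A AND B` indicator against HRD status.
#'
#' @param alterations logical samples x genes matrix.
#' @param geneA,geneB gene symbols (columns of `alterations`).
#' @param hrd named logical HRD indicator.
#' @return list: `or`, `p`, `n_both`, `flagged`.
#' @export
pair_epistasis <- function(alterations, geneA, geneB, hrd) {
  for (g in c(geneA, geneB))
    if (!g %in% colnames(alterations))
      stop_fmt("gene %s absent from the alteration matrix", g)
  ids <- rownames(alterations)
  hrd <- hrd[ids]
  keep <- !is.na(hrd)
  both <- alterations[keep, geneA] & alterations[keep, geneB]
  cc <- cooccurrence(both, hrd[keep])
  list(or = cc$or, p = cc$p, n_both = sum(both), flagged = cc$flagged)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper hypergeometric tail probability of the
#' observed overlap between `gene_list` and the set within `universe`,
#' with BH adjustment across sets.
#'
#' @param gene_list character vector of genes of interest (subset of
#'   `universe`).
#' @param universe character vector of all considered genes.
#' @param gene_sets named list of gene sets (e.g. from [read_gmt()]).
#' @return data.frame: `set`, `n_set`, `n_hits`, `p`, `q`, `hits`
#'   (comma-separated gene symbols).
#' @export
ora <- function(gene_list, universe, gene_sets) {
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, universe)
  if (length(outside))
    stop_fmt("gene_list member(s) outside the universe: %s",
             paste(outside, collapse = ", "))
  N <- length(universe); n <- length(gene_list)
  rows <- lapply(names(gene_sets), function(nm) {
    set_u <- intersect(gene_sets[[nm]], universe)
    hits <- intersect(gene_list, set_u)
    K <- length(set_u); k <- length(hits)
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, n_set = K, n_hits = k, p = p,
               hits = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[, c("set", "n_set", "n_hits", "p", "q", "hits")]
}

## z-score cell fractions within tumor type, per cell type
.zscore_fractions <- function(fractions, tumor_type) {
  z <- fractions
  for (tt in unique(tumor_type)) {
    rows <- which(tumor_type == tt)
    for (j in seq_len(ncol(fractions)))
      z[rows, j] <- zscore(fractions[rows, j])
  }
  z
}

#' Delta-Z table of cell fractions between two groups
#'
#' Cell fractions are z-scored within tumor type per cell type; for
#' each (tumor type, cell type) the table reports
#' `delta_z = mean z(group1) - mean z(group2)` with a Welch t test.
#' Tumor types with fewer than 2 samples in either group are skipped
#' with a warning.
#'
#' @param fractions samples x cell types non-negative matrix; use
#'   `relative = TRUE` to rescale rows to sum to 1 first.
#' @param annotations annotation table supplying `tumor_type`.
#' @param groups named vector, sample id -> group label (exactly two
#'   labels; NA samples ignored).
#' @param relative rescale rows to relative fractions first.
#' @param comparison optional length-2 vector fixing which label is
#'   group 1 and which group 2 (default: order of appearance).
#' @return data.frame: `tumor_type`, `cell_type`, `delta_z`, `t`, `p`,
#'   `n1`, `n2`, with attribute `comparison` = the two group labels.
#' @export
tme_delta <- function(fractions, annotations, groups, relative = FALSE,
                      comparison = NULL) {
  annotations <- annotation_table(annotations)
  if (relative) fractions <- fractions / rowSums(fractions)
  ids <- rownames(fractions)
  tt <- annotations$tumor_type[match(ids, annotations$sample_id)]
  g <- as.character(groups[ids])
  glev <- comparison %||% unique(na.omit(g))
  if (length(glev) != 2L) stop_fmt("exactly two groups are required")
  z <- .zscore_fractions(fractions, tt)
  rows <- list()
  for (type in unique(tt)) {
    in1 <- which(tt == type & g %in% glev[1])
    in2 <- which(tt == type & g %in% glev[2])
    if (length(in1) < 2 || length(in2) < 2) {
      warn_fmt("tumor type %s skipped in delta-Z: fewer than 2 samples per group",
               type)
      next
    }
    for (ct in colnames(fractions)) {
      w <- .safe_welch(z[in1, ct], z[in2, ct])
      rows[[length(rows) + 1]] <- data.frame(
        tumor_type = type, cell_type = ct,
        delta_z = mean(z[in1, ct]) - mean(z[in2, ct]),
        t = w$t, p = w$p, n1 = length(in1), n2 = length(in2),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "comparison") <- glev
  out
}

#' Cluster cell types from stacked delta-Z tables
#'
#' Stacks the delta-Z tables of one or more comparisons into a
#' (tumor type x comparison) x cell type matrix and clusters the cell
#' type columns by agglomerative hierarchical clustering (Euclidean
#' distance, average linkage by default), cutting the tree at `k`.
#'
#' @param delta_tables list of [tme_delta()] results.
#' @param k number of clusters (default 5).
#' @param method linkage method for [stats::hclust()].
#' @return named integer vector: cell type -> cluster id, with the
#'   `hclust` tree in attribute `"tree"`.
#' @export
cluster_celltypes <- function(delta_tables, k = 5, method = "average") {
  if (inherits(delta_tables, "data.frame")) delta_tables <- list(delta_tables)
  mats <- lapply(seq_along(delta_tables), function(i) {
    d <- delta_tables[[i]]
    stats::xtabs(delta_z ~ tumor_type + cell_type, data = d)
  })
  cells <- colnames(mats[[1]])
  m <- do.call(rbind, lapply(mats, function(x) x[, cells, drop = FALSE]))
  if (k > length(cells))
    stop_fmt("k = %d exceeds the number of cell types (%d)", k, length(cells))
  tree <- hclust(dist(t(m)), method = method)
  cl <- cutree(tree, k = k)
  attr(cl, "tree") <- tree
  cl
}

#' Pairwise correlation of z-scored cell fractions
#'
#' Pearson correlation between cell types over a sample subset, with
#' two-sided p values and a significance mask at `alpha`.  Constant
#' columns give undefined correlations and are masked.
#'
#' @param fractions samples x cell types matrix (already z-scored or
#'   raw; correlation is scale-invariant).
#' @param subset optional sample ids restricting the rows.
#' @param alpha significance level for the mask.
#' @return list: `r`, `p` (cell x cell matrices), `significant`
#'   (logical mask, diagonal FALSE).
#' @export
correlate_celltypes <- function(fractions, subset = NULL, alpha = 0.05) {
  m <- if (is.null(subset)) fractions else fractions[subset, , drop = FALSE]
  if (nrow(m) < 3L) stop_fmt("need at least 3 samples to correlate")
  p <- ncol(m)
  r <- suppressWarnings(cor(m))
  pv <- matrix(NA_real_, p, p, dimnames = dimnames(r))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) { pv[i, j] <- 0; next }
    if (sd(m[, i]) == 0 || sd(m[, j]) == 0) next
    pv[i, j] <- cor.test(m[, i], m[, j])$p.value
  }
  sig <- !is.na(pv) & pv < alpha
  diag(sig) <- FALSE
  list(r = r, p = pv, significant = sig)
}
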