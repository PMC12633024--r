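## Readers and writers for the tabular formats the pipeline consumes:
## somatic mutations (MAF dialect, MC3-like columns), allele-specific
## copy-number segments (ASCAT-like TSV), gene sets (GMT), and sample
## annotations.  Files are 1-based inclusive; everything downstream of
## the readers uses 0-based half-open intervals (point mutations keep
## their 1-based position since they take part in no interval
## arithmetic).

TRUNCATING_CONSEQUENCES <- c("Nonsense_Mutation", "Frame_Shift_Del",
                             "Frame_Shift_Ins", "Translation_Start_Site",
                             "Splice_Site")
NONSYNONYMOUS_CONSEQUENCES <- c("Missense_Mutation", "In_Frame_Del",
                                "In_Frame_Ins", "Nonstop_Mutation")
KNOWN_CONSEQUENCES <- c(TRUNCATING_CONSEQUENCES, NONSYNONYMOUS_CONSEQUENCES,
                        "Silent")

MUTATION_COLUMNS <- c("sample_id", "chrom", "pos", "ref", "alt",
                      "variant_class", "consequence", "sift", "polyphen",
                      "clinvar", "gene", "context", "flank5", "flank3")

.infer_variant_class <- function(ref, alt) {
  ref_len <- ifelse(ref %in% c("-", ""), 0L, nchar(ref))
  alt_len <- ifelse(alt %in% c("-", ""), 0L, nchar(alt))
  ifelse(ref_len == 1L & alt_len == 1L, "SNV",
         ifelse(ref_len > alt_len, "deletion", "insertion"))
}

.normalize_consequence <- function(x) {
  x <- as.character(x)
  out <- ifelse(is.na(x) | !(x %in% KNOWN_CONSEQUENCES), "other", x)
  out
}

#' Assemble and validate a mutation table
#'
#' Internal canonical form used by the whole pipeline: one row per
#' somatic variant with columns `sample_id`, `chrom`, `pos` (1-based),
#' `ref`, `alt`, `variant_class` (SNV / insertion / deletion),
#' `consequence`, and optional `sift`, `polyphen`, `clinvar`, `gene`,
#' `context` (3-mer, reference strand, ref base centered), `flank5`,
#' `flank3` (immediate flanking sequence, used for microhomology
#' counting without a reference FASTA).
#'
#' @param df data.frame holding at least sample_id, chrom, pos, ref, alt.
#' @return validated data.frame with all canonical columns.
#' @export
mutation_table <- function(df) {
  need <- c("sample_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fmt("mutation table lacks column(s): %s", paste(miss, collapse = ", "))
  for (col in setdiff(MUTATION_COLUMNS, names(df))) df[[col]] <- NA_character_
  df$chrom <- normalize_chrom(df$chrom)
  df$pos <- as.numeric(df$pos)
  if (any(is.na(df$pos)) || any(df$pos < 1))
    stop_fmt("mutation positions must be numeric and >= 1")
  if (any(df$ref == df$alt, na.rm = TRUE))
    stop_fmt("ref equal to alt in %d row(s)", sum(df$ref == df$alt, na.rm = TRUE))
  if (is.null(df$variant_class) || all(is.na(df$variant_class)))
    df$variant_class <- .infer_variant_class(df$ref, df$alt)
  df$consequence <- .normalize_consequence(df$consequence)
  is_del <- df$variant_class == "deletion"
  ref_len <- ifelse(df$ref %in% c("-", ""), 0L, nchar(df$ref))
  alt_len <- ifelse(df$alt %in% c("-", ""), 0L, nchar(df$alt))
  if (any(is_del & ref_len <= alt_len))
    stop_fmt("deletion records must have len(ref) > len(alt)")
  ctx <- df$context
  has_ctx <- !is.na(ctx) & df$variant_class == "SNV"
  bad_ctx <- has_ctx & (nchar(ctx) != 3L | substr(ctx, 2, 2) != df$ref)
  if (any(bad_ctx))
    stop_fmt("%d trinucleotide context(s) lack the ref base at center",
             sum(bad_ctx))
  df[, MUTATION_COLUMNS, drop = FALSE]
}

#' Read a somatic mutation file (MAF dialect)
#'
#' Expects a tab-separated file with at least the MC3 columns
#' `Tumor_Sample_Barcode`, `Chromosome`, `Start_Position`,
#' `Reference_Allele`, `Tumor_Seq_Allele2`, `Variant_Classification`.
#' Optional annotation columns (`SIFT`, `PolyPhen`, `CLIN_SIG` /
#' `ClinVar`, `Hugo_Symbol`, `CONTEXT`, `FLANK5`, `FLANK3`) map onto the
#' optional fields; anything absent becomes `NA`.  Insertion/deletion
#' class is inferred from allele lengths.
#'
#' @param path path to the MAF file.
#' @return a mutation table (see [mutation_table()]).
#' @export
read_maf <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
  mandatory <- c("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
                 "Reference_Allele", "Tumor_Seq_Allele2",
                 "Variant_Classification")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss))
    stop_fmt("MAF is missing mandatory column(s): %s",
             paste(miss, collapse = ", "))
  pos <- suppressWarnings(as.numeric(raw$Start_Position))
  if (any(is.na(pos))) {
    bad <- which(is.na(pos))[1]
    stop_fmt("non-numeric Start_Position at data line %d", bad)
  }
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(raw)) return(as.character(raw[[nm]]))
    rep(NA_character_, nrow(raw))
  }
  ctx <- pick("CONTEXT")
  ## MC3 emits an 11-mer context; reduce to the centered 3-mer
  long <- !is.na(ctx) & nchar(ctx) > 3 & nchar(ctx) %% 2 == 1
  ctx[long] <- substr(ctx[long], (nchar(ctx[long]) - 3) / 2 + 1,
                      (nchar(ctx[long]) - 3) / 2 + 3)
  df <- data.frame(
    sample_id = as.character(raw$Tumor_Sample_Barcode),
    chrom = as.character(raw$Chromosome),
    pos = pos,
    ref = as.character(raw$Reference_Allele),
    alt = as.character(raw$Tumor_Seq_Allele2),
    variant_class = NA_character_,
    consequence = as.character(raw$Variant_Classification),
    sift = pick("SIFT"), polyphen = pick("PolyPhen"),
    clinvar = pick("CLIN_SIG", "ClinVar"), gene = pick("Hugo_Symbol"),
    context = ctx, flank5 = pick("FLANK5"), flank3 = pick("FLANK3"),
    stringsAsFactors = FALSE)
  df[df == ""] <- NA
  mutation_table(df)
}

#' Write a mutation table as a MAF-dialect TSV
#'
#' @param mutations a mutation table.
#' @param path output path.
#' @export
write_maf <- function(mutations, path) {
  mutations <- mutation_table(mutations)
  out <- data.frame(
    Hugo_Symbol = mutations$gene,
    Chromosome = mutations$chrom,
    Start_Position = format(mutations$pos, scientific = FALSE, trim = TRUE),
    Reference_Allele = mutations$ref,
    Tumor_Seq_Allele2 = mutations$alt,
    Variant_Classification = mutations$consequence,
    Tumor_Sample_Barcode = mutations$sample_id,
    SIFT = mutations$sift, PolyPhen = mutations$polyphen,
    CLIN_SIG = mutations$clinvar, CONTEXT = mutations$context,
    FLANK5 = mutations$flank5, FLANK3 = mutations$flank3,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Assemble and validate an allele-specific segment table
#'
#' Internal canonical form: `sample_id`, `chrom`, `start`, `end`
#' (0-based half-open), `major`, `minor`.  Rejects `major < minor`,
#' negative copies, inverted intervals and overlapping segments within a
#' sample/chromosome; sorts by (sample, chrom, start).
#'
#' @param df data.frame with the six columns above (0-based half-open).
#' @return validated, sorted data.frame.
#' @export
segment_table <- function(df) {
  need <- c("sample_id", "chrom", "start", "end", "major", "minor")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fmt("segment table lacks column(s): %s", paste(miss, collapse = ", "))
  df <- df[, need, drop = FALSE]
  df$chrom <- normalize_chrom(df$chrom)
  for (col in c("start", "end", "major", "minor"))
    df[[col]] <- as.numeric(df[[col]])
  if (any(df$end <= df$start))
    stop_fmt("segment with end <= start (0-based half-open) in %d row(s)",
             sum(df$end <= df$start))
  if (any(df$major < 0 | df$minor < 0))
    stop_fmt("negative copy numbers")
  if (any(df$major < df$minor))
    stop_fmt("minor > major in %d row(s)", sum(df$major < df$minor))
  df <- df[order(df$sample_id, df$chrom, df$start), , drop = FALSE]
  key <- paste(df$sample_id, df$chrom)
  ov <- which(key[-1] == key[-nrow(df)] & df$start[-1] < df$end[-nrow(df)])
  if (length(ov))
    stop_fmt("overlapping segments within %s: [%s-%s] and [%s-%s]",
             key[ov[1]], format(df$start[ov[1]], scientific = FALSE),
             format(df$end[ov[1]], scientific = FALSE),
             format(df$start[ov[1] + 1], scientific = FALSE),
             format(df$end[ov[1] + 1], scientific = FALSE))
  rownames(df) <- NULL
  df
}

#' Read allele-specific copy-number segments (ASCAT-like TSV)
#'
#' Columns: `sample` (or `sample_id`), `chrom`, `start`, `end` (1-based
#' inclusive in the file), `major` (or `nMajor`), `minor` (or `nMinor`).
#'
#' @param path path to the TSV.
#' @return a validated segment table (0-based half-open).
#' @export
read_segments <- function(path) {
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(raw)) return(raw[[nm]])
    stop_fmt("segment file is missing column %s", c(...)[1])
  }
  df <- data.frame(sample_id = as.character(pick("sample", "sample_id")),
                   chrom = as.character(pick("chrom", "chr")),
                   start = as.numeric(pick("start", "startpos")),
                   end = as.numeric(pick("end", "endpos")),
                   major = as.numeric(pick("major", "nMajor")),
                   minor = as.numeric(pick("minor", "nMinor")),
                   stringsAsFactors = FALSE)
  if (any(df$end < df$start))
    stop_fmt("segment row with end < start (1-based inclusive)")
  df$start <- df$start - 1   # to 0-based half-open
  segment_table(df)
}

#' Write a segment table as a 1-based inclusive TSV
#'
#' @param segments a segment table (0-based half-open).
#' @param path output path.
#' @export
write_segments <- function(segments, path) {
  segments <- segment_table(segments)
  out <- data.frame(sample = segments$sample_id, chrom = segments$chrom,
                    start = format(segments$start + 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(segments$end, scientific = FALSE, trim = TRUE),
                    major = segments$major, minor = segments$minor)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name <TAB> description <TAB> genes...`.
#' The description is discarded and duplicate symbols collapsed.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), names = character(0)))
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop_fmt("GMT line %d has fewer than 3 fields", i)
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop_fmt("GMT set '%s' is empty", f[1])
    list(name = f[1], genes = genes)
  })
  setNames(lapply(sets, `[[`, "genes"), vapply(sets, `[[`, "", "name"))
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", unique(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble and validate sample annotations
#'
#' @param df data.frame with `sample_id`, `tumor_type` and optionally
#'   `sex` (female/male/unknown), `viral_status`
#'   (negative/positive/unknown), `subtype`, `msi_score`.
#' @return validated data.frame with all six columns.
#' @export
annotation_table <- function(df) {
  if (!all(c("sample_id", "tumor_type") %in% names(df)))
    stop_fmt("annotations need sample_id and tumor_type")
  if (any(is.na(df$tumor_type) | !nzchar(df$tumor_type)))
    stop_fmt("tumor_type must be non-empty for every sample")
  norm_enum <- function(x, levels) {
    x <- as.character(x %||% rep("unknown", nrow(df)))
    x[is.na(x) | !(x %in% levels)] <- "unknown"
    x
  }
  df$sex <- norm_enum(df$sex, c("female", "male"))
  df$viral_status <- norm_enum(df$viral_status, c("negative", "positive"))
  if (is.null(df$subtype)) df$subtype <- NA_character_
  df$msi_score <- as.numeric(df$msi_score %||% rep(NA_real_, nrow(df)))
  if (any(df$msi_score < 0, na.rm = TRUE))
    stop_fmt("msi_score must be non-negative")
  df[, c("sample_id", "tumor_type", "sex", "viral_status", "subtype",
         "msi_score"), drop = FALSE]
}

#' Read sample annotations from TSV
#' @param path path to the TSV.
#' @return validated annotation data.frame.
#' @export
read_annotations <- function(path) {
  annotation_table(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Write sample annotations to TSV
#' @param annotations annotation data.frame.
#' @param path output path.
#' @export
write_annotations <- function(annotations, path) {
  write.table(annotation_table(annotations), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Read a numeric matrix from TSV (first column = row names)
#'
#' Used for expression (genes x samples) and cell-fraction
#' (samples x cell types) matrices.
#'
#' @param path path to the TSV.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a numeric matrix to TSV (row names in the first column)
#'
#' @param m numeric matrix.
#' @param path output path.
#' @param rowname_header header for the row-name column.
#' @export
write_matrix_tsv <- function(m, path, rowname_header = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- rowname_header
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
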