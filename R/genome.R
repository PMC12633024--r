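## Genome build descriptor: chromosome lengths, centromeres, and an
## optional reference-sequence accessor.  All coordinates handled here
## are 0-based half-open; the I/O layer converts at the file boundary.

#' Construct a genome build
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param centromeres data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) giving one centromere interval per chromosome.
#' @param sequence optional function `(chrom, start, end) -> string`
#'   returning reference bases for a 0-based half-open interval.
#' @return an object of class `genome_build`.
#' @export
genome_build <- function(chrom_lengths, centromeres = NULL, sequence = NULL) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop_fmt("chrom_lengths must be a named vector")
  if (!is.null(centromeres)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(centromeres)))
    bad <- !(centromeres$chrom %in% names(chrom_lengths)) |
      centromeres$start < 0 |
      centromeres$end > chrom_lengths[centromeres$chrom]
    if (any(bad))
      stop_fmt("centromere interval outside its chromosome: %s",
               paste(centromeres$chrom[bad], collapse = ", "))
  }
  structure(list(chrom_lengths = chrom_lengths, centromeres = centromeres,
                 sequence = sequence),
            class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat(sprintf("genome_build: %d chromosomes, %.1f Mb total%s\n",
              length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6,
              if (is.null(x$sequence)) "" else ", with sequence accessor"))
  invisible(x)
}

genome_centromere <- function(genome, chrom) {
  cen <- genome$centromeres
  if (is.null(cen)) return(NULL)
  i <- match(chrom, cen$chrom)
  if (is.na(i)) return(NULL)
  c(start = cen$start[i], end = cen$end[i])
}

#' Default synthetic genome build
#'
#' A compact nine-chromosome genome (eight autosomes plus X, 1.22 Gb
#' total) with mid-chromosome centromeres, used by the cohort simulator
#' and the examples.  Chromosome names are "1".."8" and "X".
#'
#' @return a `genome_build`.
#' @export
default_genome <- function() {
  len <- c("1" = 200e6, "2" = 180e6, "3" = 160e6, "4" = 140e6,
           "5" = 120e6, "6" = 100e6, "7" = 90e6, "8" = 80e6, "X" = 150e6)
  cen_mid <- len * 0.45
  centromeres <- data.frame(chrom = names(len),
                            start = cen_mid - 1.5e6,
                            end = cen_mid + 1.5e6,
                            row.names = NULL)
  genome_build(len, centromeres)
}

#' Normalize chromosome names
#'
#' Strips a leading "chr" and unifies "23" with "X", "24" with "Y", so
#' mixed dialects compare equal.
#'
#' @param chrom character vector of chromosome names.
#' @return normalized names.
#' @export
normalize_chrom <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom))
  chrom[chrom == "23"] <- "X"
  chrom[chrom == "24"] <- "Y"
  chrom
}
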