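## SBS96 channel conventions and the packaged spectrum panel.

SBS_SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
DNA_BASES <- c("A", "C", "G", "T")

#' The 96 single-base-substitution channels
#'
#' Channels are on the pyrimidine strand, ordered substitution-major
#' (C>A, C>G, C>T, T>A, T>C, T>G), then by 5' flank (A, C, G, T), then
#' 3' flank, e.g. `"A[C>A]A"`, `"A[C>A]C"`, ...  This order is fixed and
#' every `Catalog96` / `Spectrum96` in the package uses it.
#'
#' @return character vector of length 96.
#' @export
sbs96_channels <- function() {
  unlist(lapply(SBS_SUBSTITUTIONS, function(sub) {
    unlist(lapply(DNA_BASES, function(b5) {
      paste0(b5, "[", sub, "]", DNA_BASES)
    }))
  }))
}

#' Map a substitution plus trinucleotide context to its SBS96 channel
#'
#' Purine-strand substitutions (ref A or G) are reverse-complemented
#' onto the pyrimidine strand.  The context must be a 3-mer with the
#' reference base at its center.
#'
#' @param ref,alt single reference / alternate bases.
#' @param context 3-mer trinucleotide context on the reference strand.
#' @return channel label, or `NA_character_` when unresolvable.
#' @export
sbs96_channel_of <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- toupper(rep_len(ref, n)); alt <- toupper(rep_len(alt, n))
  context <- toupper(rep_len(context, n))
  out <- rep(NA_character_, n)
  ok <- !is.na(ref) & !is.na(alt) & !is.na(context) &
    ref %in% DNA_BASES & alt %in% DNA_BASES & ref != alt &
    nchar(context) == 3L & substr(context, 2, 2) == ref &
    !grepl("[^ACGT]", context)
  if (!any(ok)) return(out)
  r <- ref[ok]; a <- alt[ok]; ctx <- context[ok]
  pur <- r %in% c("A", "G")
  if (any(pur)) {
    r[pur] <- chartr("AG", "TC", r[pur])
    a[pur] <- chartr("ACGT", "TGCA", a[pur])
    ctx[pur] <- revcomp(ctx[pur])
  }
  out[ok] <- paste0(substr(ctx, 1, 1), "[", r, ">", a, "]", substr(ctx, 3, 3))
  out
}

## Deterministic construction of a peaked spectrum: `mass` split over the
## named channels, the remainder uniform over all 96.
.spectrum <- function(peaks, mass) {
  ch <- sbs96_channels()
  p <- rep((1 - mass) / 96, 96)
  names(p) <- ch
  stopifnot(all(names(peaks) %in% ch))
  p[names(peaks)] <- p[names(peaks)] + mass * peaks / sum(peaks)
  p / sum(p)
}

.block <- function(sub) {
  ch <- sbs96_channels()
  ch[grepl(paste0("[", sub, "]"), ch, fixed = TRUE)]
}

#' Packaged SBS96 spectrum panel
#'
#' Six synthetic but COSMIC-shaped single-base-substitution spectra used
#' by the signature-refitting features and the cohort simulator:
#' \describe{
#'   \item{background_flat}{uniform over the 96 channels.}
#'   \item{clock_like}{CpG-focused C>T, the shape of clock-like aging
#'     signatures (SBS1-like).}
#'   \item{hrd_like}{near-flat with a mild excess over the T>A / T>C
#'     blocks, the flat profile characteristic of HRD (SBS3-like).}
#'   \item{mmr_like}{C>T dominant with a T>C shoulder (mismatch-repair
#'     deficiency, SBS6-like).}
#'   \item{pole_like}{extreme T\[C>A\]T peak with a T\[C>T\]G shoulder
#'     (POLE exonuclease deficiency, SBS10-like).}
#'   \item{artifact_like}{C>A-heavy profile of the 8-oxo-guanine
#'     sequencing artifact (SBS45-like).}
#' }
#' These are versioned stand-ins, synthetic by construction; substitute
#' real reference spectra for analyses of real cohorts.
#'
#' @return a 96 x 6 matrix; rows are channels, columns named spectra.
#'   Columns each sum to 1.
#' @export
spectrum_panel <- function() {
  ch <- sbs96_channels()
  background_flat <- rep(1 / 96, 96)

  cpg <- ch[grepl("\\[C>T\\]G$", ch)]
  clock_like <- .spectrum(setNames(rep(1, length(cpg)), cpg), 0.55)

  ## mild linear ramp over the 32 T>A / T>C channels keeps the HRD
  ## spectrum distinguishable from pure flat under NNLS refitting
  ta_tc <- c(.block("T>A"), .block("T>C"))
  hrd_like <- .spectrum(setNames(seq(1, 2, length.out = length(ta_tc)), ta_tc), 0.35)

  mmr_peaks <- c(setNames(rep(2, 16), .block("C>T")),
                 setNames(rep(1, 16), .block("T>C")))
  mmr_like <- .spectrum(mmr_peaks, 0.70)

  pole_like <- .spectrum(c("T[C>A]T" = 6, "T[C>T]G" = 2), 0.75)

  artifact_like <- .spectrum(setNames(rep(1, 16), .block("C>A")), 0.60)

  m <- cbind(background_flat = background_flat, clock_like = clock_like,
             hrd_like = hrd_like, mmr_like = mmr_like,
             pole_like = pole_like, artifact_like = artifact_like)
  rownames(m) <- ch
  m
}

## validate a spectrum vector (sums to 1, non-negative, length 96)
assert_spectrum <- function(p, name = "spectrum") {
  if (length(p) != 96L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop_fmt("%s must be 96 non-negative probabilities summing to 1", name)
  invisible(p)
}
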