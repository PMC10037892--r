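# Nearest-neighbor DNA thermodynamics: unified NN parameters
# (SantaLucia 1998 unified set), monovalent-salt entropy correction and a
# linear formamide depression. Duplex and hairpin free energies reuse the
# same stack table evaluated at the hybridization temperature.

# dH in kcal/mol, dS in cal/(mol K); keys are the 5'->3' top-strand dinucleotide
.nn_dh <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
.nn_ds <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
# initiation per terminal base pair
.init_dh <- c(GC = 0.1, AT = 2.3)
.init_ds <- c(GC = -2.8, AT = 4.1)

.gas_const <- 1.9872   # cal/(mol K)

.comp <- c(A = "T", C = "G", G = "C", T = "A")

.check_acgt <- function(sequence) {
  s <- toupper(sequence)
  if (grepl("[^ACGT]", s))
    stop("sequence contains ambiguous or masked bases: only A/C/G/T allowed",
         call. = FALSE)
  s
}

.seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that keeps plain
#' character vectors in and out (case is preserved by uppercasing first).
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

#' GC fraction of DNA sequences
#'
#' @param x character vector of sequences.
#' @return numeric vector of GC fractions in `[0, 1]`.
#' @export
gc_fraction <- function(x) {
  x <- toupper(x)
  n <- nchar(x)
  gc <- nchar(gsub("[^GC]", "", x))
  ifelse(n == 0, NA_real_, gc / n)
}

# sum of stack dH/dS plus both terminal initiation terms for a fully
# paired duplex segment written 5'->3'
.duplex_dh_ds <- function(chars) {
  n <- length(chars)
  di <- paste0(chars[-n], chars[-1])
  term <- ifelse(chars[c(1, n)] %in% c("G", "C"), "GC", "AT")
  list(dh = sum(.nn_dh[di]) + sum(.init_dh[term]),
       ds = sum(.nn_ds[di]) + sum(.init_ds[term]))
}

#' Nearest-neighbor melting temperature
#'
#' Computes the duplex melting temperature of a probe oligo with its perfect
#' genomic complement using unified nearest-neighbor parameters, an entropic
#' monovalent-salt correction (0.368 * (N-1) * ln\[Na+\] cal/mol/K) and a
#' linear formamide depression (default 0.72 degC per percent formamide).
#'
#' @param sequence oligo sequence, A/C/G/T only, length >= 8.
#' @param salt_molarity monovalent cation concentration in mol/L.
#' @param formamide_fraction formamide volume fraction in `[0, 1]`
#'   (0.5 = 50 percent).
#' @param oligo_conc_M total strand concentration in mol/L.
#' @param formamide_coef depression in degC per percent formamide.
#' @return melting temperature in degC.
#' @examples
#' melting_temperature(strrep("AT", 20))
#' @export
melting_temperature <- function(sequence, salt_molarity = 0.39,
                                formamide_fraction = 0,
                                oligo_conc_M = 5e-8,
                                formamide_coef = 0.72) {
  s <- .check_acgt(sequence)
  if (nchar(s) < 8) stop("sequence must be at least 8 nt", call. = FALSE)
  if (formamide_fraction < 0 || formamide_fraction > 1)
    stop("formamide_fraction must be in [0, 1]", call. = FALSE)
  ch <- .seq_chars(s)
  th <- .duplex_dh_ds(ch)
  ds_salt <- th$ds + 0.368 * (length(ch) - 1) * log(salt_molarity)
  tm_k <- th$dh * 1000 / (ds_salt + .gas_const * log(oligo_conc_M / 4))
  tm_k - 273.15 - formamide_coef * 100 * formamide_fraction
}

# Gibbs free energy of a fully paired duplex segment at temperature (degC)
.duplex_segment_dg <- function(chars, temperature) {
  th <- .duplex_dh_ds(chars)
  th$dh - (temperature + 273.15) * th$ds / 1000
}

#' Most stable duplex (dimer) free energy between two oligos
#'
#' Scans every antiparallel alignment of `seq1` against `seq2` and scores
#' each maximal run of Watson-Crick pairs with nearest-neighbor stacks plus
#' terminal initiation. Returns the minimum (most stable) free energy in
#' kcal/mol; self-dimers are scored with `seq2 = seq1`. A value of 0 means
#' no stacked duplex of at least two pairs exists.
#'
#' @param seq1,seq2 DNA sequences (A/C/G/T).
#' @param temperature evaluation temperature in degC.
#' @return minimum duplex free energy (kcal/mol, <= 0).
#' @export
duplex_dg <- function(seq1, seq2 = seq1, temperature = 37) {
  a <- .seq_chars(.check_acgt(seq1))
  # antiparallel: reverse seq2 so position-wise comparison is 5'->3' vs 3'->5'
  b <- rev(.seq_chars(.check_acgt(seq2)))
  n <- length(a); m <- length(b)
  best <- 0
  for (off in (-(m - 2)):(n - 2)) {
    i <- max(1, 1 + off); j <- min(n, m + off)
    if (j - i < 1) next
    paired <- a[i:j] == .comp[b[(i - off):(j - off)]]
    r <- rle(paired)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= 2)) {
      seg <- a[(i + starts[k] - 1):(i + ends[k] - 1)]
      dg <- .duplex_segment_dg(seg, temperature)
      if (dg < best) best <- dg
    }
  }
  best
}

# hairpin loop initiation dG at 37 degC by loop size (3..30), treated as
# purely entropic when rescaled to other temperatures
.loop_dg37 <- local({
  anchor_n <- c(3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 25, 30)
  anchor_g <- c(3.5, 3.5, 3.3, 4.0, 4.2, 4.3, 4.5, 4.4, 4.7, 5.0, 5.2, 5.4,
                5.5, 5.8, 6.0)
  stats::approx(anchor_n, anchor_g, xout = 3:30)$y
})

.loop_penalty <- function(size, temperature) {
  t_k <- temperature + 273.15
  g37 <- if (size <= 30) .loop_dg37[size - 2]
  else .loop_dg37[28] + 1.75 * .gas_const * 310.15 * log(size / 30) / 1000
  g37 * t_k / 310.15
}

#' Minimum hairpin free energy of an oligo
#'
#' Exhaustively enumerates stem-loop configurations (stem length >= `min_stem`
#' fully Watson-Crick paired, loop >= 3 nt) and scores each as the sum of
#' nearest-neighbor stack free energies over the stem plus a loop-size
#' penalty, at the given temperature. Returns the minimum over all
#' configurations, or 0 when no stem can form.
#'
#' @param sequence DNA sequence (A/C/G/T).
#' @param temperature evaluation temperature in degC.
#' @param min_stem minimum number of paired bases in a stem.
#' @return minimum hairpin free energy (kcal/mol; 0 if no hairpin possible).
#' @export
hairpin_dg <- function(sequence, temperature = 42, min_stem = 3) {
  ch <- .seq_chars(.check_acgt(sequence))
  n <- length(ch)
  best <- 0
  if (n < 2 * min_stem + 3) return(best)
  t_k <- temperature + 273.15
  # (i, j) is the loop-closing pair; the stem grows outward as (i-t, j+t)
  for (i in min_stem:(n - min_stem - 3)) {
    for (j in (i + 4):(n - min_stem + 1)) {
      loop <- j - i - 1
      if (loop < 3) next
      ext <- 0
      t_max <- min(i, n - j + 1)
      for (t in 0:(t_max - 1)) {
        if (ch[i - t] == .comp[ch[j + t]]) ext <- ext + 1 else break
      }
      if (ext < min_stem) next
      for (s in min_stem:ext) {
        stem <- ch[(i - s + 1):i]   # 5' arm, 5'->3'
        di <- paste0(stem[-s], stem[-1])
        dg <- sum(.nn_dh[di]) - t_k * sum(.nn_ds[di]) / 1000 +
          .loop_penalty(loop, temperature)
        if (dg < best) best <- dg
      }
    }
  }
  best
}
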