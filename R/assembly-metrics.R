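# Assembly contiguity and karyotype length statistics.

#' N50 of a set of sequence lengths
#'
#' The smallest length L such that sequences of length >= L together cover
#' at least half the total (descending cumulative sum).
#'
#' @param lengths positive numeric vector of sequence lengths.
#' @return N50 in the input unit.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("empty length set", call. = FALSE)
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Minimal number of largest sequences covering a fraction of the assembly
#'
#' `l_fraction(lengths, 0.9)` is the L90: how many of the largest
#' sequences are needed to reach 90 percent of the total length.
#'
#' @param lengths positive numeric vector of sequence lengths.
#' @param fraction target fraction of the total, in (0, 1].
#' @return integer count.
#' @export
l_fraction <- function(lengths, fraction = 0.9) {
  if (!length(lengths)) stop("empty length set", call. = FALSE)
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  s <- sort(lengths, decreasing = TRUE)
  which(cumsum(s) >= fraction * sum(s))[1]
}

#' Full contiguity summary of a sequence set
#'
#' @param lengths positive numeric vector of sequence lengths.
#' @param split_at_gaps optional named character vector of sequences; when
#'   given, a second set of statistics is computed on gap-split pieces
#'   (runs of N removed), labelled `contig`.
#' @return list with n_sequences, total_length, n50, l90, largest and,
#'   when sequences are supplied, a `contig` sub-list for the gap-split
#'   variant.
#' @export
assembly_stats <- function(lengths, split_at_gaps = NULL) {
  out <- list(n_sequences = length(lengths), total_length = sum(lengths),
              n50 = n50(lengths), l90 = l_fraction(lengths, 0.9),
              largest = max(lengths))
  if (!is.null(split_at_gaps)) {
    pieces <- unlist(lapply(split_at_gaps, function(s)
      nchar(strsplit(toupper(s), "N+")[[1]])), use.names = FALSE)
    pieces <- pieces[pieces > 0]
    out$contig <- list(n_sequences = length(pieces),
                       total_length = sum(pieces), n50 = n50(pieces),
                       l90 = l_fraction(pieces, 0.9))
  }
  out
}

#' Per-chromosome relative lengths across spreads
#'
#' Each spread's chromosome lengths are divided by that spread's sex
#' chromosome (X) length — cancelling the spread's compaction factor —
#' then rescaled by the grand-mean X length so values stay in the
#' measurement unit. Mean and SD across spreads are reported per
#' chromosome; spreads without an X measurement are dropped with a
#' warning.
#'
#' @param measurements data.frame: spread_id, chromosome, length_um.
#' @param reference_chromosome the normalizing chromosome label.
#' @return data.frame: chromosome, relative_length (mean), sd, n_spreads.
#' @export
relative_lengths <- function(measurements,
                             reference_chromosome = "X") {
  sp <- split(measurements, measurements$spread_id)
  keep <- vapply(sp, function(m)
    reference_chromosome %in% m$chromosome, logical(1))
  if (any(!keep))
    warning(sum(!keep), " spread(s) without a ", reference_chromosome,
            " measurement dropped", call. = FALSE)
  sp <- sp[keep]
  if (!length(sp)) stop("no usable spread", call. = FALSE)
  xlen <- vapply(sp, function(m)
    m$length_um[m$chromosome == reference_chromosome][1], numeric(1))
  grand_x <- mean(xlen)
  norm <- do.call(rbind, lapply(seq_along(sp), function(i) {
    m <- sp[[i]]
    m$rel <- m$length_um / xlen[i] * grand_x
    m
  }))
  agg <- lapply(split(norm, norm$chromosome), function(m)
    data.frame(chromosome = m$chromosome[1],
               relative_length = mean(m$rel),
               sd = if (nrow(m) > 1) stats::sd(m$rel) else 0,
               n_spreads = nrow(m), stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
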