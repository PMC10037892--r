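# File IO: FASTA through Biostrings, tab tables with a one-line provenance
# header, and the 12 mandatory PAF columns.

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a data.frame as TSV with a provenance header line
#'
#' The first line is a `#`-prefixed comment echoing the generating call's
#' parameters, so every emitted table records how it was produced.
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param params named list of parameters to echo into the header.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, params = list()) {
  hdr <- paste0("# karyopaint ", format(Sys.time(), "%Y-%m-%d"),
                if (length(params))
                  paste0(" | ", paste(names(params), unlist(params),
                                      sep = "=", collapse = " ")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path input file.
#' @return data.frame (the provenance comment line is skipped).
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

.paf_cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
               "tstart", "tend", "nmatch", "alen", "mapq")

#' Read the 12 mandatory columns of a PAF alignment file
#'
#' @param path PAF file (optional SAM-style tags beyond column 12 are
#'   ignored).
#' @return data.frame with columns qname, qlen, qstart, qend, strand,
#'   tname, tlen, tstart, tend, nmatch, alen, mapq.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- data.frame(matrix(nrow = 0, ncol = 12))
    names(out) <- .paf_cols
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12))
    stop("malformed PAF row (fewer than 12 fields) at line ",
         which(nf < 12)[1], call. = FALSE)
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  out <- data.frame(m, stringsAsFactors = FALSE)
  names(out) <- .paf_cols
  num <- c("qlen", "qstart", "qend", "tlen", "tstart", "tend", "nmatch",
           "alen", "mapq")
  for (cc in num) {
    v <- suppressWarnings(as.numeric(out[[cc]]))
    if (anyNA(v))
      stop("malformed PAF row (non-numeric ", cc, ") at line ",
           which(is.na(v))[1], call. = FALSE)
    out[[cc]] <- v
  }
  if (!all(out$strand %in% c("+", "-")))
    stop("malformed PAF row (bad strand) at line ",
         which(!out$strand %in% c("+", "-"))[1], call. = FALSE)
  out
}

#' Write alignments as PAF
#'
#' @param paf data.frame with the 12 mandatory PAF columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_paf <- function(paf, path) {
  utils::write.table(paf[, .paf_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
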