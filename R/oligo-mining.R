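# Candidate oligo mining: fixed-length genome-homolog windows filtered on
# masking, GC, melting temperature, genome-wide k-mer abundance and
# predicted hairpin structure. Coordinates are 0-based half-open on the
# scaffold throughout.

#' Mining parameter set
#'
#' Defaults correspond to a balanced probe-mining regime: 39-nt candidates,
#' hybridization at 42 degC in 50 percent formamide, Tm accepted between 42
#' and 47 degC under those conditions, GC 20-80 percent, and genome-wide
#' uniqueness enforced as at most `max_kmer_count_allowed` occurrences of
#' any constituent 18-mer on either strand.
#'
#' @param oligo_length candidate length in nt.
#' @param tm_window numeric length-2, accepted Tm range in degC.
#' @param gc_window numeric length-2, accepted GC fraction range.
#' @param k k-mer length for the uniqueness filter.
#' @param max_kmer_count_allowed maximum genome-wide k-mer count.
#' @param hybridization_temp structure-check temperature in degC.
#' @param formamide_fraction formamide volume fraction used in the Tm model.
#' @param salt_molarity monovalent salt (mol/L) used in the Tm model.
#' @param hairpin_dg_min minimum allowed hairpin free energy (kcal/mol).
#' @param spacing minimum bases between successive candidate windows.
#' @return a `mining_params` list.
#' @export
mining_params <- function(oligo_length = 39, tm_window = c(42, 47),
                          gc_window = c(0.2, 0.8), k = 18,
                          max_kmer_count_allowed = 5,
                          hybridization_temp = 42,
                          formamide_fraction = 0.5, salt_molarity = 0.39,
                          hairpin_dg_min = 0, spacing = 0) {
  if (tm_window[1] >= tm_window[2]) stop("tm_window min must be < max",
                                         call. = FALSE)
  if (k > oligo_length) stop("k must be <= oligo_length", call. = FALSE)
  structure(list(oligo_length = oligo_length, tm_window = tm_window,
                 gc_window = gc_window, k = k,
                 max_kmer_count_allowed = max_kmer_count_allowed,
                 hybridization_temp = hybridization_temp,
                 formamide_fraction = formamide_fraction,
                 salt_molarity = salt_molarity,
                 hairpin_dg_min = hairpin_dg_min, spacing = spacing),
            class = "mining_params")
}

.empty_candidates <- function() {
  data.frame(scaffold_id = character(), start = integer(), end = integer(),
             sequence = character(), tm = numeric(), gc = numeric(),
             max_kmer_count = integer(), hairpin_dg = numeric(),
             stringsAsFactors = FALSE)
}

#' Mine candidate oligos from one scaffold
#'
#' Greedy left-to-right tiling: the window advances base by base until a
#' window passes all local predicates (no masked base — N or lowercase —,
#' GC and Tm inside their windows), emits it, then jumps past it plus the
#' configured spacing. Genome-wide (k-mer) and structure filters are
#' separate passes ([kmer_filter()], [structure_check()]).
#'
#' @param scaffold scaffold sequence (masked bases as N or lowercase).
#' @param params a [mining_params()] set.
#' @param scaffold_id id recorded on the candidates.
#' @return candidate data.frame: scaffold_id, start, end, sequence, tm, gc,
#'   max_kmer_count (NA until [kmer_filter()]), hairpin_dg (NA until
#'   [structure_check()]), sorted by start.
#' @export
mine_candidates <- function(scaffold, params = mining_params(),
                            scaffold_id = "scaffold") {
  if (!nzchar(scaffold)) stop("scaffold is empty", call. = FALSE)
  L <- params$oligo_length
  n <- nchar(scaffold)
  if (n < L) return(.empty_candidates())
  ch <- .seq_chars(scaffold)
  masked <- !(ch %in% c("A", "C", "G", "T"))   # N and lowercase both masked
  is_gc <- ch %in% c("G", "C")
  # prefix sums for O(1) window mask/GC queries
  cmask <- cumsum(masked)
  cgc <- cumsum(is_gc)
  win_sum <- function(cs, st) cs[st + L] - if (st > 0) cs[st] else 0

  out <- list()
  pos <- 0L  # 0-based window start
  while (pos + L <= n) {
    if (win_sum(cmask, pos) > 0) { pos <- pos + 1L; next }
    gc <- win_sum(cgc, pos) / L
    if (gc < params$gc_window[1] || gc > params$gc_window[2]) {
      pos <- pos + 1L; next
    }
    seq <- substr(scaffold, pos + 1L, pos + L)
    tm <- melting_temperature(seq, salt_molarity = params$salt_molarity,
                              formamide_fraction = params$formamide_fraction)
    if (tm < params$tm_window[1] || tm > params$tm_window[2]) {
      pos <- pos + 1L; next
    }
    out[[length(out) + 1L]] <- data.frame(
      scaffold_id = scaffold_id, start = pos, end = pos + L,
      sequence = seq, tm = tm, gc = gc,
      max_kmer_count = NA_integer_, hairpin_dg = NA_real_,
      stringsAsFactors = FALSE)
    pos <- pos + L + as.integer(params$spacing)
  }
  if (!length(out)) return(.empty_candidates())
  do.call(rbind, out)
}

#' Count genome-wide k-mer occurrences (both strands)
#'
#' @param genome_seqs character vector of genome sequences.
#' @param k k-mer length.
#' @return a named integer vector: forward-strand occurrence count of every
#'   k-mer present in the genome. Both-strand counts of a query k-mer are
#'   `counts[kmer] + counts[revcomp(kmer)]`.
#' @export
count_genome_kmers <- function(genome_seqs, k) {
  all_k <- unlist(lapply(toupper(genome_seqs), function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    km <- substring(s, 1:(n - k + 1), k:n)
    km[!grepl("[^ACGT]", km)]
  }), use.names = FALSE)
  tbl <- table(all_k)
  stats::setNames(as.integer(tbl), names(tbl))
}

.kmer_max_count <- function(sequence, counts, k) {
  s <- toupper(sequence)
  n <- nchar(s)
  km <- substring(s, 1:(n - k + 1), k:n)
  fw <- counts[km]; fw[is.na(fw)] <- 0L
  rv <- counts[revcomp(km)]; rv[is.na(rv)] <- 0L
  max(fw + rv)
}

#' Filter candidates by genome-wide k-mer abundance
#'
#' A candidate is retained iff none of its constituent k-mers occurs more
#' than `max_kmer_count_allowed` times in the genome, counting both
#' strands. The maximum count is annotated on every candidate.
#'
#' @param candidates candidate data.frame from [mine_candidates()].
#' @param genome_seqs character vector of genome sequences (or a
#'   precomputed count vector from [count_genome_kmers()]).
#' @param k k-mer length (<= candidate length).
#' @param max_kmer_count_allowed maximum allowed both-strand count; `Inf`
#'   retains everything.
#' @return filtered candidate data.frame with `max_kmer_count` filled in.
#' @export
kmer_filter <- function(candidates, genome_seqs, k = 18,
                        max_kmer_count_allowed = 5) {
  if (!nrow(candidates)) return(candidates)
  counts <- if (is.numeric(genome_seqs)) genome_seqs
  else count_genome_kmers(genome_seqs, k)
  candidates$max_kmer_count <- vapply(
    candidates$sequence, .kmer_max_count, numeric(1),
    counts = counts, k = k, USE.NAMES = FALSE)
  candidates[candidates$max_kmer_count <= max_kmer_count_allowed, ,
             drop = FALSE]
}

#' Filter candidates by predicted hairpin structure
#'
#' Fails a candidate iff its minimum hairpin free energy at the
#' hybridization temperature is below `dg_min`; the free energy is
#' annotated on every candidate.
#'
#' @param candidates candidate data.frame.
#' @param temperature evaluation temperature in degC.
#' @param dg_min minimum allowed hairpin free energy (kcal/mol); the
#'   default 0 fails any thermodynamically favourable hairpin.
#' @return filtered candidate data.frame with `hairpin_dg` filled in.
#' @export
structure_check <- function(candidates, temperature = 42, dg_min = 0) {
  if (!nrow(candidates)) return(candidates)
  candidates$hairpin_dg <- vapply(candidates$sequence, hairpin_dg,
                                  numeric(1), temperature = temperature,
                                  USE.NAMES = FALSE)
  candidates[candidates$hairpin_dg >= dg_min, , drop = FALSE]
}

#' Filter candidates by melting temperature
#'
#' @param candidates candidate data.frame (with a `tm` column).
#' @param tm_window numeric length-2 accepted range in degC.
#' @return filtered candidate data.frame.
#' @export
filter_tm <- function(candidates, tm_window) {
  candidates[candidates$tm >= tm_window[1] & candidates$tm <= tm_window[2], ,
             drop = FALSE]
}

#' Filter candidates by GC fraction
#'
#' @param candidates candidate data.frame (with a `gc` column).
#' @param gc_window numeric length-2 accepted range.
#' @return filtered candidate data.frame.
#' @export
filter_gc <- function(candidates, gc_window) {
  candidates[candidates$gc >= gc_window[1] & candidates$gc <= gc_window[2], ,
             drop = FALSE]
}

#' Emit candidates as BED6+ rows
#'
#' @param candidates candidate data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_candidates_bed <- function(candidates, path) {
  bed <- data.frame(chrom = candidates$scaffold_id,
                    start = candidates$start, end = candidates$end,
                    name = paste0(candidates$scaffold_id, "_",
                                  candidates$start),
                    score = round(candidates$tm, 2), strand = "+",
                    gc = round(candidates$gc, 4),
                    max_kmer_count = candidates$max_kmer_count,
                    hairpin_dg = round(candidates$hairpin_dg, 3))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
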