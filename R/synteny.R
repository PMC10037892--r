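# Synteny blocks: chain co-linear whole-genome alignments, aggregate
# cross-genome chromosome associations (Sankey input), and convert blocks
# to signed arrangements for rearrangement classification.

#' Chain co-linear alignments into synteny blocks
#'
#' Alignments on the same (query chromosome, reference chromosome, strand)
#' triple are merged when both their query and reference gaps are at most
#' `max_gap` and they are co-linear in the strand's direction. Merged
#' blocks shorter than `min_block` on the query are dropped.
#'
#' @param paf alignment data.frame from [read_paf()].
#' @param min_block minimum block length on the query, in bases.
#' @param max_gap maximum bridged gap, in bases.
#' @return data.frame of blocks: query_chromosome, query_start, query_end,
#'   reference_chromosome, reference_start, reference_end, strand,
#'   aligned_bases; sorted by query position.
#' @export
chain_blocks <- function(paf, min_block = 0, max_gap = 5e5) {
  if (!nrow(paf))
    return(data.frame(query_chromosome = character(),
                      query_start = numeric(), query_end = numeric(),
                      reference_chromosome = character(),
                      reference_start = numeric(),
                      reference_end = numeric(), strand = character(),
                      aligned_bases = numeric(), stringsAsFactors = FALSE))
  paf <- paf[order(paf$qname, paf$tname, paf$strand, paf$qstart), ,
             drop = FALSE]
  key <- paste(paf$qname, paf$tname, paf$strand)
  out <- list()
  for (grp in split(paf, key)) {
    cur <- grp[1, ]
    acc <- cur$nmatch
    flush <- function(cur, acc) data.frame(
      query_chromosome = cur$qname, query_start = cur$qstart,
      query_end = cur$qend, reference_chromosome = cur$tname,
      reference_start = cur$tstart, reference_end = cur$tend,
      strand = cur$strand, aligned_bases = acc, stringsAsFactors = FALSE)
    if (nrow(grp) > 1) for (i in 2:nrow(grp)) {
      a <- grp[i, ]
      qgap <- a$qstart - cur$qend
      colinear <- if (cur$strand == "+") {
        tgap <- a$tstart - cur$tend
        qgap <= max_gap && tgap <= max_gap && a$tstart >= cur$tstart
      } else {
        tgap <- cur$tstart - a$tend
        qgap <= max_gap && tgap <= max_gap && a$tend <= cur$tend
      }
      if (colinear) {
        cur$qend <- max(cur$qend, a$qend)
        cur$tstart <- min(cur$tstart, a$tstart)
        cur$tend <- max(cur$tend, a$tend)
        acc <- acc + a$nmatch
      } else {
        out[[length(out) + 1L]] <- flush(cur, acc)
        cur <- a; acc <- a$nmatch
      }
    }
    out[[length(out) + 1L]] <- flush(cur, acc)
  }
  res <- do.call(rbind, out)
  res <- res[res$query_end - res$query_start >= min_block, , drop = FALSE]
  res <- res[order(res$query_chromosome, res$query_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cross-genome chromosome association table
#'
#' Aggregates aligned bases per (query chromosome, reference chromosome)
#' pair — the input of a Sankey diagram.
#'
#' @param blocks block data.frame from [chain_blocks()].
#' @param min_weight minimum aligned bases for a pair to be reported.
#' @return data.frame: source (query), target (reference), value (aligned
#'   bases), sorted by decreasing value.
#' @export
chromosome_associations <- function(blocks, min_weight = 0) {
  if (!nrow(blocks)) stop("no blocks", call. = FALSE)
  agg <- stats::aggregate(aligned_bases ~ query_chromosome +
                            reference_chromosome, data = blocks, FUN = sum)
  names(agg) <- c("source", "target", "value")
  agg <- agg[agg$value >= min_weight, , drop = FALSE]
  agg <- agg[order(-agg$value), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Signed block arrangements of the two genomes
#'
#' Numbers the blocks 1..n by reference position and renders each genome
#' as a list of chromosomes, each a signed integer vector (sign = strand
#' relative to the reference).
#'
#' @param blocks block data.frame from [chain_blocks()] (typically
#'   restricted to one ancestral chromosome's orthologs).
#' @return list with `reference` and `query` states (lists of signed
#'   integer vectors, named by chromosome) and the block table with an
#'   `block_id` column.
#' @export
rearrangement_states <- function(blocks) {
  b <- blocks[order(blocks$reference_chromosome, blocks$reference_start), ,
              drop = FALSE]
  b$block_id <- seq_len(nrow(b))
  ref <- lapply(split(b, b$reference_chromosome), function(x)
    x$block_id[order(x$reference_start)])
  bq <- b[order(b$query_chromosome, b$query_start), , drop = FALSE]
  qry <- lapply(split(bq, bq$query_chromosome), function(x)
    ifelse(x$strand == "+", x$block_id, -x$block_id))
  list(reference = ref, query = qry, blocks = b)
}
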