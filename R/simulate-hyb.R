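# Simulated FISH: a toy probe planner over scaffold truth, per-spread
# hybridization observations, per-spread chromosome length measurements and
# synthetic whole-genome alignments (PAF) to the originating genome.

#' Place toy probe windows on scaffolds
#'
#' Even placement of `n_probes` windows per scaffold, nudged so that no
#' window crosses a planted junction (breakpoint recovery is then
#' well-defined at the probe-window resolution). This is the lightweight
#' planner used with synthetic data; real plans come from
#' [select_probe_windows()].
#'
#' @param scaffolds a `scaffold_set`.
#' @param n_probes integer: probes per scaffold, a single value or a vector
#'   named by scaffold id.
#' @param span window span in bases.
#' @return data.frame with probe_id ("<scaffold>p<k>", k 0-based),
#'   scaffold_id, start, end (0-based half-open scaffold coordinates) and
#'   probe_index.
#' @export
plan_probes <- function(scaffolds, n_probes = 3, span = 1000) {
  stopifnot(inherits(scaffolds, "scaffold_set"))
  truth <- scaffolds$truth
  rows <- list()
  for (sid in unique(truth$scaffold_id)) {
    parts <- truth[truth$scaffold_id == sid, , drop = FALSE]
    L <- max(parts$scaffold_end)
    np <- if (length(n_probes) > 1) n_probes[[sid]] else n_probes
    junctions <- parts$junction[!is.na(parts$junction)]
    half <- span / 2
    for (k in seq_len(np) - 1L) {
      centre <- (k + 0.5) / np * L
      st <- max(0, min(L - span, round(centre - half)))
      en <- st + span
      for (j in sort(junctions)) {
        if (st < j && en > j) {
          # shift off the junction, toward the side with more of the window
          if (j - st >= en - j) { en <- j; st <- max(0, en - span) }
          else { st <- j; en <- min(L, st + span) }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = paste0(sid, "p", k), scaffold_id = sid,
        start = as.integer(st), end = as.integer(en), probe_index = k,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# map a scaffold offset to (chromosome, genome position) through the truth
.map_offset <- function(parts, offset) {
  hit <- which(offset >= parts$scaffold_start & offset < parts$scaffold_end)
  if (length(hit) != 1) return(NULL)
  p <- parts[hit, ]
  pos <- if (p$strand == "+") p$start + (offset - p$scaffold_start)
  else p$end - 1 - (offset - p$scaffold_start)
  list(chromosome = p$chromosome, pos = pos)
}

#' Simulate hybridization observations
#'
#' Each probe lights up, per metaphase spread, on the chromosome its truth
#' part belongs to. Signals on a chromosome are ranked by distance from the
#' centromere (`order_index`, 0-based); late-metaphase spreads additionally
#' record the chromosome arm ("p"/"q") the signal sits on. Probes drop out
#' independently with probability `dropout_rate`, and each spread carries a
#' multiplicative log-normal compaction factor with the stated log-sd.
#'
#' @param plan probe table from [plan_probes()] (or any data.frame with
#'   probe_id, scaffold_id, start, end).
#' @param scaffolds the `scaffold_set` the plan was made for.
#' @param genome the originating `toy_genome`.
#' @param n_spreads number of spreads.
#' @param dropout_rate per-probe per-spread dropout probability in `[0, 1)`.
#' @param length_noise_sd sd of the log compaction factor.
#' @param seed integer RNG seed.
#' @param stage "late_metaphase" (centromere side visible) or "metaphase".
#' @param colours optional named vector probe_id -> colour label, echoed
#'   into the observations.
#' @return data.frame of observations: spread_id, probe_id, scaffold_id,
#'   chromosome_label, order_index, colour, stage, centromere_side,
#'   length_scale.
#' @export
simulate_hybridization <- function(plan, scaffolds, genome, n_spreads = 3,
                                   dropout_rate = 0, length_noise_sd = 0,
                                   seed = 1, stage = "late_metaphase",
                                   colours = NULL) {
  stopifnot(inherits(scaffolds, "scaffold_set"), inherits(genome, "toy_genome"))
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  truth <- scaffolds$truth
  slen <- tapply(truth$scaffold_end, truth$scaffold_id, max)
  bad <- plan$end > slen[plan$scaffold_id] | plan$start < 0
  if (any(bad))
    stop("probe outside scaffold bounds: ",
         paste(plan$probe_id[bad], collapse = ","), call. = FALSE)

  cen <- stats::setNames(genome$chromosomes$centromere_position,
                         genome$chromosomes$id)
  # static mapping of each probe midpoint
  mapped <- lapply(seq_len(nrow(plan)), function(i) {
    parts <- truth[truth$scaffold_id == plan$scaffold_id[i], , drop = FALSE]
    m <- .map_offset(parts, floor((plan$start[i] + plan$end[i]) / 2))
    if (is.null(m)) stop("probe midpoint maps to no truth part: ",
                         plan$probe_id[i], call. = FALSE)
    m
  })
  chrom <- vapply(mapped, `[[`, character(1), "chromosome")
  pos <- vapply(mapped, `[[`, numeric(1), "pos")
  dist_cen <- abs(pos - cen[chrom])
  side <- ifelse(pos < cen[chrom], "p", "q")

  withr::with_seed(seed, {
    out <- list()
    for (sp in seq_len(n_spreads)) {
      scale <- exp(stats::rnorm(1, 0, length_noise_sd))
      keep <- stats::runif(nrow(plan)) >= dropout_rate
      idx <- which(keep)
      if (!length(idx)) next
      ord <- integer(length(idx))
      for (ch in unique(chrom[idx])) {
        sel <- idx[chrom[idx] == ch]
        ord[match(sel, idx)] <- rank(dist_cen[sel], ties.method = "first") - 1L
      }
      out[[sp]] <- data.frame(
        spread_id = paste0("spread", sp),
        probe_id = plan$probe_id[idx],
        scaffold_id = plan$scaffold_id[idx],
        chromosome_label = chrom[idx],
        order_index = ord,
        colour = if (is.null(colours)) NA_character_
                 else unname(colours[plan$probe_id[idx]]),
        stage = stage,
        centromere_side = if (stage == "late_metaphase") side[idx]
                          else NA_character_,
        length_scale = scale,
        stringsAsFactors = FALSE)
    }
    if (!length(out))
      return(data.frame(spread_id = character(), probe_id = character(),
                        scaffold_id = character(),
                        chromosome_label = character(),
                        order_index = integer(), colour = character(),
                        stage = character(), centromere_side = character(),
                        length_scale = numeric(), stringsAsFactors = FALSE))
    do.call(rbind, out)
  })
}

#' Simulate per-spread chromosome length measurements
#'
#' Applies a per-spread multiplicative log-normal compaction factor to the
#' true chromosome lengths, emulating mitotic-stage variation in condensation
#' across spreads.
#'
#' @param genome a `toy_genome`.
#' @param n_spreads number of spreads.
#' @param length_noise_sd sd of the log compaction factor.
#' @param seed integer RNG seed.
#' @param um_per_mb microns of chromatid per megabase, sets the unit.
#' @return data.frame: spread_id, chromosome, length_um, true_scale.
#' @export
simulate_spread_lengths <- function(genome, n_spreads = 5,
                                    length_noise_sd = 0.1, seed = 1,
                                    um_per_mb = 0.5) {
  stopifnot(inherits(genome, "toy_genome"))
  withr::with_seed(seed, {
    out <- lapply(seq_len(n_spreads), function(sp) {
      scale <- exp(stats::rnorm(1, 0, length_noise_sd))
      data.frame(spread_id = paste0("spread", sp),
                 chromosome = genome$chromosomes$id,
                 length_um = genome$chromosomes$length / 1e6 * um_per_mb *
                   scale,
                 true_scale = scale, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Simulate whole-genome alignments of scaffolds to their source genome
#'
#' Emits PAF-style alignment records tiling each scaffold truth part in
#' chunks, mapped to the true chromosome coordinates — the synthetic
#' counterpart of aligning draft scaffolds to a finished reference with a
#' whole-genome aligner.
#'
#' @param scaffolds a `scaffold_set`.
#' @param genome the originating `toy_genome`.
#' @param chunk alignment block length in bases.
#' @param margin unaligned margin left at each part boundary, in bases.
#' @return data.frame in PAF column order (qname, qlen, qstart, qend,
#'   strand, tname, tlen, tstart, tend, nmatch, alen, mapq).
#' @export
simulate_reference_alignments <- function(scaffolds, genome, chunk = 1500,
                                          margin = 50) {
  stopifnot(inherits(scaffolds, "scaffold_set"), inherits(genome, "toy_genome"))
  truth <- scaffolds$truth
  tlen <- stats::setNames(genome$chromosomes$length, genome$chromosomes$id)
  slen <- tapply(truth$scaffold_end, truth$scaffold_id, max)
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    p <- truth[i, ]
    lo <- p$scaffold_start + margin
    hi <- p$scaffold_end - margin
    if (hi - lo < chunk / 2) { lo <- p$scaffold_start; hi <- p$scaffold_end }
    starts <- seq(lo, max(lo, hi - chunk), by = chunk)
    for (qs in starts) {
      qe <- min(qs + chunk, hi)
      if (qe - qs < chunk / 4) next
      if (p$strand == "+") {
        ts <- p$start + (qs - p$scaffold_start); te <- ts + (qe - qs)
      } else {
        te <- p$end - (qs - p$scaffold_start); ts <- te - (qe - qs)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        qname = p$scaffold_id, qlen = unname(slen[p$scaffold_id]),
        qstart = as.integer(qs), qend = as.integer(qe), strand = p$strand,
        tname = p$chromosome, tlen = unname(tlen[p$chromosome]),
        tstart = as.integer(ts), tend = as.integer(te),
        nmatch = as.integer(qe - qs), alen = as.integer(qe - qs),
        mapq = 60L, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
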