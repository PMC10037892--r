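# FISH-guided assembly curation: vote probes onto chromosomes, flag
# chimeric / internally reordered scaffolds, localize breakpoints with
# reference synteny, split and orient scaffold parts and emit a
# chromosome-level AGP build plus idiogram table.

# mode of a vector (ties -> first in sort order)
.majority <- function(x) {
  t <- sort(table(x), decreasing = TRUE)
  names(t)[1]
}

#' Assign probes and scaffolds to chromosomes by majority vote
#'
#' Each probe takes the majority chromosome label over spreads and must be
#' supported by at least `min_spreads` concordant spreads to count as
#' placed (otherwise it is flagged ambiguous). A scaffold is assigned the
#' set of chromosomes its placed probes vote for. When both the plan and
#' the observations carry colours, observations whose colour contradicts
#' the plan are discarded (the observation, not the probe, is invalidated).
#'
#' @param observations observation data.frame (spread_id, probe_id,
#'   chromosome_label, order_index, optionally colour, centromere_side,
#'   stage).
#' @param plan probe table (probe_id, scaffold_id, start, end, optionally
#'   probe_index and colour).
#' @param min_spreads minimum concordant spreads to accept a placement.
#' @return a `fish_assignment` list: `probes` (probe_id, scaffold_id,
#'   design_index, chromosome, n_support, ambiguous, unplaced), `scaffolds`
#'   (scaffold_id, chromosomes, n_chromosomes), `ranks` (per spread
#'   scaffold-local signal order) and the filtered observations.
#' @export
assign_scaffolds <- function(observations, plan, min_spreads = 2) {
  unknown <- setdiff(observations$probe_id, plan$probe_id)
  if (length(unknown))
    stop("observed probe not in plan: ",
         paste(utils::head(unknown, 5), collapse = ","), call. = FALSE)
  if (!is.null(observations$colour) && !is.null(plan$colour)) {
    want <- stats::setNames(plan$colour, plan$probe_id)
    bad <- !is.na(observations$colour) &
      !is.na(want[observations$probe_id]) &
      observations$colour != want[observations$probe_id]
    observations <- observations[!bad, , drop = FALSE]
  }
  if (is.null(plan$probe_index)) {
    plan$probe_index <- stats::ave(plan$start, plan$scaffold_id,
                                   FUN = function(x) rank(x) - 1L)
  }
  probes <- plan[, c("probe_id", "scaffold_id", "probe_index")]
  names(probes)[3] <- "design_index"
  obs_by_probe <- split(observations, observations$probe_id)
  probes$chromosome <- NA_character_
  probes$n_support <- 0L
  for (i in seq_len(nrow(probes))) {
    ob <- obs_by_probe[[probes$probe_id[i]]]
    if (is.null(ob) || !nrow(ob)) next
    maj <- .majority(ob$chromosome_label)
    probes$chromosome[i] <- maj
    probes$n_support[i] <- sum(ob$chromosome_label == maj)
  }
  probes$unplaced <- is.na(probes$chromosome)
  probes$ambiguous <- !probes$unplaced & probes$n_support < min_spreads
  placed <- probes[!probes$unplaced & !probes$ambiguous, , drop = FALSE]
  scaff <- do.call(rbind, lapply(split(placed, placed$scaffold_id),
    function(p) data.frame(
      scaffold_id = p$scaffold_id[1],
      chromosomes = paste(sort(unique(p$chromosome)), collapse = ","),
      n_chromosomes = length(unique(p$chromosome)),
      stringsAsFactors = FALSE)))
  rownames(scaff) <- NULL

  # scaffold-local signal ranks per spread (within the probe's chromosome)
  obs <- merge(observations,
               probes[, c("probe_id", "chromosome", "design_index")],
               by = "probe_id")
  obs <- obs[!is.na(obs$chromosome) &
               obs$chromosome_label == obs$chromosome, , drop = FALSE]
  key <- paste(obs$spread_id, obs$scaffold_id, obs$chromosome_label)
  obs$local_rank <- stats::ave(obs$order_index, key,
                               FUN = function(x) rank(x,
                                 ties.method = "first") - 1L)
  structure(list(probes = probes, scaffolds = scaff, ranks = obs,
                 min_spreads = min_spreads),
            class = "fish_assignment")
}

#' @export
print.fish_assignment <- function(x, ...) {
  cat("fish_assignment:", nrow(x$probes), "probes,",
      nrow(x$scaffolds), "scaffolds placed,",
      sum(x$scaffolds$n_chromosomes > 1), "on >1 chromosome\n")
  invisible(x)
}

# consensus scaffold-local rank per probe (mode over spreads)
.consensus_ranks <- function(assignment, sid) {
  obs <- assignment$ranks[assignment$ranks$scaffold_id == sid, ,
                          drop = FALSE]
  if (!nrow(obs)) return(NULL)
  agg <- lapply(split(obs, obs$probe_id), function(o)
    as.integer(.majority(o$local_rank)))
  unlist(agg)
}

#' Classify scaffolds as clean, chimeric or reordered
#'
#' Chimeric iff its placed probes vote for two or more chromosomes
#' (chimerism takes precedence); otherwise reordered iff the consensus
#' observed signal order is neither the design order nor its full reversal
#' (a full reversal is just the opposite orientation, not an error).
#'
#' @param assignment a [assign_scaffolds()] result.
#' @param plan the probe table used for the assignment.
#' @return data.frame scaffold_id, status in {clean, chimeric, reordered};
#'   attribute `splits` holds, per chimeric junction, the flanking probes
#'   and their chromosomes (ordered along the scaffold).
#' @export
detect_anomalies <- function(assignment, plan) {
  probes <- assignment$probes
  out <- list(); splits <- list()
  for (sid in unique(probes$scaffold_id)) {
    p <- probes[probes$scaffold_id == sid & !probes$unplaced &
                  !probes$ambiguous, , drop = FALSE]
    if (!nrow(p)) next
    p <- p[order(p$design_index), , drop = FALSE]
    chroms <- unique(p$chromosome)
    if (length(chroms) >= 2) {
      status <- "chimeric"
      ch <- which(p$chromosome[-1] != p$chromosome[-nrow(p)])
      for (j in ch)
        splits[[length(splits) + 1L]] <- data.frame(
          scaffold_id = sid,
          left_probe = p$probe_id[j], right_probe = p$probe_id[j + 1],
          left_design_index = p$design_index[j],
          right_design_index = p$design_index[j + 1],
          left_chromosome = p$chromosome[j],
          right_chromosome = p$chromosome[j + 1],
          stringsAsFactors = FALSE)
    } else {
      cons <- .consensus_ranks(assignment, sid)
      if (is.null(cons) || nrow(p) < 2) status <- "clean"
      else {
        r <- unname(cons[p$probe_id])
        status <- if (identical(r, seq_along(r) - 1L) ||
                      identical(r, rev(seq_along(r) - 1L))) "clean"
        else "reordered"
      }
    }
    out[[length(out) + 1L]] <- data.frame(scaffold_id = sid,
                                          status = status,
                                          stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "splits") <- if (length(splits)) do.call(rbind, splits) else NULL
  res
}

#' Localize breakpoints of chimeric scaffolds by reference synteny
#'
#' For each chimeric junction, the breakpoint interval is the inter-probe
#' gap narrowed by alignments to a reference genome: its left bound is the
#' end of the last alignment consistent with the left side's reference
#' chromosome, its right bound the start of the first alignment consistent
#' with the right side's, both clipped to the gap. Without informative
#' alignments the full inter-probe gap is reported with evidence
#' "midpoint_fallback".
#'
#' @param anomalies a [detect_anomalies()] result (with its `splits`
#'   attribute).
#' @param plan probe table (probe_id, start, end).
#' @param paf optional alignment data.frame from [read_paf()] (query =
#'   scaffolds, target = reference genome).
#' @return data.frame: scaffold_id, left_bound, right_bound, midpoint,
#'   left_probe, right_probe, evidence, reference_left, reference_right.
#' @export
locate_breakpoints <- function(anomalies, plan, paf = NULL) {
  splits <- attr(anomalies, "splits")
  if (is.null(splits) || !nrow(splits))
    stop("no chimeric scaffold: breakpoint localization needs a chimera",
         call. = FALSE)
  if (any(splits$right_design_index != splits$left_design_index + 1))
    stop("flanking probes are not adjacent in design order", call. = FALSE)
  pe <- stats::setNames(plan$end, plan$probe_id)
  ps <- stats::setNames(plan$start, plan$probe_id)
  out <- list()
  for (i in seq_len(nrow(splits))) {
    s <- splits[i, ]
    gap_l <- unname(pe[s$left_probe]); gap_r <- unname(ps[s$right_probe])
    lb <- gap_l; rb <- gap_r; ev <- "midpoint_fallback"
    ref_l <- NA_character_; ref_r <- NA_character_
    if (!is.null(paf) && nrow(paf)) {
      al <- paf[paf$qname == s$scaffold_id, , drop = FALSE]
      if (nrow(al)) {
        left_al <- al[al$qend <= gap_l, , drop = FALSE]
        right_al <- al[al$qstart >= gap_r, , drop = FALSE]
        if (nrow(left_al)) ref_l <- .majority(left_al$tname)
        if (nrow(right_al)) ref_r <- .majority(right_al$tname)
        if (!is.na(ref_l) && !is.na(ref_r) && ref_l != ref_r) {
          in_l <- al[al$tname == ref_l & al$qend <= gap_r, , drop = FALSE]
          in_r <- al[al$tname == ref_r & al$qstart >= gap_l, , drop = FALSE]
          nl <- if (nrow(in_l)) max(in_l$qend) else gap_l
          nr <- if (nrow(in_r)) min(in_r$qstart) else gap_r
          if (nl <= nr && (nl > gap_l || nr < gap_r)) {
            lb <- max(gap_l, nl); rb <- min(gap_r, nr); ev <- "synteny"
          }
        }
      }
    }
    out[[i]] <- data.frame(
      scaffold_id = s$scaffold_id, left_bound = lb, right_bound = rb,
      midpoint = floor((lb + rb) / 2),
      left_probe = s$left_probe, right_probe = s$right_probe,
      evidence = ev, reference_left = ref_l, reference_right = ref_r,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# part label: "S" whole, "Sp<a>" single probe, "Sp<a>-<b>" probe range
.part_label <- function(sid, a, b, whole) {
  if (whole) sid
  else if (a == b) paste0(sid, "p", a)
  else paste0(sid, "p", a, "-", b)
}

#' Split chimeric scaffolds and orient all parts
#'
#' Chimeric scaffolds are cut at each breakpoint-interval midpoint (the
#' interval itself is kept in the breakpoint table). Each part is oriented
#' from late-metaphase evidence: "+" when the design probe order runs
#' centromere-to-telomere with the observed signal order, "-" ("rev") when
#' it runs opposite; single-probe parts stay "+" with a low-confidence
#' flag. Contradictory per-spread evidence leaves the orientation NA with
#' a warning.
#'
#' @param scaffold_lengths named vector of scaffold lengths.
#' @param breakpoints breakpoint table from [locate_breakpoints()] (NULL
#'   when nothing is chimeric).
#' @param assignment a [assign_scaffolds()] result.
#' @param plan probe table.
#' @return data.frame of parts: part_id, scaffold_id, start, end,
#'   orientation, assigned_chromosome, order_on_chromosome,
#'   low_confidence.
#' @export
split_and_orient <- function(scaffold_lengths, breakpoints, assignment,
                             plan) {
  probes <- assignment$probes
  if (is.null(plan$probe_index))
    plan$probe_index <- stats::ave(plan$start, plan$scaffold_id,
                                   FUN = function(x) rank(x) - 1L)
  parts <- list()
  for (sid in unique(probes$scaffold_id)) {
    L <- scaffold_lengths[[sid]]
    bp <- if (is.null(breakpoints)) NULL
    else breakpoints[breakpoints$scaffold_id == sid, , drop = FALSE]
    cuts <- if (is.null(bp) || !nrow(bp)) numeric(0) else sort(bp$midpoint)
    bounds <- c(0, cuts, L)
    p <- plan[plan$scaffold_id == sid, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    whole <- length(cuts) == 0
    for (k in seq_len(length(bounds) - 1)) {
      st <- bounds[k]; en <- bounds[k + 1]
      inwin <- p[p$start >= st & p$end <= en, , drop = FALSE]
      pr <- merge(inwin, probes[, c("probe_id", "chromosome",
                                    "design_index")], by = "probe_id")
      pr <- pr[!is.na(pr$chromosome), , drop = FALSE]
      chrom <- if (nrow(pr)) .majority(pr$chromosome) else NA_character_
      lab <- .part_label(sid, min(inwin$probe_index),
                         max(inwin$probe_index), whole)
      ori <- "+"; lowc <- FALSE
      if (nrow(pr) < 2) lowc <- TRUE
      else {
        # per-spread monotonicity votes of signal order vs design order
        obs <- assignment$ranks[
          assignment$ranks$probe_id %in% pr$probe_id, , drop = FALSE]
        votes <- vapply(split(obs, obs$spread_id), function(o) {
          if (nrow(o) < 2) return(NA_real_)
          o <- o[order(o$design_index), ]
          sign(stats::cor(o$design_index, o$order_index,
                          method = "kendall"))
        }, numeric(1))
        votes <- votes[!is.na(votes) & votes != 0]
        if (!length(votes)) lowc <- TRUE
        else if (all(votes > 0)) ori <- "+"
        else if (all(votes < 0)) ori <- "-"
        else if (sum(votes > 0) != sum(votes < 0)) {
          ori <- if (sum(votes > 0) > sum(votes < 0)) "+" else "-"
        } else {
          warning("contradictory centromere-side evidence on ", lab,
                  "; orientation left unset", call. = FALSE)
          ori <- NA_character_
        }
      }
      # chromosome-wide signal position orders parts across scaffolds
      obs_part <- assignment$ranks[
        assignment$ranks$probe_id %in% pr$probe_id, , drop = FALSE]
      mean_rank <- if (nrow(obs_part)) mean(obs_part$order_index)
      else NA_real_
      parts[[length(parts) + 1L]] <- data.frame(
        part_id = lab, scaffold_id = sid, start = st, end = en,
        orientation = ori, assigned_chromosome = chrom,
        order_rank_raw = mean_rank, low_confidence = lowc,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, parts)
  # order parts along each chromosome by their mean observed rank
  res$order_on_chromosome <- NA_integer_
  for (ch in unique(res$assigned_chromosome)) {
    if (is.na(ch)) next
    sel <- which(res$assigned_chromosome == ch)
    res$order_on_chromosome[sel] <-
      rank(res$order_rank_raw[sel], ties.method = "first") - 1L
  }
  res$order_rank_raw <- NULL
  res
}
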