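# Probe design: per-scaffold probe-count allocation under a synthesis
# budget, probe-window selection over mined candidates with spacing and
# terminus constraints, plan summary statistics and fluorophore colour
# schemes.

#' Allocate probe counts per scaffold under a library budget
#'
#' The largest scaffold receives `max_probes`; scaffolds under mis-assembly
#' suspicion receive at least 4; the remaining scaffolds are tiered into
#' 3/2/1 probes by decreasing length. Tier sizes are either given
#' explicitly (`tier_sizes`, a length-3 vector of how many scaffolds get
#' 3, 2 and 1 probes, in length order) or chosen by exhaustive search over
#' tier boundaries, maximising the total probe count under the oligo budget
#' `n_libraries * capacity` with ties broken toward larger tiers for longer
#' scaffolds. Scaffolds are finally packed into synthesis libraries,
#' longest first, none exceeding `capacity` oligos.
#'
#' @param scaffold_lengths named numeric vector of scaffold lengths (bases).
#' @param suspected character vector of scaffold ids with suspected
#'   mis-assembly.
#' @param n_libraries number of synthesis libraries.
#' @param capacity oligo capacity of one library.
#' @param n_oligo oligos per probe.
#' @param max_probes probe count for the largest scaffold (and tier cap).
#' @param tier_sizes optional integer length-3 vector: scaffolds given
#'   3, 2 and 1 probes among those not covered by the first two rules.
#' @return an `allocation_scheme`: data.frame scaffold_id, length, n_probes,
#'   library; attributes n_oligo, capacity, n_libraries.
#' @export
allocate_probe_counts <- function(scaffold_lengths, suspected = character(),
                                  n_libraries = 3, capacity = 91500,
                                  n_oligo = 1500, max_probes = 5,
                                  tier_sizes = NULL) {
  if (is.null(names(scaffold_lengths)))
    names(scaffold_lengths) <- as.character(seq_along(scaffold_lengths))
  if (capacity < n_oligo)
    stop("library capacity smaller than one probe", call. = FALSE)
  ord <- order(-scaffold_lengths, names(scaffold_lengths))
  ids <- names(scaffold_lengths)[ord]
  lens <- unname(scaffold_lengths[ord])
  n <- length(ids)
  budget <- n_libraries * capacity           # oligos
  counts <- integer(n)
  counts[1] <- max_probes
  sus <- ids %in% suspected & counts == 0
  counts[sus] <- 4L
  rest <- which(counts == 0)
  m <- length(rest)
  fixed <- sum(counts)
  if ((fixed + m) * n_oligo > budget)
    stop("infeasible budget: cannot give every scaffold one probe",
         call. = FALSE)
  if (m > 0) {
    if (!is.null(tier_sizes)) {
      if (sum(tier_sizes) != m)
        stop("tier_sizes must cover the ", m, " remaining scaffolds",
             call. = FALSE)
      tiers <- rep(c(3L, 2L, 1L), times = tier_sizes)
    } else {
      # exhaustive over tier boundaries, maximise probes, prefer big tiers
      best <- NULL
      for (x3 in m:0) {
        for (x2 in (m - x3):0) {
          x1 <- m - x3 - x2
          tot <- fixed + 3 * x3 + 2 * x2 + x1
          if (tot * n_oligo > budget) next
          key <- c(tot, x3, x2)
          if (is.null(best) || .lex_gt(key, best$key))
            best <- list(key = key, x = c(x3, x2, x1))
        }
      }
      tiers <- rep(c(3L, 2L, 1L), times = best$x)
    }
    counts[rest] <- tiers
  }
  # pack into libraries, longest first, first-fit by remaining capacity
  lib_load <- numeric(n_libraries)
  lib <- integer(n)
  for (i in seq_len(n)) {
    need <- counts[i] * n_oligo
    slot <- which(lib_load + need <= capacity)[1]
    if (is.na(slot))
      stop("infeasible budget: scaffold ", ids[i],
           " does not fit any library", call. = FALSE)
    lib[i] <- slot
    lib_load[slot] <- lib_load[slot] + need
  }
  out <- data.frame(scaffold_id = ids, length = lens, n_probes = counts,
                    library = lib, stringsAsFactors = FALSE)
  structure(out, n_oligo = n_oligo, capacity = capacity,
            n_libraries = n_libraries, class = c("allocation_scheme",
                                                 "data.frame"))
}

# strict lexicographic a > b
.lex_gt <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1]] > 0
}

# strict lexicographic a < b (numeric tuples)
.lex_lt <- function(a, b) .lex_gt(b, a)

#' Select probe windows from mined candidates
#'
#' A window is a run of `n_oligo` consecutive candidates. `n_probes`
#' disjoint windows are chosen, separated edge-to-edge by at least
#' `min_gap` and at least `min_terminus_distance` from both scaffold ends
#' when feasible (the terminus constraint is dropped with a warning
#' otherwise). Among feasible placements the selection minimises, slot by
#' slot and lexicographically, the summed (centrality, homogeneity, size)
#' criteria: distance of the window centre from its ideal equally-spaced
#' position, variance of inter-oligo spacing, and window span.
#'
#' @param candidates candidate data.frame for one scaffold (sorted by
#'   start).
#' @param n_probes number of windows to select.
#' @param n_oligo oligos per window.
#' @param min_gap minimum edge-to-edge separation between windows (bases).
#' @param min_terminus_distance minimum distance from scaffold ends (bases).
#' @param scaffold_length scaffold length in bases.
#' @param scaffold_id id used in probe names ("<id>p<k>", k 0-based).
#' @return data.frame of probe windows: probe_id, scaffold_id, start, end,
#'   probe_index, n_oligo, with a list-column `oligo_rows` of candidate row
#'   indices.
#' @export
select_probe_windows <- function(candidates, n_probes, n_oligo = 1500,
                                 min_gap = 0, min_terminus_distance = 0,
                                 scaffold_length,
                                 scaffold_id = candidates$scaffold_id[1]) {
  nc <- nrow(candidates)
  if (nc < n_probes * n_oligo)
    stop("insufficient candidates on scaffold ", scaffold_id, ": ",
         nc, " for ", n_probes, " x ", n_oligo, call. = FALSE)
  candidates <- candidates[order(candidates$start), , drop = FALSE]
  nw <- nc - n_oligo + 1
  w_start <- candidates$start[seq_len(nw)]
  w_end <- candidates$end[seq_len(nw) + n_oligo - 1]
  starts_mat <- candidates$start
  w_hom <- vapply(seq_len(nw), function(j) {
    if (n_oligo < 3) return(0)
    sp <- diff(starts_mat[j:(j + n_oligo - 1)])
    stats::var(sp)
  }, numeric(1))
  w_centre <- (w_start + w_end) / 2
  w_size <- w_end - w_start

  pick <- function(idx) {
    s <- .select_windows_dp(w_start[idx], w_end[idx], w_centre[idx],
                            w_hom[idx], w_size[idx], n_probes, min_gap,
                            scaffold_length)
    if (anyNA(s)) NULL else idx[s]
  }
  idx_ok <- which(w_start >= min_terminus_distance &
                    w_end <= scaffold_length - min_terminus_distance)
  sel <- if (length(idx_ok) >= n_probes) pick(idx_ok) else NULL
  if (is.null(sel)) {
    if (min_terminus_distance > 0)
      warning("terminus-distance constraint relaxed on scaffold ",
              scaffold_id, call. = FALSE)
    sel <- pick(seq_len(nw))
    if (is.null(sel))
      stop("no feasible probe placement on scaffold ", scaffold_id,
           call. = FALSE)
  }
  out <- data.frame(
    probe_id = paste0(scaffold_id, "p", seq_along(sel) - 1L),
    scaffold_id = scaffold_id,
    start = w_start[sel], end = w_end[sel],
    probe_index = seq_along(sel) - 1L, n_oligo = n_oligo,
    stringsAsFactors = FALSE)
  out$oligo_rows <- lapply(sel, function(j) j:(j + n_oligo - 1))
  out
}

# DP over windows sorted by start: slot k takes window j, predecessors must
# end at least min_gap before j starts. Scores are additive 3-tuples
# compared lexicographically. Returns window indices or NA if infeasible.
.select_windows_dp <- function(w_start, w_end, w_centre, w_hom, w_size,
                               n_probes, min_gap, scaffold_length) {
  nw <- length(w_start)
  if (nw < n_probes) return(NA)
  ideal <- scaffold_length * (2 * seq_len(n_probes) - 1) / (2 * n_probes)
  INF <- c(Inf, Inf, Inf)
  score <- function(k, j) c(abs(w_centre[j] - ideal[k]), w_hom[j], w_size[j])
  dp <- array(Inf, dim = c(n_probes, nw, 3))
  prev <- matrix(NA_integer_, n_probes, nw)
  for (j in seq_len(nw)) dp[1, j, ] <- score(1, j)
  if (n_probes > 1) {
    for (k in 2:n_probes) {
      # best predecessor prefix: windows sorted by start; a predecessor i is
      # valid for j iff w_end[i] + min_gap <= w_start[j]
      for (j in seq_len(nw)) {
        best <- INF; bi <- NA_integer_
        for (i in seq_len(nw)) {
          if (w_end[i] + min_gap > w_start[j]) next
          cand <- dp[k - 1, i, ]
          if (.lex_lt(cand, best)) { best <- cand; bi <- i }
        }
        if (!is.na(bi)) {
          dp[k, j, ] <- best + score(k, j)
          prev[k, j] <- bi
        }
      }
    }
  }
  best <- INF; bj <- NA_integer_
  for (j in seq_len(nw)) {
    cand <- dp[n_probes, j, ]
    if (.lex_lt(cand, best)) { best <- cand; bj <- j }
  }
  if (is.na(bj) || !is.finite(best[1])) return(NA)
  sel <- integer(n_probes)
  k <- n_probes; j <- bj
  while (k >= 1) { sel[k] <- j; j <- prev[k, j]; k <- k - 1 }
  sel
}

#' Summary statistics of a probe plan
#'
#' Window spans, within-scaffold inter-probe gaps (edge to edge), terminus
#' distances (first window start to scaffold start, last window end to
#' scaffold end) and the oligo density per kb (`n_oligo` / mean span).
#'
#' @param plan probe-window data.frame (probe_id, scaffold_id, start, end,
#'   n_oligo).
#' @param scaffold_lengths named vector of scaffold lengths.
#' @return list with `span`, `gap`, `terminus` (each mean/sd/min/max) and
#'   `oligo_density_per_kb`; `gap` is NULL and `no_gaps` TRUE when no
#'   scaffold carries two probes.
#' @export
probe_plan_stats <- function(plan, scaffold_lengths) {
  if (!nrow(plan)) stop("empty plan", call. = FALSE)
  summ <- function(x) if (!length(x)) NULL else
    list(mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x),
         n = length(x))
  spans <- plan$end - plan$start
  gaps <- numeric(0); term <- numeric(0)
  for (sid in unique(plan$scaffold_id)) {
    p <- plan[plan$scaffold_id == sid, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    if (nrow(p) > 1) gaps <- c(gaps, p$start[-1] - p$end[-nrow(p)])
    L <- scaffold_lengths[[sid]]
    term <- c(term, p$start[1], L - p$end[nrow(p)])
  }
  n_oligo <- if (!is.null(plan$n_oligo)) plan$n_oligo[1] else NA
  list(span = summ(spans), gap = summ(gaps), terminus = summ(term),
       no_gaps = !length(gaps),
       oligo_density_per_kb = n_oligo / (mean(spans) / 1000))
}

.palette3 <- c("FAM", "ATTO550", "ATTO647")
.single_colour <- c(FAM = "cyan", ATTO550 = "yellow", ATTO647 = "red")
.pair_colour <- c("FAM+ATTO550" = "green", "ATTO550+ATTO647" = "orange",
                  "FAM+ATTO647" = "violet")

#' The six-colour alphabet of a three-fluorophore palette
#'
#' Three singles plus the three unordered pairs (FAM+ATTO550 = green,
#' ATTO550+ATTO647 = orange, FAM+ATTO647 = violet).
#'
#' @param palette character vector of three fluorophores.
#' @return data.frame: colour, fluorophores (plus-separated).
#' @export
colour_alphabet <- function(palette = .palette3) {
  stopifnot(length(palette) == 3)
  pairs <- utils::combn(palette, 2)
  fl <- c(palette, apply(pairs, 2, paste, collapse = "+"))
  colour <- c(unname(.single_colour[palette]),
              unname(.pair_colour[apply(pairs, 2, paste, collapse = "+")]))
  colour[is.na(colour)] <- fl[is.na(colour)]
  data.frame(colour = colour, fluorophores = fl, stringsAsFactors = FALSE)
}

#' Assign colour schemes to probes
#'
#' Gives every scaffold an ordered pattern over the 6-colour alphabet (one
#' colour per probe), with no pattern repeated within a library pool;
#' repeats across pools are permitted and reported in the
#' `cross_pool_repeats` attribute. Patterns are enumerated deterministically
#' (mixed-radix over the alphabet) per (pool, probe-count) group.
#'
#' @param allocation an [allocate_probe_counts()] scheme.
#' @param palette three fluorophores.
#' @return data.frame with one row per probe: scaffold_id, library,
#'   probe_index, colour, fluorophores; attribute `cross_pool_repeats`
#'   lists patterns used in more than one pool.
#' @export
assign_colour_schemes <- function(allocation, palette = .palette3) {
  alpha <- colour_alphabet(palette)
  ncol6 <- nrow(alpha)
  out <- list()
  patterns_by_pool <- list()
  for (lib in sort(unique(allocation$library))) {
    sub <- allocation[allocation$library == lib, , drop = FALSE]
    used <- character(0)
    for (cnt in sort(unique(sub$n_probes), decreasing = TRUE)) {
      grp <- sub[sub$n_probes == cnt, , drop = FALSE]
      if (nrow(grp) > ncol6^cnt)
        stop("pool ", lib, " needs ", nrow(grp), " distinct ", cnt,
             "-probe patterns but only ", ncol6^cnt,
             " exist; split the pool", call. = FALSE)
      for (i in seq_len(nrow(grp))) {
        # i-th pattern in mixed-radix order over the colour alphabet
        x <- i - 1
        digs <- integer(cnt)
        for (d in cnt:1) { digs[d] <- x %% ncol6; x <- x %/% ncol6 }
        cols <- alpha$colour[digs + 1]
        key <- paste(cols, collapse = "|")
        stopifnot(!key %in% used)
        used <- c(used, key)
        out[[length(out) + 1L]] <- data.frame(
          scaffold_id = grp$scaffold_id[i], library = lib,
          probe_index = seq_len(cnt) - 1L, colour = cols,
          fluorophores = alpha$fluorophores[digs + 1],
          stringsAsFactors = FALSE)
      }
    }
    patterns_by_pool[[as.character(lib)]] <- used
  }
  res <- do.call(rbind, out)
  all_pat <- unlist(patterns_by_pool)
  structure(res, cross_pool_repeats = unique(all_pat[duplicated(all_pat)]))
}
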