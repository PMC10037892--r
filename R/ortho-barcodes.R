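# Orthogonal barcode workflow: slice a 25-mer pool into 20-mers, remove
# sequences with detectable homology to the target genome, screen self- and
# hetero-dimers, attribute primer/adapter/detector roles and assemble the
# final 79-mer oligos and amplification primers.

#' T7 promoter extension used on reverse amplification primers (33 nt)
#' @export
T7_33MER <- "CGATTGAGGCCGGTAATACGACTCACTATAGGG"

#' Slice 25-mers into all their 20-mer substrings
#'
#' Each input yields its six 20-nt substrings in offset order; duplicates
#' are retained (deduplication is a separate, later step).
#'
#' @param pool character vector of 25-mers.
#' @return character vector of length `6 * length(pool)`.
#' @export
slice_orthologs <- function(pool) {
  if (any(nchar(pool) != 25))
    stop("all input sequences must be 25-mers", call. = FALSE)
  unlist(lapply(pool, function(s) substring(s, 1:6, 20:25)),
         use.names = FALSE)
}

# Karlin-Altschul lambda for match +1 / mismatch -2 at uniform base
# composition: (1/4)e^l + (3/4)e^{-2l} = 1  =>  e^l = (3 + sqrt(21)) / 2
.ka_lambda <- log((3 + sqrt(21)) / 2)

# Best ungapped local alignment score of query against one subject strand:
# Kadane's maximum-subarray along every diagonal, vectorised across
# diagonals. Also reports the longest exact-match run (the "word" seed).
.diag_scan <- function(qch, sch, match = 1, mismatch = -2) {
  m <- length(qch); n <- length(sch)
  if (n < m) return(c(score = -Inf, run = 0))
  nd <- n - m + 1
  cur <- numeric(nd); best <- numeric(nd)
  run <- numeric(nd); maxrun <- numeric(nd)
  for (j in seq_len(m)) {
    eq <- sch[j:(j + nd - 1)] == qch[j]
    s <- ifelse(eq, match, mismatch)
    cur <- pmax(cur + s, s)
    best <- pmax(best, cur)
    run <- ifelse(eq, run + 1, 0)
    maxrun <- pmax(maxrun, run)
  }
  c(score = max(best), run = max(maxrun))
}

#' Screen 20-mers for homology to the target genome
#'
#' Scores every query against both strands of the genome with an ungapped
#' local alignment (match +1, mismatch -2), requires an exact seed word of
#' `word_size` for a hit, and converts the best score to a Karlin-Altschul
#' e-value over the two-strand search space. Queries whose best hit has
#' e-value below `evalue_cutoff` (good homology) are REMOVED — the retained
#' set is orthogonal to the genome.
#'
#' @param seqs character vector of 20-mers (any length works).
#' @param genome_seqs character vector of genome sequences.
#' @param evalue_cutoff e-value below which a sequence is discarded.
#' @param word_size minimum exact-match run to count as a hit.
#' @param K Karlin-Altschul K parameter.
#' @return data.frame seq, genome_evalue, retained; the retained subset is
#'   in attribute-free row order of the input.
#' @export
screen_ortho_homology <- function(seqs, genome_seqs, evalue_cutoff = 25,
                                  word_size = 6, K = 0.333) {
  if (!length(genome_seqs) || !sum(nchar(genome_seqs)))
    stop("genome is empty", call. = FALSE)
  subjects <- c(toupper(genome_seqs), revcomp(genome_seqs))
  sch <- lapply(subjects, .seq_chars)
  n_total <- sum(nchar(genome_seqs)) * 2
  ev <- vapply(seqs, function(q) {
    qch <- .seq_chars(toupper(q))
    best <- -Inf; seeded <- FALSE
    for (sc in sch) {
      r <- .diag_scan(qch, sc)
      if (r["run"] >= word_size) {
        seeded <- TRUE
        if (r["score"] > best) best <- r["score"]
      }
    }
    if (!seeded) Inf
    else K * length(qch) * n_total * exp(-.ka_lambda * best)
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(seq = seqs, genome_evalue = ev,
             retained = ev >= evalue_cutoff, stringsAsFactors = FALSE)
}

#' Screen a pool for self- and hetero-dimers
#'
#' Greedy in pool order: a sequence is kept iff its most stable self-dimer
#' and its most stable hetero-dimer against every already-kept sequence
#' both have free energy >= `dg_min`. Greedy order makes the filter
#' deterministic (a maximum compatible subset is NP-hard).
#'
#' @param seqs character vector of sequences.
#' @param dg_min minimum allowed duplex free energy in kcal/mol.
#' @param temperature evaluation temperature in degC.
#' @return data.frame seq, min_self_dg, min_hetero_dg (vs kept set at
#'   decision time; NA when rejected on self), retained.
#' @export
dimer_filter <- function(seqs, dg_min = -9, temperature = 37) {
  n <- length(seqs)
  self_dg <- numeric(n); het_dg <- rep(NA_real_, n)
  keep <- logical(n)
  kept_idx <- integer(0)
  for (i in seq_len(n)) {
    self_dg[i] <- duplex_dg(seqs[i], seqs[i], temperature)
    if (self_dg[i] < dg_min) next
    h <- Inf
    ok <- TRUE
    for (j in kept_idx) {
      d <- duplex_dg(seqs[i], seqs[j], temperature)
      if (d < h) h <- d
      if (d < dg_min) { ok <- FALSE; break }
    }
    het_dg[i] <- if (is.finite(h)) h else NA_real_
    if (ok) { keep[i] <- TRUE; kept_idx <- c(kept_idx, i) }
  }
  data.frame(seq = seqs, min_self_dg = self_dg, min_hetero_dg = het_dg,
             retained = keep, stringsAsFactors = FALSE)
}

.has_gc_clamp <- function(seqs, end = c("5prime", "3prime")) {
  end <- match.arg(end)
  tri <- if (end == "5prime") substr(seqs, 1, 3)
  else substr(toupper(seqs), nchar(seqs) - 2, nchar(seqs))
  nchar(gsub("[^GCgc]", "", tri)) >= 2
}

#' Attribute barcode roles to a filtered orthogonal pool
#'
#' Reverse primers are scaffold-specific within a library (injective
#' reverse -> scaffold mapping per library) but one reverse sequence serves
#' the same slot across libraries (at most `max_scaffolds_per_reverse`
#' scaffolds in total). Forward primers and adapters are
#' fluorophore-specific and shared by all libraries; each fluorophore also
#' gets a detector. Sequences with a 5' GC clamp are preferred for the
#' reverse role and 3'-clamped ones for the forward role; remaining slots
#' are filled in randomized order under the given seed.
#'
#' @param seqs character vector of orthogonal sequences (post filtering).
#' @param scaffold_ids character vector of scaffold ids needing reverse
#'   primers.
#' @param library_of named integer vector scaffold -> library (defaults to
#'   a single library).
#' @param fluorophores character vector of fluorophore names.
#' @param seed integer RNG seed for the random fill.
#' @param max_scaffolds_per_reverse reuse cap for one reverse sequence.
#' @return list with data.frames `reverse` (seq_id, seq, scaffold_id,
#'   library), `forward`, `adapter`, `detector` (seq_id, seq, fluorophore)
#'   and `pool` (seq, role).
#' @export
assign_roles <- function(seqs, scaffold_ids,
                         library_of = NULL,
                         fluorophores = .palette3, seed = 1,
                         max_scaffolds_per_reverse = 4) {
  if (is.null(library_of))
    library_of <- stats::setNames(rep(1L, length(scaffold_ids)),
                                  scaffold_ids)
  libs <- sort(unique(library_of))
  # slot s in every library is served by one reverse sequence
  per_lib <- split(names(library_of), library_of[names(library_of)])
  n_rev <- max(lengths(per_lib))
  if (length(libs) > max_scaffolds_per_reverse)
    n_rev <- max(n_rev, ceiling(length(library_of) /
                                  max_scaffolds_per_reverse))
  n_fl <- length(fluorophores)
  need <- n_rev + 2 * n_fl + n_fl
  if (length(seqs) < need)
    stop("orthogonal pool exhausted: need ", need, " sequences (",
         n_rev, " reverse, ", n_fl, " forward, ", n_fl, " adapter, ",
         n_fl, " detector), have ", length(seqs), call. = FALSE)

  withr::with_seed(seed, {
    c5 <- .has_gc_clamp(seqs, "5prime")
    c3 <- .has_gc_clamp(seqs, "3prime")
    shuffled <- sample(seq_along(seqs))
    # 5'-clamped first for reverse, 3'-clamped first for forward
    rev_order <- shuffled[order(!c5[shuffled])]
    rev_idx <- rev_order[seq_len(n_rev)]
    rest <- setdiff(shuffled, rev_idx)
    fwd_order <- rest[order(!c3[rest])]
    fwd_idx <- fwd_order[seq_len(n_fl)]
    rest <- setdiff(rest, fwd_idx)
    ad_idx <- rest[seq_len(n_fl)]
    rest <- setdiff(rest, ad_idx)
    det_idx <- rest[seq_len(n_fl)]

    rev_rows <- list()
    for (lib in libs) {
      sc <- per_lib[[as.character(lib)]]
      for (s in seq_along(sc))
        rev_rows[[length(rev_rows) + 1L]] <- data.frame(
          seq_id = paste0("R", s), seq = seqs[rev_idx[s]],
          scaffold_id = sc[s], library = lib, stringsAsFactors = FALSE)
    }
    role <- rep("unassigned", length(seqs))
    role[rev_idx] <- "reverse"; role[fwd_idx] <- "forward"
    role[ad_idx] <- "adapter"; role[det_idx] <- "detector"
    list(
      reverse = do.call(rbind, rev_rows),
      forward = data.frame(seq_id = paste0("F", seq_len(n_fl)),
                           seq = seqs[fwd_idx], fluorophore = fluorophores,
                           stringsAsFactors = FALSE),
      adapter = data.frame(seq_id = paste0("A", seq_len(n_fl)),
                           seq = seqs[ad_idx], fluorophore = fluorophores,
                           stringsAsFactors = FALSE),
      detector = data.frame(seq_id = paste0("D", seq_len(n_fl)),
                            seq = seqs[det_idx], fluorophore = fluorophores,
                            stringsAsFactors = FALSE),
      pool = data.frame(seq = seqs, role = role, stringsAsFactors = FALSE))
  })
}

#' Assemble final oligos and amplification primers
#'
#' Every oligo is reverse(20) + genome homolog(39) + forward(20) = 79 nt.
#' The reverse amplification primer is the T7 33-mer followed by the
#' reverse complement of the oligo's reverse 20-mer (53 nt); the forward
#' amplification primer is adapter(20) + forward(20) = 40 nt; the detector
#' is the adapter's reverse complement carrying the fluorophore tag.
#' Probes with a composite colour alternate their oligos between the two
#' fluorophores' forward/adapter pairs.
#'
#' @param windows probe-window data.frame from [select_probe_windows()]
#'   (or [plan_probes()] plus explicit `oligo_rows`).
#' @param candidates candidate data.frame the windows index into.
#' @param roles role assignment from [assign_roles()].
#' @param colours colour-scheme data.frame from [assign_colour_schemes()]
#'   (scaffold_id, probe_index, fluorophores).
#' @param t7 T7 promoter sequence prepended to reverse primers.
#' @return list of data.frames: `oligos` (oligo_id, probe_id, scaffold_id,
#'   homolog, start, end, R_id, F_id, fluorophore, assembled, length 79),
#'   `primers` (reverse 53-mers and forward 40-mers) and `detectors`.
#' @export
assemble_oligos <- function(windows, candidates, roles, colours,
                            t7 = T7_33MER) {
  fwd_of <- stats::setNames(roles$forward$seq, roles$forward$fluorophore)
  fid_of <- stats::setNames(roles$forward$seq_id, roles$forward$fluorophore)
  ad_of <- stats::setNames(roles$adapter$seq, roles$adapter$fluorophore)
  out <- list()
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    rv <- roles$reverse[roles$reverse$scaffold_id == w$scaffold_id, ,
                        drop = FALSE]
    if (!nrow(rv)) stop("no reverse primer assigned to scaffold ",
                        w$scaffold_id, call. = FALSE)
    rv <- rv[1, ]
    cl <- colours[colours$scaffold_id == w$scaffold_id &
                    colours$probe_index == w$probe_index, , drop = FALSE]
    if (!nrow(cl)) stop("no colour assigned to probe ", w$probe_id,
                        call. = FALSE)
    fls <- strsplit(cl$fluorophores[1], "+", fixed = TRUE)[[1]]
    if (!all(fls %in% names(fwd_of)))
      stop("missing forward/adapter role for fluorophore ",
           paste(setdiff(fls, names(fwd_of)), collapse = ","),
           call. = FALSE)
    rows <- w$oligo_rows[[1]]
    cand <- candidates[rows, , drop = FALSE]
    fl_each <- fls[(seq_along(rows) - 1) %% length(fls) + 1]
    out[[length(out) + 1L]] <- data.frame(
      oligo_id = paste0(w$probe_id, "_", seq_along(rows)),
      probe_id = w$probe_id, scaffold_id = w$scaffold_id,
      homolog = cand$sequence, start = cand$start, end = cand$end,
      R_id = rv$seq_id, F_id = unname(fid_of[fl_each]),
      fluorophore = fl_each,
      assembled = paste0(rv$seq, cand$sequence, fwd_of[fl_each]),
      stringsAsFactors = FALSE)
  }
  oligos <- do.call(rbind, out)

  rev_tab <- unique(roles$reverse[, c("seq_id", "seq")])
  primers <- rbind(
    data.frame(primer_id = paste0(rev_tab$seq_id, "_T7"),
               type = "reverse_amplification",
               seq = paste0(t7, revcomp(rev_tab$seq)),
               stringsAsFactors = FALSE),
    data.frame(primer_id = paste0(roles$forward$seq_id, "_amp"),
               type = "forward_amplification",
               seq = paste0(ad_of[roles$forward$fluorophore],
                            roles$forward$seq),
               stringsAsFactors = FALSE))
  detectors <- data.frame(
    detector_id = roles$detector$seq_id,
    fluorophore = roles$detector$fluorophore,
    seq = revcomp(ad_of[roles$detector$fluorophore]),
    stringsAsFactors = FALSE)
  list(oligos = oligos, primers = primers, detectors = detectors)
}
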