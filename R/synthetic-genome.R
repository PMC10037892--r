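# Synthetic toy genomes and scaffold sets with known truth, used to
# exercise every downstream stage (mining, probe design, curation) without
# external data. All generators are deterministic given (parameters, seed).

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# centromere offset by morphology: acrocentric within the first 5% of the
# chromosome, submetacentric off-centre, metacentric central
.place_centromere <- function(len, morphology) {
  frac <- switch(morphology,
    acrocentric    = stats::runif(1, 0.01, 0.05),
    submetacentric = stats::runif(1, 0.25, 0.35),
    metacentric    = stats::runif(1, 0.45, 0.50),
    stop("unknown morphology: ", morphology, call. = FALSE))
  as.integer(floor(frac * len))
}

#' Generate a toy multi-chromosome genome
#'
#' Builds random chromosome sequences with a per-chromosome morphology
#' (which fixes the centromere position: acrocentric centromeres sit within
#' the first 5 percent of the chromosome) and plants exact internal repeat
#' duplications until roughly `repeat_fraction` of the bases lie inside
#' recorded repeat tracts.
#'
#' @param n_chromosomes number of chromosomes (>= 1).
#' @param length_range integer vector of length 2, chromosome length range
#'   in bases (each >= 10 kb).
#' @param repeat_fraction target fraction of bases inside repeat tracts,
#'   in `[0, 1)`.
#' @param morphology_plan character vector of per-chromosome morphologies
#'   (recycled), each of "acrocentric", "submetacentric" or "metacentric".
#'   Names, if present, become chromosome ids.
#' @param seed integer RNG seed; the whole genome is reproducible from it.
#' @param repeat_unit length range of one planted repeat copy, in bases.
#' @return an object of class `toy_genome`: a list with `chromosomes`
#'   (data.frame id/length/morphology/centromere_position), `seqs` (named
#'   character vector), `repeats` (data.frame chromosome/start/end/family,
#'   0-based half-open) and the generation parameters.
#' @export
generate_toy_genome <- function(n_chromosomes, length_range = c(2e4, 5e4),
                                repeat_fraction = 0,
                                morphology_plan = "acrocentric",
                                seed = 1,
                                repeat_unit = c(300, 800)) {
  if (n_chromosomes < 1) stop("n_chromosomes must be >= 1", call. = FALSE)
  if (repeat_fraction < 0 || repeat_fraction >= 1)
    stop("repeat_fraction must be in [0, 1)", call. = FALSE)
  if (any(length_range < 1e4))
    stop("chromosome lengths must be >= 10 kb", call. = FALSE)
  morph <- rep_len(morphology_plan, n_chromosomes)
  ids <- if (!is.null(names(morphology_plan)) &&
             length(morphology_plan) == n_chromosomes) {
    names(morphology_plan)
  } else paste0("chr", seq_len(n_chromosomes))

  withr::with_seed(seed, {
    lens <- as.integer(round(stats::runif(n_chromosomes,
                                          length_range[1], length_range[2])))
    cen <- mapply(.place_centromere, lens, morph)
    seqs <- vapply(lens, .rand_dna, character(1))
    names(seqs) <- ids

    reps <- list()
    if (repeat_fraction > 0) {
      total <- sum(lens)
      covered <- integer(n_chromosomes)  # repeat bases per chromosome
      fam <- 0
      while (sum(covered) / total < repeat_fraction) {
        ci <- sample.int(n_chromosomes, 1)
        L <- lens[ci]
        u <- as.integer(round(stats::runif(1, repeat_unit[1], repeat_unit[2])))
        if (2L * u >= L) next
        src <- sample.int(L - u, 1) - 1L          # 0-based
        dst <- sample.int(L - u, 1) - 1L
        if (abs(dst - src) < u) next               # keep copies disjoint
        s <- seqs[[ci]]
        unit <- substr(s, src + 1L, src + u)
        substr(s, dst + 1L, dst + u) <- unit
        seqs[[ci]] <- s
        fam <- fam + 1
        reps[[length(reps) + 1L]] <- data.frame(
          chromosome = ids[ci],
          start = c(src, dst), end = c(src + u, dst + u),
          family = paste0("rep", fam), stringsAsFactors = FALSE)
        covered[ci] <- covered[ci] + 2L * u
      }
    }
    repeats <- if (length(reps)) do.call(rbind, reps) else
      data.frame(chromosome = character(), start = integer(),
                 end = integer(), family = character(),
                 stringsAsFactors = FALSE)

    structure(list(
      chromosomes = data.frame(id = ids, length = lens, morphology = morph,
                               centromere_position = as.integer(cen),
                               stringsAsFactors = FALSE),
      seqs = seqs,
      repeats = repeats,
      repeat_fraction = repeat_fraction,
      seed = seed), class = "toy_genome")
  })
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("toy_genome:", nrow(x$chromosomes), "chromosomes,",
      sum(x$chromosomes$length), "bp,",
      nrow(x$repeats), "repeat tract records\n")
  invisible(x)
}

# pull genome bases for one truth part, applying strand
.part_bases <- function(genome, chromosome, start, end, strand) {
  s <- substr(genome$seqs[[chromosome]], start + 1L, end)
  if (strand == "-") revcomp(s) else s
}

.build_scaffold_seq <- function(genome, parts) {
  paste(mapply(.part_bases, parts$chromosome, parts$start, parts$end,
               parts$strand, MoreArgs = list(genome = genome)),
        collapse = "")
}

#' Fragment a toy genome into scaffolds with planted mis-assemblies
#'
#' Cuts contiguous slices of the toy genome into scaffolds. Each entry of
#' `chimera_spec` produces one two-part scaffold joining material from two
#' different chromosomes, with the junction offset recorded. Entries of
#' `inversion_spec` reverse-complement a scaffold-local interval, recorded
#' in the truth as a minus-strand part. An explicit `layout` data.frame of
#' parts (scaffold_id, chromosome, start, end, strand) bypasses the random
#' placement entirely and builds exactly the scaffolds described.
#'
#' @param genome a `toy_genome`.
#' @param n_scaffolds number of scaffolds to emit (ignored when `layout`
#'   is supplied).
#' @param chimera_spec list of 2-element character vectors
#'   `c(chromA, chromB)`.
#' @param inversion_spec list of `list(scaffold_id=, start=, end=)`
#'   scaffold-local 0-based half-open intervals to invert.
#' @param seed integer RNG seed.
#' @param layout optional explicit part table (see above); parts of one
#'   scaffold are concatenated in row order.
#' @return a `scaffold_set`: list with `seqs` (named character vector) and
#'   `truth`, a data.frame with one row per part: scaffold_id, part_index,
#'   chromosome, start, end (0-based half-open genome coordinates), strand,
#'   scaffold_start, scaffold_end, is_chimeric, junction (scaffold offset of
#'   the join following this part, NA on last parts).
#' @export
fragment_into_scaffolds <- function(genome, n_scaffolds = NULL,
                                    chimera_spec = list(),
                                    inversion_spec = list(),
                                    seed = 1, layout = NULL) {
  stopifnot(inherits(genome, "toy_genome"))
  chroms <- genome$chromosomes
  known <- chroms$id

  if (is.null(layout)) {
    for (cs in chimera_spec)
      if (!all(cs %in% known))
        stop("chimera_spec references unknown chromosome: ",
             paste(setdiff(cs, known), collapse = ","), call. = FALSE)
    n_chim <- length(chimera_spec)
    if (is.null(n_scaffolds)) stop("n_scaffolds required without layout",
                                   call. = FALSE)
    if (n_scaffolds < n_chim)
      stop("n_scaffolds smaller than number of requested chimeras",
           call. = FALSE)
    layout <- withr::with_seed(seed, {
      rows <- list()
      # one random slice of a chromosome, roughly half its length
      slice <- function(chrom) {
        L <- chroms$length[chroms$id == chrom]
        w <- as.integer(round(stats::runif(1, 0.25, 0.45) * L))
        st <- sample.int(L - w, 1) - 1L
        c(st, st + w)
      }
      sid <- 0
      for (cs in chimera_spec) {
        sid <- sid + 1
        a <- slice(cs[1]); b <- slice(cs[2])
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold_id = paste0("s", sid),
          chromosome = cs, start = c(a[1], b[1]), end = c(a[2], b[2]),
          strand = "+", stringsAsFactors = FALSE)
      }
      pool <- rep_len(known, n_scaffolds)  # round-robin source chromosomes
      while (sid < n_scaffolds) {
        sid <- sid + 1
        a <- slice(pool[sid])
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold_id = paste0("s", sid),
          chromosome = pool[sid], start = a[1], end = a[2],
          strand = "+", stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    })
  }
  if (!all(layout$chromosome %in% known))
    stop("layout references unknown chromosome: ",
         paste(setdiff(layout$chromosome, known), collapse = ","),
         call. = FALSE)
  if (is.null(layout$strand)) layout$strand <- "+"

  # apply inversions: split the covering part into up to three truth parts
  for (inv in inversion_spec) {
    idx <- which(layout$scaffold_id == inv$scaffold_id)
    if (!length(idx)) stop("inversion on unknown scaffold ", inv$scaffold_id,
                           call. = FALSE)
    sub <- layout[idx, , drop = FALSE]
    off <- cumsum(c(0L, sub$end - sub$start))
    hit <- which(inv$start >= off[-length(off)] & inv$end <= off[-1])
    if (length(hit) != 1)
      stop("inversion interval must fall inside a single part", call. = FALSE)
    p <- sub[hit, ]
    ls <- inv$start - off[hit]; le <- inv$end - off[hit]  # part-local
    pieces <- list()
    if (ls > 0) pieces[[1]] <- within(p, end <- start + ls)
    mid <- p
    mid$start <- p$start + ls; mid$end <- p$start + le
    mid$strand <- if (p$strand == "+") "-" else "+"
    pieces[[length(pieces) + 1L]] <- mid
    if (p$start + le < p$end) {
      tail_p <- p; tail_p$start <- p$start + le
      pieces[[length(pieces) + 1L]] <- tail_p
    }
    sub <- rbind(sub[seq_len(hit - 1), , drop = FALSE],
                 do.call(rbind, pieces),
                 sub[-seq_len(hit), , drop = FALSE])
    layout <- rbind(layout[layout$scaffold_id != inv$scaffold_id, ], sub)
  }

  sids <- unique(layout$scaffold_id)
  seqs <- character(0)
  truth <- list()
  for (sid in sids) {
    parts <- layout[layout$scaffold_id == sid, , drop = FALSE]
    seqs[[sid]] <- .build_scaffold_seq(genome, parts)
    plens <- parts$end - parts$start
    sc_end <- cumsum(plens)
    sc_start <- sc_end - plens
    chim <- length(unique(parts$chromosome)) >= 2
    junction <- ifelse(seq_len(nrow(parts)) < nrow(parts), sc_end, NA_integer_)
    truth[[sid]] <- data.frame(
      scaffold_id = sid, part_index = seq_len(nrow(parts)) - 1L,
      chromosome = parts$chromosome, start = parts$start, end = parts$end,
      strand = parts$strand,
      scaffold_start = sc_start, scaffold_end = sc_end,
      is_chimeric = chim, junction = junction,
      stringsAsFactors = FALSE)
  }
  structure(list(seqs = seqs, truth = do.call(rbind, truth),
                 seed = seed), class = "scaffold_set")
}

#' @export
print.scaffold_set <- function(x, ...) {
  cat("scaffold_set:", length(x$seqs), "scaffolds,",
      sum(nchar(x$seqs)), "bp,",
      sum(tapply(x$truth$is_chimeric, x$truth$scaffold_id, any)),
      "chimeric\n")
  invisible(x)
}

#' Reassemble scaffold sequences from a truth table
#'
#' Concatenates the genome bases of each scaffold's truth parts (applying
#' strand) — the round-trip check that fragmentation loses nothing.
#'
#' @param genome a `toy_genome`.
#' @param truth a truth part table as produced by
#'   [fragment_into_scaffolds()].
#' @return named character vector of reconstructed scaffold sequences.
#' @export
reassemble_from_truth <- function(genome, truth) {
  sids <- unique(truth$scaffold_id)
  out <- vapply(sids, function(sid) {
    parts <- truth[truth$scaffold_id == sid, , drop = FALSE]
    parts <- parts[order(parts$part_index), , drop = FALSE]
    .build_scaffold_seq(genome, parts)
  }, character(1))
  names(out) <- sids
  out
}

#' Generate a pool of distinct orthogonal 25-mers
#'
#' Stand-in for a published orthogonal-sequence library: random distinct
#' uppercase k-mers with GC content between 20 and 80 percent.
#'
#' @param n number of sequences (>= 1).
#' @param length sequence length in nt (default 25).
#' @param seed integer RNG seed.
#' @return character vector of `n` distinct sequences.
#' @export
generate_ortho_pool <- function(n, length = 25, seed = 1) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (n > 0.5 * 4^length)
    stop("requested pool exceeds the distinct-sequence capacity",
         call. = FALSE)
  withr::with_seed(seed, {
    pool <- character(0)
    while (length(pool) < n) {
      rows <- min(3e5, ceiling(1.3 * (n - length(pool))) + 100)
      m <- matrix(sample(c("A", "C", "G", "T"), rows * length,
                         replace = TRUE), ncol = length)
      cand <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
      gc <- gc_fraction(cand)
      cand <- cand[gc >= 0.2 & gc <= 0.8]
      pool <- unique(c(pool, cand))
    }
    pool[seq_len(n)]
  })
}
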