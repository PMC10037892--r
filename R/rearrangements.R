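# Parsimony classification of chromosome rearrangements over signed block
# arrangements: bounded exhaustive search over {fission, fusion,
# translocation, inversion} event sequences. Chromosomes are
# flip-invariant (a chromosome read backwards with signs flipped is the
# same chromosome), so states are compared in canonical form.

.chrom_key <- function(v) {
  a <- paste(v, collapse = ",")
  b <- paste(-rev(v), collapse = ",")
  if (a <= b) a else b
}

.state_key <- function(state) {
  paste(sort(vapply(state, .chrom_key, character(1))), collapse = ";")
}

.fmt_chrom <- function(v) paste0("(", paste(v, collapse = " "), ")")

# all one-event neighbours of a state; each is list(state, kind, detail)
.moves <- function(state) {
  out <- list()
  add <- function(st, kind, detail, pericentric = NA) {
    st <- st[lengths(st) > 0]
    out[[length(out) + 1L]] <<- list(state = st, kind = kind,
                                     detail = detail,
                                     pericentric = pericentric)
  }
  nc <- length(state)
  for (ci in seq_len(nc)) {
    v <- state[[ci]]
    k <- length(v)
    # inversions of every proper segment; a segment touching the first
    # block spans the (proximally drawn) centromere -> pericentric
    for (i in seq_len(k)) for (j in i:k) {
      if (i == 1 && j == k) next  # whole-chromosome flip is a no-op
      w <- v
      w[i:j] <- -rev(v[i:j])
      st <- state; st[[ci]] <- w
      add(st, "inversion",
          paste0("invert ", .fmt_chrom(v[i:j]), " within ", .fmt_chrom(v)),
          pericentric = (i == 1))
    }
    # fissions at every internal boundary
    if (k > 1) for (i in seq_len(k - 1)) {
      st <- state
      st[[ci]] <- v[seq_len(i)]
      st[[length(st) + 1L]] <- v[(i + 1):k]
      add(st, "fission", paste0(.fmt_chrom(v), " -> ",
                                .fmt_chrom(v[seq_len(i)]), " + ",
                                .fmt_chrom(v[(i + 1):k])))
    }
    # translocations: move a proper segment elsewhere (same or other
    # chromosome), orientation preserved
    for (i in seq_len(k)) for (j in i:k) {
      if (i == 1 && j == k) next
      seg <- v[i:j]
      rem <- v[-(i:j)]
      for (di in seq_len(nc)) {
        tgt <- if (di == ci) rem else state[[di]]
        for (p in 0:length(tgt)) {
          if (di == ci && p == i - 1) next  # same place: no-op
          w <- append(tgt, seg, after = p)
          st <- state
          if (di == ci) st[[ci]] <- w
          else { st[[ci]] <- rem; st[[di]] <- w }
          add(st, "translocation",
              paste0("move ", .fmt_chrom(seg), " into ", .fmt_chrom(tgt),
                     " after position ", p))
        }
      }
    }
  }
  # fusions of every chromosome pair, all relative orientations
  if (nc > 1) for (ci in seq_len(nc - 1)) for (di in (ci + 1):nc) {
    a <- state[[ci]]; b <- state[[di]]
    for (fa in list(a, -rev(a))) for (fb in list(b, -rev(b))) {
      st <- state[-c(ci, di)]
      st[[length(st) + 1L]] <- c(fa, fb)
      add(st, "fusion", paste0(.fmt_chrom(fa), " + ", .fmt_chrom(fb)))
    }
  }
  out
}

# unique neighbour states (keys) of a set of state objects
.frontier_expand <- function(states) {
  res <- list()
  for (st in states) for (mv in .moves(st))
    res[[.state_key(mv$state)]] <- mv$state
  res
}

#' Classify rearrangements between two signed block arrangements
#'
#' Finds every minimum-length sequence of events from
#' {fission, fusion, translocation, inversion} transforming the reference
#' arrangement into the query arrangement, by bounded exhaustive search.
#' Chromosomes are compared flip-invariantly. When several minimal
#' scenarios differ in event order, the chronology is reported as
#' undetermined. Inversions whose segment reaches the proximal
#' (centromere-bearing, drawn first) end of their chromosome are flagged
#' pericentric.
#'
#' @param reference,query states: lists of signed integer block vectors
#'   (from [rearrangement_states()] or built directly).
#' @param max_events search bound on the number of events.
#' @param max_blocks refuse larger instances (raise `min_block` upstream
#'   to reduce the block count).
#' @return a `rearrangement_result` list: `n_events`, `scenarios` (each a
#'   data.frame kind/detail/pericentric), `event_kinds` (sorted kind
#'   multiset of one minimal scenario) and `chronology_determined`.
#' @export
classify_rearrangements <- function(reference, query, max_events = 4,
                                    max_blocks = 10) {
  nb <- sum(lengths(reference))
  if (nb > max_blocks)
    stop(nb, " blocks exceed the exhaustive-search limit (", max_blocks,
         "); raise min_block when chaining to get fewer, larger blocks",
         call. = FALSE)
  if (sum(lengths(query)) != nb ||
      !setequal(unlist(lapply(reference, abs)), unlist(lapply(query, abs))))
    stop("reference and query must contain the same blocks", call. = FALSE)
  target <- .state_key(query)
  if (.state_key(reference) == target)
    return(structure(list(n_events = 0, scenarios = list(),
                          event_kinds = character(0),
                          chronology_determined = TRUE),
                     class = "rearrangement_result"))
  # breadth-first over canonical states to get the minimal event count
  dist <- new.env(parent = emptyenv())
  assign(.state_key(reference), 0L, envir = dist)
  frontier <- stats::setNames(list(reference), .state_key(reference))
  depth <- 0L
  found <- FALSE
  while (depth < max_events && !found) {
    depth <- depth + 1L
    nxt <- list()
    for (st in frontier) for (mv in .moves(st)) {
      k <- .state_key(mv$state)
      if (!is.null(dist[[k]])) next
      dist[[k]] <- depth
      nxt[[k]] <- mv$state
      if (k == target) found <- TRUE
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  if (!found)
    stop("no scenario with at most ", max_events, " events found",
         call. = FALSE)
  n_events <- depth
  # distance-to-target map guides exhaustive path enumeration
  back <- new.env(parent = emptyenv())
  assign(target, 0L, envir = back)
  bf <- stats::setNames(list(query), target)
  for (d in seq_len(n_events)) {
    nxt <- list()
    for (st in bf) for (mv in .moves(st)) {
      k <- .state_key(mv$state)
      if (is.null(back[[k]])) { back[[k]] <- d; nxt[[k]] <- mv$state }
    }
    bf <- nxt
    if (!length(bf)) break
  }
  scenarios <- list()
  dfs <- function(state, path) {
    rem <- n_events - length(path)
    if (rem == 0) {
      if (.state_key(state) == target)
        scenarios[[length(scenarios) + 1L]] <<- do.call(rbind, path)
      return(invisible())
    }
    for (mv in .moves(state)) {
      bd <- back[[.state_key(mv$state)]]
      if (is.null(bd) || bd > rem - 1) next
      dfs(mv$state,
          c(path, list(data.frame(kind = mv$kind, detail = mv$detail,
                                  pericentric = mv$pericentric,
                                  stringsAsFactors = FALSE))))
    }
  }
  dfs(reference, list())
  orders <- unique(vapply(scenarios, function(s)
    paste(s$kind, collapse = ">"), character(1)))
  structure(list(
    n_events = n_events,
    scenarios = scenarios,
    event_kinds = sort(scenarios[[1]]$kind),
    event_orders = orders,
    chronology_determined = length(orders) == 1),
    class = "rearrangement_result")
}

#' @export
print.rearrangement_result <- function(x, ...) {
  cat("rearrangement_result:", x$n_events, "event(s);",
      length(x$scenarios), "minimal scenario(s);",
      if (x$chronology_determined) "chronology determined"
      else "chronology undetermined", "\n")
  if (length(x$event_kinds))
    cat(" kinds:", paste(x$event_kinds, collapse = ", "), "\n")
  invisible(x)
}
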