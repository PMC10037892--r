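# Independent oracles used by the tests: hand-written nearest-neighbor
# summation, brute-force window/k-mer/alignment/duplex searches and a
# plain breadth-first rearrangement distance. They share no code with the
# package implementations they check.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

rc <- function(s) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(s)))

# --- nearest-neighbor Tm oracle: table typed as a data.frame, summed by
# explicit loop over dinucleotides -------------------------------------
oracle_nn <- data.frame(
  di = c("AA", "AT", "TA", "CA", "GT", "CT", "GA", "CG", "GC", "GG"),
  dh = c(-7.9, -7.2, -7.2, -8.5, -8.4, -7.8, -8.2, -10.6, -9.8, -8.0),
  ds = c(-22.2, -20.4, -21.3, -22.7, -22.4, -21.0, -22.2, -27.2, -24.4,
         -19.9),
  stringsAsFactors = FALSE)

oracle_nn_lookup <- function(di) {
  i <- match(di, oracle_nn$di)
  if (is.na(i)) i <- match(rc(di), oracle_nn$di)
  c(oracle_nn$dh[i], oracle_nn$ds[i])
}

oracle_tm <- function(seq, na = 0.39, formamide_pct = 0, conc = 5e-8) {
  dh <- 0; ds <- 0
  for (i in 1:(nchar(seq) - 1)) {
    v <- oracle_nn_lookup(substr(seq, i, i + 1))
    dh <- dh + v[1]; ds <- ds + v[2]
  }
  for (b in c(substr(seq, 1, 1), substr(seq, nchar(seq), nchar(seq)))) {
    if (b %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (nchar(seq) - 1) * log(na)
  dh * 1000 / (ds + 1.9872 * log(conc / 4)) - 273.15 - 0.72 * formamide_pct
}

# stack free energy of a fully paired run at temperature (degC)
oracle_stack_dg <- function(seq, temp) {
  g <- 0
  for (i in 1:(nchar(seq) - 1)) {
    v <- oracle_nn_lookup(substr(seq, i, i + 1))
    g <- g + v[1] - (temp + 273.15) * v[2] / 1000
  }
  g
}

# hairpin-loop initiation dG values shared with the model (anchors of the
# published loop table), interpolated and entropically rescaled
oracle_loop_dg <- function(size, temp) {
  anchors_n <- c(3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 25, 30)
  anchors_g <- c(3.5, 3.5, 3.3, 4.0, 4.2, 4.3, 4.5, 4.4, 4.7, 5.0, 5.2,
                 5.4, 5.5, 5.8, 6.0)
  g37 <- if (size <= 30) approx(anchors_n, anchors_g, xout = size)$y
  else 6.0 + 1.75 * 1.9872 * 310.15 * log(size / 30) / 1000
  g37 * (temp + 273.15) / 310.15
}

# exhaustive hairpin search over (arm start, stem length, loop length)
oracle_hairpin <- function(seq, temp = 42, min_stem = 3) {
  n <- nchar(seq)
  best <- 0
  for (a in 1:n) for (s in min_stem:floor((n - 3) / 2)) {
    if (a + s - 1 > n) next
    max_loop <- n - a + 1 - 2 * s
    if (max_loop < 3) next
    for (loop in 3:max_loop) {
      b <- a + s + loop          # 3' arm start
      if (b + s - 1 > n) next
      arm5 <- substr(seq, a, a + s - 1)
      arm3 <- substr(seq, b, b + s - 1)
      if (arm3 != rc(arm5)) next
      g <- oracle_stack_dg(arm5, temp) + oracle_loop_dg(loop, temp)
      if (g < best) best <- g
    }
  }
  best
}

# duplex dG oracle: every antiparallel offset, runs found by position loop
oracle_duplex <- function(s1, s2, temp = 37) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  a <- strsplit(s1, "")[[1]]
  b2 <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b2)
  best <- 0
  for (off in -(m + n):(m + n)) {
    run <- ""
    for (i in 1:n) {
      j <- m - (i + off) + 1       # antiparallel partner index in s2
      pair <- !is.na(j) && j >= 1 && j <= m && b2[j] == comp[[a[i]]]
      if (pair) run <- paste0(run, a[i])
      else {
        if (nchar(run) >= 2) {
          ends <- strsplit(run, "")[[1]][c(1, nchar(run))]
          init <- sum(ifelse(ends %in% c("G", "C"), 0.1, 2.3)) -
            (temp + 273.15) *
            sum(ifelse(ends %in% c("G", "C"), -2.8, 4.1)) / 1000
          g <- oracle_stack_dg(run, temp) + init
          if (g < best) best <- g
        }
        run <- ""
      }
    }
    if (nchar(run) >= 2) {
      ends <- strsplit(run, "")[[1]][c(1, nchar(run))]
      init <- sum(ifelse(ends %in% c("G", "C"), 0.1, 2.3)) -
        (temp + 273.15) * sum(ifelse(ends %in% c("G", "C"), -2.8, 4.1)) / 1000
      g <- oracle_stack_dg(run, temp) + init
      if (g < best) best <- g
    }
  }
  best
}

# ungapped Smith-Waterman by full DP matrix + longest exact run
oracle_local_align <- function(q, s, match = 1, mismatch = -2) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  H <- matrix(0, n + 1, m + 1)
  R <- matrix(0, n + 1, m + 1)
  for (i in 1:n) for (j in 1:m) {
    sc_ij <- if (qc[i] == sc[j]) match else mismatch
    H[i + 1, j + 1] <- max(0, H[i, j] + sc_ij)
    R[i + 1, j + 1] <- if (qc[i] == sc[j]) R[i, j] + 1 else 0
  }
  c(score = max(H), run = max(R))
}

oracle_evalue <- function(q, genome_seqs, word_size = 6, K = 0.333) {
  lambda <- log((3 + sqrt(21)) / 2)
  subs <- c(genome_seqs, vapply(genome_seqs, rc, character(1)))
  best <- -Inf; seeded <- FALSE
  for (s in subs) {
    r <- oracle_local_align(q, s)
    if (r["run"] >= word_size) {
      seeded <- TRUE
      best <- max(best, r["score"])
    }
  }
  if (!seeded) return(Inf)
  K * nchar(q) * (2 * sum(nchar(genome_seqs))) * exp(-lambda * best)
}

# brute-force minimal rearrangement distance by plain BFS over raw states
oracle_rearrangement_distance <- function(ref, qry, max_d = 4) {
  keyc <- function(v) min(paste(v, collapse = ","),
                          paste(-rev(v), collapse = ","))
  key <- function(st) paste(sort(vapply(st, keyc, character(1))),
                            collapse = ";")
  neighbours <- function(st) {
    res <- list()
    nc <- length(st)
    for (ci in seq_len(nc)) {
      v <- st[[ci]]; k <- length(v)
      for (i in seq_len(k)) for (j in i:k) {
        if (i == 1 && j == k) next
        w <- v; w[i:j] <- -rev(v[i:j])
        s2 <- st; s2[[ci]] <- w; res[[length(res) + 1]] <- s2
      }
      if (k > 1) for (i in 1:(k - 1)) {
        s2 <- st; s2[[ci]] <- v[1:i]; s2[[nc + 1]] <- v[(i + 1):k]
        res[[length(res) + 1]] <- s2
      }
      for (i in seq_len(k)) for (j in i:k) {
        if (i == 1 && j == k) next
        seg <- v[i:j]; rem <- v[-(i:j)]
        for (di in seq_len(nc)) {
          tgt <- if (di == ci) rem else st[[di]]
          for (p in 0:length(tgt)) {
            if (di == ci && p == i - 1) next
            s2 <- st
            if (di == ci) s2[[ci]] <- append(rem, seg, after = p)
            else { s2[[ci]] <- rem; s2[[di]] <- append(tgt, seg, after = p) }
            s2 <- s2[lengths(s2) > 0]
            res[[length(res) + 1]] <- s2
          }
        }
      }
    }
    if (nc > 1) for (ci in 1:(nc - 1)) for (di in (ci + 1):nc) {
      for (fa in list(st[[ci]], -rev(st[[ci]])))
        for (fb in list(st[[di]], -rev(st[[di]]))) {
          s2 <- st[-c(ci, di)]; s2[[length(s2) + 1]] <- c(fa, fb)
          res[[length(res) + 1]] <- s2
        }
    }
    res
  }
  target <- key(qry)
  if (key(ref) == target) return(0)
  seen <- new.env(parent = emptyenv())
  assign(key(ref), TRUE, envir = seen)
  frontier <- list(ref)
  for (d in 1:max_d) {
    nxt <- list()
    for (st in frontier) for (nb in neighbours(st)) {
      k <- key(nb)
      if (!is.null(seen[[k]])) next
      if (k == target) return(d)
      seen[[k]] <- TRUE
      nxt[[k]] <- nb
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  Inf
}

# a small genome/scaffold/observation fixture used by several files
make_pipeline_fixture <- function(seed = 1, n_chrom = 6, n_scaffolds = 10,
                                  chimera_spec = list(c("chr2", "chr5"),
                                                      c("chr3", "chr6"))) {
  g <- generate_toy_genome(n_chrom, c(2.5e4, 4e4), seed = seed)
  sc <- fragment_into_scaffolds(g, n_scaffolds = n_scaffolds,
                                chimera_spec = chimera_spec, seed = seed + 1)
  # plant one inversion spanning the first two of three probes on a
  # non-chimeric scaffold
  inv_sid <- paste0("s", length(chimera_spec) + 1)
  L <- max(sc$truth$scaffold_end[sc$truth$scaffold_id == inv_sid])
  sc <- fragment_into_scaffolds(g, n_scaffolds = n_scaffolds,
                                chimera_spec = chimera_spec,
                                inversion_spec = list(list(
                                  scaffold_id = inv_sid,
                                  start = round(0.05 * L),
                                  end = round(0.68 * L))),
                                seed = seed + 1)
  plan <- plan_probes(sc, n_probes = 3, span = 600)
  list(genome = g, scaffolds = sc, plan = plan, inverted = inv_sid,
       chimeric = paste0("s", seq_along(chimera_spec)))
}
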