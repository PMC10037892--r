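test_that("toy genome generation honours its contract", {
  # degenerate case: one chromosome, no repeats
  g1 <- generate_toy_genome(1, c(1e4, 1.2e4), repeat_fraction = 0, seed = 1)
  expect_equal(nrow(g1$chromosomes), 1)
  expect_equal(nrow(g1$repeats), 0)
  expect_false(grepl("[^ACGT]", g1$seqs[[1]]))
  # planted repeat tracts cover the requested base fraction
  g <- generate_toy_genome(5, c(2e4, 4e4), repeat_fraction = 0.1, seed = 7)
  cov <- sum(vapply(split(g$repeats, g$repeats$chromosome), function(r) {
    m <- logical(max(r$end))
    for (i in seq_len(nrow(r))) m[(r$start[i] + 1):r$end[i]] <- TRUE
    sum(m)
  }, numeric(1)))
  expect_equal(cov / sum(g$chromosomes$length), 0.10, tolerance = 0.02)
  # determinism: same seed, byte-identical sequences
  g2 <- generate_toy_genome(5, c(2e4, 4e4), repeat_fraction = 0.1, seed = 7)
  expect_identical(g$seqs, g2$seqs)
  # morphology plan honoured, acrocentric centromere in the first 5%
  gm <- generate_toy_genome(3, c(1e4, 2e4),
                            morphology_plan = c("acrocentric",
                                                "submetacentric",
                                                "metacentric"), seed = 2)
  expect_equal(gm$chromosomes$morphology,
               c("acrocentric", "submetacentric", "metacentric"))
  acro <- gm$chromosomes[1, ]
  expect_lt(acro$centromere_position / acro$length, 0.05)
  expect_error(generate_toy_genome(2, c(1e4, 2e4), repeat_fraction = 1),
               "repeat_fraction")
  expect_error(generate_toy_genome(2, c(5e3, 2e4)), "10 kb")
})

test_that("fragmentation plants exactly the requested mis-assemblies", {
  g <- generate_toy_genome(5, c(2e4, 3e4), seed = 3)
  # no chimeras: every scaffold is one contiguous part
  sc0 <- fragment_into_scaffolds(g, n_scaffolds = 5, seed = 1)
  expect_true(all(table(sc0$truth$scaffold_id) == 1))
  expect_false(any(sc0$truth$is_chimeric))
  # one chimera on (chr2, chr5): exactly one two-part scaffold, one junction
  sc1 <- fragment_into_scaffolds(g, n_scaffolds = 5,
                                 chimera_spec = list(c("chr2", "chr5")),
                                 seed = 1)
  chim <- sc1$truth[sc1$truth$is_chimeric, ]
  expect_equal(length(unique(chim$scaffold_id)), 1)
  expect_setequal(chim$chromosome, c("chr2", "chr5"))
  expect_equal(sum(!is.na(chim$junction)), 1)
  expect_error(
    fragment_into_scaffolds(g, 5, chimera_spec = list(c("chr2", "chrNO"))),
    "unknown chromosome")
})

test_that("planted inversions are exact reverse complements of the genome", {
  g <- generate_toy_genome(3, c(2e4, 3e4), seed = 5)
  inv <- list(scaffold_id = "s3", start = 1000, end = 3000)
  sc <- fragment_into_scaffolds(g, n_scaffolds = 3,
                                inversion_spec = list(inv), seed = 2)
  part <- sc$truth[sc$truth$scaffold_id == "s3" & sc$truth$strand == "-", ]
  expect_equal(nrow(part), 1)
  slice <- substr(sc$seqs[["s3"]], inv$start + 1, inv$end)
  genome_slice <- substr(g$seqs[[part$chromosome]], part$start + 1,
                         part$end)
  expect_identical(rc(slice), genome_slice)
})

test_that("truth parts reassemble every scaffold exactly (round trip)", {
  for (seed in c(2, 9, 31)) {
    g <- generate_toy_genome(4, c(2e4, 3e4), repeat_fraction = 0.05,
                             seed = seed)
    sc <- fragment_into_scaffolds(
      g, n_scaffolds = 6, chimera_spec = list(c("chr1", "chr3")),
      inversion_spec = list(list(scaffold_id = "s4", start = 500,
                                 end = 2500)), seed = seed)
    re <- reassemble_from_truth(g, sc$truth)
    expect_identical(re[names(sc$seqs)], sc$seqs)
    # parts tile each scaffold
    for (sid in names(sc$seqs)) {
      p <- sc$truth[sc$truth$scaffold_id == sid, ]
      expect_equal(sum(p$end - p$start), nchar(sc$seqs[[sid]]))
    }
  }
})

test_that("orthogonal pools are distinct, GC-bounded and reproducible", {
  p1 <- generate_ortho_pool(1, seed = 1)
  expect_equal(nchar(p1), 25)
  p <- generate_ortho_pool(1000, seed = 3)
  expect_equal(length(unique(p)), 1000)
  gc <- gc_fraction(p)
  expect_true(all(gc >= 0.2 & gc <= 0.8))
  expect_identical(p, generate_ortho_pool(1000, seed = 3))
  expect_error(generate_ortho_pool(0), ">= 1")
  expect_error(generate_ortho_pool(10, length = 1), "capacity")
})

test_that("zero-noise hybridization reflects the truth exactly", {
  fx <- make_pipeline_fixture(seed = 4)
  obs <- simulate_hybridization(fx$plan, fx$scaffolds, fx$genome,
                                n_spreads = 3, dropout_rate = 0, seed = 1)
  # every probe observed once per spread
  expect_equal(nrow(obs), 3 * nrow(fx$plan))
  # non-chimeric scaffolds: one chromosome label per scaffold
  for (sid in setdiff(unique(fx$plan$scaffold_id), fx$chimeric)) {
    expect_equal(length(unique(obs$chromosome_label[obs$scaffold_id ==
                                                      sid])), 1)
  }
  # chimeric scaffolds light up exactly two chromosomes, split at the
  # junction-flanking probes
  truth <- fx$scaffolds$truth
  for (sid in fx$chimeric) {
    o <- obs[obs$scaffold_id == sid & obs$spread_id == "spread1", ]
    expect_equal(length(unique(o$chromosome_label)), 2)
    tp <- truth[truth$scaffold_id == sid, ]
    j <- tp$junction[!is.na(tp$junction)]
    p <- fx$plan[fx$plan$scaffold_id == sid, ]
    side_truth <- ifelse((p$start + p$end) / 2 < j, "L", "R")
    lab <- o$chromosome_label[match(p$probe_id, o$probe_id)]
    expect_equal(length(unique(paste(side_truth, lab))), 2)
  }
})

test_that("a planted inversion permutes observed signal order as the truth", {
  fx <- make_pipeline_fixture(seed = 8)
  obs <- simulate_hybridization(fx$plan, fx$scaffolds, fx$genome,
                                n_spreads = 1, seed = 1)
  o <- obs[obs$scaffold_id == fx$inverted, ]
  o <- o[order(fx$plan$probe_index[match(o$probe_id, fx$plan$probe_id)]), ]
  perm <- rank(o$order_index)
  # truth: the first two of three probes sit inside the inverted segment,
  # so their centromere-distance order swaps
  expect_equal(perm, c(2, 1, 3))
})

test_that("hybridization rejects probes outside their scaffold", {
  fx <- make_pipeline_fixture(seed = 4)
  bad <- fx$plan
  bad$end[1] <- 10^9
  expect_error(simulate_hybridization(bad, fx$scaffolds, fx$genome),
               "outside scaffold")
  expect_error(simulate_hybridization(fx$plan, fx$scaffolds, fx$genome,
                                      dropout_rate = 1), "dropout_rate")
})
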