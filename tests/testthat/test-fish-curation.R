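test_that("zero-noise assignment places every scaffold on one chromosome", {
  fx <- make_pipeline_fixture(seed = 14, chimera_spec = list())
  obs <- simulate_hybridization(fx$plan, fx$scaffolds, fx$genome,
                                n_spreads = 3, seed = 2)
  a <- assign_scaffolds(obs, fx$plan)
  expect_equal(nrow(a$scaffolds), length(fx$scaffolds$seqs))
  expect_true(all(a$scaffolds$n_chromosomes == 1))
  expect_false(any(a$probes$ambiguous | a$probes$unplaced))
  expect_error(assign_scaffolds(
    data.frame(spread_id = "s", probe_id = "ghost",
               chromosome_label = "chr1", order_index = 0), fx$plan),
    "not in plan")
})

test_that("assignment is robust to a dropout under majority voting", {
  fx <- make_pipeline_fixture(seed = 14)
  obs <- simulate_hybridization(fx$plan, fx$scaffolds, fx$genome,
                                n_spreads = 3, seed = 2)
  a0 <- assign_scaffolds(obs, fx$plan)
  # remove one observation of one probe (a single-spread dropout)
  drop_row <- which(obs$probe_id == fx$plan$probe_id[1] &
                      obs$spread_id == "spread2")[1]
  a1 <- assign_scaffolds(obs[-drop_row, ], fx$plan)
  expect_equal(a1$probes$chromosome, a0$probes$chromosome)
  expect_equal(a1$scaffolds, a0$scaffolds)
})

test_that("anomaly detection separates chimeric, reordered and clean", {
  fx <- make_pipeline_fixture(seed = 26)
  obs <- simulate_hybridization(fx$plan, fx$scaffolds, fx$genome,
                                n_spreads = 3, seed = 5)
  a <- assign_scaffolds(obs, fx$plan)
  an <- detect_anomalies(a, fx$plan)
  status <- setNames(an$status, an$scaffold_id)
  expect_true(all(status[fx$chimeric] == "chimeric"))
  expect_equal(unname(status[fx$inverted]), "reordered")
  others <- setdiff(names(status), c(fx$chimeric, fx$inverted))
  expect_true(all(status[others] == "clean"))
  # chimerism takes precedence: no scaffold is both
  expect_true(all(table(an$scaffold_id) == 1))
  # a fully reversed signal order is an orientation, not an anomaly
  plan1 <- data.frame(probe_id = paste0("zp", 0:2), scaffold_id = "z",
                      start = c(0, 1000, 2000), end = c(500, 1500, 2500),
                      probe_index = 0:2, stringsAsFactors = FALSE)
  obs_rev <- do.call(rbind, lapply(1:2, function(sp) data.frame(
    spread_id = paste0("spread", sp), probe_id = paste0("zp", 0:2),
    scaffold_id = "z", chromosome_label = "chrZ", order_index = 2:0,
    stringsAsFactors = FALSE)))
  az <- assign_scaffolds(obs_rev, plan1)
  expect_equal(detect_anomalies(az, plan1)$status, "clean")
})

test_that("breakpoints are synteny-narrowed and contain the true junction", {
  fx <- make_pipeline_fixture(seed = 33)
  obs <- simulate_hybridization(fx$plan, fx$scaffolds, fx$genome,
                                n_spreads = 3, seed = 6)
  a <- assign_scaffolds(obs, fx$plan)
  an <- detect_anomalies(a, fx$plan)
  paf <- simulate_reference_alignments(fx$scaffolds, fx$genome,
                                       chunk = 1200)
  bp <- locate_breakpoints(an, fx$plan, paf)
  truth <- fx$scaffolds$truth
  for (i in seq_len(nrow(bp))) {
    tj <- truth$junction[truth$scaffold_id == bp$scaffold_id[i] &
                           !is.na(truth$junction)]
    expect_lte(bp$left_bound[i], tj)
    expect_gte(bp$right_bound[i], tj)
    gap_l <- fx$plan$end[fx$plan$probe_id == bp$left_probe[i]]
    gap_r <- fx$plan$start[fx$plan$probe_id == bp$right_probe[i]]
    expect_equal(bp$evidence[i], "synteny")
    expect_lt(bp$right_bound[i] - bp$left_bound[i], gap_r - gap_l)
  }
  # without alignments the whole inter-probe gap is the interval
  bp0 <- locate_breakpoints(an, fx$plan, paf = NULL)
  expect_true(all(bp0$evidence == "midpoint_fallback"))
  i <- 1
  expect_equal(bp0$left_bound[i],
               fx$plan$end[fx$plan$probe_id == bp0$left_probe[i]])
  expect_equal(bp0$right_bound[i],
               fx$plan$start[fx$plan$probe_id == bp0$right_probe[i]])
  # clean input violates the precondition
  clean <- an[an$status == "clean", , drop = FALSE]
  attr(clean, "splits") <- NULL
  expect_error(locate_breakpoints(clean, fx$plan), "chimera")
})

test_that("splitting conserves bases and recovers planted orientations", {
  fx <- make_pipeline_fixture(seed = 42)
  # plant reverse-oriented scaffolds: flip two whole non-chimeric scaffolds
  truth <- fx$scaffolds$truth
  layout <- truth[, c("scaffold_id", "chromosome", "start", "end",
                      "strand")]
  flip <- c("s5", "s7")
  layout$strand[layout$scaffold_id %in% flip] <- "-"
  sc <- fragment_into_scaffolds(fx$genome, layout = layout)
  plan <- plan_probes(sc, n_probes = 3, span = 600)
  obs <- simulate_hybridization(plan, sc, fx$genome, n_spreads = 3,
                                seed = 9)
  a <- assign_scaffolds(obs, plan)
  an <- detect_anomalies(a, plan)
  paf <- simulate_reference_alignments(sc, fx$genome)
  bp <- locate_breakpoints(an, plan, paf)
  slen <- tapply(sc$truth$scaffold_end, sc$truth$scaffold_id, max)
  parts <- split_and_orient(slen, bp, a, plan)
  # every planted flip is recovered as "-", unflipped multi-probe parts "+"
  expect_true(all(parts$orientation[parts$scaffold_id %in% flip] == "-"))
  expect_true(all(parts$orientation[!parts$scaffold_id %in% flip &
                                      !parts$low_confidence] == "+"))
  # base conservation: parts tile their scaffolds exactly
  for (sid in names(slen)) {
    p <- parts[parts$scaffold_id == sid, ]
    expect_equal(sum(p$end - p$start), unname(slen[sid]))
  }
  # AGP round trip and non-gap base conservation
  agp <- build_chromosomes(parts, gap_size = 100)
  tmp <- tempfile(fileext = ".agp")
  write_agp(agp, tmp)
  back <- read_agp(tmp)
  expect_equal(as.data.frame(back), as.data.frame(agp))
  wrows <- agp[agp$component_type == "W", ]
  expect_equal(sum(wrows$object_end - wrows$object_beg + 1),
               sum(parts$end - parts$start))
  # corrected sequences: a reversed part is the scaffold's reverse
  # complement
  cseq <- corrected_scaffold_seqs(sc$seqs, parts)
  expect_identical(cseq[["s5"]], rc(sc$seqs[["s5"]]))
})

test_that("chromosome numbering follows morphology then length, stably", {
  idio <- data.frame(
    chromosome = c("cA", "cB", "cC", "cD", "X"),
    relative_length = c(4.0, 5.0, 5.5, 3.0, 10.9),
    sd = 0.1,
    morphology = c("acrocentric", "acrocentric", "submetacentric",
                   "acrocentric", "metacentric"),
    composition = c("s2", "s1", "s3", "s4", "s5"),
    stringsAsFactors = FALSE)
  num <- order_and_number(idio)
  expect_equal(num$chromosome, c("cB", "cA", "cD", "cC", "X"))
  expect_equal(num$number, c("1", "2", "3", "4", "X"))
  # the submetacentric autosome is numbered after every acrocentric even
  # though it is longer
  expect_equal(num$number[num$chromosome == "cC"], "4")
  # invariant to input permutation
  set.seed(3)
  for (i in 1:5) {
    perm <- order_and_number(idio[sample(nrow(idio)), ])
    expect_equal(perm$number, num$number)
    expect_equal(perm$chromosome, num$chromosome)
  }
})

test_that("recovery degrades monotonically with probe dropout", {
  rates <- c(0, 0.2, 0.5)
  hit <- sapply(rates, function(dr) {
    found <- 0; total <- 0
    for (seed in c(3, 11, 19)) {
      fx <- make_pipeline_fixture(seed = seed)
      obs <- simulate_hybridization(fx$plan, fx$scaffolds, fx$genome,
                                    n_spreads = 4, dropout_rate = dr,
                                    seed = seed + 100)
      a <- assign_scaffolds(obs, fx$plan)
      an <- detect_anomalies(a, fx$plan)
      status <- setNames(an$status, an$scaffold_id)
      found <- found +
        sum(status[intersect(fx$chimeric, names(status))] == "chimeric")
      total <- total + length(fx$chimeric)
    }
    found / total
  })
  expect_equal(hit[1], 1)
  expect_true(all(diff(hit) <= 0))
})
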