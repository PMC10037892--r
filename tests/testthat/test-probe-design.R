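test_that("the 68-scaffold allocation yields 170 probes in three libraries", {
  lens <- sort(round(seq(9.6e6, 120e6, length.out = 68)), decreasing = TRUE)
  names(lens) <- as.character(1:68)
  al <- allocate_probe_counts(lens, suspected = c("2", "12"),
                              n_libraries = 3, capacity = 91500,
                              n_oligo = 1500, tier_sizes = c(29, 34, 2))
  expect_equal(sum(al$n_probes), 170)
  expect_equal(sum(al$n_probes) * 1500, 255000)
  expect_equal(as.vector(table(al$n_probes)[c("5", "4", "3", "2", "1")]),
               c(1L, 2L, 29L, 34L, 2L))
  expect_true(all(al$n_probes >= 1 & al$n_probes <= 5))
  # the largest scaffold gets five probes, suspected ones at least four
  expect_equal(al$n_probes[al$scaffold_id == "1"], 5)
  expect_true(all(al$n_probes[al$scaffold_id %in% c("2", "12")] >= 4))
  # library packing respects capacity
  expect_true(all(tapply(al$n_probes, al$library, sum) * 1500 <= 91500))
})

test_that("degenerate and infeasible allocations behave", {
  one <- allocate_probe_counts(c(a = 1e6), n_libraries = 1,
                               capacity = 1500, n_oligo = 1500,
                               max_probes = 1)
  expect_equal(one$n_probes, 1)
  expect_error(allocate_probe_counts(c(a = 1e6, b = 1e6), n_libraries = 1,
                                     capacity = 1500, n_oligo = 1500),
               "infeasible budget")
  expect_error(allocate_probe_counts(c(a = 1e6), capacity = 10,
                                     n_oligo = 1500), "capacity")
})

test_that("default tiering equals the exhaustive tier-boundary oracle", {
  set.seed(19)
  for (rep in 1:5) {
    n <- sample(6:14, 1)
    lens <- sort(round(runif(n, 1e6, 9e6)), decreasing = TRUE)
    names(lens) <- paste0("sc", seq_len(n))
    budget_probes <- sample(seq(n + 2, 3 * n + 3), 1)
    al <- allocate_probe_counts(lens, n_libraries = 1,
                                capacity = budget_probes * 10,
                                n_oligo = 10)
    # oracle: enumerate every (x3, x2, x1) split of the non-top scaffolds,
    # keep the feasible split with most probes (ties: larger tiers first)
    m <- n - 1
    best <- NULL
    for (x3 in 0:m) for (x2 in 0:(m - x3)) {
      x1 <- m - x3 - x2
      tot <- 5 + 3 * x3 + 2 * x2 + x1
      if (tot > budget_probes) next
      key <- c(tot, x3, x2)
      if (is.null(best) ||
          key[1] > best[1] ||
          (key[1] == best[1] && key[2] > best[2]) ||
          (key[1] == best[1] && key[2] == best[2] && key[3] > best[3]))
        best <- key
    }
    expect_equal(sum(al$n_probes), best[1])
    expect_equal(sum(al$n_probes == 3) , best[2])
    # monotone: longer scaffolds never get fewer probes
    expect_true(all(diff(al$n_probes[order(-al$length)]) <= 0))
  }
})

test_that("window selection is central, gap-aware and equals enumeration", {
  set.seed(23)
  # uniform candidate field: a single window lands at the midpoint
  cand <- data.frame(scaffold_id = "s", start = seq(0, 960, by = 40),
                     end = seq(0, 960, by = 40) + 39,
                     sequence = "x", tm = 50, gc = 0.5,
                     max_kmer_count = 1, hairpin_dg = 0,
                     stringsAsFactors = FALSE)
  w <- select_probe_windows(cand, n_probes = 1, n_oligo = 5,
                            scaffold_length = 1000, scaffold_id = "s")
  centre <- (w$start + w$end) / 2
  expect_lt(abs(centre - 500), 40 + 1)
  # small instance equals exhaustive placement under the same criteria
  cand2 <- data.frame(scaffold_id = "s",
                      start = sort(sample(0:2000, 25)) * 1,
                      stringsAsFactors = FALSE)
  cand2$end <- cand2$start + 39
  cand2$tm <- 50; cand2$gc <- 0.5; cand2$sequence <- "x"
  L <- 2200
  w2 <- select_probe_windows(cand2, n_probes = 2, n_oligo = 5,
                             min_gap = 100, scaffold_length = L,
                             scaffold_id = "s")
  nw <- nrow(cand2) - 5 + 1
  ws <- cand2$start[1:nw]; we <- cand2$end[1:nw + 4]
  wc <- (ws + we) / 2
  wh <- vapply(1:nw, function(j) var(diff(cand2$start[j:(j + 4)])),
               numeric(1))
  ideal <- L * c(1, 3) / 4
  best <- NULL; bestpair <- NULL
  for (i in 1:nw) for (j in 1:nw) {
    if (we[i] + 100 > ws[j]) next
    sc <- c(abs(wc[i] - ideal[1]) + abs(wc[j] - ideal[2]),
            wh[i] + wh[j], (we[i] - ws[i]) + (we[j] - ws[j]))
    if (is.null(best) || sc[1] < best[1] - 1e-12 ||
        (abs(sc[1] - best[1]) < 1e-12 && sc[2] < best[2] - 1e-12) ||
        (abs(sc[1] - best[1]) < 1e-12 && abs(sc[2] - best[2]) < 1e-12 &&
         sc[3] < best[3])) {
      best <- sc; bestpair <- c(i, j)
    }
  }
  expect_equal(w2$start, ws[bestpair])
  # infeasibility names the scaffold
  expect_error(select_probe_windows(cand2, n_probes = 10, n_oligo = 5,
                                    scaffold_length = L,
                                    scaffold_id = "sX"), "sX")
})

test_that("plan statistics match hand arithmetic", {
  plan <- data.frame(probe_id = c("ap0", "ap1", "ap2"),
                     scaffold_id = "a",
                     start = c(1000, 9000, 20000),
                     end = c(3000, 12000, 24000), n_oligo = 10,
                     stringsAsFactors = FALSE)
  st <- probe_plan_stats(plan, c(a = 30000))
  expect_equal(st$span$mean, mean(c(2000, 3000, 4000)))
  expect_equal(st$gap$mean, mean(c(6000, 8000)))
  expect_equal(st$terminus$mean, mean(c(1000, 6000)))
  expect_equal(st$oligo_density_per_kb, 10 / 3)
  # single-probe plans have no gap statistics, flagged
  st1 <- probe_plan_stats(plan[1, ], c(a = 30000))
  expect_true(st1$no_gaps)
  expect_null(st1$gap)
  # the design density: 1500 oligos over a mean 401.5 kb span
  plan2 <- data.frame(probe_id = c("x", "y"), scaffold_id = c("s1", "s2"),
                      start = 0, end = 401500, n_oligo = 1500)
  expect_equal(round(probe_plan_stats(plan2,
                                      c(s1 = 5e6,
                                        s2 = 5e6))$oligo_density_per_kb, 2),
               3.74)
})

test_that("colour schemes are unique per pool and map the known pairs", {
  alpha <- colour_alphabet()
  expect_equal(nrow(alpha), 6)
  expect_equal(alpha$colour[alpha$fluorophores == "FAM+ATTO550"], "green")
  expect_equal(alpha$colour[alpha$fluorophores == "ATTO550+ATTO647"],
               "orange")
  expect_equal(alpha$colour[alpha$fluorophores == "FAM+ATTO647"], "violet")
  # 7 two-probe scaffolds in one pool: 36 ordered patterns, all distinct
  al <- data.frame(scaffold_id = paste0("s", 1:7), length = 7:1 * 1e6,
                   n_probes = 2, library = 1, stringsAsFactors = FALSE)
  cs <- assign_colour_schemes(al)
  pat <- tapply(cs$colour[order(cs$probe_index)],
                cs$scaffold_id[order(cs$probe_index)],
                paste, collapse = "|")
  expect_equal(anyDuplicated(pat), 0L)
  # 37 two-probe scaffolds exceed the 6^2 pattern space
  al37 <- data.frame(scaffold_id = paste0("s", 1:37), length = 37:1 * 1e6,
                     n_probes = 2, library = 1, stringsAsFactors = FALSE)
  expect_error(assign_colour_schemes(al37), "split the pool")
  # property: uniqueness holds across random allocations
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    al2 <- data.frame(scaffold_id = paste0("s", seq_len(n)),
                      length = sort(runif(n, 1e6, 9e6), decreasing = TRUE),
                      n_probes = sample(1:4, n, TRUE),
                      library = sample(1:2, n, TRUE),
                      stringsAsFactors = FALSE)
    cs2 <- assign_colour_schemes(al2)
    for (lib in unique(al2$library)) {
      p <- cs2[cs2$library == lib, ]
      pat <- tapply(p$colour[order(p$probe_index)],
                    p$scaffold_id[order(p$probe_index)],
                    paste, collapse = "|")
      expect_equal(anyDuplicated(pat), 0L)
    }
  }
})
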