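engine_genome <- function(len = 10000L, seed = 1) {
  withr::with_seed(seed, toy_genome(chr1 = random_seq(len)))
}

fake_hits <- function(starts, width = 5L) {
  tibble::tibble(chrom = "chr1", start = as.integer(starts),
                 end = as.integer(starts) + width - 1L,
                 strand = "+", score = 1)
}

test_that("sample_hits honours the abundance cap and stays sorted", {
  h <- fake_hits(seq(10, 100, by = 10))
  expect_identical(sample_hits(h, 20L), h)
  expect_identical(sample_hits(h, nrow(h)), h)
  expect_equal(nrow(sample_hits(h, 0L)), 0L)

  set.seed(5)
  s1 <- sample_hits(fake_hits(1:100), 5L)
  set.seed(5)
  s2 <- sample_hits(fake_hits(1:100), 5L)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 5L)
  expect_true(all(s1$start %in% 1:100))
  expect_false(is.unsorted(s1$start))
})

test_that("abundance-capped sampling is uniform over hits", {
  h <- fake_hits(c(10, 20, 30, 40))
  counts <- integer(4)
  set.seed(99)
  for (i in 1:20000) {
    pick <- sample_hits(h, 1L)
    counts[pick$start / 10] <- counts[pick$start / 10] + 1L
  }
  freq <- counts / 20000
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("placement centres on the hit midpoint and clips to bounds", {
  expect_equal(place_modification(101L, 105L, 147L, NULL, 10000L),
               c(30L, 176L))
  expect_equal(place_modification(8L, 12L, 147L, NULL, 10000L), c(1L, 83L))
  expect_equal(place_modification(50L, 50L, 10L, NULL, 52L), c(45L, 52L))
  # a fully off-chromosome placement yields no modification
  set.seed(1)
  far <- offset_normal(5000, 0)
  placements <- replicate(20, {
    p <- place_modification(9990L, 9994L, 10L, far, 10000L)
    if (is.null(p)) NA_integer_ else p[1]
  })
  expect_true(any(is.na(placements)))          # pushed off the right end
  expect_true(any(placements[!is.na(placements)] < 5100))  # and left, in range
  # persistent invalid statewidth samples error out
  expect_error(place_modification(10L, 20L, function(n) rep(0L, n), NULL, 100L),
               "statewidth sampler")
})

test_that("offset magnitudes get a uniformly random sign", {
  set.seed(12)
  off <- offset_normal(200, 0)
  centres <- replicate(400, place_modification(500L, 500L, 1L, off, 1000L)[1])
  expect_setequal(unique(centres), c(300L, 700L))
  expect_gt(mean(centres == 300L), 0.4)
  expect_lt(mean(centres == 300L), 0.6)
})

test_that("apply_binding_factor applies joint modifications per placement", {
  g <- engine_genome(200L)
  # a trigger layer supplies a concrete [50,60] footprint
  x2 <- layer_set(g, c("A", "B", "T"))
  x2 <- set_state(x2, "A", "chr1", 1L, 100L, "present")
  x2 <- set_state(x2, "T", "chr1", 50L, 60L, "present")
  bf2 <- binding_factor("swap", seq_profile("none"),
                        layer_predicate(present = "T"),
                        mods = c(A = "absent", B = "present"),
                        placement = "footprint")
  set.seed(1)
  res <- apply_binding_factor(x2, bf2, 1)
  expect_equal(res$n_applied, 1L)
  expect_equal(layer_tbl(res$layerset, "A"),
               tibble::tibble(chrom = "chr1", start = c(1L, 61L),
                              end = c(49L, 100L)))
  expect_equal(layer_tbl(res$layerset, "B"),
               tibble::tibble(chrom = "chr1", start = 50L, end = 60L))
})

test_that("abundance zero leaves the layer set unchanged", {
  g <- engine_genome(500L)
  x <- layer_set(g, "L")
  bf <- binding_factor("f", seq_profile("consensus", "A"),
                       mods = c(L = "present"), statewidth = 10L)
  set.seed(2)
  res <- apply_binding_factor(x, bf, 0)
  expect_equal(res$n_applied, 0L)
  expect_equal(covered_bp(res$layerset, "L"), 0)
})

test_that("a single application marks one statewidth-wide region", {
  g <- toy_genome(chr1 = paste0(strrep("T", 200), "CACGTG", strrep("T", 200)))
  x <- layer_set(g, "L")
  bf <- binding_factor("f", seq_profile("consensus", "CACGTG"),
                       mods = c(L = "present"), statewidth = 10L)
  set.seed(3)
  res <- apply_binding_factor(x, bf, 1)
  tbl <- layer_tbl(res$layerset, "L")
  expect_equal(nrow(tbl), 1L)
  expect_equal(tbl$end - tbl$start + 1L, 10L)
  centre <- (201L + 206L) %/% 2L
  expect_true(tbl$start <= centre && tbl$end >= centre)
})

test_that("factors see same-cycle updates from their predecessors", {
  g <- toy_genome(chr1 = paste0(strrep("T", 100), "CACGTG", strrep("T", 394)))
  x <- layer_set(g, c("mark", "echo"))
  writer <- binding_factor("writer", seq_profile("consensus", "CACGTG"),
                           mods = c(mark = "present"), statewidth = 20L)
  reader <- binding_factor("reader", seq_profile("none"),
                           layer_predicate(present = "mark",
                                           absent = "echo"),
                           mods = c(echo = "present"),
                           placement = "footprint")
  set.seed(4)
  res <- run_cycle(x, list(writer, reader),
                   c(writer = 10, reader = 10), 1L)
  # reader acted in the same cycle, exactly where writer marked
  expect_identical(layer_tbl(res$layerset, "echo"),
                   layer_tbl(res$layerset, "mark"))
  expect_equal(res$applications$n_applied, c(1L, 1L))
})

test_that("an all-zero cycle still appends history rows", {
  g <- engine_genome(500L)
  x <- layer_set(g, c("A", "B"))
  bf <- binding_factor("f", seq_profile("consensus", "ACGT"),
                       mods = c(A = "present"), statewidth = 10L)
  set.seed(5)
  res <- run_cycle(x, list(bf), c(f = 0), 1L)
  expect_equal(covered_bp(res$layerset, "A"), 0)
  expect_equal(nrow(res$layerset$history), 2L)
  expect_equal(res$layerset$history$cycle, c(1L, 1L))
})

test_that("factor order matters for antagonistic writer/eraser pairs", {
  g <- toy_genome(chr1 = paste0(strrep("T", 100), "CACGTG", strrep("T", 394)))
  writer <- binding_factor("writer", seq_profile("consensus", "CACGTG"),
                           mods = c(L = "present"), statewidth = 50L)
  eraser <- binding_factor("eraser", seq_profile("consensus", "CACGTG"),
                           mods = c(L = "absent"), statewidth = 50L)
  ab <- c(writer = 5, eraser = 5)
  x <- layer_set(g, "L")
  set.seed(6)
  wr_first <- run_cycle(x, list(writer, eraser), ab, 1L)$layerset
  set.seed(6)
  er_first <- run_cycle(x, list(eraser, writer), ab, 1L)$layerset
  expect_equal(covered_bp(wr_first, "L"), 0)    # eraser runs last, wipes
  expect_gt(covered_bp(er_first, "L"), 0)       # writer runs last, marks
})

test_that("simulations snapshot at the configured cadence", {
  g <- engine_genome(2000L)
  bf <- binding_factor("f", seq_profile("consensus", "CACGTG"),
                       mods = c(L = "present"), statewidth = 20L)
  cfg <- simulation_config(g, "L", list(bf), c(f = 2), n_cycles = 20L,
                           snapshot_every = 10L, seed = 42L)
  res <- run_simulation(cfg)
  expect_equal(names(res$snapshots), c("10", "20"))
  expect_equal(nrow(res$history), 20L)   # one layer, one row per cycle
  cfg2 <- simulation_config(g, c("L", "M"), list(bf), c(f = 2),
                            n_cycles = 6L, seed = 1L)
  res2 <- run_simulation(cfg2)
  expect_equal(nrow(res2$history), 12L)  # n_layers x n_cycles
  expect_length(res2$snapshots, 0L)
})

test_that("identical config and seed give byte-identical persisted output", {
  g <- engine_genome(3000L)
  bf <- binding_factor("f", seq_profile("consensus", "WWS"),
                       mods = c(L = "present"), statewidth = 30L,
                       offset = offset_normal(100, 20))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  mk <- function(dir) {
    simulation_config(g, "L", list(bf), c(f = 3), n_cycles = 12L,
                      snapshot_every = 4L, seed = 7L, snapshot_dir = dir)
  }
  run_simulation(mk(d1))
  run_simulation(mk(d2))
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("abundance ceilings hold and the genome is immutable", {
  g <- engine_genome(5000L)
  hash_before <- rlang::hash(as.character(g$seqs))
  bf1 <- binding_factor("many", seq_profile("consensus", "WS"),
                        mods = c(A = "present"), statewidth = 15L)
  bf2 <- binding_factor("spread", seq_profile("none"),
                        layer_predicate(present = "A", absent = "B"),
                        mods = c(B = "present"), statewidth = 40L,
                        offset = offset_normal(50, 10))
  cfg <- simulation_config(g, c("A", "B"), list(bf1, bf2),
                           c(many = 7, spread = 3), n_cycles = 15L,
                           seed = 9L)
  res <- run_simulation(cfg)
  caps <- c(many = 7, spread = 3)
  expect_true(all(res$applications$n_applied <=
                    caps[res$applications$factor]))
  expect_identical(rlang::hash(as.character(res$layerset$genome$seqs)),
                   hash_before)
})

test_that("writer-only models accumulate coverage monotonically", {
  g <- engine_genome(4000L)
  bf <- binding_factor("w", seq_profile("consensus", "SW"),
                       mods = c(L = "present"), statewidth = 25L)
  cfg <- simulation_config(g, "L", list(bf), c(w = 4), n_cycles = 25L,
                           seed = 11L)
  res <- run_simulation(cfg)
  cov <- res$history$covered_bp
  expect_true(all(diff(cov) >= 0))
  expect_gt(cov[length(cov)], 0)
})

test_that("replicates are independent, bounded and reproducible", {
  g <- engine_genome(3000L)
  bf <- binding_factor("f", seq_profile("consensus", "WW"),
                       mods = c(L = "present"), statewidth = 30L,
                       offset = offset_normal(60, 15))
  cfg <- simulation_config(g, "L", list(bf), c(f = 3), n_cycles = 10L,
                           seed = 100L)
  out <- withr::local_tempdir()
  reps <- run_replicates(cfg, 3L, base_seed = 100L, out_dir = out)
  expect_length(reps, 3L)
  track <- sum_coverage(replicate_layer_ranges(reps, "L"), g)
  v <- coverage_counts_vec(track, "chr1")
  expect_true(all(v >= 0L & v <= 3L))
  # stochastic model: replicate outputs differ somewhere
  tbls <- lapply(reps, function(r) layer_tbl(r$layerset, "L"))
  expect_false(identical(tbls[[1]], tbls[[2]]) &&
                 identical(tbls[[2]], tbls[[3]]))
  # rerunning replicate 2 alone under base_seed + 2 reproduces it exactly
  cfg2 <- cfg
  cfg2$seed <- 102L
  solo <- run_simulation(cfg2)
  expect_identical(layer_tbl(solo$layerset, "L"), tbls[[2]])
  out2 <- withr::local_tempdir()
  run_replicates(cfg, 1L, base_seed = 101L, out_dir = out2)  # = replicate 2
  expect_identical(
    readLines(file.path(out2, "replicate_001", "layer_L.bed")),
    readLines(file.path(out, "replicate_002", "layer_L.bed")))
})

test_that("a failing replicate is reported by index without aborting", {
  g <- engine_genome(1000L)
  boom <- binding_factor("boom", seq_profile("consensus", "A"),
                         mods = c(L = "present"),
                         statewidth = function(n) stop("sampler exploded"))
  cfg <- simulation_config(g, "L", list(boom), c(boom = 1), n_cycles = 1L,
                           seed = 1L)
  w <- testthat::capture_warnings(reps <- run_replicates(cfg, 2L,
                                                         base_seed = 1L))
  expect_match(w, "Replicate [12] failed", all = TRUE)
  expect_length(w, 2L)
  expect_true(all(vapply(reps, is.null, logical(1))))
})

test_that("cycle-varying abundance schedules are honoured", {
  g <- engine_genome(2000L)
  bf <- binding_factor("f", seq_profile("consensus", "W"),
                       mods = c(L = "present"), statewidth = 10L)
  sched <- function(cycle) c(f = if (cycle <= 2L) 0 else 5)
  cfg <- simulation_config(g, "L", list(bf), sched, n_cycles = 4L, seed = 3L)
  res <- run_simulation(cfg)
  app <- res$applications
  expect_equal(app$n_applied[app$cycle <= 2L], c(0L, 0L))
  expect_true(all(app$n_applied[app$cycle > 2L] == 5L))
})

test_that("configs validate factor coverage and layer declarations", {
  g <- engine_genome(500L)
  bf <- binding_factor("f", seq_profile("consensus", "ACG"),
                       mods = c(ghost = "present"), statewidth = 5L)
  expect_error(simulation_config(g, "L", list(bf), c(f = 1), n_cycles = 2L),
               "undeclared")
  bf2 <- binding_factor("f", seq_profile("consensus", "ACG"),
                        mods = c(L = "present"), statewidth = 5L)
  cfg <- simulation_config(g, "L", list(bf2), c(other = 1), n_cycles = 1L)
  expect_error(run_simulation(cfg), "No abundance")
})
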