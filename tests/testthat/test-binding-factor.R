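test_that("consensus scanning reports all matching windows on both strands", {
  g <- toy_genome(c1 = "AAGGTGTAA")
  hits <- find_sequence_hits(g, seq_profile("consensus", "GGTGT",
                                            strand = "forward"))
  expect_equal(hits$start, 3L)
  expect_equal(hits$end, 7L)

  g2 <- toy_genome(c1 = "ATTGTCTTTGT")
  h2 <- find_sequence_hits(g2, seq_profile("consensus", "WTTGT",
                                           strand = "forward"))
  expect_equal(h2$start, c(1L, 7L))
  expect_equal(h2$end, c(5L, 11L))

  # a motif present only on the minus strand
  g3 <- toy_genome(c1 = "ATTTGCAT")
  both <- find_sequence_hits(g3, seq_profile("consensus", "ATGCAAAT",
                                             strand = "both"))
  expect_equal(nrow(both), 1L)
  expect_equal(both$strand, "-")
  fwd <- find_sequence_hits(g3, seq_profile("consensus", "ATGCAAAT",
                                            strand = "forward"))
  expect_equal(nrow(fwd), 0L)

  # palindromes are reported once per position under strand = both
  g4 <- toy_genome(c1 = "TTCACGTGTT")
  pal <- find_sequence_hits(g4, seq_profile("consensus", "CACGTG",
                                            strand = "both"))
  expect_equal(nrow(pal), 1L)
})

test_that("genome N matches only a pattern N, not other profile characters", {
  g <- toy_genome(c1 = "AANTTGTAA")
  expect_equal(nrow(find_sequence_hits(
    g, seq_profile("consensus", "WTTGT", strand = "forward"))), 0L)
  expect_equal(find_sequence_hits(
    g, seq_profile("consensus", "NTTGT", strand = "forward"))$start, 3L)
})

test_that("regex scanning is non-overlapping, leftmost, forward-strand", {
  g <- toy_genome(c1 = "GGTGTGGTGT")
  h <- find_sequence_hits(g, seq_profile("regex", "GGTGT.{0,3}GGTGT"))
  expect_equal(h$start, 1L)
  expect_equal(h$end, 10L)

  g2 <- toy_genome(c1 = "GGTGTAAAAGGTGT")   # gap of 4 exceeds the bound
  expect_equal(nrow(find_sequence_hits(
    g2, seq_profile("regex", "GGTGT.{0,3}GGTGT"))), 0L)

  g3 <- toy_genome(c1 = "CGACGACGACGACG")
  h3 <- find_sequence_hits(g3, seq_profile("regex", "(CG.{0,20}){4}CG"))
  expect_equal(h3$start, 1L)
  expect_equal(h3$end, 14L)
  # independent engine (TRE instead of PCRE) agrees
  m <- gregexpr("(CG.{0,20}){4}CG", "CGACGACGACGACG", perl = FALSE)[[1]]
  expect_equal(as.integer(m), 1L)
  expect_equal(attr(m, "match.length"), 14L)

  expect_error(seq_profile("regex", "(unclosed"), "Invalid regular expression")
})

test_that("PWM scanning thresholds on the fraction of the maximum score", {
  counts <- matrix(c(20, 0, 0, 0,
                     0, 20, 0, 0,
                     0, 0, 20, 0,
                     0, 0, 0, 20), nrow = 4L, byrow = TRUE,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- seq_profile("pwm", pwm = counts, threshold = 0.9, strand = "forward")
  g <- toy_genome(c1 = "TTACGTTT")
  h <- find_sequence_hits(g, p)
  expect_equal(h$start, 3L)
  expect_gt(h$score[1], 0)
  # one mismatching base drops the window below 90% of the maximum
  g2 <- toy_genome(c1 = "TTACGATT")
  expect_equal(nrow(find_sequence_hits(g2, p)), 0L)
})

test_that("consensus and PWM scans agree with the naive per-window oracle", {
  set.seed(33)
  pats <- c("GGTGT", "WTTGT", "ATGCAAAT", "CACGTG", "GCCAMGCCTC", "RYKM")
  for (trial in 1:30) {
    seq <- random_seq(sample(200:2000, 1))
    g <- toy_genome(c1 = seq)
    pat <- sample(pats, 1)
    for (strand in c("forward", "both")) {
      hits <- find_sequence_hits(g, seq_profile("consensus", pat,
                                                strand = strand))
      oracle <- naive_consensus_hits(seq, pat, strand)
      expect_equal(hits$start, oracle$start, info = paste(pat, strand, trial))
    }
  }
  for (trial in 1:10) {
    seq <- random_seq(sample(500:2000, 1))
    g <- toy_genome(c1 = seq)
    counts <- matrix(rpois(4 * 6, 3), nrow = 4L,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    prof <- seq_profile("pwm", pwm = counts, threshold = 0.8, strand = "both")
    hits <- find_sequence_hits(g, prof)
    oracle <- naive_pwm_hits(seq, prof$pwm, 0.8, "both")
    expect_equal(hits$start, oracle$start, info = paste("pwm", trial))
  }
})

test_that("hit counting exposes strand and overlap conventions", {
  g <- toy_genome(c1 = "CACGTGCACGTG")
  expect_equal(count_sequence_hits(g, seq_profile("consensus", "CACGTG",
                                                  strand = "forward")), 2L)
  g2 <- toy_genome(c1 = "AAAA")
  p <- seq_profile("consensus", "AA", strand = "forward")
  expect_equal(count_sequence_hits(g2, p, overlap = "allow"), 3L)
  expect_equal(count_sequence_hits(g2, p, overlap = "disjoint"), 2L)
  # strand override doubles counts for a non-palindromic motif
  g3 <- toy_genome(c1 = "ATGCAAATTTATTTGCAT")
  p3 <- seq_profile("consensus", "ATGCAAAT", strand = "forward")
  expect_equal(count_sequence_hits(g3, p3), 1L)
  expect_equal(count_sequence_hits(g3, p3, strand = "both"), 2L)
})

test_that("counting finds every planted motif in a synthetic genome", {
  spec <- synth_genome_spec(
    n_chroms = 1L, chrom_length = 20000L,
    motifs = list(planted_motif("ATGCAAAT", 25L)),
    telomere_window = 1000L)
  gen <- generate_genome(spec, seed = 6)
  p <- seq_profile("consensus", "ATGCAAAT", strand = "forward")
  expect_gte(count_sequence_hits(gen$genome, p), 25L)
  hits <- find_sequence_hits(gen$genome, p)
  expect_true(all(gen$features$start %in% hits$start))
})

test_that("layer predicates use >=1 bp overlap semantics", {
  g <- toy_genome(c1 = random_seq(100))
  x <- layer_set(g, c("L1", "L2"))
  x <- set_state(x, "L1", "c1", 15L, 30L, "present")
  x <- set_state(x, "L2", "c1", 20L, 25L, "present")
  expect_true(evaluate_predicate(x, "c1", 10, 20,
                                 layer_predicate(present = "L1")))
  expect_true(evaluate_predicate(x, "c1", 10, 14,
                                 layer_predicate(absent = "L1")))
  expect_false(evaluate_predicate(x, "c1", 10, 20,
                                  layer_predicate(present = "L1",
                                                  absent = "L2")))
  # the empty predicate is always true
  expect_true(evaluate_predicate(x, "c1", 1, 100, layer_predicate()))
  # containment mode requires the footprint inside one interval
  expect_false(evaluate_predicate(x, "c1", 10, 20,
                                  layer_predicate(present = "L1",
                                                  mode = "contain")))
  expect_true(evaluate_predicate(x, "c1", 16, 20,
                                 layer_predicate(present = "L1",
                                                 mode = "contain")))
  expect_error(evaluate_predicate(x, "c1", 1, 10,
                                  layer_predicate(present = "ghost")),
               "Unknown layer")
})

test_that("match_binding_factor reduces to a plain scan for empty predicates", {
  spec <- synth_genome_spec(
    n_chroms = 1L, chrom_length = 5000L,
    motifs = list(planted_motif("GGTGT", 10L)), telomere_window = 500L)
  gen <- generate_genome(spec, seed = 10)
  x <- layer_set(gen$genome, c("sir3_potential", "sir3_bound"))
  bf <- binding_factor("RAP1", seq_profile("consensus", "GGTGT"),
                       mods = c(sir3_potential = "present"), statewidth = 10L)
  expect_equal(match_binding_factor(x, bf),
               find_sequence_hits(gen$genome,
                                  seq_profile("consensus", "GGTGT")))
})

test_that("profile-none factors draw candidates from the first present layer", {
  g <- toy_genome(c1 = random_seq(500))
  x <- layer_set(g, c("sir3_potential", "sir3_bound"))
  x <- set_state(x, "sir3_potential", "c1", 100L, 147L, "present")
  bf <- binding_factor("Sir3p", seq_profile("none"),
                       layer_predicate(present = "sir3_potential",
                                       absent = "sir3_bound"),
                       mods = c(sir3_bound = "present"), statewidth = 147L)
  h <- match_binding_factor(x, bf)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 100L)
  expect_equal(h$end, 147L)
  # once sir3_bound overlaps the candidate, it is excluded
  x2 <- set_state(x, "sir3_bound", "c1", 140L, 160L, "present")
  expect_equal(nrow(match_binding_factor(x2, bf)), 0L)

  bad <- binding_factor("orphan", seq_profile("none"),
                        layer_predicate(absent = "sir3_bound"),
                        mods = c(sir3_bound = "present"), statewidth = 10L)
  expect_error(match_binding_factor(x, bad), "candidate source")
})

test_that("cached factors scan the genome once and stay transparent", {
  g <- toy_genome(c1 = random_seq(2000))
  x <- layer_set(g, "L")
  bf_cached <- binding_factor("f", seq_profile("consensus", "CACGTG"),
                              mods = c(L = "present"), statewidth = 10L,
                              cacheable = TRUE)
  bf_fresh <- bf_cached
  bf_fresh$cacheable <- FALSE
  h_fresh <- match_binding_factor(x, bf_fresh)
  scan_count(reset = TRUE)
  h1 <- match_binding_factor(x, bf_cached)
  expect_equal(scan_count(), 1L)
  h2 <- match_binding_factor(x, bf_cached)
  expect_equal(scan_count(), 1L)     # second match performed no scan
  expect_identical(h1, h2)
  expect_identical(h1, h_fresh)      # cache transparency
})

test_that("hits never extend past chromosome ends", {
  set.seed(77)
  for (trial in 1:20) {
    seq <- random_seq(sample(50:300, 1))
    g <- toy_genome(c1 = seq)
    p <- seq_profile("consensus", sample(c("AA", "ACGT", "WSN"), 1),
                     strand = "both")
    h <- find_sequence_hits(g, p)
    if (nrow(h)) {
      expect_true(all(h$start >= 1L & h$end <= nchar(seq)))
    }
  }
})

test_that("binding factor validation catches inconsistent definitions", {
  expect_error(binding_factor("f", seq_profile("none"), layer_predicate(),
                              mods = c(L = "present"), statewidth = 10L),
               "profile and/or")
  expect_error(binding_factor("f", seq_profile("consensus", "ACGT"),
                              mods = character(), statewidth = 10L), "mods")
  expect_error(binding_factor("f", seq_profile("consensus", "ACGT"),
                              mods = c(L = "maybe"), statewidth = 10L),
               "present.*absent")
  expect_error(binding_factor("f", seq_profile("consensus", "ACGT"),
                              mods = c(L = "present")), "statewidth")
  expect_error(seq_profile("consensus", "ACGJ"), "IUPAC")
  expect_error(seq_profile("pwm", pwm = matrix(1, 3, 4)), "4-row")
})
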