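test_that("k-mer index exposes L-k+1 start positions and repeat positions", {
  con <- random_dna(19074, seed = 7)
  idx <- build_kmer_index(con, k = 20)
  expect_identical(idx$n_positions, 19074L - 20L + 1L)

  rep_idx <- build_kmer_index("ACGTACGTACGT", k = 8)
  expect_identical(kmer_positions(rep_idx, "ACGTACGT"), c(1L, 5L))
  # reverse complement finds the same positions
  expect_identical(kmer_positions(rep_idx, rev_comp("ACGTACGT")), c(1L, 5L))
  single <- build_kmer_index("AAAAAAAA", k = 8)
  expect_identical(kmer_positions(single, "AAAAAAAA"), 1L)

  expect_error(build_kmer_index("ACGT", k = 8), "construct length")
  expect_error(build_kmer_index(random_dna(100), k = 5), "between 8 and 31")
})

test_that("an exact 150-bp read increments exactly its 131 start positions", {
  con <- random_dna(2000, seed = 11)
  idx <- build_kmer_index(con, k = 20)
  read <- substr(con, 301, 450)
  tr <- count_read_kmers(read, idx)
  expect_identical(sum(tr$counts), 131L)
  expect_identical(which(tr$counts == 1L), 301:431)
  expect_identical(tr$total_read_kmers, 131)

  # a read with no construct k-mer leaves all counts unchanged
  alien <- strrep("AC", 75)
  tr0 <- count_read_kmers(alien, idx)
  expect_true(all(tr0$counts == 0L))
})

test_that("reverse-complement reads produce identical tracks", {
  con <- random_dna(1500, seed = 3)
  idx <- build_kmer_index(con, k = 20)
  set.seed(4)
  starts <- sample.int(1351, 40)
  reads <- substring(con, starts, starts + 149)
  fwd <- count_read_kmers(reads, idx)
  rev <- count_read_kmers(rev_comp(reads), idx)
  expect_identical(fwd$counts, rev$counts)
  expect_identical(fwd$total_read_kmers, rev$total_read_kmers)
})

test_that("counting agrees with a naive substring oracle", {
  for (seed in 1:4) {
    con <- random_dna(300, seed = seed)
    set.seed(seed + 100)
    reads <- c(
      substring(con, s <- sample.int(250, 5), s + 49),       # true positives
      replicate(3, random_dna(50)),                          # background
      rc_oracle(substr(con, 120, 169)))                      # minus strand
    idx <- build_kmer_index(con, k = 11)
    tr <- count_read_kmers(reads, idx)
    expect_identical(tr$counts, count_oracle(reads, con, 11))
  }
})

test_that("ambiguous and short reads are skipped and tallied", {
  con <- random_dna(500, seed = 9)
  idx <- build_kmer_index(con, k = 20)
  readN <- paste0(substr(con, 1, 30), "N", substr(con, 32, 60))
  tr <- suppressMessages(count_read_kmers(c(readN, "ACGT"), idx))
  expect_identical(tr$short_reads, 1L)
  # windows overlapping the N (20 of 41) are skipped
  expect_identical(tr$skipped_kmers, 20)
  expect_identical(tr$total_read_kmers, 21)
})

test_that("region averages split T-DNA from backbone correctly", {
  ann <- construct_annotation("construct", 1000, tdna_end = 600)
  counts <- integer(981)
  counts[1:581] <- 10L    # T-DNA k-mer starts: 1..600-20+1
  tr <- fake_track(counts, total = 1e6)
  av <- region_averages(tr, ann)
  expect_equal(av[["tdna"]], 10)
  expect_equal(av[["non_tdna"]], 0)
  expect_equal(av[["total"]], mean(counts))

  zero <- fake_track(integer(981), total = 1e6)
  expect_equal(as.numeric(region_averages(zero, ann)), c(0, 0, 0))
})

test_that("full-insertion simulation matches the coverage expectation", {
  # paired templates at depth d give ~2*d*(131/150)*(1-e)^k counts/position
  sc <- screen_scenario(host_length = 1e5, depth = 30)
  set.seed(42)
  host <- generate_host_genome(sc$host_length, sc$gc)
  built <- generate_construct(host, sc)
  ev <- apply_event(host, built$sequence, built$annotation,
                    event = "full_insertion", scenario = sc)
  reads <- simulate_reads(ev$genome, sc$depth, sc$read_length,
                          sc$error_rate)
  idx <- build_kmer_index(built$sequence, k = sc$k)
  tr <- count_read_kmers(reads, idx)
  av <- region_averages(tr, built$annotation)
  expected <- 2 * sc$depth * (131 / 150) * (1 - sc$error_rate)^sc$k
  expect_gt(av[["tdna"]], 10 * av[["non_tdna"]])
  expect_lt(abs(av[["tdna"]] - expected) / expected, 0.15)
})

test_that("position test has the conditional binomial form", {
  a <- fake_track(c(0L, 30L, 5L), total = 1e6)
  b <- fake_track(c(0L, 0L, 5L), total = 1e6)
  p <- position_test(a, b)
  expect_equal(p[1], 1)                 # no evidence
  expect_equal(p[2], 2^-30)             # closed form at equal depth
  expect_equal(p[3], pbinom(4, 10, 0.5, lower.tail = FALSE))
  expect_error(position_test(a, fake_track(c(0L, 0L, 0L), total = 0)),
               "positive total")
})

test_that("null position-test p-values are approximately uniform", {
  # high-coverage equal-depth null so the discrete exact test is close to
  # its continuous limit
  set.seed(2024)
  n <- 10000
  a <- fake_track(rpois(n, 5000), total = 5e8)
  b <- fake_track(rpois(n, 5000), total = 5e8)
  p <- position_test(a, b)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment matches a hand step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  grid <- c(0.001, 0.01, 0.02, 0.05, 0.1, 0.25, 0.5, 0.75, 0.9, 1)
  set.seed(99)
  for (len in 1:12) {
    for (rep in 1:5) {
      p <- sample(grid, len, replace = TRUE)
      expect_equal(bh_adjust(p), bh_oracle(p))
    }
  }
})

test_that("run calling reports maximal runs with matched lengths", {
  q <- rep(1, 100)
  q[c(40, 60, 61)] <- 0.001
  runs <- call_runs(q, alpha = 0.01, k = 20)
  expect_identical(runs$significant_runs$start, c(40L, 60L))
  expect_identical(runs$significant_runs$matched_length, c(20L, 21L))
  expect_identical(nrow(runs$masked_runs), 0L)

  none <- call_runs(rep(1, 50), alpha = 0.01, k = 20)
  expect_identical(nrow(none$significant_runs), 0L)
  expect_identical(nrow(none$masked_runs), 0L)
})

test_that("shared-background and low-complexity runs are masked", {
  # construct with a C-rich decoy; control elevated at the decoy
  con <- paste0(random_dna(100, seed = 5), "CCTCCCCCCCCCCCCCTCTCT",
                random_dna(100))
  n <- nchar(con) - 19L
  q <- rep(NA_real_, n)
  q[101:102] <- 1e-8           # the decoy's two k-mer start positions
  q[30] <- 1e-8                # a genuine-looking isolated hit
  counts <- integer(n)
  counts[101:102] <- 500L
  control <- fake_track(counts, total = 1e6)
  runs <- call_runs(q, alpha = 0.01, k = 20, control = control,
                    construct = con)
  expect_identical(runs$significant_runs$start, 30L)
  expect_identical(runs$masked_runs$start, 101L)
  expect_match(runs$masked_runs$reason, "control_elevated")
  expect_match(runs$masked_runs$reason, "low_complexity")
})

test_that("transgene classification follows the run geometry", {
  ann <- construct_annotation("construct", 19074, tdna_end = 12584)
  fake_cmp <- function(runs) {
    structure(list(sample_id = "s", control_id = "c", k = 20L,
                   alpha = 0.01, pvalues = rep(1, 19055),
                   qvalues = rep(NA_real_, 19055),
                   significant_runs = runs,
                   masked_runs = data.frame(start = integer(0),
                                            end = integer(0),
                                            length = integer(0),
                                            matched_length = integer(0),
                                            reason = character(0)),
                   n_testable = 0L),
              class = "screen_comparison")
  }
  runs_df <- function(start, end) {
    data.frame(start = start, end = end, length = end - start + 1L,
               matched_length = end - start + 20L)
  }
  full <- classify_transgene(fake_cmp(runs_df(1L, 12000L)), ann)
  expect_identical(full$status, "present")
  frag <- classify_transgene(fake_cmp(runs_df(c(500L, 900L), c(500L, 901L))),
                             ann)
  expect_identical(frag$status, "residual_fragments")
  none <- classify_transgene(fake_cmp(runs_df(integer(0), integer(0))), ann)
  expect_identical(none$status, "absent")
  mid <- classify_transgene(fake_cmp(runs_df(1L, 2000L)), ann)
  expect_identical(mid$status, "inconclusive")
})

test_that("marker presence mirrors the PCR assay on planted truth", {
  ann <- construct_annotation("construct", 1000, tdna_end = 600,
                              features = data.frame(name = "HPT",
                                                    start = 100L,
                                                    end = 200L))
  counts <- integer(981)
  counts[1:581] <- 20L
  full <- marker_presence(fake_track(counts, 1e6), ann, "HPT")
  expect_true(full$present)
  empty <- marker_presence(fake_track(integer(981), 1e6), ann, "HPT")
  expect_false(empty$present)
  expect_equal(empty$mean_count, 0)
  expect_error(marker_presence(fake_track(integer(981), 1e6), ann, "nope"),
               "unknown feature")
})

test_that("null screens yield no unmasked significant runs", {
  # two same-depth read sets from a transgene-free genome
  sc <- screen_scenario(host_length = 2e5, depth = 10)
  clean <- 0L
  for (seed in 1:6) {
    sim <- simulate_screen(sc, event = "none", seed = 400 + seed)
    clean <- clean +
      (nrow(sim$screen$comparison$significant_runs) == 0L)
  }
  expect_gte(clean, 5L)  # >= 95% of replicates in the large-sample contract
})
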