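test_that("host genome generation is seeded and hits the requested GC", {
  a <- generate_host_genome(5000, gc = 0.5, seed = 1)
  b <- generate_host_genome(5000, gc = 0.5, seed = 1)
  c <- generate_host_genome(5000, gc = 0.5, seed = 2)
  expect_identical(a, b)
  expect_false(identical(a, c))
  big <- generate_host_genome(2e5, gc = 0.5, seed = 3)
  gc <- mean(strsplit(big[[1]], "")[[1]] %in% c("G", "C"))
  expect_gt(gc, 0.49)
  expect_lt(gc, 0.51)
  skewed <- generate_host_genome(2e5, gc = 0.2, seed = 4)
  gc2 <- mean(strsplit(skewed[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc2 - 0.2), 0.01)
})

test_that("the default construct reproduces the study geometry", {
  sc <- screen_scenario()
  set.seed(10)
  host <- generate_host_genome(sc$host_length, sc$gc)
  built <- generate_construct(host, sc)
  ann <- built$annotation
  expect_identical(ann$length, 19074L)
  expect_identical(c(ann$tdna_start, ann$tdna_end), c(1L, 12584L))
  con <- built$sequence[[1]]
  # the C-rich decoy is present verbatim at its published coordinates
  expect_identical(substr(con, 2069, 2089), "CCTCCCCCCCCCCCCCTCTCT")
  # the homology segment is copied from the host
  hom <- ann$features[ann$features$name == "host_homology", ]
  expect_true(grepl(substr(con, hom$start, hom$end), host[[1]],
                    fixed = TRUE))
  expect_true(all(c("HPT", "Cas9") %in% ann$features$name))
})

test_that("insertion events change the genome as declared", {
  sc <- screen_scenario(host_length = 50000)
  set.seed(20)
  host <- generate_host_genome(sc$host_length, sc$gc)
  built <- generate_construct(host, sc)

  none <- apply_event(host, built$sequence, built$annotation, "none",
                      scenario = sc)
  expect_identical(none$genome[[1]], host[[1]])

  full <- apply_event(host, built$sequence, built$annotation,
                      "full_insertion", scenario = sc)
  expect_identical(nchar(full$genome[[1]]), nchar(host[[1]]) + 12584L)

  set.seed(21)
  frag <- apply_event(host, built$sequence, built$annotation, "fragment",
                      fragment_lengths = c(20L, 21L), scenario = sc)
  expect_identical(nchar(frag$genome[[1]]), nchar(host[[1]]) + 41L)
  expect_identical(frag$inserted$length, c(20L, 21L))
  # planted fragments are genuine T-DNA substrings
  for (i in 1:2) {
    expect_true(grepl(substr(built$sequence[[1]],
                             frag$inserted$construct_start[i],
                             frag$inserted$construct_end[i]),
                      frag$genome[[1]], fixed = TRUE))
  }
  expect_warning(apply_event(host, built$sequence, built$annotation,
                             "fragment", fragment_lengths = 10L,
                             scenario = sc),
                 "undetectable")
})

test_that("read simulation obeys the template arithmetic and the seed", {
  g <- generate_host_genome(1e5, 0.5, seed = 30)
  single <- simulate_reads(g, depth = 10, paired = FALSE, seed = 31)
  expect_length(single, round(10 * 1e5 / 150))
  paired <- simulate_reads(g, depth = 10, paired = TRUE, seed = 31)
  expect_length(paired, 2 * round(10 * 1e5 / 150))
  expect_match(names(paired)[1], "/1$")
  expect_match(names(paired)[2], "/2$")
  again <- simulate_reads(g, depth = 10, paired = TRUE, seed = 31)
  expect_identical(paired, again)

  # with no errors every read is a genome substring or its reverse complement
  clean <- simulate_reads(g, depth = 0.2, error_rate = 0, seed = 32)
  gg <- g[[1]]
  ok <- vapply(clean, function(r)
    grepl(r, gg, fixed = TRUE) || grepl(rc_oracle(r), gg, fixed = TRUE),
    logical(1))
  expect_true(all(ok))
})

test_that("simulated FASTQ files round-trip through the reader", {
  g <- generate_host_genome(20000, 0.5, seed = 40)
  reads <- simulate_reads(g, depth = 1, seed = 41)
  path <- withr::local_tempfile(fileext = ".fastq.gz")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_identical(as.character(back), as.character(reads))
  expect_identical(names(back), names(reads))
})

test_that("amplicon generation plants the requested alleles", {
  ref <- random_dna(200, seed = 50)
  amps <- generate_amplicons(ref, cut = 100, alleles = list(
    list(label = "wt", type = "none"),
    list(label = "del5", type = "deletion", length = 5),
    list(label = "insA", type = "insertion", length = 1, sequence = "A")))
  expect_identical(amps[["wt"]], ref)
  expect_identical(nchar(amps[["del5"]]), 195L)
  expect_identical(nchar(amps[["insA"]]), 201L)
  expect_identical(generate_amplicons(ref, list()), character(0))
  expect_error(generate_amplicons(ref, list(list(type = "deletion",
                                                 length = 5, at = 199)),
                                  cut = 100),
               "outside region")
})

test_that("trait data generation is seeded and validates inputs", {
  groups <- data.frame(label = c("a", "b"), n = c(10, 10),
                       mean = c(5, 6), sd = c(1, 1))
  x <- generate_trait_data(groups, seed = 60)
  y <- generate_trait_data(groups, seed = 60)
  expect_identical(x, y)
  expect_identical(nrow(x), 20L)
  expect_error(generate_trait_data(data.frame(label = "a", n = 5,
                                              mean = 1, sd = 0)),
               "sd must be positive")
  expect_error(generate_trait_data(data.frame(label = "a", n = 1,
                                              mean = 1, sd = 1)),
               "n >= 2")
})

test_that("an end-to-end simulation is bit-reproducible under one seed", {
  sc <- screen_scenario(host_length = 5e4, depth = 8)
  a <- simulate_screen(sc, event = "fragment", seed = 70)
  b <- simulate_screen(sc, event = "fragment", seed = 70)
  expect_identical(a$truth, b$truth)
  expect_identical(a$screen$sample$counts, b$screen$sample$counts)
  expect_identical(a$screen$comparison$qvalues, b$screen$comparison$qvalues)
})
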