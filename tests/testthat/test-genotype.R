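# the published 43-nt context around the sgRNA8 target in NUD
CTX <- "CGGCGGAGGAGGCTGCGCGGGCGTACGATGAGGCTGCCATCCT"
PROTO <- "GGCTGCGCGGGCGTACGATG"

test_that("the expected cut falls between protospacer bases 17 and 18", {
  guide <- guide_site(PROTO)
  cs <- expected_cut_site(CTX, guide)
  expect_identical(cs$start, 11L)        # protospacer begins at base 11
  expect_identical(cs$cut, 27L)          # 3 bp 5' of the AGG PAM
  expect_identical(cs$strand, "+")

  # missing or ambiguous protospacer
  expect_error(expected_cut_site(random_dna(100, seed = 1), guide),
               "occurs 0 times")
  expect_error(expected_cut_site(paste0(CTX, CTX), guide), "occurs 2 times")
})

test_that("a minus-strand protospacer gives the mirrored cut coordinate", {
  guide <- guide_site(PROTO)
  pad <- random_dna(40, seed = 2)
  ref <- paste0(pad, CTX, random_dna(40))
  fwd <- expected_cut_site(ref, guide)
  rev <- expected_cut_site(rc_oracle(ref), guide)
  expect_identical(rev$strand, "-")
  expect_identical(rev$cut, nchar(ref) - fwd$cut)
})

test_that("identical sequences align with zero edits and full score", {
  aln <- align_to_reference(CTX, CTX)
  expect_length(aln$edits, 0)
  expect_equal(aln$score, 2 * nchar(CTX))
  expect_identical(call_indel(aln)$type, "none")
})

test_that("alignment scores equal an independent affine DP oracle", {
  set.seed(33)
  for (i in 1:5) {
    a <- random_dna(300)
    # mutate: a few substitutions plus one indel
    b <- a
    for (p in sample(280, 4)) {
      substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(b, p, p)), 1)
    }
    if (i %% 2 == 0) {
      cutat <- sample(100:200, 1)
      b <- paste0(substr(b, 1, cutat), substr(b, cutat + 8, nchar(b)))
    } else {
      b <- paste0(substr(b, 1, 150), random_dna(5), substr(b, 151, nchar(b)))
    }
    aln <- align_to_reference(a, b)
    expect_equal(aln$score, nw_affine_score(a, b))
    # gapped strings reconstruct the inputs
    expect_identical(gsub("-", "", aln$aligned_ref), a)
    expect_identical(gsub("-", "", aln$aligned_query), b)
  }
})

test_that("the published alleles are recovered: 13-bp deletion, 1-bp insertion", {
  guide <- guide_site(PROTO)
  cut <- expected_cut_site(CTX, guide)$cut
  alleles <- generate_amplicons(
    CTX, cut = cut,
    alleles = list(list(label = "del13", type = "deletion", length = 13),
                   list(label = "ins1", type = "insertion", length = 1,
                        sequence = "T"),
                   list(label = "wt", type = "none")))
  del <- call_indel(align_to_reference(CTX, alleles[["del13"]]), cut = cut)
  expect_identical(del$type, "deletion")
  expect_identical(del$length, 13L)
  expect_lte(abs(del$offset_from_cut), 13L)
  ins <- call_indel(align_to_reference(CTX, alleles[["ins1"]]), cut = cut)
  expect_identical(ins$type, "insertion")
  expect_identical(ins$length, 1L)
  wt <- call_indel(align_to_reference(CTX, alleles[["wt"]]), cut = cut)
  expect_identical(wt$type, "none")
})

test_that("indels are left-aligned in repeat context", {
  ref <- paste0("GGCGGC", "AAAAAA", "TTGCGC")
  # delete two A's from anywhere in the homopolymer: call must be leftmost
  for (drop_at in 7:11) {
    query <- paste0(substr(ref, 1, drop_at - 1),
                    substr(ref, drop_at + 2, nchar(ref)))
    call <- call_indel(align_to_reference(ref, query))
    expect_identical(call$type, "deletion")
    expect_identical(call$ref_pos, 7L)
    expect_identical(call$sequence, "AA")
  }
  # inserted repeat base also shifts left
  query <- paste0(substr(ref, 1, 10), "A", substr(ref, 11, nchar(ref)))
  call <- call_indel(align_to_reference(ref, query))
  expect_identical(call$type, "insertion")
  expect_identical(call$ref_pos, 6L)
})

test_that("applying a non-complex call to the reference round-trips", {
  set.seed(44)
  ref <- random_dna(200)
  specs <- list(list(type = "deletion", length = 13, at = 90),
                list(type = "insertion", length = 4, at = 100),
                list(type = "none"))
  alleles <- generate_amplicons(ref, specs, cut = 100)
  for (a in alleles) {
    call <- call_indel(align_to_reference(ref, a))
    expect_identical(apply_indel(ref, call), a)
  }
})

test_that("distant double edits are reported as complex", {
  ref <- random_dna(300, seed = 55)
  q <- paste0(substr(ref, 1, 49), substr(ref, 53, 200),
              "ACGT", substr(ref, 201, 300))
  call <- call_indel(align_to_reference(ref, q))
  expect_identical(call$type, "complex")
  expect_length(call$clusters, 2)
})

test_that("zygosity classification reproduces the study's genotype classes", {
  guide <- guide_site(PROTO)
  cut <- expected_cut_site(CTX, guide)$cut
  alleles <- generate_amplicons(
    CTX, cut = cut,
    alleles = list(list(label = "del13", type = "deletion", length = 13),
                   list(label = "ins1", type = "insertion", length = 1,
                        sequence = "T"),
                   list(label = "wt", type = "none")))
  call_of <- function(x) call_indel(align_to_reference(CTX, alleles[[x]]),
                                    cut = cut)
  del13 <- call_of("del13"); ins1 <- call_of("ins1"); wt <- call_of("wt")

  expect_identical(classify_zygosity("nud8_3", list(del13, del13))$genotype,
                   "homozygous")
  expect_identical(classify_zygosity("nud8_8", list(del13, wt))$genotype,
                   "heterozygous")
  expect_identical(classify_zygosity("x", list(del13, ins1))$genotype,
                   "biallelic")
  expect_identical(classify_zygosity("nud8_4",
                                     list(del13, ins1, wt))$genotype,
                   "mosaic")
  expect_identical(classify_zygosity("wt", list(wt, wt))$genotype,
                   "wild_type")
})

test_that("off-target amplicon verification flags only edited sites", {
  set.seed(66)
  refs <- setNames(replicate(6, random_dna(250)), paste0("site", 1:6))
  clean <- verify_offtarget_amplicons(refs, refs)
  expect_false(any(clean$mutated))
  expect_identical(attr(clean, "summary"), "0/6 mutated")

  edited <- refs
  edited[3] <- paste0(substr(refs[3], 1, 120), substr(refs[3], 123, 250))
  res <- verify_offtarget_amplicons(refs, edited)
  expect_identical(which(res$mutated), 3L)
  expect_identical(res$type[3], "deletion")
  expect_identical(attr(res, "summary"), "1/6 mutated")
})
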