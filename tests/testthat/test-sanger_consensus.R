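# Sanger post-processing: hit extraction, greedy assembly, representative
# choice, frame translation, trimming

test_that("best-hit extraction finds embedded reference regions", {
  withr::with_seed(11, {
    ref <- random_dna(400)
    # read identical to a reference: region is the whole read
    hit <- extract_best_hit_region(ref, c(r1 = ref))
    expect_equal(hit$q_start, 0L)
    expect_equal(hit$q_end, 400L)
    # 100-nt flank + exact 400-nt reference + 100-nt flank
    read <- paste0(random_dna(100), ref, random_dna(100))
    hit2 <- extract_best_hit_region(read, c(r1 = ref))
    expect_lte(abs(hit2$q_start - 100L), 2L)
    expect_lte(abs(hit2$q_end - 500L), 2L)
    # reverse-complemented read: same interval on the read, minus strand
    hit3 <- extract_best_hit_region(rc(read), c(r1 = ref))
    expect_equal(hit3$strand, "-")
    expect_lte(abs((nchar(read) - hit3$q_end) - 100L), 2L)
    # random reads vs unrelated references: no hit
    for (i in 1:5) expect_null(extract_best_hit_region(random_dna(500),
                                                       c(r1 = random_dna(800))))
    expect_error(extract_best_hit_region("", c(r1 = ref)), class = "petfloc_input")
  })
})

test_that("translated-mode extraction maps protein hits back to read coordinates", {
  nt <- back_translate(fdx_ref[[1]])
  read <- paste0("GG", nt, "AA")
  hit <- extract_best_hit_region(read, fdx_ref, mode = "translated")
  expect_equal(hit$frame, 2L)
  expect_equal(hit$q_start, 2L)
  expect_equal(hit$q_end, 2L + nchar(nt))
  withr::with_seed(12, expect_null(
    extract_best_hit_region(random_dna(300), fdx_ref, mode = "translated")))
})

test_that("greedy assembly reconstructs templates from tiled reads", {
  withr::with_seed(21, {
    template <- random_dna(600)
    # single read -> a contig equal to the read
    one <- assemble(c(a = template))
    expect_length(one, 1L)
    expect_equal(one[[1]]$sequence, template)
    # two error-free reads overlapping by exactly 40 nt
    r1 <- substr(template, 1, 320)
    r2 <- substr(template, 281, 600)
    ctg <- assemble(c(r1 = r1, r2 = r2), min_overlap = 30)
    expect_length(ctg, 1L)
    expect_equal(ctg[[1]]$sequence, template)
    expect_equal(nchar(ctg[[1]]$sequence), nchar(r1) + nchar(r2) - 40L)
    # no qualifying overlap -> two contigs
    two <- assemble(c(a = random_dna(200), b = random_dna(200)))
    expect_length(two, 2L)
  })
})

test_that("assembly is order- and strand-robust", {
  withr::with_seed(22, {
    template <- random_dna(700)
    reads <- simulate_sanger_reads(template, n_reads = 5, read_len = 220, seed = 3)
    base <- assemble(reads)[[1]]$sequence
    expect_equal(base, template)
    # any input order gives the identical contig
    for (i in 1:3) {
      shuf <- reads[sample(length(reads))]
      expect_equal(assemble(shuf)[[1]]$sequence, base)
    }
    # reverse-complementing a subset leaves the contig equal up to strand
    flip <- reads
    flip[c(2, 4)] <- vapply(flip[c(2, 4)], rc, "")
    got <- assemble(flip)[[1]]$sequence
    expect_true(got == template || got == rc(template))
  })
})

test_that("noisy reads yield a near-perfect majority consensus", {
  # five repeated full-length runs of one amplicon: majority voting at 5x
  # coverage corrects 1% per-base substitution errors (positions covered
  # by fewer than three reads retain the raw error rate, so the accuracy
  # contract is stated for adequately covered templates)
  n_mismatch <- 0L; n_pos <- 0L
  for (i in 1:50) {
    template <- withr::with_seed(400 + i, random_dna(400))
    reads <- simulate_sanger_reads(template, n_reads = 5, read_len = 400,
                                   substitution_rate = 0.01, seed = 700 + i)
    ctg <- assemble(reads)
    longest <- ctg[[which.max(vapply(ctg, function(cc) nchar(cc$sequence), 1L))]]
    if (nchar(longest$sequence) == nchar(template)) {
      a <- strsplit(longest$sequence, "")[[1]]
      b <- strsplit(template, "")[[1]]
      n_mismatch <- n_mismatch + sum(a != b)
      n_pos <- n_pos + length(b)
    }
  }
  expect_gt(n_pos, 0)
  expect_lt(n_mismatch / n_pos, 0.001)
})

test_that("representative choice is longest-similar with deterministic ties", {
  withr::with_seed(31, {
    ref <- random_dna(300)
    similar <- ref
    unrelated <- random_dna(500)
    # the longer contig is not similar: the shorter similar one wins
    got <- pick_representative(c(unrelated, similar), c(r = ref))
    expect_equal(got$sequence, similar)
    # single similar contig -> itself
    expect_equal(pick_representative(c(similar), c(r = ref))$sequence, similar)
    expect_error(pick_representative(c(unrelated), c(r = ref)),
                 class = "petfloc_no_representative")
  })
})

test_that("reading-frame determination and trimming follow the rules", {
  nt <- back_translate(fdx_ref[[1]])
  tf <- translate_in_frame(nt, fdx_ref)
  expect_equal(tf$frame, 0L)
  expect_equal(tf$aa, unname(fdx_ref))
  # one extra leading base shifts to frame 1, same protein
  tf1 <- translate_in_frame(paste0("G", nt), fdx_ref)
  expect_equal(tf1$frame, 1L)
  expect_true(grepl(substr(fdx_ref, 1, 90), tf1$aa, fixed = TRUE))
  # minus strand is recognized
  tfm <- translate_in_frame(rc(nt), fdx_ref)
  expect_equal(tfm$strand, "-")
  expect_equal(tfm$aa, unname(fdx_ref))
  withr::with_seed(32,
    expect_error(translate_in_frame(random_dna(120), fdx_ref),
                 class = "petfloc_frame_undetermined"))
  # trimming: to the first Met, and a single trailing X
  expect_equal(trim_protein("GGAMSTK")$aa, "MSTK")
  expect_equal(trim_protein("GGAMSTK")$trimmed_leading, 3L)
  expect_equal(trim_protein("MSTKX")$aa, "MSTK")
  expect_equal(trim_protein("MSTKX")$trimmed_trailing_X, 1L)
  expect_equal(trim_protein("MSTK")$aa, "MSTK")
  # no Met anywhere: returned untrimmed but flagged
  tw <- trim_protein("GGASTK")
  expect_true(tw$trim_failed)
  expect_equal(tw$aa, "GGASTK")
  # leading trim applies only beyond the reference length when one is given
  expect_equal(trim_protein("GAMST", reference_length = 10)$trimmed_leading, 0L)
})

test_that("the whole chain rebuilds a representative from raw reads", {
  withr::with_seed(41, {
    flank1 <- random_dna(60); flank2 <- random_dna(60)
    core <- back_translate(fdx_ref[[1]])
    template <- paste0(flank1, core, flank2)
    reads <- simulate_sanger_reads(template, n_reads = 4, read_len = 160,
                                   seed = 8)
    rep <- sanger_representative(reads, fdx_ref, mode = "translated",
                                 strain_id = "S1", locus = "petF")
    expect_s3_class(rep, "representative_sequence")
    expect_equal(rep$aa, unname(fdx_ref))   # round trip through extraction,
                                            # assembly, frame call, trimming
  })
})
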