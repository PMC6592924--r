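test_that("reference generation is deterministic with distinct regions", {
  r1 <- simulate_references(5, seed = 202)
  r2 <- simulate_references(5, seed = 202)
  expect_identical(r1, r2)
  r3 <- simulate_references(5, seed = 203)
  expect_false(identical(r1$seq, r3$seq))
  # planted variable regions are pairwise distinct
  anc <- fixture_anchor()
  vars <- substr(r1$seq, 61 + nchar(anc$pattern), 60 + nchar(anc$pattern) + 33)
  expect_equal(anyDuplicated(vars), 0)
  # extractor on the references recovers exactly the planted 33-mers
  tt <- tally_tags(read_set(r1$id, r1$seq), anc)
  expect_setequal(tt$tag, vars)
  expect_true(all(tt$count_sample == 1))
  # taxonomy is nested: consecutive pairs share a genus
  g <- vapply(r1$taxonomy, function(t) parse_taxonomy(t)[["genus"]], "",
              USE.NAMES = FALSE)
  expect_equal(g[1], g[2])
  expect_false(g[2] == g[3])
})

test_that("simulated reads reproduce abundances and are reproducible", {
  refs <- simulate_references(2, seed = 211)
  comm <- synthetic_community(refs, abundance = c(0.5, 0.5),
                              error_rate = 0)
  reads_a <- simulate_reads(comm, 100, seed = 212)
  reads_b <- simulate_reads(comm, 100, seed = 212)
  expect_identical(reads_a, reads_b)
  fq <- withr::local_tempfile(fileext = ".fastq")
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  write_seqs(reads_a, fq)
  write_seqs(reads_b, fq2)
  expect_identical(readLines(fq), readLines(fq2))
  # binomial bound on the recovered 50/50 profile
  n <- 4000
  reads <- simulate_reads(comm, n, seed = 213)
  tt <- tally_tags(reads, fixture_anchor(), sample_id = "s")
  db <- build_reference_db(refs, fixture_anchor())
  tt <- annotate_table(tt, db)
  pr <- profile(tt, "s", level = "species")
  shares <- pr$abundance[grep("s__Species", names(pr$abundance))]
  m <- sum(tag_totals(tt))
  bound <- 3 * sqrt(0.5 * 0.5 / m)
  expect_equal(length(shares), 2)
  for (s in shares) expect_lt(abs(s - 0.5), bound)
  # single-taxon community recovers a pure profile
  solo <- synthetic_community(refs[1, , drop = FALSE], abundance = 1,
                              error_rate = 0)
  tts <- annotate_table(tally_tags(simulate_reads(solo, 300, seed = 214),
                                   fixture_anchor(), sample_id = "s"), db)
  expect_equal(unname(profile(tts, "s", "species")$abundance[
    grep("Species_1$", names(profile(tts, "s", "species")$abundance))]), 1)
})

test_that("read qualities encode the substitution error model", {
  refs <- simulate_references(1, seed = 221)
  noisy <- synthetic_community(refs, abundance = 1, error_rate = 0.01)
  rs <- simulate_reads(noisy, 50, seed = 222)
  expect_true(all(phred_scores(rs$qual[1]) == 20L))
  clean <- synthetic_community(refs, abundance = 1, error_rate = 0)
  rs0 <- simulate_reads(clean, 10, seed = 223)
  expect_true(all(phred_scores(rs0$qual[1]) == 40L))
  # error-free reads are exact substrings of a reference (either strand)
  for (i in 1:10) {
    hit <- grepl(rs0$seq[i], refs$seq, fixed = TRUE) ||
      grepl(reverse_complement(rs0$seq[i]), refs$seq, fixed = TRUE)
    expect_true(hit)
  }
})

test_that("degenerate sorts behave as designed", {
  refs <- simulate_references(4, seed = 231)
  comm <- synthetic_community(refs, abundance = c(0.25, 0.25, 0.25, 0.25),
                              error_rate = 0)
  reads <- simulate_reads(comm, 600, seed = 232)
  anc <- fixture_anchor()
  db <- build_reference_db(refs, anc)
  probe <- substr(db$tags[match("synthref_001", vapply(db$refs, function(r)
    r$id[1], ""))], 1, 17)
  # capture 1, carry-over 0: only probe-matching reads survive
  sorted <- simulate_sort(reads, sort_model(probe, 1, 0), seed = 233)
  tt <- annotate_table(tally_tags(sorted, anc, sample_id = "post"), db)
  expect_equal(purity(profile(tt, "post", "species"), "Species_1"), 1.0)
  expect_true(all(startsWith(tt$tag, probe)))
  # capture == carry-over: no selection beyond subsampling
  unsel <- simulate_sort(reads, sort_model(probe, 0.5, 0.5), seed = 234)
  expect_gt(nrow(unsel), 0)
  frac <- nrow(unsel) / nrow(reads)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(reads)))
  # determinism
  s1 <- simulate_sort(reads, sort_model(probe, 0.8, 0.1), seed = 235)
  s2 <- simulate_sort(reads, sort_model(probe, 0.8, 0.1), seed = 235)
  expect_identical(s1, s2)
})

test_that("constructed image pairs hit their overlap exactly", {
  im1 <- simulate_images(overlap_fraction = 1, seed = 241)
  expect_equal(manders_mcc(im1$ch1, im1$ch2, 10, 10)$M1, 1.0)
  im0 <- simulate_images(overlap_fraction = 0, seed = 242)
  expect_equal(manders_mcc(im0$ch1, im0$ch2, 10, 10)$M1, 0.0)
  im5 <- simulate_images(overlap_fraction = 0.5, seed = 243)
  m <- manders_mcc(im5$ch1, im5$ch2, 10, 10)
  expect_equal(m$M1, 0.5)
  expect_equal(m$M2, 0.5)
  # exact construction, not sampling: masks intersect at the requested size
  a <- segment_threshold(im5$ch1, 10)
  b <- segment_threshold(im5$ch2, 10)
  expect_equal(sum(a & b) / sum(a), 0.5)
  expect_error(simulate_images(overlap_fraction = 0.123, seed = 1),
               "integer")
  expect_identical(simulate_images(overlap_fraction = 0.5, seed = 7),
                   simulate_images(overlap_fraction = 0.5, seed = 7))
})

test_that("the fixture writer emits a complete readable demo set", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_set(dir, seed = 3, n_taxa = 6, n_reads = 400)
  expect_true(all(file.exists(paths)))
  tt <- read_tag_table(paths[["tags"]])
  expect_true(all(nchar(tt$tag) == 33))
  probe <- read_probe_table(paths[["probe"]])
  expect_equal(probe$length, 17L)
  expect_true(startsWith(probe$source_tag, probe$sequence))
  img <- read_channel_tiff(paths[["ch1"]])
  expect_true(sum(img$intensity > 10) > 0)
  refs <- read_reference_set(paths[["refs"]])
  expect_equal(nrow(refs), 6)
})
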