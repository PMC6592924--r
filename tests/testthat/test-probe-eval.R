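test_that("match_probe finds planted sites in either orientation", {
  probe <- "GGATCCGTAC"
  withr::local_seed(83)
  subject <- paste0(rand_dna(12), probe, rand_dna(12))
  hit <- match_probe(probe, subject)
  expect_equal(hit$position, 12L)
  expect_equal(hit$orientation, "forward")
  expect_equal(hit$mismatches, 0L)
  # reverse-complement-only site
  subject_rc <- paste0(rand_dna(9), oracle_revcomp(probe), rand_dna(9))
  hit_rc <- match_probe(probe, subject_rc)
  expect_equal(hit_rc$orientation, "revcomp")
  expect_equal(hit_rc$position, 9L)
  # restricted orientations
  expect_equal(nrow(match_probe(probe, subject_rc,
                                orientations = "forward")), 0)
  # short subject: no hit, no error
  expect_equal(nrow(match_probe(probe, "ACGT")), 0)
})

test_that("two-substitution sites are found at max_mm 2 with exact count", {
  withr::local_seed(89)
  for (i in 1:10) {
    probe <- rand_dna(17)
    site <- probe
    pos <- sample(17, 2)
    for (p in pos) {
      substr(site, p, p) <- setdiff(c("A", "C", "G", "T"),
                                    substr(site, p, p))[1]
    }
    subject <- paste0(rand_dna(20), site, rand_dna(20))
    got <- match_probe(probe, subject, max_mm = 2)
    want <- oracle_match(probe, subject, max_mm = 2)
    expect_equal(got$position, want$position)
    expect_equal(got$mismatches, want$mismatches)
    expect_true(2L %in% got$mismatches)
  }
})

test_that("hit counts are monotone in the mismatch allowance", {
  withr::local_seed(97)
  for (i in 1:20) {
    probe <- rand_dna(sample(10:20, 1))
    subject <- rand_dna(120)
    n <- vapply(0:2, function(mm)
      nrow(match_probe(probe, subject, max_mm = mm)), integer(1))
    expect_true(all(diff(n) >= 0))
  }
})

eval_table <- function(tags, counts, target_flag) {
  tag_table(tag = tags,
            annotation = ifelse(target_flag, "g__Target", "g__Other"),
            counts = list(s1 = counts))
}

test_that("coverage and specificity follow the declared formulas", {
  withr::local_seed(101)
  probe <- rand_dna(17)
  embed <- function() paste0(probe, rand_dna(16))
  # all 10 targets carry the site, no non-target hits
  tt <- eval_table(replicate(10, embed()), rep(1L, 10), rep(TRUE, 10))
  rep1 <- evaluate_probe(probe, tt, "Target")
  expect_equal(rep1$coverage, 1.0)
  expect_equal(rep1$specificity, 1.0)
  # 8/10 targets hit plus 2 non-target hits (hand-counted)
  tags <- c(replicate(8, embed()), replicate(2, rand_dna(33)),
            replicate(2, embed()), replicate(3, rand_dna(33)))
  tt2 <- eval_table(tags, rep(1L, 15), rep(c(TRUE, FALSE), c(10, 5)))
  rep2 <- evaluate_probe(probe, tt2, "Target")
  expect_equal(rep2$n_target_subjects, 10)
  expect_equal(rep2$n_target_hit, 8)
  expect_equal(rep2$n_nontarget_hit, 2)
  expect_equal(rep2$coverage, 0.8)
  expect_equal(rep2$specificity, 0.8)
  expect_equal(sum(rep2$mismatch_histogram), nrow(rep2$hits))
  # probe hitting only non-targets
  tt3 <- eval_table(c(rand_dna(33), embed()), c(1L, 1L), c(TRUE, FALSE))
  rep3 <- evaluate_probe(probe, tt3, "Target")
  expect_equal(rep3$coverage, 0.0)
  expect_equal(rep3$specificity, 0.0)
  # absent target: explicit NA, not zero
  rep4 <- evaluate_probe(probe, tt3, "Missing")
  expect_equal(rep4$n_target_subjects, 0)
  expect_true(is.na(rep4$coverage))
  # no hits at all: specificity NA, never 0/0
  tt5 <- eval_table(replicate(3, rand_dna(33)), rep(1L, 3), rep(TRUE, 3))
  expect_true(is.na(evaluate_probe(probe, tt5, "Target")$specificity))
})

test_that("count weighting separates read-level from OTU-level coverage", {
  withr::local_seed(103)
  probe <- rand_dna(17)
  tt <- eval_table(c(paste0(probe, rand_dna(16)), rand_dna(33)),
                   c(90L, 10L), c(TRUE, TRUE))
  rep <- evaluate_probe(probe, tt, "Target")
  expect_equal(rep$coverage, 0.5)            # 1 of 2 OTUs
  expect_equal(rep$weighted_coverage, 0.9)   # 90 of 100 reads
})

test_that("evaluation against a reference set finds binding sites anywhere", {
  withr::local_seed(107)
  probe <- rand_dna(17)
  refs <- data.frame(
    id = c("t1", "t2", "n1"),
    seq = c(paste0(rand_dna(40), probe, rand_dna(40)),
            paste0(rand_dna(70), oracle_revcomp(probe), rand_dna(10)),
            rand_dna(100)),
    taxonomy = c("g__Target", "g__Target", "g__Other"),
    stringsAsFactors = FALSE)
  rep <- evaluate_probe(probe, refs, "Target")
  expect_equal(rep$coverage, 1.0)
  expect_equal(rep$specificity, 1.0)
  expect_setequal(rep$hits$orientation, c("forward", "revcomp"))
  # report serialisation
  js <- withr::local_tempfile(fileext = ".json")
  hits <- withr::local_tempfile(fileext = ".tsv")
  write_specificity_report(rep, js, hits_tsv = hits)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$coverage, 1.0)
  expect_equal(nrow(read_tsv(hits)), nrow(rep$hits))
})

test_that("probe-vs-full-tag fractions obey the prefix relation", {
  withr::local_seed(109)
  full_tag <- rand_dna(33)
  probe <- substr(full_tag, 1, 17)
  # every count carries the full tag
  t1 <- tag_table(tag = full_tag, counts = list(s = 100L))
  r1 <- compare_probe_vs_tag(t1, probe, full_tag)
  expect_equal(r1$frac_matching_probe, 1.0)
  expect_equal(r1$frac_matching_tag, 1.0)
  expect_equal(r1$co_sorted_tags, character(0))
  # 90 counts full tag + 10 counts sharing only the 17 nt prefix
  other <- paste0(probe, rand_dna(16))
  t2 <- tag_table(tag = c(full_tag, other), counts = list(s = c(90L, 10L)))
  r2 <- compare_probe_vs_tag(t2, probe, full_tag)
  expect_equal(r2$frac_matching_probe, 1.0)
  expect_equal(r2$frac_matching_tag, 0.9)
  expect_equal(r2$co_sorted_tags, other)
  # no tag contains the probe
  t3 <- tag_table(tag = rand_dna(33), counts = list(s = 5L))
  r3 <- compare_probe_vs_tag(t3, probe, full_tag)
  expect_equal(r3$frac_matching_probe, 0.0)
  expect_equal(r3$frac_matching_tag, 0.0)
  expect_error(compare_probe_vs_tag(t1, "TTTTT", full_tag), "prefix")
})

test_that("probe fraction dominates tag fraction on random tables", {
  withr::local_seed(113)
  for (i in 1:25) {
    full_tag <- rand_dna(33)
    probe <- substr(full_tag, 1, 17)
    n <- sample(1:12, 1)
    tags <- unique(c(full_tag,
                     replicate(n, if (runif(1) < 0.4)
                       paste0(probe, rand_dna(16)) else rand_dna(33))))
    tt <- tag_table(tag = tags,
                    counts = list(s = sample(0:50, length(tags),
                                             replace = TRUE)))
    r <- compare_probe_vs_tag(tt, probe, full_tag)
    if (!is.na(r$frac_matching_probe)) {
      expect_gte(r$frac_matching_probe, r$frac_matching_tag)
    }
  }
})
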