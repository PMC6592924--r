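tax <- function(...) {
  labels <- c(...)
  paste(paste0(c("k__", "p__", "c__", "o__", "f__", "g__", "s__")[
    seq_along(labels)], labels), collapse = "; ")
}

test_that("taxonomy strings parse, validate and format", {
  p <- parse_taxonomy("k__Bacteria; p__Proteobacteria; c__; o__; f__; g__; s__")
  expect_equal(unname(p[1:2]), c("Bacteria", "Proteobacteria"))
  expect_equal(unname(p[3]), "")
  expect_equal(format_taxonomy(p), "k__Bacteria; p__Proteobacteria")
  expect_equal(parse_taxonomy(format_taxonomy(p)), p)
  expect_equal(unname(parse_taxonomy("Bacteria; Firmicutes")[2]),
               "Firmicutes")  # prefixes optional
  expect_error(parse_taxonomy("k__; p__Proteobacteria"), "empty rank")
  expect_equal(format_taxonomy(parse_taxonomy("")), "")
})

test_that("LCA keeps exactly the agreed rank prefix", {
  a <- parse_taxonomy(tax("B", "P1", "C1", "O1", "F1", "G1", "S1"))
  b <- parse_taxonomy(tax("B", "P1", "C1", "O1", "F1", "G1", "S2"))
  d <- parse_taxonomy(tax("B", "P2", "C9", "O9", "F9", "G9", "S9"))
  # rank-wise oracle: first disagreement between a and b is at species
  expect_equal(format_taxonomy(taxonomy_lca(list(a, b))),
               tax("B", "P1", "C1", "O1", "F1", "G1"))
  expect_equal(taxonomy_lca(list(a, a)), a)
  expect_equal(format_taxonomy(taxonomy_lca(list(a, b, d))), "k__B")
  # LCA is a rank-prefix of every input
  lca <- taxonomy_lca(list(a, b, d))
  for (p in list(a, b, d)) {
    filled <- which(nzchar(lca))
    expect_equal(lca[filled], p[filled])
  }
})

test_that("reference db construction extracts and groups tags", {
  pat <- "GGATCCTTAGGCAT"
  anc <- anchor(pat)
  withr::local_seed(61)
  v <- replicate(3, rand_dna(33))
  mk <- function(var) paste0(rand_dna(20), pat, var, rand_dna(50))
  refs <- data.frame(
    id = c("rA", "rB", "rC", "rNoAnchor"),
    seq = c(mk(v[1]), mk(v[2]), mk(v[2]), rand_dna(90)),
    taxonomy = c(tax("B", "P1", "C1", "O1", "F1", "G1", "S1"),
                 tax("B", "P1", "C1", "O1", "F1", "G2", "S2"),
                 tax("B", "P1", "C1", "O1", "F1", "G2", "S3"),
                 tax("B", "P9", "C9", "O9", "F9", "G9", "S9")),
    stringsAsFactors = FALSE)
  db <- build_reference_db(refs, anc)
  expect_equal(sort(db$tags), sort(v[1:2]))
  expect_equal(nrow(db$refs[[match(v[2], db$tags)]]), 2)
  expect_equal(db$provenance$n_without_anchor, 1)
  expect_equal(db$provenance$skipped_ids, "rNoAnchor")
  expect_error(build_reference_db(refs[0, ], anc), "empty")

  # shared tag across two species of one genus annotates to the genus
  expect_equal(annotate_tag(v[2], db),
               tax("B", "P1", "C1", "O1", "F1", "G2"))
  # unique tag recovers the full source path
  expect_equal(annotate_tag(v[1], db),
               tax("B", "P1", "C1", "O1", "F1", "G1", "S1"))
  # no match within max_mm: unannotated
  expect_true(is.na(annotate_tag(v[3], db, max_mm = 0)))
  expect_error(annotate_tag("ACGT", db), "length")

  # serialisation round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reference_db(db, path)
  db2 <- read_reference_db(path)
  expect_equal(db2$tags, db$tags)
  expect_equal(db2$tag_len, db$tag_len)
  expect_equal(annotate_tag(v[2], db2), annotate_tag(v[2], db))
})

test_that("near-matching pools equally-near references conservatively", {
  pat <- "GGATCCTTAGGCAT"
  anc <- anchor(pat)
  withr::local_seed(67)
  base <- rand_dna(33)
  var1 <- base
  var2 <- base
  substr(var2, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(base, 5, 5))[1]
  mk <- function(var) paste0(rand_dna(20), pat, var, rand_dna(50))
  refs <- data.frame(
    id = c("r1", "r2"),
    seq = c(mk(var1), mk(var2)),
    taxonomy = c(tax("B", "P1", "C1", "O1", "F1", "G1", "S1"),
                 tax("B", "P1", "C1", "O1", "F1", "G1", "S2")),
    stringsAsFactors = FALSE)
  db <- build_reference_db(refs, anc)
  # query equidistant (1 mm) from both stored tags -> LCA over the union
  query <- base
  substr(query, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                 c(substr(var1, 5, 5),
                                   substr(var2, 5, 5)))[1]
  expect_true(is.na(annotate_tag(query, db, max_mm = 0)))
  expect_equal(annotate_tag(query, db, max_mm = 1),
               tax("B", "P1", "C1", "O1", "F1", "G1"))
})

test_that("raising the mismatch allowance never unannotates a tag", {
  pat <- "GGATCCTTAGGCAT"
  anc <- anchor(pat)
  withr::local_seed(71)
  mk <- function(var) paste0(rand_dna(15), pat, var, rand_dna(40))
  vars <- replicate(6, rand_dna(33))
  refs <- data.frame(id = sprintf("r%d", 1:6),
                     seq = vapply(vars, mk, ""),
                     taxonomy = vapply(1:6, function(i)
                       tax("B", paste0("P", i), paste0("C", i),
                           paste0("O", i), paste0("F", i), paste0("G", i),
                           paste0("S", i)), ""),
                     stringsAsFactors = FALSE)
  db <- build_reference_db(refs, anc)
  for (i in 1:20) {
    q <- rand_dna(33)
    ann <- vapply(0:2, function(mm) annotate_tag(q, db, max_mm = mm), "")
    annotated <- !is.na(ann)
    expect_true(all(diff(annotated) >= 0))
  }
  # db recovers its own input paths exactly for unique tags
  for (j in 1:6) {
    expect_equal(annotate_tag(vars[j], db), refs$taxonomy[j])
  }
})

test_that("reference sets load from FASTA headers or sidecar TSV", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(paste0(">ref1 ", tax("B", "P1")), "ACGTACGTAA",
               ">ref2 k__B", "TTGGCCAATT"), fa)
  refs <- read_reference_set(fa)
  expect_equal(refs$id, c("ref1", "ref2"))
  expect_equal(refs$taxonomy[1], tax("B", "P1"))

  side <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ttaxonomy",
               paste0("ref1\t", tax("X")), paste0("ref2\t", tax("Y"))),
             side)
  refs2 <- read_reference_set(fa, taxonomy_tsv = side)
  expect_equal(refs2$taxonomy, c(tax("X"), tax("Y")))
})
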