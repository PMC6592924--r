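# 15 nt non-degenerate anchor planted in every synthetic reference.
# Chance occurrence in random flanking sequence is < 4^-15 per position.
FIXTURE_ANCHOR_PATTERN <- "ATCGGCTTCAAGCGT"

#' The fixture anchor used by the synthetic reference generator
#'
#' A 15 nt non-degenerate anchor planted immediately 5' of the variable
#' region in every synthetic reference. Real datasets require a
#' user-supplied anchor for the conserved block flanking the targeted
#' hypervariable region; no parity with any external recognition profile
#' is claimed.
#'
#' @param max_mismatches Mismatch tolerance when locating the anchor in
#'   reads (default 1, so reads carrying a single sequencing error inside
#'   the anchor are still recognised).
#' @return An [anchor()].
#' @export
fixture_anchor <- function(max_mismatches = 1L) {
  anchor(FIXTURE_ANCHOR_PATTERN, region_label = "V6",
         max_mismatches = max_mismatches, tag_offset = 0L)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

count_anchor_sites <- function(seq, pattern) {
  Biostrings::countPattern(pattern, Biostrings::DNAString(seq)) +
    Biostrings::countPattern(reverse_complement(pattern),
                             Biostrings::DNAString(seq))
}

#' Generate an annotated synthetic reference set
#'
#' Each reference is `conserved 5' block + fixture anchor + unique 33 nt
#' variable region + conserved 3' block`, with a nested 7-rank synthetic
#' taxonomy (species unique per reference, genera shared by consecutive
#' pairs, and coarser ranks in progressively larger blocks). References
#' are rejection-sampled so the anchor occurs exactly once per reference
#' (either strand). Deterministic per seed.
#'
#' @param n_taxa Number of references (>= 1).
#' @param seed Integer seed.
#' @param tag_len Variable-region length (default 33).
#' @param flank5_len,flank3_len Conserved block lengths (defaults 60; the
#'   3' block leaves room for the 81 nt representative window).
#' @return Data frame with columns `id`, `seq`, `taxonomy`.
#' @export
simulate_references <- function(n_taxa, seed, tag_len = 33L,
                                flank5_len = 60L, flank3_len = 60L) {
  stopifnot(n_taxa >= 1)
  withr::with_seed(as.integer(seed), {
    pat <- FIXTURE_ANCHOR_PATTERN
    repeat {
      flank5 <- random_dna(flank5_len)
      flank3 <- random_dna(flank3_len)
      if (count_anchor_sites(paste0(flank5, "NN", flank3), pat) == 0) break
    }
    vars <- character(0)
    seqs <- character(0)
    while (length(vars) < n_taxa) {
      v <- random_dna(tag_len)
      if (v %in% vars) next
      s <- paste0(flank5, pat, v, flank3)
      if (count_anchor_sites(s, pat) != 1) next
      vars <- c(vars, v)
      seqs <- c(seqs, s)
    }
    i <- seq_len(n_taxa)
    tax <- sprintf(paste0("k__SimBacteria; p__Phylum_%d; c__Class_%d; ",
                          "o__Order_%d; f__Family_%d; g__Genus_%d; ",
                          "s__Species_%d"),
                   (i - 1) %/% 16 + 1, (i - 1) %/% 8 + 1,
                   (i - 1) %/% 4 + 1, (i - 1) %/% 2 + 1,
                   (i - 1) %/% 2 + 1, i)
    data.frame(id = sprintf("synthref_%03d", i), seq = seqs,
               taxonomy = tax, stringsAsFactors = FALSE)
  })
}

#' Define a synthetic community over a reference set
#'
#' @param refs Reference set from [simulate_references()].
#' @param abundance True relative abundances (recycled/normalised to sum
#'   to 1). Default: a geometric rank-abundance series with ratio 0.7,
#'   the long-tailed shape typical of activated-sludge communities.
#' @param read_len Read length for simulation (default 120 nt, a
#'   post-trimming Illumina-scale length that can span anchor + tag).
#' @param error_rate Per-base substitution error rate (default 0.001,
#'   i.e. Q30-scale post-QC reads).
#' @return A `synthetic_community`.
#' @export
synthetic_community <- function(refs, abundance = NULL, read_len = 120L,
                                error_rate = 0.001) {
  n <- nrow(refs)
  if (is.null(abundance)) abundance <- 0.7^(seq_len(n) - 1)
  abundance <- rep_len(as.numeric(abundance), n)
  if (any(abundance < 0) || sum(abundance) <= 0) {
    stop("abundances must be non-negative with positive sum")
  }
  abundance <- abundance / sum(abundance)
  stopifnot(error_rate >= 0, error_rate < 1)
  structure(list(refs = refs, abundance = abundance,
                 read_len = as.integer(read_len),
                 error_rate = error_rate),
            class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf(
    "synthetic_community: %d taxa, read length %d nt, error rate %g\n",
    nrow(x$refs), x$read_len, x$error_rate))
  invisible(x)
}

apply_substitutions <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  b <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(b)) < error_rate)
  for (i in hit) {
    b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  }
  paste(b, collapse = "")
}

#' Simulate error-bearing shotgun reads from a community
#'
#' Reads are drawn from references with probability equal to their true
#' abundance, start positions uniform over the reference, strands
#' equiprobable, and substitution errors applied at the community's error
#' rate. Qualities are constant at the Phred score implied by the error
#' rate (capped at Q40). Deterministic per seed.
#'
#' @param comm A [synthetic_community()].
#' @param n_reads Number of reads (>= 1).
#' @param seed Integer seed.
#' @return A `read_set` with qualities.
#' @export
simulate_reads <- function(comm, n_reads, seed) {
  stopifnot(n_reads >= 1)
  withr::with_seed(as.integer(seed), {
    q <- if (comm$error_rate <= 0) 40L else {
      min(40L, as.integer(round(-10 * log10(comm$error_rate))))
    }
    ref_ix <- sample.int(nrow(comm$refs), n_reads, replace = TRUE,
                         prob = comm$abundance)
    id <- seq <- qual <- character(n_reads)
    for (i in seq_len(n_reads)) {
      ref <- comm$refs$seq[ref_ix[i]]
      L <- nchar(ref)
      len <- min(comm$read_len, L)
      start <- sample.int(L - len + 1L, 1)
      frag <- substr(ref, start, start + len - 1L)
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") frag <- reverse_complement(frag)
      frag <- apply_substitutions(frag, comm$error_rate)
      id[i] <- sprintf("read%06d|%s|%s", i, comm$refs$id[ref_ix[i]], strand)
      seq[i] <- frag
      qual[i] <- phred_string(rep(q, len))
    }
    read_set(id, seq, qual)
  })
}

#' Probe-based sort model
#'
#' Emulates FISH-FACS enrichment at the read level: reads whose ribotag
#' starts with the probe sequence are captured with probability `capture`;
#' all other reads leak through with probability `carry_over`. The
#' defaults reproduce the observed single-round sort behaviour (capture
#' close to 1 and a carry-over that takes a ~1.15% target to a ~94.5%
#' post-sort share).
#'
#' @param probe_seq Probe sequence (5' prefix rule).
#' @param capture Capture probability for probe-matching reads
#'   (default 1).
#' @param carry_over Carry-over probability for non-matching reads
#'   (default 6.7e-4).
#' @return A `sort_model`.
#' @export
sort_model <- function(probe_seq, capture = 1, carry_over = 6.7e-4) {
  stopifnot(capture >= 0, capture <= 1, carry_over >= 0, carry_over <= 1)
  structure(list(probe_seq = toupper(probe_seq), capture = capture,
                 carry_over = carry_over),
            class = "sort_model")
}

#' Simulate probe-based cell sorting over reads
#'
#' @param rs A `read_set`.
#' @param model A [sort_model()].
#' @param seed Integer seed.
#' @param anc Anchor for tag recognition (default [fixture_anchor()]).
#' @param tag_len Tag length (default 33).
#' @return The retained `read_set`.
#' @export
simulate_sort <- function(rs, model, seed, anc = fixture_anchor(),
                          tag_len = 33L) {
  if (nrow(rs) == 0) return(rs)
  hits <- scan_anchor_set(rs$seq, anc)
  matches <- logical(nrow(rs))
  for (i in which(!is.na(hits$position))) {
    rt <- extract_tag(rs$seq[i],
                      list(position = hits$position[i],
                           strand = hits$strand[i]),
                      anc, tag_len = tag_len, rep_len = tag_len)
    matches[i] <- !is.null(rt) && startsWith(rt$tag, model$probe_seq)
  }
  withr::with_seed(as.integer(seed), {
    p <- ifelse(matches, model$capture, model$carry_over)
    keep <- stats::runif(nrow(rs)) < p
  })
  out <- rs[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  out
}

#' Construct a two-channel image pair with known overlap
#'
#' Builds two channels whose above-threshold voxel sets have an exactly
#' constructed intersection: `|A intersect B| / |A| == overlap_fraction`.
#' Both sets have `n_fg` voxels at a uniform foreground intensity, so the
#' thresholded Manders coefficients equal the overlap fraction by
#' construction.
#'
#' @param shape Image dimensions (2-D or 3-D; default `c(32, 32)`).
#' @param overlap_fraction Desired overlap in [0, 1];
#'   `overlap_fraction * n_fg` must be an integer.
#' @param seed Integer seed (voxel placement).
#' @param n_fg Foreground voxels per channel (default 100).
#' @param fg_intensity Foreground intensity (default 100; background 0).
#' @return List of two `channel_image`s.
#' @export
simulate_images <- function(shape = c(32L, 32L), overlap_fraction, seed,
                            n_fg = 100L, fg_intensity = 100) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  k <- overlap_fraction * n_fg
  if (abs(k - round(k)) > 1e-8) {
    stop("overlap_fraction * n_fg must be an integer for exact construction")
  }
  k <- as.integer(round(k))
  total <- prod(shape)
  if (total < 2L * n_fg) stop("image too small for the requested foreground")
  withr::with_seed(as.integer(seed), {
    vox <- sample.int(total, 2L * n_fg - k)
  })
  set1 <- vox[seq_len(n_fg)]
  set2 <- c(set1[seq_len(k)], vox[n_fg + seq_len(n_fg - k)])
  mk <- function(ix, label) {
    arr <- array(0, dim = shape)
    arr[ix] <- fg_intensity
    channel_image(arr, channel = label)
  }
  list(ch1 = mk(set1, "Cy5"), ch2 = mk(set2, "Cy3"))
}

#' Write a complete synthetic demo dataset
#'
#' Generates references, a community, reads, a sorted sample, a designed
#' probe and an image pair, and writes them in the standard formats under
#' one directory. Used by the `simulate` CLI subcommand.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_taxa,n_reads Community size parameters.
#' @return Invisibly, named character vector of the written paths.
#' @export
write_fixture_set <- function(dir, seed = 1L, n_taxa = 12L,
                              n_reads = 2000L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  refs <- simulate_references(n_taxa, seed)
  comm <- synthetic_community(refs)
  reads <- simulate_reads(comm, n_reads, seed + 1L)
  anc <- fixture_anchor()
  tt <- tally_tags(quality_trim(reads), anc, sample_id = "pre")
  db <- build_reference_db(refs, anc, name = "synthetic")
  tt <- annotate_table(tt, db)
  probe <- design_probe(tt, "Genus_1", stem = "Sim1029")
  sorted <- simulate_sort(reads, sort_model(probe$sequence), seed + 2L)
  imgs <- simulate_images(overlap_fraction = 0.5, seed = seed + 3L)
  paths <- c(
    refs = file.path(dir, "references.fasta"),
    reads = file.path(dir, "reads.fastq"),
    sorted = file.path(dir, "sorted.fastq"),
    tags = file.path(dir, "tags.tsv"),
    db = file.path(dir, "reference_db.tsv"),
    probe = file.path(dir, "probes.tsv"),
    ch1 = file.path(dir, "channel1.tiff"),
    ch2 = file.path(dir, "channel2.tiff"))
  ref_rs <- read_set(paste(refs$id, refs$taxonomy), refs$seq)
  write_seqs(ref_rs, paths[["refs"]], format = "fasta")
  write_seqs(reads, paths[["reads"]], format = "fastq")
  write_seqs(sorted, paths[["sorted"]], format = "fastq")
  write_tag_table(tt, paths[["tags"]])
  write_reference_db(db, paths[["db"]])
  write_probe_table(probe, paths[["probe"]])
  write_channel_tiff(imgs$ch1, paths[["ch1"]])
  write_channel_tiff(imgs$ch2, paths[["ch2"]])
  invisible(paths)
}
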