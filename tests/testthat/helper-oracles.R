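# Independent brute-force oracles. These deliberately avoid Biostrings and
# every code path of the package: plain character loops only.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

oracle_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  sum(av != bv)
}

# Every window of `subject` within max_mm of `probe`, forward and
# reverse-complement orientations; N in the subject counts as a mismatch
# against any probe base.
oracle_match <- function(probe, subject, max_mm = 0,
                         orientations = c("forward", "revcomp")) {
  out <- NULL
  for (orient in orientations) {
    pat <- if (orient == "forward") probe else oracle_revcomp(probe)
    np <- nchar(pat)
    for (start in seq_len(max(0, nchar(subject) - np + 1))) {
      mm <- oracle_hamming(pat, substr(subject, start, start + np - 1))
      if (mm <= max_mm) {
        out <- rbind(out, data.frame(position = start - 1L,
                                     orientation = orient,
                                     mismatches = mm,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(position = integer(0), orientation = character(0),
                      mismatches = integer(0)))
  }
  out[order(out$mismatches, out$position), , drop = FALSE]
}

IUPAC_SETS <- c(A = "A", C = "C", G = "G", T = "T", M = "AC", R = "AG",
                W = "AT", S = "CG", Y = "CT", K = "GT", V = "ACG",
                H = "ACT", D = "AGT", B = "CGT", N = "ACGT")

# Brute-force IUPAC-aware anchor scan over both strands of a read; N in
# the read never matches.
oracle_find_anchor <- function(seq, pattern, max_mm) {
  pv <- strsplit(pattern, "")[[1]]
  scan <- function(subject, strand) {
    out <- NULL
    for (start in seq_len(max(0, nchar(subject) - length(pv) + 1))) {
      w <- strsplit(substr(subject, start, start + length(pv) - 1),
                    "")[[1]]
      mm <- sum(!mapply(function(p, b) {
        b != "N" && grepl(b, IUPAC_SETS[[p]], fixed = TRUE)
      }, pv, w))
      if (mm <= max_mm) {
        out <- rbind(out, data.frame(position = start - 1L, strand = strand,
                                     mismatches = mm,
                                     stringsAsFactors = FALSE))
      }
    }
    out
  }
  out <- rbind(scan(seq, "+"), scan(oracle_revcomp(seq), "-"))
  if (is.null(out)) {
    return(data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  out <- out[order(out$mismatches, out$position, out$strand != "+"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Table 1 probe/ribotag sequences used by the worked examples.
TBL_EUB338 <- "GCTGCCTCCCGTAGGAGT"
TBL_NON338 <- "ACTCCTACGGGAGGCAGC"
TBL_TAGS <- c(Thau1029 = "GTGTTCTGGCTCCCGAAGGCACCCTCGCCTCTC",
              Unk1029 = "TGCTTCGCGTCTCCGAAGAGCCGACCACCTTTC",
              Halia1029 = "TCTCACTCGCTCCCGAAGGCACCCCGACATCTC")
TBL_PROBES17 <- c(Thau1029 = "GTGTTCTGGCTCCCGAA",
                  Unk1029 = "TGCTTCGCGTCTCCGAA",
                  Halia1029 = "TCTCACTCGCTCCCGAA")
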