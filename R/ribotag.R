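#' Conserved-anchor definition for tag extraction
#'
#' An anchor is a short conserved block adjacent to a 16S hypervariable
#' region; the fixed-length ribotag starts `tag_offset` nucleotides after
#' the anchor's 3' end. The pattern may contain IUPAC degeneracy codes;
#' `N` in a read never matches any pattern position.
#'
#' @param pattern IUPAC nucleotide pattern, length >= 8.
#' @param region_label Label of the adjacent hypervariable region
#'   (default `"V6"`).
#' @param max_mismatches Maximum Hamming mismatches tolerated when locating
#'   the anchor (0--2, default 0).
#' @param tag_offset Distance in nt from the anchor's 3' end to the tag
#'   start (default 0).
#' @return An `anchor` object.
#' @seealso [fixture_anchor()] for the anchor used by the synthetic
#'   reference generator.
#' @export
anchor <- function(pattern, region_label = "V6", max_mismatches = 0L,
                   tag_offset = 0L) {
  pattern <- toupper(pattern)
  if (nchar(pattern) < 8) stop("anchor pattern must be at least 8 nt")
  if (grepl(paste0("[^", paste(names(Biostrings::IUPAC_CODE_MAP),
                               collapse = ""), "]"), pattern)) {
    stop("anchor pattern contains non-IUPAC characters")
  }
  max_mismatches <- as.integer(max_mismatches)
  if (max_mismatches < 0L || max_mismatches > 2L) {
    stop("max_mismatches must be between 0 and 2")
  }
  structure(list(pattern = pattern, region_label = region_label,
                 max_mismatches = max_mismatches,
                 tag_offset = as.integer(tag_offset)),
            class = "anchor")
}

#' @export
print.anchor <- function(x, ...) {
  cat(sprintf("anchor <%s> region %s, max %d mismatch(es), tag offset %d\n",
              x$pattern, x$region_label, x$max_mismatches, x$tag_offset))
  invisible(x)
}

# Hamming mismatches between an IUPAC pattern and a same-length literal
# window. N in the window never matches (it is outside every base set).
iupac_mismatches <- function(pattern, window) {
  p <- strsplit(pattern, "")[[1]]
  w <- strsplit(window, "")[[1]]
  sets <- Biostrings::IUPAC_CODE_MAP[p]
  hits <- mapply(function(set, base) {
    base != "N" && grepl(base, set, fixed = TRUE)
  }, sets, w)
  sum(!hits)
}

#' Locate a conserved anchor in a read
#'
#' Scans both strands of a read for windows within
#' `anchor$max_mismatches` Hamming distance of the anchor pattern.
#' Positions are 0-based starts in the *oriented* read: for `strand
#' == "-"` the position refers to the reverse complement of the read,
#' which is the orientation [extract_tag()] works in.
#'
#' @param seq A single read sequence (character).
#' @param anc An [anchor()].
#' @return Data frame with columns `position`, `strand`, `mismatches`,
#'   sorted by (mismatches, position, strand `+` first). Zero rows when the
#'   anchor is absent.
#' @export
find_anchor <- function(seq, anc) {
  seq <- toupper(seq)
  pat <- Biostrings::DNAString(anc$pattern)
  scan1 <- function(subject_chr, strand) {
    if (nchar(subject_chr) < nchar(anc$pattern)) {
      return(NULL)
    }
    m <- Biostrings::matchPattern(
      pat, Biostrings::DNAString(subject_chr),
      max.mismatch = anc$max_mismatches,
      fixed = c(pattern = FALSE, subject = TRUE))
    # drop windows hanging off either end of the subject
    m <- m[IRanges::start(m) >= 1 &
             IRanges::end(m) <= nchar(subject_chr)]
    if (length(m) == 0) return(NULL)
    st <- IRanges::start(m)
    mm <- vapply(as.character(m), function(w)
      iupac_mismatches(anc$pattern, w), integer(1), USE.NAMES = FALSE)
    data.frame(position = st - 1L, strand = strand, mismatches = mm,
               stringsAsFactors = FALSE)
  }
  hits <- rbind(scan1(seq, "+"), scan1(reverse_complement(seq), "-"))
  if (is.null(hits) || nrow(hits) == 0) {
    return(data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  ord <- order(hits$mismatches, hits$position, hits$strand != "+")
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Extract the fixed-length ribotag at an anchor hit
#'
#' The read is first re-oriented to probe orientation (reverse complemented
#' when the hit is on the `-` strand); the tag is the `tag_len` nt window
#' starting `anc$tag_offset` nt after the anchor's 3' end. A longer
#' representative window of `rep_len` nt sharing the tag's 5' end is also
#' reported when the read extends far enough.
#'
#' @param seq Read sequence the hit was found in.
#' @param hit One row of the data frame returned by [find_anchor()].
#' @param anc The [anchor()] used for the search.
#' @param tag_len Tag length in nt (default 33).
#' @param rep_len Representative length in nt (default 81).
#' @return A list with `tag`, `representative` (may be `NA`), `region`; or
#'   `NULL` when fewer than `tag_len` nt are available after the anchor.
#' @export
extract_tag <- function(seq, hit, anc, tag_len = 33L, rep_len = 81L) {
  seq <- toupper(seq)
  oriented <- if (hit$strand == "-") reverse_complement(seq) else seq
  start <- hit$position + nchar(anc$pattern) + anc$tag_offset + 1L # 1-based
  if (start + tag_len - 1L > nchar(oriented)) {
    return(NULL)
  }
  tag <- substr(oriented, start, start + tag_len - 1L)
  rep <- if (start + rep_len - 1L <= nchar(oriented)) {
    substr(oriented, start, start + rep_len - 1L)
  } else {
    NA_character_
  }
  list(tag = tag, representative = rep, region = anc$region_label)
}

#' Construct an (optionally empty) tag table
#'
#' A tag table is the sample-centric OTU unit: one row per distinct ribotag
#' with its longest observed representative, an annotation slot, and one
#' `count_<sample>` column per sample.
#'
#' @param tag,representative,annotation Character vectors (recycled NA).
#' @param counts Named list of integer count vectors, one per sample.
#' @return A `tag_table` data frame.
#' @export
tag_table <- function(tag = character(0), representative = NA_character_,
                      annotation = NA_character_, counts = list()) {
  tt <- data.frame(tag = tag,
                   representative = rep_len(representative, length(tag)),
                   annotation = rep_len(annotation, length(tag)),
                   stringsAsFactors = FALSE)
  for (s in names(counts)) {
    tt[[paste0("count_", s)]] <- as.integer(counts[[s]])
  }
  if (anyDuplicated(tt$tag)) stop("duplicate tag sequences in tag table")
  class(tt) <- c("tag_table", "data.frame")
  tt
}

#' @export
print.tag_table <- function(x, ...) {
  cat("tag_table:", nrow(x), "OTUs,",
      length(sample_columns(x)), "sample(s)\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6), ...)
  invisible(x)
}

sample_columns <- function(tt) {
  grep("^count_", names(tt), value = TRUE)
}

#' Total tag counts per sample
#'
#' @param tt A `tag_table`.
#' @param sample Sample name; when `NULL`, all samples.
#' @return Named numeric vector of totals.
#' @export
tag_totals <- function(tt, sample = NULL) {
  cols <- sample_columns(tt)
  if (!is.null(sample)) {
    cols <- paste0("count_", sample)
    if (!all(cols %in% names(tt))) stop("no such sample: ", sample)
  }
  out <- vapply(cols, function(cl) sum(tt[[cl]]), numeric(1))
  names(out) <- sub("^count_", "", names(out))
  out
}

#' Tally ribotags across a set of reads
#'
#' Runs anchor detection on every read (both strands), keeps at most one
#' tag per read (fewest mismatches, then leftmost, then `+` strand), and
#' aggregates identical tags into one row each. The representative kept per
#' tag is the longest observed; ties break to the lexicographically
#' smallest.
#'
#' @param rs A `read_set` (quality-trimmed upstream).
#' @param anc An [anchor()].
#' @param sample_id Sample label for the count column.
#' @param tag_len,rep_len Tag/representative lengths (defaults 33/81).
#' @return A [tag_table()] with one `count_<sample_id>` column.
#' @export
tally_tags <- function(rs, anc, sample_id = "sample", tag_len = 33L,
                       rep_len = 81L) {
  tags <- character(0)
  reps <- character(0)
  if (nrow(rs) > 0) {
    hits <- scan_anchor_set(rs$seq, anc)
    for (i in which(!is.na(hits$position))) {
      rt <- extract_tag(rs$seq[i],
                        list(position = hits$position[i],
                             strand = hits$strand[i]),
                        anc, tag_len = tag_len, rep_len = rep_len)
      if (!is.null(rt)) {
        tags <- c(tags, rt$tag)
        reps <- c(reps, rt$representative)
      }
    }
  }
  if (length(tags) == 0) {
    return(tag_table(counts = stats::setNames(list(integer(0)), sample_id)))
  }
  by_tag <- split(reps, tags)
  utags <- names(by_tag)
  urep <- vapply(by_tag, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) return(NA_character_)
    r <- r[nchar(r) == max(nchar(r))]
    min(r)
  }, character(1), USE.NAMES = FALSE)
  cnt <- as.integer(lengths(by_tag))
  tag_table(tag = utags, representative = urep,
            counts = stats::setNames(list(cnt), sample_id))
}

# Vectorised best-hit anchor scan: one row per read, NA position = no hit.
# Best = fewest mismatches, then leftmost (in oriented coordinates), then
# '+' strand.
scan_anchor_set <- function(seqs, anc) {
  n <- length(seqs)
  out <- data.frame(position = rep(NA_integer_, n),
                    strand = rep(NA_character_, n),
                    mismatches = rep(NA_integer_, n))
  pat <- Biostrings::DNAString(anc$pattern)
  fwd <- Biostrings::DNAStringSet(toupper(seqs))
  rev <- Biostrings::reverseComplement(fwd)
  mf <- Biostrings::vmatchPattern(pat, fwd, max.mismatch = anc$max_mismatches,
                                  fixed = c(pattern = FALSE, subject = TRUE))
  mr <- Biostrings::vmatchPattern(pat, rev, max.mismatch = anc$max_mismatches,
                                  fixed = c(pattern = FALSE, subject = TRUE))
  plen <- nchar(anc$pattern)
  widths <- nchar(seqs)
  for (i in seq_len(n)) {
    cand <- NULL
    sf <- IRanges::start(mf[[i]])
    sf <- sf[sf >= 1 & sf + plen - 1L <= widths[i]]
    sr <- IRanges::start(mr[[i]])
    sr <- sr[sr >= 1 & sr + plen - 1L <= widths[i]]
    if (length(sf) + length(sr) == 0) next
    subj_f <- as.character(fwd[[i]])
    subj_r <- as.character(rev[[i]])
    cand <- rbind(
      if (length(sf)) data.frame(position = sf - 1L, strand = "+",
        mismatches = vapply(sf, function(s) iupac_mismatches(
          anc$pattern, substr(subj_f, s, s + plen - 1L)), integer(1))),
      if (length(sr)) data.frame(position = sr - 1L, strand = "-",
        mismatches = vapply(sr, function(s) iupac_mismatches(
          anc$pattern, substr(subj_r, s, s + plen - 1L)), integer(1))))
    best <- cand[order(cand$mismatches, cand$position,
                       cand$strand != "+"), , drop = FALSE][1, ]
    out$position[i] <- best$position
    out$strand[i] <- best$strand
    out$mismatches[i] <- best$mismatches
  }
  out
}

#' Write / read a tag table as TSV
#'
#' Column order is `tag`, `representative`, `annotation`, then the
#' `count_<sample>` columns; round-trips losslessly.
#'
#' @param tt A `tag_table`.
#' @param path TSV path.
#' @return `write_tag_table()`: invisibly `path`; `read_tag_table()`: the
#'   `tag_table`.
#' @export
write_tag_table <- function(tt, path) {
  write_table(as.data.frame(tt), path, format = "tsv")
}

#' @rdname write_tag_table
#' @export
read_tag_table <- function(path) {
  df <- read_tsv(path)
  need <- c("tag", "representative", "annotation")
  if (!all(need %in% names(df))) {
    stop("not a tag table: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df$tag <- as.character(df$tag)
  df$representative <- as.character(df$representative)
  df$annotation <- as.character(df$annotation)
  class(df) <- c("tag_table", "data.frame")
  df
}
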