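#' Mismatch-tolerant probe search against one subject sequence
#'
#' Finds every window of the subject within `max_mm` Hamming mismatches of
#' the probe, in the requested orientations. `N` in the subject counts as
#' a mismatch. Positions are 0-based starts in the subject as given; for
#' `orientation == "revcomp"` the reported window matched the reverse
#' complement of the probe.
#'
#' @param probe_seq Probe sequence 5'->3'.
#' @param subject Subject nucleotide sequence.
#' @param max_mm Maximum Hamming mismatches (default 0).
#' @param orientations `"both"` (default), `"forward"` or `"revcomp"`.
#' @return Data frame with columns `position`, `orientation`, `mismatches`,
#'   sorted by (mismatches, position).
#' @export
match_probe <- function(probe_seq, subject,
                        max_mm = 0L,
                        orientations = c("both", "forward", "revcomp")) {
  orientations <- match.arg(orientations)
  probe_seq <- toupper(probe_seq)
  subject <- toupper(subject)
  empty <- data.frame(position = integer(0), orientation = character(0),
                      mismatches = integer(0))
  if (nchar(subject) < nchar(probe_seq)) return(empty)
  subj <- Biostrings::DNAString(subject)
  scan1 <- function(pat_chr, label) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat_chr), subj,
                                  max.mismatch = max_mm, fixed = TRUE)
    # max.mismatch > 0 can propose windows beyond the subject ends
    m <- m[IRanges::start(m) >= 1 & IRanges::end(m) <= nchar(subject)]
    if (length(m) == 0) return(NULL)
    st <- IRanges::start(m)
    mm <- vapply(as.character(m), function(w) hamming_dist(pat_chr, w),
                 integer(1), USE.NAMES = FALSE)
    data.frame(position = st - 1L, orientation = label, mismatches = mm,
               stringsAsFactors = FALSE)
  }
  hits <- rbind(
    if (orientations %in% c("both", "forward")) scan1(probe_seq, "forward"),
    if (orientations %in% c("both", "revcomp"))
      scan1(reverse_complement(probe_seq), "revcomp"))
  if (is.null(hits) || nrow(hits) == 0) return(empty)
  hits <- hits[order(hits$mismatches, hits$position), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' In-silico coverage and specificity of a probe
#'
#' TestProbe-style evaluation of a probe against either an annotated tag
#' table (subjects = ribotags, weighted by read counts and unweighted) or a
#' reference sequence set (subjects = full-length references). A subject is
#' "hit" when it has at least one [match_probe()] hit; a subject is
#' "target" when its taxonomy contains `target` at any rank. Coverage is
#' hit targets / all targets; specificity is hit targets / all hit
#' subjects. With no target subjects, coverage is `NA`; with no hits at
#' all, specificity is `NA` (never 0/0).
#'
#' @param probe A `probe_candidate`, or a probe sequence string.
#' @param db Annotated `tag_table`, or a reference set data frame
#'   (`id`, `seq`, `taxonomy`).
#' @param target Taxon label deciding target membership.
#' @param max_mm Maximum Hamming mismatches (default 0).
#' @param orientations Passed to [match_probe()].
#' @param name Probe name when `probe` is a bare sequence.
#' @param db_label Database label for the report.
#' @return A `specificity_report`.
#' @export
evaluate_probe <- function(probe, db, target, max_mm = 0L,
                           orientations = "both", name = NULL,
                           db_label = NULL) {
  if (inherits(probe, "probe_candidate")) {
    probe_seq <- probe$sequence
    probe_name <- probe$name
  } else {
    probe_seq <- toupper(probe)
    probe_name <- name %||% "probe"
  }
  if (inherits(db, "tag_table")) {
    subj_id <- db$tag
    subj_seq <- db$tag
    subj_tax <- db$annotation
    weights <- if (length(sample_columns(db))) {
      rowSums(as.data.frame(db)[, sample_columns(db), drop = FALSE])
    } else {
      rep(1, nrow(db))
    }
    db_label <- db_label %||% "tag_table"
  } else {
    stopifnot(all(c("id", "seq", "taxonomy") %in% names(db)))
    subj_id <- db$id
    subj_seq <- db$seq
    subj_tax <- db$taxonomy
    weights <- rep(1, nrow(db))
    db_label <- db_label %||% "reference_set"
  }
  is_target <- is_taxon_member(subj_tax, target)
  hit_rows <- lapply(seq_along(subj_seq), function(i) {
    h <- match_probe(probe_seq, subj_seq[i], max_mm = max_mm,
                     orientations = orientations)
    if (nrow(h) == 0) return(NULL)
    cbind(subject = subj_id[i], h, target = is_target[i],
          stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hit_rows)
  if (is.null(hits)) {
    hits <- data.frame(subject = character(0), position = integer(0),
                       orientation = character(0), mismatches = integer(0),
                       target = logical(0))
  }
  hit_subject <- subj_id %in% hits$subject
  n_target <- sum(is_target)
  n_target_hit <- sum(is_target & hit_subject)
  n_nontarget_hit <- sum(!is_target & hit_subject)
  histo <- stats::setNames(
    vapply(0:max_mm, function(k) sum(hits$mismatches == k), numeric(1)),
    paste0("mm", 0:max_mm))
  w_target <- sum(weights[is_target])
  structure(list(
    probe_name = probe_name,
    probe_seq = probe_seq,
    database = db_label,
    target = target,
    max_mm = as.integer(max_mm),
    n_target_subjects = n_target,
    n_target_hit = n_target_hit,
    n_nontarget_hit = n_nontarget_hit,
    coverage = if (n_target > 0) n_target_hit / n_target else NA_real_,
    specificity = if (n_target_hit + n_nontarget_hit > 0) {
      n_target_hit / (n_target_hit + n_nontarget_hit)
    } else NA_real_,
    weighted_coverage = if (w_target > 0) {
      sum(weights[is_target & hit_subject]) / w_target
    } else NA_real_,
    weighted_specificity = if (sum(weights[hit_subject]) > 0) {
      sum(weights[is_target & hit_subject]) / sum(weights[hit_subject])
    } else NA_real_,
    mismatch_histogram = histo,
    hits = hits),
    class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat(sprintf("specificity_report: %s (5'-%s-3') vs %s, target '%s', <=%d mm\n",
              x$probe_name, x$probe_seq, x$database, x$target, x$max_mm))
  cat(sprintf("  targets hit %d/%d (coverage %s); non-target hits %d (specificity %s)\n",
              x$n_target_hit, x$n_target_subjects,
              fmt_frac(x$coverage), x$n_nontarget_hit,
              fmt_frac(x$specificity)))
  invisible(x)
}

fmt_frac <- function(x) if (is.na(x)) "NA" else sprintf("%.3f", x)

#' Serialise a specificity report
#'
#' JSON report (stable key order) plus optional TSV hit list.
#'
#' @param report A `specificity_report`.
#' @param json_path JSON output path.
#' @param hits_tsv Optional TSV path for the hit list.
#' @return Invisibly, `json_path`.
#' @export
write_specificity_report <- function(report, json_path, hits_tsv = NULL) {
  payload <- report[c("probe_name", "probe_seq", "database", "target",
                      "max_mm", "n_target_subjects", "n_target_hit",
                      "n_nontarget_hit", "coverage", "specificity",
                      "weighted_coverage", "weighted_specificity")]
  payload$mismatch_histogram <- as.list(report$mismatch_histogram)
  write_table(payload, json_path, format = "json")
  if (!is.null(hits_tsv)) write_table(report$hits, hits_tsv, format = "tsv")
  invisible(json_path)
}

#' Fraction of tags matching the probe vs the full ribotag
#'
#' For a sorted (or any) sample, computes the fraction of total tag counts
#' whose tag carries the probe sequence as its 5' prefix, the fraction
#' equal to the probe's full source ribotag, and the co-sorted tags:
#' probe-matching tags other than the source tag. Because the probe is a
#' prefix of the full tag, the probe fraction can never be below the tag
#' fraction.
#'
#' @param tt A `tag_table`.
#' @param probe_seq Probe sequence (prefix of `full_tag`).
#' @param full_tag The probe's 33 nt source ribotag.
#' @param sample Sample whose counts are used; default: sum over samples.
#' @return List with `frac_matching_probe`, `frac_matching_tag`,
#'   `co_sorted_tags`.
#' @export
compare_probe_vs_tag <- function(tt, probe_seq, full_tag, sample = NULL) {
  probe_seq <- toupper(probe_seq)
  full_tag <- toupper(full_tag)
  if (!startsWith(full_tag, probe_seq)) {
    stop("probe sequence must be a prefix of the full ribotag")
  }
  cols <- if (is.null(sample)) sample_columns(tt) else paste0("count_", sample)
  if (!all(cols %in% names(tt))) stop("no such sample: ", sample)
  cnt <- if (nrow(tt)) {
    rowSums(as.data.frame(tt)[, cols, drop = FALSE])
  } else {
    numeric(0)
  }
  total <- sum(cnt)
  if (total == 0) {
    return(list(frac_matching_probe = NA_real_,
                frac_matching_tag = NA_real_,
                co_sorted_tags = character(0)))
  }
  probe_match <- startsWith(tt$tag, probe_seq)
  tag_match <- tt$tag == full_tag
  list(
    frac_matching_probe = sum(cnt[probe_match]) / total,
    frac_matching_tag = sum(cnt[tag_match]) / total,
    co_sorted_tags = tt$tag[probe_match & !tag_match & cnt > 0])
}
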