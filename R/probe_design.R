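#' Select the template ribotag for probe design
#'
#' Taxon mode picks the highest-count tag whose annotation contains the
#' taxon label at any rank (ties break to the lexicographically smallest
#' tag); explicit mode returns the given tag's row.
#'
#' @param tt An annotated `tag_table`.
#' @param target Taxon label (e.g. `"Thauera"`) or, with
#'   `mode = "tag"`, an explicit tag sequence.
#' @param sample Sample whose counts rank the tags; default: sum over all
#'   samples.
#' @param mode `"taxon"` or `"tag"`.
#' @return One-row `tag_table` slice for the selected template.
#' @export
select_template <- function(tt, target, sample = NULL,
                            mode = c("taxon", "tag")) {
  mode <- match.arg(mode)
  if (nrow(tt) == 0) stop("empty tag table")
  if (mode == "tag") {
    ix <- which(tt$tag == target)
    if (length(ix) == 0) stop("tag not present in table: ", target)
    return(tt[ix, , drop = FALSE])
  }
  member <- is_taxon_member(tt$annotation, target)
  if (!any(member)) stop("no tag annotated to taxon: ", target)
  cols <- if (is.null(sample)) sample_columns(tt) else paste0("count_", sample)
  if (!all(cols %in% names(tt))) stop("no such sample: ", sample)
  cnt <- rowSums(as.data.frame(tt)[, cols, drop = FALSE])
  cand <- which(member & cnt == max(cnt[member]))
  best <- cand[order(tt$tag[cand])][1]
  tt[best, , drop = FALSE]
}

# A taxonomy string "contains" a taxon label when the label equals one of
# its resolved rank values (rank prefixes ignored).
is_taxon_member <- function(annotation, target) {
  vapply(annotation, function(a) {
    if (is.na(a) || !nzchar(a)) return(FALSE)
    target %in% parse_taxonomy(a)
  }, logical(1), USE.NAMES = FALSE)
}

#' Truncate a ribotag from its 3' end
#'
#' Probe sequences are the 5'-most `target_len` nt of the tag; the 3' end
#' is removed.
#'
#' @param tag Tag sequence.
#' @param target_len Desired probe length, `1 <= target_len <= nchar(tag)`
#'   (default 17).
#' @return `substr(tag, 1, target_len)`.
#' @examples
#' truncate_probe("GTGTTCTGGCTCCCGAAGGCACCCTCGCCTCTC")  # Thauera 17-mer
#' @export
truncate_probe <- function(tag, target_len = 17L) {
  target_len <- as.integer(target_len)
  if (target_len < 1L || target_len > nchar(tag)) {
    stop("target_len must be between 1 and the tag length (", nchar(tag), ")")
  }
  substr(tag, 1L, target_len)
}

#' Probe nomenclature
#'
#' Names follow the pattern `Ribo_<stem>_<length>`, e.g. `Ribo_Thau1029_17`.
#'
#' @param stem Probe stem (non-empty, no whitespace).
#' @param length Probe length in nt.
#' @return The probe name.
#' @export
name_probe <- function(stem, length) {
  if (!nzchar(stem) || grepl("\\s", stem)) {
    stop("probe stem must be non-empty without whitespace")
  }
  paste0("Ribo_", stem, "_", as.integer(length))
}

#' @rdname name_probe
#' @param name A `Ribo_<stem>_<length>` probe name.
#' @return `parse_probe_name()`: list with `stem` and `length`.
#' @export
parse_probe_name <- function(name) {
  m <- regmatches(name, regexec("^Ribo_(\\S+)_(\\d+)$", name))[[1]]
  if (length(m) != 3) stop("not a valid probe name: ", name)
  list(stem = m[2], length = as.integer(m[3]))
}

# Unified nearest-neighbour parameters (Allawi & SantaLucia), dH kcal/mol,
# dS cal/(mol K), 5'->3' top-strand dimers; the other six dimers map onto
# these by reverse complement.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)

#' Nearest-neighbour melting-temperature advisory
#'
#' Duplex Tm from unified nearest-neighbour thermodynamics with the
#' entropic salt correction `0.368 (N-1) ln[Na+]`, then lowered by
#' 0.6 degrees C per percent formamide. The oligo concentration default
#' (1 nM total strands) approximates the low effective duplex concentration
#' of in-situ hybridisation, where hybrids dissociate well below
#' solution-phase predictions at bench probe concentrations. The value is
#' an advisory: working stringency for FISH probes is determined
#' empirically from formamide dissociation curves
#' ([summarize_dissociation()]).
#'
#' @param sequence Probe sequence 5'->3' (A/C/G/T only, length >= 8).
#' @param formamide_pct Formamide concentration in percent (default 0).
#' @param na_molar Monovalent cation concentration in mol/L (default 0.9,
#'   the standard FISH hybridisation buffer).
#' @param oligo_molar Total strand concentration in mol/L (default 1e-9).
#' @return Tm estimate in degrees Celsius.
#' @examples
#' estimate_tm("GTGTTCTGGCTCCCGAA")
#' @export
estimate_tm <- function(sequence, formamide_pct = 0, na_molar = 0.9,
                        oligo_molar = 1e-9) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 8) stop("sequence must be at least 8 nt")
  if (grepl("[^ACGT]", sequence)) {
    stop("sequence must contain only A, C, G, T (no N) for Tm estimation")
  }
  b <- strsplit(sequence, "")[[1]]
  n <- length(b)
  dimers <- paste0(b[-n], b[-1])
  canon <- ifelse(dimers %in% names(NN_DH), dimers,
                  reverse_complement(dimers))
  dH <- sum(NN_DH[canon])
  dS <- sum(NN_DS[canon])
  for (terminal in c(b[1], b[n])) {
    if (terminal %in% c("G", "C")) {
      dH <- dH + 0.1; dS <- dS - 2.8
    } else {
      dH <- dH + 2.3; dS <- dS + 4.1
    }
  }
  dS <- dS + 0.368 * (n - 1) * log(na_molar)
  tm_k <- dH * 1000 / (dS + 1.987 * log(oligo_molar / 4))
  tm_k - 273.15 - 0.6 * formamide_pct
}

#' Truncate a ribotag until its Tm enters a target window
#'
#' Alternative to the fixed-length default: removes 3' bases one at a time
#' (starting from the full tag) until the nearest-neighbour Tm estimate
#' falls inside `tm_window`, or the minimum length is reached. Errors when
#' no prefix of at least `min_len` nt lands in the window.
#'
#' @param tag Tag sequence.
#' @param tm_window Numeric length-2 `c(low, high)` Tm window in degrees C.
#' @param min_len Shortest admissible probe (default 14).
#' @param ... Passed to [estimate_tm()].
#' @return The longest prefix of `tag` whose Tm lies inside the window.
#' @export
truncate_to_tm <- function(tag, tm_window, min_len = 14L, ...) {
  stopifnot(length(tm_window) == 2, tm_window[1] <= tm_window[2])
  for (len in seq(nchar(tag), min_len)) {
    cand <- substr(tag, 1L, len)
    tm <- estimate_tm(cand, ...)
    if (tm >= tm_window[1] && tm <= tm_window[2]) return(cand)
  }
  stop(sprintf("no prefix of %d..%d nt has Tm inside [%g, %g] C",
               min_len, nchar(tag), tm_window[1], tm_window[2]))
}

#' Design an R-Probe candidate from a tag table
#'
#' Composes template selection, 3' truncation, nomenclature and the Tm
#' advisory into a probe candidate. The formamide advisory is the percent
#' formamide at which the Tm estimate equals the hybridisation temperature
#' (0.6 degrees C per percent; clamped to [0, 70] and rounded to 5%);
#' working stringency should still be fixed empirically.
#'
#' @param tt Annotated `tag_table`.
#' @param target Taxon label or explicit tag (see [select_template()]).
#' @param target_len Probe length (default 17).
#' @param stem Name stem; default derives from the target label and the
#'   canonical anchor site (`<target>1029`).
#' @param hybridisation_temp Reference hybridisation temperature in degrees
#'   C (default 46).
#' @param mode Passed to [select_template()].
#' @param sample Passed to [select_template()].
#' @return A `probe_candidate` list.
#' @export
design_probe <- function(tt, target, target_len = 17L, stem = NULL,
                         hybridisation_temp = 46,
                         mode = c("taxon", "tag"), sample = NULL) {
  mode <- match.arg(mode)
  row <- select_template(tt, target, sample = sample, mode = mode)
  tag <- row$tag
  sequence <- truncate_probe(tag, target_len)
  if (is.null(stem)) {
    label <- if (mode == "taxon") target else "OTU"
    stem <- paste0(gsub("\\s", "", substr(label, 1, 5)), "1029")
  }
  tm <- estimate_tm(sequence)
  fa <- max(0, min(70, (tm - hybridisation_temp) / 0.6))
  structure(list(
    name = name_probe(stem, target_len),
    sequence = sequence,
    length = as.integer(target_len),
    source_tag = tag,
    intended_target = if (mode == "taxon") target else row$annotation,
    tm_estimate = tm,
    formamide_advisory = 5 * round(fa / 5),
    hybridisation_temp = hybridisation_temp),
    class = "probe_candidate")
}

#' @export
print.probe_candidate <- function(x, ...) {
  cat(sprintf("%s  5'-%s-3'  (%d nt)\n", x$name, x$sequence, x$length))
  cat(sprintf("  target: %s\n  source tag: %s\n", x$intended_target,
              x$source_tag))
  cat(sprintf("  Tm advisory %.1f C; ~%g%% formamide at %g C (advisory only)\n",
              x$tm_estimate, x$formamide_advisory, x$hybridisation_temp))
  invisible(x)
}

#' Write / read a probe table TSV
#'
#' Columns: `name`, `sequence`, `length`, `source_tag`, `intended_target`,
#' `tm_estimate_C`, `formamide_advisory_pct`, `hybridisation_temp_C`.
#'
#' @param probes A `probe_candidate` or list of them.
#' @param path TSV path.
#' @return `write_probe_table()`: invisibly `path`; `read_probe_table()`:
#'   a data frame with one row per probe.
#' @export
write_probe_table <- function(probes, path) {
  if (inherits(probes, "probe_candidate")) probes <- list(probes)
  df <- do.call(rbind, lapply(probes, function(p) {
    data.frame(name = p$name, sequence = p$sequence, length = p$length,
               source_tag = p$source_tag,
               intended_target = p$intended_target,
               tm_estimate_C = p$tm_estimate,
               formamide_advisory_pct = p$formamide_advisory,
               hybridisation_temp_C = p$hybridisation_temp,
               stringsAsFactors = FALSE)
  }))
  write_table(df, path, format = "tsv")
}

#' @rdname write_probe_table
#' @export
read_probe_table <- function(path) {
  read_tsv(path)
}
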