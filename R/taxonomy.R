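TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
               "species")
TAX_PREFIXES <- c(kingdom = "k__", phylum = "p__", class = "c__",
                  order = "o__", family = "f__", genus = "g__",
                  species = "s__")

#' Parse a taxonomy string into a ranked path
#'
#' Accepts the conventional `"k__Bacteria; p__Proteobacteria; ..."` form
#' (prefixes optional). A path is prefix-resolved: once a rank is empty all
#' deeper ranks must be empty too.
#'
#' @param x Taxonomy string.
#' @return Character vector of length 7 named by rank; unresolved ranks are
#'   `""`.
#' @export
parse_taxonomy <- function(x) {
  out <- stats::setNames(rep("", 7L), TAX_RANKS)
  if (is.na(x) || !nzchar(trimws(x))) return(out)
  parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  parts <- sub("^[kpcofgs]__", "", parts)
  n <- min(length(parts), 7L)
  out[seq_len(n)] <- parts[seq_len(n)]
  validate_taxonomy(out)
  out
}

validate_taxonomy <- function(path) {
  filled <- nzchar(path)
  if (any(filled) && any(!filled)) {
    if (max(which(filled)) > min(which(!filled))) {
      stop("taxonomy path has an empty rank above a resolved one: ",
           format_taxonomy(path))
    }
  }
  invisible(path)
}

#' Format a ranked path back into a prefixed string
#'
#' @param path Length-7 character vector as from [parse_taxonomy()].
#' @return Taxonomy string with rank prefixes, truncated at the last
#'   resolved rank (empty string for a fully unresolved path).
#' @export
format_taxonomy <- function(path) {
  filled <- which(nzchar(path))
  if (length(filled) == 0) return("")
  keep <- seq_len(max(filled))
  paste(paste0(TAX_PREFIXES[keep], path[keep]), collapse = "; ")
}

#' Lowest common ancestor of taxonomy paths
#'
#' @param paths List of length-7 rank vectors.
#' @return Length-7 rank vector: the longest rank-prefix on which all paths
#'   agree.
#' @export
taxonomy_lca <- function(paths) {
  stopifnot(length(paths) >= 1)
  out <- paths[[1]]
  for (p in paths[-1]) {
    agree <- out == p & nzchar(out)
    cut <- which(!agree)
    if (length(cut)) out[min(cut):7L] <- ""
  }
  out
}

#' Build a reference tag database
#'
#' Runs the anchor/tag extractor over an annotated reference set and stores
#' the mapping tag sequence -> references. References in which the anchor is
#' not found (or the tag window is incomplete) are excluded and counted in
#' the provenance.
#'
#' @param refs Data frame with columns `id`, `seq`, `taxonomy` (strings as
#'   accepted by [parse_taxonomy()]). See [read_reference_set()].
#' @param anc An [anchor()].
#' @param tag_len Tag length (default 33).
#' @param name Reference set label stored in the provenance.
#' @return A `reference_tag_db`: list with `tags` (character), `refs`
#'   (list of data frames id/taxonomy per tag) and `provenance`.
#' @export
build_reference_db <- function(refs, anc, tag_len = 33L,
                               name = "reference") {
  if (nrow(refs) == 0) stop("empty reference set")
  stopifnot(all(c("id", "seq", "taxonomy") %in% names(refs)))
  tags <- rep(NA_character_, nrow(refs))
  hits <- scan_anchor_set(refs$seq, anc)
  for (i in which(!is.na(hits$position))) {
    rt <- extract_tag(refs$seq[i],
                      list(position = hits$position[i],
                           strand = hits$strand[i]),
                      anc, tag_len = tag_len, rep_len = tag_len)
    if (!is.null(rt)) tags[i] <- rt$tag
  }
  skipped <- refs$id[is.na(tags)]
  keep <- which(!is.na(tags))
  by_tag <- split(keep, tags[keep])
  db <- structure(list(
    tags = names(by_tag),
    refs = lapply(by_tag, function(ix) {
      data.frame(id = refs$id[ix], taxonomy = refs$taxonomy[ix],
                 stringsAsFactors = FALSE)
    }),
    tag_len = as.integer(tag_len),
    provenance = list(reference_set = name, anchor = anc$pattern,
                      n_refs = nrow(refs), n_without_anchor = length(skipped),
                      skipped_ids = skipped)),
    class = "reference_tag_db")
  db
}

#' @export
print.reference_tag_db <- function(x, ...) {
  cat(sprintf(
    "reference_tag_db '%s': %d tags (%d nt) from %d references (%d without anchor)\n",
    x$provenance$reference_set, length(x$tags), x$tag_len,
    x$provenance$n_refs, x$provenance$n_without_anchor))
  invisible(x)
}

hamming_dist <- function(a, b) {
  ai <- utf8ToInt(a)
  bi <- utf8ToInt(b)
  stopifnot(length(ai) == length(bi))
  sum(ai != bi)
}

#' Annotate one ribotag against a reference tag database
#'
#' Exact matches are preferred; otherwise all database tags at the minimal
#' Hamming distance `<= max_mm` are used. The returned annotation is the
#' lowest common ancestor of all matched references' taxonomies
#' (equally-near tags pool their references). No match within `max_mm`
#' yields `NA`.
#'
#' @param tag Tag sequence (same length as the database tags).
#' @param db A [build_reference_db()] result.
#' @param max_mm Maximum Hamming distance (default 0).
#' @return Taxonomy string (possibly truncated by the LCA) or
#'   `NA_character_` when unannotated.
#' @export
annotate_tag <- function(tag, db, max_mm = 0L) {
  if (nchar(tag) != db$tag_len) {
    stop("tag length ", nchar(tag), " does not match database tag length ",
         db$tag_len)
  }
  ix <- match(tag, db$tags)
  if (is.na(ix) && max_mm > 0L) {
    d <- vapply(db$tags, hamming_dist, integer(1), b = tag,
                USE.NAMES = FALSE)
    dmin <- suppressWarnings(min(d))
    if (is.finite(dmin) && dmin <= max_mm) ix <- which(d == dmin)
  }
  if (all(is.na(ix))) return(NA_character_)
  matched <- do.call(rbind, db$refs[ix])
  paths <- lapply(matched$taxonomy, parse_taxonomy)
  format_taxonomy(taxonomy_lca(paths))
}

#' Annotate every tag of a tag table
#'
#' @param tt A `tag_table`.
#' @param db A `reference_tag_db`.
#' @param max_mm Maximum Hamming distance per tag (default 0).
#' @return The `tag_table` with its `annotation` column filled
#'   (`NA` = unannotated).
#' @export
annotate_table <- function(tt, db, max_mm = 0L) {
  tt$annotation <- vapply(tt$tag, annotate_tag, character(1), db = db,
                          max_mm = max_mm, USE.NAMES = FALSE)
  tt
}

#' Read an annotated reference set
#'
#' FASTA where the description line carries the taxonomy after the first
#' space (`>ref1 k__...; p__...`), or any FASTA plus a sidecar TSV with
#' columns `id` and `taxonomy`.
#'
#' @param path FASTA path.
#' @param taxonomy_tsv Optional sidecar TSV path.
#' @return Data frame with columns `id`, `seq`, `taxonomy`.
#' @export
read_reference_set <- function(path, taxonomy_tsv = NULL) {
  rs <- read_seqs(path, format = "fasta")
  if (is.null(taxonomy_tsv)) {
    id <- sub("\\s.*$", "", rs$id)
    tax <- ifelse(grepl("\\s", rs$id), sub("^\\S+\\s+", "", rs$id), "")
  } else {
    side <- read_tsv(taxonomy_tsv)
    stopifnot(all(c("id", "taxonomy") %in% names(side)))
    id <- sub("\\s.*$", "", rs$id)
    tax <- side$taxonomy[match(id, side$id)]
    if (anyNA(tax)) {
      stop("taxonomy TSV is missing entries for: ",
           paste(utils::head(id[is.na(tax)], 3), collapse = ", "))
    }
  }
  data.frame(id = id, seq = rs$seq, taxonomy = tax, stringsAsFactors = FALSE)
}

#' Serialise / load a reference tag database as TSV
#'
#' One row per (tag, reference) pair, columns `tag`, `ref_id`, `taxonomy`;
#' provenance is stored in `#`-prefixed header comments.
#'
#' @param db A `reference_tag_db`.
#' @param path TSV path.
#' @return `write_reference_db()`: invisibly `path`; `read_reference_db()`:
#'   the database.
#' @export
write_reference_db <- function(db, path) {
  rows <- do.call(rbind, lapply(seq_along(db$tags), function(i) {
    data.frame(tag = db$tags[i], ref_id = db$refs[[i]]$id,
               taxonomy = db$refs[[i]]$taxonomy, stringsAsFactors = FALSE)
  }))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# reference_set=%s anchor=%s tag_len=%d n_refs=%d n_without_anchor=%d",
                     db$provenance$reference_set, db$provenance$anchor,
                     db$tag_len, db$provenance$n_refs,
                     db$provenance$n_without_anchor), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_reference_db
#' @export
read_reference_db <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- regmatches(header, gregexpr("(\\S+)=(\\S+)", header))[[1]]
  kv <- strsplit(meta, "=", fixed = TRUE)
  prov <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  rows <- utils::read.delim(path, sep = "\t", comment.char = "#",
                            stringsAsFactors = FALSE)
  by_tag <- split(seq_len(nrow(rows)), rows$tag)
  structure(list(
    tags = names(by_tag),
    refs = lapply(by_tag, function(ix) {
      data.frame(id = rows$ref_id[ix], taxonomy = rows$taxonomy[ix],
                 stringsAsFactors = FALSE)
    }),
    tag_len = as.integer(prov$tag_len),
    provenance = list(reference_set = prov$reference_set,
                      anchor = prov$anchor,
                      n_refs = as.integer(prov$n_refs),
                      n_without_anchor = as.integer(prov$n_without_anchor),
                      skipped_ids = character(0))),
    class = "reference_tag_db")
}
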