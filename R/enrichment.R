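#' Community profile from an annotated tag table
#'
#' Relative abundance of a taxon is the sum of tag counts annotated to the
#' taxon divided by the total number of tag counts in the sample
#' (read-weighted). Tags without annotation (or unresolved at the requested
#' rank) fall into the `"unannotated"` bucket, so abundances always sum to
#' 1. At `level = "OTU"` the tags themselves are the units.
#'
#' @param tt Annotated `tag_table`.
#' @param sample Sample name (must have a `count_<sample>` column).
#' @param level One of `"kingdom"` ... `"species"`, or `"OTU"`
#'   (default `"genus"`).
#' @return A `community_profile`: list with `sample`, `level`,
#'   `abundance` (named numeric summing to 1, including `"unannotated"`)
#'   and `total` (total tag count).
#' @export
profile <- function(tt, sample, level = "genus") {
  col <- paste0("count_", sample)
  if (!col %in% names(tt)) stop("no such sample: ", sample)
  if (!(level %in% c(TAX_RANKS, "OTU"))) {
    stop("level must be a taxonomic rank or \"OTU\"")
  }
  cnt <- as.numeric(tt[[col]])
  total <- sum(cnt)
  if (total == 0) stop("sample '", sample, "' has zero total tag counts")
  if (level == "OTU") {
    key <- tt$tag
  } else {
    key <- vapply(tt$annotation, function(a) {
      if (is.na(a) || !nzchar(a)) return(NA_character_)
      path <- parse_taxonomy(a)
      r <- match(level, TAX_RANKS)
      if (!nzchar(path[r])) return(NA_character_)
      format_taxonomy(c(path[seq_len(r)], rep("", 7L - r)))
    }, character(1), USE.NAMES = FALSE)
  }
  key[is.na(key)] <- "unannotated"
  ab <- tapply(cnt, key, sum) / total
  ab <- ab[order(names(ab))]
  if (!"unannotated" %in% names(ab)) {
    ab <- c(ab, unannotated = 0)
  }
  structure(list(sample = sample, level = level,
                 abundance = stats::setNames(as.numeric(ab), names(ab)),
                 total = total),
            class = "community_profile")
}

#' @export
print.community_profile <- function(x, ...) {
  cat(sprintf("community_profile '%s' at %s level (%g tags)\n",
              x$sample, x$level, x$total))
  ab <- sort(x$abundance, decreasing = TRUE)
  for (i in seq_len(min(8, length(ab)))) {
    cat(sprintf("  %-50s %6.2f%%\n", names(ab)[i], 100 * ab[i]))
  }
  invisible(x)
}

# Abundance of a label in a profile: exact name match first, else the
# profile entry whose taxonomy path contains the label at any rank
# (summed over matching entries). OTU-level profiles match tags exactly.
profile_abundance <- function(p, target) {
  if (target %in% names(p$abundance)) {
    return(unname(p$abundance[target]))
  }
  if (p$level == "OTU") return(NA_real_)
  hit <- is_taxon_member(names(p$abundance), target)
  if (!any(hit)) return(NA_real_)
  sum(p$abundance[hit])
}

#' Pre-/post-sort fold enrichment of a target taxon
#'
#' Fold enrichment is the post-sort relative abundance divided by the
#' pre-sort relative abundance; the integer fold is its floor (a
#' 1.06% -> 98.66% enrichment is "93 fold"). When the target is absent
#' pre-sort the fold is undefined (`NA`) and flagged, since low-depth
#' pre-sort samples may simply contain no target tags.
#'
#' @param pre,post `community_profile`s at the same level.
#' @param target Taxon (or tag, at OTU level) label.
#' @return An `enrichment_result`: list with `target`, `pre_abundance`,
#'   `post_abundance`, `fold_enrichment`, `integer_fold`, `flag`.
#' @export
fold_enrichment <- function(pre, post, target) {
  post_ab <- profile_abundance(post, target)
  if (is.na(post_ab)) stop("target absent from post-sort profile: ", target)
  pre_ab <- profile_abundance(pre, target)
  if (is.na(pre_ab)) pre_ab <- 0
  if (pre_ab == 0) {
    res <- list(target = target, pre_abundance = 0,
                post_abundance = post_ab, fold_enrichment = NA_real_,
                integer_fold = NA_integer_, flag = "target absent pre-sort")
  } else {
    fold <- post_ab / pre_ab
    res <- list(target = target, pre_abundance = pre_ab,
                post_abundance = post_ab, fold_enrichment = fold,
                integer_fold = as.integer(floor(fold)), flag = NA_character_)
  }
  structure(res, class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  if (is.na(x$fold_enrichment)) {
    cat(sprintf("enrichment of '%s': post %.4f; fold undefined (%s)\n",
                x$target, x$post_abundance, x$flag))
  } else {
    cat(sprintf("enrichment of '%s': %.4f -> %.4f (%.2f fold; %d fold truncated)\n",
                x$target, x$pre_abundance, x$post_abundance,
                x$fold_enrichment, x$integer_fold))
  }
  invisible(x)
}

#' Post-sort purity of a target
#'
#' The target's share of the post-sort community profile — the in-silico
#' analogue of sorting purity.
#'
#' @param post A `community_profile`.
#' @param target Taxon (or tag) label.
#' @return Fraction in [0, 1].
#' @export
purity <- function(post, target) {
  ab <- profile_abundance(post, target)
  if (is.na(ab)) stop("target absent from profile: ", target)
  ab
}

#' Write a community profile as TSV or JSON
#'
#' @param p A `community_profile`.
#' @param path Output path (`.json` selects JSON).
#' @return Invisibly, `path`.
#' @export
write_profile <- function(p, path) {
  if (tolower(tools::file_ext(path)) == "json") {
    write_table(list(sample = p$sample, level = p$level, total = p$total,
                     abundance = as.list(p$abundance)), path,
                format = "json")
  } else {
    write_table(data.frame(taxon = names(p$abundance),
                           abundance = as.numeric(p$abundance),
                           stringsAsFactors = FALSE), path, format = "tsv")
  }
  invisible(path)
}
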