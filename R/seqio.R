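#' Read sequences from FASTA or FASTQ
#'
#' Reads a (optionally gzip-compressed) FASTA or FASTQ file into a
#' `read_set`: a data frame with one row per record and columns `id`,
#' `seq` and `qual`. For FASTA input `qual` is `NA`; for FASTQ it holds
#' the raw quality string (Phred+33 by default, see [phred_scores()]).
#'
#' @param path Path to the sequence file. `.gz` is handled transparently.
#' @param format `"fasta"`, `"fastq"` or `"auto"` (resolve by extension:
#'   `.fq`/`.fastq` are FASTQ, `.fa`/`.fasta`/`.fna`/`.ffn` are FASTA).
#' @return A `read_set` data frame with columns `id`, `seq`, `qual`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ACGT", ">r2", "GGCC"), fa)
#' read_seqs(fa)
#' @export
read_seqs <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("sequence file not found: ", path)
  }
  if (format == "auto") {
    format <- guess_seq_format(path)
  }
  if (format == "fastq") {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(x)$qualities)
  } else {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
    qual <- rep(NA_character_, length(x))
  }
  rs <- data.frame(id = names(x) %||% character(0),
                   seq = as.character(x),
                   qual = qual,
                   stringsAsFactors = FALSE)
  rownames(rs) <- NULL
  # FASTA descriptions keep everything after the first space out of the id
  validate_read_set(rs)
  class(rs) <- c("read_set", "data.frame")
  rs
}

guess_seq_format <- function(path) {
  p <- sub("\\.gz$", "", path, ignore.case = TRUE)
  ext <- tolower(tools::file_ext(p))
  if (ext %in% c("fq", "fastq")) return("fastq")
  if (ext %in% c("fa", "fasta", "fna", "ffn", "frn")) return("fasta")
  stop("cannot resolve sequence format from extension: ", basename(path),
       " (pass format = \"fasta\" or \"fastq\")")
}

validate_read_set <- function(rs) {
  if (nrow(rs) == 0) return(invisible(rs))
  bad <- grepl("[^ACGTN]", rs$seq)
  if (any(bad)) {
    stop("non-ACGTN characters in record(s): ",
         paste(utils::head(rs$id[bad], 3), collapse = ", "))
  }
  hasq <- !is.na(rs$qual)
  mism <- hasq & nchar(rs$qual) != nchar(rs$seq)
  if (any(mism)) {
    stop("quality/sequence length mismatch in record(s): ",
         paste(utils::head(rs$id[mism], 3), collapse = ", "))
  }
  invisible(rs)
}

#' Construct a read_set from vectors
#'
#' @param id,seq,qual Character vectors (qual may be `NULL` / `NA`).
#' @return A `read_set` data frame.
#' @export
read_set <- function(id, seq, qual = NULL) {
  if (is.null(qual)) qual <- rep(NA_character_, length(seq))
  rs <- data.frame(id = as.character(id), seq = toupper(as.character(seq)),
                   qual = as.character(qual), stringsAsFactors = FALSE)
  validate_read_set(rs)
  class(rs) <- c("read_set", "data.frame")
  rs
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set with", nrow(x), "records",
      if (all(is.na(x$qual))) "(no qualities)\n" else "(with qualities)\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6), ...)
  invisible(x)
}

#' Write a read_set to FASTA or FASTQ
#'
#' Records with qualities are written as FASTQ when `format = "auto"`;
#' records without qualities as FASTA.
#'
#' @param rs A `read_set`.
#' @param path Output path (`.gz` triggers gzip compression).
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return Invisibly, `path`.
#' @export
write_seqs <- function(rs, path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (nrow(rs) > 0 && all(!is.na(rs$qual))) "fastq" else "fasta"
  }
  x <- Biostrings::DNAStringSet(rs$seq)
  names(x) <- rs$id
  compress <- grepl("\\.gz$", path, ignore.case = TRUE)
  if (format == "fastq") {
    if (any(is.na(rs$qual))) {
      stop("cannot write FASTQ: records without qualities present")
    }
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(rs$qual),
                                compress = compress)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta",
                                compress = compress)
  }
  invisible(path)
}

#' Decode a quality string into Phred scores
#'
#' @param qual Quality string.
#' @param offset ASCII offset, 33 for Phred+33 (default).
#' @return Integer vector of per-base Phred scores.
#' @examples
#' phred_scores("IIII")  # 40 40 40 40
#' @export
phred_scores <- function(qual, offset = 33L) {
  if (is.na(qual)) return(integer(0))
  utf8ToInt(qual) - as.integer(offset)
}

#' Encode Phred scores as a quality string
#'
#' @param scores Integer Phred scores.
#' @param offset ASCII offset (default 33).
#' @return Quality string.
#' @export
phred_string <- function(scores, offset = 33L) {
  if (length(scores) == 0) return("")
  intToUtf8(as.integer(scores) + as.integer(offset))
}

#' Reverse complement of a nucleotide sequence
#'
#' Standard Watson-Crick reverse complement over the alphabet
#' \{A, C, G, T, N\}; `N` maps to `N`. Vectorised over `seq`.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("GCTGCCTCCCGTAGGAGT")
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0) return(character(0))
  bad <- grepl("[^ACGTN]", toupper(seq))
  if (any(bad)) {
    stop("non-ACGTN character in sequence: ",
         utils::head(seq[bad], 1))
  }
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(toupper(seq))))
}

#' Quality-trimming policy
#'
#' @param min_phred Minimum terminal base quality; bases below it are trimmed
#'   from both ends (default 20).
#' @param min_length Minimum read length after trimming; shorter reads are
#'   discarded (default 30).
#' @return A `trim_policy` list.
#' @export
trim_policy <- function(min_phred = 20L, min_length = 30L) {
  min_phred <- as.integer(min_phred)
  min_length <- as.integer(min_length)
  stopifnot(min_phred >= 0L, min_length >= 1L)
  structure(list(min_phred = min_phred, min_length = min_length),
            class = "trim_policy")
}

#' Quality-trim reads from both ends
#'
#' Trims bases from each end of every read while the terminal base quality
#' is below `policy$min_phred` (end-scan rule), then discards reads shorter
#' than `policy$min_length`. Reads without qualities (FASTA input) pass
#' through untouched with a warning.
#'
#' @param rs A `read_set`.
#' @param policy A [trim_policy()].
#' @param offset Phred ASCII offset (default 33).
#' @return The trimmed `read_set`; discarded reads are dropped.
#' @export
quality_trim <- function(rs, policy = trim_policy(), offset = 33L) {
  if (nrow(rs) == 0) return(rs)
  if (any(is.na(rs$qual))) {
    warning("reads without qualities are not trimmed")
  }
  out <- rs
  keep <- rep(TRUE, nrow(rs))
  for (i in seq_len(nrow(rs))) {
    if (is.na(rs$qual[i])) next
    q <- phred_scores(rs$qual[i], offset)
    ok <- q >= policy$min_phred
    if (!any(ok)) {
      keep[i] <- FALSE
      next
    }
    from <- which(ok)[1]
    to <- which(ok)[length(which(ok))]
    if (to - from + 1L < policy$min_length) {
      keep[i] <- FALSE
      next
    }
    out$seq[i] <- substr(rs$seq[i], from, to)
    out$qual[i] <- substr(rs$qual[i], from, to)
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  out
}

#' Write a table as TSV or JSON
#'
#' TSV files are tab-delimited with a header row, UTF-8, `.` as the decimal
#' mark, no quoting of plain fields, and round-trip losslessly through
#' [read_tsv()].
#'
#' @param x A data frame (TSV) or any jsonlite-serialisable object (JSON).
#' @param path Output path.
#' @param format `"tsv"` or `"json"` (default by extension).
#' @return Invisibly, `path`.
#' @export
write_table <- function(x, path, format = NULL) {
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "tsv"
  }
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
  } else {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE,
                       fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path Input path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = NA, na.strings = "NA",
                    fileEncoding = "UTF-8")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
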