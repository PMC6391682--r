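#' Trimming configuration for NEXTflex-style small RNA reads
#'
#' Parameters controlling two-round trimming: 3' adapter removal by a
#' leftmost-prefix-match rule, then removal of the fixed-length
#' randomized ends added by the library protocol.
#'
#' Adapter matching declares a hit at read position `i` when the adapter
#' prefix of length `L = min(nchar(adapter), remaining read length)`
#' aligned at `i` has at most `max_mismatch_full` mismatches if
#' `L >= min_match_full`, or zero mismatches if
#' `min_match_end <= L < min_match_full`. The read is truncated at the
#' leftmost matching position. This emulates k-mer based 3' adapter
#' trimmers (k = `min_match_full`, minimum terminal overlap =
#' `min_match_end`, Hamming distance = `max_mismatch_full`) with a
#' deterministic, exhaustively checkable rule.
#'
#' @param adapter 3' adapter sequence (uppercase ACGTN). The default is
#'   the NEXTflex small RNA 3' adapter.
#' @param min_match_full minimum overlap (nt) at which mismatches are
#'   tolerated.
#' @param min_match_end minimum exact overlap (nt) at the read 3' end.
#' @param max_mismatch_full mismatches allowed in a full-length match.
#' @param force_trim_5p,force_trim_3p bases removed unconditionally from
#'   each end after adapter removal (the 4-nt randomized ends).
#' @param min_length minimum insert length retained after all trimming.
#' @return An object of class `trim_config`.
#' @examples
#' trim_config()
#' @export
trim_config <- function(adapter = "TGGAATTCTCGGGTGCCAAGG",
                        min_match_full = 19L,
                        min_match_end = 8L,
                        max_mismatch_full = 1L,
                        force_trim_5p = 4L,
                        force_trim_3p = 4L,
                        min_length = 15L) {
  check_alphabet(adapter, "adapter")
  min_match_full <- as.integer(min_match_full)
  min_match_end <- as.integer(min_match_end)
  if (!(min_match_end > 0L && min_match_end <= min_match_full &&
        min_match_full <= nchar(adapter)))
    stop("need 0 < min_match_end <= min_match_full <= nchar(adapter)",
         call. = FALSE)
  if (max_mismatch_full < 0L) stop("max_mismatch_full must be >= 0")
  if (min_length < 1L) stop("min_length must be >= 1")
  structure(
    list(adapter = toupper(adapter),
         min_match_full = min_match_full,
         min_match_end = min_match_end,
         max_mismatch_full = as.integer(max_mismatch_full),
         force_trim_5p = as.integer(force_trim_5p),
         force_trim_3p = as.integer(force_trim_3p),
         min_length = as.integer(min_length)),
    class = "trim_config")
}

#' @export
print.trim_config <- function(x, ...) {
  cat("trim_config: adapter", x$adapter, "\n",
      " full match >=", x$min_match_full, "nt (<=", x$max_mismatch_full,
      "mismatch); end match >=", x$min_match_end, "nt exact\n",
      " force trim 5'/3':", x$force_trim_5p, "/", x$force_trim_3p,
      "nt; min length", x$min_length, "nt\n")
  invisible(x)
}

# Vectorized adapter scan over reads of arbitrary lengths.
# Returns, per read, the number of bases kept (read length if no match).
adapter_trim_lengths <- function(seqs, config) {
  stopifnot(inherits(config, "trim_config"))
  seqs <- check_alphabet(seqs, "read sequence")
  n_read <- nchar(seqs)
  keep <- n_read
  a <- strsplit(config$adapter, "")[[1]]
  alen <- length(a)
  chunk <- 100000L   # bound the character-matrix working set
  for (n in unique(n_read)) {
    idx_all <- which(n_read == n)
    if (n < config$min_match_end) next
    for (off in seq(1L, length(idx_all), by = chunk)) {
    idx <- idx_all[off:min(off + chunk - 1L, length(idx_all))]
    m <- matrix(unlist(strsplit(seqs[idx], ""), use.names = FALSE),
                nrow = length(idx), ncol = n, byrow = TRUE)
    pos <- rep(NA_integer_, length(idx))
    for (i in seq_len(n)) {
      L <- min(alen, n - i + 1L)
      if (L < config$min_match_end) break
      ap <- a[seq_len(L)]
      mism <- rowSums(m[, i:(i + L - 1L), drop = FALSE] !=
                        matrix(ap, length(idx), L, byrow = TRUE))
      ok <- if (L >= config$min_match_full)
        mism <= config$max_mismatch_full else mism == 0
      hit <- ok & is.na(pos)
      if (any(hit)) pos[hit] <- i
      if (!anyNA(pos)) break
    }
    keep[idx[!is.na(pos)]] <- pos[!is.na(pos)] - 1L
    }
  }
  keep
}

#' Trim the 3' adapter from a read
#'
#' Scans the read left to right and truncates it at the leftmost
#' position where the adapter prefix matches under the rules of
#' [trim_config()]. A read without a match is returned unchanged; this
#' stage never discards.
#'
#' @param read a single read sequence (character) or a named list with a
#'   `sequence` element.
#' @param config a [trim_config()].
#' @return The (possibly truncated) read in the same form it was given.
#'   Reads trimmed to length zero return an empty string.
#' @examples
#' cfg <- trim_config()
#' trim_adapter(paste0(strrep("A", 30), cfg$adapter), cfg)
#' @export
trim_adapter <- function(read, config = trim_config()) {
  seq <- if (is.list(read)) read$sequence else read
  keep <- adapter_trim_lengths(seq, config)
  out <- substr(seq, 1L, keep)
  if (is.list(read)) { read$sequence <- out; read } else out
}

#' Remove fixed-length randomized ends after adapter trimming
#'
#' Removes `force_trim_5p` bases from the 5' end and `force_trim_3p`
#' bases from the 3' end, then discards the read if fewer than
#' `min_length` bases remain.
#'
#' @inheritParams trim_adapter
#' @return The trimmed sequence, or `NULL` when discarded.
#' @examples
#' force_trim(strrep("A", 30), trim_config())   # 22-nt insert
#' force_trim(strrep("A", 22), trim_config())   # NULL: 14 < 15
#' @export
force_trim <- function(read, config = trim_config()) {
  seq <- if (is.list(read)) read$sequence else read
  stopifnot(length(seq) == 1L)
  n <- nchar(seq)
  remaining <- n - config$force_trim_5p - config$force_trim_3p
  if (remaining < config$min_length) return(NULL)
  out <- substr(seq, config$force_trim_5p + 1L, n - config$force_trim_3p)
  if (is.list(read)) { read$sequence <- out; read } else out
}

#' Trim a FASTQ library
#'
#' Applies [trim_adapter()] then [force_trim()] to every record of a
#' FASTQ file (or in-memory read set) and reports counts. Base
#' qualities are not used.
#'
#' @param fastq_in path to a FASTQ file (optionally gzipped), or a
#'   [Biostrings::DNAStringSet] / named character vector of read
#'   sequences.
#' @param config a [trim_config()].
#' @param fastq_out optional path; retained reads are written as FASTQ.
#' @param require_adapter if `TRUE`, reads in which no adapter match was
#'   found are discarded rather than kept.
#' @return A list with elements `reads` (a named [Biostrings::DNAStringSet]
#'   of retained inserts) and `report` (a one-row data.frame with columns
#'   `n_input`, `n_adapter_trimmed`, `n_discarded`, `n_retained`).
#' @examples
#' cfg <- trim_config()
#' fq <- c(r1 = paste0("AAAA", strrep("ACGT", 6), "AAAA", cfg$adapter))
#' trim_library(fq, cfg)$report
#' @export
trim_library <- function(fastq_in, config = trim_config(),
                         fastq_out = NULL, require_adapter = FALSE) {
  seqs <- read_sequences(fastq_in)
  n_in <- length(seqs)
  if (n_in == 0L) {
    reads <- Biostrings::DNAStringSet()
    if (!is.null(fastq_out))
      Biostrings::writeXStringSet(reads, fastq_out, format = "fastq")
    return(list(reads = reads,
                report = data.frame(n_input = 0L, n_adapter_trimmed = 0L,
                                    n_discarded = 0L, n_retained = 0L)))
  }
  raw <- as.character(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("read", seq_len(n_in))
  keep_len <- adapter_trim_lengths(raw, config)
  adapter_trimmed <- keep_len < nchar(raw)
  trimmed <- substr(raw, 1L, keep_len)
  final_len <- keep_len - config$force_trim_5p - config$force_trim_3p
  discard <- final_len < config$min_length
  if (require_adapter) discard <- discard | !adapter_trimmed
  inserts <- substr(trimmed, config$force_trim_5p + 1L,
                    keep_len - config$force_trim_3p)
  reads <- Biostrings::DNAStringSet(setNames(inserts[!discard],
                                             ids[!discard]))
  if (!is.null(fastq_out))
    Biostrings::writeXStringSet(reads, fastq_out, format = "fastq")
  list(reads = reads,
       report = data.frame(n_input = n_in,
                           n_adapter_trimmed = sum(adapter_trimmed),
                           n_discarded = sum(discard),
                           n_retained = sum(!discard)))
}

# Accept a FASTQ/FASTA path, DNAStringSet, or character vector.
read_sequences <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    fmt <- if (grepl("\\.(fa|fasta)(\\.gz)?$", x)) "fasta" else "fastq"
    return(Biostrings::readDNAStringSet(x, format = fmt))
  }
  if (is.character(x)) return(Biostrings::DNAStringSet(x))
  stop("cannot interpret reads input of class ", class(x)[1L], call. = FALSE)
}
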