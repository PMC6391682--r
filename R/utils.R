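# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Stop unless all sequences are non-empty and drawn from ACGTN.
check_alphabet <- function(seqs, what = "sequence", allow_n = TRUE) {
  seqs <- as.character(seqs)
  if (any(!nzchar(seqs)))
    stop(what, " must be non-empty", call. = FALSE)
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, seqs)
  if (any(bad))
    stop(what, " contains characters outside ",
         if (allow_n) "ACGTN" else "ACGT",
         " (first offender: record ", which(bad)[1L], ")", call. = FALSE)
  invisible(seqs)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_count <- function(x, positive = TRUE) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == round(x) &&
    (if (positive) x >= 1 else x >= 0)
}

# Muffle the GenomicRanges warning emitted when two range sets share no
# seqlevels: in this package that simply means "no overlap".
quiet_overlap <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("sequence levels in common", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

# Random DNA of length n using the current RNG stream.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
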