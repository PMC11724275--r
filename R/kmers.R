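#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors of A/C/G/T/N
#' (input is normalised to uppercase; N complements to N).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp_dna(c("ACGT", "AAAC"))
revcomp_dna <- function(x) {
  if (length(x) == 0) return(character(0))
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", toupper(x)))
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographic minimum of the k-mer
#' and its reverse complement, which makes all downstream indexing
#' strand-agnostic. k-mers containing characters outside \{A,C,G,T\} have no
#' canonical form and are returned as `NA` so callers can skip them.
#'
#' @param x Character vector of k-mers (all the same length).
#' @return Character vector of canonical k-mers, `NA` where the input
#'   contains a non-ACGT character.
#' @export
#' @examples
#' canonical_kmer(c("TTTTT", "AAAAA", "CCCCT"))
canonical_kmer <- function(x) {
  if (length(x) == 0) return(character(0))
  x <- toupper(x)
  bad <- is.na(x) | grepl("[^ACGT]", x)
  x[bad] <- NA_character_
  rc <- revcomp_dna(x)
  out <- ifelse(!is.na(x) & x <= rc, x, rc)
  out[bad] <- NA_character_
  out
}

#' All k-mers of a sequence
#'
#' Returns the k-mers of `seq` at every start position, canonicalised.
#' Windows overlapping a non-ACGT character yield `NA` (they contribute no
#' k-mer and break unitig/run extension downstream).
#'
#' @param seq Single DNA string.
#' @param k k-mer size.
#' @param canonicalise Return canonical k-mers (default) or raw windows.
#' @return Character vector of length `max(0, nchar(seq) - k + 1)`; entry
#'   `i` is the (canonical) k-mer starting at 0-based position `i - 1`.
#' @export
seq_kmers <- function(seq, k, canonicalise = TRUE) {
  stopifnot(length(seq) == 1, !is.na(seq), k >= 1)
  seq <- toupper(seq)
  n <- nchar(seq) - k + 1
  if (n < 1) return(character(0))
  starts <- seq_len(n)
  win <- substring(seq, starts, starts + k - 1)
  if (canonicalise) canonical_kmer(win) else win
}

# Canonical k-mers of many sequences at once; returns a tibble
# (seq_index, pos [0-based], kmer) with NA kmers kept so run/flank logic can
# see the breaks.
kmer_table_of <- function(seqs, k) {
  seqs <- toupper(seqs)
  n <- pmax(nchar(seqs) - k + 1L, 0L)
  idx <- rep(seq_along(seqs), n)
  pos <- unlist(lapply(n, function(m) seq_len(m) - 1L), use.names = FALSE)
  if (length(idx) == 0) {
    return(tibble::tibble(seq_index = integer(), pos = integer(),
                          kmer = character()))
  }
  win <- substring(seqs[idx], pos + 1L, pos + k)
  tibble::tibble(seq_index = idx, pos = pos, kmer = canonical_kmer(win))
}

# Integer-valued hashed lookup: environment mapping key -> position.
index_env <- function(keys) {
  e <- new.env(hash = TRUE, parent = emptyenv(), size = max(29L, length(keys)))
  if (length(keys)) {
    list2env(stats::setNames(as.list(seq_along(keys)), keys), envir = e)
  }
  e
}

DNA_BASES <- c("A", "C", "G", "T")
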