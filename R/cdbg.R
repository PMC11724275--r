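#' Build a compact de Bruijn graph over target sequences
#'
#' Vertices of the underlying de Bruijn graph are the canonical k-mers of
#' the input sequences; maximal nonbranching paths are merged into unitigs.
#' The graph is bidirected: a k-mer and its reverse complement are one
#' vertex, so `k` must be odd (an odd-length k-mer is never its own reverse
#' complement). Windows containing a non-ACGT character contribute no k-mer
#' and break unitig extension. A k-mer never extends to itself or to its own
#' reverse complement, so homopolymer runs stay in one unitig.
#'
#' Unitig sequences are stored in canonical form (lexicographic minimum of
#' the sequence and its reverse complement) and numbered in lexicographic
#' order, which makes the graph deterministic for fixed input.
#'
#' @param sequences Character vector of DNA strings (a `DNAStringSet` is
#'   also accepted).
#' @param k Odd k-mer size, `k > 1`.
#' @return An object of class `cdbg`: a list with elements `k`,
#'   `unitigs` (tibble: `unitig_id`, `seq`, `n_kmers`) and `kmer_table`
#'   (tibble: `kmer`, `unitig_id`, `offset` (0-based), `orientation`
#'   (`"+"` if the canonical k-mer reads forward along the unitig)).
#' @export
#' @examples
#' g <- build_cdbg("AAACCC", k = 3)
#' g$unitigs
build_cdbg <- function(sequences, k) {
  sequences <- as.character(sequences)
  stopifnot(k > 1, length(sequences) >= 1)
  if (k %% 2 == 0) stop("k must be odd so no k-mer equals its reverse complement")
  kt <- kmer_table_of(sequences, k)
  K <- sort(unique(kt$kmer[!is.na(kt$kmer)]))
  if (length(K) == 0) {
    stop("no usable k-mers: all sequences are shorter than k (or all-N)")
  }

  adj <- cdbg_adjacency(K, k)
  kenv <- index_env(K)

  visited <- logical(length(K))
  unitig_seqs <- character(0)
  order_idx <- order(K)  # already sorted, but keep explicit
  for (i in order_idx) {
    if (visited[i]) next
    visited[i] <- TRUE
    right <- walk_chain(i, TRUE, adj, visited)
    visited[right$visited] <- TRUE
    left <- walk_chain(i, FALSE, adj, visited)
    visited[left$visited] <- TRUE
    s_left <- paste0(revcomp_dna(K[i]), left$bases)
    useq <- paste0(revcomp_dna(s_left), right$bases)
    unitig_seqs <- c(unitig_seqs, canonical_seq(useq))
  }
  unitig_seqs <- sort(unitig_seqs)

  per <- kmer_table_of(unitig_seqs, k)
  win <- substring(unitig_seqs[per$seq_index], per$pos + 1L, per$pos + k)
  kmer_table <- tibble::tibble(
    kmer = per$kmer,
    unitig_id = per$seq_index,
    offset = per$pos,
    orientation = ifelse(win == per$kmer, "+", "-")
  )
  structure(
    list(
      k = k,
      unitigs = tibble::tibble(
        unitig_id = seq_along(unitig_seqs),
        seq = unitig_seqs,
        n_kmers = nchar(unitig_seqs) - k + 1L
      ),
      kmer_table = kmer_table
    ),
    class = "cdbg"
  )
}

# Canonical form of a whole sequence: lexicographic min of seq and revcomp.
canonical_seq <- function(x) {
  rc <- revcomp_dna(x)
  ifelse(x <= rc, x, rc)
}

# Precompute, for every canonical k-mer and both orientations, the
# out-degree and (when unique) the successor's canonical index, orientation
# and appended base. Self-successors (same canonical k-mer) are excluded.
cdbg_adjacency <- function(K, k) {
  n <- length(K)
  fwd <- K
  rev <- revcomp_dna(K)
  suff_f <- substring(fwd, 2L, k)
  suff_r <- substring(rev, 2L, k)
  # candidate raw successor strings: n x 8 (4 fwd, 4 rev)
  cand <- c(
    paste0(rep(suff_f, times = 4), rep(DNA_BASES, each = n)),
    paste0(rep(suff_r, times = 4), rep(DNA_BASES, each = n))
  )
  ccand <- canonical_kmer(cand)
  hit <- match(ccand, K)
  self <- rep(seq_len(n), times = 8)
  hit[!is.na(hit) & hit == self] <- NA_integer_
  dim(hit) <- c(n, 8L)
  present <- !is.na(hit)
  outdeg_f <- rowSums(present[, 1:4, drop = FALSE])
  outdeg_r <- rowSums(present[, 5:8, drop = FALSE])

  pick_unique <- function(cols, outdeg) {
    idx <- rep(NA_integer_, n)
    orient <- rep(NA, n)
    base <- rep(NA_character_, n)
    which1 <- which(outdeg == 1)
    if (length(which1)) {
      sub <- hit[which1, cols, drop = FALSE]
      col <- max.col(!is.na(sub), ties.method = "first")
      sel <- sub[cbind(seq_along(which1), col)]
      idx[which1] <- sel
      raw <- cand[(cols[col] - 1L) * n + which1]
      orient[which1] <- raw == K[sel]
      base[which1] <- substring(raw, k, k)
    }
    list(idx = idx, orient = orient, base = base)
  }
  sf <- pick_unique(1:4, outdeg_f)
  sr <- pick_unique(5:8, outdeg_r)
  list(
    outdeg = cbind(r = outdeg_r, f = outdeg_f),  # column 1 = reverse, 2 = forward
    succ_idx = cbind(sr$idx, sf$idx),
    succ_orient = cbind(sr$orient, sf$orient),
    succ_base = cbind(sr$base, sf$base)
  )
}

# Walk maximal nonbranching extension starting from node `i` in orientation
# `fwd` (TRUE = the canonical string itself). Returns appended bases and the
# node indices consumed. `visited` is read-only here (caller marks).
walk_chain <- function(i, fwd, adj, visited) {
  bases <- character(0)
  taken <- integer(0)
  cur <- i
  cur_or <- if (fwd) 2L else 1L
  repeat {
    if (adj$outdeg[cur, cur_or] != 1L) break
    nxt <- adj$succ_idx[cur, cur_or]
    if (visited[nxt] || nxt %in% taken) break
    nxt_or <- if (adj$succ_orient[cur, cur_or]) 2L else 1L
    # in-degree of the successor = out-degree of its opposite orientation
    if (adj$outdeg[nxt, 3L - nxt_or] != 1L) break
    bases <- c(bases, adj$succ_base[cur, cur_or])
    taken <- c(taken, nxt)
    cur <- nxt
    cur_or <- nxt_or
  }
  list(bases = paste(bases, collapse = ""), visited = taken)
}

#' Look up k-mers in a compact de Bruijn graph
#'
#' Implements the Map(s, u) primitive: for each query k-mer, return the
#' unitig, 0-based offset and orientation at which its canonical form lives,
#' or a missing row if the k-mer is absent from the graph.
#'
#' @param cdbg A `cdbg` object.
#' @param kmers Character vector of query k-mers of length `cdbg$k`.
#' @return Tibble with one row per query: `query`, `found`, `unitig_id`,
#'   `offset`, `orientation` (`"forward"` if the query string itself reads
#'   along the unitig at that offset, `"reverse"` otherwise).
#' @export
lookup_kmers <- function(cdbg, kmers) {
  stopifnot(inherits(cdbg, "cdbg"))
  kmers <- toupper(as.character(kmers))
  if (any(nchar(kmers) != cdbg$k)) {
    stop("query k-mers must have length k = ", cdbg$k)
  }
  canon <- canonical_kmer(kmers)
  m <- match(canon, cdbg$kmer_table$kmer)
  found <- !is.na(m)
  uid <- ifelse(found, cdbg$kmer_table$unitig_id[m], NA_integer_)
  off <- ifelse(found, cdbg$kmer_table$offset[m], NA_integer_)
  win <- rep(NA_character_, length(kmers))
  if (any(found)) {
    win[found] <- substring(cdbg$unitigs$seq[uid[found]],
                            off[found] + 1L, off[found] + cdbg$k)
  }
  tibble::tibble(
    query = kmers,
    found = found,
    unitig_id = uid,
    offset = off,
    orientation = dplyr::case_when(
      !found ~ NA_character_,
      win == kmers ~ "forward",
      TRUE ~ "reverse"
    )
  )
}

#' Canonical k-mer set of a graph
#' @param cdbg A `cdbg` object.
#' @return Sorted character vector of all canonical k-mers in the graph.
#' @export
cdbg_kmers <- function(cdbg) sort(cdbg$kmer_table$kmer)

#' @export
print.cdbg <- function(x, ...) {
  cat("compact de Bruijn graph: k =", x$k, "|",
      nrow(x$unitigs), "unitigs |", nrow(x$kmer_table), "k-mers\n")
  invisible(x)
}

#' Export unitigs as FASTA
#' @param cdbg A `cdbg` object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_unitigs_fasta <- function(cdbg, path) {
  ss <- Biostrings::DNAStringSet(cdbg$unitigs$seq)
  names(ss) <- paste0("unitig_", cdbg$unitigs$unitig_id)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
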