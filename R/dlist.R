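#' Maximal runs of shared k-mers between a D-list sequence and a graph
#'
#' Scans a D-list sequence and returns the maximal runs of consecutive
#' k-mer start positions whose canonical k-mer is present in the target
#' compact de Bruijn graph. Each run corresponds to a stretch of at least
#' k bases occurring in both the D-list and the indexed targets; runs are
#' separated by at least one absent k-mer or a non-ACGT break.
#'
#' @param dlist_seq A single DNA string.
#' @param cdbg A `cdbg` object built with the same `k`.
#' @return Tibble with columns `start`, `end`: 0-based half-open interval of
#'   k-mer start positions. Empty if the sequence is shorter than `k` or
#'   shares no k-mer with the graph.
#' @export
find_common_runs <- function(dlist_seq, cdbg) {
  stopifnot(inherits(cdbg, "cdbg"), length(dlist_seq) == 1)
  k <- cdbg$k
  km <- seq_kmers(dlist_seq, k)
  if (length(km) == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  inside <- !is.na(km) & km %in% cdbg$kmer_table$kmer
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = starts[keep] - 1L, end = ends[keep])
}

#' Extract distinguishing flanking k-mers from a D-list
#'
#' For every maximal run of k-mers shared between a D-list sequence and the
#' target graph, the up-to-`overhang` consecutive k-mers immediately
#' upstream and immediately downstream of the run (in the D-list sequence)
#' are canonicalised and collected as distinguishing flanking k-mers (DFKs).
#' Flank extension on a side stops at the sequence boundary, at a non-ACGT
#' window, and at any k-mer already present in the graph. DFKs are by
#' construction absent from the graph: they are exactly the k-mers that
#' witness that a shared stretch continues into non-target sequence.
#'
#' @param dlist Named character vector (or `DNAStringSet`) of D-list
#'   sequences, e.g. a genome.
#' @param cdbg Target `cdbg`.
#' @param overhang Number of flanking k-mers to take on each side
#'   (`h >= 1`; `h = 1` is the default used in practice).
#' @return A list with class `dfk_extraction`:
#'   * `dfks`: tibble of distinct canonical DFKs with provenance
#'     (`kmer`, `dlist_seq`, `pos` (0-based), `side` (`upstream`/
#'     `downstream`), `rank` (1 = adjacent to the run)); the first
#'     occurrence of each k-mer is kept.
#'   * `report`: list of class `dfk_report` with `N_k` (unique k-mers in
#'     the graph), `M_k` (unique k-mers in the D-list), `dfk_count`,
#'     `run_count`, `overhang`.
#' @export
extract_dfks <- function(dlist, cdbg, overhang = 1L) {
  stopifnot(inherits(cdbg, "cdbg"))
  if (length(overhang) != 1 || is.na(overhang) || overhang < 1) {
    stop("overhang must be an integer >= 1")
  }
  overhang <- as.integer(overhang)
  nms <- names(dlist)
  dlist <- stats::setNames(as.character(dlist), nms)
  if (is.null(names(dlist)) && length(dlist) > 0) {
    names(dlist) <- paste0("dlist_", seq_along(dlist))
  }
  k <- cdbg$k
  graph_kmers <- cdbg$kmer_table$kmer

  rows <- list()
  run_count <- 0L
  M_kmers <- character(0)
  for (sid in seq_along(dlist)) {
    km <- seq_kmers(dlist[[sid]], k)
    if (length(km) == 0) next
    M_kmers <- c(M_kmers, km[!is.na(km)])
    inside <- !is.na(km) & km %in% graph_kmers
    if (!any(inside)) next
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs_s <- starts[r$values]
    runs_e <- ends[r$values]
    run_count <- run_count + length(runs_s)
    for (j in seq_along(runs_s)) {
      for (side in c("upstream", "downstream")) {
        for (h in seq_len(overhang)) {
          pos <- if (side == "upstream") runs_s[j] - h else runs_e[j] + h
          if (pos < 1L || pos > length(km)) break        # sequence boundary
          if (is.na(km[pos])) break                      # non-ACGT break
          if (inside[pos]) break                         # k-mer already in graph
          rows[[length(rows) + 1L]] <- tibble::tibble(
            kmer = km[pos], dlist_seq = names(dlist)[sid],
            pos = pos - 1L, side = side, rank = h
          )
        }
      }
    }
  }
  dfks <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(kmer = character(), dlist_seq = character(),
                   pos = integer(), side = character(), rank = integer())
  dfks <- dplyr::distinct(dfks, .data$kmer, .keep_all = TRUE)
  dfks <- dplyr::arrange(dfks, .data$kmer)
  report <- structure(
    list(
      N_k = length(unique(graph_kmers)),
      M_k = length(unique(M_kmers)),
      dfk_count = nrow(dfks),
      run_count = run_count,
      overhang = overhang
    ),
    class = "dfk_report"
  )
  structure(list(dfks = dfks, report = report), class = "dfk_extraction")
}

#' @export
print.dfk_report <- function(x, ...) {
  cat("DFK extraction: ", x$dfk_count, " DFKs from ", x$run_count,
      " shared runs (overhang ", x$overhang, ")\n",
      "graph k-mers N_k = ", x$N_k, "; D-list k-mers M_k = ", x$M_k, "\n",
      sep = "")
  invisible(x)
}

#' @export
print.dfk_extraction <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Export DFKs as FASTA with provenance headers
#' @param dfks A `dfk_extraction` object (or its `dfks` tibble).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_dfks_fasta <- function(dfks, path) {
  tab <- if (inherits(dfks, "dfk_extraction")) dfks$dfks else dfks
  ss <- Biostrings::DNAStringSet(tab$kmer)
  names(ss) <- sprintf("dfk_%d %s:%d:%s:rank%d", seq_len(nrow(tab)),
                       tab$dlist_seq, tab$pos, tab$side, tab$rank)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
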