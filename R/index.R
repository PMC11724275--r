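#' Build a quantification index
#'
#' Assembles the pseudoalignment index over target sequences: the compact
#' de Bruijn graph, the per-k-mer color sets (which targets contain each
#' canonical k-mer, in either orientation), the transcript-to-gene table,
#' and -- when a D-list is supplied -- the distinguishing flanking k-mer
#' (DFK) store. DFKs are kept apart from the colored k-mers and are never
#' colored: during mapping they act purely as a filter. A reserved D-list
#' pseudo-target id (`n_targets + 1`) is used by the `dfk_onlist` mapping
#' mode; it never appears in the t2g table and is never counted toward
#' genes.
#'
#' Standard mode indexes mature transcripts only; nac mode indexes mature
#' plus nascent (full gene span) targets.
#'
#' @param targets Tibble with `target_id`, `gene_id`, `status`, `seq`
#'   (e.g. rows of [extract_mature_transcripts()] and
#'   [extract_nascent_transcripts()]).
#' @param k Odd k-mer size (default 31).
#' @param dlist Optional named character vector of D-list sequences
#'   (typically the genome) from which DFKs are extracted.
#' @param overhang Flanking k-mers per side of each shared run (default 1).
#' @param mode `"standard"` or `"nac"`; defaults to `"nac"` when any target
#'   has nascent status, else `"standard"`.
#' @return An object of class `quant_index`.
#' @export
build_index <- function(targets, k = 31L, dlist = NULL, overhang = 1L,
                        mode = NULL) {
  stopifnot(is.data.frame(targets), nrow(targets) >= 1,
            all(c("target_id", "gene_id", "status", "seq") %in% names(targets)))
  if (anyDuplicated(targets$target_id)) stop("duplicate target ids")
  if (is.null(mode)) {
    mode <- if (any(targets$status == "nascent")) "nac" else "standard"
  }
  mode <- match.arg(mode, c("standard", "nac"))
  targets <- dplyr::arrange(tibble::as_tibble(targets), .data$target_id)
  short <- nchar(targets$seq) < k
  if (any(short)) {
    warning("skipping ", sum(short), " target(s) shorter than k = ", k)
    targets <- targets[!short, , drop = FALSE]
  }
  if (nrow(targets) == 0) stop("no target of length >= k")

  cdbg <- build_cdbg(targets$seq, k)

  # colors: canonical k-mer -> sorted set of target indices
  kt <- kmer_table_of(targets$seq, k)
  kt <- kt[!is.na(kt$kmer), ]
  cols <- lapply(split(kt$seq_index, kt$kmer), function(v) sort(unique(v)))
  color_kmers <- names(cols)

  dfks <- NULL
  if (!is.null(dlist)) {
    dfks <- extract_dfks(dlist, cdbg, overhang = overhang)
  }
  structure(
    list(
      k = as.integer(k),
      mode = mode,
      targets = targets[, c("target_id", "gene_id", "status", "seq")],
      t2g = targets[, c("target_id", "gene_id", "status")],
      cdbg = cdbg,
      color_kmers = color_kmers,
      color_sets = unname(cols),
      dfks = dfks,
      dlist_target_id = nrow(targets) + 1L
    ),
    class = "quant_index"
  )
}

#' @export
print.quant_index <- function(x, ...) {
  cat("quant_index (", x$mode, "): k = ", x$k, ", ",
      nrow(x$targets), " targets, ", length(x$color_kmers),
      " colored k-mers, ",
      if (is.null(x$dfks)) "no D-list" else
        paste0(nrow(x$dfks$dfks), " DFKs"), "\n", sep = "")
  invisible(x)
}

#' Color set of k-mers
#'
#' @param index A `quant_index`.
#' @param kmers Character vector of k-mers (canonicalised internally).
#' @return List (one element per query) of sorted target index vectors;
#'   `integer(0)` for uncolored k-mers.
#' @export
index_colors <- function(index, kmers) {
  m <- match(canonical_kmer(kmers), index$color_kmers)
  lapply(m, function(i) if (is.na(i)) integer(0) else index$color_sets[[i]])
}

#' Canonical DFK k-mers of an index
#' @param index A `quant_index`.
#' @return Character vector (empty if the index was built without a D-list).
#' @export
index_dfks <- function(index) {
  if (is.null(index$dfks)) character(0) else index$dfks$dfks$kmer
}

#' Dynamically allocated equivalence-class registry
#'
#' Equivalence classes (ECs) map integer ids to target sets. Ids are
#' allocated on demand, in order of first observation during mapping, and
#' are therefore run-local: two runs over different reads may number the
#' same target set differently. Exports key ECs by their sorted target set
#' for reproducibility.
#'
#' @return An `ec_registry` object.
#' @export
new_ec_registry <- function() {
  e <- new.env(parent = emptyenv())
  e$map <- new.env(hash = TRUE, parent = emptyenv())
  e$sets <- list()
  class(e) <- "ec_registry"
  e
}

#' Get (or allocate) the EC id of a target set
#'
#' @param registry An `ec_registry`.
#' @param target_set Nonempty integer vector of target indices.
#' @return Integer EC id (1-based), stable within the registry.
#' @export
get_ec <- function(registry, target_set) {
  stopifnot(inherits(registry, "ec_registry"))
  target_set <- sort(unique(as.integer(target_set)))
  if (length(target_set) == 0) stop("target set must be nonempty")
  key <- paste(target_set, collapse = ",")
  id <- registry$map[[key]]
  if (is.null(id)) {
    id <- length(registry$sets) + 1L
    registry$sets[[id]] <- target_set
    assign(key, id, envir = registry$map)
  }
  id
}

#' Table view of an EC registry
#' @param registry An `ec_registry`.
#' @return Tibble: `ec_id`, `targets` (list of integer vectors).
#' @export
ec_table <- function(registry) {
  tibble::tibble(ec_id = seq_along(registry$sets), targets = registry$sets)
}

#' Serialize / load an index
#'
#' The on-disk form is a versioned JSON container holding k, mode, target
#' records, t2g, colors, DFKs and unitigs. The k-mer lookup table is
#' rebuilt deterministically from the stored unitigs on load, so a
#' round-trip reproduces the index bit-exactly.
#'
#' @param index A `quant_index`.
#' @param path Output path (JSON).
#' @return `path` (write) / the restored `quant_index` (read).
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "quant_index"))
  payload <- list(
    format = "nacquant_index",
    version = 1L,
    k = index$k,
    mode = index$mode,
    targets = index$targets,
    color_kmers = index$color_kmers,
    color_sets = index$color_sets,
    dfks = if (is.null(index$dfks)) NULL else list(
      dfks = index$dfks$dfks,
      report = unclass(index$dfks$report)
    ),
    unitigs = index$cdbg$unitigs$seq
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "nacquant_index") || p$version != 1) {
    stop("not a nacquant index file (or unsupported version): ", path)
  }
  targets <- tibble::as_tibble(p$targets)
  cdbg <- build_cdbg(p$unitigs, p$k)
  dfks <- NULL
  if (!is.null(p$dfks)) {
    tab <- tibble::as_tibble(p$dfks$dfks)
    if (nrow(tab) == 0) {
      tab <- tibble::tibble(kmer = character(), dlist_seq = character(),
                            pos = integer(), side = character(),
                            rank = integer())
    }
    dfks <- structure(
      list(dfks = tab,
           report = structure(as.list(p$dfks$report), class = "dfk_report")),
      class = "dfk_extraction"
    )
  }
  structure(
    list(
      k = as.integer(p$k),
      mode = p$mode,
      targets = targets,
      t2g = targets[, c("target_id", "gene_id", "status")],
      cdbg = cdbg,
      color_kmers = as.character(p$color_kmers),
      color_sets = lapply(p$color_sets, as.integer),
      dfks = dfks,
      dlist_target_id = nrow(targets) + 1L
    ),
    class = "quant_index"
  )
}
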