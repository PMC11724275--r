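#' Collapse UMI records to molecules
#'
#' Records sharing (barcode, UMI) are merged into one molecule whose target
#' set is the intersection of their ECs' target sets; a UMI whose reads
#' disagree entirely (empty intersection) is dropped. The reserved D-list
#' pseudo-target is stripped before gene resolution, so a UMI whose only
#' evidence is the D-list target is dropped too.
#'
#' @param records Tibble `barcode`, `umi`, `ec_id`, `count` (from
#'   [map_reads()]).
#' @param ecs EC table (`ec_id`, `targets`) from the same mapping run.
#' @param index The `quant_index` used for mapping.
#' @return Tibble `barcode`, `umi`, `targets` (list of integer target
#'   indices), `n_reads`.
#' @export
collapse_umis <- function(records, ecs, index) {
  stopifnot(all(c("barcode", "umi", "ec_id", "count") %in% names(records)))
  if (nrow(records) == 0) {
    return(tibble::tibble(barcode = character(), umi = character(),
                          targets = list(), n_reads = integer()))
  }
  sets <- ecs$targets[match(records$ec_id, ecs$ec_id)]
  grp <- paste(records$barcode, records$umi, sep = "\r")
  merged <- lapply(split(sets, grp), function(s) Reduce(intersect, s))
  reads <- vapply(split(records$count, grp), sum, integer(1))
  first <- !duplicated(grp)
  key <- unique(grp)
  out <- tibble::tibble(
    barcode = records$barcode[first][match(key, grp[first])],
    umi = records$umi[first][match(key, grp[first])],
    targets = lapply(merged[key], function(t)
      sort(setdiff(t, index$dlist_target_id))),
    n_reads = unname(reads[key])
  )
  out <- out[lengths(out$targets) > 0, , drop = FALSE]
  dplyr::arrange(out, .data$barcode, .data$umi)
}

#' Classify a target set as nascent, mature or ambiguous
#'
#' For a single-gene target set: mature targets only means the molecule
#' must carry splice evidence unique to processed mRNA (`M`); the nascent
#' target only means intron-touching evidence (`N`); both together means
#' the sequence is compatible with either form (`A`). Multi-gene sets are
#' returned with one status per gene, computed from that gene's own targets
#' within the set.
#'
#' @param target_set Integer vector of target indices.
#' @param index A `quant_index`.
#' @return Tibble `gene_id`, `status` (one row per distinct gene).
#' @export
classify_targets <- function(target_set, index) {
  target_set <- setdiff(target_set, index$dlist_target_id)
  if (length(target_set) == 0 ||
      any(target_set < 1 | target_set > nrow(index$targets))) {
    stop("unknown or empty target set")
  }
  gene <- index$targets$gene_id[target_set]
  status <- index$targets$status[target_set]
  agg <- tibble::tibble(gene_id = gene, status = status)
  dplyr::summarise(
    dplyr::group_by(agg, .data$gene_id),
    status = if (all(.data$status == "mature")) "M"
             else if (all(.data$status == "nascent")) "N"
             else "A",
    .groups = "drop"
  )
}

#' Classify collapsed UMIs
#'
#' @param collapsed Output of [collapse_umis()].
#' @param index A `quant_index`.
#' @return Tibble `barcode`, `umi`, `gene_id`, `status`, `n_genes` --
#'   one row per (UMI, gene); `n_genes` is the number of distinct genes
#'   the UMI is compatible with (1 = uniquely assigned).
#' @export
classify_umis <- function(collapsed, index) {
  if (nrow(collapsed) == 0) {
    return(tibble::tibble(barcode = character(), umi = character(),
                          gene_id = character(), status = character(),
                          n_genes = integer()))
  }
  # flatten all target sets once and aggregate per (UMI, gene) with rowsum,
  # which is much cheaper than a grouped summarise per molecule
  len <- lengths(collapsed$targets)
  row <- rep(seq_len(nrow(collapsed)), len)
  tgt <- unlist(collapsed$targets, use.names = FALSE)
  if (any(tgt < 1 | tgt > nrow(index$targets))) {
    stop("unknown target id in collapsed records")
  }
  gene <- index$targets$gene_id[tgt]
  is_mat <- index$targets$status[tgt] == "mature"
  key <- paste(formatC(row, width = 9, flag = "0"), gene, sep = "\r")
  m_cnt <- rowsum(as.integer(is_mat), key)
  n_cnt <- rowsum(as.integer(!is_mat), key)
  keys <- rownames(m_cnt)
  krow <- as.integer(substring(keys, 1, 9))
  kgene <- substring(keys, 11)
  n_genes <- as.integer(table(factor(krow, levels = seq_len(nrow(collapsed)))))
  tibble::tibble(
    barcode = collapsed$barcode[krow],
    umi = collapsed$umi[krow],
    gene_id = kgene,
    status = ifelse(m_cnt[, 1] > 0 & n_cnt[, 1] > 0, "A",
                    ifelse(m_cnt[, 1] > 0, "M", "N")),
    n_genes = n_genes[krow]
  )
}

#' Build the N / M / A count matrices
#'
#' Each uniquely assigned UMI adds 1 to the matrix of its status at
#' (barcode, gene). Multi-gene UMIs are discarded by default (the field's
#' standard); with `multimapping = TRUE` they instead contribute
#' `1 / n_genes` to each compatible gene, under the status computed from
#' that gene's own targets, so entries need not be whole numbers.
#'
#' @param classified Output of [classify_umis()].
#' @param index A `quant_index` (fixes the gene universe via its t2g).
#' @param multimapping Split multi-gene UMIs uniformly instead of
#'   discarding them.
#' @param barcodes Optional character vector fixing the barcode universe
#'   (rows); defaults to the barcodes observed in `classified`.
#' @return List of class `nma_counts` with sparse barcode-by-gene matrices
#'   `N`, `M`, `A` (`Matrix::dgCMatrix`).
#' @export
count_matrices <- function(classified, index, multimapping = FALSE,
                           barcodes = NULL) {
  genes <- sort(unique(index$t2g$gene_id))
  if (is.null(barcodes)) barcodes <- sort(unique(classified$barcode))
  cl <- classified
  if (!multimapping) cl <- cl[cl$n_genes == 1L, , drop = FALSE]
  weight <- if (nrow(cl)) 1 / cl$n_genes else numeric(0)
  mats <- lapply(c(N = "N", M = "M", A = "A"), function(s) {
    rows <- cl$status == s
    Matrix::sparseMatrix(
      i = match(cl$barcode[rows], barcodes),
      j = match(cl$gene_id[rows], genes),
      x = weight[rows],
      dims = c(length(barcodes), length(genes)),
      dimnames = list(barcodes, genes)
    )
  })
  structure(mats, class = "nma_counts")
}

#' @export
print.nma_counts <- function(x, ...) {
  cat("N/M/A count matrices:", nrow(x$N), "barcodes x", ncol(x$N),
      "genes; UMIs N =", sum(x$N), " M =", sum(x$M), " A =", sum(x$A), "\n")
  invisible(x)
}

#' Sum N / M / A matrices
#'
#' `cell` counts molecules attributable to the cytoplasmic transcriptome
#' (M + A), `nucleus` those attributable to unspliced transcription
#' (N + A), and `total` everything (N + M + A).
#'
#' @param counts An `nma_counts` list (or any list with N, M, A matrices of
#'   equal shape).
#' @param mode One of `"cell"`, `"nucleus"`, `"total"`.
#' @return A sparse barcode-by-gene matrix.
#' @export
sum_matrices <- function(counts, mode = c("cell", "nucleus", "total")) {
  mode <- match.arg(mode)
  if (!all(dim(counts$N) == dim(counts$M)) ||
      !all(dim(counts$M) == dim(counts$A))) {
    stop("N, M, A matrices must have identical shapes")
  }
  switch(mode,
         cell = counts$M + counts$A,
         nucleus = counts$N + counts$A,
         total = counts$N + counts$M + counts$A)
}

#' Transcript-compatibility count (TCC) matrix
#'
#' UMI counts per (EC, barcode), where an EC is keyed by its sorted target
#' set so that output files are reproducible across runs despite run-local
#' EC ids.
#'
#' @param collapsed Output of [collapse_umis()] (target sets already
#'   intersected per UMI).
#' @param index A `quant_index`.
#' @return List with `matrix` (sparse EC-by-barcode) and `ecs` (tibble
#'   `ec_key`, `targets`); rows of the matrix are labelled by `ec_key`,
#'   the comma-separated sorted target ids.
#' @export
tcc_matrix <- function(collapsed, index) {
  if (nrow(collapsed) == 0) {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(0, 0))
    return(list(matrix = m,
                ecs = tibble::tibble(ec_key = character(), targets = list())))
  }
  name_of <- function(t) paste(index$targets$target_id[t], collapse = ",")
  key <- vapply(collapsed$targets, name_of, character(1))
  keys <- sort(unique(key))
  barcodes <- sort(unique(collapsed$barcode))
  m <- Matrix::sparseMatrix(
    i = match(key, keys),
    j = match(collapsed$barcode, barcodes),
    x = rep(1, nrow(collapsed)),
    dims = c(length(keys), length(barcodes)),
    dimnames = list(keys, barcodes)
  )
  uniq <- collapsed$targets[match(keys, key)]
  list(matrix = m, ecs = tibble::tibble(ec_key = keys, targets = uniq))
}

#' Write / read a count matrix as MatrixMarket plus label TSVs
#'
#' Writes `<prefix>.mtx`, `<prefix>.barcodes.txt` (rows) and
#' `<prefix>.genes.txt` (columns).
#'
#' @param mat Sparse barcode-by-gene matrix with dimnames.
#' @param prefix Output path prefix.
#' @return The `.mtx` path (write) / the matrix (read), with dimnames.
#' @export
write_count_matrix <- function(mat, prefix) {
  mtx <- paste0(prefix, ".mtx")
  Matrix::writeMM(methods::as(
    methods::as(mat, "generalMatrix"), "TsparseMatrix"), mtx)
  writeLines(rownames(mat), paste0(prefix, ".barcodes.txt"))
  writeLines(colnames(mat), paste0(prefix, ".genes.txt"))
  invisible(mtx)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(prefix) {
  m <- Matrix::readMM(paste0(prefix, ".mtx"))
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(readLines(paste0(prefix, ".barcodes.txt")),
                      readLines(paste0(prefix, ".genes.txt")))
  m
}

#' One-call quantification pipeline
#'
#' Chains [map_reads()], [collapse_umis()], [classify_umis()] and
#' [count_matrices()].
#'
#' @param index A `quant_index`.
#' @param reads Tibble `barcode`, `umi`, `seq`.
#' @param multimapping,dfk_onlist,barcode_onlist Passed through.
#' @param barcodes Row universe for the matrices (defaults to
#'   `barcode_onlist`, else observed barcodes).
#' @return List: `counts` (`nma_counts`), `stats`, `records`, `ecs`,
#'   `classified`.
#' @export
quantify_reads <- function(index, reads, multimapping = FALSE,
                           dfk_onlist = FALSE, barcode_onlist = NULL,
                           barcodes = NULL) {
  mapping <- map_reads(index, reads, dfk_onlist = dfk_onlist,
                       barcode_onlist = barcode_onlist)
  collapsed <- collapse_umis(mapping$records, mapping$ecs, index)
  classified <- classify_umis(collapsed, index)
  if (is.null(barcodes)) barcodes <- barcode_onlist
  counts <- count_matrices(classified, index, multimapping = multimapping,
                           barcodes = barcodes)
  list(counts = counts, stats = mapping$stats, records = mapping$records,
       ecs = mapping$ecs, classified = classified, collapsed = collapsed)
}
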