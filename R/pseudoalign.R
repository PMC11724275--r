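#' Pseudoalign a single read
#'
#' A read is mapped by intersecting the color sets of its canonical k-mers.
#' k-mers absent from the index are skipped (they carry no evidence), with
#' one exception: a k-mer in the DFK store means the read straddles target
#' and non-target sequence, and the read is discarded (`dfk_filtered`).
#' Under `dfk_onlist = TRUE` a DFK hit instead adds the reserved D-list
#' pseudo-target to the equivalence class, so such reads stay visible
#' downstream instead of silently going unaligned.
#'
#' @param index A `quant_index`.
#' @param read DNA string.
#' @param dfk_onlist Annotate DFK hits instead of discarding the read.
#' @return List with `status` (`"mapped"`, `"unmapped"`, `"dfk_filtered"`),
#'   `targets` (sorted integer target indices, possibly including
#'   `index$dlist_target_id`), and `dfk_hit` (logical).
#' @export
pseudoalign_read <- function(index, read, dfk_onlist = FALSE) {
  stopifnot(inherits(index, "quant_index"), length(read) == 1)
  res <- map_read_batch(index, read, dfk_onlist)
  list(status = res$status[[1]], targets = res$targets[[1]],
       dfk_hit = res$dfk_hit[[1]])
}

# Vectorised core: maps many reads at once.
# Returns tibble(status, targets (list), dfk_hit).
map_read_batch <- function(index, seqs, dfk_onlist = FALSE) {
  n <- length(seqs)
  status <- rep("unmapped", n)
  targets <- rep(list(integer(0)), n)
  dfk_hit <- rep(FALSE, n)
  if (n == 0) {
    return(tibble::tibble(status = character(), targets = list(),
                          dfk_hit = logical()))
  }
  kt <- kmer_table_of(seqs, index$k)
  kt <- kt[!is.na(kt$kmer), , drop = FALSE]
  if (nrow(kt) > 0) {
    dfk_kmers <- index_dfks(index)
    if (length(dfk_kmers)) {
      hit_rows <- kt$kmer %in% dfk_kmers
      dfk_hit[unique(kt$seq_index[hit_rows])] <- TRUE
    }
    cm <- match(kt$kmer, index$color_kmers)
    colored <- !is.na(cm)
    per_read <- split(cm[colored], kt$seq_index[colored])
    for (nm in names(per_read)) {
      i <- as.integer(nm)
      if (dfk_hit[i] && !dfk_onlist) next
      sets <- index$color_sets[unique(per_read[[nm]])]
      inter <- Reduce(intersect, sets)
      if (length(inter) > 0) {
        status[i] <- "mapped"
        targets[[i]] <- sort(inter)
      }
    }
  }
  if (dfk_onlist) {
    # DFK hit annotates rather than discards: append the D-list
    # pseudo-target; reads whose only evidence is a DFK map to it alone.
    only_dfk <- dfk_hit & status == "unmapped"
    status[only_dfk] <- "mapped"
    add <- dfk_hit & status == "mapped"
    targets[add] <- lapply(targets[add], function(t)
      sort(c(t, index$dlist_target_id)))
  } else {
    status[dfk_hit] <- "dfk_filtered"
    targets[dfk_hit] <- list(integer(0))
  }
  tibble::tibble(status = status, targets = targets, dfk_hit = dfk_hit)
}

#' Map barcoded reads to UMI records
#'
#' Pseudoaligns each read and emits one record per mapped read, collapsed
#' to counts over (barcode, UMI, EC). ECs are allocated dynamically, in
#' order of first use; the registry with the id-to-target-set mapping is
#' returned alongside the records (the text analog of a BUS file plus its
#' EC table).
#'
#' @param index A `quant_index`.
#' @param reads Tibble with columns `barcode`, `umi`, `seq`.
#' @param dfk_onlist Annotate DFK hits instead of discarding (see
#'   [pseudoalign_read()]).
#' @param barcode_onlist Optional character vector of accepted barcodes;
#'   reads with other barcodes are dropped before mapping.
#' @return List of class `mapping_result`:
#'   * `records`: tibble `barcode`, `umi`, `ec_id`, `count` (reads),
#'   * `ecs`: tibble `ec_id`, `targets` (list of integer target indices),
#'   * `stats`: list `n_reads`, `mapped`, `unmapped`, `dfk_filtered`,
#'     `dfk_onlist_only` (reads whose EC is the D-list target alone),
#'     `barcode_filtered`.
#' @export
map_reads <- function(index, reads, dfk_onlist = FALSE,
                      barcode_onlist = NULL) {
  stopifnot(inherits(index, "quant_index"),
            all(c("barcode", "umi", "seq") %in% names(reads)))
  n_in <- nrow(reads)
  bc_dropped <- 0L
  if (!is.null(barcode_onlist)) {
    keep <- reads$barcode %in% barcode_onlist
    bc_dropped <- sum(!keep)
    reads <- reads[keep, , drop = FALSE]
  }
  res <- map_read_batch(index, reads$seq, dfk_onlist = dfk_onlist)
  mapped <- res$status == "mapped"
  registry <- new_ec_registry()
  ec_id <- rep(NA_integer_, nrow(reads))
  for (i in which(mapped)) ec_id[i] <- get_ec(registry, res$targets[[i]])
  records <- tibble::tibble(
    barcode = reads$barcode[mapped],
    umi = reads$umi[mapped],
    ec_id = ec_id[mapped]
  )
  records <- dplyr::count(records, .data$barcode, .data$umi, .data$ec_id,
                          name = "count")
  records <- dplyr::arrange(records, .data$barcode, .data$umi, .data$ec_id)
  dfk_only <- sum(mapped & res$dfk_hit &
                    vapply(res$targets, function(t)
                      identical(t, index$dlist_target_id), logical(1)))
  structure(
    list(
      records = records,
      ecs = ec_table(registry),
      stats = list(
        n_reads = n_in,
        mapped = sum(mapped),
        unmapped = sum(res$status == "unmapped"),
        dfk_filtered = sum(res$status == "dfk_filtered"),
        dfk_onlist_only = dfk_only,
        barcode_filtered = bc_dropped
      )
    ),
    class = "mapping_result"
  )
}

#' @export
print.mapping_result <- function(x, ...) {
  s <- x$stats
  cat("mapping result:", s$n_reads, "reads |", s$mapped, "mapped |",
      s$unmapped, "unmapped |", s$dfk_filtered, "DFK-filtered\n")
  invisible(x)
}

#' Read a 10x-style FASTQ pair into a read table
#'
#' R1 carries the cell barcode and UMI as its first
#' `barcode_len + umi_len` bases; R2 carries the cDNA sequence.
#'
#' @param r1_path,r2_path FASTQ paths (may be uncompressed or gzipped).
#' @param barcode_len,umi_len Technical read layout.
#' @return Tibble `barcode`, `umi`, `seq`.
#' @export
read_fastq_pair <- function(r1_path, r2_path, barcode_len = 16L,
                            umi_len = 12L) {
  r1 <- tryCatch(
    Biostrings::readDNAStringSet(r1_path, format = "fastq"),
    error = function(e) stop("malformed FASTQ '", r1_path, "': ",
                             conditionMessage(e))
  )
  r2 <- tryCatch(
    Biostrings::readDNAStringSet(r2_path, format = "fastq"),
    error = function(e) stop("malformed FASTQ '", r2_path, "': ",
                             conditionMessage(e))
  )
  if (length(r1) != length(r2)) {
    stop("R1 and R2 record counts differ (", length(r1), " vs ",
         length(r2), ")")
  }
  tech <- unname(as.character(r1))
  if (length(tech) && any(nchar(tech) < barcode_len + umi_len)) {
    stop("R1 reads shorter than barcode_len + umi_len")
  }
  tibble::tibble(
    barcode = substring(tech, 1L, barcode_len),
    umi = substring(tech, barcode_len + 1L, barcode_len + umi_len),
    seq = unname(as.character(r2))
  )
}

#' Write a read table as a 10x-style FASTQ pair
#'
#' @param reads Tibble `barcode`, `umi`, `seq` (optionally `read_id`).
#' @param r1_path,r2_path Output FASTQ paths.
#' @return Invisibly, c(r1_path, r2_path).
#' @export
write_fastq_pair <- function(reads, r1_path, r2_path) {
  ids <- if ("read_id" %in% names(reads)) reads$read_id else
    paste0("read", seq_len(nrow(reads)))
  tech <- paste0(reads$barcode, reads$umi)
  r1 <- Biostrings::DNAStringSet(tech)
  r2 <- Biostrings::DNAStringSet(reads$seq)
  names(r1) <- ids
  names(r2) <- ids
  Biostrings::writeXStringSet(r1, r1_path, format = "fastq")
  Biostrings::writeXStringSet(r2, r2_path, format = "fastq")
  invisible(c(r1_path, r2_path))
}

#' Write / read the UMI record stream as TSV
#'
#' Plain-text analog of a sorted BUS file: columns barcode, umi, ec_id,
#' count. The EC table goes to a companion file via [write_ec_table()].
#'
#' @param records Tibble `barcode`, `umi`, `ec_id`, `count`.
#' @param path TSV path.
#' @return `path` (write) / tibble (read).
#' @export
write_umi_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_umi_records
#' @export
read_umi_records <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("barcode", "umi", "ec_id", "count"),
                           colClasses = c("character", "character",
                                          "integer", "integer"))
  tibble::as_tibble(tab)
}

#' Write / read an EC table (`ec.txt`)
#'
#' One line per EC: id, tab, comma-separated sorted target ids.
#'
#' @param ecs Tibble `ec_id`, `targets` (list of integer indices).
#' @param index The `quant_index` used for mapping (to name targets).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ec_table <- function(ecs, index, path) {
  name_of <- function(t) {
    ifelse(t == index$dlist_target_id, "__dlist__",
           index$targets$target_id[t])
  }
  lines <- vapply(seq_len(nrow(ecs)), function(i) {
    paste0(ecs$ec_id[i], "\t",
           paste(name_of(ecs$targets[[i]]), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
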