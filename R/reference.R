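#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return Named uppercase character vector of contig sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  # FASTA headers may carry descriptions after the first token
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unname(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Parses exon records (attributes `gene_id` and `transcript_id` required)
#' into tidy gene/transcript/exon tables. GTF coordinates are 1-based
#' inclusive on disk and are converted to 0-based half-open intervals here;
#' all downstream arithmetic uses the converted form. Gene spans are the
#' union span of their exons. The annotation is taken as given: no biotype
#' or level filtering is applied.
#'
#' @param path GTF path.
#' @return A list of class `gene_annotation` with tibbles:
#'   * `genes`: `gene_id`, `contig`, `strand`, `start`, `end`
#'   * `transcripts`: `transcript_id`, `gene_id`
#'   * `exons`: `transcript_id`, `gene_id`, `contig`, `strand`, `start`,
#'     `end`, ordered by genomic coordinate within transcript.
#' @export
read_gtf <- function(path) {
  g <- rtracklayer::readGFF(path)
  g <- tibble::as_tibble(as.data.frame(g))
  ex <- dplyr::filter(g, .data$type == "exon")
  if (nrow(ex) == 0) stop("no exon records in GTF: ", path)
  if (!all(c("gene_id", "transcript_id") %in% names(ex))) {
    stop("GTF exon records must carry gene_id and transcript_id attributes")
  }
  exons <- tibble::tibble(
    transcript_id = as.character(ex$transcript_id),
    gene_id = as.character(ex$gene_id),
    contig = as.character(ex$seqid),
    strand = as.character(ex$strand),
    start = as.integer(ex$start) - 1L,  # to 0-based half-open
    end = as.integer(ex$end)
  )
  new_gene_annotation(exons)
}

#' Assemble an annotation object from an exon table
#'
#' Entry point for annotations built in code (e.g. by the simulator).
#' Intervals are 0-based half-open.
#'
#' @param exons Tibble with columns `transcript_id`, `gene_id`, `contig`,
#'   `strand` (`+` or `-`), `start`, `end`.
#' @return A `gene_annotation` object (see [read_gtf()]).
#' @export
new_gene_annotation <- function(exons) {
  stopifnot(all(c("transcript_id", "gene_id", "contig", "strand",
                  "start", "end") %in% names(exons)))
  if (!all(exons$strand %in% c("+", "-"))) {
    stop("exon strand must be '+' or '-'")
  }
  if (any(exons$end <= exons$start)) stop("empty or inverted exon interval")
  exons <- dplyr::arrange(exons, .data$gene_id, .data$transcript_id,
                          .data$start)
  # exons within a transcript must not overlap
  chk <- dplyr::group_by(exons, .data$transcript_id)
  chk <- dplyr::summarise(
    chk, bad = any(.data$start[-1] < .data$end[-length(.data$end)]) %in% TRUE,
    .groups = "drop"
  )
  if (any(chk$bad)) {
    stop("overlapping exons within transcript(s): ",
         paste(chk$transcript_id[chk$bad], collapse = ", "))
  }
  genes <- dplyr::summarise(
    dplyr::group_by(exons, .data$gene_id),
    contig = .data$contig[1], strand = .data$strand[1],
    start = min(.data$start), end = max(.data$end), .groups = "drop"
  )
  transcripts <- dplyr::distinct(exons, .data$transcript_id, .data$gene_id)
  structure(
    list(genes = genes, transcripts = transcripts, exons = exons),
    class = "gene_annotation"
  )
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene annotation:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,", nrow(x$exons), "exons\n")
  invisible(x)
}

check_contig <- function(annotation_tbl, genome) {
  missing <- setdiff(unique(annotation_tbl$contig), names(genome))
  if (length(missing)) {
    stop("annotation refers to contig(s) absent from the genome: ",
         paste(missing, collapse = ", "))
  }
  len <- nchar(genome)[annotation_tbl$contig]
  if (any(annotation_tbl$start < 0) || any(annotation_tbl$end > len)) {
    stop("interval outside contig bounds")
  }
}

#' Extract mature (spliced) transcript sequences
#'
#' The mature sequence of a transcript is the concatenation of its exon
#' subsequences in genomic order, reverse-complemented for minus-strand
#' transcripts so every target reads 5' to 3' of the mRNA.
#'
#' @param genome Named character vector of contigs (see
#'   [read_genome_fasta()]).
#' @param annotation A `gene_annotation` object.
#' @return Tibble: `target_id`, `gene_id`, `status` (`"mature"`), `seq`,
#'   `length`.
#' @export
extract_mature_transcripts <- function(genome, annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  ex <- annotation$exons
  check_contig(ex, genome)
  piece <- substring(genome[ex$contig], ex$start + 1L, ex$end)
  spliced <- vapply(
    split(seq_len(nrow(ex)), ex$transcript_id),
    function(i) paste(piece[i], collapse = ""), character(1)
  )
  tx <- annotation$transcripts
  seqs <- spliced[tx$transcript_id]
  strand <- annotation$genes$strand[match(tx$gene_id, annotation$genes$gene_id)]
  neg <- strand == "-"
  seqs[neg] <- revcomp_dna(seqs[neg])
  tibble::tibble(
    target_id = tx$transcript_id,
    gene_id = tx$gene_id,
    status = "mature",
    seq = unname(seqs),
    length = nchar(unname(seqs))
  )
}

#' Extract nascent (unspliced) transcript sequences
#'
#' The nascent target of a gene spans the full gene body: one contiguous
#' genomic subsequence over the union span of the gene's exons, containing
#' exons and introns alike, reverse-complemented for minus-strand genes.
#' One nascent target is emitted per gene; overlapping genes yield
#' overlapping nascent targets (their shared k-mers simply acquire
#' multi-gene colors in the index).
#'
#' @inheritParams extract_mature_transcripts
#' @param suffix Suffix appended to `gene_id` to form the nascent target id.
#' @return Tibble: `target_id`, `gene_id`, `status` (`"nascent"`), `seq`,
#'   `length`.
#' @export
extract_nascent_transcripts <- function(genome, annotation, suffix = "-I") {
  stopifnot(inherits(annotation, "gene_annotation"))
  gn <- annotation$genes
  check_contig(gn, genome)
  seqs <- substring(genome[gn$contig], gn$start + 1L, gn$end)
  neg <- gn$strand == "-"
  seqs[neg] <- revcomp_dna(seqs[neg])
  tibble::tibble(
    target_id = paste0(gn$gene_id, suffix),
    gene_id = gn$gene_id,
    status = "nascent",
    seq = unname(seqs),
    length = nchar(unname(seqs))
  )
}

#' Build the transcript-to-gene table
#'
#' One `mature` entry per transcript and one `nascent` entry per gene
#' (target id = `gene_id` plus `suffix`), in deterministic (sorted) order.
#' For a `standard` (mature-only) index pass `mode = "standard"` to omit
#' the nascent entries.
#'
#' @param annotation A `gene_annotation` object.
#' @param mode `"nac"` (mature + nascent) or `"standard"` (mature only).
#' @param suffix Nascent target id suffix.
#' @return Tibble: `target_id`, `gene_id`, `status`.
#' @export
build_t2g <- function(annotation, mode = c("nac", "standard"), suffix = "-I") {
  stopifnot(inherits(annotation, "gene_annotation"))
  mode <- match.arg(mode)
  tx <- annotation$transcripts
  if (anyDuplicated(tx$transcript_id)) stop("duplicate transcript ids")
  if (anyDuplicated(annotation$genes$gene_id)) stop("duplicate gene ids")
  mature <- tibble::tibble(
    target_id = tx$transcript_id, gene_id = tx$gene_id, status = "mature"
  )
  out <- mature
  if (mode == "nac") {
    nascent <- tibble::tibble(
      target_id = paste0(annotation$genes$gene_id, suffix),
      gene_id = annotation$genes$gene_id, status = "nascent"
    )
    if (any(nascent$target_id %in% mature$target_id)) {
      stop("nascent target id collides with a transcript id; ",
           "choose a different suffix")
    }
    out <- dplyr::bind_rows(mature, nascent)
  }
  dplyr::arrange(out, .data$target_id)
}

#' Write / read a transcript-to-gene table as 3-column TSV
#' @param t2g Tibble with `target_id`, `gene_id`, `status`.
#' @param path TSV path.
#' @return `path` (write) or the t2g tibble (read).
#' @export
write_t2g <- function(t2g, path) {
  utils::write.table(t2g[, c("target_id", "gene_id", "status")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_t2g
#' @export
read_t2g <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("target_id", "gene_id", "status"),
                           colClasses = "character")
  tibble::as_tibble(tab)
}

#' Write an annotation to GTF
#'
#' Emits gene, transcript and exon records (coordinates converted back to
#' 1-based inclusive).
#'
#' @param annotation A `gene_annotation` object.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "gene_annotation"))
  ex <- annotation$exons
  gr_ex <- GenomicRanges::GRanges(
    seqnames = ex$contig,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand, type = "exon",
    gene_id = ex$gene_id, transcript_id = ex$transcript_id
  )
  tx_span <- dplyr::summarise(
    dplyr::group_by(ex, .data$transcript_id),
    gene_id = .data$gene_id[1], contig = .data$contig[1],
    strand = .data$strand[1],
    start = min(.data$start), end = max(.data$end), .groups = "drop"
  )
  gr_tx <- GenomicRanges::GRanges(
    seqnames = tx_span$contig,
    ranges = IRanges::IRanges(start = tx_span$start + 1L, end = tx_span$end),
    strand = tx_span$strand, type = "transcript",
    gene_id = tx_span$gene_id, transcript_id = tx_span$transcript_id
  )
  gn <- annotation$genes
  gr_gn <- GenomicRanges::GRanges(
    seqnames = gn$contig,
    ranges = IRanges::IRanges(start = gn$start + 1L, end = gn$end),
    strand = gn$strand, type = "gene",
    gene_id = gn$gene_id, transcript_id = NA_character_
  )
  gr <- c(gr_gn, gr_tx, gr_ex)
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr))]
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
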