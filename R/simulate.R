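#' Simulation configuration
#'
#' Parameters of the synthetic single-cell experiment: a toy genome of
#' `n_genes` genes (alternating exons and introns, random uniform base
#' composition, random strand) separated by intergenic spacers, and a
#' droplet-style read set with cell barcodes and UMIs. Reads are drawn from
#' mature molecules (spliced transcripts), nascent molecules (full gene
#' spans) and intergenic windows according to `origin_mix`; intergenic
#' windows always overlap at least one intergenic base and may straddle a
#' gene boundary, which is exactly the read class a genome D-list exists to
#' filter. Sequencing errors are applied afterwards in three passes --
#' mismatches first, then deletions, then insertions (see
#' [inject_errors()]); the default mismatch rate of 0.5% matches common
#' short-read simulation practice, with indels off by default.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Integer range (min, max) of exons per gene.
#' @param exon_length,intron_length Base-pair ranges (min, max).
#' @param intergenic_fraction Fraction of the contig that is intergenic
#'   spacer (0 makes genes tile the contig).
#' @param n_cells Number of cells (one synthetic barcode each).
#' @param umis_per_cell Molecules captured per cell.
#' @param reads_per_umi Reads sequenced per molecule.
#' @param read_length cDNA read length (R2).
#' @param origin_mix Named numeric proportions (`mature`, `nascent`,
#'   `intergenic`); must sum to 1.
#' @param mismatch_rate,del_rate,ins_rate Per-base error rates in `[0, 1)`.
#' @param barcode_len,umi_len Technical read layout (R1).
#' @param seed Default random seed used by the simulation operations.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20L,
                       exons_per_gene = c(2L, 4L),
                       exon_length = c(150L, 400L),
                       intron_length = c(200L, 600L),
                       intergenic_fraction = 0.3,
                       n_cells = 50L,
                       umis_per_cell = 200L,
                       reads_per_umi = 1L,
                       read_length = 90L,
                       origin_mix = c(mature = 0.55, nascent = 0.35,
                                      intergenic = 0.10),
                       mismatch_rate = 0.005,
                       del_rate = 0,
                       ins_rate = 0,
                       barcode_len = 16L,
                       umi_len = 12L,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    intergenic_fraction = intergenic_fraction,
    n_cells = as.integer(n_cells), umis_per_cell = as.integer(umis_per_cell),
    reads_per_umi = as.integer(reads_per_umi),
    read_length = as.integer(read_length),
    origin_mix = origin_mix, mismatch_rate = mismatch_rate,
    del_rate = del_rate, ins_rate = ins_rate,
    barcode_len = as.integer(barcode_len), umi_len = as.integer(umi_len),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!isTRUE(all.equal(sum(cfg$origin_mix), 1)) ||
      !all(c("mature", "nascent", "intergenic") %in% names(cfg$origin_mix))) {
    stop("origin_mix must be named (mature, nascent, intergenic) and sum to 1")
  }
  rates <- c(cfg$mismatch_rate, cfg$del_rate, cfg$ins_rate)
  if (any(rates < 0) || any(rates >= 1)) stop("error rates must be in [0, 1)")
  if (cfg$n_genes < 1 || cfg$n_cells < 1 || cfg$umis_per_cell < 1) {
    stop("n_genes, n_cells and umis_per_cell must be positive")
  }
  if (cfg$intergenic_fraction < 0 || cfg$intergenic_fraction >= 1) {
    stop("intergenic_fraction must be in [0, 1)")
  }
  if (cfg$read_length > cfg$exons_per_gene[1] * cfg$exon_length[1]) {
    stop("read_length exceeds the shortest possible mature transcript; ",
         "increase exon_length/exons_per_gene or shorten reads")
  }
  invisible(cfg)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# sample() treats a scalar first argument as 1:x; guard degenerate ranges
sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n) else sample(lo:hi, n, replace = TRUE)
}

# Encode integers 0..(4^len - 1) as DNA strings of length len.
int_to_dna <- function(x, len) {
  out <- matrix("A", nrow = length(x), ncol = len)
  for (j in seq_len(len)) {
    out[, len - j + 1L] <- DNA_BASES[(x %% 4L) + 1L]
    x <- x %/% 4L
  }
  apply(out, 1, paste, collapse = "")
}

#' Simulate a toy genome and annotation
#'
#' One contig; genes with alternating exons and introns, random strand,
#' one transcript per gene, separated by intergenic spacers sized so the
#' requested fraction of the contig is intergenic. Deterministic for a
#' fixed seed.
#'
#' @param config A `sim_config`.
#' @param seed Random seed (defaults to `config$seed`).
#' @return List of class `sim_reference`: `genome` (named character),
#'   `annotation` (`gene_annotation`), `config`.
#' @export
simulate_reference <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(seed, {
    n <- config$n_genes
    n_ex <- sample_range(config$exons_per_gene[1], config$exons_per_gene[2],
                         n)
    gene_parts <- vector("list", n)
    gene_len <- integer(n)
    for (g in seq_len(n)) {
      ex <- sample_range(config$exon_length[1], config$exon_length[2],
                         n_ex[g])
      intr <- if (n_ex[g] > 1) {
        sample_range(config$intron_length[1], config$intron_length[2],
                     n_ex[g] - 1L)
      } else integer(0)
      gene_parts[[g]] <- list(exons = ex, introns = intr)
      gene_len[g] <- sum(ex) + sum(intr)
    }
    f <- config$intergenic_fraction
    total_spacer <- round(f / (1 - f) * sum(gene_len))
    spacer <- if (total_spacer > 0) {
      s <- rep(total_spacer %/% (n + 1L), n + 1L)
      s[1] <- s[1] + total_spacer - sum(s)
      s
    } else rep(0L, n + 1L)

    exon_rows <- list()
    cursor <- 0L
    for (g in seq_len(n)) {
      cursor <- cursor + spacer[g]
      gid <- sprintf("gene%02d", g)
      strand <- sample(c("+", "-"), 1)
      p <- gene_parts[[g]]
      pos <- cursor
      for (e in seq_along(p$exons)) {
        exon_rows[[length(exon_rows) + 1L]] <- tibble::tibble(
          transcript_id = paste0(gid, ".t1"), gene_id = gid,
          contig = "chr1", strand = strand,
          start = pos, end = pos + p$exons[e]
        )
        pos <- pos + p$exons[e]
        if (e < length(p$exons)) pos <- pos + p$introns[e]
      }
      cursor <- cursor + gene_len[g]
    }
    contig_len <- cursor + spacer[n + 1L]
    genome <- c(chr1 = random_dna(contig_len))
    annotation <- new_gene_annotation(dplyr::bind_rows(exon_rows))
    structure(list(genome = genome, annotation = annotation, config = config),
              class = "sim_reference")
  })
}

#' Simulate barcoded reads with ground truth
#'
#' Each molecule (one UMI) is drawn from an origin class according to
#' `config$origin_mix`; its reads are uniform windows of the molecule.
#' The expected classification follows sequence compatibility with the
#' gene's two target forms: a window found only in the spliced transcript
#' (it spans an exon-exon junction) is `M`, a window carrying sequence
#' unique to an intron is `N`, a window present in both forms (purely
#' exonic, up to rare single-base coincidences at boundaries) is `A`, and
#' intergenic windows are `filtered` (they never enter the truth
#' matrices). Reads are error-free; apply [inject_errors()] afterwards.
#'
#' @param reference A `sim_reference`.
#' @param seed Random seed (defaults to the config's).
#' @return List of class `truth_bundle`: `reads` (tibble `read_id`,
#'   `barcode`, `umi`, `seq`, `origin`, `expected_class`, `gene_id`),
#'   `truth` (`nma_counts` of expected classes), `barcodes` (the synthetic
#'   on-list), `config`.
#' @export
simulate_reads <- function(reference, seed = reference$config$seed) {
  stopifnot(inherits(reference, "sim_reference"))
  config <- reference$config
  ann <- reference$annotation
  genome <- reference$genome
  L <- config$read_length
  withr::with_seed(seed, {
    mature <- extract_mature_transcripts(genome, ann)
    nascent <- extract_nascent_transcripts(genome, ann)
    genes <- ann$genes
    # intergenic-overlapping window starts (0-based): windows not fully
    # inside any gene span
    contig_len <- nchar(genome[[1]])
    ok_start <- rep(TRUE, contig_len - L + 1L)
    for (g in seq_len(nrow(genes))) {
      lo <- genes$start[g]
      hi <- genes$end[g] - L
      if (hi >= lo) ok_start[(lo + 1L):(hi + 1L)] <- FALSE
    }
    intergenic_starts <- which(ok_start) - 1L

    barcodes <- sort(int_to_dna(
      sample.int(4^config$barcode_len %/% 16L, config$n_cells) - 1L,
      config$barcode_len
    ))
    n_mol <- config$n_cells * config$umis_per_cell
    mol <- tibble::tibble(
      barcode = rep(barcodes, each = config$umis_per_cell),
      umi = int_to_dna(
        unlist(lapply(seq_len(config$n_cells), function(i)
          sample.int(4^config$umi_len %/% 16L, config$umis_per_cell) - 1L)),
        config$umi_len
      ),
      origin = sample(names(config$origin_mix), n_mol, replace = TRUE,
                      prob = config$origin_mix)
    )
    mol$gene_idx <- NA_integer_
    is_gene <- mol$origin != "intergenic"
    mol$gene_idx[is_gene] <- sample.int(nrow(genes), sum(is_gene),
                                        replace = TRUE)
    mol$gene_id <- ifelse(is_gene, genes$gene_id[mol$gene_idx], NA_character_)

    reads <- mol[rep(seq_len(n_mol), each = config$reads_per_umi), ]
    nr <- nrow(reads)
    seqs <- character(nr)
    cls <- character(nr)
    for (i in seq_len(nr)) {
      o <- reads$origin[i]
      if (o == "mature") {
        gi <- reads$gene_idx[i]
        mseq <- mature$seq[gi]
        pos <- sample.int(nchar(mseq) - L + 1L, 1) - 1L
        seqs[i] <- substring(mseq, pos + 1L, pos + L)
        # a window also compatible with the unspliced form is ambiguous;
        # junction-spanning windows (absent from the nascent target) are M
        cls[i] <- if (grepl(seqs[i], nascent$seq[gi], fixed = TRUE))
          "A" else "M"
      } else if (o == "nascent") {
        gi <- reads$gene_idx[i]
        nseq <- nascent$seq[gi]
        pos <- sample.int(nchar(nseq) - L + 1L, 1) - 1L
        seqs[i] <- substring(nseq, pos + 1L, pos + L)
        # windows carrying sequence unique to the intron (absent from the
        # spliced form) are N; purely exonic windows are ambiguous
        cls[i] <- if (grepl(seqs[i], mature$seq[gi], fixed = TRUE))
          "A" else "N"
      } else {
        pos <- intergenic_starts[sample.int(length(intergenic_starts), 1)]
        w <- substring(genome[[1]], pos + 1L, pos + L)
        if (sample(c(TRUE, FALSE), 1)) w <- revcomp_dna(w)
        seqs[i] <- w
        cls[i] <- "filtered"
      }
    }
    reads$seq <- seqs
    reads$expected_class <- cls
    reads$read_id <- sprintf("read%06d", seq_len(nr))
    reads <- reads[, c("read_id", "barcode", "umi", "seq", "origin",
                       "expected_class", "gene_id")]

    truth <- truth_matrices(reads, barcodes, sort(genes$gene_id))
    structure(list(reads = reads, truth = truth, barcodes = barcodes,
                   config = config),
              class = "truth_bundle")
  })
}

#' Truth count matrices from simulated reads
#'
#' Tallies one count per UMI at its expected classification (reads of one
#' UMI agree by construction); filtered reads contribute nothing.
#'
#' @param reads Read tibble from [simulate_reads()].
#' @param barcodes,genes Row / column universes.
#' @return An `nma_counts` list.
#' @export
truth_matrices <- function(reads, barcodes, genes) {
  um <- dplyr::distinct(reads[reads$expected_class != "filtered", ],
                        .data$barcode, .data$umi, .data$gene_id,
                        .data$expected_class)
  mats <- lapply(c(N = "N", M = "M", A = "A"), function(s) {
    rows <- um$expected_class == s
    Matrix::sparseMatrix(
      i = match(um$barcode[rows], barcodes),
      j = match(um$gene_id[rows], genes),
      x = rep(1, sum(rows)),
      dims = c(length(barcodes), length(genes)),
      dimnames = list(barcodes, genes)
    )
  })
  structure(mats, class = "nma_counts")
}

#' Inject sequencing errors
#'
#' Per-base independent errors applied in three passes over each read:
#' first substitutions (uniform among the three alternative bases), then
#' deletions, then insertions (a uniform base inserted after the position).
#' Read lengths change under indels. Deterministic for a fixed seed.
#'
#' @param seqs Character vector of reads.
#' @param mismatch_rate,del_rate,ins_rate Per-base rates in `[0, 1)`.
#' @param seed Random seed.
#' @return Character vector of mutated reads.
#' @export
inject_errors <- function(seqs, mismatch_rate = 0.005, del_rate = 0,
                          ins_rate = 0, seed = 1L) {
  stopifnot(all(c(mismatch_rate, del_rate, ins_rate) >= 0),
            all(c(mismatch_rate, del_rate, ins_rate) < 1))
  if (length(seqs) == 0) return(seqs)
  withr::with_seed(seed, {
    chars <- strsplit(toupper(seqs), "", fixed = TRUE)
    lens <- lengths(chars)
    read_of <- rep(seq_along(seqs), lens)
    flat <- unlist(chars, use.names = FALSE)
    # pass 1: mismatches
    if (mismatch_rate > 0) {
      hit <- which(stats::runif(length(flat)) < mismatch_rate)
      if (length(hit)) {
        alt <- vapply(flat[hit], function(b)
          sample(setdiff(DNA_BASES, b), 1), character(1))
        flat[hit] <- alt
      }
    }
    # pass 2: deletions
    if (del_rate > 0) {
      keep <- stats::runif(length(flat)) >= del_rate
      flat <- flat[keep]
      read_of <- read_of[keep]
    }
    # pass 3: insertions (after the position)
    if (ins_rate > 0) {
      ins <- which(stats::runif(length(flat)) < ins_rate)
      if (length(ins)) {
        newb <- sample(DNA_BASES, length(ins), replace = TRUE)
        ord <- c(seq_along(flat), ins + 0.5)
        flat <- c(flat, newb)[order(ord)]
        read_of <- c(read_of, read_of[ins])[order(ord)]
      }
    }
    out <- vapply(split(flat, factor(read_of, levels = seq_along(seqs))),
                  paste, character(1), collapse = "")
    unname(out)
  })
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("simulated reference:", nchar(x$genome[[1]]), "bp contig,",
      nrow(x$annotation$genes), "genes\n")
  invisible(x)
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat("truth bundle:", nrow(x$reads), "reads,",
      length(x$barcodes), "cells; expected classes:",
      paste(names(table(x$reads$expected_class)),
            table(x$reads$expected_class), collapse = ", "), "\n")
  invisible(x)
}
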