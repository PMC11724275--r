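# Brute-force oracles and fixture builders shared across the suite.
# Oracles deliberately avoid the package's index/graph machinery: they work
# by direct substring scans and naive double loops.

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Canonical k-mer set of sequences, by direct window scan.
oracle_kmer_set <- function(seqs, k) {
  out <- unlist(lapply(seqs, function(s) {
    n <- nchar(s) - k + 1
    if (n < 1) return(character(0))
    win <- substring(s, seq_len(n), seq_len(n) + k - 1)
    win
  }))
  canon <- canonical_kmer(out)
  sort(unique(canon[!is.na(canon)]))
}

# Membership of a query k-mer in a sequence set, either orientation.
oracle_contains <- function(seqs, kmer) {
  rc <- revcomp_dna(kmer)
  any(vapply(seqs, function(s)
    grepl(kmer, s, fixed = TRUE) || grepl(rc, s, fixed = TRUE), logical(1)))
}

# Color oracle: which targets contain the k-mer (either orientation).
oracle_colors <- function(target_seqs, kmer) {
  rc <- revcomp_dna(kmer)
  which(vapply(target_seqs, function(s)
    grepl(kmer, s, fixed = TRUE) || grepl(rc, s, fixed = TRUE), logical(1),
    USE.NAMES = FALSE))
}

# DFK oracle: scan every D-list k-mer, mark membership in the target k-mer
# set, take up to h flanking k-mers on each side of each maximal present
# run, stopping at boundaries, non-ACGT windows and in-graph k-mers.
oracle_dfks <- function(dlist_seqs, target_seqs, k, h = 1) {
  K <- oracle_kmer_set(target_seqs, k)
  found <- character(0)
  for (s in dlist_seqs) {
    n <- nchar(s) - k + 1
    if (n < 1) next
    km <- canonical_kmer(substring(s, seq_len(n), seq_len(n) + k - 1))
    inside <- !is.na(km) & km %in% K
    # maximal runs by explicit scan
    i <- 1
    while (i <= n) {
      if (!inside[i]) { i <- i + 1; next }
      j <- i
      while (j < n && inside[j + 1]) j <- j + 1
      for (side in c(-1, 1)) {
        anchor <- if (side < 0) i else j
        for (step in seq_len(h)) {
          p <- anchor + side * step
          if (p < 1 || p > n) break
          if (is.na(km[p]) || inside[p]) break
          found <- c(found, km[p])
        }
      }
      i <- j + 1
    }
  }
  sort(unique(found))
}

# Naive metric oracle: double loops, rank-then-Pearson Spearman.
oracle_metrics <- function(y, yhat) {
  n <- nrow(y); m <- ncol(y)
  sq <- 0; fp <- 0; fn <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sq <- sq + (y[i, j] - yhat[i, j])^2
    if (y[i, j] == 0 && yhat[i, j] > 0) fp <- fp + 1
    if (y[i, j] > 0 && yhat[i, j] == 0) fn <- fn + 1
  }
  r <- numeric(n); rho <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- suppressWarnings(stats::cor(y[i, ], yhat[i, ]))
    keep <- !(y[i, ] == 0 & yhat[i, ] == 0)
    rho[i] <- if (sum(keep) < 2) NA_real_ else
      suppressWarnings(stats::cor(rank(y[i, keep]), rank(yhat[i, keep])))
  }
  list(rmse = sqrt(sq / (n * m)), fpr = fp / (n * m), fnr = fn / (n * m),
       r = r, rho = rho)
}

# Tiny fixed exon-intron-exon gene on a genome with intergenic flanks.
# Layout (0-based): [0,40) intergenic, exon1 [40,70), intron [70,100),
# exon2 [100,130), [130,170) intergenic.
toy_gene_fixture <- function(seed = 42) {
  withr::with_seed(seed, {
    genome <- c(chr1 = random_dna_str(170))
    ann <- new_gene_annotation(tibble::tibble(
      transcript_id = "tx1", gene_id = "g1", contig = "chr1",
      strand = "+", start = c(40L, 100L), end = c(70L, 130L)
    ))
    list(genome = genome, annotation = ann)
  })
}

# Random (targets, D-list) instance: targets are random sequences; the
# D-list embeds target fragments in random context so shared runs exist.
random_dfk_instance <- function(k = 5, n_targets = 2) {
  targets <- replicate(n_targets, random_dna_str(sample(15:40, 1)))
  dlist <- vapply(seq_len(sample(1:3, 1)), function(i) {
    t <- targets[sample(n_targets, 1)]
    len <- nchar(t)
    a <- sample(len - k, 1)
    b <- min(len, a + sample(k:(2 * k), 1))
    paste0(random_dna_str(sample(0:8, 1)), substring(t, a, b),
           random_dna_str(sample(0:8, 1)))
  }, character(1))
  list(targets = targets, dlist = dlist, k = k)
}

mature_nascent_targets <- function(genome, annotation) {
  dplyr::bind_rows(
    extract_mature_transcripts(genome, annotation),
    extract_nascent_transcripts(genome, annotation)
  )
}
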