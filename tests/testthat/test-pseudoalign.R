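single_target_index <- function() {
  build_index(
    tibble::tibble(target_id = "t1", gene_id = "g1", status = "mature",
                   seq = "AAAAACCCCC"),
    k = 5, dlist = c(d1 = "GGAAAAACCCCCTT")
  )
}

test_that("reads containing a DFK are filtered; clean reads map", {
  idx <- single_target_index()
  res <- pseudoalign_read(idx, "GGAAAAACCC")      # contains DFK GAAAA
  expect_equal(res$status, "dfk_filtered")
  expect_length(res$targets, 0)
  expect_true(res$dfk_hit)

  res <- pseudoalign_read(idx, "AAAAACCCCC")
  expect_equal(res$status, "mapped")
  expect_equal(res$targets, 1L)

  expect_equal(pseudoalign_read(idx, "GTGTGTGTGT")$status, "unmapped")
  expect_equal(pseudoalign_read(idx, "ACG")$status, "unmapped")  # < k
})

test_that("dfk_onlist annotates with the D-list pseudo-target instead of discarding", {
  idx <- single_target_index()
  res <- pseudoalign_read(idx, "GGAAAAACCC", dfk_onlist = TRUE)
  expect_equal(res$status, "mapped")
  expect_true(idx$dlist_target_id %in% res$targets)
  expect_true(1L %in% res$targets)
  # a read whose only index evidence is DFKs maps to the pseudo-target alone
  res <- pseudoalign_read(idx, "TGGAAAATT", dfk_onlist = TRUE)
  expect_equal(res$targets, idx$dlist_target_id)
})

test_that("mapped ECs equal the brute-force color intersection", {
  withr::with_seed(120, {
    for (rep in 1:6) {
      k <- 5
      seqs <- replicate(3, random_dna_str(sample(20:40, 1)))
      targets <- tibble::tibble(
        target_id = paste0("t", 1:3), gene_id = paste0("g", 1:3),
        status = "mature", seq = seqs
      )
      idx <- build_index(targets, k = k)
      for (i in 1:8) {
        # half substring reads (mappable), half random
        read <- if (i %% 2 == 0) {
          src <- seqs[sample(3, 1)]
          a <- sample(nchar(src) - k, 1)
          substring(src, a, min(nchar(src), a + sample(k:(2 * k), 1)))
        } else random_dna_str(sample(k:(2 * k), 1))
        res <- pseudoalign_read(idx, read)
        n <- nchar(read) - k + 1
        wins <- substring(read, seq_len(n), seq_len(n) + k - 1)
        per_win <- lapply(wins, oracle_colors, target_seqs = seqs)
        per_win <- per_win[lengths(per_win) > 0]   # absent k-mers skipped
        want <- if (length(per_win) == 0) integer(0) else
          sort(Reduce(intersect, per_win))
        if (length(want)) {
          expect_equal(res$status, "mapped")
          expect_equal(res$targets, want)
        } else {
          expect_equal(res$status, "unmapped")
        }
      }
      # substring soundness: full-read targets always in the EC
      src <- sample(3, 1)
      a <- sample(nchar(seqs[src]) - 2 * k, 1)
      read <- substring(seqs[src], a, a + 2 * k)
      expect_true(src %in% pseudoalign_read(idx, read)$targets)
    }
  })
})

test_that("the D-list is a no-op for reads drawn from indexed targets", {
  fix <- toy_gene_fixture()
  targets <- mature_nascent_targets(fix$genome, fix$annotation)
  nac_plain <- build_index(targets, k = 7)
  nac_dlist <- build_index(targets, k = 7, dlist = fix$genome)
  withr::with_seed(8, {
    reads <- vapply(1:40, function(i) {
      src <- targets$seq[sample(nrow(targets), 1)]
      a <- sample(nchar(src) - 20, 1)
      substring(src, a, a + 20)
    }, character(1))
  })
  r1 <- map_read_batch(nac_plain, reads)
  r2 <- map_read_batch(nac_dlist, reads)
  expect_equal(r1$status, r2$status)
  expect_equal(r1$targets, r2$targets)
  expect_false(any(r2$dfk_hit))
})

test_that("with a standard index, boundary-crossing reads are filtered not mapped", {
  fix <- toy_gene_fixture()
  targets <- mature_nascent_targets(fix$genome, fix$annotation)
  std <- build_index(targets[targets$status == "mature", ],
                     k = 7, dlist = fix$genome)
  # take the exon1-adjacent downstream flank from the provenance and build
  # the 15 bp reads that contain that k-mer (they straddle the boundary)
  dn <- std$dfks$dfks[std$dfks$dfks$side == "downstream", ]
  p1 <- min(dn$pos) + 1L                   # 1-based start of the flank k-mer
  starts <- (p1 - 8L):p1                   # read starts whose window holds it
  reads <- substring(fix$genome, starts, starts + 14L)
  for (r in reads) {
    expect_equal(pseudoalign_read(std, r)$status, "dfk_filtered")
  }
  # the same index without a D-list never filters those reads, and
  # erroneously maps every one that still carries a full exonic k-mer
  std_plain <- build_index(targets[targets$status == "mature", ], k = 7)
  plain <- vapply(reads, function(r) pseudoalign_read(std_plain, r)$status,
                  character(1), USE.NAMES = FALSE)
  expect_false(any(plain == "dfk_filtered"))
  expect_gte(sum(plain == "mapped"), 5)
})

test_that("map_reads produces sorted records, dynamic ECs and honest stats", {
  idx <- single_target_index()
  reads <- tibble::tibble(
    barcode = rep("AAAACCCC", 14),
    umi = c(rep("ACGT", 10), rep("TTTT", 4)),
    seq = c(rep("AAAAACCCCC", 10),               # 10 copies, one UMI
            rep("GGAAAAACCC", 3),                # DFK reads
            "GTGTGTGTGT")                        # unmapped
  )
  out <- map_reads(idx, reads)
  expect_equal(out$stats$mapped, 10)
  expect_equal(out$stats$dfk_filtered, 3)
  expect_equal(out$stats$unmapped, 1)
  expect_equal(nrow(out$records), 1)             # collapsed to one record
  expect_equal(out$records$count, 10)
  expect_equal(out$ecs$targets[[out$records$ec_id]], 1L)
  # empty input
  empty <- map_reads(idx, reads[0, ])
  expect_equal(nrow(empty$records), 0)
  expect_equal(empty$stats$mapped, 0)
  # barcode on-list drops foreign barcodes before mapping
  onl <- map_reads(idx, reads, barcode_onlist = "TTTTTTTT")
  expect_equal(onl$stats$barcode_filtered, 14)
  expect_equal(nrow(onl$records), 0)
})

test_that("FASTQ pair round-trip preserves barcodes, UMIs and sequences", {
  dir <- withr::local_tempdir()
  reads <- tibble::tibble(
    read_id = c("r1", "r2"),
    barcode = c("AAAACCCCGGGGTTTT", "ACGTACGTACGTACGT"),
    umi = c("ACGTACGTACGT", "TTTTCCCCAAAA"),
    seq = c("AAAAACCCCC", "GGGGGTTTTT")
  )
  write_fastq_pair(reads, file.path(dir, "R1.fq"), file.path(dir, "R2.fq"))
  back <- read_fastq_pair(file.path(dir, "R1.fq"), file.path(dir, "R2.fq"))
  expect_equal(back$barcode, reads$barcode)
  expect_equal(back$umi, reads$umi)
  expect_equal(back$seq, reads$seq)
  expect_error(read_fastq_pair(file.path(dir, "R1.fq"),
                               file.path(dir, "missing.fq")), "FASTQ")
})
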