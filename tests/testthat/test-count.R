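# Two-gene nac index over disjoint random sequences: g1 has an intron,
# g2 is single-exon, so g1 yields M/N/A and g2 only A.
two_gene_index <- function() {
  withr::with_seed(55, {
    genome <- c(chr1 = random_dna_str(420))
    ann <- new_gene_annotation(tibble::tibble(
      transcript_id = c("tx1", "tx1", "tx2"),
      gene_id = c("g1", "g1", "g2"),
      contig = "chr1", strand = "+",
      start = c(30L, 140L, 250L), end = c(90L, 200L, 380L)
    ))
    targets <- mature_nascent_targets(genome, ann)
    list(genome = genome, ann = ann, targets = targets,
         index = build_index(targets, k = 9))
  })
}

test_that("UMI collapse intersects ECs and drops disagreements", {
  idx <- two_gene_index()$index
  reg <- new_ec_registry()
  i_t1 <- which(idx$targets$target_id == "tx1")
  i_n1 <- which(idx$targets$target_id == "g1-I")
  i_t2 <- which(idx$targets$target_id == "tx2")
  ec_both <- get_ec(reg, c(i_t1, i_n1))
  ec_t1 <- get_ec(reg, i_t1)
  ec_t2 <- get_ec(reg, i_t2)
  records <- tibble::tibble(
    barcode = c("b1", "b1", "b2", "b2", "b3"),
    umi = c("u1", "u1", "u2", "u2", "u3"),
    ec_id = c(ec_both, ec_t1, ec_t1, ec_t2, ec_both),
    count = c(1L, 1L, 1L, 1L, 1L)
  )
  out <- collapse_umis(records, ec_table(reg), idx)
  # b1/u1: {t1,n1} ∩ {t1} = {t1}; b2/u2: {t1} ∩ {t2} = {} dropped
  expect_equal(nrow(out), 2)
  expect_equal(out$targets[[which(out$barcode == "b1")]], i_t1)
  expect_equal(out$targets[[which(out$barcode == "b3")]], sort(c(i_t1, i_n1)))
  expect_equal(out$n_reads, c(2L, 1L))
  # single record passes through
  one <- collapse_umis(records[5, ], ec_table(reg), idx)
  expect_equal(nrow(one), 1)
})

test_that("target sets classify to M, N or A per gene", {
  idx <- two_gene_index()$index
  i_t1 <- which(idx$targets$target_id == "tx1")
  i_n1 <- which(idx$targets$target_id == "g1-I")
  expect_equal(classify_targets(i_t1, idx),
               tibble::tibble(gene_id = "g1", status = "M"))
  expect_equal(classify_targets(i_n1, idx),
               tibble::tibble(gene_id = "g1", status = "N"))
  expect_equal(classify_targets(c(i_t1, i_n1), idx),
               tibble::tibble(gene_id = "g1", status = "A"))
  expect_error(classify_targets(99L, idx), "unknown")
  # multi-gene set: per-gene statuses
  i_t2 <- which(idx$targets$target_id == "tx2")
  multi <- classify_targets(c(i_t1, i_n1, i_t2), idx)
  expect_equal(multi$status[multi$gene_id == "g1"], "A")
  expect_equal(multi$status[multi$gene_id == "g2"], "M")
})

test_that("count matrices tally UMIs by status; multimapping splits uniformly", {
  idx <- two_gene_index()$index
  classified <- tibble::tibble(
    barcode = c("b1", "b1", "b1", "b2", "b2"),
    umi = c("u1", "u2", "u3", "u4", "u4"),
    gene_id = c("g1", "g1", "g1", "g1", "g2"),
    status = c("M", "M", "M", "M", "M"),
    n_genes = c(1L, 1L, 1L, 2L, 2L)
  )
  cm <- count_matrices(classified, idx)
  expect_equal(cm$M["b1", "g1"], 3)
  expect_equal(sum(cm$N), 0)
  expect_equal(sum(cm$A), 0)
  expect_equal(sum(cm$M["b2", ]), 0)          # multi-gene discarded
  cm2 <- count_matrices(classified, idx, multimapping = TRUE)
  expect_equal(cm2$M["b2", "g1"], 0.5)
  expect_equal(cm2$M["b2", "g2"], 0.5)
  # conservation: every UMI contributes total weight 1
  expect_equal(sum(cm2$N) + sum(cm2$M) + sum(cm2$A), 4)
})

test_that("sum modes satisfy cell + nucleus - A = total", {
  bc <- c("b1", "b2")
  gn <- c("g1", "g2")
  mk <- function(x) Matrix::Matrix(matrix(x, 2, 2,
                                          dimnames = list(bc, gn)),
                                   sparse = TRUE)
  counts <- structure(list(N = mk(c(2, 0, 1, 0)), M = mk(c(3, 1, 0, 0)),
                           A = mk(c(1, 0, 0, 5))), class = "nma_counts")
  cell <- sum_matrices(counts, "cell")
  nuc <- sum_matrices(counts, "nucleus")
  tot <- sum_matrices(counts, "total")
  expect_equal(cell["b1", "g1"], 4)
  expect_equal(nuc["b1", "g1"], 3)
  expect_equal(tot["b1", "g1"], 6)
  expect_equal(as.matrix(cell + nuc - counts$A), as.matrix(tot))
  # N = 0 everywhere makes cell and total coincide
  counts0 <- counts
  counts0$N <- mk(rep(0, 4))
  expect_equal(as.matrix(sum_matrices(counts0, "cell")),
               as.matrix(sum_matrices(counts0, "total")))
  bad <- counts
  bad$A <- mk(rep(0, 4))[1, , drop = FALSE]
  expect_error(sum_matrices(bad, "cell"), "shape")
})

test_that("TCC matrix counts UMIs per sorted target set", {
  idx <- two_gene_index()$index
  i_t1 <- which(idx$targets$target_id == "tx1")
  i_t2 <- which(idx$targets$target_id == "tx2")
  collapsed <- tibble::tibble(
    barcode = c("b1", "b1", "b1"),
    umi = c("u1", "u2", "u3"),
    targets = list(i_t1, i_t1, sort(c(i_t1, i_t2))),
    n_reads = c(1L, 1L, 1L)
  )
  tcc <- tcc_matrix(collapsed, idx)
  expect_equal(dim(tcc$matrix), c(2L, 1L))
  expect_equal(as.numeric(tcc$matrix["tx1", "b1"]), 2)
  expect_equal(as.numeric(tcc$matrix["tx1,tx2", "b1"]), 1)
  empty <- tcc_matrix(collapsed[0, ], idx)
  expect_equal(dim(empty$matrix), c(0L, 0L))
})

test_that("a sliding error-free read reproduces the classification table", {
  tg <- two_gene_index()
  L <- 31L
  k <- 9L
  gene <- tg$ann$genes[tg$ann$genes$gene_id == "g1", ]
  nasc <- tg$targets$seq[tg$targets$target_id == "g1-I"]
  # classify every window of the gene body against the nac index
  nac <- tg$index
  exon_end <- 90L - gene$start    # local half-open end of exon 1
  intron_end <- 140L - gene$start # local start of exon 2
  starts <- 0:(nchar(nasc) - L)
  res <- map_read_batch(nac, substring(nasc, starts + 1, starts + L))
  cls <- vapply(seq_along(starts), function(i)
    classify_targets(res$targets[[i]], nac)$status, character(1))
  covers_intron <- starts < intron_end & starts + L > exon_end
  expect_true(all(cls[covers_intron] == "N"))
  expect_true(all(cls[!covers_intron] == "A"))   # fully within an exon
  # junction windows of the mature transcript classify M
  mat <- tg$targets$seq[tg$targets$target_id == "tx1"]
  j <- 60L                        # exon 1 contributes 60 bases
  jstarts <- (j - L + 1):(j - 1)
  jres <- map_read_batch(nac, substring(mat, jstarts + 1, jstarts + L))
  jcls <- vapply(seq_along(jstarts), function(i)
    classify_targets(jres$targets[[i]], nac)$status, character(1))
  expect_true(all(jcls == "M"))
  # nac classifications identical with and without a D-list
  nac_d <- build_index(tg$targets, k = k, dlist = tg$genome)
  res_d <- map_read_batch(nac_d, substring(nasc, starts + 1, starts + L))
  expect_equal(res_d$targets, res$targets)
  expect_equal(res_d$status, res$status)
})

test_that("a standard index leaves N empty and boundary reads depend on the D-list", {
  tg <- two_gene_index()
  L <- 31L
  std_mature <- tg$targets[tg$targets$status == "mature", ]
  std <- build_index(std_mature, k = 9)
  std_d <- build_index(std_mature, k = 9, dlist = tg$genome)
  nasc <- tg$targets$seq[tg$targets$target_id == "g1-I"]
  gene <- tg$ann$genes[tg$ann$genes$gene_id == "g1", ]
  exon_end <- 90L - gene$start
  intron_end <- 140L - gene$start
  starts <- 0:(nchar(nasc) - L)
  windows <- substring(nasc, starts + 1, starts + L)
  covers_intron <- starts < intron_end & starts + L > exon_end

  plain <- map_read_batch(std, windows)
  withd <- map_read_batch(std_d, windows)
  # without the D-list some intron-touching windows map erroneously
  expect_gt(sum(plain$status[covers_intron] == "mapped"), 0)
  # with the D-list no intron-touching window maps
  expect_false(any(withd$status[covers_intron] == "mapped"))
  # purely exonic windows are unaffected by the D-list and classify M
  expect_equal(withd$status[!covers_intron], plain$status[!covers_intron])
  expect_true(all(withd$status[!covers_intron] == "mapped"))
  # with only mature targets every mapped UMI is M: N stays identically zero
  reads <- tibble::tibble(
    barcode = "b1", umi = sprintf("u%03d", seq_along(windows)), seq = windows
  )
  q <- quantify_reads(std_d, reads)
  expect_equal(sum(q$counts$N), 0)
  expect_gt(sum(q$counts$M), 0)
})
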