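# Signature-motif scanning and the authentic/rejected partition.

# independent oracle: naive character-by-character sliding-window scan
oracle_scan <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n <- length(ch)
  heme <- integer(0); exxr <- integer(0)
  for (i in seq_len(max(0, n - 9))) {
    w <- ch[i:(i + 9)]
    if (w[1] == "F" && w[4] == "G" && w[8] == "C" && w[10] == "G" && all(w %in% std))
      heme <- c(heme, i)
  }
  for (i in seq_len(max(0, n - 3))) {
    w <- ch[i:(i + 3)]
    if (w[1] == "E" && w[4] == "R" && all(w %in% std))
      exxr <- c(exxr, i)
  }
  list(heme = heme, exxr = exxr,
       authentic = length(heme) > 0 && length(exxr) > 0 && min(exxr) < max(heme))
}

test_that("scan_motifs finds both motifs in order and calls authenticity", {
  s <- scan_motifs("MAEVLRAAAAFGRGRHRCLG")
  expect_identical(s$exxr_positions, 3L)
  expect_identical(s$heme_positions, 11L)
  expect_true(s$authentic)

  # heme motif present but no EXXR anywhere
  s2 <- scan_motifs("MFGRGRHRCLG")
  expect_length(s2$exxr_positions, 0)
  expect_identical(s2$heme_positions, 2L)
  expect_false(s2$authentic)

  # EXXR downstream of the heme motif does not authenticate
  seq_wrong <- paste0("MFAAGAAACAG", "AEAARAA")
  s3 <- scan_motifs(seq_wrong)
  expect_gt(length(s3$heme_positions), 0)
  expect_gt(length(s3$exxr_positions), 0)
  expect_false(s3$authentic)
})

test_that("X never matches a motif position and input is cleaned", {
  # X at the F anchor and at a wildcard position both block the match
  expect_length(scan_motifs("AXAAGAAACAGA")$heme_positions, 0)
  expect_length(scan_motifs("AFXAGAAACAGA")$heme_positions, 0)
  expect_length(scan_motifs("AEXXRA")$exxr_positions, 0)
  # lowercase + terminal stop are tolerated
  s <- scan_motifs("maevlraaaafgrgrhrclg*")
  expect_true(s$authentic)
  expect_error(scan_motifs(""), "empty")
  expect_error(scan_motifs("MAEVB1"), "non-amino-acid")
})

test_that("overlapping matches are all reported in ascending order", {
  # EAERAAR: EXXR at 1 (E..R at 4) and at 3 (E..R at 7)? build explicitly
  s <- scan_motifs("EAEREAAR")
  expect_identical(s$exxr_positions, c(1L, 5L))
  agree <- oracle_scan("EAEREAAR")
  expect_identical(s$exxr_positions, as.integer(agree$exxr))
})

test_that("scan_motifs agrees with the naive sliding-window oracle", {
  set.seed(101)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]
  for (i in 1:200) {
    seq <- paste(sample(aa, sample(20:120, 1), replace = TRUE, prob = c(rep(1, 20), 0.3)),
                 collapse = "")
    got <- scan_motifs(seq)
    want <- oracle_scan(seq)
    expect_identical(got$heme_positions, as.integer(want$heme))
    expect_identical(got$exxr_positions, as.integer(want$exxr))
    expect_identical(got$authentic, want$authentic)
  }
})

test_that("planting motifs authenticates and ablating anchors de-authenticates", {
  set.seed(202)
  for (i in 1:1000) {
    base <- random_nonmotif_protein(60)
    planted <- plant_motifs(base, e_pos = 10, h_pos = 40)
    expect_true(scan_motifs(planted)$authentic)
    ch <- strsplit(planted, "")[[1]]
    anchors_heme <- c(40, 43, 47, 49)
    anchors_exxr <- c(10, 13)
    ch_h <- ch; ch_h[sample(anchors_heme, 1)] <- "A"
    expect_false(scan_motifs(paste(ch_h, collapse = ""))$authentic)
    ch_e <- ch; ch_e[sample(anchors_exxr, 1)] <- "A"
    expect_false(scan_motifs(paste(ch_e, collapse = ""))$authentic)
  }
})

test_that("filter_authentic partitions exhaustively with machine-readable reasons", {
  ok <- plant_motifs(random_nonmotif_protein(60), 10, 40)
  no_exxr <- local({
    ch <- strsplit(ok, "")[[1]]; ch[10] <- "A"; paste(ch, collapse = "")
  })
  recs <- rbind(make_record("a", ok), make_record("b", no_exxr),
                make_record("c", ok))
  out <- filter_authentic(recs)
  expect_identical(out$authentic$id, c("a", "c"))
  expect_identical(out$rejected$id, "b")
  expect_identical(out$rejected$reason, "missing-exxr")
  expect_equal(nrow(out$authentic) + nrow(out$rejected), nrow(recs))

  no_heme <- local({
    ch <- strsplit(ok, "")[[1]]; ch[47] <- "A"; paste(ch, collapse = "")
  })
  wrong_order <- paste0("MFAAGAAACAG", "AEAARAA")
  recs2 <- rbind(make_record("h", no_heme), make_record("w", wrong_order),
                 make_record("x", "MAEV*B"))
  out2 <- filter_authentic(recs2)
  expect_identical(out2$rejected$reason, c("missing-heme", "wrong-order", "bad-sequence"))
})

test_that("filter_authentic handles empty input, duplicates, and order invariance", {
  empty <- make_record("x", "MAEVLRAAAAFGRGRHRCLG")[0, ]
  out <- filter_authentic(empty)
  expect_identical(nrow(out$authentic), 0L)
  expect_identical(nrow(out$rejected), 0L)

  recs <- rbind(make_record("a", "MAEVLRAAAAFGRGRHRCLG"),
                make_record("a", "MAEVLRAAAAFGRGRHRCLG"))
  expect_error(filter_authentic(recs), "duplicate record ids: a")

  set.seed(7)
  many <- do.call(rbind, lapply(1:20, function(i)
    make_record(paste0("g", i), plant_motifs(random_nonmotif_protein(60), 10, 40))))
  shuffled <- many[sample(nrow(many)), ]
  expect_setequal(filter_authentic(many)$authentic$id,
                  filter_authentic(shuffled)$authentic$id)
  # order of the authentic list preserves input order
  expect_identical(filter_authentic(shuffled)$authentic$id, shuffled$id)
})

test_that("rejected fraction equals the planted pseudogene fraction exactly", {
  b <- synthetic_genomes(synthetic_config(seed = 31, pseudo_fraction = 0.1))
  out <- filter_authentic(b$proteins)
  expect_identical(nrow(out$rejected), as.integer(round(0.1 * nrow(b$proteins))))
  expect_setequal(out$rejected$id, b$truth$genes$gene_id[b$truth$genes$pseudo])
})

test_that("protein FASTA round-trips through id|species|cyp_name headers", {
  recs <- rbind(make_record("g1", "MAEVLRAAAAFGRGRHRCLG", "SpA", "CYP63A1"),
                make_record("g2", "MFGRGRHRCLG", "SpB", "CYP512B2"))
  f <- tempfile(fileext = ".fasta")
  write_protein_fasta(recs, f)
  back <- read_protein_fasta(f)
  expect_identical(back[, c("id", "species", "cyp_name", "sequence")],
                   recs[, c("id", "species", "cyp_name", "sequence")])
  # sidecar TSV fallback for plain headers
  f2 <- tempfile(fileext = ".fasta")
  writeLines(c(">g1", recs$sequence[1], ">g2", recs$sequence[2]), f2)
  side <- tempfile(fileext = ".tsv")
  write.table(recs[, c("id", "species", "cyp_name")], side, sep = "\t",
              quote = FALSE, row.names = FALSE)
  back2 <- read_protein_fasta(f2, side)
  expect_identical(back2$cyp_name, recs$cyp_name)
})
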