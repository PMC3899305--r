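# Gene models, structure profiles, similarity, paralog/ortholog calling,
# and intron summaries.

test_that("load_gene_models converts GFF3 1-based inclusive to 0-based half-open", {
  p <- write_test_gff3(gff3_gene("g1", "s1", "+", cbind(1, 300)))
  m <- load_gene_models(p)
  expect_identical(unname(m[["g1"]]$exons[, 1]), 0)
  expect_identical(unname(m[["g1"]]$exons[, 2]), 300)
  expect_identical(structure_profile(m[["g1"]])$n_introns, 0L)
})

test_that("minus-strand genes list the genomically-last exon first", {
  p <- write_test_gff3(gff3_gene("g1", "s1", "-", cbind(c(101, 501), c(200, 800))))
  m <- load_gene_models(p)
  prof <- structure_profile(m[["g1"]])
  expect_identical(prof$exon_lengths, c(300, 100))
  expect_identical(prof$intron_offsets, 300)
})

test_that("CDS features are preferred over exon features, never mixed", {
  lines <- c(gff3_gene("g1", "s1", "+", cbind(c(1, 1001), c(400, 1400)), type = "exon"),
             sprintf("s1\ttest\tCDS\t%d\t%d\t.\t+\t0\tID=g1.c;Parent=g1", c(101, 1001), c(400, 1300)))
  p <- write_test_gff3(lines)
  m <- load_gene_models(p)
  expect_identical(structure_profile(m[["g1"]])$exon_lengths, c(300, 300))
})

test_that("invalid gene models are reported per record", {
  p <- write_test_gff3(gff3_gene("bad", "s1", "+", cbind(c(1, 200), c(300, 500))))
  expect_error(load_gene_models(p), "overlapping")
  p2 <- write_test_gff3(gff3_gene("nostrand", "s1", ".", cbind(1, 300)))
  expect_error(load_gene_models(p2), "strand")
})

test_that("CDS length vs protein length consistency check warns, not errors", {
  p <- write_test_gff3(gff3_gene("g1", "s1", "+", cbind(1, 300)))
  meta_ok <- data.frame(id = "g1", species = "SpA", cyp_name = "CYP63A1",
                        protein_length = 99)   # 3*99+3 == 300
  expect_silent(load_gene_models(p, meta_ok))
  meta_bad <- meta_ok; meta_bad$protein_length <- 120
  expect_warning(load_gene_models(p, meta_bad), "CDS length")
})

test_that("structure profiles follow the worked example and strand invariance", {
  g <- gm("g", cbind(c(0, 200, 500), c(100, 400, 800)))
  prof <- structure_profile(g)
  expect_identical(prof$exon_lengths, c(100, 200, 300))
  expect_identical(prof$n_introns, 2L)
  expect_identical(prof$intron_offsets, c(100, 300))

  single <- structure_profile(gm("s", cbind(0, 300)))
  expect_identical(single$n_introns, 0L)
  expect_length(single$intron_offsets, 0)

  # mirroring coordinates and flipping strand leaves the profile unchanged
  set.seed(73)
  for (i in 1:25) {
    k <- sample(1:6, 1)
    starts <- cumsum(sample(450:900, k)) + sample(1e3, 1)
    ends <- starts + sample(30:400, k)
    span <- max(ends) + 100
    fwd <- gm("f", cbind(starts, ends), strand = "+")
    rev_ <- gm("r", cbind(span - rev(ends), span - rev(starts)), strand = "-")
    expect_identical(structure_profile(fwd)$exon_lengths,
                     structure_profile(rev_)$exon_lengths)
    expect_identical(structure_profile(fwd)$intron_offsets,
                     structure_profile(rev_)$intron_offsets)
  }
})

test_that("structure similarity gates on intron count then scores exon lengths", {
  pa <- structure_profile(gm("a", cbind(c(0, 200, 500), c(100, 400, 800))))
  pb <- structure_profile(gm("b", cbind(c(0, 200, 500), c(100, 403, 800))))
  s <- structure_similarity(pa, pb)                    # |200-203| <= 3
  expect_identical(s$score, 1)
  expect_true(s$same_structure)
  expect_identical(structure_similarity(pa, pa)$score, 1)

  pc <- structure_profile(gm("c", cbind(c(0, 200), c(100, 400))))
  s2 <- structure_similarity(pa, pc)                   # 2 vs 1 introns
  expect_identical(s2$score, 0)
  expect_false(s2$same_structure)

  pd <- structure_profile(gm("d", cbind(c(0, 200, 500), c(100, 450, 800))))
  s3 <- structure_similarity(pa, pd)                   # one exon off by 50
  expect_equal(s3$score, 2 / 3)
  expect_false(s3$same_structure)                      # below theta = 0.8
  expect_true(structure_similarity(pa, pd, theta = 0.6)$same_structure)
})

test_that("similarity is symmetric with scores in [0,1] on random profiles", {
  set.seed(79)
  mk <- function() {
    k <- sample(1:8, 1)
    starts <- cumsum(sample(450:900, k))
    gm(paste0("r", sample(1e6, 1)), cbind(starts, starts + sample(30:400, k)))
  }
  for (i in 1:40) {
    a <- structure_profile(mk()); b <- structure_profile(mk())
    s_ab <- structure_similarity(a, b); s_ba <- structure_similarity(b, a)
    expect_identical(s_ab$score, s_ba$score)
    expect_identical(s_ab$same_structure, s_ba$same_structure)
    expect_gte(s_ab$score, 0); expect_lte(s_ab$score, 1)
    if (s_ab$same_structure) expect_identical(a$n_introns, b$n_introns)
  }
})

test_that("paralog clustering is single linkage over same-structure edges", {
  # A~B and B~C share structure, A~C misses one exon by > tol: one cluster
  a <- gm("A", cbind(c(0, 200), c(100, 400)))          # 100, 200
  b <- gm("B", cbind(c(0, 203), c(103, 400)))          # 103, 197
  c_ <- gm("C", cbind(c(0, 206), c(106, 400)))         # 106, 194
  cl <- cluster_paralogs(list(a, b, c_))
  expect_length(cl$clusters, 1)
  expect_setequal(cl$clusters[[1]], c("A", "B", "C"))
  expect_length(cl$singletons, 0)

  # all pairwise non-matching: no duplicate groups
  d <- gm("D", cbind(0, 400))
  e <- gm("E", cbind(c(0, 300), c(200, 500)))
  cl2 <- cluster_paralogs(list(d, e))
  expect_length(cl2$clusters, 0)
  expect_setequal(cl2$singletons, c("D", "E"))
  expect_identical(cluster_paralogs(list())$clusters, list())
})

test_that("an eightfold-duplicated gene forms a single cluster of eight", {
  base <- cbind(c(0, 200, 500), c(100, 400, 800))
  copies <- lapply(1:8, function(i) gm(paste0("dup", i), base + i * 5000))
  cl <- cluster_paralogs(copies)
  expect_length(cl$clusters, 1)
  expect_length(cl$clusters[[1]], 8)
})

test_that("ortholog candidates are same-structure cross-species pairs", {
  a1 <- gm("a1", cbind(c(0, 200), c(100, 400)), species = "SpA")
  b1 <- gm("b1", cbind(c(0, 201), c(101, 400)), species = "SpB")
  o <- ortholog_candidates(list(a1, b1))
  expect_identical(nrow(o), 1L)
  expect_identical(o$gene_a, "a1")
  expect_identical(o$gene_b, "b1")

  # disjoint intron counts across species: empty
  b2 <- gm("b2", cbind(0, 500), species = "SpB")
  expect_identical(nrow(ortholog_candidates(list(a1, b2))), 0L)
  # single species: empty
  expect_identical(nrow(ortholog_candidates(list(a1, a1))), 0L)

  # one SpA gene vs a five-copy SpB cluster: five pairs (many-to-one)
  base <- cbind(c(0, 200), c(100, 400))
  bs <- lapply(1:5, function(i) gm(paste0("b", i), base + i * 3000, species = "SpB"))
  o5 <- ortholog_candidates(c(list(a1), bs))
  expect_identical(nrow(o5), 5L)
  expect_true(all(o5$gene_a == "a1"))
})

test_that("intron_summary applies the 400-aa filter and the P/I rule", {
  mk <- function(id, n_introns, plen) {
    k <- n_introns + 1
    starts <- seq(0, by = 1000, length.out = k)
    gm(id, cbind(starts, starts + rep(100, k)), protein_length = plen)
  }
  s <- intron_summary(list(mk("a", 13, 450), mk("b", 13, 500), mk("c", 9, 420)))
  expect_identical(s$min_introns, 9L)
  expect_identical(s$max_introns, 13L)
  expect_identical(s$P, 2L)
  expect_identical(s$I, 13L)

  # a short gene is excluded from the count
  s2 <- intron_summary(list(mk("a", 10, 450), mk("b", 12, 350)))
  expect_identical(c(s2$min_introns, s2$max_introns), c(10L, 10L))
  expect_identical(c(s2$P, s2$I), c(1L, 10L))

  # tie on the mode: both listed, P/I reports the smaller count
  s3 <- intron_summary(list(mk("a", 8, 450), mk("b", 8, 450),
                            mk("c", 11, 450), mk("d", 11, 450)))
  expect_identical(s3$modal_counts, c(8L, 11L))
  expect_identical(s3$I, 8L)

  s4 <- intron_summary(list(mk("a", 10, 350)))
  expect_true(s4$na)
  tab <- intron_summary_table(list(mk("a", 13, 450), mk("b", 13, 500), mk("c", 9, 420)))
  expect_identical(tab$min_max, "9-13")
  expect_identical(tab$p_over_i, "2/13")
})

test_that("intron summaries match a brute-force recount on synthetic data", {
  b <- synthetic_genomes(synthetic_config(seed = 17))
  g <- b$truth$genes
  tab <- intron_summary_table(b$models, min_len = 400)
  for (r in seq_len(nrow(tab))) {
    sub <- g[g$family == tab$family[r] & g$species == tab$species[r] &
               g$protein_length >= 400, ]
    ic <- sub$n_exons - 1
    if (nrow(sub) == 0) {
      expect_identical(tab$min_max[r], "NA")
    } else {
      expect_identical(tab$min_max[r], paste0(min(ic), "-", max(ic)))
      tt <- table(ic)
      expect_identical(tab$p_over_i[r],
                       paste(sprintf("%d/%s", max(tt), names(tt)[tt == max(tt)]),
                             collapse = ";"))
    }
  }
})

test_that("synthetic GFF3 round-trips planted structures exactly", {
  b <- synthetic_genomes(synthetic_config(seed = 19))
  d <- tempfile()
  write_synthetic(b, d)
  m <- load_gene_models(file.path(d, "genes.gff3"),
                        utils::read.delim(file.path(d, "names.tsv")))
  expect_identical(length(m), length(b$models))
  for (gid in sample(names(m), 25)) {
    expect_identical(structure_profile(m[[gid]])$exon_lengths,
                     structure_profile(b$models[[gid]])$exon_lengths)
    expect_identical(m[[gid]]$strand, b$models[[gid]]$strand)
    expect_identical(as.character(m[[gid]]$scaffold), as.character(b$models[[gid]]$scaffold))
  }
  # duplicate pairs share identical profiles at zero jitter
  g <- b$truth$genes
  dup <- g[!is.na(g$parent), ][1:10, ]
  for (r in seq_len(nrow(dup))) {
    expect_identical(structure_profile(m[[dup$gene_id[r]]])$exon_lengths,
                     structure_profile(m[[dup$parent[r]]])$exon_lengths)
  }
})

test_that("paralog recovery: ARI is 1 at zero jitter and >= 0.9 at jitter 3", {
  skip_if_not_installed("mclust")
  for (seed in c(3, 4)) {
    b0 <- synthetic_genomes(synthetic_config(seed = seed, jitter_nt = 0))
    keep <- !b0$truth$genes$pseudo
    m0 <- b0$models[b0$truth$genes$gene_id[keep]]
    pred <- predict_paralog_partition(m0)
    expect_identical(mclust::adjustedRandIndex(pred, b0$truth$paralog_cluster[names(pred)]), 1)

    b3 <- synthetic_genomes(synthetic_config(seed = seed, jitter_nt = 3))
    keep3 <- !b3$truth$genes$pseudo
    m3 <- b3$models[b3$truth$genes$gene_id[keep3]]
    pred3 <- predict_paralog_partition(m3)
    expect_gte(mclust::adjustedRandIndex(pred3, b3$truth$paralog_cluster[names(pred3)]), 0.9)
  }
})
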