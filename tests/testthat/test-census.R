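# CYP nomenclature parsing, census building, and the enrichment cutoff.

test_that("parse_cyp_name splits family, subfamily and member", {
  p <- parse_cyp_name("CYP5035C1")
  expect_identical(p$family, "CYP5035")
  expect_identical(p$subfamily, "C")
  expect_identical(p$member, 1L)

  p2 <- parse_cyp_name("CYP63B")
  expect_identical(p2$family, "CYP63")
  expect_identical(p2$subfamily, "B")
  expect_true(is.na(p2$member))

  p3 <- parse_cyp_name("cyp512")   # prefix case-insensitive, bare family
  expect_identical(p3$family, "CYP512")
  expect_true(is.na(p3$subfamily))
  expect_true(is.na(p3$member))

  expect_error(parse_cyp_name("ABC1"), "ABC1")
  expect_error(parse_cyp_name(c("CYP1A2", "P450-63")), "P450-63")
})

test_that("build_census counts per species and family with numeric family order", {
  recs <- data.frame(id = c("a", "b", "c"),
                     species = c("X", "X", "Y"),
                     cyp_name = c("CYP63A1", "CYP63B1", "CYP5144A1"),
                     stringsAsFactors = FALSE)
  cen <- build_census(recs)
  expect_identical(dim(cen$counts), c(2L, 2L))
  expect_identical(cen$families, c("CYP63", "CYP5144"))  # numeric, not lexicographic
  expect_identical(unname(rowSums(cen$counts)), c(2, 1))
  expect_identical(cen$total, 3L)

  empty <- build_census(recs[0, ])
  expect_identical(empty$total, 0L)
  expect_identical(length(empty$families), 0L)

  bad <- recs; bad$cyp_name[2] <- "notacyp"
  expect_error(build_census(bad), "notacyp")
})

test_that("census is permutation-invariant and conserved under relabeling", {
  set.seed(11)
  recs <- data.frame(id = paste0("g", 1:60),
                     species = sample(c("S1", "S2", "S3"), 60, replace = TRUE),
                     cyp_name = paste0(sample(c("CYP63", "CYP512", "CYP5144"), 60,
                                              replace = TRUE), "A", 1:60),
                     stringsAsFactors = FALSE)
  c1 <- build_census(recs)
  c2 <- build_census(recs[sample(60), ])
  expect_identical(c1$counts, c2$counts)
  relab <- recs
  relab$species <- chartr("S", "Z", relab$species)
  expect_identical(unname(build_census(relab)$counts[order(c("Z1","Z2","Z3")), ]),
                   unname(c1$counts))
})

test_that("the 2% cutoff of 1061 total P450s is 21 and enrichment follows it", {
  expect_identical(census_cutoff(1061, 0.02), 21L)
  # a family totalling 183 clears the cutoff of 21
  recs <- data.frame(
    id = paste0("g", 1:(183 + 878)),
    species = rep(c("S1", "S2"), length.out = 1061),
    cyp_name = c(paste0("CYP5144A", 1:183),
                 paste0("CYP", rep(5201:5298, length.out = 878), "A", 1:878)),
    stringsAsFactors = FALSE)
  cen <- build_census(recs)
  expect_identical(cen$total, 1061L)
  e <- enrich(cen, 0.02)
  expect_identical(e$cutoff, 21L)
  expect_true("CYP5144" %in% e$enriched)
})

test_that("enrichment handles edge cases and the species-specific rule", {
  recs <- data.frame(id = paste0("g", 1:10), species = rep(c("A", "B"), 5),
                     cyp_name = paste0("CYP", rep(c(51, 52), 5), "A", 1:10),
                     stringsAsFactors = FALSE)
  cen <- build_census(recs)
  # cutoff floor: round-half-up(0.02*10) = 0 -> floored at 1
  e <- enrich(cen, 0.02)
  expect_identical(e$cutoff, 1L)
  # all totals strictly below the cutoff -> empty enriched list
  e2 <- enrich(cen, 0.9)
  expect_identical(e2$cutoff, 9L)
  expect_length(e2$enriched, 0)
  # species-specific flag: enriched family in <= k species
  recs3 <- data.frame(id = paste0("g", 1:20),
                      species = c(rep("A", 10), rep(c("A", "B"), 5)),
                      cyp_name = c(paste0("CYP99A", 1:10), paste0("CYP7A", 1:10)),
                      stringsAsFactors = FALSE)
  e3 <- enrich(build_census(recs3), fraction = 0.4, k_species_specific = 1)
  expect_setequal(e3$enriched, c("CYP99", "CYP7"))
  expect_identical(e3$species_specific, "CYP99")
  expect_error(enrich(build_census(recs3[0, ])), "zero")
})

test_that("enriched set matches brute force and shrinks as the fraction grows", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(50:300, 1)
    recs <- data.frame(id = paste0("g", 1:n),
                       species = sample(paste0("S", 1:4), n, replace = TRUE),
                       cyp_name = paste0("CYP", sample(c(63, 512, 5035, 5144, 5150), n,
                                                       replace = TRUE), "A", 1:n),
                       stringsAsFactors = FALSE)
    cen <- build_census(recs)
    f <- runif(1, 0.01, 0.5)
    e <- enrich(cen, f)
    # definitional brute force: column sum >= round-half-up(f * total)
    cut <- floor(f * cen$total + 0.5)
    brute <- cen$families[colSums(cen$counts) >= max(1, cut)]
    expect_setequal(e$enriched, brute)
    # monotonicity: raising the fraction never adds a family
    e_hi <- enrich(cen, min(f * 1.5, 0.9))
    expect_true(all(e_hi$enriched %in% e$enriched))
  }
})

test_that("planted synthetic counts are recovered exactly", {
  b <- synthetic_genomes(synthetic_config(seed = 13))
  fa <- filter_authentic(b$proteins)
  cen <- build_census(fa$authentic)
  expect_identical(cen$counts, b$truth$census)
  expect_identical(cen$total, sum(b$truth$census))
})
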