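test_that("profiles are built from ortholog calls with provenance", {
  om <- structure(data.frame(
    family_id = c("ruvA", "ruvB", "ruvC", "ruvA"),
    genome_id = c("g1", "g1", "g1", "g2"),
    gene_id = c("g1_a", "g1_b", "g1_c", "g2_a"),
    raw_score = 1, evalue = 1e-5,
    role = c("ortholog", "ortholog", "ortholog", "paralog")),
    class = c("ortholog_map", "data.frame"))
  genomes <- list(make_genome("g1"), make_genome("g2"), make_genome("g3"))
  p <- build_profile(om, genomes, families = c("ruvA", "ruvB", "ruvC", "recU"))
  expect_equal(unname(p$matrix["g1", ]), c(1L, 1L, 1L, 0L))
  expect_equal(unname(p$matrix["g3", ]), rep(0L, 4))   # empty genome row
  expect_equal(unname(p$matrix["g2", "ruvA"]), 0L)     # paralogs don't count
  expect_equal(p$provenance["g1", "ruvC"], "g1_c")
})

test_that("the trait truth table over (A,B,C,U) matches the signature logic", {
  expected <- function(A, B, C, U) {
    if (A && B && C && !U) "RuvABC"
    else if (A && B && U && !C) "RuvAB+RecU"
    else if (A && B && C && U) "both"
    else if (A && B && !C && !U) "RuvAB-only"
    else "absent"
  }
  for (A in 0:1) for (B in 0:1) for (C in 0:1) for (U in 0:1) {
    row <- c(ruvA = A, ruvB = B, ruvC = C, recU = U)
    tc <- call_trait(row)
    expect_equal(tc$status, expected(A, B, C, U),
                 info = paste(A, B, C, U))
    expect_equal(length(tc$anomaly) > 0, C == 1 && !(A == 1 && B == 1),
                 info = paste(A, B, C, U))
  }
})

test_that("co-occurrence statistics match closed forms and the oracle", {
  m <- matrix(0L, 10, 2, dimnames = list(sprintf("g%02d", 1:10), c("x", "y")))
  m[1:5, "x"] <- 1L; m[1:5, "y"] <- 1L
  p <- phyletic_profile(m)
  co <- cooccurrence(p, "x", "y")
  expect_equal(co$jaccard, 1.0)
  # identical 5/10 profiles: single admissible extreme table
  expect_equal(co$fisher_p, 1 / choose(10, 5), tolerance = 1e-12)
  # complement -> jaccard 0
  m2 <- m; m2[, "y"] <- 1L - m2[, "x"]
  expect_equal(cooccurrence(phyletic_profile(m2), "x", "y")$jaccard, 0)
  # MI(x, x) equals the entropy of x
  expect_equal(cooccurrence(p, "x", "x")$mutual_information,
               -(0.5 * log(0.5) + 0.5 * log(0.5)))
  # symmetry
  set.seed(3)
  m3 <- matrix(rbinom(40, 1, 0.5), 20, 2, dimnames = list(NULL, c("x", "y")))
  rownames(m3) <- sprintf("g%02d", 1:20)
  p3 <- phyletic_profile(m3)
  expect_equal(cooccurrence(p3, "x", "y"), cooccurrence(p3, "y", "x"))
  # all-absent family warns and returns the defined degenerate values
  m4 <- m; m4[, "y"] <- 0L
  expect_warning(co4 <- cooccurrence(phyletic_profile(m4), "x", "y"),
                 "absent")
  expect_equal(co4, list(jaccard = 0, mutual_information = 0, fisher_p = 1))
})

test_that("Fisher p equals hypergeometric enumeration on random tables", {
  set.seed(29)
  for (i in 1:200) {
    cells <- as.vector(stats::rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    expect_equal(
      traitscan:::.fisher_enrichment_p(cells[1], cells[2], cells[3], cells[4]),
      oracle_fisher_p(cells[1], cells[2], cells[3], cells[4]),
      tolerance = 1e-12)
  }
})

test_that("partner ranking excludes anchors and is permutation-equivariant", {
  set.seed(31)
  n <- 30
  anchor <- rbinom(n, 1, 0.5)
  partner <- ifelse(rbinom(n, 1, 0.95) == 1, anchor, 1 - anchor)
  decoys <- matrix(rbinom(n * 5, 1, 0.5), n, 5)
  m <- cbind(ruvC = anchor, yebC = as.integer(partner), decoys)
  colnames(m)[3:7] <- paste0("d", 1:5)
  rownames(m) <- sprintf("g%02d", 1:n)
  storage.mode(m) <- "integer"
  p <- phyletic_profile(m)
  rep1 <- rank_partners(p, "ruvC", c(yebC = 0.8))
  expect_false("ruvC" %in% rep1$family_id)
  expect_equal(rep1$family_id[1], "yebC")
  # relabeling decoys permutes ranks identically
  perm <- c("d3", "d1", "d5", "d2", "d4")
  m2 <- m; colnames(m2)[3:7] <- perm
  rep2 <- rank_partners(phyletic_profile(m2), "ruvC", c(yebC = 0.8))
  expect_equal(rep1$combined[match("d1", rep1$family_id)],
               rep2$combined[match("d3", rep2$family_id)])
  expect_equal(sort(rep1$combined), sort(rep2$combined))
  # a fusion with an anchor lifts the combined score
  fus <- data.frame(gene_id = "g", genome_id = "g01",
                    family_1 = "d1", family_2 = "ruvC")
  rep3 <- rank_partners(p, "ruvC", c(yebC = 0.8), fusions = fus)
  i1 <- match("d1", rep1$family_id); i3 <- match("d1", rep3$family_id)
  expect_gt(rep3$combined[i3], rep1$combined[i1])
})

test_that("per-taxon occurrence fractions partition the genomes", {
  m <- matrix(c(1L, 1L, 1L, 0L), 4, 1,
              dimnames = list(paste0("g", 1:4), "ruvA"))
  p <- phyletic_profile(m)
  genomes <- lapply(1:4, function(i)
    make_genome(paste0("g", i), taxon = "phylum_X"))
  occ <- occurrence_by_taxon(p, genomes)
  expect_equal(occ$n_genomes, 4L)
  expect_equal(occ$frac_ruvA, 0.75)
  calls <- data.frame(genome_id = paste0("g", 1:4),
                      status = c("RuvABC", "RuvABC", "RuvAB-only", "absent"))
  occ2 <- occurrence_by_taxon(p, genomes, trait_calls = calls)
  fracs <- unlist(occ2[grep("frac_status", names(occ2))])
  expect_equal(sum(fracs), 1)
  # unresolvable taxon labels fall into "unmapped" with a warning
  tr <- ape::read.tree(text = "(phylum_X:1,phylum_Y:1);")
  genomes[[4]] <- make_genome("g4", taxon = "phylum_Z")
  expect_warning(occ3 <- occurrence_by_taxon(p, genomes, tr), "unmapped")
  expect_true("unmapped" %in% occ3$taxon)
})
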