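test_that("progressive alignment handles identity, gaps, and invariants", {
  seqs <- c(a = "MKLVAQ", b = "MKLVAQ", c = "MKLVAQ")
  ali <- progressive_align(seqs)
  expect_equal(ncol(ali), 6L)
  expect_false(any(ali == "-"))
  # {"ACDEF", "ACEF"}: one gap column aligning D against '-'
  ali2 <- progressive_align(c(x = "ACDEF", y = "ACEF"))
  expect_equal(ncol(ali2), 5L)
  expect_equal(paste(ali2["y", ], collapse = ""), "AC-EF")
  # single sequence returned unchanged
  ali1 <- progressive_align(c(z = "MKV"))
  expect_equal(unname(msa_to_strings(ali1)), "MKV")
  # ungapping any row reproduces its input; width >= longest input
  set.seed(23)
  seqs3 <- setNames(vapply(1:6, function(i)
    random_protein(sample(20:40, 1)), ""), paste0("s", 1:6))
  ali3 <- progressive_align(seqs3)
  expect_gte(ncol(ali3), max(nchar(seqs3)))
  expect_equal(ungap_rows(ali3), seqs3)
})

test_that("gap-rich columns are masked with a usable column map", {
  rows <- c(a = "AC-E", b = "AC-E", c = "ACDE", d = "-C-E")
  m <- msa_from_strings(rows)
  # column 3 has 3/4 gaps; column 1 has 1/4
  masked <- mask_gappy_columns(m, max_gap_fraction = 0.5)
  expect_equal(ncol(masked), 3L)
  expect_equal(attr(masked, "column_map"), c(1L, 2L, 4L))
  # gapless alignment unchanged
  g <- msa_from_strings(c(a = "ACDE", b = "ACDE"))
  expect_equal(ncol(mask_gappy_columns(g)), 4L)
  # everything masked -> error advising the threshold
  allgap <- msa_from_strings(c(a = "--", b = "A-", c = "-C"))
  expect_error(mask_gappy_columns(allgap, 0.3), "max_gap_fraction")
})

test_that("Kimura-corrected distances match closed forms", {
  # p = 0.1 over 10 columns
  m <- msa_from_strings(c(a = "AAAAAAAAAA", b = "AAAAAAAAAC"))
  d <- protein_distance(m)
  expect_equal(d["a", "b"], -log(1 - 0.1 - 0.2 * 0.01), tolerance = 1e-12)
  expect_equal(diag(d), c(a = 0, b = 0))
  # identical rows -> 0; symmetry and zero diagonal on random alignments
  set.seed(5)
  rows <- setNames(vapply(1:5, function(i) random_protein(30), ""),
                   paste0("s", 1:5))
  dm <- suppressWarnings(protein_distance(msa_from_strings(rows)))
  expect_true(isSymmetric(dm))
  expect_true(all(diag(dm) == 0))
  # beyond the correction domain -> configured ceiling with warning
  far <- msa_from_strings(c(a = paste(rep("A", 20), collapse = ""),
                            b = paste(rep("W", 20), collapse = "")))
  expect_warning(df <- protein_distance(far), "Kimura")
  expect_equal(df["a", "b"], 10)
  # zero overlap is an error
  no <- msa_from_strings(c(a = "AC--", b = "--DE"))
  expect_error(protein_distance(no), "overlap")
})

test_that("neighbor joining recovers additive trees exactly", {
  # four-taxon worked example: tree ((A:1,B:2):1,C:3,D:4)
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(D)
  expect_equal(max(abs(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
                       - D)), 0, tolerance = 1e-12)
  truth <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  expect_equal(phangorn::RF.dist(tr, truth), 0)
  # three taxa: closed-form star lengths
  D3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- neighbor_joining(D3)
  lens <- setNames(tr3$edge.length, tr3$tip.label[tr3$edge[, 2]])
  expect_equal(lens[["A"]], (2 + 3 - 4) / 2)
  expect_equal(lens[["B"]], (2 + 4 - 3) / 2)
  expect_equal(lens[["C"]], (3 + 4 - 2) / 2)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("neighbor joining is exact on random additive matrices", {
  set.seed(37)
  for (i in 1:25) {
    ra <- random_additive(sample(4:8, 1))
    tr <- neighbor_joining(ra$D)
    labs <- rownames(ra$D)
    expect_equal(phangorn::RF.dist(tr, ra$tree), 0)
    expect_lt(max(abs(ape::cophenetic.phylo(tr)[labs, labs] - ra$D)), 1e-9)
  }
})

test_that("neighbor joining agrees with ape on noisy matrices", {
  set.seed(41)
  for (i in 1:10) {
    ra <- random_additive(6)
    D <- ra$D + matrix(runif(36, 0, 0.01), 6, 6)
    D <- (D + t(D)) / 2; diag(D) <- 0
    expect_equal(phangorn::RF.dist(neighbor_joining(D), ape::nj(D)), 0)
  }
})

test_that("bootstrap counts are deterministic and bounded", {
  # two fixed, internally identical clades: the split survives any resample
  rows <- c(a1 = "AAAAAAAAAA", a2 = "AAAAAAAAAA",
            b1 = "CCCCCCCCCC", b2 = "CCCCCCCCCC")
  tr <- bootstrap_support(msa_from_strings(rows), n_replicates = 50, seed = 1)
  expect_equal(unname(attr(tr, "bootstrap")), 50L)
  # determinism and bounds on a random alignment
  set.seed(43)
  rows2 <- setNames(vapply(1:6, function(i) random_protein(40), ""),
                    paste0("s", 1:6))
  m2 <- msa_from_strings(rows2)
  t1 <- bootstrap_support(m2, n_replicates = 30, seed = 9)
  t2 <- bootstrap_support(m2, n_replicates = 30, seed = 9)
  expect_identical(attr(t1, "bootstrap"), attr(t2, "bootstrap"))
  expect_true(all(attr(t1, "bootstrap") >= 0 &
                  attr(t1, "bootstrap") <= 30))
})

test_that("Fitch scoring matches forced cases and the enumeration oracle", {
  tree <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
  m_same <- msa_from_strings(setNames(rep("A", 4), paste0("t", 1:4)))
  expect_equal(parsimony_score(m_same, tree), 0L)
  m_split <- msa_from_strings(setNames(c("A", "A", "C", "C"),
                                       paste0("t", 1:4)))
  expect_equal(parsimony_score(m_split, tree), 1L)
  expect_error(parsimony_score(m_split, ape::rtree(5)), "leaves")
  # oracle comparison over random topologies, columns, and gaps
  set.seed(47)
  states <- c("A", "C", "G", "T")
  for (rep in 1:8) {
    n <- sample(4:5, 1)
    tr <- ape::rtree(n)
    cols <- replicate(6, sample(c(states, "-"), n, TRUE,
                                prob = c(rep(0.22, 4), 0.12)))
    rownames(cols) <- tr$tip.label
    m <- cols
    class(m) <- c("msa", class(m))
    expect_equal(parsimony_score(m, tr), oracle_parsimony(m, tr, states),
                 info = paste("rep", rep))
  }
})

test_that("Fitch scoring agrees with phangorn on protein columns", {
  set.seed(53)
  rows <- setNames(vapply(1:8, function(i) random_protein(30), ""),
                   paste0("s", 1:8))
  m <- msa_from_strings(rows)
  tr <- ape::rtree(8, tip.label = rownames(m))
  pd <- phangorn::phyDat(m, type = "AA")
  expect_equal(parsimony_score(m, tr),
               as.integer(phangorn::parsimony(tr, pd)))
})

test_that("subtype splitting partitions at the midpoint root", {
  # clean two-clade tree
  tr <- ape::read.tree(
    text = "((a1:0.1,a2:0.1):0.5,(b1:0.1,(b2:0.05,b3:0.05):0.05):0.5);")
  lab <- split_subtypes(tr)
  expect_equal(sort(names(lab[lab == lab[["b1"]]])), c("b1", "b2", "b3"))
  expect_equal(sort(names(lab[lab == lab[["a1"]]])), c("a1", "a2"))
  # the larger clade is subtype I by default
  expect_equal(unname(lab[["b1"]]), "I")
  # reference leaf overrides the size rule
  lab2 <- split_subtypes(tr, reference_leaf = "a1")
  expect_equal(unname(lab2[["a1"]]), "I")
  expect_equal(unname(lab2[["b1"]]), "II")
  # two leaves: one per subtype
  tr2 <- ape::read.tree(text = "(x:1,y:1);")
  expect_setequal(unname(split_subtypes(tr2)), c("I", "II"))
  # zero-length tree -> unassigned with warning
  tr0 <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  expect_warning(lab0 <- split_subtypes(tr0), "unassigned")
  expect_true(all(lab0 == "unassigned"))
  # relabeling leaves permutes the assignment identically
  tr_perm <- tr
  tr_perm$tip.label <- sub("^a", "z", tr_perm$tip.label)
  lab3 <- split_subtypes(tr_perm)
  expect_equal(unname(lab3[c("z1", "z2")]), unname(lab[c("a1", "a2")]))
})
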