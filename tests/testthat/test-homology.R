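test_that("local alignment matches hand-derived and degenerate cases", {
  # perfect self-alignment: sum of BLOSUM62 diagonal entries
  al <- smith_waterman("ACDEFG", "ACDEFG")
  expect_equal(al$raw_score, 4 + 9 + 6 + 5 + 6 + 6)
  expect_equal(al$a_start, 0L); expect_equal(al$a_end, 6L)
  # no positive-scoring residue pair -> empty alignment, score 0
  al0 <- smith_waterman("AAAA", "WWWW")
  expect_equal(al0$raw_score, 0)
  expect_equal(al0$a_end - al0$a_start, 0L)
  expect_error(smith_waterman("", "ACD"), "empty")
})

test_that("local alignment score is symmetric and maximal on self", {
  set.seed(7)
  for (i in 1:20) {
    a <- random_protein(sample(5:40, 1))
    b <- random_protein(sample(5:40, 1))
    expect_equal(smith_waterman(a, b)$raw_score,
                 smith_waterman(b, a)$raw_score)
    expect_gte(smith_waterman(a, a)$raw_score,
               smith_waterman(a, b)$raw_score)
  }
})

test_that("alignment equals the exhaustive-matching oracle on short pairs", {
  mat <- traitscan:::blosum62()
  set.seed(11)
  alph <- c("A", "C", "D")
  for (i in 1:60) {
    a <- paste(sample(alph, sample(1:4, 1), TRUE), collapse = "")
    b <- paste(sample(alph, sample(1:4, 1), TRUE), collapse = "")
    expect_equal(smith_waterman(a, b)$raw_score,
                 oracle_local_align(a, b, mat, 11, 1),
                 info = paste(a, b))
  }
})

test_that("batched score kernel agrees with the traceback kernel", {
  set.seed(13)
  seqs <- replicate(6, random_protein(sample(20:60, 1)))
  alpha <- rownames(traitscan:::blosum62())
  enc <- lapply(seqs, function(s) match(strsplit(s, "")[[1]], alpha))
  S <- traitscan:::sw_scores_cpp(enc, enc, traitscan:::blosum62(), 11, 1)
  for (i in 1:6) for (j in 1:6)
    expect_equal(S[i, j], smith_waterman(seqs[i], seqs[j])$raw_score)
})

test_that("E-values follow the Karlin-Altschul form", {
  e <- evalue(36, 200, 200, lambda_ = 0.318, K = 0.134)
  expect_equal(e, 0.134 * 200 * 200 * exp(-0.318 * 36))
  expect_equal(e, 0.0572, tolerance = 1e-2)
  # strictly decreasing in score; linear in length
  expect_gt(evalue(30, 200, 200), evalue(31, 200, 200))
  expect_equal(evalue(36, 400, 200), 2 * evalue(36, 200, 200))
  expect_error(evalue(10, 0, 200), "length")
})

test_that("family scanning retains homologs and drops unrelated genes", {
  set.seed(17)
  seed_seq <- random_protein(120)
  member <- seed_seq                      # identical -> must be retained
  g <- genome("gA", "t", data.frame(
    gene_id = c("gA_1", "gA_2"), contig_id = "chr1",
    start = c(100L, 1000L), end = c(460L, 1360L), strand = "+",
    protein = c(member, random_protein(120)), stringsAsFactors = FALSE))
  hits <- find_family_members(list(g), c(s1 = seed_seq),
                              c(s1 = "famA"), evalue_cutoff = 0.1,
                              lambda_ = 0.1, K = 0.1)
  expect_true("gA_1" %in% hits$subject_id)
  # the unrelated gene's E-value exceeds the cutoff at stringent lambda
  expect_false("gA_2" %in% hits$subject_id)
})

test_that("bidirectional best hits form a partial matching with tie rules", {
  hits_ab <- data.frame(
    query_id = c("x1", "x1", "x2", "x3"),
    subject_id = c("y1", "y2", "y2", "y3"),
    raw_score = c(100, 50, 80, 60), evalue = c(1e-9, 1e-4, 1e-6, 1e-5))
  hits_ba <- data.frame(
    query_id = c("y1", "y2", "y3"),
    subject_id = c("x1", "x2", "x1"),          # y3's best is x1, not x3
    raw_score = c(100, 80, 70), evalue = c(1e-9, 1e-6, 1e-5))
  bbh <- bidirectional_best_hits(hits_ab, hits_ba)
  expect_setequal(bbh$a_id, c("x1", "x2"))
  expect_false("x3" %in% bbh$a_id)             # reciprocity violated
  expect_true(all(!duplicated(bbh$a_id)) && all(!duplicated(bbh$b_id)))
  # equal score and E-value -> lexicographically smaller subject wins
  tie_ab <- data.frame(query_id = "x1", subject_id = c("y2", "y1"),
                       raw_score = 50, evalue = 1e-5)
  tie_ba <- data.frame(query_id = c("y1", "y2"), subject_id = "x1",
                       raw_score = 50, evalue = 1e-5)
  bbh2 <- bidirectional_best_hits(tie_ab, tie_ba)
  expect_equal(bbh2$b_id, "y1")
})

test_that("planted orthologs are recovered and extras become paralogs", {
  set.seed(19)
  fams <- paste0("fam", 1:4)
  seeds <- setNames(vapply(fams, function(f) random_protein(100), ""), fams)
  mutate <- function(s) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(length(ch), 5)
    ch[i] <- vapply(ch[i], function(x)
      sample(setdiff(traitscan:::AA_ALPHABET20, x), 1), "")
    paste(ch, collapse = "")
  }
  mk <- function(id) {
    prot <- vapply(seeds, mutate, "")
    genome(id, "t", data.frame(
      gene_id = paste0(id, "_", fams), contig_id = "chr1",
      start = seq(100L, by = 500L, length.out = 4),
      end = seq(100L, by = 500L, length.out = 4) + 300L,
      strand = "+", protein = unname(prot), stringsAsFactors = FALSE))
  }
  genomes <- list(mk("gA"), mk("gB"))
  hits <- find_family_members(genomes, seeds, setNames(fams, fams))
  om <- assign_orthologs(hits)
  orth <- om[om$role == "ortholog", ]
  expect_equal(nrow(orth), 8L)                # 4 families x 2 genomes
  expect_true(all(orth$gene_id == paste0(orth$genome_id, "_", orth$family_id)))
  # no gene assigned as ortholog of two families
  expect_false(any(duplicated(orth$gene_id)))
})
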