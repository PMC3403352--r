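#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment under an affine gap model where a gap of length
#' `k` costs `gap_open + k * gap_extend`. The traceback is deterministic:
#' it starts at the highest-scoring cell (ties broken by lowest row, then
#' lowest column) and prefers diagonal over up over left moves.
#'
#' @param seq_a,seq_b amino-acid strings (non-empty).
#' @param matrix substitution matrix with residue dimnames; default BLOSUM62.
#' @param gap_open,gap_extend non-negative gap costs, `gap_open >= gap_extend`.
#' @return a list with `raw_score` and the aligned spans `a_start`, `a_end`,
#'   `b_start`, `b_end` (0-based half-open; empty spans for score 0).
#' @export
smith_waterman <- function(seq_a, seq_b, matrix = blosum62(),
                           gap_open = 11, gap_extend = 1) {
  .stop_if(!nzchar(seq_a) || !nzchar(seq_b), "empty sequence")
  .stop_if(gap_open < gap_extend || gap_extend < 0,
           "need gap_open >= gap_extend >= 0")
  alpha <- rownames(matrix)
  ia <- match(strsplit(seq_a, "")[[1]], alpha)
  ib <- match(strsplit(seq_b, "")[[1]], alpha)
  .stop_if(anyNA(ia) || anyNA(ib), "sequence letter not in substitution matrix")
  r <- sw_affine_cpp(ia, ib, matrix, gap_open, gap_extend)
  # spans from the kernel are already 0-based half-open
  list(raw_score = r$score, a_start = r$a_start, a_end = r$a_end,
       b_start = r$b_start, b_end = r$b_end)
}

#' Karlin-Altschul E-value for an ungapped-statistics local alignment score
#'
#' `E = K * len_a * len_b * exp(-lambda * raw_score)`. The defaults
#' (`lambda = 0.318`, `K = 0.134`) are the published ungapped BLOSUM62
#' constants, adequate for ranking at this scale.
#'
#' @param raw_score alignment raw score.
#' @param len_a,len_b positive sequence lengths.
#' @param lambda_,K positive Karlin-Altschul parameters.
#' @return the E-value (positive real).
#' @export
evalue <- function(raw_score, len_a, len_b, lambda_ = 0.318, K = 0.134) {
  .stop_if(any(len_a <= 0) || any(len_b <= 0), "non-positive sequence length")
  .stop_if(lambda_ <= 0 || K <= 0, "lambda and K must be positive")
  K * len_a * len_b * exp(-lambda_ * raw_score)
}

#' Scan genomes for members of seed-defined protein families
#'
#' Aligns every gene against every seed and retains genes whose best-seed
#' E-value passes the cutoff (the paper-style `E <= 0.1` homolog filter).
#' Every passing seed-gene hit is returned (needed downstream for gene-fusion
#' detection); the row carrying each gene's overall best seed is flagged
#' `is_best`, and that seed's family is the gene's family vote.
#'
#' @param genomes list of [genome] objects.
#' @param seeds named character vector of seed protein sequences
#'   (`names = seed_id`).
#' @param seed_families named character vector mapping `seed_id` to
#'   `family_id`.
#' @param evalue_cutoff E-value threshold (default 0.1).
#' @param matrix,gap_open,gap_extend,lambda_,K alignment parameters.
#' @return a data.frame hit table: `query_id` (seed), `subject_id` (gene),
#'   `genome_id`, `family_id`, `raw_score`, `evalue`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `is_best`.
#' @export
find_family_members <- function(genomes, seeds, seed_families,
                                evalue_cutoff = 0.1, matrix = blosum62(),
                                gap_open = 11, gap_extend = 1,
                                lambda_ = 0.318, K = 0.134) {
  .stop_if(length(seeds) == 0L, "need at least one seed")
  .stop_if(!all(names(seeds) %in% names(seed_families)),
           "every seed needs a family label")
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  alpha <- rownames(matrix)
  enc <- function(s) {
    i <- match(strsplit(s, "")[[1]], alpha)
    .stop_if(anyNA(i), "sequence letter not in substitution matrix")
    i
  }
  seed_enc <- lapply(unname(seeds), enc)
  seed_ids <- names(seeds)
  rows <- vector("list", length(genomes))
  for (gi in seq_along(genomes)) {
    g <- genomes[[gi]]
    n_gene <- nrow(g$genes)
    if (n_gene == 0L) next
    gene_enc <- lapply(g$genes$protein, enc)
    # scores for all seed x gene pairs in one batched DP call
    S <- sw_scores_cpp(seed_enc, gene_enc, matrix, gap_open, gap_extend)
    Ev <- K * outer(nchar(seeds), nchar(g$genes$protein)) * exp(-lambda_ * S)
    out <- vector("list", n_gene)
    for (i in seq_len(n_gene)) {
      pass <- which(Ev[, i] <= evalue_cutoff)
      if (length(pass) == 0L) next
      o <- order(-S[pass, i], Ev[pass, i], seed_ids[pass])
      pass <- pass[o]
      spans <- lapply(pass, function(s)
        smith_waterman(seeds[[s]], g$genes$protein[i], matrix,
                       gap_open, gap_extend))
      out[[i]] <- data.frame(
        query_id = seed_ids[pass], subject_id = g$genes$gene_id[i],
        genome_id = g$genome_id,
        family_id = unname(seed_families[seed_ids[pass]]),
        raw_score = S[pass, i], evalue = Ev[pass, i],
        q_start = vapply(spans, `[[`, 0L, "a_start"),
        q_end = vapply(spans, `[[`, 0L, "a_end"),
        s_start = vapply(spans, `[[`, 0L, "b_start"),
        s_end = vapply(spans, `[[`, 0L, "b_end"),
        is_best = seq_along(pass) == 1L,
        stringsAsFactors = FALSE)
    }
    rows[[gi]] <- do.call(rbind, out)
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(query_id = character(), subject_id = character(),
                      genome_id = character(), family_id = character(),
                      raw_score = numeric(), evalue = numeric(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      is_best = logical(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

.best_hit <- function(h) {
  # returns the single best row index, or NA when a full tie survives
  o <- order(-h$raw_score, h$evalue, h$subject_id)
  h <- h[o, , drop = FALSE]
  if (nrow(h) > 1 &&
      h$raw_score[1] == h$raw_score[2] && h$evalue[1] == h$evalue[2] &&
      h$subject_id[1] == h$subject_id[2]) return(NA_integer_)
  o[1]
}

#' Bidirectional best hits between two sequence sets
#'
#' `(x, y)` is reported iff `y` is `x`'s unique best hit in B and `x` is
#' `y`'s unique best hit in A. Ties on raw score are broken by E-value, then
#' by lexicographic subject ID; a tie surviving all breaks disqualifies the
#' pair.
#'
#' @param hits_ab,hits_ba hit tables (as from [find_family_members()]) with
#'   columns `query_id`, `subject_id`, `raw_score`, `evalue`; `hits_ab` has
#'   A-side queries, `hits_ba` B-side queries.
#' @return data.frame with columns `a_id`, `b_id`, `raw_score`, `evalue`.
#' @export
bidirectional_best_hits <- function(hits_ab, hits_ba) {
  best_of <- function(h) {
    res <- list()
    for (q in unique(h$query_id)) {
      sub <- h[h$query_id == q, , drop = FALSE]
      i <- .best_hit(sub)
      if (!is.na(i)) res[[q]] <- sub[i, , drop = FALSE]
    }
    res
  }
  ab <- best_of(hits_ab)
  ba <- best_of(hits_ba)
  out <- list()
  for (x in names(ab)) {
    y <- ab[[x]]$subject_id
    if (!is.null(ba[[y]]) && ba[[y]]$subject_id == x)
      out[[length(out) + 1L]] <- data.frame(
        a_id = x, b_id = y, raw_score = ab[[x]]$raw_score,
        evalue = ab[[x]]$evalue, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(a_id = character(), b_id = character(),
                      raw_score = numeric(), evalue = numeric()))
  do.call(rbind, out)
}

#' Assign one ortholog per family per genome by reciprocal best hit
#'
#' Treats the seed set as a reference proteome: a gene is the ortholog of
#' family `f` in genome `g` iff its overall best seed belongs to `f` (the
#' seed-set vote standing in for domain-database corroboration) and it is the
#' reciprocal best such gene in `g`. Additional passing members are reported
#' as paralogs, not orthologs.
#'
#' @param hit_table output of [find_family_members()].
#' @return object of class `ortholog_map`: data.frame `family_id`,
#'   `genome_id`, `gene_id`, `raw_score`, `evalue`, `role`
#'   ("ortholog"/"paralog").
#' @export
assign_orthologs <- function(hit_table) {
  best <- hit_table[hit_table$is_best, , drop = FALSE]
  out <- list()
  for (g in unique(best$genome_id)) {
    bg <- best[best$genome_id == g, , drop = FALSE]
    for (f in unique(bg$family_id)) {
      cand <- bg[bg$family_id == f, , drop = FALSE]
      # reciprocal step: family side picks its unique best gene in g
      cand$query_id <- cand$family_id
      i <- .best_hit(cand)
      if (is.na(i)) next
      cand$role <- "paralog"
      cand$role[i] <- "ortholog"
      out[[length(out) + 1L]] <-
        cand[, c("family_id", "genome_id", "subject_id",
                 "raw_score", "evalue", "role")]
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(family_id = character(), genome_id = character(),
               subject_id = character(), raw_score = numeric(),
               evalue = numeric(), role = character())
  names(res)[names(res) == "subject_id"] <- "gene_id"
  rownames(res) <- NULL
  class(res) <- c("ortholog_map", "data.frame")
  res
}

#' Detect candidate gene fusions from a hit table
#'
#' A gene is called a fusion of families `f1 != f2` when it carries hits to a
#' seed of each family, each covering at least `min_cover` of that seed's
#' length, on disjoint spans of the gene.
#'
#' @param hit_table output of [find_family_members()].
#' @param seed_lengths named integer vector of seed sequence lengths.
#' @param min_cover minimum fraction of the seed covered (default 0.6).
#' @return data.frame `gene_id`, `genome_id`, `family_1`, `family_2`.
#' @export
detect_fusions <- function(hit_table, seed_lengths, min_cover = 0.6) {
  out <- list()
  h <- hit_table
  h$cover <- (h$q_end - h$q_start) / seed_lengths[h$query_id]
  h <- h[h$cover >= min_cover, , drop = FALSE]
  for (gene in unique(h$subject_id)) {
    sub <- h[h$subject_id == gene, , drop = FALSE]
    fams <- unique(sub$family_id)
    if (length(fams) < 2L) next
    for (i in seq_along(fams)) for (j in seq_along(fams)) {
      if (i >= j) next
      a <- sub[sub$family_id == fams[i], , drop = FALSE]
      b <- sub[sub$family_id == fams[j], , drop = FALSE]
      disjoint <- any(outer(a$s_end, b$s_start, "<=") |
                      outer(a$s_start, b$s_end, ">="))
      if (disjoint)
        out[[length(out) + 1L]] <- data.frame(
          gene_id = gene, genome_id = sub$genome_id[1],
          family_1 = fams[i], family_2 = fams[j], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(), genome_id = character(),
                      family_1 = character(), family_2 = character()))
  do.call(rbind, out)
}
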