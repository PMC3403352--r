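#' Build an alignment matrix from aligned strings
#'
#' @param x named character vector of equal-length aligned rows
#'   (amino acids + `-`).
#' @return character matrix, one row per sequence, of class `msa`.
#' @export
msa_from_strings <- function(x) {
  .stop_if(length(unique(nchar(x))) != 1L, "aligned rows differ in length")
  m <- do.call(rbind, strsplit(x, ""))
  rownames(m) <- names(x)
  class(m) <- c("msa", class(m))
  m
}

#' @rdname msa_from_strings
#' @param m alignment matrix.
#' @export
msa_to_strings <- function(m) {
  setNames(apply(m, 1, paste, collapse = ""), rownames(m))
}

#' Remove the gaps of one aligned row
#' @param m alignment matrix.
#' @return named character vector of ungapped sequences.
#' @export
ungap_rows <- function(m) {
  setNames(apply(m, 1, function(r) paste(r[r != "-"], collapse = "")),
           rownames(m))
}

.kmer_counts <- function(s, k) {
  n <- nchar(s) - k + 1L
  table(substring(s, seq_len(n), seq_len(n) + k - 1L))
}

.kmer_dist <- function(seqs, k = 3L) {
  k <- min(k, min(nchar(seqs)))
  counts <- lapply(seqs, .kmer_counts, k = k)
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ci <- counts[[i]]; cj <- counts[[j]]
    shared <- sum(pmin(ci[names(cj)], cj), na.rm = TRUE)
    denom <- min(sum(ci), sum(cj))
    D[i, j] <- D[j, i] <- 1 - shared / denom
  }
  D
}

.profile_freq <- function(m) {
  # 20 x L residue frequency profile; gaps and X contribute nothing
  L <- ncol(m)
  f <- matrix(0, length(AA_ALPHABET20), L, dimnames = list(AA_ALPHABET20, NULL))
  for (a in AA_ALPHABET20) f[a, ] <- colMeans(m == a)
  f
}

.merge_alignments <- function(ma, mb, matrix, gap_open, gap_extend) {
  fa <- .profile_freq(ma); fb <- .profile_freq(mb)
  S <- t(fa) %*% matrix[AA_ALPHABET20, AA_ALPHABET20] %*% fb
  r <- nw_profile_cpp(S, gap_open, gap_extend)
  take <- function(m, path) {
    out <- matrix("-", nrow(m), length(path), dimnames = list(rownames(m), NULL))
    out[, path > 0] <- m[, path[path > 0], drop = FALSE]
    out
  }
  rbind(take(ma, r$path_a), take(mb, r$path_b))
}

#' Progressive multiple sequence alignment
#'
#' Standard guide-tree progressive aligner: k-mer distances, a UPGMA guide
#' tree, and profile-profile Needleman-Wunsch merges (affine gaps, end gaps
#' penalized). Deterministic for fixed inputs.
#'
#' @param seqs named character vector of protein sequences.
#' @param matrix substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend affine gap costs.
#' @return an alignment matrix (class `msa`), rows in input order.
#' @export
progressive_align <- function(seqs, matrix = blosum62(),
                              gap_open = 11, gap_extend = 1) {
  .stop_if(length(seqs) == 0L, "no sequences")
  .stop_if(is.null(names(seqs)) || anyDuplicated(names(seqs)) > 0L,
           "sequences need unique names")
  if (length(seqs) == 1L) return(msa_from_strings(seqs))
  if (length(seqs) == 2L) {
    ali <- .merge_alignments(msa_from_strings(seqs[1]),
                             msa_from_strings(seqs[2]),
                             matrix, gap_open, gap_extend)
  } else {
    D <- .kmer_dist(seqs)
    hc <- hclust(as.dist(D), method = "average")
    nodes <- vector("list", nrow(hc$merge))
    leaf <- function(i) msa_from_strings(seqs[names(seqs)[i]])
    for (r in seq_len(nrow(hc$merge))) {
      a <- hc$merge[r, 1]; b <- hc$merge[r, 2]
      ma <- if (a < 0) leaf(-a) else nodes[[a]]
      mb <- if (b < 0) leaf(-b) else nodes[[b]]
      nodes[[r]] <- .merge_alignments(ma, mb, matrix, gap_open, gap_extend)
    }
    ali <- nodes[[nrow(hc$merge)]]
  }
  ali <- ali[names(seqs), , drop = FALSE]
  class(ali) <- c("msa", "matrix", "array")
  ali
}

#' Mask gap-rich alignment columns
#'
#' Columns whose gap fraction exceeds `max_gap_fraction` are removed
#' (the usual exclusion of ambiguous, highly variable regions before
#' distance estimation). The original indices of the retained columns are
#' kept in the `column_map` attribute so downstream column reports can be
#' mapped back to original alignment coordinates.
#'
#' @param m alignment matrix.
#' @param max_gap_fraction maximum tolerated gap fraction (default 0.5).
#' @return filtered alignment matrix with attribute `column_map`.
#' @export
mask_gappy_columns <- function(m, max_gap_fraction = 0.5) {
  gf <- colMeans(m == "-")
  keep <- which(gf <= max_gap_fraction)
  .stop_if(length(keep) == 0L,
           "all columns are gap-rich; raise max_gap_fraction")
  out <- m[, keep, drop = FALSE]
  attr(out, "column_map") <- keep
  class(out) <- c("msa", "matrix", "array")
  out
}

#' Kimura-corrected protein distance matrix
#'
#' For each pair, the mismatch fraction `p` over mutually ungapped columns is
#' corrected as `d = -ln(1 - p - 0.2 p^2)` (expected replacements per
#' position). Where the correction is undefined (`p >= 0.8541`) the distance
#' is set to `ceiling` with a warning.
#'
#' @param m alignment matrix (>= 2 rows).
#' @param ceiling distance assigned beyond the correction's domain
#'   (default 10).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
protein_distance <- function(m, ceiling = 10) {
  n <- nrow(m)
  .stop_if(n < 2L, "need at least 2 sequences")
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  capped <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    .stop_if(!any(ok), "zero ungapped overlap between ", rownames(m)[i],
             " and ", rownames(m)[j])
    p <- mean(m[i, ok] != m[j, ok])
    arg <- 1 - p - 0.2 * p^2
    if (arg <= 0) { d <- ceiling; capped <- capped + 1L } else d <- -log(arg)
    D[i, j] <- D[j, i] <- d
  }
  if (capped > 0L)
    warning(capped, " pair(s) beyond the Kimura correction domain set to ",
            ceiling)
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining: at each step the pair minimizing
#' `Q(i,j) = (N-2) d_ij - r_i - r_j` is joined (ties broken by the smallest
#' row index pair in the current matrix). Negative branch lengths are clamped
#' to zero with the deficit moved to the sister branch (their sum is
#' preserved). Exact on additive matrices.
#'
#' @param D symmetric distance matrix with zero diagonal and >= 3 labeled
#'   taxa.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  .stop_if(!isSymmetric(unname(D)), "distance matrix must be symmetric")
  n <- nrow(D)
  .stop_if(n < 3L, "need at least 3 taxa")
  .stop_if(is.null(rownames(D)), "distance matrix needs taxon labels")
  fmt <- function(x) sprintf("%.17g", max(x, 0))
  labs <- rownames(D)   # newick fragment per active node
  while (nrow(D) > 3L) {
    N <- nrow(D)
    r <- rowSums(D)
    Q <- (N - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_lab <- paste0("(", labs[i], ":", fmt(li), ",",
                      labs[j], ":", fmt(lj), ")")
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    labs <- c(labs[keep], new_lab)
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", labs[1], ":", fmt(la), ",", labs[2], ":", fmt(lb),
                ",", labs[3], ":", fmt(lc), ");")
  ape::read.tree(text = nwk)
}

.tree_splits <- function(tree) {
  # canonical split key per internal edge (key excludes the first tip label)
  nt <- length(tree$tip.label)
  ref <- tree$tip.label[1]
  keys <- character()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= nt) next
    tips <- ape::extract.clade(tree, child)$tip.label
    if (ref %in% tips) tips <- setdiff(tree$tip.label, tips)
    if (length(tips) < 2L || length(tips) > nt - 2L) next
    keys[as.character(child)] <- paste(sort(tips), collapse = "|")
  }
  keys
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement, rebuilds the
#' distance + neighbor-joining tree per replicate, and counts how often each
#' internal branch (bipartition) of the original tree is recovered.
#'
#' @param m alignment matrix (>= 4 rows).
#' @param n_replicates number of bootstrap replicates (default 100).
#' @param seed integer seed for the resampling.
#' @param ceiling passed to [protein_distance()].
#' @return the original NJ tree with `node.label` holding the bootstrap
#'   count of the branch above each internal node ("" for the root).
#' @export
bootstrap_support <- function(m, n_replicates = 100, seed = 1, ceiling = 10) {
  .stop_if(nrow(m) < 4L, "need at least 4 taxa for bootstrap support")
  tree <- neighbor_joining(suppressWarnings(protein_distance(m, ceiling)))
  keys <- .tree_splits(tree)
  counts <- setNames(integer(length(keys)), keys)
  if (n_replicates > 0) {
    set.seed(seed)
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_tree <- neighbor_joining(
        suppressWarnings(protein_distance(m[, cols, drop = FALSE], ceiling)))
      rep_keys <- .tree_splits(rep_tree)
      hit <- keys[keys %in% rep_keys]
      counts[hit] <- counts[hit] + 1L
    }
  }
  nt <- length(tree$tip.label)
  lab <- rep("", tree$Nnode)
  for (node in names(keys))
    lab[as.integer(node) - nt] <- as.character(counts[[keys[[node]]]])
  tree$node.label <- lab
  attr(tree, "bootstrap") <- counts
  attr(tree, "n_replicates") <- n_replicates
  tree
}

#' Fitch small-parsimony score of an alignment on a tree
#'
#' Sums, over alignment columns, the minimum number of state changes under
#' the Fitch set algorithm. Gaps and `X` are treated as missing (they
#' constrain nothing). The tree may be unrooted; it is rooted on the edge to
#' its first tip for scoring, which leaves the score unchanged. Binary trees
#' only.
#'
#' @param m alignment matrix whose rownames equal the tree's tip labels.
#' @param tree a `phylo` tree.
#' @return integer parsimony score.
#' @export
parsimony_score <- function(m, tree) {
  .stop_if(!setequal(rownames(m), tree$tip.label),
           "alignment rows and tree leaves differ")
  tr <- tree
  if (!ape::is.rooted(tr) || !ape::is.binary(tr))
    tr <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[1],
                    resolve.root = TRUE)
  .stop_if(!ape::is.binary(tr), "binary trees only")
  tr <- ape::reorder.phylo(tr, "postorder")
  nt <- length(tr$tip.label)
  L <- ncol(m)
  full <- bitwShiftL(1L, length(AA_ALPHABET20)) - 1L
  enc <- function(chars) {
    i <- match(chars, AA_ALPHABET20)
    out <- ifelse(is.na(i), full, bitwShiftL(1L, i - 1L))
    as.integer(out)
  }
  nnode <- nt + tr$Nnode
  M <- matrix(NA_integer_, nnode, L)
  for (t in seq_len(nt)) M[t, ] <- enc(m[tr$tip.label[t], ])
  score <- 0L
  edges <- tr$edge
  kids <- split(edges[, 2], edges[, 1])
  for (parent in unique(edges[, 1])) {   # postorder guarantees children done
    ch <- kids[[as.character(parent)]]
    acc <- M[ch[1], ]
    for (c2 in ch[-1]) {
      inter <- bitwAnd(acc, M[c2, ])
      zero <- inter == 0L
      score <- score + sum(zero)
      inter[zero] <- bitwOr(acc[zero], M[c2, ][zero])
      acc <- inter
    }
    M[parent, ] <- acc
  }
  as.integer(score)
}

#' Partition a gene tree into two subtypes at the root
#'
#' Midpoint-roots the tree (or roots on a designated outgroup leaf); the two
#' child clades of the root are the subtypes. Subtype I is the clade
#' containing `reference_leaf` when given, otherwise the larger clade (ties
#' broken in favor of the clade containing the lexicographically smallest
#' leaf ID).
#'
#' @param tree a `phylo` with branch lengths and >= 2 leaves.
#' @param rooting `"midpoint"` or a tip label to use as outgroup.
#' @param reference_leaf optional leaf defining subtype I.
#' @return named character vector over leaves with values `"I"`, `"II"`, or
#'   `"unassigned"` (all-zero-length trees, with a warning).
#' @export
split_subtypes <- function(tree, rooting = "midpoint", reference_leaf = NULL) {
  .stop_if(length(tree$tip.label) < 2L, "need at least 2 leaves")
  if (is.null(tree$edge.length) || sum(tree$edge.length) == 0) {
    warning("tree has no branch-length signal; subtypes unassigned")
    return(setNames(rep("unassigned", length(tree$tip.label)),
                    tree$tip.label))
  }
  if (length(tree$tip.label) == 2L)
    return(setNames(c("I", "II"), sort(tree$tip.label)))
  rooted <- if (identical(rooting, "midpoint")) {
    phangorn::midpoint(tree)
  } else {
    .stop_if(!rooting %in% tree$tip.label, "unknown outgroup leaf: ", rooting)
    ape::root(tree, outgroup = rooting, resolve.root = TRUE)
  }
  nt <- length(rooted$tip.label)
  root <- nt + 1L
  ch <- rooted$edge[rooted$edge[, 1] == root, 2]
  clades <- lapply(ch, function(node) {
    if (node <= nt) rooted$tip.label[node]
    else ape::extract.clade(rooted, node)$tip.label
  })
  # with >2 root children (degenerate midpoint), biggest clade vs the rest
  if (length(clades) > 2L) {
    o <- order(-lengths(clades))
    clades <- list(clades[[o[1]]], unlist(clades[o[-1]]))
  }
  pick_I <- if (!is.null(reference_leaf)) {
    .stop_if(!reference_leaf %in% rooted$tip.label,
             "unknown reference leaf: ", reference_leaf)
    if (reference_leaf %in% clades[[1]]) 1L else 2L
  } else if (length(clades[[1]]) != length(clades[[2]])) {
    which.max(lengths(clades))
  } else if (min(clades[[1]]) < min(clades[[2]])) 1L else 2L
  out <- setNames(rep("II", nt), rooted$tip.label)
  out[clades[[pick_I]]] <- "I"
  out[sort(names(out))]
}
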