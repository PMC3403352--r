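# Independent brute-force oracles used to freeze expected values.

# Exhaustive local alignment: enumerate every increasing matching of
# positions (i1<...<ik) x (j1<...<jk); internal unmatched runs cost
# gap_open + gap_extend * len per sequence; ends are free.
oracle_local_align <- function(a, b, mat, gap_open, gap_extend) {
  ia <- match(strsplit(a, "")[[1]], rownames(mat))
  ib <- match(strsplit(b, "")[[1]], rownames(mat))
  n <- length(ia); m <- length(ib)
  best <- 0
  gap_cost <- function(len) if (len > 0) gap_open + gap_extend * len else 0
  for (k in seq_len(min(n, m))) {
    combs_a <- utils::combn(n, k, simplify = FALSE)
    combs_b <- utils::combn(m, k, simplify = FALSE)
    for (ca in combs_a) for (cb in combs_b) {
      sc <- sum(mat[cbind(ia[ca], ib[cb])])
      if (k > 1) {
        sc <- sc - sum(vapply(seq_len(k - 1), function(t)
          gap_cost(ca[t + 1] - ca[t] - 1) + gap_cost(cb[t + 1] - cb[t] - 1),
          0))
      }
      if (sc > best) best <- sc
    }
  }
  best
}

# One-tailed Fisher exact enrichment p by explicit enumeration of all 2x2
# tables with the observed margins and count >= n11.
oracle_fisher_p <- function(n11, n10, n01, n00) {
  m1 <- n11 + n10; k <- n11 + n01; n <- n11 + n10 + n01 + n00
  ks <- max(0, k - (n - m1)):min(m1, k)
  probs <- choose(m1, ks) * choose(n - m1, k - ks) / choose(n, k)
  sum(probs[ks >= n11])
}

# Minimum number of state changes on a (rooted binary) tree by brute force
# over all internal-node assignments. `tip_states` is named by tip label;
# NA means missing (free). `states` is the candidate state universe.
oracle_parsimony_column <- function(tree, tip_states, states) {
  nt <- length(tree$tip.label)
  internal <- nt + seq_len(tree$Nnode)
  free_tips <- which(is.na(tip_states[tree$tip.label]))
  vars <- c(internal, free_tips)
  grid <- expand.grid(rep(list(states), length(vars)),
                      stringsAsFactors = FALSE)
  assign_all <- function(row) {
    st <- character(nt + tree$Nnode)
    st[seq_len(nt)] <- tip_states[tree$tip.label]
    st[vars] <- unlist(row)
    sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
  }
  min(apply(grid, 1, assign_all))
}

oracle_parsimony <- function(m, tree, states) {
  sum(vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col[!col %in% states] <- NA
    oracle_parsimony_column(tree, setNames(col, rownames(m)), states)
  }, 0))
}

# random tree with strictly positive branch lengths -> additive matrix
random_additive <- function(n) {
  tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
  tr <- ape::unroot(tr)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}
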