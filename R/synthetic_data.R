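#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-genome generator. The generator
#' plants the statistical structure the pipeline must recover: gene families
#' gained and lost along a species tree, a resolvase trait (RuvABC or
#' RuvAB/RecU), a partner family ("yebC") whose presence tracks the trait
#' and whose gene sits in the resolvase operon in a fraction of genomes, and
#' a two-subtype protein family with diagnostic columns.
#'
#' @param n_genomes number of genomes (leaves of the species tree).
#' @param birth_rate,loss_rate per-unit-time gain/loss rates of the two-state
#'   family presence chain (tree height is scaled to 1).
#' @param n_decoy_families number of independently evolving decoy families.
#' @param linkage_strength probability that the partner's presence equals the
#'   trait's presence in a genome.
#' @param operon_fraction fraction of trait-and-partner genomes where the
#'   partner is placed immediately downstream of the resolvase gene.
#' @param operon_gap_bp maximum intergenic gap (bp) used for the planted
#'   operon placement.
#' @param subtype_divergence per-site substitution probability between the
#'   two subtypes of the partner family.
#' @param n_diagnostic_columns number of planted subtype-diagnostic columns
#'   (>= 1).
#' @param protein_len protein length in residues (default 200).
#' @param protein_divergence per-site substitution probability between a
#'   family's seed and each genome's copy (partner family excepted; its
#'   sequences come from [evolve_subtype_family()]).
#' @param seed integer root seed fixing all randomness.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genomes = 50, birth_rate = 1, loss_rate = 0.5,
                       n_decoy_families = 20, linkage_strength = 0.95,
                       operon_fraction = 0.6, operon_gap_bp = 100,
                       subtype_divergence = 0.3, n_diagnostic_columns = 20,
                       protein_len = 200, protein_divergence = 0.05,
                       seed = 1) {
  cfg <- list(n_genomes = n_genomes, birth_rate = birth_rate,
              loss_rate = loss_rate, n_decoy_families = n_decoy_families,
              linkage_strength = linkage_strength,
              operon_fraction = operon_fraction,
              operon_gap_bp = operon_gap_bp,
              subtype_divergence = subtype_divergence,
              n_diagnostic_columns = n_diagnostic_columns,
              protein_len = protein_len,
              protein_divergence = protein_divergence, seed = seed)
  .stop_if(birth_rate < 0 || loss_rate < 0, "rates must be >= 0")
  .stop_if(linkage_strength < 0 || linkage_strength > 1,
           "linkage_strength must be in [0, 1]")
  .stop_if(operon_fraction < 0 || operon_fraction > 1,
           "operon_fraction must be in [0, 1]")
  .stop_if(subtype_divergence < 0 || subtype_divergence > 1,
           "subtype_divergence must be in [0, 1]")
  .stop_if(is.null(seed) || is.na(seed), "seed is required")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an ultrametric species tree
#'
#' Yule (pure-birth) tree with `n_genomes` leaves, rescaled to height 1 and
#' relabeled `g001 ...`.
#'
#' @param n_genomes number of leaves (>= 2).
#' @param seed integer seed.
#' @return an ultrametric `phylo`.
#' @export
simulate_species_tree <- function(n_genomes, seed = 1) {
  .stop_if(n_genomes < 2, "need n_genomes >= 2")
  set.seed(stage_seed(seed, "species_tree"))
  tr <- ape::rphylo(n_genomes, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("g%03d", seq_len(n_genomes))
  tr
}

.random_protein <- function(len) paste(sample(AA_ALPHABET20, len, TRUE),
                                       collapse = "")

.mutate_protein <- function(seq, prob, skip_cols = integer()) {
  if (prob <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < prob)
  hit <- setdiff(hit, skip_cols)
  for (i in hit) ch[i] <- sample(setdiff(AA_ALPHABET20, ch[i]), 1)
  paste(ch, collapse = "")
}

# two-state presence chain down the tree; returns 0/1 per leaf
.sim_presence_chain <- function(tree, gain, loss, root_state) {
  n_tip <- length(tree$tip.label)
  tot <- gain + loss
  pi1 <- if (tot > 0) gain / tot else 0
  state <- integer(n_tip + tree$Nnode)
  state[n_tip + 1L] <- root_state
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edges))) {
    par <- state[edges[e, 1]]
    t <- lens[e]
    pflip <- if (tot > 0) {
      if (par == 1) (1 - pi1) * (1 - exp(-tot * t))
      else pi1 * (1 - exp(-tot * t))
    } else 0
    state[edges[e, 2]] <- if (runif(1) < pflip) 1L - par else par
  }
  setNames(state[seq_len(n_tip)], tree$tip.label)
}

#' Evolve gene family content along a species tree
#'
#' Family presence evolves as a two-state Markov chain (gain = `birth_rate`,
#' loss = `loss_rate`). The planted structure: `ruvA`/`ruvB` are universal;
#' a resolvase trait chain (root present) decides which genomes carry a
#' resolvase, and a slow lineage-type chain decides whether it is `ruvC` or
#' `recU`; the partner family `yebC` matches the trait with probability
#' `linkage_strength` and is placed immediately downstream of the resolvase
#' gene (same strand, gap uniform on `[0, operon_gap_bp]`) in
#' `operon_fraction` of the co-occurring genomes; decoy families evolve
#' independently; gene orders are otherwise shuffled.
#'
#' @param tree species tree from [simulate_species_tree()].
#' @param config a [sim_config()].
#' @param partner_seqs optional named (by leaf) protein sequences for the
#'   partner family, typically from [evolve_subtype_family()].
#' @return list with `genomes` (list of [genome]), `profile` (truth
#'   [phyletic_profile]), `seeds` + `seed_families` (family seed proteins),
#'   and `truth` (trait vector, partner presence, operon placements).
#' @export
evolve_gene_content <- function(tree, config, partner_seqs = NULL) {
  set.seed(stage_seed(config$seed, "gene_content"))
  leaves <- tree$tip.label
  n <- length(leaves)
  decoys <- sprintf("decoy%02d", seq_len(config$n_decoy_families))
  families <- c("ruvA", "ruvB", "ruvC", "recU", "yebC", decoys)

  trait <- .sim_presence_chain(tree, config$birth_rate, config$loss_rate, 1L)
  type_u <- .sim_presence_chain(tree, 0.3, 0.3, 0L)  # 1 -> RecU lineage
  partner_match <- rbinom(n, 1, config$linkage_strength)
  pres <- matrix(0L, n, length(families), dimnames = list(leaves, families))
  pres[, "ruvA"] <- 1L
  pres[, "ruvB"] <- 1L
  pres[, "ruvC"] <- trait * (1L - type_u)
  pres[, "recU"] <- trait * type_u
  pres[, "yebC"] <- ifelse(partner_match == 1, trait, 1L - trait)
  for (d in decoys)
    pres[, d] <- .sim_presence_chain(tree, config$birth_rate, config$loss_rate,
                                     rbinom(1, 1, config$birth_rate /
                                              (config$birth_rate +
                                               config$loss_rate)))

  # one ancestral (seed) protein per family
  seeds <- setNames(vapply(families, function(f)
    .random_protein(config$protein_len), ""), families)
  if (!is.null(partner_seqs)) {
    anc <- attr(partner_seqs, "ancestor")
    if (!is.null(anc)) seeds[["yebC"]] <- anc
  }

  cooc <- leaves[trait == 1 & pres[, "yebC"] == 1]
  n_op <- round(config$operon_fraction * length(cooc))
  operon_genomes <- sort(sample(cooc, n_op))

  taxa <- .assign_taxa(tree)
  genomes <- list()
  for (g in leaves) {
    fams <- families[pres[g, ] == 1L]
    prot <- vapply(fams, function(f) {
      if (f == "yebC" && !is.null(partner_seqs)) partner_seqs[[g]]
      else .mutate_protein(seeds[[f]], config$protein_divergence)
    }, "")
    ord <- sample(fams)
    resolvase <- intersect(c("ruvC", "recU"), fams)
    in_operon <- g %in% operon_genomes && length(resolvase) == 1 &&
      "yebC" %in% fams
    if (in_operon) {
      ord <- setdiff(ord, "yebC")
      at <- match(resolvase, ord)
      ord <- append(ord, "yebC", after = at)
    }
    strand <- sample(c("+", "-"), length(ord), TRUE)
    gaps <- sample(200:500, length(ord), TRUE)
    if (in_operon) {
      i <- match("yebC", ord)
      strand[i] <- strand[i - 1]
      gaps[i] <- sample.int(config$operon_gap_bp + 1L, 1L) - 1L
    }
    len_nt <- 3L * nchar(prot[ord])
    start <- cumsum(c(1000L, len_nt[-length(ord)] + gaps[-1]))
    genomes[[g]] <- genome(
      g, taxa[[g]],
      data.frame(gene_id = paste0(g, "_", ord), contig_id = "chr1",
                 start = start, end = start + len_nt, strand = strand,
                 protein = unname(prot[ord]), stringsAsFactors = FALSE))
  }
  list(genomes = genomes,
       profile = phyletic_profile(pres),
       seeds = seeds,
       seed_families = setNames(families, families),
       truth = list(trait = trait, partner_presence = pres[, "yebC"],
                    operon_genomes = operon_genomes,
                    resolvase_type = ifelse(type_u == 1, "recU", "ruvC")))
}

# deterministic taxon labels: cut the tree into up to 5 depth-based groups
.assign_taxa <- function(tree, k = 5L) {
  n <- length(tree$tip.label)
  k <- min(k, n)
  cl <- stats::cutree(hclust(as.dist(ape::cophenetic.phylo(tree)), "average"),
                      k = k)
  setNames(sprintf("taxon_%d", cl), names(cl))
}

#' Evolve a two-subtype protein family
#'
#' Emulates an anciently duplicated family with two subtypes: the leaves are
#' split into two clades (lexicographically, half and half); each clade
#' evolves down its own Yule-shaped gene tree from a common ancestral
#' sequence, with a root-to-leaf per-site substitution probability of
#' `subtype_divergence / 2` per lineage (so two leaves from different clades
#' differ at about `subtype_divergence` of the free sites).
#' `n_diagnostic_columns` planted columns are held fixed at residue `a` in
#' clade I and a different residue `b` in clade II; they never mutate, so
#' they differ between the clades in every sequence.
#'
#' @param tree species tree (supplies the leaf set).
#' @param config a [sim_config()] (uses `subtype_divergence`,
#'   `n_diagnostic_columns`, `protein_len`, `seed`).
#' @return named character vector of protein sequences with attributes
#'   `labels` (named "I"/"II"), `diagnostic_columns` (planted column
#'   indices), and `ancestor` (the root sequence, usable as a search seed).
#' @export
evolve_subtype_family <- function(tree, config) {
  k <- config$n_diagnostic_columns
  .stop_if(k < 1, "n_diagnostic_columns must be >= 1")
  .stop_if(config$protein_len < k, "sequence length < n_diagnostic_columns")
  set.seed(stage_seed(config$seed, "subtype_family"))
  leaves <- sort(tree$tip.label)
  n <- length(leaves)
  nI <- ceiling(n / 2)
  clade <- setNames(rep(c("I", "II"), c(nI, n - nI)), leaves)

  anc <- .random_protein(config$protein_len)
  diag_cols <- sort(sample.int(config$protein_len, k))
  anc_ch <- strsplit(anc, "")[[1]]
  anc_I <- anc_ch
  anc_II <- anc_ch
  for (i in diag_cols)
    anc_II[i] <- sample(setdiff(AA_ALPHABET20, anc_I[i]), 1)

  q <- config$subtype_divergence / 2   # root-to-leaf substitution probability
  evolve_clade <- function(members, anc_chars) {
    out <- list()
    if (length(members) == 1L) {
      ch <- anc_chars
      hit <- setdiff(which(runif(length(ch)) < q), diag_cols)
      for (i in hit) ch[i] <- sample(setdiff(AA_ALPHABET20, ch[i]), 1)
      out[[members]] <- paste(ch, collapse = "")
      return(out)
    }
    gt <- ape::rphylo(length(members), birth = 1, death = 0)
    gt$edge.length <- gt$edge.length / max(ape::node.depth.edgelength(gt))
    gt$tip.label <- members
    n_tip <- length(members)
    seqs <- vector("list", n_tip + gt$Nnode)
    seqs[[n_tip + 1L]] <- anc_chars
    edges <- ape::reorder.phylo(gt, "cladewise")$edge
    lens <- ape::reorder.phylo(gt, "cladewise")$edge.length
    for (e in seq_len(nrow(edges))) {
      ch <- seqs[[edges[e, 1]]]
      p_branch <- 1 - (1 - q)^lens[e]
      hit <- setdiff(which(runif(length(ch)) < p_branch), diag_cols)
      for (i in hit) ch[i] <- sample(setdiff(AA_ALPHABET20, ch[i]), 1)
      seqs[[edges[e, 2]]] <- ch
    }
    for (t in seq_len(n_tip)) out[[gt$tip.label[t]]] <-
      paste(seqs[[t]], collapse = "")
    out
  }
  seqs_I <- evolve_clade(names(clade)[clade == "I"], anc_I)
  seqs_II <- evolve_clade(names(clade)[clade == "II"], anc_II)
  res <- unlist(c(seqs_I, seqs_II))[leaves]
  attr(res, "labels") <- clade
  attr(res, "diagnostic_columns") <- diag_cols
  attr(res, "ancestor") <- anc
  res
}

#' Simulate a complete dataset on disk
#'
#' Runs [simulate_species_tree()], [evolve_subtype_family()] and
#' [evolve_gene_content()], and writes per-genome FASTA + GFF3, a seed FASTA
#' (`seeds.faa`) with a `seed_families.tsv` map, the species tree
#' (`species_tree.nwk`), and `truth.json` holding the planted ground truth.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the in-memory simulation (as from
#'   [evolve_gene_content()], plus `tree` and `subtype`).
#' @export
simulate_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_species_tree(config$n_genomes, config$seed)
  subtype <- evolve_subtype_family(tree, config)
  sim <- evolve_gene_content(tree, config, partner_seqs = subtype)
  ape::write.tree(tree, file.path(out_dir, "species_tree.nwk"))
  gdir <- file.path(out_dir, "genomes")
  dir.create(gdir, showWarnings = FALSE)
  for (g in sim$genomes)
    write_genome(g, file.path(gdir, paste0(g$genome_id, ".faa")),
                 file.path(gdir, paste0(g$genome_id, ".gff3")))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sim$seeds),
                              file.path(out_dir, "seeds.faa"))
  write.table(
    data.frame(seed_id = names(sim$seed_families),
               family_id = unname(sim$seed_families)),
    file.path(out_dir, "seed_families.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(
    families = colnames(sim$profile$matrix),
    presence = apply(sim$profile$matrix, 1, function(r) as.list(r)),
    trait = as.list(sim$truth$trait),
    partner = "yebC",
    anchors = c("ruvA", "ruvB", "ruvC", "recU"),
    operon_genomes = sim$truth$operon_genomes,
    subtype_labels = as.list(attr(subtype, "labels")),
    diagnostic_columns = attr(subtype, "diagnostic_columns"))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(sim, list(tree = tree, subtype = subtype)))
}
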