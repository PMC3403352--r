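#' Phyletic (presence/absence) profiles
#'
#' @param m binary integer matrix, genomes in rows, families in columns, with
#'   unique dimnames.
#' @param provenance optional character matrix of the same shape holding the
#'   supporting gene ID for each presence call ("" where absent).
#' @return object of class `phyletic_profile`.
#' @export
phyletic_profile <- function(m, provenance = NULL) {
  .stop_if(is.null(rownames(m)) || is.null(colnames(m)),
           "profile matrix needs genome and family names")
  .stop_if(anyDuplicated(rownames(m)) > 0L || anyDuplicated(colnames(m)) > 0L,
           "profile row/column labels must be unique")
  .stop_if(!all(m %in% c(0L, 1L)), "profile entries must be 0/1")
  storage.mode(m) <- "integer"
  structure(list(matrix = m, provenance = provenance),
            class = "phyletic_profile")
}

#' @export
print.phyletic_profile <- function(x, ...) {
  cat("<phyletic_profile>", nrow(x$matrix), "genomes x",
      ncol(x$matrix), "families;",
      sum(x$matrix), "presences\n")
  invisible(x)
}

#' Build a phyletic profile from ortholog calls
#'
#' A cell is 1 iff an ortholog of the family was assigned in the genome;
#' the supporting gene ID is kept as provenance.
#'
#' @param ortholog_map an `ortholog_map` from [assign_orthologs()].
#' @param genomes list of [genome] objects (defines the row set, so genomes
#'   with no hits appear as all-zero rows).
#' @param families optional character vector fixing the column set.
#' @return a [phyletic_profile].
#' @export
build_profile <- function(ortholog_map, genomes, families = NULL) {
  om <- ortholog_map[ortholog_map$role == "ortholog", , drop = FALSE]
  gids <- vapply(genomes, function(g) g$genome_id, "")
  if (is.null(families)) families <- sort(unique(om$family_id))
  m <- matrix(0L, length(gids), length(families),
              dimnames = list(gids, families))
  prov <- matrix("", length(gids), length(families),
                 dimnames = list(gids, families))
  keep <- om$genome_id %in% gids & om$family_id %in% families
  om <- om[keep, , drop = FALSE]
  m[cbind(om$genome_id, om$family_id)] <- 1L
  prov[cbind(om$genome_id, om$family_id)] <- om$gene_id
  phyletic_profile(m, prov)
}

#' Call the Holliday-junction resolution trait from a profile row
#'
#' Implements the signature logic: the trait is scored from co-occurrence of
#' RuvABC, or of RuvAB with RecU. Status is `RuvABC` (A,B,C without U),
#' `RuvAB+RecU` (A,B,U without C), `both` (all four), `RuvAB-only` (A,B and
#' neither resolvase), else `absent`. A row with RuvC but not both RuvA and
#' RuvB is anomalous (in real data all RuvC-containing organisms have RuvAB)
#' and is flagged.
#'
#' @param profile_row named 0/1 vector covering `ruvA`, `ruvB`, `ruvC`,
#'   `recU` (missing families are treated as absent).
#' @param families optional names of the four marker families, in the order
#'   ruvA, ruvB, ruvC, recU.
#' @return list with `status` and `anomaly` (character vector, possibly
#'   empty).
#' @export
call_trait <- function(profile_row,
                       families = c("ruvA", "ruvB", "ruvC", "recU")) {
  profile_row <- as.list(profile_row)
  p <- function(f) isTRUE(profile_row[[f]] == 1)
  A <- p(families[1]); B <- p(families[2])
  C <- p(families[3]); U <- p(families[4])
  status <- if (A && B && C && !U) "RuvABC"
    else if (A && B && U && !C) "RuvAB+RecU"
    else if (A && B && C && U) "both"
    else if (A && B && !C && !U) "RuvAB-only"
    else "absent"
  anomaly <- character()
  if (C && !(A && B)) anomaly <- "RuvC_without_RuvAB"
  list(status = status, anomaly = anomaly)
}

#' Trait calls for every genome of a profile
#'
#' @param profile a [phyletic_profile].
#' @inheritParams call_trait
#' @return data.frame `genome_id`, `status`, `anomaly`.
#' @export
call_traits <- function(profile,
                        families = c("ruvA", "ruvB", "ruvC", "recU")) {
  m <- profile$matrix
  rows <- lapply(rownames(m), function(g) {
    tc <- call_trait(m[g, ], families)
    data.frame(genome_id = g, status = tc$status,
               anomaly = paste(tc$anomaly, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.fisher_enrichment_p <- function(n11, n10, n01, n00) {
  # one-tailed (enrichment) Fisher exact p for the 2x2 table, via the
  # hypergeometric upper tail with fixed margins
  m1 <- n11 + n10        # x present
  k <- n11 + n01         # y present
  n <- n11 + n10 + n01 + n00
  phyper(n11 - 1, m1, n - m1, k, lower.tail = FALSE)
}

#' Co-occurrence statistics for two families in a profile
#'
#' Computes, across genomes: the Jaccard index of the two presence vectors,
#' the mutual information (in nats) of the empirical 2x2 joint, and a
#' one-tailed Fisher exact enrichment p-value.
#'
#' @param profile a [phyletic_profile].
#' @param family_x,family_y family column names.
#' @return list `jaccard`, `mutual_information`, `fisher_p`.
#' @export
cooccurrence <- function(profile, family_x, family_y) {
  m <- profile$matrix
  .stop_if(nrow(m) < 2L, "need at least 2 genomes")
  x <- m[, family_x]; y <- m[, family_y]
  if (sum(x) == 0L || sum(y) == 0L) {
    warning("family absent everywhere: co-occurrence undefined, returning ",
            "jaccard = 0, MI = 0, fisher_p = 1")
    return(list(jaccard = 0, mutual_information = 0, fisher_p = 1))
  }
  n11 <- sum(x & y); n10 <- sum(x & !y)
  n01 <- sum(!x & y); n00 <- sum(!x & !y)
  n <- length(x)
  jac <- n11 / (n11 + n10 + n01)
  mi <- 0
  for (cnt in list(c(n11, sum(x), sum(y)), c(n10, sum(x), n - sum(y)),
                   c(n01, n - sum(x), sum(y)), c(n00, n - sum(x), n - sum(y)))) {
    pxy <- cnt[1] / n
    if (pxy > 0) mi <- mi + pxy * log(pxy * n * n / (cnt[2] * cnt[3]))
  }
  list(jaccard = jac, mutual_information = mi,
       fisher_p = .fisher_enrichment_p(n11, n10, n01, n00))
}

#' Rank candidate partner families of an anchor set
#'
#' Every non-anchor family is scored on two channels mapped to `[0, 1)`:
#' co-occurrence `s_cooc = 1 - fisher_p` against the anchor presence vector,
#' and a neighborhood score `s_nbr` (see [neighborhood_score()]); a detected
#' gene fusion with an anchor family adds a fixed bonus channel
#' `s_fus = 0.5`. Evidence is combined as
#' `1 - (1 - s_cooc)(1 - s_nbr)(1 - s_fus)` and families are ranked by
#' descending combined score (ties by family ID).
#'
#' @param profile a [phyletic_profile].
#' @param anchor_families character vector of anchor family columns.
#' @param neighborhood_scores named numeric vector of `s_nbr` per candidate
#'   family (missing families score 0).
#' @param fusions optional data.frame from [detect_fusions()].
#' @param anchor_presence optional explicit 0/1 anchor vector (named by
#'   genome); default: 1 iff all anchor families present.
#' @return data.frame of class `linkage_report`: `family_id`, `jaccard`,
#'   `mutual_information`, `fisher_p`, `s_cooc`, `s_nbr`, `fusion`,
#'   `combined`, `rank`.
#' @export
rank_partners <- function(profile, anchor_families,
                          neighborhood_scores = numeric(),
                          fusions = NULL, anchor_presence = NULL) {
  m <- profile$matrix
  .stop_if(!all(anchor_families %in% colnames(m)) && is.null(anchor_presence),
           "anchor families not in profile")
  if (is.null(anchor_presence)) {
    anchor_presence <- as.integer(rowSums(
      m[, intersect(anchor_families, colnames(m)), drop = FALSE]) ==
        length(intersect(anchor_families, colnames(m))))
    names(anchor_presence) <- rownames(m)
  }
  aug <- phyletic_profile(cbind(m, `.anchor` = anchor_presence[rownames(m)]))
  cands <- setdiff(colnames(m), anchor_families)
  rows <- lapply(cands, function(f) {
    co <- suppressWarnings(cooccurrence(aug, f, ".anchor"))
    s_cooc <- 1 - co$fisher_p
    s_nbr <- if (f %in% names(neighborhood_scores))
      unname(neighborhood_scores[[f]]) else 0
    fus <- FALSE
    if (!is.null(fusions) && nrow(fusions) > 0)
      fus <- any((fusions$family_1 == f & fusions$family_2 %in% anchor_families) |
                 (fusions$family_2 == f & fusions$family_1 %in% anchor_families))
    data.frame(family_id = f, jaccard = co$jaccard,
               mutual_information = co$mutual_information,
               fisher_p = co$fisher_p, s_cooc = s_cooc, s_nbr = s_nbr,
               fusion = fus,
               combined = 1 - (1 - s_cooc) * (1 - s_nbr) * (1 - 0.5 * fus),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep <- rep[order(-rep$combined, rep$family_id), , drop = FALSE]
  rep$rank <- seq_len(nrow(rep))
  rownames(rep) <- NULL
  class(rep) <- c("linkage_report", "data.frame")
  rep
}

#' Per-taxon occurrence summary
#'
#' For each taxon label: the number of genomes, the fraction carrying each
#' family, and the fraction in each trait status. Genomes whose taxon label
#' cannot be resolved to a leaf or named internal node of the reference tree
#' are tallied under `"unmapped"` with a warning.
#'
#' @param profile a [phyletic_profile].
#' @param genomes list of [genome] objects supplying `taxon_label`s.
#' @param reference_tree optional `phylo`; used only to validate labels.
#' @param trait_calls optional data.frame from [call_traits()].
#' @return data.frame, one row per non-empty taxon.
#' @export
occurrence_by_taxon <- function(profile, genomes, reference_tree = NULL,
                                trait_calls = NULL) {
  gids <- vapply(genomes, function(g) g$genome_id, "")
  taxa <- vapply(genomes, function(g) g$taxon_label, "")
  if (!is.null(reference_tree)) {
    known <- c(reference_tree$tip.label, reference_tree$node.label)
    bad <- !(taxa %in% known)
    if (any(bad)) {
      warning(sum(bad), " genome(s) with unresolvable taxon label -> 'unmapped'")
      taxa[bad] <- "unmapped"
    }
  }
  m <- profile$matrix[gids, , drop = FALSE]
  out <- list()
  for (tx in sort(unique(taxa))) {
    sel <- taxa == tx
    if (!any(sel)) next
    row <- data.frame(taxon = tx, n_genomes = sum(sel),
                      stringsAsFactors = FALSE)
    for (f in colnames(m))
      row[[paste0("frac_", f)]] <- mean(m[sel, f])
    if (!is.null(trait_calls)) {
      st <- trait_calls$status[match(gids[sel], trait_calls$genome_id)]
      for (s in c("RuvABC", "RuvAB+RecU", "both", "RuvAB-only", "absent"))
        row[[paste0("frac_status_", s)]] <- mean(st == s)
    }
    out[[tx]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
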