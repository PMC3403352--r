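#' Infer operons from gene coordinates
#'
#' An operon is a maximal run of consecutive same-strand genes on one contig
#' whose successive intergenic gaps (`next.start - prev.end`) are at most
#' `max_gap_bp`. Singleton genes form one-gene operons, so operons partition
#' each contig.
#'
#' @param g a [genome].
#' @param max_gap_bp maximum intergenic gap in bp (default 100, a common
#'   operon-prediction heuristic).
#' @return data.frame `operon_id`, `contig_id`, `strand`, `gene_id`,
#'   `position` (1-based position of the gene within its operon).
#' @export
infer_operons <- function(g, max_gap_bp = 100) {
  stopifnot(inherits(g, "genome"))
  genes <- g$genes
  out <- list()
  oid <- 0L
  for (ctg in unique(genes$contig_id)) {
    gc <- genes[genes$contig_id == ctg, , drop = FALSE]
    brk <- c(TRUE, gc$strand[-1] != gc$strand[-nrow(gc)] |
                   (gc$start[-1] - gc$end[-nrow(gc)]) > max_gap_bp)
    grp <- cumsum(brk)
    for (k in unique(grp)) {
      oid <- oid + 1L
      sel <- grp == k
      out[[oid]] <- data.frame(
        operon_id = sprintf("%s_op%04d", g$genome_id, oid),
        contig_id = ctg, strand = gc$strand[sel][1],
        gene_id = gc$gene_id[sel], position = seq_len(sum(sel)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene-rank proximity between candidate and anchor genes
#'
#' For each candidate gene, finds the minimal gene-rank distance (number of
#' gene steps along the contig order) to any anchor gene on the same contig,
#' whether they share a strand, and whether they lie in the same operon.
#' Candidate-anchor pairs on different contigs yield no record; a candidate
#' that is itself an anchor is skipped.
#'
#' @param g a [genome].
#' @param candidate_gene_ids,anchor_gene_ids character vectors of gene IDs.
#' @param operons output of [infer_operons()] for `g`; computed on demand if
#'   `NULL`.
#' @param max_gap_bp passed to [infer_operons()] when `operons` is `NULL`.
#' @return data.frame `genome_id`, `candidate_gene_id`, `anchor_gene_id`,
#'   `distance` (integer >= 1), `same_operon`, `same_strand`.
#' @export
proximity <- function(g, candidate_gene_ids, anchor_gene_ids,
                      operons = NULL, max_gap_bp = 100) {
  stopifnot(inherits(g, "genome"))
  if (is.null(operons)) operons <- infer_operons(g, max_gap_bp)
  genes <- g$genes
  op_of <- setNames(operons$operon_id, operons$gene_id)
  out <- list()
  for (cand in setdiff(candidate_gene_ids, anchor_gene_ids)) {
    ci <- match(cand, genes$gene_id)
    if (is.na(ci)) next
    ctg <- genes$contig_id[ci]
    gc <- genes[genes$contig_id == ctg, , drop = FALSE]
    crank <- match(cand, gc$gene_id)
    arank <- match(intersect(anchor_gene_ids, gc$gene_id), gc$gene_id)
    if (length(arank) == 0L) next
    d <- abs(arank - crank)
    anchors <- gc$gene_id[arank]
    same_op <- op_of[anchors] == op_of[[cand]]
    # nearest anchor; ties prefer same-operon, then lexicographic anchor ID
    o <- order(d, !same_op, anchors)[1]
    out[[length(out) + 1L]] <- data.frame(
      genome_id = g$genome_id, candidate_gene_id = cand,
      anchor_gene_id = anchors[o], distance = d[o],
      same_operon = unname(same_op[o]),
      same_strand = gc$strand[arank[o]] == gc$strand[crank],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(genome_id = character(), candidate_gene_id = character(),
                      anchor_gene_id = character(), distance = integer(),
                      same_operon = logical(), same_strand = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate proximity records into a neighborhood score
#'
#' Per genome the best record contributes weight 1 when candidate and anchor
#' share an operon, 0.5 when the gene-rank distance is at most `D`, else 0;
#' the score is `s = min(0.999, sum(w) / n_genomes)`, bounded in `[0, 1)`.
#'
#' @param proximity_records data.frame as from [proximity()], possibly
#'   row-bound over genomes.
#' @param n_genomes total number of genomes scanned (> 0).
#' @param D gene-rank distance window for the half weight (default 3).
#' @return numeric score in `[0, 0.999]`.
#' @export
neighborhood_score <- function(proximity_records, n_genomes, D = 3) {
  .stop_if(n_genomes <= 0, "n_genomes must be positive")
  if (nrow(proximity_records) == 0L) return(0)
  w <- ifelse(proximity_records$same_operon, 1,
              ifelse(proximity_records$distance <= D, 0.5, 0))
  per_genome <- tapply(w, proximity_records$genome_id, max)
  min(0.999, sum(per_genome) / n_genomes)
}
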