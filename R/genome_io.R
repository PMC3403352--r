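#' Annotated genome objects
#'
#' A genome is an ordered set of protein-coding genes on one or more contigs.
#' Coordinates are stored 0-based half-open internally; GFF3 input/output
#' converts at the boundary (GFF3 is 1-based inclusive).
#'
#' @param genome_id single string.
#' @param taxon_label single string, e.g. a phylum or clade name.
#' @param genes data.frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` ("+"/"-") and `protein` (uppercase amino acids).
#' @return an object of class `genome`.
#' @export
genome <- function(genome_id, taxon_label, genes) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  need <- c("gene_id", "contig_id", "start", "end", "strand", "protein")
  .stop_if(!all(need %in% names(genes)), "genes must have columns: ",
           paste(need, collapse = ", "))
  .stop_if(anyDuplicated(genes$gene_id) > 0L,
           "duplicate gene_id within genome ", genome_id)
  .stop_if(any(genes$start >= genes$end), "gene start must be < end")
  .stop_if(any(!nzchar(genes$protein)), "empty protein sequence")
  .stop_if(!all(genes$strand %in% c("+", "-")), "strand must be '+' or '-'")
  .check_protein(genes$protein)
  # deterministic order: (contig, start, gene_id)
  o <- order(genes$contig_id, genes$start, genes$gene_id, method = "radix")
  genes <- genes[o, , drop = FALSE]
  dup <- duplicated(genes[, c("contig_id", "start", "end")])
  if (any(dup)) {
    warning("genome ", genome_id, ": ", sum(dup),
            " gene(s) with duplicate coordinates dropped (kept first by ID)")
    genes <- genes[!dup, , drop = FALSE]
  }
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id, taxon_label = taxon_label,
                 genes = genes), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome>", x$genome_id, "(", x$taxon_label, "):",
      nrow(x$genes), "genes on",
      length(unique(x$genes$contig_id)), "contig(s)\n")
  invisible(x)
}

#' Read an annotated genome from protein FASTA + GFF3
#'
#' Only `CDS` and `gene` features are consumed (others are counted and
#' ignored); where both are present for an ID, `CDS` wins. GFF3 coordinates
#' (1-based inclusive) are converted to the internal 0-based half-open
#' convention. Every consumed feature must have a protein in the FASTA,
#' matched by its `ID` attribute.
#'
#' @param fasta_path protein FASTA path.
#' @param gff3_path GFF3 path.
#' @param genome_id,taxon_label identifiers; default to the FASTA file stem.
#' @return a [genome] object.
#' @export
read_genome <- function(fasta_path, gff3_path,
                        genome_id = sub("\\.[^.]*$", "", basename(fasta_path)),
                        taxon_label = genome_id) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  prot <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  types <- as.character(gr$type)
  keep <- types %in% c("CDS", "gene")
  if (any(!keep))
    message("read_genome: ignored ", sum(!keep), " non-CDS/gene feature(s)")
  gr <- gr[keep]
  ids <- gr$ID
  .stop_if(any(is.na(ids) | !nzchar(ids)), "GFF3 feature without ID attribute")
  # prefer CDS over gene for the same ID
  pref <- order(match(as.character(gr$type), c("CDS", "gene")))
  gr <- gr[pref][!duplicated(ids[pref])]
  miss <- setdiff(gr$ID, names(prot))
  .stop_if(length(miss) > 0L, "no protein in FASTA for annotated CDS: ",
           paste(miss, collapse = ", "))
  genes <- data.frame(
    gene_id = gr$ID,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # 1-based incl -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    protein = unname(prot[gr$ID]),
    stringsAsFactors = FALSE)
  genome(genome_id, taxon_label, genes)
}

#' Write a genome as protein FASTA + GFF3
#'
#' Inverse of [read_genome()]: internal 0-based half-open coordinates are
#' emitted as 1-based inclusive GFF3 `CDS` features.
#'
#' @param g a [genome].
#' @param fasta_path,gff3_path output paths.
#' @return invisibly, the two paths.
#' @export
write_genome <- function(g, fasta_path, gff3_path) {
  stopifnot(inherits(g, "genome"))
  aa <- Biostrings::AAStringSet(setNames(g$genes$protein, g$genes$gene_id))
  Biostrings::writeXStringSet(aa, fasta_path)
  gr <- GenomicRanges::GRanges(
    seqnames = g$genes$contig_id,
    ranges = IRanges::IRanges(start = g$genes$start + 1L, end = g$genes$end),
    strand = g$genes$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- g$genes$gene_id
  rtracklayer::export(gr, gff3_path, format = "gff3")
  invisible(c(fasta_path, gff3_path))
}

#' Read a reference tree in Newick format
#'
#' Thin wrapper around `ape::read.tree` that first locates unbalanced
#' parentheses or a missing terminal semicolon and reports the character
#' offset of the problem.
#'
#' @param path Newick file path.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    .stop_if(depth < 0L, "malformed Newick: unmatched ')' at offset ", i)
  }
  .stop_if(depth != 0L, "malformed Newick: ", depth,
           " unclosed '(' by offset ", nchar(txt))
  .stop_if(!grepl(";", txt, fixed = TRUE),
           "malformed Newick: missing ';' by offset ", nchar(txt))
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL)
  .stop_if(is.null(tr), "malformed Newick: ape failed to parse ", path)
  .stop_if(anyDuplicated(tr$tip.label) > 0L, "duplicate leaf labels in ", path)
  tr
}

#' Write / read a phyletic profile as TSV
#'
#' The TSV has a header row of family IDs and one row per genome (row names
#' in the first column). `read_profile_tsv(write_profile_tsv(p))` is the
#' identity.
#'
#' @param profile a [phyletic_profile].
#' @param path output path.
#' @return `write_profile_tsv`: the path, invisibly; `read_profile_tsv`: a
#'   [phyletic_profile].
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "phyletic_profile"))
  .stop_if(nrow(profile$matrix) == 0L || ncol(profile$matrix) == 0L,
           "empty profile")
  df <- data.frame(genome_id = rownames(profile$matrix), profile$matrix,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  phyletic_profile(m)
}
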