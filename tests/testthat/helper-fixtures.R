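# In-code fixtures shared across tests.

make_genome <- function(id = "gA", starts = c(100L, 500L, 900L),
                        strands = c("+", "+", "+"),
                        proteins = c("MKLVA", "MARNDC", "MQEGH"),
                        contig = "chr1", taxon = "taxon_1") {
  genome(id, taxon, data.frame(
    gene_id = paste0(id, "_g", seq_along(starts)),
    contig_id = contig, start = starts,
    end = starts + 3L * nchar(proteins), strand = strands,
    protein = proteins, stringsAsFactors = FALSE))
}

random_protein <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(traitscan:::AA_ALPHABET20, len, TRUE), collapse = "")
}

# tiny two-clade alignment: cladeA conserved K at col 3, cladeB conserved R
two_clade_msa <- function(n_per = 3) {
  base <- "AGAGG"
  rows <- c(setNames(rep("AGKGG", n_per), paste0("I", seq_len(n_per))),
            setNames(rep("AGRGG", n_per), paste0("J", seq_len(n_per))))
  msa_from_strings(rows)
}
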