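#' Classify alignment columns by subtype specificity
#'
#' For each column and each subtype the consensus residue and its
#' conservation fraction are computed (gaps count against conservation and
#' can never be the consensus). A column is `I-specific` iff its clade-I
#' consensus `a` reaches conservation `>= strict` within I while `a`'s
#' frequency within II is `<= 1 - strict`; `II-specific` symmetrically. A
#' column specific on both sides - fixed for different residues, the
#' classical specificity-determining position - is flagged `diagnostic`.
#' Columns conserved `>= strict` on the same residue in both groups are
#' `shared-conserved`; everything else is `variable`.
#'
#' @param m alignment matrix.
#' @param subtype_labels named vector ("I"/"II") covering all rows.
#' @param strict conservation threshold in (0, 1] (default 1.0, i.e.
#'   strictly conserved; 0.9 recommended for noisy data).
#' @param min_group minimum members per subtype (default 3).
#' @return data.frame of class `sdp_table`: `column`, `orig_column` (via the
#'   `column_map` attribute when `m` was masked), `consensus_I`, `frac_I`,
#'   `consensus_II`, `frac_II`, `I_specific`, `II_specific`, `category`.
#' @export
classify_columns <- function(m, subtype_labels, strict = 1.0, min_group = 3) {
  .stop_if(!all(rownames(m) %in% names(subtype_labels)),
           "labels must cover all alignment rows")
  lab <- subtype_labels[rownames(m)]
  .stop_if(sum(lab == "I") < min_group || sum(lab == "II") < min_group,
           "a subtype has fewer than min_group (", min_group, ") members")
  cmap <- attr(m, "column_map")
  if (is.null(cmap)) cmap <- seq_len(ncol(m))
  mi <- m[lab == "I", , drop = FALSE]
  mii <- m[lab == "II", , drop = FALSE]
  cons <- function(sub) {
    apply(sub, 2, function(col) {
      tab <- table(factor(col[col %in% AA_ALPHABET20],
                          levels = AA_ALPHABET20))
      if (sum(tab) == 0L) return(c(res = "-", frac = "0"))
      best <- names(tab)[which.max(tab)]   # ties: alphabetical first
      c(res = best, frac = as.character(tab[[best]] / nrow(sub)))
    })
  }
  ci <- cons(mi); cii <- cons(mii)
  freq_in <- function(sub, res) {
    vapply(seq_along(res), function(j)
      if (res[j] == "-") 0 else mean(sub[, j] == res[j]), 0)
  }
  frac_I <- as.numeric(ci["frac", ])
  frac_II <- as.numeric(cii["frac", ])
  res_I <- ci["res", ]
  res_II <- cii["res", ]
  i_spec <- frac_I >= strict & freq_in(mii, res_I) <= (1 - strict)
  ii_spec <- frac_II >= strict & freq_in(mi, res_II) <= (1 - strict)
  shared <- frac_I >= strict & frac_II >= strict & res_I == res_II
  category <- ifelse(i_spec & ii_spec, "diagnostic",
              ifelse(i_spec, "I-specific",
              ifelse(ii_spec, "II-specific",
              ifelse(shared, "shared-conserved", "variable"))))
  out <- data.frame(column = seq_len(ncol(m)), orig_column = cmap,
                    consensus_I = res_I, frac_I = frac_I,
                    consensus_II = res_II, frac_II = frac_II,
                    I_specific = i_spec, II_specific = ii_spec,
                    category = category, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("sdp_table", "data.frame")
  out
}

.SDP_CODES <- c("diagnostic" = "D", "I-specific" = "1", "II-specific" = "2",
                "shared-conserved" = "*", "variable" = ".")

#' Write an SDP report and an annotated alignment
#'
#' Writes the classification as TSV (columns reported in original alignment
#' coordinates) and an annotated FASTA: the alignment rows followed by a
#' `#category` tag row with one symbol per column (`D` diagnostic, `1`
#' I-specific, `2` II-specific, `*` shared-conserved, `.` variable).
#'
#' @param sdp_table output of [classify_columns()].
#' @param m the alignment matrix that was classified.
#' @param tsv_path,fasta_path output paths.
#' @return invisibly, the two paths.
#' @export
sdp_report <- function(sdp_table, m, tsv_path, fasta_path) {
  write.table(sdp_table, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  tags <- .SDP_CODES[sdp_table$category]
  lines <- character()
  for (id in rownames(m))
    lines <- c(lines, paste0(">", id), paste(m[id, ], collapse = ""))
  lines <- c(lines, ">#category", paste(tags, collapse = ""))
  writeLines(lines, fasta_path)
  invisible(c(tsv_path, fasta_path))
}

#' Parse an annotated alignment written by [sdp_report()]
#'
#' @param fasta_path annotated FASTA path.
#' @return list with `msa` (alignment matrix) and `category` (per-column
#'   category vector).
#' @export
read_sdp_annotation <- function(fasta_path) {
  lines <- readLines(fasta_path)
  heads <- grep("^>", lines)
  ids <- sub("^>", "", lines[heads])
  seqs <- setNames(lines[heads + 1L], ids)
  tag <- seqs[["#category"]]
  seqs <- seqs[names(seqs) != "#category"]
  codes <- strsplit(tag, "")[[1]]
  list(msa = msa_from_strings(seqs),
       category = unname(setNames(names(.SDP_CODES), .SDP_CODES)[codes]))
}
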