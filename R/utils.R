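#' @useDynLib traitscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats as.dist hclust phyper runif rbinom setNames
#' @importFrom utils read.delim write.table head
NULL

AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Derive a deterministic per-stage seed from a root seed
#'
#' All randomness in the package flows from one root seed; each named stage
#' gets its own reproducible substream so that rerunning a single stage gives
#' the same draws as a full run.
#'
#' @param seed integer root seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 32749
  as.integer((abs(as.numeric(seed)) %% 65521 * 32749 + h) %% 2147483647)
}

.stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

.check_protein <- function(x, what = "protein_seq") {
  bad <- grepl(paste0("[^", paste(c(AA_ALPHABET20, "X"), collapse = ""), "]"), x)
  .stop_if(any(bad), what, " contains non-amino-acid letters: ",
           paste(utils::head(x[bad], 3), collapse = ", "))
  invisible(TRUE)
}

# BLOSUM62 restricted to the 20 canonical residues plus X, from Biostrings.
blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      keep <- c(AA_ALPHABET20, "X")
      m <<- e$BLOSUM62[keep, keep]
    }
    m
  }
})
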