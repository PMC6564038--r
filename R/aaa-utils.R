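#' @importFrom methods as is
#' @importFrom stats median pbinom rbinom rlnorm rnorm rpois runif setNames
#'   chisq.test wilcox.test
#' @importFrom utils read.delim write.table head tail
NULL

DNA_CODES <- c(A = 65L, C = 67L, G = 71L, T = 84L, N = 78L)

# Fast random DNA string; probs over A/C/G/T.
random_dna <- function(n, prob = c(0.375, 0.125, 0.125, 0.375)) {
  if (n <= 0L) return("")
  intToUtf8(DNA_CODES[c("A", "C", "G", "T")][sample.int(4L, n, replace = TRUE, prob = prob)])
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Genetic code tables
#'
#' Returns a named character vector mapping codons to one-letter amino acids.
#' The ciliate nuclear code (NCBI translation table 6) reassigns TAA and TAG
#' to glutamine, leaving TGA as the only stop; it is the default code
#' throughout the package because *Tetrahymena* (and ciliates generally) use
#' it, and standard-code translation would introduce spurious internal stops.
#'
#' @param code `"ciliate"` (table 6) or `"standard"` (table 1).
#' @return Named character vector of length 64.
#' @export
genetic_code <- function(code = c("ciliate", "standard")) {
  code <- match.arg(code)
  id <- if (code == "ciliate") "6" else "1"
  gc <- Biostrings::getGeneticCode(id)
  setNames(as.character(gc), names(gc))
}

LEUCINE_CODONS <- c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG")

split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic TSV writer: no quoting, LF endings, fixed column order
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, function(x) {
      if (is.numeric(x)) format(x, trim = TRUE, scientific = FALSE, digits = 15) else as.character(x)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, check.names = FALSE)
}
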