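#' @import methods
#' @importFrom stats rbinom runif rlnorm setNames
#' @importFrom utils write.table read.table head tail
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom IRanges IRanges reduce width start end
#' @importFrom data.table data.table setkey setkeyv := .N .SD
NULL

# Valid sequence alphabet after normalization
.SEQ_ALPHABET <- c("A", "C", "G", "T", "N")

#' Normalize a raw sequence string to the {A,C,G,T,N} alphabet
#'
#' Uppercases, maps U to T, and rejects anything else. Used by every reader
#' so that one alphabet convention holds package-wide.
#'
#' @param x character vector of raw sequences.
#' @param what label used in error messages (e.g. a record id).
#' @return character vector over {A,C,G,T,N}.
#' @keywords internal
.normalizeSeq <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    i <- which(bad)[1L]
    ch <- regmatches(x[i], regexpr("[^ACGTN]", x[i]))
    stop("invalid character '", ch, "' in ", what,
         if (length(what) == length(x)) "" else paste0(" (record ", i, ")"),
         "; allowed alphabet is A,C,G,T,N (U is mapped to T)", call. = FALSE)
  }
  x
}

# Reverse complement on plain character strings (strict alphabet).
.revcomChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Longest strictly increasing subsequence length
#'
#' Patience-sorting O(n log n); used to test collinearity of k-mer anchor
#' matches.
#' @param x numeric vector.
#' @return integer, the LIS length (0 for empty input).
#' @keywords internal
.lisLength <- function(x) {
  n <- length(x)
  if (n == 0L) return(0L)
  tails <- numeric(0)
  for (v in x) {
    # first tail >= v gets replaced (strictly increasing LIS)
    pos <- findInterval(v - 0.5, tails) + 1L
    if (pos > length(tails)) tails <- c(tails, v) else tails[pos] <- v
  }
  length(tails)
}

# Run a block of code with a private, seeded RNG stream, restoring the
# caller's RNG state afterwards. All package randomness goes through this.
.withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", sample.kind = "Rejection")
  force(code)
}

# Count N characters in a string (vectorized).
.countN <- function(x) {
  nchar(x) - nchar(gsub("N", "", x, fixed = TRUE))
}

# Write a data.frame as TSV (the package's report format).
.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
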