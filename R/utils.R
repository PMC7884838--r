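#' @importFrom methods is as
#' @importFrom stats predict runif setNames
#' @importFrom utils head read.delim write.table
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; published tables in this field are
#' rounded half-up, so derived percentages must be too (e.g. 8.05 -> 8.1).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Reverse complement of a plain character vector of sequences.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

as_dna <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  if (is.character(x)) {
    out <- Biostrings::DNAStringSet(toupper(x))
    if (!is.null(names(x))) names(out) <- names(x)
    return(out)
  }
  stop("expected a DNAStringSet, DNAString or character vector of sequences")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
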