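# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Row-wise numerically stable softmax.  max.col() gives the row
## maxima without the interpreter overhead of apply().
row_softmax <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / rowSums(E)
}

## Add a length-d vector to every row of an m x d matrix.
add_rowvec <- function(M, b) {
  M + matrix(b, nrow(M), length(b), byrow = TRUE)
}

sigmoid <- function(x) stats::plogis(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= 0
}

## The pad character.  Inputs may carry the typographic minus sign
## (U+2212); it is normalized to ASCII '-' on ingestion.
PAD_CHAR <- "-"
RNA_ALPHABET <- c("A", "C", "G", "U")

MOD_TAGS <- c("m6A", "m1A", "m5C", "m5U", "m6Am", "m7G", "Psi", "I",
              "Am", "Cm", "Gm", "Um")

## Expected centre base per modification type (candidate-site chemistry).
MOD_CENTER_BASE <- c(
  m6A = "A", m1A = "A", m6Am = "A", Am = "A", I = "A",
  m5C = "C", Cm = "C",
  m7G = "G", Gm = "G",
  m5U = "U", Um = "U", Psi = "U"
)
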