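# Synthetic labelled 41-nt window generator.
#
# The generator states the world the classifier assumes: fixed-length
# windows with the candidate base forced at the centre in every sample
# (positives and negatives alike, mirroring candidate-site extraction),
# i.i.d. background nucleotides, and a degenerate position-weight
# motif planted around the centre of positives.  Motif insertion is
# probabilistic per positive (signal_strength), so signal_strength = 0
# makes positives and negatives exactly exchangeable.

#' Random degenerate position-weight motif
#'
#' Each column places probability `dominance` on one randomly chosen
#' base and spreads the remainder uniformly over the other three.
#'
#' @param width motif width in positions.
#' @param dominance probability of the dominant base per column
#'   (default 0.95, a near-deterministic motif).
#' @param seed integer seed.
#' @return A `4 x width` column-stochastic matrix with rownames
#'   `A, C, G, U`.
#' @export
random_pwm <- function(width, dominance = 0.95, seed = 1L) {
  if (dominance < 0.25 || dominance > 1)
    stopf("dominance must lie in [0.25, 1]")
  withr::with_seed(as.integer(seed), {
    M <- matrix((1 - dominance) / 3, 4L, width,
                dimnames = list(RNA_ALPHABET, NULL))
    dom <- sample.int(4L, width, replace = TRUE)
    for (j in seq_len(width)) M[dom[[j]], j] <- dominance
    M
  })
}

#' Specification of a synthetic window dataset
#'
#' @param n_pos,n_neg numbers of positive and negative windows.  The
#'   benchmark designs are 1:1 and 1:10; `ratio_preset` is a shorthand
#'   that derives `n_neg` from `n_pos`.
#' @param window window length (41).
#' @param center_base candidate base forced at the centre of every
#'   window.
#' @param motif `4 x w` position-weight matrix over `A,C,G,U` (columns
#'   sum to 1), or `NULL` to draw one with [random_pwm()].
#' @param motif_offset 0-based offset of the motif's first column
#'   relative to the centre position (negative = upstream).  Default
#'   `-4` places an 8-wide motif across the centre.
#' @param signal_strength probability in `[0, 1]` that a positive
#'   window carries the motif (background otherwise); 0 gives an
#'   exchangeable null.
#' @param background per-position background distribution: `4 x window`
#'   column-stochastic matrix, or `NULL` for i.i.d. uniform.
#' @param ratio_preset `"1:1"` or `"1:10"`; used when `n_neg` is `NULL`.
#' @param modification tag stored on the generated samples.
#' @param pad_fraction fraction of windows whose outermost bases are
#'   replaced by a head or tail pad run (exercises the padded
#'   vocabulary); default 0.
#' @param seed integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pos, n_neg = NULL, window = 41L,
                           center_base = "A", motif = NULL,
                           motif_offset = -4L, signal_strength = 1,
                           background = NULL,
                           ratio_preset = c("1:1", "1:10"),
                           modification = "unknown",
                           pad_fraction = 0, seed = 1L) {
  ratio_preset <- match.arg(ratio_preset)
  if (is.null(n_neg))
    n_neg <- if (ratio_preset == "1:1") n_pos else 10L * n_pos
  if (!center_base %in% RNA_ALPHABET)
    stopf("center_base must be one of A, C, G, U")
  if (signal_strength < 0 || signal_strength > 1)
    stopf("signal_strength must lie in [0, 1]")
  if (is.null(motif))
    motif <- random_pwm(8L, seed = seed + 1000L)
  if (nrow(motif) != 4L || any(abs(colSums(motif) - 1) > 1e-8))
    stopf("motif columns must be distributions over A, C, G, U")
  if (ncol(motif) > window) stopf("motif wider than the window")
  centre <- (window + 1L) %/% 2L
  m_start <- centre + motif_offset
  if (m_start < 1L || m_start + ncol(motif) - 1L > window)
    stopf("motif (offset %d, width %d) does not fit in the window",
          motif_offset, ncol(motif))
  if (!is.null(background) &&
      (nrow(background) != 4L || ncol(background) != window ||
       any(abs(colSums(background) - 1) > 1e-8)))
    stopf("background must be a 4 x window column-stochastic matrix")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 window = as.integer(window), center_base = center_base,
                 motif = motif, motif_offset = as.integer(motif_offset),
                 signal_strength = signal_strength,
                 background = background, modification = modification,
                 pad_fraction = pad_fraction, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic labelled window dataset
#'
#' Negatives are pure background; each positive carries the motif with
#' probability `signal_strength`.  The centre base is forced in every
#' window.  Identical spec (including seed) reproduces the dataset
#' bit-for-bit.
#'
#' @param spec a [synthetic_spec()].
#' @param name dataset name.
#' @return A [methyl_dataset()] with `n_pos` positives followed by
#'   `n_neg` negatives.
#' @export
generate_dataset <- function(spec, name = "synthetic") {
  w <- spec$window
  centre <- (w + 1L) %/% 2L
  bg <- spec$background %||%
    matrix(0.25, 4L, w, dimnames = list(RNA_ALPHABET, NULL))
  n <- spec$n_pos + spec$n_neg
  label <- rep(c(1L, 0L), c(spec$n_pos, spec$n_neg))
  m_cols <- spec$motif_offset + centre + seq_len(ncol(spec$motif)) - 1L
  seqs <- character(n)
  withr::with_seed(spec$seed, {
    for (i in seq_len(n)) {
      chars <- vapply(seq_len(w), function(j)
        sample(RNA_ALPHABET, 1L, prob = bg[, j]), "")
      if (label[[i]] == 1L &&
          stats::runif(1) < spec$signal_strength) {
        chars[m_cols] <- vapply(seq_len(ncol(spec$motif)), function(j)
          sample(RNA_ALPHABET, 1L, prob = spec$motif[, j]), "")
      }
      chars[[centre]] <- spec$center_base
      if (spec$pad_fraction > 0 && stats::runif(1) < spec$pad_fraction) {
        n_pad <- sample.int(5L, 1L)
        side <- sample(c("head", "tail"), 1L)
        if (side == "head") chars[seq_len(n_pad)] <- PAD_CHAR
        else chars[w - seq_len(n_pad) + 1L] <- PAD_CHAR
      }
      seqs[[i]] <- paste(chars, collapse = "")
    }
  })
  methyl_dataset(sprintf("syn%d", seq_len(n)), seqs, label,
                 spec$modification, name = name)
}

#' Generate a pair of datasets for cross-modification experiments
#'
#' With `shared_motif = TRUE` both datasets' positives embed the same
#' position-weight motif (possibly with different centre bases), so a
#' model trained on one should rank the other's positives above chance;
#' otherwise the two motifs are drawn independently.
#'
#' @param spec_a,spec_b [synthetic_spec()]s.  When a spec has no
#'   explicit motif, one is drawn from its seed; under `shared_motif`
#'   the motif of `spec_a` is copied into `spec_b`.
#' @param shared_motif logical.
#' @return `list(a = methyl_dataset, b = methyl_dataset)`.
#' @export
generate_pair <- function(spec_a, spec_b, shared_motif = TRUE) {
  if (shared_motif) {
    spec_b$motif <- spec_a$motif
    spec_b$motif_offset <- spec_a$motif_offset
  }
  list(a = generate_dataset(spec_a, name = paste0(spec_a$modification, "_syn")),
       b = generate_dataset(spec_b, name = paste0(spec_b$modification, "_syn")))
}
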