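# Reading, validating, normalizing, padding and splitting labelled
# RNA sequence windows.
#
# The atomic unit is a 41-character window over {A,C,G,U,-} with the
# candidate (modified or unmodified) base at the centre position, a
# binary label (1 = modified) and a modification tag.  Pad characters,
# when present, form one contiguous run at the head or the tail of the
# window, never the interior.

WINDOW_LENGTH <- 41L

## ---- validation -----------------------------------------------------

# A window is valid when it is WINDOW_LENGTH long, uses only the RNA
# alphabet plus '-', and any dashes form a single head or tail run.
validate_window <- function(sequence, where = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stopf("%s: expected a single character string", where)
  if (nchar(sequence) != WINDOW_LENGTH)
    stopf("%s: window length is %d, expected %d",
          where, nchar(sequence), WINDOW_LENGTH)
  bad <- setdiff(strsplit(sequence, "")[[1]], c(RNA_ALPHABET, PAD_CHAR))
  if (length(bad) > 0L)
    stopf("%s: illegal character '%s'", where, bad[[1L]])
  if (!grepl("^-*[ACGU]+$|^[ACGU]+-*$", sequence))
    stopf("%s: pad characters must form a single run at the head or tail",
          where)
  invisible(sequence)
}

# Uppercase, DNA->RNA (T->U) and unicode-minus -> '-'.  Returns the
# normalized string; the number of T->U replacements is recorded in
# attribute "n_t2u".
normalize_sequence <- function(sequence) {
  s <- toupper(sequence)
  s <- gsub("−", PAD_CHAR, s, fixed = TRUE)
  n_t <- sum(strsplit(s, "")[[1]] == "T")
  s <- gsub("T", "U", s, fixed = TRUE)
  structure(s, n_t2u = n_t)
}

## ---- dataset container ----------------------------------------------

#' Construct a labelled methylation window dataset
#'
#' A `methyl_dataset` holds an ordered collection of fixed-length
#' (41 nt) sequence windows, each with a binary label (1 = modified,
#' 0 = unmodified) and a modification tag.  All windows are validated:
#' length exactly 41, alphabet `{A,C,G,U,-}`, and any `-` pads forming a
#' single contiguous run at the head or the tail.
#'
#' @param id character vector of record identifiers.
#' @param sequence character vector of 41-character windows.
#' @param label integer vector of 0/1 labels.
#' @param modification modification tag(s), one of
#'   `r paste(MOD_TAGS, collapse = ", ")` or `"unknown"`; recycled.
#' @param name dataset name.
#' @return An object of class `methyl_dataset`: a list with elements
#'   `samples` (data.frame with columns id, sequence, label,
#'   modification), `name`, and `ratio` (positive and negative counts).
#' @examples
#' ds <- methyl_dataset(
#'   id = c("a", "b"),
#'   sequence = c(strrep("A", 41), strrep("G", 41)),
#'   label = c(1, 0), modification = "unknown")
#' ds$ratio
#' @export
methyl_dataset <- function(id, sequence, label, modification = "unknown",
                           name = "dataset") {
  n <- length(sequence)
  if (length(id) != n || length(label) != n)
    stopf("id, sequence and label must have equal length")
  modification <- rep_len(as.character(modification), n)
  label <- as.integer(label)
  if (n > 0 && !all(label %in% c(0L, 1L)))
    stopf("labels must be 0 or 1")
  ok_mod <- modification %in% c(MOD_TAGS, "unknown")
  if (!all(ok_mod))
    stopf("unknown modification tag '%s'", modification[!ok_mod][1L])
  for (i in seq_len(n))
    validate_window(sequence[[i]], where = sprintf("record %d (%s)", i, id[[i]]))
  ## centre-base consistency is advisory only
  known <- modification %in% names(MOD_CENTER_BASE)
  if (any(known)) {
    centre <- substr(sequence, 21L, 21L)
    bad <- known & centre != MOD_CENTER_BASE[modification]
    if (any(bad))
      warning(sprintf(
        "%d record(s) have a centre base inconsistent with their modification tag (e.g. %s: centre '%s', expected '%s')",
        sum(bad), id[bad][1L], centre[bad][1L],
        MOD_CENTER_BASE[[modification[bad][1L]]]), call. = FALSE)
  }
  samples <- data.frame(id = as.character(id), sequence = sequence,
                        label = label, modification = modification,
                        stringsAsFactors = FALSE)
  structure(list(samples = samples, name = name,
                 ratio = c(pos = sum(label == 1L), neg = sum(label == 0L))),
            class = "methyl_dataset")
}

#' @export
print.methyl_dataset <- function(x, ...) {
  cat(sprintf("<methyl_dataset '%s': %d samples (%d pos : %d neg), mods: %s>\n",
              x$name, nrow(x$samples), x$ratio[["pos"]], x$ratio[["neg"]],
              paste(unique(x$samples$modification), collapse = ",")))
  invisible(x)
}

#' @export
length.methyl_dataset <- function(x) nrow(x$samples)

#' Subset a methylation dataset by sample index
#'
#' @param dataset a [methyl_dataset()].
#' @param idx integer index vector.
#' @param name name for the subset (defaults to the parent name).
#' @return A `methyl_dataset` containing the selected samples, in the
#'   order of `idx`.
#' @export
dataset_subset <- function(dataset, idx, name = dataset$name) {
  s <- dataset$samples[idx, , drop = FALSE]
  methyl_dataset(s$id, s$sequence, s$label, s$modification, name = name)
}

## ---- file I/O -------------------------------------------------------

parse_fasta_header <- function(header, i) {
  parts <- strsplit(header, "|", fixed = TRUE)[[1]]
  id <- parts[[1]]
  kv <- parts[-1]
  get <- function(key) {
    hit <- grep(paste0("^", key, "="), kv, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    sub(paste0("^", key, "="), "", hit[[1L]])
  }
  label <- get("label")
  if (is.na(label))
    stopf("FASTA record %d ('%s'): header carries no label= field", i, id)
  if (!label %in% c("0", "1"))
    stopf("FASTA record %d ('%s'): label must be 0 or 1, got '%s'",
          i, id, label)
  list(id = id, label = as.integer(label), mod = get("mod"))
}

#' Read labelled sequence windows from FASTA or TSV
#'
#' FASTA headers are self-describing: `>id|label={0,1}|mod={tag}` (the
#' `mod` field is optional).  TSV files carry two columns
#' `sequence<TAB>label` (an optional third column gives the modification
#' tag); a header row `sequence label` is tolerated.  Sequences are
#' uppercased and `T` is mapped to `U` (a message reports the
#' replacement count); windows shorter than 41 nt can be padded and
#' longer ones centre-cropped on explicit request.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"fasta"` or `"tsv"`.
#' @param pad_side if non-`NULL`, pad shorter sequences with `-` on this
#'   side (`"head"` or `"tail"`).
#' @param crop if `TRUE`, centre-crop sequences longer than 41 nt
#'   (keeping the middle base); otherwise such records are an error.
#' @param name dataset name (defaults to the file name).
#' @return A [methyl_dataset()].
#' @seealso [write_samples()], [pad_to_length()], [center_crop_sequence()]
#' @export
read_samples <- function(path, format = c("auto", "fasta", "tsv"),
                         pad_side = NULL, crop = FALSE, name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (format == "fasta") {
    recs <- Biostrings::readBStringSet(path)
    if (length(recs) == 0L) stopf("no FASTA records in %s", path)
    heads <- lapply(seq_along(recs), function(i)
      parse_fasta_header(names(recs)[[i]], i))
    id <- vapply(heads, `[[`, "", "id")
    label <- vapply(heads, `[[`, 0L, "label")
    mod <- vapply(heads, function(h) h$mod %||% NA_character_, "")
    mod[is.na(mod)] <- "unknown"
    seqs <- as.character(recs)
  } else {
    tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    if (ncol(tab) < 2L)
      stopf("TSV %s: expected at least 2 columns (sequence, label)", path)
    if (nrow(tab) > 0 && tolower(tab[1, 1]) %in% c("sequence", "seq"))
      tab <- tab[-1, , drop = FALSE]
    if (nrow(tab) == 0L) stopf("no records in %s", path)
    seqs <- tab[[1]]
    label <- tab[[2]]
    bad <- which(!label %in% c("0", "1"))
    if (length(bad) > 0L)
      stopf("TSV %s line %d: label must be 0 or 1, got '%s'",
            path, bad[[1L]], label[[bad[[1L]]]])
    label <- as.integer(label)
    mod <- if (ncol(tab) >= 3L) tab[[3]] else "unknown"
    id <- sprintf("seq%d", seq_along(seqs))
  }
  n_t2u <- 0L
  for (i in seq_along(seqs)) {
    s <- normalize_sequence(seqs[[i]])
    n_t2u <- n_t2u + attr(s, "n_t2u")
    s <- as.character(s)
    if (nchar(s) > WINDOW_LENGTH) {
      if (!crop)
        stopf("record %d ('%s'): sequence length %d exceeds %d (use crop = TRUE to centre-crop)",
              i, id[[i]], nchar(s), WINDOW_LENGTH)
      s <- center_crop_sequence(s, WINDOW_LENGTH)
    }
    if (nchar(s) < WINDOW_LENGTH) {
      if (is.null(pad_side))
        stopf("record %d ('%s'): sequence length %d is short of %d (supply pad_side to pad)",
              i, id[[i]], nchar(s), WINDOW_LENGTH)
      s <- pad_to_length(s, WINDOW_LENGTH, side = pad_side)
    }
    seqs[[i]] <- s
  }
  if (n_t2u > 0L)
    message(sprintf("read_samples: normalized %d 'T' character(s) to 'U'",
                    n_t2u))
  methyl_dataset(id, seqs, label, mod, name = name %||% basename(path))
}

#' Write a methylation dataset to FASTA or TSV
#'
#' FASTA output preserves ids, labels and modification tags in the
#' header (`>id|label=1|mod=m6A`) and round-trips exactly through
#' [read_samples()].  TSV output is the plain 2-column dialect
#' (sequence, label) plus a third modification column, so ids are not
#' preserved.
#'
#' @param dataset a [methyl_dataset()].
#' @param path output file.
#' @param format `"fasta"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_samples <- function(dataset, path, format = c("fasta", "tsv")) {
  format <- match.arg(format)
  s <- dataset$samples
  if (format == "fasta") {
    x <- Biostrings::BStringSet(s$sequence)
    names(x) <- sprintf("%s|label=%d|mod=%s", s$id, s$label, s$modification)
    Biostrings::writeXStringSet(x, path, width = 80L)
  } else {
    utils::write.table(
      data.frame(s$sequence, s$label, s$modification),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

## ---- padding / cropping ---------------------------------------------

#' Pad a sequence with '-' to a target length
#'
#' @param sequence string over `{A,C,G,U}` (pads allowed only on the
#'   side being extended).
#' @param target target length (default 41).
#' @param side `"tail"` (default) or `"head"`.
#' @return A string of length `target` whose original characters are
#'   preserved contiguously, with the pad run on the requested side.
#' @examples
#' pad_to_length(strrep("A", 38))            # "AAA...A---"
#' pad_to_length(strrep("A", 40), side = "head")
#' @export
pad_to_length <- function(sequence, target = 41L, side = c("tail", "head")) {
  side <- match.arg(side)
  L <- nchar(sequence)
  if (L > target)
    stopf("sequence length %d exceeds target %d; use center_crop_sequence()",
          L, target)
  pad <- strrep(PAD_CHAR, target - L)
  if (side == "tail") paste0(sequence, pad) else paste0(pad, sequence)
}

#' Centre-crop a sequence to a target length
#'
#' Keeps the middle base: for odd `target` and odd input length the
#' centre character of the output is the centre character of the input.
#'
#' @param sequence input string, length at least `target`.
#' @param target output length (default 41).
#' @return The centred substring of length `target`.
#' @export
center_crop_sequence <- function(sequence, target = 41L) {
  L <- nchar(sequence)
  if (L < target) stopf("sequence length %d is shorter than target %d", L, target)
  start <- (L - target) %/% 2L + 1L
  substr(sequence, start, start + target - 1L)
}

## ---- cross-validation split -----------------------------------------

#' Label-stratified k-fold partition of a dataset
#'
#' Each class is shuffled under the given seed and dealt round-robin
#' into `k` folds, so per-fold class counts differ by at most one from
#' perfect stratification.  Every sample appears in exactly one
#' validation fold.
#'
#' @param dataset a [methyl_dataset()].
#' @param k number of folds (at least 2, at most the minority-class
#'   count).
#' @param seed integer seed; identical seeds give identical partitions.
#' @return A list of `k` elements, each `list(train, validation)` of
#'   sample indices into `dataset$samples`.
#' @export
kfold_split <- function(dataset, k, seed = 1L) {
  if (!is_count(k) || k < 2L) stopf("k must be an integer >= 2")
  lab <- dataset$samples$label
  n_min <- min(table(factor(lab, levels = c(0L, 1L))))
  if (k > n_min)
    stopf("k = %d exceeds the minority-class count (%d)", k, n_min)
  fold_of <- integer(length(lab))
  withr::with_seed(as.integer(seed), {
    for (cl in c(0L, 1L)) {
      idx <- which(lab == cl)
      idx <- sample(idx)
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), validation = which(fold_of == f)))
}
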