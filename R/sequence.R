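#' The canonical amino-acid alphabet
#'
#' The 20 canonical amino acids in alphabetical one-letter order. All
#' variant sequences handled by the package are strings over this
#' alphabet; ambiguity codes (X, B, Z) are rejected in strict mode.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

assert_canonical <- function(residues, what = "sequence") {
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), aa_alphabet())
  if (length(bad) > 0) {
    stop(sprintf("%s contains non-canonical residue(s): %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(residues)
}

#' Construct a parent protein sequence
#'
#' A parent sequence is the reference against which point substitutions
#' are named and enumerated. Positions are 1-based on the full expressed
#' construct, so printed variant names (e.g. \code{G20R}) stay valid even
#' when part of the construct (an affinity tag, say) is barred from
#' mutation via \code{exclude}.
#'
#' @param residues Amino-acid string over the 20-letter canonical
#'   alphabet.
#' @param id Text label for the sequence.
#' @param exclude Integer vector of 1-based positions barred from
#'   mutation (e.g. a His-tag region). Must lie within the sequence.
#' @return An object of class \code{parent_seq}: a list with elements
#'   \code{id}, \code{residues} and \code{exclude}.
#' @examples
#' p <- parent_sequence("MGGAVLKT", id = "toy", exclude = 1:2)
#' nchar(p$residues)
#' @export
parent_sequence <- function(residues, id = "parent", exclude = integer()) {
  stopifnot(is.character(residues), length(residues) == 1)
  residues <- toupper(residues)
  if (nchar(residues) == 0) stop("parent sequence must be non-empty", call. = FALSE)
  assert_canonical(residues, "parent sequence")
  exclude <- sort(unique(as.integer(exclude)))
  if (length(exclude) > 0 &&
      (min(exclude) < 1 || max(exclude) > nchar(residues))) {
    stop("excluded positions must lie within [1, sequence length]", call. = FALSE)
  }
  structure(list(id = id, residues = residues, exclude = exclude),
            class = "parent_seq")
}

#' @export
print.parent_seq <- function(x, ...) {
  cat(sprintf("<parent_seq> %s: %d aa, %d excluded position(s)\n",
              x$id, nchar(x$residues), length(x$exclude)))
  invisible(x)
}

#' Parse point-mutation notation
#'
#' Parses tokens in the standard \code{<wt><position><mut>} notation
#' (e.g. \code{"G20R"}: glycine 20 to arginine) into a tidy table.
#' Silent substitutions (wild-type equals mutant) and non-canonical
#' letters are errors.
#'
#' @param tokens Character vector of mutation tokens.
#' @return A tibble with columns \code{wt}, \code{position}, \code{mut}
#'   and the normalized \code{mutation} string, one row per token.
#' @examples
#' parse_mutations(c("G20R", "L100N"))
#' @export
parse_mutations <- function(tokens) {
  stopifnot(is.character(tokens))
  tokens <- toupper(trimws(tokens))
  m <- regmatches(tokens, regexec("^([A-Z])([0-9]+)([A-Z])$", tokens))
  bad <- tokens[vapply(m, length, 1L) != 4L]
  if (length(bad) > 0) {
    stop("malformed mutation token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  wt <- vapply(m, `[[`, "", 2L)
  pos <- as.integer(vapply(m, `[[`, "", 3L))
  mut <- vapply(m, `[[`, "", 4L)
  if (any(!wt %in% aa_alphabet()) || any(!mut %in% aa_alphabet())) {
    stop("mutation token(s) with non-canonical amino-acid letters",
         call. = FALSE)
  }
  if (any(pos < 1)) stop("mutation position must be >= 1", call. = FALSE)
  if (any(wt == mut)) {
    stop("silent substitution(s) (wild-type equals mutant): ",
         paste(tokens[wt == mut], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(wt = wt, position = pos, mut = mut,
                 mutation = paste0(wt, pos, mut))
}

#' Split a semicolon-separated mutation list into a tidy table
#'
#' @param mutation_list Single string like \code{"G20R;L100N"}, or
#'   \code{""} for the wild type.
#' @return A tibble as from [parse_mutations()]; zero rows for the
#'   wild type.
#' @export
parse_mutation_list <- function(mutation_list) {
  stopifnot(length(mutation_list) == 1)
  if (is.na(mutation_list) || trimws(mutation_list) == "") {
    return(tibble::tibble(wt = character(), position = integer(),
                          mut = character(), mutation = character()))
  }
  parse_mutations(strsplit(trimws(mutation_list), ";\\s*")[[1]])
}

#' Apply point substitutions to a parent sequence
#'
#' Each mutation's stated wild-type residue must match the parent at its
#' position; a mismatch signals a numbering or reference error and
#' aborts. Positions must be distinct.
#'
#' @param parent A [parent_sequence()].
#' @param mutations A tibble from [parse_mutations()], or a character
#'   vector of tokens.
#' @return The full-length mutated sequence (single string).
#' @examples
#' p <- parent_sequence("MGGA")
#' apply_mutations(p, "G3A")
#' @export
apply_mutations <- function(parent, mutations) {
  stopifnot(inherits(parent, "parent_seq"))
  if (is.character(mutations)) mutations <- parse_mutations(mutations)
  if (nrow(mutations) == 0) return(parent$residues)
  if (anyDuplicated(mutations$position)) {
    stop("duplicate mutation position(s): at most one substitution per site",
         call. = FALSE)
  }
  L <- nchar(parent$residues)
  if (any(mutations$position > L)) {
    stop("mutation position beyond parent length ", L, call. = FALSE)
  }
  chars <- strsplit(parent$residues, "")[[1]]
  found <- chars[mutations$position]
  if (any(found != mutations$wt)) {
    i <- which(found != mutations$wt)[1]
    stop(sprintf(
      "wild-type mismatch at position %d: parent has %s, mutation says %s",
      mutations$position[i], found[i], mutations$wt[i]), call. = FALSE)
  }
  chars[mutations$position] <- mutations$mut
  paste(chars, collapse = "")
}

#' Recover the mutation set of a variant by diffing against the parent
#'
#' Inverse of [apply_mutations()]: compares an equal-length variant
#' sequence with the parent and returns the substitutions as a
#' normalized mutation-list string.
#'
#' @param parent A [parent_sequence()].
#' @param sequence Full-length variant sequence.
#' @return Semicolon-separated mutation string (\code{""} if identical
#'   to the parent).
#' @export
diff_to_mutations <- function(parent, sequence) {
  stopifnot(inherits(parent, "parent_seq"))
  if (nchar(sequence) != nchar(parent$residues)) {
    stop(sprintf("variant length %d does not match parent length %d",
                 nchar(sequence), nchar(parent$residues)), call. = FALSE)
  }
  assert_canonical(sequence, "variant sequence")
  a <- strsplit(parent$residues, "")[[1]]
  b <- strsplit(sequence, "")[[1]]
  pos <- which(a != b)
  if (length(pos) == 0) return("")
  paste0(a[pos], pos, b[pos], collapse = ";")
}

#' Enumerate the complete single-substitution library of a parent
#'
#' Generates every variant that differs from the parent at exactly one
#' non-excluded position: 19 substitutions per position, ordered
#' position-major then alphabetically by mutant residue, so downstream
#' ranking ties break reproducibly.
#'
#' @param parent A [parent_sequence()].
#' @param with_sequence Attach the full mutant sequence for each row
#'   (default \code{TRUE}; needed for kernel computations).
#' @return A tibble with one row per candidate: \code{mutation},
#'   \code{wt}, \code{position}, \code{mut} and (optionally)
#'   \code{sequence}. Exactly \code{19 * (L - n_excluded)} rows.
#' @examples
#' nrow(enumerate_single_mutants(parent_sequence("MGGAVLKTQW")))  # 190
#' @export
enumerate_single_mutants <- function(parent, with_sequence = TRUE) {
  stopifnot(inherits(parent, "parent_seq"))
  chars <- strsplit(parent$residues, "")[[1]]
  positions <- setdiff(seq_along(chars), parent$exclude)
  if (length(positions) == 0) {
    stop("all positions are excluded; nothing to enumerate", call. = FALSE)
  }
  aa <- aa_alphabet()
  rows <- purrr::map_dfr(positions, function(p) {
    muts <- setdiff(aa, chars[p])
    tibble::tibble(wt = chars[p], position = p, mut = muts)
  })
  rows <- dplyr::mutate(rows, mutation = paste0(.data$wt, .data$position, .data$mut))
  if (with_sequence) {
    L <- length(chars)
    seqs <- vapply(seq_len(nrow(rows)), function(i) {
      s <- chars
      s[rows$position[i]] <- rows$mut[i]
      paste(s, collapse = "")
    }, character(1))
    rows$sequence <- seqs
  }
  dplyr::select(rows, "mutation", "wt", "position", "mut",
                dplyr::any_of("sequence"))
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file (one or more records).
#' @param strict Reject any residue outside the 20-letter canonical
#'   alphabet (default \code{TRUE}); with \code{strict = FALSE},
#'   offending records are dropped with a warning instead.
#' @return A list of [parent_sequence()] objects in file order.
#' @export
read_fasta <- function(path, strict = TRUE) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("FASTA file has no records: ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  ok <- !grepl(paste0("[^", paste(aa_alphabet(), collapse = ""), "]"), seqs)
  if (!all(ok)) {
    msg <- paste0("record(s) with non-canonical residues: ",
                  paste(names(set)[!ok], collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, " (dropped)")
    seqs <- seqs[ok]
    set <- set[ok]
    if (length(set) == 0) stop("no canonical records left", call. = FALSE)
  }
  purrr::map2(seqs, names(set), function(s, nm) {
    parent_sequence(s, id = sub("\\s.*$", "", nm))
  })
}

#' Write sequences to FASTA
#'
#' @param seqs A [parent_sequence()], a list of them, or a named
#'   character vector of sequences.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "parent_seq")) seqs <- list(seqs)
  if (is.list(seqs)) {
    v <- vapply(seqs, function(p) p$residues, character(1))
    names(v) <- vapply(seqs, function(p) p$id, character(1))
    seqs <- v
  }
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a measured variant table
#'
#' Reads the screening-data shape used throughout the package: one row
#' per variant with either a semicolon-separated mutation list or a
#' full-length sequence, plus numeric target columns (by convention
#' \code{rate}, the carboxylation rate to maximize, and
#' \code{atp_ratio}, the ATP-per-carboxylation ratio to minimize).
#' Rows carrying a full sequence are diffed against the parent to
#' recover their mutation sets; rows carrying mutations are expanded to
#' full sequences. A row identical to the parent is kept as the
#' wild-type control (empty mutation set).
#'
#' @param path TSV or CSV file with a header row containing \code{id}
#'   and at least one of \code{mutations} / \code{sequence}, plus the
#'   target columns.
#' @param parent A [parent_sequence()].
#' @param targets Character vector of target column names that must be
#'   present and numeric.
#' @return A tibble with columns \code{id}, \code{mutations},
#'   \code{sequence}, \code{n_mutations} and the targets; the parent is
#'   attached as attribute \code{"parent"}.
#' @export
read_variant_table <- function(path, parent,
                               targets = c("rate", "atp_ratio")) {
  stopifnot(inherits(parent, "parent_seq"))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (!"id" %in% names(df)) stop("variant table needs an 'id' column", call. = FALSE)
  if (anyDuplicated(df$id)) {
    stop("duplicate variant id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  }
  missing_t <- setdiff(targets, names(df))
  if (length(missing_t) > 0) {
    stop("missing target column(s): ", paste(missing_t, collapse = ", "),
         call. = FALSE)
  }
  for (t in targets) {
    v <- df[[t]]
    if (!is.numeric(v)) {
      suppressWarnings(v <- as.numeric(v))
      if (anyNA(v) && !anyNA(df[[t]])) {
        stop("non-numeric values in target column '", t, "'", call. = FALSE)
      }
      df[[t]] <- v
    }
  }
  has_seq <- "sequence" %in% names(df) && any(!is.na(df$sequence) & df$sequence != "")
  has_mut <- "mutations" %in% names(df)
  if (!has_seq && !has_mut) {
    stop("variant table needs a 'mutations' or 'sequence' column", call. = FALSE)
  }
  n <- nrow(df)
  sequence <- character(n)
  mutations <- character(n)
  for (i in seq_len(n)) {
    s <- if (has_seq) df$sequence[i] else NA_character_
    if (!is.na(s) && nzchar(s)) {
      s <- toupper(s)
      mutations[i] <- diff_to_mutations(parent, s)
      sequence[i] <- s
    } else {
      ml <- df$mutations[i]
      if (is.na(ml)) ml <- ""
      muts <- parse_mutation_list(ml)
      sequence[i] <- apply_mutations(parent, muts)
      mutations[i] <- if (nrow(muts) == 0) "" else
        paste(muts$mutation, collapse = ";")
    }
  }
  out <- tibble::tibble(
    id = as.character(df$id),
    mutations = mutations,
    sequence = sequence,
    n_mutations = vapply(mutations, function(m)
      if (m == "") 0L else length(strsplit(m, ";")[[1]]), integer(1),
      USE.NAMES = FALSE)
  )
  for (t in targets) out[[t]] <- df[[t]]
  attr(out, "parent") <- parent
  out
}

#' Write a variant table to TSV
#'
#' @param data Variant tibble (as from [read_variant_table()] or
#'   [simulate_landscape()]).
#' @param path Output TSV path.
#' @export
write_variant_table <- function(data, path) {
  readr::write_tsv(data, path, progress = FALSE)
  invisible(path)
}
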