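#' The BLOSUM62 substitution matrix over the canonical alphabet
#'
#' Returns the published BLOSUM62 log-odds score table restricted to
#' the 20 canonical amino acids, as shipped with Biostrings.
#'
#' @return A symmetric 20 x 20 integer matrix with dimnames over
#'   [aa_alphabet()].
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[aa_alphabet(), aa_alphabet()]
  storage.mode(m) <- "double"
  m
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-separated score tables distributed with BLAST
#' (comment lines starting with \code{#}, a header row of residue
#' letters, one labelled row per residue).
#'
#' @param path Matrix file.
#' @return Symmetric numeric matrix restricted to the canonical
#'   residues present in the file.
#' @export
read_substitution_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, comment.char = "#",
                                   check.names = FALSE))
  keep <- intersect(aa_alphabet(), rownames(m))
  if (length(keep) < 20) {
    stop("substitution matrix does not cover all 20 canonical residues",
         call. = FALSE)
  }
  m <- m[aa_alphabet(), aa_alphabet()]
  if (!isSymmetric(unname(m))) {
    stop("substitution matrix is not symmetric", call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}

#' Specify a sequence-similarity kernel
#'
#' Two kernel families over equal-length protein sequences are
#' supported. \code{"blosum_position"} (the default) scores a pair by
#' summing the BLOSUM62 entry at every aligned position,
#' \eqn{k_{raw}(x, y) = \sum_i B(x_i, y_i)}; with
#' \code{normalize = TRUE} the raw score is cosine-normalized,
#' \eqn{k = k_{raw}(x,y) / \sqrt{k_{raw}(x,x)\,k_{raw}(y,y)}}, so every
#' sequence has unit self-similarity. \code{"hamming"} returns the
#' fraction of identical positions.
#'
#' @param family \code{"blosum_position"} or \code{"hamming"}.
#' @param substitution_matrix Symmetric score table over the canonical
#'   alphabet (default [blosum62()]); ignored by the hamming family.
#' @param normalize Cosine-normalize the blosum_position kernel
#'   (default \code{TRUE}). The hamming kernel is already in [0, 1].
#' @return An object of class \code{kernel_spec}.
#' @export
kernel_spec <- function(family = c("blosum_position", "hamming"),
                        substitution_matrix = NULL,
                        normalize = TRUE) {
  family <- match.arg(family)
  if (family == "blosum_position") {
    if (is.null(substitution_matrix)) substitution_matrix <- blosum62()
    stopifnot(is.matrix(substitution_matrix))
    if (!all(aa_alphabet() %in% rownames(substitution_matrix))) {
      stop("substitution matrix must cover all 20 canonical residues",
           call. = FALSE)
    }
    sm <- substitution_matrix[aa_alphabet(), aa_alphabet()]
    if (!isSymmetric(unname(sm))) {
      stop("substitution matrix must be symmetric", call. = FALSE)
    }
  } else {
    sm <- NULL
  }
  structure(list(family = family, substitution_matrix = sm,
                 normalize = isTRUE(normalize)),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> %s%s\n", x$family,
              if (x$family == "blosum_position" && x$normalize)
                " (cosine-normalized)" else ""))
  invisible(x)
}

# sequences -> n x L integer matrix of alphabet indices
encode_sequences <- function(seqs) {
  stopifnot(length(seqs) > 0)
  L <- nchar(seqs[1])
  if (any(nchar(seqs) != L)) {
    stop("all sequences must have equal length", call. = FALSE)
  }
  chars <- strsplit(seqs, "")
  idx <- match(unlist(chars), aa_alphabet())
  if (anyNA(idx)) stop("non-canonical residue in sequence set", call. = FALSE)
  matrix(idx, nrow = length(seqs), ncol = L, byrow = TRUE)
}

# raw position-summed substitution score between row-encoded sets
raw_cross_blosum <- function(xm, zm, sm) {
  n <- nrow(xm); m <- nrow(zm); L <- ncol(xm)
  K <- matrix(0, n, m)
  for (l in seq_len(L)) {
    K <- K + sm[xm[, l], zm[, l], drop = FALSE]
  }
  K
}

raw_self_blosum <- function(xm, sm) {
  d <- diag(sm)
  rowSums(matrix(d[xm], nrow = nrow(xm)))
}

#' Kernel value between two sequences
#'
#' @param x,y Equal-length sequences over the canonical alphabet.
#' @param spec A [kernel_spec()].
#' @return A single numeric kernel value.
#' @examples
#' kernel_value("AAA", "AAT", kernel_spec("hamming"))  # 2/3
#' @export
kernel_value <- function(x, y, spec = kernel_spec()) {
  drop(cross_gram(x, y, spec))
}

#' Gram matrix over a set of sequences
#'
#' Pairwise kernel values over one sequence set; symmetric with unit
#' diagonal under the normalized blosum_position kernel. The kernel
#' specification and sequence ids travel with the matrix as attributes.
#'
#' @param seqs Character vector of equal-length sequences.
#' @param spec A [kernel_spec()].
#' @param ids Optional row/column labels (default names of \code{seqs}
#'   or indices).
#' @return An n x n numeric matrix of class \code{gram_matrix} with
#'   attributes \code{kernel} and \code{ids}.
#' @export
gram <- function(seqs, spec = kernel_spec(), ids = NULL) {
  if (length(seqs) == 0) stop("empty sequence set", call. = FALSE)
  K <- cross_gram(seqs, seqs, spec)
  K <- (K + t(K)) / 2   # enforce exact symmetry against fp noise
  if (is.null(ids)) ids <- names(seqs) %||% as.character(seq_along(seqs))
  dimnames(K) <- list(ids, ids)
  structure(K, kernel = spec, ids = ids, class = c("gram_matrix", "matrix"))
}

#' Cross-kernel matrix between two sequence sets
#'
#' @param x,z Character vectors of equal-length sequences (rows index
#'   \code{x}, columns \code{z}).
#' @param spec A [kernel_spec()].
#' @return An \code{length(x)} x \code{length(z)} numeric matrix.
#' @export
cross_gram <- function(x, z, spec = kernel_spec()) {
  if (length(x) == 0 || length(z) == 0) stop("empty sequence set", call. = FALSE)
  if (nchar(x[1]) != nchar(z[1])) {
    stop("sequence sets have different lengths", call. = FALSE)
  }
  xm <- encode_sequences(x)
  zm <- encode_sequences(z)
  if (spec$family == "hamming") {
    L <- ncol(xm)
    K <- matrix(0, nrow(xm), nrow(zm))
    for (l in seq_len(L)) {
      K <- K + outer(xm[, l], zm[, l], "==")
    }
    return(K / L)
  }
  sm <- spec$substitution_matrix
  K <- raw_cross_blosum(xm, zm, sm)
  if (spec$normalize) {
    sx <- raw_self_blosum(xm, sm)
    sz <- raw_self_blosum(zm, sm)
    K <- K / sqrt(outer(sx, sz))
  }
  K
}

#' Self-similarity (kernel diagonal) of sequences
#'
#' \eqn{k(x, x)} for each sequence: 1 under the normalized
#' blosum_position and hamming kernels, the raw self-score otherwise.
#'
#' @param seqs Character vector of sequences.
#' @param spec A [kernel_spec()].
#' @return Numeric vector.
#' @export
kernel_self <- function(seqs, spec = kernel_spec()) {
  if (spec$family == "hamming" || spec$normalize) {
    return(rep(1, length(seqs)))
  }
  raw_self_blosum(encode_sequences(seqs), spec$substitution_matrix)
}

#' Repair a Gram matrix to positive semidefiniteness
#'
#' Position-summed substitution scores are not guaranteed to yield a
#' positive-semidefinite kernel. Mode \code{"none"} trusts the additive
#' regularization used downstream and returns the input; mode
#' \code{"clip"} eigen-decomposes, zeroes negative eigenvalues and
#' re-symmetrizes.
#'
#' @param G Symmetric numeric matrix (typically from [gram()]).
#' @param mode \code{"none"} (default) or \code{"clip"}.
#' @return A matrix of the same shape (attributes preserved).
#' @export
psd_repair <- function(G, mode = c("none", "clip")) {
  mode <- match.arg(mode)
  if (!isSymmetric(unname(unclass(G)), tol = 1e-8)) {
    stop("psd_repair expects a symmetric matrix", call. = FALSE)
  }
  if (mode == "none") return(G)
  at <- attributes(G)
  e <- eigen(unclass(G), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  R <- e$vectors %*% (lam * t(e$vectors))
  R <- (R + t(R)) / 2
  attributes(R) <- utils::modifyList(at, list(dim = dim(R)))
  R
}

`%||%` <- function(a, b) if (is.null(a)) b else a
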