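#' One-hot sequence embedding
#'
#' Embeds equal-length sequences into a fixed-length real vector space
#' by indicator coding: dimension 20 x L, one 1 per position. This is
#' the default feature set for the tree-ensemble baseline; externally
#' computed embeddings (e.g. averaged language-model hidden states) can
#' be supplied instead via [read_embedding_tsv()].
#'
#' @param sequences Character vector of equal-length canonical
#'   sequences.
#' @param ids Optional row labels.
#' @return Numeric matrix (n x 20L) with attribute
#'   \code{embedding_name = "onehot"}.
#' @export
onehot_embed <- function(sequences, ids = NULL) {
  xm <- encode_sequences(sequences)
  n <- nrow(xm); L <- ncol(xm)
  M <- matrix(0, n, 20L * L)
  off <- (seq_len(L) - 1L) * 20L
  for (l in seq_len(L)) {
    M[cbind(seq_len(n), off[l] + xm[, l])] <- 1
  }
  rownames(M) <- ids %||% names(sequences)
  colnames(M) <- paste0(rep(seq_len(L), each = 20), "_",
                        rep(aa_alphabet(), L))
  attr(M, "embedding_name") <- "onehot"
  M
}

#' Load an externally computed embedding table
#'
#' Reads a TSV of per-variant embedding vectors (first column
#' \code{id}, remaining columns numeric coordinates) such as averaged
#' hidden-state protein-language-model embeddings computed outside R.
#'
#' @param path TSV file: header row, \code{id} column plus D numeric
#'   columns.
#' @param ids Optional character vector of variant ids that must all be
#'   present; the returned rows follow this order.
#' @return Numeric matrix (n x D) with rownames = ids and attribute
#'   \code{embedding_name}.
#' @export
read_embedding_tsv <- function(path, ids = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"id" %in% names(df)) stop("embedding table needs an 'id' column",
                                 call. = FALSE)
  M <- as.matrix(df[setdiff(names(df), "id")])
  if (!is.numeric(M) || anyNA(M)) {
    stop("embedding table has non-numeric or missing coordinates ",
         "(ragged rows?)", call. = FALSE)
  }
  rownames(M) <- df$id
  if (!is.null(ids)) {
    missing_ids <- setdiff(ids, df$id)
    if (length(missing_ids) > 0) {
      stop("embedding table is missing variant id(s): ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    M <- M[ids, , drop = FALSE]
  }
  attr(M, "embedding_name") <- sub("\\.tsv$", "", basename(path))
  M
}

#' Random-forest baseline: fit on embeddings, predict test points
#'
#' The comparison model for the GP ranker: a random forest regressor on
#' fixed-length sequence embeddings, package-default settings, one
#' forest per target. Deterministic given the seed. Tree-ensemble
#' predictions never extrapolate beyond the training-target range.
#'
#' @param train_x Training embedding matrix (n x D).
#' @param train_y Data frame / tibble of numeric targets (n rows).
#' @param test_x Test embedding matrix (m x D, same D).
#' @param seed Integer seed.
#' @param ntree Number of trees (default 100, matching the baseline
#'   protocol's default regressor settings).
#' @return Tibble of predictions, one column per target, m rows.
#' @export
rf_fit_predict <- function(train_x, train_y, test_x, seed = 1,
                           ntree = 100) {
  stopifnot(nrow(train_x) >= 2, nrow(train_x) == nrow(train_y))
  if (ncol(train_x) != ncol(test_x)) {
    stop("train/test embedding dimension mismatch (",
         ncol(train_x), " vs ", ncol(test_x), ")", call. = FALSE)
  }
  preds <- purrr::map(names(train_y), function(t) {
    with_seed(seed, {
      fit <- randomForest::randomForest(x = train_x, y = train_y[[t]],
                                        ntree = ntree)
      unname(stats::predict(fit, test_x))
    })
  })
  names(preds) <- names(train_y)
  tibble::as_tibble(preds)
}
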