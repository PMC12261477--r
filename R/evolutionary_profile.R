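#' Column-frequency counting matrix of an aligned family
#'
#' For N aligned homologs of length L, entry (i, v) is the relative frequency
#' of vocabulary token v at column i: the count of sequences carrying v at i
#' divided by N. Every cell of the alignment holds exactly one token (gaps are
#' `<pad>`), so each row sums to 1 and no pseudocounts are needed.
#'
#' @param family An [aligned_family()].
#' @param include_query Whether the query row (if identified by
#'   `query_index`) contributes to the counts. Default `TRUE`.
#' @param weights Optional per-sequence weights (length N, nonnegative). The
#'   default `NULL` weights every sequence equally (unweighted counts).
#' @return L x 25 matrix of class `count_matrix`, columns named by the
#'   vocabulary; rows sum to 1.
#' @export
#' @examples
#' fam <- aligned_family(c("ACDE", "ACDE", "AC-E"))
#' count_matrix(fam)[3, c("D", "<pad>")]
count_matrix <- function(family, include_query = TRUE, weights = NULL) {
  stopifnot(inherits(family, "aligned_family"))
  grid <- family$sequences
  if (!include_query && !is.na(family$query_index)) {
    grid <- grid[-family$query_index, , drop = FALSE]
    if (!is.null(weights)) weights <- weights[-family$query_index]
  }
  n <- nrow(grid)
  if (n == 0L) stop("no sequences to count")
  vocab <- token_vocabulary()
  w <- weights %||% rep(1, n)
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  L <- ncol(grid)
  C <- matrix(0, nrow = L, ncol = length(vocab),
              dimnames = list(NULL, vocab))
  for (v in seq_along(vocab)) {
    C[, v] <- colSums((grid == vocab[v]) * w)
  }
  C <- C / sum(w)
  class(C) <- c("count_matrix", class(C))
  C
}

#' Evolutionary logits from column frequencies
#'
#' Applies a row-wise log-softmax directly to the relative frequencies: for
#' column i and token v, `O[i, v] = log(exp(C[i, v]) / sum_v' exp(C[i, v']))`.
#' Softmax shift-invariance gives the exact identity
#' `O[i, a] - O[i, b] = C[i, a] - C[i, b]`, so within-column logit differences
#' live in [-1, 1] and a substitution away from a fully conserved residue
#' scores exactly -1.
#'
#' @param counts A `count_matrix` (or any L x 25 frequency matrix).
#' @return L x 25 matrix with attribute `role = "evolutionary"`;
#'   `exp()` of each row sums to 1.
#' @export
evolutionary_logits <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) == vocab_size(),
            all(is.finite(counts)))
  O <- row_log_softmax(unclass(counts))
  colnames(O) <- token_vocabulary()
  logit_matrix(O, role = "evolutionary")
}

row_log_softmax <- function(x) {
  m <- apply(x, 1L, max)
  shifted <- x - m
  shifted - log(rowSums(exp(shifted)))
}

#' Construct a logit matrix
#'
#' Thin wrapper tagging an L x 25 real matrix with its role in the scoring
#' pipeline: `native` (language-model forward pass), `evolutionary`
#' (alignment-derived) or `blended` (convex combination of the two).
#'
#' @param values L x 25 numeric matrix, finite entries.
#' @param role One of "native", "evolutionary", "blended".
#' @return The matrix with class `logit_matrix` and attribute `role`.
#' @export
logit_matrix <- function(values, role = c("native", "evolutionary", "blended")) {
  role <- match.arg(role)
  stopifnot(is.matrix(values), is.numeric(values), all(is.finite(values)),
            ncol(values) == vocab_size())
  if (is.null(colnames(values))) colnames(values) <- token_vocabulary()
  structure(values, role = role, class = c("logit_matrix", "matrix", "array"))
}

#' @export
print.logit_matrix <- function(x, ...) {
  cat(sprintf("logit_matrix (%s): %d positions x %d tokens\n",
              attr(x, "role"), nrow(x), ncol(x)))
  invisible(x)
}

#' Write / read a logit matrix as TSV
#'
#' Tab-separated table with a header row of the 25 token symbols and one row
#' per residue (1-based position order). Lines starting with `#` are ignored
#' on read.
#'
#' @param logits A [logit_matrix()] or plain L x 25 matrix.
#' @param path File path.
#' @return `write_logits`: `path` invisibly. `load_external_logits`: a
#'   `logit_matrix` with role "native".
#' @export
write_logits <- function(logits, path) {
  df <- as.data.frame(unclass(logits))
  colnames(df) <- token_vocabulary()
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_logits
#' @param role Role to assign to the loaded matrix (default "native", for
#'   logits exported from an external pretrained model).
#' @export
load_external_logits <- function(path, role = "native") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE)
  vocab <- token_vocabulary()
  if (ncol(df) != length(vocab) || !all(colnames(df) == vocab)) {
    stop("logits table header does not match the 25-token vocabulary")
  }
  logit_matrix(as.matrix(df), role = role)
}
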