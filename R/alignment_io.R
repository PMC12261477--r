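#' Aligned homolog family
#'
#' Container for a query-length-aligned set of homologous sequences over the
#' 25-token vocabulary: an N x L character matrix of tokens plus provenance.
#' Rows are sequences, columns are query residue positions.
#'
#' @param sequences N x L character matrix of vocabulary tokens, or a
#'   character vector of equal-length token strings (split per character and
#'   normalized).
#' @param query_id Identifier of the query sequence.
#' @param source One of "a2m", "a3m", "foldseek", "synthetic".
#' @param query_index Row index of the query within `sequences`, or `NA` if
#'   the query is not a row of the family.
#' @param row_ids Optional per-row identifiers.
#' @return An object of class `aligned_family`.
#' @export
aligned_family <- function(sequences, query_id = "query",
                           source = c("a2m", "a3m", "foldseek", "synthetic"),
                           query_index = NA_integer_, row_ids = NULL) {
  source <- match.arg(source)
  if (is.character(sequences) && !is.matrix(sequences)) {
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L) stop("alignment rows have unequal lengths")
    sequences <- do.call(rbind, strsplit(sequences, ""))
    sequences[] <- normalize_alignment_chars(sequences)
  }
  stopifnot(is.matrix(sequences), is.character(sequences))
  if (nrow(sequences) < 1L) stop("empty alignment: at least one sequence required")
  bad <- setdiff(unique(as.vector(sequences)), token_vocabulary())
  if (length(bad) > 0L) {
    stop("non-vocabulary tokens in family: ", paste(bad, collapse = ", "))
  }
  structure(
    list(query_id = query_id, sequences = sequences, source = source,
         query_index = query_index,
         row_ids = row_ids %||% paste0("seq", seq_len(nrow(sequences)))),
    class = "aligned_family")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.aligned_family <- function(x, ...) {
  cat(sprintf("aligned_family: %d sequences x %d columns (source: %s, query: %s)\n",
              nrow(x$sequences), ncol(x$sequences), x$source, x$query_id))
  invisible(x)
}

#' @export
dim.aligned_family <- function(x) dim(x$sequences)

read_fasta_records <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment file: ", path)
  list(ids = names(set), seqs = as.character(set))
}

#' Read an a2m alignment
#'
#' Reads a FASTA-style a2m alignment and normalizes it: lowercase letters are
#' converted to uppercase and special characters (gaps `-`, `.`, `*`, etc.)
#' are replaced with the `<pad>` token. Non-standard residue letters map to
#' `<unk>`. All rows must have the same length after normalization.
#'
#' @param path Path to the a2m file.
#' @param pad_token Token substituted for gap/special characters.
#' @return An [aligned_family()] with `source = "a2m"`. The first record is
#'   taken as the query (row 1).
#' @export
read_a2m <- function(path, pad_token = "<pad>") {
  rec <- read_fasta_records(path)
  lens <- nchar(rec$seqs)
  if (length(unique(lens)) != 1L) {
    stop("a2m alignment rows have unequal lengths after normalization: ",
         paste(unique(lens), collapse = ", "))
  }
  grid <- do.call(rbind, strsplit(rec$seqs, ""))
  grid[] <- normalize_alignment_chars(grid, pad_token)
  aligned_family(grid, query_id = rec$ids[1], source = "a2m",
                 query_index = 1L, row_ids = rec$ids)
}

#' Read an a3m alignment
#'
#' In a3m files, lowercase letters mark insertion states relative to the query
#' (columns absent from the query). These insertion columns are removed so
#' every row has the query's length, then the same normalization as
#' [read_a2m()] applies.
#'
#' @inheritParams read_a2m
#' @return An [aligned_family()] with `source = "a3m"`; row 1 is the query.
#' @export
read_a3m <- function(path, pad_token = "<pad>") {
  rec <- read_fasta_records(path)
  strip_insertions <- function(s) {
    chars <- strsplit(s, "")[[1]]
    chars[!(chars %in% letters)]
  }
  rows <- lapply(rec$seqs, strip_insertions)
  qlen <- length(rows[[1]])
  lens <- vapply(rows, length, integer(1))
  if (any(lens != qlen)) {
    stop("a3m realignment error: match-state count (",
         paste(unique(lens[lens != qlen]), collapse = ", "),
         ") differs from query length ", qlen)
  }
  grid <- do.call(rbind, rows)
  grid[] <- normalize_alignment_chars(grid, pad_token)
  aligned_family(grid, query_id = rec$ids[1], source = "a3m",
                 query_index = 1L, row_ids = rec$ids)
}

#' Parse structure-search (Foldseek-style) JSON alignments
#'
#' Each hit carries a pairwise alignment of the query (`qaln`) against a
#' target (`taln`) over query positions `qstart..qend` (1-based inclusive).
#' Columns where the query has a gap are deleted from both strings; the
#' surviving target string is placed at `qstart..qend` of a gap-initialized
#' row of the full query length, and gaps normalize to `pad_token`.
#'
#' @param json Path to a JSON file or a JSON string. The payload is a list of
#'   hit objects with fields `target`, `prob`, `eval`, `qaln`, `taln`,
#'   `qstart`, `qend`; unknown fields are ignored. A top-level list may wrap
#'   the hits under `$results[[i]]$alignments` or be the hit list itself.
#' @param full_query The complete query amino-acid sequence (string).
#' @param pad_token Token substituted for gaps.
#' @param query_id Identifier for the query.
#' @return An [aligned_family()] with `source = "foldseek"`; row 1 is the full
#'   query, subsequent rows are the padded target alignments.
#' @export
parse_foldseek_results <- function(json, full_query, pad_token = "<pad>",
                                   query_id = "query") {
  payload <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  hits <- extract_foldseek_hits(payload)
  if (length(hits) == 0L) stop("no alignment hits found in payload")
  L <- nchar(full_query)
  qchars <- strsplit(toupper(full_query), "")[[1]]
  rows <- list(qchars)
  ids <- query_id
  for (h in hits) {
    qa <- strsplit(h$qaln, "")[[1]]
    ta <- strsplit(h$taln, "")[[1]]
    if (length(qa) != length(ta)) {
      stop("hit '", h$target, "': query and target alignment lengths differ")
    }
    keep <- qa != "-" & qa != "."
    qa <- qa[keep]; ta <- ta[keep]
    qstart <- as.integer(h$qstart); qend <- as.integer(h$qend)
    if (qstart > qend || qstart < 1L || qend > L) {
      stop("hit '", h$target, "': alignment coordinates out of range")
    }
    expected <- qchars[qstart:qend]
    if (length(qa) != length(expected) ||
        !all(toupper(qa) == expected)) {
      stop("hit '", h$target, "': degapped query alignment disagrees with ",
           "query positions ", qstart, "..", qend)
    }
    row <- rep("-", L)
    row[qstart:qend] <- ta
    rows[[length(rows) + 1L]] <- row
    ids <- c(ids, h$target %||% paste0("hit", length(rows) - 1L))
  }
  grid <- do.call(rbind, rows)
  grid[] <- normalize_alignment_chars(grid, pad_token)
  aligned_family(grid, query_id = query_id, source = "foldseek",
                 query_index = 1L, row_ids = ids)
}

# Accept either a bare list of hits or nested {results: [{alignments: [...]}]}
extract_foldseek_hits <- function(payload) {
  is_hit <- function(x) is.list(x) && !is.null(x$qaln) && !is.null(x$taln)
  if (is_hit(payload)) return(list(payload))
  if (is.list(payload) && all(vapply(payload, is_hit, logical(1))) &&
      length(payload) > 0L) {
    return(payload)
  }
  hits <- list()
  if (!is.null(payload$results)) {
    for (res in payload$results) {
      alns <- res$alignments %||% list()
      # alignments may be nested one level deeper (per-database lists)
      for (a in alns) {
        if (is_hit(a)) hits <- c(hits, list(a))
        else hits <- c(hits, Filter(is_hit, a))
      }
    }
  }
  hits
}

#' Write an aligned family as a2m
#'
#' `<pad>` is rendered as `-` and `<unk>` as `X`; reading the file back with
#' [read_a2m()] reproduces the token grid exactly.
#'
#' @param family An [aligned_family()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_a2m <- function(family, path) {
  stopifnot(inherits(family, "aligned_family"))
  grid <- family$sequences
  if (nrow(grid) < 1L || ncol(grid) < 1L) stop("empty family")
  grid[grid == PAD_TOKEN] <- "-"
  grid[grid == UNK_TOKEN] <- "X"
  multi <- nchar(grid) > 1L
  if (any(multi)) grid[multi] <- "X"  # other specials have no a2m glyph
  lines <- character(2L * nrow(grid))
  lines[c(TRUE, FALSE)] <- paste0(">", family$row_ids)
  lines[c(FALSE, TRUE)] <- apply(grid, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}
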