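#' Read the first sequence from a FASTA file
#'
#' @param path FASTA path.
#' @return Character scalar (named by its FASTA header).
#' @export
read_fasta_seq <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  out <- as.character(set[[1L]])
  names(out) <- names(set)[1L]
  out
}

read_family <- function(path, format, query = NULL) {
  switch(format,
         a2m = read_a2m(path),
         a3m = read_a3m(path),
         foldseek = {
           if (is.null(query)) stop("foldseek input requires the full query sequence")
           parse_foldseek_results(path, query)
         },
         stop("unknown alignment format: ", format))
}

#' Run the full zero-shot scoring pipeline
#'
#' Wires the stages together: normalize the homolog alignment, compute
#' evolutionary logits, obtain native logits (from a trained toy model file
#' or an external logits table), blend at the retrieval ratio, and score the
#' mutant list. A provenance record (seeds, ratio, input digests) is written
#' alongside the scores.
#'
#' @param config Named list with fields: `seq` (FASTA path), `mutants` (CSV
#'   path with a `mutant` column), `out_dir`; optional `msa` + `msa_format`
#'   ("a2m", "a3m" or "foldseek"), `native_logits` (TSV path) or `params`
#'   (RDS path of trained parameters) + `struct_tokens` (token file),
#'   `alpha` (default 0.8), `seed`.
#' @return Invisible list with `scores` (data frame) and `provenance`; side
#'   effects: `scores.csv` and `provenance.json` in `config$out_dir`.
#' @export
run_score_pipeline <- function(config) {
  for (field in c("seq", "mutants", "out_dir")) {
    if (is.null(config[[field]])) stop("config is missing '", field, "'")
  }
  alpha <- config$alpha %||% default_alpha()
  wt <- read_fasta_seq(config$seq)
  family <- NULL
  if (!is.null(config$msa)) {
    family <- read_family(config$msa, config$msa_format %||% "a2m", wt)
  }
  native <- NULL
  if (!is.null(config$native_logits)) {
    native <- load_external_logits(config$native_logits)
  } else if (!is.null(config$params)) {
    params <- readRDS(config$params)
    stoks <- if (!is.null(config$struct_tokens)) {
      read_structure_tokens(config$struct_tokens)
    } else rep(1L, nchar(wt))
    native <- native_logits(wt, stoks, params)
  }
  mutants <- utils::read.csv(config$mutants, stringsAsFactors = FALSE)
  if (!"mutant" %in% colnames(mutants)) {
    stop("mutant table must have a 'mutant' column")
  }
  scores <- score_batch(wt, mutants$mutant, family = family, native = native,
                        alpha = alpha)
  out <- mutants
  out$score <- scores$score
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  score_path <- file.path(config$out_dir, "scores.csv")
  utils::write.csv(out, score_path, row.names = FALSE, quote = FALSE)
  prov <- list(
    alpha = alpha,
    seed = config$seed %||% NA,
    template_length = nchar(wt),
    msa = if (!is.null(config$msa)) {
      list(path = config$msa, format = config$msa_format %||% "a2m",
           n_sequences = nrow(family$sequences),
           digest = unname(tools::md5sum(config$msa)))
    },
    native_source = config$native_logits %||% config$params %||% "none",
    inputs = lapply(
      Filter(Negate(is.null),
             config[intersect(c("seq", "mutants", "native_logits"),
                              names(config))]),
      function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(scores = out, provenance = prov))
}

#' Retrieval-strategy x ratio ablation
#'
#' Scores one assay under every combination of homolog-retrieval strategy and
#' retrieval ratio, reporting the Spearman correlation against the assay
#' scores for each cell.
#'
#' @param wt_seq Template sequence.
#' @param assay Data frame with `mutant` and `DMS_score` columns.
#' @param families Named list of [aligned_family()] objects (one per
#'   retrieval strategy).
#' @param native Native [logit_matrix()] shared by all cells (optional if
#'   all `alphas` equal 1).
#' @param alphas Numeric vector of retrieval ratios.
#' @return Data frame with columns `strategy`, `alpha`, `rho`.
#' @export
run_ablation <- function(wt_seq, assay, families, native = NULL,
                         alphas = c(0, 0.5, 0.8, 1)) {
  stopifnot(length(families) >= 1L, length(alphas) >= 1L)
  rows <- list()
  for (nm in names(families)) {
    for (a in alphas) {
      sc <- score_batch(wt_seq, assay$mutant, family = families[[nm]],
                        native = native, alpha = a)
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = nm, alpha = a,
        rho = spearman_rho(sc$score, assay$DMS_score),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
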