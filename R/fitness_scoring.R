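#' Blend native and evolutionary logits
#'
#' Elementwise convex combination
#' `O_out = (1 - alpha) * O_native + alpha * O_evo`. The retrieval ratio
#' `alpha` controls the weight of the alignment-derived evolutionary
#' distribution against the model's native distribution; the shipped default
#' is 0.8.
#'
#' @param native,evo L x 25 logit matrices of identical shape.
#' @param alpha Retrieval ratio in [0, 1] (default 0.8).
#' @return A [logit_matrix()] with role "blended".
#' @export
blend_logits <- function(native, evo, alpha = default_alpha()) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]")
  }
  if (!all(dim(native) == dim(evo))) {
    stop("native and evolutionary logits have different shapes")
  }
  out <- (1 - alpha) * unclass(native) + alpha * unclass(evo)
  attr(out, "role") <- NULL
  out <- logit_matrix(out, role = "blended")
  attr(out, "alpha") <- alpha
  out
}

#' Default retrieval ratio
#'
#' @return The shipped default weight on the evolutionary logits, 0.8.
#' @export
default_alpha <- function() 0.8

#' Parse mutant notation
#'
#' Standard substitution notation: wild-type letter, 1-based position, mutant
#' letter (e.g. `"Y449G"`). Multi-site mutants join substitutions with `:`
#' (`;` and `,` are accepted on read). `""` and `"WT"` denote the wild type
#' (empty substitution set). Each claimed wild-type letter is validated
#' against `wt_sequence`.
#'
#' @param text Mutant string.
#' @param wt_sequence Wild-type amino-acid sequence the positions refer to.
#' @return Object of class `mutant_spec`: a data frame with columns `pos`,
#'   `wt`, `mut` (possibly zero rows for the wild type).
#' @export
parse_mutant <- function(text, wt_sequence) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  L <- nchar(wt_sequence)
  wt_chars <- strsplit(toupper(wt_sequence), "")[[1]]
  if (text == "" || toupper(text) == "WT") {
    spec <- data.frame(pos = integer(0), wt = character(0),
                       mut = character(0), stringsAsFactors = FALSE)
    class(spec) <- c("mutant_spec", class(spec))
    return(spec)
  }
  parts <- trimws(strsplit(text, "[:;,]")[[1]])
  parts <- parts[nzchar(parts)]
  m <- regmatches(parts, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", parts))
  rows <- lapply(seq_along(parts), function(k) {
    g <- m[[k]]
    if (length(g) != 4L) stop("malformed mutant token: '", parts[k], "'")
    wt <- toupper(g[2]); mut <- toupper(g[4]); pos <- as.integer(g[3])
    if (!(wt %in% STANDARD_AA) || !(mut %in% STANDARD_AA)) {
      stop("mutant token '", parts[k],
           "' uses a non-standard residue; substitutions are defined over ",
           "the 20 standard amino acids")
    }
    if (wt == mut) stop("mutant token '", parts[k], "' is not a substitution")
    if (pos < 1L || pos > L) {
      stop("position ", pos, " outside sequence of length ", L)
    }
    if (wt_chars[pos] != wt) {
      stop("wild-type mismatch at position ", pos, ": notation says ", wt,
           " but the sequence has ", wt_chars[pos])
    }
    data.frame(pos = pos, wt = wt, mut = mut, stringsAsFactors = FALSE)
  })
  spec <- do.call(rbind, rows)
  if (anyDuplicated(spec$pos)) stop("duplicate mutated position in '", text, "'")
  class(spec) <- c("mutant_spec", class(spec))
  spec
}

#' Format a mutant spec back to canonical notation
#'
#' @param spec A `mutant_spec`.
#' @return Canonical string (substitutions joined by `:`; `"WT"` if empty).
#' @export
format_mutant <- function(spec) {
  if (nrow(spec) == 0L) return("WT")
  paste0(spec$wt, spec$pos, spec$mut, collapse = ":")
}

#' Score a mutant from blended logits
#'
#' The fitness score is the sum over mutated sites of the logit difference
#' between the mutant and wild-type residue types,
#' `F = sum_t (O[t, mut] - O[t, wt])`. The wild type scores exactly 0 and the
#' score is additive over disjoint substitution sets.
#'
#' @param blended An L x 25 [logit_matrix()] (any role).
#' @param mutant A `mutant_spec` from [parse_mutant()].
#' @return Numeric fitness score.
#' @export
score_mutant <- function(blended, mutant) {
  if (nrow(mutant) == 0L) return(0)
  if (any(mutant$pos > nrow(blended))) {
    stop("mutated position beyond logit matrix length ", nrow(blended))
  }
  O <- unclass(blended)
  sum(O[cbind(mutant$pos, match(mutant$mut, token_vocabulary()))] -
        O[cbind(mutant$pos, match(mutant$wt, token_vocabulary()))])
}

#' Score a batch of mutants
#'
#' End-to-end zero-shot scoring: evolutionary logits are computed from the
#' homolog family, blended with native logits at ratio `alpha`, and each
#' mutant is scored by summed logit differences.
#'
#' @param wt_seq Wild-type (template) amino-acid sequence.
#' @param mutants Character vector of mutant strings (see [parse_mutant()]).
#' @param family Optional [aligned_family()]; its column count must equal
#'   `nchar(wt_seq)`. Required unless `alpha = 0`.
#' @param native Optional L x 25 native [logit_matrix()] (e.g. from
#'   [native_logits()] or [load_external_logits()]). Required unless
#'   `alpha = 1`.
#' @param alpha Retrieval ratio in [0, 1].
#' @param include_query Passed to [count_matrix()].
#' @return Data frame with columns `mutant` and `score`, one row per mutant,
#'   in input order.
#' @export
score_batch <- function(wt_seq, mutants, family = NULL, native = NULL,
                        alpha = default_alpha(), include_query = TRUE) {
  L <- nchar(wt_seq)
  evo <- NULL
  if (!is.null(family)) {
    if (ncol(family$sequences) != L) {
      stop("alignment has ", ncol(family$sequences),
           " columns but the template sequence has ", L,
           " residues; re-align before scoring")
    }
    evo <- evolutionary_logits(count_matrix(family, include_query))
  }
  if (is.null(evo) && alpha > 0) stop("alpha > 0 requires a homolog family")
  if (is.null(native) && alpha < 1) stop("alpha < 1 requires native logits")
  zero <- logit_matrix(matrix(0, L, vocab_size()), role = "native")
  blended <- blend_logits(native %||% zero, evo %||% zero, alpha)
  scores <- vapply(mutants, function(mt) {
    score_mutant(blended, parse_mutant(mt, wt_seq))
  }, numeric(1))
  data.frame(mutant = mutants, score = unname(scores),
             stringsAsFactors = FALSE)
}
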