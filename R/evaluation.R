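#' Reference alignments
#'
#' A reference alignment is a manually curated set of
#' (source code, target code) pairs in which each source code is assigned
#' its single closest target code.
#'
#' @param pairs Data frame with columns `source` and `target` (or
#'   `source_code`/`target_code`).
#' @return A `vacc_reference` data frame.
#' @export
reference_alignment <- function(pairs) {
  nm <- names(pairs)
  if (all(c("source_code", "target_code") %in% nm)) {
    pairs <- data.frame(source = pairs$source_code, target = pairs$target_code)
  }
  stopifnot(all(c("source", "target") %in% names(pairs)))
  pairs <- unique(data.frame(source = as.character(pairs$source),
                             target = as.character(pairs$target)))
  if (anyDuplicated(pairs$source)) {
    stop("reference alignment assigns several targets to source code(s): ",
         paste(unique(pairs$source[duplicated(pairs$source)]), collapse = ", "))
  }
  rownames(pairs) <- NULL
  structure(pairs, class = c("vacc_reference", "data.frame"))
}

#' @rdname reference_alignment
#' @param path TSV file with header columns `source_code, target_code`.
#' @export
read_reference <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = "character", fileEncoding = "UTF-8")
  reference_alignment(df)
}

#' @rdname reference_alignment
#' @param ref A `vacc_reference`.
#' @export
write_reference <- function(ref, path) {
  utils::write.table(
    data.frame(source_code = ref$source, target_code = ref$target),
    path, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Compare a generated alignment with a reference
#'
#' `confusion()` counts the generated pairs found in the reference (true
#' positives), the generated pairs absent from it (false positives), and
#' the reference pairs that were not generated (false negatives); a
#' tie-expanded generated assignment contributes each of its pairs
#' individually. `evaluate_alignment()` adds precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and the F-score (harmonic mean); any measure with a zero
#' denominator is 0.
#'
#' @param generated A `vacc_alignment`.
#' @param reference A `vacc_reference` (or data frame of pairs).
#' @return `confusion()`: named integer vector `tp`, `fp`, `fn`.
#'   `evaluate_alignment()`: a `vacc_eval` list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f_score`.
#' @export
confusion <- function(generated, reference) {
  stopifnot(inherits(generated, "vacc_alignment"))
  if (!inherits(reference, "vacc_reference")) {
    reference <- reference_alignment(reference)
  }
  src_universe <- attr(generated, "source_codes")
  if (!is.null(src_universe)) {
    bad <- setdiff(reference$source, src_universe)
    if (length(bad)) {
      stop("reference refers to source code(s) absent from the aligned ",
           "coding system: ", paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  gkey <- paste(generated$source, generated$target, sep = "\r")
  rkey <- paste(reference$source, reference$target, sep = "\r")
  tp <- sum(gkey %in% rkey)
  c(tp = tp, fp = length(gkey) - tp, fn = sum(!rkey %in% gkey))
}

#' @rdname confusion
#' @export
evaluate_alignment <- function(generated, reference) {
  prf(confusion(generated, reference))
}

# precision/recall/F from a tp/fp/fn vector, zero-denominator convention 0
prf <- function(cf) {
  tp <- unname(cf["tp"]); fp <- unname(cf["fp"]); fn <- unname(cf["fn"])
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f_score = f), class = "vacc_eval")
}

#' @export
print.vacc_eval <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d | precision %.3f  recall %.3f  F %.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f_score))
  invisible(x)
}

#' Average evaluation results over source coding systems
#'
#' `macro_average()` takes the unweighted mean of precision, recall and
#' F-score over per-system results (the caller excludes reflexive
#' alignments when averaging over a reference set). `micro_average()` sums
#' the TP/FP/FN counts first and then computes the measures.
#'
#' @param results Non-empty list of `vacc_eval` objects (for
#'   `micro_average`, objects with `tp`, `fp`, `fn` components or plain
#'   confusion vectors).
#' @return A `vacc_eval` (macro results carry `NA` counts).
#' @export
macro_average <- function(results) {
  if (length(results) == 0L) stop("cannot average an empty result list")
  m <- function(f) mean(vapply(results, function(r) r[[f]], numeric(1)))
  structure(list(tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
                 precision = m("precision"), recall = m("recall"),
                 f_score = m("f_score")), class = "vacc_eval")
}

#' @rdname macro_average
#' @export
micro_average <- function(results) {
  if (length(results) == 0L) stop("cannot average an empty result list")
  tot <- c(tp = 0L, fp = 0L, fn = 0L)
  for (r in results) {
    if (is.list(r)) r <- c(tp = r$tp, fp = r$fp, fn = r$fn)
    tot <- tot + r[c("tp", "fp", "fn")]
  }
  prf(tot)
}

#' Sweep the similarity threshold
#'
#' Aligns a source to a target coding system at each threshold in
#' `thresholds`, evaluates against a reference, and tabulates the measures.
#' The similarity matrix is computed once and reused across thresholds, so
#' the sweep costs one scoring pass plus cheap re-assignment. Because the
#' assignment set at a higher threshold is a subset of the assignment set
#' at a lower one, the recall column is non-increasing in the threshold.
#'
#' @inheritParams align_codes
#' @param reference A `vacc_reference`.
#' @param thresholds Numeric vector of thresholds (default 0 to 1 in steps
#'   of 0.1).
#' @return Data frame with one row per threshold: `threshold`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f_score`.
#' @export
threshold_sweep <- function(source, target, reference,
                            method = c("properties", "classes", "equivalence",
                                       "tokens", "external"),
                            thresholds = seq(0, 1, by = 0.1), index = NULL,
                            dictionary = NULL, languages = NULL,
                            targets_gate = "equal", external_tagger = NULL,
                            exclude_roots = TRUE) {
  method <- match.arg(method)
  reps <- prepare_reps(source, target, method, index, dictionary, languages,
                       exclude_roots, external_tagger)
  S <- similarity_matrix(reps$src, reps$tgt, method,
                         targets_gate = targets_gate,
                         external_tagger = external_tagger)
  rows <- lapply(thresholds, function(th) {
    al <- assign_from_matrix(S, reps$src_cs, reps$tgt_cs, th, method)
    ev <- evaluate_alignment(al, reference)
    data.frame(threshold = th, tp = ev$tp, fp = ev$fp, fn = ev$fn,
               precision = ev$precision, recall = ev$recall,
               f_score = ev$f_score)
  })
  do.call(rbind, rows)
}
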