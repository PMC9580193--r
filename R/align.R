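#' Jaccard coefficient of two sets
#'
#' `|intersect| / |union|`, defined as 0 when both sets are empty.
#'
#' @param s,t Character vectors (treated as sets).
#' @return Numeric scalar in `[0, 1]`.
#' @export
jaccard <- function(s, t) {
  s <- unique(s)
  t <- unique(t)
  u <- length(union(s, t))
  if (u == 0L) return(0)
  length(intersect(s, t)) / u
}

#' Code similarity methods
#'
#' Four ways of scoring the similarity of two vaccine codes from their
#' descriptors, all bounded in `[0, 1]` and symmetric:
#'
#' * **Tokens** — Jaccard coefficient of the normalized token sets
#'   (a purely lexical baseline).
#' * **Classes** — Jaccard coefficient of the identified ontology class
#'   sets C(t); 0 if either set is empty.
#' * **Equivalence** — 1 if the compiled vaccine classes V(t) are
#'   equivalent (mutual subsumption) and neither code is uninformative,
#'   else 0.
#' * **Properties** — 0 if the `immunizes-against` value sets differ (or
#'   both codes are uninformative); otherwise the Jaccard coefficient of
#'   the pooled (property, filler) pairs of the two property-value maps
#'   P(t).
#'
#' @param a,b For `similarity_tokens`: descriptor strings or token vectors.
#'   For `similarity_classes`: character vectors of class identifiers. For
#'   `similarity_equivalence`: `vacc_expr` objects (with their
#'   `uninformative` attribute). For `similarity_properties`:
#'   `vacc_propvals` objects.
#' @return Numeric scalar in `[0, 1]`.
#' @export
similarity_tokens <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- normalize_text(a)
  if (is.character(b) && length(b) == 1L) b <- normalize_text(b)
  jaccard(a, b)
}

#' @rdname similarity_tokens
#' @export
similarity_classes <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(0)
  jaccard(a, b)
}

#' @rdname similarity_tokens
#' @param index A `vacc_index` (for the equivalence method).
#' @export
similarity_equivalence <- function(a, b, index) {
  if (isTRUE(attr(a, "uninformative")) || isTRUE(attr(b, "uninformative"))) {
    return(0)
  }
  as.numeric(is_subsumed(index, a, b) && is_subsumed(index, b, a))
}

#' @rdname similarity_tokens
#' @param targets_gate How "the immunizes-against values differed" is read:
#'   `"equal"` (default) gates on strict set inequality of the
#'   immunization-target sets; `"overlap"` gates only when the sets are
#'   disjoint.
#' @param target_property The gating property
#'   (default `"immunizes-against"`).
#' @export
similarity_properties <- function(a, b, targets_gate = c("equal", "overlap"),
                                  target_property = "immunizes-against") {
  targets_gate <- match.arg(targets_gate)
  if (isTRUE(attr(a, "uninformative")) && isTRUE(attr(b, "uninformative"))) {
    return(0)
  }
  ta <- a[[target_property]] %||% character(0)
  tb <- b[[target_property]] %||% character(0)
  gate_fires <- if (targets_gate == "equal") {
    !setequal(ta, tb)
  } else {
    length(intersect(ta, tb)) == 0L && (length(ta) > 0L || length(tb) > 0L)
  }
  if (gate_fires) return(0)
  pool <- function(p) {
    unlist(lapply(names(p), function(nm) {
      if (length(p[[nm]])) paste(nm, p[[nm]], sep = "\r") else character(0)
    }))
  }
  jaccard(pool(a), pool(b))
}

#' Precompute code representations for alignment
#'
#' For every code in a coding system, computes the normalized tokens, the
#' identified class set C(t), the compiled vaccine class V(t) (internalized
#' into one shared augmented index so equivalence queries are lookups), and
#' the property values P(t). Codes with a language tag are tagged only with
#' dictionary entries in that language; untagged codes use the `languages`
#' filter (all languages when `NULL`).
#'
#' @param cs A `vacc_coding_system`.
#' @param index A `vacc_index` from [classify()].
#' @param dictionary A `vacc_dictionary` (built from the index's ontology
#'   when missing).
#' @param languages Optional default language filter.
#' @param exclude_roots Passed to the property-value normalization.
#' @return A `vacc_code_reps` list.
#' @export
code_representations <- function(cs, index, dictionary = NULL,
                                 languages = NULL, exclude_roots = TRUE) {
  stopifnot(inherits(cs, "vacc_coding_system"), inherits(index, "vacc_index"))
  if (is.null(dictionary)) dictionary <- build_dictionary(index$ont)
  n <- nrow(cs)
  tokens <- vector("list", n)
  classes <- vector("list", n)
  exprs <- vector("list", n)
  for (i in seq_len(n)) {
    lang <- if (!is.na(cs$language[i])) cs$language[i] else languages
    tags <- tag_text(cs$descriptor[i], dictionary, languages = lang)
    tokens[[i]] <- unique(tags$tokens)
    classes[[i]] <- tags$classes
    exprs[[i]] <- compile_set(tags$classes, index$ont)
  }
  aug <- augment_index(index, exprs)
  propvals <- lapply(seq_len(n), function(i) {
    if (isTRUE(attr(exprs[[i]], "uninformative"))) {
      props <- vaccine_properties(index)
      structure(stats::setNames(rep(list(character(0)), length(props)), props),
                uninformative = TRUE, class = "vacc_propvals")
    } else {
      vals <- lapply(vaccine_properties(index), function(p) {
        entailed_fillers_id(aug$index, aug$ids[i], p,
                            exclude_roots = exclude_roots)
      })
      names(vals) <- vaccine_properties(index)
      structure(vals, uninformative = FALSE, class = "vacc_propvals")
    }
  })
  structure(list(cs = cs, tokens = tokens, classes = classes, exprs = exprs,
                 expr_ids = aug$ids, index = aug$index, propvals = propvals,
                 uninformative = vapply(exprs, function(e) {
                   isTRUE(attr(e, "uninformative"))
                 }, logical(1))),
            class = "vacc_code_reps")
}

# Similarity matrix (source rows x target columns) for one method.
similarity_matrix <- function(src, tgt, method, targets_gate = "equal",
                              external_tagger = NULL) {
  ns <- nrow(src$cs)
  nt <- nrow(tgt$cs)
  S <- matrix(0, ns, nt, dimnames = list(src$cs$code, tgt$cs$code))
  if (method == "external") {
    if (is.null(external_tagger)) {
      stop("method 'external' requires an external_tagger function")
    }
    sa <- lapply(src$cs$descriptor, external_tagger)
    sb <- lapply(tgt$cs$descriptor, external_tagger)
    for (i in seq_len(ns)) for (j in seq_len(nt)) {
      if (length(sa[[i]]) && length(sb[[j]])) S[i, j] <- jaccard(sa[[i]], sb[[j]])
    }
    return(S)
  }
  for (i in seq_len(ns)) {
    for (j in seq_len(nt)) {
      S[i, j] <- switch(method,
        tokens = jaccard(src$tokens[[i]], tgt$tokens[[j]]),
        classes = similarity_classes(src$classes[[i]], tgt$classes[[j]]),
        equivalence = {
          if (src$uninformative[i] || tgt$uninformative[j]) 0 else {
            # each direction queries the augmented index in which its
            # subject expression was internalized
            as.numeric(
              entails_expr(src$index, src$expr_ids[i], tgt$exprs[[j]]) &&
              entails_expr(tgt$index, tgt$expr_ids[j], src$exprs[[i]]))
          }
        },
        properties = similarity_properties(src$propvals[[i]], tgt$propvals[[j]],
                                           targets_gate = targets_gate),
        stop("unknown similarity method: ", method)
      )
    }
  }
  S
}

# Threshold + hierarchy-aware assignment from a similarity matrix.
assign_from_matrix <- function(S, source_cs, target_cs, threshold, method) {
  rows <- list()
  unassigned <- character(0)
  ties <- 0L
  for (i in seq_len(nrow(S))) {
    m <- if (ncol(S)) max(S[i, ]) else -Inf
    if (m > threshold) {
      tied <- colnames(S)[S[i, ] >= m - 1e-9]
      if (length(tied) > 1L) {
        ties <- ties + 1L
        if (attr(target_cs, "has_hierarchy")) {
          # keep the most general tied targets: those with no proper
          # ancestor inside the tied set
          keep <- vapply(tied, function(tc) {
            !any(code_ancestors(target_cs, tc) %in% tied)
          }, logical(1))
          tied <- tied[keep]
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        source = source_cs$code[i], target = tied, score = m)
    } else {
      unassigned <- c(unassigned, source_cs$code[i])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(source = character(0), target = character(0),
               score = numeric(0))
  }
  rownames(out) <- NULL
  structure(out, class = c("vacc_alignment", "data.frame"),
            method = method, threshold = threshold, unassigned = unassigned,
            source_codes = source_cs$code, n_ties = ties)
}

#' Align two coding systems
#'
#' Scores every source code against every target code under the chosen
#' similarity method and assigns each source code to the target code(s)
#' with the highest score, provided that score strictly exceeds the
#' threshold. When several targets tie at the maximum and the target system
#' has a taxonomic hierarchy, only the most general tied targets (those
#' with no proper ancestor inside the tied set) are kept. Source codes
#' whose best score does not exceed the threshold stay unassigned.
#'
#' @param source,target `vacc_coding_system` objects (or `vacc_code_reps`
#'   from [code_representations()], which skips recomputation).
#' @param method One of `"properties"`, `"classes"`, `"equivalence"`,
#'   `"tokens"`, or `"external"`.
#' @param threshold Similarity threshold in `[0, 1]`; default 0.1, the
#'   value with the highest average F-score in a 0-to-1 sweep.
#' @param index A `vacc_index`; required for the ontology-based methods.
#' @param dictionary,languages,exclude_roots Passed to
#'   [code_representations()].
#' @param targets_gate Gate interpretation for the Properties method; see
#'   [similarity_properties()].
#' @param external_tagger For `method = "external"`: a function mapping a
#'   descriptor string to a character vector of external concept
#'   identifiers; similarity is their Jaccard coefficient.
#' @return A `vacc_alignment`: data frame `source`, `target`, `score` with
#'   attributes `method`, `threshold`, `unassigned`, `source_codes`.
#' @examples
#' ont <- mini_vacco()
#' ix <- classify(ont)
#' cs <- coding_system("toy", data.frame(
#'   code = c("A", "B"),
#'   descriptor = c("Flu vaccine", "Tuberculosis vaccine")))
#' align_codes(cs, cs, method = "properties", index = ix)
#' @export
align_codes <- function(source, target,
                        method = c("properties", "classes", "equivalence",
                                   "tokens", "external"),
                        threshold = 0.1, index = NULL, dictionary = NULL,
                        languages = NULL, targets_gate = "equal",
                        external_tagger = NULL, exclude_roots = TRUE) {
  method <- match.arg(method)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  reps <- prepare_reps(source, target, method, index, dictionary, languages,
                       exclude_roots, external_tagger)
  if (nrow(reps$tgt_cs) == 0L) {
    warning("empty target coding system: all source codes unassigned")
    return(assign_from_matrix(
      matrix(0, nrow(reps$src_cs), 0,
             dimnames = list(reps$src_cs$code, NULL)),
      reps$src_cs, reps$tgt_cs, threshold, method))
  }
  S <- similarity_matrix(reps$src, reps$tgt, method,
                         targets_gate = targets_gate,
                         external_tagger = external_tagger)
  assign_from_matrix(S, reps$src_cs, reps$tgt_cs, threshold, method)
}

prepare_reps <- function(source, target, method, index, dictionary, languages,
                         exclude_roots, external_tagger) {
  needs_ont <- method %in% c("classes", "equivalence", "properties")
  as_reps <- function(x) {
    if (inherits(x, "vacc_code_reps")) return(x)
    stopifnot(inherits(x, "vacc_coding_system"))
    if (needs_ont) {
      if (is.null(index)) {
        stop("method '", method, "' requires a classified ontology (index =)")
      }
      code_representations(x, index, dictionary, languages, exclude_roots)
    } else {
      # lexical/external methods only need tokens/descriptors
      toks <- lapply(x$descriptor, function(d) unique(normalize_text(d)))
      structure(list(cs = x, tokens = toks), class = "vacc_code_reps")
    }
  }
  src <- as_reps(source)
  tgt <- as_reps(target)
  list(src = src, tgt = tgt, src_cs = src$cs, tgt_cs = tgt$cs)
}

#' @export
print.vacc_alignment <- function(x, ...) {
  cat("Alignment (method = ", attr(x, "method"),
      ", threshold = ", attr(x, "threshold"), "): ",
      nrow(x), " assignment(s), ", length(attr(x, "unassigned")),
      " unassigned source code(s)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 15))
  invisible(x)
}

#' Read and write alignments
#'
#' Interchange format: TSV with columns
#' `source_code, target_code, score, method, threshold`, one row per
#' assignment; unassigned source codes appear with empty target and score.
#'
#' @param al A `vacc_alignment`.
#' @param path File path.
#' @return `write_alignment` returns `path` invisibly; `read_alignment`
#'   returns a `vacc_alignment`.
#' @export
write_alignment <- function(al, path) {
  stopifnot(inherits(al, "vacc_alignment"))
  n <- nrow(al)
  df <- data.frame(source_code = al$source, target_code = al$target,
                   score = if (n) format(al$score, digits = 10) else character(0),
                   method = rep(attr(al, "method"), n),
                   threshold = rep(attr(al, "threshold"), n))
  un <- attr(al, "unassigned")
  if (length(un)) {
    df <- rbind(df, data.frame(source_code = un, target_code = "", score = "",
                               method = attr(al, "method"),
                               threshold = attr(al, "threshold")))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_alignment
#' @export
read_alignment <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = "character", fileEncoding = "UTF-8")
  need <- c("source_code", "target_code", "score")
  if (!all(need %in% names(df))) {
    stop("alignment file '", path, "' must have columns ",
         paste(need, collapse = ", "))
  }
  assigned <- nzchar(df$target_code)
  out <- data.frame(source = df$source_code[assigned],
                    target = df$target_code[assigned],
                    score = as.numeric(df$score[assigned]))
  structure(out, class = c("vacc_alignment", "data.frame"),
            method = if ("method" %in% names(df) && nrow(df)) df$method[1] else NA,
            threshold = if ("threshold" %in% names(df) && nrow(df)) {
              as.numeric(df$threshold[1])
            } else NA_real_,
            unassigned = df$source_code[!assigned],
            source_codes = unique(df$source_code))
}
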