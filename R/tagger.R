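#' Normalize free text to a token sequence
#'
#' Lower-cases, folds accents to ASCII, splits on any non-alphanumeric
#' character and drops empty tokens. Digits are preserved, so valence terms
#' like `"3-valent"` become the tokens `"3", "valent"`.
#'
#' @param text A character scalar.
#' @return Character vector of tokens (length 0 for empty input).
#' @examples
#' normalize_text("Live/attenuated influenza vaccine")
#' normalize_text("VACUNA ANTIGRIPAL")
#' @export
normalize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) return(character(0))
  x <- stringi::stri_trans_general(text, "Latin-ASCII")
  x <- tolower(x)
  toks <- strsplit(x, "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Build the ontology dictionary
#'
#' The ontology dictionary is the set of all (term, class) pairs collected
#' from the class labels. Every label becomes one entry, pre-normalized with
#' [normalize_text()]. Distinct classes sharing a normalized term are all
#' retained — a match then yields every associated class — and reported with
#' a warning, since ambiguous terms are a known source of tagging error.
#'
#' @param ont A `vacc_ontology`.
#' @return A `vacc_dictionary`: a data frame with columns `term` (normalized,
#'   space-joined), `ntok`, `class`, `lang`.
#' @export
build_dictionary <- function(ont) {
  stopifnot(inherits(ont, "vacc_ontology"))
  if (!nrow(ont$labels)) {
    d <- data.frame(term = character(0), ntok = integer(0),
                    class = character(0), lang = character(0))
    return(structure(d, class = c("vacc_dictionary", "data.frame")))
  }
  toks <- lapply(ont$labels$term, normalize_text)
  d <- data.frame(
    term = vapply(toks, paste, character(1), collapse = " "),
    ntok = lengths(toks),
    class = ont$labels$class,
    lang = ont$labels$lang
  )
  d <- d[d$ntok > 0L, , drop = FALSE]
  d <- unique(d)
  amb <- unique(d[, c("term", "class")])
  amb <- amb$term[duplicated(amb$term)]
  if (length(amb)) {
    warning("ambiguous dictionary term(s) mapping to several classes: ",
            paste(unique(amb), collapse = ", "))
  }
  rownames(d) <- NULL
  structure(d, class = c("vacc_dictionary", "data.frame"))
}

#' Identify ontology classes in free text
#'
#' Scans the normalized token sequence left to right with greedy longest
#' match against the ontology dictionary; matches do not overlap. Each
#' matched term is a reference to its associated class(es). Matches of the
#' seven fundamental category classes (for instance the bare word
#' "vaccine") are recorded in the spans but dropped from the returned class
#' set: the compilation step reintroduces the vaccine category implicitly,
#' and category matches carry no specific information.
#'
#' @param text Character scalar.
#' @param dictionary A `vacc_dictionary` from [build_dictionary()].
#' @param languages Optional character vector of language tags; when given,
#'   only entries in these languages can match.
#' @return A list of class `vacc_tags`: `classes` (sorted character vector —
#'   the identified class set), `spans` (data frame `start`, `end`, `class`
#'   in token coordinates, including category matches), and `tokens`.
#' @examples
#' ont <- mini_vacco()
#' dic <- build_dictionary(ont)
#' tag_text("Live/attenuated influenza vaccine", dic)$classes
#' @export
tag_text <- function(text, dictionary, languages = NULL) {
  stopifnot(inherits(dictionary, "vacc_dictionary"))
  toks <- normalize_text(text)
  d <- dictionary
  if (!is.null(languages)) d <- d[d$lang %in% languages, , drop = FALSE]
  spans <- data.frame(start = integer(0), end = integer(0),
                      class = character(0))
  n <- length(toks)
  maxlen <- if (nrow(d)) max(d$ntok) else 0L
  i <- 1L
  while (i <= n) {
    hit <- NULL
    if (maxlen > 0L) {
      for (len in seq(min(maxlen, n - i + 1L), 1L)) {
        key <- paste(toks[i:(i + len - 1L)], collapse = " ")
        cls <- unique(d$class[d$term == key])
        if (length(cls)) {
          hit <- list(len = len, classes = sort(cls))
          break
        }
      }
    }
    if (is.null(hit)) {
      i <- i + 1L
    } else {
      spans <- rbind(spans, data.frame(start = i, end = i + hit$len - 1L,
                                       class = hit$classes))
      i <- i + hit$len
    }
  }
  classes <- sort(setdiff(unique(spans$class), fundamental_roots()))
  structure(list(classes = classes, spans = spans, tokens = toks),
            class = "vacc_tags")
}

#' @export
print.vacc_tags <- function(x, ...) {
  cat("C(t) = {", paste(x$classes, collapse = ", "), "}\n", sep = "")
  invisible(x)
}
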