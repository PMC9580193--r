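#' Coding systems
#'
#' A coding system is a set of codes, each defined by a short free-text
#' descriptor, optionally carrying a taxonomic parent link and a language
#' tag. `coding_system()` builds one from a data frame; `read_coding_system()`
#' reads the delimited text interchange format (TSV or CSV by file
#' extension, UTF-8, header row required, columns
#' `code, descriptor[, parent][, language]`).
#'
#' @param name Coding-system name.
#' @param codes Data frame with columns `code`, `descriptor` and optionally
#'   `parent`, `language`. Missing parents/languages are `NA`.
#' @return A `vacc_coding_system`: the codes data frame with attributes
#'   `name` and `has_hierarchy`.
#' @export
coding_system <- function(name, codes) {
  stopifnot(is.data.frame(codes), all(c("code", "descriptor") %in% names(codes)))
  codes$code <- as.character(codes$code)
  codes$descriptor <- as.character(codes$descriptor)
  if (!"parent" %in% names(codes)) {
    codes$parent <- rep(NA_character_, nrow(codes))
  }
  if (!"language" %in% names(codes)) {
    codes$language <- rep(NA_character_, nrow(codes))
  }
  codes$parent <- as.character(codes$parent)
  codes$parent[!is.na(codes$parent) & !nzchar(codes$parent)] <- NA_character_
  codes$language <- as.character(codes$language)
  codes$language[!is.na(codes$language) & !nzchar(codes$language)] <- NA_character_
  codes <- codes[, c("code", "descriptor", "parent", "language")]
  if (anyDuplicated(codes$code)) {
    stop("duplicate code(s) in coding system '", name, "': ",
         paste(unique(codes$code[duplicated(codes$code)]), collapse = ", "))
  }
  bad <- codes$parent[!is.na(codes$parent) & !codes$parent %in% codes$code]
  if (length(bad)) {
    stop("parent code(s) not defined in coding system '", name, "': ",
         paste(unique(bad), collapse = ", "))
  }
  # parent links must be acyclic
  par <- stats::setNames(codes$parent, codes$code)
  for (c0 in codes$code) {
    seen <- character(0)
    c1 <- c0
    while (!is.na(par[[c1]])) {
      if (c1 %in% seen) stop("cycle in parent links of coding system '",
                             name, "' at code '", c1, "'")
      seen <- c(seen, c1)
      c1 <- par[[c1]]
    }
  }
  rownames(codes) <- NULL
  structure(codes, name = name, has_hierarchy = any(!is.na(codes$parent)),
            class = c("vacc_coding_system", "data.frame"))
}

#' @rdname coding_system
#' @param path File path (`.csv` is comma-separated, anything else
#'   tab-separated).
#' @export
read_coding_system <- function(path, name = sub("\\.[^.]+$", "", basename(path))) {
  if (!file.exists(path)) stop("coding-system file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    utils::read.delim(path, sep = sep, header = TRUE, quote = "",
                      colClasses = "character", fileEncoding = "UTF-8",
                      check.names = TRUE, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse coding-system file '", path, "': ",
                             conditionMessage(e))
  )
  if (!all(c("code", "descriptor") %in% names(df))) {
    stop("coding-system file '", path,
         "' must have a header row with columns 'code' and 'descriptor'")
  }
  coding_system(name, df)
}

#' @rdname coding_system
#' @param cs A `vacc_coding_system`.
#' @export
write_coding_system <- function(cs, path) {
  stopifnot(inherits(cs, "vacc_coding_system"))
  df <- as.data.frame(cs)
  df$parent[is.na(df$parent)] <- ""
  df$language[is.na(df$language)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.vacc_coding_system <- function(x, ...) {
  cat("Coding system '", attr(x, "name"), "': ", nrow(x), " codes",
      if (attr(x, "has_hierarchy")) " (hierarchical)", "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more codes\n")
  invisible(x)
}

# code -> all proper ancestor codes within the system
code_ancestors <- function(cs, code) {
  par <- stats::setNames(cs$parent, cs$code)
  out <- character(0)
  c1 <- par[[code]]
  while (!is.na(c1)) {
    out <- c(out, c1)
    c1 <- par[[c1]]
  }
  out
}
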