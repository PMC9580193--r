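#' Specify a synthetic alignment benchmark
#'
#' A benchmark emulates the heterogeneity of real vaccine coding systems:
#' two coding systems describe the same underlying vaccine groups through
#' different descriptor styles (pathogen name vs disease name, abbreviation,
#' product name, or a style decorated with strategy/route/valence terms) and
#' different languages, with optional descriptor noise and an optional
#' two-level taxonomic hierarchy on the target side. Each group has a
#' pathogen and a disease linked causally in both directions, so
#' property-value normalization unifies the two naming conventions.
#'
#' Lexicons are synthetic: every class receives a deterministic pseudoword
#' term per language, with disjoint syllable inventories per language, so
#' cross-lingual descriptors share no tokens.
#'
#' @param n_groups Number of underlying vaccine groups (>= 1).
#' @param style_source,style_target Descriptor style per side: one of
#'   `"pathogen-name"`, `"disease-name"`, `"abbreviation"`,
#'   `"product-name"`, `"with-strategy"`, `"with-route"`, `"with-valence"`.
#' @param lang_source,lang_target Language per side: `"en"`, `"es"`,
#'   `"it"` or `"ca"`.
#' @param noise Named numeric vector of probabilities:
#'   `dropout` (a content term is dropped from a descriptor), `distractor`
#'   (an out-of-dictionary token is appended), `synonym` (a content term is
#'   replaced by an out-of-dictionary synonym).
#' @param hierarchy_target Build a two-level target hierarchy (general
#'   disease-level codes over strategy-specific children); the gold
#'   alignment maps each source code to the most specific representable
#'   target.
#' @param seed Integer seed; the whole benchmark is a deterministic
#'   function of the spec.
#' @return A `vacc_benchmark_spec` list.
#' @export
benchmark_spec <- function(n_groups = 20,
                           style_source = "pathogen-name",
                           style_target = "disease-name",
                           lang_source = "en", lang_target = "es",
                           noise = c(dropout = 0, distractor = 0, synonym = 0),
                           hierarchy_target = FALSE, seed = 1L) {
  styles <- c("pathogen-name", "disease-name", "abbreviation", "product-name",
              "with-strategy", "with-route", "with-valence")
  style_source <- match.arg(style_source, styles)
  style_target <- match.arg(style_target, styles)
  full <- c(dropout = 0, distractor = 0, synonym = 0)
  full[names(noise)] <- noise
  stopifnot(n_groups >= 1, all(full >= 0 & full <= 1))
  structure(list(n_groups = as.integer(n_groups),
                 style_source = style_source, style_target = style_target,
                 lang_source = lang_source, lang_target = lang_target,
                 noise = full, hierarchy_target = isTRUE(hierarchy_target),
                 seed = as.integer(seed)),
            class = "vacc_benchmark_spec")
}

# disjoint syllable inventories -> languages never share pseudoword tokens
bench_syllables <- list(
  en = c("bar", "ven", "tor", "mal", "sed", "lin", "pox", "ral", "gam", "fet"),
  es = c("ca", "mi", "ro", "lu", "pa", "te", "ni", "so", "ve", "da"),
  it = c("zi", "no", "va", "re", "li", "mo", "tu", "sa", "pe", "ga"),
  ca = c("xa", "bo", "quel", "ler", "vi", "nu", "tre", "gol", "mar", "fi")
)

bench_vacword <- c(en = "vaccine", es = "vacuna", it = "vaccino", ca = "vacuna")

# deterministic pseudoword: base-10 digits of k select syllables
pseudoword <- function(lang, k, nsyl = 3L) {
  syl <- bench_syllables[[lang]]
  if (is.null(syl)) stop("no synthetic lexicon for language '", lang, "'")
  d <- integer(nsyl)
  for (i in seq_len(nsyl)) {
    d[i] <- k %% 10L
    k <- k %/% 10L
  }
  paste(syl[d + 1L], collapse = "")
}

#' Generate a synthetic benchmark
#'
#' Builds the group ontology, renders the source and target coding systems
#' in the requested styles and languages, applies noise, and emits the gold
#' reference alignment (each source code mapped to the most specific
#' representable target code of its group).
#'
#' @param spec A `vacc_benchmark_spec`.
#' @return A `vacc_benchmark` list: `ontology`, `source`, `target`
#'   (`vacc_coding_system`s), `reference` (`vacc_reference`), `spec`.
#' @examples
#' bm <- generate_benchmark(benchmark_spec(n_groups = 5, seed = 42))
#' bm$source$descriptor
#' @export
generate_benchmark <- function(spec) {
  stopifnot(inherits(spec, "vacc_benchmark_spec"))
  langs <- unique(c(spec$lang_source, spec$lang_target))
  n <- spec$n_groups

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  labs_for <- function(base) {
    out <- vapply(langs, function(lg) pseudoword(lg, base), character(1))
    names(out) <- langs
    out
  }

  ont <- ontology()
  ont <- add_class(ont, "Active-ingredient", parent = "Ingredient")
  for (lg in langs) {
    ont$labels <- rbind(ont$labels, data.frame(
      class = "Vaccine", term = bench_vacword[[lg]], lang = lg))
  }
  # shared decoration classes
  strategies <- sprintf("Strategy-%d", 1:3)
  for (i in 1:3) {
    ont <- add_class(ont, strategies[i], parent = "Strategy",
                     labels = labs_for(700 + i))
  }
  routes <- sprintf("Route-%d", 1:2)
  for (i in 1:2) {
    ont <- add_class(ont, routes[i], parent = "Route",
                     labels = labs_for(730 + i))
  }
  valences <- sprintf("Valence-%d", 1:3)
  for (i in 1:3) {
    lab <- rep(paste(i, "valent"), length(langs))
    names(lab) <- langs
    ont <- add_class(ont, valences[i], parent = "Valence", labels = lab)
  }

  groups <- data.frame(
    g = seq_len(n),
    pathogen = sprintf("Pathogen-%02d", seq_len(n)),
    disease = sprintf("Disease-%02d", seq_len(n)),
    abbrev = sprintf("Group-%02d", seq_len(n)),
    product = sprintf("Product-%02d", seq_len(n)),
    antigen = sprintf("Antigen-%02d", seq_len(n)),
    strategy = sample(strategies, n, replace = TRUE),
    route = sample(routes, n, replace = TRUE),
    valence = sample(valences, n, replace = TRUE)
  )

  for (i in seq_len(n)) {
    ab_lab <- rep(sprintf("vax%02d", i), length(langs))
    names(ab_lab) <- langs
    ont <- add_class(ont, groups$pathogen[i], parent = "Pathogen",
                     labels = labs_for(10 + i))
    ont <- add_class(ont, groups$disease[i], parent = "Disease",
                     labels = labs_for(240 + i))
    ont <- add_class(ont, groups$abbrev[i], parent = "Vaccine",
                     labels = ab_lab)
    ont <- add_class(ont, groups$product[i], parent = "Vaccine",
                     labels = labs_for(470 + i))
    ont <- add_class(ont, groups$antigen[i], parent = "Active-ingredient")
    ont <- add_assertion(ont, groups$pathogen[i], "causes", groups$disease[i])
    ont <- add_assertion(ont, groups$disease[i], "caused-by",
                         groups$pathogen[i])
    ont <- add_assertion(ont, groups$abbrev[i], "immunizes-against",
                         groups$disease[i])
    ont <- add_assertion(ont, groups$abbrev[i], "has-strategy",
                         groups$strategy[i])
    ont <- add_assertion(ont, groups$product[i], "has-ingredient",
                         groups$antigen[i])
    ont <- add_assertion(ont, groups$antigen[i], "immunizes-against",
                         groups$disease[i])
    ont <- add_assertion(ont, groups$antigen[i], "has-strategy",
                         groups$strategy[i])
  }
  ont <- add_property(ont, "immunizes-against", "Vaccine",
                      c("Pathogen", "Disease"))
  ont <- add_property(ont, "has-strategy", "Vaccine", "Strategy")
  ont <- add_property(ont, "has-ingredient", "Vaccine", "Ingredient")
  ont <- add_property(ont, "has-valence", "Vaccine", "Valence")
  ont <- add_property(ont, "has-route", "Vaccine", "Route")
  ont <- add_property(ont, "causes", "Pathogen", "Disease")
  ont <- add_property(ont, "caused-by", "Disease", "Pathogen")
  ont <- add_chain(ont, "has-ingredient", "immunizes-against",
                   "immunizes-against")
  ont <- add_chain(ont, "has-ingredient", "has-strategy", "has-strategy")
  ont <- add_chain(ont, "immunizes-against", "causes", "immunizes-against")
  ont <- add_chain(ont, "immunizes-against", "caused-by", "immunizes-against")
  ont <- validate_ontology(ont)

  label_of <- function(class, lang) {
    ont$labels$term[ont$labels$class == class & ont$labels$lang == lang][1]
  }
  render <- function(i, style, lang) {
    vac <- bench_vacword[[lang]]
    content <- switch(style,
      "pathogen-name" = label_of(groups$pathogen[i], lang),
      "disease-name" = label_of(groups$disease[i], lang),
      "abbreviation" = label_of(groups$abbrev[i], lang),
      "product-name" = label_of(groups$product[i], lang),
      "with-strategy" = c(label_of(groups$disease[i], lang),
                          label_of(groups$strategy[i], lang)),
      "with-route" = c(label_of(groups$disease[i], lang),
                       label_of(groups$route[i], lang)),
      "with-valence" = c(label_of(groups$disease[i], lang),
                         label_of(groups$valence[i], lang))
    )
    list(content = content, vac = vac)
  }
  distractor_counter <- 0L
  apply_noise <- function(parts, lang) {
    nz <- spec$noise
    content <- parts$content
    if (nz["synonym"] > 0 && length(content)) {
      swap <- stats::runif(length(content)) < nz["synonym"]
      if (any(swap)) {
        content[swap] <- vapply(which(swap), function(k) {
          distractor_counter <<- distractor_counter + 1L
          paste0("syn", pseudoword(lang, 900 + distractor_counter))
        }, character(1))
      }
    }
    if (nz["dropout"] > 0 && length(content)) {
      content <- content[stats::runif(length(content)) >= nz["dropout"]]
    }
    extra <- character(0)
    if (nz["distractor"] > 0 && stats::runif(1) < nz["distractor"]) {
      distractor_counter <<- distractor_counter + 1L
      extra <- paste0("zz", pseudoword(lang, 500 + distractor_counter))
    }
    paste(c(content, parts$vac, extra), collapse = " ")
  }

  src <- data.frame(
    code = sprintf("S%02d", seq_len(n)),
    descriptor = vapply(seq_len(n), function(i) {
      apply_noise(render(i, spec$style_source, spec$lang_source),
                  spec$lang_source)
    }, character(1)),
    language = spec$lang_source
  )
  source_cs <- coding_system("synthetic-source", src)

  if (spec$hierarchy_target) {
    gen <- data.frame(
      code = sprintf("G%02d", seq_len(n)),
      descriptor = vapply(seq_len(n), function(i) {
        apply_noise(render(i, "disease-name", spec$lang_target),
                    spec$lang_target)
      }, character(1)),
      parent = "", language = spec$lang_target
    )
    chl <- data.frame(
      code = sprintf("T%02d", seq_len(n)),
      descriptor = vapply(seq_len(n), function(i) {
        apply_noise(render(i, "with-strategy", spec$lang_target),
                    spec$lang_target)
      }, character(1)),
      parent = sprintf("G%02d", seq_len(n)), language = spec$lang_target
    )
    target_cs <- coding_system("synthetic-target", rbind(gen, chl))
    gold <- data.frame(source = src$code, target = chl$code)
  } else {
    tgt <- data.frame(
      code = sprintf("T%02d", seq_len(n)),
      descriptor = vapply(seq_len(n), function(i) {
        apply_noise(render(i, spec$style_target, spec$lang_target),
                    spec$lang_target)
      }, character(1)),
      language = spec$lang_target
    )
    target_cs <- coding_system("synthetic-target", tgt)
    gold <- data.frame(source = src$code, target = tgt$code)
  }

  structure(list(ontology = ont, source = source_cs, target = target_cs,
                 reference = reference_alignment(gold), spec = spec),
            class = "vacc_benchmark")
}

#' @export
print.vacc_benchmark <- function(x, ...) {
  cat("Synthetic benchmark:", x$spec$n_groups, "vaccine groups;",
      x$spec$style_source, "/", x$spec$lang_source, "vs",
      x$spec$style_target, "/", x$spec$lang_target, "\n")
  invisible(x)
}
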