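#' Curated miniature vaccine-description ontology
#'
#' A small, fully curated ontology covering the seven fundamental property
#' categories with a handful of pathogens, their vaccine-preventable
#' diseases (linked by causal relations), vaccine strategies, administration
#' routes, valences, abbreviation classes defined by existential axioms
#' (DTwP, DTaP, IIV3), and two vaccine products with ingredient assertions
#' (Havrix, Influvac). Labels are multilingual (English plus small Spanish,
#' Italian and Catalan lexicons).
#'
#' All four property chains are declared: propagation of immunization
#' targets and strategies from ingredients to the containing vaccine, and
#' the causal unification of pathogens and diseases as immunization targets
#' in both directions. Causal assertions are curated so that group and
#' product descriptors normalize to disease-level immunization targets
#' (every pathogen `causes` its disease; the disease-to-pathogen link is
#' declared only for cervical cancer/HPV, where descriptor equivalence in
#' both directions is wanted).
#'
#' @return A validated `vacc_ontology`.
#' @examples
#' ont <- mini_vacco()
#' ix <- classify(ont)
#' property_values("DTwP", ix)
#' @export
mini_vacco <- function() {
  ont <- ontology()
  # category subdivisions (unlabelled: they should not match in text)
  ont <- add_class(ont, "Virus", parent = "Pathogen")
  ont <- add_class(ont, "Bacteria", parent = "Pathogen")

  # pathogens
  ont <- add_class(ont, "Influenza-virus", parent = "Virus",
    labels = c(en = "influenza a virus", en = "orthomyxovirus"))
  ont <- add_class(ont, "HPV", parent = "Virus",
    labels = c(en = "human papillomavirus", en = "hpv", en = "papillomavirus",
               es = "virus del papiloma humano"))
  ont <- add_class(ont, "Hepatitis-A-virus", parent = "Virus",
    labels = c(en = "hepatitis a virus", en = "hav"))
  ont <- add_class(ont, "M-tuberculosis", parent = "Bacteria",
    labels = c(en = "mycobacterium tuberculosis", en = "m tuberculosis"))
  ont <- add_class(ont, "B-pertussis", parent = "Bacteria",
    labels = c(en = "bordetella pertussis"))
  ont <- add_class(ont, "C-diphtheriae", parent = "Bacteria",
    labels = c(en = "corynebacterium diphtheriae"))
  ont <- add_class(ont, "C-tetani", parent = "Bacteria",
    labels = c(en = "clostridium tetani"))

  # vaccine-preventable diseases
  ont <- add_class(ont, "Influenza", parent = "Disease",
    labels = c(en = "influenza", en = "flu", es = "gripe", es = "antigripal",
               it = "influenza", ca = "grip"))
  ont <- add_class(ont, "Cervical-cancer", parent = "Disease",
    labels = c(en = "cervical cancer", es = "cancer cervical"))
  ont <- add_class(ont, "Tuberculosis", parent = "Disease",
    labels = c(en = "tuberculosis", es = "tuberculosis", it = "tubercolosi"))
  ont <- add_class(ont, "Hepatitis-A", parent = "Disease",
    labels = c(en = "hepatitis a", es = "hepatitis a", it = "epatite a",
               ca = "hepatitis a"))
  ont <- add_class(ont, "Pertussis", parent = "Disease",
    labels = c(en = "pertussis", en = "whooping cough", es = "tos ferina",
               it = "pertosse"))
  ont <- add_class(ont, "Diphtheria", parent = "Disease",
    labels = c(en = "diphtheria", es = "difteria", it = "difterite"))
  ont <- add_class(ont, "Tetanus", parent = "Disease",
    labels = c(en = "tetanus", es = "tetanos", it = "tetano", ca = "tetanus"))

  # strategies
  ont <- add_class(ont, "Live-attenuated", parent = "Strategy",
    labels = c(en = "live", en = "attenuated", en = "live attenuated",
               es = "atenuada", es = "viva", it = "attenuato", it = "vivo"))
  ont <- add_class(ont, "Inactivated", parent = "Strategy",
    labels = c(en = "inactivated", en = "whole cell", es = "inactivada",
               it = "inattivato"))
  ont <- add_class(ont, "Toxoid", parent = "Strategy",
    labels = c(en = "toxoid", es = "toxoide", it = "tossoide"))
  ont <- add_class(ont, "Conjugated", parent = "Strategy",
    labels = c(en = "conjugated", en = "conjugate", es = "conjugada"))
  ont <- add_class(ont, "Subunit", parent = "Strategy",
    labels = c(en = "subunit", en = "acellular", es = "subunidades",
               es = "acelular", it = "acellulare"))

  # routes
  ont <- add_class(ont, "Oral-route", parent = "Route",
    labels = c(en = "oral", es = "oral", it = "orale", ca = "oral"))
  ont <- add_class(ont, "Intramuscular-route", parent = "Route",
    labels = c(en = "intramuscular", en = "im", es = "intramuscular"))

  # valences 1-4
  ont <- add_class(ont, "Valence-1", parent = "Valence",
    labels = c(en = "monovalent", en = "1 valent"))
  ont <- add_class(ont, "Valence-2", parent = "Valence",
    labels = c(en = "bivalent", en = "divalent", en = "2 valent"))
  ont <- add_class(ont, "Valence-3", parent = "Valence",
    labels = c(en = "trivalent", en = "3 valent"))
  ont <- add_class(ont, "Valence-4", parent = "Valence",
    labels = c(en = "quadrivalent", en = "tetravalent", en = "4 valent"))

  # ingredients
  ont <- add_class(ont, "Active-ingredient", parent = "Ingredient")
  ont <- add_class(ont, "HAV-antigen", parent = "Active-ingredient",
    labels = c(en = "hepatitis a antigen"))
  ont <- add_class(ont, "HA-antigen", parent = "Active-ingredient",
    labels = c(en = "haemagglutinin"))

  # vaccine category labels (matches of these are category matches)
  ont$labels <- rbind(ont$labels, data.frame(
    class = "Vaccine",
    term = c("vaccine", "vaccines", "vacuna", "vacunas", "vaccino", "vaccini",
             "vacuna"),
    lang = c("en", "en", "es", "es", "it", "it", "ca")))

  # abbreviation classes defined by existential axioms
  ont <- add_class(ont, "DTwP", parent = "Vaccine", labels = c(en = "dtwp"))
  ont <- add_assertion(ont, "DTwP", "immunizes-against", "Diphtheria")
  ont <- add_assertion(ont, "DTwP", "immunizes-against", "Tetanus")
  ont <- add_assertion(ont, "DTwP", "immunizes-against", "Pertussis")
  ont <- add_assertion(ont, "DTwP", "has-strategy", "Inactivated")
  ont <- add_class(ont, "DTaP", parent = "Vaccine", labels = c(en = "dtap"))
  ont <- add_assertion(ont, "DTaP", "immunizes-against", "Diphtheria")
  ont <- add_assertion(ont, "DTaP", "immunizes-against", "Tetanus")
  ont <- add_assertion(ont, "DTaP", "immunizes-against", "Pertussis")
  ont <- add_assertion(ont, "DTaP", "has-strategy", "Subunit")
  ont <- add_class(ont, "IIV3", parent = "Vaccine", labels = c(en = "iiv3"))
  ont <- add_assertion(ont, "IIV3", "immunizes-against", "Influenza")
  ont <- add_assertion(ont, "IIV3", "has-strategy", "Inactivated")
  ont <- add_assertion(ont, "IIV3", "has-valence", "Valence-3")

  # vaccine products with ingredient assertions
  ont <- add_class(ont, "Havrix", parent = "Vaccine", labels = c(en = "havrix"))
  ont <- add_assertion(ont, "Havrix", "has-ingredient", "HAV-antigen")
  ont <- add_assertion(ont, "HAV-antigen", "immunizes-against", "Hepatitis-A")
  ont <- add_assertion(ont, "HAV-antigen", "has-strategy", "Inactivated")
  ont <- add_class(ont, "Influvac", parent = "Vaccine",
                   labels = c(en = "influvac"))
  ont <- add_assertion(ont, "Influvac", "has-ingredient", "HA-antigen")
  ont <- add_assertion(ont, "HA-antigen", "immunizes-against", "Influenza")
  ont <- add_assertion(ont, "HA-antigen", "has-strategy", "Subunit")

  # object properties
  ont <- add_property(ont, "immunizes-against", "Vaccine",
                      c("Pathogen", "Disease"))
  ont <- add_property(ont, "has-strategy", "Vaccine", "Strategy")
  ont <- add_property(ont, "has-ingredient", "Vaccine", "Ingredient")
  ont <- add_property(ont, "has-valence", "Vaccine", "Valence")
  ont <- add_property(ont, "has-route", "Vaccine", "Route")
  ont <- add_property(ont, "causes", "Pathogen", "Disease")
  ont <- add_property(ont, "caused-by", "Disease", "Pathogen")

  # property chains: ingredient propagation and causal unification
  ont <- add_chain(ont, "has-ingredient", "immunizes-against",
                   "immunizes-against")
  ont <- add_chain(ont, "has-ingredient", "has-strategy", "has-strategy")
  ont <- add_chain(ont, "immunizes-against", "causes", "immunizes-against")
  ont <- add_chain(ont, "immunizes-against", "caused-by", "immunizes-against")

  # causal assertions: pathogen -> disease everywhere; disease -> pathogen
  # only where equivalence of pathogen- and disease-based descriptors is
  # curated (cervical cancer / HPV)
  ont <- add_assertion(ont, "Influenza-virus", "causes", "Influenza")
  ont <- add_assertion(ont, "HPV", "causes", "Cervical-cancer")
  ont <- add_assertion(ont, "Cervical-cancer", "caused-by", "HPV")
  ont <- add_assertion(ont, "Hepatitis-A-virus", "causes", "Hepatitis-A")
  ont <- add_assertion(ont, "M-tuberculosis", "causes", "Tuberculosis")
  ont <- add_assertion(ont, "B-pertussis", "causes", "Pertussis")
  ont <- add_assertion(ont, "C-diphtheriae", "causes", "Diphtheria")
  ont <- add_assertion(ont, "C-tetani", "causes", "Tetanus")

  validate_ontology(ont)
}
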