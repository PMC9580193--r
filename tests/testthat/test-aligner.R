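ont <- mini_vacco()
ix <- classify(ont)
dic <- build_dictionary(ont)

toy_cs <- coding_system("toy", data.frame(
  code = c("FLU", "FLU-LIVE", "TB", "HEPA", "DTP"),
  descriptor = c("Flu vaccine", "Live attenuated influenza vaccine",
                 "Tuberculosis vaccine", "Hepatitis A, inactivated", "DTwP")))
toy_reps <- code_representations(toy_cs, ix, dic)

test_that("token similarity is the Jaccard coefficient of token sets", {
  expect_equal(similarity_tokens("hepatitis a vaccine", "hepatitis b vaccine"),
               0.5)
  expect_equal(similarity_tokens("Flu vaccine", "Flu vaccine"), 1)
  expect_equal(similarity_tokens("alpha beta", "gamma delta"), 0)
  expect_equal(similarity_tokens("", ""), 0)
})

test_that("class similarity is Jaccard with empty sets scoring zero", {
  expect_equal(similarity_classes(c("Influenza", "Live-attenuated"),
                                  "Influenza"), 0.5)
  expect_equal(similarity_classes("Influenza", "Influenza"), 1)
  expect_equal(similarity_classes(character(0), "Influenza"), 0)
  expect_equal(similarity_classes(character(0), character(0)), 0)
})

test_that("equivalence similarity is 1 only under mutual subsumption", {
  v_cc <- vaccine_class("Vaccine against cervical cancer", ont, dic)
  v_hpv <- vaccine_class("Human papillomavirus vaccine", ont, dic)
  expect_equal(similarity_equivalence(v_cc, v_hpv, ix), 1)
  # strict specialization scores 0
  v_flu <- vaccine_class("Flu vaccine", ont, dic)
  v_flu_att <- vaccine_class("Live attenuated flu vaccine", ont, dic)
  expect_equal(similarity_equivalence(v_flu, v_flu_att, ix), 0)
  expect_equal(similarity_equivalence(v_flu, v_flu, ix), 1)
  # uninformative codes are equivalent to nothing, including each other
  v_un <- vaccine_class("mystery", ont, dic)
  expect_equal(similarity_equivalence(v_un, v_un, ix), 0)
})

test_that("property similarity gates on immunization targets", {
  pv <- function(d) property_values(d, ix, dic)
  expect_equal(similarity_properties(pv("Flu vaccine"), pv("Flu vaccine")), 1)
  # same targets, one extra strategy pair: {(imm,Flu),(strat,X)} vs {(imm,Flu)}
  expect_equal(similarity_properties(pv("Influenza vaccine, inactivated"),
                                     pv("Flu vaccine")), 0.5)
  # differing target sets score 0 even though they overlap
  dtp <- pv("diphtheria tetanus pertussis vaccine")
  dt <- pv("diphtheria tetanus vaccine")
  expect_equal(similarity_properties(dtp, dt), 0)
  # the overlap gate only fires on disjoint target sets
  expect_gt(similarity_properties(dtp, dt, targets_gate = "overlap"), 0)
  expect_equal(similarity_properties(pv("Flu vaccine"), pv("mystery")), 0)
  expect_equal(similarity_properties(pv("mystery"), pv("mystery")), 0)
})

test_that("similarities are symmetric, bounded, and 1 on self", {
  n <- nrow(toy_cs)
  for (m in c("tokens", "classes", "equivalence", "properties")) {
    S <- vaccalign:::similarity_matrix(toy_reps, toy_reps, m)
    expect_true(all(S >= 0 & S <= 1), info = m)
    expect_equal(S, t(S), info = m)
    expect_equal(unname(diag(S)), rep(1, n), info = m)
    if (m == "equivalence") expect_true(all(S %in% c(0, 1)))
  }
})

test_that("positive property similarity implies equal target sets", {
  S <- vaccalign:::similarity_matrix(toy_reps, toy_reps, "properties")
  for (i in seq_len(nrow(S))) {
    for (j in seq_len(ncol(S))) {
      if (S[i, j] > 0) {
        expect_setequal(toy_reps$propvals[[i]][["immunizes-against"]],
                        toy_reps$propvals[[j]][["immunizes-against"]])
      }
    }
  }
})

test_that("alignment assigns the best target above the threshold", {
  src <- coding_system("src", data.frame(
    code = "S1", descriptor = "Flu vaccine"))
  tgt <- coding_system("tgt", data.frame(
    code = c("T1", "T2"),
    descriptor = c("Influenza virus vaccine", "Tuberculosis vaccine")))
  al <- align_codes(src, tgt, method = "properties", threshold = 0.1,
                    index = ix)
  expect_equal(al$source, "S1")
  expect_equal(al$target, "T1")
  expect_equal(al$score, 1)
  # below threshold: unassigned
  al2 <- align_codes(src, tgt, method = "tokens", threshold = 0.9)
  expect_equal(nrow(al2), 0)
  expect_equal(attr(al2, "unassigned"), "S1")
})

test_that("hierarchy-aware tie-breaking keeps only the most general target", {
  src <- coding_system("src", data.frame(
    code = "S1", descriptor = "Flu vaccine"))
  tgt <- coding_system("tgt", data.frame(
    code = c("PARENT", "CHILD", "OTHER"),
    descriptor = c("Influenza vaccine", "Influenza virus vaccine",
                   "Tetanus vaccine"),
    parent = c("", "PARENT", "")))
  al <- align_codes(src, tgt, method = "properties", threshold = 0.1,
                    index = ix)
  # both influenza targets tie at score 1; the parent is kept
  expect_equal(al$target, "PARENT")
  # without a hierarchy both tied targets are assigned
  tgt_flat <- coding_system("tgt", data.frame(
    code = c("PARENT", "CHILD", "OTHER"),
    descriptor = c("Influenza vaccine", "Influenza virus vaccine",
                   "Tetanus vaccine")))
  al2 <- align_codes(src, tgt_flat, method = "properties", threshold = 0.1,
                     index = ix)
  expect_setequal(al2$target, c("PARENT", "CHILD"))
})

test_that("raising the threshold only removes assignments", {
  bm <- generate_benchmark(benchmark_spec(n_groups = 8, seed = 31,
                                          noise = c(dropout = 0.3)))
  bix <- classify(bm$ontology)
  pairs_at <- function(th) {
    al <- align_codes(bm$source, bm$target, method = "properties",
                      threshold = th, index = bix)
    paste(al$source, al$target)
  }
  prev <- pairs_at(0)
  for (th in c(0.2, 0.5, 0.8, 1)) {
    cur <- pairs_at(th)
    expect_true(all(cur %in% prev), info = paste("threshold", th))
    prev <- cur
  }
})

test_that("unknown methods and empty targets are handled explicitly", {
  src <- coding_system("src", data.frame(code = "S1", descriptor = "x"))
  expect_error(align_codes(src, src, method = "metamap"))
  empty <- coding_system("tgt", data.frame(code = character(0),
                                           descriptor = character(0)))
  expect_warning(al <- align_codes(src, empty, method = "tokens"),
                 "empty target")
  expect_equal(attr(al, "unassigned"), "S1")
})

test_that("a pluggable external tagger yields a Jaccard similarity method", {
  # toy external concept tagger: maps known words to concept ids
  lex <- c(flu = "C1", influenza = "C1", vaccine = "C2", tetanus = "C3")
  tagger <- function(d) unname(lex[intersect(normalize_text(d), names(lex))])
  src <- coding_system("src", data.frame(
    code = c("A", "B"), descriptor = c("flu vaccine", "tetanus vaccine")))
  tgt <- coding_system("tgt", data.frame(
    code = c("X", "Y"),
    descriptor = c("influenza vaccine", "tetanus vaccine")))
  al <- align_codes(src, tgt, method = "external", threshold = 0.1,
                    external_tagger = tagger)
  expect_equal(al$target[al$source == "A"], "X")
  expect_equal(al$target[al$source == "B"], "Y")
})

test_that("alignments round-trip through the TSV interchange format", {
  src <- coding_system("src", data.frame(
    code = c("S1", "S2"), descriptor = c("Flu vaccine", "gibberish")))
  al <- align_codes(src, toy_cs, method = "properties", index = ix)
  f <- tempfile(fileext = ".tsv")
  write_alignment(al, f)
  al2 <- read_alignment(f)
  expect_equal(as.data.frame(al2)[c("source", "target")],
               as.data.frame(al)[c("source", "target")])
  expect_equal(al2$score, al$score, tolerance = 1e-9)
  expect_equal(attr(al2, "unassigned"), attr(al, "unassigned"))
})

test_that("equivalence works across independently built representations", {
  # orders differ on the two sides, so internalized ids must not be mixed up
  src <- coding_system("src", data.frame(
    code = c("S-TB", "S-FLU"),
    descriptor = c("Tuberculosis vaccine", "Flu vaccine")))
  tgt <- coding_system("tgt", data.frame(
    code = c("T-FLU", "T-TB"),
    descriptor = c("Influenza vaccine", "Mycobacterium tuberculosis vaccine")))
  al <- align_codes(src, tgt, method = "equivalence", threshold = 0.1,
                    index = ix)
  expect_equal(al$target[al$source == "S-FLU"], "T-FLU")
  expect_equal(nrow(al[al$source == "S-TB", ]), 0)
})
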