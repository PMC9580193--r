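mk_alignment <- function(pairs, sources = unique(pairs$source)) {
  structure(pairs, class = c("vacc_alignment", "data.frame"),
            method = "test", threshold = 0.1,
            unassigned = setdiff(sources, pairs$source),
            source_codes = sources)
}

test_that("confusion counts generated pairs literally", {
  ref <- reference_alignment(data.frame(source = c("a", "b", "c"),
                                        target = c("x", "y", "z")))
  # identity
  al <- mk_alignment(data.frame(source = c("a", "b", "c"),
                                target = c("x", "y", "z")))
  expect_equal(confusion(al, ref), c(tp = 3, fp = 0, fn = 0))
  # disjoint
  al <- mk_alignment(data.frame(source = c("a", "b"), target = c("y", "x")),
                     sources = c("a", "b", "c"))
  expect_equal(confusion(al, ref), c(tp = 0, fp = 2, fn = 3))
  # tie expansion: extra tied targets count as individual false positives
  al <- mk_alignment(data.frame(source = c("a", "a", "b", "c"),
                                target = c("x", "w", "y", "q")))
  ev <- evaluate_alignment(al, ref)
  expect_equal(c(ev$tp, ev$fp, ev$fn), c(2, 2, 1))
  expect_equal(ev$precision, 2 / 4)
  expect_equal(ev$recall, 2 / 3)
})

test_that("precision, recall and F use the zero-denominator convention", {
  prf_from <- function(tp, fp, fn) {
    vaccalign:::prf(c(tp = tp, fp = fp, fn = fn))
  }
  e <- prf_from(2, 1, 1)
  expect_equal(e$precision, 2 / 3)
  expect_equal(e$recall, 2 / 3)
  expect_equal(e$f_score, 2 / 3)
  z <- prf_from(0, 0, 0)
  expect_equal(c(z$precision, z$recall, z$f_score), c(0, 0, 0))
})

test_that("reference alignments are single-valued per source code", {
  expect_error(reference_alignment(
    data.frame(source = c("a", "a"), target = c("x", "y"))), "several")
  expect_error(confusion(
    mk_alignment(data.frame(source = "a", target = "x")),
    reference_alignment(data.frame(source = "ghost", target = "x"))),
    "absent")
})

test_that("macro and micro averages follow their definitions", {
  e1 <- vaccalign:::prf(c(tp = 3, fp = 0, fn = 0))   # P=R=F=1
  e2 <- vaccalign:::prf(c(tp = 1, fp = 1, fn = 1))   # P=R=F=0.5
  mac <- macro_average(list(e1, e2))
  expect_equal(mac$f_score, 0.75)
  expect_equal(macro_average(list(e2))$f_score, 0.5)
  mic <- micro_average(list(list(tp = 1, fp = 0, fn = 0),
                            list(tp = 0, fp = 1, fn = 1)))
  expect_equal(c(mic$precision, mic$recall, mic$f_score), c(0.5, 0.5, 0.5))
  mic0 <- micro_average(list(list(tp = 0, fp = 0, fn = 0)))
  expect_equal(mic0$f_score, 0)
  expect_error(macro_average(list()), "empty")
  expect_error(micro_average(list()), "empty")
})

test_that("threshold sweeps have non-increasing recall", {
  bm <- generate_benchmark(benchmark_spec(n_groups = 8, seed = 5,
                                          noise = c(dropout = 0.3,
                                                    distractor = 0.2)))
  bix <- classify(bm$ontology)
  for (m in c("properties", "tokens")) {
    tab <- threshold_sweep(bm$source, bm$target, bm$reference, method = m,
                           index = bix)
    expect_equal(tab$threshold, seq(0, 1, by = 0.1))
    expect_true(all(diff(tab$recall) <= 1e-12), info = m)
    # strict > 1 can never assign anything
    expect_equal(tab$recall[tab$threshold == 1], 0, info = m)
  }
})
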