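test_that("strict matching compares canonical product sets", {
  expect_true(match_strict("OCC", "CCO"))
  expect_false(match_strict("C/C=C/C", "C/C=C\\C"))
  expect_true(match_strict("CCO.CC", "CC.OCC"))
  expect_false(match_strict("CCO", "CCN"))
  # unparseable candidate is a soft miss, unparseable truth a hard error
  expect_false(match_strict("Xq", "CCO"))
  expect_error(match_strict("CCO", "Xq"), "ground-truth")
})

test_that("stereo-agnostic matching collapses E/Z and chirality", {
  expect_true(match_stereo_agnostic("C/C=C/C", "C/C=C\\C"))
  expect_true(match_stereo_agnostic("C[C@@H](N)C(=O)O", "C[C@H](N)C(=O)O"))
  expect_false(match_stereo_agnostic("CCO", "CCN"))
})

test_that("formula-level matching equates isomers but not different formulas", {
  # hand-derived: both cresol-type isomers are C7H8O
  expect_true(match_formula_level("Cc1ccccc1O", "Cc1ccc(O)cc1"))
  # C2H6O vs C2H4O
  expect_false(match_formula_level("CCO", "CC=O"))
})

test_that("the relaxation chain strict => stereo => formula holds", {
  pairs <- list(
    c("OCC", "CCO"), c("C/C=C/C", "C/C=C\\C"), c("Cc1ccccc1O", "Cc1ccc(O)cc1"),
    c("CCO", "CC=O"), c("CCO.CC", "CC.OCC"), c("CCN", "CCO"),
    c("C[C@@H](N)C(=O)O", "C[C@H](N)C(=O)O")
  )
  for (p in pairs) {
    s <- match_strict(p[1], p[2])
    a <- match_stereo_agnostic(p[1], p[2])
    f <- match_formula_level(p[1], p[2])
    expect_true(!s || a, label = paste(p, collapse = " vs "))
    expect_true(!a || f, label = paste(p, collapse = " vs "))
  }
})

test_that("top-k accuracy implements rank semantics and degenerate inputs", {
  corp <- tiny_corpus()
  r <- corpus_records(corp)
  truth1 <- paste(r$products[[1]], collapse = ".")
  # truth at rank 3 of 5
  preds <- prediction_set(list(
    r1 = c("CCO", "CCN", truth1, "CCC", "CC")
  ))
  ev <- topk_accuracy(preds, corp, "r1", ks = c(1, 3, 5), policies = "strict")
  expect_equal(accuracy_at(ev, 1), 0)
  expect_equal(accuracy_at(ev, 3), 1)
  expect_equal(accuracy_at(ev, 5), 1)
  expect_equal(ev$ranks$rank[1], 3L)
  # empty prediction lists everywhere -> all zeros
  empty <- prediction_set(stats::setNames(
    rep(list(character(0)), 3), c("r1", "r2", "r3")))
  ev0 <- topk_accuracy(empty, corp, c("r1", "r2", "r3"), policies = "strict")
  expect_true(all(ev0$accuracy$accuracy == 0))
  # missing record id in corpus is a hard error
  expect_error(topk_accuracy(preds, corp, "nope"), "missing from corpus")
})

test_that("duplicate candidates collapse to their best rank", {
  corp <- tiny_corpus()
  r <- corpus_records(corp)
  truth1 <- paste(r$products[[1]], collapse = ".")
  # rank-1 duplicate of a decoy eats a slot unless collapsed
  preds <- prediction_set(list(r1 = c("CCO", "OCC", truth1)))
  ev <- topk_accuracy(preds, corp, "r1", ks = 2, policies = "strict")
  expect_equal(accuracy_at(ev, 2), 1)
})

test_that("top-k accuracy equals a brute-force recount on random fixtures", {
  corp <- small_gen_corpus(seed = 21, n_documents = 40)
  r <- corpus_records(corp)
  pool <- unique(unlist(lapply(r$products, paste, collapse = ".")))
  matchers <- list(strict = match_strict,
                   stereo_agnostic = match_stereo_agnostic,
                   formula_level = match_formula_level)
  withr::with_seed(99, {
    ids <- sample(r$record_id, 60)
    cand <- lapply(ids, function(id) {
      truth <- paste(r$products[[match(id, r$record_id)]], collapse = ".")
      k <- sample(0:5, 1)
      out <- sample(setdiff(pool, truth), k)
      if (stats::runif(1) < 0.6) {
        pos <- sample(seq_len(k + 1), 1)
        out <- append(out, truth, after = pos - 1)
      }
      out
    })
    names(cand) <- ids
  })
  preds <- prediction_set(cand)
  ev <- topk_accuracy(preds, corp, ids, ks = c(1, 3, 5))
  for (pol in names(matchers)) {
    for (k in c(1, 3, 5)) {
      recount <- mean(vapply(ids, function(id) {
        truth <- paste(r$products[[match(id, r$record_id)]], collapse = ".")
        cs <- cand[[id]]
        # independent re-implementation of the dedup-then-cutoff contract
        keep <- rep(TRUE, length(cs))
        if (length(cs) > 1) {
          for (i in 2:length(cs)) {
            for (j in seq_len(i - 1)) {
              if (keep[j] && matchers[[pol]](cs[i], cs[j])) keep[i] <- FALSE
            }
          }
        }
        cs <- utils::head(cs[keep], k)
        any(vapply(cs, matchers[[pol]], logical(1), truth = truth))
      }, logical(1)))
      a <- ev$accuracy
      expect_equal(a$accuracy[a$policy == pol & a$k == k], recount,
                   label = paste(pol, "k =", k))
    }
  }
  # monotonicity in k and across policies, on this fixture
  for (pol in names(matchers)) {
    acc <- ev$accuracy$accuracy[ev$accuracy$policy == pol]
    expect_true(all(diff(acc) >= 0))
  }
  for (k in c(1, 3, 5)) {
    a <- ev$accuracy
    expect_lte(a$accuracy[a$policy == "strict" & a$k == k],
               a$accuracy[a$policy == "stereo_agnostic" & a$k == k])
    expect_lte(a$accuracy[a$policy == "stereo_agnostic" & a$k == k],
               a$accuracy[a$policy == "formula_level" & a$k == k])
  }
})

test_that("predictions round-trip through JSONL", {
  preds <- prediction_set(list(a = c("CCO", "CC"), b = character(0)))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_predictions(preds, path)
  got <- read_predictions(path)
  expect_identical(got$a, c("CCO", "CC"))
  expect_identical(got$b, character(0))
})

test_that("single-round iterated prediction equals a direct call", {
  fix <- grignard_fixture()
  r <- corpus_records(fix)
  train_ids <- r$record_id[r$class_code == "1.1.1"]
  lib <- fit_library(fix, train_ids)
  pred <- as_predictor(lib)
  i <- match("te01", r$record_id)
  direct <- pred(r$reactants[[i]], r$agents[[i]], 5)
  iter1 <- iterate_predict(pred, r$reactants[[i]], r$agents[[i]], rounds = 1)
  expect_identical(as.character(iter1), direct)
  expect_identical(attr(iter1, "rounds_run"), 1L)
})

test_that("two rounds recover the double addition a single-step library misses", {
  fix <- grignard_fixture()
  r <- corpus_records(fix)
  train_ids <- r$record_id[r$class_code == "1.1.1"]
  test_ids <- r$record_id[r$class_code == "1.2.1"]
  lib <- fit_library(fix, train_ids)
  expect_false("T_grignard_double" %in% names(lib$entries))
  ev1 <- topk_accuracy(predict_corpus(lib, fix, test_ids, rounds = 1),
                       fix, test_ids, ks = 1, policies = "strict")
  ev2 <- topk_accuracy(predict_corpus(lib, fix, test_ids, rounds = 2),
                       fix, test_ids, ks = 1, policies = "strict")
  expect_equal(accuracy_at(ev1, 1), 0)
  expect_gt(accuracy_at(ev2, 1), 0.5)
})

test_that("the replace-largest carry rule swaps the heavy substrate only", {
  seen <- list()
  fake <- function(reactants, agents, k) {
    seen[[length(seen) + 1]] <<- reactants
    "CC(=O)c1c(C)cc(CC)cc1"  # a ketone, smaller than the ester
  }
  out <- iterate_predict(fake, c("COC(=O)c1c(C)cc(CC)cc1", "CC[Mg]Br"),
                         rounds = 2, carry_rule = "replace_largest")
  expect_setequal(seen[[2]], c("CC(=O)c1c(C)cc(CC)cc1", "CC[Mg]Br"))
  # predictor running dry mid-way flags truncation
  dry <- function(reactants, agents, k) character(0)
  out2 <- iterate_predict(dry, c("CCO"), rounds = 3)
  expect_true(attr(out2, "truncated"))
  expect_identical(attr(out2, "rounds_run"), 1L)
})
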