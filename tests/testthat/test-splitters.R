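corp <- small_gen_corpus(seed = 42, n_documents = 60)
N <- length(corpus_ids(corp))

test_that("reaction split has exact sizes and is deterministic", {
  sp <- split_on_reactions(corp, 0.2, seed = 7)
  expect_length(sp$test_ids, round(0.2 * N))
  expect_length(sp$train_ids, N - round(0.2 * N))
  sp2 <- split_on_reactions(corp, 0.2, seed = 7)
  expect_identical(sp$test_ids, sp2$test_ids)
  expect_false(identical(sp$test_ids,
                         split_on_reactions(corp, 0.2, seed = 8)$test_ids))
  expect_error(split_on_reactions(corp, 1.2, seed = 1), "test_fraction")
  expect_true(attr(audit_split(sp, corp), "ok"))
})

test_that("reaction split test membership is uniform over seeds", {
  hits <- stats::setNames(numeric(N), corpus_ids(corp))
  n_seeds <- 200
  for (s in seq_len(n_seeds)) {
    sp <- split_on_reactions(corp, 0.2, seed = s)
    hits[sp$test_ids] <- hits[sp$test_ids] + 1
  }
  freq <- hits / n_seeds
  se <- sqrt(0.2 * 0.8 / n_seeds)
  expect_true(all(abs(freq - 0.2) < 5 * se))
  expect_lt(abs(mean(freq) - 0.2), 0.01)
})

test_that("document split assigns whole documents, near target fraction", {
  sp <- split_on_documents(corp, 0.2, seed = 3)
  r <- corpus_records(corp)
  test_docs <- unique(r$doc_id[r$record_id %in% sp$test_ids])
  train_docs <- unique(r$doc_id[r$record_id %in% sp$train_ids])
  expect_length(intersect(test_docs, train_docs), 0)
  expect_lt(abs(sp$params$realized_fraction - 0.2), 0.05)
  expect_true(attr(audit_split(sp, corp), "ok"))
})

test_that("document split matches enumeration on the three-document fixture", {
  rows <- corpus_records(tiny_corpus())[c(1, 2, 3, 7), ]
  rows$doc_id <- c("D1", "D1", "D2", "D3")
  fix <- rxn_corpus(rows)
  # target is one test record; only the singleton documents achieve it
  for (seed in 1:12) {
    sp <- split_on_documents(fix, 0.25, seed = seed)
    expect_true(identical(sp$test_ids, "r3") || identical(sp$test_ids, "r7"))
  }
  # ten singleton documents at 0.5 give exactly five test records
  many <- corpus_records(small_gen_corpus(seed = 1, n_documents = 30))
  many <- many[!duplicated(many$doc_id), ][1:10, ]
  many$doc_id <- sprintf("S%02d", 1:10)
  sp <- split_on_documents(rxn_corpus(many), 0.5, seed = 2)
  expect_length(sp$test_ids, 5)
  # single document corpus fails
  one <- rows[1:2, ]
  expect_error(split_on_documents(rxn_corpus(one), 0.5, 1), "single document")
})

test_that("author split co-assigns connected co-authorship components", {
  # D1 by {A,B}, D2 by {B,C}, D3 by {D}: D1 and D2 share a component
  rows <- corpus_records(tiny_corpus())[c(1, 3, 7), ]
  rows$doc_id <- c("D1", "D2", "D3")
  rows$authors <- list(c("A", "B"), c("B", "C"), "D")
  fix <- rxn_corpus(rows)
  # independent component oracle by transitive closure over shared authors
  comp_oracle <- local({
    docs <- rows$doc_id
    auth <- rows$authors
    grp <- seq_along(docs)
    repeat {
      changed <- FALSE
      for (i in seq_along(docs)) for (j in seq_along(docs)) {
        if (grp[i] != grp[j] && length(intersect(auth[[i]], auth[[j]])) > 0) {
          grp[grp == grp[j]] <- grp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    split(docs, grp)
  })
  expect_length(comp_oracle, 2)
  for (seed in 1:10) {
    sp <- split_on_authors(fix, 0.34, seed = seed)
    d1_side <- "r1" %in% sp$test_ids
    d2_side <- "r3" %in% sp$test_ids
    expect_identical(d1_side, d2_side)
    a <- audit_split(sp, fix)
    expect_true(attr(a, "ok"))
  }
})

test_that("author split on generated corpora keeps every author on one side", {
  sp <- split_on_authors(corp, 0.2, seed = 11)
  r <- corpus_records(corp)
  side <- function(ids) unique(unlist(r$authors[r$record_id %in% ids]))
  expect_length(intersect(side(sp$train_ids), side(sp$test_ids)), 0)
  expect_true(attr(audit_split(sp, corp), "ok"))
})

test_that("author split errors on a single connected component", {
  rows <- corpus_records(tiny_corpus())
  rows$authors <- lapply(rows$authors, function(a) c(a, "Omni"))
  fix <- rxn_corpus(rows)
  expect_error(split_on_authors(fix, 0.25, 1), "single connected component")
})

# two well-populated late test years; the earlier cutoff keeps a decent pool
yrs <- table(corpus_records(corp)$year)
late <- yrs[as.integer(names(yrs)) >= 2008]
test_years <- as.integer(names(sort(late, decreasing = TRUE))[1:2])
cutoffs <- c(2007L, max(test_years))

test_that("time series respects year bounds, disjointness and size control", {
  series <- make_time_series(corp, test_years = test_years,
                             cutoffs = cutoffs,
                             test_size_per_year = 10, train_size = 40,
                             seed = 5)
  r <- corpus_records(corp)
  for (cutoff in names(series$train_sets)) {
    ids <- series$train_sets[[cutoff]]
    expect_length(ids, 40)
    expect_true(all(r$year[r$record_id %in% ids] <= as.integer(cutoff)))
  }
  all_test <- unlist(series$test_sets)
  expect_false(anyDuplicated(all_test) > 0)
  expect_length(intersect(all_test, unlist(series$train_sets)), 0)
  expect_true(attr(audit_time_series(series, corp), "ok"))
  # determinism
  series2 <- make_time_series(corp, test_years, cutoffs, 10, 40, seed = 5)
  expect_identical(series$train_sets, series2$train_sets)
  # errors name the offending year / cutoff
  expect_error(make_time_series(corp, test_years[1], cutoffs[1],
                                test_size_per_year = 1e4),
               as.character(test_years[1]))
  expect_error(make_time_series(corp, test_years[1], cutoffs[1], 5,
                                train_size = 1e5),
               as.character(cutoffs[1]))
})

test_that("pairing cutoffs and test years yields auditable time splits", {
  series <- make_time_series(corp, test_years, cutoffs, 10,
                             train_size = 40, seed = 5)
  sp <- time_split(series, cutoffs[1], max(test_years))
  expect_true(attr(audit_split(sp, corp), "ok"))
  expect_error(time_split(series, 1970, max(test_years)), "cutoff")
})

test_that("class hold-out honors exclusion and exact baseline size", {
  spec <- class_holdout_spec("3.1", baseline_n = 40)
  ch <- make_class_holdout(corp, spec, test_fraction_other = 0.1, seed = 2)
  r <- corpus_records(corp)
  cls <- function(ids) r$class_code[r$record_id %in% ids]
  expect_identical(ch$baseline$test_ids, ch$holdout$test_ids)
  expect_equal(sum(match_class_prefix(cls(ch$baseline$train_ids), "3.1")), 40)
  expect_equal(sum(match_class_prefix(cls(ch$holdout$train_ids), "3.1")), 0)
  expect_true(all(match_class_prefix(cls(ch$shared_test), "3.1")))
  expect_false(any(cls(ch$baseline$train_ids) == "0.0"))
  expect_false(any(cls(ch$id_test) == "0.0"))
  expect_true(attr(audit_split(ch$baseline, corp), "ok"))
  expect_true(attr(audit_split(ch$holdout, corp), "ok"))
  expect_error(
    make_class_holdout(corp, class_holdout_spec("3.1", baseline_n = 1e5)),
    "baseline_n")
  expect_error(make_class_holdout(corp, class_holdout_spec("9.9")),
               "no records match")
})

test_that("ablation variants are nested and exclude the right prefixes", {
  ab <- make_ablation_variants(corp, "3.1.2", "3.1", seed = 4)
  r <- corpus_records(corp)
  cls <- function(ids) r$class_code[r$record_id %in% ids]
  expect_identical(ab$all_classes$test_ids, ab$siblings_only$test_ids)
  expect_identical(ab$all_classes$test_ids, ab$parent_excluded$test_ids)
  expect_true(all(ab$parent_excluded$train_ids %in% ab$siblings_only$train_ids))
  expect_true(all(ab$siblings_only$train_ids %in% ab$all_classes$train_ids))
  expect_false(any(match_class_prefix(cls(ab$siblings_only$train_ids), "3.1.2")))
  expect_true(any(match_class_prefix(cls(ab$siblings_only$train_ids), "3.1.1")))
  expect_false(any(match_class_prefix(cls(ab$parent_excluded$train_ids), "3.1")))
  for (v in ab) expect_true(attr(audit_split(v, corp), "ok"))
  expect_error(make_ablation_variants(corp, "2.1.1", "3.1"), "does not extend")
})

test_that("named-reaction test set equals its set-arithmetic definition", {
  series <- make_time_series(corp, test_years, cutoffs,
                             10, train_size = 40, seed = 5)
  got <- make_named_reaction_testset(corp, "3.2.1", series)
  r <- corpus_records(corp)
  class_ids <- r$record_id[match_class_prefix(r$class_code, "3.2.1")]
  in_train <- unique(unlist(series$train_sets))
  expect_setequal(got, setdiff(class_ids, in_train))
  expect_length(intersect(got, in_train), 0)
  # a class absent from all training sets comes back whole
  expect_warning(empty <- make_named_reaction_testset(corp, "8.8", series),
                 "no records")
  expect_length(empty, 0)
})

test_that("the audit detects corrupted splits", {
  sp <- split_on_documents(corp, 0.2, seed = 3)
  bad <- sp
  bad$train_ids <- c(bad$train_ids, bad$test_ids[1])
  a <- audit_split(bad, corp)
  expect_false(attr(a, "ok"))
  expect_false(a$pass[a$check == "train_test_disjoint"])
})

test_that("split manifests round-trip through JSON", {
  sp <- split_on_authors(corp, 0.2, seed = 11)
  path <- withr::local_tempfile(fileext = ".json")
  write_split(sp, path)
  got <- read_split(path)
  expect_identical(got$train_ids, sp$train_ids)
  expect_identical(got$test_ids, sp$test_ids)
  expect_identical(got$strategy, sp$strategy)
  expect_true(attr(audit_split(got, corp), "ok"))
})
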