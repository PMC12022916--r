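# Split construction. Every splitter returns an `rxn_split` (or, for the
# time series, an `rxn_timesplit`) holding record-id sets plus the
# parameters needed for the independent post-hoc audit.

new_split <- function(name, strategy, train_ids, test_ids, seed, params = list()) {
  structure(
    list(name = name, strategy = strategy,
         train_ids = sort(unique(train_ids)), test_ids = sort(unique(test_ids)),
         seed = seed, params = params),
    class = "rxn_split"
  )
}

#' @export
print.rxn_split <- function(x, ...) {
  cat("<rxn_split> ", x$name, " [", x$strategy, "] train=",
      length(x$train_ids), " test=", length(x$test_ids),
      " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Random (reaction-level) split
#'
#' The conventional random split: records are assigned to the test side
#' uniformly at random, ignoring document and author structure. Because
#' documents contain many similar reactions, this split spreads a
#' document's substrate-scope series across both sides and is the
#' overoptimistic baseline the grouped splits are compared against.
#'
#' @param corpus A deduplicated `rxn_corpus`.
#' @param test_fraction Fraction of records assigned to the test set
#'   (0 < f < 1).
#' @param seed Integer seed; the partition is deterministic given it.
#' @return An `rxn_split`.
#' @export
split_on_reactions <- function(corpus, test_fraction, seed) {
  ids <- corpus_ids(corpus)
  n <- length(ids)
  if (n == 0) stop("empty corpus", call. = FALSE)
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  n_test <- round(test_fraction * n)
  test <- withr::with_seed(seed, sample(ids, n_test))
  new_split("reactions", "reaction", setdiff(ids, test), test, seed,
            list(test_fraction = test_fraction))
}

# Greedy group assignment shared by the document and author splits:
# shuffle groups by seed, then walk the shuffled order adding a group to
# the test side whenever doing so brings the test record count strictly
# closer to the target; stop once the target is reached. Residual
# over/undershoot is accepted and reported in params.
.assign_groups <- function(groups, ids, test_fraction, seed) {
  target <- round(test_fraction * length(ids))
  ord <- withr::with_seed(seed, sample(seq_along(groups)))
  test <- character(0)
  taken <- 0
  for (g in ord) {
    if (taken >= target) break
    s <- length(groups[[g]])
    if (abs(taken + s - target) < abs(target - taken)) {
      test <- c(test, groups[[g]])
      taken <- taken + s
    }
  }
  list(test = test, realized_fraction = taken / length(ids))
}

#' Document-based split
#'
#' All reactions of a document end up together on one side, so a model is
#' never evaluated on reactions from a document it trained on.
#'
#' @inheritParams split_on_reactions
#' @return An `rxn_split`.
#' @export
split_on_documents <- function(corpus, test_fraction, seed) {
  ids <- corpus_ids(corpus)
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  docs <- corpus_index(corpus, "doc_id")
  if (length(docs) < 2) {
    stop("corpus has a single document; cannot produce nonempty train and test",
         call. = FALSE)
  }
  a <- .assign_groups(docs, ids, test_fraction, seed)
  new_split("documents", "document", setdiff(ids, a$test), a$test, seed,
            list(test_fraction = test_fraction,
                 realized_fraction = a$realized_fraction))
}

#' Author-based split
#'
#' Builds the author-document co-occurrence graph, computes its connected
#' components and assigns whole components to one side. Consequently no
#' author -- and hence no document -- has reactions on both sides, which
#' is the strictest of the retrospective splits.
#'
#' @inheritParams split_on_reactions
#' @return An `rxn_split`.
#' @export
split_on_authors <- function(corpus, test_fraction, seed) {
  ids <- corpus_ids(corpus)
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  r <- corpus_records(corpus)
  if (any(lengths(r$authors) == 0)) stop("records without authors", call. = FALSE)
  edges <- tibble::tibble(
    doc = paste0("d:", rep(r$doc_id, lengths(r$authors))),
    author = paste0("a:", unlist(r$authors))
  )
  edges <- unique(edges)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  doc_comp <- comp$membership[paste0("d:", unique(r$doc_id))]
  if (length(unique(doc_comp)) < 2) {
    sizes <- sort(table(comp$membership), decreasing = TRUE)
    stop("author-document graph is a single connected component ",
         "(component sizes: ", paste(sizes, collapse = ", "),
         "); cannot split on authors", call. = FALSE)
  }
  doc_ids <- sub("^d:", "", names(doc_comp))
  by_doc <- corpus_index(corpus, "doc_id")
  groups <- lapply(split(doc_ids, doc_comp), function(ds) {
    unlist(by_doc[ds], use.names = FALSE)
  })
  a <- .assign_groups(groups, ids, test_fraction, seed)
  new_split("authors", "author", setdiff(ids, a$test), a$test, seed,
            list(test_fraction = test_fraction,
                 realized_fraction = a$realized_fraction,
                 n_components = length(groups)))
}

#' Time-based split series
#'
#' First samples a fixed-size held-out test set from each test year, then
#' builds one training set per cutoff year from the remaining records
#' with `year <= cutoff`. When `train_size` is set, each cutoff's
#' training pool is subsampled (independently per cutoff) to exactly that
#' size, controlling for training-set size across cutoffs.
#'
#' @param corpus A deduplicated `rxn_corpus`.
#' @param test_years Integer vector of years to hold out test sets for.
#' @param cutoffs Integer vector of training cutoff years.
#' @param test_size_per_year Records sampled per test year.
#' @param train_size Optional exact training-set size per cutoff.
#' @param seed Integer seed.
#' @return An `rxn_timesplit` with `test_sets` (year -> ids) and
#'   `train_sets` (cutoff -> ids).
#' @export
make_time_series <- function(corpus, test_years, cutoffs, test_size_per_year,
                             train_size = NULL, seed = 1) {
  stopifnot(length(test_years) > 0, length(cutoffs) > 0)
  r <- corpus_records(corpus)
  withr::with_seed(seed, {
    test_sets <- list()
    for (y in sort(test_years)) {
      pool <- r$record_id[r$year == y]
      if (length(pool) < test_size_per_year) {
        stop("test year ", y, " has only ", length(pool),
             " records (need ", test_size_per_year, ")", call. = FALSE)
      }
      test_sets[[as.character(y)]] <- sort(sample(pool, test_size_per_year))
    }
    held_out <- unlist(test_sets, use.names = FALSE)
    remainder <- r[!(r$record_id %in% held_out), ]
    train_sets <- list()
    for (cutoff in sort(cutoffs)) {
      pool <- remainder$record_id[remainder$year <= cutoff]
      if (!is.null(train_size)) {
        if (length(pool) < train_size) {
          stop("cutoff ", cutoff, " has a training pool of ", length(pool),
               " records (need ", train_size, ")", call. = FALSE)
        }
        pool <- sample(pool, train_size)
      }
      train_sets[[as.character(cutoff)]] <- sort(pool)
    }
  })
  structure(
    list(test_sets = test_sets, train_sets = train_sets,
         train_size = train_size, seed = seed,
         params = list(test_size_per_year = test_size_per_year)),
    class = "rxn_timesplit"
  )
}

#' @export
print.rxn_timesplit <- function(x, ...) {
  cat("<rxn_timesplit> ", length(x$test_sets), " test years (",
      x$params$test_size_per_year, " records each), cutoffs: ",
      paste(names(x$train_sets), collapse = ", "),
      if (!is.null(x$train_size)) paste0(" (train_size=", x$train_size, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Cutoff/test-year split from a time series
#'
#' @param series An `rxn_timesplit`.
#' @param cutoff A cutoff year present in the series.
#' @param test_year A test year present in the series.
#' @return An `rxn_split` pairing that training set with that test set.
#' @export
time_split <- function(series, cutoff, test_year) {
  train <- series$train_sets[[as.character(cutoff)]]
  test <- series$test_sets[[as.character(test_year)]]
  if (is.null(train)) stop("unknown cutoff ", cutoff, call. = FALSE)
  if (is.null(test)) stop("unknown test year ", test_year, call. = FALSE)
  new_split(paste0("time_", cutoff, "_on_", test_year), "time",
            train, test, series$seed,
            list(cutoff = as.integer(cutoff), test_year = as.integer(test_year)))
}

#' Class hold-out specification
#'
#' @param holdout_prefix Class-code prefix defining the held-out class.
#' @param train_exclusion_prefix Prefix removed from training; defaults
#'   to `holdout_prefix`.
#' @param baseline_n Held-out-class records moved into training for the
#'   intrinsic-difficulty baseline (default 1000).
#' @param drop_uncategorized Drop class `"0.0"` records before splitting
#'   (default `TRUE`).
#' @return A `class_holdout_spec`.
#' @export
class_holdout_spec <- function(holdout_prefix,
                               train_exclusion_prefix = holdout_prefix,
                               baseline_n = 1000,
                               drop_uncategorized = TRUE) {
  if (!startsWith(holdout_prefix, train_exclusion_prefix) &&
      holdout_prefix != train_exclusion_prefix) {
    stop("train_exclusion_prefix must cover holdout_prefix", call. = FALSE)
  }
  structure(
    list(holdout_prefix = holdout_prefix,
         train_exclusion_prefix = train_exclusion_prefix,
         baseline_n = as.integer(baseline_n),
         drop_uncategorized = isTRUE(drop_uncategorized)),
    class = "class_holdout_spec"
  )
}

#' Reaction-class hold-out splits
#'
#' Divides the held-out class's records into a `baseline_n`-sized subset
#' (added to training for the intrinsic-difficulty baseline) and a shared
#' test remainder. The hold-out variant's training set contains no record
#' matching `train_exclusion_prefix`; both variants are evaluated on the
#' identical class test set. An in-distribution context test set is drawn
#' from the remaining classes. Uncategorized (`"0.0"`) records are
#' dropped throughout when the spec says so.
#'
#' @param corpus A deduplicated `rxn_corpus`.
#' @param spec A [class_holdout_spec()].
#' @param test_fraction_other Fraction of non-held-out records reserved
#'   as the in-distribution context test set.
#' @param seed Integer seed.
#' @return A list with `baseline` and `holdout` (`rxn_split`s),
#'   `shared_test` and `id_test` (record-id vectors).
#' @export
make_class_holdout <- function(corpus, spec, test_fraction_other = 0.1, seed = 1) {
  stopifnot(inherits(spec, "class_holdout_spec"))
  r <- corpus_records(corpus)
  if (spec$drop_uncategorized) r <- r[r$class_code != "0.0", ]
  in_class <- r$record_id[match_class_prefix(r$class_code, spec$holdout_prefix)]
  if (length(in_class) == 0) {
    stop("no records match holdout prefix '", spec$holdout_prefix, "'",
         call. = FALSE)
  }
  if (length(in_class) < spec$baseline_n + 1) {
    stop("only ", length(in_class), " records match '", spec$holdout_prefix,
         "' (need baseline_n + 1 = ", spec$baseline_n + 1, ")", call. = FALSE)
  }
  excluded <- r$record_id[match_class_prefix(r$class_code,
                                             spec$train_exclusion_prefix)]
  other <- setdiff(r$record_id, excluded)
  withr::with_seed(seed, {
    baseline_subset <- sample(in_class, spec$baseline_n)
    shared_test <- sort(setdiff(in_class, baseline_subset))
    n_id_test <- round(test_fraction_other * length(other))
    id_test <- sort(sample(other, n_id_test))
  })
  other_train <- setdiff(other, id_test)
  params <- list(holdout_prefix = spec$holdout_prefix,
                 train_exclusion_prefix = spec$train_exclusion_prefix,
                 baseline_n = spec$baseline_n,
                 drop_uncategorized = spec$drop_uncategorized)
  baseline <- new_split(
    paste0("class_", spec$holdout_prefix, "_baseline"), "class_holdout",
    c(other_train, sort(baseline_subset)), shared_test, seed,
    c(params, list(variant = "baseline"))
  )
  holdout <- new_split(
    paste0("class_", spec$holdout_prefix, "_holdout"), "class_holdout",
    other_train, shared_test, seed,
    c(params, list(variant = "holdout"))
  )
  list(baseline = baseline, holdout = holdout,
       shared_test = shared_test, id_test = id_test)
}

#' Training-set ablation variants for a held-out subclass
#'
#' Builds one shared test set of subclass records and three nested
#' training variants: (i) all classes including the remaining subclass
#' records, (ii) sibling subclasses of the parent retained but the
#' subclass excluded, (iii) the whole parent class excluded.
#'
#' @param corpus A deduplicated `rxn_corpus`.
#' @param subclass_prefix Held-out subclass (e.g. `"3.1.2"`).
#' @param parent_prefix Parent class (e.g. `"3.1"`); must prefix
#'   `subclass_prefix`.
#' @param test_fraction Fraction of subclass records used as the shared
#'   test set.
#' @param drop_uncategorized Drop `"0.0"` records (default `TRUE`).
#' @param seed Integer seed.
#' @return Named list of three `rxn_split`s: `all_classes`,
#'   `siblings_only`, `parent_excluded`.
#' @export
make_ablation_variants <- function(corpus, subclass_prefix, parent_prefix,
                                   test_fraction = 0.5,
                                   drop_uncategorized = TRUE, seed = 1) {
  if (!match_class_prefix(subclass_prefix, parent_prefix)) {
    stop("subclass_prefix '", subclass_prefix,
         "' does not extend parent_prefix '", parent_prefix, "'", call. = FALSE)
  }
  r <- corpus_records(corpus)
  if (drop_uncategorized) r <- r[r$class_code != "0.0", ]
  sub_ids <- r$record_id[match_class_prefix(r$class_code, subclass_prefix)]
  parent_ids <- r$record_id[match_class_prefix(r$class_code, parent_prefix)]
  if (length(sub_ids) < 2) {
    stop("too few records match subclass '", subclass_prefix, "'", call. = FALSE)
  }
  test <- withr::with_seed(seed,
    sort(sample(sub_ids, max(1, round(test_fraction * length(sub_ids))))))
  rest <- setdiff(r$record_id, test)
  params <- list(subclass_prefix = subclass_prefix, parent_prefix = parent_prefix)
  list(
    all_classes = new_split(
      paste0("ablation_", subclass_prefix, "_all"), "class_holdout",
      rest, test, seed, c(params, list(variant = "all_classes"))),
    siblings_only = new_split(
      paste0("ablation_", subclass_prefix, "_siblings"), "class_holdout",
      setdiff(rest, sub_ids), test, seed,
      c(params, list(variant = "siblings_only",
                     train_exclusion_prefix = subclass_prefix))),
    parent_excluded = new_split(
      paste0("ablation_", subclass_prefix, "_parent_excl"), "class_holdout",
      setdiff(rest, parent_ids), test, seed,
      c(params, list(variant = "parent_excluded",
                     train_exclusion_prefix = parent_prefix)))
  )
}

#' Named-reaction prospective test set
#'
#' All records of a class (by code prefix) that appear in no training set
#' of a time-split series -- the static test set used to track how models
#' trained at successive cutoffs pick up a newly discovered reaction.
#'
#' @param corpus The corpus the series was built from.
#' @param class_prefix Class-code prefix of the named reaction.
#' @param series An `rxn_timesplit` built from `corpus`.
#' @return Character vector of record ids (possibly empty, with a
#'   warning).
#' @export
make_named_reaction_testset <- function(corpus, class_prefix, series) {
  r <- corpus_records(corpus)
  class_ids <- r$record_id[match_class_prefix(r$class_code, class_prefix)]
  in_train <- unique(unlist(series$train_sets, use.names = FALSE))
  out <- sort(setdiff(class_ids, in_train))
  if (length(out) == 0) {
    warning("no records of class '", class_prefix,
            "' outside the training sets", call. = FALSE)
  }
  out
}

# ---- audits ----------------------------------------------------------------

.audit_row <- function(check, pass, detail = "") {
  tibble::tibble(check = check, pass = pass, detail = detail)
}

#' Audit a split against its corpus
#'
#' Independent post-hoc checker: rescans the corpus and verifies
#' record-level and canonical-key-level train/test disjointness plus the
#' strategy-specific guarantees (document and author integrity, time
#' bounds, class-exclusion and baseline-size contracts) recorded in the
#' split's params.
#'
#' @param split An `rxn_split`.
#' @param corpus The `rxn_corpus` it was built from.
#' @return A tibble of checks with columns `check`, `pass`, `detail`;
#'   attribute `ok` is `TRUE` iff all checks passed.
#' @export
audit_split <- function(split, corpus) {
  r <- corpus_records(corpus)
  train <- split$train_ids; test <- split$test_ids
  out <- list()
  out[[length(out) + 1]] <- .audit_row(
    "train_test_disjoint", length(intersect(train, test)) == 0)
  out[[length(out) + 1]] <- .audit_row(
    "ids_in_corpus", all(c(train, test) %in% r$record_id))
  keys_train <- r$canonical_key[r$record_id %in% train]
  keys_test <- r$canonical_key[r$record_id %in% test]
  out[[length(out) + 1]] <- .audit_row(
    "canonical_key_disjoint", length(intersect(keys_train, keys_test)) == 0)
  side <- function(ids) r[r$record_id %in% ids, ]
  if (split$strategy %in% c("document", "author")) {
    straddle <- intersect(side(train)$doc_id, side(test)$doc_id)
    out[[length(out) + 1]] <- .audit_row(
      "documents_on_one_side", length(straddle) == 0,
      paste(utils::head(straddle, 3), collapse = ","))
  }
  if (split$strategy == "author") {
    a_train <- unique(unlist(side(train)$authors))
    a_test <- unique(unlist(side(test)$authors))
    straddle <- intersect(a_train, a_test)
    out[[length(out) + 1]] <- .audit_row(
      "authors_on_one_side", length(straddle) == 0,
      paste(utils::head(straddle, 3), collapse = ","))
  }
  if (split$strategy == "time") {
    cutoff <- split$params$cutoff
    out[[length(out) + 1]] <- .audit_row(
      "train_years_within_cutoff", all(side(train)$year <= cutoff))
  }
  if (split$strategy == "class_holdout") {
    p <- split$params
    if (!is.null(p$train_exclusion_prefix) &&
        !identical(p$variant, "baseline") &&
        !identical(p$variant, "all_classes")) {
      n_bad <- sum(match_class_prefix(side(train)$class_code,
                                      p$train_exclusion_prefix))
      out[[length(out) + 1]] <- .audit_row(
        "no_excluded_class_in_train", n_bad == 0, paste0(n_bad, " leaked"))
    }
    if (identical(p$variant, "baseline")) {
      n_in <- sum(match_class_prefix(side(train)$class_code, p$holdout_prefix))
      out[[length(out) + 1]] <- .audit_row(
        "baseline_subset_exact", n_in == p$baseline_n,
        paste0(n_in, " vs ", p$baseline_n))
    }
    if (isTRUE(p$drop_uncategorized)) {
      n_unc <- sum(c(side(train)$class_code, side(test)$class_code) == "0.0")
      out[[length(out) + 1]] <- .audit_row(
        "uncategorized_dropped", n_unc == 0)
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "ok") <- all(res$pass)
  res
}

#' Audit a time-split series
#'
#' Verifies the year bound for every cutoff, pairwise disjointness of
#' test sets, disjointness of every test set from every training set, and
#' exact size control when `train_size` is set.
#'
#' @param series An `rxn_timesplit`.
#' @param corpus The corpus it was built from.
#' @return A tibble of checks; attribute `ok` as in [audit_split()].
#' @export
audit_time_series <- function(series, corpus) {
  r <- corpus_records(corpus)
  out <- list()
  for (cutoff in names(series$train_sets)) {
    ids <- series$train_sets[[cutoff]]
    yrs <- r$year[r$record_id %in% ids]
    out[[length(out) + 1]] <- .audit_row(
      paste0("years_le_cutoff_", cutoff), all(yrs <= as.integer(cutoff)))
    if (!is.null(series$train_size)) {
      out[[length(out) + 1]] <- .audit_row(
        paste0("train_size_exact_", cutoff), length(ids) == series$train_size,
        paste0(length(ids), " vs ", series$train_size))
    }
  }
  test_all <- unlist(series$test_sets, use.names = FALSE)
  out[[length(out) + 1]] <- .audit_row(
    "test_sets_pairwise_disjoint", !anyDuplicated(test_all))
  train_all <- unique(unlist(series$train_sets, use.names = FALSE))
  out[[length(out) + 1]] <- .audit_row(
    "test_disjoint_from_all_train", length(intersect(test_all, train_all)) == 0)
  res <- dplyr::bind_rows(out)
  attr(res, "ok") <- all(res$pass)
  res
}

# ---- split manifests -------------------------------------------------------

#' Write a split manifest as JSON
#' @param split An `rxn_split`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(
    list(name = split$name, strategy = split$strategy, seed = split$seed,
         params = split$params, train_ids = split$train_ids,
         test_ids = split$test_ids),
    path, auto_unbox = TRUE, pretty = FALSE
  )
  invisible(path)
}

#' Read a split manifest
#' @param path JSON manifest path written by [write_split()].
#' @return An `rxn_split`.
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_split(x$name, x$strategy, x$train_ids, x$test_ids, x$seed,
            as.list(x$params))
}
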