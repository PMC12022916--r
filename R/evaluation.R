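# Matching policies and top-k accuracy. Ground truth is the record's full
# product set; all comparisons are on canonical SMILES, with products
# treated as a set (dot-joined sorted canonical molecules).

# Normalize a (possibly multi-molecule) product string under a policy.
# Returns NA_character_ when the string does not parse; the caller decides
# whether that is a soft miss (candidate) or a hard error (truth).
normalize_products <- function(smiles_set, policy) {
  vapply(smiles_set, function(s) {
    tryCatch({
      mols <- strsplit(s, ".", fixed = TRUE)[[1]]
      if (policy %in% c("stereo_agnostic", "formula_level")) {
        mols <- strip_stereo(mols)
      }
      if (policy == "formula_level") {
        paste(sort(molecular_formula(mols)), collapse = ".")
      } else {
        paste(sort(canonical_smiles(mols)), collapse = ".")
      }
    }, error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
}

.match_policy <- function(candidate, truth, policy) {
  t_norm <- normalize_products(truth, policy)
  if (is.na(t_norm)) {
    stop("ground-truth products do not parse: ", truth, call. = FALSE)
  }
  c_norm <- normalize_products(candidate, policy)
  !is.na(c_norm) && c_norm == t_norm
}

#' Strict product match
#'
#' True iff candidate and truth denote the same product set after SMILES
#' canonicalization (dot-joined sorted canonical molecules compared as
#' strings). An unparseable candidate counts as a non-match; an
#' unparseable truth is a hard error.
#'
#' @param candidate,truth Product SMILES strings (molecules dot-joined).
#' @return Logical scalar.
#' @export
match_strict <- function(candidate, truth) {
  .match_policy(candidate, truth, "strict")
}

#' Stereochemistry-agnostic product match
#'
#' Strict match after deleting all tetrahedral and double-bond stereo
#' annotations from both sides, so E/Z pairs and enantiomers collapse.
#'
#' @inheritParams match_strict
#' @return Logical scalar.
#' @export
match_stereo_agnostic <- function(candidate, truth) {
  .match_policy(candidate, truth, "stereo_agnostic")
}

#' Formula-level product match
#'
#' True iff the multisets of molecular formulas agree, so regioisomers
#' (and, deliberately, other constitutional isomers) count as matches.
#'
#' @inheritParams match_strict
#' @return Logical scalar.
#' @export
match_formula_level <- function(candidate, truth) {
  .match_policy(candidate, truth, "formula_level")
}

#' Prediction set
#'
#' @param candidates Named list: record id -> ranked character vector of
#'   candidate product SMILES (rank 1 first).
#' @param predictor Name of the predictor that produced the ranking.
#' @param params Optional list of predictor parameters.
#' @return An `rxn_predictions` object.
#' @export
prediction_set <- function(candidates, predictor = "unknown", params = list()) {
  stopifnot(is.list(candidates), !is.null(names(candidates)))
  structure(candidates, class = "rxn_predictions",
            predictor = predictor, params = params)
}

#' @export
print.rxn_predictions <- function(x, ...) {
  cat("<rxn_predictions> ", length(x), " records, predictor=",
      attr(x, "predictor"), "\n", sep = "")
  invisible(x)
}

#' Write predictions as JSONL
#' @param predictions An `rxn_predictions`.
#' @param path Output path; one `{record_id, candidates}` object per line.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(predictions, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (id in names(predictions)) {
    writeLines(jsonlite::toJSON(
      list(record_id = id, candidates = as.list(predictions[[id]])),
      auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read predictions from JSONL
#' @param path JSONL path written by [write_predictions()].
#' @return An `rxn_predictions`.
#' @export
read_predictions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (l in lines) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    out[[x$record_id]] <- as.character(unlist(x$candidates))
  }
  prediction_set(out, predictor = "file")
}

# Match rank of the truth within a ranked candidate list under a policy.
# Candidates that normalize identically are collapsed keeping their best
# rank before the k-cutoff is applied. NA = no match.
match_rank <- function(candidates, truth, policy) {
  if (length(candidates) == 0) return(NA_integer_)
  t_norm <- normalize_products(truth, policy)
  if (is.na(t_norm)) {
    stop("ground-truth products do not parse: ", truth, call. = FALSE)
  }
  c_norm <- normalize_products(candidates, policy)
  keep <- is.na(c_norm) | !duplicated(c_norm)
  c_norm <- c_norm[keep]
  hit <- which(!is.na(c_norm) & c_norm == t_norm)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Top-k accuracy of ranked product predictions
#'
#' For each requested k and policy, the fraction of test records whose
#' recorded product set appears among the first k ranked candidates.
#' Records with no prediction list count as misses. Duplicate candidates
#' (after policy normalization) are collapsed keeping the best rank.
#'
#' @param predictions An `rxn_predictions` (or named list of ranked
#'   candidate vectors).
#' @param corpus The `rxn_corpus` holding ground truth.
#' @param test_ids Record ids to evaluate; all must exist in the corpus.
#' @param ks Integer vector of k values (default `c(1, 3, 5)`, matching a
#'   ranking depth of 5).
#' @param policies Matching policies to evaluate.
#' @return An `rxn_eval` report: tibble `accuracy` (policy, k, accuracy,
#'   n), tibble `ranks` (record_id, policy, rank).
#' @export
topk_accuracy <- function(predictions, corpus, test_ids, ks = c(1, 3, 5),
                          policies = c("strict", "stereo_agnostic",
                                       "formula_level")) {
  stopifnot(all(ks >= 1))
  policies <- match.arg(policies, several.ok = TRUE)
  r <- corpus_records(corpus)
  idx <- match(test_ids, r$record_id)
  if (anyNA(idx)) {
    stop("test id(s) missing from corpus: ",
         paste(utils::head(test_ids[is.na(idx)], 3), collapse = ", "),
         call. = FALSE)
  }
  ranks <- list()
  for (policy in policies) {
    rk <- vapply(seq_along(test_ids), function(i) {
      truth <- paste(r$products[[idx[i]]], collapse = ".")
      cand <- predictions[[test_ids[i]]]
      if (is.null(cand)) return(NA_integer_)
      match_rank(cand, truth, policy)
    }, integer(1))
    ranks[[policy]] <- tibble::tibble(
      record_id = test_ids, policy = policy, rank = rk)
  }
  ranks <- dplyr::bind_rows(ranks)
  accuracy <- dplyr::bind_rows(lapply(split(ranks, ranks$policy), function(d) {
    tibble::tibble(
      policy = d$policy[1], k = as.integer(ks),
      accuracy = vapply(ks, function(k) mean(!is.na(d$rank) & d$rank <= k),
                        numeric(1)),
      n = length(d$rank)
    )
  }))
  structure(list(accuracy = accuracy, ranks = ranks),
            class = "rxn_eval")
}

#' @export
print.rxn_eval <- function(x, ...) {
  cat("<rxn_eval> top-k accuracy over", x$accuracy$n[1], "records\n")
  print(as.data.frame(x$accuracy), row.names = FALSE)
  invisible(x)
}

#' Accuracy lookup in an evaluation report
#' @param eval_report An `rxn_eval`.
#' @param k Rank cutoff.
#' @param policy Matching policy.
#' @return The accuracy value.
#' @export
accuracy_at <- function(eval_report, k = 1, policy = "strict") {
  a <- eval_report$accuracy
  a$accuracy[a$k == k & a$policy == policy]
}

# ---- iterated prediction ---------------------------------------------------

# carry rule: round r's top-1 product replaces the heavy-atom-largest
# reactant of round r-1; other reactants and agents are retained.
.carry_replace_largest <- function(reactants, agents, product) {
  sizes <- heavy_atom_count(reactants)
  biggest <- which.max(sizes)
  reactants[[biggest]] <- NULL
  list(reactants = c(strsplit(product, ".", fixed = TRUE)[[1]],
                     unlist(reactants)),
       agents = agents)
}

.carry_replace_all <- function(reactants, agents, product) {
  list(reactants = strsplit(product, ".", fixed = TRUE)[[1]], agents = agents)
}

#' Iterated (multi-round) prediction
#'
#' Runs a predictor for several rounds, feeding the top-1 product of each
#' round back as a reactant for the next via a carry rule. With
#' `rounds = 1` this is a direct predictor call. The default carry rule
#' `"replace_largest"` substitutes the product for the heavy-atom-largest
#' reactant and keeps the remaining reactants and agents, modelling a
#' reagent still present in excess (e.g. the second Grignard equivalent).
#'
#' @param predictor A function `(reactants, agents, k) -> ranked character
#'   vector of product SMILES`.
#' @param reactants,agents Character vectors of molecule SMILES.
#' @param rounds Number of prediction rounds (>= 1).
#' @param carry_rule `"replace_largest"`, `"replace_all"`, or a function
#'   `(reactants, agents, product) -> list(reactants, agents)`.
#' @param k Ranking depth requested from the predictor.
#' @return Ranked candidate vector from the final round, with attributes
#'   `rounds_run` and `truncated` (TRUE when an intermediate round
#'   returned no candidates).
#' @export
iterate_predict <- function(predictor, reactants, agents = character(0),
                            rounds = 1, carry_rule = "replace_largest", k = 5) {
  stopifnot(rounds >= 1)
  carry <- if (is.function(carry_rule)) carry_rule
  else switch(carry_rule,
              replace_largest = .carry_replace_largest,
              replace_all = .carry_replace_all,
              stop("unknown carry_rule: ", carry_rule, call. = FALSE))
  cur_reactants <- reactants
  cur_agents <- agents
  out <- character(0)
  truncated <- FALSE
  rounds_run <- 0
  for (r in seq_len(rounds)) {
    out <- predictor(cur_reactants, cur_agents, k)
    rounds_run <- r
    if (length(out) == 0) {
      truncated <- r < rounds
      break
    }
    if (r < rounds) {
      nxt <- carry(as.list(cur_reactants), cur_agents, out[1])
      cur_reactants <- nxt$reactants
      cur_agents <- nxt$agents
    }
  }
  structure(out, rounds_run = rounds_run, truncated = truncated)
}
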