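# Template-retrieval baseline predictor. It can only apply transforms it
# has seen in training -- exactly the extrapolation failure mode the
# splits are designed to expose -- and ranks candidate products by the
# similarity of the query reactants to the training reactions that used
# each transform.

#' Fit a template library from a training split
#'
#' Collects the distinct transforms among the training records, each with
#' its support: the ids and reactant fingerprints of the training records
#' that used it. A held-out class's transform is absent iff no training
#' record used it.
#'
#' @param corpus An `rxn_corpus` whose records carry transform strings
#'   (synthetic corpora do).
#' @param train_ids Training record ids.
#' @param radius,width Fingerprint parameters (see
#'   [reactant_fingerprint()]).
#' @return An `rxn_template_library`.
#' @export
fit_library <- function(corpus, train_ids, radius = 3, width = 2048) {
  r <- corpus_records(corpus)
  train <- r[r$record_id %in% train_ids, ]
  train <- train[!is.na(train$transform), ]
  if (nrow(train) == 0) {
    stop("no training record carries a transform string; fit_library needs ",
         "a synthetic corpus or explicit templates", call. = FALSE)
  }
  unknown <- setdiff(unique(train$transform), names(.TEMPLATES))
  if (length(unknown) > 0) {
    stop("unknown transform(s) in corpus: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  support_fp <- fingerprint_matrix(corpus, train$record_id, "reactant",
                                   radius, width)
  entries <- lapply(split(seq_len(nrow(train)), train$transform), function(ix) {
    list(support_ids = train$record_id[ix],
         n_support = length(ix),
         fp = support_fp[ix, , drop = FALSE])
  })
  structure(
    list(entries = entries, radius = radius, width = width,
         n_train = length(train_ids)),
    class = "rxn_template_library"
  )
}

#' @export
print.rxn_template_library <- function(x, ...) {
  cat("<rxn_template_library> ", length(x$entries), " transforms from ",
      x$n_train, " training records\n", sep = "")
  for (id in names(x$entries)) {
    cat("  ", id, ": support ", x$entries[[id]]$n_support, "\n", sep = "")
  }
  invisible(x)
}

#' Supports of a template library
#' @param library An `rxn_template_library`.
#' @return Tibble with `transform_id` and `n_support`.
#' @export
library_supports <- function(library) {
  tibble::tibble(
    transform_id = names(library$entries),
    n_support = vapply(library$entries, `[[`, integer(1), "n_support")
  )
}

# Score one applicable template for a query fingerprint (1 x width sparse
# row): max cosine similarity to the support, damped by log support size.
.template_score <- function(entry, qfp) {
  sims <- cosine_similarity_matrix(qfp, entry$fp)
  max(sims) * log1p(entry$n_support)
}

#' Predict ranked products with a template library
#'
#' Applies every library transform that matches the query reactants and
#' ranks the resulting candidate product sets by
#' `max cosine similarity(query reactant fingerprint, support) *
#' log(1 + support count)`; ties break by canonical product string. The
#' predictor never emits a transform absent from its library.
#'
#' @param object An `rxn_template_library`.
#' @param reactants Character vector of reactant molecule SMILES.
#' @param agents Character vector of agent SMILES (unused by this
#'   predictor, part of the predictor contract).
#' @param k Ranking depth (default 5, the usual beam width).
#' @param ... Unused.
#' @return Ranked character vector of product SMILES (length <= k; empty
#'   when no library template applies).
#' @export
predict.rxn_template_library <- function(object, reactants,
                                         agents = character(0), k = 5, ...) {
  stopifnot(k >= 1)
  cands <- applicable_templates(reactants)
  cands <- cands[names(cands) %in% names(object$entries)]
  if (length(cands) == 0) return(character(0))
  qfp <- Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0),
    dims = c(1, object$width))
  fp <- reactant_fingerprint(reactants, object$radius, object$width)
  if (length(fp) > 0) {
    qfp[1, as.integer(names(fp))] <- as.numeric(fp)
  }
  prods <- vapply(cands, function(p) paste(p, collapse = "."), character(1))
  canon <- vapply(prods, function(p) {
    paste(sort(canonical_smiles(strsplit(p, ".", fixed = TRUE)[[1]])),
          collapse = ".")
  }, character(1))
  scores <- vapply(names(cands), function(id) {
    .template_score(object$entries[[id]], qfp)
  }, numeric(1))
  ord <- order(-scores, canon)
  prods <- prods[ord]; canon <- canon[ord]
  prods <- prods[!duplicated(canon)]
  utils::head(unname(prods), k)
}

#' Predictor-contract closure over a template library
#'
#' @param library An `rxn_template_library`.
#' @return A function `(reactants, agents, k) -> ranked products`,
#'   suitable for [iterate_predict()].
#' @export
as_predictor <- function(library) {
  force(library)
  function(reactants, agents = character(0), k = 5) {
    predict(library, reactants, agents, k)
  }
}

#' Batch prediction over a test set
#'
#' @param library An `rxn_template_library`.
#' @param corpus The corpus holding the test records.
#' @param test_ids Record ids to predict for.
#' @param k Ranking depth.
#' @param rounds Prediction rounds per record (see [iterate_predict()]).
#' @param carry_rule Carry rule for `rounds > 1`.
#' @return An `rxn_predictions` keyed by record id.
#' @export
predict_corpus <- function(library, corpus, test_ids, k = 5, rounds = 1,
                           carry_rule = "replace_largest") {
  r <- corpus_records(corpus)
  idx <- match(test_ids, r$record_id)
  if (anyNA(idx)) stop("unknown test ids", call. = FALSE)
  pred <- as_predictor(library)
  out <- lapply(idx, function(i) {
    as.character(iterate_predict(pred, r$reactants[[i]], r$agents[[i]],
                                 rounds = rounds, carry_rule = carry_rule,
                                 k = k))
  })
  names(out) <- test_ids
  prediction_set(out, predictor = "template_retrieval",
                 params = list(k = k, rounds = rounds,
                               radius = library$radius,
                               width = library$width))
}
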