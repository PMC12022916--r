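# Distribution-shift diagnostics: how far is each test reaction from the
# training set it will be scored against, in reactant fingerprint space
# (substrate novelty) or difference-reaction fingerprint space (transform
# novelty)?

#' Nearest-neighbor distance profile of a split
#'
#' For every test record, computes cosine distances to all training
#' records in the chosen fingerprint space and averages the `m` smallest
#' (ties broken by a stable sort on distance then training record id).
#' Reactant space uses summed reactant count fingerprints (distances in
#' `[0, 1]`); reaction space uses signed difference fingerprints
#' (product minus reactant counts; distances in `[0, 2]`).
#'
#' @param corpus An `rxn_corpus`.
#' @param train_ids,test_ids Record-id vectors; both nonempty and
#'   `m <= length(train_ids)`.
#' @param space `"reactant"` or `"reaction"`.
#' @param m Number of nearest neighbors averaged (default 5).
#' @param radius,width Fingerprint parameters.
#' @return An `rxn_shift_profile`: tibble `distances` (record_id,
#'   mean_nn_distance), summary quartiles and the fingerprint params.
#' @export
nn_distance_profile <- function(corpus, train_ids, test_ids,
                                space = c("reactant", "reaction"),
                                m = 5, radius = 3, width = 2048) {
  space <- match.arg(space)
  if (length(train_ids) == 0 || length(test_ids) == 0) {
    stop("train and test sets must be nonempty", call. = FALSE)
  }
  if (m < 1 || m > length(train_ids)) {
    stop("m must be between 1 and the training-set size (", length(train_ids),
         ")", call. = FALSE)
  }
  train_ids <- sort(train_ids)
  A <- fingerprint_matrix(corpus, test_ids, space, radius, width)
  B <- fingerprint_matrix(corpus, train_ids, space, radius, width)
  D <- 1 - cosine_similarity_matrix(A, B)
  D[D < 0] <- 0  # guard rounding
  mean_nn <- vapply(seq_along(test_ids), function(i) {
    d <- D[i, ]
    ord <- order(d, train_ids)
    mean(d[ord[seq_len(m)]])
  }, numeric(1))
  distances <- tibble::tibble(record_id = test_ids,
                              mean_nn_distance = mean_nn)
  structure(
    list(distances = distances, space = space, m = m,
         params = list(radius = radius, width = width, counted = TRUE),
         summary = stats::quantile(mean_nn, c(0.25, 0.5, 0.75))),
    class = "rxn_shift_profile"
  )
}

#' @export
print.rxn_shift_profile <- function(x, ...) {
  cat("<rxn_shift_profile> space=", x$space, " m=", x$m, " n=",
      nrow(x$distances), "\n  quartiles: ",
      paste(signif(x$summary, 4), collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' Median nearest-neighbor distance of a profile
#' @param profile An `rxn_shift_profile`.
#' @return The median of the per-record mean nearest-neighbor distances.
#' @export
profile_median <- function(profile) {
  stats::median(profile$distances$mean_nn_distance)
}

#' Compare distribution-shift profiles across splits
#'
#' Orders split profiles by median nearest-neighbor distance (an easy
#' split has test reactions close to training; larger medians indicate a
#' stronger shift, which tends to track the observed empirical difficulty
#' of the split) and bins the per-record distances on a shared grid for
#' plotting.
#'
#' @param profiles Named list of `rxn_shift_profile`s sharing space and
#'   fingerprint params.
#' @param n_bins Number of shared histogram bins.
#' @return An `rxn_shift_comparison`: tibble `ranking` (name, median,
#'   q25, q75, rank), matrix `histogram` (bin x split counts), vector
#'   `breaks`.
#' @export
compare_splits <- function(profiles, n_bins = 20) {
  stopifnot(length(profiles) >= 1)
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    names(profiles) <- paste0("split", seq_along(profiles))
  }
  ref <- profiles[[1]]
  for (p in profiles) {
    if (!identical(p$space, ref$space) || !identical(p$params, ref$params)) {
      stop("profiles have mismatched spaces or fingerprint params",
           call. = FALSE)
    }
  }
  med <- vapply(profiles, profile_median, numeric(1))
  q25 <- vapply(profiles, function(p) unname(p$summary[1]), numeric(1))
  q75 <- vapply(profiles, function(p) unname(p$summary[3]), numeric(1))
  ranking <- tibble::tibble(
    name = names(profiles), median = unname(med), q25 = unname(q25),
    q75 = unname(q75), rank = unname(rank(med, ties.method = "min"))
  )
  ranking <- ranking[order(ranking$median), ]
  all_d <- unlist(lapply(profiles, function(p) p$distances$mean_nn_distance))
  breaks <- seq(0, max(max(all_d), 1e-9), length.out = n_bins + 1)
  histogram <- vapply(profiles, function(p) {
    graphics::hist(p$distances$mean_nn_distance, breaks = breaks,
                   plot = FALSE)$counts
  }, numeric(n_bins))
  structure(list(ranking = ranking, histogram = histogram, breaks = breaks,
                 space = ref$space),
            class = "rxn_shift_comparison")
}

#' @export
print.rxn_shift_comparison <- function(x, ...) {
  cat("<rxn_shift_comparison> space=", x$space,
      " (easiest to hardest by median NN distance)\n", sep = "")
  print(as.data.frame(x$ranking), row.names = FALSE)
  invisible(x)
}
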