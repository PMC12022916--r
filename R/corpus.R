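#' Reaction corpus
#'
#' A corpus is a tibble of reaction records plus metadata about the
#' canonicalization routine used to key them. Each record carries a
#' reaction (reactants, agents, products as molecule SMILES lists) and the
#' "hidden" literature metadata the out-of-distribution splits operate on:
#' document identifier, author list, publication year and hierarchical
#' reaction-class code (`"a.b.c"`, `"0.0"` = uncategorized).
#'
#' @param records A data frame with columns `record_id` (character,
#'   unique), `reactants`, `agents`, `products` (list columns of character
#'   vectors), `doc_id` (character), `authors` (list column of nonempty
#'   character vectors), `year` (integer), `class_code` (character) and
#'   optionally `transform` (character, `NA` allowed) and `canonical_key`.
#'   `canonical_key` is computed when absent.
#' @param validate Check all record invariants (default `TRUE`).
#' @return An object of class `rxn_corpus`.
#' @export
rxn_corpus <- function(records, validate = TRUE) {
  records <- tibble::as_tibble(records)
  required <- c("record_id", "reactants", "agents", "products",
                "doc_id", "authors", "year", "class_code")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"transform" %in% names(records)) records$transform <- NA_character_
  records$year <- as.integer(records$year)
  if (!"canonical_key" %in% names(records)) {
    records$canonical_key <- compute_canonical_keys(records)
  }
  corpus <- structure(
    list(records = records, canonicalizer = "openbabel-can"),
    class = "rxn_corpus"
  )
  if (validate) validate_corpus(corpus)
  corpus
}

compute_canonical_keys <- function(records) {
  # canonicalize the molecule universe in one batched call, then assemble
  # keys with a plain map lookup
  mols <- unique(unlist(c(records$reactants, records$agents, records$products)))
  if (length(mols) == 0) return(character(0))
  cmap <- stats::setNames(canonical_smiles(mols), mols)
  part <- function(x) {
    if (length(x) == 0) "" else paste(sort.int(unname(cmap[x])), collapse = ".")
  }
  vapply(seq_len(nrow(records)), function(i) {
    paste(part(records$reactants[[i]]), part(records$agents[[i]]),
          part(records$products[[i]]), sep = ">")
  }, character(1))
}

#' @export
print.rxn_corpus <- function(x, ...) {
  r <- x$records
  cat("<rxn_corpus> ", nrow(r), " reactions, ",
      length(unique(r$doc_id)), " documents, ",
      length(unique(unlist(r$authors))), " authors, years ",
      if (nrow(r)) paste0(min(r$year), "-", max(r$year)) else "-", ", ",
      length(unique(r$class_code)), " classes\n", sep = "")
  invisible(x)
}

#' Records of a corpus
#' @param corpus An `rxn_corpus`.
#' @return The records tibble.
#' @export
corpus_records <- function(corpus) {
  stopifnot(inherits(corpus, "rxn_corpus"))
  corpus$records
}

#' Record identifiers of a corpus
#' @param corpus An `rxn_corpus`.
#' @return Character vector of record ids.
#' @export
corpus_ids <- function(corpus) corpus_records(corpus)$record_id

#' Index a corpus by a metadata field
#'
#' @param corpus An `rxn_corpus`.
#' @param by One of `"doc_id"`, `"author"`, `"year"`, `"class_code"`.
#' @return A named list mapping each key to the record ids carrying it.
#' @export
corpus_index <- function(corpus, by = c("doc_id", "author", "year", "class_code")) {
  by <- match.arg(by)
  r <- corpus_records(corpus)
  if (by == "author") {
    pairs <- tibble::tibble(
      author = unlist(r$authors),
      record_id = rep(r$record_id, lengths(r$authors))
    )
    return(split(pairs$record_id, pairs$author))
  }
  split(r$record_id, as.character(r[[by]]))
}

#' Validate corpus invariants
#'
#' Checks record-id uniqueness, nonempty products and author lists,
#' class-code syntax, and that every SMILES parses (via canonical-key
#' computation).
#'
#' @param corpus An `rxn_corpus`.
#' @return Invisibly, the corpus; errors describe the first violation.
#' @export
validate_corpus <- function(corpus) {
  r <- corpus_records(corpus)
  if (anyDuplicated(r$record_id)) {
    stop("duplicate record_id values", call. = FALSE)
  }
  empty_products <- lengths(r$products) == 0
  if (any(empty_products)) {
    stop("record '", r$record_id[which(empty_products)[1]],
         "' has no products", call. = FALSE)
  }
  if (any(lengths(r$authors) == 0)) {
    stop("record '", r$record_id[which(lengths(r$authors) == 0)[1]],
         "' has an empty author list", call. = FALSE)
  }
  bad_code <- !grepl("^[0-9]+(\\.[0-9]+){0,2}$", r$class_code)
  if (any(bad_code)) {
    stop("invalid class_code '", r$class_code[which(bad_code)[1]],
         "' (expected digits with up to two dot-separated levels)",
         call. = FALSE)
  }
  if (anyNA(r$year)) stop("missing year", call. = FALSE)
  # canonical keys imply every SMILES parsed
  stopifnot(is.character(r$canonical_key))
  invisible(corpus)
}

#' Deduplicate a corpus by canonical reaction key
#'
#' Keeps exactly one record per canonical reaction so that each reaction
#' is associated with a single document. When a key occurs in several
#' records, the earliest-year record is retained (the first disclosure);
#' remaining ties break by lexicographically smallest `doc_id`, then
#' smallest `record_id`.
#'
#' @param corpus An `rxn_corpus`.
#' @return The deduplicated corpus, with a `dedup_report` attribute
#'   recording `n_in`, `n_out` and `n_dropped`. Idempotent.
#' @export
deduplicate <- function(corpus) {
  r <- corpus_records(corpus)
  ord <- order(r$canonical_key, r$year, r$doc_id, r$record_id)
  r <- r[ord, ]
  keep <- !duplicated(r$canonical_key)
  out <- r[keep, ]
  out <- out[order(match(out$record_id, corpus_records(corpus)$record_id)), ]
  res <- corpus
  res$records <- out
  attr(res, "dedup_report") <- list(
    n_in = nrow(r), n_out = nrow(out), n_dropped = nrow(r) - nrow(out)
  )
  res
}

# Subset a corpus to the given record ids (order preserved as in corpus).
corpus_subset <- function(corpus, ids) {
  r <- corpus_records(corpus)
  res <- corpus
  res$records <- r[r$record_id %in% ids, ]
  res
}

# ---- serialization ---------------------------------------------------------

.records_to_flat <- function(r) {
  tibble::tibble(
    record_id = r$record_id,
    rxn_smiles = vapply(seq_len(nrow(r)), function(i) {
      paste(paste(r$reactants[[i]], collapse = "."),
            paste(r$agents[[i]], collapse = "."),
            paste(r$products[[i]], collapse = "."), sep = ">")
    }, character(1)),
    doc_id = r$doc_id,
    authors = vapply(r$authors, paste, character(1), collapse = ";"),
    year = r$year,
    class_code = r$class_code,
    transform = r$transform
  )
}

.flat_to_records <- function(flat, source = "corpus") {
  required <- c("rxn_smiles", "doc_id", "authors", "year", "class_code")
  missing <- setdiff(required, names(flat))
  if (length(missing) > 0) {
    stop("schema error in ", source, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(flat)
  parts <- strsplit(flat$rxn_smiles, ">", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 2 || length(p) > 3, logical(1))
  split_part <- function(p) {
    if (is.na(p) || !nzchar(p)) character(0) else strsplit(p, ".", fixed = TRUE)[[1]]
  }
  if (any(bad)) {
    stop("malformed reaction SMILES at row ", which(bad)[1], " of ", source,
         " (expected 'reactants>agents>products')", call. = FALSE)
  }
  tibble::tibble(
    record_id = if ("record_id" %in% names(flat)) as.character(flat$record_id)
                else sprintf("r%06d", seq_len(n)),
    reactants = lapply(parts, function(p) split_part(p[1])),
    agents = lapply(parts, function(p) if (length(p) >= 2) split_part(p[2]) else character(0)),
    products = lapply(parts, function(p) if (length(p) >= 3) split_part(p[3]) else character(0)),
    doc_id = as.character(flat$doc_id),
    authors = strsplit(as.character(flat$authors), ";", fixed = TRUE),
    year = as.integer(flat$year),
    class_code = as.character(flat$class_code),
    transform = if ("transform" %in% names(flat)) as.character(flat$transform)
                else NA_character_
  )
}

#' Write a corpus to CSV, TSV or JSONL
#'
#' Reaction SMILES are serialized as `"R>A>P"`, author lists with a `";"`
#' separator. A round trip through [read_corpus()] reproduces all fields.
#'
#' @param corpus An `rxn_corpus`.
#' @param path Output file path.
#' @param format One of `"csv"`, `"tsv"`, `"jsonl"`; inferred from the
#'   file extension when omitted.
#' @return Invisibly, `path`.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "csv", "tsv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  flat <- .records_to_flat(corpus_records(corpus))
  if (format == "csv") {
    readr::write_csv(flat, path, na = "")
  } else if (format == "tsv") {
    readr::write_tsv(flat, path, na = "")
  } else {
    con <- file(path, open = "w")
    on.exit(close(con))
    for (i in seq_len(nrow(flat))) {
      row <- as.list(flat[i, ])
      if (is.na(row$transform)) row$transform <- NULL
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Read a corpus from CSV, TSV or JSONL
#'
#' @param path Input file path.
#' @param format One of `"csv"`, `"tsv"`, `"jsonl"`; inferred from the
#'   file extension when omitted.
#' @param validate Check record invariants after reading (default `TRUE`).
#' @return An `rxn_corpus`.
#' @export
read_corpus <- function(path, format = c("auto", "csv", "tsv", "jsonl"),
                        validate = TRUE) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  flat <- if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else if (format == "tsv") {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    rows <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
    dplyr::bind_rows(lapply(rows, function(x) {
      tibble::as_tibble(x[!vapply(x, is.null, logical(1))])
    }))
  }
  if ("transform" %in% names(flat)) {
    flat$transform[!is.na(flat$transform) & flat$transform == ""] <- NA_character_
  }
  records <- .flat_to_records(flat, source = path)
  rxn_corpus(records, validate = validate)
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = "csv", tsv = "tsv", jsonl = "jsonl", json = "jsonl",
    stop("cannot infer format from extension '", ext,
         "'; pass format=", call. = FALSE)
  )
}

# Prefix matching on "." boundaries: "3.1" matches "3.1.2" but not "3.10.2".
#' Match class codes against a hierarchical prefix
#'
#' @param codes Character vector of class codes (`"a.b.c"`).
#' @param prefix A class-code prefix; matching respects `"."` boundaries,
#'   so `"3.1"` matches `"3.1.2"` but not `"3.10.2"`.
#' @return Logical vector.
#' @export
match_class_prefix <- function(codes, prefix) {
  codes == prefix | startsWith(codes, paste0(prefix, "."))
}
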