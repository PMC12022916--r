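# Package-level caches. Canonicalization, graph parsing and formula
# computation all go through OpenBabel, which is far too slow to call once
# per record; everything is memoised on the molecule SMILES string.
.rxn_cache <- new.env(parent = emptyenv())

.cache_get <- function(store, keys) {
  env <- .rxn_cache[[store]]
  if (is.null(env)) {
    env <- new.env(parent = emptyenv())
    .rxn_cache[[store]] <- env
  }
  mget(keys, envir = env, ifnotfound = list(NULL))
}

.cache_set <- function(store, keys, values) {
  env <- .rxn_cache[[store]]
  if (is.null(env)) {
    env <- new.env(parent = emptyenv())
    .rxn_cache[[store]] <- env
  }
  for (i in seq_along(keys)) env[[keys[[i]]]] <- values[[i]]
  invisible(NULL)
}

#' Clear the molecule-level caches
#'
#' Canonical SMILES, molecule graphs, formulas and fingerprints are cached
#' per process. Tests and long-running sessions can reset the caches here.
#'
#' @return Invisibly, `NULL`.
#' @export
clear_chem_cache <- function() {
  rm(list = ls(.rxn_cache), envir = .rxn_cache)
  invisible(NULL)
}

# Raw OpenBabel batch canonicalization. Input must be single-component
# SMILES without whitespace. Returns a character vector aligned with the
# input, NA where OpenBabel could not parse the molecule.
.ob_canonical_batch <- function(smiles) {
  n <- length(smiles)
  titles <- paste0("m", seq_len(n))
  src <- paste0(paste(smiles, titles, collapse = "\n"), "\n")
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = src),
    error = function(e) ""
  )
  res <- rep(NA_character_, n)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 2) {
      idx <- match(parts[[2]], titles)
      if (!is.na(idx)) res[idx] <- parts[[1]]
    }
  }
  # A hard parse error aborts the rest of an OpenBabel batch; retry the
  # unresolved molecules one at a time so each gets a definite verdict.
  miss <- which(is.na(res))
  if (length(miss) > 0 && n > 1) {
    for (i in miss) res[i] <- .ob_canonical_batch(smiles[i])
  }
  res
}

#' Canonicalize molecule SMILES
#'
#' Maps each single-molecule SMILES string to its canonical form so that
#' chemically identical inputs compare equal as strings. The routine is
#' OpenBabel's canonical SMILES writer; its identity is recorded in corpus
#' metadata (see [rxn_corpus()]) so corpora canonicalized with a different
#' routine are detectable.
#'
#' @param smiles Character vector of single-component SMILES strings.
#' @return Character vector of canonical SMILES, same length as the input.
#' @examples
#' \dontrun{
#' canonical_smiles(c("C(C)O", "OCC"))  # both "CCO"
#' }
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  if (anyNA(smiles) || any(!nzchar(smiles)) || any(grepl("\\s", smiles))) {
    stop("SMILES must be non-empty strings without whitespace", call. = FALSE)
  }
  cached <- .cache_get("canon", smiles)
  need <- which(vapply(cached, is.null, logical(1)))
  if (length(need) > 0) {
    todo <- unique(smiles[need])
    got <- .ob_canonical_batch(todo)
    if (anyNA(got)) {
      bad <- todo[is.na(got)][1]
      stop("unparseable SMILES: '", bad, "'", call. = FALSE)
    }
    .cache_set("canon", todo, as.list(got))
    cached <- .cache_get("canon", smiles)
  }
  unlist(cached, use.names = FALSE)
}

# Canonicalize a possibly multi-component SMILES string ("A.B") into a
# sorted dot-joined canonical set representation.
canonical_molecule_set <- function(smiles_set) {
  vapply(smiles_set, function(s) {
    mols <- strsplit(s, ".", fixed = TRUE)[[1]]
    paste(sort(canonical_smiles(mols)), collapse = ".")
  }, character(1), USE.NAMES = FALSE)
}

#' Canonicalize a reaction
#'
#' Builds the canonical reaction string `"R>A>P"` from the three molecule
#' lists: each part is canonicalized molecule-wise, sorted
#' lexicographically and dot-joined. The result is invariant under
#' reordering of molecules within a part and under non-canonical input
#' SMILES, and is idempotent.
#'
#' @param reactants,agents,products Character vectors of molecule SMILES.
#'   `agents` may be empty; `products` must be nonempty.
#' @return A single canonical reaction string.
#' @examples
#' \dontrun{
#' canonicalize_reaction(c("CCO", "CC(=O)O"), character(0), "CCOC(C)=O")
#' }
#' @export
canonicalize_reaction <- function(reactants, agents = character(0), products) {
  if (length(products) == 0) {
    stop("products must be nonempty", call. = FALSE)
  }
  part <- function(mols, what) {
    if (length(mols) == 0) return("")
    out <- tryCatch(canonical_smiles(mols), error = function(e) {
      stop(conditionMessage(e), " (in ", what, ")", call. = FALSE)
    })
    paste(sort(out), collapse = ".")
  }
  paste(part(reactants, "reactants"), part(agents, "agents"),
        part(products, "products"), sep = ">")
}

# ---- molecule graphs -------------------------------------------------------

# Parse canonical molecule SMILES into a light graph structure used by the
# fingerprint code: element symbols, heavy-atom adjacency and bond orders.
.parse_graphs <- function(smiles) {
  cached <- .cache_get("graph", smiles)
  need <- which(vapply(cached, is.null, logical(1)))
  if (length(need) > 0) {
    todo <- unique(smiles[need])
    chunks <- split(todo, ceiling(seq_along(todo) / 400))
    for (chunk in chunks) {
      names(chunk) <- paste0("g", seq_along(chunk))
      # single-atom molecules have no bond block and trip validSDF
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(chunk))
      graphs <- lapply(seq_along(chunk), function(i) {
        ab <- ChemmineR::atomblock(sdf[[i]])
        bb <- ChemmineR::bondblock(sdf[[i]])
        elems <- sub("_.*$", "", rownames(ab))
        n <- length(elems)
        if (is.null(dim(bb)) && length(bb) >= 3) bb <- matrix(bb, nrow = 1)
        bonds <- if (is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3) {
          matrix(integer(0), ncol = 3)
        } else {
          cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
        }
        list(elements = elems, bonds = bonds, n = n)
      })
      .cache_set("graph", chunk, graphs)
    }
    cached <- .cache_get("graph", smiles)
  }
  cached
}

# Heavy-atom count of a (possibly multi-component) SMILES string.
heavy_atom_count <- function(smiles) {
  vapply(smiles, function(s) {
    mols <- canonical_smiles(strsplit(s, ".", fixed = TRUE)[[1]])
    sum(vapply(.parse_graphs(mols), function(g) g$n, numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
}

# ---- molecular formulas ----------------------------------------------------

#' Molecular formula of molecule SMILES
#'
#' @param smiles Character vector of single-molecule SMILES.
#' @return Character vector of Hill-order molecular formulas.
#' @export
molecular_formula <- function(smiles) {
  can <- canonical_smiles(smiles)
  cached <- .cache_get("formula", can)
  need <- which(vapply(cached, is.null, logical(1)))
  if (length(need) > 0) {
    todo <- unique(can[need])
    names(todo) <- paste0("f", seq_along(todo))
    sdf <- ChemmineR::smiles2sdf(todo)
    mf <- ChemmineR::MF(sdf, addH = TRUE)
    .cache_set("formula", todo, as.list(unname(mf)))
    cached <- .cache_get("formula", can)
  }
  unlist(cached, use.names = FALSE)
}

#' Remove stereochemistry annotations from a SMILES string
#'
#' Deletes tetrahedral (`@`) and double-bond (`/`, `\`) stereo markers.
#' The result is re-canonicalized by the caller where needed.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector with stereo annotations removed.
#' @export
strip_stereo <- function(smiles) {
  gsub("@", "", gsub("[/\\\\]", "", smiles))
}
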