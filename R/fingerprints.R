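# Counted circular (Morgan-style) fingerprints over OpenBabel molecule
# graphs. Each atom contributes one hashed identifier per radius
# 0..`radius`; identifiers are folded into `width` bins and counted.
# Consequence used as a test oracle: the counts of a molecule always sum
# to n_atoms * (radius + 1).

# Polynomial hash of an integer vector, modulo the Mersenne prime 2^31-1.
# Multiplier kept small so intermediates stay exact in doubles.
.hash_ints <- function(v) {
  a <- 17
  for (x in v) a <- (a * 31 + x + 1) %% 2147483647
  a
}

.element_code <- function(symbols) {
  tab <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I",
           "Mg", "Li", "Zn", "Sn", "Na", "K", "Pd", "Cu", "Fe", "Mn", "Cr")
  code <- match(symbols, tab)
  code[is.na(code)] <- length(tab) + 1L
  code
}

# Per-atom environment identifiers for one molecule graph.
.atom_identifiers <- function(graph, radius) {
  n <- graph$n
  bonds <- graph$bonds
  nb <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (i in seq_len(nrow(bonds))) {
      a <- bonds[i, 1]; b <- bonds[i, 2]; o <- bonds[i, 3]
      nb[[a]] <- rbind(nb[[a]], c(b, o))
      nb[[b]] <- rbind(nb[[b]], c(a, o))
    }
  }
  elem <- .element_code(graph$elements)
  ids <- matrix(0, nrow = n, ncol = radius + 1)
  for (a in seq_len(n)) {
    deg <- if (is.null(nb[[a]])) 0L else nrow(nb[[a]])
    bsum <- if (is.null(nb[[a]])) 0L else sum(nb[[a]][, 2])
    ids[a, 1] <- .hash_ints(c(elem[a], deg, bsum))
  }
  if (radius > 0) {
    for (r in seq_len(radius)) {
      for (a in seq_len(n)) {
        if (is.null(nb[[a]])) {
          ids[a, r + 1] <- .hash_ints(c(r, ids[a, r]))
        } else {
          pairs <- cbind(nb[[a]][, 2], ids[nb[[a]][, 1], r])
          ord <- order(pairs[, 1], pairs[, 2])
          ids[a, r + 1] <- .hash_ints(c(r, ids[a, r], t(pairs[ord, , drop = FALSE])))
        }
      }
    }
  }
  ids
}

# Counted fingerprint of a single canonical molecule SMILES, as a named
# count vector (names = bin indices, 1-based).
.molecule_fp <- function(can_smiles, radius, width) {
  key <- paste0(can_smiles, "|", radius, "|", width)
  hit <- .cache_get("molfp", key)[[1]]
  if (!is.null(hit)) return(hit)
  graph <- .parse_graphs(can_smiles)[[1]]
  ids <- as.vector(.atom_identifiers(graph, radius))
  bins <- (ids %% width) + 1
  counts <- table(bins)
  fp <- as.integer(counts)
  names(fp) <- names(counts)
  .cache_set("molfp", key, list(fp))
  fp
}

.sum_fps <- function(fps) {
  all <- unlist(fps)
  if (is.null(all)) return(integer(0))
  tapply(all, names(all), sum)
}

#' Reactant fingerprint of a reaction
#'
#' Sum of per-reactant hashed circular substructure count vectors. Agents
#' are excluded; the vector is invariant to reactant ordering.
#'
#' @param reactants Character vector of reactant molecule SMILES.
#' @param radius Circular environment radius (default 3).
#' @param width Hash width, i.e. fingerprint length (default 2048).
#' @return A sparse named count vector (names are 1-based bin indices).
#' @export
reactant_fingerprint <- function(reactants, radius = 3, width = 2048) {
  can <- canonical_smiles(reactants)
  fp <- .sum_fps(lapply(can, .molecule_fp, radius = radius, width = width))
  structure(fp, class = "rxn_fp", radius = radius, width = width,
            space = "reactant")
}

#' Difference reaction fingerprint
#'
#' Signed count vector: product fingerprint minus reactant fingerprint.
#' Reactions applying the same transform to different substrates yield
#' nearby vectors; a null transform (products identical to reactants)
#' yields the zero vector. Agents are excluded.
#'
#' @param reactants,products Character vectors of molecule SMILES.
#' @inheritParams reactant_fingerprint
#' @return A sparse named signed count vector.
#' @export
reaction_fingerprint <- function(reactants, products, radius = 3, width = 2048) {
  rf <- .sum_fps(lapply(canonical_smiles(reactants), .molecule_fp,
                        radius = radius, width = width))
  pf <- .sum_fps(lapply(canonical_smiles(products), .molecule_fp,
                        radius = radius, width = width))
  keys <- union(names(rf), names(pf))
  d <- stats::setNames(numeric(length(keys)), keys)
  d[names(pf)] <- pf
  d[names(rf)] <- d[names(rf)] - rf
  d <- d[d != 0]
  structure(d, class = "rxn_fp", radius = radius, width = width,
            space = "reaction")
}

# Sparse fingerprint matrix (records x width) for a set of records in a
# corpus, in the requested space.
fingerprint_matrix <- function(corpus, ids, space = c("reactant", "reaction"),
                               radius = 3, width = 2048) {
  space <- match.arg(space)
  recs <- corpus_records(corpus)
  rows <- match(ids, recs$record_id)
  if (anyNA(rows)) stop("unknown record ids", call. = FALSE)
  triplets_i <- vector("list", length(ids))
  triplets_j <- vector("list", length(ids))
  triplets_x <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    r <- rows[[k]]
    fp <- if (space == "reactant") {
      reactant_fingerprint(recs$reactants[[r]], radius, width)
    } else {
      reaction_fingerprint(recs$reactants[[r]], recs$products[[r]],
                           radius, width)
    }
    if (length(fp) > 0) {
      triplets_i[[k]] <- rep.int(k, length(fp))
      triplets_j[[k]] <- as.integer(names(fp))
      triplets_x[[k]] <- as.numeric(fp)
    }
  }
  Matrix::sparseMatrix(
    i = unlist(triplets_i), j = unlist(triplets_j), x = unlist(triplets_x),
    dims = c(length(ids), width),
    dimnames = list(ids, NULL)
  )
}

# Cosine similarity between the rows of two sparse matrices. Zero rows get
# similarity 0 against everything except another zero row, which counts as
# similarity 1 (identical null vectors, e.g. two null transforms).
cosine_similarity_matrix <- function(A, B) {
  na <- sqrt(Matrix::rowSums(A^2))
  nb <- sqrt(Matrix::rowSums(B^2))
  za <- na == 0; zb <- nb == 0
  na[za] <- 1; nb[zb] <- 1
  S <- as.matrix(Matrix::tcrossprod(A, B))
  S <- S / outer(na, nb)
  if (any(za) && any(zb)) S[za, zb] <- 1
  S
}
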