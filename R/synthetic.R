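# Synthetic literature-structured reaction corpus.
#
# Reactions are built from a small constrained substrate grammar: five
# aryl cores (benzene 1,3,5- and 1,2,4-substituted, pyridine, thiophene,
# furan), each carrying a reactive site prefix, a document-level
# "series" decoration A and a per-reaction "scope" decoration B. Products
# are produced by substructure-rewrite templates keyed by a hierarchical
# class code, emulating name-reaction classified corpora: couplings
# (3.1.x siblings differing only in the halide leaving group, plus a
# late-introduced amination 3.2.1), Grignard additions to esters with a
# single/double-addition pair (1.1.1/1.2.1), acylations with an
# N- vs O-acylation ambiguity (2.1.1/2.1.2), an aryl ether synthesis
# (2.2.1) and an uncategorized benzylic oxidation ("0.0").

# In every core the series decoration A sits ortho to the reactive site,
# so the substrate series is visible within the circular-environment
# radius of the atoms a transform changes.
.CORES <- list(
  benzene135 = list(
    body = function(A, B) paste0("c1c(", A, ")cc(", B, ")cc1"),
    host = function(br, A, B) paste0("c1(", br, ")c(", A, ")cc(", B, ")cc1"),
    frag = function(A, B, ring) sprintf("c%1$dc(%2$s)cc(%3$s)cc%1$d", ring, A, B),
    rx = "c1c\\((.+)\\)cc\\((.+)\\)cc1"
  ),
  benzene124 = list(
    body = function(A, B) paste0("c1c(", A, ")ccc(", B, ")c1"),
    host = function(br, A, B) paste0("c1(", br, ")c(", A, ")ccc(", B, ")c1"),
    frag = function(A, B, ring) sprintf("c%1$dc(%2$s)ccc(%3$s)c%1$d", ring, A, B),
    rx = "c1c\\((.+)\\)ccc\\((.+)\\)c1"
  ),
  pyridine = list(
    body = function(A, B) paste0("c1c(", A, ")cc(", B, ")cn1"),
    host = function(br, A, B) paste0("c1(", br, ")c(", A, ")cc(", B, ")cn1"),
    frag = function(A, B, ring) sprintf("c%1$dc(%2$s)cc(%3$s)cn%1$d", ring, A, B),
    rx = "c1c\\((.+)\\)cc\\((.+)\\)cn1"
  ),
  thiophene = list(
    body = function(A, B) paste0("c1c(", A, ")cc(", B, ")s1"),
    host = function(br, A, B) paste0("c1(", br, ")c(", A, ")cc(", B, ")s1"),
    frag = function(A, B, ring) sprintf("c%1$dc(%2$s)cc(%3$s)s%1$d", ring, A, B),
    rx = "c1c\\((.+)\\)cc\\((.+)\\)s1"
  ),
  furan = list(
    body = function(A, B) paste0("c1c(", A, ")cc(", B, ")o1"),
    host = function(br, A, B) paste0("c1(", br, ")c(", A, ")cc(", B, ")o1"),
    frag = function(A, B, ring) sprintf("c%1$dc(%2$s)cc(%3$s)o%1$d", ring, A, B),
    rx = "c1c\\((.+)\\)cc\\((.+)\\)o1"
  )
)

.SITE_PREFIX <- c(
  bromide = "Br", chloride = "Cl", iodide = "I", fluoride = "F",
  boronic = "OB(O)", ester = "COC(=O)", acid_chloride = "O=C(Cl)",
  benzylic_alcohol = "OC"
)

.esc_rx <- function(s) gsub("([][().=])", "\\\\\\1", s)

# Parse a molecule of the substrate grammar into (site, core, A, B), or a
# Grignard reagent / ketone intermediate. Returns NULL when the molecule
# is not a recognized substrate. Memoised per SMILES string.
parse_substrate <- function(smiles) {
  hit <- .cache_get("substrate", smiles)[[1]]
  if (!is.null(hit)) return(if (identical(hit, list("none"))) NULL else hit)
  res <- NULL
  for (site in names(.SITE_PREFIX)) {
    for (core in names(.CORES)) {
      m <- regmatches(smiles, regexec(
        paste0("^", .esc_rx(.SITE_PREFIX[[site]]), .CORES[[core]]$rx, "$"),
        smiles))[[1]]
      if (length(m) == 3) {
        res <- list(kind = "aryl", site = site, core = core, A = m[2], B = m[3])
        break
      }
    }
    if (!is.null(res)) break
  }
  if (is.null(res)) {
    for (core in names(.CORES)) {
      m <- regmatches(smiles, regexec(
        paste0("^(C{1,3})C\\(=O\\)", .CORES[[core]]$rx, "$"), smiles))[[1]]
      if (length(m) == 4) {
        res <- list(kind = "aryl", site = "ketone", core = core,
                    alkyl = m[2], A = m[3], B = m[4])
        break
      }
    }
  }
  if (is.null(res)) {
    m <- regmatches(smiles, regexec("^(C{1,3})\\[Mg\\]Br$", smiles))[[1]]
    if (length(m) == 2) res <- list(kind = "grignard", alkyl = m[2])
  }
  if (is.null(res)) {
    if (grepl("^NC{1,3}$", smiles) || smiles == "NCCO") {
      res <- list(kind = "amine", group = smiles)
    } else if (grepl("^OC{1,3}$", smiles)) {
      res <- list(kind = "alcohol", group = sub("^O", "", smiles))
    }
  }
  # NCCO is bifunctional: record the O-nucleophile reading separately.
  .cache_set("substrate", smiles,
             list(if (is.null(res)) list("none") else res))
  res
}

# Find, among parsed reactants, the first one satisfying `pred`.
.pick <- function(parsed, pred) {
  for (i in seq_along(parsed)) {
    p <- parsed[[i]]
    if (!is.null(p) && pred(p)) return(p)
  }
  NULL
}

.alcohol_branch <- function(p) {
  # O-nucleophile branch ("OCC..." attached via O) for alcohols and the
  # amino alcohol NCCO (which reacts through its terminal OH).
  if (p$kind == "alcohol") paste0("O", p$group)
  else if (p$kind == "amine" && p$group == "NCCO") "OCCN"
  else NULL
}

.coupling_template <- function(id, class_code, site) {
  force(site)
  list(
    id = id, class_code = class_code, arity = 2L,
    apply = function(parsed) {
      ar1 <- .pick(parsed, function(p) p$kind == "aryl" && p$site == site)
      ar2 <- .pick(parsed, function(p) p$kind == "aryl" && p$site == "boronic")
      if (is.null(ar1) || is.null(ar2)) return(NULL)
      branch <- paste0("-", .CORES[[ar2$core]]$frag(ar2$A, ar2$B, 2))
      .CORES[[ar1$core]]$host(branch, ar1$A, ar1$B)
    }
  )
}

.TEMPLATES <- list(
  .coupling_template("T_coupling_br", "3.1.1", "bromide"),
  .coupling_template("T_coupling_cl", "3.1.2", "chloride"),
  .coupling_template("T_coupling_i", "3.1.3", "iodide"),
  list(
    id = "T_amination", class_code = "3.2.1", arity = 2L,
    apply = function(parsed) {
      ar <- .pick(parsed, function(p) p$kind == "aryl" && p$site == "bromide")
      am <- .pick(parsed, function(p) p$kind == "amine")
      if (is.null(ar) || is.null(am)) return(NULL)
      .CORES[[ar$core]]$host(am$group, ar$A, ar$B)
    }
  ),
  list(
    id = "T_grignard_single", class_code = "1.1.1", arity = 2L,
    apply = function(parsed) {
      g <- .pick(parsed, function(p) p$kind == "grignard")
      if (is.null(g)) return(NULL)
      es <- .pick(parsed, function(p) p$kind == "aryl" && p$site == "ester")
      if (!is.null(es)) {
        return(paste0(g$alkyl, "C(=O)", .CORES[[es$core]]$body(es$A, es$B)))
      }
      ke <- .pick(parsed, function(p) p$kind == "aryl" && p$site == "ketone")
      if (!is.null(ke)) {
        return(paste0(ke$alkyl, "C(O)(", g$alkyl, ")",
                      .CORES[[ke$core]]$body(ke$A, ke$B)))
      }
      NULL
    }
  ),
  list(
    id = "T_grignard_double", class_code = "1.2.1", arity = 2L,
    apply = function(parsed) {
      g <- .pick(parsed, function(p) p$kind == "grignard")
      es <- .pick(parsed, function(p) p$kind == "aryl" && p$site == "ester")
      if (is.null(g) || is.null(es)) return(NULL)
      paste0(g$alkyl, "C(O)(", g$alkyl, ")", .CORES[[es$core]]$body(es$A, es$B))
    }
  ),
  list(
    id = "T_amide", class_code = "2.1.1", arity = 2L,
    apply = function(parsed) {
      ac <- .pick(parsed, function(p) p$kind == "aryl" && p$site == "acid_chloride")
      am <- .pick(parsed, function(p) p$kind == "amine")
      if (is.null(ac) || is.null(am)) return(NULL)
      paste0("O=C(", am$group, ")", .CORES[[ac$core]]$body(ac$A, ac$B))
    }
  ),
  list(
    id = "T_esterification", class_code = "2.1.2", arity = 2L,
    apply = function(parsed) {
      ac <- .pick(parsed, function(p) p$kind == "aryl" && p$site == "acid_chloride")
      ol <- .pick(parsed, function(p) !is.null(.alcohol_branch(p)))
      if (is.null(ac) || is.null(ol)) return(NULL)
      paste0("O=C(", .alcohol_branch(ol), ")", .CORES[[ac$core]]$body(ac$A, ac$B))
    }
  ),
  list(
    id = "T_ether", class_code = "2.2.1", arity = 2L,
    apply = function(parsed) {
      ar <- .pick(parsed, function(p) p$kind == "aryl" && p$site == "fluoride")
      ol <- .pick(parsed, function(p) !is.null(.alcohol_branch(p)))
      if (is.null(ar) || is.null(ol)) return(NULL)
      .CORES[[ar$core]]$host(.alcohol_branch(ol), ar$A, ar$B)
    }
  ),
  list(
    id = "T_oxidation", class_code = "0.0", arity = 1L,
    apply = function(parsed) {
      al <- .pick(parsed, function(p) p$kind == "aryl" && p$site == "benzylic_alcohol")
      if (is.null(al)) return(NULL)
      paste0("O=C", .CORES[[al$core]]$body(al$A, al$B))
    }
  )
)
names(.TEMPLATES) <- vapply(.TEMPLATES, `[[`, character(1), "id")

#' Transform template library
#'
#' @return A tibble of the built-in toy transform templates: identifier,
#'   linked class code and arity.
#' @export
transform_templates <- function() {
  tibble::tibble(
    transform_id = vapply(.TEMPLATES, `[[`, character(1), "id"),
    class_code = vapply(.TEMPLATES, `[[`, character(1), "class_code"),
    arity = vapply(.TEMPLATES, `[[`, integer(1), "arity")
  )
}

#' Apply a transform template to substrates
#'
#' @param transform_id One of the identifiers from [transform_templates()].
#' @param substrates Character vector of substrate molecule SMILES.
#' @return Character vector of product SMILES.
#' @export
apply_template <- function(transform_id, substrates) {
  tpl <- .TEMPLATES[[transform_id]]
  if (is.null(tpl)) stop("unknown transform_id: ", transform_id, call. = FALSE)
  parsed <- lapply(substrates, parse_substrate)
  prod <- tpl$apply(parsed)
  if (is.null(prod)) {
    stop("template ", transform_id, " does not match substrates: ",
         paste(substrates, collapse = " + "), call. = FALSE)
  }
  prod
}

# Candidate products from every applicable template; named list
# transform_id -> product SMILES.
applicable_templates <- function(reactants) {
  parsed <- lapply(reactants, parse_substrate)
  out <- list()
  for (tpl in .TEMPLATES) {
    prod <- tpl$apply(parsed)
    if (!is.null(prod)) out[[tpl$id]] <- prod
  }
  out
}

# ---- generator configuration ----------------------------------------------

#' Default reaction-class table for the synthetic generator
#'
#' Ten classes spanning three top-level families, with sibling coupling
#' subclasses differing only in the leaving group (3.1.1/3.1.2/3.1.3), a
#' late-introduced amination class (3.2.1) whose popularity rises after
#' its introduction year, a Grignard single/double-addition pair
#' (1.1.1/1.2.1), and an uncategorized class "0.0". Popularity weights
#' interpolate linearly between `w_start` (first year) and `w_end`
#' (last year) and are zero before `intro_year`.
#'
#' @return A tibble with columns `class_code`, `transform_id`,
#'   `intro_year`, `w_start`, `w_end`.
#' @export
default_class_table <- function() {
  tibble::tribble(
    ~class_code, ~transform_id,       ~intro_year, ~w_start, ~w_end,
    "3.1.1",     "T_coupling_br",      -Inf,        0.20,     0.14,
    "3.1.2",     "T_coupling_cl",      -Inf,        0.05,     0.09,
    "3.1.3",     "T_coupling_i",       -Inf,        0.09,     0.03,
    "3.2.1",     "T_amination",        2010,        0.00,     0.22,
    "1.1.1",     "T_grignard_single",  -Inf,        0.16,     0.07,
    "1.2.1",     "T_grignard_double",  -Inf,        0.07,     0.12,
    "2.1.1",     "T_amide",            -Inf,        0.14,     0.10,
    "2.1.2",     "T_esterification",   -Inf,        0.09,     0.12,
    "2.2.1",     "T_ether",            -Inf,        0.08,     0.07,
    "0.0",       "T_oxidation",        -Inf,        0.07,     0.04
  )
}

#' Synthetic corpus generator configuration
#'
#' Describes the literature structure being emulated: author teams drawn
#' from labs writing multi-reaction documents, each document applying
#' (mostly) one transform to decorated variants of one substrate core
#' (a substrate-scope series), class popularity drifting across years and
#' new classes appearing at their introduction year.
#'
#' @param n_documents Number of documents.
#' @param authors_pool_size Total number of distinct authors.
#' @param n_labs Number of author communities; teams are drawn within a
#'   lab, with probability `p_cross_lab` of one cross-lab co-author.
#' @param team_size Integer range `c(min, max)` of authors per document.
#' @param reactions_per_document Integer range `c(min, max)`.
#' @param year_range Integer range `c(first, last)` of publication years.
#' @param class_table See [default_class_table()].
#' @param intra_document_same_class_prob Probability that a reaction uses
#'   its document's class (otherwise a fresh class is drawn from the
#'   year's popularity schedule).
#' @param author_specialization_prob Probability that a document's
#'   substrate core and decoration pool are drawn from its lab's
#'   preferred set (substrate-space specialization).
#' @param class_specialization_prob Probability that a document's class
#'   is drawn from its lab's preferred classes.
#' @param partner_vary_prob Probability that an individual reaction
#'   resamples its partner reagent instead of reusing the document's,
#'   widening the scope series.
#' @param n_pref_decorations Size of each lab's preferred decoration
#'   subset.
#' @param p_cross_lab Probability of a co-author from the lab's partner
#'   lab on a document; partner labs are fixed disjoint pairs, so
#'   co-authorship components merge at most lab pairs.
#' @param amino_alcohol_prob Probability that an acylation (2.1.x) or
#'   ether (2.2.1) reaction uses the bifunctional amino alcohol partner,
#'   which makes N- vs O-selectivity ambiguous from the reactants alone.
#' @param decorations Substituent set for the scope decoration slots.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A validated `rxn_generator_config`.
#' @export
generator_config <- function(n_documents = 600,
                             authors_pool_size = 180,
                             n_labs = 90,
                             team_size = c(1, 4),
                             reactions_per_document = c(6, 16),
                             year_range = c(1998, 2022),
                             class_table = default_class_table(),
                             intra_document_same_class_prob = 0.9,
                             author_specialization_prob = 0.85,
                             class_specialization_prob = 0.6,
                             partner_vary_prob = 0.5,
                             n_pref_decorations = 3,
                             p_cross_lab = 0.06,
                             amino_alcohol_prob = 0.35,
                             decorations = c("C", "CC", "CCC", "C(C)C",
                                             "CC(C)(C)C", "C(F)(F)F", "OC",
                                             "OCC", "N(C)C", "C#N", "CO"),
                             seed = 1) {
  cfg <- list(
    n_documents = as.integer(n_documents),
    authors_pool_size = as.integer(authors_pool_size),
    n_labs = as.integer(n_labs),
    team_size = as.integer(team_size),
    reactions_per_document = as.integer(reactions_per_document),
    year_range = as.integer(year_range),
    class_table = tibble::as_tibble(class_table),
    intra_document_same_class_prob = intra_document_same_class_prob,
    author_specialization_prob = author_specialization_prob,
    class_specialization_prob = class_specialization_prob,
    partner_vary_prob = partner_vary_prob,
    n_pref_decorations = as.integer(min(n_pref_decorations,
                                        length(decorations))),
    p_cross_lab = p_cross_lab,
    amino_alcohol_prob = amino_alcohol_prob,
    decorations = decorations,
    seed = as.integer(seed)
  )
  class(cfg) <- "rxn_generator_config"
  validate_generator_config(cfg)
  cfg
}

class_weights_at <- function(class_table, year, year_range) {
  frac <- if (year_range[2] > year_range[1]) {
    (year - year_range[1]) / (year_range[2] - year_range[1])
  } else 0
  w <- class_table$w_start + (class_table$w_end - class_table$w_start) * frac
  w[class_table$intro_year > year] <- 0
  pmax(w, 0)
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_documents > 0, cfg$authors_pool_size >= cfg$n_labs,
            length(cfg$year_range) == 2,
            cfg$year_range[1] <= cfg$year_range[2],
            all(cfg$class_table$w_start >= 0),
            all(cfg$class_table$w_end >= 0))
  unknown <- setdiff(cfg$class_table$transform_id, names(.TEMPLATES))
  if (length(unknown) > 0) {
    stop("unknown transform_id in class_table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (y in seq(cfg$year_range[1], cfg$year_range[2])) {
    if (sum(class_weights_at(cfg$class_table, y, cfg$year_range)) <= 0) {
      stop("no reaction class available in year ", y, call. = FALSE)
    }
  }
  invisible(cfg)
}

# ---- generation ------------------------------------------------------------

.sample_partner_context <- function(class_code, cfg) {
  amines <- c("NC", "NCC", "NCCC")
  alcohols <- c("OC", "OCC", "OCCC")
  grignards <- c("C[Mg]Br", "CC[Mg]Br", "CCC[Mg]Br")
  amino <- stats::runif(1) < cfg$amino_alcohol_prob
  switch(substr(class_code, 1, 3),
    "3.1" = {
      core <- sample(names(.CORES), 1)
      decs <- sample(cfg$decorations, 2, replace = TRUE)
      paste0("OB(O)", .CORES[[core]]$body(decs[1], decs[2]))
    },
    "3.2" = sample(amines, 1),
    "1.1" = ,
    "1.2" = sample(grignards, 1),
    "2.1" = {
      if (amino) "NCCO"
      else if (class_code == "2.1.1") sample(amines, 1)
      else sample(alcohols, 1)
    },
    "2.2" = if (amino) "NCCO" else sample(alcohols, 1),
    "0.0" = NA_character_,
    stop("no partner rule for class ", class_code, call. = FALSE)
  )
}

.substrate_prefix <- function(class_code) {
  switch(class_code,
    "3.1.1" = "Br", "3.1.2" = "Cl", "3.1.3" = "I", "3.2.1" = "Br",
    "1.1.1" = "COC(=O)", "1.2.1" = "COC(=O)",
    "2.1.1" = "O=C(Cl)", "2.1.2" = "O=C(Cl)",
    "2.2.1" = "F", "0.0" = "OC",
    stop("no substrate rule for class ", class_code, call. = FALSE)
  )
}

.class_agents <- function(class_code) {
  switch(substr(class_code, 1, 1),
    "3" = "[Pd]",
    "1" = "C1CCOC1",
    "2" = "CCN(CC)CC",
    "0" = "O=[Mn]=O",
    character(0)
  )
}

#' Generate a literature-structured synthetic reaction corpus
#'
#' Documents receive a year (uniform over the configured range), an
#' author team drawn from a lab community, and a reaction class sampled
#' from the year's popularity schedule (restricted to classes already
#' introduced); each document applies mostly one transform to decorated
#' variants of one substrate core, creating intra-document
#' substrate-scope similarity. Every record carries class code, transform
#' identifier, document, authors and year; generation is deterministic
#' given the config seed.
#'
#' @param config An [generator_config()] object.
#' @return An `rxn_corpus` (subclass `rxn_synthetic_corpus`) carrying the
#'   planted generative labels retrievable with [planted_truth()].
#' @export
generate_corpus <- function(config) {
  validate_generator_config(config)
  cfg <- config
  withr::with_seed(cfg$seed, {
    authors <- sprintf("A%03d", seq_len(cfg$authors_pool_size))
    lab_of <- rep_len(seq_len(cfg$n_labs), cfg$authors_pool_size)
    labs <- split(authors, lab_of)
    mean_w <- (cfg$class_table$w_start + cfg$class_table$w_end) / 2
    # each lab prefers one class from every top-level family (a balanced
    # research portfolio), drawn systematically in proportion to the
    # family-internal popularity, so the class mix of any subset of labs
    # tracks the global schedule
    top_level <- sub("\\..*$", "", cfg$class_table$class_code)
    pref_deck <- withr::with_seed(cfg$seed + 1L, {
      decks <- lapply(split(seq_len(nrow(cfg$class_table)), top_level),
                      function(ix) {
        if (length(ix) == 1 && cfg$class_table$class_code[ix] == "0.0") {
          return(NULL)  # uncategorized chemistry is nobody's specialty
        }
        share <- pmax(1, round(mean_w[ix] / sum(mean_w[ix]) * cfg$n_labs))
        rep_len(sample(rep(cfg$class_table$class_code[ix], share)),
                cfg$n_labs)
      })
      decks[!vapply(decks, is.null, logical(1))]
    })
    # globally unique signature series: each lab is dealt two composite
    # decorations from a shuffled deck, so no two labs study the same
    # substrate series
    deck <- expand.grid(p1 = cfg$decorations, p2 = cfg$decorations,
                        p3 = cfg$decorations, stringsAsFactors = FALSE)
    deck <- paste0("C(", deck$p1, ")(", deck$p2, ")", deck$p3)
    # small decoration sets cannot fill the deck; recycle (collisions are
    # then unavoidable and harmless for such configs)
    deck <- rep_len(sample(deck), 2 * cfg$n_labs)
    lab_prefs <- lapply(seq_len(cfg$n_labs), function(i) {
      list(
        classes = unique(vapply(pref_deck, `[[`, character(1), i)),
        cores = sample(names(.CORES), 2),
        decorations = sample(cfg$decorations, cfg$n_pref_decorations),
        composites = deck[c(2 * i - 1, 2 * i)]
      )
    })
    # disjoint partner-lab pairs bound cross-lab co-authorship components
    partner_lab <- seq_len(cfg$n_labs)
    if (cfg$n_labs > 1) {
      for (i in seq(1, cfg$n_labs - 1, by = 2)) {
        partner_lab[i] <- i + 1
        partner_lab[i + 1] <- i
      }
    }
    rows <- vector("list", cfg$n_documents)
    for (d in seq_len(cfg$n_documents)) {
      doc_id <- sprintf("D%04d", d)
      year <- sample(seq(cfg$year_range[1], cfg$year_range[2]), 1)
      lab <- sample(cfg$n_labs, 1)
      size <- sample(seq(cfg$team_size[1], cfg$team_size[2]), 1)
      team <- sample(labs[[lab]], min(size, length(labs[[lab]])))
      if (stats::runif(1) < cfg$p_cross_lab && partner_lab[lab] != lab) {
        team <- unique(c(team, sample(labs[[partner_lab[lab]]], 1)))
      }
      w <- class_weights_at(cfg$class_table, year, cfg$year_range)
      avail <- cfg$class_table$class_code[w > 0]
      doc_class <- NULL
      if (stats::runif(1) < cfg$class_specialization_prob) {
        prefs <- intersect(lab_prefs[[lab]]$classes, avail)
        if (length(prefs) > 0) doc_class <- sample(prefs, 1)
      }
      if (is.null(doc_class)) {
        doc_class <- sample(avail, 1, prob = w[w > 0])
      }
      specialized <- stats::runif(1) < cfg$author_specialization_prob
      doc_core <- if (specialized) sample(lab_prefs[[lab]]$cores, 1)
                  else sample(names(.CORES), 1)
      doc_decs <- if (specialized) lab_prefs[[lab]]$decorations
                  else cfg$decorations
      # the document's series decoration is a composite group; specialized
      # documents revisit one of the lab's signature series, so a lab's
      # documents cluster tightly in substrate space
      doc_A <- if (specialized) sample(lab_prefs[[lab]]$composites, 1)
               else paste0("C(", sample(cfg$decorations, 1), ")(",
                           sample(cfg$decorations, 1), ")",
                           sample(cfg$decorations, 1))
      doc_partner <- .sample_partner_context(doc_class, cfg)
      n_rxn <- sample(seq(cfg$reactions_per_document[1],
                          cfg$reactions_per_document[2]), 1)
      seen <- character(0)
      doc_rows <- vector("list", n_rxn)
      for (j in seq_len(n_rxn)) {
        if (stats::runif(1) < cfg$intra_document_same_class_prob) {
          cls <- doc_class
          # a scope series varies commodity reagents (amines, alcohols,
          # Grignards) freely; an aryl coupling partner keeps its identity
          # (core and series decoration), varying only its scope slot
          partner <- if (stats::runif(1) < cfg$partner_vary_prob) {
            if (startsWith(cls, "3.1")) {
              pp <- parse_substrate(doc_partner)
              paste0("OB(O)", .CORES[[pp$core]]$body(
                pp$A, sample(doc_decs, 1)))
            } else .sample_partner_context(cls, cfg)
          } else doc_partner
          core <- doc_core; A <- doc_A
        } else {
          # an off-series reaction: its own class AND substrate context
          cls <- sample(avail, 1, prob = w[w > 0])
          partner <- .sample_partner_context(cls, cfg)
          core <- sample(names(.CORES), 1)
          A <- paste0("C(", sample(cfg$decorations, 1), ")(",
                      sample(cfg$decorations, 1), ")",
                      sample(cfg$decorations, 1))
        }
        B <- sample(doc_decs, 1)
        key <- paste(cls, partner, core, A, B, sep = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        substrate <- paste0(.substrate_prefix(cls),
                            .CORES[[core]]$body(A, B))
        reactants <- c(substrate, if (!is.na(partner)) partner)
        tid <- cfg$class_table$transform_id[cfg$class_table$class_code == cls]
        products <- apply_template(tid, reactants)
        doc_rows[[j]] <- list(
          reactants = reactants, agents = .class_agents(cls),
          products = products, doc_id = doc_id, authors = team,
          year = year, class_code = cls, transform = tid,
          core = core, A = A, B = B
        )
      }
      rows[[d]] <- doc_rows[!vapply(doc_rows, is.null, logical(1))]
    }
    rows <- unlist(rows, recursive = FALSE)
    pull_chr <- function(f) vapply(rows, function(x) x[[f]], character(1))
    records <- tibble::tibble(
      record_id = sprintf("r%05d", seq_along(rows)),
      reactants = lapply(rows, `[[`, "reactants"),
      agents = lapply(rows, `[[`, "agents"),
      products = lapply(rows, `[[`, "products"),
      doc_id = pull_chr("doc_id"),
      authors = lapply(rows, `[[`, "authors"),
      year = vapply(rows, function(x) x$year, numeric(1)),
      class_code = pull_chr("class_code"),
      transform = pull_chr("transform")
    )
    planted <- tibble::tibble(
      record_id = records$record_id,
      class_code = records$class_code,
      transform_id = records$transform,
      doc_id = records$doc_id,
      authors = records$authors,
      year = as.integer(records$year),
      core = pull_chr("core"), A = pull_chr("A"), B = pull_chr("B")
    )
    corpus <- rxn_corpus(records)
    class(corpus) <- c("rxn_synthetic_corpus", class(corpus))
    attr(corpus, "planted") <- planted
    attr(corpus, "generator_config") <- cfg
    corpus
  })
}

#' Planted generative ground truth of a synthetic corpus
#'
#' @param corpus A corpus produced by [generate_corpus()].
#' @return A tibble of the generative labels (class, transform, document,
#'   authors, year, substrate core and decorations) per record.
#' @export
planted_truth <- function(corpus) {
  planted <- attr(corpus, "planted")
  if (!inherits(corpus, "rxn_synthetic_corpus") || is.null(planted)) {
    stop("not a corpus produced by generate_corpus()", call. = FALSE)
  }
  planted
}
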