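test_that("template application is deterministic and rejects non-matches", {
  s <- c("Brc1c(C)cc(CC)cc1", "OB(O)c1c(OC)cc(C)cc1")
  p1 <- apply_template("T_coupling_br", s)
  p2 <- apply_template("T_coupling_br", s)
  expect_identical(p1, p2)
  expect_identical(canonical_smiles(p1), canonical_smiles(p1))
  # hand-derived rewrite for one fixture pair
  expect_identical(
    canonical_smiles(apply_template("T_coupling_br",
                                    c("Brc1c(C)cc(CC)cc1",
                                      "OB(O)c1c(OC)cc(C)cc1"))),
    canonical_smiles("c1(-c2c(OC)cc(C)cc2)c(C)cc(CC)cc1"))
  expect_error(apply_template("T_coupling_br", c("CCO", "CC")),
               "does not match")
  expect_error(apply_template("T_nope", "CCO"), "unknown transform")
})

test_that("two single additions compose to the double addition", {
  es <- "COC(=O)c1c(OC)cc(C#N)s1"
  g <- "C[Mg]Br"
  step1 <- apply_template("T_grignard_single", c(es, g))
  step2 <- apply_template("T_grignard_single", c(step1, g))
  direct <- apply_template("T_grignard_double", c(es, g))
  expect_identical(canonical_smiles(step2), canonical_smiles(direct))
})

test_that("generated corpora satisfy corpus invariants without repair", {
  corp <- generate_corpus(generator_config(
    n_documents = 40, decorations = c("C", "CC", "OC", "C#N"), seed = 13))
  expect_silent(validate_corpus(corp))
  r <- corpus_records(corp)
  expect_true(all(lengths(r$products) > 0))
  expect_true(all(lengths(r$authors) > 0))
  # determinism given seed
  corp2 <- generate_corpus(generator_config(
    n_documents = 40, decorations = c("C", "CC", "OC", "C#N"), seed = 13))
  expect_identical(corpus_records(corp), corpus_records(corp2))
})

test_that("classes never appear before their introduction year", {
  tab <- default_class_table()
  tab$intro_year[tab$class_code == "3.2.1"] <- 2015
  corp <- generate_corpus(generator_config(
    n_documents = 80, class_table = tab,
    decorations = c("C", "CC", "OC"), seed = 3))
  r <- corpus_records(corp)
  expect_true(all(r$year[r$class_code == "3.2.1"] >= 2015))
  expect_gt(sum(r$class_code == "3.2.1"), 0)
  # infeasible config: no class available in the first year
  tab2 <- default_class_table()
  tab2$intro_year <- 2015
  expect_error(generator_config(n_documents = 10, class_table = tab2),
               "no reaction class available")
})

test_that("intra-document same-class probability one gives single-class documents", {
  corp <- generate_corpus(generator_config(
    n_documents = 50, intra_document_same_class_prob = 1,
    decorations = c("C", "CC", "OC"), seed = 8))
  r <- corpus_records(corp)
  per_doc <- tapply(r$class_code, r$doc_id, function(x) length(unique(x)))
  expect_true(all(per_doc == 1))
})

test_that("per-year class frequencies track the configured schedule", {
  # specialization off so the marginal law equals the schedule
  cfg <- generator_config(
    n_documents = 900, author_specialization_prob = 0,
    class_specialization_prob = 0, intra_document_same_class_prob = 1,
    decorations = c("C", "CC", "OC"), seed = 101)
  corp <- generate_corpus(cfg)
  pl <- planted_truth(corp)
  doc <- pl[!duplicated(pl$doc_id), ]  # class is drawn once per document
  for (y in c(2000, 2010, 2020)) {
    window <- (y - 2):(y + 2)
    sub <- doc[doc$year %in% window, ]
    p_by_year <- vapply(window, function(yy) {
      w <- class_weights_at(cfg$class_table, yy, cfg$year_range)
      w / sum(w)
    }, numeric(nrow(cfg$class_table)))
    p <- stats::setNames(rowMeans(p_by_year), cfg$class_table$class_code)
    p <- p[p > 0]  # classes not yet introduced have zero mass
    obs <- table(factor(sub$class_code, levels = names(p)))
    # multinomial goodness of fit against the configured schedule
    gof <- withr::with_seed(500 + y, suppressWarnings(
      stats::chisq.test(obs, p = p, rescale.p = TRUE,
                        simulate.p.value = TRUE, B = 4000)))
    expect_gt(gof$p.value, 0.001, label = paste("window", y))
  }
  # rising-adoption class share is nondecreasing across year bins
  late <- pl$class_code == "3.2.1"
  bins <- cut(pl$year, breaks = c(2009, 2014, 2018, 2022))
  share <- tapply(late[pl$year > 2009], bins[pl$year > 2009], mean)
  expect_true(all(diff(share) > -0.05))
})

test_that("planted truth matches the corpus and rejects foreign corpora", {
  corp <- generate_corpus(generator_config(
    n_documents = 30, decorations = c("C", "CC", "OC"), seed = 2))
  pl <- planted_truth(corp)
  r <- corpus_records(corp)
  expect_setequal(pl$record_id, r$record_id)
  expect_identical(pl$class_code, r$class_code)
  expect_identical(pl$transform_id, r$transform)
  # class/transform pairing agrees with the configured table
  cfg_tab <- default_class_table()
  expect_identical(
    pl$transform_id,
    cfg_tab$transform_id[match(pl$class_code, cfg_tab$class_code)])
  expect_error(planted_truth(tiny_corpus()), "generate_corpus")
})

test_that("documents are substrate-scope series: intra-document reactions are closer", {
  corp <- small_gen_corpus(seed = 23, n_documents = 30)
  r <- corpus_records(corp)
  docs <- withr::with_seed(6, sample(unique(r$doc_id), 12))
  fps <- lapply(seq_len(nrow(r)), function(i)
    reactant_fingerprint(r$reactants[[i]]))
  dist <- function(i, j) {
    x <- fps[[i]]; y <- fps[[j]]
    keys <- union(names(x), names(y))
    vx <- stats::setNames(numeric(length(keys)), keys); vx[names(x)] <- x
    vy <- stats::setNames(numeric(length(keys)), keys); vy[names(y)] <- y
    1 - sum(vx * vy) / sqrt(sum(vx^2) * sum(vy^2))
  }
  intra <- c(); inter <- c()
  withr::with_seed(5, {
    for (d in docs) {
      in_doc <- which(r$doc_id == d)
      out_doc <- sample(which(r$doc_id != d), 4)
      if (length(in_doc) < 2) next
      pair <- sample(in_doc, 2)
      intra <- c(intra, dist(pair[1], pair[2]))
      inter <- c(inter, vapply(out_doc, dist, numeric(1), i = pair[1]))
    }
  })
  expect_lt(mean(intra), mean(inter))
})
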