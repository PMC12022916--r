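# Fixtures are built in code. Molecules come from the package's own
# substrate grammar so the process-level canonicalization cache is shared
# across test files.

# A small handcrafted corpus: 4 documents, known authors/years/classes.
tiny_corpus <- function() {
  mk <- function(id, reactants, products, doc, authors, year, class,
                 transform = NA_character_, agents = character(0)) {
    tibble::tibble(
      record_id = id, reactants = list(reactants), agents = list(agents),
      products = list(products), doc_id = doc, authors = list(authors),
      year = year, class_code = class, transform = transform
    )
  }
  rows <- dplyr::bind_rows(
    mk("r1", c("Brc1c(C)cc(CC)cc1", "OB(O)c1c(OC)cc(C)cc1"),
       apply_template("T_coupling_br",
                      c("Brc1c(C)cc(CC)cc1", "OB(O)c1c(OC)cc(C)cc1")),
       "D1", c("Ada", "Bob"), 1999L, "3.1.1", "T_coupling_br", "[Pd]"),
    mk("r2", c("Brc1c(C)cc(OC)cc1", "OB(O)c1c(OC)cc(C)cc1"),
       apply_template("T_coupling_br",
                      c("Brc1c(C)cc(OC)cc1", "OB(O)c1c(OC)cc(C)cc1")),
       "D1", c("Ada", "Bob"), 1999L, "3.1.1", "T_coupling_br", "[Pd]"),
    mk("r3", c("COC(=O)c1c(C)cc(CC)cc1", "CC[Mg]Br"),
       apply_template("T_grignard_single",
                      c("COC(=O)c1c(C)cc(CC)cc1", "CC[Mg]Br")),
       "D2", c("Bob", "Cid"), 2003L, "1.1.1", "T_grignard_single"),
    mk("r4", c("COC(=O)c1c(C)cc(OC)cc1", "CC[Mg]Br"),
       apply_template("T_grignard_double",
                      c("COC(=O)c1c(C)cc(OC)cc1", "CC[Mg]Br")),
       "D2", c("Bob", "Cid"), 2003L, "1.2.1", "T_grignard_double"),
    mk("r5", c("O=C(Cl)c1c(CC)cc(C)cc1", "NCC"),
       apply_template("T_amide", c("O=C(Cl)c1c(CC)cc(C)cc1", "NCC")),
       "D3", "Dee", 2010L, "2.1.1", "T_amide"),
    mk("r6", c("O=C(Cl)c1c(CC)cc(OC)cc1", "OCC"),
       apply_template("T_esterification",
                      c("O=C(Cl)c1c(CC)cc(OC)cc1", "OCC")),
       "D3", "Dee", 2010L, "2.1.2", "T_esterification"),
    mk("r7", "OCc1c(C)cc(C#N)cc1",
       apply_template("T_oxidation", "OCc1c(C)cc(C#N)cc1"),
       "D4", c("Eve", "Fay"), 2015L, "0.0", "T_oxidation"),
    mk("r8", c("Fc1c(C)cc(CC)cc1", "OCC"),
       apply_template("T_ether", c("Fc1c(C)cc(CC)cc1", "OCC")),
       "D4", c("Eve", "Fay"), 2015L, "2.2.1", "T_ether")
  )
  rxn_corpus(rows)
}

# Small generated corpus for split tests; restricted decorations keep the
# molecule universe (and hence canonicalization work) small.
small_gen_corpus <- function(seed = 42, n_documents = 60, ...) {
  deduplicate(generate_corpus(generator_config(
    n_documents = n_documents,
    decorations = c("C", "CC", "OC", "C#N", "N(C)C"),
    seed = seed, ...
  )))
}

# Grignard-ester fixture family: single-addition training corpus plus
# double-addition test records whose truths are the twofold adduct.
grignard_fixture <- function() {
  decs <- c("C", "CC", "CCC", "OC", "C#N", "N(C)C")
  esters <- paste0("COC(=O)c1c(", decs, ")cc(C)cc1")
  g <- "CC[Mg]Br"
  train <- dplyr::bind_rows(lapply(seq_along(esters), function(i) {
    tibble::tibble(
      record_id = sprintf("tr%02d", i),
      reactants = list(c(esters[i], g)), agents = list("C1CCOC1"),
      products = list(apply_template("T_grignard_single", c(esters[i], g))),
      doc_id = sprintf("DT%02d", i), authors = list(sprintf("Auth%02d", i)),
      year = 2005L, class_code = "1.1.1", transform = "T_grignard_single"
    )
  }))
  test_esters <- paste0("COC(=O)c1c(", decs, ")cc(OC)cc1")
  test <- dplyr::bind_rows(lapply(seq_along(test_esters), function(i) {
    tibble::tibble(
      record_id = sprintf("te%02d", i),
      reactants = list(c(test_esters[i], g)), agents = list("C1CCOC1"),
      products = list(apply_template("T_grignard_double", c(test_esters[i], g))),
      doc_id = sprintf("DU%02d", i), authors = list(sprintf("Buth%02d", i)),
      year = 2010L, class_code = "1.2.1", transform = "T_grignard_double"
    )
  }))
  rxn_corpus(dplyr::bind_rows(train, test))
}
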