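test_that("textbook ATP hydrolysis is balanced, element and charge", {
  m <- fixture_core_energy()
  b <- check_mass_balance(m, "ATPM")
  expect_equal(b$status, "balanced")
  expect_equal(b$charge_delta, 0)
})

test_that("structure-unknown participants make balance undetermined", {
  m <- toy_chain_model()
  b <- check_mass_balance(m, "R_UNK")
  expect_equal(b$status, "undetermined")
  expect_null(b$delta[[1]])
})

test_that("element deltas are reported for unbalanced reactions", {
  m <- toy_chain_model()
  b <- check_mass_balance(m, "R_AB")   # CH4 -> CH2
  expect_equal(b$status, "unbalanced")
  expect_equal(b$delta[[1]], c(H = -2))
})

test_that("charge-only imbalance is unbalanced, and optional", {
  mets <- dplyr::bind_rows(met_row("X[c]", "C2", 0L), met_row("Y[c]", "C2", -1L))
  m <- flux_model(mets,
                  tibble::tibble(id = "R", direction = "forward"),
                  tibble::tibble(reaction_id = c("R", "R"),
                                 metabolite_id = c("X[c]", "Y[c]"),
                                 coef = c(-1, 1)))
  expect_equal(check_mass_balance(m, "R")$status, "unbalanced")
  expect_equal(check_mass_balance(m, "R", check_charge = FALSE)$status,
               "balanced")
})

test_that("unknown metabolite references are a referential-integrity error", {
  mets <- met_row("A[c]", "C")
  expect_error(
    flux_model(mets, tibble::tibble(id = "R", direction = "forward"),
               tibble::tibble(reaction_id = "R", metabolite_id = "ghost[c]",
                              coef = -1)),
    "unknown metabolite")
})

test_that("normalization yields minimal whole-integer stoichiometry", {
  mets <- dplyr::bind_rows(met_row("A[c]", "C"), met_row("B[c]", "C"),
                           met_row("C2[c]", "C2"))
  build <- function(co) {
    flux_model(mets, tibble::tibble(id = "R", direction = "forward"),
               tibble::tibble(reaction_id = rep("R", 3),
                              metabolite_id = c("A[c]", "B[c]", "C2[c]"),
                              coef = co))
  }
  # common factor removed
  m1 <- normalize_stoichiometry(build(c(-2, -2, 2)))
  expect_equal(sort(m1$stoich$coef), c(-1, -1, 1))
  # fractional coefficients cleared by the LCM of denominators
  m2 <- normalize_stoichiometry(build(c(-1, -1.5, 1)))
  expect_equal(sort(m2$stoich$coef), c(-3, -2, 2))
  # input untouched
  m0 <- build(c(-2, -2, 2))
  invisible(normalize_stoichiometry(m0))
  expect_equal(sort(m0$stoich$coef), c(-2, -2, 2))
})

test_that("half-molecule oxygen conventions normalize to whole molecules", {
  m <- fixture_core_energy("ijo")
  n <- normalize_stoichiometry(m, "CYTOCHROME-BO-OXIDASE")
  st <- n$stoich[n$stoich$reaction_id == "CYTOCHROME-BO-OXIDASE", ]
  o2 <- st$coef[st$metabolite_id == "o2[c]"]
  qh2 <- st$coef[st$metabolite_id == "q8h2[c]"]
  expect_equal(o2, -1)
  expect_equal(qh2, -2)
})

test_that("normalization never changes balance status", {
  m <- fixture_fermentation()
  before <- check_mass_balance(m)
  after <- check_mass_balance(normalize_stoichiometry(m))
  expect_equal(after$status, before$status)
  # and an arbitrary rational rescale of one reaction is undone
  m2 <- m
  i <- m2$stoich$reaction_id == "CITSYN-RXN"
  m2$stoich$coef[i] <- m2$stoich$coef[i] * 2.5
  expect_equal(check_mass_balance(m2, "CITSYN-RXN")$status, "balanced")
})

test_that("complex knockouts disable, isozymes and redundant units rescue", {
  m <- toy_gpr_model()
  # either subunit of an obligate two-gene complex kills the reaction
  expect_true("R_COMPLEX" %in% gene_disabled_reactions(m, "pyrI"))
  expect_true("R_COMPLEX" %in% gene_disabled_reactions(m, "pyrB"))
  # the complex-only member of a redundant association is ineffective
  expect_false("R_REDUNDANT" %in% gene_disabled_reactions(m, "entD"))
  # but removing a gene present in the complex and its own unit disables
  # only when every unit is hit
  expect_false("R_REDUNDANT" %in% gene_disabled_reactions(m, c("entD", "entE")))
  expect_true("R_REDUNDANT" %in%
                gene_disabled_reactions(m, c("entE", "entF", "entG")))
})

test_that("substrate suppliers disable only without an alternative", {
  m <- toy_gpr_model()
  d <- gene_disabled_reactions(m, "acpP")
  expect_true("R_CARRIER" %in% d)     # sole supplier
  expect_false("R_CARRIER2" %in% d)   # acpQ still supplies
  expect_true("R_CARRIER2" %in% gene_disabled_reactions(m, c("acpP", "acpQ")))
})

test_that("unknown knockout genes warn and disable nothing", {
  m <- toy_gpr_model()
  expect_warning(d <- gene_disabled_reactions(m, "ghost"), "ghost")
  expect_length(d, 0)
})

test_that("gene disabling is monotone in the knockout set", {
  m <- fixture_fermentation()
  genes <- model_genes(m)
  set.seed(7)
  for (i in 1:20) {
    k1 <- sample(genes, sample(1:4, 1))
    k2 <- union(k1, sample(genes, sample(1:4, 1)))
    d1 <- gene_disabled_reactions(m, k1)
    d2 <- gene_disabled_reactions(m, k2)
    expect_true(all(d1 %in% d2))
  }
})

test_that("every subunit of a single-unit complex is disabling (n <= 4)", {
  # brute-force truth table: a unit survives iff some gene remains
  for (n in 1:4) {
    genes <- paste0("g", seq_len(n))
    mets <- dplyr::bind_rows(met_row("S[c]", "C"), met_row("P[c]", "C"))
    m <- flux_model(
      mets, tibble::tibble(id = "R", direction = "forward"),
      tibble::tibble(reaction_id = c("R", "R"),
                     metabolite_id = c("S[c]", "P[c]"), coef = c(-1, 1)),
      gpr = tibble::tibble(reaction_id = "R", unit = 1L, gene = genes))
    for (g in genes) {
      expect_true("R" %in% gene_disabled_reactions(m, g))
    }
    # and the full subset lattice agrees with the truth-table oracle
    subsets <- unlist(lapply(seq_len(n), function(k)
      utils::combn(genes, k, simplify = FALSE)), recursive = FALSE)
    for (K in subsets) {
      oracle_dead <- length(intersect(genes, K)) > 0    # unit intersected?
      expect_equal("R" %in% gene_disabled_reactions(m, K), oracle_dead)
    }
  }
})
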