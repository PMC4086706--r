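base_media_tbl <- function() {
  metabolite_set(
    c("glc__D[p]", "o2[c]", "nh4[p]", "pi[c]", "so4[p]", "fe3[p]", "h2o[c]"),
    coef = c(10, NA, NA, NA, NA, NA, NA),
    role = c("C", NA, "N", "P", "S", NA, NA))
}

test_that("media construction swaps exactly the varied element role", {
  base <- base_media_tbl()
  med <- build_media_nutrients(base, "succ", "C")
  expect_false("glc__D[p]" %in% med$metabolite_id)
  expect_true("succ[p]" %in% med$metabolite_id)
  # N/P/S sources untouched
  expect_true(all(c("nh4[c]", "pi[c]", "so4[p]") %in% med$metabolite_id))
  # element-role exclusivity: one source per role after the swap
  for (r in c("C", "N", "P", "S")) {
    expect_equal(sum(med$role == r, na.rm = TRUE), 1L)
  }
})

test_that("self-replacement reproduces the base media", {
  base <- base_media_tbl()
  med <- build_media_nutrients(base, "glc__D[p]", "C")
  norm <- function(x) sort(x$metabolite_id)
  ref <- build_media_nutrients(base, "succ", "C")
  expect_setequal(setdiff(norm(med), "glc__D[p]"),
                  setdiff(norm(ref), "succ[p]"))
  expect_true("glc__D[p]" %in% med$metabolite_id)
})

test_that("sulfur wells drop sulfate; ferric iron becomes ferrous; ammonium is cytosolic", {
  base <- base_media_tbl()
  med <- build_media_nutrients(base, "cystine", "S")
  expect_false("so4[p]" %in% med$metabolite_id)
  expect_true("cystine[p]" %in% med$metabolite_id)
  expect_true("fe2[p]" %in% med$metabolite_id)
  expect_false("fe3[p]" %in% med$metabolite_id)
  expect_true("nh4[c]" %in% med$metabolite_id)
})

test_that("MOPS, when present, is flagged usable as a sulfur source", {
  base <- dplyr::bind_rows(base_media_tbl(),
                           metabolite_set("mops[p]", role = NA))
  med_c <- build_media_nutrients(base, "succ", "C")
  expect_equal(med_c$role[med_c$metabolite_id == "mops[p]"], "S")
  # on a sulfur plate both the base sulfur source and MOPS are removed
  med_s <- build_media_nutrients(base, "cystine", "S")
  expect_false("mops[p]" %in% med_s$metabolite_id)
})

test_that("consensus scoring combines normal/low and requires unanimity", {
  expect_equal(pm_consensus(c("normal", "low", "low", "normal")), "positive")
  expect_equal(pm_consensus(c("none", "none", "none", "none")), "negative")
  expect_equal(pm_consensus(c("normal", "none", "low", "none")), "no-consensus")
  # permutation invariance
  set.seed(3)
  sc <- c("normal", "none", "low", "none")
  for (i in 1:5) expect_equal(pm_consensus(sample(sc)), "no-consensus")
  # adding an agreeing dataset never flips a consensus
  expect_equal(pm_consensus(c("low", "low", "normal")), "positive")
  expect_equal(pm_consensus(c("low", "low", "normal", "low")), "positive")
  # majority policy is available as the alternative reading
  expect_equal(pm_consensus(c("normal", "normal", "none"), policy = "majority"),
               "positive")
  expect_equal(pm_consensus(c("normal", "none"), policy = "majority"),
               "no-consensus")
})

test_that("anaerobic adjustment changes exactly three things and is idempotent", {
  net <- growth_network_with_anaerobic_members()
  an <- apply_anaerobic_mods(net)
  # (1) oxygen closed
  expect_equal(an$reactions$ub[an$reactions$id == "UPTAKE[o2[c]]"], 0)
  # (2) formate-hydrogen lyase enabled
  expect_equal(an$reactions$ub[an$reactions$id == "FHL-RXN"], Inf)
  # (3) the two biomass members removed
  st <- an$stoich[an$stoich$reaction_id == "BIOMASS", ]
  expect_false(any(c("pheme[c]", "pydx5p[c]") %in% st$metabolite_id))
  # structural diff: nothing else moved
  rx_a <- an$reactions[!an$reactions$id %in% c("UPTAKE[o2[c]]", "FHL-RXN"), ]
  rx_b <- net$reactions[!net$reactions$id %in% c("UPTAKE[o2[c]]", "FHL-RXN"), ]
  expect_equal(rx_a, rx_b)
  st_a <- an$stoich[an$stoich$reaction_id != "BIOMASS", ]
  st_b <- net$stoich[net$stoich$reaction_id != "BIOMASS", ]
  expect_equal(st_a, st_b)
  bio_a <- an$stoich[an$stoich$reaction_id == "BIOMASS", ]
  bio_b <- net$stoich[net$stoich$reaction_id == "BIOMASS", ]
  expect_equal(bio_a,
               bio_b[!bio_b$metabolite_id %in% c("pheme[c]", "pydx5p[c]"), ])
  # idempotence
  an2 <- apply_anaerobic_mods(an)
  expect_equal(an2$reactions, an$reactions)
  expect_equal(an2$stoich, an$stoich)
  # members absent from the biomass are a logged no-op
  plain <- fixture_growth_network()
  an3 <- apply_anaerobic_mods(plain)
  expect_true(any(grepl("no-op", attr(an3, "anaerobic_log"))))
})

test_that("the anaerobic network grows, and FHL relief is monotone", {
  an <- apply_anaerobic_mods(fixture_growth_network())
  mu_fhl <- solve_fba(an)$objective_value
  expect_gt(mu_fhl, 1e-6)
  no_fhl <- set_bounds(an, "FHL-RXN", ub = 0)
  mu_plain <- solve_fba(no_fhl)$objective_value
  expect_gte(mu_fhl, mu_plain - 1e-9)
})

test_that("pm_screen scores consensus wells against growth predictions", {
  net <- fixture_growth_network()
  # ground truth from the model itself: glucose supports growth, pyruvate
  # and succinate do not (no gluconeogenesis), an unknown compound cannot
  truth <- tibble::tibble(
    well = c("A01", "A02", "A03", "A04"),
    nutrient_id = c("glc__D[p]", "pyr[p]", "succ[p]", "mystery[p]"),
    role = "C",
    truth = c("positive", "negative", "negative", "negative"))
  wells <- generate_pm_dataset(truth, n_datasets = 4, disagreement = 0,
                               seed = 5)
  res <- suppressWarnings(
    pm_screen(net, wells, base = base_media_tbl(), aerobic = TRUE))
  expect_equal(res$stats$accuracy, 100.0)
  expect_equal(res$stats$tp, 1)
  expect_equal(res$stats$tn, 3)
  expect_length(res$no_consensus, 0)
  # an injected conflict is excluded, not scored
  wells2 <- wells
  wells2$score[wells2$well == "A01" & wells2$dataset == 1] <- "none"
  res2 <- suppressWarnings(
    pm_screen(net, wells2, base = base_media_tbl(), aerobic = TRUE))
  expect_equal(res2$no_consensus, "A01")
  expect_equal(res2$stats$total, 3)
})

test_that("nutrient-utilization accuracy matches the reported tables", {
  aero <- confusion_stats(137, 15, 46, 115)
  expect_equal(aero$accuracy, 80.5)
  anaero <- confusion_stats(35, 14, 8, 39)
  expect_equal(anaero$accuracy, 77.1)
  conv <- confusion_stats(17, 0, 0, 5)
  expect_equal(conv$accuracy, 100.0)
  overall <- confusion_stats(137 + 35 + 17, 15 + 14 + 0, 46 + 8 + 0,
                             115 + 39 + 5)
  expect_equal(overall$accuracy, 80.7)
  expect_equal(overall$total, 431)
  expect_equal(overall$correct, 348)
})
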