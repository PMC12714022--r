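test_that("ARI run selection finds the first stable window and its best k", {
  sweep <- tibble::tibble(k = 4:10,
                          ari = c(0.5, 0.7, 0.7, 0.8, 0.66, 0.7, 0.4))
  sel <- select_k_by_ari(sweep, threshold = 0.65, window = 5)
  expect_equal(sel$range_k, 5:9)
  expect_equal(sel$chosen_k, 7)

  # constant sweep: whole range qualifies, tie goes to the smallest k
  flat <- tibble::tibble(k = 2:8, ari = 0.9)
  sel_flat <- select_k_by_ari(flat, window = 4)
  expect_equal(sel_flat$range_k, 2:8)
  expect_equal(sel_flat$chosen_k, 2)
})

test_that("selection fails explicitly when no run qualifies", {
  sweep <- tibble::tibble(k = 2:9, ari = rep(0.4, 8))
  expect_error(select_k_by_ari(sweep), class = "plastispot_no_stable_range")
  expect_error(select_k_by_ari(tibble::tibble(k = 1:3, ari = rep(0.9, 3)),
                               window = 5), "at least")
  expect_error(select_k_by_ari(tibble::tibble(k = c(2, 2, 3, 4, 5),
                                              ari = rep(0.9, 5))),
               "strictly increasing")
  expect_error(select_k_by_ari(tibble::tibble(k = 1:5,
                                              ari = c(2, 0.9, 0.9, 0.9, 0.9))),
               "\\[-1, 1\\]")
})

test_that("selection is invariant to candidates after the qualifying run", {
  base <- tibble::tibble(k = 4:10,
                         ari = c(0.5, 0.7, 0.7, 0.8, 0.66, 0.7, 0.4))
  extended <- dplyr::bind_rows(base,
                               tibble::tibble(k = 11:15,
                                              ari = c(0.9, 0.9, 0.9, 0.9,
                                                      0.95)))
  s1 <- select_k_by_ari(base)
  s2 <- select_k_by_ari(extended)
  expect_equal(s1$chosen_k, s2$chosen_k)
  expect_equal(s1$range_k, s2$range_k)
})

test_that("regional plasticity averages spot scores and ranks descending", {
  labels <- tibble::tibble(spot_id = sprintf("s%d", 1:6),
                           subdomain = rep(c("d1", "d2", "d3"), each = 2))
  scores <- tibble::tibble(spot_id = sprintf("s%d", 1:6),
                           plasticity = c(0.2, 0.4, 0.8, 0.8, 0.35, 0.45))
  rp <- regional_plasticity(labels, scores)
  expect_equal(rp$regional_plasticity[rp$subdomain == "d1"], 0.3)
  expect_equal(rp$subdomain[rp$rank == 1], "d2")
  expect_equal(rp$subdomain[rp$rank == 3], "d1")

  # equal scores: tie broken by sub-domain id ascending
  tied <- tibble::tibble(spot_id = sprintf("s%d", 1:4),
                         plasticity = rep(0.5, 4))
  lab2 <- tibble::tibble(spot_id = sprintf("s%d", 1:4),
                         subdomain = rep(c("zeta", "alpha"), each = 2))
  rp2 <- regional_plasticity(lab2, tied)
  expect_equal(rp2$subdomain, c("alpha", "zeta"))

  expect_error(regional_plasticity(labels, scores[1:3, ]), "plasticity score")
  lab3 <- dplyr::mutate(labels,
                        subdomain = factor(subdomain,
                                           levels = c("d1", "d2", "d3",
                                                      "empty")))
  expect_error(regional_plasticity(lab3, scores), "Empty")
})

test_that("ranking is invariant to order-preserving score transforms", {
  set.seed(8)
  labels <- tibble::tibble(spot_id = sprintf("s%d", 1:30),
                           subdomain = sample(c("a", "b", "c"), 30,
                                              replace = TRUE))
  scores <- tibble::tibble(spot_id = labels$spot_id,
                           plasticity = runif(30))
  r1 <- regional_plasticity(labels, scores)
  # affine transforms preserve mean ordering
  r2 <- regional_plasticity(
    labels, dplyr::mutate(scores, plasticity = 3 * plasticity + 2))
  expect_equal(r1$subdomain[order(r1$rank)], r2$subdomain[order(r2$rank)])
})

test_that("composition summary walks the cumulative-with-floor rule", {
  lab <- tibble::tibble(spot_id = sprintf("s%02d", 1:20), subdomain = "d1")
  dom <- tibble::tibble(spot_id = lab$spot_id,
                        dominant_type = rep(c("A", "B", "C", "D"),
                                            c(10, 6, 3, 1)))
  cs <- composition_summary(lab, dom)
  expect_equal(cs$fraction, c(0.50, 0.30, 0.15, 0.05))
  expect_equal(cs$included, c(TRUE, TRUE, TRUE, FALSE))

  # single dominant type
  dom1 <- dplyr::mutate(dom, dominant_type = "A")
  cs1 <- composition_summary(lab, dom1)
  expect_equal(cs1$included, TRUE)

  # heavy head with an ineligible tail: inclusion stops below the target
  lab2 <- tibble::tibble(spot_id = sprintf("t%02d", 1:40), subdomain = "d1")
  dom2 <- tibble::tibble(spot_id = lab2$spot_id,
                         dominant_type = rep(c("A", paste0("x", 1:6)),
                                             c(34, rep(1, 6))))
  cs2 <- composition_summary(lab2, dom2)
  expect_equal(cs2$cell_type[cs2$included], "A")

  # removing both thresholds returns the full composition
  cs_all <- composition_summary(lab, dom, cum_threshold = 1, min_frac = 0)
  expect_true(all(cs_all$included))
  expect_lte(sum(cs$fraction[cs$included]), 1)
  expect_true(all(cs$fraction[cs$included] >= 0.05))
})

test_that("the alternative accumulate-first ordering is selectable", {
  lab <- tibble::tibble(spot_id = sprintf("s%02d", 1:20), subdomain = "d1")
  dom <- tibble::tibble(spot_id = lab$spot_id,
                        dominant_type = rep(c("A", "B", "C", "D"),
                                            c(10, 6, 3, 1)))
  cs <- composition_summary(lab, dom, rule_order = "accumulate_first")
  expect_equal(cs$included, c(TRUE, TRUE, TRUE, FALSE))
  expect_error(composition_summary(lab, dom, cum_threshold = 0), "\\(0, 1\\]")
  expect_error(composition_summary(lab, dom, min_frac = 1), "\\[0, 1\\)")
})

test_that("neighbor calls need enough sub-domains and time points", {
  comp <- function(sample, condition, day, type, subs) {
    tibble::tibble(sample = sample, condition = condition, day = day,
                   subdomain = subs, cell_type = type, fraction = 0.2,
                   included = TRUE)
  }
  compositions <- dplyr::bind_rows(
    comp("s1", "normal", 7, "FB", c("d1", "d2")),
    comp("s2", "normal", 10, "FB", c("d1", "d2", "d3")),
    comp("s1", "normal", 7, "Loner", "d1"),
    comp("s2", "normal", 10, "Loner", "d2"),
    comp("s1", "normal", 7, "OneDay", c("d1", "d2", "d3")),
    comp("s2", "normal", 10, "OneDay", "d1")
  )
  nb <- neighbor_celltypes(compositions)
  # both thresholds met on two days
  expect_true("FB" %in% nb$cell_type)
  # one sub-domain per sample: candidate threshold unmet
  expect_false("Loner" %in% nb$cell_type)
  # candidate on a single day only
  expect_false("OneDay" %in% nb$cell_type)
})

test_that("differing type universes draw a warning, not an error", {
  compositions <- tibble::tibble(
    sample = c("s1", "s2"), condition = "normal", day = c(7, 10),
    subdomain = "d1", cell_type = c("A", "B"), fraction = 1,
    included = TRUE
  )
  expect_warning(neighbor_celltypes(compositions), "union")
})

test_that("the planted wedge tip band ranks most plastic", {
  wsim <- sim_spots(tissue_wedge(base_width = 400, height = 600), seed = 2)
  pf <- sim_proportion_field(
    wsim,
    list(src = logistic_profile(0.6, 8, "increasing"),
         snk = logistic_profile(0.6, 8, "decreasing")),
    noise_sd = 0, seed = 2
  )
  props <- assign_dominant(abundance_to_proportion(pf$abundance),
                           exclude_types = character(0))
  spp <- spot_plasticity(props,
                         tibble::tibble(cell_type = c("src", "snk"),
                                        plasticity = c(1, 0)))
  ax <- wsim$truth$true_axial_fraction[match(spp$by_spot$spot_id,
                                             wsim$truth$spot_id)]
  bands <- tibble::tibble(spot_id = spp$by_spot$spot_id,
                          subdomain = paste0("band",
                                             pmin(floor(ax * 4), 3) + 1))
  rp <- regional_plasticity(bands, spp$by_spot)
  expect_equal(rp$subdomain[rp$rank == 1], "band1")
})

test_that("the recursive driver picks the valve-richest domain", {
  spots <- tibble::tibble(spot_id = sprintf("s%02d", 1:30),
                          x = rep(1:30), y = 0)
  dominant <- tibble::tibble(
    spot_id = spots$spot_id,
    dominant_type = c(rep("vCM", 15), rep("Valve", 12), rep("vCM", 3))
  )
  stub_cluster <- function(sp, round) {
    if (round == 1L) {
      tibble::tibble(spot_id = sp$spot_id,
                     cluster = ifelse(sp$x <= 15, "myo", "valve_zone"))
    } else {
      tibble::tibble(spot_id = sp$spot_id,
                     cluster = ifelse(sp$x <= 22, "sub1", "sub2"))
    }
  }
  res <- recursive_subdomains(spots, dominant, stub_cluster,
                              valve_types = "Valve")
  expect_equal(res$valve_domain, "valve_zone")
  expect_equal(nrow(res$labels), 15)
  expect_setequal(unique(res$labels$subdomain), c("sub1", "sub2"))
})
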