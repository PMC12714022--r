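test_that("velocity magnitudes are L2 norms, min-max scaled", {
  v <- tibble::tibble(cell_id = c("a", "b", "c"),
                      vx = c(3, 0, 6), vy = c(4, 0, 8))
  res <- velocity_magnitude(v)
  expect_equal(res$magnitude, c(5, 0, 10))
  expect_equal(res$scaled_magnitude, c(0.5, 0, 1))

  # constant field degenerates to all zeros
  flat <- tibble::tibble(cell_id = c("a", "b"), vx = 1, vy = 1)
  expect_equal(velocity_magnitude(flat)$scaled_magnitude, c(0, 0))

  expect_error(velocity_magnitude(
    tibble::tibble(cell_id = "a", vx = Inf, vy = 0)), "finite")
  expect_error(velocity_magnitude(
    tibble::tibble(cell_id = "a", vx = 1, vy = 0, vz = 1)), "2-D")
})

test_that("net flow reproduces hand-worked examples", {
  m <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m["a", "b"] <- 0.6; m["a", "c"] <- 0.4; m["b", "c"] <- 0.5
  nf <- net_flow(m)
  expect_equal(nf$netflow, c(0.5, -0.1, -0.45))
  expect_equal(nf$scaled_netflow, c(1, 7 / 19, 0), tolerance = 1e-12)

  m2 <- matrix(0, 2, 2); m2[1, 2] <- 0.8
  nf2 <- net_flow(m2)
  expect_equal(nf2$netflow, c(0.8, -0.8))
  expect_equal(nf2$scaled_netflow, c(1, 0))
})

test_that("symmetric transition matrices have zero net flow everywhere", {
  set.seed(3)
  m <- matrix(runif(36), 6, 6)
  m <- m + t(m)
  nf <- net_flow(m)
  expect_true(all(nf$netflow == 0))
  expect_true(all(nf$scaled_netflow == 0))
})

test_that("self-transitions and negative entries are handled per contract", {
  m <- matrix(0, 2, 2)
  m[1, 1] <- 0.9; m[1, 2] <- 0.4   # diagonal must be ignored
  nf <- net_flow(m)
  expect_equal(nf$netflow, c(0.4, -0.4))

  m[2, 1] <- -0.1
  expect_error(net_flow(m), "nonnegative")
  expect_error(net_flow(matrix(0, 2, 3)), "square")
})

test_that("net flow matches the double-loop oracle on random sparse graphs", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    m <- matrix(sample(c(0, 0.25, 0.5, 0.75), n * n, replace = TRUE,
                       prob = c(0.55, 0.15, 0.15, 0.15)), n, n)
    nf <- net_flow(m)
    expect_identical(nf$netflow, net_flow_oracle(m))
    expect_identical(nf$scaled_netflow, minmax_oracle(net_flow_oracle(m)))
  }
})

test_that("net flow is permutation equivariant", {
  set.seed(12)
  n <- 8
  m <- matrix(runif(n * n) * (runif(n * n) > 0.5), n, n)
  dimnames(m) <- list(letters[1:n], letters[1:n])
  perm <- sample(n)
  nf <- net_flow(m)
  nf_p <- net_flow(m[perm, perm])
  expect_equal(nf_p$netflow, nf$netflow[perm], tolerance = 1e-14)
  expect_equal(nf_p$cell_id, nf$cell_id[perm])
})

test_that("cell plasticity is the product of the two scaled scores", {
  mags <- tibble::tibble(cell_id = c("a", "b", "c"),
                         scaled_magnitude = c(0.8, 0.9, 1))
  flows <- tibble::tibble(cell_id = c("a", "b", "c"),
                          scaled_netflow = c(0.5, 0, 1))
  res <- cell_plasticity(mags, flows)
  expect_equal(res$plasticity, c(0.4, 0, 1))

  expect_error(cell_plasticity(mags, flows[1:2, ]), "same cells")
  bad <- dplyr::mutate(flows, scaled_netflow = c(1.2, 0, 0))
  expect_error(cell_plasticity(mags, bad), "\\[0, 1\\]")
})

test_that("cell-type aggregation averages then rescales across types", {
  scores <- tibble::tibble(cell_id = c("a1", "a2", "b1"),
                           plasticity = c(0.2, 0.4, 0.8))
  ann <- tibble::tibble(cell_id = c("a1", "a2", "b1"),
                        cell_type = c("A", "A", "B"))
  res <- celltype_plasticity(scores, ann)
  expect_equal(res$mean_plasticity[match(c("A", "B"), res$cell_type)],
               c(0.3, 0.8))
  expect_equal(res$plasticity[match(c("A", "B"), res$cell_type)], c(0, 1))

  # single type and all-equal means both collapse to zero
  one <- celltype_plasticity(scores[3, ], ann[3, ])
  expect_equal(one$plasticity, 0)
  eq <- celltype_plasticity(
    tibble::tibble(cell_id = c("a1", "b1"), plasticity = c(0.5, 0.5)),
    tibble::tibble(cell_id = c("a1", "b1"), cell_type = c("A", "B")))
  expect_equal(eq$plasticity, c(0, 0))

  # factor annotations expose empty types
  ann_f <- dplyr::mutate(ann,
                         cell_type = factor(cell_type,
                                            levels = c("A", "B", "Ghost")))
  expect_error(celltype_plasticity(scores, ann_f), "Ghost")
  expect_error(celltype_plasticity(scores, ann[1:2, ]), "annotation")
})

test_that("spot projection weights type scores by proportions", {
  props <- tibble::tibble(spot_id = c("s1", "s2"),
                          A = c(0.5, 1), B = c(0.5, 0))
  scores <- tibble::tibble(cell_type = c("A", "B"), plasticity = c(1, 0))
  res <- spot_plasticity(props, scores)
  expect_equal(res$by_spot$plasticity[match(c("s1", "s2"),
                                            res$by_spot$spot_id)],
               c(0.5, 1))

  scores2 <- tibble::tibble(cell_type = c("A", "B"),
                            plasticity = c(0.3, 0.9))
  res2 <- spot_plasticity(props, scores2)
  expect_equal(res2$by_spot$plasticity[res2$by_spot$spot_id == "s2"], 0.3)

  # subset sum: no renormalization over the included types
  props3 <- tibble::tibble(spot_id = "s1", FB1 = 0.3, FB2 = 0.1,
                           Other = 0.6)
  scores3 <- tibble::tibble(cell_type = c("FB1", "FB2", "Other"),
                            plasticity = c(1, 1, 0.2))
  res3 <- spot_plasticity(props3, scores3,
                          include_types = c("FB1", "FB2"))
  expect_equal(res3$by_spot$plasticity, 0.4)

  expect_error(spot_plasticity(props, scores, include_types = "Nope"),
               "not covered")
})

test_that("excluded spots are dropped from spot projection", {
  props <- tibble::tibble(spot_id = c("s1", "s2"), A = c(1, 0.2),
                          B = c(0, 0.8),
                          dominant_type = c("A", "B"),
                          excluded = c(TRUE, FALSE))
  res <- spot_plasticity(props,
                         tibble::tibble(cell_type = c("A", "B"),
                                        plasticity = c(1, 1)))
  expect_equal(res$by_spot$spot_id, "s2")
})

test_that("planted chain sources score 1 and sinks 0, decreasing in between", {
  ch <- sim_transition_chain(c(50, 50, 50),
                             c("immature", "intermediate", "mature"),
                             forward_p = 0.8, noise_p = 0, seed = 21)
  nf <- net_flow(ch$transition)
  vm <- velocity_magnitude(dplyr::select(ch$cells, cell_id, vx, vy))
  cp <- cell_plasticity(vm, nf)
  tp <- celltype_plasticity(cp, dplyr::select(ch$cells, cell_id, cell_type))
  scores <- tp$plasticity[match(c("immature", "intermediate", "mature"),
                                tp$cell_type)]
  expect_equal(scores[1], 1)
  expect_equal(scores[3], 0)
  expect_true(all(diff(scores) < 0))
  expect_true(all(tp$plasticity >= 0 & tp$plasticity <= 1))
})

test_that("spot-level plasticity tracks the planted source proportion", {
  sim <- annulus_sim()
  pf <- sim_proportion_field(
    sim,
    list(immature = logistic_profile(0.5, 10, "increasing"),
         mature = logistic_profile(0.5, 10, "decreasing")),
    noise_sd = 0, seed = 5
  )
  props <- assign_dominant(abundance_to_proportion(pf$abundance),
                           exclude_types = character(0))
  scores <- tibble::tibble(cell_type = c("immature", "mature"),
                           plasticity = c(1, 0))
  spp <- spot_plasticity(props, scores)
  truth_src <- pf$truth_proportions$immature[
    match(spp$by_spot$spot_id, pf$truth_proportions$spot_id)]
  expect_gt(cor(spp$by_spot$plasticity, truth_src, method = "spearman"),
            0.99)
})
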