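toy_neurons <- function(n, m_type = "L5_TTPC1", spread = 50) {
  data.frame(neuron_id = paste0("n", seq_len(n)), m_type = m_type,
             layer = "L5", synapse_class = "E",
             x = seq(0, spread, length.out = n), y = 100,
             z = seq(0, spread, length.out = n))
}

syn_row <- function(pre, post, m_type = "L5_TTPC1", arc = 1) {
  data.frame(pre_id = pre, post_id = post, pre_mtype = m_type,
             post_mtype = m_type, post_compartment = "dendrite",
             x = 0, y = 0, z = 0, arc_length_um = arc, gap_um = 0)
}

test_that("connection probability counts eligible ordered pairs correctly", {
  nn <- toy_neurons(3)
  syn <- rbind(syn_row("n1", "n2"), syn_row("n1", "n3"), syn_row("n2", "n1"),
               syn_row("n2", "n3"), syn_row("n3", "n1"), syn_row("n3", "n2"))
  cs <- connection_stats(syn, nn, distance_cutoff = 100)
  expect_equal(cs$pathways$c_p, 1)

  # ground truth: 5 of 20 eligible ordered pairs connected
  nn5 <- toy_neurons(5, spread = 10)
  conns <- list(c("n1", "n2"), c("n2", "n1"), c("n3", "n4"), c("n4", "n5"),
                c("n5", "n1"))
  syn5 <- do.call(rbind, lapply(conns, function(cc) {
    rbind(syn_row(cc[1], cc[2]), syn_row(cc[1], cc[2], arc = 5))
  }))
  cs5 <- connection_stats(syn5, nn5, distance_cutoff = 100)
  expect_equal(cs5$pathways$c_p, 5 / 20)
  expect_equal(cs5$pathways$n_eligible_pairs, 20L)
  expect_equal(cs5$pathways$s_m, 2) # every connection carries two synapses

  # no eligible pairs: undefined, not zero
  cs0 <- connection_stats(syn5, nn5, distance_cutoff = 1e-6)
  expect_true(is.na(cs0$pathways$c_p))
  expect_equal(cs0$pathways$n_eligible_pairs, 0L)

  # horizontal distance convention: vertical offsets do not count; only the
  # n1 -> n2 ordered pair is connected, n2 -> n1 is not, so C_p = 1/2
  nn2 <- toy_neurons(2, spread = 0)
  nn2$y <- c(0, 400)
  cs2 <- connection_stats(syn_row("n1", "n2"), nn2, distance_cutoff = 100)
  expect_equal(cs2$pathways$c_p, 0.5)
  cs2e <- connection_stats(syn_row("n1", "n2"), nn2, distance_cutoff = 100,
                           distance_mode = "euclidean")
  expect_true(is.na(cs2e$pathways$c_p))
})

test_that("bouton merging follows the inter-synapse interval rule", {
  lens <- data.frame(neuron_id = "a", axon_length_um = 10)
  two <- data.frame(pre_id = "a", arc_length_um = c(0, 0.5))
  bs <- bouton_stats(two, lens)
  expect_equal(bs$n_boutons, 1)
  expect_equal(bs$synapses_per_bouton, 2)

  three <- data.frame(pre_id = "a", arc_length_um = c(0, 0.9, 3))
  bs3 <- bouton_stats(three, lens)
  expect_equal(bs3$n_boutons, 2)
  expect_equal(sort(bs3$synapses_per_bouton), c(1, 2))
  # one interval between the two bouton midpoints: 3 - 0.45
  expect_equal(bs3$intervals, 3 - 0.45)

  # merging can only reduce the bouton count
  set.seed(8)
  unif <- data.frame(pre_id = "b", arc_length_um = runif(200, 0, 1000))
  lens_b <- data.frame(neuron_id = "b", axon_length_um = 1000)
  expect_lte(bouton_stats(unif, lens_b)$b_d_measured, 0.2)
  d0 <- bouton_stats(unif, lens_b, merge_distance = 0)$b_d_measured
  expect_equal(d0, 0.2) # merge distance 0 is the raw synapse density
  d1 <- bouton_stats(unif, lens_b, merge_distance = 1)$b_d_measured
  d5 <- bouton_stats(unif, lens_b, merge_distance = 5)$b_d_measured
  expect_true(d5 <= d1 && d1 <= d0)

  # axons without synapses still contribute axon length to the density
  lens2 <- rbind(lens_b, data.frame(neuron_id = "c", axon_length_um = 1000))
  expect_equal(bouton_stats(unif, lens2, merge_distance = 0)$b_d_measured,
               0.1)

  # central-region restriction drops out-of-radius synapses
  unif$x <- c(rep(0, 100), rep(100, 100))
  unif$z <- 0
  bs_c <- bouton_stats(unif, lens_b, central_axis = c(0, 0), radius = 37.5,
                       merge_distance = 0)
  expect_equal(bs_c$n_boutons, 100)
})

test_that("volumetric densities use four disjoint boxes per layer", {
  layers <- data.frame(layer = "L5", y_min = 0, y_max = 200)
  center <- c(100, 100)
  empty <- data.frame(x = numeric(), y = numeric(), z = numeric())
  vd0 <- volumetric_density(empty, layers, center)
  expect_true(all(vd0$per_box$density_um3 == 0))

  # 1000 synapses uniform in the first box only
  set.seed(9)
  b1 <- data.frame(x = runif(1000, 75, 100), y = runif(1000, 87.5, 112.5),
                   z = runif(1000, 75, 100))
  vd <- volumetric_density(b1, layers, center)
  expect_equal(sort(vd$per_box$n_synapses, decreasing = TRUE)[1], 1000)
  expect_equal(max(vd$per_box$density_um3), 1000 / 15625)
  expect_equal(sum(vd$per_box$n_synapses), 1000) # boxes are disjoint

  expect_error(
    volumetric_density(empty, layers, center,
                       bounds = list(x = c(0, 90), y = c(0, 200),
                                     z = c(0, 200))),
    "outside")
})

test_that("in-silico patch groups map coordinates to distinct neurons", {
  set.seed(10)
  nn <- data.frame(neuron_id = paste0("n", 1:300), m_type = "L5_TTPC1",
                   layer = "L5", synapse_class = "E",
                   x = runif(300, 0, 200), y = runif(300, 0, 200),
                   z = runif(300, 0, 200))
  syn <- syn_row(paste0("n", 1:40), paste0("n", 41:80))
  layers <- data.frame(layer = "L5", y_min = 0, y_max = 200)
  spec <- patch_sample_spec("L5", "L5_TTPC1", n_sets = 5)

  # a 12-coordinate set probes at most 12 * 11 = 132 ordered pairs
  twelve <- list(matrix(0, 12, 3))
  g <- insilico_patch(syn, nn, spec, layers, extent = c(200, 200), seed = 2,
                      coordinate_sets = twelve)
  expect_equal(length(g[[1]]$members), 12)
  expect_equal(sum(upper.tri(g[[1]]$adjacency)) +
                 sum(lower.tri(g[[1]]$adjacency)), 132)
  # coincident coordinates still map to distinct neurons
  expect_equal(anyDuplicated(g[[1]]$members), 0)

  g1 <- insilico_patch(syn, nn, spec, layers, extent = c(200, 200), seed = 4)
  g2 <- insilico_patch(syn, nn, spec, layers, extent = c(200, 200), seed = 4)
  expect_identical(g1, g2)
  sizes <- vapply(generate_patch_coordinates(spec, 3), nrow, integer(1))
  expect_true(all(sizes >= 2 & sizes <= 12))
})

test_that("patch-based connection probability converges to the census value", {
  set.seed(11)
  n <- 250
  nn <- data.frame(neuron_id = paste0("n", 1:n), m_type = "L5_TTPC1",
                   layer = "L5", synapse_class = "E",
                   x = runif(n, 0, 300), y = runif(n, 0, 300),
                   z = runif(n, 0, 300))
  # distance-independent connectivity at p = 0.08
  adj <- matrix(runif(n * n) < 0.08, n, n); diag(adj) <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  syn <- syn_row(nn$neuron_id[idx[, 1]], nn$neuron_id[idx[, 2]])
  layers <- data.frame(layer = "L5", y_min = 0, y_max = 300)
  spec <- patch_sample_spec("L5", "L5_TTPC1", n_sets = 40)
  groups <- insilico_patch(syn, nn, spec, layers, extent = c(300, 300),
                           seed = 6)
  probed <- do.call(rbind, lapply(groups, function(g) {
    m <- g$adjacency
    cbind(sum(m[row(m) != col(m)]), sum(row(m) != col(m)))
  }))
  cp_patch <- sum(probed[, 1]) / sum(probed[, 2])
  n_probe <- sum(probed[, 2])
  ci <- 3 * sqrt(0.08 * 0.92 / n_probe)
  expect_lt(abs(cp_patch - 0.08), ci + 0.01)
})

test_that("common-neighbour statistics detect clustering and not noise", {
  # minimal motif: c projects to both a and b; pair (a, b) has one common
  # neighbour in either-direction mode
  A <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  A["c", "a"] <- 1; A["c", "b"] <- 1
  cn <- common_neighbors(A, mode = "either")
  expect_equal(cn$counts[1], 1) # pair (a, b)
  expect_equal(common_neighbors(A, mode = "out")$counts[1], 0)
  expect_equal(common_neighbors(A, mode = "in")$counts[1], 1)

  # independence baseline: an Erdos-Renyi graph has ratio ~ 1 (bound is 3x
  # the empirical spread of the ratio at n = 200, p = 0.1)
  set.seed(12)
  n <- 200
  er <- matrix(runif(n * n) < 0.1, n, n); diag(er) <- FALSE
  expect_lt(abs(common_neighbors(er)$ratio - 1), 0.035)

  # planted two-block structure: connected pairs share more neighbours
  blk <- matrix(runif(n * n) < 0.02, n, n)
  blk[1:100, 1:100] <- runif(100 * 100) < 0.3
  blk[101:200, 101:200] <- runif(100 * 100) < 0.3
  diag(blk) <- FALSE
  expect_gt(common_neighbors(blk)$ratio, 1.2)

  expect_error(common_neighbors(matrix(0, 2, 2)), "3")
})

test_that("wiring-capacity fraction is the normalized binary entropy", {
  expect_equal(capacity_fraction(0.5), 1)
  expect_equal(capacity_fraction(0.3), 0.8812909, tolerance = 1e-7)
  expect_equal(capacity_fraction(0.1), 0.4689956, tolerance = 1e-7)
  expect_equal(capacity_fraction(0), 0)
  expect_equal(capacity_fraction(1), 0)
  a <- seq(0, 1, by = 0.05)
  expect_equal(capacity_fraction(a), capacity_fraction(1 - a))
  expect_error(capacity_fraction(1.2), "0, 1")
})

test_that("correlation helper and bundled reference tables behave", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(table_correlations(x, x)$r, 1)
  expect_equal(table_correlations(x, -x)$r, -1)
  expect_error(table_correlations(x, rep(1, 5)), "variance")
  expect_error(table_correlations(x, x[1:3]), "mismatch")

  t1 <- reference_table("synapses_per_connection")
  t2 <- reference_table("connection_probabilities")
  t3 <- reference_table("bouton_densities")
  expect_equal(nrow(t1), 38)
  expect_equal(nrow(t2), 14)
  expect_equal(nrow(t3), 40)
  # spot anchors of the transcription
  expect_equal(t1$all_2.5[t1$pre == "L5_TTPC1" & t1$post == "L5_TTPC1"], 3.79)
  expect_equal(t2$bio[t2$pre == "L5_TTPC1" & t2$post == "L5_TTPC1"], 0.12)
  expect_equal(t3$bio[t3$m_type == "L5_TTPC1"], 0.15)
})
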