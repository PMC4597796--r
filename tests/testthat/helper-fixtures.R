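# Shared fixture builders: all geometry and tables are constructed in code.

# A neuron whose axon is a single straight polyline; a far-away dendrite stub
# keeps it usable as a postsynaptic candidate without spurious touches.
straight_axon_neuron <- function(id, from, to, radius = 0.5,
                                 synapse_class = "E", m_type = "L5_TTPC1",
                                 n_points = 2) {
  pts <- mapply(function(a, b) seq(a, b, length.out = n_points), from, to)
  morphology(id, m_type, "L5", synapse_class, from, list(
    section("axon", pts, radius),
    section("basal", rbind(from + c(0, 1e5, 0), from + c(0, 1e5 + 10, 0)),
            radius)
  ))
}

# A neuron whose dendrite is a single straight polyline; its axon is placed
# far away so it cannot generate touches of its own.
straight_dendrite_neuron <- function(id, from, to, radius = 0.5,
                                     synapse_class = "E",
                                     m_type = "L5_TTPC1", type = "basal",
                                     n_points = 2) {
  pts <- mapply(function(a, b) seq(a, b, length.out = n_points), from, to)
  morphology(id, m_type, "L5", synapse_class, from, list(
    section(type, pts, radius),
    section("axon", rbind(from - c(0, 1e5, 0), from - c(0, 1e5 + 10, 0)),
            radius)
  ))
}

# A compact random circuit of grown morphologies for oracle comparisons.
random_circuit <- function(n_neurons, seed, box = 60) {
  spec <- circuit_spec(
    layers = data.frame(layer = "L5", y_min = 0, y_max = box),
    composition = data.frame(layer = "L5",
                             m_type = c("L5_TTPC1", "L5_MC"),
                             synapse_class = c("E", "I"),
                             count = c(ceiling(n_neurons / 2),
                                       floor(n_neurons / 2))),
    width = box, depth = box
  )
  stubs <- place_neurons(spec, seed)
  lapply(seq_len(nrow(stubs)), function(i) {
    generate_morphology(stubs[i, ], list(axon_length = 150,
                                         dendrite_length = 120,
                                         axon_branches = 1,
                                         dendrite_branches = 1,
                                         step = 8), seed)
  })
}

# Hand-built apposition rows for rule-filtering tests.
apposition_row <- function(pre_mtype, post_mtype, pre_class, post_class,
                           compartment) {
  data.frame(pre_id = paste0(pre_mtype, "_1"),
             post_id = paste0(post_mtype, "_2"),
             pre_mtype = pre_mtype, post_mtype = post_mtype,
             pre_class = pre_class, post_class = post_class,
             post_compartment = compartment,
             x = 0, y = 0, z = 0, arc_length_um = 1, gap_um = 0)
}

# Chi-squared goodness-of-fit p-value of counts against geometric(p) on
# {1, 2, ...}, binning the tail so all expected counts are >= 5.
geom_gof_p <- function(k, p) {
  n <- length(k)
  kmax <- 1
  while (n * (1 - p)^kmax * p >= 5) kmax <- kmax + 1
  obs <- c(tabulate(pmin(k, kmax + 1), nbins = kmax + 1))
  probs <- c((1 - p)^(seq_len(kmax) - 1) * p, (1 - p)^kmax)
  suppressWarnings(stats::chisq.test(obs, p = probs)$p.value)
}

# Row-set equality on the identifying apposition columns, order-insensitive.
apposition_keys <- function(tab) {
  sort(paste(tab$pre_id, tab$post_id, tab$pre_section, tab$pre_segment,
             tab$post_section, tab$post_segment,
             signif(tab$gap_um, 8), sep = "|"))
}
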