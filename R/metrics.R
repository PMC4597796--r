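# Validation-statistics suite: connection probabilities, bouton statistics,
# volumetric synapse densities, in-silico multi-patch sampling, common
# neighbour clustering, wiring-capacity estimates, and correlation checks
# against the bundled reference tables.

#' Connection probability and synapse-count statistics per pathway
#'
#' `C_p` is the fraction of eligible ordered pairs (pre m-type, post m-type;
#' inter-soma distance within the cutoff) that are connected in the synapse
#' table; `S_m`/`S_sd` summarise synapse counts over connected pairs only.
#'
#' @param synapses Synapse (or apposition) data frame with `pre_id`,
#'   `post_id`, `pre_mtype`, `post_mtype`.
#' @param neurons Neuron metadata with `neuron_id`, `m_type`, `x`, `y`, `z`.
#' @param distance_cutoff Maximal inter-soma distance, micrometres
#'   (default 100).
#' @param distance_mode `"horizontal"` (x-z plane, the convention for layered
#'   cortex; default) or `"euclidean"`.
#' @param distance_breaks Optional bin edges for a distance-binned `C_p`
#'   profile.
#' @return List with `pathways` (per pathway: `c_p`, `s_m`, `s_sd`,
#'   `n_eligible_pairs`, `n_connected`; pathways with no eligible pair get
#'   `NA` metrics, not zero) and optionally `profile` (per pathway x distance
#'   bin `c_p`).
#' @export
connection_stats <- function(synapses, neurons, distance_cutoff = 100,
                             distance_mode = c("horizontal", "euclidean"),
                             distance_breaks = NULL) {
  distance_mode <- match.arg(distance_mode)
  pw_tab <- unique(synapses[, c("pre_mtype", "post_mtype")])
  conn_key <- paste(synapses$pre_id, synapses$post_id, sep = "\r")
  out <- list()
  prof <- list()
  for (i in seq_len(nrow(pw_tab))) {
    pre <- neurons[neurons$m_type == pw_tab$pre_mtype[i], , drop = FALSE]
    post <- neurons[neurons$m_type == pw_tab$post_mtype[i], , drop = FALSE]
    pairs <- expand.grid(a = seq_len(nrow(pre)), b = seq_len(nrow(post)))
    pairs <- pairs[pre$neuron_id[pairs$a] != post$neuron_id[pairs$b], ,
                   drop = FALSE]
    d <- if (distance_mode == "horizontal") {
      sqrt((pre$x[pairs$a] - post$x[pairs$b])^2 +
             (pre$z[pairs$a] - post$z[pairs$b])^2)
    } else {
      sqrt((pre$x[pairs$a] - post$x[pairs$b])^2 +
             (pre$y[pairs$a] - post$y[pairs$b])^2 +
             (pre$z[pairs$a] - post$z[pairs$b])^2)
    }
    elig <- d <= distance_cutoff
    key <- paste(pre$neuron_id[pairs$a], post$neuron_id[pairs$b], sep = "\r")
    connected <- key %in% conn_key
    pwk <- paste(pw_tab$pre_mtype[i], pw_tab$post_mtype[i], sep = ":")
    n_elig <- sum(elig)
    if (n_elig == 0) {
      out[[i]] <- data.frame(pathway = pwk, c_p = NA_real_, s_m = NA_real_,
                             s_sd = NA_real_, n_eligible_pairs = 0L,
                             n_connected = 0L)
      next
    }
    conn_elig <- key[elig & connected]
    k <- as.integer(table(conn_key)[conn_elig])
    out[[i]] <- data.frame(
      pathway = pwk, c_p = sum(elig & connected) / n_elig,
      s_m = if (length(k)) mean(k) else NA_real_,
      s_sd = if (length(k) > 1) stats::sd(k) else NA_real_,
      n_eligible_pairs = n_elig, n_connected = sum(elig & connected)
    )
    if (!is.null(distance_breaks)) {
      bin <- cut(d, distance_breaks, include.lowest = TRUE)
      prof[[i]] <- data.frame(
        pathway = pwk,
        bin = levels(bin),
        c_p = as.vector(tapply(connected, bin, mean)),
        n_pairs = as.vector(tapply(connected, bin, length))
      )
    }
  }
  res <- list(pathways = reset_rows(do.call(rbind, out)))
  if (length(prof)) res$profile <- reset_rows(do.call(rbind, prof))
  res
}

#' Bouton statistics along axons
#'
#' Sorts efferent synapses per presynaptic axon by arc length and merges runs
#' of synapses whose successive gaps are below the merge distance into single
#' boutons. Reports the bouton density (boutons per micrometre of axon),
#' the inter-bouton interval distribution (successive bouton midpoints), and
#' the synapses-per-bouton distribution. When a central axis is supplied,
#' only synapses (and axons) within the stated radius of it enter the
#' statistics, mirroring central-region sampling in a reconstructed volume.
#'
#' @param synapses Synapse data frame with `pre_id` and `arc_length_um`
#'   (and `x`, `z` if a central axis is used).
#' @param axon_lengths Data frame with `neuron_id`, `axon_length_um`.
#' @param central_axis Optional `c(x, z)` of the vertical central axis.
#' @param radius Radius of the central region, micrometres (default 37.5).
#' @param merge_distance Synapses closer than this along the same axon share a
#'   bouton, micrometres (default 1).
#' @return List with `b_d_measured`, `intervals`, `synapses_per_bouton`,
#'   `n_boutons`, `total_axon_length`.
#' @export
bouton_stats <- function(synapses, axon_lengths, central_axis = NULL,
                         radius = 37.5, merge_distance = 1.0) {
  syn <- synapses
  if (!is.null(central_axis)) {
    r <- sqrt((syn$x - central_axis[1])^2 + (syn$z - central_axis[2])^2)
    syn <- syn[r <= radius, , drop = FALSE]
  }
  # the denominator is the whole axon population handed in (axons without a
  # single synapse still contribute length); axons with no in-region length
  # are excluded by the caller leaving them out of `axon_lengths`
  pop <- axon_lengths[!is.na(axon_lengths$axon_length_um) &
                        axon_lengths$axon_length_um > 0, , drop = FALSE]
  syn <- syn[syn$pre_id %in% pop$neuron_id, , drop = FALSE]
  per_axon <- split(syn$arc_length_um, syn$pre_id)
  lens <- pop$axon_length_um
  intervals <- list()
  sizes <- list()
  n_boutons <- 0L
  for (i in seq_along(per_axon)) {
    a <- sort(per_axon[[i]])
    if (length(a) == 0) next
    new_bouton <- c(TRUE, diff(a) >= merge_distance)
    grp <- cumsum(new_bouton)
    mids <- as.vector(tapply(a, grp, mean))
    sizes[[i]] <- as.vector(table(grp))
    n_boutons <- n_boutons + length(mids)
    if (length(mids) > 1) intervals[[i]] <- diff(mids)
  }
  list(
    b_d_measured = n_boutons / sum(lens),
    intervals = unlist(intervals, use.names = FALSE),
    synapses_per_bouton = unlist(sizes, use.names = FALSE),
    n_boutons = n_boutons,
    total_axon_length = sum(lens)
  )
}

#' Volumetric synapse density at layer centres
#'
#' Counts synapses inside four cubic sampling boxes centred on the geometric
#' centre of each layer, offset in x/z so the boxes are pairwise disjoint, and
#' reports the density per box and the per-layer mean and SD.
#'
#' @param synapses Synapse data frame with `x`, `y`, `z` (pre-filter to
#'   e.g. inhibitory synapses before calling if desired).
#' @param layers Layer geometry: data frame with `layer`, `y_min`, `y_max`.
#' @param center `c(x, z)` of the column centre.
#' @param box_edge Edge of the sampling cubes, micrometres (default 25).
#' @param offsets Two offset magnitudes applied as the four (+/-, +/-)
#'   combinations in x/z (default both 12.5).
#' @param bounds Optional list with `x = c(min, max)`, `y = ...`, `z = ...`;
#'   a box extending outside these bounds is an error.
#' @return Data frame per layer and box with `density_um3`, plus attributes
#'   none; use `aggregate` on the result for the mean/SD summary, or read the
#'   columns `mean_density` / `sd_density` in the per-layer summary component.
#' @export
volumetric_density <- function(synapses, layers, center, box_edge = 25,
                               offsets = c(12.5, 12.5), bounds = NULL) {
  half <- box_edge / 2
  off <- expand.grid(ox = c(-offsets[1], offsets[1]),
                     oz = c(-offsets[2], offsets[2]))
  rows <- list()
  for (i in seq_len(nrow(layers))) {
    yc <- (layers$y_min[i] + layers$y_max[i]) / 2
    for (b in seq_len(nrow(off))) {
      cx <- center[1] + off$ox[b]
      cz <- center[2] + off$oz[b]
      box <- list(x = c(cx - half, cx + half), y = c(yc - half, yc + half),
                  z = c(cz - half, cz + half))
      if (!is.null(bounds)) {
        for (ax in c("x", "y", "z")) {
          if (box[[ax]][1] < bounds[[ax]][1] - 1e-9 ||
              box[[ax]][2] > bounds[[ax]][2] + 1e-9) {
            stop("sampling box extends outside the circuit volume (",
                 ax, " axis, layer ", layers$layer[i], ")")
          }
        }
      }
      n <- sum(synapses$x >= box$x[1] & synapses$x < box$x[2] &
                 synapses$y >= box$y[1] & synapses$y < box$y[2] &
                 synapses$z >= box$z[1] & synapses$z < box$z[2])
      rows[[length(rows) + 1L]] <- data.frame(
        layer = layers$layer[i], box = b, n_synapses = n,
        density_um3 = n / box_edge^3
      )
    }
  }
  per_box <- reset_rows(do.call(rbind, rows))
  summ <- do.call(rbind, lapply(split(per_box, per_box$layer), function(d) {
    data.frame(layer = d$layer[1], mean_density = mean(d$density_um3),
               sd_density = stats::sd(d$density_um3))
  }))
  list(per_box = per_box, summary = reset_rows(summ))
}

#' Patch-sampling specification and coordinate-set generator
#'
#' Describes an in-silico multi-patch sampling protocol: sets of relative
#' soma coordinates to be dropped at random anchors inside a target layer,
#' each coordinate mapped to the nearest neuron of a target m-type. The
#' generator draws set sizes from a normal law truncated to the admissible
#' range and spreads relative coordinates uniformly in a horizontal disc.
#'
#' @param n_sets Number of coordinate sets (default 46).
#' @param size_mean,size_sd Mean and SD of coordinates per set (defaults 8.2
#'   and 3.4).
#' @param size_range Admissible set sizes (default `c(2, 12)`).
#' @param spread_radius Radius of the disc the relative coordinates occupy,
#'   micrometres (default 100).
#' @param target_layer Layer the anchors are drawn in.
#' @param target_mtypes m-types eligible for mapping.
#' @return Object of class `patch_sample_spec`.
#' @export
patch_sample_spec <- function(target_layer, target_mtypes, n_sets = 46,
                              size_mean = 8.2, size_sd = 3.4,
                              size_range = c(2, 12), spread_radius = 100) {
  stopifnot(size_range[1] >= 2, size_range[2] >= size_range[1])
  structure(list(target_layer = target_layer, target_mtypes = target_mtypes,
                 n_sets = n_sets, size_mean = size_mean, size_sd = size_sd,
                 size_range = size_range, spread_radius = spread_radius),
            class = "patch_sample_spec")
}

#' @rdname patch_sample_spec
#' @param spec A `patch_sample_spec`.
#' @param seed Integer root seed.
#' @return For `generate_patch_coordinates()`: list of n x 3 matrices of
#'   relative coordinates (micrometres).
#' @export
generate_patch_coordinates <- function(spec, seed) {
  with_seed(substream_seed(seed, "patch"), {
    sizes <- round(stats::rnorm(spec$n_sets, spec$size_mean, spec$size_sd))
    sizes <- pmin(spec$size_range[2], pmax(spec$size_range[1], sizes))
    lapply(sizes, function(n) {
      ang <- stats::runif(n, 0, 2 * pi)
      rad <- spec$spread_radius * sqrt(stats::runif(n))
      cbind(rad * cos(ang), stats::runif(n, -20, 20), rad * sin(ang))
    })
  })
}

#' In-silico multi-patch sampling of connectivity
#'
#' Translates each relative coordinate set to a uniformly random anchor within
#' the target layer, maps every coordinate to the nearest not-yet-used neuron
#' of a target m-type (without replacement within a set), and returns each
#' group's members together with its directed connectivity submatrix.
#'
#' @param synapses Synapse table defining connectivity (`pre_id`, `post_id`).
#' @param neurons Neuron metadata with positions and `layer`, `m_type`.
#' @param spec A [patch_sample_spec()].
#' @param layers Layer geometry data frame (`layer`, `y_min`, `y_max`).
#' @param extent `c(width, depth)` of the horizontal extent.
#' @param seed Integer root seed.
#' @param coordinate_sets Optional externally supplied list of relative
#'   coordinate matrices (e.g. recorded experimental coordinates); defaults to
#'   [generate_patch_coordinates()].
#' @param max_retries Anchor retries per set before the group is skipped with
#'   a warning.
#' @return List of groups; each has `members` (neuron ids) and `adjacency`
#'   (directed logical matrix).
#' @export
insilico_patch <- function(synapses, neurons, spec, layers, extent, seed,
                           coordinate_sets = NULL, max_retries = 20) {
  if (is.null(coordinate_sets)) {
    coordinate_sets <- generate_patch_coordinates(spec, seed)
  }
  band <- layers[layers$layer == spec$target_layer, ]
  if (nrow(band) != 1) stop("unknown target layer: ", spec$target_layer)
  pool <- neurons[neurons$m_type %in% spec$target_mtypes, , drop = FALSE]
  if (nrow(pool) == 0) stop("no neurons of the target m-types")
  conn_key <- unique(paste(synapses$pre_id, synapses$post_id, sep = "\r"))
  with_seed(substream_seed(seed, "patch") + 1L, {
    groups <- list()
    for (cs in coordinate_sets) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        anchor <- c(stats::runif(1, 0, extent[1]),
                    stats::runif(1, band$y_min, band$y_max),
                    stats::runif(1, 0, extent[2]))
        coords <- sweep(cs, 2, anchor, "+")
        taken <- integer(0)
        members <- character(nrow(coords))
        good <- TRUE
        for (ci in seq_len(nrow(coords))) {
          d2 <- (pool$x - coords[ci, 1])^2 + (pool$y - coords[ci, 2])^2 +
            (pool$z - coords[ci, 3])^2
          d2[taken] <- Inf
          j <- which.min(d2)
          if (!is.finite(d2[j])) { good <- FALSE; break }
          taken <- c(taken, j)
          members[ci] <- pool$neuron_id[j]
        }
        if (good) { ok <- TRUE; break }
      }
      if (!ok) {
        warning("patch group skipped: could not map distinct neurons")
        next
      }
      n <- length(members)
      adj <- matrix(FALSE, n, n, dimnames = list(members, members))
      for (a in seq_len(n)) for (b in seq_len(n)) {
        if (a != b) {
          adj[a, b] <- paste(members[a], members[b],
                             sep = "\r") %in% conn_key
        }
      }
      groups[[length(groups) + 1L]] <- list(members = members,
                                            adjacency = adj)
    }
    groups
  })
}

#' Common-neighbour statistics of a directed connectivity matrix
#'
#' A common neighbour of a pair (i, j) is a third neuron adjacent to both. The
#' adjacency sense is configurable: `"either"` (default, matching the
#' multi-patch experimental readout) treats a neuron as a neighbour if it is
#' connected to the reference cell in either direction. Returns the
#' neighbour-count distribution over unordered pairs, the connection
#' probability binned by neighbour count, the ratio of mean neighbour counts
#' for connected versus unconnected pairs, and the independent-random baseline
#' expected from the same overall connection density.
#'
#' @param adjacency Square logical/0-1 matrix (directed; diagonal ignored).
#' @param mode `"either"`, `"out"`, or `"in"`.
#' @return List with `counts` (per unordered pair), `distribution` (tabled),
#'   `cp_by_neighbors` (data frame), `ratio` (connected/unconnected mean
#'   neighbour counts), and `baseline_ratio` (independence expectation, 1).
#' @export
common_neighbors <- function(adjacency, mode = c("either", "out", "in")) {
  mode <- match.arg(mode)
  n <- nrow(adjacency)
  if (n < 3) stop("need at least 3 neurons")
  A <- (adjacency != 0) * 1
  diag(A) <- 0
  M <- switch(mode, either = ((A + t(A)) > 0) * 1, out = A, `in` = t(A))
  # neighbour sets as rows of M (for "out": k is a neighbour of i if i -> k)
  cn_mat <- M %*% t(M)
  pairs <- which(upper.tri(cn_mat), arr.ind = TRUE)
  counts <- cn_mat[upper.tri(cn_mat)]
  connected <- (A + t(A))[upper.tri(A)] > 0
  cp_by <- do.call(rbind, lapply(split(connected, counts), function(v) {
    data.frame(n_pairs = length(v), c_p = mean(v))
  }))
  cp_by <- cbind(common_neighbors = as.integer(rownames(cp_by)), cp_by)
  cp_by <- cp_by[order(cp_by$common_neighbors), , drop = FALSE]
  rownames(cp_by) <- NULL
  ratio <- if (any(connected) && any(!connected)) {
    mean(counts[connected]) / mean(counts[!connected])
  } else NA_real_
  list(counts = counts, distribution = table(counts),
       cp_by_neighbors = cp_by, ratio = ratio, baseline_ratio = 1)
}

#' Wiring-capacity fraction of the plasticity reserve
#'
#' With a fraction `a3` of viable multi-synapse connections active, the
#' information carried by the choice of the active set is the binary entropy
#' `H(a3) = -a3 log2(a3) - (1 - a3) log2(1 - a3)` bits per viable connection,
#' maximal (1 bit) at `a3 = 0.5`. The returned value is the fraction of that
#' maximum.
#'
#' @param a3 Active fraction(s) in `[0, 1]`.
#' @return Normalized capacity in `[0, 1]` (vectorized).
#' @export
capacity_fraction <- function(a3) {
  if (any(a3 < 0 | a3 > 1)) stop("a3 must lie in [0, 1]")
  h <- function(x) ifelse(x <= 0 | x >= 1, 0,
                          -x * log2(x) - (1 - x) * log2(1 - x))
  h(a3)
}

#' Pearson correlation between model and reference values
#'
#' @param model,reference Equal-length numeric vectors (N >= 3, non-zero
#'   variance in both).
#' @return List with `r`, `p_value`, `n`.
#' @export
table_correlations <- function(model, reference) {
  if (length(model) != length(reference)) stop("length mismatch")
  if (length(model) < 3) stop("need at least 3 paired values")
  if (stats::sd(model) == 0 || stats::sd(reference) == 0) {
    stop("zero variance")
  }
  ct <- stats::cor.test(model, reference, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(model))
}

#' Bundled reference tables of published connectivity statistics
#'
#' Three tables of reported connectivity statistics for the rat somatosensory
#' cortex microcircuit, transcribed from the published literature compilation:
#' mean appositions/synapses per connection for 38 pathways
#' (`"synapses_per_connection"`), connection probabilities within 100 um for
#' 14 pathways (`"connection_probabilities"`), and apposition/bouton densities
#' for 40 m-types (`"bouton_densities"`). Columns: `all_*` = apposition-based
#' values at the stated touch distance (micrometres), `pruned_*` = after
#' three-step pruning with biological parametrization, `predictive_*` = after
#' pruning with fully derived parametrization, `bio` = reported biological
#' value.
#'
#' @param name Which table to load.
#' @return Data frame.
#' @export
reference_table <- function(name = c("synapses_per_connection",
                                     "connection_probabilities",
                                     "bouton_densities")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "synprune",
                      mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE)
}

#' Correlation validations against the bundled reference tables
#'
#' Recomputes the headline model-versus-biology Pearson correlations from the
#' bundled tables: pruned connection probabilities vs reported (N = 14),
#' predicted and apposition-based synapses per connection vs reported
#' (N = 38), and predicted bouton densities vs reported (N = 40).
#'
#' @return Data frame with `comparison`, `r`, `p_value`, `n`.
#' @export
validate_reference_correlations <- function() {
  t1 <- reference_table("synapses_per_connection")
  t2 <- reference_table("connection_probabilities")
  t3 <- reference_table("bouton_densities")
  rows <- list(
    c("cp_pruned_vs_bio", table_correlations(t2$pruned_2.5, t2$bio)),
    c("sm_predictive_vs_bio", table_correlations(t1$predictive_2.5, t1$bio)),
    c("sm_appositions_vs_bio", table_correlations(t1$all_2.5, t1$bio)),
    c("bd_predictive_vs_bio", table_correlations(t3$predictive_2.5, t3$bio))
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(comparison = r[[1]], r = r[[2]], p_value = r[[3]], n = r[[4]])
  }))
}
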