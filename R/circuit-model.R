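# Synthetic circuit model: domain constructors plus deterministic-seeded
# generators at two fidelity levels (geometric morphologies, or purely
# statistical apposition sampling with geometric per-connection counts).

#' Neuron morphology
#'
#' Container for a single neuron: labelled 3D polyline arbors with radii,
#' plus placement metadata. Sections are polylines of at least two points;
#' compartment types follow the SWC convention extended with an explicit
#' axon-initial-segment ("AIS") label.
#'
#' @param neuron_id Character or integer identifier.
#' @param m_type Morphological type label (e.g. `"L5_TTPC1"`).
#' @param layer Layer label (e.g. `"L5"`).
#' @param synapse_class `"E"` (excitatory) or `"I"` (inhibitory).
#' @param soma_position Numeric 3-vector, micrometres.
#' @param sections List of sections; each a list with elements `type`
#'   (one of `"axon"`, `"basal"`, `"apical"`, `"soma"`, `"AIS"`), `points`
#'   (n x 3 numeric matrix, micrometres) and `radii` (length-n positive
#'   numeric, micrometres).
#' @return An object of class `morphology`. `axon_total_length` (the summed
#'   segment length of all axonal sections, AIS included) is computed and
#'   stored on construction.
#' @examples
#' m <- morphology("n1", "L5_TTPC1", "L5", "E", c(0, 0, 0),
#'   list(section("axon", rbind(c(0, 0, 0), c(0, -50, 0)), 0.5)))
#' m$axon_total_length
#' @export
morphology <- function(neuron_id, m_type, layer, synapse_class,
                       soma_position, sections) {
  stopifnot(length(soma_position) == 3, synapse_class %in% c("E", "I"))
  for (s in sections) {
    if (!is.list(s) || !all(c("type", "points", "radii") %in% names(s))) {
      stop("each section needs fields type, points, radii")
    }
    if (!s$type %in% c("axon", "basal", "apical", "soma", "AIS")) {
      stop("unknown compartment type: ", s$type)
    }
    if (nrow(s$points) < 2) stop("every section must have >= 2 points")
    if (any(s$radii <= 0)) stop("radii must be positive")
    if (length(s$radii) != nrow(s$points)) stop("radii/points length mismatch")
  }
  obj <- list(
    neuron_id = as.character(neuron_id), m_type = m_type, layer = layer,
    synapse_class = synapse_class, soma_position = as.numeric(soma_position),
    sections = sections
  )
  obj$axon_total_length <- sum(vapply(
    sections, function(s) {
      if (s$type %in% c("axon", "AIS")) polyline_length(s$points) else 0
    }, numeric(1)
  ))
  class(obj) <- "morphology"
  obj
}

#' @rdname morphology
#' @param type Compartment type of the section.
#' @param points n x 3 matrix of coordinates.
#' @param radii Radii (recycled to the number of points).
#' @export
section <- function(type, points, radii) {
  points <- as.matrix(points)
  list(type = type, points = points,
       radii = rep_len(as.numeric(radii), nrow(points)))
}

polyline_length <- function(points) {
  if (nrow(points) < 2) return(0)
  sum(sqrt(rowSums((points[-1, , drop = FALSE] -
                      points[-nrow(points), , drop = FALSE])^2)))
}

#' @export
print.morphology <- function(x, ...) {
  cat("morphology", x$neuron_id, sprintf("(%s, %s, class %s)", x$m_type,
                                         x$layer, x$synapse_class), "\n")
  cat(" sections:", length(x$sections),
      " axon length:", round(x$axon_total_length, 2), "um\n")
  invisible(x)
}

#' Circuit specification
#'
#' Describes a layered box volume and the neuron content per (layer, m-type).
#' The vertical axis is y (pia towards white matter); layers are y-bands that
#' tile the vertical extent without overlap. Horizontal extent is
#' `[0, width] x [0, depth]` in x/z.
#'
#' @param layers Data frame with columns `layer`, `y_min`, `y_max` (micrometres).
#' @param composition Data frame with columns `layer`, `m_type`,
#'   `synapse_class`, `count`.
#' @param width,depth Horizontal extents in micrometres.
#' @return Object of class `circuit_spec` with derived per-row neuron densities
#'   (`density_mm3`, neurons per cubic millimetre).
#' @export
circuit_spec <- function(layers, composition, width, depth) {
  stopifnot(all(c("layer", "y_min", "y_max") %in% names(layers)),
            all(c("layer", "m_type", "synapse_class", "count") %in%
                  names(composition)),
            width > 0, depth > 0)
  layers <- layers[order(layers$y_min), , drop = FALSE]
  if (any(layers$y_max <= layers$y_min)) stop("degenerate layer band")
  if (nrow(layers) > 1) {
    gaps <- layers$y_min[-1] - layers$y_max[-nrow(layers)]
    if (any(abs(gaps) > 1e-9)) stop("layers must tile the vertical extent")
  }
  if (any(composition$count < 0)) stop("counts must be >= 0")
  if (!all(composition$layer %in% layers$layer)) stop("unknown layer in composition")
  thick <- layers$y_max[match(composition$layer, layers$layer)] -
    layers$y_min[match(composition$layer, layers$layer)]
  vol_mm3 <- width * depth * thick * 1e-9  # um^3 -> mm^3
  composition$density_mm3 <- composition$count / vol_mm3
  structure(list(layers = layers, composition = composition,
                 width = width, depth = depth),
            class = "circuit_spec")
}

#' Place neuron somata within their layers
#'
#' Somata are placed uniformly at random inside the layer band and bounding
#' volume; counts per (layer, m-type) match the specification exactly and the
#' result is deterministic given the seed.
#'
#' @param spec A [circuit_spec()].
#' @param seed Integer root seed (placement uses its own substream).
#' @param min_separation Optional minimum pairwise soma distance in
#'   micrometres within a layer; placement fails explicitly if a band is too
#'   thin/small to honour it.
#' @param max_tries Rejection-sampling attempts per neuron when
#'   `min_separation > 0`.
#' @return Data frame with columns `neuron_id`, `m_type`, `layer`,
#'   `synapse_class`, `x`, `y`, `z`.
#' @export
place_neurons <- function(spec, seed, min_separation = 0, max_tries = 200) {
  stopifnot(inherits(spec, "circuit_spec"))
  comp <- spec$composition
  n_total <- sum(comp$count)
  cols <- c("neuron_id", "m_type", "layer", "synapse_class", "x", "y", "z")
  if (n_total == 0) {
    out <- data.frame(neuron_id = character(), m_type = character(),
                      layer = character(), synapse_class = character(),
                      x = numeric(), y = numeric(), z = numeric())
    return(out[cols])
  }
  with_seed(substream_seed(seed, "placement"), {
    rows <- vector("list", nrow(comp))
    idx <- 0L
    for (i in seq_len(nrow(comp))) {
      n <- comp$count[i]
      if (n == 0) next
      band <- spec$layers[spec$layers$layer == comp$layer[i], ]
      placed <- matrix(NA_real_, n, 3)
      kept <- 0L
      # all previously placed somata of this layer, for min-separation checks
      prev <- do.call(rbind, lapply(rows[seq_len(i - 1)], function(r) {
        if (is.null(r) || !any(r$layer == comp$layer[i])) return(NULL)
        as.matrix(r[r$layer == comp$layer[i], c("x", "y", "z")])
      }))
      tries <- 0L
      while (kept < n) {
        cand <- c(stats::runif(1, 0, spec$width),
                  stats::runif(1, band$y_min, band$y_max),
                  stats::runif(1, 0, spec$depth))
        ok <- TRUE
        if (min_separation > 0) {
          ref <- rbind(placed[seq_len(kept), , drop = FALSE], prev)
          if (!is.null(ref) && nrow(ref) > 0) {
            ok <- all(sqrt(rowSums(sweep(ref, 2, cand)^2)) >= min_separation)
          }
        }
        if (ok) {
          kept <- kept + 1L
          placed[kept, ] <- cand
          tries <- 0L
        } else {
          tries <- tries + 1L
          if (tries > max_tries) {
            stop("cannot place ", n, " somata in layer ", comp$layer[i],
                 " at min separation ", min_separation, " um")
          }
        }
      }
      rows[[i]] <- data.frame(
        neuron_id = sprintf("%s_%d", comp$m_type[i], idx + seq_len(n)),
        m_type = comp$m_type[i], layer = comp$layer[i],
        synapse_class = comp$synapse_class[i],
        x = placed[, 1], y = placed[, 2], z = placed[, 3]
      )
      idx <- idx + n
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    rownames(out) <- NULL
    out[cols]
  })
}

#' Grow a synthetic morphology around a placed soma
#'
#' Arbors are branched random walks with a vertical orientation bias. These
#' are geometry fixtures: they respect total-length and branching contracts
#' but make no claim of biophysical realism.
#'
#' @param stub One-row data frame as returned by [place_neurons()].
#' @param growth_params List with elements `axon_length`, `dendrite_length`
#'   (total lengths, micrometres, > 0), `axon_branches`, `dendrite_branches`
#'   (number of additional branch points, >= 0), `step` (segment step length,
#'   default 10), `vertical_bias` (weight in `[0, 1)` pulling axon growth
#'   towards -y and dendrite growth towards +y, default 0.3),
#'   `axon_radius`/`dendrite_radius` (default 0.3 / 0.5), and `ais_length`
#'   (initial arc length of axon relabelled as AIS, default 0 = off).
#' @param seed Integer root seed (arbor growth uses its own substream).
#' @return A [morphology()].
#' @export
generate_morphology <- function(stub, growth_params, seed) {
  gp <- utils::modifyList(list(step = 10, vertical_bias = 0.3,
                               axon_branches = 0, dendrite_branches = 0,
                               axon_radius = 0.3, dendrite_radius = 0.5,
                               ais_length = 0), growth_params)
  if (gp$axon_length <= 0 || gp$dendrite_length <= 0) {
    stop("arbor lengths must be positive")
  }
  origin <- c(stub$x, stub$y, stub$z)
  with_seed(substream_seed(seed, "arbors") + as.integer(
    sum(utf8ToInt(as.character(stub$neuron_id)))), {
    axon <- grow_tree(origin, gp$axon_length, gp$axon_branches, gp$step,
                      -gp$vertical_bias, gp$axon_radius, "axon")
    dend <- grow_tree(origin, gp$dendrite_length, gp$dendrite_branches,
                      gp$step, gp$vertical_bias, gp$dendrite_radius, "basal")
    soma_sec <- section("soma", rbind(origin, origin + c(0, 1, 0)), 5)
    secs <- c(list(soma_sec), axon, dend)
    if (gp$ais_length > 0) secs <- relabel_ais(secs, gp$ais_length)
    morphology(stub$neuron_id, stub$m_type, stub$layer, stub$synapse_class,
               origin, secs)
  })
}

# Random-walk tree: the requested total length is split across 1 + n_branches
# neurites; each grows in fixed-length steps with a vertical drift so the
# summed length is exactly the request.
grow_tree <- function(origin, total_length, n_branches, step, vbias, radius,
                      type) {
  n_sec <- 1L + as.integer(n_branches)
  lens <- rep(total_length / n_sec, n_sec)
  start <- origin
  out <- vector("list", n_sec)
  for (i in seq_len(n_sec)) {
    n_step <- max(2L, ceiling(lens[i] / step))
    seg_len <- lens[i] / n_step
    dirs <- matrix(stats::rnorm(3 * n_step), ncol = 3)
    dirs[, 2] <- dirs[, 2] + vbias * 3
    dirs <- dirs / sqrt(rowSums(dirs^2))
    pts <- apply(dirs * seg_len, 2, cumsum)
    pts <- sweep(rbind(0, pts), 2, start, "+")
    out[[i]] <- section(type, pts, radius)
    # subsequent branches start part-way along the first neurite
    if (i == 1L && n_sec > 1L) {
      start <- pts[max(2L, floor(nrow(pts) / 2)), ]
    }
  }
  out
}

# Relabel the first `ais_length` um of the first axonal section as AIS,
# splitting the section at the cut point.
relabel_ais <- function(sections, ais_length) {
  for (i in seq_along(sections)) {
    if (sections[[i]]$type != "axon") next
    s <- sections[[i]]
    seg <- sqrt(rowSums((s$points[-1, , drop = FALSE] -
                           s$points[-nrow(s$points), , drop = FALSE])^2))
    cum <- cumsum(seg)
    cut <- which(cum >= ais_length)[1]
    if (is.na(cut)) { # whole section within AIS extent
      sections[[i]]$type <- "AIS"
      return(sections)
    }
    ais <- section("AIS", s$points[seq_len(cut + 1), , drop = FALSE],
                   s$radii[seq_len(cut + 1)])
    rest <- section("axon", s$points[(cut + 1):nrow(s$points), , drop = FALSE],
                    s$radii[(cut + 1):nrow(s$points)])
    sections[[i]] <- ais
    return(append(sections, list(rest), after = i))
  }
  sections
}

#' Statistical pathway specification
#'
#' Describes a (pre m-type, post m-type) pathway for the purely statistical
#' apposition sampler: the probability that a pair is apposed at all, and the
#' geometric law on \{1, 2, ...\} governing how many appositions an apposed
#' pair carries.
#'
#' @param pre,post m-type labels.
#' @param p Geometric parameter in (0, 1]; the mean apposition count per
#'   apposed pair is `1/p`.
#' @param apposed_fraction Either a single probability or a function of
#'   horizontal inter-soma distance (micrometres) returning values in `[0, 1]`.
#' @param axon_length Presynaptic axon length per neuron, micrometres, used to
#'   place appositions along arc length.
#' @export
statistical_pathway_spec <- function(pre, post, p, apposed_fraction = 1,
                                     axon_length = 1000) {
  if (p <= 0 || p > 1) stop("p must lie in (0, 1]")
  if (is.numeric(apposed_fraction) &&
      (apposed_fraction < 0 || apposed_fraction > 1)) {
    stop("apposed_fraction must lie in [0, 1]")
  }
  structure(list(pre = pre, post = post, p = p,
                 apposed_fraction = apposed_fraction,
                 axon_length = axon_length),
            class = "statistical_pathway_spec")
}

#' Sample an apposition table from statistical pathway specifications
#'
#' For every ordered neuron pair matching a pathway specification, the pair is
#' apposed with the spec's (possibly distance-dependent) probability; apposed
#' pairs draw a geometric apposition count on \{1, 2, ...\} and each apposition
#' receives a uniform arc-length position on the presynaptic axon plus a
#' synthetic 3D position between the two somata.
#'
#' @param specs List of [statistical_pathway_spec()]; every neuron pair must
#'   match at most one spec.
#' @param neurons Data frame from [place_neurons()].
#' @param seed Integer root seed (apposition sampling uses its own substream).
#' @return Apposition data frame with columns `pre_id`, `post_id`, `pre_mtype`,
#'   `post_mtype`, `post_compartment`, `x`, `y`, `z`, `arc_length_um`, `gap_um`.
#' @export
sample_statistical_appositions <- function(specs, neurons, seed) {
  keys <- vapply(specs, function(s) paste(s$pre, s$post, sep = ":"),
                 character(1))
  if (anyDuplicated(keys)) stop("a neuron pair maps to more than one spec")
  names(specs) <- keys
  with_seed(substream_seed(seed, "appositions"), {
    out <- list()
    for (s in specs) {
      pre <- neurons[neurons$m_type == s$pre, , drop = FALSE]
      post <- neurons[neurons$m_type == s$post, , drop = FALSE]
      if (nrow(pre) == 0 || nrow(post) == 0) next
      pairs <- expand.grid(i = seq_len(nrow(pre)), j = seq_len(nrow(post)))
      pairs <- pairs[pre$neuron_id[pairs$i] != post$neuron_id[pairs$j], ,
                     drop = FALSE]
      if (nrow(pairs) == 0) next
      d_xz <- sqrt((pre$x[pairs$i] - post$x[pairs$j])^2 +
                     (pre$z[pairs$i] - post$z[pairs$j])^2)
      frac <- if (is.function(s$apposed_fraction)) {
        s$apposed_fraction(d_xz)
      } else rep(s$apposed_fraction, nrow(pairs))
      if (any(frac < 0 | frac > 1)) stop("apposed fraction outside [0, 1]")
      apposed <- stats::runif(nrow(pairs)) < frac
      pairs <- pairs[apposed, , drop = FALSE]
      if (nrow(pairs) == 0) next
      k <- stats::rgeom(nrow(pairs), s$p) + 1L
      idx <- rep(seq_len(nrow(pairs)), k)
      mid <- cbind(
        (pre$x[pairs$i] + post$x[pairs$j]) / 2,
        (pre$y[pairs$i] + post$y[pairs$j]) / 2,
        (pre$z[pairs$i] + post$z[pairs$j]) / 2
      )[idx, , drop = FALSE]
      jit <- matrix(stats::rnorm(3 * length(idx), sd = 5), ncol = 3)
      out[[length(out) + 1L]] <- data.frame(
        pre_id = pre$neuron_id[pairs$i][idx],
        post_id = post$neuron_id[pairs$j][idx],
        pre_mtype = s$pre, post_mtype = s$post,
        post_compartment = "dendrite",
        x = mid[, 1] + jit[, 1], y = mid[, 2] + jit[, 2],
        z = mid[, 3] + jit[, 3],
        arc_length_um = stats::runif(length(idx), 0, s$axon_length),
        gap_um = 0
      )
    }
    if (length(out) == 0) return(empty_apposition_table())
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Minimal geometric-connection fixture
#'
#' Builds an apposition table of `n_connections` independent connections whose
#' apposition counts follow a geometric law on \{1, 2, ...\} — the minimal
#' input the parameter-derivation and pruning machinery needs. Each connection
#' uses its own presynaptic neuron with a fixed axon length, so bouton
#' densities are well defined.
#'
#' @param n_connections Number of connections.
#' @param p Geometric parameter in (0, 1].
#' @param seed Integer root seed.
#' @param pre_mtype,post_mtype Pathway labels.
#' @param axon_length Axon length per presynaptic neuron, micrometres.
#' @return List with `appositions` (data frame) and `neurons` (metadata with
#'   `axon_length_um`).
#' @export
geometric_connection_fixture <- function(n_connections, p, seed,
                                         pre_mtype = "L5_TTPC1",
                                         post_mtype = "L5_TTPC1",
                                         axon_length = 100) {
  if (p <= 0 || p > 1) stop("p must lie in (0, 1]")
  with_seed(substream_seed(seed, "appositions"), {
    k <- stats::rgeom(n_connections, p) + 1L
    idx <- rep(seq_len(n_connections), k)
    appositions <- data.frame(
      pre_id = sprintf("pre_%07d", idx),
      post_id = sprintf("post_%07d", idx),
      pre_mtype = pre_mtype, post_mtype = post_mtype,
      post_compartment = "dendrite",
      x = stats::runif(length(idx), 0, 100),
      y = stats::runif(length(idx), 0, 100),
      z = stats::runif(length(idx), 0, 100),
      arc_length_um = stats::runif(length(idx), 0, axon_length),
      gap_um = 0
    )
    neurons <- data.frame(
      neuron_id = sprintf("pre_%07d", seq_len(n_connections)),
      m_type = pre_mtype, axon_length_um = axon_length
    )
    list(appositions = appositions, neurons = neurons)
  })
}

empty_apposition_table <- function() {
  data.frame(pre_id = character(), post_id = character(),
             pre_mtype = character(), post_mtype = character(),
             post_compartment = character(), x = numeric(), y = numeric(),
             z = numeric(), arc_length_um = numeric(), gap_um = numeric())
}
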