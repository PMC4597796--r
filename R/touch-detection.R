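# Touch detection: find appositions ("potential synapses") between the axon of
# one neuron and the dendrites/soma/AIS of another, using class-specific touch
# distances, then filter them with compartment-exception rules.

# Flatten a morphology into a table of line segments with per-segment radii,
# compartment labels, and (for axonal segments) the cumulative arc length from
# the axon root.
segment_table <- function(m) {
  rows <- list()
  arc <- 0
  for (si in seq_along(m$sections)) {
    s <- m$sections[[si]]
    n <- nrow(s$points)
    p1 <- s$points[-n, , drop = FALSE]
    p2 <- s$points[-1, , drop = FALSE]
    len <- sqrt(rowSums((p2 - p1)^2))
    axonal <- s$type %in% c("axon", "AIS")
    arc_start <- if (axonal) arc + cumsum(c(0, len[-length(len)])) else NA_real_
    if (axonal) arc <- arc + sum(len)
    rows[[si]] <- data.frame(
      section = si, segment = seq_len(n - 1L), type = s$type,
      p1x = p1[, 1], p1y = p1[, 2], p1z = p1[, 3],
      p2x = p2[, 1], p2y = p2[, 2], p2z = p2[, 3],
      r = (s$radii[-n] + s$radii[-1]) / 2,
      len = len, arc_start = arc_start
    )
  }
  do.call(rbind, rows)
}

# Closest approach between paired 3D segments (vectorized over rows).
# Returns the centreline distance, and the position/parameter of the closest
# point on the first segment. Standard clamped closest-point algorithm.
segment_pair_distance <- function(P1, P2, Q1, Q2) {
  d1 <- P2 - P1
  d2 <- Q2 - Q1
  r <- P1 - Q1
  a <- rowSums(d1 * d1)
  e <- rowSums(d2 * d2)
  b <- rowSums(d1 * d2)
  c_ <- rowSums(d1 * r)
  f <- rowSums(d2 * r)
  denom <- a * e - b * b
  s <- ifelse(denom > 1e-12, pmin(1, pmax(0, (b * f - c_ * e) / denom)), 0)
  t <- ifelse(e > 1e-12, (b * s + f) / e, 0)
  t_cl <- pmin(1, pmax(0, t))
  # re-project s where t was clamped
  s <- ifelse(t != t_cl & a > 1e-12,
              pmin(1, pmax(0, (b * t_cl - c_) / a)), s)
  cp <- P1 + d1 * s
  cq <- Q1 + d2 * t_cl
  list(distance = sqrt(rowSums((cp - cq)^2)), s = s, point = cp)
}

compartment_label <- function(type) {
  c(axon = "axon", AIS = "AIS", soma = "soma",
    basal = "dendrite", apical = "dendrite")[type]
}

#' Find appositions between morphologies
#'
#' Reports an apposition wherever the surface-to-surface distance (centreline
#' distance minus both radii, floored at zero) between a presynaptic axonal
#' segment and a postsynaptic target segment does not exceed the touch
#' distance of the presynaptic synapse class. Runs of adjacent touching
#' segment pairs (contiguous along both arbors) are merged into a single
#' apposition at the point of minimum gap. Ordered pairs are handled
#' independently: (a, b) and (b, a) are both probed.
#'
#' @param morphologies List of [morphology()] objects.
#' @param touch_distance_E,touch_distance_I Maximal bridgeable membrane gap in
#'   micrometres for excitatory and inhibitory presynaptic neurons.
#' @param method `"grid"` (uniform-cell spatial index, the default) or
#'   `"bruteforce"` (all segment pairs; the oracle the index is tested
#'   against).
#' @param merge_adjacent Collapse contiguous touching segment pairs into one
#'   apposition (default `TRUE`).
#' @param include_axon_targets Also probe plain axonal shafts as targets
#'   (default `FALSE`; AIS segments are always probed).
#' @return Apposition data frame with columns `pre_id`, `post_id`,
#'   `pre_mtype`, `post_mtype`, `pre_class`, `post_class`, `pre_section`,
#'   `pre_segment`, `post_section`, `post_segment`, `post_compartment`,
#'   `x`, `y`, `z`, `arc_length_um`, `gap_um`.
#' @export
find_appositions <- function(morphologies,
                             touch_distance_E = 2.5,
                             touch_distance_I = 0.5,
                             method = c("grid", "bruteforce"),
                             merge_adjacent = TRUE,
                             include_axon_targets = FALSE) {
  method <- match.arg(method)
  if (touch_distance_E <= 0 || touch_distance_I <= 0) {
    stop("touch distances must be positive")
  }
  segs <- lapply(morphologies, segment_table)
  ids <- vapply(morphologies, function(m) m$neuron_id, character(1))
  out <- list()
  for (ai in seq_along(morphologies)) {
    pre_m <- morphologies[[ai]]
    td <- if (pre_m$synapse_class == "E") touch_distance_E else touch_distance_I
    pre_seg <- segs[[ai]]
    pre_seg <- pre_seg[pre_seg$type %in% c("axon", "AIS"), , drop = FALSE]
    if (nrow(pre_seg) == 0) {
      warning("neuron ", pre_m$neuron_id, " has no axon; skipped as ",
              "presynaptic candidate")
      next
    }
    for (bi in seq_along(morphologies)) {
      if (bi == ai) next
      post_m <- morphologies[[bi]]
      tgt_types <- c("basal", "apical", "soma", "AIS")
      if (include_axon_targets) tgt_types <- c(tgt_types, "axon")
      post_seg <- segs[[bi]]
      post_seg <- post_seg[post_seg$type %in% tgt_types, , drop = FALSE]
      if (nrow(post_seg) == 0) next
      pairs <- candidate_pairs(pre_seg, post_seg, td, method)
      if (nrow(pairs) == 0) next
      pp <- pre_seg[pairs$i, , drop = FALSE]
      qq <- post_seg[pairs$j, , drop = FALSE]
      cd <- segment_pair_distance(
        as.matrix(pp[, c("p1x", "p1y", "p1z")]),
        as.matrix(pp[, c("p2x", "p2y", "p2z")]),
        as.matrix(qq[, c("p1x", "p1y", "p1z")]),
        as.matrix(qq[, c("p2x", "p2y", "p2z")])
      )
      gap <- pmax(0, cd$distance - pp$r - qq$r)
      keep <- gap <= td
      if (!any(keep)) next
      hits <- data.frame(
        pre_id = pre_m$neuron_id, post_id = post_m$neuron_id,
        pre_mtype = pre_m$m_type, post_mtype = post_m$m_type,
        pre_class = pre_m$synapse_class, post_class = post_m$synapse_class,
        pre_section = pp$section[keep], pre_segment = pp$segment[keep],
        post_section = qq$section[keep], post_segment = qq$segment[keep],
        post_compartment = unname(compartment_label(qq$type[keep])),
        x = cd$point[keep, 1], y = cd$point[keep, 2], z = cd$point[keep, 3],
        arc_length_um = pp$arc_start[keep] + cd$s[keep] * pp$len[keep],
        gap_um = gap[keep]
      )
      if (merge_adjacent) hits <- merge_adjacent_hits(hits)
      out[[length(out) + 1L]] <- hits
    }
  }
  if (length(out) == 0) {
    res <- empty_apposition_table()
    res$pre_class <- character(0); res$post_class <- character(0)
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Candidate segment pairs: either everything, or only pairs whose midpoints
# fall in the same or adjacent cells of a uniform grid with cell size
# touch distance + the longest segment (so no true hit can be missed).
candidate_pairs <- function(pre_seg, post_seg, td, method) {
  if (method == "bruteforce") {
    return(expand.grid(i = seq_len(nrow(pre_seg)),
                       j = seq_len(nrow(post_seg))))
  }
  cell <- td + max(pre_seg$len, post_seg$len) +
    2 * max(pre_seg$r, post_seg$r)
  mid <- function(s) cbind((s$p1x + s$p2x) / 2, (s$p1y + s$p2y) / 2,
                           (s$p1z + s$p2z) / 2)
  key <- function(m) floor(m / cell)
  kp <- key(mid(pre_seg))
  kq <- key(mid(post_seg))
  # hash post segments by cell
  hq <- split(seq_len(nrow(post_seg)),
              paste(kq[, 1], kq[, 2], kq[, 3], sep = ","))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ii <- jj <- vector("list", nrow(pre_seg))
  for (i in seq_len(nrow(pre_seg))) {
    neigh <- sweep(offs, 2, kp[i, ], "+")
    keys <- paste(neigh[, 1], neigh[, 2], neigh[, 3], sep = ",")
    js <- unlist(hq[keys], use.names = FALSE)
    if (length(js)) {
      ii[[i]] <- rep.int(i, length(js))
      jj[[i]] <- js
    }
  }
  data.frame(i = unlist(ii), j = unlist(jj))
}

# Collapse contiguous contact regions into one apposition at the minimum gap:
# two touching segment pairs belong to the same region when they sit on the
# same pre/post sections and differ by at most one segment index along both
# arbors (8-connectivity on the segment-pair grid, via union-find).
merge_adjacent_hits <- function(hits) {
  if (nrow(hits) <= 1) return(hits)
  parent <- seq_len(nrow(hits))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  grp <- split(seq_len(nrow(hits)),
               paste(hits$pre_section, hits$post_section))
  for (ix in grp) {
    lookup <- new.env(parent = emptyenv())
    for (i in ix) {
      assign(paste(hits$pre_segment[i], hits$post_segment[i]), i,
             envir = lookup)
    }
    for (i in ix) {
      for (da in -1:1) for (db in -1:1) {
        key <- paste(hits$pre_segment[i] + da, hits$post_segment[i] + db)
        j <- lookup[[key]]
        if (!is.null(j) && j != i) parent[find(j)] <- find(i)
      }
    }
  }
  cluster <- vapply(seq_len(nrow(hits)), find, integer(1))
  keep <- vapply(split(seq_len(nrow(hits)), cluster), function(ix) {
    ix[which.min(hits$gap_um[ix])]
  }, integer(1))
  res <- hits[sort(keep), ]
  rownames(res) <- NULL
  res
}

#' Compartment-exception rule set
#'
#' Builds the preparatory filtering rules that restrict potential synapses to
#' biologically plausible postsynaptic compartments. Rules are matched
#' most-specific-first (top to bottom); the first match decides. The defaults
#' encode: chandelier-cell axons target exclusively the axon initial segment
#' of pyramidal cells; excitatory axons never touch excitatory somata
#' (dendrites only for E-E); all other pathways may target dendrite and soma;
#' axonal shafts are never targets.
#'
#' @param overrides Optional data frame with columns `pre`, `post`,
#'   `compartments` prepended (highest priority) to the default rules. `pre`
#'   and `post` entries are either a synapse class (`"E"`/`"I"`), `"*"`, or a
#'   regular expression matched against the m-type. `compartments` is a
#'   comma-separated subset of `dendrite,soma,AIS,axon` (or `"none"`).
#' @return Data frame of class `compartment_rules`.
#' @export
compartment_rules <- function(overrides = NULL) {
  base <- data.frame(
    pre = c("ChC", "ChC", "E", "E", "I"),
    post = c("PC", "*", "E", "I", "*"),
    compartments = c("AIS", "none", "dendrite", "dendrite,soma",
                     "dendrite,soma")
  )
  if (!is.null(overrides)) {
    stopifnot(all(c("pre", "post", "compartments") %in% names(overrides)))
    base <- rbind(overrides[, c("pre", "post", "compartments")], base)
  }
  class(base) <- c("compartment_rules", "data.frame")
  base
}

match_token <- function(token, m_type, synapse_class) {
  if (token == "*") return(rep(TRUE, length(m_type)))
  if (token %in% c("E", "I")) return(synapse_class == token)
  grepl(token, m_type)
}

#' Apply compartment-exception rules to an apposition table
#'
#' Keeps only appositions whose postsynaptic compartment is allowed by the
#' first matching rule for the (pre, post) pathway; all surviving rows are
#' unmodified copies of input rows. An apposition whose pathway matches no
#' rule is an error: the rule set must be total.
#'
#' @param appositions Apposition data frame (needs `pre_mtype`, `post_mtype`,
#'   `pre_class`, `post_class`, `post_compartment`; missing class columns are
#'   looked up from `neurons`).
#' @param rules A [compartment_rules()] rule set.
#' @param neurons Optional neuron metadata (columns `neuron_id`, `m_type`,
#'   `synapse_class`) used to fill in missing class columns.
#' @return The filtered apposition data frame.
#' @export
apply_compartment_rules <- function(appositions, rules = compartment_rules(),
                                    neurons = NULL) {
  if (nrow(appositions) == 0) return(appositions)
  if (!"post_compartment" %in% names(appositions)) {
    stop("appositions must carry a post_compartment column")
  }
  for (side in c("pre", "post")) {
    col <- paste0(side, "_class")
    if (!col %in% names(appositions)) {
      if (is.null(neurons)) stop("missing ", col, " and no neuron metadata")
      appositions[[col]] <- neurons$synapse_class[
        match(appositions[[paste0(side, "_id")]], neurons$neuron_id)]
    }
  }
  n <- nrow(appositions)
  decided <- rep(FALSE, n)
  keep <- rep(FALSE, n)
  for (ri in seq_len(nrow(rules))) {
    hit <- !decided &
      match_token(rules$pre[ri], appositions$pre_mtype,
                  appositions$pre_class) &
      match_token(rules$post[ri], appositions$post_mtype,
                  appositions$post_class)
    if (!any(hit)) next
    allowed <- strsplit(rules$compartments[ri], ",", fixed = TRUE)[[1]]
    keep[hit] <- appositions$post_compartment[hit] %in% trimws(allowed)
    decided[hit] <- TRUE
  }
  if (!all(decided)) {
    miss <- appositions[!decided, c("pre_mtype", "post_mtype")]
    stop("no compartment rule matches pathway ",
         paste0(miss$pre_mtype[1], " -> ", miss$post_mtype[1]),
         " (rule set must be total)")
  }
  res <- appositions[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}
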