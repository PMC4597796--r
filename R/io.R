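# Readers and writers: SWC morphologies, TSV tables, YAML/JSON run
# configuration. All tabular artifacts are plain TSV so runs diff cleanly.

#' Read a morphology from an SWC file
#'
#' Standard seven-column SWC (id, type, x, y, z, radius, parent). Type codes:
#' 1 = soma, 2 = axon, 3 = basal dendrite, 4 = apical dendrite. Nodes are
#' assembled into unbranched sections between branch points; the first
#' `ais_length` micrometres of axonal arc from the soma are relabelled as the
#' axon initial segment (AIS is a derived compartment, not a native SWC type).
#'
#' @param path SWC file path.
#' @param neuron_id,m_type,layer,synapse_class Metadata for the morphology
#'   (defaults derive the id from the file name).
#' @param ais_length Arc length of axon relabelled as AIS, micrometres
#'   (default 40; 0 disables).
#' @return A [morphology()].
#' @export
read_swc <- function(path, neuron_id = NULL, m_type = "generic",
                     layer = "L0", synapse_class = "E", ais_length = 40) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("no data rows in ", path)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) != 7)
  if (length(bad)) {
    stop("malformed SWC row at line ", which(keep)[bad[1]])
  }
  tab <- as.data.frame(do.call(rbind, lapply(fields, as.numeric)))
  names(tab) <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (anyNA(tab)) stop("non-numeric SWC field in ", path)
  if (!all(tab$type %in% 1:4)) {
    stop("unknown SWC type code at line ",
         which(keep)[which(!tab$type %in% 1:4)[1]])
  }
  idx <- match(tab$parent, tab$id)
  orphan <- tab$parent != -1 & is.na(idx)
  if (any(orphan)) {
    stop("orphan SWC node id ", tab$id[which(orphan)[1]],
         " (parent ", tab$parent[which(orphan)[1]], " not found)")
  }
  # cycle check by walking each node to a root
  for (i in seq_len(nrow(tab))) {
    seen <- integer(0)
    j <- i
    while (tab$parent[j] != -1) {
      if (j %in% seen) stop("cyclic parent reference at node ", tab$id[i])
      seen <- c(seen, j)
      j <- idx[j]
    }
  }
  roots <- which(tab$parent == -1)
  soma_rows <- which(tab$type == 1)
  soma_pos <- if (length(soma_rows)) {
    colMeans(tab[soma_rows, c("x", "y", "z"), drop = FALSE])
  } else as.numeric(tab[roots[1], c("x", "y", "z")])
  # children count per node to find branch points
  n_children <- tabulate(idx[!is.na(idx)], nbins = nrow(tab))
  type_name <- c("soma", "axon", "basal", "apical")
  sections <- list()
  # walk from every section start: root children and branch-point children
  starts <- which(!is.na(idx) &
                    (n_children[idx] > 1 | tab$type != tab$type[idx] |
                       tab$parent == -1))
  starts <- union(starts, which(tab$parent == -1))
  for (s in starts) {
    chain <- s
    j <- s
    while (n_children[j] == 1) {
      child <- which(idx == j)
      if (tab$type[child] != tab$type[j]) break
      chain <- c(chain, child)
      j <- child
    }
    if (length(chain) < 2) {
      # prepend the parent point so the section has a geometric extent
      if (!is.na(idx[s])) chain <- c(idx[s], chain) else next
    } else if (!is.na(idx[s])) {
      chain <- c(idx[s], chain)
    }
    sections[[length(sections) + 1L]] <- section(
      type_name[tab$type[chain[length(chain)]]],
      as.matrix(tab[chain, c("x", "y", "z")]),
      tab$radius[chain]
    )
  }
  if (!length(sections)) stop("no sections assembled from ", path)
  if (ais_length > 0) sections <- relabel_ais(sections, ais_length)
  if (is.null(neuron_id)) {
    neuron_id <- sub("\\.swc$", "", basename(path), ignore.case = TRUE)
  }
  morphology(neuron_id, m_type, layer, synapse_class, soma_pos, sections)
}

#' Write a morphology to an SWC file
#'
#' Inverse of [read_swc()]: AIS sections are written back as axon (type 2),
#' so read-write-read round-trips the geometry losslessly.
#'
#' @param m A [morphology()].
#' @param path Output path.
#' @export
write_swc <- function(m, path) {
  type_code <- c(soma = 1, axon = 2, AIS = 2, basal = 3, apical = 4)
  rows <- list()
  id <- 0L
  # index previously written points so shared section endpoints reuse ids
  seen <- new.env(parent = emptyenv())
  pt_key <- function(p) paste(sprintf("%.9g", p), collapse = ",")
  for (s in m$sections) {
    parent <- -1L
    for (i in seq_len(nrow(s$points))) {
      key <- pt_key(s$points[i, ])
      prior <- if (!is.null(seen[[key]])) seen[[key]] else NA_integer_
      if (!is.na(prior)) { parent <- prior; next }
      id <- id + 1L
      seen[[key]] <- id
      rows[[id]] <- sprintf("%d %d %.6f %.6f %.6f %.6f %d", id,
                            type_code[[s$type]], s$points[i, 1],
                            s$points[i, 2], s$points[i, 3], s$radii[i],
                            parent)
      parent <- id
    }
  }
  writeLines(c("# SWC written by synprune", unlist(rows)), path)
  invisible(path)
}

#' Read and write the package's TSV table artifacts
#'
#' Apposition/synapse tables, derived pruning parameters, pathway constraints
#' and neuron metadata all round-trip through plain TSV.
#'
#' @param tab Data frame to write.
#' @param path File path.
#' @return `read_tsv_table()` returns the data frame.
#' @export
write_tsv_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("table file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Default run configuration
#'
#' All tunables of a reconstruction run with their defaults: touch distances
#' (2.5 um excitatory / 0.5 um inhibitory), the generalized coefficient of
#' variation (0.32), the fallback bouton density (0.2 per um), and the metric
#' settings (100 um connection-probability cutoff, 1 um bouton merge
#' distance, 25 um sampling boxes, 37.5 um central-region radius, 40 um AIS
#' extent).
#'
#' @param path Optional YAML (or JSON) file whose entries override the
#'   defaults.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- list(
    seed = 1L,
    touch_distance_E = 2.5,
    touch_distance_I = 0.5,
    cv = 0.32,
    b_d_default = 0.2,
    use_biological_b_d = TRUE,
    distance_cutoff = 100,
    merge_distance = 1.0,
    box_edge = 25,
    central_radius = 37.5,
    ais_length = 40,
    compartment_rule_overrides = NULL
  )
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) stop("unknown config keys: ",
                              paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(cfg, user)
  }
  if (cfg$touch_distance_E <= 0 || cfg$touch_distance_I <= 0 || cfg$cv <= 0) {
    stop("touch distances and cv must be positive")
  }
  class(cfg) <- "run_config"
  cfg
}
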