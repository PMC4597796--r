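# The three-step stochastic pruning engine: general pruning of individual
# potential synapses (f1), multi-synapse pruning of whole connections through
# a sigmoid on the synapse count (mu2), and plasticity-reserve pruning of
# whole connections independent of synapse count (a3).

pathway_key <- function(tab) paste(tab$pre_mtype, tab$post_mtype, sep = ":")
connection_key <- function(tab) paste(tab$pre_id, tab$post_id, sep = "\r")

# Stochastic results must not depend on the caller's row order: every step
# sorts its input into a canonical order before drawing random numbers.
canonical_order <- function(tab) {
  order(pathway_key(tab), tab$pre_id, tab$post_id, tab$arc_length_um,
        method = "radix")
}

lookup_param <- function(tab, params, col) {
  pw <- pathway_key(tab)
  val <- params[[col]][match(pw, params$pathway)]
  if (anyNA(val)) {
    stop("no ", col, " parameter for pathway ", pw[which(is.na(val))[1]])
  }
  val
}

#' Step 1: general pruning of potential synapses
#'
#' Each potential synapse survives independently with its pathway's survival
#' fraction `f1`; removed synapses go to the inactive pool, accessible to
#' structural plasticity.
#'
#' @param appositions Apposition data frame (preparatory-filtered).
#' @param params Parameter data frame with columns `pathway` and `f1` (see
#'   [derive_parameters()]).
#' @param seed Integer root seed (step 1 draws from its own substream).
#' @return List with `kept` and `inactive_pool` data frames.
#' @export
prune_general <- function(appositions, params, seed) {
  if (nrow(appositions) == 0) {
    return(list(kept = appositions, inactive_pool = appositions))
  }
  f1 <- lookup_param(appositions, params, "f1")
  if (any(f1 < 0 | f1 > 1)) stop("f1 must lie in [0, 1]")
  o <- canonical_order(appositions)
  tab <- appositions[o, , drop = FALSE]
  f1 <- f1[o]
  keep <- with_seed(substream_seed(seed, "prune1"),
                    stats::runif(nrow(tab)) < f1)
  list(kept = reset_rows(tab[keep, , drop = FALSE]),
       inactive_pool = reset_rows(tab[!keep, , drop = FALSE]))
}

#' Step 2: multi-synapse pruning of whole connections
#'
#' A connection (all remaining synapses between one ordered neuron pair)
#' survives with probability [sigmoid_acceptance()] of its synapse count;
#' synapse multisets of surviving connections are unchanged.
#'
#' @param appositions Apposition data frame after step 1 (zero-synapse
#'   connections are already absent by construction).
#' @param params Parameter data frame with columns `pathway` and `mu2`.
#' @param seed Integer root seed (step 2 draws from its own substream).
#' @return List with `kept` and `removed` data frames.
#' @export
prune_multisynapse <- function(appositions, params, seed) {
  if (nrow(appositions) == 0) {
    return(list(kept = appositions, removed = appositions))
  }
  o <- canonical_order(appositions)
  tab <- appositions[o, , drop = FALSE]
  conn <- connection_key(tab)
  first <- !duplicated(conn)
  ns <- as.vector(table(conn)[conn[first]])
  mu2 <- lookup_param(tab[first, , drop = FALSE], params, "mu2")
  if (any(mu2 <= 0)) stop("mu2 must be positive")
  surv <- with_seed(substream_seed(seed, "prune2"),
                    stats::runif(length(ns)) < sigmoid_acceptance(ns, mu2))
  keep_conn <- conn[first][surv]
  keep <- conn %in% keep_conn
  list(kept = reset_rows(tab[keep, , drop = FALSE]),
       removed = reset_rows(tab[!keep, , drop = FALSE]))
}

#' Step 3: plasticity-reserve pruning
#'
#' Each surviving multi-synapse connection becomes active independently with
#' probability `a3`, regardless of its synapse count; removed connections are
#' stored intact in the reserve pool of viable multi-synaptic connections.
#'
#' @param appositions Apposition data frame after step 2.
#' @param params Parameter data frame with columns `pathway` and `a3`.
#' @param seed Integer root seed (step 3 draws from its own substream).
#' @return List with `active` and `reserve_pool` data frames.
#' @export
prune_plasticity <- function(appositions, params, seed) {
  if (nrow(appositions) == 0) {
    return(list(active = appositions, reserve_pool = appositions))
  }
  o <- canonical_order(appositions)
  tab <- appositions[o, , drop = FALSE]
  conn <- connection_key(tab)
  first <- !duplicated(conn)
  a3 <- lookup_param(tab[first, , drop = FALSE], params, "a3")
  if (any(a3 < 0 | a3 > 1)) stop("a3 must lie in [0, 1]")
  surv <- with_seed(substream_seed(seed, "prune3"),
                    stats::runif(sum(first)) < a3)
  keep <- conn %in% conn[first][surv]
  list(active = reset_rows(tab[keep, , drop = FALSE]),
       reserve_pool = reset_rows(tab[!keep, , drop = FALSE]))
}

reset_rows <- function(tab) { rownames(tab) <- NULL; tab }

#' Run the full pruning pipeline
#'
#' Applies the preparatory compartment filter and the three pruning steps in
#' fixed order (general, multi-synapse, plasticity-reserve). Every active
#' synapse is an unmodified row of the input apposition table (the synapse
#' location rule); the three output pools are disjoint and, together with the
#' active set and step-2 removals, conserve the filtered input row count.
#'
#' @param appositions Raw apposition data frame.
#' @param params Parameter data frame with `pathway`, `f1`, `mu2`, `a3`.
#' @param rules Compartment rule set for the preparatory filter; `NULL` skips
#'   filtering (e.g. for statistical fixtures that are already plausible).
#' @param seed Integer root seed; the three steps draw from independent
#'   substreams of it.
#' @param neurons Optional neuron metadata passed to the compartment filter.
#' @return Object of class `connectome_result`: a list with `active`,
#'   `inactive_pool`, `step2_removed`, `reserve_pool`, `stats` (realized
#'   per-pathway statistics), `params`, and `seed`.
#' @export
run_pipeline <- function(appositions, params, rules = compartment_rules(),
                         seed = 1L, neurons = NULL) {
  filtered <- if (is.null(rules)) appositions else {
    apply_compartment_rules(appositions, rules, neurons)
  }
  s1 <- prune_general(filtered, params, seed)
  s2 <- prune_multisynapse(s1$kept, params, seed)
  s3 <- prune_plasticity(s2$kept, params, seed)
  res <- list(active = s3$active,
              inactive_pool = s1$inactive_pool,
              step2_removed = s2$removed,
              reserve_pool = s3$reserve_pool,
              stats = realized_stats(s3$active),
              params = params, seed = seed,
              n_input = nrow(filtered))
  class(res) <- "connectome_result"
  res
}

#' Realized per-pathway connectivity statistics
#'
#' @param active Active synapse table.
#' @return Data frame with `pathway`, `n_connections`, `n_synapses`, realized
#'   `s_m` and `s_sd`.
#' @export
realized_stats <- function(active) {
  if (nrow(active) == 0) {
    return(data.frame(pathway = character(), n_connections = integer(),
                      n_synapses = integer(), s_m = numeric(),
                      s_sd = numeric()))
  }
  pw <- pathway_key(active)
  conn <- connection_key(active)
  out <- lapply(split(conn, pw), function(cc) {
    k <- as.integer(table(cc))
    data.frame(n_connections = length(k), n_synapses = sum(k),
               s_m = mean(k), s_sd = stats::sd(k))
  })
  res <- do.call(rbind, out)
  res <- cbind(pathway = names(split(conn, pw)), res)
  rownames(res) <- NULL
  res
}

#' @export
print.connectome_result <- function(x, ...) {
  cat("connectome_result (seed ", x$seed, ")\n", sep = "")
  cat(sprintf(" input synapses: %d\n active: %d  inactive pool: %d  step-2 removed: %d  reserve: %d\n",
              x$n_input, nrow(x$active), nrow(x$inactive_pool),
              nrow(x$step2_removed), nrow(x$reserve_pool)))
  if (nrow(x$stats) > 0) {
    cat(" realized pathway statistics:\n")
    print(x$stats, row.names = FALSE)
  }
  invisible(x)
}
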