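# Derivation of the three per-pathway pruning parameters (f1, mu2, a3) from
# connectivity constraints, via the closed forms that exploit the geometric
# law of apposition counts per connection, plus the axon-length/bouton-density
# budget bookkeeping.

#' Maximum-likelihood fit of the geometric apposition-count law
#'
#' Apposition counts per connected pair follow a geometric distribution on
#' \{1, 2, ...\}: `P(n = k) = (1 - p)^(k - 1) * p`. The ML estimate is
#' `p = 1 / mean(counts)`.
#'
#' @param counts Positive integer apposition counts, one per connection.
#' @return The geometric parameter `p` in (0, 1].
#' @export
fit_geometric <- function(counts) {
  if (length(counts) == 0) stop("empty count vector")
  if (any(counts < 1)) stop("all counts must be >= 1")
  1 / mean(counts)
}

#' Per-pathway apposition statistics
#'
#' Summarises an apposition table into the statistics the parameter derivation
#' consumes: mean appositions per connected pair (`s_m_struc`), the geometric
#' parameter `p = 1/s_m_struc`, the number of apposed pairs, and the total
#' presynaptic axon length.
#'
#' @param appositions Apposition data frame with `pre_id`, `post_id`,
#'   `pre_mtype`, `post_mtype`.
#' @param neurons Neuron metadata with `neuron_id` and `axon_length_um`
#'   (`NA` total axon length is reported if absent).
#' @return Data frame with one row per pathway: `pathway`, `pre_mtype`,
#'   `post_mtype`, `s_m_struc`, `p`, `n_pairs_apposed`, `total_axon_length_um`.
#' @export
apposition_stats <- function(appositions, neurons = NULL) {
  if (nrow(appositions) == 0) {
    return(data.frame(pathway = character(), pre_mtype = character(),
                      post_mtype = character(), s_m_struc = numeric(),
                      p = numeric(), n_pairs_apposed = integer(),
                      total_axon_length_um = numeric()))
  }
  pw <- paste(appositions$pre_mtype, appositions$post_mtype, sep = ":")
  conn <- paste(appositions$pre_id, appositions$post_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(appositions)), pw), function(ix) {
    k <- as.integer(table(conn[ix]))
    pre_ids <- unique(appositions$pre_id[ix])
    axlen <- if (!is.null(neurons) && "axon_length_um" %in% names(neurons)) {
      sum(neurons$axon_length_um[match(pre_ids, neurons$neuron_id)])
    } else NA_real_
    data.frame(
      pathway = pw[ix[1]],
      pre_mtype = appositions$pre_mtype[ix[1]],
      post_mtype = appositions$post_mtype[ix[1]],
      s_m_struc = mean(k), p = 1 / mean(k),
      n_pairs_apposed = length(k),
      total_axon_length_um = axlen
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Predict pathway constraints from apposition statistics
#'
#' Where no biological measurements exist, the target connectivity statistics
#' are predicted from the structural (apposition-based) mean: for E-E pathways
#' `S_m = 1.5 * S_m_struc`; for all other pathways
#' `S_m = 9 * sqrt(S_m_struc - 1) - 2` (floored at 1). The standard deviation
#' is predicted through a generalized coefficient of variation
#' (`S_sd = cv * S_m`, floored just above 0.5, the minimum the parameter
#' derivation admits), and the bouton density defaults to a grand average
#' unless a per-m-type biological value is supplied.
#'
#' @param stats One-row slice of [apposition_stats()] output, or a data frame
#'   of several pathways.
#' @param pathway_class `"EE"` or `"other"`, recycled along `stats`.
#' @param cv Generalized coefficient of variation (default 0.32).
#' @param b_d_default Fallback bouton density in synapses per micrometre
#'   (default 0.2).
#' @param b_d_table Optional per-m-type bouton density lookup (columns
#'   `m_type`, `bio`), e.g. [reference_table]`("bouton_densities")`.
#' @return Data frame with `pathway`, `s_m`, `s_sd`, `b_d`, `source`, `cv`.
#' @export
predict_constraints <- function(stats, pathway_class, cv = 0.32,
                                b_d_default = 0.2, b_d_table = NULL) {
  if (any(stats$s_m_struc < 1)) stop("s_m_struc must be >= 1")
  pathway_class <- rep_len(pathway_class, nrow(stats))
  s_m <- ifelse(pathway_class == "EE",
                1.5 * stats$s_m_struc,
                9 * sqrt(stats$s_m_struc - 1) - 2)
  s_m <- pmax(s_m, 1.0)
  s_sd <- pmax(cv * s_m, 0.5 + 1e-6)
  b_d <- rep(b_d_default, nrow(stats))
  if (!is.null(b_d_table)) {
    hit <- match(stats$pre_mtype, b_d_table$m_type)
    b_d <- ifelse(is.na(hit), b_d, b_d_table$bio[hit])
  }
  data.frame(pathway = stats$pathway, s_m = s_m, s_sd = s_sd, b_d = b_d,
             source = "derived", cv = cv)
}

#' Sigmoid acceptance probability of multi-synapse pruning
#'
#' A connection carrying `ns` synapses survives the multi-synapse pruning step
#' with probability `1 / (1 + exp(-(16 / mu2) * (ns - mu2)))`: a rising
#' sigmoid centred at `mu2` whose transition width is `0.25 * mu2`. Evaluated
#' through `plogis()`, which is overflow-safe for large arguments.
#'
#' @param ns Synapse counts (vectorized).
#' @param mu2 Sigmoid offset (> 0).
#' @return Survival probabilities in (0, 1).
#' @export
sigmoid_acceptance <- function(ns, mu2) {
  stopifnot(mu2 > 0)
  stats::plogis((16 / mu2) * (ns - mu2))
}

#' Analytic expectation of the first two pruning steps
#'
#' Exact expectation (up to a configurable tail quantile of the geometric law)
#' of the state after general pruning and multi-synapse pruning: apposition
#' counts `k ~ geometric(p)` on \{1, 2, ...\}, surviving synapse counts
#' `j ~ binomial(k, f1)` (connections thinned to zero synapses are dropped),
#' and sigmoid acceptance of `j` with offset `mu2`.
#'
#' @param p Geometric parameter of the input apposition counts.
#' @param f1 General-pruning synapse survival fraction in `[0, 1]`.
#' @param mu2 Multi-synapse pruning offset (> 0).
#' @param tail_quantile Geometric support is truncated at this CDF quantile
#'   (default `1 - 1e-9`).
#' @param n_connections,total_axon_length If both are given, the expected
#'   post-step-2 synapse density `b2` (synapses per micrometre of presynaptic
#'   axon, i.e. the bouton density if every surviving multi-synapse connection
#'   were retained) is also returned.
#' @return List with `mean_synapses` (per surviving connection),
#'   `survival_fraction` (connections surviving steps 1-2),
#'   `synapses_per_connection` (unconditional expectation), and `b2`
#'   (or `NA` when lengths are not supplied).
#' @export
expected_survival <- function(p, f1, mu2, tail_quantile = 1 - 1e-9,
                              n_connections = NULL,
                              total_axon_length = NULL) {
  stopifnot(p > 0, p <= 1, f1 >= 0, f1 <= 1, mu2 > 0)
  if (f1 == 0) {
    return(list(mean_synapses = NaN, survival_fraction = 0,
                synapses_per_connection = 0, b2 = 0))
  }
  k_max <- if (p < 1) {
    max(3L, ceiling(log1p(-tail_quantile) / log1p(-p)))
  } else 1L
  e_surv <- 0
  e_syn <- 0
  for (k in seq_len(k_max)) {
    pk <- (1 - p)^(k - 1) * p
    j <- seq_len(k)
    bj <- stats::dbinom(j, k, f1)
    acc <- sigmoid_acceptance(j, mu2)
    e_surv <- e_surv + pk * sum(bj * acc)
    e_syn <- e_syn + pk * sum(j * bj * acc)
  }
  b2 <- if (!is.null(n_connections) && !is.null(total_axon_length)) {
    n_connections * e_syn / total_axon_length
  } else NA_real_
  list(mean_synapses = e_syn / e_surv, survival_fraction = e_surv,
       synapses_per_connection = e_syn, b2 = b2)
}

#' Derive the three pruning parameters for one pathway
#'
#' Implements the closed-form solution of the pruning equation system under
#' the geometric apposition-count law:
#' `p' = 1 / (S_sd + 0.5)` (the geometric parameter targeted after general
#' pruning), `f1 = p / (1 - p) * (1 - p') / p'`,
#' `mu2 = 0.5 + S_m - S_sd`, and `a3 = B_d / B2` where `B2` is the synapse
#' density after the first two steps. `f1` and `a3` are clamped to `[0, 1]`
#' with flags; when `f1` clamps, `mu2` is re-solved numerically so that the
#' expected post-step-2 mean still hits `S_m` (the priority order is
#' `S_m > S_sd > B_d`). A reserve-rule warning flag is set whenever
#' `a3 > 0.5`, i.e. when less than half of the viable multi-synapse
#' connections would remain in the plasticity reserve.
#'
#' @param stats One row of [apposition_stats()] (needs `p`,
#'   `n_pairs_apposed`, `total_axon_length_um`).
#' @param constraints One row with `s_m`, `s_sd`, `b_d` (see
#'   [predict_constraints()] or biological values).
#' @param mu2_floor Smallest admissible `mu2` (default 0.001).
#' @return Data frame row with `pathway`, `f1`, `mu2`, `a3`, `p_prime`, `b2`,
#'   and logical flags `f1_clamped`, `a3_clamped`, `reserve_rule_warning`.
#' @export
derive_parameters <- function(stats, constraints, mu2_floor = 1e-3) {
  if (nrow(stats) > 1) {
    out <- lapply(seq_len(nrow(stats)), function(i) {
      derive_parameters(stats[i, , drop = FALSE],
                        constraints[i, , drop = FALSE], mu2_floor)
    })
    return(do.call(rbind, out))
  }
  p <- stats$p
  s_m <- constraints$s_m
  s_sd <- constraints$s_sd
  if (s_sd <= 0.5) stop("s_sd must exceed 0.5")
  p_prime <- 1 / (s_sd + 0.5)
  f1_raw <- if (p >= 1) Inf else (p / (1 - p)) * ((1 - p_prime) / p_prime)
  f1_clamped <- f1_raw > 1
  f1 <- min(1, f1_raw)
  mu2 <- max(0.5 + s_m - s_sd, mu2_floor)
  if (f1_clamped) {
    # f1 cannot thin enough: re-solve mu2 so the post-step-2 mean equals S_m
    mu2 <- solve_mu2(p, f1, s_m, lower = 0.5, upper = 50, tol = 1e-4)
  }
  es <- expected_survival(p, f1, mu2,
                          n_connections = stats$n_pairs_apposed,
                          total_axon_length = stats$total_axon_length_um)
  b2 <- es$b2
  a3_raw <- if (is.na(b2) || b2 <= 0) NA_real_ else constraints$b_d / b2
  a3_clamped <- !is.na(a3_raw) && a3_raw > 1
  a3 <- if (is.na(a3_raw)) NA_real_ else min(1, max(0, a3_raw))
  data.frame(
    pathway = stats$pathway, f1 = f1, mu2 = mu2, a3 = a3,
    p_prime = p_prime, b2 = b2,
    f1_clamped = f1_clamped, a3_clamped = a3_clamped,
    reserve_rule_warning = !is.na(a3) && a3 > 0.5
  )
}

# Solve mu2 against the analytic post-step-2 mean. The mean is not monotone
# in mu2 (the sigmoid's transition width grows with its offset, so very large
# mu2 flattens the cutoff again); a grid scan finds a bracket on the rising
# flank, then bisection refines it. If the target mean is unattainable the
# best-effort mu2 (the grid argmax) is returned.
solve_mu2 <- function(p, f1, s_m_target, lower = 0.5, upper = 50,
                      tol = 1e-4) {
  g <- function(mu2) expected_survival(p, f1, mu2)$mean_synapses - s_m_target
  if (g(lower) >= 0) return(lower)
  grid <- exp(seq(log(lower), log(upper), length.out = 60))
  vals <- vapply(grid, g, numeric(1))
  above <- which(vals >= 0)
  if (length(above) == 0) return(grid[which.max(vals)])
  hi <- grid[above[1]]
  lo <- if (above[1] > 1) grid[above[1] - 1] else lower
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Axon-length/bouton-density budget check
#'
#' The total synapse budget of a presynaptic m-type `a` is
#' `A_l(a) * B_d(a)`; the connectivity spends
#' `sum_b S_m(a,b) * Chat_p(a,b) * Chat_d(b)` of it across postsynaptic types
#' `b`. This returns the relative residual per presynaptic m-type, and splits
#' any residual budget across pathways whose properties are unknown,
#' proportionally to their apposition counts (the Peters'-rule split).
#'
#' @param pathways Data frame with columns `pre_mtype`, `post_mtype`, `s_m`,
#'   `c_p_hat` (mean connection probability over the axonal extent), `c_d_hat`
#'   (potential target count within the axonal extent), `known` (logical), and
#'   `n_appositions`.
#' @param pre_types Data frame with columns `m_type`, `a_l` (total axon
#'   length, micrometres), `b_d` (target bouton density, per micrometre).
#' @return List with `residuals` (per pre m-type: `lhs`, `rhs`, `residual` =
#'   (lhs - rhs)/rhs) and `unknown_allocation` (per unknown pathway: the
#'   allocated `s_m * c_p_hat * c_d_hat` product budget).
#' @export
check_budget <- function(pathways, pre_types) {
  need <- c("pre_mtype", "post_mtype", "s_m", "c_p_hat", "c_d_hat", "known",
            "n_appositions")
  stopifnot(all(need %in% names(pathways)),
            all(c("m_type", "a_l", "b_d") %in% names(pre_types)))
  if (anyNA(pre_types$a_l) || anyNA(pre_types$b_d)) {
    stop("missing a_l or b_d for a presynaptic m-type")
  }
  res <- lapply(seq_len(nrow(pre_types)), function(i) {
    a <- pre_types$m_type[i]
    pw <- pathways[pathways$pre_mtype == a, , drop = FALSE]
    lhs <- sum(pw$s_m * pw$c_p_hat * pw$c_d_hat)
    rhs <- pre_types$a_l[i] * pre_types$b_d[i]
    data.frame(m_type = a, lhs = lhs, rhs = rhs,
               residual = (lhs - rhs) / rhs)
  })
  residuals <- do.call(rbind, res)
  alloc <- lapply(seq_len(nrow(pre_types)), function(i) {
    a <- pre_types$m_type[i]
    pw <- pathways[pathways$pre_mtype == a, , drop = FALSE]
    known <- pw[pw$known, , drop = FALSE]
    unknown <- pw[!pw$known, , drop = FALSE]
    if (nrow(unknown) == 0) return(NULL)
    budget <- pre_types$a_l[i] * pre_types$b_d[i] -
      sum(known$s_m * known$c_p_hat * known$c_d_hat)
    share <- unknown$n_appositions / sum(unknown$n_appositions)
    data.frame(pre_mtype = a, post_mtype = unknown$post_mtype,
               allocated_product = budget * share)
  })
  alloc <- alloc[!vapply(alloc, is.null, logical(1))]
  list(residuals = residuals,
       unknown_allocation = if (length(alloc)) do.call(rbind, alloc) else
         data.frame(pre_mtype = character(), post_mtype = character(),
                    allocated_product = numeric()))
}
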