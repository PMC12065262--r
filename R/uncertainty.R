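#' Build a posterior chain ensemble
#'
#' Draws `k` coefficient vectors from the fitted posterior of each model in
#' the chain and defines the Cartesian product of draws as the ensemble of
#' chain realizations. The two diel depth models share one ensemble slot
#' (their draws are indexed jointly), so the product has exactly four
#' factors — depth, cost, HIF, ingestion — and `k^4` members (10,000 at the
#' default `k = 10`). Members are enumerated lazily as index tuples; full
#' prediction maps are never materialized for all members at once.
#'
#' @param models model list from [fit_energetics_models()] (all five fitted
#'   objects, each carrying a coefficient covariance)
#' @param k draws per model slot (>= 1; default 10)
#' @param seed integer seed (draws are reproducible)
#' @param percentiles percentiles reported by [anomaly_percentiles()]
#' @return an object of class `chain_ensemble`
#' @examples
#' \donttest{
#' # ensemble_size(build_ensemble(models, k = 10)) == 10000
#' }
#' @export
build_ensemble <- function(models, k = 10, seed = 1L,
                           percentiles = c(5, 95)) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (any(percentiles <= 0 | percentiles >= 100) ||
      is.unsorted(percentiles))
    stop("percentiles must be ascending within (0, 100)", call. = FALSE)
  slots <- c("depth_day", "depth_night", "cost", "hif", "ingestion")
  for (s in slots)
    if (is.null(models[[s]]$covariance))
      stop("model '", s, "' carries no coefficient covariance",
           call. = FALSE)
  draws <- lapply(stats::setNames(nm = slots), function(s)
    simulate_coefficients(models[[s]], k, derive_seed(seed, "draw", s)))
  structure(list(models = models, k = as.integer(k), draws = draws,
                 percentiles = percentiles, seed = seed),
            class = "chain_ensemble")
}

#' @export
print.chain_ensemble <- function(x, ...) {
  cat(sprintf("<chain_ensemble> k = %d per slot -> %d chain realizations\n",
              x$k, ensemble_size(x)))
  invisible(x)
}

#' Number of chain realizations in an ensemble
#' @param ensemble a `chain_ensemble`
#' @return `k^4`
#' @export
ensemble_size <- function(ensemble) as.integer(round(ensemble$k^4))

#' Enumerate ensemble members as index tuples
#'
#' One row per chain realization: the draw index used for the (joint)
#' depth slot, the cost, HIF and ingestion slots.
#'
#' @param ensemble a `chain_ensemble`
#' @return data.frame with `k^4` rows and columns `depth`, `cost`, `hif`,
#'   `ingestion`
#' @export
ensemble_realizations <- function(ensemble) {
  k <- ensemble$k
  expand.grid(depth = seq_len(k), cost = seq_len(k), hif = seq_len(k),
              ingestion = seq_len(k), KEEP.OUT.ATTRS = FALSE)
}

# coefficient overrides for one member (row of ensemble_realizations)
member_coefs <- function(ensemble, member) {
  list(depth_day = ensemble$draws$depth_day[member[["depth"]], ],
       depth_night = ensemble$draws$depth_night[member[["depth"]], ],
       cost = ensemble$draws$cost[member[["cost"]], ],
       hif = ensemble$draws$hif[member[["hif"]], ],
       ingestion = ensemble$draws$ingestion[member[["ingestion"]], ])
}

#' Per-member future-minus-historical balance maps
#'
#' Evaluates the projected change in daily kJ balance for each requested
#' ensemble member over one month, returning a member x cell matrix.
#' Evaluating all `k^4` members is rarely necessary; pass a subset of
#' realization rows (e.g. a random sample) for Monte-Carlo summaries.
#'
#' @param ensemble a `chain_ensemble`
#' @param env_hist,env_fut `env_field_set`s on a common grid
#' @param const an [energetics_constants()]
#' @param month month index to evaluate
#' @param members data.frame of realization rows (default: all)
#' @return matrix `n_members x n_cells` of balance changes (kJ), cells in
#'   column-major grid order
#' @export
ensemble_delta_balance <- function(ensemble, env_hist, env_fut,
                                   const = energetics_constants(),
                                   month = 1,
                                   members = NULL) {
  if (is.null(members)) members <- ensemble_realizations(ensemble)
  out <- matrix(NA_real_, nrow(members),
                env_hist$grid$n_lon * env_hist$grid$n_lat)
  for (i in seq_len(nrow(members))) {
    cf <- member_coefs(ensemble, as.list(members[i, ]))
    mh <- project_energetics(env_hist, ensemble$models, const,
                             months = month, coefs = cf)[[1]]
    mf <- project_energetics(env_fut, ensemble$models, const,
                             months = month, coefs = cf)[[1]]
    out[i, ] <- as.vector(mf$fields$balance - mh$fields$balance)
  }
  out
}

#' Per-cell percentiles of ensemble balance anomalies
#'
#' Empirical percentiles of the future balance anomaly per grid cell
#' across ensemble members, plus the mask of cells whose percentile
#' interval contains zero (no resolvable direction of change).
#'
#' @param member_matrix member x cell matrix (e.g. from
#'   [ensemble_delta_balance()])
#' @param percentiles ascending percentiles in (0, 100)
#' @return list with `percentiles` (a `length(percentiles) x n_cells`
#'   matrix) and `overlap_zero` (logical per cell)
#' @export
anomaly_percentiles <- function(member_matrix, percentiles = c(5, 95)) {
  if (nrow(member_matrix) < 2)
    stop("need at least 2 ensemble members", call. = FALSE)
  q <- apply(member_matrix, 2, stats::quantile,
             probs = percentiles / 100, names = FALSE)
  q <- matrix(q, nrow = length(percentiles))
  rownames(q) <- paste0("p", percentiles)
  list(percentiles = q,
       overlap_zero = q[1, ] <= 0 & q[nrow(q), ] >= 0)
}

#' Attribute projection spread to chain slots and the climate ensemble
#'
#' One-factor-at-a-time design: for each slot (each fitted model, and the
#' choice of climate source), the spread of the summary statistic — the
#' mean future-minus-historical balance over the grid — when only that slot
#' varies and everything else sits at its point estimate (or first source).
#' The joint spread with all slots varying (paired draws crossed with
#' sources) is also computed, and the difference between it and the sum of
#' single-slot variances is reported as the interaction remainder; shares
#' are not forced to sum to one.
#'
#' @param models model list from [fit_energetics_models()]
#' @param envs_hist,envs_fut named lists of `env_field_set`s, one per
#'   climate source (>= 1)
#' @param const an [energetics_constants()]
#' @param k draws per model slot
#' @param seed integer seed
#' @param month month index to evaluate
#' @return list with `table` (data.frame slot/variance/share, ranked),
#'   `total_variance` and `interaction_remainder`
#' @export
variance_attribution <- function(models, envs_hist, envs_fut,
                                 const = energetics_constants(),
                                 k = 10, seed = 1L, month = 1) {
  ens <- build_ensemble(models, k, seed)
  stat <- function(env_h, env_f, cf = list()) {
    mh <- project_energetics(env_h, models, const, months = month,
                             coefs = cf)[[1]]
    mf <- project_energetics(env_f, models, const, months = month,
                             coefs = cf)[[1]]
    mean(mf$fields$balance - mh$fields$balance)
  }
  point_coefs <- list()
  sources <- names(envs_hist)
  base_h <- envs_hist[[1]]; base_f <- envs_fut[[1]]

  vals <- list()
  # climate-source slot
  if (length(sources) >= 2)
    vals$climate_source <- vapply(sources, function(s)
      stat(envs_hist[[s]], envs_fut[[s]], point_coefs), 0)
  # one GAM slot at a time (depth models vary jointly)
  slot_defs <- list(depth = c("depth_day", "depth_night"), cost = "cost",
                    hif = "hif", ingestion = "ingestion")
  for (sl in names(slot_defs)) {
    if (k < 2) next
    vals[[sl]] <- vapply(seq_len(k), function(i) {
      cf <- list()
      for (mname in slot_defs[[sl]]) cf[[mname]] <- ens$draws[[mname]][i, ]
      stat(base_h, base_f, cf)
    }, 0)
  }
  if (!length(vals))
    stop("fewer than 2 levels in every slot; nothing to attribute",
         call. = FALSE)
  variances <- vapply(vals, stats::var, 0)

  # joint spread: paired draws crossed with sources
  joint <- unlist(lapply(seq_len(max(k, 1)), function(i) {
    cf <- member_coefs(ens, list(depth = i, cost = i, hif = i,
                                 ingestion = i))
    vapply(sources, function(s)
      stat(envs_hist[[s]], envs_fut[[s]], cf), 0)
  }))
  total <- stats::var(joint)

  svar <- sum(variances)
  tab <- data.frame(slot = names(variances), variance = variances,
                    share = if (svar > 0) variances / svar
                            else rep(0, length(variances)))
  tab <- tab[order(-tab$variance), ]
  rownames(tab) <- NULL
  list(table = tab, total_variance = total,
       interaction_remainder = total - sum(variances))
}
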