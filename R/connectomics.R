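# Functional-connectomics statistics on tabular pair data: per-presynaptic
# corrections of pairwise metrics and synapse counts, binned synapse
# conversion-rate curves with bootstrap s.d., weighted bootstrap mean
# differences, and the exponential-decay fit.

check_pair_table <- function(table) {
  need <- c("presyn_id", "postsyn_id", "connected", "n_syn", "co_travel_mm")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("pair table lacks columns: ", paste(miss, collapse = ", "))
  if (any(table$co_travel_mm <= 0)) stop("co_travel_mm must be positive")
  if (any(table$connected & table$n_syn < 1) ||
      any(!table$connected & table$n_syn != 0))
    stop("n_syn must be >= 1 exactly for connected pairs")
  invisible(table)
}

#' Per-presynaptic correction of a pairwise metric
#'
#' Subtracts each presynaptic neuron's mean of the metric (over its connected
#' and ADP pairs alike) and adds back the regional baseline, the global mean
#' over all pairs. Within-presyn orderings are preserved; the grand mean is
#' unchanged.
#'
#' @param table pair table (data.frame; see [synthetic_connectome()] for the
#'   column contract)
#' @param metric_name column to adjust
#' @return the table with column `<metric_name>_adj` appended
#' @export
adjust_pairwise_metric <- function(table, metric_name) {
  check_pair_table(table)
  if (!metric_name %in% names(table)) stop("missing metric: ", metric_name)
  v <- table[[metric_name]]
  pre_mean <- stats::ave(v, table$presyn_id, FUN = mean)
  table[[paste0(metric_name, "_adj")]] <- v - pre_mean + mean(v)
  table
}

#' Per-presynaptic correction of synapse counts
#'
#' Each presynaptic neuron's synapse conversion rate is its total synapse
#' count divided by its total co-travel distance (over connected and ADP
#' pairs). The expected count for a pair is rate x co-travel; the adjusted
#' count is observed - expected + regional expectation (regional rate x
#' co-travel). Totals are conserved.
#'
#' @param table pair table
#' @return table with column `n_syn_adj` appended
#' @export
adjust_synapse_counts <- function(table) {
  check_pair_table(table)
  tot_syn <- stats::ave(table$n_syn, table$presyn_id, FUN = sum)
  tot_ct <- stats::ave(table$co_travel_mm, table$presyn_id, FUN = sum)
  if (any(tot_ct <= 0)) stop("zero total co-travel for a presynaptic neuron")
  rate_pre <- tot_syn / tot_ct
  rate_reg <- sum(table$n_syn) / sum(table$co_travel_mm)
  expected <- rate_pre * table$co_travel_mm
  table$n_syn_adj <- table$n_syn - expected + rate_reg * table$co_travel_mm
  table
}

#' Synapse conversion rate by metric bin
#'
#' Bins all pairs (connected and ADP) by a pairwise metric; the rate in a
#' bin is total synapses / total co-travel distance. Bins are kept only if
#' they hold strictly more than `min_connected` connected pairs and at least
#' `min_connected_frac` of all connected pairs. The s.d. per bin comes from
#' resampling pairs with replacement and re-binning.
#'
#' @param table pair table
#' @param metric_name metric column to bin on
#' @param bin_edges numeric vector of edges; default: equal-count octiles of
#'   the metric among connected pairs
#' @param n_boot bootstrap resamples for the s.d. (default 200)
#' @param min_connected strict minimum connected pairs per kept bin (10)
#' @param min_connected_frac minimum share of connected pairs per bin (0.025)
#' @param seed RNG seed (mandatory)
#' @return data.frame: bin_mid, rate, sd, n_connected, total_co_travel
#' @export
conversion_rate_by_bin <- function(table, metric_name, bin_edges = NULL,
                                   n_boot = 200, min_connected = 10,
                                   min_connected_frac = 0.025, seed) {
  check_pair_table(table)
  v <- table[[metric_name]]
  if (is.null(v)) stop("missing metric: ", metric_name)
  if (is.null(bin_edges)) {
    q <- stats::quantile(v[table$connected], probs = seq(0, 1, length.out = 9))
    bin_edges <- unique(as.numeric(q))
    bin_edges[1] <- min(v) - 1e-9
    bin_edges[length(bin_edges)] <- max(v) + 1e-9
  }
  nb <- length(bin_edges) - 1
  if (nb < 1) stop("need at least one bin")
  assign_bins <- function(vals) pmin(pmax(findInterval(vals, bin_edges), 1L), nb)
  bin <- assign_bins(v)
  n_conn_tot <- sum(table$connected)
  per_bin <- function(b, idx = seq_len(nrow(table))) {
    sel <- idx[bin[idx] == b]
    c(rate = sum(table$n_syn[sel]) / sum(table$co_travel_mm[sel]),
      n_conn = sum(table$connected[sel]),
      ct = sum(table$co_travel_mm[sel]))
  }
  stats0 <- t(vapply(seq_len(nb), per_bin, numeric(3)))
  keep <- stats0[, "n_conn"] > min_connected &
    stats0[, "n_conn"] >= min_connected_frac * n_conn_tot
  if (!any(keep)) stop("no bin survives the connected-pair thresholds")
  withr_seed(seed)
  n <- nrow(table)
  boots <- matrix(NA_real_, n_boot, nb)
  for (bb in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    bidx <- bin[idx]
    syn <- tapply(table$n_syn[idx], factor(bidx, levels = seq_len(nb)), sum)
    ct <- tapply(table$co_travel_mm[idx], factor(bidx, levels = seq_len(nb)), sum)
    boots[bb, ] <- as.numeric(syn) / as.numeric(ct)
  }
  mids <- (bin_edges[-1] + bin_edges[-(nb + 1)]) / 2
  out <- data.frame(bin_lo = bin_edges[-(nb + 1)][keep],
                    bin_hi = bin_edges[-1][keep],
                    bin_mid = mids[keep],
                    rate = stats0[keep, "rate"],
                    sd = apply(boots[, keep, drop = FALSE], 2,
                               stats::sd, na.rm = TRUE),
                    n_connected = stats0[keep, "n_conn"],
                    total_co_travel = stats0[keep, "ct"])
  rownames(out) <- NULL
  attr(out, "bin_edges") <- bin_edges
  out
}

#' Exponential-decay fit
#'
#' Least-squares fit of `y = a exp(-b x) + c` (Levenberg-Marquardt), with
#' R-squared computed as 1 - SS_res / SS_tot about the mean of `y`. Constant
#' data fall back to the c-only fit with R-squared 0; a monotone-increasing
#' trend yields a negative decay rate, flagged via `increasing = TRUE`.
#'
#' @param x,y numeric vectors, >= 4 points
#' @return list: amplitude, rate, offset, r_squared, increasing, fitted
#' @export
fit_exponential_decay <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(y) < 1e-12) {
    return(list(amplitude = 0, rate = 0, offset = mean(y), r_squared = 0,
                increasing = FALSE, fitted = rep(mean(y), length(y))))
  }
  rng <- diff(range(x))
  slope <- stats::coef(stats::lm(y ~ x))[2]
  a0 <- y[which.min(x)] - min(y)
  if (a0 == 0) a0 <- diff(range(y))
  start <- list(a = if (slope <= 0) abs(a0) else -abs(a0),
                b = 1 / max(rng, 1e-9), c = min(y))
  fit <- try(minpack.lm::nlsLM(y ~ a * exp(-b * x) + c,
                               start = start,
                               control = minpack.lm::nls.lm.control(maxiter = 500)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    res <- y - mean(y)
    return(list(amplitude = NA_real_, rate = NA_real_, offset = mean(y),
                r_squared = 0, increasing = slope > 0,
                fitted = rep(mean(y), length(y)),
                diagnostics = summary(res)))
  }
  cf <- stats::coef(fit)
  fitted <- cf["a"] * exp(-cf["b"] * x) + cf["c"]
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(amplitude = unname(cf["a"]), rate = unname(cf["b"]),
       offset = unname(cf["c"]), r_squared = r2,
       increasing = unname(cf["a"] * cf["b"]) < 0, fitted = unname(fitted))
}

#' Weighted bootstrap mean-difference test
#'
#' Resamples each group with replacement using the supplied weights
#' (connected pairs are conventionally weighted by adjusted synapse count,
#' ADP controls by co-travel distance), forms the bootstrap distribution of
#' the difference in means, and reports a two-sided p value floored at
#' `1 / n_resamples`.
#'
#' @param group_a_values,group_b_values numeric vectors
#' @param weights_a,weights_b nonnegative weights (default uniform)
#' @param n_resamples bootstrap resamples (default 10000)
#' @param seed RNG seed (mandatory)
#' @return list: difference (weighted mean difference), p, p_floored,
#'   boot (the resampled differences)
#' @export
bootstrap_mean_difference <- function(group_a_values, group_b_values,
                                      weights_a = NULL, weights_b = NULL,
                                      n_resamples = 10000, seed) {
  a <- as.numeric(group_a_values); b <- as.numeric(group_b_values)
  stopifnot(length(a) >= 1, length(b) >= 1)
  wa <- if (is.null(weights_a)) rep(1, length(a)) else as.numeric(weights_a)
  wb <- if (is.null(weights_b)) rep(1, length(b)) else as.numeric(weights_b)
  if (sum(wa) <= 0 || sum(wb) <= 0) stop("zero total weight")
  withr_seed(seed)
  na <- length(a); nb <- length(b)
  ia <- matrix(sample.int(na, na * n_resamples, replace = TRUE, prob = wa),
               na, n_resamples)
  ib <- matrix(sample.int(nb, nb * n_resamples, replace = TRUE, prob = wb),
               nb, n_resamples)
  boot <- colMeans(matrix(a[ia], na, n_resamples)) -
    colMeans(matrix(b[ib], nb, n_resamples))
  diff_obs <- stats::weighted.mean(a, wa) - stats::weighted.mean(b, wb)
  p <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  p <- min(p, 1)
  floored <- p < 1 / n_resamples
  list(difference = diff_obs, p = max(p, 1 / n_resamples),
       p_floored = floored, boot = boot)
}

#' Poisson regression of synapse counts with presynaptic fixed effects
#'
#' Simplified significance model for conversion-rate trends: Poisson GLM of
#' the synapse count on the pairwise metric with presynaptic-neuron fixed
#' effects and log co-travel distance as offset.
#'
#' @param table pair table
#' @param metric_name metric column
#' @return the fitted `glm` object
#' @export
synapse_count_regression <- function(table, metric_name) {
  check_pair_table(table)
  dat <- data.frame(n_syn = table$n_syn,
                    metric = table[[metric_name]],
                    presyn = factor(table$presyn_id),
                    off = log(table$co_travel_mm))
  stats::glm(n_syn ~ metric + presyn + offset(off), data = dat,
             family = stats::poisson())
}
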