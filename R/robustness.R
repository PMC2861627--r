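# Monte-Carlo robustness experiments on the continuous model.

#' Fraction of successes under random parameter assignment
#'
#' Draws `n_trials` random parameter sets for the network, integrates the
#' deterministic dynamics (sigma = 0) and reports the fraction that
#' reproduce the wild-type sequential profile.
#'
#' @param network a `sign_network`.
#' @param n_trials number of random parameter sets.
#' @param ranges [parameter_ranges()].
#' @param params [continuous_params()].
#' @return a `robustness_result`: network code, kind, n_trials, n_success,
#'   fraction.
#' @export
param_robustness <- function(network, n_trials = 2000L,
                             ranges = parameter_ranges(),
                             params = continuous_params()) {
  thetas <- sample_parameters(network, n_trials, ranges)
  ok <- wt_success_batch(network, thetas, params, sigma = 0)
  structure(list(code = encode_network(with_x(network)),
                 kind = "parameter_variation", n_trials = n_trials,
                 n_success = sum(ok), fraction = mean(ok)),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("robustness [%s] network %s: %d/%d successes (fraction %.4f)\n",
              x$kind, format(x$code), x$n_success, x$n_trials, x$fraction))
  invisible(x)
}

#' Collect parameter sets that succeed without noise
#'
#' Rejection-samples random parameter sets until `n_good` deterministic
#' successes are collected.  Errors out if the success rate appears to be
#' below `min_rate`.
#'
#' @param network a `sign_network`.
#' @param n_good number of successful sets to collect.
#' @param ranges,params as elsewhere.
#' @param batch draw size per rejection round.
#' @param min_rate abort threshold on the success rate.
#' @return list with matrices `J`, `S` of the successful sets (n_good rows).
#' @export
harvest_good_params <- function(network, n_good = 1000L,
                                ranges = parameter_ranges(),
                                params = continuous_params(),
                                batch = 5000L, min_rate = 1e-4) {
  J <- matrix(0, 0, 15); S <- matrix(0, 0, 5)
  tried <- 0L
  while (nrow(J) < n_good) {
    thetas <- sample_parameters(network, batch, ranges)
    ok <- wt_success_batch(network, thetas, params, sigma = 0)
    J <- rbind(J, thetas$J[ok, , drop = FALSE])
    S <- rbind(S, thetas$S[ok, , drop = FALSE])
    tried <- tried + batch
    if (tried * min_rate > nrow(J) + 1 && tried >= 10 * batch)
      stop("success rate below ", min_rate, "; aborting harvest")
  }
  list(J = J[seq_len(n_good), , drop = FALSE], S = S[seq_len(n_good), , drop = FALSE])
}

#' Fraction of successes under expression noise
#'
#' Given parameter sets that succeed without noise, repeats stochastic
#' integrations at noise intensity `sigma` and reports the relative success
#' fraction over all (set, trial) pairs.
#'
#' @param network a `sign_network`.
#' @param good_params list with `J`, `S` matrices of noise-free successes
#'   (checked; a failing set raises an error).
#' @param sigma noise intensity.
#' @param trials_per_set stochastic repeats per parameter set.
#' @param params [continuous_params()].
#' @param recheck verify the noise-free precondition (default TRUE).
#' @return a `robustness_result` with kind "noise".
#' @export
noise_robustness <- function(network, good_params, sigma, trials_per_set = 50L,
                             params = continuous_params(), recheck = TRUE) {
  if (recheck) {
    ok0 <- wt_success_batch(network, good_params, params, sigma = 0)
    if (!all(ok0)) stop("good_params contains sets that fail at sigma = 0")
  }
  nset <- nrow(good_params$J)
  rep_idx <- rep(seq_len(nset), each = trials_per_set)
  thetas <- list(J = good_params$J[rep_idx, , drop = FALSE],
                 S = good_params$S[rep_idx, , drop = FALSE])
  ok <- wt_success_batch(network, thetas, params, sigma = sigma)
  structure(list(code = encode_network(with_x(network)), kind = "noise",
                 sigma = sigma, n_trials = length(ok), n_success = sum(ok),
                 fraction = mean(ok)),
            class = "robustness_result")
}

# resolve a sweep axis name to a sampled-parameter slot
axis_slot <- function(name) {
  if (grepl("^S_", name)) {
    g <- sub("^S_", "", name)
    return(list(kind = "S", col = match(g, GENES5)))
  }
  parts <- strsplit(sub("^J_", "", name), "_")[[1]]  # J_<target>_<regulator>
  i <- match(parts[1], TARGETS); j <- match(parts[2], GENES5)
  list(kind = "J", col = (i - 1L) * 5L + j)
}

#' Two-dimensional success-fraction sweep
#'
#' Fixes two parameters on a grid (e.g. a regulation strength and a default
#' promoter activity), draws the remaining parameters randomly per cell, and
#' records the success fraction in each cell.
#'
#' @param network a `sign_network`.
#' @param axis1,axis2 parameter names: `"J_<target>_<regulator>"` (e.g.
#'   `"J_pdm_Kr"`) or `"S_<gene>"` (e.g. `"S_pdm"`).  Values given to a `J`
#'   axis are used as-is (sign included).
#' @param grid1,grid2 numeric grids for the two axes.
#' @param n_per_cell random trials per grid cell.
#' @param ranges,params as elsewhere.
#' @return a `sweep_grid`: fraction matrix (length(grid1) x length(grid2)).
#' @export
sweep_2d <- function(network, axis1, grid1, axis2, grid2, n_per_cell = 300L,
                     ranges = parameter_ranges(), params = continuous_params()) {
  s1 <- axis_slot(axis1); s2 <- axis_slot(axis2)
  frac <- matrix(NA_real_, length(grid1), length(grid2),
                 dimnames = list(signif(grid1, 4), signif(grid2, 4)))
  for (a in seq_along(grid1)) for (b in seq_along(grid2)) {
    thetas <- sample_parameters(network, n_per_cell, ranges)
    if (s1$kind == "J") thetas$J[, s1$col] <- grid1[a] else thetas$S[, s1$col] <- grid1[a]
    if (s2$kind == "J") thetas$J[, s2$col] <- grid2[b] else thetas$S[, s2$col] <- grid2[b]
    frac[a, b] <- mean(wt_success_batch(network, thetas, params, sigma = 0))
  }
  structure(list(axis1 = axis1, grid1 = grid1, axis2 = axis2, grid2 = grid2,
                 n_per_cell = n_per_cell, fraction = frac),
            class = "sweep_grid")
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat("success-fraction sweep:", x$axis1, "x", x$axis2,
      sprintf("(%d trials/cell)\n", x$n_per_cell))
  print(round(x$fraction, 3))
  invisible(x)
}

#' Rank functional networks by robustness
#'
#' Computes the parameter-variation success fraction for each network of a
#' (collapsed) functional set and tabulates it against the distance to the
#' Drosophila network.
#'
#' @param codes 15-slot codes (typically the 120 distinct networks after
#'   [collapse_self_feedback()]).
#' @param n_trials trials per network.
#' @param ranges,params as elsewhere.
#' @param reference reference network for the distance column.
#' @return data.frame (code, n_d, fraction), sorted by n_d then fraction,
#'   with attribute `drosophila_top`: does a distance-0 network attain the
#'   maximum fraction?
#' @export
rank_functional_networks <- function(codes, n_trials = 2000L,
                                     ranges = parameter_ranges(),
                                     params = continuous_params(),
                                     reference = drosophila_network(TRUE, TRUE)) {
  nd <- ensemble_distances(codes, reference)$distances
  frac <- vapply(codes, function(cd) {
    param_robustness(decode_network(cd, include_x = TRUE), n_trials,
                     ranges, params)$fraction
  }, 0)
  out <- data.frame(code = codes, n_d = nd, fraction = frac)
  out <- out[order(out$n_d, -out$fraction), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drosophila_top") <- max(out$fraction[out$n_d == 0]) >= max(out$fraction)
  out
}

#' Summarize successful parameter sets
#'
#' Location and spread of the parameter sets that reproduce the wild-type
#' profile without noise (log scale for the sampled magnitudes), one row per
#' parameter -- a tabular reduction of per-network successful-set profiles.
#'
#' @param good_params list with `J`, `S` matrices (see
#'   [harvest_good_params()]).
#' @return data.frame: parameter, mean_log10, sd_log10, n.
#' @export
summarize_good_params <- function(good_params) {
  jn <- as.vector(t(outer(TARGETS, REGULATORS, paste, sep = "<-")))
  cols <- cbind(good_params$J, good_params$S)
  colnames(cols) <- c(paste0("J_", gsub("<-", "_", jn)), paste0("S_", GENES5))
  keep <- colSums(cols != 0) > 0
  out <- do.call(rbind, lapply(colnames(cols)[keep], function(nm) {
    v <- abs(cols[, nm])
    data.frame(parameter = nm, mean_log10 = mean(log10(v)),
               sd_log10 = sd(log10(v)), n = length(v))
  }))
  rownames(out) <- NULL
  out
}
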