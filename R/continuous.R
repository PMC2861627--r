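# Continuous stochastic model of the cascade and its parameter sampling.
#
# mRNA and protein concentrations follow
#   dM_i/dt = F_i({P_j}) - d_M M_i + eta_i,   dP_i/dt = M_i - d_P P_i
# with promoter activity F_i = g(S_i(t) + sum_j Jt_ij h(P_j)), the
# piecewise-linear g(u) = max(u, 0) and Hill saturation
# h(P) = P^n / (K_M^n + P^n).  eta_i is additive white Gaussian noise of
# intensity sigma, acting on transcription only; for the input genes hb and
# x it is switched off together with their promoters.  Protein dynamics are
# discretized against the threshold P_th for criterion matching.

GENES5 <- c("hb", "Kr", "pdm", "cas", "x")

#' Fixed constants of the continuous model
#'
#' @param d_M,d_P degradation rates of mRNA and protein (1/time).
#' @param K_M Michaelis constant of the promoter Hill functions.
#' @param hill_n Hill coefficient.
#' @param t_hb,t_x times at which the hb and x promoters switch off.
#' @param p_th discretization threshold on protein levels (ties map to OFF).
#' @param dt Euler-Maruyama step.
#' @param t_total total simulated time.
#' @param p_oe protein level at which an overexpressed gene is held.
#' @return list of constants.
#' @export
continuous_params <- function(d_M = 1.0, d_P = 0.2, K_M = 0.1, hill_n = 2.0,
                              t_hb = 10.0, t_x = 20.0, p_th = 0.2,
                              dt = 0.01, t_total = 70.0, p_oe = 1.0) {
  stopifnot(d_M > 0, d_P > 0, K_M > 0, hill_n > 0, dt > 0, t_total > 0, p_th > 0)
  list(d_M = d_M, d_P = d_P, K_M = K_M, hill_n = hill_n, t_hb = t_hb,
       t_x = t_x, p_th = p_th, dt = dt, t_total = t_total, p_oe = p_oe)
}

#' Sampling ranges for the random parameters
#'
#' Regulation strengths and default promoter activities are drawn
#' log-uniformly; repression strengths take the negative of the drawn
#' magnitude.  Entries of Jt are forced to exactly 0 wherever the Boolean
#' network has no regulation.
#'
#' @param j_range magnitude range for regulation strengths.
#' @param s_range range for the default promoter activities of Kr, pdm, cas.
#' @param s_input_range range for the (pre-switch-off) promoter activities
#'   of hb and x.
#' @return list of ranges.
#' @export
parameter_ranges <- function(j_range = c(0.1, 10), s_range = c(0.01, 1),
                             s_input_range = c(0.1, 10)) {
  stopifnot(j_range[1] > 0, j_range[1] < j_range[2],
            s_range[1] > 0, s_range[1] < s_range[2],
            s_input_range[1] > 0, s_input_range[1] < s_input_range[2])
  list(j_range = j_range, s_range = s_range, s_input_range = s_input_range)
}

rlogunif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

#' Draw random continuous parameter sets for a network
#'
#' @param network a `sign_network` (x column added if missing).
#' @param n number of parameter sets.
#' @param ranges a [parameter_ranges()] list.
#' @return list with matrices `J` (n x 15, columns target-major over
#'   regulators hb,Kr,pdm,cas,x) and `S` (n x 5, columns hb,Kr,pdm,cas,x).
#' @export
sample_parameters <- function(network, n, ranges = parameter_ranges()) {
  network <- with_x(network)
  Jm <- unclass(network)
  J <- matrix(0, n, 15L)
  for (i in 1:3) for (j in 1:5) {
    col <- (i - 1L) * 5L + j
    if (Jm[i, j] > 0L) J[, col] <- rlogunif(n, ranges$j_range[1], ranges$j_range[2])
    if (Jm[i, j] < 0L) J[, col] <- -rlogunif(n, ranges$j_range[1], ranges$j_range[2])
  }
  S <- matrix(0, n, 5L)
  S[, 1] <- rlogunif(n, ranges$s_input_range[1], ranges$s_input_range[2])
  S[, 5] <- rlogunif(n, ranges$s_input_range[1], ranges$s_input_range[2])
  for (g in 2:4) S[, g] <- rlogunif(n, ranges$s_range[1], ranges$s_range[2])
  list(J = J, S = S)
}

#' Promoter activity of one gene (reference implementation)
#'
#' @param proteins named numeric vector of protein levels (hb,Kr,pdm,cas,x).
#' @param target gene name.
#' @param J numeric vector of 15 regulation strengths (as one row of
#'   [sample_parameters()]'s `J`), ignored for hb and x.
#' @param S named numeric vector of default promoter activities.
#' @param params [continuous_params()].
#' @param t time.
#' @return transcription rate (non-negative).
#' @export
promoter_activity <- function(proteins, target, J, S, params, t) {
  stopifnot(all(proteins >= 0))
  if (target == "hb") return(if (t < params$t_hb) S[["hb"]] else 0)
  if (target == "x")  return(if (t < params$t_x) S[["x"]] else 0)
  i <- match(target, TARGETS)
  h <- proteins^params$hill_n / (params$K_M^params$hill_n + proteins^params$hill_n)
  u <- S[[target]] + sum(J[(i - 1L) * 5L + 1:5] * h[GENES5])
  max(u, 0)
}

clamp_spec <- function(geno) {
  geno <- as_genotype(geno)
  if (is.null(geno$gene)) return(list(gene = -1L, mode = 0L))
  list(gene = match(geno$gene, GENES5) - 1L,
       mode = if (geno$mode == "loss") 0L else 1L)
}

#' Integrate the continuous model for one parameter set
#'
#' @param network a `sign_network`.
#' @param theta list with `J` (length-15) and `S` (length-5) vectors, e.g.
#'   one row of [sample_parameters()] output.
#' @param params [continuous_params()].
#' @param sigma noise intensity (0 for deterministic dynamics).
#' @param geno genotype (clamps as in the Boolean model).
#' @return a `continuous_trajectory`: list with `time`, `M`, `P` matrices.
#' @export
simulate_continuous <- function(network, theta, params = continuous_params(),
                                sigma = 0, geno = "wt") {
  cl <- clamp_spec(geno)
  res <- sde_trajectory(as.numeric(theta$J), as.numeric(theta$S),
                        params$d_M, params$d_P, params$K_M, params$hill_n,
                        params$t_hb, params$t_x, params$dt, params$t_total,
                        sigma, cl$gene, cl$mode, params$p_oe)
  colnames(res$M) <- GENES5; colnames(res$P) <- GENES5
  structure(res, class = "continuous_trajectory", sigma = sigma,
            genotype = as_genotype(geno)$label)
}

#' Discretize a continuous trajectory against the threshold
#'
#' @param traj a `continuous_trajectory`.
#' @param p_th threshold (ties map to OFF).
#' @return 0/1 matrix genes x time (rows hb,Kr,pdm,cas), with time as
#'   column names, suitable for [compress_trajectory()] and
#'   [matches_criterion()].
#' @export
discretize_trajectory <- function(traj, p_th = 0.2) {
  m <- t(traj$P[, c("hb", "Kr", "pdm", "cas")] > p_th) * 1L
  colnames(m) <- traj$time
  m
}

# window stats for many parameter sets at once (internal, Rcpp-backed)
batch_windows <- function(network, thetas, params, sigma, geno = "wt") {
  cl <- clamp_spec(geno)
  sde_window_stats(thetas$J, thetas$S, params$d_M, params$d_P, params$K_M,
                   params$hill_n, params$t_hb, params$t_x, params$p_th,
                   params$dt, params$t_total, sigma, cl$gene, cl$mode,
                   params$p_oe)
}

windows_to_df <- function(row) {
  data.frame(gene = c("hb", "Kr", "pdm", "cas"),
             onset = ifelse(row[c(1, 4, 7, 10)] < 0, NA_real_, row[c(1, 4, 7, 10)]),
             offset = ifelse(row[c(2, 5, 8, 11)] < 0, NA_real_, row[c(2, 5, 8, 11)]),
             segments = as.integer(row[c(3, 6, 9, 12)]))
}

#' Wild-type success of the continuous dynamics
#'
#' Integrates, discretizes at `params$p_th` and checks the wild-type
#' sequential-expression criterion -- the same window-order matcher used by
#' the Boolean screens ([matches_criterion()]).
#'
#' @param network a `sign_network`.
#' @param theta parameter set (list with `J`, `S`).
#' @param params [continuous_params()].
#' @param sigma noise intensity.
#' @return logical.
#' @export
wt_success <- function(network, theta, params = continuous_params(), sigma = 0) {
  th <- list(J = matrix(as.numeric(theta$J), 1), S = matrix(as.numeric(theta$S), 1))
  st <- batch_windows(network, th, params, sigma)
  matches_criterion(NULL, criterion_for("wt"), windows = windows_to_df(st[1, ]),
                    t_final = params$t_total)
}

# vectorized wild-type success over many parameter sets
wt_success_batch <- function(network, thetas, params, sigma = 0) {
  st <- batch_windows(network, thetas, params, sigma)
  crit <- criterion_for("wt")
  on <- st[, c(1, 4, 7, 10), drop = FALSE]
  off <- st[, c(2, 5, 8, 11), drop = FALSE]
  seg <- st[, c(3, 6, 9, 12), drop = FALSE]
  ok <- !is.na(on[, 1]) & on[, 1] >= 0
  for (g in 1:4) ok <- ok & on[, g] >= 0 & seg[, g] == 1
  for (g in 2:4) ok <- ok & off[, g - 1] <= off[, g]
  for (i in 2:4) for (j in 1:(i - 1))
    ok <- ok & !(on[, i] == on[, j] & off[, i] == off[, j])
  ok & !is.na(ok)
}
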