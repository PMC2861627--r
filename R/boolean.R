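# Synchronous Boolean dynamics of the temporal cascade.
#
# Update rule for the dynamic genes Kr, pdm, cas: the next state is 1 when
# the summed regulatory input is positive, 0 when negative, and the gene's
# default expression state s0 when exactly zero.  hb, svp and x are inputs:
# hb is ON for t = 0,1 and switched off by the svp pulse at t = 1; x (when
# present) changes state once, at the switching step t_x.

#' Genotype specification
#'
#' The nine in-silico genotypes: wild type, loss-of-function and
#' overexpression of each of hb, Kr, pdm, cas.  A clamped gene is held at its
#' clamp value (0 for loss, 1 for overexpression) at every step including
#' t = 0.
#'
#' @param gene one of "hb","Kr","pdm","cas", or NULL for wild type.
#' @param mode "loss" or "overexpression" (ignored for wild type).
#' @return an object of class `genotype`.
#' @export
genotype <- function(gene = NULL, mode = c("loss", "overexpression")) {
  if (is.null(gene))
    return(structure(list(gene = NULL, mode = "wt", label = "wt"),
                     class = "genotype"))
  mode <- match.arg(mode)
  stopifnot(gene %in% c("hb", "Kr", "pdm", "cas"))
  label <- paste0(gene, if (mode == "loss") "-" else "++")
  structure(list(gene = gene, mode = mode, label = label), class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat("genotype:", x$label, "\n"); invisible(x)
}

#' All nine genotypes of the screen
#' @return named list of `genotype` objects.
#' @export
nine_genotypes <- function() {
  g <- list(genotype())
  for (gene in c("hb", "Kr", "pdm", "cas")) g <- c(g, list(genotype(gene, "loss")))
  for (gene in c("hb", "Kr", "pdm", "cas")) g <- c(g, list(genotype(gene, "overexpression")))
  names(g) <- vapply(g, `[[`, "", "label")
  g
}

as_genotype <- function(g) {
  if (inherits(g, "genotype")) return(g)
  all9 <- nine_genotypes()
  if (is.character(g) && g %in% names(all9)) return(all9[[g]])
  stop("unknown genotype: ", g)
}

#' Input schedule for a Boolean simulation
#'
#' Fixes the simulation horizon, the x switching step and polarity.  The svp
#' pulse always occurs at t = 1 and is not configurable; hb is ON for
#' t in {0, 1} unless clamped.  x changes state exactly once, at `t_x`
#' (ON -> OFF polarity: ON for t < t_x).  One t_x is shared by all genotypes
#' of a screen.
#'
#' @param t_end final time step (trajectory covers t = 0..t_end).
#' @param t_x x switching step in `[1, t_end]`; NA when the network has no x.
#' @param x_polarity "on_off" or "off_on".
#' @return an object of class `input_schedule`.
#' @export
input_schedule <- function(t_end = 10L, t_x = NA_integer_,
                           x_polarity = c("on_off", "off_on")) {
  x_polarity <- match.arg(x_polarity)
  t_end <- as.integer(t_end)
  stopifnot(t_end >= 2L, is.na(t_x) || (t_x >= 1L && t_x <= t_end))
  structure(list(t_end = t_end, t_x = as.integer(t_x), x_polarity = x_polarity),
            class = "input_schedule")
}

# Input trajectories implied by a schedule and genotype (hb clamps override).
input_trajectories <- function(schedule, geno) {
  tt <- 0:schedule$t_end
  hb <- as.integer(tt <= 1L)
  if (!is.null(geno$gene) && geno$gene == "hb")
    hb <- rep(if (geno$mode == "loss") 0L else 1L, length(tt))
  svp <- as.integer(tt == 1L)
  if (is.na(schedule$t_x)) {
    x <- rep(0L, length(tt))
  } else if (schedule$x_polarity == "on_off") {
    x <- as.integer(tt < schedule$t_x)
  } else {
    x <- as.integer(tt >= schedule$t_x)
  }
  list(hb = hb, svp = svp, x = x)
}

#' One synchronous update of the dynamic genes
#'
#' Reference (scalar) implementation of the update rule.  Only Kr, pdm and
#' cas are updated; hb, svp and x keep their values in `state` (they are
#' inputs, advanced by [simulate_boolean()]).  A gene clamped by the genotype
#' keeps its clamp value.
#'
#' @param state named integer vector of ON/OFF bits over
#'   `c("hb","Kr","pdm","cas","svp","x")`.
#' @param network a `sign_network`.
#' @param defaults named integer vector `c(Kr=,pdm=,cas=)` of default states.
#' @param geno a `genotype` (or label).
#' @return the next state (same shape as `state`).
#' @export
boolean_step <- function(state, network, defaults, geno = genotype()) {
  geno <- as_genotype(geno)
  stopifnot(all(GENES %in% names(state)), all(TARGETS %in% names(defaults)))
  regs <- colnames(network)
  nxt <- state
  for (tg in TARGETS) {
    s <- sum(unclass(network)[tg, ] * state[regs])
    nxt[tg] <- if (s > 0) 1L else if (s < 0) 0L else as.integer(defaults[tg])
  }
  if (!is.null(geno$gene) && geno$gene %in% TARGETS)
    nxt[geno$gene] <- if (geno$mode == "loss") 0L else 1L
  nxt
}

#' Simulate the Boolean cascade
#'
#' Runs the synchronous dynamics from the canonical initial condition (all
#' genes OFF except hb; x starts ON under ON -> OFF polarity) under a
#' genotype clamp and input schedule.
#'
#' @param network a `sign_network`.
#' @param geno a `genotype` or its label (e.g. `"wt"`, `"hb-"`, `"Kr++"`).
#' @param defaults named integer vector of default states for Kr, pdm, cas.
#' @param schedule an [input_schedule()].
#' @return a `boolean_trajectory`: integer matrix genes x time (columns
#'   t = 0..t_end).
#' @export
simulate_boolean <- function(network, geno = "wt",
                             defaults = c(Kr = 0L, pdm = 0L, cas = 0L),
                             schedule = input_schedule()) {
  geno <- as_genotype(geno)
  if (!attr(network, "include_x") && !is.na(schedule$t_x))
    network <- with_x(network)
  if (attr(network, "include_x") && is.na(schedule$t_x) &&
      any(network[, "x"] != 0L))
    stop("network has x regulations but the schedule fixes no t_x")
  network <- with_x(network)
  inp <- input_trajectories(schedule, geno)
  tt <- 0:schedule$t_end
  traj <- matrix(0L, length(GENES), length(tt), dimnames = list(GENES, tt))
  state <- setNames(integer(length(GENES)), GENES)
  state["hb"] <- inp$hb[1]; state["svp"] <- inp$svp[1]; state["x"] <- inp$x[1]
  if (!is.null(geno$gene) && geno$gene %in% TARGETS)
    state[geno$gene] <- if (geno$mode == "loss") 0L else 1L
  traj[, 1] <- state
  for (t in seq_len(schedule$t_end)) {
    state <- boolean_step(state, network, defaults, geno)
    state["hb"] <- inp$hb[t + 1]; state["svp"] <- inp$svp[t + 1]
    state["x"] <- inp$x[t + 1]
    traj[, t + 1] <- state
  }
  structure(traj, class = "boolean_trajectory", genotype = geno$label,
            defaults = defaults, schedule = schedule)
}

#' @export
print.boolean_trajectory <- function(x, ...) {
  cat("Boolean trajectory, ", attr(x, "genotype"), " genotype, t = 0..",
      ncol(x) - 1L, "\n", sep = "")
  strip <- apply(unclass(x), 1, function(r) paste(ifelse(r == 1L, "#", "."), collapse = ""))
  for (g in rownames(x)) cat(sprintf("%4s %s\n", g, strip[g]))
  invisible(x)
}

#' Compress a trajectory to its sequence of distinct states
#'
#' Drops consecutive duplicate (hb, Kr, pdm, cas) states, keeping order.
#' Idempotent.
#'
#' @param traj a `boolean_trajectory` (or matrix with those four rows).
#' @return integer matrix: four rows, one column per phase.
#' @export
compress_trajectory <- function(traj) {
  m <- unclass(traj)[c("hb", "Kr", "pdm", "cas"), , drop = FALSE]
  keys <- apply(m, 2, paste, collapse = "")
  keep <- c(TRUE, keys[-1] != keys[-length(keys)])
  out <- m[, keep, drop = FALSE]
  colnames(out) <- NULL
  out
}

#' Expression windows of a trajectory
#'
#' For each of hb, Kr, pdm, cas: the first and last ON step and the number of
#' contiguous ON segments.  `onset`/`offset` are NA for genes never ON.
#'
#' @param traj a `boolean_trajectory`.
#' @return data.frame with columns gene, onset, offset, segments.
#' @export
expression_windows <- function(traj) {
  m <- unclass(traj)[c("hb", "Kr", "pdm", "cas"), , drop = FALSE]
  tt <- suppressWarnings(as.numeric(colnames(traj)))
  if (!length(tt) || anyNA(tt)) tt <- seq_len(ncol(m)) - 1L
  res <- lapply(rownames(m), function(g) {
    on <- which(m[g, ] == 1L)
    if (!length(on))
      return(data.frame(gene = g, onset = NA_real_, offset = NA_real_, segments = 0L))
    data.frame(gene = g, onset = tt[min(on)], offset = tt[max(on)],
               segments = 1L + sum(diff(on) > 1L))
  })
  do.call(rbind, res)
}

#' Export a trajectory as tidy CSV
#' @param traj a `boolean_trajectory`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(t = rep(as.integer(colnames(traj)), each = nrow(traj)),
                   gene = rep(rownames(traj), ncol(traj)),
                   state = as.vector(unclass(traj)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
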