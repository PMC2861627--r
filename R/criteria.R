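# Genotype expression-profile criteria and the window-matching predicate.
#
# The criteria are literature-encoded fixtures (inst/extdata/
# profile_criteria.json), one per genotype.  A trajectory matches when
#   * every gene of the ordered profile is expressed in a single contiguous
#     window,
#   * the windows appear in profile order, compared by their offsets
#     (nondecreasing; overlaps and ties of onsets are allowed),
#   * all windows of the profile are pairwise distinct (the additional
#     condition that expression time windows differ for any two genes),
#   * genes marked absent are never expressed, and an overexpression-clamped
#     gene is ON throughout (it takes no part in the ordering),
#   * where the profile freezes or maintains its terminal factor (pdm-, cas-,
#     hb++, Kr++), that gene must still be expressed at the final step.

criteria_env <- new.env(parent = emptyenv())

#' Expression-profile criteria
#'
#' @return `profile_criteria()`: named list of all nine criteria;
#'   `criterion_for(genotype)`: the criterion for one genotype.
#' @export
profile_criteria <- function() {
  if (is.null(criteria_env$crit)) {
    path <- system.file("extdata", "profile_criteria.json", package = "nbcascade")
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)$criteria
    crit <- lapply(raw, function(cr) {
      structure(list(genotype = cr$genotype,
                     order = unlist(cr$order),
                     clamped_on = if (is.null(cr$clamped_on)) NULL else cr$clamped_on,
                     absent = as.character(unlist(cr$absent)),
                     persist = isTRUE(cr$persist)),
                class = "profile_criterion")
    })
    names(crit) <- vapply(crit, `[[`, "", "genotype")
    criteria_env$crit <- crit
  }
  criteria_env$crit
}

#' @rdname profile_criteria
#' @param geno a `genotype` object or label.
#' @export
criterion_for <- function(geno) {
  label <- if (inherits(geno, "genotype")) geno$label else geno
  crit <- profile_criteria()
  if (!label %in% names(crit)) stop("no criterion for genotype ", label)
  crit[[label]]
}

#' @export
print.profile_criterion <- function(x, ...) {
  cat("criterion [", x$genotype, "]: ", paste(x$order, collapse = " > "),
      if (x$persist) " (terminal gene persists)", "\n", sep = "")
  if (!is.null(x$clamped_on)) cat("  clamped ON:", x$clamped_on, "\n")
  if (length(x$absent)) cat("  never expressed:", paste(x$absent, collapse = ", "), "\n")
  invisible(x)
}

#' Does a trajectory match a genotype criterion?
#'
#' Works on any trajectory carrying ON/OFF (or thresholded) states for hb,
#' Kr, pdm, cas: a [simulate_boolean()] result or the discretized output of
#' the continuous model.  Windows may also be supplied directly.
#'
#' @param traj a trajectory matrix (genes x time, rows incl. hb,Kr,pdm,cas),
#'   or NULL if `windows` is given.
#' @param criterion a `profile_criterion` (see [criterion_for()]).
#' @param windows optional data.frame as from [expression_windows()].
#' @param t_final final time of the observation (defaults to the last
#'   trajectory column).
#' @param strict_offsets require strictly increasing offsets along the
#'   profile order.  The default (FALSE) allows ties, which are generic in
#'   the discrete-time model; the continuous scoring sets TRUE, where exact
#'   ties can only arise from truncation at the simulation horizon.
#' @return logical.
#' @export
matches_criterion <- function(traj, criterion, windows = NULL, t_final = NULL,
                              strict_offsets = FALSE) {
  if (is.null(windows)) {
    windows <- expression_windows(traj)
    if (is.null(t_final)) {
      tt <- suppressWarnings(as.numeric(colnames(traj)))
      t_final <- if (length(tt) && !anyNA(tt)) max(tt) else ncol(traj) - 1L
    }
  }
  stopifnot(!is.null(t_final))
  w <- function(g) windows[windows$gene == g, ]
  # clamped-ON gene: expressed the whole time
  if (!is.null(criterion$clamped_on)) {
    cw <- w(criterion$clamped_on)
    if (is.na(cw$onset) || cw$segments != 1L || cw$offset < t_final) return(FALSE)
  }
  for (g in criterion$absent) if (!is.na(w(g)$onset)) return(FALSE)
  ord <- criterion$order
  ws <- lapply(ord, w)
  for (wi in ws) if (is.na(wi$onset) || wi$segments != 1L) return(FALSE)
  offs <- vapply(ws, `[[`, 0, "offset")
  if (strict_offsets) {
    if (any(diff(offs) <= 0)) return(FALSE)
  } else if (any(diff(offs) < 0)) return(FALSE)
  ons <- vapply(ws, `[[`, 0, "onset")
  if (length(ord) >= 2) {
    for (i in 2:length(ord)) for (j in 1:(i - 1))
      if (ons[i] == ons[j] && offs[i] == offs[j]) return(FALSE)
  }
  if (criterion$persist && offs[length(offs)] < t_final) return(FALSE)
  TRUE
}

#' Is a network functional for a given witness?
#'
#' A network is functional when, for one shared choice of default states and
#' input schedule, its simulated dynamics match the criteria of all nine
#' genotypes.
#'
#' @param network a `sign_network`.
#' @param defaults named defaults for Kr, pdm, cas.
#' @param schedule an [input_schedule()].
#' @return logical.
#' @export
is_functional <- function(network, defaults, schedule) {
  for (g in names(nine_genotypes())) {
    traj <- simulate_boolean(network, g, defaults, schedule)
    if (!matches_criterion(traj, criterion_for(g))) return(FALSE)
  }
  TRUE
}
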