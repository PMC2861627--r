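# Output writers, run manifests and the command-line entry point.

#' Write a scan report as JSON
#' @param report a `scan_report`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_scan_report <- function(report, path) {
  jsonlite::write_json(unclass(report)[setdiff(names(report), "wt_flags")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a run manifest
#'
#' Records command, configuration, seed and output files of a run, so that
#' any run can be reproduced from its manifest.
#'
#' @param path manifest path.
#' @param command character description of the command.
#' @param config named list of configuration values.
#' @param seed RNG seed used (or NA).
#' @param outputs character vector of output files.
#' @return the path, invisibly.
#' @export
write_run_manifest <- function(path, command, config = list(), seed = NA,
                               outputs = character()) {
  jsonlite::write_json(list(command = command,
                            package = "nbcascade",
                            version = as.character(utils::packageVersion("nbcascade")),
                            config = config, seed = seed, outputs = outputs,
                            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

cli_usage <- function() {
  cat("usage: nbcascade <command> [options]\n",
      "commands:\n",
      "  scan              --t-end N [--with-x --polarity on-off|off-on] --out PREFIX\n",
      "  simulate-boolean  --network drosophila|minimum|CODE --genotype G\n",
      "                    [--tx N --t-end N --defaults d,d,d] --out FILE\n",
      "  robustness        --network drosophila|minimum|CODE --trials N --seed S --out FILE\n",
      sep = "")
}

cli_opt <- function(args, name, default = NULL) {
  i <- which(args == name)
  if (!length(i)) return(default)
  args[i[1] + 1L]
}

cli_network <- function(spec) {
  if (spec == "drosophila") return(drosophila_network(TRUE, TRUE))
  if (spec == "minimum") return(minimum_network())
  decode_network(as.numeric(spec), include_x = TRUE)
}

#' Command-line entry point
#'
#' Thin dispatcher used by the `inst/cli/nbcascade` script; callable from R
#' for testing.  Returns an exit status (0 on success).
#'
#' @param args character vector of command-line arguments.
#' @return integer status, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { cli_usage(); return(invisible(1L)) }
  cmd <- args[1]; rest <- args[-1]
  seed <- cli_opt(rest, "--seed")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (cmd == "scan") {
    t_end <- as.integer(cli_opt(rest, "--t-end", "10"))
    out <- cli_opt(rest, "--out", "scan")
    if ("--with-x" %in% rest) {
      pol <- if (identical(cli_opt(rest, "--polarity", "on-off"), "off-on"))
        "off_on" else "on_off"
      res <- scan_with_x(pol, t_end)
      write.csv(res$records, paste0(out, "_functional.csv"), row.names = FALSE)
      write_scan_report(res$report, paste0(out, "_report.json"))
      outs <- paste0(out, c("_functional.csv", "_report.json"))
    } else {
      rep <- scan_known_factors(t_end)
      write_scan_report(rep, paste0(out, "_report.json"))
      outs <- paste0(out, "_report.json")
    }
    write_run_manifest(paste0(out, "_manifest.json"), paste(c(cmd, rest), collapse = " "),
                       list(t_end = t_end), if (is.null(seed)) NA else as.integer(seed), outs)
    return(invisible(0L))
  }
  if (cmd == "simulate-boolean") {
    net <- cli_network(cli_opt(rest, "--network", "drosophila"))
    g <- cli_opt(rest, "--genotype", "wt")
    t_end <- as.integer(cli_opt(rest, "--t-end", "10"))
    t_x <- cli_opt(rest, "--tx")
    t_x <- if (is.null(t_x)) {
      if (attr(net, "include_x") && any(net[, "x"] != 0L)) 6L else NA_integer_
    } else as.integer(t_x)
    defs <- as.integer(strsplit(cli_opt(rest, "--defaults", "0,0,0"), ",")[[1]])
    out <- cli_opt(rest, "--out", "trajectory.csv")
    traj <- simulate_boolean(net, g, c(Kr = defs[1], pdm = defs[2], cas = defs[3]),
                             input_schedule(t_end, t_x))
    write_trajectory_csv(traj, out)
    write_run_manifest(paste0(out, ".manifest.json"),
                       paste(c(cmd, rest), collapse = " "),
                       list(t_end = t_end, t_x = t_x, defaults = defs,
                            genotype = g),
                       if (is.null(seed)) NA else as.integer(seed), out)
    return(invisible(0L))
  }
  if (cmd == "robustness") {
    net <- cli_network(cli_opt(rest, "--network", "drosophila"))
    n <- as.integer(cli_opt(rest, "--trials", "2000"))
    out <- cli_opt(rest, "--out", "robustness.json")
    res <- param_robustness(net, n)
    jsonlite::write_json(unclass(res), out, auto_unbox = TRUE, digits = NA)
    write_run_manifest(paste0(out, ".manifest.json"),
                       paste(c(cmd, rest), collapse = " "),
                       list(trials = n), if (is.null(seed)) NA else as.integer(seed), out)
    return(invisible(0L))
  }
  cli_usage()
  invisible(1L)
}
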