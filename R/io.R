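# CSV interchange schemas and run-level report functions.

check_columns <- function(df, required, what) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing required column(s): %s (found: %s)",
                 what, paste(missing_cols, collapse = ", "),
                 paste(names(df), collapse = ", ")))
  invisible(df)
}

#' Read a current-trace CSV
#'
#' Interchange format: header \code{time_s,current_nA}.
#'
#' @param path file path.
#' @param sign +1 or -1, see [current_trace()].
#' @return A [current_trace()].
#' @export
read_trace_csv <- function(path, sign = 1) {
  df <- utils::read.csv(path)
  check_columns(df, c("time_s", "current_nA"), basename(path))
  current_trace(df$time_s, df$current_nA, sign = sign)
}

#' Read an application-window table CSV
#'
#' Header \code{label,t_start_s,t_end_s}.
#'
#' @param path file path.
#' @return A data frame of labeled windows.
#' @export
read_windows_csv <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("label", "t_start_s", "t_end_s"), basename(path))
  if (any(df$t_start_s >= df$t_end_s))
    stop("window table: every t_start_s must be < t_end_s")
  df
}

#' Read a radioligand binding table CSV
#'
#' Header \code{ligand_conc_nM,total_cpm,nonspecific_cpm,replicate}.
#'
#' @param path file path.
#' @return A data frame with an added \code{specific_cpm} column.
#' @export
read_binding_csv <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("ligand_conc_nM", "total_cpm", "nonspecific_cpm"),
                basename(path))
  sp <- specific_binding(df$total_cpm, df$nonspecific_cpm)
  df$specific_cpm <- sp$specific_cpm
  df
}

#' Read a modulation concentration-response CSV
#'
#' Header \code{modulator_conc_uM,percent_of_control,replicate}.
#'
#' @param path file path.
#' @return A data frame.
#' @export
read_modulation_csv <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("modulator_conc_uM", "percent_of_control"),
                basename(path))
  df
}

#' Read a binding time-course CSV
#'
#' Header \code{time_min,percent_of_control,replicate}.
#'
#' @param path file path.
#' @return A data frame.
#' @export
read_timecourse_csv <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("time_min", "percent_of_control"), basename(path))
  df
}

#' Read a photolabeling area table CSV
#'
#' Header \code{peptide_id,condition,labeled_area,unlabeled_area,replicate}.
#'
#' @param path file path.
#' @return A data frame.
#' @export
read_areas_csv <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("peptide_id", "condition", "labeled_area",
                      "unlabeled_area"), basename(path))
  df
}

#' Occupancy analysis report from measured open probabilities
#'
#' Runs the full inversion workflow: L*Gamma from the peak, Q from the
#' control steady state, optionally Q* from a steroid steady state, the
#' occupancy vectors, high-affinity sums, and (when a steroid value is
#' given) the predicted binding fold change. Probabilities are stored at
#' full precision; the \code{display} element rounds to two decimals for
#' reporting.
#'
#' @param peak_popen peak open probability.
#' @param ss_popen control steady-state open probability.
#' @param ss_popen_steroid optional steroid steady-state open probability.
#' @param seed seed recorded in the report (no randomness is used here).
#' @return An object of class \code{"occupancy_report"} (a list).
#' @examples
#' run_occupancy(0.71, 0.121, 0.077)
#' @export
run_occupancy <- function(peak_popen, ss_popen, ss_popen_steroid = NULL,
                          seed = NA_integer_) {
  occ <- occupancy_from_measurements(
    measured_response(peak_popen, ss_popen, condition_label = "control"))
  rep <- list(
    inputs = list(peak_popen = peak_popen, ss_popen = ss_popen,
                  ss_popen_steroid = ss_popen_steroid),
    seed = seed,
    package_version = as.character(utils::packageVersion("gabarod")),
    l_gamma = attr(occ, "l_gamma"),
    q = attr(occ, "q"),
    occupancy = as.list(unclass(occ)),
    high_affinity_sum = high_affinity_fraction(occ))
  if (!is.null(ss_popen_steroid)) {
    occ_s <- occupancy_from_measurements(
      measured_response(peak_popen, ss_popen_steroid,
                        condition_label = "steroid"))
    rep$q_star <- attr(occ_s, "q")
    rep$occupancy_steroid <- as.list(unclass(occ_s))
    rep$high_affinity_sum_steroid <- high_affinity_fraction(occ_s)
    rep$binding_fold_change <- binding_fold_change(occ, occ_s)
  }
  rnd <- function(v) round(v, 2)
  rep$display <- list(
    p_desensitized = rnd(rep$occupancy$p_desensitized),
    high_affinity_sum = rnd(rep$high_affinity_sum))
  if (!is.null(ss_popen_steroid)) {
    rep$display$p_desensitized_steroid <-
      rnd(rep$occupancy_steroid$p_desensitized)
    rep$display$high_affinity_sum_steroid <- rnd(rep$high_affinity_sum_steroid)
  }
  structure(rep, class = "occupancy_report")
}

#' @export
print.occupancy_report <- function(x, ...) {
  cat("ROD occupancy report\n")
  cat(sprintf("  inputs: peak %.3g, steady-state %.3g%s\n",
              x$inputs$peak_popen, x$inputs$ss_popen,
              if (is.null(x$inputs$ss_popen_steroid)) "" else
                sprintf(" (steroid %.3g)", x$inputs$ss_popen_steroid)))
  cat(sprintf("  L*Gamma = %.4g, Q = %.4g\n", x$l_gamma, x$q))
  cat(sprintf("  control: P_rest %.2f, P_open %.2f, P_des %.2f (sum high-affinity %.2f)\n",
              x$occupancy$p_resting, x$occupancy$p_open,
              x$occupancy$p_desensitized, x$high_affinity_sum))
  if (!is.null(x$q_star)) {
    cat(sprintf("  steroid: Q* = %.4g, P_des %.2f (sum high-affinity %.2f)\n",
                x$q_star, x$occupancy_steroid$p_desensitized,
                x$high_affinity_sum_steroid))
    cat(sprintf("  predicted binding fold change: %.3g\n",
                x$binding_fold_change))
  }
  invisible(x)
}

#' Run a simulation from a config list and write its output files
#'
#' Thin driver over the generators: dispatches on \code{config$kind}
#' (\code{"responses"}, \code{"trace"}, \code{"isotherm"},
#' \code{"modulation"}, \code{"timecourse"}), writes the CSV table and a JSON
#' sidecar recording the config and seed, and returns the table invisibly.
#' Identical config + seed give byte-identical files.
#'
#' @param config a named list; \code{kind} and \code{seed} are required,
#'   remaining entries are passed to the matching generator.
#' @param out_csv,out_json output paths (JSON sidecar optional).
#' @return The generated table, invisibly.
#' @export
run_simulate <- function(config, out_csv, out_json = NULL) {
  stopifnot(is.list(config), !is.null(config$kind), !is.null(config$seed))
  kind <- config$kind
  args <- config[setdiff(names(config), "kind")]
  tab <- if (kind == "responses") {
    do.call(simulate_responses, args)
  } else if (kind == "trace") {
    args$seed <- NULL
    tr <- do.call(simulate_trace, args)
    data.frame(time_s = tr$time_s, current_nA = tr$current_nA)
  } else if (kind %in% c("isotherm", "modulation", "timecourse")) {
    do.call(simulate_binding, c(list(kind = kind), args))
  } else stop("unknown simulation kind: ", kind)
  utils::write.csv(tab, out_csv, row.names = FALSE)
  if (!is.null(out_json)) {
    meta <- list(kind = kind, seed = config$seed,
                 package_version =
                   as.character(utils::packageVersion("gabarod")),
                 config = config[!vapply(config, is.object, logical(1))])
    jsonlite::write_json(meta, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(tab)
}

#' Fit a table read from one of the interchange CSVs
#'
#' Dispatches to the matching fitter: \code{"isotherm"} expects the binding
#' schema (fits specific binding vs concentration in nM), \code{"hill"} the
#' modulation schema, \code{"timecourse"} the time-course schema.
#'
#' @param subcommand one of \code{"isotherm"}, \code{"hill"},
#'   \code{"timecourse"}.
#' @param table a data frame in the matching schema (see the readers).
#' @param report_json optional path: write the fit report as JSON.
#' @return The \code{"rod_fit"} object.
#' @export
run_fit <- function(subcommand = c("isotherm", "hill", "timecourse"), table,
                    report_json = NULL) {
  subcommand <- match.arg(subcommand)
  fit <- switch(subcommand,
    isotherm = {
      check_columns(table, c("ligand_conc_nM", "total_cpm",
                             "nonspecific_cpm"), "binding table")
      sp <- specific_binding(table$total_cpm, table$nonspecific_cpm)
      fit_isotherm(table$ligand_conc_nM, sp$specific_cpm)
    },
    hill = {
      check_columns(table, c("modulator_conc_uM", "percent_of_control"),
                    "modulation table")
      fit_hill_modulation(table$modulator_conc_uM, table$percent_of_control)
    },
    timecourse = {
      check_columns(table, c("time_min", "percent_of_control"),
                    "time-course table")
      fit_mono_exponential(table$time_min, table$percent_of_control)
    })
  if (!is.null(report_json)) {
    payload <- list(kind = fit$kind, converged = fit$converged,
                    package_version =
                      as.character(utils::packageVersion("gabarod")))
    if (fit$converged) {
      payload$estimates <- fit$estimates
      payload$se <- fit$se
      payload$rss <- fit$rss
    } else payload$message <- fit$message
    jsonlite::write_json(payload, report_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  fit
}
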