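#' Read and write donor panels as comma-separated text
#'
#' Panels are plain CSV with a `donor_id` column and one column per
#' factor; comment lines beginning `#` (used for units) are skipped on
#' read and written from `units` on write.
#'
#' @param path File path.
#' @param panel Donor panel data frame.
#' @param units Optional named character vector of per-factor units,
#'   written as a `#` header comment.
#' @return `read_donor_panel` returns the panel data frame;
#'   `write_donor_panel` returns `path` invisibly.
#' @export
read_donor_panel <- function(path) {
  panel <- utils::read.csv(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!"donor_id" %in% names(panel))
    stop("panel file must have a donor_id column", call. = FALSE)
  panel$donor_id <- as.character(panel$donor_id)
  panel
}

#' @rdname read_donor_panel
#' @export
write_donor_panel <- function(panel, path, units = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(units))
    writeLines(paste0("# units: ",
                      paste(names(units), units, sep = " = ",
                            collapse = "; ")), con)
  utils::write.csv(panel, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write CFSE event tables
#'
#' Event tables are CSV with columns `condition`, `fluorescence` and,
#' for simulated data, `true_generation` (carried for verification;
#' ignored by all analysis functions).
#'
#' @param path File path.
#' @param events Event table data frame.
#' @return `read_event_table` returns the data frame;
#'   `write_event_table` returns `path` invisibly.
#' @export
read_event_table <- function(path) {
  ev <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"fluorescence" %in% names(ev))
    stop("event table must have a fluorescence column", call. = FALSE)
  ev
}

#' @rdname read_event_table
#' @export
write_event_table <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write dose-response tables
#'
#' CSV with columns `dose`, `response` and optionally `replicate`.
#'
#' @param path File path.
#' @param dr Dose-response data frame.
#' @return `read_dose_response` returns the data frame;
#'   `write_dose_response` returns `path` invisibly.
#' @export
read_dose_response <- function(path) {
  dr <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("dose", "response") %in% names(dr)))
    stop("dose-response table needs dose and response columns",
         call. = FALSE)
  dr
}

#' @rdname read_dose_response
#' @export
write_dose_response <- function(dr, path) {
  utils::write.csv(dr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write simulation configurations
#'
#' Serializes a [sim_config()] to nested key-value YAML and back; the
#' read result is validated through `sim_config()`.
#'
#' @param path File path.
#' @param config A `sim_config` object.
#' @return `read_sim_config` returns a validated `sim_config`;
#'   `write_sim_config` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  fs <- raw$factor_specs
  if (!is.null(fs) && !is.data.frame(fs))
    fs <- do.call(rbind, lapply(fs, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  args <- list(seed = raw$seed, n_donors = raw$n_donors)
  if (!is.null(fs)) args$factor_specs <- fs
  for (nm in c("cfse_spec", "dose_spec", "pair_spec"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  do.call(sim_config, args)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$factor_specs <- lapply(seq_len(nrow(x$factor_specs)), function(i)
    as.list(x$factor_specs[i, , drop = FALSE]))
  yaml::write_yaml(x, path)
  invisible(path)
}
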