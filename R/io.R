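# io_cli: trace and dataset readers/writers with units provenance, and
# serialization of inversion results.

#' Write a trace to delimited text
#'
#' Comma-separated with a header row and a leading `# units:` comment
#' line recording the column units.
#'
#' @param trace data frame with at least `t`, `v`, `ca`.
#' @param path output file path.
#' @param units named character vector of units per column; defaults to
#'   the package-wide convention (ms, mV, mM).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path,
                        units = c(t = "ms", v = "mV", ca = "mM")) {
  stopifnot(all(c("t", "v", "ca") %in% names(trace)))
  u <- vapply(names(trace), function(nm) {
    if (nm %in% names(units)) units[[nm]] else "A/F|mmol/ms"
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", paste(names(trace), u, sep = "=",
                                       collapse = ",")), con)
  utils::write.table(trace, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path file path.
#' @return data frame with a `units` attribute; errors on a missing units
#'   header or ragged rows, reporting the offending line.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  if (!grepl("^# units:", first)) {
    stop("line 1: missing '# units:' header in ", path)
  }
  units_spec <- sub("^# units:\\s*", "", first)
  pairs <- strsplit(strsplit(units_spec, ",")[[1]], "=")
  units <- stats::setNames(vapply(pairs, `[`, character(1), 2),
                           vapply(pairs, `[`, character(1), 1))
  tr <- tryCatch(
    utils::read.csv(path, comment.char = "#", check.names = FALSE),
    error = function(e) stop("malformed trace file ", path, ": ",
                             conditionMessage(e))
  )
  n_fields <- utils::count.fields(path, sep = ",", comment.char = "#")
  if (length(unique(n_fields)) != 1) {
    stop("ragged row at line ",
         which(n_fields != n_fields[1])[1] + 1, " of ", path)
  }
  if (!all(c("t", "v", "ca") %in% names(tr))) {
    stop("trace file must have columns t, v, ca")
  }
  attr(tr, "units") <- units
  tr
}

#' Write a dose escalation dataset to a JSON envelope
#'
#' Stores every trace, the dose ladder, units and provenance metadata in
#' one structured file; the round trip through [read_dataset()] is exact
#' to full double precision.
#'
#' @param dataset a `dose_escalation_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  payload <- list(
    format = "cardioinverse-dataset",
    version = 1L,
    doses = dataset$doses,
    units = dataset$units,
    meta = dataset$meta,
    traces = lapply(dataset$traces, as.list)
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a dataset JSON envelope
#'
#' @param path file written by [write_dataset()].
#' @return a `dose_escalation_dataset`.
#' @export
read_dataset <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$format, "cardioinverse-dataset")) {
    stop("not a cardioinverse dataset file: ", path)
  }
  traces <- lapply(x$traces, function(tr) {
    as.data.frame(lapply(tr, function(col) as.numeric(unlist(col))))
  })
  meta <- lapply(x$meta, function(f) {
    if (is.list(f)) unlist(f) else f
  })
  dose_escalation_dataset(traces, as.numeric(unlist(x$doses)), x$units,
                          meta)
}

#' Write an inversion result to JSON
#'
#' Includes the fitted factors and potencies, the derived IC50 table, the
#' continuation path, seed and configuration echo, so a run can be
#' re-executed bit-compatibly.
#'
#' @param result an `inversion_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_inversion_result <- function(result, path) {
  payload <- list(
    format = "cardioinverse-inversion",
    version = 1L,
    lambda = as.list(result$lambda),
    eps = as.list(result$eps),
    ic50 = as.list(result$ic50),
    units = result$units,
    doses = result$doses,
    final_cost = result$final_cost,
    seed = result$seed,
    config = result$config[c("free_lambda", "free_eps", "M", "starts",
                             "iters_early", "iters_late", "late_from",
                             "lambda_halfwidth", "eps_range", "seed")],
    path = as.list(result$path)
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read an inversion result JSON
#'
#' @param path file written by [write_inversion_result()].
#' @return list with the stored fields (`lambda`, `eps`, `ic50`, ...).
#' @export
read_inversion_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$format, "cardioinverse-inversion")) {
    stop("not a cardioinverse inversion file: ", path)
  }
  num <- function(f) {
    out <- vapply(f, function(z) if (is.null(z)) NA_real_ else
      as.numeric(z), numeric(1))
    out
  }
  x$lambda <- num(x$lambda)
  x$eps <- num(x$eps)
  x$ic50 <- num(x$ic50)
  x$doses <- as.numeric(unlist(x$doses))
  x$seed <- as.integer(x$seed)
  x$final_cost <- as.numeric(x$final_cost)
  x$path <- as.data.frame(lapply(x$path, num))
  x
}
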