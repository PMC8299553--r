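#' Read a time series from delimited text
#'
#' Accepts single-column or named-column delimiter-separated text with a
#' header. With several columns, `column` selects by name (default: a
#' column named `x`, else the last numeric column, so `time,x` files work
#' directly). Values are parsed as doubles; a non-numeric entry is a parse
#' error naming the offending line.
#'
#' @param path File path.
#' @param dt Sampling interval (required; delimited text carries no rate).
#' @param column Optional column name.
#' @param sep Field separator (default `","`).
#' @return A `langevin_ts`.
#' @export
load_timeseries <- function(path, dt, column = NULL, sep = ",") {
  if (!file.exists(path)) lr_error(paste0("no such file: ", path), "configuration_error")
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, colClasses = "character",
               check.names = FALSE),
    error = function(e) lr_error(paste0("cannot parse ", path, ": ",
                                        conditionMessage(e)), "parse_error")
  )
  if (ncol(df) == 0L || nrow(df) == 0L) lr_error("empty input file", "parse_error")
  col <- if (!is.null(column)) {
    if (!column %in% names(df)) {
      lr_error(paste0("no column '", column, "' in ", path), "parse_error")
    }
    column
  } else if ("x" %in% names(df)) "x" else names(df)[ncol(df)]
  raw <- df[[col]]
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    lr_error(sprintf("non-numeric entry '%s' in column '%s', data line %d",
                     raw[bad], col, bad), "parse_error")
  }
  langevin_ts(vals, dt, label = basename(path))
}

#' Write a time series as delimited text
#'
#' Two columns, `time` and `x`, with header.
#'
#' @param ts A `langevin_ts`.
#' @param path Output path.
#' @param sep Field separator.
#' @export
save_timeseries <- function(ts, path, sep = ",") {
  stopifnot(inherits(ts, "langevin_ts"))
  df <- data.frame(time = (seq_along(ts$values) - 1L) * ts$dt, x = ts$values)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Model JSON serialization
#'
#' The fixed interchange schema shared by the fit/simulate/select tools:
#' `{"drift": [{"name","degree","coeff"}...], "diffusion": [...],
#' "polar_ito_term": bool, "domain": [lo, hi]}`. A model round-trips
#' losslessly (coefficients written at full precision).
#'
#' @param model A `langevin_model`.
#' @param path JSON file path.
#' @return `load_model()` returns a `langevin_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "langevin_model"))
  obj <- list(
    drift = data.frame(
      name = names(model$drift_library),
      degree = library_degrees(model$drift_library),
      coeff = model$drift_coeffs
    ),
    diffusion = data.frame(
      name = names(model$diffusion_library),
      degree = library_degrees(model$diffusion_library),
      coeff = model$diffusion_coeffs
    ),
    polar_ito_term = model$polar_ito_term,
    domain = model$domain
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) lr_error(paste0("no such file: ", path), "configuration_error")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("drift", "diffusion", "polar_ito_term", "domain")
  if (!all(need %in% names(obj))) {
    lr_error("model JSON missing required fields", "parse_error")
  }
  mk_lib <- function(tab, kind) {
    function_library(
      mapply(function(d, nm) function_term(d, kind, name = nm),
             tab$degree, tab$name, SIMPLIFY = FALSE)
    )
  }
  langevin_model(
    drift_library = mk_lib(obj$drift, "drift"),
    drift_coeffs = obj$drift$coeff,
    diffusion_library = mk_lib(obj$diffusion, "diffusion"),
    diffusion_coeffs = obj$diffusion$coeff,
    polar_ito_term = isTRUE(obj$polar_ito_term),
    domain = as.numeric(obj$domain)
  )
}

#' Export binned moments as a delimited table
#'
#' Columns: `bin_center, count, m1, m2, w1, w2, valid`.
#'
#' @param binned A `binned_moments`.
#' @param path Output path.
#' @param sep Field separator.
#' @export
save_moments <- function(binned, path, sep = ",") {
  stopifnot(inherits(binned, "binned_moments"))
  df <- data.frame(
    bin_center = binned$grid$centers, count = binned$counts,
    m1 = binned$m1, m2 = binned$m2, w1 = binned$w1, w2 = binned$w2,
    valid = binned$valid
  )
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
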