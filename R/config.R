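#' Full model configuration
#'
#' Aggregates every tunable constant of the delivery, dosimetry, and
#' tumor-response layers in one flat list, with all defaults equal to the
#' published values for the astatine-211 xenograft analysis (transfer
#' coefficients 0.33/1/0.5/0.1/0.5 per hour, 7.21 h half-life, 5.45 Gy/h per
#' MBq in a 1.5 g tumor, lam 0.14/day, b 0.3/Gy, c 0.1/day, t0 0, N0 2e9,
#' Nm 4e10, V0 577 mm3). The decay rate is always derived from the half-life,
#' never stored.
#'
#' @param ... Named overrides of any configuration field (see
#'   [default_config_values()] for names and defaults). Unknown names are an
#'   error.
#' @return An object of class `model_config` (a named list of scalars).
#' @seealso [load_config()], [write_config()], and the accessors
#'   [config_rates()], [config_conversion()], [config_params()].
#' @examples
#' cfg <- model_config(half_life_h = 10)
#' config_rates(cfg)$y # log(2)/10
#' @export
model_config <- function(...) {
  defaults <- default_config_values()
  overrides <- list(...)
  if (length(overrides) > 0 &&
      (is.null(names(overrides)) || any(names(overrides) == ""))) {
    abort("All configuration overrides must be named.",
          class = "trtsim_config_error")
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown configuration key(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "trtsim_config_error")
  }
  for (nm in names(overrides)) {
    x <- overrides[[nm]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
      abort(sprintf("Configuration key `%s` must be a single number.", nm),
            class = "trtsim_config_error")
    }
  }
  cfg <- modifyList(defaults, overrides)
  class(cfg) <- "model_config"
  # enforce the member-type invariants by constructing each piece
  config_rates(cfg)
  config_conversion(cfg)
  config_params(cfg)
  cfg
}

#' @rdname model_config
#' @export
default_config_values <- function() {
  list(
    a12 = 0.33, a13 = 1, a14 = 0.5, a21 = 0.1, a31 = 0.5,
    half_life_h = 7.21,
    gy_per_h_per_mbq = 5.45, tumor_mass_g = 1.5,
    lam = 0.14, b = 0.3, c = 0.1, t0 = 0,
    N0 = 2e9, Nm = 4e10, V0 = 577
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  for (nm in names(unclass(x))) cat(sprintf("  %s = %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @rdname model_config
#' @param cfg A `model_config` object.
#' @export
config_rates <- function(cfg) {
  with_config_errors(
    delivery_rates(a12 = cfg$a12, a13 = cfg$a13, a14 = cfg$a14,
                   a21 = cfg$a21, a31 = cfg$a31,
                   half_life_h = cfg$half_life_h)
  )
}

#' @rdname model_config
#' @export
config_conversion <- function(cfg) {
  with_config_errors(
    dose_conversion(gy_per_h_per_mbq = cfg$gy_per_h_per_mbq,
                    tumor_mass_g = cfg$tumor_mass_g)
  )
}

#' @rdname model_config
#' @export
config_params <- function(cfg) {
  with_config_errors(
    tumor_params(lam = cfg$lam, b = cfg$b, c = cfg$c, t0 = cfg$t0,
                 N0 = cfg$N0, Nm = cfg$Nm, V0 = cfg$V0)
  )
}

with_config_errors <- function(expr) {
  tryCatch(expr, trtsim_invalid_input = function(e) {
    abort(paste0("Invalid configuration: ", conditionMessage(e)),
          class = "trtsim_config_error")
  })
}

#' Read / write a flat key-value configuration file
#'
#' The configuration file format is one `key = value` pair per line; blank
#' lines and lines starting with `#` are ignored. Keys missing from the file
#' take the published defaults; unknown keys are rejected with an error that
#' names the key. `write_config()` and `load_config()` round-trip losslessly.
#'
#' @param path Path to the configuration file.
#' @return `load_config()` returns a [model_config()]; `write_config()`
#'   returns `path` invisibly.
#' @examples
#' path <- tempfile(fileext = ".cfg")
#' write_config(model_config(b = 0.25), path)
#' load_config(path)$b
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Configuration file not found: %s", path),
          class = "trtsim_config_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  values <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      abort(sprintf("Malformed configuration line (expected `key = value`): %s",
                    ln),
            class = "trtsim_config_error")
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- suppressWarnings(as.numeric(trimws(sub("^[^=]*=", "", ln))))
    if (is.na(val)) {
      abort(sprintf("Configuration key `%s` has a non-numeric value.", key),
            class = "trtsim_config_error")
    }
    values[[key]] <- val
  }
  do.call(model_config, values)
}

#' @rdname load_config
#' @param cfg A [model_config()] to serialize.
#' @export
write_config <- function(cfg, path) {
  if (!inherits(cfg, "model_config")) {
    abort("`cfg` must be a `model_config`.", class = "trtsim_config_error")
  }
  lines <- vapply(names(unclass(cfg)), function(nm) {
    sprintf("%s = %s", nm, format(cfg[[nm]], digits = 17))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
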