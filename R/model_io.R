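# Model serialization: a small JSON dialect in which every number is stored
# as a decimal string, so printed constants survive a round trip exactly.
# The dialect is described by inst/extdata/gma-model-schema.json; the
# validator below mirrors that schema and reports JSON-pointer paths.

# Shortest decimal string that parses back to exactly x.
dec_string <- function(x) {
  for (d in 1:17) {
    s <- sprintf("%.*g", d, x)
    if (as.numeric(s) == x) return(s)
  }
  sprintf("%.17g", x)
}

num_from_string <- function(s) as.numeric(s)

fail_at <- function(pointer, msg) {
  stop("model file invalid at ", pointer, ": ", msg, call. = FALSE)
}

check_numstr <- function(x, pointer) {
  if (!is.character(x) && !is.numeric(x))
    fail_at(pointer, "expected a decimal string")
  v <- suppressWarnings(as.numeric(x))
  if (length(v) != 1L || is.na(v)) fail_at(pointer, "not a parseable number")
  v
}

validate_model_list <- function(obj) {
  for (key in c("variables", "fluxes", "rows"))
    if (is.null(obj[[key]]) || !is.list(obj[[key]]) || !length(obj[[key]]))
      fail_at(paste0("/", key), "missing or empty array")

  for (i in seq_along(obj$variables)) {
    v <- obj$variables[[i]]; p <- sprintf("/variables/%d", i - 1L)
    if (is.null(v$name) || !nzchar(v$name)) fail_at(paste0(p, "/name"), "missing name")
    if (is.null(v$role) || !v$role %in% c("tunable", "solved", "fixed"))
      fail_at(paste0(p, "/role"), "role must be tunable|solved|fixed")
    if (is.null(v$basal)) fail_at(paste0(p, "/basal"), "missing basal value")
    check_numstr(v$basal, paste0(p, "/basal"))
    if (!is.null(v$bounds)) {
      if (length(v$bounds) != 2L) fail_at(paste0(p, "/bounds"), "bounds must be [lo, hi]")
      lo <- check_numstr(v$bounds[[1]], paste0(p, "/bounds/0"))
      hi <- check_numstr(v$bounds[[2]], paste0(p, "/bounds/1"))
      if (lo > hi) fail_at(paste0(p, "/bounds"), "lo > hi")
    }
  }
  for (i in seq_along(obj$fluxes)) {
    f <- obj$fluxes[[i]]; p <- sprintf("/fluxes/%d", i - 1L)
    if (is.null(f$name) || !nzchar(f$name)) fail_at(paste0(p, "/name"), "missing name")
    if (is.null(f$rate_constant)) fail_at(paste0(p, "/rate_constant"), "missing rate constant")
    rc <- check_numstr(f$rate_constant, paste0(p, "/rate_constant"))
    if (rc <= 0) fail_at(paste0(p, "/rate_constant"), "rate constant must be > 0")
    if (!is.null(f$kinetic_orders)) {
      if (!is.list(f$kinetic_orders) && !is.numeric(f$kinetic_orders) &&
          !is.character(f$kinetic_orders))
        fail_at(paste0(p, "/kinetic_orders"), "expected an object")
      ko <- as.list(f$kinetic_orders)
      if (length(ko) && is.null(names(ko)))
        fail_at(paste0(p, "/kinetic_orders"), "expected variable -> exponent map")
      for (nm in names(ko))
        check_numstr(ko[[nm]], paste0(p, "/kinetic_orders/", nm))
    }
  }
  for (i in seq_along(obj$rows)) {
    r <- obj$rows[[i]]; p <- sprintf("/rows/%d", i - 1L)
    if (is.null(r$pool) || !nzchar(r$pool)) fail_at(paste0(p, "/pool"), "missing pool")
    if (is.null(r$terms) || !length(r$terms))
      fail_at(paste0(p, "/terms"), "row needs at least one term")
    for (j in seq_along(r$terms)) {
      t <- r$terms[[j]]; pt <- sprintf("%s/terms/%d", p, j - 1L)
      if (length(t) != 2L) fail_at(pt, "term must be [flux, coefficient]")
      if (!nzchar(as.character(t[[1]]))) fail_at(paste0(pt, "/0"), "missing flux name")
      check_numstr(t[[2]], paste0(pt, "/1"))
    }
  }
  invisible(TRUE)
}

model_from_list <- function(obj) {
  validate_model_list(obj)
  variables <- lapply(obj$variables, function(v)
    gma_variable(v$name, v$role, num_from_string(v$basal),
                 if (!is.null(v$bounds))
                   c(num_from_string(v$bounds[[1]]), num_from_string(v$bounds[[2]]))))
  fluxes <- lapply(obj$fluxes, function(f) {
    ko <- as.list(f$kinetic_orders)
    power_law_flux(f$name, num_from_string(f$rate_constant),
                   stats::setNames(vapply(ko, num_from_string, numeric(1)),
                                   names(ko)))
  })
  rows <- lapply(obj$rows, function(r) {
    fl <- vapply(r$terms, function(t) as.character(t[[1]]), character(1))
    cf <- vapply(r$terms, function(t) num_from_string(t[[2]]), numeric(1))
    stoich_row(r$pool, stats::setNames(cf, fl))
  })
  md <- if (is.null(obj$metadata)) list() else obj$metadata
  gma_model(variables, fluxes, rows, metadata = md)
}

model_to_list <- function(model) {
  list(
    variables = lapply(model$variables, function(v) {
      out <- list(name = v$name, role = v$role, basal = dec_string(v$basal))
      if (!is.null(v$bounds))
        out$bounds <- list(dec_string(v$bounds[1]), dec_string(v$bounds[2]))
      out
    }),
    fluxes = lapply(model$fluxes, function(f) {
      ko <- f$kinetic_orders
      list(name = f$name, rate_constant = dec_string(f$rate_constant),
           kinetic_orders = if (length(ko))
             stats::setNames(lapply(unname(ko), dec_string), names(ko))
           else stats::setNames(list(), character()))
    }),
    rows = lapply(model$rows, function(r)
      list(pool = r$pool,
           terms = mapply(function(fl, cf) list(fl, dec_string(cf)),
                          names(r$terms), unname(r$terms),
                          SIMPLIFY = FALSE, USE.NAMES = FALSE))),
    metadata = model$metadata
  )
}

#' Read a GMA model from its JSON file
#'
#' The file must follow the package model dialect (see
#' `system.file("extdata", "gma-model-schema.json", package = "ncga")`);
#' numbers are stored as decimal strings so that printed constants are kept
#' exact.  Invalid files fail with a JSON-pointer to the offending field.
#'
#' @param path Path to a model JSON file.
#' @return A `gma_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  model_from_list(obj)
}

#' Write a GMA model to JSON
#'
#' Inverse of [load_model()]: `load_model(save_model(m, f))` reproduces every
#' numeric field bit-exactly.
#'
#' @param model A `gma_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gma_model"))
  jsonlite::write_json(model_to_list(model), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
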