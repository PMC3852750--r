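#' @title RDKit backend bridge
#' @description Internal plumbing that hands standard cheminformatics work
#'   (parsing, layout, SMARTS matching, fingerprint hashing and the per-bit
#'   environment report) to the RDKit toolkit through a shipped Python
#'   helper. Everything simmapr contributes on top of the toolkit lives in
#'   R; this file only moves JSON across a subprocess boundary.
#' @details Requests are batched (one process launch per call) and memoised
#'   for the session, so repeated fingerprinting of the same molecules in a
#'   test run costs one subprocess each.
#' @name backend
#' @keywords internal
NULL

.simmapr_env <- new.env(parent = emptyenv())

simmapr_python <- function() {
  p <- getOption("simmapr.python", Sys.getenv("SIMMAPR_PYTHON", "python"))
  path <- Sys.which(p)
  if (!nzchar(path)) {
    abort(sprintf("python interpreter '%s' not found on PATH", p),
          "simmapr_backend_error")
  }
  path
}

backend_script <- function() {
  path <- system.file("python", "rdkit_backend.py", package = "simmapr")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ is mapped automatically; this
    # fallback covers running from a source checkout without installation
    path <- file.path("inst", "python", "rdkit_backend.py")
  }
  if (!file.exists(path)) {
    abort("rdkit_backend.py not found; is simmapr installed correctly?",
          "simmapr_backend_error")
  }
  path
}

#' Call the RDKit helper with a request list, returning its parsed result.
#' @noRd
rdkit_call <- function(op, req) {
  req$op <- op
  payload <- jsonlite::toJSON(req, auto_unbox = TRUE, digits = NA, null = "null")
  key <- paste0(op, "\r", payload)
  cache <- .simmapr_env
  if (!is.null(cache[[key]])) {
    return(cache[[key]])
  }
  infile <- tempfile(fileext = ".json")
  on.exit(unlink(infile), add = TRUE)
  writeLines(payload, infile)
  out <- suppressWarnings(system2(
    simmapr_python(), shQuote(backend_script()),
    stdout = TRUE, stderr = FALSE, stdin = infile
  ))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    abort(sprintf("rdkit backend exited with status %d", status),
          "simmapr_backend_error")
  }
  res <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
  if (!isTRUE(res$ok)) {
    abort(paste0("rdkit backend error: ", res$error), "simmapr_backend_error")
  }
  cache[[key]] <- res$result
  res$result
}

#' Signal a classed simmapr condition.
#' @noRd
abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "simmapr_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}
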