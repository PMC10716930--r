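# Bridge to the persistent RDKit worker process.
#
# A single Python subprocess (inst/python/chem_worker.py) is started lazily
# per R session and reused for every chemistry call; requests and responses
# are newline-delimited JSON on the worker's stdin/stdout.

.patgen <- new.env(parent = emptyenv())

worker_script <- function() {
  path <- system.file("python", "chem_worker.py", package = "patgen")
  if (path == "") {
    # during development (pkgload) system.file resolves inst/ itself
    path <- system.file("inst", "python", "chem_worker.py", package = "patgen")
  }
  if (path == "") stop("chem_worker.py not found in the installed package")
  path
}

#' Start (or fetch) the chemistry worker process
#'
#' The worker is a long-lived Python subprocess running RDKit; it performs
#' the standard cheminformatics primitives (parsing, standardization,
#' identifiers, descriptors, fingerprints, substructure matching) on behalf
#' of the package. Started on first use and cached for the session.
#'
#' @param restart Kill any existing worker and start a fresh one.
#' @return A `processx::process` handle (invisibly).
#' @export
chem_worker <- function(restart = FALSE) {
  w <- .patgen$worker
  if (!restart && !is.null(w) && w$is_alive()) {
    return(invisible(w))
  }
  if (!is.null(w) && w$is_alive()) w$kill()
  w <- processx::process$new(
    "python", c("-u", worker_script()),
    stdin = "|", stdout = "|", stderr = "|"
  )
  .patgen$worker <- w
  .patgen$req_id <- 0L
  # fail fast if python/rdkit is unusable
  res <- tryCatch(chem_request("ping", list()), error = function(e) e)
  if (!identical(res, "pong")) {
    err <- paste(w$read_error_lines(), collapse = "\n")
    stop("chemistry worker failed to start: ", conditionMessage(res), "\n", err)
  }
  invisible(w)
}

#' Stop the chemistry worker
#' @return `TRUE` invisibly.
#' @export
chem_worker_stop <- function() {
  w <- .patgen$worker
  if (!is.null(w) && w$is_alive()) w$kill()
  .patgen$worker <- NULL
  invisible(TRUE)
}

# Send one request to the worker and wait for its reply.
chem_request <- function(op, args, timeout = 600) {
  w <- chem_worker()
  .patgen$req_id <- .patgen$req_id + 1L
  req <- jsonlite::toJSON(
    list(id = .patgen$req_id, op = op, args = args),
    auto_unbox = TRUE, null = "null", digits = NA
  )
  # large requests exceed the pipe buffer: loop until fully written
  pending <- charToRaw(paste0(req, "\n"))
  while (length(pending) > 0) {
    pending <- w$write_input(pending)
    if (length(pending) > 0) w$poll_io(50)
  }
  line <- ""
  deadline <- Sys.time() + timeout
  repeat {
    w$poll_io(1000)
    out <- w$read_output_lines(n = 1)
    if (length(out) == 1) {
      line <- out
      break
    }
    if (!w$is_alive()) {
      stop(
        "chemistry worker died: ",
        paste(w$read_error_lines(), collapse = "\n")
      )
    }
    if (Sys.time() > deadline) stop("chemistry worker timed out on op ", op)
  }
  resp <- jsonlite::fromJSON(line, simplifyVector = FALSE)
  if (!isTRUE(resp$ok)) stop("chemistry worker error: ", resp$error)
  resp$result
}

# Batch helper: send smiles in chunks to bound single-message size.
chem_request_chunked <- function(op, smiles, extra = list(), chunk = 20000L) {
  if (length(smiles) == 0) return(list())
  idx <- split(seq_along(smiles), ceiling(seq_along(smiles) / chunk))
  out <- vector("list", length(smiles))
  for (ii in idx) {
    args <- c(list(smiles = as.list(smiles[ii])), extra)
    out[ii] <- chem_request(op, args)
  }
  out
}
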