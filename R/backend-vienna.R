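# Adapter to the ViennaRNA nearest-neighbor implementation, through a
# persistent Python worker speaking JSON lines over a pair of named
# pipes.  One worker is shared per R session; it is started lazily and
# shut down when the backend is garbage collected or R exits.

the_worker <- new.env(parent = emptyenv())

find_python <- function() {
  py <- Sys.getenv("RNAFITNESS_PYTHON", "")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) stop("no python interpreter found on PATH")
  py
}

worker_script <- function() {
  path <- system.file("python", "vienna_worker.py", package = "rnafitness")
  if (!nzchar(path)) stop("vienna_worker.py not found in the installed package")
  path
}

#' Is the ViennaRNA backend usable in this session?
#'
#' Checks that a Python interpreter with importable ViennaRNA bindings
#' is on the PATH (set `RNAFITNESS_PYTHON` to override the
#' interpreter).
#'
#' @return Logical scalar.
#' @export
vienna_available <- function() {
  ok <- tryCatch({
    py <- find_python()
    out <- suppressWarnings(system2(py, c("-c", shQuote("import RNA")),
                                    stdout = TRUE, stderr = TRUE))
    is.null(attr(out, "status")) || attr(out, "status") == 0
  }, error = function(e) FALSE)
  isTRUE(ok)
}

start_worker <- function() {
  if (!is.null(the_worker$req_con)) return(invisible(the_worker))
  py <- find_python()
  # fail fast with a clear message rather than blocking on the pipe
  chk <- suppressWarnings(system2(py, c("-c", shQuote("import RNA")),
                                  stdout = TRUE, stderr = TRUE))
  if (!is.null(attr(chk, "status")) && attr(chk, "status") != 0)
    stop("python cannot import the ViennaRNA bindings:\n",
         paste(chk, collapse = "\n"))
  dir <- tempfile("vrna_worker_")
  dir.create(dir)
  req <- file.path(dir, "req")
  resp <- file.path(dir, "resp")
  if (system2("mkfifo", c(req, resp)) != 0) stop("mkfifo failed")
  system2(py, c(worker_script(), req, resp), wait = FALSE)
  the_worker$req_con <- fifo(req, open = "w", blocking = TRUE)
  the_worker$resp_con <- fifo(resp, open = "r", blocking = TRUE)
  the_worker$dir <- dir
  ver <- worker_call(list(op = "version"))
  the_worker$version <- ver$viennarna
  reg.finalizer(the_worker, function(e) stop_worker(), onexit = TRUE)
  invisible(the_worker)
}

stop_worker <- function() {
  if (is.null(the_worker$req_con)) return(invisible())
  try({
    writeLines(jsonlite::toJSON(list(op = "quit"), auto_unbox = TRUE),
               the_worker$req_con)
    flush(the_worker$req_con)
  }, silent = TRUE)
  try(close(the_worker$req_con), silent = TRUE)
  try(close(the_worker$resp_con), silent = TRUE)
  the_worker$req_con <- NULL
  the_worker$resp_con <- NULL
  invisible()
}

worker_call <- function(req) {
  start_worker()
  writeLines(jsonlite::toJSON(req, auto_unbox = TRUE, digits = NA),
             the_worker$req_con)
  flush(the_worker$req_con)
  line <- readLines(the_worker$resp_con, n = 1L)
  if (length(line) == 0) stop("ViennaRNA worker terminated unexpectedly")
  resp <- jsonlite::fromJSON(line, simplifyVector = TRUE,
                             simplifyMatrix = FALSE)
  if (!is.null(resp$error)) stop("ViennaRNA worker error: ", resp$error)
  resp
}

#' ViennaRNA backend
#'
#' Folding, free energies, partition-function quantities, ensemble
#' defect and Wuchty suboptimal enumeration as implemented by the
#' ViennaRNA package (default model parameters, 37 degrees C),
#' accessed through its Python bindings in a persistent worker
#' process.
#'
#' @return A backend usable with all `be_*` operations.
#' @export
vienna_backend <- function() {
  structure(list(name = "vienna"),
            class = c("vienna_backend", "rna_backend"))
}

#' @export
be_rt.vienna_backend <- function(backend) 0.6163208

#' @export
backend_version.vienna_backend <- function(backend) {
  start_worker()
  paste0("ViennaRNA ", the_worker$version)
}

vec_op <- function(op, seqs, structs) {
  if (length(structs) == 1L) structs <- rep(structs, length(seqs))
  stopifnot(length(seqs) == length(structs))
  as.numeric(worker_call(list(op = op, seqs = as.list(seqs),
                              structs = as.list(structs)))$values)
}

#' @export
be_energy.vienna_backend <- function(backend, seqs, structs)
  vec_op("eval", seqs, structs)

#' @export
be_prob.vienna_backend <- function(backend, seqs, structs)
  vec_op("prob", seqs, structs)

#' @export
be_defect.vienna_backend <- function(backend, seqs, structs)
  vec_op("defect", seqs, structs)

#' @export
be_ensemble_g.vienna_backend <- function(backend, seqs)
  as.numeric(worker_call(list(op = "ensemble_g", seqs = as.list(seqs)))$values)

#' @export
be_mfe.vienna_backend <- function(backend, seqs) {
  resp <- worker_call(list(op = "mfe", seqs = as.list(seqs)))
  list(structures = as.character(unlist(resp$structures)),
       energies = as.numeric(resp$energies))
}

#' @export
be_coopt.vienna_backend <- function(backend, seqs) {
  resp <- worker_call(list(op = "coopt", seqs = as.list(seqs)))
  lapply(resp$structures, function(x) as.character(unlist(x)))
}

#' @export
be_subopt.vienna_backend <- function(backend, seq, window, max_count = 1e6) {
  resp <- worker_call(list(op = "subopt", seq = seq, window = window,
                           cap = max_count))
  list(structures = as.character(unlist(resp$structures)),
       energies = as.numeric(resp$energies),
       complete = isTRUE(resp$complete))
}

#' @export
be_subopt_pick.vienna_backend <- function(backend, seq, window, max_count, u) {
  resp <- worker_call(list(op = "subopt_pick", seq = seq, window = window,
                           cap = max_count, u = u))
  list(count = resp$count,
       structure = if (isTRUE(resp$skipped)) NA_character_ else resp$structure,
       skipped = isTRUE(resp$skipped))
}

#' @export
be_bpp.vienna_backend <- function(backend, seq) {
  resp <- worker_call(list(op = "bpp", seq = seq))
  n <- resp$n
  m <- matrix(0, n, n)
  if (length(resp$i) > 0) {
    idx <- cbind(resp$i, resp$j)
    m[idx] <- resp$p
    m[idx[, c(2, 1), drop = FALSE]] <- resp$p
  }
  m
}
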