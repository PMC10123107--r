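# File formats and run metadata.  FASTA goes through Biostrings;
# dot-bracket is the canonical structure form; CT is accepted for
# natural sequence/structure inputs because curated collections ship
# in it.

#' Read a FASTA file of RNA sequences
#'
#' DNA-style T is mapped to U (with a message); sequences are
#' upper-cased and validated against the A/C/G/U alphabet.
#'
#' @param path FASTA file.
#' @return Data frame with columns `id` and `seq`, in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  if (any(grepl("T", seqs, fixed = TRUE))) {
    message("mapping T to U in ", sum(grepl("T", seqs, fixed = TRUE)),
            " sequence(s)")
    seqs <- gsub("T", "U", seqs, fixed = TRUE)
  }
  for (k in seq_along(seqs)) encode_seq(seqs[[k]]) # validate alphabet
  data.frame(id = names(set), seq = unname(seqs), row.names = NULL)
}

#' Write sequences to FASTA
#'
#' @param ids record identifiers.
#' @param seqs sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, seqs, path) {
  stopifnot(length(ids) == length(seqs))
  set <- Biostrings::BStringSet(setNames(as.character(seqs), ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a connectivity-table (CT) structure file
#'
#' Standard 6-column CT: a header line giving the length (and
#' optionally a title), then one row per nucleotide with 1-based
#' index, base, previous/next indices, pairing partner (0 when
#' unpaired) and the index again.  The pairing must be properly
#' nested; pseudoknotted (crossing) pairings are rejected since the
#' model here covers nested structures only.
#'
#' @param path CT file.
#' @return List with `id`, `seq` and `structure` (an
#'   `rna_structure`).
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("CT file has no records")
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(header[[1]]))
  if (is.na(n)) stop("CT header does not start with the sequence length")
  id <- if (length(header) > 1) paste(header[-1], collapse = " ") else ""
  if (length(lines) < n + 1) stop("CT file truncated: expected ", n, " rows")
  bases <- character(n)
  pm <- integer(n)
  for (r in seq_len(n)) {
    f <- strsplit(trimws(lines[[r + 1]]), "\\s+")[[1]]
    if (length(f) < 6) stop("malformed CT row ", r)
    i <- as.integer(f[[1]])
    if (i != r) stop("CT row ", r, " has index ", i)
    bases[r] <- toupper(f[[2]])
    pm[r] <- as.integer(f[[5]])
  }
  pm[pm == 0L] <- which(pm == 0L)
  for (r in seq_len(n)) {
    if (pm[r] != r && pm[pm[r]] != r)
      stop("inconsistent pair columns at CT row ", r)
  }
  seq <- paste(bases, collapse = "")
  seq <- gsub("T", "U", seq, fixed = TRUE)
  st <- tryCatch(validate_structure(new_structure(pm)),
                 error = function(e)
                   stop("CT structure rejected: ", conditionMessage(e),
                        call. = FALSE))
  list(id = id, seq = seq, structure = st)
}

#' Write a results table as TSV
#'
#' Numeric columns are printed with 2 decimals (mirroring benchmark
#' table conventions); a sidecar `<path>.full.tsv` keeps full
#' precision.
#'
#' @param table data frame.
#' @param path output TSV path.
#' @param digits printed decimals for numeric columns.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, digits = 2) {
  rounded <- table
  half_up <- function(x) { # display rounding: .5 always rounds away from 0
    s <- sign(x)
    s * floor(abs(x) * 10^digits + 0.5 + 1e-9) / 10^digits
  }
  for (cl in names(rounded)) {
    if (is.double(rounded[[cl]]))
      rounded[[cl]] <- formatC(half_up(rounded[[cl]]), format = "f",
                               digits = digits)
  }
  utils::write.table(rounded, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table, paste0(path, ".full.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Machine-readable run metadata
#'
#' @param backend backend in use.
#' @param master_seed master RNG seed of the run.
#' @param ... further fields to record (walk parameters, dataset
#'   paths, fitness labels...).
#' @return A list with package version, backend version, seed, date
#'   and the extra fields.
#' @export
run_metadata <- function(backend, master_seed, ...) {
  c(list(package = paste0("rnafitness ",
                          as.character(utils::packageVersion("rnafitness"))),
         backend = backend_version(backend),
         master_seed = master_seed,
         date = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    list(...))
}

#' Write run metadata as JSON
#'
#' @param meta list from [run_metadata()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
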