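# File I/O, configuration and structured logging.

#' Read protein sequences from FASTA
#'
#' Wraps `Biostrings::readAAStringSet`, uppercases, and validates the
#' 20-letter canonical alphabet: `validate = "strict"` fails on the first
#' offending record (reported by name), `"skip"` drops offending records
#' with a warning.
#'
#' @param path FASTA file.
#' @param validate `"strict"` (default) or `"skip"`.
#' @return `AAStringSet`.
#' @export
readFastaAA <- function(path, validate = c("strict", "skip")) {
  validate <- match.arg(validate)
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readAAStringSet(path)
  ch <- toupper(as.character(x))
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), "]"), ch)
  if (any(bad)) {
    if (validate == "strict")
      stop(sprintf("non-canonical residues in record(s): %s",
                   paste(utils::head(names(x)[bad], 5L), collapse = ", ")))
    warning(sprintf("dropping %d record(s) with non-canonical residues", sum(bad)))
    ch <- ch[!bad]
  }
  Biostrings::AAStringSet(ch)
}

#' Write protein sequences to FASTA
#'
#' 60-column wrapped plain FASTA. Refuses to overwrite an existing file
#' unless `force = TRUE`.
#'
#' @param seqs `AAStringSet` (or character vector, named).
#' @param path Output file.
#' @param force Overwrite permission.
#' @return Invisibly, `path`.
#' @export
writeFastaAA <- function(seqs, path, force = FALSE) {
  if (file.exists(path) && !force) stop("refusing to overwrite ", path, " (use force = TRUE)")
  if (!methods::is(seqs, "AAStringSet")) {
    nm <- names(seqs) %||% sprintf("seq_%d", seq_along(seqs))
    seqs <- Biostrings::AAStringSet(setNames(.asSeqChar(seqs), nm))
  }
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read a constraint file
#'
#' Two-column whitespace- or comma-separated text: position, residue
#' letter. A header line is detected and skipped.
#'
#' @param path Constraint file.
#' @return A [ConstraintSet-class].
#' @export
readConstraints <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[,[:space:]]+")
  bad <- vapply(fields, length, integer(1)) != 2L
  if (any(bad)) stop("malformed constraint line(s): ", paste(which(bad), collapse = ","))
  pos <- suppressWarnings(as.integer(vapply(fields, `[`, "", 1L)))
  res <- toupper(vapply(fields, `[`, "", 2L))
  if (is.na(pos[1L]) && length(pos) > 1L) { pos <- pos[-1L]; res <- res[-1L] }  # header
  if (anyNA(pos)) stop("non-integer position in constraint file")
  ConstraintSet(pos, res)
}

#' Write a constraint file
#'
#' @param constraints A [ConstraintSet-class].
#' @param path Output file.
#' @param force Overwrite permission.
#' @return Invisibly, `path`.
#' @export
writeConstraints <- function(constraints, path, force = FALSE) {
  if (file.exists(path) && !force) stop("refusing to overwrite ", path, " (use force = TRUE)")
  utils::write.table(data.frame(position = constraints@positions,
                                residue = constraints@residues),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# allowed run-configuration keys and their types
.configSchema <- list(
  seed = "integer", frame_length = "integer", steps = "integer",
  beta_min = "numeric", beta_max = "numeric",
  widths = "integer", kernel = "integer", pos_channels = "integer",
  batch_size = "integer", learning_rate = "numeric", weight_decay = "numeric",
  max_steps = "integer", ratio = "numeric", threshold = "numeric",
  n = "integer", gap_margin = "numeric", paths = "list")

#' Read and validate a run configuration
#'
#' Single-document YAML (or JSON) configuration for pipeline runs. Unknown
#' keys are rejected; `seed` is mandatory so that every stochastic stage is
#' reproducible from the configuration alone.
#'
#' @param path YAML or JSON file.
#' @return Named list of validated settings, with a `configHash` attribute.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(.configSchema))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop("configuration must set an integer 'seed'")
  for (key in names(cfg)) {
    want <- .configSchema[[key]]
    val <- cfg[[key]]
    ok <- switch(want,
                 integer = is.numeric(val) && all(val == round(val)),
                 numeric = is.numeric(val),
                 list = is.list(val))
    if (!ok) stop(sprintf("configuration key '%s' must be %s", key, want))
  }
  attr(cfg, "configHash") <- rlang::hash(cfg)
  cfg
}

# append one JSON line (UTC timestamp + fields) to an open connection
.logLine <- function(con, fields) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")), fields)
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 8), con)
}

#' Save a diffusion model checkpoint
#'
#' One serialized file carrying the parameters, architecture and schedule
#' hyperparameters (a binary artifact for run-time use, not a text format).
#'
#' @param model A [SeqDiffusionModel-class].
#' @param path Output file.
#' @param force Overwrite permission.
#' @return Invisibly, `path`.
#' @export
saveModel <- function(model, path, force = FALSE) {
  if (file.exists(path) && !force) stop("refusing to overwrite ", path, " (use force = TRUE)")
  saveRDS(model, path)
  invisible(path)
}

#' Load a diffusion model checkpoint
#'
#' @param path Checkpoint written by [saveModel()].
#' @return A [SeqDiffusionModel-class].
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  if (!methods::is(model, "SeqDiffusionModel")) stop("not a model checkpoint: ", path)
  model
}
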