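#' Write a session design or behavioral table to a delimited file
#'
#' Long-format tab-separated tables with a versioned comment header that
#' records the schema, seed, and timing parameters, so any table can be
#' reloaded into the exact object that produced it.
#'
#' @param x a `session_design` or behavioral data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_session <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# expectviol session schema v1", con)
  if (!is.null(attr(x, "experiment"))) {
    writeLines(paste0("# experiment=", attr(x, "experiment")), con)
  }
  if (!is.null(attr(x, "seed"))) {
    writeLines(paste0("# seed=", attr(x, "seed")), con)
  }
  tm <- attr(x, "timing")
  if (!is.null(tm)) {
    writeLines(paste0("# timing=", paste(names(tm), unlist(tm), sep = ":",
                                         collapse = ",")), con)
  }
  utils::write.table(as.data.frame(x), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a session design written by [write_session()]
#'
#' @param path file path.
#' @return a `session_design` (or plain data frame when the header carries
#'   no design attributes).
#' @export
read_session <- function(path) {
  hdr <- character(0)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || !startsWith(line, "#")) break
    hdr <- c(hdr, line)
  }
  close(con); on.exit(NULL)
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  get_field <- function(key) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    sub(paste0("^# ", key, "="), "", m[1])
  }
  seed <- get_field("seed")
  exp <- get_field("experiment")
  timing <- get_field("timing")
  if (!is.null(timing)) {
    parts <- strsplit(strsplit(timing, ",")[[1]], ":")
    timing <- stats::setNames(lapply(parts, function(p) as.numeric(p[2])),
                              vapply(parts, `[[`, "", 1))
  }
  if (!is.null(exp)) {
    x <- structure(x, class = c("session_design", "data.frame"),
                   experiment = exp,
                   seed = if (!is.null(seed)) as.integer(seed) else NULL,
                   timing = timing)
  }
  x
}

#' Write one observer's pupil trace matrix as a long delimited file
#'
#' Columns `t` (ms relative to target onset), `trial_id`, `d`, `missing`;
#' one file per observer.
#'
#' @param trace a per-observer element of a cohort's `pupil` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pupil_trace <- function(trace, path) {
  long <- data.frame(
    t = rep(trace$t_rel, times = ncol(trace$d)),
    trial_id = rep(trace$trials$trial_id, each = length(trace$t_rel)),
    d = as.vector(trace$d),
    missing = as.vector(trace$missing))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# expectviol pupil trace schema v1 (t in ms from target onset)",
             con)
  utils::write.table(long, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load an external behavioral deposit through a column mapping
#'
#' Maps a long-format delimited table with arbitrary column names (such as
#' a public data deposit) into the package's behavioral schema. The mapping
#' gives, for each canonical column, the name it carries in the deposit.
#' Unmapped deposit columns are reported in attribute `unmapped`; missing
#' required columns raise a field-by-field diagnostic.
#'
#' @param path delimited file (tab- or comma-separated; autodetected).
#' @param mapping named character vector, names = canonical columns
#'   (`observer_id`, `condition`, `violation`, `choice_correct`, `rt`,
#'   `reproduction`, ...), values = deposit column names. Canonical columns
#'   absent from the mapping are assumed to already carry canonical names.
#' @return behavioral data frame in the package schema.
#' @export
load_osf_deposit <- function(path, mapping = character(0)) {
  first <- readLines(path, n = 2)
  sep <- if (grepl("\t", first[length(first)])) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", stringsAsFactors = FALSE)
  required <- c("observer_id", "condition", "violation",
                "choice_correct", "rt", "reproduction")
  optional <- c("trial_id", "n_initial", "penultimate", "target",
                "missed", "repro_error", "choice", "dp", "cue_valid")
  canonical <- c(required, optional)
  out <- raw
  for (nm in names(mapping)) {
    if (!mapping[[nm]] %in% names(raw)) {
      stop("mapping error: deposit has no column '", mapping[[nm]],
           "' (wanted for '", nm, "'); available: ",
           paste(names(raw), collapse = ", "))
    }
    names(out)[names(out) == mapping[[nm]]] <- nm
  }
  miss <- setdiff(required, names(out))
  if (length(miss)) {
    stop("deposit lacks required fields after mapping: ",
         paste(miss, collapse = ", "))
  }
  if (!"repro_error" %in% names(out) && "target" %in% names(out)) {
    out$repro_error <- axial_wrap(out$reproduction - out$target)
  }
  attr(out, "unmapped") <- setdiff(names(raw),
                                   c(unname(mapping),
                                     intersect(names(raw), canonical)))
  out
}
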