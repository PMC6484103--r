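# Edge-list and trace serialization.
#
# Edge-list format: delimited text with header columns source, target, weight
# (tab-separated by default; comma accepted). Node ids may be integers or
# strings; they are mapped to 1..N and the mapping is kept as node names.

#' Read a weighted directed edge list
#'
#' Reads a connectome-style edge list. Raw interaction strengths are rescaled
#' into `(0, 1]` by division by the maximum weight; self-loops are dropped
#' (with a warning reporting the count, as is conventional for parcellation
#' connectomes that record self-interaction); duplicate edges keep the first
#' occurrence with a warning.
#'
#' @param path Path to a TSV/CSV file with columns `source`, `target`,
#'   `weight`.
#' @param delim Field delimiter; default inferred from the extension
#'   (`","` for `.csv`, tab otherwise).
#' @param rescale Divide weights by their maximum (default `TRUE`).
#' @return A fresh `decay_network`; node labels, when not plain integers,
#'   are kept in `$node_names`.
#' @export
read_edgelist <- function(path, delim = NULL, rescale = TRUE) {
  if (!file.exists(path)) {
    abort(sprintf("Edge-list file not found: %s", path),
          class = "neurodecay_io_error")
  }
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    # weights read as text and converted with strtod (correctly rounded),
    # so full-precision round trips are exact
    readr::read_delim(path, delim = delim, col_types = readr::cols(
      .default = readr::col_character()
    ), progress = FALSE),
    error = function(e) abort(sprintf("Failed to parse %s: %s", path,
                                      conditionMessage(e)),
                              class = "neurodecay_io_error")
  )
  if (!all(c("source", "target", "weight") %in% names(df))) {
    abort(sprintf("%s must have columns source, target, weight.", path),
          class = "neurodecay_io_error")
  }
  raw <- df$weight
  df$weight <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(df$weight) | is.na(df$source) | is.na(df$target))
  if (length(bad) > 0L) {
    abort(sprintf("Malformed row in %s at line %d (weight '%s').",
                  path, bad[1] + 1L, raw[bad[1]]),
          class = "neurodecay_io_error")
  }
  if (any(df$weight <= 0)) {
    abort(sprintf("Non-positive weight in %s (line %d).",
                  path, which(df$weight <= 0)[1] + 1L),
          class = "neurodecay_validation_error")
  }
  loops <- df$source == df$target
  if (any(loops)) {
    warn(sprintf("Dropped %d self-loop(s) from %s.", sum(loops), path))
    df <- df[!loops, ]
  }
  dup <- duplicated(paste(df$source, df$target, sep = "\r"))
  if (any(dup)) {
    warn(sprintf("Dropped %d duplicate edge(s) from %s (kept first occurrence).",
                 sum(dup), path))
    df <- df[!dup, ]
  }
  if (nrow(df) == 0L) {
    abort(sprintf("No edges left in %s.", path), class = "neurodecay_io_error")
  }
  ids <- unique(c(df$source, df$target))
  numeric_ids <- !anyNA(suppressWarnings(as.integer(ids))) &&
    all(as.integer(ids) == as.numeric(ids))
  if (numeric_ids) ids <- as.character(sort(unique(as.integer(ids))))
  from <- match(df$source, ids)
  to <- match(df$target, ids)
  w <- df$weight
  if (rescale) w <- w / max(w)
  decay_network(length(ids), from, to, eps0 = w,
                node_names = if (numeric_ids) NULL else ids)
}

#' Write a network as an edge list
#'
#' Writes the initial strengths as a tab-separated edge list with header
#' `source<TAB>target<TAB>weight`, rows sorted by source then target, weights
#' at full double precision, so write-read-write is byte-identical.
#'
#' @param network A `decay_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(network, path) {
  stopifnot(inherits(network, "decay_network"))
  e <- network$edges[order(network$edges$from, network$edges$to), ]
  labels <- network$node_names %||% as.character(seq_len(network$n_nodes))
  lines <- c("source\ttarget\tweight",
             sprintf("%s\t%s\t%.17g", labels[e$from], labels[e$to], e$eps0))
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(err) {
    abort(sprintf("Failed to write %s: %s", path, conditionMessage(err)),
          class = "neurodecay_io_error")
  })
  invisible(path)
}

#' Write or read a simulation trace
#'
#' Traces are plain CSV with the columns recorded by [run_decay()].
#'
#' @param trace A `decay_trace` (or ensemble mean).
#' @param path File path.
#' @return `write_trace()`: `path`, invisibly. `read_trace()`: a tibble.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(as_tibble(trace), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
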