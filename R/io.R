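#' Read and write the pipeline's CSV dialects
#'
#' Track tables: `track_id,group,t_min,x_um,y_um`.  Phenotype tables:
#' `embryo_id,genotype,side,p1..p5,cb1..cb5,fusions`.  Timelines:
#' `pouch_index,formation_time_hpf`.  Readers are tolerant of extra
#' columns (kept verbatim); rows or tracks that fail validation are
#' dropped and collected, with their file line numbers, into the
#' `errors` attribute of the result — unless `strict = TRUE`, in which
#' case the first problem aborts the read.
#'
#' @param x Table to write.
#' @param path File path.
#' @param strict Abort on the first malformed record instead of
#'   collecting errors.
#' @return Readers return the validated data frame with an `errors`
#'   attribute (a data frame `line`, `id`, `message`, possibly empty).
#' @name pouchtrack-io
NULL

#' @rdname pouchtrack-io
#' @export
write_tracks <- function(x, path) {
  need <- c("track_id", "group", "t_min", "x_um", "y_um")
  if (!all(need %in% names(x))) input_error("track table is missing required columns")
  utils::write.csv(x[, c(need, setdiff(names(x), need)), drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pouchtrack-io
#' @export
read_tracks <- function(path, strict = FALSE) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "group", "t_min", "x_um", "y_um")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    input_error(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  df$.line <- seq_len(nrow(df)) + 1L  # header is line 1
  errors <- list()
  keep_ids <- character(0)
  for (id in unique(df$track_id)) {
    tr <- df[df$track_id == id, ]
    msg <- NULL
    if (nrow(tr) < 2L) {
      msg <- "track has fewer than 2 points"
    } else if (any(!is.finite(tr$t_min)) || any(!is.finite(tr$x_um)) ||
               any(!is.finite(tr$y_um))) {
      msg <- "non-finite coordinate or time"
    } else if (any(diff(tr$t_min) <= 0)) {
      msg <- "non-monotone timestamps"
    }
    if (is.null(msg)) {
      keep_ids <- c(keep_ids, id)
    } else {
      bad_line <- if (grepl("monotone", msg)) {
        tr$.line[which(diff(tr$t_min) <= 0)[1] + 1L]
      } else {
        tr$.line[1]
      }
      err <- sprintf("track '%s' (line %d): %s", id, bad_line, msg)
      if (strict) input_error(err)
      errors[[length(errors) + 1L]] <- data.frame(
        line = bad_line, id = id, message = msg, stringsAsFactors = FALSE)
    }
  }
  out <- df[df$track_id %in% keep_ids, , drop = FALSE]
  out$.line <- NULL
  rownames(out) <- NULL
  structure(out, errors = bind_error_rows(errors))
}

#' @rdname pouchtrack-io
#' @export
write_phenotypes <- function(x, path) {
  need <- c("embryo_id", "genotype", "side", paste0("p", 1:5),
            paste0("cb", 1:5), "fusions")
  if (!all(need %in% names(x))) input_error("phenotype table is missing required columns")
  utils::write.csv(x[, c(need, setdiff(names(x), need)), drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pouchtrack-io
#' @export
read_phenotypes <- function(path, strict = FALSE) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(fusions = "character"))
  need <- c("embryo_id", "genotype", "side", paste0("p", 1:5),
            paste0("cb", 1:5), "fusions")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    input_error(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  df$fusions[is.na(df$fusions)] <- ""
  errors <- list()
  ok <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    msg <- tryCatch({
      score_record(df[i, , drop = FALSE])  # runs full state validation
      NULL
    }, error = function(e) conditionMessage(e))
    if (is.null(msg) && !df$side[i] %in% c("left", "right")) {
      msg <- sprintf("invalid side '%s'", df$side[i])
    }
    if (is.null(msg)) {
      ok[i] <- TRUE
    } else {
      if (strict) input_error(sprintf("line %d: %s", i + 1L, msg))
      errors[[length(errors) + 1L]] <- data.frame(
        line = i + 1L, id = df$embryo_id[i], message = msg,
        stringsAsFactors = FALSE)
    }
  }
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, errors = bind_error_rows(errors))
}

#' @rdname pouchtrack-io
#' @export
write_timeline <- function(x, path) {
  need <- c("pouch_index", "formation_time_hpf")
  if (!all(need %in% names(x))) input_error("timeline is missing required columns")
  utils::write.csv(x[, need, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname pouchtrack-io
#' @export
read_timeline <- function(path, strict = FALSE) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pouch_index", "formation_time_hpf")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    input_error(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(df$pouch_index)) {
    msg <- "duplicate pouch_index"
    if (strict) input_error(msg)
  }
  df <- df[order(df$formation_time_hpf), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, errors = bind_error_rows(list()))
}

bind_error_rows <- function(errors) {
  if (length(errors)) {
    do.call(rbind, errors)
  } else {
    data.frame(line = integer(0), id = character(0), message = character(0),
               stringsAsFactors = FALSE)
  }
}
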