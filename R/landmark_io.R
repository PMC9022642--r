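#' Read a TPS landmark digitization file
#'
#' Parses the classic tpsDig/tpsUtil text format: an `LM=<count>` line, then
#' `<count>` whitespace-separated `x y` coordinate lines, optionally followed
#' by `IMAGE=`, `ID=` and `SCALE=` lines per record. Keys are case-insensitive,
#' unknown keys are skipped with a warning, and Windows/Unix line endings and
#' trailing blank lines are tolerated.
#'
#' @param path Path to a TPS text file.
#' @return A list of records; each record is a list with `landmark_count`,
#'   `coords` (`k x 2` matrix, file units), `image`, `id` and `scale`
#'   (`NA` when absent). Record order follows the file.
#' @examples
#' f <- tempfile(fileext = ".tps")
#' writeLines(c("LM=3", "0 0", "1 0", "0 1", "ID=a", "SCALE=0.5"), f)
#' read_tps(f)
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stopf("TPS file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  records <- list()
  rec <- NULL
  pending <- 0L
  lineno <- 0L
  flush_rec <- function(rec) {
    if (is.null(rec)) return(NULL)
    if (nrow(rec$coords) != rec$landmark_count) {
      stopf("TPS record %s: LM=%d but %d coordinate line(s) found",
            if (nzchar(rec$id)) shQuote(rec$id) else length(records) + 1,
            rec$landmark_count, nrow(rec$coords))
    }
    rec
  }
  for (line in lines) {
    lineno <- lineno + 1L
    if (!nzchar(trimws(line))) next
    m <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(m) == 3L) {
      key <- toupper(m[2])
      val <- trimws(m[3])
      if (key == "LM") {
        if (pending > 0L) {
          stopf("line %d: new LM record while %d coordinate line(s) missing",
                lineno, pending)
        }
        records <- c(records, list(flush_rec(rec)))
        cnt <- suppressWarnings(as.integer(val))
        if (is.na(cnt) || cnt < 0) stopf("line %d: bad LM count '%s'", lineno, val)
        rec <- list(landmark_count = cnt,
                    coords = matrix(numeric(0), 0, 2),
                    image = "", id = "", scale = NA_real_)
        pending <- cnt
      } else if (is.null(rec)) {
        stopf("line %d: '%s' before any LM record", lineno, key)
      } else if (key == "IMAGE") {
        rec$image <- val
      } else if (key == "ID") {
        rec$id <- val
      } else if (key == "SCALE") {
        sc <- suppressWarnings(as.numeric(val))
        if (is.na(sc) || sc <= 0) stopf("line %d: bad SCALE '%s'", lineno, val)
        rec$scale <- sc
      } else {
        warnf("line %d: ignoring unknown TPS key '%s'", lineno, key)
      }
    } else {
      if (is.null(rec) || pending == 0L) {
        stopf("line %d: unexpected coordinate line outside an LM record", lineno)
      }
      xy <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
      if (length(xy) != 2L || anyNA(xy)) {
        stopf("line %d: non-numeric or malformed coordinate line", lineno)
      }
      rec$coords <- rbind(rec$coords, xy)
      pending <- pending - 1L
    }
  }
  if (pending > 0L) {
    stopf("end of file: %d coordinate line(s) missing in last record", pending)
  }
  records <- c(records, list(flush_rec(rec)))
  records <- Filter(Negate(is.null), records)
  lapply(records, function(r) {
    dimnames(r$coords) <- list(NULL, c("x", "y"))
    r
  })
}

#' Write TPS records
#'
#' Inverse of [read_tps()]: writes one `LM=` block per record with 6-decimal
#' fixed coordinate formatting, plus `IMAGE=`/`ID=`/`SCALE=` lines when set.
#'
#' @param records List of records as returned by [read_tps()], or a
#'   [landmark_dataset()] (ids become `ID=` lines, scale becomes `SCALE=`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(records, path) {
  if (inherits(records, "landmark_dataset")) {
    ds <- records
    records <- lapply(seq_along(ds$ids), function(i) {
      list(landmark_count = n_landmarks(ds),
           coords = ds$coords[i, , ] / ds$scale[i],
           image = "", id = ds$ids[i], scale = ds$scale[i])
    })
  }
  out <- unlist(lapply(records, function(r) {
    c(sprintf("LM=%d", r$landmark_count),
      apply(r$coords, 1, function(p) paste(fmt6(p[1]), fmt6(p[2]))),
      if (nzchar(r$image %||% "")) sprintf("IMAGE=%s", r$image),
      if (nzchar(r$id %||% "")) sprintf("ID=%s", r$id),
      if (!is.na(r$scale %||% NA)) sprintf("SCALE=%s", fmt6(r$scale)))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Assemble TPS records into a landmark dataset
#'
#' Applies the per-record `SCALE=` calibration (absent scale = 1, i.e. the
#' file is already in mm) and attaches group labels via `group_map`.
#'
#' @param records List of TPS records from [read_tps()].
#' @param group_map Named character vector mapping record id to group label.
#' @param require_k Expected landmark count (default 9, this study's schema;
#'   set to `NULL` to accept any common count).
#' @return A [landmark_dataset()].
#' @export
to_dataset <- function(records, group_map, require_k = 9L) {
  ids <- vapply(records, function(r) r$id, "")
  if (any(!nzchar(ids))) stopf("every TPS record needs an ID= line")
  if (anyDuplicated(ids)) {
    stopf("duplicate record id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  ks <- vapply(records, function(r) r$landmark_count, 0L)
  if (!is.null(require_k) && any(ks != require_k)) {
    stopf("record(s) %s have landmark count != %d",
          paste(ids[ks != require_k], collapse = ", "), require_k)
  }
  if (length(unique(ks)) != 1L) stopf("records have differing landmark counts")
  missing <- setdiff(ids, names(group_map))
  if (length(missing)) {
    stopf("id(s) missing from group_map: %s", paste(missing, collapse = ", "))
  }
  coords <- lapply(records, function(r) {
    s <- if (is.na(r$scale)) 1 else r$scale
    r$coords * s
  })
  scale <- vapply(records, function(r) if (is.na(r$scale)) 1 else r$scale, 0)
  landmark_dataset(coords, ids, unname(group_map[ids]), scale,
                   require_k = require_k)
}

#' Read / write a delimited landmark table
#'
#' Comma- or tab-separated table with a header and columns
#' `id, group, x1, y1, ..., xk, yk[, scale]`; coordinates are multiplied by
#' `scale` (column or argument) to give mm.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab.
#' @param scale Calibration override applied when the table has no `scale`
#'   column.
#' @return [read_landmark_table()]: a [landmark_dataset()].
#' @export
read_landmark_table <- function(path, sep = NULL, scale = 1) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "group")
  if (!all(need %in% names(df))) stopf("table must have 'id' and 'group' columns")
  xs <- grep("^x[0-9]+$", names(df), value = TRUE)
  k <- length(xs)
  if (k == 0) stopf("no coordinate columns x1..xk found")
  cols <- as.vector(rbind(paste0("x", 1:k), paste0("y", 1:k)))
  if (!all(cols %in% names(df))) stopf("coordinate columns must be x1,y1,...,x%d,y%d", k, k)
  sc <- if ("scale" %in% names(df)) df$scale else rep(scale, nrow(df))
  coords <- array(NA_real_, c(nrow(df), k, 2))
  coords[, , 1] <- as.matrix(df[paste0("x", 1:k)]) * sc
  coords[, , 2] <- as.matrix(df[paste0("y", 1:k)]) * sc
  landmark_dataset(coords, df$id, df$group, sc)
}

#' @rdname read_landmark_table
#' @param x A [landmark_dataset()].
#' @return [write_landmark_table()]: `path`, invisibly.
#' @export
write_landmark_table <- function(x, path, sep = ",") {
  df <- as.data.frame(x)
  # store file-unit coordinates so the scale column round-trips
  cc <- grep("^[xy][0-9]+$", names(df))
  df[cc] <- df[cc] / x$scale
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt6)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
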