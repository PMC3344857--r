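#' A single SC backbone trace
#'
#' An ordered 3D polyline in physical units (um), as produced by filament
#' tracing of a 3D microscopy stack, by the synthetic generator, or by unit
#' conversion of a simulated conformation.
#'
#' @param points numeric matrix, one row per backbone point, columns X,Y,Z.
#' @param sc_id label of the SC within its nucleus.
#' @param nucleus_id label of the nucleus.
#' @return an object of class `sc_trace`.
#' @export
sc_trace <- function(points, sc_id = "SC", nucleus_id = "") {
  points <- as.matrix(points)
  dimnames(points) <- list(NULL, c("X", "Y", "Z"))
  storage.mode(points) <- "double"
  if (nrow(points) < 2L) stop("a trace needs at least 2 points")
  if (!all(is.finite(points))) stop("trace coordinates must be finite")
  if (any(rowSums(diff(points)^2) == 0))
    stop("consecutive trace points must be distinct")
  structure(list(points = points, sc_id = as.character(sc_id),
                 nucleus_id = as.character(nucleus_id)),
            class = "sc_trace")
}

#' @export
print.sc_trace <- function(x, ...) {
  cat(sprintf("<sc_trace %s/%s: %d points, contour %.3g um>\n",
              x$nucleus_id, x$sc_id, nrow(x$points), arclength(x)))
  invisible(x)
}

#' Total arclength of a trace
#'
#' @param trace an `sc_trace` or a point matrix.
#' @return contour length in the trace's units.
#' @export
arclength <- function(trace) {
  p <- trace_points(trace)
  sum(sqrt(rowSums(diff(p)^2)))
}

# accept either an sc_trace or a bare point matrix everywhere downstream
trace_points <- function(trace) {
  if (inherits(trace, "sc_trace")) trace$points else as.matrix(trace)
}

#' A set of SC traces belonging to one nucleus
#'
#' @param traces list of [sc_trace()] objects with unique `sc_id`s.
#' @param nucleus_id label.
#' @param source one of `"experimental"`, `"synthetic"`, `"simulation"`.
#' @param geometry optional list describing the bounding cavity (e.g.
#'   `list(shape = "sphere", diameter_um = 10)`).
#' @return an object of class `nucleus_dataset`.
#' @export
nucleus_dataset <- function(traces, nucleus_id = "nucleus",
                            source = c("experimental", "synthetic",
                                       "simulation"),
                            geometry = NULL) {
  source <- match.arg(source)
  if (length(traces) < 1L) stop("a nucleus dataset needs at least one trace")
  stopifnot(all(vapply(traces, inherits, TRUE, "sc_trace")))
  ids <- vapply(traces, `[[`, "", "sc_id")
  if (anyDuplicated(ids)) stop("sc_ids within a nucleus must be unique")
  structure(list(nucleus_id = as.character(nucleus_id), traces = traces,
                 source = source, geometry = geometry),
            class = "nucleus_dataset")
}

#' @export
print.nucleus_dataset <- function(x, ...) {
  cat(sprintf("<nucleus_dataset %s (%s): %d traces>\n",
              x$nucleus_id, x$source, length(x$traces)))
  invisible(x)
}

read_one_sheet <- function(df, label) {
  names(df) <- toupper(trimws(names(df)))
  for (col in c("X", "Y", "Z"))
    if (!col %in% names(df))
      stop("sheet '", label, "' lacks coordinate column ", col)
  xyz <- df[, c("X", "Y", "Z")]
  for (col in c("X", "Y", "Z")) {
    v <- suppressWarnings(as.numeric(xyz[[col]]))
    bad <- which(is.na(v) & !is.na(xyz[[col]]))
    if (is.character(xyz[[col]]) && length(bad) > 0L)
      stop("sheet '", label, "': non-numeric value in column ", col,
           " at row ", bad[1L])
    if (anyNA(v))
      stop("sheet '", label, "': missing value in column ", col,
           " at row ", which(is.na(v))[1L])
    xyz[[col]] <- v
  }
  as.matrix(xyz)
}

#' Read per-nucleus stacks of reconstructed SC coordinates
#'
#' Reads the supplementary layout of reconstructed SC backbones: one stack
#' per nucleus, one sheet (or delimited file) of X/Y/Z coordinates per SC,
#' point order preserved.  Two dialects are accepted: a directory per
#' nucleus containing one CSV per SC, or an xlsx workbook per nucleus with
#' one sheet per SC (requires the readxl package).  Coordinate columns are
#' identified by header names X/Y/Z, case-insensitively.
#'
#' @param path directory containing the per-nucleus stacks.
#' @param units `"auto"` (um if the maximum extent is below 100, else nm,
#'   converted to um), `"um"` or `"nm"`.
#' @return list of [nucleus_dataset()] objects (source `"experimental"`).
#' @export
read_sc_stacks <- function(path, units = c("auto", "um", "nm")) {
  units <- match.arg(units)
  if (!dir.exists(path)) stop("no such directory: ", path)
  subdirs <- list.dirs(path, recursive = FALSE)
  xlsx <- list.files(path, pattern = "\\.xlsx$", full.names = TRUE)
  stacks <- c(as.list(subdirs), as.list(xlsx))
  datasets <- list()
  for (stack in stacks) {
    nucleus_id <- sub("\\.xlsx$", "", basename(stack))
    sheets <- list()
    if (dir.exists(stack)) {
      files <- list.files(stack, pattern = "\\.(csv|tsv|txt)$",
                          full.names = TRUE)
      for (f in sort(files)) {
        sep <- if (grepl("\\.csv$", f)) "," else "\t"
        df <- utils::read.delim(f, sep = sep, check.names = FALSE)
        sheets[[sub("\\.(csv|tsv|txt)$", "", basename(f))]] <-
          read_one_sheet(df, paste0(nucleus_id, "/", basename(f)))
      }
    } else {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading xlsx stacks requires the readxl package")
      for (sh in readxl::excel_sheets(stack))
        sheets[[sh]] <- read_one_sheet(
          as.data.frame(readxl::read_excel(stack, sheet = sh)),
          paste0(nucleus_id, "/", sh))
    }
    if (length(sheets) == 0L) {
      warning("stack ", nucleus_id, " is empty; skipped")
      next
    }
    scale <- switch(units,
                    um = 1,
                    nm = 1e-3,
                    auto = {
                      ext <- max(abs(unlist(sheets)))
                      if (ext >= 100) 1e-3 else 1
                    })
    traces <- lapply(names(sheets), function(id)
      sc_trace(sheets[[id]] * scale, sc_id = id, nucleus_id = nucleus_id))
    datasets[[nucleus_id]] <- nucleus_dataset(traces, nucleus_id,
                                              source = "experimental")
  }
  datasets
}

#' Write nucleus datasets in the per-nucleus stack layout
#'
#' Emits one directory per nucleus, one CSV per SC with an X,Y,Z header —
#' the same layout [read_sc_stacks()] reads, so roundtrips are lossless to
#' printed precision.
#'
#' @param datasets a [nucleus_dataset()] or list of them.
#' @param path output directory (created if needed).
#' @export
write_traces <- function(datasets, path) {
  if (inherits(datasets, "nucleus_dataset")) datasets <- list(datasets)
  if (length(datasets) == 0L) stop("no datasets to write")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (ds in datasets) {
    ddir <- file.path(path, ds$nucleus_id)
    dir.create(ddir, showWarnings = FALSE)
    for (tr in ds$traces) {
      df <- as.data.frame(tr$points)
      utils::write.csv(format(df, digits = 12, trim = TRUE),
                       file.path(ddir, paste0(tr$sc_id, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  invisible(NULL)
}

#' Resample a trace to uniform arclength spacing
#'
#' Places `n_points` points at equal arclength spacing along the
#' piecewise-linear input, preserving both endpoints exactly.  Used to put
#' simulated and experimental traces at matched discretization before
#' crossing-number and density comparisons.
#'
#' @param trace an `sc_trace` or point matrix.
#' @param n_points number of output points (>= 2).
#' @return same type as the input.
#' @export
resample_uniform <- function(trace, n_points) {
  stopifnot(n_points >= 2L)
  p <- trace_points(trace)
  s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  total <- s[length(s)]
  if (total <= 0) stop("cannot resample a zero-length trace")
  target <- seq(0, total, length.out = n_points)
  out <- vapply(1:3, function(a) approx(s, p[, a], xout = target,
                                        ties = "ordered")$y,
                numeric(n_points))
  out[1L, ] <- p[1L, ]
  out[n_points, ] <- p[nrow(p), ]
  if (inherits(trace, "sc_trace")) {
    trace$points <- `dimnames<-`(out, list(NULL, c("X", "Y", "Z")))
    trace
  } else out
}

#' Per-trace summary statistics of a nucleus dataset
#'
#' @param dataset a [nucleus_dataset()].
#' @return data.frame with one row per trace: `sc_id`, `n_points`,
#'   `contour` (sum of segment lengths), `end_to_end` distance and its
#'   square, in the dataset's units.
#' @export
trace_summary <- function(dataset) {
  stopifnot(inherits(dataset, "nucleus_dataset"))
  rows <- lapply(dataset$traces, function(tr) {
    r2 <- squared_end_to_end(tr)
    data.frame(nucleus_id = tr$nucleus_id, sc_id = tr$sc_id,
               n_points = nrow(tr$points), contour = arclength(tr),
               end_to_end = sqrt(r2), sq_end_to_end = r2)
  })
  do.call(rbind, rows)
}
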