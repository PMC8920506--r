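# Readers and writers for the delimited interchange formats. Every writer
# has a reader that round-trips losslessly (within numeric text precision).

.sidecarPath <- function(path) paste0(path, ".json")

#' Write / read a TraceSet as delimited text plus a JSON sidecar
#'
#' The table is long format (cell_id, frame, F); acquisition metadata,
#' hierarchy keys, condition and any ground-truth rowData columns go to a
#' JSON sidecar at \code{<path>.json}.
#'
#' @param ts a \linkS4class{TraceSet}
#' @param path output CSV path
#' @return \code{writeTraceSet}: the path, invisibly. \code{readTraceSet}:
#'   the reconstructed \linkS4class{TraceSet}
#' @export
writeTraceSet <- function(ts, path) {
  f <- traces(ts)
  long <- data.frame(cell_id = rep(rownames(f), each = ncol(f)),
                     frame = rep(seq_len(ncol(f)), times = nrow(f)),
                     F = as.numeric(t(f)))
  write.csv(long, path, row.names = FALSE)
  rd <- as.data.frame(SummarizedExperiment::rowData(ts))
  side <- list(frame_period_s = framePeriod(ts),
               stim_frame = stimFrame(ts),
               condition = condition(ts),
               row_data = rd)
  jsonlite::write_json(side, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeTraceSet
#' @export
readTraceSet <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  rd <- as.data.frame(side$row_data)
  cells <- unique(long$cell_id)
  nf <- max(long$frame)
  f <- matrix(NA_real_, length(cells), nf,
              dimnames = list(cells, NULL))
  f[cbind(match(long$cell_id, cells), long$frame)] <- long$F
  rd <- rd[match(cells, rd$cell), , drop = FALSE]
  hier <- rd[, c("mouse", "slice", "field", "cell")]
  extra <- rd[, setdiff(colnames(rd), colnames(hier)), drop = FALSE]
  traceSet(f, side$frame_period_s, side$stim_frame, hierarchy = hier,
           condition = as.list(side$condition),
           truth = if (ncol(extra)) extra else NULL)
}

#' Write / read a population table as tab-delimited text
#'
#' @param pop population data.frame from
#'   \code{\link{genPopulationDataset}}
#' @param path output TSV path
#' @return \code{writePopulation}: the path, invisibly;
#'   \code{readPopulation}: the data.frame
#' @export
writePopulation <- function(pop, path) {
  utils::write.table(pop, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writePopulation
#' @export
readPopulation <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a SweepSet as delimited text plus a JSON sidecar
#'
#' Wide CSV (time_s then one column per sweep); mode, unit, command table
#' and protocol go to \code{<path>.json}. Generator ground truth is not
#' serialised (it is a test-time oracle, not part of the interchange
#' format).
#'
#' @param ss a \linkS4class{SweepSet}
#' @param path output CSV path
#' @return \code{writeSweepSet}: the path, invisibly;
#'   \code{readSweepSet}: the \linkS4class{SweepSet}
#' @export
writeSweepSet <- function(ss, path) {
  d <- sweepData(ss)
  colnames(d) <- sprintf("sweep_%03d", seq_len(ncol(d)))
  write.csv(cbind(data.frame(time_s = sweepTimes(ss)), d), path,
            row.names = FALSE)
  side <- list(mode = ss@mode, unit = ss@unit,
               command = sweepCommand(ss), protocol = sweepProtocol(ss))
  jsonlite::write_json(side, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeSweepSet
#' @export
readSweepSet <- function(path) {
  tab <- read.csv(path)
  side <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  cmd <- as.data.frame(side$command)
  sweepSet(as.matrix(tab[, -1, drop = FALSE]), tab$time_s,
           side$mode, side$unit, command = cmd,
           protocol = as.list(side$protocol))
}

#' Write / read a flat key = value report file
#'
#' One \code{key = value} pair per line, keys in dotted namespaces, values
#' formatted with full precision; diff-able and schema-checkable.
#'
#' @param x named list of scalars
#' @param path output path
#' @return \code{writeKeyValue}: the path invisibly;
#'   \code{readKeyValue}: a named list (numbers parsed as numeric)
#' @export
writeKeyValue <- function(x, path) {
  stopifnot(!is.null(names(x)), all(nzchar(names(x))))
  vals <- vapply(x, function(v) {
    if (is.numeric(v)) format(v, digits = 17, scientific = FALSE)
    else as.character(v)
  }, "")
  writeLines(paste(names(x), vals, sep = " = "), path)
  invisible(path)
}

#' @rdname writeKeyValue
#' @export
readKeyValue <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^=]+?)\\s*=\\s*(.*)$", lines))
  out <- list()
  for (m in kv) {
    if (length(m) != 3) stop("malformed key/value line")
    val <- m[3]
    num <- suppressWarnings(as.numeric(val))
    out[[trimws(m[2])]] <- if (!is.na(num)) num else val
  }
  out
}

#' Read / write a movie stack as multi-page TIFF (requires the tiff
#' package)
#'
#' @param movie numeric array height x width x frames, values in [0, 1]
#' @param path TIFF path
#' @return \code{writeMovieTiff}: the path invisibly;
#'   \code{readMovieTiff}: the array
#' @export
writeMovieTiff <- function(movie, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required for movie I/O")
  pages <- lapply(seq_len(dim(movie)[3]), function(i) movie[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname writeMovieTiff
#' @export
readMovieTiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required for movie I/O")
  pages <- tiff::readTIFF(path, all = TRUE)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}
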