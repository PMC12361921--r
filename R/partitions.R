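#' Construct a partition scheme
#'
#' A partition scheme assigns named column ranges of a concatenated
#' alignment to regions, each labelled with a class (\code{"plastid"} or
#' \code{"nuclear"}).  Spans are 1-based inclusive, the convention used in
#' partition files and throughout the package.  Ranges may not overlap
#' across regions.
#'
#' @param regions a data frame with columns \code{name}, \code{klass},
#'   \code{start}, \code{end} (1-based inclusive).  A region may span
#'   several rows (multiple ranges).
#' @return an object of class \code{"dup_partitions"}.
#' @export
partition_scheme <- function(regions) {
  stopifnot(is.data.frame(regions),
            all(c("name", "klass", "start", "end") %in% names(regions)))
  regions$name  <- as.character(regions$name)
  regions$klass <- as.character(regions$klass)
  regions$start <- as.integer(regions$start)
  regions$end   <- as.integer(regions$end)
  if (any(!regions$klass %in% c("plastid", "nuclear")))
    stop("region class must be 'plastid' or 'nuclear'")
  if (any(regions$start < 1L) || any(regions$end < regions$start))
    stop("invalid span: start must be >= 1 and end >= start")
  occupied <- integer(0)
  for (i in seq_len(nrow(regions))) {
    span <- regions$start[i]:regions$end[i]
    clash <- intersect(span, occupied)
    if (length(clash))
      stop(sprintf("overlapping partition spans at column %d (region '%s')",
                   clash[1L], regions$name[i]))
    occupied <- c(occupied, span)
  }
  structure(list(table = regions), class = "dup_partitions")
}

#' @export
print.dup_partitions <- function(x, ...) {
  cat(sprintf("Partition scheme: %d region(s)\n", length(region_names(x))))
  print(x$table)
  invisible(x)
}

#' Region names of a partition scheme
#' @param scheme a \code{dup_partitions}.
#' @export
region_names <- function(scheme) unique(scheme$table$name)

#' Class of each region
#' @param scheme a \code{dup_partitions}.
#' @return named character vector, region name -> class.
#' @export
region_classes <- function(scheme) {
  tab <- scheme$table[!duplicated(scheme$table$name), ]
  structure(tab$klass, names = tab$name)
}

#' Columns belonging to one region
#' @param scheme a \code{dup_partitions}.
#' @param name region name.
#' @return integer vector of 1-based column indices, in alignment order.
#' @export
region_columns <- function(scheme, name) {
  tab <- scheme$table[scheme$table$name == name, , drop = FALSE]
  if (!nrow(tab)) stop("unknown region: ", name)
  sort(unlist(mapply(seq.int, tab$start, tab$end, SIMPLIFY = FALSE)))
}

#' Columns belonging to one partition class
#' @param scheme a \code{dup_partitions}.
#' @param klass \code{"plastid"} or \code{"nuclear"}.
#' @return integer vector of 1-based column indices, in alignment order.
#' @export
class_columns <- function(scheme, klass) {
  tab <- scheme$table[scheme$table$klass == klass, , drop = FALSE]
  if (!nrow(tab)) stop("no region with class: ", klass)
  sort(unlist(mapply(seq.int, tab$start, tab$end, SIMPLIFY = FALSE)))
}

#' Regions of one class, preserving declaration order
#' @param scheme a \code{dup_partitions}.
#' @param klass class label, or \code{NULL} for all regions.
#' @export
class_regions <- function(scheme, klass = NULL) {
  rc <- region_classes(scheme)
  if (is.null(klass)) names(rc) else names(rc)[rc == klass]
}

#' Read a partition configuration file
#'
#' Plain-text format, one range per line:
#' \preformatted{  name, class, start-end}
#' e.g. \code{ITS, nuclear, 4113-4910}.  Spans are 1-based inclusive.
#' Lines starting with \code{#} and blank lines are ignored.
#'
#' @param path path to the partition file.
#' @param n_columns optional alignment width; spans are checked against it.
#' @return a \code{dup_partitions}.
#' @export
read_partitions <- function(path, n_columns = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(seq_along(lines), function(i) {
    parts <- trimws(strsplit(lines[i], ",")[[1L]])
    if (length(parts) != 3L)
      stop(sprintf("malformed partition line %d: '%s'", i, lines[i]))
    span <- trimws(strsplit(parts[3L], "-")[[1L]])
    if (length(span) != 2L || anyNA(suppressWarnings(as.integer(span))))
      stop(sprintf("malformed span on line %d: '%s'", i, parts[3L]))
    data.frame(name = parts[1L], klass = parts[2L],
               start = as.integer(span[1L]), end = as.integer(span[2L]))
  })
  scheme <- partition_scheme(do.call(rbind, rows))
  if (!is.null(n_columns) && max(scheme$table$end) > n_columns)
    stop(sprintf("partition span ends at column %d but alignment has %d columns",
                 max(scheme$table$end), n_columns))
  scheme
}

#' Write a partition configuration file
#' @param scheme a \code{dup_partitions}.
#' @param path output path.
#' @export
write_partitions <- function(scheme, path) {
  tab <- scheme$table
  writeLines(sprintf("%s, %s, %d-%d", tab$name, tab$klass, tab$start, tab$end),
             path)
  invisible(path)
}
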