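#' Read and write the pipeline's CSV formats
#'
#' Thin readers for the four raw data streams, with ISO-8601 UTC timestamp
#' parsing (fractional seconds supported for high-rate TDR records):
#' \describe{
#'   \item{GPS}{`bird_id,timestamp,lon,lat`}
#'   \item{TDR}{`bird_id,timestamp,depth_m[,wet]`}
#'   \item{camera}{`bird_id,timestamp,social[,n_conspecifics]`}
#'   \item{flocks}{`direction,size`}
#' }
#'
#' @param path CSV file path.
#' @return A data frame with typed columns.
#' @name cpf_io
NULL

parse_utc <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(out)) stop("unparseable timestamps (expect ISO-8601 UTC)")
  out
}

#' @rdname cpf_io
#' @export
read_gps_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("bird_id", "timestamp", "lon", "lat") %in% names(d)))
  d$timestamp <- parse_utc(d$timestamp)
  d
}

#' @rdname cpf_io
#' @export
read_tdr_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("bird_id", "timestamp", "depth_m") %in% names(d)))
  d$timestamp <- parse_utc(d$timestamp)
  if ("wet" %in% names(d)) d$wet <- as.logical(d$wet)
  d
}

#' @rdname cpf_io
#' @export
read_camera_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("bird_id", "timestamp", "social") %in% names(d)))
  d$timestamp <- parse_utc(d$timestamp)
  d$social <- as.logical(d$social)
  d
}

#' @rdname cpf_io
#' @export
read_flock_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("direction", "size") %in% names(d)))
  d$direction <- factor(d$direction, levels = c("outbound", "inbound"))
  d$size <- as.integer(d$size)
  d
}

#' @rdname cpf_io
#' @param x Data frame to write; `POSIXct` columns are serialised as
#'   ISO-8601 UTC with millisecond precision.
#' @export
write_cpf_csv <- function(x, path) {
  for (cl in names(x)) {
    if (inherits(x[[cl]], "POSIXct"))
      x[[cl]] <- format(x[[cl]], "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
  }
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
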