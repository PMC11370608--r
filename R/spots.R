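#' Construct a spot set
#'
#' A spot set ties an ordered vector of unique spot identifiers to their
#' coordinates in D-dimensional Euclidean space (D >= 1, typically 2, in
#' arbitrary length units). Spot order is preserved and defines the spot
#' order of every downstream matrix.
#'
#' @param spot_ids character vector of unique identifiers.
#' @param coords numeric matrix (or data.frame) with one row per spot.
#' @return An object of class `spot_set` with elements `spot_ids` and
#'   `coords` (matrix with `spot_ids` as rownames).
#' @export
spot_set <- function(spot_ids, coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  spot_ids <- as.character(spot_ids)
  if (nrow(coords) != length(spot_ids))
    stop("number of coordinates does not match number of spot ids")
  if (nrow(coords) < 2L)
    stop("a spot set needs at least 2 spots")
  if (anyDuplicated(spot_ids))
    stop("spot ids must be unique")
  if (!all(is.finite(coords)))
    stop("spot coordinates must be finite")
  rownames(coords) <- spot_ids
  structure(list(spot_ids = spot_ids, coords = coords), class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat("spot_set:", length(x$spot_ids), "spots in",
      ncol(x$coords), "dimensions\n")
  invisible(x)
}

n_spots <- function(spots) length(spots$spot_ids)

as_spot_set <- function(x) {
  if (inherits(x, "spot_set")) return(x)
  if (is.matrix(x) || is.data.frame(x)) {
    ids <- rownames(x)
    if (is.null(ids)) ids <- paste0("spot", seq_len(nrow(x)))
    return(spot_set(ids, x))
  }
  stop("cannot interpret object as a spot set")
}

#' Pairwise Euclidean distances between spots
#'
#' @param spots a [spot_set()] (or a coordinate matrix).
#' @return A symmetric N x N matrix of Euclidean distances with zero
#'   diagonal, rows/columns named by spot id.
#' @export
pairwise_distances <- function(spots) {
  spots <- as_spot_set(spots)
  d <- as.matrix(dist(spots$coords))
  dimnames(d) <- list(spots$spot_ids, spots$spot_ids)
  d
}

#' Read spot coordinates from a TSV file
#'
#' Expects a header line `spot_id<TAB>x<TAB>y` (further coordinate columns
#' are allowed). Row order in the file defines the spot order used by all
#' downstream artifacts.
#'
#' @param path path to the coordinates TSV.
#' @return A [spot_set()].
#' @export
read_coordinates <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  if (ncol(tab) < 3L)
    stop("coordinates file needs at least columns: spot_id, x, y")
  coords <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(coords)) stop("non-numeric coordinate column")
  spot_set(tab[[1L]], coords)
}

#' Write spot coordinates to TSV
#'
#' @param spots a [spot_set()].
#' @param path output path.
#' @param header_lines optional `#`-prefixed header lines.
#' @export
write_coordinates <- function(spots, path, header_lines = NULL) {
  spots <- as_spot_set(spots)
  d <- ncol(spots$coords)
  cn <- if (d == 2L) c("x", "y") else paste0("x", seq_len(d))
  tab <- data.frame(spot_id = spots$spot_ids, spots$coords,
                    check.names = FALSE)
  names(tab) <- c("spot_id", cn)
  write_tsv(tab, path, header_lines)
}
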