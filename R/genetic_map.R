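#' Genetic maps
#'
#' A genetic map converts physical coordinates (bp) to genetic-map
#' coordinates (centiMorgans).  Two modes are supported: a uniform
#' recombination rate in cM/Mb, and a piecewise-linear table of
#' (bp, cM) anchor points interpolated with [stats::approx()].
#'
#' @param rate_cm_per_mb Recombination rate, centiMorgans per megabase.
#'   Must be positive.  The human genome average is close to 1 cM/Mb.
#' @return An object of class `genetic_map`.
#' @examples
#' gm <- genetic_map_uniform(1)
#' map_cm(gm, c(1e6, 1220400))
#' @export
genetic_map_uniform <- function(rate_cm_per_mb = 1) {
  stopifnot(is.numeric(rate_cm_per_mb), length(rate_cm_per_mb) == 1L)
  if (!is.finite(rate_cm_per_mb) || rate_cm_per_mb <= 0)
    stop("genetic map rate must be a positive finite number (cM/Mb)")
  structure(list(mode = "uniform", rate = rate_cm_per_mb),
            class = "genetic_map")
}

#' @rdname genetic_map_uniform
#' @param bp,cm Anchor coordinates for a table-mode map: physical position
#'   (bp, strictly increasing) and genetic position (cM, non-decreasing).
#' @export
genetic_map_table <- function(bp, cm) {
  stopifnot(is.numeric(bp), is.numeric(cm), length(bp) == length(cm))
  if (length(bp) < 2L) stop("a table map needs at least two anchor points")
  if (any(diff(bp) <= 0)) stop("table map bp anchors must be strictly increasing")
  if (any(diff(cm) < 0)) stop("table map cM anchors must be non-decreasing")
  structure(list(mode = "table", bp = as.numeric(bp), cm = as.numeric(cm)),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  if (x$mode == "uniform") {
    cat(sprintf("Uniform genetic map: %g cM/Mb\n", x$rate))
  } else {
    cat(sprintf("Table genetic map: %d anchors, %g-%g bp, %g-%g cM\n",
                length(x$bp), min(x$bp), max(x$bp), min(x$cm), max(x$cm)))
  }
  invisible(x)
}

#' Convert physical to genetic coordinates
#'
#' @param map A `genetic_map`.
#' @param pos Physical positions, bp.
#' @return Genetic positions in centiMorgans.  In table mode positions
#'   outside the anchored range are an error (the map does not cover the
#'   region); in uniform mode the conversion is `pos * rate / 1e6`.
#' @export
map_cm <- function(map, pos) {
  stopifnot(inherits(map, "genetic_map"), is.numeric(pos))
  if (map$mode == "uniform") return(pos * map$rate / 1e6)
  if (any(pos < min(map$bp) | pos > max(map$bp), na.rm = TRUE))
    stop("genetic map table does not cover all requested positions")
  stats::approx(map$bp, map$cm, xout = pos, ties = "ordered")$y
}

#' Convert genetic to physical coordinates
#'
#' Inverse of [map_cm()], used by the cohort simulator to place
#' recombination breakpoints drawn in genetic distance.  For table maps
#' with flat (zero-recombination) stretches the leftmost bp attaining the
#' requested cM is returned.
#'
#' @param map A `genetic_map`.
#' @param cm Genetic positions, centiMorgans.
#' @return Physical positions, bp.
#' @export
map_bp <- function(map, cm) {
  stopifnot(inherits(map, "genetic_map"), is.numeric(cm))
  if (map$mode == "uniform") return(cm / map$rate * 1e6)
  if (any(cm < min(map$cm) | cm > max(map$cm), na.rm = TRUE))
    stop("genetic map table does not cover all requested cM values")
  stats::approx(map$cm, map$bp, xout = cm, ties = min)$y
}

#' Read a genetic map from a two-column TSV
#'
#' Expects a header line `bp<TAB>cm` followed by anchor rows.
#'
#' @param path Path to the TSV file.
#' @return A table-mode `genetic_map`.
#' @export
read_genetic_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE)
  names(tab) <- tolower(names(tab))
  if (!all(c("bp", "cm") %in% names(tab)))
    stop("genetic map TSV must have columns 'bp' and 'cm': ", path)
  genetic_map_table(tab$bp, tab$cm)
}
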