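#' Class legend for six-class optic nerve head masks
#'
#' The segmentation classes are 0 background, 1 optic disc, 2 optic cup,
#' 3 blood vessels, 4 peripapillary atrophy (PPA) beta zone, 5 PPA alpha zone.
#' The default display colors follow the standard web color names commonly
#' used for these structures: black background, dark-blue disc,
#' medium-sea-green cup, dark-cyan vessels, yellow-green beta zone and yellow
#' alpha zone.
#'
#' @param class_id integer class identifiers (must be exactly 0..5 by default
#'   invariants, but any distinct non-negative set is accepted).
#' @param class_name character names, same length as `class_id`.
#' @param color integer matrix with one RGB row (0-255) per class.
#' @return An object of class `class_legend`: a data frame with columns
#'   `class_id`, `class_name`, `r`, `g`, `b`.
#' @examples
#' leg <- class_legend()
#' leg$class_name
#' @export
class_legend <- function(class_id = 0:5,
                         class_name = c("background", "optic_disc", "optic_cup",
                                        "vessels", "ppa_beta", "ppa_alpha"),
                         color = rbind(c(0, 0, 0), c(0, 0, 139), c(60, 179, 113),
                                       c(0, 139, 139), c(154, 205, 50),
                                       c(255, 255, 0))) {
  class_id <- as.integer(class_id)
  color <- matrix(as.integer(color), ncol = 3)
  stopifnot(length(class_id) == length(class_name), nrow(color) == length(class_id))
  if (anyDuplicated(class_id)) stop("class ids must be distinct")
  if (anyDuplicated(apply(color, 1, paste, collapse = ",")))
    stop("legend colors must be pairwise distinct")
  if (any(color < 0L | color > 255L)) stop("colors must be in 0-255")
  out <- data.frame(class_id = class_id, class_name = as.character(class_name),
                    r = color[, 1], g = color[, 2], b = color[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("class_legend", "data.frame")
  out
}

#' Render a class-id mask as a color image
#'
#' @param mask 2-D integer matrix of class ids.
#' @param legend a [class_legend()].
#' @return H x W x 3 integer array of colors (0-255).
#' @examples
#' m <- matrix(0L, 4, 4); m[2, 2] <- 2L
#' img <- labels_to_color(m)
#' img[2, 2, ]  # medium sea green
#' @export
labels_to_color <- function(mask, legend = class_legend()) {
  mask <- as_label_matrix(mask)
  unknown <- setdiff(unique(as.vector(mask)), legend$class_id)
  if (length(unknown))
    stop("mask contains class ids absent from the legend: ",
         paste(unknown, collapse = ", "))
  pos <- match(as.vector(mask), legend$class_id)
  out <- array(0L, c(nrow(mask), ncol(mask), 3L))
  out[, , 1] <- legend$r[pos]
  out[, , 2] <- legend$g[pos]
  out[, , 3] <- legend$b[pos]
  out
}

#' Recover a class-id mask from a legend-colored image
#'
#' Each pixel is assigned the legend class whose RGB color is nearest in
#' Euclidean distance; pixels farther than `tolerance` from every legend color
#' raise an error reporting the offending pixel count and the first location.
#'
#' @param image H x W x 3 array of colors (0-255).
#' @param legend a [class_legend()].
#' @param tolerance non-negative maximal Euclidean RGB distance.
#' @return Integer matrix of class ids.
#' @export
color_to_labels <- function(image, legend = class_legend(), tolerance = 0) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be H x W x 3")
  if (tolerance < 0) stop("tolerance must be non-negative")
  d <- dim(image)
  px <- matrix(as.numeric(image), d[1] * d[2], 3L)
  cols <- as.matrix(legend[, c("r", "g", "b")])
  # squared distances to every legend color: N x K
  d2 <- outer(rowSums(px^2), rep(1, nrow(cols))) -
    2 * px %*% t(cols) + outer(rep(1, nrow(px)), rowSums(cols^2))
  best <- max.col(-d2, ties.method = "first")
  mind <- sqrt(pmax(d2[cbind(seq_len(nrow(px)), best)], 0))
  bad <- mind > tolerance + 1e-9
  if (any(bad)) {
    first <- which(bad)[1]
    stop(sprintf("%d pixel(s) farther than tolerance %g from every legend color; first at (row %d, col %d)",
                 sum(bad), tolerance, (first - 1) %% d[1] + 1, (first - 1) %/% d[1] + 1))
  }
  matrix(legend$class_id[best], d[1], d[2])
}

as_label_matrix <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a 2-D matrix")
  if (any(abs(mask - round(mask)) > 0)) stop("mask must be integer-valued")
  storage.mode(mask) <- "integer"
  mask
}
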