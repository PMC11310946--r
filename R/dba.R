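#' Dynamic body acceleration metrics
#'
#' @description
#' ODBA (overall dynamic body acceleration) is the sum of the absolute
#' gravity-free components across the three axes; VeDBA (vectorial dynamic
#' body acceleration) is their Euclidean norm. Both are movement-intensity
#' proxies; VeDBA is invariant under sensor rotation, ODBA is not, which is
#' why VeDBA is the metric fed into the energy equations.
#'
#' The dynamic components are signed, so ODBA is defined with absolute
#' values (the standard definition); without them the "sum" could be
#' negative.
#'
#' For any sample the two are bracketed:
#' `VeDBA <= ODBA <= sqrt(3) * VeDBA`.
#'
#' @param d a data.frame of dynamic samples with columns `dx, dy, dz`
#'   (as produced by [remove_gravity()]), or a numeric vector of `dx` values.
#' @param dy,dz numeric vectors when `d` is given as a vector of `dx`.
#' @return numeric vector of per-sample values, in the unit of the inputs
#'   (mG throughout the pipeline).
#' @examples
#' odba(3, 4, 0)   # 7
#' vedba(3, 4, 0)  # 5
#' @export
odba <- function(d, dy = NULL, dz = NULL) {
  v <- dyn_components(d, dy, dz)
  abs(v$dx) + abs(v$dy) + abs(v$dz)
}

#' @rdname odba
#' @export
vedba <- function(d, dy = NULL, dz = NULL) {
  v <- dyn_components(d, dy, dz)
  sqrt(v$dx^2 + v$dy^2 + v$dz^2)
}

#' @rdname odba
#' @description `mean_vedba()` is the per-window summary used by the
#'   one-minute aggregation: the arithmetic mean of per-sample VeDBA.
#' @export
mean_vedba <- function(d, dy = NULL, dz = NULL) {
  v <- vedba(d, dy, dz)
  if (length(v) == 0) stop("mean_vedba over an empty window", call. = FALSE)
  mean(v)
}

dyn_components <- function(d, dy, dz) {
  if (is.data.frame(d)) {
    if (!all(c("dx", "dy", "dz") %in% names(d))) {
      stop("expected columns dx, dy, dz", call. = FALSE)
    }
    list(dx = d$dx, dy = d$dy, dz = d$dz)
  } else {
    stopifnot(is.numeric(d), is.numeric(dy), is.numeric(dz))
    list(dx = d, dy = dy, dz = dz)
  }
}
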