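#' The ethogram
#'
#' Behavior codes used throughout the package: `E` eating, `L` lying down,
#' `R` ruminating, `S` standing, `W` walking. `RUN` (running) is an optional
#' extension enabled per call where relevant; it is not part of the core
#' ethogram because running is rare in pasture sheep and the energy model
#' treats it as a fixed multiple of walking.
#'
#' @param extended if `TRUE`, include the optional `RUN` code.
#' @return character vector of behavior codes.
#' @export
#' @examples
#' behavior_codes()
#' behavior_codes(extended = TRUE)
behavior_codes <- function(extended = FALSE) {
  core <- c("E", "L", "R", "S", "W")
  if (extended) c(core, "RUN") else core
}

# Tie-break order for predominant-behavior ties: higher-energy behavior wins.
# RUN > W > (S = E = R share one equation; fixed order S, E, R for
# reproducibility) > L.
behavior_energy_rank <- function() {
  c(RUN = 6, W = 5, S = 4, E = 3, R = 2, L = 1)
}

assert_behaviors <- function(b, extended = TRUE) {
  ok <- b %in% behavior_codes(extended = extended)
  if (!all(ok)) {
    stop("unknown behavior code(s): ",
         paste(unique(b[!ok]), collapse = ", "), call. = FALSE)
  }
  invisible(b)
}
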