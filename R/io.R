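## State serialization (JSON) shared by the library API and the
## command-line driver.

#' Write a network state to JSON
#'
#' Numbers are serialized with 17 significant digits so that round
#' trips and determinism are testable byte-wise.
#'
#' @param state a `network_state`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_state_json <- function(state, path) {
  doc <- list(
    temp = state$temp,
    iteration = state$iteration,
    amounts = lapply(state$amounts, as.list),
    in_transit = as.list(state$in_transit),
    tool = paste0("nashmet ",
                  as.character(utils::packageVersion("nashmet"))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a network state from JSON
#' @param path file written by [write_state_json()].
#' @return a `network_state`.
#' @export
read_state_json <- function(path) {
  if (!file.exists(path)) stop("no such state file: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$amounts) || is.null(doc$temp)) {
    stop("state file '", path, "': missing 'amounts' or 'temp'")
  }
  amounts <- lapply(doc$amounts, function(a) {
    stats::setNames(vapply(a, as.numeric, numeric(1)), names(a))
  })
  in_transit <- if (length(doc$in_transit)) {
    stats::setNames(vapply(doc$in_transit, as.numeric, numeric(1)),
                    names(doc$in_transit))
  } else numeric(0)
  network_state(amounts, temp = as.numeric(doc$temp),
                iteration = as.integer(doc$iteration %||% 0L),
                in_transit = in_transit)
}
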