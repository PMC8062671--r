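#' Cause taxonomy for wildfire ignition records
#'
#' Fire agencies record one raw ignition cause per fire: lightning (the only
#' natural cause) plus fifteen anthropogenic causes, alongside the catch-all
#' codes `miscellaneous` and `unknown`. For analysis the fifteen anthropogenic
#' codes are grouped into transportation (railroad, vehicle, aircraft), human
#' activity (equipment use, smoking, campfire, debris burning, arson, playing
#' with fire, firefighter training, non-firefighter training, escaped
#' prescribed burn, illegal campfire) and construction (powerline, structure).
#' The raw-code-to-group mapping is shipped as a versioned CSV
#' (`system.file("extdata", "cause_codes.csv", package = "firescape")`) so the
#' grouping is data, not code.
#'
#' @return `cause_vocabulary()` returns a tibble with columns `code` and
#'   `group`; `cause_groups()` returns the six group labels in canonical
#'   order.
#' @export
cause_vocabulary <- function() {
  path <- system.file("extdata", "cause_codes.csv", package = "firescape")
  vocab <- readr::read_csv(path, col_types = readr::cols(
    code = readr::col_character(),
    group = readr::col_character(),
    version = readr::col_integer()
  ))
  vocab[, c("code", "group")]
}

#' @rdname cause_vocabulary
#' @export
cause_groups <- function() {
  c("natural", "human_transportation", "human_activity",
    "human_construction", "miscellaneous", "unknown")
}

# cached vocabulary lookup (code -> group)
.cause_env <- new.env(parent = emptyenv())

cause_lookup <- function() {
  if (is.null(.cause_env$map)) {
    vocab <- cause_vocabulary()
    .cause_env$map <- setNames(vocab$group, vocab$code)
  }
  .cause_env$map
}

#' Classify raw ignition cause codes into cause groups
#'
#' Maps each raw cause code to one of the six cause groups (see
#' [cause_vocabulary()]). The mapping is total over the closed vocabulary and
#' deterministic; `lightning` maps to `natural` and the fifteen anthropogenic
#' codes partition into the three human groups.
#'
#' @param cause_code character vector of raw cause codes.
#' @return character vector of group labels, a factor-free subset of
#'   [cause_groups()].
#' @examples
#' classify_cause(c("powerline", "lightning", "vehicle"))
#' @export
classify_cause <- function(cause_code) {
  map <- cause_lookup()
  bad <- setdiff(unique(cause_code), names(map))
  if (length(bad) > 0) {
    abort(paste0("Unknown cause code(s): ", paste(bad, collapse = ", ")),
          class = "firescape_cause_error")
  }
  unname(map[cause_code])
}

#' Collapse cause groups to the binary natural/human view
#'
#' @param group character vector of cause-group labels.
#' @return character vector with values `natural`, `human`, `miscellaneous`
#'   or `unknown`.
#' @export
cause_binary <- function(group) {
  stopifnot(all(group %in% cause_groups()))
  out <- group
  out[group %in% c("human_transportation", "human_activity",
                   "human_construction")] <- "human"
  out
}
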