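#' Canonical HDM component catalog
#'
#' The 11 house dust mite allergen components measured by the multiplex
#' specific-IgE panel, in canonical alphanumeric order. Every panel table,
#' sensitization matrix and network fixture in the package uses this order.
#'
#' @return character vector of 11 component names.
#' @export
#' @examples
#' hdm_components()
hdm_components <- function() {
  c("Der f 1", "Der f 2", "Der p 1", "Der p 2", "Der p 5", "Der p 7",
    "Der p 10", "Der p 11", "Der p 20", "Der p 21", "Der p 23")
}

# Case-, space- and underscore-insensitive header key ("Der_f_1" == "Der f 1").
normalize_header <- function(x) {
  tolower(gsub("[ _]+", "", x))
}
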