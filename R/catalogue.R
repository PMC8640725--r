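#' Load a condition catalogue
#'
#' A catalogue lists the long-term conditions the analysis recognises, one
#' row per condition: an opaque `code`, a display `name`, a logical
#' `resolvable` flag (whether resolution/remission dates are recorded for the
#' condition) and a `cluster` label A--F grouping conditions that tend to
#' co-occur (A mental health, B cardiovascular, C pain, D liver disease,
#' E dependence, F unclustered).
#'
#' @param path Path to a catalogue CSV with columns
#'   `code,name,resolvable,cluster`. Defaults to the 32-condition catalogue
#'   shipped with the package.
#' @return A data.frame with columns `code`, `name`, `resolvable` (logical)
#'   and `cluster` (character, one of A--F).
#' @export
#' @examples
#' cat32 <- read_catalogue()
#' nrow(cat32)            # 32 conditions
#' sum(cat32$resolvable)  # 12 carry resolution dates
read_catalogue <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "conditions.csv", package = "ltctraj",
                        mustWork = TRUE)
  }
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("code", "name", "resolvable", "cluster")
  miss <- setdiff(need, names(cat))
  if (length(miss)) {
    stop("catalogue is missing column(s): ", paste(miss, collapse = ", "))
  }
  cat$resolvable <- as.logical(cat$resolvable)
  if (anyDuplicated(cat$code)) stop("catalogue has duplicated condition codes")
  if (!all(cat$cluster %in% LETTERS[1:6])) {
    stop("catalogue cluster labels must be A-F")
  }
  cat
}

#' The default 32-condition catalogue
#'
#' @return data.frame as [read_catalogue()].
#' @export
default_catalogue <- function() read_catalogue()
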