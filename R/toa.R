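#' Convert a TOA table to a matrix
#'
#' The TOA (time-of-arrival) table has one row per transmission with a `ping`
#' index column followed by one column of arrival times (seconds) per
#' hydrophone; `NA` marks a missed detection. When `array` is supplied the
#' columns are checked against its ids and reordered to match.
#'
#' @param toa TOA tibble (`ping` plus one column per hydrophone).
#' @param array Optional hydrophone array table used to validate/order columns.
#' @return Numeric matrix, pings by hydrophones, with hydro ids as colnames.
#' @export
as_toa_matrix <- function(toa, array = NULL) {
  if (!is.data.frame(toa) || !"ping" %in% names(toa))
    abort("`toa` must be a data frame with a `ping` column")
  if (anyDuplicated(toa$ping)) abort("duplicated ping index in TOA table")
  ids <- setdiff(names(toa), "ping")
  if (!is.null(array)) {
    array <- validate_array(array)
    missing_cols <- setdiff(array$hydro, ids)
    extra_cols <- setdiff(ids, array$hydro)
    if (length(missing_cols) || length(extra_cols))
      abort(paste0("TOA columns do not match hydrophone ids",
                   if (length(missing_cols)) paste0("; missing: ", paste(missing_cols, collapse = ", ")),
                   if (length(extra_cols)) paste0("; unknown: ", paste(extra_cols, collapse = ", "))))
    ids <- array$hydro
  }
  m <- as.matrix(toa[order(toa$ping), ids, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- NULL
  m
}

toa_tibble <- function(m, ids) {
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- ids
  dplyr::bind_cols(tibble::tibble(ping = seq_len(nrow(m))), out)
}

#' Number of detecting hydrophones per transmission
#'
#' @param toa TOA tibble.
#' @return Integer vector, one count per ping (in ping order).
#' @export
detect_counts <- function(toa) {
  m <- as_toa_matrix(toa)
  as.integer(rowSums(!is.na(m)))
}
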