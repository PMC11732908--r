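#' Construct a person-by-item response matrix
#'
#' @param resp Numeric matrix of 0/1/NA cells, persons in rows and items in
#'   columns, with dimnames. Missing cells are allowed and excluded from all
#'   likelihoods.
#' @param group Optional group label per person (length `nrow(resp)`).
#' @param rt Optional response-time matrix (milliseconds), same shape as
#'   `resp`.
#' @return An object of class `"response_matrix"` with elements `resp`,
#'   `group`, `rt`.
#' @export
response_matrix <- function(resp, group = NULL, rt = NULL) {
  resp <- as.matrix(resp)
  if (nrow(resp) < 2L || ncol(resp) < 2L)
    stop("a response matrix needs at least 2 persons and 2 items", call. = FALSE)
  vals <- resp[!is.na(resp)]
  if (!all(vals %in% c(0, 1)))
    stop("response cells must be 0, 1 or NA", call. = FALSE)
  if (is.null(rownames(resp))) rownames(resp) <- paste0("p", seq_len(nrow(resp)))
  if (is.null(colnames(resp))) colnames(resp) <- paste0("i", seq_len(ncol(resp)))
  if (!is.null(group)) {
    if (length(group) != nrow(resp))
      stop("group must have one label per person", call. = FALSE)
    group <- as.character(group)
  }
  if (!is.null(rt)) {
    rt <- as.matrix(rt)
    if (!all(dim(rt) == dim(resp)))
      stop("rt must have the same dimensions as resp", call. = FALSE)
  }
  structure(list(resp = resp, group = group, rt = rt),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("Response matrix: %d persons x %d items (%.1f%% observed)%s%s\n",
              nrow(x$resp), ncol(x$resp),
              100 * mean(!is.na(x$resp)),
              if (!is.null(x$group))
                sprintf(", %d group(s)", length(unique(x$group))) else "",
              if (!is.null(x$rt)) ", with RTs" else ""))
  invisible(x)
}

as_response_matrix <- function(x) {
  if (inherits(x, "response_matrix")) return(x)
  if (is.matrix(x) || is.data.frame(x)) return(response_matrix(as.matrix(x)))
  stop("cannot interpret input as a response matrix", call. = FALSE)
}
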