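#' Construct an item bank
#'
#' An item bank is a data frame of lexical stimuli with one row per item:
#' `item_id` (unique), `stimulus`, `category` ("real" or "pseudo"),
#' `difficulty` (logits, finite) and `calibrated` (logical; only calibrated
#' items may contribute to scoring).
#'
#' @param item_id Character vector of unique identifiers.
#' @param stimulus Character vector of letter strings.
#' @param category "real" or "pseudo" per item.
#' @param difficulty Difficulty in logits.
#' @param calibrated Logical; defaults to `TRUE`.
#' @param provenance Free-text note carried as an attribute.
#' @return A data frame of class `"item_bank"`.
#' @export
item_bank <- function(item_id, stimulus, category, difficulty,
                      calibrated = TRUE, provenance = "") {
  item_id <- as.character(item_id)
  n <- length(item_id)
  calibrated <- rep_len(as.logical(calibrated), n)
  bank <- data.frame(item_id = item_id,
                     stimulus = as.character(stimulus),
                     category = as.character(category),
                     difficulty = as.numeric(difficulty),
                     calibrated = calibrated,
                     stringsAsFactors = FALSE)
  validate_bank(bank)
  structure(bank, class = c("item_bank", "data.frame"),
            provenance = provenance)
}

validate_bank <- function(bank) {
  dup <- duplicated(bank$item_id)
  if (any(dup))
    stop("duplicate item_id in bank: ", paste(unique(bank$item_id[dup]), collapse = ", "),
         call. = FALSE)
  bad <- !bank$category %in% c("real", "pseudo")
  if (any(bad))
    stop("category must be 'real' or 'pseudo' (offending items: ",
         paste(bank$item_id[bad], collapse = ", "), ")", call. = FALSE)
  if (anyNA(bank$difficulty) || any(!is.finite(bank$difficulty)))
    stop("difficulty must be finite for every item", call. = FALSE)
  if (anyNA(bank$calibrated))
    stop("calibrated flag must be TRUE/FALSE for every item", call. = FALSE)
  invisible(bank)
}

#' @export
print.item_bank <- function(x, ...) {
  counts <- category_counts(x)
  cat(sprintf("Item bank: %d items (%d real / %d pseudo), %d calibrated\n",
              nrow(x), counts[["real"]], counts[["pseudo"]], sum(x$calibrated)))
  cat(sprintf("Difficulty range: [%.2f, %.2f] logits\n",
              min(x$difficulty), max(x$difficulty)))
  invisible(x)
}

#' Items per category
#'
#' @param bank An [item_bank()].
#' @param calibrated_only Count only calibrated items.
#' @return Named integer vector with elements `real` and `pseudo`.
#' @export
category_counts <- function(bank, calibrated_only = FALSE) {
  b <- if (calibrated_only) bank[bank$calibrated, , drop = FALSE] else bank
  c(real = sum(b$category == "real"), pseudo = sum(b$category == "pseudo"))
}

#' Remove items from a bank
#'
#' Drops the named items (e.g. items whose difficulty was unstable across
#' populations, or extreme outliers) and returns a new bank; the input is
#' untouched. The canonical six-item removal applied to the original 252-item
#' lexical decision bank leaves 246 items split 123/123.
#'
#' @param bank An [item_bank()].
#' @param remove_ids Character vector of item ids, all present in the bank.
#' @return The pruned `"item_bank"`; new category counts are reported via
#'   `message()`.
#' @export
prune_bank <- function(bank, remove_ids) {
  remove_ids <- as.character(remove_ids)
  unknown <- setdiff(remove_ids, bank$item_id)
  if (length(unknown))
    stop("unknown item id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  out <- bank[!bank$item_id %in% remove_ids, , drop = FALSE]
  rownames(out) <- NULL
  out <- structure(out, class = c("item_bank", "data.frame"),
                   provenance = attr(bank, "provenance"))
  counts <- category_counts(out)
  message(sprintf("pruned %d item(s); bank now %d items (%d real / %d pseudo)",
                  length(remove_ids), nrow(out), counts[["real"]], counts[["pseudo"]]))
  out
}

#' The six items removed from the original 252-item bank
#'
#' Two items with population-dependent difficulty ("an", "rackle") plus the
#' two most difficult real words ("potent", "garment") and pseudowords
#' ("bads", "streat").
#'
#' @return Character vector of six stimulus-named item ids.
#' @export
canonical_removals <- function() {
  c("an", "rackle", "potent", "garment", "bads", "streat")
}
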