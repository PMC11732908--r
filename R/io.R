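#' Read an item bank from CSV
#'
#' Schema (UTF-8, header row): `item_id,stimulus,category,difficulty,calibrated`
#' with `category` in {real, pseudo} and `calibrated` in {0, 1}. Malformed
#' values are rejected, never coerced, with the offending line number (header
#' is line 1).
#'
#' @param path CSV file path.
#' @return An [item_bank()].
#' @export
read_bank <- function(path) {
  if (!file.exists(path)) stop("bank file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("item_id", "stimulus", "category", "difficulty", "calibrated")
  if (!identical(names(raw)[seq_along(need)], need))
    stop("bank header must be ", paste(need, collapse = ","), call. = FALSE)
  line <- seq_len(nrow(raw)) + 1L
  dup <- duplicated(raw$item_id)
  if (any(dup))
    stop(sprintf("duplicated item_id '%s' on line %d", raw$item_id[which(dup)[1]],
                 line[which(dup)[1]]), call. = FALSE)
  badc <- !raw$category %in% c("real", "pseudo")
  if (any(badc))
    stop(sprintf("unknown category '%s' on line %d (column category)",
                 raw$category[which(badc)[1]], line[which(badc)[1]]), call. = FALSE)
  diff <- suppressWarnings(as.numeric(raw$difficulty))
  badd <- is.na(diff) | !is.finite(diff)
  if (any(badd))
    stop(sprintf("non-numeric difficulty '%s' on line %d (column difficulty)",
                 raw$difficulty[which(badd)[1]], line[which(badd)[1]]), call. = FALSE)
  badf <- !raw$calibrated %in% c("0", "1")
  if (any(badf))
    stop(sprintf("calibrated must be 0 or 1 on line %d (column calibrated)",
                 line[which(badf)[1]]), call. = FALSE)
  item_bank(raw$item_id, raw$stimulus, raw$category, diff,
            raw$calibrated == "1", provenance = path)
}

#' Write an item bank to CSV
#'
#' @param bank An [item_bank()].
#' @param path Output path.
#' @export
write_bank <- function(bank, path) {
  out <- data.frame(item_id = bank$item_id, stimulus = bank$stimulus,
                    category = bank$category,
                    difficulty = format(bank$difficulty, digits = 17, trim = TRUE,
                                        scientific = FALSE),
                    calibrated = as.integer(bank$calibrated),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a response matrix from CSV
#'
#' Long format: columns `person_id,item_id,correct` plus optional `rt_ms`
#' and `group`. Wide format: a `person_id` column followed by one 0/1 column
#' per item. Cells outside {0, 1, missing} are rejected.
#'
#' @param path CSV file path.
#' @param format `"long"` or `"wide"`.
#' @return A [response_matrix()].
#' @export
read_responses <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("response file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty response file: ", path, call. = FALSE)
  if (format == "long") {
    need <- c("person_id", "item_id", "correct")
    if (!all(need %in% names(raw)))
      stop("long format needs columns ", paste(need, collapse = ","), call. = FALSE)
    bad <- !raw$correct %in% c("0", "1", "", "NA")
    if (any(bad))
      stop(sprintf("invalid correct value '%s' on line %d", raw$correct[which(bad)[1]],
                   which(bad)[1] + 1L), call. = FALSE)
    persons <- unique(raw$person_id); items <- unique(raw$item_id)
    m <- matrix(NA_real_, length(persons), length(items),
                dimnames = list(persons, items))
    val <- suppressWarnings(as.numeric(raw$correct))
    m[cbind(match(raw$person_id, persons), match(raw$item_id, items))] <- val
    rt <- NULL
    if ("rt_ms" %in% names(raw)) {
      rt <- matrix(NA_real_, length(persons), length(items),
                   dimnames = dimnames(m))
      rt[cbind(match(raw$person_id, persons), match(raw$item_id, items))] <-
        suppressWarnings(as.numeric(raw$rt_ms))
    }
    group <- NULL
    if ("group" %in% names(raw))
      group <- raw$group[match(persons, raw$person_id)]
    response_matrix(m, group = group, rt = rt)
  } else {
    if (names(raw)[1] != "person_id")
      stop("wide format needs a leading person_id column", call. = FALSE)
    m <- as.matrix(raw[, -1, drop = FALSE])
    ok <- m %in% c("0", "1", "", "NA")
    if (!all(ok)) {
      bad <- which(!matrix(ok, nrow(m)), arr.ind = TRUE)[1, ]
      stop(sprintf("invalid cell '%s' on line %d (column %s)",
                   m[bad[1], bad[2]], bad[1] + 1L,
                   colnames(m)[bad[2]]), call. = FALSE)
    }
    num <- suppressWarnings(matrix(as.numeric(m), nrow(m), dimnames =
                                     list(raw$person_id, colnames(m))))
    response_matrix(num)
  }
}

#' Write a response matrix to long CSV
#'
#' Observed cells only, columns `person_id,item_id,correct[,rt_ms][,group]`.
#'
#' @param x A [response_matrix()].
#' @param path Output path.
#' @export
write_responses <- function(x, path) {
  rm <- as_response_matrix(x)
  obs <- which(!is.na(rm$resp), arr.ind = TRUE)
  out <- data.frame(person_id = rownames(rm$resp)[obs[, 1]],
                    item_id = colnames(rm$resp)[obs[, 2]],
                    correct = as.integer(rm$resp[obs]),
                    stringsAsFactors = FALSE)
  if (!is.null(rm$rt)) out$rt_ms <- rm$rt[obs]
  if (!is.null(rm$group)) out$group <- rm$group[obs[, 1]]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write session logs as JSONL
#'
#' One trial record per line: `person_id`, `arm`, plus the trial fields of
#' [run_session()].
#'
#' @param sessions Named list of `"cat_session"` objects.
#' @param path Output path.
#' @param arm Arm label(s), recycled over sessions.
#' @export
write_session_log <- function(sessions, path, arm = "cat") {
  arm <- rep_len(arm, length(sessions))
  ids <- names(sessions) %||% paste0("p", seq_along(sessions))
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_along(sessions)) {
    tr <- sessions[[k]]$trials
    for (i in seq_len(nrow(tr))) {
      rec <- c(list(person_id = ids[k], arm = arm[k]), as.list(tr[i, ]))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Read a JSONL session log
#'
#' @param path JSONL path written by [write_session_log()].
#' @return Data frame of trial records.
#' @export
read_session_log <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
}

#' Read a session/scenario configuration from YAML
#'
#' Recognised keys: `selector`, `bounds` (two numbers), `counterbalance`,
#' `test_length`, `initial_theta`, `seed`, `validation_schedule`
#' (`n_scored`, `every`, `n_new`), `block_sizes`.
#'
#' @param path YAML file path.
#' @return A [cat_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cat_config(selector = y$selector %||% "mfi",
             bounds = if (!is.null(y$bounds)) theta_bounds(y$bounds[[1]], y$bounds[[2]])
                      else theta_bounds(),
             counterbalance = y$counterbalance %||% TRUE,
             test_length = y$test_length,
             initial_theta = y$initial_theta %||% 0,
             seed = y$seed,
             validation_schedule = y$validation_schedule,
             block_sizes = unlist(y$block_sizes))
}

#' @rdname read_config
#' @param config A [cat_config()].
#' @export
write_config <- function(config, path) {
  y <- list(selector = config$selector,
            bounds = c(config$bounds$lo, config$bounds$hi),
            counterbalance = config$counterbalance,
            test_length = config$test_length,
            initial_theta = config$initial_theta)
  if (!is.null(config$seed)) y$seed <- config$seed
  if (!is.null(config$validation_schedule))
    y$validation_schedule <- config$validation_schedule
  if (!is.null(config$block_sizes)) y$block_sizes <- config$block_sizes
  yaml::write_yaml(y, path)
  invisible(path)
}

# FNV-1a-style hash of a serialised object, folded into 31 bits so it stays
# within R's integer range; used for manifest config fingerprints.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 216613626
  for (b in bytes) h <- (bitwXor(as.integer(h), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Write a run manifest
#'
#' Records inputs, configuration, its hash, the seed and the package version
#' next to a run's outputs, so every artifact can be traced to the exact
#' settings that produced it.
#'
#' @param dir Output directory.
#' @param inputs Named character vector/list of input paths.
#' @param config Arbitrary configuration object (serialised into the hash).
#' @param seed Seed used for the run.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, inputs = list(), config = list(), seed = NA) {
  man <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              package_version = as.character(utils::packageVersion("adaptlex")),
              seed = seed, config_hash = config_hash(config),
              inputs = inputs, config = config)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
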