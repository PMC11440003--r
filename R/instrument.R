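#' Load an instrument definition
#'
#' Reads a JSON instrument file (item catalogue, subscale assignment, item
#' weights and the weighted-score cut-off) and validates it.  The package
#' ships a definition of the 57-item Autism Behavior Checklist (ABC) under
#' `inst/extdata/abc_instrument.json`; [abc_instrument()] loads it directly.
#'
#' @param path Path to a JSON file with fields `name`, `cutoff_score` and
#'   `items`, the latter a list of `{id, text, subscale, weight}` records.
#' @return An object of class `instrument`: a list with `name`,
#'   `cutoff_score` and `items` (a data.frame with one row per item).
#' @export
load_instrument <- function(path) {
  if (!file.exists(path)) stop("instrument file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  for (fld in c("name", "cutoff_score", "items")) {
    if (is.null(raw[[fld]])) stop("instrument schema error: missing field '", fld, "'")
  }
  items <- as.data.frame(raw$items, stringsAsFactors = FALSE)
  for (fld in c("id", "subscale", "weight")) {
    if (is.null(items[[fld]])) stop("instrument schema error: items lack field '", fld, "'")
  }
  if (is.null(items$text)) items$text <- ""
  items$text[is.na(items$text)] <- ""
  items$id <- as.integer(items$id)
  items$weight <- as.integer(items$weight)
  validate_instrument_items(items)
  structure(list(name = raw$name,
                 cutoff_score = as.integer(raw$cutoff_score),
                 items = items),
            class = "instrument")
}

validate_instrument_items <- function(items) {
  if (anyDuplicated(items$id)) {
    stop("instrument validation error: duplicate item ids: ",
         paste(unique(items$id[duplicated(items$id)]), collapse = ", "))
  }
  if (!identical(sort(items$id), seq_len(nrow(items)))) {
    stop("instrument validation error: item ids must be contiguous 1..",
         nrow(items))
  }
  bad_w <- items$id[!(items$weight %in% 1:4)]
  if (length(bad_w)) {
    stop("instrument validation error: weight outside 1..4 for item(s) ",
         paste(bad_w, collapse = ", "))
  }
  allowed <- c("relating", "sensory", "language", "body_object_use",
               "social_self_help")
  bad_s <- items$id[!(items$subscale %in% allowed)]
  if (length(bad_s)) {
    stop("instrument validation error: unknown subscale for item(s) ",
         paste(bad_s, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  }
  invisible(items)
}

#' @describeIn load_instrument Load the packaged ABC definition (57 items,
#'   five subscales, weighted-score cut-off 68).
#' @export
abc_instrument <- function() {
  load_instrument(system.file("extdata", "abc_instrument.json",
                              package = "raschdif", mustWork = TRUE))
}

#' @export
print.instrument <- function(x, ...) {
  cat("<instrument> ", x$name, "\n",
      "  items: ", nrow(x$items),
      "  subscales: ", length(unique(x$items$subscale)),
      "  cut-off: ", x$cutoff_score, "\n", sep = "")
  invisible(x)
}

#' Rescore weighted responses to dichotomous form
#'
#' The checklist scores an endorsed item with its catalogue weight (1-4
#' points) and a non-endorsed item with 0.  Rasch calibration consumes the
#' endorsement indicator only, so each cell is rescored to 1 (endorsed) or 0,
#' discarding the weight.  Missing cells stay missing.
#'
#' @param raw_scores Numeric matrix, persons x items; each non-missing cell
#'   must equal 0 or the item's weight.
#' @param instrument An [load_instrument()] object; column count must match.
#' @return Integer matrix of 0/1 (and `NA`) with the input dimnames.
#' @export
dichotomize <- function(raw_scores, instrument) {
  raw_scores <- as.matrix(raw_scores)
  w <- instrument$items$weight
  if (ncol(raw_scores) != length(w)) {
    stop("raw score matrix has ", ncol(raw_scores), " columns but instrument has ",
         length(w), " items")
  }
  wmat <- matrix(w, nrow(raw_scores), ncol(raw_scores), byrow = TRUE)
  ok <- is.na(raw_scores) | raw_scores == 0 | raw_scores == wmat
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    pid <- if (!is.null(rownames(raw_scores))) rownames(raw_scores)[bad[1]] else bad[1]
    iid <- if (!is.null(colnames(raw_scores))) colnames(raw_scores)[bad[2]] else bad[2]
    stop("invalid raw score for person ", pid, ", item ", iid,
         ": must be 0 or the item weight (", wmat[bad[1], bad[2]], ")")
  }
  out <- ifelse(raw_scores > 0, 1L, 0L)
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(raw_scores)
  out
}

#' Weighted total score and positive classification
#'
#' Sums one person's weighted item points and classifies the sheet against
#' the instrument cut-off: a total strictly above `cutoff_score - 1` (i.e.
#' `> 67` for the ABC, whose cut-off is set at 68) is positive.
#'
#' @param raw_scores Numeric vector of one person's weighted scores; missing
#'   values are treated as not administered and contribute 0.
#' @param instrument An instrument object.
#' @return List with `total` (integer) and `positive` (logical).
#' @export
weighted_total <- function(raw_scores, instrument) {
  w <- instrument$items$weight
  if (length(raw_scores) != length(w)) {
    stop("score vector length ", length(raw_scores),
         " does not match instrument item count ", length(w))
  }
  obs <- !is.na(raw_scores)
  bad <- which(obs & raw_scores != 0 & raw_scores != w)
  if (length(bad)) {
    stop("invalid raw score for item ", bad[1], ": must be 0 or the item weight (",
         w[bad[1]], ")")
  }
  total <- as.integer(sum(raw_scores[obs]))
  list(total = total, positive = total > (instrument$cutoff_score - 1L))
}
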