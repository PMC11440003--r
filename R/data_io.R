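#' @keywords internal
covariate_levels <- list(
  gender = c("male", "female"),
  age_group = c("infant", "kindergarten", "primary", "junior_high", "high"),
  symptom_level = c("non_autism", "mild_moderate", "severe")
)

#' Construct a response matrix object
#'
#' The core analysis container: a persons x items matrix of dichotomous
#' responses (`NA` = not administered) plus per-person categorical
#' covariates (gender, age group, symptom-severity class).
#'
#' @param X Matrix of 0/1/`NA`; rownames are person ids, colnames item ids.
#' @param covariates `data.frame` with columns `person_id`, `gender`,
#'   `age_group`, `symptom_level`, one row per person, or `NULL` when no
#'   covariates are attached.
#' @return Object of class `response_matrix` with elements `X`, `persons`,
#'   `items`, `covariates`.
#' @export
response_matrix <- function(X, covariates = NULL) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("P", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("item_", seq_len(ncol(X)))
  vals <- X[!is.na(X)]
  if (length(vals) && !all(vals %in% c(0, 1))) {
    stop("response matrix validation error: non-missing cells must be 0 or 1 (found ",
         paste(utils::head(unique(vals[!(vals %in% c(0, 1))]), 3), collapse = ", "), ")")
  }
  if (nrow(X) < 2 || ncol(X) < 2) {
    stop("response matrix validation error: need at least 2 persons and 2 items")
  }
  storage.mode(X) <- "integer"
  if (!is.null(covariates)) {
    covariates <- validate_covariates(covariates, rownames(X))
  }
  structure(list(X = X, persons = rownames(X), items = colnames(X),
                 covariates = covariates),
            class = "response_matrix")
}

validate_covariates <- function(cov, person_ids) {
  cov <- as.data.frame(cov, stringsAsFactors = FALSE)
  need <- c("person_id", "gender", "age_group", "symptom_level")
  miss <- setdiff(need, names(cov))
  if (length(miss)) stop("covariate file lacks column(s): ", paste(miss, collapse = ", "))
  cov$person_id <- as.character(cov$person_id)
  if (!setequal(cov$person_id, person_ids) || anyDuplicated(cov$person_id)) {
    stop("person id mismatch between response matrix and covariates")
  }
  for (v in names(covariate_levels)) {
    bad <- setdiff(unique(cov[[v]]), covariate_levels[[v]])
    if (length(bad)) {
      stop("unknown ", v, " level(s): ", paste(bad, collapse = ", "),
           " (allowed: ", paste(covariate_levels[[v]], collapse = ", "), ")")
    }
    cov[[v]] <- factor(cov[[v]], levels = covariate_levels[[v]])
  }
  cov[match(person_ids, cov$person_id), need, drop = FALSE]
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("<response_matrix> ", length(x$persons), " persons x ", length(x$items),
      " items; ", sum(is.na(x$X)), " missing cells; covariates: ",
      if (is.null(x$covariates)) "none" else "gender, age_group, symptom_level",
      "\n", sep = "")
  invisible(x)
}

#' Read responses and covariates from wide CSV
#'
#' The response file is wide CSV: first column the person id, remaining
#' columns one item each; empty cells are missing.  The covariate file has
#' columns `person_id, gender, age_group, symptom_level`.  Row and column
#' order are preserved from file.
#'
#' @param matrix_path,covariates_path File paths; `covariates_path` may be
#'   `NULL` to read responses alone.
#' @return A [response_matrix()].
#' @export
read_responses <- function(matrix_path, covariates_path = NULL) {
  if (!file.exists(matrix_path)) stop("response file not found: ", matrix_path)
  tab <- utils::read.csv(matrix_path, check.names = FALSE,
                         stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 3) stop("response file needs a person id column plus >= 2 items")
  ids <- tab[[1]]
  X <- as.matrix(tab[, -1, drop = FALSE])
  X[X == ""] <- NA
  suppressWarnings(storage.mode(X) <- "numeric")
  rownames(X) <- ids
  cov <- NULL
  if (!is.null(covariates_path)) {
    if (!file.exists(covariates_path)) stop("covariates file not found: ", covariates_path)
    cov <- utils::read.csv(covariates_path, stringsAsFactors = FALSE)
  }
  response_matrix(X, cov)
}

#' Write responses (and covariates) to the CSV pair `read_responses` reads
#'
#' @param data A `response_matrix`.
#' @param matrix_path,covariates_path Output paths; covariates are written
#'   only when present and a path is given.
#' @return Invisibly, `matrix_path`.
#' @export
write_responses <- function(data, matrix_path, covariates_path = NULL) {
  out <- data.frame(person_id = data$persons, data$X, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, matrix_path, row.names = FALSE, na = "")
  if (!is.null(covariates_path) && !is.null(data$covariates)) {
    utils::write.csv(data$covariates, covariates_path, row.names = FALSE)
  }
  invisible(matrix_path)
}

#' Remove extreme persons and items
#'
#' Persons whose observed responses are all 0 or all 1, and items endorsed
#' by nobody or everybody, carry no information for joint maximum
#' likelihood and make it inestimable.  Removal is iterative: dropping an
#' extreme item can create a newly extreme person, and vice versa, so
#' passes repeat until none remain.  Removed ids are reported, never
#' silently dropped.
#'
#' @param data A `response_matrix`.
#' @return List with `kept` (a `response_matrix`), `extreme_persons`,
#'   `extreme_items` (character vectors of removed ids).
#' @export
screen_extremes <- function(data) {
  X <- data$X
  gone_p <- character(0)
  gone_i <- character(0)
  repeat {
    rs <- rowMeans(X, na.rm = TRUE)
    robs <- rowSums(!is.na(X))
    ext_p <- robs == 0 | rs == 0 | rs == 1
    if (any(ext_p)) {
      gone_p <- c(gone_p, rownames(X)[ext_p])
      X <- X[!ext_p, , drop = FALSE]
    }
    if (nrow(X) == 0) stop("degenerate data: all persons extreme")
    cs <- colMeans(X, na.rm = TRUE)
    cobs <- colSums(!is.na(X))
    ext_i <- cobs == 0 | cs == 0 | cs == 1
    if (any(ext_i)) {
      gone_i <- c(gone_i, colnames(X)[ext_i])
      X <- X[, !ext_i, drop = FALSE]
    }
    if (ncol(X) == 0) stop("degenerate data: all items extreme")
    if (!any(ext_p) && !any(ext_i)) break
  }
  if (nrow(X) < 2 || ncol(X) < 2) {
    stop("degenerate data: fewer than 2 persons or 2 items remain after screening")
  }
  cov <- data$covariates
  if (!is.null(cov)) cov <- cov[cov$person_id %in% rownames(X), , drop = FALSE]
  list(kept = response_matrix(X, cov),
       extreme_persons = gone_p, extreme_items = gone_i)
}
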